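#' Probe region classes
#'
#' The scoring regions an MLPA probe can belong to. `SUBTEL_1P` (distal
#' 1p35--1pter), `PARACEN_1P` (the rest of 1p) and `Q19` are the three
#' deletion regions used by the co-deletion criteria; `REFERENCE` probes
#' anchor normalization and are never counted in any deletion region;
#' `MUTATION` probes detect specific point mutations (e.g. IDH1 R132H) and
#' carry a `target_variant`.
#'
#' @format A character vector of the five region tokens.
#' @export
probe_regions <- c("SUBTEL_1P", "PARACEN_1P", "Q19", "REFERENCE", "MUTATION")

#' @rdname probe_regions
#' @export
deletion_regions <- c("SUBTEL_1P", "PARACEN_1P", "Q19")

manifest_columns <- c(
  "probe_id", "target_gene", "chromosome", "arm", "region",
  "cytoband", "position_mb", "target_variant"
)

#' Construct and validate a probe manifest
#'
#' A probe manifest is a tibble with one row per MLPA probe and columns
#' `probe_id`, `target_gene`, `chromosome` (`chr1`, `chr19` or `other`),
#' `arm` (`p`, `q` or `none`), `region` (see [probe_regions]), `cytoband`,
#' `position_mb` (informational, 1-based megabases, may be `NA`) and
#' `target_variant` (`NA` except for `MUTATION` probes). The manifest is
#' the single source of truth for which probes make up the three scoring
#' regions; every caller reads the region assignment from it.
#'
#' Validation enforces: unique probe ids; known region tokens;
#' `SUBTEL_1P`/`PARACEN_1P` probes on chr1p; `Q19` probes on chr19q; a
#' `target_variant` on every `MUTATION` probe.
#'
#' @param probes A data frame with the columns above (`position_mb` and
#'   `target_variant` optional).
#' @param name Optional manifest name, stored as the `"manifest_name"`
#'   attribute.
#' @return A validated `probe_manifest` tibble.
#' @seealso [manifest_default()], [read_manifest()]
#' @export
probe_manifest <- function(probes, name = NULL) {
  probes <- tibble::as_tibble(probes)
  missing_cols <- setdiff(
    c("probe_id", "chromosome", "arm", "region"), names(probes)
  )
  if (length(missing_cols) > 0) {
    stop("manifest is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"target_gene" %in% names(probes)) probes$target_gene <- NA_character_
  if (!"cytoband" %in% names(probes)) probes$cytoband <- NA_character_
  if (!"position_mb" %in% names(probes)) probes$position_mb <- NA_real_
  if (!"target_variant" %in% names(probes)) probes$target_variant <- NA_character_
  probes <- normalize_manifest_columns(probes)
  validate_manifest(probes)
  class(probes) <- c("probe_manifest", class(probes))
  attr(probes, "manifest_name") <- name %||% "unnamed"
  probes
}

normalize_manifest_columns <- function(probes) {
  probes$probe_id <- as.character(probes$probe_id)
  probes$region <- as.character(probes$region)
  probes$chromosome <- as.character(probes$chromosome)
  probes$arm <- as.character(probes$arm)
  probes$position_mb <- as.numeric(probes$position_mb)
  dplyr::select(probes, dplyr::all_of(manifest_columns))
}

validate_manifest <- function(probes) {
  dup <- unique(probes$probe_id[duplicated(probes$probe_id)])
  if (length(dup) > 0) {
    stop("duplicate probe_id in manifest: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  bad_region <- setdiff(unique(probes$region), probe_regions)
  if (length(bad_region) > 0) {
    stop("unknown region token(s) in manifest: ",
         paste(bad_region, collapse = ", "),
         "; expected one of ", paste(probe_regions, collapse = ", "),
         call. = FALSE)
  }
  bad_chr <- setdiff(unique(probes$chromosome), c("chr1", "chr19", "other"))
  if (length(bad_chr) > 0) {
    stop("unknown chromosome token(s): ", paste(bad_chr, collapse = ", "),
         call. = FALSE)
  }
  p1 <- probes$region %in% c("SUBTEL_1P", "PARACEN_1P")
  if (any(p1 & !(probes$chromosome == "chr1" & probes$arm == "p"))) {
    bad <- probes$probe_id[p1 & !(probes$chromosome == "chr1" & probes$arm == "p")]
    stop("1p region probe(s) not on chr1p: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  q19 <- probes$region == "Q19"
  if (any(q19 & !(probes$chromosome == "chr19" & probes$arm == "q"))) {
    bad <- probes$probe_id[q19 & !(probes$chromosome == "chr19" & probes$arm == "q")]
    stop("Q19 region probe(s) not on chr19q: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  mut <- probes$region == "MUTATION"
  if (any(mut & is.na(probes$target_variant))) {
    bad <- probes$probe_id[mut & is.na(probes$target_variant)]
    stop("MUTATION probe(s) without target_variant: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(probes)
}

#' Default P088-style probe manifest
#'
#' A bundled manifest mirroring the layout of the widely used commercial
#' 1p/19q MLPA probemix: 19 probes on 1p (8 subtelomeric, spanning
#' 1p35--1p36.3, and 11 pericentromeric covering the rest of the arm) and
#' 11 probes on 19q, plus 10 autosomal `REFERENCE` probes and 2
#' mutation-specific probes (IDH1 R132H, IDH2 R172K). Probe ids are
#' placeholders; real kit definitions can be supplied via
#' [read_manifest()] and every downstream computation honours the
#' user-supplied region assignment.
#'
#' The subtelomeric region is taken as 1p35--1pter. Positions are
#' approximate megabase midpoints, informational only.
#'
#' @return A `probe_manifest` tibble with 42 rows.
#' @export
manifest_default <- function() {
  subtel <- tibble::tibble(
    probe_id = sprintf("P1p_S%02d", 1:8),
    target_gene = c("TP73", "CHD5", "CAMTA1", "PER3", "ERRFI1", "PARK7",
                    "CASZ1", "MTHFR"),
    chromosome = "chr1", arm = "p", region = "SUBTEL_1P",
    cytoband = c("1p36.32", "1p36.31", "1p36.31", "1p36.23", "1p36.23",
                 "1p36.23", "1p36.22", "1p36.22"),
    position_mb = c(3.6, 6.1, 6.8, 7.8, 8.0, 8.0, 10.7, 11.8)
  )
  paracen <- tibble::tibble(
    probe_id = sprintf("P1p_C%02d", 1:11),
    target_gene = c("MYCL", "MUTYH", "CDKN2C", "JUN", "GADD45A", "FUBP1",
                    "GSTM1", "NRAS", "TRIM33", "NOTCH2", "AMPD1"),
    chromosome = "chr1", arm = "p", region = "PARACEN_1P",
    cytoband = c("1p34.2", "1p34.1", "1p32.3", "1p32.1", "1p31.3",
                 "1p31.1", "1p13.3", "1p13.2", "1p13.2", "1p12", "1p13.1"),
    position_mb = c(39.9, 45.3, 51.2, 58.8, 67.7, 77.9, 110.2, 114.7,
                    114.9, 120.0, 114.7)
  )
  q19 <- tibble::tibble(
    probe_id = sprintf("P19q_%02d", 1:11),
    target_gene = c("GLTSCR2", "PLAUR", "BAX", "CCNE1", "XRCC1", "ERCC2",
                    "ERCC1", "PPP2R1A", "POLD1", "PRKCG", "ZNF331"),
    chromosome = "chr19", arm = "q", region = "Q19",
    cytoband = c("19q13.33", "19q13.31", "19q13.33", "19q12", "19q13.31",
                 "19q13.32", "19q13.32", "19q13.41", "19q13.33", "19q13.42",
                 "19q13.42"),
    position_mb = c(44.8, 43.6, 48.9, 29.8, 43.5, 45.3, 45.4, 52.2,
                    50.4, 53.9, 53.5)
  )
  reference <- tibble::tibble(
    probe_id = sprintf("REF_%02d", 1:10),
    target_gene = sprintf("REFGENE%d", 1:10),
    chromosome = "other", arm = "none", region = "REFERENCE",
    cytoband = NA_character_, position_mb = NA_real_
  )
  mutation <- tibble::tibble(
    probe_id = c("MUT_IDH1_R132H", "MUT_IDH2_R172K"),
    target_gene = c("IDH1", "IDH2"),
    chromosome = "other", arm = "none", region = "MUTATION",
    cytoband = c("2q34", "15q26.1"), position_mb = NA_real_,
    target_variant = c("IDH1 R132H", "IDH2 R172K")
  )
  probes <- dplyr::bind_rows(subtel, paracen, q19, reference, mutation)
  probe_manifest(probes, name = "P088-style default")
}

# cytoband -> region fallback used when a manifest file carries no explicit
# region column: 1p35-1p36.x is subtelomeric, other 1p bands pericentromeric,
# 19q bands Q19. Anything else must be labelled explicitly.
region_from_cytoband <- function(chromosome, arm, cytoband) {
  region <- rep(NA_character_, length(cytoband))
  on_1p <- chromosome == "chr1" & arm == "p"
  on_19q <- chromosome == "chr19" & arm == "q"
  subtel <- on_1p & grepl("^1p3[56]", cytoband)
  region[on_1p] <- "PARACEN_1P"
  region[subtel] <- "SUBTEL_1P"
  region[on_19q] <- "Q19"
  region
}

#' Read a probe manifest from TSV or JSON
#'
#' TSV manifests need a header with at least `probe_id`, `chromosome` and
#' `arm`; `region` may be given explicitly (tokens of [probe_regions]) or
#' derived from `cytoband` (1p35/1p36 bands become `SUBTEL_1P`, other 1p
#' bands `PARACEN_1P`, 19q bands `Q19`). JSON manifests are an object with
#' optional `name` and a `probes` array of per-probe objects with the same
#' fields.
#'
#' @param path Path to a `.tsv`/`.txt` or `.json` manifest file.
#' @return A validated `probe_manifest`.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest file not found: ", path, call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    probes <- tibble::as_tibble(obj$probes %||% obj)
    name <- obj$name %||% basename(path)
  } else {
    probes <- readr::read_tsv(path, show_col_types = FALSE,
                              progress = FALSE)
    name <- basename(path)
  }
  if (!"region" %in% names(probes)) {
    if (!"cytoband" %in% names(probes)) {
      stop("manifest needs a 'region' or a 'cytoband' column", call. = FALSE)
    }
    probes$region <- region_from_cytoband(
      probes$chromosome, probes$arm, probes$cytoband
    )
    if (anyNA(probes$region)) {
      stop("could not resolve region from cytoband for probe(s): ",
           paste(probes$probe_id[is.na(probes$region)], collapse = ", "),
           call. = FALSE)
    }
  }
  probe_manifest(probes, name = name)
}

#' Write a probe manifest to TSV
#'
#' @param manifest A `probe_manifest`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  readr::write_tsv(tibble::as_tibble(manifest), path, progress = FALSE)
  invisible(path)
}

#' Count probes per region
#'
#' @param manifest A `probe_manifest`.
#' @return A tibble with `region` and `n_probes`, one row per region
#'   present.
#' @export
region_counts <- function(manifest) {
  dplyr::count(tibble::as_tibble(manifest), .data$region, name = "n_probes")
}

region_probe_ids <- function(manifest, region) {
  manifest$probe_id[manifest$region %in% region]
}

#' @export
print.probe_manifest <- function(x, ...) {
  cat("<probe_manifest> ", attr(x, "manifest_name"), "\n", sep = "")
  counts <- table(factor(x$region, levels = probe_regions))
  cat(paste(sprintf("%s=%d", names(counts), counts), collapse = ", "), "\n")
  NextMethod()
}
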