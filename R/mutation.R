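assay_statuses <- c("MUTANT", "WILDTYPE", "INDETERMINATE", "NOT_TESTED")

#' Call mutations from sequencing peak heights
#'
#' Direct (Sanger) sequencing of a hotspot produces a mutant and a
#' wild-type electropherogram peak; the sample is scored mutant when the
#' mutant peak reaches at least `min_ratio` of the wild-type peak (default
#' 25%, boundary inclusive). The rule is scale-invariant: only the ratio
#' of the two raw heights matters. Observations from a nested (two-round)
#' PCR product are flagged with method `SANGER_NESTED`; the same rule
#' applies.
#'
#' @param observations Data frame with one row per sequencing observation:
#'   `sample_id`, `locus` (e.g. `IDH1_c132`, `IDH2_c172`,
#'   `TERT_promoter`), `variant` (e.g. `"R132H"`), `mut_peak_height`,
#'   `wt_peak_height` (nonnegative, finite), and optionally `nested`
#'   (logical, default `FALSE`).
#' @param min_ratio Minimum mutant/wild-type peak-height ratio (default
#'   0.25).
#' @return A tibble of assay calls: `sample_id`, `marker` (the locus),
#'   `method` (`SANGER` / `SANGER_NESTED`), `status`, `variant`. Both
#'   peaks zero yields `INDETERMINATE` (failed sequencing); a zero
#'   wild-type peak with any mutant signal is `MUTANT`.
#' @export
call_sequencing <- function(observations, min_ratio = 0.25) {
  obs <- tibble::as_tibble(observations)
  stopifnot(all(c("sample_id", "locus", "variant",
                  "mut_peak_height", "wt_peak_height") %in% names(obs)))
  if (!"nested" %in% names(obs)) obs$nested <- FALSE
  bad <- !is.finite(obs$mut_peak_height) | !is.finite(obs$wt_peak_height) |
    obs$mut_peak_height < 0 | obs$wt_peak_height < 0
  if (any(bad)) {
    stop("peak heights must be finite and nonnegative (sample ",
         obs$sample_id[bad][1], ")", call. = FALSE)
  }
  failed <- obs$mut_peak_height == 0 & obs$wt_peak_height == 0
  mutant <- !failed & obs$mut_peak_height >= min_ratio * obs$wt_peak_height
  tibble::tibble(
    sample_id = as.character(obs$sample_id),
    marker = as.character(obs$locus),
    method = ifelse(obs$nested, "SANGER_NESTED", "SANGER"),
    status = dplyr::case_when(
      failed ~ "INDETERMINATE",
      mutant ~ "MUTANT",
      TRUE ~ "WILDTYPE"
    ),
    variant = ifelse(mutant & !failed, as.character(obs$variant),
                     NA_character_)
  )
}

#' Call mutations from MLPA mutation-specific probes
#'
#' Mutation-specific MLPA probes only ligate (and hence amplify) on the
#' mutant allele, so wild-type DNA gives essentially no signal; any robust
#' signal on the normalized reference scale is evidence for the mutation.
#' A probe is scored `MUTANT` when its normalized value is at or above
#' `presence_threshold` (default 0.1, boundary inclusive).
#'
#' @param profiles An `mlpa_profiles` tibble that includes values for the
#'   manifest's `MUTATION` probes.
#' @param manifest A `probe_manifest` with at least one `MUTATION` probe.
#' @param presence_threshold Minimum normalized signal called mutant.
#' @return A tibble of assay calls (`method = "MLPA_PROBE"`), one row per
#'   sample x mutation probe with a non-missing value; `marker` is the
#'   probe's target gene and `variant` its `target_variant`. Returns an
#'   empty tibble with a warning when the manifest has no mutation probes.
#' @export
call_mlpa_mutation <- function(profiles, manifest, presence_threshold = 0.1) {
  mut_probes <- manifest[manifest$region == "MUTATION", ]
  empty <- tibble::tibble(
    sample_id = character(), marker = character(), method = character(),
    status = character(), variant = character()
  )
  if (nrow(mut_probes) == 0) {
    warn("manifest contains no MUTATION probes; returning empty call set")
    return(empty)
  }
  vals <- tibble::as_tibble(profiles) |>
    dplyr::filter(.data$probe_id %in% mut_probes$probe_id)
  if (nrow(vals) == 0) return(empty)
  vals |>
    dplyr::inner_join(
      dplyr::select(tibble::as_tibble(mut_probes),
                    "probe_id", "target_gene", "target_variant"),
      by = "probe_id"
    ) |>
    dplyr::transmute(
      .data$sample_id,
      marker = .data$target_gene,
      method = "MLPA_PROBE",
      status = ifelse(.data$ratio >= presence_threshold,
                      "MUTANT", "WILDTYPE"),
      variant = ifelse(.data$ratio >= presence_threshold,
                       .data$target_variant, NA_character_)
    )
}

#' Integrate IDH assay calls into a per-sample consensus
#'
#' Combines IDH1 R132H immunohistochemistry, direct sequencing, nested-PCR
#' sequencing and MLPA mutation-probe calls. Precedence reflects the
#' antibody's near-perfect sensitivity for R132H:
#'
#' 1. IHC positive: consensus `MUTANT` (R132H) regardless of sequencing;
#'    flagged `LOW_FRACTION` when every molecular assay (sanger, nested,
#'    MLPA probe) is wild-type — the immunopositive fraction of cells is
#'    below the molecular detection limit.
#' 2. Otherwise any `MUTANT` sequencing call (nested counts) wins, carrying
#'    its variant.
#' 3. Otherwise an MLPA-probe `MUTANT` wins, flagged `SEQ_DISCORDANT` when
#'    direct sequencing was informative and wild-type.
#' 4. Otherwise `WILDTYPE` when at least one assay is informative, else
#'    `INDETERMINATE`.
#'
#' A mutant assay whose variant disagrees with the consensus variant adds
#' a `VARIANT_CONFLICT` flag. The result never depends on the row order of
#' the input and is never `WILDTYPE` when any assay is `MUTANT`.
#'
#' @param assay_calls Data frame of per-assay calls as produced by
#'   [call_sequencing()], [call_mlpa_mutation()] or hand-scored IHC rows:
#'   `sample_id`, `method` (`IHC`, `SANGER`, `SANGER_NESTED`,
#'   `MLPA_PROBE`), `status`, `variant` (optional).
#' @return A tibble with one row per sample: `sample_id`, `status`,
#'   `variant`, `flags` (`;`-separated, `""` when clean).
#' @export
integrate_idh <- function(assay_calls) {
  calls <- tibble::as_tibble(assay_calls)
  stopifnot(all(c("sample_id", "method", "status") %in% names(calls)))
  if (!"variant" %in% names(calls)) calls$variant <- NA_character_
  bad_m <- setdiff(unique(calls$method),
                   c("IHC", "SANGER", "SANGER_NESTED", "MLPA_PROBE"))
  if (length(bad_m) > 0) {
    stop("unknown assay method(s): ", paste(bad_m, collapse = ", "),
         call. = FALSE)
  }
  calls |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::group_modify(~ integrate_one_sample(.x)) |>
    dplyr::ungroup()
}

integrate_one_sample <- function(calls) {
  # several rows per method are allowed (e.g. one MLPA probe per variant):
  # any mutant row makes the method mutant
  status_of <- function(method) {
    s <- calls$status[calls$method == method]
    if (length(s) == 0) return(NA_character_)
    if (any(s == "MUTANT")) return("MUTANT")
    if (any(s == "WILDTYPE")) return("WILDTYPE")
    s[1]
  }
  variant_of <- function(method) {
    v <- calls$variant[calls$method == method & calls$status == "MUTANT"]
    v <- v[!is.na(v)]
    if (length(v) == 0) NA_character_ else v[1]
  }
  informative <- function(s) !is.na(s) & s %in% c("MUTANT", "WILDTYPE")

  ihc <- status_of("IHC")
  sanger <- status_of("SANGER")
  nested <- status_of("SANGER_NESTED")
  mlpa <- status_of("MLPA_PROBE")
  flags <- character()

  if (!is.na(ihc) && ihc == "MUTANT") {
    status <- "MUTANT"
    variant <- variant_of("IHC") %|na|% "IDH1 R132H"
    molecular <- c(sanger, nested, mlpa)
    if (any(informative(molecular)) &&
        all(molecular[informative(molecular)] == "WILDTYPE")) {
      flags <- c(flags, "LOW_FRACTION")
    }
  } else if (isTRUE(sanger == "MUTANT") || isTRUE(nested == "MUTANT")) {
    status <- "MUTANT"
    variant <- if (isTRUE(sanger == "MUTANT")) {
      variant_of("SANGER")
    } else {
      variant_of("SANGER_NESTED")
    }
  } else if (isTRUE(mlpa == "MUTANT")) {
    status <- "MUTANT"
    variant <- variant_of("MLPA_PROBE")
    if (isTRUE(sanger == "WILDTYPE")) flags <- c(flags, "SEQ_DISCORDANT")
  } else if (any(informative(c(ihc, sanger, nested, mlpa)))) {
    status <- "WILDTYPE"
    variant <- NA_character_
  } else {
    status <- "INDETERMINATE"
    variant <- NA_character_
  }

  if (status == "MUTANT") {
    mut_variants <- calls$variant[calls$status == "MUTANT"]
    mut_variants <- unique(normalize_variant(mut_variants))
    mut_variants <- mut_variants[!is.na(mut_variants)]
    if (length(mut_variants) > 1 ||
        (length(mut_variants) == 1 && !is.na(variant) &&
         mut_variants != normalize_variant(variant))) {
      flags <- c(flags, "VARIANT_CONFLICT")
    }
  }
  tibble::tibble(status = status, variant = variant,
                 flags = paste(sort(unique(flags)), collapse = ";"))
}

# "IDH1 R132H" and "R132H" denote the same variant
normalize_variant <- function(v) {
  sub("^IDH[12] +", "", v)
}

`%|na|%` <- function(x, y) if (length(x) == 0 || is.na(x)) y else x
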