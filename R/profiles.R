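#' Read MLPA profiles (normalized probe ratios)
#'
#' Profiles are stored long: one row per `(sample_id, probe_id)` with a
#' dimensionless copy-number `ratio` (1.0 = diploid reference). Wide files
#' (one row per sample, one column per probe, first column `sample_id`)
#' are detected from the header and pivoted. Blank/NA cells become missing
#' probes, which are excluded from every downstream denominator.
#'
#' @param path TSV or CSV file, wide or long.
#' @param manifest A `probe_manifest`; every probe in the file must exist
#'   in it.
#' @return An `mlpa_profiles` tibble with columns `sample_id`, `probe_id`,
#'   `ratio` (missing ratios dropped).
#' @export
read_profiles <- function(path, manifest) {
  if (!file.exists(path)) stop("profile file not found: ", path, call. = FALSE)
  reader <- if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::read_csv
  } else {
    readr::read_tsv
  }
  # ratios are parsed via base R's strtod so that 17-digit decimals written
  # by write_profiles() round-trip bit-for-bit
  tab <- reader(path, show_col_types = FALSE, progress = FALSE,
                col_types = readr::cols(.default = readr::col_character()))
  num_cols <- setdiff(names(tab), c("sample_id", "probe_id"))
  tab[num_cols] <- lapply(tab[num_cols], as.numeric)
  long <- if (all(c("sample_id", "probe_id", "ratio") %in% names(tab))) {
    dplyr::select(tab, "sample_id", "probe_id", "ratio")
  } else {
    if (!"sample_id" %in% names(tab)) {
      stop("profile table needs a 'sample_id' column (wide) or ",
           "'sample_id', 'probe_id', 'ratio' columns (long)", call. = FALSE)
    }
    tidyr::pivot_longer(tab, -"sample_id",
                        names_to = "probe_id", values_to = "ratio")
  }
  mlpa_profiles(long, manifest)
}

#' Construct a validated set of MLPA profiles
#'
#' @param ratios Long data frame with `sample_id`, `probe_id`, `ratio`.
#' @param manifest A `probe_manifest`.
#' @return An `mlpa_profiles` tibble (rows with missing ratio removed).
#' @export
mlpa_profiles <- function(ratios, manifest) {
  ratios <- tibble::as_tibble(ratios)[c("sample_id", "probe_id", "ratio")]
  ratios$sample_id <- as.character(ratios$sample_id)
  ratios$probe_id <- as.character(ratios$probe_id)
  ratios$ratio <- as.numeric(ratios$ratio)

  unknown <- setdiff(unique(ratios$probe_id), manifest$probe_id)
  if (length(unknown) > 0) {
    stop("probe_id not in manifest: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  dup <- duplicated(ratios[c("sample_id", "probe_id")])
  if (any(dup)) {
    stop("duplicated (sample_id, probe_id) entries, e.g. ",
         ratios$sample_id[dup][1], "/", ratios$probe_id[dup][1],
         call. = FALSE)
  }
  neg <- !is.na(ratios$ratio) & ratios$ratio < 0
  if (any(neg)) {
    stop("negative ratio(s), e.g. sample ", ratios$sample_id[neg][1],
         " probe ", ratios$probe_id[neg][1], call. = FALSE)
  }
  all_samples <- unique(ratios$sample_id)
  kept <- ratios[!is.na(ratios$ratio), ]
  empty <- setdiff(all_samples, unique(kept$sample_id))
  if (length(empty) > 0) {
    stop("sample(s) with no informative ratio: ",
         paste(empty, collapse = ", "), call. = FALSE)
  }
  kept <- dplyr::arrange(kept, .data$sample_id, .data$probe_id)
  class(kept) <- c("mlpa_profiles", class(kept))
  kept
}

#' Write MLPA profiles to a long TSV
#'
#' Ratios are written with 17 significant digits, which round-trips
#' doubles exactly through [read_profiles()].
#'
#' @param profiles An `mlpa_profiles` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  out <- tibble::as_tibble(profiles)
  out$ratio <- vapply(out$ratio, format, character(1), digits = 17)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Normalize a raw peak table to copy-number ratios
#'
#' Two-step median-reference normalization, the standard MLPA scheme:
#' within each sample, every peak is divided by the median peak height of
#' that sample's `REFERENCE` probes; the resulting intra-sample values are
#' then divided, probe by probe, by the mean intra-sample value of the
#' designated (non-tumor) reference samples. Reference samples therefore
#' come out at ratio ~1 for reference probes, and a locus hemizygously
#' deleted in a fraction p of cells is expected at 1 - p/2.
#'
#' @param raw Long data frame with `sample_id`, `probe_id`, `peak_height`
#'   (relative fluorescence units, nonnegative and finite).
#' @param manifest A `probe_manifest` with at least 2 `REFERENCE` probes.
#' @param reference_samples Character vector of sample ids used as the
#'   inter-sample reference; must be non-empty and present in `raw`.
#' @return An `mlpa_profiles` tibble. Probes absent from every reference
#'   sample are dropped (missing in the output).
#' @export
normalize_peaks <- function(raw, manifest, reference_samples) {
  raw <- tibble::as_tibble(raw)
  stopifnot(all(c("sample_id", "probe_id", "peak_height") %in% names(raw)))
  raw$sample_id <- as.character(raw$sample_id)
  raw$probe_id <- as.character(raw$probe_id)
  if (length(reference_samples) == 0) {
    stop("at least one reference sample is required", call. = FALSE)
  }
  missing_ref <- setdiff(reference_samples, raw$sample_id)
  if (length(missing_ref) > 0) {
    stop("reference sample(s) absent from peak table: ",
         paste(missing_ref, collapse = ", "), call. = FALSE)
  }
  unknown <- setdiff(unique(raw$probe_id), manifest$probe_id)
  if (length(unknown) > 0) {
    stop("probe_id not in manifest: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  ref_probes <- region_probe_ids(manifest, "REFERENCE")
  if (length(ref_probes) < 2) {
    stop("manifest must contain at least 2 REFERENCE probes", call. = FALSE)
  }
  bad <- !is.finite(raw$peak_height) | raw$peak_height < 0
  if (any(bad)) {
    stop("non-finite or negative peak height(s), e.g. sample ",
         raw$sample_id[bad][1], call. = FALSE)
  }

  # step 1: intra-sample scaling by the median reference-probe peak
  intra <- raw |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::mutate(
      ref_median = median(.data$peak_height[.data$probe_id %in% ref_probes])
    ) |>
    dplyr::ungroup()
  failed <- intra |>
    dplyr::distinct(.data$sample_id, .data$ref_median) |>
    dplyr::filter(is.na(.data$ref_median) | .data$ref_median == 0)
  if (nrow(failed) > 0) {
    stop("sample failed (reference-probe median zero or absent): ",
         paste(failed$sample_id, collapse = ", "), call. = FALSE)
  }
  intra$value <- intra$peak_height / intra$ref_median

  # step 2: inter-sample scaling by the mean value of the reference samples
  ref_means <- intra |>
    dplyr::filter(.data$sample_id %in% reference_samples) |>
    dplyr::group_by(.data$probe_id) |>
    dplyr::summarise(ref_mean = mean(.data$value), .groups = "drop")

  out <- intra |>
    dplyr::inner_join(ref_means, by = "probe_id") |>
    dplyr::filter(.data$ref_mean > 0) |>
    dplyr::transmute(.data$sample_id, .data$probe_id,
                     ratio = .data$value / .data$ref_mean)
  mlpa_profiles(out, manifest)
}

#' Order samples by mean copy-number ratio
#'
#' Reporting order for heat maps and tables: ascending mean of the
#' non-missing ratios over the deletion-region loci (most deleted first),
#' ties broken lexicographically by sample id.
#'
#' @param profiles An `mlpa_profiles` tibble.
#' @param manifest A `probe_manifest`.
#' @return Character vector of sample ids.
#' @export
order_samples <- function(profiles, manifest) {
  del <- region_probe_ids(manifest, deletion_regions)
  means <- tibble::as_tibble(profiles) |>
    dplyr::filter(.data$probe_id %in% del) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(mean_ratio = mean(.data$ratio), .groups = "drop") |>
    dplyr::arrange(.data$mean_ratio, .data$sample_id)
  means$sample_id
}
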