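marker_columns <- c(
  histology = "histology", idh = "idh_status", tert = "tert_status",
  atrx = "atrx_loss"
)

#' Cross-tabulate markers against co-deletion status per criteria
#'
#' For each scoring criteria, dichotomizes the calls into complete
#' co-deletion vs no co-deletion (segmental and no-deletion pooled;
#' `INDETERMINATE` excluded) and crosses them with histology (3 levels)
#' and the ATRX / TERT / IDH marker statuses (2 levels each), running
#' [association_test()] on every table. Rows not tested for a marker
#' (`NOT_TESTED` / `INDETERMINATE` / `NA`) are excluded from that marker's
#' table only.
#'
#' @param markers Per-case marker tibble: `sample_id`, `histology`
#'   (`ASTROCYTIC` / `MIXED` / `OLIGODENDROGLIAL`), `idh_status`,
#'   `tert_status` (`MUTANT` / `WILDTYPE` / ...), `atrx_loss` (logical).
#' @param calls A `codel_calls` tibble from [call_codel()].
#' @param policy Test-selection policy passed to [association_test()].
#' @return A tibble with one row per criteria x marker: `criteria`,
#'   `marker`, `table` (list of matrices, co-deletion status in columns),
#'   `test` (list of `assoc_test`), `p_value`, `test_used`.
#' @export
build_marker_tables <- function(markers, calls, policy = "auto") {
  markers <- tibble::as_tibble(markers)
  calls <- tibble::as_tibble(calls)
  joined <- dplyr::inner_join(
    dplyr::filter(calls, .data$call != "INDETERMINATE"),
    markers, by = "sample_id"
  )
  if (nrow(joined) == 0) {
    stop("no samples shared between calls and marker table", call. = FALSE)
  }
  joined$codel <- factor(
    ifelse(joined$call == "COMPLETE_CODELETION", "Co-deletion",
           "No co-deletion"),
    levels = c("Co-deletion", "No co-deletion")
  )

  grid <- tidyr::expand_grid(
    criteria = unique(joined$criteria),
    marker = names(marker_columns)
  )
  rows <- purrr::pmap(grid, function(criteria, marker) {
    sub <- joined[joined$criteria == criteria, ]
    lev <- marker_level(sub[[marker_columns[[marker]]]], marker)
    keep <- !is.na(lev)
    tab <- table(lev[keep], sub$codel[keep])
    res <- association_test(unclass(as.matrix(tab)), policy = policy)
    tibble::tibble(
      criteria = criteria, marker = marker, table = list(tab),
      test = list(res), p_value = res$p_value, test_used = res$test_used
    )
  })
  dplyr::bind_rows(rows)
}

marker_level <- function(x, marker) {
  if (marker == "atrx") {
    if (is.logical(x)) {
      factor(ifelse(x, "Loss", "Retention"), levels = c("Loss", "Retention"))
    } else {
      factor(as.character(x), levels = c("Loss", "Retention"))
    }
  } else if (marker == "histology") {
    factor(as.character(x),
           levels = c("ASTROCYTIC", "MIXED", "OLIGODENDROGLIAL"))
  } else {
    x <- as.character(x)
    x[!x %in% c("MUTANT", "WILDTYPE")] <- NA
    factor(x, levels = c("MUTANT", "WILDTYPE"))
  }
}

#' Pairwise Spearman correlation of deletion-region loci
#'
#' Rank-based correlation of the per-sample copy-number values between
#' every pair of deletion-region probes, on pairwise-complete
#' observations. High correlation between subtelomeric 1p and 19q loci is
#' what makes pooled per-arm majority rules prone to over-calling
#' segmental deletions as complete co-deletions.
#'
#' @param profiles An `mlpa_profiles` tibble with at least 3 samples.
#' @param manifest A `probe_manifest`.
#' @return A symmetric correlation matrix over deletion-region probe ids
#'   (diagonal 1); a probe constant across samples yields `NA` against
#'   every other probe.
#' @export
locus_correlation <- function(profiles, manifest) {
  del <- region_probe_ids(manifest, deletion_regions)
  wide <- tibble::as_tibble(profiles) |>
    dplyr::filter(.data$probe_id %in% del) |>
    tidyr::pivot_wider(names_from = "probe_id", values_from = "ratio") |>
    dplyr::select(-"sample_id")
  if (nrow(wide) < 3) {
    stop("locus correlation needs at least 3 samples", call. = FALSE)
  }
  wide <- wide[, intersect(del, names(wide)), drop = FALSE]
  rho <- suppressWarnings(
    cor(as.matrix(wide), method = "spearman", use = "pairwise.complete.obs")
  )
  diag(rho) <- 1
  rho
}

#' Marker-by-co-deletion cross-tabulations from a published glioma cohort
#'
#' Printed cross-tabulations from a published 150-case adult diffuse
#' glioma MLPA study comparing three co-deletion scoring criteria
#' (all-loci at 0.8; per-arm majority at 0.75; three-region majority at
#' 0.75) against histology, ATRX immunohistochemistry, TERT promoter and
#' IDH mutation status. Counts are cases; columns are complete
#' co-deletion vs no co-deletion. Marker totals differ slightly because
#' not every assay was informative in every case.
#'
#' These tables let the association tests be exercised against published
#' results without any per-case data.
#'
#' @return A tibble: `criteria` (`jeuken`, `natte`, `ours`), `marker`,
#'   `level`, `codel`, `no_codel`.
#' @export
glioma_marker_crosstabs <- function() {
  tibble::tribble(
    ~criteria, ~marker, ~level, ~codel, ~no_codel,
    "jeuken", "histology", "ASTROCYTIC", 0L, 68L,
    "jeuken", "histology", "MIXED", 7L, 46L,
    "jeuken", "histology", "OLIGODENDROGLIAL", 6L, 23L,
    "jeuken", "atrx", "Loss", 0L, 49L,
    "jeuken", "atrx", "Retention", 13L, 87L,
    "jeuken", "tert", "MUTANT", 12L, 78L,
    "jeuken", "tert", "WILDTYPE", 1L, 58L,
    "jeuken", "idh", "MUTANT", 13L, 74L,
    "jeuken", "idh", "WILDTYPE", 0L, 63L,
    "natte", "histology", "ASTROCYTIC", 4L, 64L,
    "natte", "histology", "MIXED", 24L, 29L,
    "natte", "histology", "OLIGODENDROGLIAL", 18L, 11L,
    "natte", "atrx", "Loss", 6L, 43L,
    "natte", "atrx", "Retention", 40L, 60L,
    "natte", "tert", "MUTANT", 42L, 48L,
    "natte", "tert", "WILDTYPE", 4L, 55L,
    "natte", "idh", "MUTANT", 37L, 50L,
    "natte", "idh", "WILDTYPE", 9L, 54L,
    "ours", "histology", "ASTROCYTIC", 1L, 67L,
    "ours", "histology", "MIXED", 17L, 36L,
    "ours", "histology", "OLIGODENDROGLIAL", 18L, 11L,
    "ours", "atrx", "Loss", 1L, 48L,
    "ours", "atrx", "Retention", 35L, 65L,
    "ours", "tert", "MUTANT", 34L, 56L,
    "ours", "tert", "WILDTYPE", 2L, 57L,
    "ours", "idh", "MUTANT", 31L, 56L,
    "ours", "idh", "WILDTYPE", 5L, 58L
  )
}

#' Association tests over the published cross-tabulations
#'
#' Runs [association_test()] on every criteria x marker table of
#' [glioma_marker_crosstabs()].
#'
#' @param policy Test-selection policy (default `"auto"`, Cochran's rule,
#'   matching the published "depending on number of observations" usage).
#' @return A tibble: `criteria`, `marker`, `p_value`, `test_used`, `n`,
#'   `test` (list of `assoc_test`).
#' @export
published_association_tests <- function(policy = "auto") {
  glioma_marker_crosstabs() |>
    dplyr::group_by(.data$criteria, .data$marker) |>
    dplyr::group_modify(function(df, key) {
      counts <- as.matrix(df[, c("codel", "no_codel")])
      rownames(counts) <- df$level
      test <- association_test(counts, policy = policy)
      tibble::tibble(p_value = test$p_value, test_used = test$test_used,
                     n = test$n, test = list(test))
    }) |>
    dplyr::ungroup()
}
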