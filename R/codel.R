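#' Co-deletion call levels
#'
#' Ordered from least to most severe; the three-region rule is monotone in
#' this ordering when any single ratio decreases.
#' @export
codel_call_levels <- c(
  "NO_DELETION", "ISOLATED_SEGMENTAL_DELETION", "COMPLETE_CODELETION",
  "INDETERMINATE"
)

#' Co-deletion scoring criteria
#'
#' Three named presets are built in:
#'
#' * `ours` — three-region majority rule (threshold 0.75): complete
#'   co-deletion when a strict majority of informative loci is deleted in
#'   each of subtelomeric 1p, pericentromeric 1p and 19q; isolated
#'   segmental deletion when the subtelomeric majority holds but the full
#'   conjunction does not; no deletion otherwise.
#' * `jeuken` — all-loci rule (threshold 0.8): complete co-deletion only
#'   when every informative 1p and 19q deletion-region locus is at or
#'   below the threshold; defines no segmental class.
#' * `natte` — per-arm majority rule (threshold 0.75): complete
#'   co-deletion when more than 50% of informative loci are deleted on 1p
#'   (both regions pooled) and, separately, on 19q.
#'
#' A locus counts as deleted when its ratio is `<= threshold` (boundary
#' inclusive); "majority" is strictly greater than 50% of the informative
#' (non-missing) loci. In low-purity material the threshold may be shifted
#' to 0.80 via `threshold`.
#'
#' @param name `"ours"`, `"jeuken"`, `"natte"`, or a custom label when
#'   `rule` is supplied explicitly.
#' @param threshold Deletion threshold in (0, 1); defaults to the preset's
#'   published value (0.75 for `ours`/`natte`, 0.8 for `jeuken`).
#' @param rule One of `"REGION_MAJORITY"`, `"ALL_LOCI"`, `"ARM_MAJORITY"`.
#' @param min_loci Minimum informative loci per required scoring unit
#'   below which the call is `INDETERMINATE` (default 3).
#' @return A `criteria_spec` list with fields `name`, `rule`, `threshold`,
#'   `min_loci`.
#' @export
codel_criteria <- function(name = c("ours", "jeuken", "natte"),
                           threshold = NULL, rule = NULL, min_loci = 3) {
  if (is.null(rule)) {
    name <- match.arg(name)
    rule <- switch(name,
      ours = "REGION_MAJORITY",
      jeuken = "ALL_LOCI",
      natte = "ARM_MAJORITY"
    )
  } else {
    rule <- match.arg(rule, c("REGION_MAJORITY", "ALL_LOCI", "ARM_MAJORITY"))
  }
  threshold <- threshold %||% if (rule == "ALL_LOCI") 0.8 else 0.75
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold <= 0 || threshold >= 1) {
    stop("threshold must be a single number strictly between 0 and 1",
         call. = FALSE)
  }
  if (!is.numeric(min_loci) || min_loci < 1) {
    stop("min_loci must be a positive integer", call. = FALSE)
  }
  structure(
    list(name = name, rule = rule, threshold = threshold,
         min_loci = as.integer(min_loci)),
    class = "criteria_spec"
  )
}

#' @export
print.criteria_spec <- function(x, ...) {
  cat(sprintf("<criteria_spec> %s: rule=%s, threshold=%g, min_loci=%d\n",
              x$name, x$rule, x$threshold, x$min_loci))
  invisible(x)
}

#' Deleted fraction of a scoring region
#'
#' Counts, per sample, how many informative (non-missing) loci of one
#' deletion region lie at or below the threshold.
#'
#' @param profiles An `mlpa_profiles` tibble.
#' @param manifest A `probe_manifest`.
#' @param region One of `SUBTEL_1P`, `PARACEN_1P`, `Q19`.
#' @param threshold Deletion threshold in (0, 1).
#' @return A tibble with `sample_id`, `region`, `n_deleted`,
#'   `n_informative`, `fraction` (`NaN` when no informative loci).
#' @export
region_deleted_fraction <- function(profiles, manifest, region,
                                    threshold = 0.75) {
  region <- match.arg(region, deletion_regions)
  if (threshold <= 0 || threshold >= 1) {
    stop("threshold must lie strictly between 0 and 1", call. = FALSE)
  }
  ids <- region_probe_ids(manifest, region)
  if (length(ids) == 0) {
    stop("manifest has no probes in region ", region, call. = FALSE)
  }
  samples <- unique(tibble::as_tibble(profiles)$sample_id)
  out <- tibble::as_tibble(profiles) |>
    dplyr::filter(.data$probe_id %in% ids) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      n_deleted = sum(.data$ratio <= threshold),
      n_informative = dplyr::n(),
      .groups = "drop"
    )
  out <- tibble::tibble(sample_id = samples) |>
    dplyr::left_join(out, by = "sample_id") |>
    dplyr::mutate(
      n_deleted = dplyr::coalesce(.data$n_deleted, 0L),
      n_informative = dplyr::coalesce(.data$n_informative, 0L),
      region = region,
      fraction = .data$n_deleted / .data$n_informative
    ) |>
    dplyr::select("sample_id", "region", "n_deleted", "n_informative",
                  "fraction")
  out
}

# per-sample region summary for all three deletion regions, wide
region_summary <- function(profiles, manifest, threshold) {
  purrr::map(deletion_regions, function(r) {
    region_deleted_fraction(profiles, manifest, r, threshold)
  }) |>
    dplyr::bind_rows() |>
    tidyr::pivot_wider(
      names_from = "region",
      values_from = c("n_deleted", "n_informative", "fraction")
    )
}

majority <- function(n_deleted, n_informative) {
  n_informative > 0 & n_deleted > n_informative / 2
}

call_one_criteria <- function(profiles, manifest, spec) {
  rs <- region_summary(profiles, manifest, spec$threshold)
  call <- switch(spec$rule,
    REGION_MAJORITY = {
      indet <- rs$n_informative_SUBTEL_1P < spec$min_loci |
        rs$n_informative_PARACEN_1P < spec$min_loci |
        rs$n_informative_Q19 < spec$min_loci
      complete <- majority(rs$n_deleted_SUBTEL_1P, rs$n_informative_SUBTEL_1P) &
        majority(rs$n_deleted_PARACEN_1P, rs$n_informative_PARACEN_1P) &
        majority(rs$n_deleted_Q19, rs$n_informative_Q19)
      segmental <- majority(rs$n_deleted_SUBTEL_1P, rs$n_informative_SUBTEL_1P)
      dplyr::case_when(
        indet ~ "INDETERMINATE",
        complete ~ "COMPLETE_CODELETION",
        segmental ~ "ISOLATED_SEGMENTAL_DELETION",
        TRUE ~ "NO_DELETION"
      )
    },
    ALL_LOCI = {
      n_inf <- rs$n_informative_SUBTEL_1P + rs$n_informative_PARACEN_1P +
        rs$n_informative_Q19
      n_del <- rs$n_deleted_SUBTEL_1P + rs$n_deleted_PARACEN_1P +
        rs$n_deleted_Q19
      dplyr::case_when(
        n_inf < spec$min_loci ~ "INDETERMINATE",
        n_del == n_inf ~ "COMPLETE_CODELETION",
        TRUE ~ "NO_DELETION"
      )
    },
    ARM_MAJORITY = {
      n_inf_1p <- rs$n_informative_SUBTEL_1P + rs$n_informative_PARACEN_1P
      n_del_1p <- rs$n_deleted_SUBTEL_1P + rs$n_deleted_PARACEN_1P
      dplyr::case_when(
        n_inf_1p < spec$min_loci |
          rs$n_informative_Q19 < spec$min_loci ~ "INDETERMINATE",
        majority(n_del_1p, n_inf_1p) &
          majority(rs$n_deleted_Q19, rs$n_informative_Q19) ~
          "COMPLETE_CODELETION",
        TRUE ~ "NO_DELETION"
      )
    }
  )
  tibble::tibble(
    sample_id = rs$sample_id,
    criteria = spec$name,
    call = factor(call, levels = codel_call_levels),
    subtel1p_n_deleted = rs$n_deleted_SUBTEL_1P,
    subtel1p_n = rs$n_informative_SUBTEL_1P,
    subtel1p_frac = rs$fraction_SUBTEL_1P,
    paracen1p_n_deleted = rs$n_deleted_PARACEN_1P,
    paracen1p_n = rs$n_informative_PARACEN_1P,
    paracen1p_frac = rs$fraction_PARACEN_1P,
    q19_n_deleted = rs$n_deleted_Q19,
    q19_n = rs$n_informative_Q19,
    q19_frac = rs$fraction_Q19,
    threshold = spec$threshold
  )
}

#' Call 1p/19q co-deletion status
#'
#' Applies one or more scoring criteria (see [codel_criteria()]) to every
#' sample. Per-region deleted fractions are always reported, whatever the
#' rule, so 19q-only or pericentromeric-only losses stay visible next to
#' the categorical call. Samples with too few informative loci in a
#' required scoring unit come back `INDETERMINATE` rather than failing the
#' batch.
#'
#' @param profiles An `mlpa_profiles` tibble (see [read_profiles()]).
#' @param manifest A `probe_manifest`; must have probes in all three
#'   deletion regions.
#' @param criteria Character vector of preset names, or a list of
#'   `criteria_spec` objects.
#' @param threshold Optional threshold override applied to every
#'   criterion (e.g. 0.80 for low-purity cohorts).
#' @param min_loci Minimum informative loci per required scoring unit.
#' @return A `codel_calls` tibble, one row per sample x criteria, ordered
#'   by sample then criteria, with columns `sample_id`, `criteria`,
#'   `call`, per-region `*_n_deleted`, `*_n`, `*_frac`, and `threshold`.
#' @examples
#' cohort <- simulate_cohort(sim_config(n_samples = 6, seed = 1))
#' call_codel(cohort$profiles, manifest_default())
#' @export
call_codel <- function(profiles, manifest,
                       criteria = c("ours", "jeuken", "natte"),
                       threshold = NULL, min_loci = 3) {
  specs <- purrr::map(criteria, function(cr) {
    if (inherits(cr, "criteria_spec")) {
      cr
    } else {
      codel_criteria(cr, threshold = threshold, min_loci = min_loci)
    }
  })
  out <- purrr::map(specs, function(s) {
    call_one_criteria(profiles, manifest, s)
  }) |>
    dplyr::bind_rows() |>
    dplyr::mutate(
      criteria = factor(.data$criteria, levels = unique(.data$criteria))
    ) |>
    dplyr::arrange(.data$sample_id, .data$criteria) |>
    dplyr::mutate(criteria = as.character(.data$criteria))
  n_ind <- sum(out$call == "INDETERMINATE")
  if (n_ind > 0) {
    warn(sprintf("%d call(s) are INDETERMINATE (fewer than min_loci informative loci)",
                 n_ind))
  }
  class(out) <- c("codel_calls", class(out))
  out
}

#' @rdname call_codel
#' @param ... Passed on to [call_codel()].
#' @export
call_ours <- function(profiles, manifest, ...) {
  call_codel(profiles, manifest, criteria = "ours", ...)
}

#' @rdname call_codel
#' @export
call_jeuken <- function(profiles, manifest, ...) {
  call_codel(profiles, manifest, criteria = "jeuken", ...)
}

#' @rdname call_codel
#' @export
call_natte <- function(profiles, manifest, ...) {
  call_codel(profiles, manifest, criteria = "natte", ...)
}
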