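#' Heat map of copy-number ratios across a cohort
#'
#' Probes are ordered by manifest position within region (subtelomeric 1p,
#' then the rest of 1p, then 19q); samples are ordered by their mean ratio
#' over the deletion-region loci via [order_samples()], most deleted
#' first. The fill scale is clamped to 0.5--1 so hemizygous losses use the
#' full dynamic range.
#'
#' @param profiles An `mlpa_profiles` tibble.
#' @param manifest A `probe_manifest`.
#' @param limits Fill clamp, default `c(0.5, 1)`.
#' @return A ggplot object.
#' @export
plot_cohort_heatmap <- function(profiles, manifest, limits = c(0.5, 1)) {
  del <- tibble::as_tibble(manifest) |>
    dplyr::filter(.data$region %in% deletion_regions) |>
    dplyr::mutate(region = factor(.data$region, levels = deletion_regions)) |>
    dplyr::arrange(.data$region, .data$position_mb)
  ord <- order_samples(profiles, manifest)
  dat <- tibble::as_tibble(profiles) |>
    dplyr::filter(.data$probe_id %in% del$probe_id) |>
    dplyr::mutate(
      sample_id = factor(.data$sample_id, levels = ord),
      probe_id = factor(.data$probe_id, levels = del$probe_id),
      ratio_clamped = pmin(pmax(.data$ratio, limits[1]), limits[2]),
      region = factor(
        del$region[match(.data$probe_id, del$probe_id)],
        levels = deletion_regions
      )
    )
  ggplot2::ggplot(dat, ggplot2::aes(.data$sample_id, .data$probe_id,
                                    fill = .data$ratio_clamped)) +
    ggplot2::geom_tile() +
    ggplot2::facet_grid(ggplot2::vars(.data$region),
                        scales = "free_y", space = "free_y") +
    ggplot2::scale_fill_gradient2(
      low = "#2166ac", mid = "#f7f7f7", high = "#b2182b",
      midpoint = mean(limits), limits = limits, name = "ratio"
    ) +
    ggplot2::labs(x = "sample (ordered by mean ratio)", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Per-sample line plots of probe ratios with the deletion threshold
#'
#' One panel per sample (optionally grouped by call), probes in genomic
#' order within region, a horizontal line at the deletion threshold.
#'
#' @param profiles An `mlpa_profiles` tibble.
#' @param manifest A `probe_manifest`.
#' @param calls Optional `codel_calls` tibble (single criteria) used to
#'   facet samples by call.
#' @param threshold Threshold line position (default 0.75).
#' @return A ggplot object.
#' @export
plot_profile_lines <- function(profiles, manifest, calls = NULL,
                               threshold = 0.75) {
  del <- tibble::as_tibble(manifest) |>
    dplyr::filter(.data$region %in% deletion_regions) |>
    dplyr::mutate(region = factor(.data$region, levels = deletion_regions)) |>
    dplyr::arrange(.data$region, .data$position_mb)
  dat <- tibble::as_tibble(profiles) |>
    dplyr::filter(.data$probe_id %in% del$probe_id) |>
    dplyr::mutate(
      probe_idx = match(.data$probe_id, del$probe_id),
      region = del$region[match(.data$probe_id, del$probe_id)]
    )
  if (!is.null(calls)) {
    calls <- tibble::as_tibble(calls)
    dat <- dplyr::left_join(
      dat, dplyr::select(calls, "sample_id", "call"), by = "sample_id"
    )
  }
  p <- ggplot2::ggplot(dat, ggplot2::aes(.data$probe_idx, .data$ratio,
                                         group = .data$sample_id)) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$region), size = 0.8) +
    ggplot2::geom_hline(yintercept = threshold, colour = "red",
                        linewidth = 1) +
    ggplot2::labs(x = "probe (genomic order)", y = "copy-number ratio") +
    ggplot2::theme_minimal()
  if (!is.null(calls)) p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$call))
  p
}

#' Bar chart of calls per criteria
#'
#' @param object A `codel_calls` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @method autoplot codel_calls
#' @export
autoplot.codel_calls <- function(object, ...) {
  dat <- tibble::as_tibble(object) |>
    dplyr::count(.data$criteria, .data$call)
  ggplot2::ggplot(dat, ggplot2::aes(.data$criteria, .data$n,
                                    fill = .data$call)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(x = NULL, y = "samples") +
    ggplot2::theme_minimal()
}
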