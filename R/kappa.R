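#' Cohen's kappa for paired categorical calls, optionally weighted
#'
#' Chance-corrected agreement between two raters (or two analysis runs) of
#' the same samples. For ordered categories, weighted kappa penalizes
#' disagreements by how far apart the two calls sit in `categories`:
#' disagreement weights are `|i - j|` (linear) or `(i - j)^2` (quadratic)
#' over category indices; unweighted kappa uses 0/1 weights. With two
#' categories all three schemes coincide. Kappa is
#' `(P_o - P_e) / (1 - P_e)` with observed and expected agreement computed
#' on the normalized agreement-weight scale.
#'
#' When every pair falls in one identical category, chance agreement is 1
#' and kappa is undefined; by convention the function returns 1 with
#' `degenerate = TRUE`.
#'
#' @param calls_a,calls_b Equal-length vectors of categorical calls on the
#'   same samples, values drawn from `categories`.
#' @param categories Category order (low to high); defaults to the sorted
#'   union of observed values. The order matters for weighted kappa, e.g.
#'   no deletion (0) < segmental deletion (1) < complete co-deletion (2).
#' @param weighting `"quadratic"` (default), `"linear"`, or `"none"`.
#' @return A `kappa_result`: `kappa`, `weighting`, `categories`,
#'   `weights` (disagreement-weight matrix), `p_observed`, `p_expected`,
#'   the cross-table, `n`, `degenerate`. [tidy()] gives a one-row tibble.
#' @examples
#' a <- c(0, 0, 1, 2, 2, 1)
#' b <- c(0, 1, 1, 2, 1, 1)
#' cohen_kappa(a, b, categories = 0:2, weighting = "quadratic")
#' @export
cohen_kappa <- function(calls_a, calls_b, categories = NULL,
                        weighting = c("quadratic", "linear", "none")) {
  weighting <- match.arg(weighting)
  if (length(calls_a) != length(calls_b)) {
    stop("calls_a and calls_b must have equal length", call. = FALSE)
  }
  if (length(calls_a) == 0) stop("no paired calls supplied", call. = FALSE)
  calls_a <- as.character(calls_a)
  calls_b <- as.character(calls_b)
  categories <- as.character(categories %||% sort(unique(c(calls_a, calls_b))))
  outside <- setdiff(unique(c(calls_a, calls_b)), categories)
  if (length(outside) > 0) {
    stop("call value(s) outside the category order: ",
         paste(outside, collapse = ", "), call. = FALSE)
  }

  k <- length(categories)
  fa <- factor(calls_a, levels = categories)
  fb <- factor(calls_b, levels = categories)
  tab <- table(fa, fb)
  n <- sum(tab)
  p <- tab / n
  e <- outer(rowSums(p), colSums(p))

  idx <- seq_len(k)
  d <- switch(weighting,
    none = 1 * outer(idx, idx, `!=`),
    linear = abs(outer(idx, idx, `-`)),
    quadratic = outer(idx, idx, `-`)^2
  )
  disagree_obs <- sum(d * p)
  disagree_exp <- sum(d * e)
  degenerate <- disagree_exp == 0
  kappa <- if (degenerate) 1 else 1 - disagree_obs / disagree_exp

  d_max <- max(d)
  w <- if (d_max == 0) array(1, dim(d)) else 1 - d / d_max
  structure(
    list(kappa = kappa, weighting = toupper(weighting),
         categories = categories, weights = d,
         p_observed = sum(w * p), p_expected = sum(w * e),
         table = tab, n = n, degenerate = degenerate),
    class = "kappa_result"
  )
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf("<kappa_result> kappa = %.4f (%s weights, n = %d)%s\n",
              x$kappa, tolower(x$weighting), x$n,
              if (x$degenerate) " [degenerate: single category]" else ""))
  print(x$table)
  invisible(x)
}

#' @rdname cohen_kappa
#' @param x A `kappa_result`.
#' @param ... Unused.
#' @method tidy kappa_result
#' @export
tidy.kappa_result <- function(x, ...) {
  tibble::tibble(
    kappa = x$kappa,
    weighting = x$weighting,
    p.observed = x$p_observed,
    p.expected = x$p_expected,
    n = x$n,
    n.categories = length(x$categories),
    degenerate = x$degenerate
  )
}

#' @rdname cohen_kappa
#' @method glance kappa_result
#' @export
glance.kappa_result <- function(x, ...) tidy.kappa_result(x)
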