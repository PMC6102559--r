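# Two-sided Fisher exact p-value by complete enumeration of tables with
# the observed margins. The two-sided convention is the conventional
# point-probability one: sum the null probabilities of every table whose
# probability does not exceed the observed table's. Ties are compared with
# a 1e-7 relative tolerance so that algebraically equal probabilities
# reached by different floating-point paths still count as ties.

exact_tie_tol <- 1e-7

fisher_exact_p <- function(counts) {
  if (nrow(counts) == 2 && ncol(counts) == 2) {
    fisher_exact_p_2x2(counts)
  } else {
    fisher_exact_p_rxc(counts)
  }
}

fisher_exact_p_2x2 <- function(counts) {
  r1 <- sum(counts[1, ])
  r2 <- sum(counts[2, ])
  c1 <- sum(counts[, 1])
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- dhyper(support, r1, r2, c1)
  p_obs <- dhyper(counts[1, 1], r1, r2, c1)
  min(1, sum(probs[probs <= p_obs * (1 + exact_tie_tol)]))
}

# Freeman-Halton extension: recursive enumeration over all r x c tables
# with the observed margins; log-probability of a table T under the
# multivariate hypergeometric null is
#   sum(lgamma(row!+1)) + sum(lgamma(col!+1)) - lgamma(n+1) - sum(lgamma(T+1))
fisher_exact_p_rxc <- function(counts, max_tables = 5e6) {
  rows <- rowSums(counts)
  cols <- colSums(counts)
  n <- sum(counts)
  log_const <- sum(lgamma(rows + 1)) + sum(lgamma(cols + 1)) - lgamma(n + 1)
  log_p_obs <- log_const - sum(lgamma(counts + 1))

  n_visited <- 0L
  p_total <- 0
  nr <- length(rows)
  nc <- length(cols)

  # fill row by row; within a row, cell by cell, keeping running margins
  recurse <- function(row_idx, col_left, acc_lgamma) {
    if (row_idx == nr) {
      # last row forced by the column margins
      n_visited <<- n_visited + 1L
      if (n_visited > max_tables) {
        stop("exact r x c enumeration exceeds ", max_tables,
             " tables; use policy = \"chisq\"", call. = FALSE)
      }
      log_p <- log_const - acc_lgamma - sum(lgamma(col_left + 1))
      if (log_p <= log_p_obs + log1p(exact_tie_tol)) {
        p_total <<- p_total + exp(log_p)
      }
      return(invisible())
    }
    fill_row <- function(col_idx, row_left, col_left, acc) {
      if (col_idx == nc) {
        if (row_left <= col_left[nc]) {
          col_left[nc] <- col_left[nc] - row_left
          recurse(row_idx + 1L, col_left, acc + lgamma(row_left + 1))
        }
        return(invisible())
      }
      for (x in 0:min(row_left, col_left[col_idx])) {
        col_left2 <- col_left
        col_left2[col_idx] <- col_left2[col_idx] - x
        fill_row(col_idx + 1L, row_left - x, col_left2, acc + lgamma(x + 1))
      }
    }
    fill_row(1L, rows[row_idx], col_left, acc_lgamma)
  }
  recurse(1L, cols, 0)
  min(1, p_total)
}

#' Test association in a contingency table
#'
#' Chooses between Pearson's chi-square test and Fisher's exact test the
#' way small-sample practice dictates (Cochran's rule): when any expected
#' cell count under independence is below 5 the two-sided exact test is
#' used, otherwise chi-square without continuity correction. Either test
#' can be forced via `policy`. The exact test is computed by complete
#' enumeration of tables with the observed margins (the Freeman-Halton
#' extension for tables larger than 2x2), with the two-sided p defined as
#' the total null probability of tables no more probable than the one
#' observed.
#'
#' Rows or columns whose margin is zero carry no information and are
#' dropped with a warning before testing.
#'
#' @param counts A matrix/table of nonnegative integer counts (at least
#'   2x2 after dropping empty margins), or a data frame of two columns of
#'   categorical observations to be cross-tabulated.
#' @param policy `"auto"` (Cochran's rule), `"fisher"`, or `"chisq"`.
#' @param correct Continuity correction for the 2x2 chi-square (default
#'   `FALSE`).
#' @return An `assoc_test` object: `p_value`, `test_used` (`FISHER_EXACT`
#'   or `CHI_SQUARE`), `statistic` and `df` (chi-square only),
#'   `odds_ratio` (2x2 only; the sample cross-product ratio), `expected`
#'   counts and the analyzed table. Use [tidy()] for a one-row summary.
#' @examples
#' association_test(matrix(c(0, 13, 49, 87), 2, 2))
#' @export
association_test <- function(counts, policy = c("auto", "fisher", "chisq"),
                             correct = FALSE) {
  policy <- match.arg(policy)
  if (is.data.frame(counts)) {
    stopifnot(ncol(counts) == 2)
    counts <- table(counts[[1]], counts[[2]])
  }
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be nonnegative integers", call. = FALSE)
  }
  keep_r <- rowSums(counts) > 0
  keep_c <- colSums(counts) > 0
  if (!all(keep_r) || !all(keep_c)) {
    warn("dropping zero-margin row(s)/column(s) from contingency table")
    counts <- counts[keep_r, keep_c, drop = FALSE]
  }
  if (nrow(counts) < 2 || ncol(counts) < 2) {
    stop("contingency table needs at least 2 informative rows and columns",
         call. = FALSE)
  }
  n <- sum(counts)
  expected <- outer(rowSums(counts), colSums(counts)) / n
  use_exact <- switch(policy,
    auto = any(expected < 5),
    fisher = TRUE,
    chisq = FALSE
  )
  if (use_exact) {
    p <- fisher_exact_p(counts)
    statistic <- NA_real_
    df <- NA_integer_
    test_used <- "FISHER_EXACT"
  } else {
    ct <- suppressWarnings(chisq.test(counts, correct = correct))
    p <- unname(ct$p.value)
    statistic <- unname(ct$statistic)
    df <- unname(ct$parameter)
    test_used <- "CHI_SQUARE"
  }
  odds_ratio <- if (all(dim(counts) == c(2, 2))) {
    (counts[1, 1] * counts[2, 2]) / (counts[1, 2] * counts[2, 1])
  } else {
    NA_real_
  }
  structure(
    list(p_value = p, test_used = test_used, statistic = statistic,
         df = df, odds_ratio = odds_ratio, expected = expected,
         observed = counts, n = n, policy = policy),
    class = "assoc_test"
  )
}

#' @export
print.assoc_test <- function(x, ...) {
  cat(sprintf("<assoc_test> %s: p = %.4g (n = %d, %dx%d table)\n",
              x$test_used, x$p_value, x$n, nrow(x$observed),
              ncol(x$observed)))
  if (!is.na(x$odds_ratio)) cat(sprintf("  odds ratio = %.3g\n", x$odds_ratio))
  invisible(x)
}

#' @rdname association_test
#' @param x An `assoc_test` object.
#' @param ... Unused.
#' @method tidy assoc_test
#' @export
tidy.assoc_test <- function(x, ...) {
  tibble::tibble(
    p.value = x$p_value,
    method = x$test_used,
    statistic = x$statistic,
    df = as.numeric(x$df),
    odds.ratio = x$odds_ratio,
    n = x$n
  )
}

#' @rdname association_test
#' @method glance assoc_test
#' @export
glance.assoc_test <- function(x, ...) tidy.assoc_test(x)
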