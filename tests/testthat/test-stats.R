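test_that("kappa is 1 for identical vectors and flags the degenerate case", {
  a <- c("x", "y", "z", "x", "y")
  k <- cohen_kappa(a, a, categories = c("x", "y", "z"))
  expect_equal(k$kappa, 1)
  expect_false(k$degenerate)

  same <- rep("x", 10)
  k2 <- cohen_kappa(same, same, categories = c("x", "y"))
  expect_equal(k2$kappa, 1)
  expect_true(k2$degenerate)
})

test_that("worked three-category example matches the double-summation oracle", {
  a <- c(0, 0, 1, 2, 2, 1)
  b <- c(0, 1, 1, 2, 1, 1)
  for (w in c("quadratic", "linear")) {
    got <- cohen_kappa(a, b, categories = 0:2, weighting = w)$kappa
    want <- oracle_weighted_kappa(a, b, 0:2,
                                  power = if (w == "quadratic") 2 else 1)
    expect_equal(got, want, tolerance = 1e-12)
  }
  # frozen oracle values
  expect_equal(cohen_kappa(a, b, 0:2, "quadratic")$kappa, 2 / 3,
               tolerance = 1e-12)
  expect_equal(cohen_kappa(a, b, 0:2, "linear")$kappa, 4 / 7,
               tolerance = 1e-12)
})

test_that("binary collapse makes weighted and unweighted kappa identical", {
  withr::local_seed(8)
  for (i in 1:20) {
    a <- sample(c("codel", "no_codel"), 38, replace = TRUE)
    b <- ifelse(runif(38) < 0.8, a, sample(c("codel", "no_codel"), 38,
                                           replace = TRUE))
    ks <- vapply(c("none", "linear", "quadratic"), function(w) {
      cohen_kappa(a, b, categories = c("no_codel", "codel"),
                  weighting = w)$kappa
    }, numeric(1))
    expect_equal(max(ks) - min(ks), 0)
  }
  # full agreement on the binary distinction gives kappa = 1
  a <- sample(c("codel", "no_codel"), 38, replace = TRUE)
  expect_equal(cohen_kappa(a, a, c("no_codel", "codel"))$kappa, 1)
})

test_that("kappa respects category order, never exceeds 1, survives relabeling", {
  withr::local_seed(9)
  a <- sample(0:2, 60, replace = TRUE)
  b <- sample(0:2, 60, replace = TRUE)
  k1 <- cohen_kappa(a, b, categories = 0:2)$kappa
  expect_lte(k1, 1)
  # order-preserving relabeling leaves kappa unchanged
  relabel <- c("low", "mid", "high")
  k2 <- cohen_kappa(relabel[a + 1], relabel[b + 1],
                    categories = relabel)$kappa
  expect_equal(k1, k2, tolerance = 1e-15)
  expect_error(cohen_kappa(a, b, categories = 0:1), "outside")
  expect_error(cohen_kappa(a, b[-1]), "equal length")
})

test_that("exact 2x2 p-values equal hypergeometric enumeration and fisher.test", {
  withr::local_seed(13)
  for (i in 1:100) {
    n <- sample(6:40, 1)
    cells <- as.vector(stats::rmultinom(1, n, prob = runif(4, 0.2, 1)))
    tab <- matrix(cells, 2, 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    res <- association_test(tab, policy = "fisher")
    expect_equal(res$p_value, oracle_fisher_2x2(tab), tolerance = 1e-12)
    expect_equal(res$p_value, stats::fisher.test(tab)$p.value,
                 tolerance = 1e-9)
  }
})

test_that("exact test is invariant to transposition and row swaps", {
  withr::local_seed(14)
  for (i in 1:25) {
    tab <- matrix(sample(1:15, 4, replace = TRUE), 2, 2)
    p <- association_test(tab, policy = "fisher")$p_value
    expect_equal(association_test(t(tab), policy = "fisher")$p_value, p,
                 tolerance = 1e-12)
    expect_equal(association_test(tab[2:1, ], policy = "fisher")$p_value, p,
                 tolerance = 1e-12)
  }
})

test_that("r x c enumeration matches fisher.test's Freeman-Halton values", {
  withr::local_seed(15)
  for (i in 1:15) {
    tab <- matrix(sample(0:8, 6, replace = TRUE), 3, 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    got <- association_test(tab, policy = "fisher")$p_value
    want <- stats::fisher.test(tab)$p.value
    expect_equal(got, want, tolerance = 1e-7)
  }
})

test_that("test policy follows Cochran's rule and can be forced", {
  big <- matrix(c(30, 20, 25, 35), 2, 2) # all expected counts >= 5
  small <- matrix(c(1, 9, 8, 2), 2, 2)
  expect_equal(association_test(big)$test_used, "CHI_SQUARE")
  expect_equal(association_test(small)$test_used, "FISHER_EXACT")
  expect_equal(association_test(big, policy = "fisher")$test_used,
               "FISHER_EXACT")
  expect_equal(association_test(small, policy = "chisq")$test_used,
               "CHI_SQUARE")
  expect_equal(association_test(matrix(c(5, 5, 5, 5), 2, 2))$p_value, 1)

  # sanity envelope: with healthy expected counts the chi-square
  # approximation tracks the exact test in the significant regime, and the
  # gap (driven by the discreteness of the exact null) vanishes as the
  # table scales up
  withr::local_seed(16)
  checked <- 0
  while (checked < 25) {
    tab <- matrix(sample(5:80, 4, replace = TRUE), 2, 2)
    if (any(outer(rowSums(tab), colSums(tab)) / sum(tab) < 5)) next
    p_ex <- association_test(tab, policy = "fisher")$p_value
    if (p_ex >= 0.05) next
    p_chi <- association_test(tab, policy = "chisq")$p_value
    expect_lt(abs(p_chi - p_ex), 0.025)
    checked <- checked + 1
  }
  base <- matrix(c(11, 7, 6, 12), 2, 2)
  gaps <- vapply(c(1, 4, 16), function(k) {
    abs(association_test(base * k, policy = "chisq")$p_value -
          association_test(base * k, policy = "fisher")$p_value)
  }, numeric(1))
  expect_true(all(diff(gaps) < 0))
  expect_lt(gaps[3], 0.01)

  expect_warning(
    dropped <- association_test(rbind(c(0, 0), c(3, 4), c(5, 2))),
    "zero-margin"
  )
  expect_equal(dim(dropped$observed), c(2L, 2L))
})

test_that("marker tables reproduce a naive group-by tally", {
  m <- fixture_manifest()
  cohort <- simulate_cohort(sim_config(n_samples = 80, seed = 21))
  calls <- call_codel(cohort$profiles, m, criteria = "ours")
  tabs <- build_marker_tables(cohort$markers, calls)
  expect_setequal(tabs$marker, c("histology", "idh", "tert", "atrx"))

  joined <- dplyr::inner_join(tibble::as_tibble(calls), cohort$markers,
                              by = "sample_id") |>
    dplyr::filter(call != "INDETERMINATE")
  codel <- joined$call == "COMPLETE_CODELETION"
  idh_tab <- tabs$table[tabs$marker == "idh"][[1]]
  expect_equal(
    unname(idh_tab["MUTANT", "Co-deletion"]),
    sum(codel & joined$idh_status == "MUTANT")
  )
  expect_equal(
    unname(idh_tab["WILDTYPE", "No co-deletion"]),
    sum(!codel & joined$idh_status == "WILDTYPE")
  )
  atrx_tab <- tabs$table[tabs$marker == "atrx"][[1]]
  expect_equal(unname(atrx_tab["Loss", "Co-deletion"]),
               sum(codel & joined$atrx_loss))
  expect_error(build_marker_tables(cohort$markers[0, ], calls), "no samples")
})

test_that("published cross-tabulations are consistent and reproduce the exact p", {
  tabs <- glioma_marker_crosstabs()
  # the three-region criteria block: 36 co-deleted of 150 by histology
  ours_hist <- tabs[tabs$criteria == "ours" & tabs$marker == "histology", ]
  expect_equal(sum(ours_hist$codel), 36)
  expect_equal(sum(ours_hist$codel) + sum(ours_hist$no_codel), 150)
  jeuken_atrx <- tabs[tabs$criteria == "jeuken" & tabs$marker == "atrx", ]
  res <- association_test(as.matrix(jeuken_atrx[, c("codel", "no_codel")]))
  expect_lt(abs(res$p_value - 0.0051), 0.0005)
})

test_that("locus correlation is rank-based on pairwise-complete values", {
  m <- fixture_manifest()
  withr::local_seed(23)
  profiles <- random_profiles(m, 10)
  rho <- locus_correlation(profiles, m)
  del_ids <- m$probe_id[m$region %in% deletion_regions]
  expect_equal(dim(rho), c(30, 30))
  expect_equal(unname(diag(rho)), rep(1, 30))
  expect_equal(rho, t(rho))

  # independent rank-then-Pearson recomputation for a probe pair
  wide <- tidyr::pivot_wider(tibble::as_tibble(profiles),
                             names_from = probe_id, values_from = ratio)
  x <- rank(wide[[del_ids[1]]])
  y <- rank(wide[[del_ids[5]]])
  expect_equal(rho[del_ids[1], del_ids[5]],
               sum((x - mean(x)) * (y - mean(y))) /
                 sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2)),
               tolerance = 1e-12)

  # duplicated locus and negated locus
  tab <- tibble::as_tibble(profiles)
  dup <- tab[tab$probe_id == del_ids[1], ]
  dup$probe_id <- del_ids[2]
  neg <- tab[tab$probe_id == del_ids[1], ]
  neg$probe_id <- del_ids[3]
  neg$ratio <- max(neg$ratio) + min(neg$ratio) - neg$ratio
  tab2 <- dplyr::bind_rows(
    tab[!tab$probe_id %in% del_ids[2:3], ], dup, neg
  )
  rho2 <- locus_correlation(mlpa_profiles(tab2, m), m)
  expect_equal(rho2[del_ids[1], del_ids[2]], 1)
  expect_equal(rho2[del_ids[1], del_ids[3]], -1)

  # constant locus yields missing correlations
  tab3 <- tab
  tab3$ratio[tab3$probe_id == del_ids[4]] <- 0.9
  rho3 <- locus_correlation(mlpa_profiles(tab3, m), m)
  expect_true(all(is.na(rho3[del_ids[4], setdiff(del_ids, del_ids[4])])))
  expect_error(locus_correlation(mlpa_profiles(tab[tab$sample_id %in%
    c("r0001", "r0002"), ], m), m), "at least 3")
})

test_that("tidy and glance summarize kappa and association objects", {
  k <- cohen_kappa(c(0, 1, 2, 1), c(0, 1, 2, 2), categories = 0:2)
  tk <- tidy(k)
  expect_s3_class(tk, "tbl_df")
  expect_equal(tk$kappa, k$kappa)
  expect_equal(tk$n, 4L)

  res <- association_test(matrix(c(1, 9, 8, 2), 2, 2))
  tr <- tidy(res)
  expect_equal(tr$p.value, res$p_value)
  expect_equal(tr$method, "FISHER_EXACT")
  expect_equal(glance(res), tr)
})
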