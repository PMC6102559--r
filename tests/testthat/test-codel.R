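test_that("region deleted fractions count informative loci at the threshold", {
  m <- fixture_manifest()
  subtel <- m$probe_id[m$region == "SUBTEL_1P"]
  p <- flat_profile(m, base = 1,
                    override = setNames(rep(0.5, 5), subtel[1:5])) |>
    mlpa_profiles(m)
  rf <- region_deleted_fraction(p, m, "SUBTEL_1P", threshold = 0.75)
  expect_equal(rf$n_deleted, 5L)
  expect_equal(rf$n_informative, 8L)
  expect_equal(rf$fraction, 0.625)

  # a ratio exactly at the threshold counts as deleted (<= convention)
  p2 <- flat_profile(m, override = setNames(0.75, subtel[1])) |>
    mlpa_profiles(m)
  expect_equal(
    region_deleted_fraction(p2, m, "SUBTEL_1P", 0.75)$n_deleted, 1L
  )

  # all loci of the region missing -> 0/0 with NaN fraction
  long <- flat_profile(m)
  long <- long[!long$probe_id %in% subtel, ]
  p3 <- mlpa_profiles(long, m)
  rf3 <- region_deleted_fraction(p3, m, "SUBTEL_1P", 0.75)
  expect_equal(rf3$n_informative, 0L)
  expect_true(is.nan(rf3$fraction))

  refs_only <- probe_manifest(
    tibble::as_tibble(m)[m$region == "REFERENCE", ]
  )
  expect_error(region_deleted_fraction(p, refs_only, "Q19"), "no probes")
})

test_that("three-region rule separates complete, segmental and no deletion", {
  m <- fixture_manifest()
  subtel <- m$probe_id[m$region == "SUBTEL_1P"]
  q19 <- m$probe_id[m$region == "Q19"]

  cases <- list(
    list(profile = flat_profile(m, base = 0.5), want = "COMPLETE_CODELETION"),
    list(profile = flat_profile(m, base = 1,
                                override = setNames(rep(0.5, 8), subtel)),
         want = "ISOLATED_SEGMENTAL_DELETION"),
    list(profile = flat_profile(m, base = 1), want = "NO_DELETION"),
    # subtelomeric + 19q majorities without the pericentromeric one stay
    # segmental: the complete call needs all three regions
    list(profile = flat_profile(m, base = 1,
                                override = setNames(rep(0.5, 19),
                                                    c(subtel, q19))),
         want = "ISOLATED_SEGMENTAL_DELETION")
  )
  for (cs in cases) {
    calls <- call_ours(mlpa_profiles(cs$profile, m), m)
    expect_equal(as.character(calls$call), cs$want)
  }
})

test_that("all-loci rule is defeated by a single surviving locus", {
  m <- fixture_manifest()
  del_ids <- m$probe_id[m$region %in% deletion_regions]
  p_all79 <- flat_profile(m, base = 0.79) |> mlpa_profiles(m)
  expect_equal(as.character(call_jeuken(p_all79, m)$call),
               "COMPLETE_CODELETION")

  one_up <- flat_profile(m, base = 0.5,
                         override = setNames(0.85, del_ids[17])) |>
    mlpa_profiles(m)
  expect_equal(as.character(call_jeuken(one_up, m)$call), "NO_DELETION")

  p_flat <- flat_profile(m, base = 1) |> mlpa_profiles(m)
  expect_equal(as.character(call_jeuken(p_flat, m)$call), "NO_DELETION")
})

test_that("per-arm majority rule needs strict majorities on both arms", {
  m <- fixture_manifest()
  ids_1p <- m$probe_id[m$region %in% c("SUBTEL_1P", "PARACEN_1P")]
  ids_19q <- m$probe_id[m$region == "Q19"]

  both <- flat_profile(m, base = 1, override = setNames(
    rep(0.5, 16), c(ids_1p[1:10], ids_19q[1:6])
  )) |> mlpa_profiles(m)
  expect_equal(as.character(call_natte(both, m)$call), "COMPLETE_CODELETION")

  # exactly 50% of informative 1p loci (9 of 18) is not a majority
  long <- flat_profile(m, base = 1, override = setNames(
    rep(0.5, 9 + 6), c(ids_1p[1:9], ids_19q[1:6])
  ))
  long <- long[long$probe_id != ids_1p[19], ] # 18 informative 1p loci
  half <- mlpa_profiles(long, m)
  expect_equal(as.character(call_natte(half, m)$call), "NO_DELETION")

  flat <- flat_profile(m, base = 1) |> mlpa_profiles(m)
  expect_equal(as.character(call_natte(flat, m)$call), "NO_DELETION")
})

test_that("batch calling returns one ordered row per sample and criteria", {
  m <- fixture_manifest()
  p <- flat_profile(m, "s1", base = 0.5) |> mlpa_profiles(m)
  calls <- call_codel(p, m)
  expect_equal(nrow(calls), 3)
  expect_equal(calls$criteria, c("ours", "jeuken", "natte"))

  cohort <- simulate_cohort(
    sim_config(n_samples = 12, purity = 1, noise_sigma = 0,
               artifact_rate = 0, class_mix = c(CODEL = 1, SEGMENTAL = 0,
                                                NORMAL = 0), seed = 2)
  )
  all_calls <- call_codel(cohort$profiles, m)
  expect_true(all(all_calls$call == "COMPLETE_CODELETION"))
  expect_equal(nrow(all_calls), 36)
})

test_that("calls agree with brute-force transcriptions of the three rules", {
  m <- fixture_manifest()
  withr::local_seed(99)
  profiles <- random_profiles(m, 300,
                              ratio_fun = function(k) runif(k, 0.4, 1.2))
  for (cr in c("ours", "jeuken", "natte")) {
    got <- call_codel(profiles, m, criteria = cr)
    want <- oracle_call(profiles, m, cr)
    expect_identical(as.character(got$call), want$call)
  }
})

test_that("sparse regions yield INDETERMINATE without failing the batch", {
  m <- fixture_manifest()
  subtel <- m$probe_id[m$region == "SUBTEL_1P"]
  long <- dplyr::bind_rows(
    flat_profile(m, "ok", base = 0.5),
    flat_profile(m, "sparse", base = 0.5) |>
      dplyr::filter(!probe_id %in% subtel[1:6]) # 2 informative subtel loci
  )
  p <- mlpa_profiles(long, m)
  expect_warning(calls <- call_ours(p, m), "INDETERMINATE")
  got <- setNames(as.character(calls$call), calls$sample_id)
  expect_equal(got[["sparse"]], "INDETERMINATE")
  expect_equal(got[["ok"]], "COMPLETE_CODELETION")
})

test_that("decreasing one ratio never softens the three-region call", {
  m <- fixture_manifest()
  severity <- c(NO_DELETION = 0, ISOLATED_SEGMENTAL_DELETION = 1,
                COMPLETE_CODELETION = 2)
  withr::local_seed(123)
  profiles <- random_profiles(m, 40,
                              ratio_fun = function(k) runif(k, 0.5, 1.1))
  tab <- tibble::as_tibble(profiles)
  base_calls <- call_ours(profiles, m)
  for (i in seq_len(40)) {
    sid <- sprintf("r%04d", i)
    rows <- which(tab$sample_id == sid)
    j <- sample(rows, 1)
    bumped <- tab
    bumped$ratio[j] <- bumped$ratio[j] * runif(1, 0.2, 0.9)
    new_call <- call_ours(mlpa_profiles(bumped[rows, ], m), m)
    expect_gte(
      severity[[as.character(new_call$call)]],
      severity[[as.character(base_calls$call[base_calls$sample_id == sid])]]
    )
  }
})

test_that("profiles wholly at or below 0.75 are complete by all three presets", {
  m <- fixture_manifest()
  withr::local_seed(17)
  for (rep in 1:10) {
    p <- random_profiles(m, 1, ratio_fun = function(k) runif(k, 0.2, 0.75))
    calls <- call_codel(p, m)
    expect_true(all(calls$call == "COMPLETE_CODELETION"))
  }
})

test_that("calls only change when a ratio lies between the two thresholds", {
  m <- fixture_manifest()
  withr::local_seed(31)
  profiles <- random_profiles(m, 50)
  tab <- tibble::as_tibble(profiles)
  t1 <- 0.75; t2 <- 0.8
  c1 <- call_codel(profiles, m, criteria = "ours", threshold = t1)
  c2 <- call_codel(profiles, m, criteria = "ours", threshold = t2)
  crossed <- tab |>
    dplyr::group_by(sample_id) |>
    dplyr::summarise(any_between = any(ratio > t1 & ratio <= t2))
  same <- as.character(c1$call) == as.character(c2$call)
  expect_true(all(same[!crossed$any_between]))
})

test_that("noise-free detection limit sits exactly at 50% purity", {
  m <- fixture_manifest()
  for (p in c(0.40, 0.45, 0.49, 0.50, 0.51, 0.75, 1.0)) {
    cohort <- simulate_cohort(
      sim_config(n_samples = 1, class_mix = c(CODEL = 1, SEGMENTAL = 0,
                                              NORMAL = 0),
                 purity = p, noise_sigma = 0, artifact_rate = 0, seed = 1)
    )
    call <- as.character(call_ours(cohort$profiles, m)$call)
    expect_equal(call == "COMPLETE_CODELETION", p >= 0.5,
                 label = sprintf("purity %.2f -> %s", p, call))
  }
})
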