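# Shared fixtures and independent oracles. Oracles are deliberately naive
# transcriptions, written before the implementation paths they check.

fixture_manifest <- function() manifest_default()

# profile with a constant ratio everywhere except chosen probes
flat_profile <- function(manifest, sample_id = "s1", base = 1,
                         override = numeric()) {
  ids <- manifest$probe_id[manifest$region %in% deletion_regions]
  ratio <- rep(base, length(ids))
  names(ratio) <- ids
  ratio[names(override)] <- override
  tibble::tibble(sample_id = sample_id, probe_id = ids, ratio = unname(ratio))
}

random_profiles <- function(manifest, n, ratio_fun = function(k) runif(k, 0.3, 1.3)) {
  ids <- manifest$probe_id[manifest$region %in% deletion_regions]
  purrr::map(seq_len(n), function(i) {
    tibble::tibble(
      sample_id = sprintf("r%04d", i),
      probe_id = ids,
      ratio = ratio_fun(length(ids))
    )
  }) |>
    dplyr::bind_rows() |>
    mlpa_profiles(manifest)
}

# ---- brute-force transcriptions of the three published cutoff rules ----
# operate on one sample's named ratio vector; missing probes simply absent

oracle_regions <- function(manifest) {
  list(
    subtel = manifest$probe_id[manifest$region == "SUBTEL_1P"],
    paracen = manifest$probe_id[manifest$region == "PARACEN_1P"],
    q19 = manifest$probe_id[manifest$region == "Q19"]
  )
}

oracle_ours <- function(ratios, manifest, t = 0.75, min_loci = 3) {
  rg <- oracle_regions(manifest)
  maj <- function(ids) {
    x <- ratios[names(ratios) %in% ids]
    if (length(x) < min_loci) return(NA)
    sum(x <= t) > length(x) / 2
  }
  m <- c(maj(rg$subtel), maj(rg$paracen), maj(rg$q19))
  if (anyNA(m)) return("INDETERMINATE")
  if (all(m)) return("COMPLETE_CODELETION")
  if (m[1]) return("ISOLATED_SEGMENTAL_DELETION")
  "NO_DELETION"
}

oracle_jeuken <- function(ratios, manifest, t = 0.8, min_loci = 3) {
  rg <- oracle_regions(manifest)
  x <- ratios[names(ratios) %in% c(rg$subtel, rg$paracen, rg$q19)]
  if (length(x) < min_loci) return("INDETERMINATE")
  if (all(x <= t)) "COMPLETE_CODELETION" else "NO_DELETION"
}

oracle_natte <- function(ratios, manifest, t = 0.75, min_loci = 3) {
  rg <- oracle_regions(manifest)
  x1p <- ratios[names(ratios) %in% c(rg$subtel, rg$paracen)]
  x19 <- ratios[names(ratios) %in% rg$q19]
  if (length(x1p) < min_loci || length(x19) < min_loci) return("INDETERMINATE")
  if (sum(x1p <= t) > length(x1p) / 2 && sum(x19 <= t) > length(x19) / 2) {
    "COMPLETE_CODELETION"
  } else {
    "NO_DELETION"
  }
}

oracle_call <- function(profiles, manifest, criteria) {
  oracle_fun <- switch(criteria, ours = oracle_ours, jeuken = oracle_jeuken,
                       natte = oracle_natte)
  tibble::as_tibble(profiles) |>
    dplyr::group_by(sample_id) |>
    dplyr::group_modify(function(df, key) {
      ratios <- setNames(df$ratio, df$probe_id)
      tibble::tibble(call = oracle_fun(ratios, manifest))
    }) |>
    dplyr::ungroup()
}

# ---- exact-test oracle: choose()-based hypergeometric enumeration ----
oracle_fisher_2x2 <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  n <- r1 + r2
  prob_a <- function(a) {
    choose(r1, a) * choose(r2, c1 - a) / choose(n, c1)
  }
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- vapply(support, prob_a, numeric(1))
  p_obs <- prob_a(tab[1, 1])
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# ---- weighted-kappa oracle: closed-form double summation ----
oracle_weighted_kappa <- function(a, b, categories, power = 2) {
  k <- length(categories)
  n <- length(a)
  obs <- matrix(0, k, k)
  for (i in seq_len(n)) {
    r <- match(a[i], categories); c <- match(b[i], categories)
    obs[r, c] <- obs[r, c] + 1
  }
  p <- obs / n
  num <- 0; den <- 0
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      w <- abs(i - j)^power
      num <- num + w * p[i, j]
      den <- den + w * sum(p[i, ]) * sum(p[, j])
    }
  }
  1 - num / den
}
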