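sim_classes <- c("CODEL", "SEGMENTAL", "NORMAL")

# per-class marker-state probabilities; calibrated to the marker margins of
# the published 150-case cohort (co-deleted tumors oligodendroglial-biased,
# IDH/TERT mutant, ATRX retained; non-co-deleted tumors astrocytic-biased)
default_mutation_model <- function() {
  list(
    CODEL = list(
      histology = c(ASTROCYTIC = 0.03, MIXED = 0.47, OLIGODENDROGLIAL = 0.50),
      p_idh = 0.88, p_tert = 0.94, p_atrx_loss = 0.03,
      p_tp53 = 0.30, p_egfr = 0.60
    ),
    SEGMENTAL = list(
      histology = c(ASTROCYTIC = 0.62, MIXED = 0.28, OLIGODENDROGLIAL = 0.10),
      p_idh = 0.55, p_tert = 0.38, p_atrx_loss = 0.45,
      p_tp53 = 0.55, p_egfr = 0.60
    ),
    NORMAL = list(
      histology = c(ASTROCYTIC = 0.57, MIXED = 0.33, OLIGODENDROGLIAL = 0.10),
      p_idh = 0.45, p_tert = 0.40, p_atrx_loss = 0.40,
      p_tp53 = 0.50, p_egfr = 0.60
    )
  )
}

#' Configuration for the synthetic MLPA cohort simulator
#'
#' Defaults emulate the published 150-case diffuse-glioma cohort: class
#' mix 24% complete co-deletion, 32% isolated segmental 1p deletion, 44%
#' no deletion; tumor purity uniform on 0.6--1 (surgical glioma specimens
#' selected for high tumor content); multiplicative log-normal probe noise
#' with sigma 0.05 (typical MLPA inter-probe variability); FFPE artifact
#' loci appearing at an average of `artifact_rate` spuriously deleted loci
#' per sample at the depth of a purity-0.8 hemizygous loss.
#'
#' @param n_samples Cohort size (default 150).
#' @param class_mix Named proportions over `CODEL`, `SEGMENTAL`, `NORMAL`;
#'   must sum to 1.
#' @param purity Tumor cell fraction: a single value in (0, 1] or a
#'   length-2 range sampled uniformly per sample.
#' @param noise_sigma Standard deviation of log-scale multiplicative
#'   probe noise (>= 0).
#' @param artifact_rate Poisson mean count of artifact loci per sample
#'   (>= 0), drawn uniformly over both arms' deletion-region probes.
#' @param artifact_purity Apparent purity of artifact losses; their
#'   expected ratio is `1 - artifact_purity/2` (default 0.8 -> 0.6).
#' @param mutation_model Per-class marker probabilities; see
#'   `codelcall:::default_mutation_model` for the expected shape.
#' @param seed Integer seed; identical config + seed reproduces the cohort
#'   byte-for-byte.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_samples = 150,
                       class_mix = c(CODEL = 0.24, SEGMENTAL = 0.32,
                                     NORMAL = 0.44),
                       purity = c(0.6, 1),
                       noise_sigma = 0.05,
                       artifact_rate = 0.5,
                       artifact_purity = 0.8,
                       mutation_model = default_mutation_model(),
                       seed = 1L) {
  stopifnot(n_samples >= 1)
  if (is.null(names(class_mix))) names(class_mix) <- sim_classes
  stopifnot(setequal(names(class_mix), sim_classes))
  if (abs(sum(class_mix) - 1) > 1e-8) {
    stop("class_mix must sum to 1", call. = FALSE)
  }
  if (any(purity <= 0) || any(purity > 1) || !length(purity) %in% 1:2) {
    stop("purity must be one value or a range within (0, 1]", call. = FALSE)
  }
  stopifnot(noise_sigma >= 0, artifact_rate >= 0,
            artifact_purity > 0, artifact_purity <= 1)
  structure(
    list(n_samples = as.integer(n_samples),
         class_mix = class_mix[sim_classes],
         purity = purity, noise_sigma = noise_sigma,
         artifact_rate = artifact_rate, artifact_purity = artifact_purity,
         mutation_model = mutation_model, seed = as.integer(seed)),
    class = "sim_config"
  )
}

deleted_probe_ids <- function(true_class, manifest) {
  switch(true_class,
    CODEL = region_probe_ids(manifest, deletion_regions),
    SEGMENTAL = region_probe_ids(manifest, "SUBTEL_1P"),
    NORMAL = character()
  )
}

#' Simulate one MLPA profile from a truth record
#'
#' A hemizygous loss present in a tumor-cell fraction `purity` among
#' diploid normal cells gives an expected copy-number ratio of
#' `1 - purity/2`; unaffected loci have expectation 1. `CODEL` samples
#' lose every 1p and 19q deletion-region locus, `SEGMENTAL` samples the
#' subtelomeric 1p loci only. Artifact loci are set to the artifact
#' expectation, then every deletion-region ratio is multiplied by
#' `exp(N(0, noise_sigma^2))`. Reference and mutation probes are appended:
#' reference probes at 1 with noise, mutation probes near 0 (or at 0.5
#' scaled by purity when the truth carries an IDH1-R132H-detectable
#' mutation and the manifest has a matching probe).
#'
#' Uses the current RNG state; [simulate_cohort()] seeds it from the
#' config.
#'
#' @param truth One-row truth record (see [simulate_cohort()]):
#'   `sample_id`, `true_class`, `purity`, `artifact_loci` (list column),
#'   `idh_variant`.
#' @param manifest A `probe_manifest`.
#' @param config A `sim_config`.
#' @return A long tibble `sample_id`, `probe_id`, `ratio`.
#' @export
simulate_profile <- function(truth, manifest, config) {
  del <- deleted_probe_ids(truth$true_class, manifest)
  artifacts <- truth$artifact_loci[[1]]
  probes <- tibble::as_tibble(manifest)

  expected <- rep(1, nrow(probes))
  expected[probes$probe_id %in% del] <- 1 - truth$purity / 2
  art <- probes$probe_id %in% setdiff(artifacts, del)
  expected[art] <- 1 - config$artifact_purity / 2

  is_mut_probe <- probes$region == "MUTATION"
  expected[is_mut_probe] <- 0
  if (!is.na(truth$idh_variant)) {
    hit <- is_mut_probe &
      normalize_variant(probes$target_variant) ==
        normalize_variant(truth$idh_variant)
    hit[is.na(hit)] <- FALSE
    # heterozygous mutant allele in the tumor fraction: half the diploid dose
    expected[hit] <- 0.5 * truth$purity
  }

  noise <- exp(rnorm(nrow(probes), 0, config$noise_sigma))
  tibble::tibble(
    sample_id = truth$sample_id,
    probe_id = probes$probe_id,
    ratio = expected * noise
  )
}

#' Simulate a truth-labelled MLPA cohort
#'
#' Draws per-sample true classes, purities, FFPE artifact loci and marker
#' states from [sim_config()], then generates every profile with
#' [simulate_profile()]. Fully reproducible from `config$seed`.
#'
#' @param config A `sim_config`.
#' @param manifest A `probe_manifest` (default [manifest_default()]).
#' @return A list of class `mlpa_cohort`:
#'   * `profiles` — `mlpa_profiles` tibble for all samples;
#'   * `truth` — `sample_id`, `true_class`, `purity`, `artifact_loci`
#'     (list column), `idh_variant`;
#'   * `markers` — per-case marker tibble (`histology`, `idh_status`,
#'     `tert_status`, `atrx_loss`, `tp53_expression`, `egfr_expression`).
#' @examples
#' cohort <- simulate_cohort(sim_config(n_samples = 20, seed = 7))
#' table(cohort$truth$true_class)
#' @export
simulate_cohort <- function(config, manifest = manifest_default()) {
  stopifnot(inherits(config, "sim_config"))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)

  n <- config$n_samples
  ids <- sprintf("S%04d", seq_len(n))
  classes <- sample(sim_classes, n, replace = TRUE, prob = config$class_mix)
  purity <- if (length(config$purity) == 1) {
    rep(config$purity, n)
  } else {
    runif(n, config$purity[1], config$purity[2])
  }
  del_pool <- region_probe_ids(manifest, deletion_regions)
  n_art <- pmin(rpois(n, config$artifact_rate), length(del_pool))
  artifact_loci <- purrr::map(n_art, function(k) {
    sort(sample(del_pool, k))
  })

  mm <- config$mutation_model
  draw <- function(cls, field) {
    vapply(cls, function(cl) mm[[cl]][[field]], numeric(1))
  }
  histology <- vapply(classes, function(cl) {
    sample(names(mm[[cl]]$histology), 1, prob = mm[[cl]]$histology)
  }, character(1))
  idh_mut <- runif(n) < draw(classes, "p_idh")
  # most IDH-mutant gliomas carry R132H; the rest split over rarer alleles
  idh_variant <- ifelse(
    idh_mut,
    sample(c("IDH1 R132H", "IDH1 R132C", "IDH2 R172K"), n, replace = TRUE,
           prob = c(0.90, 0.05, 0.05)),
    NA_character_
  )
  markers <- tibble::tibble(
    sample_id = ids,
    histology = histology,
    idh_status = ifelse(idh_mut, "MUTANT", "WILDTYPE"),
    tert_status = ifelse(runif(n) < draw(classes, "p_tert"),
                         "MUTANT", "WILDTYPE"),
    atrx_loss = runif(n) < draw(classes, "p_atrx_loss"),
    tp53_expression = runif(n) < draw(classes, "p_tp53"),
    egfr_expression = runif(n) < draw(classes, "p_egfr")
  )
  truth <- tibble::tibble(
    sample_id = ids, true_class = classes, purity = purity,
    artifact_loci = artifact_loci, idh_variant = idh_variant
  )
  profiles <- purrr::map(seq_len(n), function(i) {
    simulate_profile(truth[i, ], manifest, config)
  }) |>
    dplyr::bind_rows() |>
    mlpa_profiles(manifest)

  structure(
    list(profiles = profiles, truth = truth, markers = markers,
         config = config),
    class = "mlpa_cohort"
  )
}

#' @export
print.mlpa_cohort <- function(x, ...) {
  cat(sprintf("<mlpa_cohort> %d samples (seed %d): ",
              x$config$n_samples, x$config$seed))
  print(table(x$truth$true_class))
  invisible(x)
}

call_to_class <- c(
  COMPLETE_CODELETION = "CODEL",
  ISOLATED_SEGMENTAL_DELETION = "SEGMENTAL",
  NO_DELETION = "NORMAL",
  INDETERMINATE = "INDETERMINATE"
)

#' Score calls against simulation truth
#'
#' Maps calls onto the simulator's class labels
#' (`COMPLETE_CODELETION -> CODEL`,
#' `ISOLATED_SEGMENTAL_DELETION -> SEGMENTAL`, `NO_DELETION -> NORMAL`)
#' and tallies a per-class confusion summary. `INDETERMINATE` calls are
#' counted separately and enter neither sensitivity nor specificity.
#'
#' @param calls A `codel_calls` tibble for a single criteria (filter
#'   first when several were run).
#' @param truth The `truth` tibble of an [simulate_cohort()] result.
#' @return A tibble with one row per class: `class`, `n_true`,
#'   `n_called`, `tp`, `fn`, `fp`, `tn`, `n_indeterminate`,
#'   `sensitivity`, `specificity`; overall accuracy over determinate
#'   calls in the `"accuracy"` attribute, the full confusion matrix in
#'   `"confusion"`.
#' @export
evaluate_recovery <- function(calls, truth) {
  calls <- tibble::as_tibble(calls)
  if (length(unique(calls$criteria)) > 1) {
    stop("evaluate_recovery expects calls from a single criteria; got: ",
         paste(unique(calls$criteria), collapse = ", "), call. = FALSE)
  }
  joined <- dplyr::inner_join(
    dplyr::select(calls, "sample_id", "call"),
    dplyr::select(tibble::as_tibble(truth), "sample_id", "true_class"),
    by = "sample_id"
  )
  if (nrow(joined) == 0) stop("calls and truth share no samples", call. = FALSE)
  joined$called_class <- call_to_class[as.character(joined$call)]

  confusion <- table(
    truth = factor(joined$true_class, levels = sim_classes),
    called = factor(joined$called_class,
                    levels = c(sim_classes, "INDETERMINATE"))
  )
  determinate <- joined$called_class != "INDETERMINATE"
  metrics <- purrr::map(sim_classes, function(cl) {
    is_true <- joined$true_class == cl
    is_called <- joined$called_class == cl
    tp <- sum(is_true & is_called & determinate)
    fn <- sum(is_true & !is_called & determinate)
    fp <- sum(!is_true & is_called & determinate)
    tn <- sum(!is_true & !is_called & determinate)
    tibble::tibble(
      class = cl, n_true = sum(is_true), n_called = sum(is_called),
      tp = tp, fn = fn, fp = fp, tn = tn,
      n_indeterminate = sum(is_true & !determinate),
      sensitivity = ifelse(tp + fn > 0, tp / (tp + fn), NA_real_),
      specificity = ifelse(tn + fp > 0, tn / (tn + fp), NA_real_)
    )
  }) |>
    dplyr::bind_rows()
  attr(metrics, "accuracy") <-
    sum(joined$true_class == joined$called_class & determinate) /
    sum(determinate)
  attr(metrics, "confusion") <- confusion
  metrics
}
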