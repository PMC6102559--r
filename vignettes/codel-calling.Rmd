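---
title: "Scoring the 1p/19q co-deletion from MLPA probe ratios"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring the 1p/19q co-deletion from MLPA probe ratios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codelcall)
library(dplyr)
```

## The measurement and its model

MLPA reports, for each probe *i*, a normalized ratio $r_i \ge 0$ with
$r_i = 1$ at diploid copy number. For a hemizygous (one-of-two-copies)
loss present in a tumor-cell fraction $p$ of an otherwise diploid
specimen, the expected ratio is

$$\mathrm{E}[r_i] = (1 - p) \cdot 1 + p \cdot \tfrac{1}{2} = 1 - \frac{p}{2},$$

the single most important identity in the package: it links every
threshold on $r$ to a tumor-purity detection limit. At the conventional
deletion threshold $t = 0.75$, a co-deleted sample is detectable only
when $1 - p/2 \le 0.75$, i.e. $p \ge 0.5$. Specimens below ~50% tumor
content are structurally unable to produce a complete-co-deletion call,
whatever the caller does; the package exposes `threshold = 0.80`
(detection limit $p \ge 0.4$) as the documented fallback for low-purity
material, at the cost of specificity.

`normalize_peaks()` converts raw capillary-electrophoresis peak heights
into this ratio scale with the standard two-step scheme: each peak is
divided by the median peak of the sample's `REFERENCE` probes
(intra-sample), then by the mean of those values over the designated
non-tumor reference samples (inter-sample, per probe). The scheme is
scale-invariant per sample, which is also a property test. The exact
normalization arithmetic is not standardized across laboratories; the
median/mean two-step used here is the common choice and anything already
on the ratio scale can be loaded directly with `read_profiles()`.

## The three scoring rules

All three rules count a locus as deleted when $r_i \le t$, boundary
inclusive — the operational definitions in the source literature use
$\le$, and the difference only matters for ratios exactly at $t$
(which the purity algebra makes a meaningful point: $p = 0.5$ at
$t = 0.75$). "Majority" is everywhere *strictly greater than half* of the
informative (non-missing) loci, so ties never call.

* **Three-region majority** (`ours`): majorities required separately in
  subtelomeric 1p (1p35–1pter), pericentromeric 1p (the rest of the arm)
  and 19q. A subtelomeric majority alone yields
  `ISOLATED_SEGMENTAL_DELETION`. Splitting 1p in two is the point of the
  rule: the segmental 1p36 deletion of astrocytic tumors produces a
  subtelomeric majority but leaves the pericentromeric region intact,
  while a whole-arm loss takes all three regions with it.
* **All-loci** (`jeuken`, $t = 0.8$): every informative deletion-region
  locus must be at or below threshold. Maximally specific, fragile to a
  single noisy locus.
* **Per-arm majority** (`natte`): $> 50\%$ of informative loci per arm,
  1p pooled. Sensitive, but a strong segmental 1p deletion plus a few
  low 19q loci can reach both majorities — the documented specificity
  failure mode of pooled-arm scoring (subtelomeric 1p and 19q copy
  numbers are substantially correlated in real cohorts, which
  `locus_correlation()` quantifies).

Segmental labelling ignores 19q on purpose: the segmental class is
defined by the subtelomeric-versus-rest-of-1p contrast, and per-region
deleted fractions are always present in the output tibble, so 19q-only
losses remain visible even though no categorical label claims them. The
subtelomeric boundary follows the operational 1p35–1pter definition; a
1p34.2 boundary has also been described for recurrent partial deletions,
and users who prefer it can relabel the manifest — every caller reads
region membership from the manifest, never from hard-coded probe lists.

Missing ratios are excluded from every denominator. A region (or pooled
scoring unit) with fewer than `min_loci = 3` informative loci makes the
call `INDETERMINATE` rather than letting a majority over one or two loci
decide; the source rules are silent on missing data, and three is the
smallest count for which "strict majority" is distinguishable from a
single noisy probe.

## Mutation calling and IDH integration

Direct sequencing scores a hotspot as mutant when the mutant peak is at
least 25% of the wild-type peak (inclusive); the rule is a pure ratio, so
it is scale-invariant, and a failed trace (both peaks zero) is
`INDETERMINATE`, not an error. Raw peak heights are compared — background
subtraction, if any, is upstream of this package. MLPA mutation-specific
probes only ligate on the mutant allele, so wild-type DNA yields
essentially zero signal; any normalized value at or above
`presence_threshold = 0.1` is called mutant. That threshold is not given
by the source literature; 0.1 sits well below the ~0.3 expected for a
heterozygous mutation at 60% purity and well above reference-scale noise,
and it is exposed as configuration.

`integrate_idh()` encodes the assay hierarchy: the R132H antibody is
treated as authoritative for its one variant (immunopositivity wins even
over wild-type sequencing, flagged `LOW_FRACTION` when every molecular
assay missed it), then sequencing (nested PCR counts), then the MLPA
probe (flagged `SEQ_DISCORDANT` against informative wild-type
sequencing). Conflicting variant identities between mutant assays flag
`VARIANT_CONFLICT` without demoting the consensus. The integration is
order-independent and never returns wild-type over any mutant assay.

## Statistics

`association_test()` selects between Pearson's chi-square (no continuity
correction by default) and the two-sided Fisher exact test by Cochran's
rule: any expected cell count below 5 forces the exact test. This is the
operational reading of choosing the test "by the number of observations",
and the zero-cell tables that strict criteria produce require the exact
test anyway. The exact p is computed by complete enumeration of tables
with the observed margins — hypergeometric for 2×2, the Freeman–Halton
multivariate extension for r×c — under the point-probability two-sided
convention: the total null probability of all tables no more probable
than the observed one (ties compared with a 10⁻⁷ relative tolerance).
Two-sided conventions differ between implementations, which is why the
definition is spelled out here; this one matches `stats::fisher.test`.

One honest caveat found while property-testing: the folklore that
chi-square and exact p agree within 0.01 once expected counts reach 5 is
false under this convention — the gap decays only like $n^{-1/2}$ and
still exceeds 0.01 at $n = 20{,}000$ for mid-range p. The test suite
asserts what actually holds: agreement within 0.025 in the significant
regime (exact $p < 0.05$) and a monotonically vanishing gap as a fixed
table is scaled up.

`cohen_kappa()` computes chance-corrected agreement
$\kappa = (P_o - P_e)/(1 - P_e)$ with disagreement weights $|i-j|$
(linear), $(i-j)^2$ (quadratic, the default, as is conventional for
ordered categories) or 0/1 (unweighted) over an explicit category order —
for co-deletion concordance, no deletion (0) < segmental (1) < complete
(2). With two categories all schemes coincide, so binary-collapse results
are weighting-independent. When every pair sits in one identical category
$P_e = 1$ and $\kappa$ is undefined; the package reports 1 with a
`degenerate` flag rather than `NaN`.

## The simulator: what it emulates, what it does not

`simulate_cohort()` draws, per sample: a true class (default mix 24%
co-deleted / 32% segmental / 44% normal, the composition of the 150-case
cohort the package's cross-tabulations come from), a tumor purity
(default uniform on 0.6–1, reflecting neurosurgical specimens selected
for tumor content), FFPE artifact loci (Poisson count, default mean 0.5
per sample, placed uniformly over both arms at the depth of a purity-0.8
loss, i.e. expected ratio 0.6), and marker states (per-class categorical
draws calibrated to the published cohort's margins: co-deleted tumors
oligodendroglial-biased, IDH/TERT-mutant, ATRX-retained). Ratios are the
class expectation times $e^{\varepsilon}$,
$\varepsilon \sim N(0, \sigma^2)$ with $\sigma = 0.05$ — multiplicative
log-normal noise because ratios are positive and probe variance scales
with signal. Everything is reproducible byte-for-byte from
`sim_config(seed=)`.

Deliberate simplifications, hence what passing tests do *not* show about
real data: losses are all-or-none per region (no subclonality, no focal
events within a region); probe noise is i.i.d. (no probe-specific bias,
no GC/fixation covariates); the inter-locus correlation that drives the
per-arm rule's real-world false positives is absent, so the simulator
cannot reproduce that failure mode — it is exercised instead through the
published cross-tabulations; artifact loci are independent draws, whereas
fixation artifacts may cluster. Cohort-level published figures that
depend on the authors' per-case data (the 36/48/66 split, the repeat
κ = 0.87, marker frequencies) are emulated qualitatively, not asserted.

## Numerical and design choices

* Boundary conventions: deleted at $r \le t$; mutant at
  mut/wt $\ge 0.25$; mutation-probe present at $\ge$ threshold. All
  inclusive, all configurable.
* Problem sizes used by the tests and the acceptance script (chosen as
  comfortable for the statistics they check): 1,000 random profiles for
  caller/oracle equivalence, 500-sample cohorts for recovery, 300 for
  artifact false positives, 200 random tables for the exact-test oracle,
  10⁴ peak pairs for scale invariance.
* Recovery on the default simulator settings is essentially perfect
  (≥ 99% at purity ≥ 0.7, σ = 0.05) because noise-free deleted ratios at
  those purities sit ≥ 5σ from the threshold; this validates the
  machinery, not clinical performance.
* Ties in reporting order: samples sort by mean deletion-region ratio,
  then lexicographically by id; calls tabulate samples before criteria.
* The 17-digit decimal round-trip for profile files is deliberate:
  ratios re-read from disk are bit-identical, so calls never change
  across a write/read cycle.
* `INDETERMINATE` never fails a batch; it is warned about, reported, and
  excluded from kappa and marker tables.

## Known limitations

No FISH/CISH, array, or NGS segmentation; no clinical report text or WHO
integrated diagnosis; IHC enters as externally scored booleans; the
sequencing caller consumes peak heights, not trace files. The bundled
manifest uses placeholder probe ids with a plausible gene/band layout —
real kit definition files should be loaded with `read_manifest()` for
production use.
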