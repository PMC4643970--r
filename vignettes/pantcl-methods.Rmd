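---
title: "Methods: models, parameters and numerical conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and numerical conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pantcl)
```

`pantcl` re-implements, as explicit and testable functions, the analysis
chain used to derive a shared gene signature across five mature T-cell
lymphoma subtypes and to characterize the CAV1-high tumour
microenvironment. This vignette documents the statistical models, the
parameters that matter, the numerical conventions, and what the synthetic
cohorts do and do not establish.

## The expression model behind the simulator

Expression is simulated on the log2 scale and exponentiated, so signal is
strictly positive (MAS5-like arbitrary linear units) and planted effects
are multiplicative fold-changes:

$$\log_2 X_{pj} = \beta_{g(p)} + \delta_{g(p),s(j)} + o_p + \varepsilon_{pj},
\qquad \varepsilon_{pj} \sim N(0, \sigma^2)$$

with per-gene baseline $\beta_g \sim N(\mu_0, \tau^2)$, subtype effect
$\delta_{g,s}$ (zero for healthy CD4/CD8 samples), per-probe offset $o_p$,
and i.i.d. noise. Signed linear fold-changes $f$ translate to additive
effects $\delta = \log_2 f$ (up) or $-\log_2(-f)$ (down).

Key defaults of `sim_config()`:

| parameter | default | meaning |
|---|---|---|
| `n_healthy_cd4` + `n_healthy_cd8` | 26 + 26 | 52 healthy controls |
| `n_per_subtype` | 43/45/13/8/78 | AITL/ALCL/ATLL/HSTL/PTCL-NOS (187 biopsies) |
| `n_genes` | 2000 | planted + null genes |
| `probes_per_gene_range` | [1, 3] | probes per gene symbol |
| `baseline_log2_mean`, `baseline_log2_sd` | 7, 1.2 | log2 units; MAS5-like signal around a few hundred |
| `noise_log2_sd` | 0.5 | within-group log2 SD; no published within-group variance exists for this design, so a mid-range microarray value was fixed once |
| `planted_signature` | 21 genes | the published per-subtype fold-change table |
| `cav1_high_prob` | .77/.47/.85/.75/.69 | per-subtype CAV1-High mixture weights |
| `cav1_high_log2_shift` | 5 | CAV1-High samples sit 2^5 above the healthy baseline |
| `n_tme_genes`, `tme_coupling_r` | 30, 0.6 | CAV1-coupled microenvironment block |
| `tme_positive_frac` | 2/3 | share positively coupled, matching the observed two-thirds up-fraction in the High-vs-Low comparison |
| `panel_size` | 217 | emitted T-cell compartment panel |

Design points worth calling out:

* **CAV1 is bimodal, not a fixed shift.** When `cav1_high_prob` is
  supplied, each malignant sample is independently CAV1-High (log2 shift
  above the healthy baseline) with its subtype's probability; Low samples
  draw from the healthy distribution. This is the only way to make
  threshold stratification a recoverable planted truth. With
  `cav1_high_prob = NULL`, CAV1 follows its fold-change entry like every
  other planted gene — that configuration is what makes the "generating
  group mean equals baseline × fold-change exactly at zero noise"
  property testable for CAV1 itself. The two behaviours are mutually
  exclusive by construction.
* **Exactly one probe per gene is maximal.** One probe per gene has
  offset 0; the others draw offsets from U(−2, −0.25), so the maximal
  probe is unique with probability one and recorded in the truth object —
  this makes probe collapsing truth-checkable.
* **Coupled microenvironment genes.** A coupled gene's log2 signal is
  $\pm(z_j - \bar z) + N(0, s^2)$ around its own baseline, where $z_j$ is
  the sample's *measured* CAV1 log2 signal and
  $s = \mathrm{sd}(z)\sqrt{1/r^2 - 1}$ calibrates the Pearson correlation
  to the target $r$ over malignant samples. Coupled genes are excluded
  from the compartment panel: the panel represents T-cell biology while
  the coupled block represents the microenvironment, and keeping them
  apart also keeps the signature's null false-positive rate
  interpretable.
* **Healthy CD4 and CD8 share generating means** — the analyses pool them
  as one control group, so no CD4/CD8 difference is planted.

What the simulator does *not* emulate: array batch effects, normalization
artifacts, probe-level .CEL structure, heavy-tailed or gene-dependent
variance, correlated null genes, and clinical covariates. Passing tests
on this generator demonstrate that the statistical machinery recovers
known truth under its stated model; they do not certify performance on
real compendia, where between-study heterogeneity dominates.

## Class comparison

Per-gene statistics are classical pooled-variance two-sample t statistics
on log2 signal. The pooled test was chosen as the default (Welch is
available via `var_equal = FALSE`) for three reasons: it is the
class-comparison convention of the microarray tools this pipeline
mirrors; the generating model is homoscedastic, so pooling is exact; and
with cohorts as unbalanced as 8 vs 52 the Welch statistic's permutation
distribution acquires tails so heavy that jointly requiring p < 0.001 and
FDR < 0.001 becomes unattainable for fold-changes below about 2
regardless of the permutation budget.

Fold-changes are ratios of linear-scale geometric means with the signed
convention (−(h/m) below one), so |FC| ≥ 1 always; the geometric mean on
the linear scale is the arithmetic mean on the log scale, keeping the
two reported quantities consistent.

The permutation test is *multivariate*: each of the B label permutations
is applied to all genes jointly, preserving gene–gene correlation, and
p = (1 + #{|t*| ≥ |t|})/(B + 1) with add-one smoothing so p ≥ 1/(B+1).
When the number of distinct label assignments is at most B the test
enumerates all of them (observed assignment included) and drops the
smoothing. Duplicate random permutations are not tracked — at B = 1000
and 40+ samples the bias is negligible. Degenerate genes (constant across
all samples) are flagged and assigned t = 0, p = 1 rather than erroring.
Comparisons |t*| ≥ |t| use a relative tolerance of 1e−8 so that the
observed assignment always counts against itself in exact enumeration.

**Choosing B.** The default `n_permutations = 1000` matches the reference
setting and is adequate for per-gene p-values at the 0.001 level. It is
*not* adequate when BH q-values must also clear 0.001: the smallest
achievable p is 1/(B+1), so over an m-gene panel the k top genes can
never have q below m/(k(B+1)) — at B = 1000, m = 217, k = 21 that floor
is ≈ 0.01, ten times the threshold, and no gene whatsoever can pass.
The packaged signature analyses therefore use B = 50,000, which puts the
floor near 2 × 10⁻⁴ while keeping a five-subtype run under a minute.

**Korn step-down.** For control of the proportion of false discoveries at
level γ with confidence 1 − α, genes are rejected in decreasing order of
|t|, allowing u(r) = ⌊γr⌋ false discoveries among the first r rejections.
The critical value at rank r is the (1 − α) quantile, across permutation
replicates (observed labelling included), of the (u+1)-th largest |t*|
over the genes excluding the r − u − 1 most significant (which may be
true positives); ranks where ⌊γr⌋ increments are rejected automatically,
and the first failed comparison stops the procedure. For u = 0 the
per-rank reference maxima are computed once as suffix maxima, making the
procedure linear in practice.

## Signature intersection

A gene is pan-up iff significant with FC > 1 in every subtype (pan-down
analogously with FC < −1); relaxed membership needs one consistent
direction in ≥ `min_support` (default 3) subtypes. Genes significant up
in some subtypes and down in others are excluded from both lists and
reported as direction-conflicted — shared lists are only meaningful with
a direction attached. The published workflow compiled its shared list
manually; the deterministic intersection is the only reproducible
reading. Expect recovery of the planted signature to be imperfect at the
defaults: four of the 21 genes carry a sub-2 fold-change in at least one
small subtype (HSTL n = 8, ATLL n = 13), where the joint
p < 0.001 & q < 0.001 criterion has intrinsically limited power, so
individual cohorts typically recover 18–21 of 21 with no direction
errors.

## Top-scoring pairs

Δ scores every unordered candidate pair from the within-sample ordering
only, making the classifier invariant to any monotone within-sample
transformation. Within-sample ties count as "not (i < j)"; Δ ties break
by the secondary rank score Γ (between-class gap of the mean
within-sample rank difference), then lexicographically — all ties are
thus deterministic. A single top pair is used (no k-TSP voting), matching
the single published CAV1–BCL10 rule. Evaluation defaults to leave-one-out
cross-validation with in-fold pair reselection — resubstitution is also
available and is optimistically biased — with malignant as the positive
class for sensitivity/specificity.

## Stratification

T = μ_h + 2σ_h on the linear signal of the designated gene (default
CAV1), with the sample (n−1) standard deviation — the reference analysis
leaves the denominator convention unstated, and n−1 is the small-sample
default. Values
exactly at T classify as Low ("above the threshold" read strictly).
Healthy outliers use the boxplot rule with quartiles by linear
interpolation (R type 7), recorded in the output because outlier sets
differ between quartile conventions. Percentages throughout the package
round half *up* (62.5 → 63), matching how the reference clinical tables
are rounded; R's default half-even rounding would disagree on exactly
these boundary cases.

## Microenvironment comparison

The correlation filter computes Pearson r on log2 signal over the
*malignant* samples only — the High/Low contrast lives within the
malignancies; the sample set is recorded in the output and switchable.
Both conditions (p < 0.01 and |r| ≥ 0.22) are enforced jointly, with the
|r| boundary inclusive under a 1e−12 float guard. Constant genes have
undefined r and fail the filter explicitly. The High-vs-Low comparison
then delegates to the class-comparison engine in Korn mode (γ = 1%,
confidence 99%), so it equals a direct run on the filtered submatrix by
construction.

## Enrichment statistics

Over/under-representation uses the exact binomial test of the observed
category count against n × (category frequency in the universe),
two-sided by doubling the smaller tail (capped at 1) since categories are
reported in both directions; the hypergeometric variant is available when
sampling without replacement is the better model. Rank enrichment is a
two-sided Mann–Whitney comparison of signed fold-changes, exact by
enumeration of all $\binom{n_1+n_2}{n_1}$ assignments when both groups
have ≤ 8 members, otherwise a normal approximation with tie correction
and no continuity correction; a fully tied vector yields p = 1.
Bonferroni correction multiplies by the number of categories actually
tested (empty intersections are skipped with a warning, not counted).
These are methodological equivalents of the web-tool statistics used for
such lists, not replicas: term-level counts depend on ontology database
versions and are not reproducible targets.

## Immunohistochemistry summaries

A patient is positive for a marker iff *any* of their cores is scored
positive or light ("light" merged into positive — the reference counts
only reconcile under this rule), with the all-cores rule available. The
patient-level denominators, any-core rule and half-up rounding together
reproduce every published subtype × marker percentage from its printed
fraction. Where a printed summary percentage conflicts with its own
fraction (one marker's pooled value), the recomputed value is reported.

## Problem sizes and determinism

The test-suite and acceptance runs use: the full default cohort
(2000 genes, 239 samples) with B = 50,000 for signature recovery; a
5000-gene global-null calibration at B = 1000; 200 replicate 1000-gene
simulations for the false-discovery-proportion check; and exhaustive
small instances (≤ 10 genes × ≤ 20 samples) for brute-force oracle
equivalence of the pair scorer and the exact statistics. All randomness
is seeded; identical configurations produce byte-identical artifacts,
and the pipeline manifest records parameters, seeds and md5 checksums of
every output.

## Known limitations

* Power at the published thresholds is intrinsically marginal for
  fold-changes below ~2 in subtypes with n ≤ 13; this is a property of
  the design sizes, not of the implementation.
* The simulator's independence assumptions (between null genes, between
  samples) make false-positive behaviour cleaner than on real arrays.
* The published cohort-level numbers that depend on the real microarray
  compendia and 2015-era annotation databases (the exact signature
  content, the 98.4%/88.5% classifier performance, the 7,170/2,624
  microenvironment gene counts, and term-level enrichment p-values) are
  documentation context here, not desk-scale reproduction targets.
* Survival/outcome association of CAV1-High status is out of scope.
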