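---
title: "Methods: from a diverse-population muscle proteome to compound reversal scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from a diverse-population muscle proteome to compound reversal scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(irfinger)
options(irfinger.quiet = TRUE)
```

`irfinger` implements a drug-repurposing strategy for insulin resistance
built on systems genetics: phenotype a genetically diverse mouse
population, associate muscle protein abundance with insulin sensitivity,
keep the associations that genetics can plausibly call causal, and score
compound expression signatures for their ability to reverse that causal
set. This vignette documents the models, the tunable parameters, the
numerical choices, and — because the package ships its own synthetic-data
generator instead of real deposited data — exactly what the generator does
and does not emulate.

## Phenotypes

**Matsuda Index.** Whole-body insulin sensitivity is summarised as
`10000 / sqrt(G0 * I0 * Gmean * Imean)` from a glucose-tolerance test with
glucose sampled at 0, 15, 30, 45, 60, 90 min and insulin at 0 and 15 min.
Two conventions needed fixing:

* the GTT means **include the baseline (t = 0) value**, the convention of
  the index's original derivation; `matsuda_index(include_baseline =
  FALSE)` gives the post-bolus alternative;
* the insulin mean uses the two measured timepoints only — no
  interpolation.

The index is scale-equivariant, not unit-free: doubling all glucose values
halves it. The package therefore treats glucose/insulin units as arbitrary
but internally consistent; any consistent unit system gives the same
*rankings* and the same fold-differences across mice.

**Adiposity** is percent fat of body mass and enters the association model
as a covariate; comparing adjusted and unadjusted scans
(`consensus_overlap()`) separates muscle-intrinsic signals from
adiposity-driven ones.

## Protein–trait association

Per protein, ordinary least squares on complete cases:

`log2(Matsuda) = alpha + beta * protein + covariates + eps`

with a two-sided Wald t-test on `beta` (df = n − k − 1). Negative `beta`
means more protein, less insulin sensitivity — the direction the
fingerprint keeps. Rank-deficient designs (constant proteins) are flagged
and excluded from multiple testing. There is no imputation; complete-case
analysis is the default for a ~10% MCAR missingness regime.

Multiple testing uses Storey q-values: `pi0` is estimated by the smoother
method (natural estimates over `lambda = 0.05 … 0.95`, cubic smoothing
spline, evaluated at `lambda = 0.95`, clipped to (0, 1]); the q-value is
`pi0` times the Benjamini–Hochberg step-up value, so forcing `pi0 = 1`
reproduces BH exactly. Q-values are computed **within each fraction**
(mitochondrial vs post-mitochondrial) because significance is reported per
fraction; `pool_fractions = TRUE` is available. The significance threshold
that feeds the fingerprint defaults to q < 0.05 and is an explicit
argument, never a constant baked into the code.

## Protein QTL mapping

The scan is a single-marker linear mixed model. For protein `y`:
`y = X0 b + x_m a + u + e`, `u ~ N(0, sg^2 K)`, with `K = A A' / m` the
realised kinship from column-standardised dosages. The variance ratio
`lambda = sg^2 / se^2` is estimated **once per protein** on the null model
by profile REML over the eigendecomposition of `K`, then held fixed across
markers; rotating by the eigenvectors and scaling by
`1/sqrt(lambda d_i + 1)` whitens the model so every marker fit is OLS and
the scan reduces to one cross-product. `LOD = (n/2) log10(RSS0/RSS1)`.
With `use_kinship = FALSE` this is exactly OLS (asserted in the tests).

Numerical details worth knowing:

* markers collinear with the null design get LOD 0 and a logged warning;
* `RSS1` is floored at `1e-12 * RSS0` so perfect fits give large finite
  LODs instead of `Inf`;
* kinship is computed genome-wide, not leave-one-chromosome-out. LOCO
  mainly matters when the focal marker's own chromosome dominates the
  relatedness estimate; at the package's default genome size the overall
  matrix is the simpler, adequate choice, and the scan structure admits a
  LOCO `K` being passed per chromosome by a caller that wants it.

**Hidden-factor correction.** Before scanning, proteins are z-scored and
the top `n_factors` (default 10) latent factors — estimated by truncated
SVD on the mean-imputed matrix — are regressed out. This is a light-weight
stand-in for probabilistic factor models (PEER-style): at a few hundred
proteins the probabilistic machinery adds cost, not insight, and the
function accepts any externally computed factor matrix if a caller wants a
faithful PEER. One pitfall is documented by a test: with few proteins and
many shared cis effects, aggressive factor removal absorbs genetic signal,
so the factor count should stay well below the protein count.

**Permutation thresholds.** Genome-wide significance comes from permuting
the **whitened null-model residuals** (exchangeable under the null once
covariates and kinship are projected out and whitened away) rather than raw
phenotypes — naive shuffling breaks the covariance structure the mixed
model is there to respect. Each permutation records the genome-wide maximum
LOD; `threshold(alpha)` is the empirical `1 - alpha` quantile, and the
peak's genome-wide p-value carries the +1 correction,
`p = (1 + #{perm max >= observed}) / (n_perm + 1)`, so p is never 0 and
never below `1/(n_perm + 1)`. Fewer than 20 permutations are refused. The
null calibration of this scheme on kinship-structured phenotypes is checked
directly in the acceptance tests (false-positive rate at alpha = 0.05 over
200 independent null traits inside the exact binomial confidence band).

**Classification.** The peak is the single global maximum-LOD marker (ties
broken toward the lowest chromosome, then position). Coordinates are
1-based bp and the ±2 Mbp cis window is inclusive at both ends. The rule is
two-tier: *cis* requires the peak on the gene's chromosome within the
window at genome-wide p < 0.1; otherwise *trans* requires p < 0.05. A local
peak with 0.05 ≤ p < 0.1 is therefore still cis, while the same evidence
away from the gene is called nothing.

## The fingerprint

`build_fingerprint()` intersects {negative effect, q below threshold} with
{classification == cis}. The causal rationale: when local genotype explains
a protein's abundance, the phenotype cannot be driving the observed
abundance differences, so a protein-to-phenotype association is plausibly
causal — an argument that only holds for cis effects. Gene-symbol
collisions across fractions collapse to the more significant entry, and the
exported query set (`export_query_set()`, standard GMT) is
single-directional: one "up in insulin resistance" set, with reversal
defined as negative enrichment of that one set. Connectivity services often
take paired up/down sets; this package deliberately consumes a single list
because the upstream filter produces one.

## The enrichment core

One weighted Kolmogorov–Smirnov implementation serves three callers: GSEA
over proteins ranked by trait effect size, GSEA over proteins ranked by CV,
and connectivity scoring. Walking the ranking, set members add
`|metric|^w / sum(|metric|^w over members)`, non-members subtract
`1/(N - n_set)`; the enrichment score is the signed extremum of the running
sum, bounded in [−1, 1]. Ties in the ranking metric are broken by gene id.
An exact `|max| == |min|` tie of the extremum resolves **positive**, the
convention of standard GSEA implementations (and verified against one in
the tests); consequently the identity "reversing the ranking negates the
ES" holds whenever the extremum is untied, and only magnitude equality can
hold at exact ties. The weight default is `w = 1` for the GSEA callers and
`w = 0` (rank-only, classic KS) for connectivity, where the query is an
unordered set; for `w > 0` on rank-only signatures a monotone rank-derived
metric in (0, 1] stands in.

Connectivity scores average the per-cell-line ES into the compound's raw
score (no percentile/reference-set machinery, which would require a
reference database); negative = reversal, so output is sorted ascending.
Signatures covering <90% of the query are scored on the intersection with
a logged warning.

## Screen scoring and integration

Hit thresholds are 50%-of-control rules on replicate-mean responses with a
strict `>`:

| mode | threshold |
|---|---|
| basal agonist | `basal + 0.5 (ins100 − basal)` |
| insulin sensitiser | `ins1 + 0.5 (ins100 − ins1)` |
| resistance reverser | `palm + 0.5 (ins100 − palm)` |

The basal-agonist rule is interpreted as 50% of the insulin *response*
above basal, parallel to the two difference-based rules; the literal
alternative (absolute 50% of the 100 nM insulin level) is available via
`basal_rule = "absolute"`. A mode whose 100 nM insulin control does not
exceed its reference control has no assay window and is refused.

Integration z-scores each assay's mean response and the connectivity score
**over the consensus compounds only** (z-scores are always relative to the
scored set and recomputed after any restriction), then
`overall = (z_bas + z_sens + z_rev)/3 + z_cmap`. Raw connectivity is
**negated before z-scoring** by default so that stronger reversal
contributes positively to `overall` — the plain sum is sign-ambiguous, and
without the negation a reverser could never top the ranking;
`cmap_sign = "raw"` restores the literal sum. A compound missing an assay
contributes z = 0 (population-neutral) for it and is flagged. Sample
(n − 1) standard deviations are used everywhere an SD appears, including
CVs, which are computed on linear-scale intensities (CVs of log values are
not scale-free).

## The synthetic-data generator

`simulate_study()` produces every input with known truth:

* **Genotypes** — founder mosaics: each chromosome copy is a mosaic of
  founder segments (breakpoints Poisson, rate `breakpoint_rate` per
  chromosome), dosages are sums of two founder allele states. This gives
  genuine kinship and local LD — necessary to exercise the mixed model and
  the cis window — unlike i.i.d. genotypes.
* **Proteome** — unit-variance proteins built from a cis share (`cis_h2`,
  the expected local-marker R²), a shared hidden-factor share
  (`latent_share`, batch-like structure for the factor correction to
  remove), and a residual. A single noise knob cannot serve both the
  proteome and the trait, so there are two: the protein residual (`noise_sd`, `NULL` = complement so shares sum
  to one) and the trait residual (`trait_noise_sd`) — one scale cannot
  serve both roles.
* **Trait** — log Matsuda is a linear model over the planted causal
  proteins plus an adiposity confounder plus noise; glucose curves follow a
  fixed bolus shape with per-mouse variation and a single positive insulin
  multiplier is solved in closed form so the stored target round-trips
  through `matsuda_index()` to machine precision. Adiposity is a latent hit
  both by the trait and by a subset of non-causal proteins, so the
  with/without-covariate contrast is reproducible in silico.
* **Signatures** — complete rankings of the gene universe per compound ×
  cell line; planted reversers shift the fingerprint genes down by
  `reversal_strength` SD of the ranking score; neutral compounds are
  uniform.
* **Screen** — three plate sets with the controls each mode needs, planted
  actives at `screen_effect` (default 0.75) of the assay window above the
  reference control, Gaussian well noise. One planted signature-reverser is
  also made active in every mode (the "dual-active") and should win the
  integrated ranking.

**Identifiability by design.** Three generator choices exist purely so that
planted truth is recoverable by the marginal methods the pipeline uses, and
they are the main way the simulation is *cleaner* than real data:

1. the trait consumes the **latent-free biological signal** of causal
   proteins — hidden/batch factors contaminate measurements, not
   physiology. Without this, shared factors make much of the proteome
   genuinely trait-associated and the null proportion collapses;
2. planted causal loci are mutually near-uncorrelated (pairwise dosage
   |r| ≤ 0.2) and other genetic proteins' drivers are kept off those loci
   (|r| ≤ 0.5): marginal association cannot separate co-localised pQTL;
3. causal residuals are orthogonalised in-sample against the other causal
   signals, so a planted effect's marginal coefficient is not diluted by
   chance correlations among the six drivers.

Real data honour none of these: co-localisation, pervasive correlation and
phenotype-correlated batch structure all occur. Passing the recovery tests
therefore demonstrates that the *pipeline machinery* is correct and
calibrated, not that the design would achieve the same precision/recall on
a real cohort.

**Default conditions.** 215 mice (the cohort scale the design targets),
8 founders, 5 chromosomes × 40 markers over 100 Mbp (≈2.5 Mbp marker
spacing, comfortably inside the ±2 Mbp window), 300 proteins in two
fractions with 25% cis / 5% trans (matching the observed ~30% pQTL rate,
predominantly cis, in populations of this kind), `cis_h2 = 0.3`, 10%
MCAR missingness, 6 causal drivers at ≈0.8 SD effect (marginal per-protein
R² is bounded near 1/k for k drivers, so a sparse architecture is what
gives per-protein power at n = 215), adiposity effect −0.35 SD, trait noise
0.5. Compound side: 100 compounds × 3 cell lines, 5 reversers at strength
4, 8 actives per screen mode at 75% of the assay window, well noise 2
percentage points.

**Problem sizes in the tests.** The unit suite runs miniature studies
(60–120 mice, tens of proteins); the acceptance suite runs the full default
study with 200 permutations per protein and the calibration studies at
n = 100 mice × 500 markers × 200 permutations × 200 null traits — sizes
chosen as the smallest at which the quantities being checked (binomial
confidence bands, recovery rates) are statistically meaningful.

## Pipeline, artifacts, determinism

`run_pipeline()` chains all stages and optionally writes flat TSV artifacts
(UTF-8, `NA` missing, a `#` header carrying package version, seed and a
hash of the configuration) plus `truth.json`/`config.json`, so any stage
can be re-run from disk or replaced with real data later. Reruns skip
existing artifacts unless `force = TRUE`. Everything is seeded through the
single config seed (stage seeds are derived deterministically), so two runs
with the same configuration are byte-identical; there is no network access
anywhere. The package's interface is R functions returning tibbles — the
natural shell for an analysis library; there is no separate command-line
binary, and `scripts/acceptance.R` shows the scripted entry point pattern.

## Known limitations

* Dosage-based single-marker scans, not founder-haplotype-probability
  regression; no allele (founder) effects, no QTL support intervals.
* The factor correction is a truncated SVD, not a probabilistic model;
  factor count is a free parameter with the absorption caveat above.
* Connectivity is a raw mean ES across cell lines — no reference-set
  (tau/percentile) normalisation, no cell-line weighting.
* The generator's MCAR missingness, Gaussian well noise and fixed glucose
  curve shape are simplifications; none of the acceptance quantities
  depend on those details beyond their stated rates.
* Units entering the Matsuda formula are arbitrary-but-consistent; absolute
  index values are comparable only within a unit system.
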