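---
title: "Data-driven GPS methodology for detraining muscle change"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Data-driven GPS methodology for detraining muscle change}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(detraingps)
```

## The scientific setting

When older adults stop a structured exercise programme, muscle mass and
knee-extensor strength decline at strikingly different individual rates.
`detraingps` implements the data-driven genetic predisposition score (GPS)
approach to ask how much of that variability is captured by candidate
muscle-related variants: screen a panel of SNPs against each change score,
keep the ones that survive stepwise selection, count each participant's
*favourable* alleles (the alleles associated with less decline), and model
the change on that count.

Five phenotypes are handled throughout: whole-body skeletal muscle mass
(SMM, kg, estimated from bioimpedance), peak isometric knee-extension
torque at 60° flexion (PT_IM60, Nm), peak isotonic extension velocity at
20% load (PV_IT20, °/s), and peak isokinetic torque at 60 and 240 °/s
(PT_IK60, PT_IK240, Nm). The response is always the per-participant
relative change, `100 × (follow-up − post) / post`, in percent. The
per-participant definition matters: the ratio of group means is *not* the
mean of individual ratios, and all downstream modelling is at the
individual level.

SMM comes from the Janssen bioimpedance equation,

$$\mathrm{SMM\,(kg)} = 0.401\,\frac{\mathrm{Ht}^2}{R}
  + 3.825\,\mathrm{sex} - 0.071\,\mathrm{age} + 5.102,$$

with height in cm, whole-body resistance R in ohm, sex coded men = 1 /
women = 0, and age in years. The equation's published standard error of
estimate is around 9%, which is worth remembering when interpreting
ΔSMM-driven SNP selections: measurement noise in both timepoints
propagates into the change score.

## Panel quality control

`run_qc()` reduces a candidate panel in three fixed stages:

1. **Detection filter** — SNPs with call rate strictly below 0.80 are
   removed. The inequality is strict: a SNP typed in exactly 80% of
   participants stays.
2. **Monomorphic filter** — SNPs whose non-missing calls are a single
   genotype carry no information; SNPs with *no* calls at all are removed
   here too (they cannot enter any later stage) and logged.
3. **LD subgrouping** — an edge joins two SNPs when the absolute Pearson
   correlation of their minor-allele dosages, over jointly non-missing
   participants, exceeds 0.8. Subgroups are connected components of size
   ≥ 2; within each, the SNP with the largest subgroup degree is kept,
   ties broken by the larger publication count, then by lexicographically
   smaller rs identifier. Plain dosage correlation (not r² or D′) is used
   deliberately — it is the quantity the grouping threshold refers to —
   and correlations use pairwise-complete observations, with pairs sharing
   fewer than 3 observations never forming an edge.

The stage order is forced by the mathematics: monomorphic SNPs have
undefined correlations, so they must leave before LD analysis. The
partition invariant `kept + removed_low_detection + removed_monomorphic +
removed_ld = input` is asserted on every run.

## GPS construction

`build_gps()` pools both training groups (their change distributions are
modelled as exchangeable) and runs classical stepwise regression of the
change score on the panel's minor-allele dosages with **entry α = 0.10**
and **stay α = 0.05**: at each step the candidate with the smallest
partial-F p-value enters if p < 0.10, then included variables with
p > 0.05 are removed one at a time, largest first. The procedure stops
when no candidate can enter, when the variable just entered is immediately
removed again (oscillation guard), or at `max_steps`. Ties on the entry
p-value resolve by panel order; candidates collinear with the included set
are skipped and logged.

Covariates are *not* included during selection — selection screens the
marginal additive association of each SNP with the change score, matching
the data-driven GPS tradition; an `include_post`-style sensitivity flag
exists downstream, where covariates belong.

Each selected SNP is then oriented: if the minor-allele dosage coefficient
is positive, the minor allele is favourable; otherwise the major allele is
favourable and the coefficient's sign flips (counting the other allele
reverses the dosage). Genotype scores count favourable alleles — for a
C/G SNP with favourable G: GG = 2, CG = 1, CC = 0 — and the GPS is their
unweighted sum, so 0 ≤ GPS ≤ 2k for k SNPs. Orientation works on allele
*letters*, not on dosage codes, which makes the whole model invariant to
which allele a file happens to store first.

Missing calls: stepwise selection is complete-case per fit (a participant
is dropped only from fits that use a SNP they are missing); GPS summation
mean-imputes the per-SNP score by default so every participant is
scoreable, with a complete-case option. The asymmetry is deliberate —
imputation inside selection would perturb the partial-F tests, while at
summation time it preserves sample size.

## Association model

`fit_gps_glm()` fits ordinary least squares of the change on GPS, sex
(M = 1, F = 0), age, BMI and — except for ΔSMM — the post-training
phenotype value. The ΔSMM model omits the post-training covariate by
default (its reference analysis does the same; the flag restores it).
Reported per term:

* the raw estimate (percent change per favourable allele for the GPS);
* the standardized coefficient `estimate × sd(term) / sd(change)`;
* **Type-III partial r²** `(SSE(model − term) − SSE(full)) / SS(total)`,
  i.e. each term entered last — equal to the squared semi-partial
  correlation, which the test suite verifies against a
  residual-on-residual oracle at 10⁻¹⁰;
* two-sided p-values, plus the model's adjusted r².

`gps_bins()` reproduces the standard presentation figure: GPS values are
rounded to integers and merged *from the distribution tails inward* —
while the lowest bin holds fewer than `min_bin` (default 3) participants
it merges with its right neighbour, the highest bin symmetrically with its
left — and each final bin gets a covariate-adjusted least-squares mean and
standard error, alongside the covariate-adjusted linear trend. With a
single resulting bin the LS-mean is the overall mean with the
covariate-model residual SE. On the degenerate count pattern {2, 5, 2}
with `min_bin = 3` this rule yields one merged bin of 9; no contiguous
two-bin partition of that pattern satisfies the minimum on both sides.

## The synthetic cohort generator

No cohort of this kind is publicly deposited, so the generator is a
first-class, tested module rather than a fixture. Its defaults define the
emulated study conditions:

* **Cohort**: 113 participants (44 FIT, 69 WBV), ages uniform on 61–81,
  half women. Height, body mass and BIA resistance come from sex-specific
  normals (women ≈ 161 ± 7 cm, 68 ± 9 kg, 575 ± 55 Ω; men ≈ 174 ± 6 cm,
  80 ± 11 kg, 465 ± 45 Ω); the resistance locations were chosen so the
  Janssen equation returns SMM values typical of the two sexes at these
  ages (≈ 18 and 30 kg). Follow-up mass and resistance are the
  post-training values under small relative perturbations.
* **Panel**: 224 SNPs, MAF uniform on [0.05, 0.5], genotypes drawn under
  Hardy–Weinberg equilibrium. Twelve SNPs are forced below the 80% call
  rate, three are monomorphic, and 58 SNPs form 19 LD blocks (18 × 3 +
  1 × 4) — the structure the QC stage is expected to undo, leaving 170.
  Remaining missingness is MCAR at 2%, a typical array-genotyping rate.
  Structural roles are assigned deterministically from the panel's tail so
  the leading SNPs — including the bundled reference sets of
  `gps_snp_sets()` — stay clean.
* **LD blocks** copy the block seed's haplotype allele indicators with
  retention probability equal to the correlation target, redrawing at the
  block allele frequency otherwise. This yields integer genotypes, exact
  HWE marginals, and pairwise dosage correlation ≈ the target — adequate
  for grouping tests, though it produces equicorrelated blocks rather than
  the decaying correlation of real haplotype structure.
* **Changes** are additive: intercept + Σⱼ βⱼ·dosageⱼ + covariate terms +
  Gaussian noise. `default_effect_spec()` carries per-phenotype presets
  (per-allele effects 2.09–4.53%, genetic variance fractions 0.26–0.37,
  covariate coefficients and intercepts) mirroring the reference
  association models, with the matching reference SNP set as the causal
  set.
* **Calibration**: with a target genetic variance fraction *f*,
  `calibrate_effects()` solves `noise_var = var_genetic × (1 − f)/f −
  var_covariates`, using the empirical dosage covariance of the causal
  SNPs and the cohort's covariate distribution (exact Janssen values for
  SMM; the generating sex-specific distribution otherwise). Targets whose
  covariate variance already exceeds the non-genetic budget are rejected
  rather than silently truncated.

What the generator does **not** emulate: genotyping batch effects,
population stratification, haplotype-scale LD decay, non-additive
(dominance/epistatic) effects, floor/ceiling effects in dynamometry, and
any physiology of detraining (fibre-type shifts, methylation). Passing
tests therefore certify the statistical machinery under the stated
generating model — not biological validity on real cohorts.

## Honest evaluation: what the in-sample numbers do not mean

Because SNP selection and GPS evaluation use the same sample, the
in-sample GPS partial r² is optimistic — with 170 candidates at entry
α = 0.1, stepwise selection captures variance even from pure noise. The
evaluation module makes this measurable rather than anecdotal:

* `cross_validate()` repeats the **entire** pipeline (selection,
  orientation, scoring, GLM) inside every training fold and scores
  held-out participants; reusing a selection across folds would be
  exactly the bias under study, so it is never done. Folds with empty
  selections fall back to covariates-only prediction, logged.
* `permutation_null()` permutes the change scores (keeping the paired
  post-training value with them), reruns the full pipeline per
  permutation, and returns the null distribution of the in-sample GPS
  partial r² with an add-one empirical p-value. Its mean sits well above
  zero — that elevation *is* the selection optimism.
* `recovery_experiment()` simulates replicate cohorts under a known
  effect specification and aggregates the recovered GPS coefficient,
  partial r² and selected-SNP count, under either data-driven
  (`"stepwise"`) or known-truth (`"oracle"`) selection.

Two opposing distortions of the equal-weight data-driven GPS deserve
emphasis, and both are exercised by the test suite. At small n, winner's
curse inflates the in-sample estimate and variance explained. At large n,
selection recovers every causal SNP but *also* keeps admitting null SNPs
(the entry test's false-positive rate does not vanish with n), and because
summation is unweighted, those passengers dilute the fitted common slope
below the true per-allele effect. Oracle selection shows neither
distortion. Consequently the number of SNPs a stepwise screen retains over
a large panel should be read as "causal candidates plus an
α-level-governed allowance of false entries", not as a count of true
signals — even when every true effect is individually large.

## Numerical and scale choices

* Stepwise entry uses the smallest p-value (equivalent to the largest
  partial F), with ties broken by panel order; backward removal takes the
  largest p first. The oscillation guard (stop when the variable just
  entered is removed in the same step) prevents entry/removal cycles
  between the two thresholds.
* Rank-deficient candidate fits are detected via NA coefficients and the
  candidate skipped; a rank-deficient final GLM is an error naming the
  collinear terms, not a silent drop.
* Zero-variance responses in the group-comparison ANOVAs return NA
  p-values (or an exact time-effect p of 1/0 for constant difference
  scores) instead of erroring on a zero residual sum of squares.
* Degenerate-input contracts: zero participants is a valid (empty)
  cohort; an empty panel, fewer than 10 non-missing changes, a zero
  selection coefficient at orientation, or a GPS model with no entries
  are errors.
* Test and acceptance problem sizes are the package's own choices to keep
  a desk run in minutes: cohort-scale checks use n = 113 with 40–170-SNP
  panels; law-of-large-numbers checks use n = 10,000 with small panels;
  recovery means use 500 replicates at n = 113; the large-cohort
  selection check uses n = 2,000. Monte-Carlo tolerances follow from
  these sizes (e.g. ±0.02 on a calibrated variance fraction at
  n = 10,000).

## Known limitations

* The equal-weight GPS is the only score implemented; weighted,
  elastic-net or total-GPS variants are out of scope, though the model's
  `weight` field leaves room for them.
* LD handling is a pruning step, not a haplotype model; no population
  stratification correction is applied.
* The repeated-measures decomposition is the exact two-timepoint
  difference-score form; it does not generalise to three or more
  timepoints (no sphericity machinery).
* The generator's monomorphic SNPs are coded as homozygous for the first
  stored allele; real assay failure modes are more varied.
* Cross-validated R² estimates at n ≈ 113 are themselves noisy; they
  demonstrate the optimism gap robustly, but their point values should
  not be over-read.
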