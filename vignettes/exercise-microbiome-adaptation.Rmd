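---
title: "Exercise response, the gut microbiome, and metabolic adaptation: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exercise response, the gut microbiome, and metabolic adaptation: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`gutfit` analyzes small exercise-intervention cohorts in which each
participant contributes pre- and post-training body composition,
whole-room calorimetry, doubly-labeled-water (DLW) energy expenditure,
and shotgun-metagenomic stool profiles. This vignette documents the
models the package implements, the tunable parameters that matter, what
the synthetic-data generator does and does not emulate, and the design
decisions taken where the methodology was genuinely open.

## The energetics chain

**Resting metabolic rate (RMR).** A 60-minute whole-room trace of
per-minute VO₂ and VCO₂ (litres) is converted minute-by-minute with the
Weir equation, EE = 3.9·VO₂ + 1.1·VCO₂ kcal, and only the final 20
minutes are averaged (scaled to kcal/day): the early part of a supine
measurement carries a settling transient. `rmr_from_trace()` therefore
ignores minutes 0–39 entirely, and the synthetic trace generator can
plant an exponential settling artifact (time constant 10 min, confined to
minutes 0–39) precisely so that this windowing rule is consequential and
testable.

**Total daily energy expenditure (TDEE).** The DLW inversion follows the
classical two-point protocol. Enrichments are recorded in δ‰ against
VSMOW (²H/¹H = 155.76 ppm, ¹⁸O/¹⁶O = 2005.20 ppm) and converted to heavy
mole fractions; the plateau rise (mean of the 4 h and 5 h samples minus
baseline) gives the dilution spaces N = (dose/M)·(APE/100)/rise; total
body water averages the exchange-corrected spaces (1.041 for ²H, 1.007
for ¹⁸O); elimination rates come from the log-ratio of the plateau to
the mean day-10 void excesses; CO₂ production uses the constant-folded
Schoeller-form two-point equation rCO₂ = 0.4554·TBW·(1.01·k_O −
1.04·k_D) mol/day (22.4 L/mol); and TDEE = rCO₂·(3.9/RQ + 1.1) with RQ
fixed at 0.86. Every constant sits in `dlw_constants()` because the
literature offers variants of the exchange corrections and two-point
multipliers; the package's default is one reproducible choice, and the
synthetic DLW generator is defined as the *exact inverse* of this chain,
so round-trip correctness is testable independently of which variant a
user configures.

DLW is analytically delicate: the energy estimate rests on the small
difference 1.01·k_O − 1.04·k_D, so permil-level enrichment noise
propagates to roughly 5% TDEE error. The generator's default analytic
noise (1.0‰ for ²H, 0.25‰ for ¹⁸O) matches the duplicate-QC tolerances
of cavity-spectroscopy assays, and the pipeline tests budget for this
sensitivity; it is a feature of the technique, not an implementation
artifact.

**Metabolic adaptation** is defined as the measured change in EE minus
the change predicted from body composition. The prediction model is not
uniquely determined by that definition; the package fits ordinary least
squares of *baseline* EE on baseline FFM and FM across the cohort
(intercept included) and applies those coefficients to post-intervention
body composition. The alternative — regressing ΔEE on ΔFFM and ΔFM —
is available (`method = "delta_reg"`) but its intercept absorbs the
cohort-mean adaptation, so it only resolves between-subject contrasts.
The baseline-coefficient method is the default because it preserves the
mean adaptation signal. Both error out when FFM and FM are collinear
(condition number above 1e8), advising an FFM-only model.

## Responder classification

A responder is a participant whose fat-free-mass change exceeds their
fat-mass change: score = ΔFFM − ΔFM with the strict rule score > 0. The
boundary case score = 0 (e.g. post identical to pre) is a non-responder;
this is pinned by tests because the rule is strict. Baseline balance is
checked with Fisher's exact test (sex) and exact Wilcoxon rank-sum tests
(age, BMI, FM, FFM), BH-adjusted within that family of five.

## Diversity and ordination

* **Shannon index** uses natural logarithms (nats) by default — the
  convention of the surrounding software ecosystem — with the base
  configurable and pinned by tests.
* **Faith's PD** includes every edge on the paths from the root to the
  present leaves (the stem path counts). This must be pinned one way or
  the other for oracle tests; the brute-force path-union oracle in the
  test suite enumerates exactly this definition.
* **Weighted UniFrac** defaults to the normalized variant,
  Σ l·|A−B| / Σ l·(A+B) over branches, matching the common default; the
  raw numerator is available via `normalized = FALSE`.
* **PCoA** drops non-positive eigenvalues without Cailliez/Lingoes
  correction and reports the negative-eigenvalue mass so users can judge
  how non-Euclidean a dissimilarity was. Dispersion analyses use *all*
  retained positive axes, not just the two that are plotted.
* **PERMANOVA** permutes whole-sample labels; pre/post samples of one
  subject are not constrained to move together, because the analysis
  being reproduced reports no stratification. A `strata` argument
  restricts permutations to subject level for sensitivity analysis.
* **The dispersion test** embeds via PCoA, measures each sample's
  Euclidean distance to its own group centroid (the group mean — not the
  spatial median), and permutes labels over those fixed distances, the
  standard permutation scheme for this test. Permutation p-values use
  the add-one estimator (1 + exceedances)/(1 + permutations).

## The biomarker screen

Species are first filtered on pre-training samples: mean relative
abundance > 0.05% and detection in ≥ 80% of samples, in deterministic
order (descending mean abundance, ties by id). Each surviving species is
scored by univariate logistic regression under 10-repeat stratified
3-fold cross-validation. Choices a reader should know about:

* **Fold sharing.** Within a repeat, all species see the same fold
  split, making AUROCs comparable across species; the fold assignments
  are exposed on the result object so this is assertable.
* **Aggregation.** Out-of-fold scores are pooled within a repeat into
  one ROC AUC; the reported AUROC is the mean over repeats (the per-fold
  average is also emitted). Pooling mixes fold calibrations, so AUROC is
  invariant to monotone abundance transforms only up to a small pooling
  effect.
* **Separability.** On 11 training subjects a single species frequently
  separates the classes perfectly and the unpenalized MLE diverges; a
  fixed tiny ridge (1e-6) on the slope keeps the Newton solver finite
  without materially moving the decision scores.
* **Inference.** The Mann–Whitney p-value is computed on the per-subject
  scores averaged over repeats (exploiting U/(n₁n₀) = AUROC), exactly
  for these sample sizes; BH q-values run across species; the 95% CI is
  a stratified percentile bootstrap over subjects, and "CI > 0.5" is
  read as the lower bound exceeding 0.5. A species is
  `highly_predictive` when mean AUROC > 0.8 and `robust` when q < 0.1
  and the CI lower bound exceeds 0.5.
* **Multivariate check.** L1-penalized logistic regression on z-scored
  abundances, with the penalty chosen by stratified 3-fold CV on AUROC
  under the one-standard-error rule (largest penalty within one SE of
  the best). The 1-SE rule, rather than the bare argmax, is what makes
  the selection collapse to the empty model under label-permuted nulls
  at this sample size; an empty selection is reported, not an error.

## The synthetic world

The generator's defaults restate the studied condition: 16 sedentary
overweight adults (ages 21–45, BMI 25–30 kg/m², half female), half of
whom respond; 300 species; 9 planted predictor species elevated 1.5 log2
units in responders at baseline; responder subject-level community
spread halved; ΔShannon coupled to TDEE adaptation at ρ = 0.73 and
baseline Shannon to RMR adaptation at ρ = −0.65; total weight change
centered at zero (sd 2.1 kg); true energies affine in FFM around
midpoints 1600 (RMR) and 2700 (TDEE) kcal/day, with the post-training
TDEE additionally carrying the prescribed exercise energy
(20 kcal/kg/week) and a planted subject-level adaptation (RMR −60 ± 80,
TDEE −100 ± 250 kcal/day — energy conservation on average).

**Abundance model.** Compositions are logistic-normal: a species
log-profile (sd 2.0) plus subject offsets plus sample noise through a
softmax, with abundances below 1e-5 zeroed and renormalized to emulate a
classifier's detection floor. The subject/sample log-sd defaults (0.4
and 0.22) are calibration choices, fixed once so that the stated world
holds — the planted predictors are recoverable (≥ 7/9 above AUROC 0.8 in
most seeds) while a zero planted effect leaves them at chance. Alpha
diversity is controlled exactly by tempering: per-sample Shannon targets
are drawn through a Gaussian copula on the subject-level adaptation
latents and each composition is exponent-scaled (p ∝ p^(1/T), T solved
by root finding) to hit its target, which both plants the
diversity–adaptation correlations and removes any accidental coupling
between diversity and response group.

**What it does not emulate.** No read-level sequencing noise, classifier
error, or count data (compositions are exact up to the detection floor);
species are conditionally independent given subject (real communities
have strong covariance); diet is a constant-calories column; dropout and
compliance are absent. A green recovery test therefore establishes that
the *analysis* recovers what the *model* plants — not that the model
captures every feature of real stool metagenomes.

**A known honest failure.** One stated acceptance property — that with
zero planted effect the set of species with mean cross-validated
AUROC > 0.8 is empty in ≥ 90% of seeds — cannot hold at this design
size: with ~16 subjects and a couple hundred screened species, the null
spread of cross-validated AUROC (raw-AUC sd ≈ 0.15) yields a few chance
exceedances per seed regardless of how quiet the generator is, because
AUROC is rank-based and thus scale-invariant. The corresponding test is
implemented literally and left failing, with the companion measurements
showing that the *final* reported set (highly predictive **and** robust)
does empty out under the null. This is the package's own illustration of
why a robustness layer on top of an AUROC threshold is necessary at this
cohort size.

## Numerical and degenerate-input policy

Exact Wilcoxon distributions are used up to n = 25 per group (dynamic
programming over rank subsets / sign assignments), with midranks plus
tie-corrected normal approximation and continuity correction beyond or
under ties; a statistic exactly at its null mean reports p = 1. Zero
paired differences are dropped. Two-sided doubling is capped at 1.
Degenerate DLW kinetics (k_O at or below the two-point boundary) are
flagged at generation and refuse inversion. Compositions are validated
to sum to one within 1e-6; a planted effect that drives any single
species above 0.99 relative abundance on the raw (untempered)
composition is an error. All generators are deterministic given their
seed, and every derived seed stays within 32-bit range.

## Limitations

The pipeline targets two-group, two-timepoint designs with n in the
tens; the exact tests do not scale to hundreds of subjects (the normal
approximations take over), and the screen's CV design assumes both
classes have at least k members. PERMANOVA and the dispersion test are
one-way only. The multivariate selection at n = 16 is unstable under
duplicated or highly collinear features — one of a correlated pair is
selected essentially arbitrarily — which is inherent to L1 selection,
not a defect the package attempts to hide.
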