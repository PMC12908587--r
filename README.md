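# gutfit

Tools for asking whether the gut microbiome explains who responds to
moderate aerobic exercise training — and who merely adapts their
metabolism instead.

`gutfit` is aimed at exercise-physiology and microbiome researchers
running small, deeply phenotyped intervention cohorts (here: 16 sedentary
overweight adults, 12 weeks of moderate-intensity training). It
implements, as one tested R pipeline:

* **Energetics.** Resting metabolic rate from whole-room indirect
  calorimetry via the Weir equation `EE = 3.9·VO₂ + 1.1·VCO₂` (kcal,
  litres), averaging the final 20 min of a 60-min trace; total daily
  energy expenditure from doubly labeled water: δ‰ → mole-fraction
  conversion against VSMOW, plateau dilution spaces
  `N = (dose/M)·(APE/100)/rise`, exchange-corrected total body water
  `TBW = (N_D/1.041 + N_O/1.007)/2`, two-point elimination kinetics
  `k = ln(E₁/E₂)/Δt`, CO₂ production
  `rCO₂ = 0.4554·TBW·(1.01·k_O − 1.04·k_D)` and TDEE at a fixed RQ of
  0.86. **Metabolic adaptation** is the measured minus the
  body-composition-predicted change in EE (OLS of baseline EE on FFM and
  FM).
* **Response classification.** A responder improves body composition:
  `(FFM_post − FFM_pre) − (FM_post − FM_pre) > 0` (strictly), with
  Fisher/Wilcoxon baseline-balance checks under Benjamini–Hochberg FDR.
* **Diversity.** Shannon index, Faith's PD, Bray–Curtis, weighted
  UniFrac, PCoA, one-way PERMANOVA (pseudo-F, label permutation),
  multivariate homogeneity of group dispersions, and centroid-distance
  comparisons.
* **Biomarker screen.** Mean-abundance/prevalence species filtering, then
  per-species univariate logistic regression evaluated by 10-repeat
  stratified 3-fold cross-validated AUROC, exact Mann–Whitney p-values
  (`U/(n₁n₀) = AUROC`), BH q-values, stratified-bootstrap CIs, an
  L1-regularized multivariate check, and flagged-group AUROC contrasts.
* **Exact small-sample statistics.** The Wilcoxon rank-sum and
  signed-rank tests and Fisher's exact test are implemented with exact
  null distributions (n = 16 cohorts leave no room for asymptotics), each
  verified against brute-force enumeration oracles.
* **A synthetic cohort generator** that plants known effects — predictive
  species elevated in responders, tighter responder community dispersion,
  and Gaussian-copula couplings between Shannon diversity and metabolic
  adaptation — so every stage has a ground-truth recovery test.

## Worked example

```r
library(gutfit)
res <- run_study_pipeline(synth_config(seed = 1), n_perm = 9999)
print(res)
#> gutfit pipeline run
#>   subjects: 16 (8 responders / 8 non-responders)
#>   baseline balanced: TRUE
#>   weighted_unifrac: PERMANOVA p = 0.0023, dispersion p = 0.0104
#>   bray_curtis: PERMANOVA p = 0.0034, dispersion p = 0.0001
#>   highly predictive species: 8 of 129 screened
#>   dShannon ~ TDEE adaptation: r = 0.66 (p = 0.00547)
#>   Shannon(pre) ~ RMR adaptation: r = -0.84 (p = 3.91e-05)
```

Reading the output: the cohort splits 8/8 into responders and
non-responders with no baseline confounding (all balance q > 0.05). Both
beta-diversity metrics separate the groups in centroid location
(PERMANOVA) *and* spread (dispersion test) — responder communities form
the tighter cluster, as planted. The screen flags 8 of 129 filtered
species as highly predictive (mean cross-validated AUROC > 0.8); this
seed planted 9, and the flagged-vs-other contrast is strong:

```r
g <- res$group_auroc
sprintf("planted %.2f ± %.2f vs other %.2f ± %.2f, p = %.2g",
        g$mean_flagged, g$sd_flagged, g$mean_other, g$sd_other, g$p.value)
#> "planted 0.88 ± 0.09 vs other 0.54 ± 0.14, p = 8.1e-07"
```

Finally, the pre-to-post gain in Shannon diversity correlates positively
with TDEE adaptation (r = 0.66 here; the generator plants ρ = 0.73,
attenuated by energy-measurement noise), and baseline diversity
correlates negatively with RMR adaptation — subjects with diverse
baseline communities conserved resting energy.

The same stages run on files (abundance TSV, Newick tree, cohort CSV, DLW
CSV, per-sample gas-trace CSVs) written and read by `write_study()` /
`read_abundance()`; `inst/scripts/run_all.R` is a command-line wrapper.

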