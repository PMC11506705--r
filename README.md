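# h1prm

Targeted-proteomics assay design and absolute quantification for families of
near-identical proteins, built around the seven somatic histone H1 subtypes
(H1.0–H1.5, H1X).

The relative proportions of the H1 subtypes — the *H1 complement* — shift
with cell type and disease, making them candidate cancer biomarkers. But the
replication-dependent subtypes are too similar for gels or antibodies to
quantify individually. Parallel reaction monitoring (PRM) solves this with
*proteotypic peptides*: for each subtype, a peptide that occurs in no other
family member is monitored together with a spiked stable-isotope-labelled
(SIS) copy, and the light/heavy ratio of summed fragment-ion peak areas

    LH = Σ light XIC areas / Σ matched heavy XIC areas

is converted to an absolute amount through a calibration line
`LH = a·amount + b` (single-point proportional calibration by default),
with limits `LOD = 3.3·s_yx/slope` and `LOQ = 10·s_yx/slope`.

The package covers, for users designing or analysing such assays:

* **Assay design** — in-silico trypsin/Glu-C digestion (`digest()`),
  unique-candidate selection under length/mass filters
  (`enumerate_candidates()`), PeptideAtlas suitability-score annotation
  (`annotate_ess()`).
* **Mass arithmetic** — monoisotopic masses, heavy-label (+8/+7/+4) shifts,
  precursor and b/y fragment m/z (`monoisotopic_mass()`, `heavy_mass()`,
  `fragment_mz()`).
* **Calibration & quantification** — curve fitting with LOD/LOQ
  (`fit_calibration()`), LH ratios with oxidation and missed-cleavage
  corrections (`lh_ratio()`, `combine_oxidized()`,
  `external_curve_correct()`), complement profiles and gel-band
  reconciliation (`complement_profile()`, `expected_band_percentages()`).
* **Biomarker statistics** — ROC/Youden/AUC, Matthews correlation, exact
  small-cohort rank-biserial critical values
  (`roc_curve()`, `mcc()`, `brcc_critical()`), correlation-distance
  clustering and PCA of patient profiles.
* **Simulation** — ground-truth-known generators for every input format
  (`simulate_calibration()`, `simulate_sample_report()`,
  `simulate_cohort()`).

## Worked example

The package ships a synthetic-context H1 family (the real quantification
peptides embedded in simulated flanking sequence) so the whole pipeline runs
without instrument data:

```r
library(h1prm)

## 1. assay design: unique candidates per subtype
fam  <- synthetic_h1_family()
cand <- enumerate_candidates(fam)
candidate_counts(cand)$per_subtype
#> H1.0 H1.1 H1.2 H1.3 H1.4 H1.5  H1X
#>   17   17   18   21   16   15   18

## 2. calibration from a simulated dilution series (3 replicates, 10% noise)
cfg <- simulation_config(seed = 42)
cal <- simulate_calibration(cfg)
des <- cal$design[cal$design$peptide == "ALVQNDTLLQVK", ]
pts <- do.call(rbind, lapply(seq_len(nrow(des)), function(j) {
  recs <- cal$report[cal$report$peptide == "ALVQNDTLLQVK" &
                       cal$report$sample == sprintf("cal_L%02d", des$level[j]) &
                       cal$report$replicate == des$replicate[j], ]
  data.frame(amount = des$amount[j], lh = lh_ratio(recs))
}))
fit_calibration(pts, peptide = "ALVQNDTLLQVK")
#> Calibration curve [ALVQNDTLLQVK]: LH = 1.0115 * amount + -0.019504
#>   adj r2 = 0.99718, s_yx = 0.09088, n = 21
#>   LOD = 0.2965, LOQ = 0.8985

## 3. quantify a simulated sample and derive the complement
sim <- simulate_sample_report(cfg)
q   <- quantify_report(sim$report, cfg$assay, heavy_spike_ng = 1)
round(complement_profile(q)$percent, 1)
#> H1.0 H1.1 H1.2 H1.3 H1.4 H1.5  H1X
#>  5.2 10.5 20.6  0.5 29.4 29.5  4.3

## 4. cohort statistics: can total H1 separate responders from non-responders?
co <- simulate_cohort(seed = 42)          # 6 responders, 2 non-responders
r  <- roc_curve(co$total_h1_ng_ml, co$group, positive = "non_responder")
r
#> ROC: AUC = 1, Youden J = 1 at threshold 102.8 (sens 1, spec 1)
mcc(classify_at(co$total_h1_ng_ml, co$group, r$best_threshold,
                positive = "non_responder"))
#> [1] 1
brcc_critical(8, 2, 0.05)$critical_r     # exact small-cohort threshold on r
#> [1] 0.875
```

Reading the numbers: the fitted slope (≈1.01 against a generating slope of
1) and adjusted r² > 0.99 say the simulated series is linear at the
configured noise; the LOQ (≈0.9 ng here) is the smallest amount reportable
as quantified. The complement percentages recover the generating mixture
(H1.4/H1.5 dominant, H1.3 near the floor). In the simulated cohort the two
non-responders have the highest total H1, so the ROC separates perfectly and
the rank-biserial effect size reaches the exact significance threshold for a
cohort this small (r ≥ 0.875 at one-sided α = 0.05 for group sizes 8 and 2).

A command-line interface wrapping the same functions is in
`inst/cli/h1prm.R` (subcommands `select-peptides`, `calibrate`, `quantify`,
`stats`, `simulate`).

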