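---
title: "Methods: PRM assay design and quantification for histone H1 subtypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PRM assay design and quantification for histone H1 subtypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(h1prm)
```

## The problem

Human somatic cells express up to seven histone H1 subtypes (H1.0–H1.5 and
H1X) whose relative proportions — the *H1 complement* — vary with cell type
and disease state. Because the replication-dependent subtypes share more than
65 % sequence identity, neither gel electrophoresis nor antibodies can
quantify them individually in one sample. Parallel reaction monitoring (PRM)
can: each subtype is represented by a *proteotypic* peptide found in no other
family member, a stable-isotope-labelled (SIS) copy of that peptide is spiked
at known amount, and the light/heavy (L/H) ratio of summed fragment-ion peak
areas converts directly into an absolute amount.

`h1prm` implements that workflow end to end: candidate selection by in-silico
digestion, mass/transition arithmetic, calibration with detection limits,
quantification with oxidation and missed-cleavage corrections, complement
profiles, and the small-cohort statistics used to judge a candidate
biomarker. A simulation module generates every input format with known ground
truth, which is how the package tests itself.

## Candidate selection

`digest()` cleaves C-terminal to K/R (trypsin, cleavage suppressed before
proline) or to E — optionally E and D — for endoproteinase Glu-C. Both Glu-C
specificities are first-class because the enzyme's specificity depends on the
digestion buffer; `enumerate_candidates()` can therefore be run (or gridded)
over both modes. With `max_missed_cleavages = k` every concatenation of up to
k + 1 adjacent fully cleaved fragments is enumerated, and each product records
its 1-based coordinates, so peptide positions always round-trip against the
parent sequence.

Candidate filters follow the assay's design rules: length at most 24 residues
("shorter than 25"), neutral unmodified monoisotopic mass at least 600 Da,
and uniqueness within the supplied family, evaluated as exact substring
occurrence (I and L distinct) in exactly one member's full sequence.
Enumeration defaults to zero missed cleavages; missed-cleavage quantification
species (such as the H1.1 peptide `KKPAGPSVSELIVQAASSSK`) are declared
explicitly in the assay table rather than auto-selected, because picking them
requires instrument evidence, not sequence logic. PeptideAtlas empirical
suitability scores are *consumed* (`annotate_ess()`, `rank_by_ess()`), never
computed.

The package ships `synthetic_h1_family()`: the seven real quantification
peptides embedded at their catalogued coordinates inside deterministic,
synthetic H1-like flanking sequence (lysine/alanine/proline-rich). This keeps
every positional and uniqueness test self-contained; it does *not* reproduce
the canonical UniProt sequences, so benchmark candidate counts obtained on
the true family (53 unique candidates; 15 for H1X; 4 for H1.4) can only be
checked after the user supplies those sequences, which the package does not
redistribute.

## Mass arithmetic

Neutral monoisotopic masses use the standard residue table
(water 18.010565 Da, proton 1.007276 Da). Heavy labels are full
¹³C/¹⁵N substitutions — K +8.0142, L/I +7.017165, A +4.0071 Da — the exact
values behind the nominal +8/+7/+4 names; the label site per SIS peptide is
part of the assay definition since it is a synthesis choice. Fragment ions
follow the b/y conventions, and the identity
`b_i(1+) + y_(n−i)(1+) = M + 2·proton` is property-tested over random
peptides. One deliberate consequence: the H1.2 peptide `TAPAAPAAAPPAE` and
the H1.4 peptide `TAPAAPAAPAPAE` have identical composition and hence
*exactly* equal masses; the toolkit keys everything by (sequence, subtype),
never by mass.

## Calibration and limits

`fit_calibration()` is ordinary least squares of LH on amount (`lm()`),
reporting the adjusted r² and the residual standard error
`s_yx = sqrt(SSres/(n−2))`. Limits use the calibration-curve method,
`LOD = 3.3·s_yx/slope`, `LOQ = 10·s_yx/slope`, chosen because it is the
ICH-standard construction and the only one consistent with a fixed
LOQ/LOD = 10/3.3 ratio across peptides; a blank-based sigma can be passed
instead. Weighted regression and inter-day drift modelling are out of scope.

Sample quantification uses one calibration point by default
(`single_point_quantify()`, proportional through the origin:
`amount = LH · ref_amount / ref_LH`), the right model when the spiked heavy
standard itself is the reference; inverting the full fitted line is available
as `mode = "curve"`. Negative curve-mode estimates are clamped to zero with a
warning rather than propagated.

## Quantification rules

* **L/H ratio** (`lh_ratio()`): light and heavy areas are summed over the
  *intersection* of fragments observed in both labels — a transition seen in
  one label only never enters the ratio.
* **Oxidation** (`combine_oxidized()`): for Met-containing peptides
  (the H1.0 peptide `YSDMIVAAIQAEK`), oxidized and canonical areas are summed
  per label *before* ratioing. Area-level summation was chosen over
  amount-level addition because both forms share the same precursor response
  and the correction must also work when the oxidized form appears in only
  one label.
* **Missed cleavage** (`external_curve_correct()`): missed-cleavage species
  have no heavy counterpart, so each detected form is quantified against its
  own external light-peptide curve and the amounts are added; a form below
  its curve's LOD contributes zero and is flagged. External curves carry no
  same-day guarantee and no drift correction is attempted.
* **Complement** (`complement_profile()`): percentages are taken over
  subtypes not flagged below LOQ and renormalized to 100; excluded subtypes
  are reported, not silently dropped.
* **Band reconciliation** (`expected_band_percentages()`): the default
  `band_model()` maps high = {H1.3, H1.4, H1.5}, intermediate = {H1.1, H1.2},
  low = {H1.0}; H1X runs outside the resolvable bands and is removed with
  renormalization before band sums.
* **Reproducibility** (`replicate_cv()`): 100·sd/mean with the n−1 standard
  deviation.

`method_comparison()` compares PRM-derived and gel-derived band percentages
on the logit scale with a pooled two-sample t test per (cell, band) contrast
and Benjamini–Hochberg adjustment across contrasts. A joint linear model with
general-linear-hypothesis machinery would be an alternative; the per-contrast
construction was chosen because the scientific read-out is the per-contrast
significance label, and it keeps the test surface fully specified.

## Small-cohort statistics

`mcc()` implements the confusion-matrix formula directly (zero denominator →
0 by convention; heuristic benchmark 0.5). `mann_whitney_u()` counts pairs
with half-credit ties. `brcc()` is Wendt's rank-biserial
`r = 1 − 2U/(n1·n2)`, and `brcc_critical()` finds the minimal significant r
by *full enumeration* of the exact Mann–Whitney null over all
`choose(n1+n2, n2)` arrangements — one-sided, because that is the only
direction under which the published critical value for an (8, 2) cohort
(r = 0.875, printed as 0.88) is reachable; the tests cross-check the
enumeration against R's exact `pwilcox` distribution for all `n1 + n2 <= 12`.
Group sizes are always taken from the data, never hard-coded.

`roc_curve()` builds the empirical ROC with thresholds at midpoints between
distinct scores, AUC by concordance counting (ties ½, so the Mann–Whitney
identity holds exactly), and the Youden-optimal operating point (ties broken
toward higher specificity, then lower threshold). `hierarchical_cluster()`
uses 1 − Pearson correlation with average linkage (`hclust`), rejecting
zero-variance profiles; `pca_profiles()` wraps `prcomp` with variance
percentages summing to 100 and a largest-loading-positive sign convention.
Confidence intervals on AUC and multivariable risk models are out of scope.

## What the simulators emulate

`simulate_calibration()` and `simulate_sample_report()` emit transition-level
peak-area tables in the same CSV dialect the readers consume. Light areas are
proportional to the true amount, heavy areas to the spike, and noise is
multiplicative log-normal with a per-transition CV — the error structure of
integrated XIC areas, for which additive Gaussian noise would be a poor
stand-in. Default study conditions: 3 injection replicates, 10 % transition
CV, a 7-level calibration series (0.05–5 ng) at a 1 ng heavy spike, a
cell-line-like complement with H1.4/H1.5 dominant and one subtype near the
detection floor, a 20 % oxidized fraction for the Met peptide, and optional
missed-cleavage fractions emitted as light-only rows (matching the
external-curve workflow). `simulate_cohort()` draws total H1 per mL from
group-shifted normals (responders 60 ± 20 ng/mL, non-responders +60 by
default, a clearly separable but overlapping effect) and subtype percentages
from group-specific Dirichlet distributions — respecting the sum-to-100
constraint — with non-responders low in H1.0, H1.1 and H1X.

What the simulators do **not** model: chromatographic peak shape and
integration, retention-time drift, matrix interference, between-day
calibration drift, and correlated transition noise. Passing recovery tests
therefore demonstrates the correctness of the arithmetic and correction
rules, not robustness to those instrument-level effects.

Problem sizes in the test-suite simulations (3–48 replicates, 30–40 Monte
Carlo runs, cohorts of 8) were chosen so each property is measured with
comfortable margin while the whole suite stays fast.

## Numerical choices and degenerate inputs

Boundary proportions are clamped to ε = 1e−6 before the logit. Calibration
requires two distinct amounts; `s_yx` is undefined below three points; limits
require a positive slope. A heavy sum of zero, an empty light/heavy fragment
intersection, an all-below-LOQ profile and a zero-mean CV are all hard
errors — the toolkit never silently substitutes a value. Simulators restore
the caller's RNG state and are byte-identical under a fixed seed.

## Known limitations

* Uniqueness is within the supplied family; proteome-wide screening requires
  supplying a background FASTA as additional family members.
* The 1:1 peptide:protein stoichiometry of `to_absolute()` ignores
  incomplete digestion of the target itself beyond the declared
  missed-cleavage forms.
* `brcc_critical()` enumerates `choose(n1+n2, n2)` arrangements and is meant
  for the small cohorts it was designed around (n1 + n2 ≲ 20).
* The shipped FASTA is a synthetic-context family; benchmark candidate
  counts on the canonical sequences require a one-time download by the user.
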