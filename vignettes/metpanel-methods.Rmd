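---
title: "Methods: count-rule metastasis panels and the calibrated synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: count-rule metastasis panels and the calibrated synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metpanel)
```

## The model

`metpanel` evaluates multi-marker *count-rule* classifiers for distant
metastasis in clear cell renal cell carcinoma. The raw material is one
number per tumour per marker: relative expression (RQ) for four
protein-coding genes and a methylation index (MI) for miRNA gene promoters.
Each marker is binarised into an **event** at a cutoff — expression low
(value ≤ cutoff), methylation high (value > cutoff) — and a sample is called
high-risk when at least *k* of the *m* panel events fire. The built-in
panels use 3 of 4 expression events, 4 of 5 methylation events, and 6 of all
9 events.

The count rule is deliberately simple: it needs no fitted weights, degrades
gracefully when a marker is borderline, and its single tuning knob *k*
trades sensitivity against specificity monotonically (a property the test
suite asserts on random event matrices). The ordinal event count (0..m) is
exposed alongside the binary call so the whole operating family — every
k-of-m rule is a threshold on the count — can be inspected as one ROC curve.

## Quantification scales

**Relative expression.** RQ = E^(−ΔΔCt) with
ΔΔCt = (Ct_target − Ct_ref)_tumour − (Ct_target − Ct_ref)_normal, reference
gene GAPDH, paired normal tissue from the same kidney. The amplification
efficiency E defaults to 2.0 (perfect doubling per cycle) and is
configurable per call; no standard-curve estimation is attempted. RQ = 1
means no change; the analysis scale for logistic regression is log2(RQ)
because RQ spans orders of magnitude, while rank-based statistics (U test,
ROC) are unaffected by that choice.

**Methylation index.** MI = 100·Q_M/(Q_M + Q_U), Q = E^(−Ct), from the
methylated-specific and unmethylated-specific reactions. A reaction that
never crosses threshold ("undetermined") contributes Q = 0, so the
boundaries MI = 0 and MI = 100 arise *only* from single-channel
amplification — for finite Ct pairs MI is strictly interior, and MI is
strictly decreasing in Ct_M. There is an alternative convention that
normalises against a fully-methylated control; with no basis for choosing
it, the M/(M+U) fraction is used because it satisfies the 0–100%
endpoint semantics exactly.

**Conversion QC.** Bisulfite conversion is verified per sample on the ACTB
locus with primers specific to the *unconverted* template: any signal before
35 cycles (configurable) fails the sample, and failing samples lose all
methylation values rather than carrying a biased MI. The "undetermined"
token in input files is parsed as a true missing value and never coerced to
a pseudo-cycle count such as 40.

## Marker screening

Association with metastasis is screened per marker with the two-sided
Mann–Whitney U test (exact enumeration when the smaller group has ≤ 8
observations and there are no ties; otherwise the normal approximation with
tie and continuity correction), Benjamini–Hochberg adjustment, and
univariate logistic regression with a Wald test. Design choices the data do
not dictate, made once:

* **FDR families.** BH is applied within modality (expression markers one
  family, methylation markers the other), mirroring how the two marker
  groups are reported separately; `fdr_family = "global"` pools them.
* **Logistic scale.** log2 for expression, raw percent for methylation.
* **Separation.** A diverging slope (quasi-)separation is flagged and the
  p-value withheld rather than reported as a meaningless Wald number.
* **Missingness.** Pairwise deletion per marker; markers more than half
  missing are dropped with a warning.

## ROC cutoffs

The empirical ROC is swept over observed values only, so a reported cutoff
is always a data value rendered with its direction ("≤ v" for expression,
"> v" for methylation, the expression boundary inclusive and the methylation
boundary strict). The direction is fixed a priori by modality, never flipped
to whichever AUC is larger — flipping would overfit the direction to noise.
The optimal cutoff maximises Youden's J = sensitivity + specificity − 1;
ties are broken toward higher specificity, and J is compared on the integer
scale tp·n₀ − fp·n₁ so exact ties are resolved exactly rather than by
floating-point noise. AUC uncertainty uses the DeLong placement-value
variance (95% CI, two-sided z test against 0.5); degenerate curves (AUC 0
or 1) clip the interval with a warning. The per-marker AUC equals the
Mann–Whitney U divided by n₁·n₀, a duality the tests check on every
synthetic cohort.

## Panel performance

Diagnostic rates are reported in percent with exact Clopper–Pearson 95%
intervals from the binomial distribution of each confusion cell. PPV or NPV
with an empty denominator is reported as undefined, not as a number.
Percentages are rounded half-up to two decimals only at the reporting layer;
all comparisons happen on unrounded values.

`reconstruct_confusion()` inverts published sensitivity/specificity and
group sizes into the unique integer confusion matrix (rounding half-up) and
verifies the rates round back — this is what makes a published performance
table auditable without its underlying data, and the acceptance script uses
it to recompute the published panels' NPV/PPV exactly.

## The synthetic cohort generator

The reference study's per-sample values are unavailable, so the generator
emulates their statistical structure: 31 metastatic and 49 non-metastatic
samples; for each marker a distribution whose *group medians* equal the
published ones, because medians are what the study reports.

* **Expression** is log-normal with log-median equal to the log of the
  configured median. The log-scale SD is a calibrated constant per marker,
  solved in closed form from AUC = Φ(log(m₀/m₁)/(σ√2)) so that the
  large-sample single-marker AUC equals the published one (CA9 1.453,
  NDUFA4L2 1.907, EGLN3 1.094, BHLHE41 0.723).
* **Methylation** is Beta rescaled to [0, 100], parameterised by a location
  µ (solved by bisection so the Beta median equals the configured median)
  and a concentration κ calibrated numerically against the published AUC
  (MIR125B1 5.22, MIR137 3.24, MIR375 2.31, MIR193A 3.83, MIR34BC 3.67,
  MIR1258 19.9). The three miRNAs without a published ROC row (MIR107,
  MIR203A, MIR132) take the median significant-miRNA concentration, 3.67.
* **Dynamic range.** Draws are clipped to the values resolvable within a
  45-cycle qPCR run (at most 24 cycles between paired reactions, i.e. RQ in
  [2⁻²⁰, 2²⁰], MI within ~6·10⁻⁴% of the boundaries); more extreme values
  would be unmeasurable in the assay the generator imitates.
* **Determinism.** Each marker draws from its own substream seeded from
  (global seed, marker name), so cohorts are fully reproducible and adding a
  marker never perturbs the others.
* **Raw-Ct emission.** The generator can invert the quantification
  equations: expression quadruples anchor the reference at 20 cycles and
  normal-tissue target at 24 (only differences matter to ΔΔCt); methylation
  pairs anchor the stronger channel at 20 cycles and encode MI in the Ct
  difference. Quantifying these tables reproduces the simulated values to
  ~10⁻¹² (round-trip-tested), and the ACTB control is emitted as
  undetermined so all samples pass QC.

What the generator does **not** model — and therefore what green tests do
not certify about real cohorts: between-marker correlation (markers are
drawn independently, although co-regulated hypoxia genes are correlated in
tumours, so simulated combined-panel performance is optimistic), batch and
plate effects, PCR efficiency variation, clinical covariates, and any
relationship between expression and methylation in the same sample.

## Numerical and testing choices

Unit and property tests run on small cohorts and tiny problem sizes chosen
for speed: 100 random instances (n ≤ 30) for the AUC/Youden brute-force
oracles, a 20000-draw permutation check of the Mann–Whitney approximation
at n = 15/15, 500 null replicates at n = 80 for the type-I error of the
screen, 9 replicate cohorts at n = 5000/group for median-calibration
convergence (the median of replicate estimates is compared at 5% because a
single group-median estimate at that size still has ~3% sampling error for
the widest calibrated dispersions), and 200 replicates at the study size
for unbiasedness sign tests (BH-controlled across the 26 marker × group
combinations). An independent ROC implementation (pROC) cross-checks AUC
and DeLong intervals in the tests but is never used in the computation
path.

## Known limitations

* Published per-gene medians, AUCs and cutoffs are calibration references,
  not reproducible targets, without the original per-sample data.
* The published panel CIs came from an unspecified calculator; this package
  reports Clopper–Pearson, so interval bounds are comparable only in
  spirit, while the point estimates match exactly.
* Whether the published logistic p-values are Wald, score or LR tests is
  unstated; Wald was chosen and documented.
* The count-rule thresholds k = 3/4/6 are taken as given, not re-optimised;
  `count_panel()` defaults to k = ⌈2m/3⌉ for other marker sets, which
  reproduces the built-ins.
* MIR1258 is available as a marker (with its published cutoff) but is not a
  member of any built-in panel, matching the published panel composition.
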