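---
title: "Methylation-based early-recurrence prediction: models and methods"
author: "pdacmeth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methylation-based early-recurrence prediction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdacmeth)
```

## The problem and the data model

Pancreatic ductal adenocarcinoma recurs within six months of curative
surgery in a sizeable minority of patients, and these early-recurrence
(ER) patients have markedly worse overall survival. `pdacmeth`
implements a methylation-array workflow for finding CpG markers of ER
and combining them into a small diagnostic voting panel.

The workbench object is the **beta matrix**: probes × samples methylation
fractions β = M/(M+U) in [0, 1], optionally paired with detection
p-values (the probability that a probe's fluorescence is background
noise in a given sample). Internally everything is kept on the fraction
scale; percentages appear only at I/O boundaries and in diagnostic
cut-offs, because the clinical quantification platform (pyrosequencing)
reports percent. `convert_scale()` is the single bridge between the two.

Clinical records carry a tissue group — C (normal control pancreas from
non-cancer patients), N (non-cancerous tissue from cancer patients),
T (tumour) — plus recurrence status and recurrence-free/overall survival
times in days.

## Probe quality control

Two ordered exclusion passes (`filter_probes()`):

1. **Low call proportion.** A probe is *called* in a sample when its
   detection p < 0.01; probes called in fewer than 90% of samples are
   removed. Persistent low detection often reflects polymorphism at the
   probe CpG rather than biology.
2. **Sex chromosomes.** Remaining X/Y probes are removed to avoid
   sex-linked methylation bias in mixed-sex cohorts.

A probe failing both rules is counted once, under the first rule — the
exclusion reasons partition the removed probes, so the totals always add
up regardless of overlap between the two sets. Both thresholds
(`detection_alpha = 0.01`, `call_prop_min = 0.90`) are parameters.
Matrices without detection p-values can skip pass 1 explicitly
(`require_detection = FALSE`); silence is never the default.

## Differential methylation screens

`differential_screen()` tests each probe with Welch's unequal-variance
*t* and filters on effect size. A probe is selected when

* (Bonferroni-adjusted) p < α, with the family size m equal to the
  number of probes *actually tested in that screen* (the post-QC set,
  minus probes with fewer than two non-missing values per group, which
  are skipped and flagged rather than failed), and
* |Δβ| > 0.1, where Δβ is the difference of group means.

Two-sided p-values are used throughout; for a genome-wide screen no
direction is privileged a priori. The tissue screens (T vs C, T vs N)
apply Bonferroni; the ER marker screen deliberately does not (see
below). Missing betas are handled pairwise per probe. Selection is
invariant to probe and sample order, and swapping the groups negates
every Δβ and exchanges the hyper/hypo counts — both properties are
enforced by tests.

## Epigenotyping

PCA (`pca_project()`) runs on mean-centred, unscaled probes — betas
already share a common scale, so variance scaling would only inflate
noise probes. Component signs are fixed by making the largest-magnitude
loading positive; eigen-decompositions are otherwise sign-ambiguous and
unstable across BLAS implementations.

Ward clustering (`ward_cluster()`) uses the Ward-on-Euclidean-distances
convention (`hclust` method `ward.D2`). Two details are deliberate:

* Samples are sorted by id before clustering and clusters renumbered by
  first appearance, so the partition and labels are reproducible and
  independent of column order.
* The number of clusters `k` is a parameter (default 4), not a fitted
  quantity; model selection (silhouette, gap, consensus) is out of
  scope.

Cluster–clinical associations (`associate_clusters()`) are Fisher exact
tests on a 2×2 table of a binary cluster super-grouping against a binary
clinical factor. Super-groupings are an explicit user-supplied mapping
(`merge_clusters()`), mirroring the common practice of post-hoc merging
of clusters with similar clinical tendencies; the package does not
choose the merge itself (`run_pipeline()` merges the upper half of
clusters ranked by ER incidence, purely as a demonstration default).

## The ER marker panel

**ER definition.** ER is relapse within `er_window_days` after surgery;
the default is 183 days. "Six months" is not a well-defined number of
days, so the window is an explicit parameter; 183 = ⌈365.25/2⌉.
Non-recurrent patients whose follow-up is shorter than the window are
counted non-ER but flagged indeterminate — with near-complete recurrence
ascertainment in the target setting this is a minor approximation, and
silently dropping such patients would bias specificity upward.

**Marker screen.** `screen_candidates()` is two-staged: a raw-p Welch
screen (p < 0.05, |Δβ| > 0.1) followed by an ROC filter (AUC > 0.7,
strict). The omission of Bonferroni here is intentional asymmetry: the
marker screen is a candidate generator whose false positives are pruned
by the AUC filter and by validation, not a genome-wide inference. The
marker's direction is fixed at screening time by the sign of Δβ —
ER mean below non-ER mean makes low values call ER — and never refit.

**Cut-offs.** Each marker's threshold is the Youden-index optimum of its
empirical ROC curve. Candidate thresholds are midpoints between
consecutive distinct pooled values (± infinite sentinels), which keeps
calls stable under measurement jitter; the AUC is the trapezoid over the
resulting operating points and equals the tie-corrected rank statistic.
Ties on J are broken toward higher sensitivity (a recurrence missed is
costlier than a false alarm in this screening context), then toward the
more permissive threshold. A sample exactly at the cut-off is **not**
called positive; the rule is strictly "below" (or "above").

**Voting panel.** `fit_er_panel()` keeps the top `n_markers` (default 3)
by AUC and declares a patient panel-positive when at least
`min_positive` (default 2) markers call ER. For every dataset the k-of-n
family is monotone — sensitivity non-increasing, specificity
non-decreasing in k — which is asserted at evaluation time.
`transfer_panel()`/`predict()` apply the frozen rule to new cohorts;
missing marker measurements are an error, never imputed. On synthetic
data the top-3-by-AUC rule stands in for the published panels' marker
choice, which also weighed PCR feasibility — a criterion that cannot be
modelled.

**Pyrosequencing.** Replicate merging follows the duplicate rule: mean
of two measurements, unless they differ by more than 10 percentage
points (absolute points, which is what the protocol's wording implies),
in which case a third replicate is required and the mean of three is
used. `merge_replicates()` returns an explicit needs-third signal rather
than guessing. `calibration_linearity()` checks the 0/50/100% control
line (slope within 0.2 of unity, residuals ≤ 10 points by default) and
`concordance_check()` reports Pearson r between platforms.

## The synthetic cohort generator

`simulate_cohort()` draws the cohort the analysis assumes, with full
ground truth. Design choices:

* **Beta-mixture background.** Each probe's betas come from one of two
  Beta components (modes near 0.2 and 0.8), reproducing the bimodality
  of array betas and respecting [0, 1] natively. The default
  concentration (36) gives a per-group SD of about 0.07 at mid-range
  betas — realistic inter-sample variability for tissue cohorts. No
  distributional facts about any particular deposited dataset are
  implied; these are stated modelling assumptions.
* **Mean-shift planting via shapes.** Planted probes shift the affected
  group's *mean* through the Beta shape parameters at constant
  concentration rather than by additive offset, avoiding probability
  mass piling at the clip boundaries. Planted probes start in the
  component with headroom for their shift (hypermethylation is planted
  on unmethylated-mode probes and vice versa — the direction
  carcinogenic drift takes in practice), so realized Δβ is unbiased;
  a test checks the 50-seed average against the configured Δ within
  0.02.
* **Defaults mirror the study design**: 17 C / 34 N / 82 T samples,
  22/82 ER patients, tissue-effect Δβ = 0.30, ER-marker Δβ = 0.15,
  AUC bar 0.7, 1% planted detection failures, 2% sex-chromosome probes.
  ER signal is planted in T samples only. ER patients relapse at 60–180
  days and die at RFS + 100–400 days; non-ER patients mostly relapse
  late (200–1500 days) or are censored, and OS never precedes RFS.
* `simulate_validation_cohort()` re-draws tumour samples from the same
  generative model (same probe roles and background means, new
  patients), emulating an independent series on the same platform.

What the generator does **not** emulate: Infinium I/II chemistry biases,
batch effects, tumour-purity gradients, spatially correlated
co-methylation, or FFPE artefacts. Passing recovery tests therefore
demonstrate correctness of the pipeline's logic under its stated
assumptions, not expected performance on real cohorts — where effect
sizes are confounded with cellularity and the marker screen's false
positives are pruned only by external validation.

## Numerical conventions and degenerate inputs

* Fisher's two-sided p uses the probability-mass rule (sum of
  hypergeometric probabilities ≤ that of the observed table, with a
  1e-7 relative tie guard); a zero margin returns p = 1.
* Welch with both variances zero: statistic 0 and p = 1 when means are
  equal, ±∞ and p = 0 otherwise — degenerate probes must not crash a
  genome-wide screen.
* Kaplan–Meier median: the smallest observed event time with
  S(t) ≤ 0.5; `NA` when never reached. The log-rank variance uses the
  standard hypergeometric form, and the test refuses to run with no
  events at all.
* The QC, screen and panel stages never reorder samples; all outputs
  carry ids.

## Problem sizes used in the shipped tests

The test-suite and acceptance studies run at sizes chosen to give the
properties adequate power while keeping the suite quick: cohorts of
1,200–5,000 probes at the full 133-sample design, 50 seeds for the
recovery/transfer studies, 12 null screens of 2,000 probes for the
family-wise-error check, 8,000 simulated tests for the null-uniformity
of Welch p-values, and exhaustive Fisher enumeration over all 2×2 tables
with total ≤ 24. These are the package's own choices of demonstration
scale; all thresholds in the code are the analysis defaults stated
above, independent of test size.

## Known limitations

* Bonferroni is the only multiplicity correction offered (by design;
  FDR methods would change the screens' meaning).
* No Cox models or multivariable clinical prediction; survival analysis
  is two-group KM/log-rank.
* Cluster-count selection and dendrogram graphics are out of scope.
* The published panels rest on pyrosequencing measurements that are not
  publicly deposited, so their exact confusion counts are reproducible
  only as arithmetic on the printed group sizes — which the acceptance
  script does — not by re-measurement.
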