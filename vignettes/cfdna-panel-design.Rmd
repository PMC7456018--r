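---
title: "Designing cfDNA capture panels from low-burden mutation signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing cfDNA capture panels from low-burden mutation signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panelforge)
library(dplyr)
```

## The problem and the model

Circulating tumor DNA (ctDNA) is typically well under 1% of the cell-free
DNA (cfDNA) in plasma, so a targeted sequencing panel for tumor-variant
detection must spend its limited genomic footprint on the mutations most
likely to be present — across patients and across the subclones of a
heterogeneous tumor. panelforge implements a machine-learning route to that
prioritization built on a *low-burden hypothesis*: tumors accumulate
passenger mutations as they evolve, so mutations observed in tumors with
the **lowest** overall mutational burden are enriched for drivers and for
clonal variants — exactly the mutations most worth capturing in cfDNA.

The pipeline is:

1. **Burden labeling.** Cohort donors are sorted by somatic mutation count
   and split at the median into Low Burden (LB) and High Burden (HB)
   halves; every mutation inherits its donor's class. Driver enrichment of
   the LB class can be checked with an upper-tail hypergeometric test
   against a driver-gene list.
2. **Classification.** A class-weighted linear support vector classifier
   (SVC) is trained on per-mutation feature annotations (e.g. functional
   impact, regulatory context, conservation — consumed as an input table,
   never computed here) to discriminate LB from HB mutations, with
   stratified 10-fold cross-validation and drop-one feature selection.
3. **Ranking.** Every mutation in the catalog is scored by its signed
   perpendicular distance from the decision hyperplane,
   $d = (w \cdot x + b) / \lVert w \rVert$, positive on the LB side; larger
   distance means more "driver-like" under the hypothesis.
4. **Gene-length correction.** Raw distances are z-scored within
   gene-length bins so that long genes do not crowd the panel.
5. **Panel construction.** The top-ranked mutations are expanded by
   ±175 bp (the modal dinucleosomal cfDNA fragment is ~350 bp) and merged
   into non-overlapping probe intervals.
6. **Evaluation.** Panels are compared by in-silico capture of per-focus
   somatic call sets (paired t-test across foci), and cfDNA screens are
   filtered by depth/alt-read QC, multi-focus somatic presence, and a
   germline allele-fraction bound.

## Why a linear max-margin classifier

The LB/HB labels are intentionally noisy: drivers also occur in HB tumors
(the hypothesis claims *enrichment*, not partition), so a large fraction of
LB-labeled mutations are effectively mislabeled passengers. A linear
max-margin model tolerates label noise gracefully and keeps feature weights
interpretable — the single-feature weight view
(`single_feature_weights()`, `autoplot()` on a fitted model) directly shows
which annotations pull toward LB and which toward HB.

The solver is an L2-regularized squared-hinge linear SVC fit by dual
coordinate descent with shrinking (in C++ via Rcpp). Drop-one feature
selection refits the model with each feature excluded in every
cross-validation fold — about 3,400 fits at catalog scale — which is why
the package carries its own solver with warm starts across the drop-one
sweep. An independent SVM implementation (e1071/libsvm) is used in the test
suite to cross-check hyperplane directions; it plays no role in the
pipeline itself.

## Tunable parameters

| Parameter | Default | Where | Meaning |
|---|---|---|---|
| `max_len` | 200 bp | `filter_indel_length()` | largest indel length change kept in the catalog |
| `target_n` | 50,000 | `downsample_mutations()` | training rows after ratio-preserving down-sampling |
| `k` | 10 | `train_cv()`, `select_features()` | cross-validation folds (stratified) |
| `drop_threshold` | 0.001 | `select_features()` | minimum mean accuracy drop (0.1%) for a feature to be retained |
| `C` | 1 | all fitting functions | hinge-loss cost; class weights additionally scale it inversely to class frequency |
| `tol` | 0.01 | all fitting functions | projected-gradient-range stopping tolerance of the dual solver |
| `n_bins` | 10 | `standardize_scores()` | gene-length quantile bins for score standardization |
| `k` | 7,034 | `select_top()` | panel size in mutations (~2.5 Mb probe footprint at ±175 bp) |
| `flank` | 175 bp | `build_probes()` | probe half-width around each mutation |
| `min_donors` | 2 | `build_frequency_panel()` | recurrence bound for the comparison panel |
| `min_depth`, `min_alt_reads` | 500, 5 | `screen_config()` | cfDNA QC floors (reported in output provenance) |
| `germline_af_max` | 0.20 | `screen_config()` | strict upper bound on somatic allele fraction |
| `min_foci` | 2 | `screen_config()` | tumor foci a variant must appear in |

Accuracy is raw held-out accuracy (a balanced variant can be computed from
the stored per-row predictions); the ROC is built from decision values
pooled across held-out folds, with LB positive. Class probabilities, where
wanted for plots, come from a Platt-type sigmoid fit to decision values
(`platt_calibration()`) — the max-margin model itself is not probabilistic.

## Design choices made where the design was open

* **Median split ties and odd cohorts.** Donors are ordered by burden with
  ties broken lexicographically by donor id, so the split is deterministic;
  with an odd donor count the extra donor goes to LB by default
  (`odd_to =`), keeping candidate drivers in play.
* **Cross-class variants.** A variant carried by donors of both classes is
  labeled LB in the unique-variant view, again to avoid discarding
  candidate drivers.
* **Gene-length standardization.** The correction is within-bin z-scoring
  over 10 gene-length quantile bins — the simplest transform that
  decorrelates gene length from per-gene selection counts while leaving
  non-coding and unannotated mutations untouched. Bins are quantile-based
  (not fixed-width) so each bin is populated; bins with fewer than two
  mutations pass scores through unscaled with a warning. When a gene has
  several transcript lengths, the longest is used.
* **Germline bound strictness.** The allele-fraction bound is strict
  (`af < 0.20`): heterozygous germline variants concentrate near 0.5, so
  the boundary itself is treated as presumptively germline.
* **Panel comparison test.** Captured counts are matched per (patient,
  focus), so the default comparison is a *paired* two-sided t-test across
  foci; Welch's two-sample test is available. With a single focus the
  statistic is flagged undefined rather than computed.
* **Capture rule.** A variant is captured if its reference span overlaps
  any probe by ≥1 bp (hybrid capture pulls any overlapping fragment);
  indels therefore count when they graze a probe edge. Probe intervals are
  0-based half-open and only converted at the BED boundary; variant
  coordinates are 1-based throughout.

## The synthetic cohort generator

`sim_config()` / `simulate_cohort()` generate cohorts with known ground
truth: 550 donors split into a low- and a high-burden negative-binomial
component, 339 per-mutation features of which 20 carry a +1.5 sd mean
shift for mutations of truth-low-burden donors, a compact 4 × 50 Mb genome
with 200 genes spanning ~1 kb–2 Mb, a shared hotspot pool creating
class-agnostic recurrence, 3 tumor foci per patient at 0.8 sharing, and
cfDNA read counts drawn binomially at 2500× depth and 4% tumor fraction.
Germline variants are planted at allele fraction ≈ 0.5 so the 20% bound is
exercised from above.

Defaults that are not externally fixed were chosen once as plausible
desk-scale values and are documented rather than revisited: per-donor
burden means (20 vs 800) are a deliberately scaled-down stand-in for
whole-genome burdens that preserves the ~1:40 LB:HB mutation ratio the
classifier must cope with; the indel fraction (9%) matches the rough
SNV/indel composition of large somatic catalogs.

What the generator does *not* emulate: mutational signatures and sequence
context, correlated feature blocks (real annotation features are strongly
collinear), clonal hematopoiesis, and caller-specific artifacts. Passing
tests on this generator therefore demonstrate the correctness of the
machinery — labeling arithmetic, solver geometry, interval algebra, filter
logic — not clinical performance on real cfDNA.

## Numerical notes and a known limitation

* The solver stops when the projected-gradient range of the dual falls
  below `tol` (default 0.01); coordinate sweep order comes from a private
  deterministic generator, so fits do not consume R's RNG stream and every
  stage is byte-reproducible under `seed`.
* Score ties (in ranking and top-k selection) break by variant key, so
  panels are reproducible row-for-row.
* Degenerate inputs are handled explicitly: constant features get weight 0;
  empty panels summarize to zeros; probe intervals near the chromosome
  origin are clipped at 0 with a warning; a feature-selection run in which
  no feature clears the threshold errors with advice rather than returning
  an empty model.
* **Drop-one selection saturates on separable data.** If the planted
  signal is strong enough that held-out accuracy is at ceiling, excluding
  any single informative feature barely moves accuracy (removing one of
  $m$ equal effects scales the class separation by $\sqrt{(m-1)/m}$), and
  a fixed absolute threshold such as 0.1% retains few or no features. The
  procedure is informative precisely in the non-saturated regime — e.g.
  at ~0.76 accuracy, where the method is meant to operate. Unit tests pin
  the non-saturated behavior (exact recovery of 2 planted features among
  10 at n = 8,000, where a 0.1% drop exceeds sampling noise); the
  saturated regime is exercised deliberately and documents this
  limitation.

## Problem sizes used by the tests

The shipped tests run cohorts of 20–550 donors, feature matrices up to
5,000 × 339 (the drop-one sweep, ~1 minute) and 8,000 × 10, and screening
fixtures of a few hundred calls — sizes chosen so the whole suite
completes in a few minutes while still exercising every code path at the
catalog-shaped aspect ratios the pipeline targets.
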