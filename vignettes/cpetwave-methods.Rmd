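---
title: "Methods: wavelet features and SVM classification of CPET signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wavelet features and SVM classification of CPET signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpetwave)
```

## The problem and the model

Cardiopulmonary exercise testing produces, per subject, a handful of
breath-by-breath time series (heart rate, V̇O₂, V̇CO₂, ventilation,
respiratory rate, and — depending on the equipment — METS, RER and tidal
volumes). Series lengths differ between subjects and sampling is irregular
(one row per breath), which rules out fixed-length vector methods applied
to the raw traces. `cpetwave` follows a two-stage design:

1. **Per-variable multiresolution summary.** Each signal is decomposed with
   the orthogonal Daubechies-2 (db2) discrete wavelet transform into detail
   bands `d1..dL` (finest to coarsest) and a final approximation `ap`.
   Because the DWT is linear and db2 has two vanishing moments, the detail
   bands capture breath-to-breath and mid-scale fluctuation while `ap`
   carries the slow rest–ramp–recovery profile. Taking the **mean and
   variance of each coefficient vector** turns a recording of arbitrary
   length into `2(L + 1)` numbers per variable — a drastic, deliberately
   cheap dimensionality reduction whose working assumption is that class
   information lives in signal levels and band-wise variability, not in
   precise temporal alignment.
2. **Maximum-margin classification** on the resulting subject × feature
   matrix, with repeated cross-validated evaluation.

The five feature layouts differ only in the component set and variable set:
`X` (raw mean/variance), `BW3`/`BW5` (wavelet summaries at 3/5 levels,
two-class variable set), `MW3`/`MW5` (3/5 levels, three-class variable
set). Column counts are `2V` and `2V(L + 1)`.

### Variable sets

The two-class (HF vs MS) source exports nine usable breath-by-breath
variables, but the documented two-class matrix is 30 × 16, i.e. eight
variables. We drop the expiratory tidal volume `Vtex` and keep `Vtin`: the
two are near-duplicates (same breath volume measured on the two half
cycles), so removing either reconciles the counts with minimal information
loss. The default two-class set is therefore `METS, HR, VO2, VCO2, RER,
VE, RR, Vtin`, and the three-class set is `HR, VO2, VCO2, VE, RR` — the
five variables available for all three cohorts. Both are configurable in
`feature_config()`.

## Numerical choices in the DWT

* **Boundary handling.** Default is half-point *symmetric* extension — the
  common default in mainstream wavelet toolboxes, and it keeps the details
  of a constant signal exactly zero. *Periodization* is also provided; it
  makes the transform orthonormal, so coefficient energy equals signal
  energy exactly, which is the property the test suite uses as an
  independent check (the analysis operator, written as an explicit matrix,
  is verified to satisfy `W Wᵀ = I`). Both modes reconstruct the input to
  machine precision (contract: 1e−8 relative).
* **Feasibility rule.** Each level requires its input to be at least the
  filter length (4 samples). Decomposing further raises an error that
  states the maximum feasible depth rather than silently truncating.
* **Variance convention.** Coefficient variances use the unbiased (n−1)
  denominator, matching the default of mainstream numerical environments;
  the biased form is available (`variance = "biased"`). A length-1
  coefficient vector gets variance 0 rather than NA.
* **Column order.** Feature names follow
  `<VAR>__<component>__<mean|var>`, variable-major then component
  (`d1..dL, ap`) then statistic. Classification is order-invariant; the
  fixed order exists so that persisted matrices are byte-reproducible.

## The classifiers

Binary machines solve the usual soft-margin dual (box constraint C = 1 by
default) with an SMO-type solver using maximal-violating-pair working-set
selection; the contract is on the decisions, not solver internals, and the
solver is deterministic — the `seed` argument exists only for API
stability. Kernels: linear `x·z`, polynomial `(1 + x·z)³` and RBF
`exp(−‖x−z‖²/s²)`, all with defaults mirroring the common toolbox defaults
(degree 3, offset 1, scale 1) because no tuning is part of the method.
Features are standardized to zero mean / unit variance **using training
rows only**; a zero-variance feature maps to exactly 0. Convergence
tolerance is 1e−6.

The three-class model is one-vs-one ECOC: one binary machine per class
pair, a `{+1, −1, 0}` coding matrix, and decoding by minimal mean binary
hinge loss `max(0, 1 − m·f)/2` over the machines each class participates
in. Ties — including the fully degenerate case of identical feature rows —
break to the lowest class index (HF before MS before H). On a two-class
problem, decoding a single pairwise machine reduces exactly to the binary
decision rule (tested).

## Evaluation

* **Folds.** Unstratified by default: a seeded random permutation of the
  subject indices is cut into k contiguous blocks whose sizes differ by at
  most one. Stratified splitting is available behind a flag but is not the
  documented default.
* **Confusion-matrix orientation.** Rows are *predicted*, columns *true*.
  This orientation is forced by the per-label reduction: the row-m sum
  minus the diagonal must be the false positives of class m.
* **Pooling.** Within one repeat, the k held-out prediction sets are pooled
  into a single confusion matrix before metrics are computed; reported
  metrics are the arithmetic mean over repeats. Pooled-then-averaged was
  chosen over per-fold averaging because fold-level matrices on 6–9
  subjects are too unstable to give meaningful ratios.
* **Degenerate ratios.** Any 0/0 metric (e.g. precision with no positive
  predictions) is reported as 0 and flagged in an attribute, so macro
  averages never propagate NaN. A training split that lost an entire class
  (possible without stratification at small n) raises a warning and the
  fold is skipped and recorded in the report.
* **Positive class.** For two-class reports the per-label table contains
  both classes; HF (index 1) is the conventional positive class.

## The synthetic cohort generator

The generator exists so that every pipeline stage is testable without
clinical data. It emulates exactly the structure the method relies on:

* a three-phase protocol — constant rest baseline (15% of the record),
  linear incremental ramp to a class-dependent peak (60%), exponential
  recovery toward baseline (25%, time constant 0.25 × recovery length, so
  the endpoint settles within ~2% of baseline);
* class-dependent physiology at `delta = 1`: HF with blunted peaks (peak
  V̇O₂ 1.2 L/min, peak HR 110), MS intermediate (2.0 L/min, HR 150, with a
  slightly elevated resting HR), H highest (2.8 L/min, HR 170) — values in
  the range reported for incremental treadmill tests;
* a separation dial `delta` that linearly scales all between-class
  parameter differences around their class means: `delta = 0` makes the
  classes exchangeable in expectation, larger values exaggerate contrast
  (peak V̇O₂ ordering HF < MS < H holds by construction for any
  `delta > 0`);
* per-subject log-normal variation (sd 0.08 on baselines and peaks),
  stationary AR(1) breath-to-breath noise (ρ = 0.3, sd = 5% of each
  variable's class-mean dynamic range), and variable record lengths
  (120–480 breaths) to exercise the length-agnostic contracts.

What it does **not** emulate: irregular within-test protocol changes,
measurement artefacts and sensor dropouts, demographic covariates and their
confounding, inter-device calibration differences, or any physiologic
coupling between variables beyond shared phase structure (each variable
gets independent noise). A green synthetic test therefore establishes that
the pipeline is *correct and discriminates when class structure exists*; it
says nothing about clinical accuracy on real cohorts, which must be
assessed on real recordings loaded through `load_cohort()`.

## Known limitations

* The db2 wavelet is fixed (the filter pair is hard-wired); other wavelet
  families would require extending `db_filters()`.
* No hyperparameter search: kernels run at their documented defaults, as
  the method prescribes.
* No resampling/interpolation of the breath-by-breath series: features are
  per-variable statistics, so unequal lengths are fine, but methods needing
  aligned multichannel samples are out of scope.
* Exact replication of any particular external solver's decision boundary
  is not guaranteed (different SMO implementations can select different
  support vectors on non-separable data); all contracts are therefore on
  decisions, metrics and their invariants.
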