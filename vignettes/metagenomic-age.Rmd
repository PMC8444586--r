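---
title: "Functional metagenomic profiling and relative metagenomic age"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional metagenomic profiling and relative metagenomic age}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metagage)
```

## The problem

Longitudinal two-cohort infant studies ask whether one cohort's gut
microbiome *functional capacities* (gene families and the modules and
pathways they form) develop more slowly than the other's. Cross-sectional
differential abundance at each sampled age answers *which* functions differ;
it cannot by itself distinguish a developmental **delay** — cohort B at
month 9 looking like cohort A at month 7 — from a general, age-independent
disruption. `metagage` implements the full analysis chain for this
question: functional profiling from read-level annotations, per-time-point
differential abundance, and a replicate machine-learning protocol that
quantifies delay in months.

## Functional profiling

Profiling converts tables of tied best-hit alignments (one row per
read-gene pair) into normalized module and pathway abundances.

* **Fractional counting.** A read tied between $k$ genes contributes $1/k$
  to each, so each read carries total weight exactly 1; a gene annotated
  with $m$ KEGG Orthology groups (KOs) splits its count evenly over them.
  Reads mapping to genes with no KO annotation are never silently dropped:
  they accumulate in a per-sample loss tally, and
  $\sum_\text{KO} + \text{loss} = \text{reads}$ holds exactly. This exact
  conservation is the module's primary test surface.
* **Single-copy normalization.** Each sample's KO counts are divided by the
  median count of a user-supplied list of universal single-copy KOs, so
  abundances approximate average copy number per cell (the universal-KO
  median of the output is exactly 1). A sample whose universal median is
  zero cannot be normalized and is reported by name. The full
  gene-length-aware machinery of dedicated normalization tools is
  deliberately reduced to this scaling, which is the core idea and is fully
  testable.
* **Support-based aggregation.** A KO belonging to several modules
  distributes its abundance proportionally to each module's *support* — the
  fraction of the module's member KOs detected (nonzero) in that sample.
  Support is presence-based rather than abundance-weighted (a configurable
  implementation choice; presence-based support is the simpler estimator
  and degrades gracefully: with equal supports the split is even). Mass is
  conserved per sample up to an explicitly reported unmapped tally.

## Differential abundance

At each shared time point, every feature is compared between cohorts with a
two-tailed Wilcoxon rank-sum test: exact when both groups have at most 12
samples and the data are tie-free, otherwise the midrank normal
approximation with tie-corrected variance and continuity correction.
P-values are converted to q-values by Benjamini–Hochberg **within one
feature level at one time point** (modules at month 4 form one family,
separate from pathways at month 4); this matches the granularity at which
such results are conventionally reported, and is configurable simply by
adjusting which results are pooled before adjustment.

Effect sizes are $\log_{10}$ ratios of group medians with a pseudocount
$\varepsilon = 10^{-10}$ (on the normalized, copy-number-like scale) to
guard zero medians — small enough to be invisible for any detected feature,
large enough to keep ratios finite. Temporal patterns collapse per-time-point
calls into per-feature label strings with a directional-consistency flag,
and "expansion" between two time points uses a *strict* inequality on
$|\log_{10}|$ ratios: ties are measure-zero on continuous data, and strictness
keeps the count deterministic. Category enrichment between the two cohorts'
significant feature sets uses Pearson's chi-squared on the 2×2 table
without continuity correction by default (configurable), erroring on zero
marginals rather than returning an undefined statistic.

## The metagenomic age protocol

The core of the package. For one training cohort:

1. **Balanced subsampling.** Samples are randomly down-sampled so every
   modeled time point contributes the same count $n_t$ (the minimum
   available, or a configured cap). Balance prevents the age regressor from
   exploiting unequal time-point representation.
2. **Stratified 70–30 split.** Per time point, $\lfloor 0.7\,n_t \rfloor$
   training samples and the rest for testing. The floor rule uniquely
   reproduces both canonical design tables: $n_t = 23$ over 5 time points
   gives 80/35 total (16/7 per time point); $n_t = 29$ over 8 gives 160/72
   (20/9).
3. **Regularized random forest.** Host age (months) is regressed on the
   functional features with a guided-regularization forest: the split gain
   of a feature not yet used anywhere in the forest is multiplied by
   $\gamma \in (0,1]$ (default 0.8), steering trees toward a compact
   feature set; $\gamma = 1$ is a plain random forest and all protocol
   properties hold for both. `mtry` defaults to $\lfloor p/3 \rfloor$, the
   regression-forest convention of the randomForest/RRF family. The default
   forest size is 10,000 trees; at the sample sizes involved, performance
   statistics stabilize far earlier, and the package's own validation runs
   use 200 trees to keep full protocol replications fast. Training is
   single-threaded and deterministic under a fixed seed.
4. **Spline calibration.** A cubic smoothing spline with 3 effective
   degrees of freedom (trace of the smoother matrix, matched internally by
   the smoothing-parameter search to within 0.01) is fitted to the
   replicate's *own held-out* test predictions as a function of true age.
   Because linear functions lie in the penalty's null space, the spline
   reproduces exactly-linear data with zero residuals, and evaluation
   beyond the observed age range extrapolates linearly (natural-spline
   boundary behavior).
5. **Relative metagenomic age.** Every sample of the *opposite* cohort is
   scored by each replicate model:
   $\text{rel}(s, r) = \hat{a}_r(s) - g_r(a_s)$, the prediction minus the
   calibration spline at the sample's true age. The spline, not the
   identity line, is the reference: it absorbs the regression-to-the-mean
   compression that tree ensembles show at extreme ages, so a sample
   developing on the training cohort's schedule centers at zero.
6. **Delay testing.** Per replicate and time point, a two-tailed Wilcoxon
   signed-rank test of median zero. The exact sign-flip permutation
   distribution is used for $n \le 14$ — computed by convolution over the
   observed midranks, so it remains exact under ties — and the
   tie-corrected normal approximation beyond. Significance is assessed per
   replicate and summarized as the fraction of replicates calling a
   significant negative (delay) or positive (acceleration) shift;
   pooling estimates across replicates is reserved for description, since
   replicate models share samples and are not independent. A cohort-level
   "delay call" is made per time point — the final modeled time point being
   the headline, as the delay is expected to accumulate with age.

Replicates (default $R = 10$) differ in both the subsample and the split,
with fresh seeds derived per replicate from one master seed; the entire
protocol is byte-reproducible.

## The synthetic study generator

Every stage is validated against a generator with known ground truth. It
emulates a two-cohort longitudinal design (default: 25 subjects per cohort,
one sample each at months 2, 4, 6, 9 and 12, 300 KO features):

* **Age trends.** A fraction (default 0.5) of features follow logistic
  (monotone saturating) curves in age,
  $f_k(t) = b_k\,\big(1 + u_k\,\sigma((t - m_k)/s_k)\big)$, with
  feature-specific baseline, amplitude, midpoint and rate. Midpoints are
  drawn from $U(2, 15)$ — extending past the oldest sampled age because
  functional maturation of the infant gut is still ongoing at one year;
  a generator whose trends all saturate inside the window would contradict
  the developmental regime it is meant to emulate and would leave the last
  time point uninformative. Amplitudes take both signs (increasing features
  up to 3×, decreasing bounded so means stay positive).
* **Delay.** Cohort B's mean at age $t$ is $f_k(\max(t - \delta,\,
  t_{\min}))$: a pure time shift, floored at the youngest modeled age so
  the delayed cohort stays inside the modeled domain. The floor makes the
  first time point carry no delay signal by construction.
* **Cohort shifts.** A disjoint fraction (default 0.2) of features is flat
  in age but multiplied in cohort B by a factor drawn log-uniformly from
  [1.25, 2.5] (either direction) — the scale of typical published
  module-level cohort effects, where ratios above 2 are already the
  "large" tier. These features make differential abundance and delay
  separable signals: they are detectable cross-sectionally but carry no
  developmental information.
* **Noise.** Multiplicative log-normal, $\sigma = 0.3$ by default. The
  noise law of real module abundances is not well characterized; this
  default is chosen for test power, not realism, and is a tunable study
  condition.

What the generator does **not** emulate — and therefore what passing tests
do not establish about real data: compositional coupling and correlation
between features (features are independent given age), within-subject
longitudinal autocorrelation (each sample's noise is independent, so
subjects have no persistent individual microbiome signature), unequal
cohort sizes and missing visits, sequencing-depth variation, and any
taxonomic structure underneath the functional profiles.

## Validation scale and measured behavior

The package's stochastic validation runs use the generator's default study
design with 200-tree forests, 10 replicate models per cohort, and 20
independent simulated studies per scenario — sizes at which every protocol
replication completes in seconds while the quantities of interest are
stable. Under these conditions the test suite and the acceptance script
verify, among others: exact split arithmetic; exact mass conservation;
agreement of every statistical primitive with brute-force enumeration
oracles; a null ($\delta = 0$) majority-replicate delay-call rate at the
final time point within its nominal bound; recovery of a 2-month delay
(negative median relative age of the delayed cohort, positive for the
reference cohort — the mirror-image property) at the final time point; and
monotonicity of the recovered median in $\delta \in \{0, 1, 2, 3\}$.

## Known limitations

* Tree ensembles cannot extrapolate beyond the training age range, so
  relative ages are compressed at the boundary time points; the delay
  estimate at the final time point is conservative (biased toward zero).
* Strong non-developmental cohort differences push the opposite cohort's
  samples off the training feature distribution; the resulting predictions
  shrink toward the mean training age, which at late time points mimics a
  small delay and at early ones a small acceleration. The synthetic
  separability of shift and delay keeps this bias visible and bounded in
  testing, but on real data it argues for corroborating any delay call
  with the differential-abundance stage rather than reading it in
  isolation.
* With few distinct time points, the df-3 calibration spline is fitted on
  as few as 5 distinct abscissae; it needs at least 4 and will refuse
  degenerate designs.
* The delay statistic is cohort-level; per-subject developmental
  trajectories are out of scope.
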