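---
title: "Detecting and comparing 24-hour rhythms with diurnal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and comparing 24-hour rhythms with diurnal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diurnal)
library(dplyr)
```

## The problem

Mammalian physiology runs on a roughly 24-hour schedule set by light and by
feeding. In tissues such as liver, a substantial fraction of the
transcriptome — and the chromatin occupancy of the transcription machinery —
oscillates over the light/dark cycle. Two separable forces drive these
oscillations: the endogenous circadian clock, and the response to food
intake, which in nocturnal rodents under night-restricted feeding is itself
rhythmic. Disentangling them requires comparing time courses across
conditions in which one of the two signals has been removed (a clock
knockout) or flattened (feeding spread evenly around the clock), and it
requires a small set of statistical tools applied consistently:

1. a per-feature test for 24-h rhythmicity with amplitude and peak-time
   (phase) estimates,
2. an experiment-level false discovery rate for the resulting rhythmic gene
   lists,
3. set-level comparisons across conditions (which genes keep cycling, with
   what amplitude and phase change),
4. unsupervised grouping of temporal profiles, and
5. targeted comparisons of occupancy scores between day and night, or
   between two chosen timepoints.

`diurnal` implements this toolchain for tabular time courses (features ×
samples, each sample annotated with condition, zeitgeber time, day, and
replicate), together with a synthetic-data generator that plants known
rhythms and day/night effects so that every stage can be validated by
parameter recovery rather than by eyeballing.

## The rhythm model

For a feature measured at times $t$ (hours, zeitgeber time; ZT0 = lights
on), the package fits the first-harmonic (cosinor) regression with a fixed
24-h period:

$$y = b_0 + b_1 \cos\!\left(\frac{2\pi t}{24}\right)
        + b_2 \sin\!\left(\frac{2\pi t}{24}\right) + \varepsilon .$$

This is ordinary least squares on a three-column design, so the estimates
are closed-form and fast. Derived quantities:

* **mesor** $b_0$ — the fitted daily mean (log2 units);
* **amplitude** $A = \sqrt{b_1^2 + b_2^2}$ — half the peak-to-trough range
  of the fitted curve, in log2 units. An amplitude of 0.25 corresponds to a
  peak-to-trough fold change of $2^{2 \times 0.25} \approx 1.4$;
* **phase** $\varphi = \operatorname{atan2}(b_2, b_1) \cdot 24 / 2\pi$
  mapped into $[0, 24)$ — the clock time of the fitted maximum. The
  two-argument arctangent is used deliberately: the one-argument
  $\arctan(b_1/b_2)$ form is ambiguous between opposite quadrants of the
  $(b_1, b_2)$ plane, i.e. between a peak and a trough 12 h apart. When the
  amplitude is numerically zero the phase is undefined and reported as
  `NA`;
* **rhythm test** — the nested-model F statistic (intercept-only vs. full),
  $F = (SS_{\text{model}}/2)/(SS_{\text{resid}}/(n-3))$ on $(2, n-3)$
  degrees of freedom, with the exact F distribution for the p-value.

Fitting uses every individual sample: two sampling days collapse onto one
cycle through ZT, so day-1 and day-2 samples at the same ZT act as
replicates, which is what a single fixed 24-h harmonic assumes. Samples
must cover at least three distinct ZTs (full-rank design) and at least four
samples are required (one residual degree of freedom); features failing
these conditions are flagged rather than dropped silently.

A feature is *called rhythmic* when its p-value is strictly below the
threshold (default $10^{-4}$ for genome-wide expression screens, 0.05 for
the looser locus-level occupancy question). The strict inequality is a
deliberate boundary convention, as is its mirror image in the amplitude
filter: `amplitude_filter()` *eliminates* features with amplitude strictly
below the cutoff (default 0.25 log2 units), so a feature exactly at the
boundary is retained.

## Permutation FDR

P-value thresholds on thousands of parallel tests need an empirical
calibration. `estimate_fdr()` destroys the time structure by shuffling the
sample-to-ZT assignment — one joint shuffle of the column labels per
permutation, identical for all features, which preserves the gene–gene
correlation structure of the matrix — refits every feature, and counts
rhythm calls. The estimate is

$$\widehat{FDR} = \frac{\text{mean permuted count}}{\text{observed count}},$$

clipped to $[0, 1]$, and undefined (with a note) when nothing is called on
the observed data. The default is 1000 permutations; because all features
share one design, each permutation is a single matrix product and the full
procedure stays fast at genome scale. Under a pure null the observed and
permuted counts are exchangeable and the estimate concentrates near 1; with
planted signal it drops to near 0. Both behaviours are exercised in the
test suite. Whether label permutation should be joint or per-feature is not
decidable from first principles; the joint choice is the conservative one
for correlated features and is recorded in the output metadata.

## Set-level comparisons

* `partition_sets()` decomposes 2–3 per-condition rhythmic sets into their
  disjoint intersection regions (the Venn decomposition), with counts and
  memberships.
* `rcf()` computes reverse cumulative frequency curves of amplitudes — the
  fraction of values strictly greater than each grid point — for comparing
  amplitude distributions between gene groups.
* `phase_histogram()` bins phases into half-open hourly bins $[k, k+1)$;
  a phase of exactly 24 must be normalised to 0 upstream, and the bins
  match the "ZT22–23" reporting dialect.
* `phase_shift()` pairs the fits of two conditions and reports per-feature
  wrapped phase differences in $(-12, 12]$ hours. The group-level summary
  is the **circular mean** of the differences, not the arithmetic mean:
  when shifts straddle the midnight wrap, arithmetic averaging of wrapped
  values is biased toward 0, while the circular mean remains consistent.
  Features with undefined phase in either condition are excluded and
  counted.
* `normalize_rows()` rescales each feature's profile linearly to $[0, 1]$
  across the concatenated per-timepoint means of all conditions (min–max,
  matching a white-to-red heatmap where white is the row minimum);
  z-scoring is *not* used here because the display convention is
  range-based. Constant rows cannot be scaled and are mapped to 0.5 with a
  flag.

## Clustering temporal profiles

`profile_matrix()` reduces a condition's time course to per-feature mean
profiles over ZT and z-scores each row by default, so that the Euclidean
distance between profiles reflects *shape and phase* rather than absolute
level or amplitude — which is what temporal clustering is meant to
interpret. Both the standardisation and the metric are configurable.

`pam_kmedoids()` implements partitioning around medoids: BUILD greedily
seeds $k$ medoids (first the point of minimal total dissimilarity, then the
point with the largest gain), and SWAP repeatedly applies the single
(medoid, non-medoid) exchange that most reduces the total dissimilarity
until none improves it. The objective is non-increasing across SWAP steps
and all ties break toward the lowest point index.

SWAP explores only single exchanges, so it is a local search: on a few
percent of small random instances the converged solution is not the global
optimum (this is equally true of the classical single-start implementation
in other packages — a tie in the BUILD gain can send the descent into a
different basin). Because the package promises oracle-verifiable optima on
small problems, `pam_kmedoids()` therefore runs several SWAP descents: the
deterministic BUILD start plus `n_starts - 1` seeded random medoid sets
(default 5 starts in total), keeping the best converged objective. The
result is deterministic given the seed, and `n_starts = 1` reproduces the
classic algorithm exactly.

`select_k()` scans $k$ over 2–10 (configurable), computes the mean
silhouette width $s_i = (b_i - a_i)/\max(a_i, b_i)$ for each candidate, and
returns the model with the best mean; ties go to the smallest $k$.
Singleton clusters receive silhouette 0 by convention, and all-identical
profiles are rejected because the silhouette is undefined there.

## Day/night occupancy comparisons

Occupancy scores (log2 IP/Input, spike-in normalised upstream; the
"occupied in at least one sample" locus pre-selection is likewise an
upstream input) are compared between sample groups with a moderated
two-sample t. Day is ZT $\in [0, 12)$ and night ZT $\in [12, 24)$ — lights
on at ZT0, food available at night in the reference regimen.

Per locus, with group sizes $n_a, n_b$ and pooled residual variance $s^2$
on $d = n_a + n_b - 2$ degrees of freedom, the variance is shrunk toward a
prior $s_0^2$ with $d_0$ prior degrees of freedom:

$$\tilde s^2 = \frac{d_0 s_0^2 + d s^2}{d_0 + d},\qquad
  t = \frac{\bar y_b - \bar y_a}{\tilde s \sqrt{1/n_a + 1/n_b}},$$

referred to a t distribution with $d + d_0$ degrees of freedom. The
hyper-parameters are fitted across loci by method of moments on
$\log s^2$: under the scaled inverse-chi-square prior,
$\operatorname{var}(\log s^2) = \psi'(d/2) + \psi'(d_0/2)$, so $d_0$ comes
from a Newton inversion of the trigamma function (with $d_0 = \infty$, i.e.
complete pooling, when the observed variance of $\log s^2$ does not exceed
$\psi'(d/2)$), and $s_0^2$ from the matching first-moment equation. The
implementation is self-contained and closed-form so that it can be checked
against two independent routes: with $d_0$ forced to 0 it must equal the
classical pooled t exactly, and with the fitted prior it is cross-checked
against an established empirical-Bayes implementation in the test suite.
The posterior variance is by construction always between $s^2$ and $s_0^2$.

`day_night_compare()` reports MVA coordinates per locus: M is the night
minus day difference and A the midpoint. Following the reporting convention
for this analysis, M and A are computed from the per-timepoint averages
(three day timepoint means vs. three night ones in the canonical design),
while the test statistic uses all individual samples; in a balanced design
the two coincide. `timepoint_pair_compare()` applies the same machinery to
two single timepoints — by default ZT02 vs ZT10, the start against the end
of the light period, which isolates a clock-driven anticipatory rise in
occupancy before the feeding period from the feeding response itself.
Significance is reported at unadjusted p < 0.05 per condition (recorded in
the output); multiplicity handling beyond that is left to the caller.
`cosine_fit_fraction()` asks the complementary question — how many loci
follow a smooth 24-h cosine at all — by running the cosinor at p < 0.05.

## The synthetic-data generator

`simulate_expression()` emulates the canonical design: 6 ZTs (2, 6, 10, 14,
18, 22) sampled over 2 consecutive days with 3 replicates per timepoint per
day (36 samples per condition), one or more conditions, Gaussian noise on
the log2 scale (default sd 0.2, a typical residual scale for expression
arrays). A feature's expected value is
$\text{mesor} + A\cos(2\pi(t - \varphi)/24)$, with $A = 0$ for arrhythmic
features. Defaults: rhythmic amplitudes uniform on $[0.25, 1.5]$ log2
units, mesors uniform on $[4, 10]$, and phases drawn from a bimodal
mixture at ZT14 and ZT22 (1.5 h jitter), reflecting the two dominant phase
groups of liver diurnal transcriptomes (early night and end of night).
The first condition is the reference; derived conditions keep its rhythmic
features (subject to their own rhythmic fraction) with amplitudes
multiplied by a damping factor and phases shifted by a constant — the two
knobs needed to encode "constant feeding damps amplitudes and advances
phases" and "clock knockout abolishes most rhythms" scenarios. Ground
truth (flag, amplitude, phase, mesor per feature and condition) is
returned alongside the data.

`simulate_occupancy()` plants the two occupancy mechanisms directly: a
`night_effect` added to all night samples of an affected locus (feeding
response), an `anticipation_effect` added at the last daytime timepoint
when the clock is on (anticipatory rise), and a global `condition_offset`
(e.g. loss of a repressor raising baseline occupancy). Defaults: base mean
1.0, noise sd 0.2, and the canonical 12-sample condition (6 ZTs × 2 days ×
1 replicate, i.e. 2 samples per ZT after collapsing days).

All randomness flows from one explicit seed per dataset; identical
configuration and seed give bit-identical output.

What the generator does *not* emulate — and hence what passing tests do not
show about real data: probe-level microarray artefacts and normalisation
residue, read-level ChIP-seq noise and mappability structure, gene–gene
correlation (noise is independent across features, so the permutation FDR's
robustness to correlated nulls is designed-in but not stress-tested by
these simulations), heteroskedasticity across expression levels,
non-sinusoidal waveforms, and missing-data patterns beyond simple dropout.

## Numerical choices and degenerate inputs

* Amplitudes below $10^{-9}$ are treated as zero when deciding whether the
  phase is defined; a fitted phase within $10^{-9}$ h of 24 snaps to 0.
* A constant feature has $SS_{\text{model}} = 0$ and is reported as
  $F = 0$, $p = 1$ rather than 0/0.
* Written TSVs print doubles with `%.17g` and are re-read with base R's
  correctly-rounded parser, so a write/read round trip is bit-exact.
* Missing values are `NA`; features with missing samples are refit on the
  finite subset when the design still permits it (`status = "incomplete"`)
  and flagged `"unfittable"` otherwise.
* In `moderated_group_test()`, loci with zero variance and zero difference
  report $t = 0$, $p = 1$; zero variance with a non-zero difference reports
  an infinite statistic.

## Problem sizes in the test suite

The suite validates calibration claims by simulation at sizes chosen to
make Monte-Carlo bands tight while keeping a full run in the order of a
minute: 10,000 features for type-I error and p-value uniformity (99%
binomial band [0.045, 0.055] at p < 0.05), 2,000 features × 200
permutations for the FDR's null and planted behaviour, 100 random instances
for the least-squares oracle, 50 instances with $n \le 8$ for the
exhaustive PAM oracle, 600 genes in three phase groups for silhouette
selection (expected $k = 3$, adjusted Rand index vs. truth ≥ 0.9), and
500-locus occupancy panels for the day/night and anticipation operating
points (sensitivity ≥ 0.9, false positive rate ≤ 0.07 at p < 0.05).

## Known limitations

* The period is fixed (default 24 h): no period scanning, no second
  harmonic, and no non-parametric alternatives; signals with strongly
  non-sinusoidal waveforms lose power.
* The permutation FDR is experiment-level (expected false discoveries over
  the whole list), not a per-feature q-value.
* PAM is the exact BUILD+SWAP family, quadratic in the number of clustered
  features; profiles beyond a few thousand features will be slow (no
  CLARA-style subsampling is provided).
* Day/night classification is hard-coded to the ZT12 boundary; regimens
  with shifted light schedules must re-map ZT upstream.
* The moderated test assumes a common variance prior across all loci; no
  intensity-dependent (trended) prior is fitted.
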