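# diurnal

Detection and comparison of 24-hour rhythms in expression and occupancy
time courses.

Tissues entrained to a light/dark cycle oscillate: a sizeable fraction of
the transcriptome, and the chromatin occupancy of the transcription
machinery, varies with zeitgeber time (ZT; hours since lights-on). Two
forces drive these oscillations — the endogenous circadian clock and the
response to rhythmic food intake — and separating them requires comparing
time courses across conditions (control, clock knockout, altered feeding
regimens) with a consistent statistical toolchain. `diurnal` provides that
toolchain for tabular time courses (feature × sample matrices whose samples
carry condition, ZT, day and replicate annotations), in tidyverse style:
data frames in, tibbles out, `autoplot()` views, `tidy()`/`glance()`
summaries.

## What it computes

**Rhythm detection (cosinor).** Per feature, ordinary least squares of
`y = b0 + b1*cos(2πt/24) + b2*sin(2πt/24)`; amplitude `A = sqrt(b1² + b2²)`
(half peak-to-trough, log2 units), phase `atan2(b2, b1) * 24/2π` in
`[0, 24)` (time of the fitted maximum), and the nested-model F test on
`(2, n − 3)` df. A feature is rhythmic when `p < 1e-4` (strict).

**Permutation FDR.** Sample-to-ZT labels are shuffled jointly for all
features (preserving gene–gene correlation), every feature refit, and the
false discovery rate estimated as mean permuted call count over observed
call count (default 1000 permutations).

**Rhythmic-set comparisons.** Amplitude filtering (cutoff 0.25 log2 ≈
1.4-fold peak to trough), Venn partition of 2–3 per-condition rhythmic
sets, reverse cumulative amplitude frequency curves, hourly phase
histograms, and per-feature phase/amplitude shifts between conditions with
a circular-mean group summary.

**Clustering.** Partitioning around medoids (BUILD + SWAP, multistart) on
z-scored per-ZT mean profiles, with the number of clusters selected by the
best mean silhouette width over k = 2–10.

**Occupancy day/night analysis.** Condition and timepoint means of
log2(IP/Input) locus scores, and moderated two-group comparisons
(day vs night, or ZT10 vs ZT02) using an empirical-Bayes variance shrinkage
fitted by method of moments on the log variances; per-locus M (difference)
and A (average) coordinates for MVA plots; the fraction of loci whose
occupancy itself follows a cosine.

**Synthetic data.** `simulate_expression()` and `simulate_occupancy()`
plant known rhythms, amplitude damping, phase shifts, night effects and
end-of-day anticipatory effects under the canonical 6-timepoint, two-day
design, returning ground truth alongside the data so every stage is
testable by parameter recovery.

## Worked example

```r
library(diurnal)
library(dplyr)

cfg <- sim_config(
  500, seed = 42,
  conditions = list(
    condition_spec("control", rhythmic_fraction = 0.2),
    condition_spec("constant_fed", rhythmic_fraction = 0.2,
                   amplitude_damping = 0.6, phase_shift_h = -1.5)))
sim <- simulate_expression(cfg)

fit   <- cosinor_fit(sim$data)
calls <- call_rhythmic(fit, p_threshold = 1e-4)
count(calls, condition, rhythmic)
#>   condition    rhythmic     n
#> 1 constant_fed FALSE      411
#> 2 constant_fed TRUE        89
#> 3 control      FALSE      402
#> 4 control      TRUE        98
```

98 of the 100 planted control rhythms are recalled at the strict threshold
(89 under constant feeding, where amplitudes were damped by 0.6×). The
permutation FDR confirms the list is clean:

```r
estimate_fdr(filter(sim$data, condition == "control"), n_perm = 200, seed = 1)
#>   condition n_observed mean_permuted      fdr p_threshold n_perm  seed
#> 1 control           98         0.055 0.000561      0.0001    200     1
```

On average 0.055 features per permutation reach `p < 1e-4` against 98
observed calls: an estimated FDR of 0.0006. Phase shifts between the
conditions recover the planted −1.5 h advance:

```r
kept  <- amplitude_filter(filter(calls, condition == "control", rhythmic))
shift <- phase_shift(filter(fit, condition == "control"),
                     filter(fit, condition == "constant_fed"),
                     features = kept$feature_id)
attr(shift, "mean_shift")
#> [1] -1.49
```

Clustering the control profiles selects two clusters — the two phase groups
(early night, end of night) that the generator's default bimodal phase
distribution plants:

```r
prof  <- profile_matrix(filter(sim$data, condition == "control"),
                        features = kept$feature_id)
model <- select_k(prof, k_range = 2:6)
model
#> <diurnal_pam> k = 2, n = 98, mean silhouette 0.712, objective 75.686
#> cluster sizes: 47, 51
autoplot(model)          # silhouette-vs-k curve
```

Occupancy day/night comparison on a 573-locus panel with a planted night
effect at 10% of loci:

```r
occ <- simulate_occupancy(
  occupancy_spec(573, night_effect = 0.5, anticipation_effect = 0.4,
                 affected_fraction = 0.1, seed = 7),
  sim_config(0, replicates_per_timepoint = 1))
dn <- day_night_compare(occ$data)
glance(dn)
#>   n_loci n_a n_b   d0    s02 alpha n_significant n_up n_down
#> 1    573   6   6 460. 0.0420  0.05            70   60     10
autoplot(dn)             # MVA plot, significant loci emphasised
```

60 of the 70 significant loci are more occupied at night, dominated by the
57 planted ones (the anticipatory ZT10 effect pulls a few day means up,
which is exactly what `timepoint_pair_compare(occ$data, 2, 10)` is for).

A thin command-line wrapper over the same functions ships in
`inst/cli/diurnal.R` (subcommands `simulate`, `fit`, `fdr`, `filter`,
`rcf`, `phases`, `cluster`, `daynight`, `ztpair`, `cosfrac`, `run`).

## Documentation

The methods vignette (`vignettes/rhythm-analysis.Rmd`) describes the model,
the estimation and calibration choices, the synthetic-data generator and
its limits, and the package's design decisions in detail.
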