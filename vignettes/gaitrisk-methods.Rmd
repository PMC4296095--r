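---
title: "Daily-life gait extremes and fall risk: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Daily-life gait extremes and fall risk: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitrisk)
```

## The scientific question

Week-long trunk accelerometry in older adults yields thousands of 10-second
walking epochs per person. The conventional summary of a gait characteristic
— sample entropy, harmonic ratio, stride regularity, and so on — is its
median over all epochs. But daily life is heterogeneous: a person's *best*
and *worst* walking episodes may carry information the median hides. Raw
minima and maxima over a week are too unreliable to use, so the 10th and
90th percentiles serve as reliable proxies for the extremes. The analysis
this package implements asks two things:

1. Do the percentile extremes of daily-life gait characteristics associate
   with prospective falls more strongly than the medians?
2. Does substituting extremes for medians improve a stepwise logistic
   fall-risk model, beyond what the freedom of model selection produces by
   chance?

The second question is answered with a Monte Carlo block-permutation test on
the AUC improvement between nested model specifications.

## Pipeline overview

```
synth_cohort()  ->  extract_features()  ->  exclude_running()
      -> summarize_percentiles()  ->  univariate_scan() + build_models()
      -> compare_models()
```

Every stage is a data-frame-in, tibble-out function, and every random draw
derives from an explicit seed.

## The synthetic cohort generator

No raw data from the original cohort is available, so the package ships a
generator whose defaults emulate the study conditions: 202 participants,
target faller fraction 0.35 (70 of 202) over 6 months, tri-axial trunk
acceleration epochs of 10 s at 100 Hz, and the questionnaire and activity
covariates consumed by the models.

**Signal model** (`synth_gait_epoch()`). Trunk acceleration during steady
gait is modeled as a sum of four even and four odd stride harmonics per
axis. The vertical (VT) and anterior-posterior (AP) axes carry their
step-symmetric content at even stride harmonics (step frequency and
multiples); the mediolateral (ML) axis is fundamentally periodic at stride
frequency. An `asymmetry` parameter scales the wrong-parity harmonics per
axis, so asymmetry 0 with no noise gives an exactly periodic, perfectly
step-symmetric signal — the regime in which harmonic ratio and index of
harmonicity have closed-form values used by the tests. The instantaneous
stride frequency wanders as an Ornstein-Uhlenbeck process (relaxation time
1 s) so that phase is continuous, and white noise is added per axis. Gait
speed ground truth enters through the vertical-displacement amplitude: a
vertical excursion *h* is planted as the first even VT harmonic with
amplitude $(2\pi \cdot 2 f_s)^2 h/2$, which the inverted-pendulum estimator
can recover.

**Cohort model** (`synth_cohort()`). Participant $i$ carries two stable
traits: a latent gait-quality scalar $q_i \sim N(0, 1)$ and a lognormal
epoch-dispersion scalar $s_i$ (SD 0.5 on the log scale, mean 1). Each of the
30 characteristics has a catalog entry (`gait_feature_catalog()`) with a
plausible population baseline, a between-participant SD, an epoch-to-epoch
SD, and the sign with which it improves with quality. Between-participant
profiles follow a one-factor covariance: the quality factor carries 40% of
each characteristic's between-participant variance (`quality_share`), the
rest is characteristic-specific. This matters: if all characteristics were
deterministic functions of a single factor, the cohort covariance would be
rank one, every median would be an interchangeable proxy for every other,
and no selection procedure could identify which characteristic actually
drives the outcome. A moderate factor share gives inter-characteristic
correlations around 0.4, in line with what families of related gait
measures show, while keeping effects identifiable.

Epoch values are the participant profile plus $s_i$-scaled noise, so the
*spread* between a participant's good and bad epochs — and hence the gap
between their percentile extremes and their median — is itself a stable
trait. That is exactly the ingredient that makes "outcome driven by a 10th
percentile" distinguishable from "outcome driven by the median".

The fall outcome is Bernoulli with logit equal to an intercept
(`qlogis(0.35)`) plus a linear combination of *z*-scaled cohort-table
columns. The default coefficients mirror the magnitudes of typical
significant univariate associations in cohorts of this kind: fall history
0.55, depression score 0.45, lying duration -0.40, and three gait medians
(sample entropy VT 0.41, low-frequency percentage VT 0.38, harmonic ratio
VT -0.43). Because the outcome is generated from the very columns the scan
analyzes, recovery tests target the generative coefficients exactly.
Participants whose summaries are undefined (too few retained epochs)
contribute at baseline odds.

Two generation modes exist, both first-class. `mode = "signal"` synthesizes
raw epochs and closes the loop through `extract_features()`; it is the
ground-truth check that the whole chain (signal to feature to summary to
model) hangs together, and is priced at roughly 0.2 s per epoch. `mode =
"feature"` (the default) draws per-epoch feature rows directly from the
generative model, which makes cohort-scale simulation studies — 100 cohorts
by 200 permutation refits — tractable. The two modes share the participant-
and outcome-level machinery.

**What the generator does not emulate.** Real daily-life data contain
turning episodes, wear artifacts, device tilt, activity misclassification,
and feature distributions with heavier tails and more intricate dependence
than a one-factor Gaussian model. Passing tests on synthetic cohorts
demonstrate that the *procedures* are implemented correctly and behave as
designed under known truth — not that the original study's effect sizes
would replicate. The default synthetic cohort in fact carries a cleaner
sensor signal than real data (most medians associate significantly with the
generated outcome), so absolute AUCs printed by the worked examples sit
above the study's.

## The 30 gait characteristics

Three whole-epoch measures (gait speed, speed variability, stride
frequency) and nine per axis. All operate on mean-centered ("dynamic")
acceleration; no tilt correction is applied since the synthetic signals are
axis-aligned (an extension point for real data). Undefined values propagate
as `NA` with reason codes in `qc_flags`, never as sentinel numbers, so
percentile summaries skip rather than absorb them.

* **Stride frequency** — exhaustive peak search of the unbiased normalized
  autocorrelation of VT over stride lags 0.625-2.5 s (0.4-1.6 Hz), with
  parabolic lag refinement and a detection floor (peak autocorrelation
  0.25); below the floor the epoch is flagged `stride_undefined`. A
  perfectly step-symmetric signal is genuinely stride-ambiguous (one stride
  equals two identical steps); ties resolve to the smallest peak lag.
* **RMS** — of the centered signal, per axis.
* **Stride regularity** — unbiased normalized autocorrelation at the lag
  nearest one stride, grid-maximized within ±10% of the nominal lag. The
  grid maximum (not a parabolic fit) is used because the autocorrelation of
  a periodic signal peaks with a kink that a parabola overshoots past 1.
* **Low-frequency percentage** — Welch power below the axis cutoff (0.7 Hz
  VT/AP, 10 Hz ML) over total power in 0.1 Hz-Nyquist. The default segment
  length equals the 10-s epoch (the Welch estimate then reduces to one Hann
  periodogram): shorter segments blur a 0.5 Hz line across the 0.7 Hz
  cutoff by a few percent, which is exactly the contrast this
  characteristic must resolve.
* **Index of harmonicity** — power at the axis fundamental (step frequency
  on VT/AP, stride frequency on ML) over the summed power of the
  fundamental plus its first 5 harmonics, each integrated over ±1 bin.
* **Harmonic ratio** — summed spectral amplitudes at the first 20 even
  stride harmonics over odd (VT/AP), inverted for ML; amplitudes read from
  a zero-padded Hann spectrum within ±1 bin of each harmonic. Ratios at or
  above the configured cap (default 100, reached when the out-of-phase
  content is essentially zero) return the cap with a flag.
* **Frequency variability** — coefficient of variation of the dominant
  frequency across 50%-overlapping 2.5-s sub-windows in the 0.5-3.5 Hz
  band; undefined with fewer than 3 valid sub-windows.
* **Local dynamic stability** — Rosenstein-style short-term logarithmic
  divergence: delay embedding (dimension 5, delay 10 samples), nearest
  neighbors with a one-stride temporal exclusion, least-squares slope of
  the mean log-divergence over 0-0.5 stride, in 1/s. Higher = less stable.
  Caveat documented for users: when the initial neighbor distance is
  dominated by broadband noise the divergence curve starts near its
  saturation scale and the slope *shrinks*, so comparisons across noise
  conditions are only meaningful when the deterministic dynamics dominate
  the neighbor scale.
* **Sample entropy** — $-\ln(A/B)$ with template length $m = 5$ and
  tolerance $r = 0.3$ interpreted as a fraction of the per-epoch, per-axis
  SD (the field's convention when no units are stated); self-matches
  excluded; zero counts yield `NA` (undefined), not infinity. Counting runs
  in compiled code and is verified against a direct $O(N^2)$ counter.
* **Dominant frequency amplitude** — window-gain-corrected amplitude of the
  spectral peak within ±30% of the axis fundamental, from an 8× zero-padded
  Hann spectrum.
* **Gait speed and variability** — inverted pendulum: zero-phase high-pass
  (Butterworth order 2, 0.5 Hz) on VT, double integration with re-filtering
  to curb drift, 1 s trimmed at each end for filter transients, per-step
  vertical excursion $h$ from consecutive step windows, step length
  $2\sqrt{2lh - h^2}$ with configurable leg length $l$ (default 0.9 m),
  speed = mean step length × step frequency, variability = SD of per-step
  speeds.

## Week summaries and reliability

Epochs suspected to reflect running — stride time strictly below 0.8 s
and/or vertical RMS strictly above 5 m/s² — are discarded before
summarization; boundary values survive. Percentiles use linear
interpolation between order statistics (R type 7), and a participant needs
at least 10 defined values for a characteristic (configurable) to receive a
summary. Between-week reliability uses the two-way random-effects,
absolute-agreement, single-measure ICC, the standard form for test-retest
of continuous gait measures, computed from the ANOVA mean squares (no
suitable ICC routine ships with the pre-installed stack, so the
decomposition is implemented directly and cross-checked against `aov()`).
On two-week synthetic cohorts the percentile extremes are systematically
more reliable than raw minima/maxima and track the median's reliability —
the motivation for using percentiles as extreme proxies in the first place.

## Risk models

All candidates are *z*-transformed before fitting, so coefficients are
log-odds per SD. Logistic fits use a Newton (IRLS) core in compiled code —
the stepwise and permutation machinery performs on the order of a million
small fits per simulation study — with convergence tolerance 1e-8, Wald
tests, and explicit separation/singularity flags; the test suite verifies
it against `glm()` and a brute-force likelihood grid.

* **Model 1**: fall history + GDS depression score.
* **Model 2**: Model 1 candidates + the 7 activity amounts + all 30
  characteristic medians.
* **Model 3**: Model 2 candidates, with a characteristic's median replaced
  by its 10th or 90th percentile when that percentile's univariate P value
  is the lowest of the three and below .05 (otherwise the median stays).

Each model is built by stepwise forward selection: at every step the
candidate with the lowest added-coefficient Wald P value below .05 enters,
provided its absolute Spearman correlation with every already-selected
parameter is at most .7. The entry test is the Wald P of the added
coefficient (the natural reading of "lowest P value when added"); the
Spearman screen is computed on the untransformed columns over complete
cases, which is equivalent on ranks to any monotone transform. Exact ties
in the minimal P break by lexicographic parameter order, for determinism.
Candidates whose fit shows separation or singularity are skipped in that
sweep. If nothing ever qualifies the model is intercept-only, with a note.
Fits are complete-case over the model's candidate set; row counts are
carried on the result.

Discrimination is the in-sample AUC (rank statistic, ties counted 1/2) —
deliberately not cross-validated, matching the original design, and checked
against an all-pairs concordance oracle. Calibration is the
Hosmer-Lemeshow test on deciles of predicted risk; tied risks that leave a
group under 3 observations cause group merging with adjusted degrees of
freedom.

Both the entry-step and the final-refit Wald P values are reported per
selected parameter (`p_entry`, `p_value`), since printed stepwise tables in
the literature are ambiguous between the two.

## The block-permutation test

Adding sensor-derived parameters to a model *must* raise the in-sample AUC
somewhat, because the selection procedure is free to pick whatever fits the
realized outcomes. The permutation test calibrates the improvement against
exactly that freedom: each permutation reassigns the entire sensor block —
all 7 activity amounts and all 90 feature percentiles — jointly across
participants (one uniform random permutation; fixed points are allowed,
harmless and rare), leaving questionnaire data and fall outcome in place.
Joint reassignment preserves every within-block correlation, so the
permuted cohorts are realistic except that sensors carry no information
about this outcome. Both models are rebuilt from scratch on every permuted
cohort, *including* re-running the percentile-selection rule when Model 3
is involved (whether the original analysis re-ran it inside the permutation
is not documented; re-running is the choice consistent with "the entire
selection freedom is under the null"). Model 1 uses no sensor columns and
is computed once.

The P value is the proportion of permutations whose AUC increase strictly
exceeds the observed increase — the plain ratio, no small-sample
correction, for fidelity to the original estimator; the `(k+1)/(n+1)`
version is available behind `small_sample_correction`. Permutations are
drawn up-front from the master seed, so results are independent of
execution order.

Two diagnostics are retained on the result. First, the distribution of
permuted baseline AUCs: permuted data typically start from a lower Model-2
AUC than the original data, which makes the test conservative for
median-vs-extreme comparisons (an improvement of fixed size is easier from
a lower base). Second, tie counts: when a permuted rebuild selects the
identical questionnaire-only model as the observed fit, its delta ties the
observed delta exactly, and the strict "larger" count treats ties as
non-exceedances. The plain P value therefore has an atom and never
approaches 1; under the null its rejection rate stays at or below nominal.
The calibration test in the suite accordingly checks the rejection band on
the plain P and checks uniformity on the tie-randomized version
$p^* = (k_{>} + U\,(1 + k_{=}))/(n+1)$, which is exactly uniform under
exchangeability.

## Numerical and design choices

* Percentile rule: linear interpolation (type 7), config-exposed.
* Spectral amplitudes: Hann window, coherent-gain corrected, 4-8× zero
  padding, ±1-bin neighborhoods around harmonics.
* Sample-entropy tolerance scales with the per-epoch SD; a constant signal
  has entropy 0 (all templates match), while an epoch whose axis is
  identically zero is flagged degenerate at extraction.
* Stepwise ties: lexicographic; duplicate candidate columns are screened
  out by the ρ cap (|ρ| = 1 > 0.7).
* All heavy simulation sizes in the test suite are chosen to keep the whole
  run deterministic and desk-scale: 50 seeds for recovery and
  designed-advantage studies, 100 cohorts × 199 permutations for
  calibration, signal-mode cohorts only at small n.

## Known limitations

* In-sample AUCs are optimistic by construction; no cross-validation or
  external validation is implemented.
* The Gaussian one-factor cohort model understates the messiness of real
  daily-life feature distributions; effect sizes on synthetic cohorts are
  not forecasts for real cohorts.
* Signal-mode synthesis models steady walking only — no turns, transitions,
  or non-gait activity; the running filter is exercised by construction
  rather than by simulated running.
* The stride-frequency estimator cannot disambiguate stride from step on
  perfectly symmetric signals (no real gait is).
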