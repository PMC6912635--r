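---
title: "circaclock: models, detectors and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{circaclock: models, detectors and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circaclock)
```

## The scientific problem

Insects kept in activity monitors reveal two complementary faces of their
circadian clock. Under a light–dark (LD) cycle the clock is entrained: daily
activity has a characteristic phase, summarised by the Zeitgeber times (ZT,
hours after lights-on) at which activity starts (onset), culminates (peak)
and returns to the nocturnal baseline (offset). Released into constant
darkness (DD), the clock free-runs at its intrinsic period τ, which can be
read off the drift of activity bouts across days. In *Nasonia vitripennis*,
both τ and the activity phase vary between populations sampled along a
European latitudinal cline — southern wasps run faster clocks and are active
earlier than northern ones — and rhythmicity itself varies with sex and
mating status. circaclock implements the full analysis chain for such
studies and, because raw recordings of this kind are rarely deposited, pairs
it with a synthetic-data generator so that every estimator is validated by
recovery of planted parameters.

## Data model

Recordings are TriKinetics DAM2 monitor files: tab-delimited rows of 10
metadata columns (reading index, date `dd mmm yy`, time, status code, five
device fields, a light-sensor flag) followed by 32 per-channel beam-cross
counts, one row per minute. The reader validates a strictly monotone 1-min
timestamp sequence; rows with a non-OK status are flagged, never silently
dropped. Timestamp gaps fail loudly by default because a silent gap shifts
every subsequent phase estimate; `fill_gaps = TRUE` inserts zero-count rows
explicitly flagged as imputed. The writer reproduces the payload bit-exactly
so that simulated cohorts can be pushed through the identical reader used
for real data.

Each analysed individual is an `activity_record`: a minute-indexed count
series, its `light_schedule`, and metadata (population, latitude, isofemale
line, sex, mating status). ZT 0 is the lights-on instant; recording is
assumed to start there, and under DD the ZT scale continues by 24-h
extrapolation of the last LD segment.

**Dead-animal filter.** The original screening — visual inspection of
double-plotted actograms — is not reproducible, so `mark_dead()` substitutes
an explicit rule: an individual is flagged dead at the start of a terminal
all-zero run of at least 24 h (configurable). The rule is idempotent and can
only shorten the usable series. Individuals dead before two complete days of
the analysed segment are excluded entirely; records with fewer than five
usable DD days never enter the periodogram. On simulated cohorts with
planted deaths the filter recovers exactly the planted individuals, because
a live simulated wasp crosses the beam every day whereas the post-death
series is identically zero; on real data a wasp that survives but stops
moving for a day would be a false positive, which is why the threshold is a
visible parameter rather than a constant.

## The synthetic-activity model

The generator drives per-minute Poisson counts with an expected rate that is
a smooth unimodal function of the internal clock phase φ (hours, mod 24):

* baseline rate *b* outside the active window;
* a raised-cosine ramp from *b* at `onset` to the peak rate *p* at `peak`;
* a raised-cosine ramp back to *b* at `offset`; all three knots circular.

Parameterising the waveform directly by its three phase markers means the
planted values of every downstream detector are explicit. Under LD the phase
is entrained, φ = ZT (no transients). At the LD→DD transition φ is
continuous, and thereafter advances by 24/τ subjective hours per real hour,
so the expected rate free-runs with period τ exactly. Arrhythmic individuals
emit the constant time-average of their template, preserving total activity.
Counts are `rpois(1, rate)` per minute — beam crosses are event counts — and
each individual owns a private seed derived from the cohort master seed, so
cohorts are byte-reproducible.

Cohort structure mirrors an isofemale-line design: individual τ =
`tau_mean` + line intercept (Normal, `between_line_sd`) + individual noise
(Normal, `tau_sd`), truncated to [18, 30] h to stay inside the periodogram
search range; rhythmic flags are Bernoulli; deaths (optional) occur
uniformly in the middle 70 % of the recording. Emitted monitors hold 32
individuals each.

**What the generator does and does not emulate.** It reproduces entrained
unimodal activity, free-run with drift, nested line variance, arrhythmicity
and mortality. It deliberately omits masking and lights-on startle
artifacts, twilight ramps, bimodal (morning + evening) profiles,
overdispersion beyond Poisson, and entrainment transients. Passing
recovery tests therefore demonstrates correctness of the estimators under
the stated model, not robustness to those phenomena; the masking-free
assumption matters most for phase markers, where real lights-on responses
could sharpen onsets relative to the smooth ramps simulated here.

**Preset parameters.** The built-in presets plant published *Nasonia*
population values: free-running periods 24.3 h (southern isogenic), 26.7 h
(northern isogenic), 24.6 h (Corsica virgin females), 25.42 h (Oulu virgin
females); long-day (LD 16:8) templates onset/peak/offset = 0/5/13 (south)
and 2/8/16 (north); short-day (LD 8:16) templates 21.5/2.5/8 (south) and
0/4/10.5 (north). Free-run presets use 4 days LD 16:8 followed by 10 days
DD; profile presets use 10 days of the stated LD cycle. Two preset
constants are not published anywhere and were fixed by design, once:

* *Within-cohort τ dispersion.* Published standard errors (≈ 0.1 h at
  n ≈ 28) imply a total SD near 0.5 h, but that total includes periodogram
  measurement error and between-line variance. Presets plant
  `tau_sd = 0.25` h within line and `between_line_sd = 0.1` h, which keeps a
  30-individual cohort's sampling drift (SE ≈ 0.06 h) below the periodogram
  grid step, so that cohort-level recovery checks measure the estimator
  rather than sampling noise.
* *Count rates.* Baseline 0.1 and peak 8 crosses/min were selected in a
  one-shot design study over candidate pairs: nights are nearly silent
  (≈ 2 counts per 20-min bin) as in real DAM traces, and the peak-to-baseline
  contrast keeps single-bin Poisson noise small relative to the waveform so
  the threshold detectors operate close to the planted phases (see the
  marker section for their residual bias). The pair was frozen before the
  validation suite was finalised and is not adjusted per analysis.

## Chi-square periodogram

For binned counts `X_1..X_N` (default 10-min bins of the DD segment) and a
candidate period of `P` bins, fold the series into columns `h = 1..P` with
column means `M_h` over `n_h` entries and grand mean `M̄`; the statistic is

\[
Q_P \;=\; \frac{N \sum_h n_h (M_h - \bar M)^2}{\sum_{i=1}^N (X_i - \bar M)^2},
\]

asymptotically \(\chi^2_{P-1}\) for an exchangeable (arrhythmic) series.
Candidates are every integer bin multiple in the search range (default
18–30 h; at 10-min bins, 73 candidates with ≈ 0.17 h spacing near 24 h). A
constant series is defined to have \(Q_P = 0\) everywhere and is
arrhythmic; series shorter than two cycles of the longest candidate are
rejected.

**Folding dialect.** The textbook statistic uses only the
`K = floor(N/P)` complete cycles. On a 10-day record that convention makes
candidates that divide the record length (exactly 24.0 h) use all 1440 bins
while their neighbours discard up to a full cycle, and since the noiseless
maximum of \(Q_P\) is proportional to the number of bins used, estimates
for τ between about 24.0 and 24.4 h collapse onto exactly 24.0 — a known
record-length bias of the complete-fold chi-square periodogram. circaclock
therefore defaults to folding the trailing partial cycle as well
(`n_h`-weighted column means, all `N` bins in both sums), which scores every
candidate on the full record and has the same \(\chi^2\) null; the
complete-fold dialect remains available (`include_partial = FALSE`).

**Thresholding and the τ pick.** The default significance line is the
pointwise \(1-\alpha\) χ² quantile at each candidate's df, the convention
of interactive periodogram software; `correction = "bonferroni"` divides α
by the number of candidates and is what the calibrated type-I simulations
use (measured false-positive rate 0.02–0.03 at nominal 0.05 over 1000 null
replicates). τ̂ is the candidate maximising \(Q_P -\) threshold among
significant candidates — the height *above the line*, matching how
periodogram plots are read — with ties broken toward the shorter period. An
individual is rhythmic iff some candidate is significant.

At the preset signal-to-noise ratio, ≥ 95 % of rhythmic simulants are
detected and land within one grid step of their planted τ; arrhythmic
simulants are rejected at the nominal rate.

## Phase markers

Markers are computed per wasp per day after excluding the first four
entrainment days (both the exclusion and the day count are parameters).
Two tracks are derived from the same record: 20-min bin sums (onset,
offset) and the minute series smoothed by a centred circular 30-min moving
average (peak).

* **Baseline.** `b` and `s` are the mean and SD of the bins in a night
  reference window. The default window is the 4 h centred on mid-dark.
  A "last 4 h of darkness" window may look natural but is contaminated for
  phenotypes with anticipatory activity before lights-on — the southern
  short-day template starts activity at ZT 21.5, inside that window under
  LD 8:16 — whereas the mid-dark window is quiescent for all four published
  templates. The window is a visible parameter.
* **Onset** — scanning circularly from mid-dark (so pre-dawn onsets are
  found without wrap artifacts), the start of the first bin exceeding
  `b + 2s` whose successor is not lower ("rises consecutively",
  confirmation length 2). The 2-SD multiplier and confirmation length are
  parameters; the defaults are declared, not derived, because the original
  procedure specifies no threshold.
* **Offset** — the start of the first bin at or below `b + 2s` sustained
  for two consecutive bins, scanning circularly from the day's maximum.
* **Peak** — the maximum of the smoothed minute track. Smoothing turns an
  isolated spike into a flat plateau, so exact ties resolve to the circular
  centre of the maximal plateau encountered first when scanning from
  mid-dark: a single spike at ZT 5 is reported as exactly 5.0, and of two
  equal spikes the one nearer the scan origin wins.
* Days with no qualifying bin (all-zero, constant, or never crossing the
  threshold) yield missing markers, which propagate as `NA`.

All three detectors are exactly shift-equivariant, and the moving average
conserves the daily mean.

**Operating characteristics.** A threshold rule on a smooth waveform has a
deterministic bias: the signal crosses `b + 2s` after the true onset and
before the true offset, by an amount that shrinks as the ramp steepens. At
the default rates this bias is about +0.3 h (onset, reported at the bin
start) and −0.5 h (offset); peaks are unbiased to within ≈ 0.2 h. Cohort
circular means therefore recover the planted markers to within half an
hour, which is the resolution claimed for marker comparisons. Sub-bin
precision is not attainable by construction — markers live on a 20-min
grid.

**Averaging.** Markers are circular quantities; 23.5 h and 0.5 h average
to 0.0, not 12.0. Summaries use the vector (circular) mean and circular SD,
first across days within an individual, then across individuals; the pooled
per-day summary is also reported. Whether the original analyses averaged per
individual or on pooled profiles is ambiguous; per-individual is the
default, and `daily_profile()` provides the pooled profile path.

## Cohort statistics

**Random-intercept mixed model.** τ analyses use
\(y = X\beta + u_{line} + e\), with one variance component for isofemale
line (nested in location by making line labels location-unique). The fit
profiles the likelihood over the ratio \(\lambda = \sigma^2_u/\sigma^2\):
at fixed λ the fixed effects are the GLS solution and σ² is closed-form,
leaving a 1-D optimisation over log λ (plus an explicit boundary check at
λ = 0, where the model collapses to ordinary regression — reproduced to
1e-6). ML is the default so likelihood-ratio tests on fixed effects are
valid; REML is available for variance reporting. Against `lme4::lmer` on
common datasets the fit agrees in coefficients, variance components and
log-likelihood to ≈ 1e-6 (lme4 is used only as a cross-check in the test
suite, never in the implementation).

**Likelihood-ratio tests** compare nested ML fits on identical data
(checked), with df equal to the parameter-count difference. Under null
simulations at the experiment's design scale (≈ 20 lines × 6 individuals)
the measured type-I error is ≈ 0.06 at nominal 0.05 — the mild liberality
expected when a covariate varies only between ~20 groups — and stays within
the nominal + 3 Monte-Carlo-SE band used by the calibration suite; planted
slopes are recovered without detectable bias.

**Rhythmicity proportions** use a binomial-logit GLM with factor tests by
analysis-of-deviance χ² (dropping each factor from the full model).
Complete separation is detected and flagged as unreliable rather than
reported as an arbitrarily large statistic. On a 2×2 table the deviance
χ² equals the hand-computed G statistic, the oracle used in tests.

**Phase–τ regression** unwraps peak phase (signed circular deviation from
the cohort circular mean) into a continuous covariate before regressing τ
on it with a line random intercept — an approximation that is accurate when
phases cluster within a few hours, as they do within a photoperiod, and
that fails deliberately (error) when the phase is constant.

**Cline summaries** report per-population mean τ ± SE ordered by latitude
plus the latitude slope from the mixed model, restricted to a subgroup
(e.g. virgin females) when requested. Only rhythmic individuals carry a τ
into any of these models; missing values are dropped listwise per model.

## Numerical and validation choices

* Problem sizes used by the validation suite: 30-individual cohorts for the
  four free-run presets, 25 for the four LD templates (matching the 25–32
  wasps per profile panel of the motivating study), 1000 replicates for
  type-I calibration, 100 random series for the brute-force/vectorised
  periodogram equivalence (tolerance 1e-10 relative). These sizes make
  Monte-Carlo error small relative to every tolerance tested.
* All randomness flows from one master seed per cohort; individual seeds
  are drawn once from it, so records are reproducible individually and
  jointly.
* Ties: periodogram τ toward the shorter period; peak plateaus toward the
  scan origin. Degenerate inputs (constant series, all-zero days, singular
  designs, single-group fits) are defined outcomes — zero statistic,
  missing marker, error, OLS fallback with a warning — never silent.
* The pipeline stamps the config MD5 into every CSV header and regenerates
  byte-identical outputs from the same config and seed.

## Known limitations

* Onset/offset estimates inherit the threshold rule's bias toward the
  interior of the active window; comparisons *between* groups are unbiased
  because the bias is shared, but absolute marker values are conservative.
* The periodogram grid is the bin width; τ precision below ~0.17 h (10-min
  bins) comes only from cohort averaging.
* The LRT on between-line covariates is mildly liberal at realistic line
  counts; where exact type-I control matters, a parametric bootstrap would
  be the next step (not implemented).
* The circular-to-linear unwrap in the phase–τ regression breaks down if
  phases span most of the clock face.
* Real-data phenomena excluded from the generator (masking, bimodality,
  overdispersion) are untested territory by design.
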