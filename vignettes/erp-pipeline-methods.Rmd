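---
title: "Methods: simulating and analyzing response-related ERPs in a cued go/nogo task"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analyzing response-related ERPs in a cued go/nogo task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`gonogoerp` is an end-to-end, tested re-implementation of the analysis
pipeline of a cued go/nogo ERP study with a within-subject stimulation
(active vs. sham) crossover. Because the original recordings were never
deposited, the package pairs the analysis chain with a synthetic-data
generator whose ground truth is known, so that the whole inference
machinery — including its ability to *support a null* — can be exercised
and validated. This vignette is the package's own account of the models,
conventions, numerical choices, and their limits.

## The task and what is measured

Each trial presents a fixation cross (500 ms), a cue that stays on for the
whole cue–target interval (1500 ms), and a target (1000 ms), followed by a
uniformly jittered inter-trial gap (young-adult profile: 1500–2500 ms,
mean 2000; older-adult profile: 2500–3500 ms, mean 3000). Sessions have
five blocks of 80 trials: three blocks with *directional* cues that
announce the responding hand (30% of their targets are nogo stimuli), and
two with *non-directional* cues that announce only target timing. Four
physiological measures plus behavior are quantified per subject, session
and condition:

* **RT** — mean response time over correct go trials, per cue × hand cell;
  omission and nogo false-alarm rates are tabulated but, as in the study
  design this emulates, not formally analyzed.
* **CNV** — mean amplitude at Cz over the last 200 ms of the cue–target
  interval (1300–1500 ms post-cue), baselined to the 200 ms preceding
  fixation onset.
* **P300** — peak amplitude and latency at Pz in 200–500 ms post-target
  (250–650 ms in the older-adult profile), 200 ms pre-target baseline.
* **LRP onsets** — the lateralized readiness potential is derived by the
  double subtraction
  `LRP = ½ [(C4 − C3)_left-hand + (C3 − C4)_right-hand]`,
  low-pass filtered at 30 Hz (zero-phase), and its onset estimated by 25%
  fractional-area latency: the threshold is the mean amplitude over the
  measurement window, area is accumulated (trapezoidally) only where the
  waveform is beyond that threshold in the negative direction, and the
  onset is the linearly interpolated time at which 25% of the total area
  has accumulated. Windows: 100–600 ms post-target (tLRP) and −300 to
  −100 ms before the response (rLRP, baselined −700 to −500 ms
  pre-response).

The alternative reading of the fractional-area convention — area of the
raw waveform relative to zero, rather than beyond the window mean — is
implemented behind `fractional_area_latency(mode = "beyond_zero")`; the
beyond-mean reading is the default everywhere.

## The signal chain

`prepare_session()` applies, in order: average-mastoid re-referencing
(rejected if applied twice); a 50 Hz zero-phase notch (RBJ biquad, Q = 30);
a 0.02–30 Hz zero-phase band-pass implemented as cascaded order-2
Butterworth high- and low-pass sections (an order-4 band-pass in one
transfer function is numerically ill-conditioned with a 0.02 Hz edge at
these sampling rates; the cascade has the same magnitude response and is
stable — for recordings under 60 s, where even the cascade's high-pass is
fragile, linear detrending substitutes and is flagged); epoch extraction
on the half-open convention `[t_start, t_end)` with 0-based sample index
`round(ms × fs / 1000)`; per-epoch baseline subtraction; artifact marking
at ±100 µV on any scalp channel, with subjects excluded when more than 40%
of their epochs are marked (the emulated study names neither number; both
mirror field conventions and are configurable); and arithmetic averaging
of correct go trials per cue × hand cell. Cue-locked epochs span −800 to
+2300 ms around the cue — i.e. 300 ms before fixation to 800 ms after the
target, honoring the stated endpoints (which span 3100 ms, not the
nominally stated 3000).

## The generator

`simulate_subject()` sums, on a continuous timeline: a CNV template
(half-cosine ramp at Cz with fixed scalp spread, rising from 500 ms
post-cue to target onset, decaying over 400 ms) scaled so that its mean
over the CNV window equals the configured amplitude exactly; a Gaussian
P300 bump at Pz (σ = 50 ms) on go trials; a lateralized motor pulse at the
electrode contralateral to the responding hand; 1/f^α Gaussian noise
(α = 1, RMS 4 µV per channel by default) plus a 2 µV 50 Hz line sinusoid;
and behavioral events — ex-Gaussian RTs per cue × hand cell, omissions and
false alarms at configured rates (1.61% and 0.1%). Nogo trials carry the
CNV but no response and no motor potential. All randomness derives from
one seed via a documented splitting scheme (per subject × session ×
channel), so cohorts are bit-reproducible.

**The motor template is response-locked and calibrated.** A fixed pulse
(power-curvature rise to a peak 20–110 ms before the keypress, short
half-cosine decay) is anchored to each trial's response. Its rise start is
root-solved so that the *response-locked average* — which is the pulse
itself, since every trial contributes it in perfect alignment — has its
25% fractional-area onset exactly at the configured `rlrp_onset`. Its peak
position is root-solved so that the *expected target-locked average* —
the pulse convolved with the cue condition's ex-Gaussian RT mixture, under
the pipeline's pre-target baseline — has its onset at the configured
`tlrp_onset`. This geometry is not a convenience but a necessity: no
waveform that is identical in both time-locking frames can jointly produce
onsets like tLRP ≈ 271 ms, mean RT ≈ 391 ms and rLRP ≈ −109 ms under the
beyond-mean threshold convention (any suprathreshold area early enough for
the target-locked onset falls inside the response-locked window and drags
its onset far earlier). RT variability seen through the two locking frames
is exactly what reconciles such values, and the generator reproduces that
mechanism. Consequences worth knowing:

* Noiseless recovery of the response-locked onset, CNV, and P300 values is
  exact (≤ 1 sample / < 0.1 µV). The measured target-locked onset equals
  the configured value up to the RT-sampling error of a finite session
  (unbiased; sd ≈ 5 ms at 168 go trials per cue).
* Per-subject and stimulation-induced onset variation is realized as a
  single time shift of the calibrated pulse (the mean of the two onset
  offsets); the target-locked onset additionally tracks the subject's
  mean-RT offset, as it does in real data. An injected stimulation shift
  on RT therefore also shifts the measured tLRP — a dependency real
  recordings share.
* Calibration is cached per parameter tuple; one cohort needs only a few
  solves.

**Dispersion defaults are conventions, set once.** The emulated study
prints only condition means and standard errors, so: ex-Gaussian σ = 40 ms
and τ = 60 ms (the printed cell means are taken as the ex-Gaussian mean
µ + τ); between-subject spread uses a shared per-subject offset per
parameter class (amplitudes 1.5 µV, onsets 20 ms, RT 50 ms) plus a smaller
independent per-condition jitter (0.5 µV / 6 ms / 10 ms) — the printed
cue-effect F statistics imply cue-difference spreads far smaller than cell
spreads, which forces exactly this correlated structure; and background
noise is 4 µV RMS 1/f, chosen so that session-level measurement
variability of the onset estimates matches the printed standard errors
(≈ 7–10 ms), the only dispersion information available. The motor
amplitude (−3.5 µV) is a typical LRP magnitude; no printed value exists
for it. None of these values were revisited after the acceptance checks were
first run.

**A real instability, faithfully reproduced.** A beyond-mean fractional
area onset that lies within ~20 ms of the window edge (as a directional
rLRP of −109 ms does, with the window ending at −100 ms) must concentrate
~75% of its suprathreshold area in those last few milliseconds; so little
signal area remains that background noise dominates the estimate at any
realistic trial count, biasing it toward the window center. The pipeline
does not hide this: noiseless data recover the configured value exactly,
noisy data produce early-biased, high-variance estimates — which is what
any faithful implementation of this convention would produce, and why such
printed values are best read as group means of noisy per-subject
estimates. (The standard remedy, jackknifed onsets, is deliberately out of
scope.) The cue contrast in rLRP onsets remains strongly detectable; its
measured sign under noise can differ from the noiseless one.

What the generator does *not* emulate: ocular artifacts and their
topography (only a square-pulse injector for testing rejection),
volume-conduction head geometry, channel-correlated noise (off by
default), habituation or time-on-task drifts, and the non-directional
cue's early positive tLRP dip. Passing tests therefore validate the
*machinery* — measurement conventions, statistics, null behavior — not
claims about any particular real dataset.

## The inference layer

`rm_anova()` is a classical repeated-measures/mixed ANOVA (engine:
`stats::aov` with `Error(subject/...)` strata): within effects test
against their subject-by-effect interaction, a between factor against
subjects-within-groups; balance is validated with missing cells named.
With all factors two-level, every numerator df is 1 and sphericity is not
an issue. The oracle identity F = (paired t on subject cell means)² holds
to 10⁻⁸ and is tested across randomized tables, as is total
sum-of-squares conservation.

`jzs_bf()` implements default-prior (JZS-class) Bayes factors for the
factorial linear models: fixed factors enter through orthonormal
sum-to-zero contrasts with zero-centered g-priors on standardized
coefficients, one g per model term with scale r = 0.5; the subject
blocking term (present in every model, including the null) has its own g
with scale 1.0. Under this coding a single two-level within factor
collapsed to within-pair differences is *exactly* the JZS one-sample t
Bayes factor with Cauchy scale r, which gives the package a closed
one-dimensional quadrature path and the tests an independent oracle
(a different substitution of the same integral, agreeing within 1%).
General models are integrated over their g vector by fixed-seed Monte
Carlo with the prior as proposal (default 10⁴ draws; 1/g ~ χ²₁/r²), with
the Monte-Carlo standard error reported and flagged above 0.2 on the log
Bayes factor. Model enumeration respects full marginality (2 / 5 / 19
models for 1 / 2 / 3 factors). Degenerate constant responses reduce to
the Occam penalty alone, so the null wins, as it should.

`model_comparison()` reports the strongest model, the strongest model
containing stimulation, and two summary ratios. The scientifically
meaningful one — the *stimulation exclusion ratio* — divides the strongest
stimulation-free model's Bayes factor by the strongest
stimulation-containing one: with a large cue effect in the data, comparing
stimulation models against the bare subject-only null would be swamped by
the cue term, and published statements like "the null effects model was N
times more likely than the strongest model including stimulation" are only
arithmetically possible under the exclusion reading. The subject-only
ratio is reported alongside for completeness.

## Reproducibility, sizes, and degenerate inputs

All simulation sizes used in the tests and acceptance script are the
package's own desk-scale choices: synthesis at 128 Hz (windows are
specified in ms, so the rate is free; 2048 Hz originals would change
nothing but runtime), 6–8 channel montages for replicate cohorts (the
64-channel montage exists and is exercised in the I/O tests), and 16–40
trials per block for cohort replicates (chosen by a sizing pilot as the
smallest counts that preserve comfortable detection margins for the
smallest cue effect; single-subject fidelity checks use the full 80).
Cohort sizes and all condition means are the study profiles' (n = 23;
n = 37 split 21/16).

Numerical edge cases are handled explicitly: undefined onset latencies
(zero suprathreshold area) raise a dedicated condition class rather than
returning a number, and a subject with an undefined cell is dropped from
that measure's balanced analysis; empty condition cells are errors naming
the cell; events outside the recording, unknown codes, responses without
targets, double re-referencing, band edges at or beyond Nyquist are all
rejected with informative messages. EDF storage is 16-bit with per-channel
physical ranges (5% headroom); round trips are exact up to the
quantization step, and the event stream (TSV) and montage (JSON)
round-trip exactly.

## Known limitations

Beyond the generator's non-goals listed above: the fractional-area
instability near window edges is inherent to the convention, not fixable
here; stimulation shifts of the two LRP onsets cannot be injected
independently of each other (single-template geometry); the Monte-Carlo
Bayes factors carry sampling error that the quadrature path avoids only
for collapsed designs; and the aov-based mixed ANOVA uses Type-I sums of
squares, which coincide with the usual tests only because the within-cells
are balanced by construction (unbalanced data are rejected rather than
approximated).
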