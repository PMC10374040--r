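---
title: "Decoding the envelope of speech with inserted pauses: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding the envelope of speech with inserted pauses: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`pausetrack` studies a simple question in auditory electrophysiology: if
silent pauses are inserted between the words of continuous speech, does
cortical tracking of the speech envelope — measured as the accuracy with
which the envelope can be reconstructed from EEG — increase? The package
implements the full analysis chain (stimulus manipulation, envelope
extraction, segmentation into pauses/onsets/non-onsets, backward mTRF
decoding, cross-validated evaluation, permutation inference) together with
a synthetic speech/EEG generator, so every stage can be validated against
known ground truth.

## The decoder

The backward multivariate temporal response function (the *decoder*)
reconstructs the stimulus feature from lagged multichannel EEG:

$$\hat S(t) = \sum_n \sum_\tau r(t+\tau, n)\, g(\tau, n),$$

where $r$ is the EEG, $n$ indexes channels and $\tau$ ranges over a lag
window (0–300 ms by default, 0–500 ms as a variant; at 128 Hz these are 39
and 65 sample lags). The anticausal sign ($t+\tau$) reflects that the
stimulus precedes the response. Weights are estimated by regularised least
squares on the lagged design matrix $R$:

$$g = (R^\top R + \lambda M)^{-1} R^\top S,$$

with $M$ a per-channel tridiagonal second-difference penalty (diagonal
$1, 2, \dots, 2, 1$, off-diagonals $-1$) that penalises curvature of the
weights across lags. $M$ extends block-diagonally over channels — lag
smoothing within a channel, no cross-channel coupling — which is the
convention of the standard decoder implementations this model family comes
from. $\lambda$ multiplies $M$ unscaled and is selected from 50
logarithmically spaced values between $10^{-2}$ and $10^{12}$ by
leave-one-out cross-validation over the speech segments: fit on all
segments but one, score the held-out segment by Pearson correlation, select
the $\lambda$ with the highest fold-averaged $r$ (ties go to the smaller
$\lambda$). The selection is made on the same cross-validated scores that
are reported, which is mildly optimistic; it replicates the conventional
procedure, and the per-fold scores are retained so a nested analysis can be
run downstream if desired.

Numerical choices worth knowing about:

* **Centring instead of an intercept.** Design columns and the target are
  mean-centred over the retained rows before solving. The constant vector
  lies in each penalty block's null space, so an unpenalised intercept
  column would be redundant and ill-conditioned; Pearson $r$ is
  offset-invariant, so centring does not affect the reported accuracy.
  Within cross-validation, held-out predictions add back the training
  offset before the MSE is computed.
* **A structurally singular system.** After common-average referencing the
  EEG channels sum to zero at every sample, so the lagged design
  annihilates the all-ones weight vector — which is also in the null space
  of $M$. The penalised normal equations are therefore singular *by
  construction*, at every $\lambda$. Because the right-hand side
  $R^\top S$ is orthogonal to that null vector, adding an escalating tiny
  diagonal jitter (starting at $10^{-10}$ of the mean diagonal) before the
  Cholesky factorisation returns the minimum-norm solution at factorisation
  cost; an SVD pseudoinverse is the last-resort fallback, and an exactly
  singular system at $\lambda = 0$ is reported as an error advising
  regularisation.
* **Exclusion semantics.** Masked samples (pauses, or whichever feature
  segments are excluded) are dropped from the fitting rows and from the
  scoring — algebraically identical to physically deleting those rows,
  which the test suite asserts to $10^{-12}$. The evaluation engine works
  on per-segment sufficient statistics ($X^\top X$, $X^\top y$, sums), so
  fits across the 50-point $\lambda$ grid, the nine train-by-test feature
  cells, and the hundreds of refits inside a permutation test reuse the
  same Gram matrices.

At $\lambda \to \infty$ the weights do not shrink to zero: they converge to
the penalty null space (constant across lags within each channel), i.e. the
best "flat" decoder. The penalty energy $g^\top M g$ is monotonically
non-increasing in $\lambda$, which is the property the tests assert.

## Signal processing

The broadband envelope is the magnitude of the analytic (Hilbert) signal of
the waveform. Band-limited features and EEG use one shared filter
contract: a linear-phase Hamming-window FIR band-pass whose length is
`round(6.6 * fs / shortest transition bandwidth)` forced odd, applied with
group-delay compensation so the net phase is zero. Transition bandwidths
default to 25% of each corner frequency, with the upper transition floored
at 2 Hz and the lower transition capped at the lower corner (the common
default of reference EEG software); the delta band is 1–4 Hz, theta
4–8 Hz. EEG preprocessing is common-average reference → band-pass →
resample to 128 Hz → per-channel z-normalisation with the population
(1/N) standard deviation, in that order.

Rate conversion deserves a note: the polyphase resampler available in the
R ecosystem measurably overshot a passband sinusoid's amplitude by ~15%
and delayed it by one sample in our oracle tests, so the package resamples
in the frequency domain instead — exact for band-limited signals — and
uses plain decimation when the ratio is an integer (everything resampled
here is already low-passed far below the target Nyquist; decimation also
preserves exact zeros inside pauses). Modulation spectra are averaged
periodograms (Hamming windows, 50% overlap) of the broadband envelope,
normalised to unit total power on 0–32 Hz; this is a deliberate
simplification relative to narrowband filter-bank modulation spectra,
adequate for the qualitative comparisons made here.

## Segmentation

Pauses are detected on the *broadband* envelope at the analysis rate — a
band-passed envelope oscillates about zero and has no stable "zero level"
— as runs of at least `min_pause_ms` (default 100 ms) below
`threshold_frac` (default 0.01) of the envelope's 95th-percentile
amplitude. The mask is then applied to the band-limited features. After
each pause, the first 150 ms of speech (19 samples at 128 Hz) is labelled
*onset*; remaining speech is *non-onset*; the three labels partition the
time axis. The 100 ms minimum keeps brief intra-word dips from counting as
pauses; neither parameter has an authoritative value, so both are exposed
in configuration. For synthetic data the generator's exact pause intervals
can be used directly (`mask_source = "ground_truth"`, the default in the
pipeline); threshold detection is validated against them to within two
samples at each edge.

"Pauses-removed" decoding excludes pause-labelled sample indices from both
the target and the corresponding rows of the lagged design — the EEG rows
at those same time indices — rather than splicing the raw signals, so the
temporal context entering each retained row is untouched.

## The synthetic generator

The generator emulates the study design: each cohort has 16 subjects, 4
speech segments per pause condition, and three conditions — natural speech,
250 ms (short) and 500 ms (long) silent pauses spliced into every
between-word gap (`n_words - 1` insertions, none after the final word).
Words are rendered as rectified-sinusoid bursts at the syllabic rate
(4.5 Hz, placing the envelope's modulation peak in the 4–5 Hz range) under
a 30 ms raised-cosine attack/decay; word durations and natural pauses are
lognormal (means 0.35 s and 0.08 s — the corpus statistics are not
authoritative, so these are exposed placeholders). The same seed produces
the identical word sequence across conditions, so pause-excised envelopes
— and hence their modulation spectra — coincide exactly across conditions,
while the inserted pauses add low-frequency (delta-band) modulation power.

EEG is generated forward: each channel is

```
onset_gain * gain_on[ch] * (k_on * onset_drive)
  + sustained_gain * gain_sus[ch] * (k_sus * envelope)  + 1/f noise
```

(`*` denoting convolution). The sustained kernel is a causal Gaussian bump
(peak 150 ms, FWHM 120 ms). The onset kernel is *biphasic* — a negative
deflection at 100 ms followed by a positive one at 180 ms — emulating the
N1–P2 complex of the auditory late response; a monophasic bump is too
lowpass to carry theta-band information, and with it the theta-band
condition effect cannot arise. The onset drive is the envelope inside the
first 150 ms of speech after each pause, scaled per onset by
$1 - e^{-\text{gap}/\tau}$ with $\tau$ = 1 s: the saturating enhancement of
auditory late responses by longer preceding silence. This recovery
mechanism is the generator's expression of the physiological effect the
stimulus manipulation is designed to exploit; setting
`onset_recovery_tau_s = 0` disables it. Noise is Gaussian with power
$\propto 1/f$, generated spectrally and scaled so each channel's
clean-to-noise power ratio equals `snr_db` exactly. Every recording draws
from its own RNG stream derived from the master seed by a fixed counter
scheme over (subject, segment, condition); per-channel gains are drawn
from a subject-level stream so a subject's "head" is constant across
conditions.

What the generator does *not* emulate: phonetics (no formant structure,
no coarticulation), ocular/muscle artifacts, mains interference,
channel-specific response latencies, attention or intelligibility effects.
Passing tests therefore show that the pipeline recovers what this model
family encodes — linear onset/sustained envelope responses in 1/f noise —
not that real EEG behaves this way.

## Statistical inference

Per-recording significance uses a permutation null: envelope–EEG pairings
are mismatched in both training and testing, the *entire* cross-validation
including $\lambda$ selection is re-run per permutation (500 by default),
and the observed mean $r$ is compared to the empirical 95th-percentile of
the null, taken as the smallest null value with at least $1-\alpha$ of the
null at or below it (conservative with finite draws). All segments are
truncated to the shortest segment so any envelope can be paired with any
EEG. With only 4 segments the derangement pool has 9 elements — too few
support points for a calibrated 5% test (it degenerates to "observed
exceeds the null maximum", a 10% rule) — so for four or fewer segments the
pairings are drawn from **all non-identity permutations** (23 for n = 4);
with five or more segments strict derangements are used. Under this
scheme the measured false-positive rate on null synthetic data is at the
nominal 5%.

Group comparisons use Friedman tests across pause conditions within each
decoder cell and Wilcoxon signed-rank tests between cells (zeros dropped,
mid-ranks for ties, exact p for up to 25 effective pairs and a
continuity-corrected normal approximation beyond), with Bonferroni
correction: $\alpha/3$ across conditions, $\alpha/27$ for the nine
train-by-test cells tested pairwise per band, $\alpha/9$ in the
pauses-removed analysis. Fully tied Friedman data (a 0/0 tie correction)
is reported as statistic 0, p = 1.

## Problem sizes used in the test-suite and acceptance runs

The shipped tests exercise the pipeline at reduced scale, chosen once as
the smallest sizes at which the studied effects are comfortably visible:
cohort checks use 16 subjects, 8 EEG channels, 4 segments of ~100 words
(about 43/68/93 s per segment for natural/short/long), envelope and EEG
synthesised at 512 Hz and analysed at 128 Hz; the noiseless recovery check
uses 4 × 2-minute segments; permutation calibration uses 200 independent
null datasets of 4 × ~17 s segments with 200 permutations each. The
acceptance script repeats these computations (with a smaller calibration
batch) from a user-supplied seed.

## Known limitations

* $\lambda$ is selected per train-by-test cell on the reported scores; a
  nested selection would remove the small optimism this induces.
* The permutation fast path applies to the full-envelope feature; masked
  features fall back to a slower general path.
* Real-audio workflows expect word boundaries from an external aligner via
  TSV; no alignment is performed in-package, and no EDF/BDF reader is
  bundled — the fixture format (WAV + TSV + JSON) is the supported
  container.
* The duration-matched analysis truncates from the start of each segment;
  the choice of which material to retain is not varied.

## A miniature end-to-end run

```{r, eval = FALSE}
library(pausetrack)

config <- run_config(
  sim = sim_config(n_subjects = 4, n_channels = 8, words_per_segment = 60,
                   fs_env = 512, fs_eeg = 512, onset_gain = 5,
                   sustained_gain = 1, snr_db = 0, seed = 1L),
  bands = c("delta", "theta"),
  lambda_grid = default_lambda_grid(25)
)
study <- run_full_study(config)
report <- make_report(study)
report$summary
report$plots$condition_means
```
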