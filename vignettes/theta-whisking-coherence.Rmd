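---
title: "Theta-whisking coherence: models, statistics, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Theta-whisking coherence: models, statistics, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thetawhisk)
```

## The scientific problem

In rats, two prominent rhythms occupy the same 5-12 Hz ("theta") band: the
hippocampal theta oscillation of the CA1 local field potential (LFP), and the
forward-backward sweeping of the whiskers ("whisking"). The two rhythms arise
from independent generators — whisking survives ablation of the septo-
hippocampal system — and in an open arena they are no more coherent than
independent oscillators would be. The question this package's analyses are
built for is whether, and when, those generators *become* coherent: in
particular, during whisker-mediated texture discrimination, when sensory
evidence acquired by whisking must be matched against a memorized reward
rule, a computation that engages the hippocampus.

The pipeline answers that question with four coupled analyses:

1. **Episode segmentation.** Each trial is divided into behavioral episodes
   anchored at whisker-stimulus contact: baseline (2.5-3 s before first
   contact), approach (the 500 ms leading up to contact), touch (first to
   final contact), turn, and reward. Fixed-length episodes use 500 ms, chosen
   to match the mean touch duration (~540 ms). The turn episode is segmented
   but excluded from spectral and synchronization analyses.
2. **Spectral analysis.** Episode power spectra (Hanning taper, 4-20 Hz) and
   an adaptive multitaper spectrogram (window 8 cycles long at each
   frequency, Slepian tapers), with baseline normalization and trial-shuffle
   randomization tests.
3. **Phase synchronization.** Band-pass both signals to 5-12 Hz, extract
   instantaneous phase by the Hilbert transform, and compute the Phase
   Synchronization Index over short windows, judged against a bootstrap
   chance level built by destroying the trial pairing.
4. **Spike phase locking.** Assign each barrel-cortex spike a phase of the
   reference rhythm and quantify locking with circular statistics: the
   Rayleigh test, von Mises fits, pooled and per-neuron summaries, and
   equal-sample bootstraps.

A synthetic-session generator with known ground truth makes every stage
verifiable without recordings.

## The synchronization model

The Phase Synchronization Index between two narrow-band signals with
instantaneous phases $\phi_x(t)$ (theta) and $\phi_y(t)$ (whisking) is the
mean resultant length of the phase difference
$\theta_{xy}(t) = n\,\phi_x(t) - m\,\phi_y(t)$ over a window:

$$\mathrm{PSI} = \sqrt{\langle\cos\theta_{xy}\rangle^2 +
                       \langle\sin\theta_{xy}\rangle^2},$$

ranging from 0 (no consistent phase relationship) to 1 (constant phase
difference). Because both rhythms share one spectral band, only 1:1 locking
($n = m = 1$) is analyzed. The circular mean of $\theta_{xy}$ is reported as
the phase delay, with the sign convention *theta minus whisking* (the
direction is not dictated by the mathematics; the package fixes and documents
one choice).

Two facts shape every design decision downstream:

* **Short windows inflate PSI.** Over 250 ms (about two theta cycles) the
  phase difference of even independent oscillators drifts little, so
  single-window PSI is far above zero under the null. Absolute PSI values are
  therefore meaningless without a chance level.
* **The chance level must preserve everything except the pairing.** The
  bootstrap pairs the theta phase of trial $i$ with the whisking phase of a
  different trial (a random derangement), computes the mean PSI of each of
  2,000 such sets, and takes the upper bound of their 95% interval. The
  package uses the 97.5th percentile of the set-mean distribution by default;
  the mean + 1.96 SD alternative is available by argument, since "mean + 95%
  confidence interval" admits both readings.

### Phase extraction and its bias

Instantaneous phase comes from the analytic signal of the 5-12 Hz band-passed
trace. The filter is a zero-phase (forward-backward) Butterworth of order 4
per pass — a standard choice with minimal ringing over a 7 Hz-wide band; the
paper-trail for the filter realization is in the function documentation.
Hilbert edge effects are reduced by reflect-padding one second at each end;
analysis windows are expected to stay at least 0.25 s from signal edges.

Asymmetric oscillation wave shape makes some phases over-occupied, which
biases every phase-locking statistic upward. `psi_bias_correct()` tests the
session-wide phase distribution for uniformity (Rayleigh, $\alpha = 0.05$)
and, when non-uniform, applies the rank transform
$\Psi(\phi) = 2\pi \hat F(\phi) - \pi$, where $\hat F$ is the session
empirical CDF of phase. The output distribution is uniform by construction.
The exact construction of this transform is not uniquely fixed by precedent;
the empirical-CDF reading implemented here is one standard choice, and the
correction is skipped (with a flag) below 100 samples, where the empirical
CDF itself is too noisy to help.

When the two signals are sampled at different rates (2 kHz LFP against
1 kHz whisking), phase differences are evaluated at the LFP phase-sample
times by linear interpolation of the *unwrapped* whisking phase — wrapped
interpolation would be wrong near $\pm\pi$ — avoiding any resampling of raw
signals.

### Trial-level PSI and behavior

Per trial, PSI is computed over a common window length
$L = \min(250\ \mathrm{ms}, \text{touch duration})$: approach ends at contact
onset, touch starts there. The trial metrics table derives: PSI change
(touch minus approach), normalized duration (per-rat maximum duration minus
the trial's duration, so faster trials score higher), duration groups cut at
the per-rat mean $\pm$ 0.4 SD, PSI groups cut at the mean $\pm$ 0.5 SD, and
exclusion of outlier durations (< 0.15 s or > 2 s). The behavioral statistics
report Pearson correlations (overall, per group), paired Wilcoxon signed-rank
tests, a 10,000-iteration two-sample randomization test for correct versus
incorrect PSI, and one-tail t tests; all randomization p-values use the
add-one rule, so no permutation p is ever exactly zero.

## Spike phase locking

Spikes are assigned phases by linear interpolation of unwrapped phase at
spike times (nearest-sample assignment is available by argument). Locking is
tested with the Rayleigh statistic in the form $Z = 2nr^2$ with
$p = \exp(-Z/2)$, the survival function of $\chi^2_2$. Note that the more
common convention is $Z = nr^2$ with $p = \exp(-nr^2)$: the two differ by a
factor of 2 in $Z$ but give *identical* p-values; the package implements the
$2nr^2$ form and documents the discrepancy rather than resolving it. A
finite-sample (Zar) correction to the p-value is available behind a flag,
default off.

The von Mises fit uses the circular mean for $\hat\theta$ and solves
$I_1(\kappa)/I_0(\kappa) = r$ for $\hat\kappa$ by monotone root finding;
degenerate samples ($r \ge 1 - 10^{-9}$) cap $\kappa$ at a documented maximum
with a flag. Because $r$ — hence $Z$ and $\hat\kappa$ — depends on sample
size (fitted $\kappa$ of uniform phases inflates at small $n$), comparisons
across conditions use an equal-sample bootstrap: every condition is resampled
to the smallest condition's spike count for 500 iterations and the medians of
$Z$ and $\kappa$ are compared. Per-neuron analyses apply the inclusion rule
that neurons with fewer than 1,000 spikes per condition are excluded unless
already significantly locked; per-neuron significance uses Rayleigh
$p < 0.05$ with no multiple-testing correction across neurons (a deliberate
mirror of the analysis this package re-implements; the choice is noted here
rather than silently changed).

The shuffle control for pooled histograms assigns each spike a phase drawn
from the within-window phase pool rather than from a uniform distribution:
this preserves residual phase-occupancy bias, which is exactly what a
"shuffled across time" control should preserve.

## Spectral choices

* Episode spectra: Hanning-tapered periodograms of equal-length (500 ms)
  windows, zero-padded to an effective 0.25 Hz grid — the resolution at which
  theta peak frequencies are conventionally reported — and restricted to
  4-20 Hz. Unequal window lengths are an error, not a warning, because mixed
  lengths silently change the frequency resolution per window.
* Spectrogram: window length $8/f$ at each frequency $f$ (so 1 s at 8 Hz),
  three Slepian tapers with time-bandwidth product $NW = 2$ (the taper count
  is configurable; three is the standard choice at this $NW$). The signal is
  low-pass decimated internally (default to 200 Hz) before tapering: the
  analysis band ends at 20 Hz, and computing 4,000-point eigenvector
  problems at 2 kHz would buy nothing. Baseline normalization of the
  spectrogram is a per-frequency power ratio by default, with a dB-difference
  alternative; both are exposed because the printed convention covers only
  the episode spectra (the 10 log10 power divided by the 4 Hz baseline
  log-power), which `normalize_power()` implements literally.
* Randomization tests shuffle window-to-group assignment, use the add-one
  two-sided p, and apply Bonferroni across frequencies. Two-sidedness is a
  package decision; the source convention is unstated.
* Peak frequency is the in-band argmax; an all-equal tie breaks to the
  lowest frequency with a flag. Across subjects, peaks are aggregated as
  per-subject peak then mean $\pm$ SD, with a one-way ANOVA plus Tukey
  comparisons across episodes.

## The synthetic-session generator

The generator encodes the data-generating assumptions the analyses test:
independent rhythmic generators that can become coherent, with coupling that
depends on the behavioral episode.

**Coupled oscillators.** Phases evolve by Euler-Maruyama integration at the
LFP rate:

$$d\phi_x = 2\pi f_\theta\,dt + \sigma\,dW_x, \qquad
  d\phi_y = 2\pi f_w\,dt + \varepsilon(t)\sin(\phi_x - \phi_y - \delta)\,dt
            + \sigma\,dW_y,$$

a Kuramoto-style sine pull of theta on the whisking phase only. The
underlying biology argues for reciprocal interaction, but no quantitative
model of it is established; unidirectional coupling is the minimal structure
that yields controllable PSI and a controllable phase lag $\delta$. Coupling
and amplitude change stepwise at episode boundaries (no ramps), which keeps
the ground truth of every analysis window unambiguous. The LFP waveform is
$A_x(t)\cos\phi_x$ plus 1/f ("pink") background noise; whisking is an offset
plus $A_y\cos\phi_y$ with white noise — so the spectral stages see realistic
backgrounds.

**Default conditions.** LFP at 2 kHz and whisking at 1,000 frames/s match
the recording conditions the pipeline targets; theta at 8 Hz (the baseline
peak is near 7.9 Hz) and whisking at 10 Hz (the palpation peak). Touch
durations are drawn around 0.54 s with SD 0.224 s; turn durations around
0.26 s. Phase noise of 3 rad/√s with touch-level coupling
$\varepsilon = 30$ /s places the 250 ms-window PSI in the empirically
observed regime: chance near 0.5, coupled touch windows near 0.75-0.9.
Coupling multipliers are 0.8 during approach and 1 during the first 500 ms of
touch against a 0.05 background, so coherence is an episode phenomenon, not a
session constant. The generator compresses the task's long (several-second)
inter-trial intervals to a configurable 2.6 s gap: sessions stay compact
while the pre-trial waiting span remains long enough for waiting-period
spike analyses. One step change in coupling at contact onset is an
*assumption of convenience*: nothing here claims that is how contact acts as
a timing signal in the animal, only that it produces the episode contrast
the analyses must detect.

**Trial independence.** Each trial is generated as an independent block with
fresh random initial phases, then blocks are concatenated. That matches the
exchangeability assumption behind the trial-shuffle chance level, and makes
the null calibration property testable: with coupling set to zero, the
observed session-mean PSI should exceed the 97.5th-percentile chance level in
about 2.5% of sessions — a property the test suite verifies over 200 seeded
sessions.

**Planted behavior.** Each trial's realized PSI is measured from the emitted
waveforms with the same band-pass + Hilbert route the analysis uses (planting
on the latent generating phases would leave the planted correlation
attenuated by estimation noise, making recovery tests conflate two different
questions). Touch durations are then a linear function of PSI change plus
Gaussian noise calibrated to hit the target Pearson correlation in
expectation, clamped to a plausible range; correct/incorrect flags are
Bernoulli draws from a logistic link on PSI-touch whose intercept and slope
are solved numerically so the expected proportion correct and the expected
correct-minus-incorrect PSI difference match their targets exactly. Default
targets — correlation 0.146, PSI difference 0.05, proportion correct 0.78 —
are the empirical operating points the pipeline is expected to resolve.

**Spikes.** Spike trains are inhomogeneous Poisson with intensity
$\lambda(t) = r_0\,e^{\kappa\cos(\phi(t)-\theta)}/I_0(\kappa)$, sampled
exactly by thinning (the intensity is bounded). The normalization by
$I_0(\kappa)$ makes the mean rate exactly $r_0$ and the spike-phase law von
Mises$(\theta, \kappa)$ under uniform phase occupancy — so parameter-recovery
tests have exact targets.

**What the generator does not emulate.** No biophysics: no conductances, no
closed sensorimotor loops, no spike waveforms. Whisking amplitude asymmetries
(protraction faster than retraction), theta harmonics, and amplitude-phase
coupling are absent, so the wave-shape bias that motivates the
$\Psi$-transform is much milder in synthetic data than in recordings; the
transform is therefore exercised by dedicated tests with skewed phase
distributions, not by the generator's defaults. Passing tests certify the
statistical machinery under the stated model, not the neuroscience of any
particular recording.

## Numerical and scale choices

* All randomness flows through R's RNG; every generator and every resampling
  routine takes a seed, and identical configuration plus seed reproduces
  sessions and reports bit-identically (the integrator draws its noise from
  the same stream via Rcpp).
* The chance-level computation evaluates the full pairwise trial-by-trial
  PSI matrix once (four real matrix products) and then scores each of the
  2,000 derangements by indexing — this turns an $O(\text{shuffles} \times
  \text{trials} \times \text{samples})$ computation into one matrix product
  plus cheap lookups, which is what makes 200-session calibration runs
  affordable in the test suite.
* The monotonicity property (mean PSI strictly increasing over coupling
  $\varepsilon \in \{0, 0.5, 1, 2, 5, 10\}$ /s) is tested with 10 s windows,
  a 0.2 Hz detuning and phase noise of 1 rad/√s, 100 windows per level:
  250 ms windows saturate near the null (short-window inflation) and cannot
  separate $\varepsilon = 0$ from $0.5$; long windows expose the stationary
  concentration of the phase difference, which is monotone in the coupling.
  The test-suite problem sizes throughout (e.g., 1,010 s of signal per
  coupling level, 915-trial sessions for the planted-effect recovery, 500
  null runs for family-wise error) were chosen once as the smallest sizes at
  which the tested quantities are stable.
* Touch durations are clamped to [0.155 s, 1.995 s] inside the generator so
  that planted durations never trigger the pipeline's own outlier exclusion;
  the exclusion logic is exercised by explicit metric-table tests instead.
* `fit_von_mises()` refuses samples below 10 phases; $\kappa$ is capped at
  1e3 on degenerate input. The Bessel ratio uses exponentially scaled
  `besselI` and an asymptotic tail above $\kappa = 700$, so the root finder
  never overflows.

## Known limitations

* The waiting-period epoch has no instrumented boundaries; windows are tiled
  over inter-trial intervals at a guard distance (default 1 s) from flanking
  events. The epoch definition is configurable because no canonical bounds
  exist.
* The unidirectional coupling model cannot represent phase resetting of
  theta by contact, only a step in coupling strength; directionality
  inference is explicitly out of scope.
* Absolute PSI levels in synthetic sessions depend on window length and
  noise in ways that real recordings need not reproduce; all cross-condition
  claims in the test suite are therefore relative (above/below chance,
  monotone in coupling, planted minus recovered), never absolute.
* The analyses assume stationary sampling rates and gap-free signals; the
  session container enforces this.
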