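---
title: "Cortical oscillation analysis with megosc: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cortical oscillation analysis with megosc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7)
library(megosc)
```

## Scope and scientific background

`megosc` implements a group-level analysis chain for trial-epoched MEG
recordings of visual responses, of the kind used to study cortical
excitability in conditions such as visual snow syndrome: high-contrast
grating stimuli reliably suppress occipital alpha (8–13 Hz) power and
induce narrow-band gamma (40–70 Hz) oscillations in primary visual
cortex, and the phase of alpha modulates the amplitude of gamma
(phase–amplitude coupling, PAC).  The pipeline covers:

1. **Pre-processing** — zero-phase Butterworth band-pass (0.5–250 Hz,
   4th order) and power-line notch filtering, epoching around stimulus
   onset with generous padding, and decimation to 300 Hz.
2. **Source analysis** — an LCMV beamformer on a volumetric grid:
   band-limited sensor covariance over combined baseline + stimulus
   windows, 5% diagonal loading, per-grid-point stimulus/baseline power
   change in dB, selection of the region-of-interest grid point with the
   largest gamma increase, and extraction of a broadband "virtual
   electrode" through that point's spatial filter.
3. **Spectral metrics** — multitaper (gamma) and single-Hanning-taper
   (alpha) sliding-window power, baseline-normalised band changes in dB,
   peak frequency of the change spectrum, and absolute baseline power.
4. **PAC** — amplitude-normalised mean-vector-length (MVL)
   comodulograms over phases 7–13 Hz × amplitudes 34–100 Hz, baseline
   corrected by subtraction.
5. **Group statistics** — pooled-variance t-tests with Cohen's d, and a
   two-dimensional cluster-based permutation test over comodulograms.
6. **Synthetic cohorts** — a generator producing epoched recordings with
   fully known ground truth, used to validate every stage end to end.

Because raw patient MEG of this kind cannot be shared, the package's
empirical claims are validated on synthetic cohorts whose generating
parameters mirror the published group-level statistics of a
patient/control grating study (18 patients, 16 controls, roughly 110 and
117 clean trials per subject).

## The generative model

Each simulated trial is

$$x(t) = a_\alpha \sin(2\pi f_\alpha t + \phi_0)
       + g(t)\,\sin(2\pi f_\gamma t + \psi_0) + \varepsilon(t),$$

with gamma envelope

$$g(t) = a_\gamma\,\frac{1 + m \cos(\phi_\alpha(t) - \phi_{pref})}
        {\sqrt{1 + m^2/2}},$$

where $\phi_\alpha(t)$ is the instantaneous alpha phase, $m \in [0,1]$
the PAC modulation depth, and $\varepsilon$ is $1/f$ background noise.
Design notes:

* **Power-invariant coupling normalisation.**  The mean square of
  $1 + m\cos(\cdot)$ is $1 + m^2/2$, so dividing the envelope by
  $\sqrt{1 + m^2/2}$ makes total gamma power exactly independent of
  $m$.  A simpler $1/(1+m)$ normalisation is *not* power-invariant (it
  biases gamma power by $-2.1$ dB at $m = 0.3$), which would confound
  coupling and power manipulations; we therefore use the exact form.
* **Induced, not evoked.**  $\phi_0, \psi_0$ are drawn uniformly per
  trial, so trial-averaged *amplitude* cancels while trial-averaged
  *power* survives — matching the analysis' focus on induced activity.
* **Stimulus onset switches amplitudes, phases stay continuous.**  Before
  $t = 0$ the baseline amplitudes ($a_\alpha^{base}$,
  $a_\gamma^{base}$) and baseline coupling ($m_{base}$, default 0)
  apply; after onset the stimulus values apply.  The default alpha
  change is $-2$ dB and gamma $+3$ dB.
* **Background noise.**  `noise_amp = 1` (SD of the standardised
  $1/f$ series) puts gamma-band SNR near 10.  This was chosen from the
  signal model: with a much cleaner baseline, the coupling *sidebands*
  at $f_\gamma \pm f_\alpha$ — which exist only post-stimulus when
  coupling is induced — show larger dB changes than the gamma carrier
  itself and capture the peak-frequency detector at the band edges.
  At SNR ≈ 10 the carrier dominates for realistic $m$, while the
  downward bias of the recovered gamma change stays ≈ 0.2 dB.  This is
  a real property of narrow-band AM signals, worth remembering when
  interpreting peak frequencies from strongly coupled data.

### Cohort-level defaults

`cohort_spec()` draws per-subject parameters from group distributions
whose defaults encode the study conditions the package emulates:

| parameter | patients | controls | between-subject SD |
|---|---|---|---|
| subjects | 18 | 16 | — |
| trials | 110 | 117 | — |
| gamma change (dB) | 3.20 | 2.27 | 1.26 |
| alpha change (dB) | −1.57 | −1.99 | 1.4 |
| coupling depth m | 0.04 | 0.12 | 0.065 |
| gamma frequency (Hz) | 53.2 | 52.6 | 3 |
| alpha frequency (Hz) | 10.8 | 10.7 | 1 |

The gamma/alpha dB distributions reproduce the published group means and
the pooled SD implied by the published effect sizes (e.g.
$(3.20-2.27)/1.26 = 0.74$).  The coupling means and SD were calibrated
once, from the MVL signal model, so that the expected maximum
comodulogram Cohen's d is near 1.2 — the size of the published PAC group
difference; they were not adjusted afterwards.  Frequency draws are
clipped to stay inside the analysis bands.  The paper-like absolute
amplitudes ($a_\alpha = 3$, $a_\gamma^{base} = 1.5$, noise 1) are free
parameters of the generator — no amplitude calibration data exist for
the original recordings — and are surfaced in `subject_sim_config()`.

## Numerical choices

* **Zero-phase filtering.**  All Butterworth filtering is applied as the
  squared magnitude response $|H(\omega)|^2$ on the FFT of the padded
  epoch — the steady-state equivalent of forward–backward (`filtfilt`)
  application, vectorised across trials and channels.  Wrap-around
  transients are confined to the 2.5 s padding, which is trimmed before
  any windowed statistic.  Filters are designed with `signal::butter()`
  and designs with poles outside the unit circle are rejected.
* **Decimation** (1000 → 300 Hz) applies an 8th-order Butterworth
  anti-alias response with corner 135 Hz (= 0.45 × target rate; a
  250 Hz passband would alias) and resamples by Fourier truncation,
  which is exact for band-limited content and preserves the epoch's
  endpoints to within one output sample.  The 135 Hz corner keeps the
  whole 34–100 Hz PAC amplitude range (plus its ±13 Hz sidebands)
  intact.
* **Multitaper parameters.**  0.5 s windows, 0.02 s steps, ±7 Hz
  smoothing: time–bandwidth product 3.5, hence $\lfloor 2 \cdot 3.5 - 1
  \rfloor = 6$ DPSS tapers, computed from the standard tridiagonal
  commuting matrix and normalised to unit energy.  The 2 Hz gamma
  frequency step matches the 0.5 s window's native resolution.
* **Alpha window length.**  A literal 0.1 s sliding window cannot
  resolve a 1 Hz frequency grid (its resolution is ≥ 10 Hz), so the
  alpha analysis interprets 0.1 s as the *slide step* with a 0.5 s
  Hanning window; both are exposed as arguments.
* **Stimulus window.**  0.3–1.5 s after onset versus a 1.2 s baseline
  (−1.5 to −0.3 s) everywhere, skipping the evoked transient.  (Where a
  0.3–1.2 s stimulus window is preferred for the gamma average, pass
  `stim_win = c(0.3, 1.2)`.)
* **Peak frequency** is the largest *strict interior* local extremum of
  the baseline-normalised dB spectrum (findpeaks semantics); monotone
  spectra fall back to the band argmax with an `interior = FALSE` flag.
  The dB-change spectrum (not the raw stimulus spectrum) is used, since
  the quantity of interest is the stimulus-induced response.  Detection
  is sign-adaptive: when the mean band change is a *decrease* (alpha
  suppression) peaks are found on the inverted spectrum, so the detected
  frequency always marks the strongest induced change — peaking the
  signed spectrum of a suppressed band would instead return whichever
  noise-floor bin changed least.
* **PAC bandwidths.**  Phase filters are ±1 Hz (matching the 1 Hz phase
  grid).  Amplitude filters are ±13 Hz — at least the highest phase
  frequency — so the modulation sidebands that carry the coupling
  survive filtering; narrower amplitude bands demonstrably degrade
  modulation recovery.  Trials are windowed (0.3–1.5 s), concatenated,
  and summarised by a single MVL per bin; baseline correction subtracts
  the equal-length baseline comodulogram (subtraction, not ratio, so
  corrected values may legitimately be negative).
* **Comodulogram grid.**  7 phase bins (7–13 Hz) × 34 amplitude bins
  (34–100 Hz in 2 Hz steps), both endpoints included; the grid is fully
  configurable.
* **Beamformer.**  Fixed-orientation scalar lead fields; band-limited
  covariance per analysis band; common filter from the combined
  baseline + stimulus covariance with 5% diagonal loading; source power
  as $w^\top C_{win} w$ (equivalent to window-averaged power through the
  filter and numerically simpler than time-resolved power).  ROI peak
  ties break deterministically to the lowest grid index.  The virtual
  electrode applies gamma-band-derived weights to *broadband* data.
* **Cluster statistic.**  The cluster summary is the maximum |t| within
  the cluster (the more common sum-of-t is available via
  `cluster_stat = "sum"`), thresholded at the two-tailed 5% critical
  value, 4-connectivity by default (8 available), separate positive and
  negative tails each tested at 0.025, permutation p-values with the
  add-one correction, and exact enumeration available for small samples.
  Zero-variance bins are treated as sub-threshold rather than
  propagating NaN.

## The toy forward model

`toy_source_model()` places 30 sensors on a spherical cap over a 4×4×4
source grid with lead field $L_{sg} = 1/(d_{sg}^2 + 0.05)$ and labels a
posterior-inferior 2×2×2 block as the region of interest.  This
exercises everything the LCMV stage needs — unit gain ($w^\top l = 1$),
point-source recovery, regularisation behaviour — without claiming any
head-model physics.  Real-anatomy forward modelling (single-shell
surfaces, MRI co-registration, atlas parcellation) is out of scope; the
`source_model` structure accepts user-supplied positions, lead fields
and ROI masks.

## What the synthetic validation does and does not show

The generator reproduces the *statistical structure* the analysis
assumes: 1/f background, induced band-limited power changes, induced
alpha-phase→gamma-amplitude coupling, and between-subject variability
matched to published group statistics.  It does not emulate evoked
components, artifacts (blinks, cardiac, SQUID jumps), head movement,
inter-regional dynamics, or realistic field spread.  Passing tests
therefore demonstrate that the *estimators and tests recover known
ground truth under the assumed signal model*, not that the pipeline is
robust to every pathology of real recordings.

Two further honesty notes.  First, the alpha peak frequencies of the
cohort defaults follow the published per-group means (≈10.7 Hz), so the
group-level PAC difference is centred at 10–11 Hz phase bins; in the
original data the PAC effect peaked at 8–9 Hz phase even though alpha
peaked near 10.7 Hz — a dissociation outside this generative model.  The
structural-replication check therefore asserts *overlap* of the
significant cluster with the published 8–9 Hz × 54–76 Hz region, not
equality of topology.  Second, group-level t statistics from a single
synthetic cohort carry the full sampling variability of an n = 34
design (the gamma-power contrast has only ≈ 55% power at the generating
effect size of d = 0.74), so individual runs legitimately fluctuate
around the published values.

## A short worked example

```{r example, eval = FALSE}
library(megosc)

# one strongly coupled subject, simulated at the analysis rate
cfg <- subject_sim_config(fs_raw = 300, n_trials = 60, coupling_m = 0.8,
                          seed = 1)
ve <- as_virtual_electrode(simulate_subject(cfg))

tfr <- multitaper_tfr(ve)
band_power_change(tfr, c(40, 70))        # ~ +3 dB programmed change

cm <- corrected_comodulogram(ve)
print(cm)                                # peak near (10 Hz, 54-56 Hz)
plot(cm)

# the full experiment (several minutes at default sizes)
res <- run_replication(replication_config(seed = 1))
summary(res)
```

## Problem sizes used in the shipped tests

The package's own test suite validates the estimators on reduced problem
sizes chosen to keep the full suite fast while leaving comfortable
statistical margins: comodulogram peak recovery uses 20 seeds × 100
trials; gamma-dB recovery 10 seeds × 40 trials through the full raw-rate
chain; beamformer localisation 20 seeds at 0 dB SNR; cluster-test
type-I control 30 cohorts at 1000 permutations; and the end-to-end
structural replication one cohort at 40 trials per subject with 1000
permutations.  `scripts/acceptance.R` runs the full default conditions
(110/117 trials, 10 000 permutations).

## Known limitations

* MVL is the only PAC estimator; modulation-index and GLM-based
  estimators are out of scope, as is theta–gamma coupling (the 1.2 s
  windows are too short to estimate it reliably).
* The cluster permutation assumes exchangeability of subjects under the
  null; covariates (age, sex) are not modelled.
* Peak frequencies read from the dB-change spectrum are biased a few Hz
  above the true oscillation frequency when the background is $1/f$: the
  noise floor declines across the ±7 Hz smoothing plateau, tilting the
  ratio spectrum upward.  Group *differences* in peak frequency are
  unaffected (both groups share the bias), but absolute peak estimates
  should be read with this in mind.
* The beamformer has no depth-bias correction or noise normalisation, so
  absolute source amplitudes across grid points are not comparable —
  only baseline-normalised changes are interpreted.
* The epoch container uses R serialisation; it is an interchange format
  for this package's stages, not a cross-language archive format.
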