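---
title: "Methods: simulating and characterising stimulator interference in MEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and characterising stimulator interference in MEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Telemetric deep-brain stimulators can stream local field potentials (LFP)
from chronically implanted electrodes while the patient sits in an MEG
scanner. This opens the door to cortico-subcortical coherence studies
without externalised leads, but the implant is an aggressive interference
source: telemetry radiates narrowband tones and combs, the stimulation pulse
train produces a harmonic stack plus system-specific mixing products, the
ferromagnetic pulse generator moves with breathing, and monopolar
stimulation currents drive cryogenic SQUID sensors into flux-lock resets.
`perceptmeg` re-creates this situation synthetically for three system
profiles — a 275-channel axial-gradiometer system at 19.2 kHz, a 306-channel
planar-gradiometer/magnetometer system at 5 kHz, and a 62-channel wearable
OPM array at 6 kHz — and implements the analysis chain used to characterise
the interference and to map LFP-referenced coherence.

## The simulator's world

Each operating condition is an additive composition of independent artefact
sources on top of shaped sensor noise. The load-bearing facts the generator
encodes:

* **Noise floors** (per sensor type, piecewise log-log ASD curves): flat
  3.5 fT/\(\sqrt{Hz}\) for the axial-gradiometer system (below its 5
  fT/\(\sqrt{Hz}\) reference bound); planar gradiometers below 0.6
  fT/(mm\(\cdot\sqrt{Hz}\)); magnetometers rising towards 100
  fT/\(\sqrt{Hz}\) below 50 Hz; the OPM floor below 30 fT/\(\sqrt{Hz}\)
  above 30 Hz, rising to 540 fT/\(\sqrt{Hz}\) at 10 Hz. Mains lines (50 Hz
  family; plus a 60 Hz family in the CTF room) and the OPM's intrinsic peaks
  (26, 120, 155, 160, 173, 180 Hz) sit on top.
* **Telemetry**: an open modern-protocol session adds a single narrow
  123 Hz line (harmonics beyond 200 Hz); open legacy telemetry adds a comb
  of 14.3 Hz harmonics up to 150 Hz; legacy *streaming* additionally fills
  in a dense comb, modelled as 14.3/3 = 4.77 Hz harmonics with 1/n amplitude
  decay (the individual frequencies of the dense comb are not documented;
  the choice of fundamental is configurable).
* **Communicator proximity**: 2 Hz harmonics between 4 and 48 Hz.
* **Stimulation** (default 5 mA / 60 µs / 145 Hz): a charge-balanced
  biphasic pulse train projected through a current dipole at the lead
  position. Bipolar mode adds system extras — five extra tones on the CTF
  system (32.6, 65, 80, 112, 177 Hz), a broadened 72.5 Hz subharmonic on a
  quarter of the planar-gradiometer channels. Monopolar mode is severe:
  sidelobes 16 Hz below / 11 Hz above the stimulation peak on the CTF
  system, a ~20 dB broadband lift and Poisson (0.05/s/channel) step jumps of
  50–500 channel SDs on cryogenic channels. The OPM array is deliberately
  spared the lift and jumps: open-loop OPMs recover after over-ranging,
  which is one of the phenomena of interest.
* **OPM nonlinearity**: the sensor's internal 923 Hz modulation tone mixes
  with strong interferers through `y = x + αx² + βx³`, producing
  intermodulation lines at \(|n f_{stim} - m f_{mod}|\) (53, 92, 198 Hz at
  quadratic order; 39, 106, 184 Hz at cubic order, visible only under the
  stronger monopolar artefact).
* **LFP stream**: 250 Hz, two hemispheres, on its own clock
  \(t_{lfp} = a + b\,t_{meg}\) (defaults a = 1.25 s, b = 1+5×10⁻⁵). The
  145 Hz stimulation artefact aliases to 105 Hz at this rate. Optional ECG
  contamination and an oscillation coherent with a simulated cortical
  source support the alignment and coherence-recovery tests.

### Amplitude calibration

Printed sources document artefact *frequencies*, not field amplitudes.
Default amplitudes are therefore calibrated in dB relative to the local
noise floor at the 3 s / Hann analysis resolution (where a tone of amplitude
A produces an ASD peak of ≈ A): telemetry tones +35 dB, combs +35 dB with
their decay laws, communicator comb +24 dB, stimulation fundamental +46 dB
(bipolar) / +55 dB (monopolar), sidelobes +40 dB (20 dB above the
monopolar-lifted floor). The nonlinearity coefficients α = 9×10⁻⁸/fT and
β = 1.2×10⁻¹³/fT² put the quadratic and cubic products 25–40 dB below the
stimulation fundamental, the design window adopted for these invented
scales; β is placed so the cubic family crosses the 6 dB detection
threshold only in monopolar mode, which is what makes the two stimulation
modes distinguishable by their peak sets.

### Numerical choices in the simulator

* The stimulation artefact is synthesised band-limited from the analytic
  Fourier series of the biphasic train (|c_k| ∝ sin²(πk f·pw)/k, ≤ 20
  harmonics): a 60 µs pulse is narrower than one sample at the 5–6 kHz
  profiles, and band-limiting keeps the OPM nonlinearity alias-free.
  Harmonic phases are scrambled deterministically (golden-ratio sequence) —
  dispersion in the signal path does this in practice — which preserves
  every spectral line while removing the pulse-like crest that would
  otherwise trip the jump detector in every segment. The standalone
  `pulse_train()` renders the rectangular train through an oversampled
  anti-alias front end for the same reason.
* The polynomial nonlinearity is evaluated at 3× internal oversampling and
  low-passed back to the native Nyquist before decimation, so cubic
  distortion cannot alias; products below 200 Hz appear exactly at the
  frequencies `predict_intermod()` names.
* Every artefact source draws from its own deterministic sub-stream of the
  root seed, so enabling one source never changes another's realisation;
  conditions differing in one factor are comparable bin by bin.
* Desk scale: the full arrays (275/306/62 channels) at native rates for
  120 s would need gigabytes per condition; `simulate_condition()` defaults
  to an 18-channel evenly spaced subset (2:1 gradiometer:magnetometer ratio
  preserved on the triplet system). Sampling rates are never reduced.

## Spectral analysis

`welch_asd()` uses Hann windows, 50 % overlap, per-segment constant
detrending and window-power correction, so `ASD = sqrt(2σ²/fs)` holds
exactly in expectation for white noise and Parseval holds for tones. The
3 s segment default gives 1/3 Hz resolution. `reject_bad_segments()`
implements the cleaning step needed for cryogenic monopolar data: a segment
is dropped when it contains ≥ 10 identical consecutive samples or any first
difference above 20× the channel's diff-MAD. The thresholds are
configurable; the defaults catch the simulator's jump magnitudes with a
large margin while passing the band-limited stimulation artefact.

`detect_peaks()` takes the median spectrum and reports local maxima at
least 6 dB above a running *lower-quartile* baseline over 5 Hz. A lower
quartile (not the median) is used because in a dense comb the taper
mainlobes occupy about half the bins and drag a median baseline up to the
peak shoulders, hiding the comb. Comb fundamentals are estimated by a grid
search scored by the number of peaks within tolerance of an integer
multiple; ties go to the smallest total deviation, then to the larger
fundamental (otherwise ~1 Hz pseudo-fundamentals explain everything).

## Alignment

Three methods mirror practice: (1) stimulation toggling — a band-limited
envelope around the stimulation frequency (folded below Nyquist for the
LFP, where 145 Hz appears at 105 Hz), 100 ms smoothing, hysteresis
thresholds at the 10/90 envelope percentiles; channels with isolated
extreme first differences (flux jumps) are routed through the
log-|first-difference| transform first, whose smoothed level is bimodal
under toggling. A unimodality gate (fraction of samples mid-range > 0.25)
rejects envelopes that merely fluctuate. (2) tapping — the same transient
machinery on broadband envelopes; only impacts well above the noise floor
are claimed, reflecting its reported unreliability in patients. (3) ECG
cross-correlation with a confidence ratio (main/next peak ≥ 1.2). Event
pairs fit `t_lfp = a + b·t_meg` by least squares; with two events the fit
interpolates exactly. Residual misalignment after the round trip is held
below one LFP sample over 300 s — a package tolerance, not a documented
requirement.

## Coherence mapping

1 s epochs (1 Hz resolution, one Hann taper each) feed magnitude-squared
coherence against the LFP reference. The permutation test builds 10 null
images by permuting the reference's epoch order (identity excluded) and
compares the observed image against them with a two-sample equal-variance
t-statistic per (channel, frequency) cell, Bonferroni-corrected at
α = 0.05 with a cluster-extent threshold (100 cells at full image
resolution, scaled proportionally on toy grids). Because the far Bonferroni
tail of a 1-vs-10 t-test is unusable on skewed coherence values, cells are
first mapped through the exact null quantile transform
`qnorm(1 − (1 − coh)^(L−1))` — under independence the null MSC satisfies
\(P(C > c) = (1-c)^{L-1}\) — which makes the cells near-Gaussian; with this
choice the empirical family-wise error over 100 null simulations stays
within 2× nominal while planted coupling on 5 of 60 channels is recovered.
The exact degrees-of-freedom convention of the original neuroimaging
implementation is not documented; this transform is this package's own,
documented choice.

DICS source images use the analytic single-sphere (Sarvas) forward model on
a 10 mm grid: radial dipoles are silent, so each grid point's lead field is
reduced to its two tangential components by SVD; the band-averaged sensor
CSD is inverted through an eigendecomposition truncated to rank 150
(clamped to the channel count on toy arrays); the scalar orientation is the
dominant eigenvector of the inverted-projected matrix (unit-gain
power-optimal); images are z-scored across the grid. The original analysis
used a template-fitted corrected-sphere model — out of scope here; all
source-space validation is synthetic-truth recovery on the same analytic
model, so a green test establishes internal consistency, not anatomical
accuracy.

## What a green test does and does not establish

The generator reproduces the *spectral fingerprints* of the documented
conditions: peak frequencies, comb fundamentals, intermodulation lines,
floor levels, jump statistics, clock drift. It does not model implant
circuit physics, realistic head/torso conductors, sensor cross-talk,
environmental non-stationarity, or the communicator's link protocol; tone
amplitudes and topographies are calibrated inventions. Consequently, a
passing acceptance suite shows the analysis chain recovers what the
generator encodes at realistic SNR — it does not validate the simulator
against physical recordings (the public phantom dataset can serve that
purpose, but is deliberately not required by any test).

## Known limitations

* Peak detection reports bin centres; off-grid tones (72.5 Hz at 1/3 Hz
  resolution) are reported at the nearest bin.
* The permutation test assumes epochs are exchangeable; autocorrelated
  references inflate its error rate (as in the original design).
* The tapping and ECG alignment paths are validated on synthetic
  transients/templates only.
* `estimate_comb` assumes one dominant comb; mixtures return the better
  scorer.
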