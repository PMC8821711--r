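---
title: "Methods: stereo passive acoustic monitoring of sperm whale clicks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stereo passive acoustic monitoring of sperm whale clicks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stereopam)
```

## The problem

A two-hydrophone (stereo) antenna moored at depth records the ocean for
months at a time. Foraging sperm whales (*Physeter macrocephalus*) emit
loud, regular echolocation clicks, so a long stereo recording carries,
in principle, the number of animals within acoustic range, their body
sizes, and how their presence co-varies with ambient noise. `stereopam`
implements the full chain from raw audio to those quantities:

1. **Detection** — bandpass + Teager–Kaiser energy transient detector
   (high recall, low precision by design);
2. **Tracking** — per-click time-difference-of-arrival (TDoA) between
   the two channels, clustered into per-animal tracks, grouped into
   passages, counted;
3. **Classification** — a small depthwise CNN separating sperm whale
   clicks from other transients, and its recall-versus-SNR curve;
4. **Size** — inter-pulse-interval (IPI) estimation per click train and
   conversion to body length;
5. **Noise** — octave-band levels and a Wenz-curve calibration of the
   acquisition gain;
6. **Density** — a Monte-Carlo effective-detection-area model feeding a
   cue-density estimate;
7. **Statistics** — the nonparametric battery used throughout
   (Shapiro–Wilk, Mann–Whitney, Kruskal–Wallis, Dunn–Bonferroni).

Because the multi-year recordings such surveys analyse are not
distributable, the package ships a **synthetic-scene generator** whose
output carries exact ground truth (click times, TDoAs, IPIs, received
levels, noise levels). Every pipeline stage is tested against that
truth.

## The synthetic world

`render_scene()` builds a 2-channel, 50 kHz pressure time series (units
µPa; WAV output is scaled by a stated full-scale level, default
170 dB re 1 µPa):

* **Clicks** are multipulse transients per the bent-horn anatomy: the
  initial pulse reverberates between two air sacs, producing decaying
  replicas P0, P1, P2, … separated by the IPI. Each pulse is a
  Gaussian-windowed tone burst (default centre 12 kHz, bandwidth 6 kHz,
  1 ms); no waveform model is published for the survey, so this choice
  is ours: it matches the reported click band and the 2 ms RMS
  measurement convention. Default pulse decay is 6 dB per bounce, so P0
  dominates and the envelope still shows 3–5 pulses.
* **Geometry** is straight-ray: channel delays are slant-range
  differences over a 1500 m/s sound speed, with hydrophones 1.83 m
  apart at 25 m depth on a 230° axis. The transmission-loss model used
  everywhere is range-only (spherical spreading + linear absorption),
  so omitting refraction is internally consistent. True TDoA is bounded
  by spacing/c = 1.22 ms.
* **Noise** is Gaussian noise spectrally shaped to an analytic
  approximation of the Wenz ambient-noise curves (turbulence +
  shipping + wind/sea-state + thermal components, the widely used
  analytic fits), driven by a *continuous* sea state obtained by
  monotone (Hyman) spline through the WMO wave-height borders, with
  wave height from wind speed via `h = 0.27 v / g` (`v` in km/h; the
  dimensional oddity of that published rule is applied exactly as
  printed, as an empirical calibration, not "fixed"). Ferry windows
  multiply the noise by a broadband gain — a deliberate idealisation of
  a passing ship.
* **Received level** honours `SL + G − TL(r)` with an isotropic source
  by default; click amplitudes are scaled so the 2 ms RMS around the
  main pulse equals the received level.

What the generator does **not** emulate: surface multipath, Doppler,
codas, click-train interleaving artefacts, sensor self-noise spikes, or
real species variety. A green test therefore establishes that the
algorithms are correct against the stated physics, *not* that field
performance equals the original survey's.

## Stage-by-stage choices

### Detection

The published chain is "bandpass centred at 12.5 kHz, then
Teager–Kaiser". We realise the bandpass as a 4th-order Butterworth
10–15 kHz applied forward–backward (zero phase, so click times do not
shift), and TK as `x[n]² − x[n−1]x[n+1]`. The adaptive threshold
(running median + 8·MAD of the smoothed TK envelope over 2 s blocks),
20 ms refractory, and the 200 ms noise window ending 50 ms before each
click are our parameterisation: the source detector's constants are not
published. SNR conventions follow the survey exactly: click RMS over
2 ms in the 6–15 kHz band against an adjacent noise RMS.

### Tracking

The original track extraction was human-in-the-loop on a TDoA scatter
display. The automatic stand-in is greedy nearest-neighbour chaining in
(time, TDoA) with a 120 s maximum gap, a 0.1 ms/s maximum TDoA drift,
and a 0.1 ms jitter allowance, followed by a minimum-support filter:
≥ 20 points, ≥ 5 min, **and ≥ 0.2 points/s**. The density criterion was
added after testing: with sparse uniform false alarms the drift
allowance integrated over long gaps lets chance chains reach 20 points,
while real foraging click trains run at 0.5–2 clicks/s and pass
easily. Passages split on gaps ≥ 3600 s (a tie at exactly 1 h splits —
the strict "at least 1 h" reading), and the number of individuals in a
passage is the sweep-line maximum of simultaneous tracks. Identity
across passages is deliberately not inferred.

### Classifier

The published network is "3 depth-wise convolution layers of 128
kernels of size 7, log mel-spectrum input, ~10k parameters, binary
cross-entropy with class weights 3 (sperm whale) and 10 (other
cetacean)". Input conventions (unpublished) are ours: 250 ms clips,
64 mel bands, 1024-point FFT, 50% hop. The architecture is an input
pointwise projection (64 mel → 128 channels), three depthwise temporal
convolutions of 128 kernels of size 7, global average pooling, and a
dense sigmoid head: 11,521 parameters. We considered inserting a
pointwise mixing layer after every depthwise layer, but at 128 channels
each such layer alone costs ~16k parameters, tripling the stated
budget; the input projection plus the dense head provide the channel
mixing instead. Log-mel features have the per-clip median removed, so
the classifier is invariant to the absolute recording gain — necessary
because the recall-versus-SNR procedure rescales noise over a huge
dynamic range. Training (Adam, seeded shuffling) is exactly
reproducible for a fixed seed.

The recall curve is measured by remixing clean clicks with ambient
noise at controlled SNRs (same 2 ms / 6–15 kHz conventions; the
*unfiltered* mixture is scored), then fitted with
`L / (1 + exp(−k(snr − x0)))` by least squares; `recall(x0) = L/2` by
construction. The decision threshold for recall is 0.5; the 0.95
confidence level is only used for the day-flagging rule (strictly more
than 40 confidences strictly above 0.95).

### IPI and size

Each click yields two IPI candidates in a 2–10 ms search band: the real
cepstrum peak, and the peak of the envelope of the autocorrelation of
the bandpassed click (pulse replicas are coherent, so the ACF peaks at
the IPI lag while noise contributes only near lag zero). Candidates
whose in-band maximum hugs the band edge are rejected — a smoothly
decaying curve (single-pulse click) otherwise fakes a peak. A click
is kept when the two views agree within 0.5 ms; the track-level
consensus is a 20%-trimmed mean, replacing the original three-human
averaging. Estimation refuses passages with more than two simultaneous
animals, whose interleaved trains cannot be attributed.

Size conversion uses the juvenile-calibrated quadratic
(`4.833 + 1.453·IPI − 0.001·IPI²`) below 4 ms and the adult-calibrated
line (`1.258·IPI + 5.736`) at and above 4 ms. Exactly 4 ms is assigned
to the adult branch (the published strict inequalities leave it
undefined); the branch discontinuity is 0.139 m and the chosen branch is
always reported. Size classes: < 9 m immature, 9–12 m adult female or
juvenile male, ≥ 12 m adult male; boundaries assigned upward, again
because the published inequalities are strict on both sides.

### Noise calibration

Octave levels are measured with zero-phase 6th-order Butterworth octave
filters at the nine standard centres 50–12,800 Hz, on one channel only
(stereo recorders in such surveys commonly have one corrupted channel).
The Wenz prediction uses analytic component formulas rather than a
shipped coefficient table — the published account names no
coefficients, and the classic analytic fits reproduce the curve shapes
the calibration needs; they are versioned in code. The session gain is
`median(predicted − measured)`, robust to the outlier fraction a median
tolerates. The round trip (synthesise at a known sea state and gain,
recover the gain) closes within 1 dB.

### Effective area and density

The sonar chain is exact arithmetic: `SNR = SL + G − TL − NL`,
`TL = 20log₁₀(r) + α·r` (r in m for spreading, km for absorption), with
α from the Francois–Garrison model (1.42 dB/km at 12.5 kHz, 11 °C,
38.5 ppt, 500 m, pH 8 — the survey's stated conditions print 1.43,
inside model-variant tolerance). The Monte-Carlo model spreads
emissions area-uniformly over a 400 km disc, samples depth uniformly on
[0, 1600 m] by default (the alternative log-normal model, mean 2.55
log₁₀ m ≈ 354 m, sd 0.3, resampled above 1600 m since the published
account does not say how the cap interacts with the distribution, gave
equivalent results there and here), and samples orientation uniformly
on the sphere. Detection probability per emission comes from the
sigmoid recall model; then `p = mean`, `a_e = πR²p`,
`r_e = √(a_e/π)`, with a standard error from the mean estimator.
Results are bit-reproducible for a fixed seed, and noise sweeps reuse
common random numbers so the radius–noise curve is smooth.

The source level is configurable (default 200 dB re 1 µPa RMS): the
original survey never states its assumed SL, only that a
relative-amplitude published beam pattern was offset by +161 dB to
match an absolute one. The beam interface is pluggable (isotropic,
circular piston with configurable `ka`, or a user table with constant
offset) precisely because the published patterns are cited, not
reproduced; reproducing the survey's r_e = 32.9 km is therefore not an
acceptance target — property checks (closed-form oracle agreement,
monotonicity in noise, budget symmetry) substitute.

Density reads `D = n/a`, but the printed worked numbers (422 animals,
147 days, 1700 km² → 1.69/1000 km²) only follow when `n` is the
per-day average count; `whale_density()` implements that reading:
`D = (n_animals / n_days) / area × 1000`. (The function is named
`whale_density` rather than `density` to avoid masking
`stats::density`.) NL in the budget is conventionally the 12,800 Hz
octave level, the band at the centre of the click emissions.

### Statistics

Thin wrappers over base R: `shapiro.test`, `wilcox.test` (two groups),
`kruskal.test` (more), with an in-package Dunn post-hoc (joint-rank z
tests with tie correction, Bonferroni-adjusted) run only when the
omnibus test is significant at α = 0.05. Presence probability is
effort-normalised at 1-minute resolution (duty cycles of 5 min on /
15 min off occur in such surveys): per hour-of-day bin, the fraction of
*recorded* minutes intersecting an active passage; zero-effort bins are
missing, not zero. Day periods default to Night 00–06, Morning 06–12,
Afternoon 12–18, Evening 18–24 local — the original analysis never
defines its period bounds, so these are configurable.

## Numerical notes

* Butterworth filters are designed as second-order sections (conjugate
  pole pairing, per-section gain normalised at the warped band centre)
  and applied forward–backward with odd-reflection padding; SOS form
  keeps the 50 Hz octave (normalised edge ~0.0014) stable at order 6.
* Noise synthesis shapes white Gaussian noise in the frequency domain
  by √(PSD·fs/2), so octave levels of the output match the analytic
  model (verified within 1 dB over ≥ 10 s).
* The cepstrum floors |FFT| at 1e−12 before the log; the log-mel floor
  is 1e−6.
* TDoA is the argmax of the FFT cross-correlation restricted to
  physically possible lags (±61 samples at defaults), so gross outliers
  are impossible by construction; sub-sample interpolation is not
  attempted (±1 sample ≈ ±20 µs suffices for tracking).
* All randomness flows through explicit seeds; the Monte-Carlo module
  and the trainer are bit-reproducible.

## Known limitations

* Two sensors give a bearing-cone (TDoA) only: no ranges or 3-D
  positions, hence no per-whale localisation.
* The track clusterer is a stand-in for human scatter-plot annotation;
  crossing tracks with similar TDoA can swap identities.
* Classifier results on synthetic clips do not transfer to real
  recordings without retraining; the original survey's AUC on its own
  data is not reproducible here and is not claimed.
* The Wenz approximation is a deep-water average; site-specific
  spectra (shipping lanes, biological choruses) will calibrate with a
  bias absorbed into the session gain.
* At and above 3 simultaneous animals the IPI module refuses rather
  than risks attributing interleaved trains.
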