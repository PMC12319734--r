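---
title: "Cross-platform MEG fingerprinting: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-platform MEG fingerprinting: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

Optically pumped magnetometer (OPM) MEG systems are replacing cryogenic
SQUID systems, and the field needs ways to show that the two architectures
capture the *same* information about brain function. Group-average
"primary" responses (evoked fields, beta-band desynchronisation and
rebound) are stable across people, so matching them across platforms says
little about the subtler, subject-specific structure in the data. Neural
fingerprinting inverts the question: if an individual can be identified
from a group by correlating their recording on one platform with their
recording on the other, the two instruments must be capturing the same
between-subject variance.

`megfingerprint` implements that analysis end to end on synthetic data: a
somatosensory attention-switching paradigm, two simulated sensor arrays (a
64-site triaxial OPM helmet, 192 channels at 375 Hz with a 15 fT/&radic;Hz
noise floor; a 275-channel SQUID axial-gradiometer array with 29 reference
channels at 600 Hz with a 5 fT/&radic;Hz floor), source simulation with
subject-stable response signatures, preprocessing, beamformer and
minimum-norm imaging, Hilbert-envelope spectral dynamics, and the
fingerprinting statistics.

# The paradigm

Each trial starts at the end of an auditory cue ("attend left"/"attend
right"). Five braille pins patterns are presented bilaterally, the first at
1.17 s, then every 1.37 s, each lasting 0.37 s, followed by 7 s of rest.
Targets occupy exactly 20% of stimulus slots — sampled without
replacement, so the default 80-trial experiment has exactly 80 targets and
320 non-targets. Cue sides are balanced 40/40 in seeded random order; the
balance is our choice (it keeps the attentional contrast symmetric), as is
treating the cue as a 2 s segment preceding trial start. Trials are
concatenated end to end with t = 0 (cue end) at trial start, so the trial
duration is the last stimulus offset plus the rest period, 14.02 s.

# Forward model

The conductor is a homogeneous sphere (radius 0.09 m), for which the
external field of a current dipole has the Sarvas closed form. This keeps
the key property of the realistic single-shell models used on real
anatomy — radial dipole moments are externally silent — while remaining
analytic and fast. Sensor sites are Fibonacci lattices on helmet spheres
(OPM stand-off 6.5 mm; SQUID inner coil 20 mm, outer coil 5 cm further
out; both configurable — the stand-offs are our defaults, not measured
values). Reference sensors sit on a shell 0.4 m above the helmet, which is
sufficient for regression-based gradiometry. The source space is a cubic
grid (5 mm by default) strictly inside an 0.08 m sphere, offset by half a
voxel so no point falls on the degenerate sphere centre.

# The synthetic cohort

Each subject carries left and right primary-sensory sources whose
parameters are drawn once and reused for all four sessions (2 platforms x
2 runs):

* source positions (≈ ±3.5 cm lateral, jitter s.d. 9 mm per axis) and a
  Gaussian patch extent σ of 6–14 mm;
* a beta-band carrier — Gaussian noise filtered to the subject's peak
  frequency (16–28 Hz) with a subject-specific bandwidth (2.5–5.5 Hz; the
  "spectral content" fingerprint dimension) — at 5–12 nAm RMS baseline
  amplitude;
* an envelope that drops by the ERD depth (0.3–0.7) during each stimulus
  (0.05–0.55 s post-onset) and rebounds above baseline afterwards
  (Gaussian bump at 0.85 s, σ = 0.12 s) with per-stimulus amplitudes
  0.2–0.8 allowed a monotone trend across the five stimuli (some subjects
  rebound harder to later stimuli — a real phenomenon that makes a good
  fingerprint dimension);
* a deterministic evoked transient (difference of Gaussians; latency
  35–65 ms, width ≈ 20 ms, 15–35 nAm, with a smaller response at stimulus
  offset) shared between hemispheres, because bilateral simultaneous
  stimulation drives correlated evoked responses — which is exactly why
  the evoked pathway uses a minimum-norm inverse rather than a beamformer;
* a tonic attentional suppression (12–28%) of the beta envelope in the
  hemisphere contralateral to the cued hand, from −0.8 s to 1 s around cue
  end.

Run-to-run variation is multiplicative jitter (s.d. 5% by default) on the
amplitude-like parameters plus fresh carrier and sensor noise. The
between-subject spreads are not reported quantities anywhere; they are
package defaults chosen once so that identifiability is a controllable
property: scaling the spreads to zero (`betweenScale = 0`) makes subjects
statistically identical and drops identification to chance, and shrinking
run jitter drives it towards 100%. Passing tests on this cohort therefore
demonstrate that the *analysis* recovers planted structure — not that real
brains behave like the generator. Real data add 1/f noise, line
interference, artefacts, head-geometry differences and non-stationarity
that the generator deliberately omits (white sensor noise is the default;
uniform-field interference and reference-correlated drift are available
behind flags for testing the corrections that remove them).

# Preprocessing

The order is fixed: channel screening → interference suppression →
filtering → epoching → trial rejection.

* *Screening* (OPM): Welch amplitude spectral density (2 s Hann segments,
  50% overlap — our choice, giving sub-hertz resolution), channels with a
  60–80 Hz floor below 5 or above 20 fT/&radic;Hz removed. The upper cut
  is automated at exactly 20 (determinism preferred over operator
  judgement). SQUID screening is operator-driven in practice; the same
  automated rule is available behind a flag.
* *HFC* (OPM): least-squares projection of each time sample onto the
  3-column basis of channel orientations is subtracted — an orthogonal,
  idempotent projector that removes any spatially uniform interference at
  the cost of three spatial degrees of freedom.
* *Gradiometry* (SQUID): each scalp channel is regressed on the 29
  reference channels over the full record and the fit subtracted. This is
  a zeroth-order stand-in for synthetic third-order gradiometry, whose
  vendor balancing coefficients are proprietary; the property that matters
  here (suppression of reference-correlated interference) is preserved.
* *Filtering*: zero-phase Hamming-window FIR; length = 6.6 / (shortest
  transition band), transition widths min(max(edge/4, 2 Hz), edge), −6 dB
  cutoffs half a transition band outside the passband. Bands: 1–100 Hz
  (broadband), 13–30 Hz (beta), 5–40 Hz (evoked).
* *Rejection*: any 0–1.2 s stimulus epoch in which any channel exceeds
  4 pT peak-to-peak is dropped (automated for OPM; flag for SQUID, where
  the practice is visual inspection). Rejection runs after HFC on
  band-filtered data.

# Source reconstruction

**LCMV beamformer.** The data covariance is the average of an "early"
(0.2–0.5 s, desynchronisation) and "late" (0.75–1.05 s, rebound) window
covariance, regularised by adding 5% of its maximum singular value to the
diagonal. Per voxel the orientation maximising projected power is the
minimiser of l&prime;C⁻¹l over the three cardinal gains — with the
near-null (radial, magnetically silent) eigenvector excluded, the one
numerical trap of spherical conductors; ties are broken by fixing the sign
of the dominant component. Weights w = C⁻¹l / (l&prime;C⁻¹l) satisfy unit
gain. The beta image is the normalised contrast
(P_late − P_early)/(P_late + P_early): the field names this a pseudo-T
without a canonical formula, and the symmetric normalisation keeps images
on a common [−1, 1] scale across platforms and SNRs, which matters when
images from different instruments are correlated. Both window definitions
and the regularisation fraction are config keys.

**Minimum norm.** For the (correlated) evoked responses,
J = L&prime;(LL&prime; + λ² tr(LL&prime;)/N · I)⁻¹ m with λ² = 1/9 (the
SNR = 3 convention), identity noise covariance and no depth weighting —
all three unspecified by common practice and logged as our defaults. The
per-voxel power is the quadrature sum over the three orientations, and the
image is taken at each dataset's own evoked-peak time, since that timing
differs across subjects.

**Virtual electrodes** project channel data through one voxel's weights:
broadband-covariance weights for the time–frequency spectrum, beta-band
weights for beta envelopes. Peak locations are the per-hemisphere argmax
of the pseudo-T image (hemispheres split on the x coordinate of the shared
grid; all synthetic subjects share one source space, so no template
morphing is needed). A 1.5 cm midline strip is excluded from the peak
search: leakage between the correlated bilateral sources concentrates
near the interhemispheric plane and can produce spurious deep maxima
there.

# Spectral dynamics

The broadband virtual electrode is filtered into overlapping 1 Hz bands
(centres every 0.5 Hz, 1.5–99.5 Hz), Hilbert envelopes are epoched into
full 14.02 s trials and averaged (envelope averaging precedes baseline
division), and R(t, f) = (A(t, f) − B(f))/B(f) with B the mean over the
12–13.5 s rest window. Numerical choices: 0.5 s reflection padding before
filtering; band edges are raised-cosine in the frequency domain; a 1 Hz
analysis bandwidth implies roughly one second of temporal smoothing per
band (the bandwidth–time tradeoff), so a 0.5 s desynchronisation appears
shallower in the TFS than at source — sustained envelope changes are
recovered at full depth.

# Fingerprinting statistics

A dataset's features are its pseudo-T image and its TFSs at the left- and
right-hemisphere beta peaks, stacked along the frequency axis (each
dataset uses its own peaks; a flag can fix the voxel per subject). Similarity is the mean of the two Pearson
correlations, with profiles resampled onto a shared 1 ms grid when
platforms' sampling rates differ. Within-platform matrices compare run 1
of subject i against run 2 of subject j only (one independent comparison
per cell); the cross-platform matrix averages the four OPM-run x SQUID-run
comparisons. Identification is the row-maximum-on-diagonal rule, with ties
counted as misses (conservative and deterministic). The diagonal
permutation test relabels the second-dataset axis only — one-axis
relabelling preserves the within-dataset correlation structure — and uses
the +1-corrected empirical p, one-tailed, with 100,000 permutations by
default. The sham-mixing group null pools the 15 + 15 subject-average
timecourses and splits them randomly (a subject's two traces may share a
group), 10,000 times, with a two-tailed percentile. The evoked feature
set (evoked image + quadrature power timecourse) is available as a
variant. The chance-identifiability model simulates i.i.d. Gaussian
similarity matrices; because row maxima are then independent with hit
probability 1/N, the count of identified subjects is Binomial(N, 1/N),
which the Monte-Carlo estimate is checked against.

The attentional contrast averages, per subject and hemisphere, the beta
envelope difference (attend-left − attend-right) over −0.8..1 s around cue
end, and compares hemispheres with a paired two-sided Wilcoxon signed-rank
test (sidedness is our choice; complete cases only).

# Problem sizes

The default configuration is the full-scale experiment (80 trials, 5 mm
grid, 0.5 Hz TFS band step, 15 subjects x 2 platforms x 2 runs). The test
suite exercises the full pipeline at desk scale: 8 trials per run, a 16 mm
grid and 3 Hz-wide bands every 3 Hz for the identifiability checks, and a
4-trial, 25 mm variant for the zero-variance (chance) control;
single-dipole localisation checks use the full 5 mm spacing on a
restricted 5 cm sphere.
These sizes are the package's choices for quick, deterministic runs;
identification margins only improve with more trials and finer grids.

# Known limitations

* The spherical conductor and shared source grid ignore individual
  anatomy, coregistration error and MNI morphing — all real-data concerns
  that cross-platform fingerprinting is partly designed to expose.
* White sensor noise flatters both platforms; realistic low-frequency
  interference would stress HFC and gradiometry harder than the synthetic
  flags do.
* Reference-array gradiometry is zeroth order; vendor third-order
  balancing is not reproduced.
* The evoked generative model is a stylised biphasic pulse; evoked-feature
  fingerprinting on synthetic data is therefore easier than on real data,
  and no claim is made that its identification rates mirror empirical
  ones.
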