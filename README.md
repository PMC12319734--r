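# megfingerprint

Cross-platform MEG equivalence analysis via neural fingerprinting, on
synthetic data.

## The problem

Wearable optically-pumped magnetometer (OPM) MEG is a candidate
replacement for cryogenic SQUID MEG, which raises a validation question:
do the two architectures capture the *same* information about brain
function? Group-average responses (evoked fields, beta-band
desynchronisation/rebound) are stable across people, so matching them
across platforms says nothing about the subtler subject-specific
structure. Neural fingerprinting asks the sharper question: can an
individual be identified from a group by correlating their recording on
one platform with their recording on the other? If yes, the platforms
agree on between-subject variance too.

`megfingerprint` is a simulation + analysis package for that question,
aimed at methodologists who want a fully controlled testbed. It provides:

* a braille somatosensory attention paradigm (80 trials, 5 stimuli each,
  target probability 0.2);
* two simulated arrays — 64 triaxial OPM sensors (192 channels, 375 Hz,
  15 fT/√Hz) and a 275-channel SQUID axial-gradiometer system with 29
  references (600 Hz, 5 fT/√Hz) — with a Sarvas spherical-conductor
  forward model;
* a synthetic cohort whose subjects carry stable "fingerprint" parameters
  (source positions and extent, beta peak frequency, ERD depth, rebound
  profile, evoked latency, attentional modulation);
* preprocessing: Welch channel screening (5–20 fT/√Hz bounds in 60–80 Hz),
  homogeneous field correction, reference gradiometry, zero-phase FIR
  filters, 4 pT peak-to-peak trial rejection;
* source analysis: LCMV beamformer with 5% singular-value regularisation
  and early (0.2–0.5 s) vs late (0.75–1.05 s) pseudo-T contrast
  `(P_late − P_early)/(P_late + P_early)`, minimum-norm evoked imaging,
  virtual electrodes;
* spectral dynamics: Hilbert-envelope time–frequency spectra
  `R(t,f) = (A(t,f) − B(f))/B(f)` with a 12–13.5 s rest baseline, beta
  envelope timecourses;
* fingerprinting statistics: within-OPM / within-SQUID / cross-platform
  identifiability matrices (element `[i,j]` = mean of the pseudo-T-image
  and TFS correlations between subject *i*'s and subject *j*'s datasets),
  row-maximum identification, diagonal-vs-off-diagonal permutation tests
  (100,000 relabellings), a sham-mixing group-timecourse null (10,000
  splits), an attentional Wilcoxon contrast, and the chance-identifiability
  model: for an information-free N×N similarity matrix the number of
  correctly identified subjects is Binomial(N, 1/N).

## Worked example

```r
library(megfingerprint)

## chance identifiability for a 15-subject cohort
chance <- chanceIdentifiability(nSubjects = 15, nSim = 100000, seed = 1)
round(chance$pmf[1:5], 3)
#> [1] 0.355 0.382 0.189 0.060 0.013
round(chance$binomial[1:5], 3)
#> [1] 0.355 0.381 0.190 0.059 0.013
```

If fingerprint matrices carried no subject information, identifying 0 or 1
of 15 subjects would be the norm (probabilities ≈ 0.35 and 0.38); even 4
identifications would have probability ≈ 0.013 — so high observed
identification counts are very unlikely by chance.

```r
## a small end-to-end synthetic run (3 subjects, desk scale)
cfg <- runConfig(nSubjects = 3, nTrials = 6, gridSpacing = 0.016,
                 tfsFreqs = seq(2, 98, 2), featureSets = "beta")
res <- runPipeline(cfg)
res$identification$beta
#>     within_opm   within_squid cross_platform
#>              3              3              3
res$matrices$beta$cross_platform
#> FingerprintMatrix [cross_platform, beta features]: 3 x 3, 3/3 identified
```

Each matrix cell is an averaged correlation between one subject's datasets
on the two axes; identification succeeds for a row when its largest value
sits on the diagonal. `res$permTests` holds the permutation nulls for the
diagonal−off-diagonal statistic, `res$groupNull` the sham-mixing null for
the group-average beta envelope correlation between platforms, and
`res$attention` the per-platform attentional contrasts.

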