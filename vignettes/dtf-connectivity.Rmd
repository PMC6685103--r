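---
title: "Directed transfer function connectivity and global brain connectivity: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Directed transfer function connectivity and global brain connectivity: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dtfnet)
```

## The problem this package addresses

Resting EEG and resting-state fMRI are the two workhorse modalities for
characterising brain networks in patients who cannot perform tasks, such as
patients with disorders of consciousness. `dtfnet` implements a complete,
testable version of a widely used analysis pair:

* **EEG effective connectivity** via the directed transfer function (DTF)
  computed from a multivariate autoregressive (MVAR) model, with
  surrogate-data significance pruning and electrode-wise group comparison;
* **fMRI global brain connectivity (GBC)**: the mean correlation of each
  voxel with every other voxel inside a network mask (e.g. default mode or
  executive control network).

Because clinical recordings of this kind are rarely shareable, the package
ships first-class synthetic-data generators with known ground truth; every
stage is validated end to end against closed forms or simulation oracles.

## The MVAR/DTF model

A multichannel recording \(X(t) \in \mathbb{R}^N\) is modelled as

\[
X(t) = \sum_{n=1}^{p} A_n X(t-n) + E(t),
\]

with \(E(t)\) zero-mean white noise and \(A_n\) the \(N \times N\) lag
coefficient matrices.  In the frequency domain, with
\(A(f) = \sum_{n=0}^{p} A_n e^{-j 2 \pi f n \Delta t}\) and \(A_0 = -I\),
the transfer matrix is \(H(f) = A(f)^{-1}\), and the DTF is the
row-normalised squared transfer magnitude

\[
\gamma_{ij}^2(f) = \frac{|H_{ij}(f)|^2}{\sum_{m=1}^{N} |H_{im}(f)|^2},
\]

the share of inflow to channel \(i\) contributed by channel \(j\) at
frequency \(f\).  Rows of \(\gamma^2\) sum to one at every frequency by
construction; this invariant is asserted to \(10^{-10}\) in the test suite.
The overall sign convention of \(A(f)\) cancels after squaring.

A worked closed form used throughout the tests: for the two-channel system
with the single edge \(1 \to 2\), coupling 0.5, \(\det A(f) = 1\) and the
adjugate gives \(|H_{21}|^2 = 0.25\), \(|H_{22}|^2 = 1\), hence
\(\gamma^2_{21} = 0.2\) and \(\gamma^2_{12} = 0\) at *every* frequency:

```{r}
A1 <- matrix(0, 2, 2); A1[2, 1] <- 0.5
d <- dtf(A1, fs = 128)
range(d$gamma2[2, 1, ])
```

### Estimation and order selection

Coefficients are estimated by ordinary least squares on the lagged
regression (QR factorisation), channels demeaned first; with epoched data
the normal equations are pooled across epochs and no lag window crosses an
epoch boundary.  The residual covariance uses the small-sample divisor
\(n_e - Np - 1\).  The model order is selected by minimising Schwarz's
Bayesian Criterion (SBC; default) or the log final prediction error (FPE)
over a configurable range, both in their standard ARfit approximations
(documented in `select_order()`); all candidate orders are scored on the
same regression rows so the criteria are comparable.  The default search
range is \([1, 20]\).  Whether one should fit one model per epoch and
average DTF, or pool epochs into one fit, is a genuinely open choice;
pooling is the default here (it uses the data most efficiently and keeps a
single well-conditioned fit), and per-epoch fits remain available — the
pipeline uses them to give a single subject replicate-level electrode
values.

### Band summary and `dtf_mean`

DTF is evaluated on a 1–45 Hz grid in 0.5-Hz steps by default and averaged
over a named band; the gamma band is defined here as 30–45 Hz, keeping its
upper edge below the 49–51 Hz notch.  Both the grid and the band edges are
configuration items recorded in every report.  The scalar summary
`dtf_mean` averages the *off-diagonal* band means: each row of \(\gamma^2\)
is dominated by the self-inflow term \(\gamma^2_{ii}\), which would swamp a
summary meant to measure interactions.  A flag restores the
diagonal-inclusive average for users who want the literal mean of all
matrix elements.

## Preprocessing

Conditioning applies zero-phase (forward–backward) Butterworth filters — an
order-4 low-pass at 100 Hz and an order-2 band-stop at 49–51 Hz — followed
by removal of a per-channel least-squares polynomial baseline (order 3 by
default).  Zero-phase filtering is used because group delay would distort
the lagged regression that the MVAR stage runs on.  Two practical notes:

* a zero-phase narrow notch has a long impulse response, so a finite
  recording keeps an edge transient of roughly a second at each end even
  though steady-state attenuation at the notch centre is below −70 dB;
* conditioning is close to idempotent in the passband (the tests bound the
  in-band power change of a second pass below 1%).

Artifact handling is a deliberate simplification: epochs (2-s,
non-overlapping by default) containing any sample beyond ±100 µV are
dropped whole and logged.  This is a transparent stand-in for dedicated
artifact-removal toolboxes, which are out of scope; the validation studies
in this package use clean synthetic data, so the amplitude screen exists to
make the pipeline honest about real data, not to compete with ICA-based
cleaning.

Per-channel SNR is the variance ratio
\(\mathrm{SNR}_i = \sigma^2_{\mathrm{signal}(i)} / \sigma^2_{\mathrm{noise}(i)}\),
with the noise standard deviation estimated from a designated quiet
interval.  For resting data no event-locked "pre" interval exists, so the
default noise interval is the first second of the recording and is
configurable — this is a declared convention, not a claim about what any
particular laboratory did.  A working range of 7–10 can be checked with
`snr_gate()`; the gate reports rather than drops.

## Surrogate-data significance testing

The null hypothesis of no connectivity is materialised by destroying
cross-channel temporal alignment: each channel's samples are independently
randomly permuted (within epochs, so surrogates keep the epoch structure of
the observed data), the MVAR is refit at the *fixed* observed order, and
the band-mean DTF recorded, 1000 times by default.  Permutation preserves
each channel's amplitude distribution while removing temporal structure.
The order is held fixed because re-selecting it per surrogate would mix
order-selection variability into the null.  Each directed link is tested
against its own null distribution (link-level decisions, no pooling), kept
when the observed band-mean exceeds the empirical \(1-\alpha\) quantile
(\(\alpha = 0.05\) by default), with add-one p-values
\(p = (1 + \#\{\mathrm{null} \ge \mathrm{obs}\})/(1 + n_{\mathrm{shuffles}})\)
that can never be exactly zero.  No multiple-comparison correction is
applied by default, matching common practice for this procedure; a
Benjamini–Hochberg flag is available.

Calibration is measured, not assumed: across 200 independent white-noise
datasets the per-link rejection rate at \(\alpha = 0.05\) must land in
\([0.03, 0.07]\), and on a strongly coupled pair (coupling 0.5,
\(n = 20{,}000\)) the true direction must be detected while the reverse
stays at the false-positive level.

## Electrode profiles and group comparison

The per-electrode scalar plotted in topographic DTF maps is not uniquely
defined; the package implements three reductions of the pruned band-mean
matrix — mean significant inflow (off-diagonal row mean), mean outflow
(column mean), and their average (`total`, the default) — and logs the
choice in every report.  For a single subject compared against a control
group, the subject's replicates are its per-epoch profiles (epochs are the
only within-subject replicates available); to keep both sides on the same
estimator scale, each control subject's value is likewise the mean of its
per-epoch profiles.  Electrode-wise comparison uses a two-sample t-test
when both sides pass Shapiro–Wilk normality at 0.05 and Wilcoxon's rank-sum
test otherwise (`auto`), with a conventional strong-evidence selection
threshold of \(p < 0.001\) by default and \(\alpha\) exposed as a parameter.

## Synthetic data: what it emulates and what it does not

`simulate_mvar()` draws from a ground-truth `mvar_network` (stability
enforced via the companion-matrix spectral radius) with Gaussian i.i.d.
innovations — Gaussian so that closed-form Yule–Walker checks apply — and
discards a 1000-sample burn-in to erase initial-condition transients, since
the model defines the stationary process, not its start-up.  The
patient-vs-controls study (`replica_study()`) builds a 32-channel control-like
network of two coupling modules (anterior and posterior electrode groups,
neighbour-ring couplings, AR(1) self terms), jitters coupling strengths by
±15% per control subject to model between-subject variability, and creates
the "patient" by attenuating all couplings of the 15 posterior electrodes
to 15%.  Keeping the two modules disconnected gives unambiguous ground
truth about which electrodes a posterior lesion may affect.  Study-scale
defaults — 8 controls, 32 s of signal at 256 Hz per subject, 2-s epochs,
order search over \([1, 3]\), 200 shuffles — are the package's validation
conditions, chosen to exercise every stage at realistic dimensionality.

None of this emulates rhythms, 1/f spectra, eye or muscle artifacts, or
volume conduction; passing the synthetic studies demonstrates correctness
of the estimators and the decision machinery, not robustness to real-world
artifact structure.  The sampling rate and montage reference of a real
study are free parameters of the simulator.

`simulate_fmri_blocks()` builds voxel time series as community-shared
latent factors plus voxel noise, mixed to hit target within- and
between-community correlations (a single global factor induces the
cross-community correlation; factors are orthonormalised in sample so the
realised factor correlations are exact).  For two equal communities of
size \(k\) with within-correlation \(w\) and between-correlation \(b\),
every voxel's expected GBC is \((w(k-1) + bk)/(2k-1)\) — the closed form
the acceptance checks use.

## GBC numerical choices

GBC is computed on linearly detrended voxel time series with plain Pearson
correlation, and correlations are averaged *raw* (not Fisher-z), following
the plain reading of "correlations, then averaged"; a Fisher-z flag is
provided.  Constant (zero-variance) voxels get a missing value, are logged,
and are excluded from other voxels' averages.  Network masks are inputs;
deriving them from an atlas, and fMRI preprocessing beyond detrending, are
out of scope.  Pre/post comparison of GBC maps is deliberately descriptive
(difference maps and region means, no inferential statistic).

## Determinism and provenance

Every stochastic step takes an explicit integer seed; the pipeline expands
one global seed into per-stage seeds deterministically, and a repeated run
with the same configuration reproduces every output file byte for byte.
Each results directory carries a manifest (package version, seed, config
hash) sufficient to reproduce it.

## Known limitations

* DTF variants (partial directed coherence, direct DTF, full-frequency DTF)
  are not implemented.
* The surrogate scheme is sample permutation only; phase-randomisation
  surrogates, which preserve per-channel spectra, are not provided.
* The amplitude screen is no substitute for ocular/muscle artifact removal
  on real recordings.
* EDF support covers continuous uniform-rate recordings (the layout the
  package writes); discontinuous EDF+ files are not parsed.
* MVAR estimation assumes within-epoch stationarity; strongly
  non-stationary data violate the model.
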