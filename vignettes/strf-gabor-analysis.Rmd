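---
title: "Quantifying auditory receptive fields with Gabor matching pursuit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying auditory receptive fields with Gabor matching pursuit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

A spectro-temporal receptive field (STRF) is the linear kernel that best maps
the recent time–frequency history of a sound to an auditory neuron's
instantaneous firing tendency. STRFs estimated from single-unit recordings
are noisy 2D patches; a long-standing observation is that they resemble
Gabor functions — sinusoidal carriers under smooth envelopes — parameterized
by a temporal modulation rate (Hz) and a spectral modulation rate
(cycles/Bark). `strfgabor` implements a complete quantitative chain around
this idea:

1. a Bark-scaled spectrogram front-end (`bark_spectrogram`),
2. ridge-regularized reverse correlation for STRF estimation
   (`estimate_strf` and its parts),
3. a complex Gabor dictionary (`build_gabor_bank`) and greedy 2D matching
   pursuit (`mp_decompose`) that rewrites an STRF as a sparse weighted sum
   of Gabor atoms,
4. summary statistics over decompositions: the diagonality index kappa and
   the atom importance eta,
5. a linear–nonlinear–Poisson (LNP) simulator (`lnp_respond`,
   `recovery_experiment`) that validates the estimator end-to-end against
   known ground-truth filters, and
6. a spectro-temporal feature front-end for sound classification
   (`filter_features`, `mfcc_features`, `classify_events`).

# The periphery

Audio at 16 kHz is analyzed with 4 ms periodic-Hann windows hopped by 2 ms,
zero-padded to a 128-point DFT. Short-time *power* spectra are summed into
Bark bands by trapezoid weights — unit plateau of half a bandwidth, linear
flanks reaching zero at 3/4 bandwidth, so channels spaced one bandwidth
apart cross at half height — and the band power is compressed as
`power^(1/3)`. Consequences worth knowing:

* The Hz-to-Bark map is the Zwicker–Terhardt closed form
  `13 atan(0.00076 f) + 3.5 atan((f/7500)^2)`. It anchors 0 Hz at 0 Bark,
  is strictly increasing, and places 8 kHz at about 21.27 Bark, so exactly
  21 one-Bark channels (centers 0.5 … 20.5 Bark) cover the band.
* Compression acts on summed power, not magnitude. Doubling the waveform
  amplitude therefore scales every output by `2^(2/3)`. Whether
  compression should precede or follow band summation, and whether it acts
  on magnitude or power, is a convention; this one keeps the band values
  interpretable as compressed band energies.
* Channel count and the 2 ms frame period are functions of the
  configuration only, never of signal content.

# The Gabor dictionary

An atom is the separable product of complex exponential carriers and Hann
envelopes along both axes,

$$ g(t,f) = e^{2\pi i\,\omega_t t}\, e^{2\pi i\,\omega_s f}\,
   h_{b_t}(t)\, h_{b_s}(f), \qquad
   h_b(x) = \tfrac12 + \tfrac12\cos(2\pi x/b)\ \text{ for } |x|<b/2 . $$

The center-peaked envelope is the standard Hann usage; the edge-peaked
variant (maximal at the support boundary, zero mid-patch) would not act as
a window at all, so the center-peaked form is adopted deliberately.

The bank covers temporal modulations 0–125 Hz and spectral modulations
0–0.25 cyc/Bark — each exactly half the Nyquist rate of the 2 ms / 1 Bark
grid, which the constructor asserts for any configuration. The modulation
grid is geometric (octave spacing by default), descending from the maxima;
envelope widths follow a constant-Q rule (one carrier period within the
half-height width, `b = 2/omega`) until capped by the 21-band x 100 ms
patch, and the capped entry terminates the descent. Purely temporal,
purely spectral, DC (envelope-only) atoms, and both diagonal orientations
of every mixed atom are always present — 32 complex atoms at the defaults.

For dictionary use, the real and imaginary parts of each complex atom
become separate real atoms. Each is made zero-sum *within its envelope
support* (so a DC offset in the target cannot dominate selection, while
the atom stays exactly zero outside its support) and is normalized to unit
Euclidean norm.

# STRF estimation

With stimulus windows $s_n \in \mathbb{R}^D$ (100 ms x 21 channels,
$D = 1050$, column-centered) and binned responses $r_n$, the estimator
solves

$$ \left( \tfrac1N S^\top S + \lambda I \right) h = \tfrac1N S^\top r . $$

$\lambda = 0$ is the whitened (pseudo-inverse) solution; large $\lambda$
shrinks toward the plain spike-triggered average direction. The ridge norm
is non-increasing in $\lambda$, and both limits are covered by tests. When
fewer samples than dimensions are available the dual (kernel) form is used
automatically.

**Penalty selection.** 5-fold cross-validation over a logarithmic grid
($10^{-4}\ldots10^{4}$ times the mean Gram diagonal) maximizing held-out
Pearson correlation between $s\cdot h$ and $r$; exact ties break toward
the larger penalty. Folds are *contiguous blocks*: adjacent stimulus
windows overlap by 49 of 50 frames, and random fold assignment would leak
nearly identical samples between train and test.

**Significance masking.** 20% of the response bins are drawn without
replacement, the ridge estimate recomputed, and this is repeated 1000
times. A per-coefficient two-sided z-test of the subsample mean against
zero (level 0.05) decides which coefficients survive; the rest are set to
exactly zero. One correction is essential: the spread of estimates over
20% subsamples overstates the sampling deviation of the full-sample
estimate by the factor $\sqrt{(1-f)/f}$ ($f = 0.2$), so the test divides
it out. Without this, the test is so conservative that essentially nothing
is ever rejected under the null; with it, the null keep-rate is
approximately the nominal 5% (the calibration is exact in the
strong-shrinkage regime, which is also where penalty selection lands under
the null because of the larger-penalty tie-break). No multiple-testing
correction is applied across the 1050 coefficients — a deliberate
reproduction of the per-coefficient rule, not a statistical endorsement.

Isolated non-zero pixels whose existing 8-neighbors are all zero are then
removed in a single idempotent pass, and an STRF is flagged as included
only if its cross-validated prediction correlation reaches 0.25.

# Matching pursuit, kappa and eta

The dictionary is expanded over temporal shifts: each real atom is
translated to every position at which its envelope support still fits
inside the 21 x 50 patch. Restricting shifts this way (rather than
clipping and renormalizing partial atoms) keeps every dictionary element
an exact unit-norm translate, so matching pursuit's energy identity
$\|res_{i}\|^2 = \|target\|^2 - \sum_{j\le i}\gamma_j^2$ and the
orthogonality of the updated residual to the selected atom hold to
machine precision. Spectral shifts are off by default (atoms span the full
21 bands, as for MP on 21-band STRFs) but available.

Each iteration selects the shifted atom with the largest absolute inner
product $\gamma$ with the residual, subtracts $\gamma \times$ atom, and
stops once the Pearson correlation between target and reconstruction
reaches the threshold $\theta$ (default 0.8; `max_iter` 50, with failure
to reach $\theta$ flagged, never silent). Signed weights are kept;
importance uses their absolute values. A subtlety: the *residual norm*
decreases exactly monotonically, and on white random targets the
correlation track is monotone too, but on strongly structured targets the
Pearson correlation can dip by up to a few parts in $10^4$ between
iterations because it renormalizes by the reconstruction norm. The
package reports the full track rather than enforcing monotonicity.

The diagonality of an atom is the L1 norm of its L2-normalized modulation
vector,
$\kappa_\omega = (|\omega_t| + |\omega_s|)/\sqrt{\omega_t^2+\omega_s^2}$,
computed on modulations normalized to cycles per sample
($\omega_t \cdot 2\,\mathrm{ms}$, $\omega_s \cdot 1\,\mathrm{Bark}$) so
the axes are commensurate; a decomposition's kappa is the mean over its
entries. The attainable range for a 2-vector is $[1, \sqrt 2]$ — purely
temporal or spectral atoms give exactly 1, exact diagonals $\sqrt 2$ —
and the package does not rescale this to any other range. The DC atom has
no orientation; it is assigned kappa 1 by documented policy. Atom
importance is $\eta_j = \sum_i \sum_k |\gamma_{ijk}|$ over all iterations
and all decomposed STRFs; `kappa_vs_theta` exploits the prefix property
of greedy MP (a lower-threshold run is a prefix of a higher-threshold
run) to trace kappa over a threshold grid with one decomposition per
target.

# The LNP simulator

Ground-truth neurons are Gabor filters followed by a static nonlinearity
and Poisson spike generation. The default nonlinearity is rectified
linear with threshold at the median drive and gain solved so the mean
rate equals the target (20 spikes/s by default); an exponential variant
is available, and `gain = 0` yields a drive-independent control neuron.
Counts are drawn per 2 ms bin, independently per repetition (10 by
default), and everything is a pure function of (config, seed).

The probe stimulus emulates an *ensemble* of ripple presentations: the
spectrogram is generated in 1 s segments, each a fresh superposition of
30 ripples $a\cos(2\pi(\omega_t t + \omega_s f) + \phi)$ with modulation
frequencies drawn uniformly within the configured bounds. A single
superposition held for the whole recording would span only a
low-dimensional stimulus subspace and leave most of the 1050 filter
coefficients unidentifiable; redrawing per segment matches how such
experiments actually present many distinct short stimuli. Component
amplitudes are tapered as
$(1+\omega_t/\omega_t^{max})^{-1}(1+|\omega_s|/\omega_s^{max})^{-2}$:
a low-pass bias in both axes with a deliberately steeper spectral decay,
encoding the anisotropy of conspecific-song modulation spectra (song
carries temporal modulation energy out to fast rates but is spectrally
smooth). This anisotropy is what makes purely spectral filters recover
with visibly lower fidelity than purely temporal ones in
`recovery_experiment` — the simulator's analog of re-estimating the
filter bank through the LNP chain; under a symmetric taper the two
categories recover identically. `recovery_experiment` shares one stimulus
ensemble, its fold Gram matrices and eigendecompositions across all
neurons, so per-neuron cost is a few cross-products.

What the generator does *not* emulate: harmonic structure, syllable
rhythm, amplitude statistics of real song, or any adaptation and
plasticity in the neuron. Passing recovery tests therefore demonstrates
estimator correctness under the stated stimulus statistics, not
performance on physiological recordings.

# Features and classification

2D filtering slides each filter across all 21 channels (edge rows
clipped) and correlates causally along time with same-length output, so
52 filters yield 1092 feature dimensions. Spectrally wide filters produce
strongly correlated adjacent channels; channels closer than a quarter of
the filter's spectral width to the last kept channel are dropped in a
bottom-up scan anchored at channel 1. Widths come from the 1/e decay
point of the Gabor envelope (closed form `b_s * acos(2/e - 1) / pi`) or,
for STRFs, from the smallest contiguous span holding 90% of squared
energy grown outward from the energy centroid (ties toward lower
channels). PCA is fit on training features only; a mean-pool decimation
option (factor 5) provides the 10 ms-rate variants.

When comparing the PCA cumulative-variance curves of two filter sets
(redundant STRF-like filters versus the diverse Gabor bank), filters must
be commensurate: unit-norm, zero-sum patterns. An un-normalized DC atom
otherwise swamps the variance of its own set and inverts the comparison.
With commensurate sets, the redundant set's curve dominates the diverse
set's pointwise throughout the informative range (up to 99% coverage of
either set) and reaches any coverage with fewer components; beyond that
range both curves sit within a few parts in 10^4 of 1 and their ordering
is numerical noise, so no claim is made there. The MFCC baseline is
pinned to one dialect: 25 ms periodic-Hann frames, 10 ms hop, 23
triangular mel filters to Nyquist, orthonormal DCT-II, 13 coefficients
with c0 replaced by frame log-energy, 7-point linear-slope deltas and
9-point slopes of those deltas — 39 dimensions.

The synthetic corpus contains six event classes chosen for distinct
modulation signatures (tone complexes, AM tones, FM sweeps, click trains,
noise bursts, AM noise); per-event parameters are randomized, SNR mixing
is exact over the event support, and the whole corpus is a pure function
of its spec. Events are pooled to mean+sd vectors per feature dimension
before classification — the per-frame-vs-per-event choice is not fixed by
convention, and event-level pooling keeps the harness small. One-vs-all
radial-kernel SVMs with winner-take-all decoding are tuned by 5-fold grid
search. Because the classes differ mainly in temporal modulation, purely
spectral feature subsets are expected to confuse some class pairs that
spectro-temporal features separate; the test suite asserts exactly this
ordering, not any absolute accuracy.

# Numerical choices and problem sizes

* Default test-suite scales: estimator recovery uses a 120 s ripple
  ensemble with 10 repetitions for the single-filter check and a shared
  60 s ensemble for the 10+10 temporal/spectral comparison; the null
  calibration of masking uses 3000 white stimulus windows at D = 1050
  with 1000 bootstrap replicates. These sizes give stable statistics while
  keeping a full run on a single core in the tens of minutes.
* Ridge systems are solved primal or dual depending on which dimension is
  smaller; cross-validation reuses per-fold Gram eigendecompositions so a
  penalty grid costs one eigendecomposition per fold.
* `sigma = 0` coefficients in masking: kept if their mean is non-zero
  (a deterministic coefficient), masked if both are zero.
* All stochastic steps take explicit seeds; bootstrap replicates are drawn
  sequentially from one seeded stream.

# Known limitations

* No spike sorting, PSTH smoothing, nonlinear STRF estimators, or
  time-varying receptive fields.
* Greedy MP only — no orthogonal MP or basis-pursuit variants.
* The classification experiment is a synthetic toy; absolute accuracies on
  real corpora are out of scope by design.
* The periphery has no cochlear filterbank or loudness model and refuses
  to resample: input must be 16 kHz mono.
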