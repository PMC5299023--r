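# strfgabor

Quantitative analysis of auditory spectro-temporal receptive fields
(STRFs) in R: estimate STRFs from stimulus/spike data by ridge-regularized
reverse correlation, decompose them into Gabor atoms by two-dimensional
matching pursuit, and summarize their spectro-temporal character with the
diagonality index κ and the atom-importance index η — validated
end-to-end against a built-in linear–nonlinear–Poisson (LNP) neuron
simulator, with a Bark-spectrogram / Gabor / MFCC feature front-end for
sound classification on the side.

## Who this is for

Auditory and computational neuroscientists who estimate receptive fields
from spike data and want a compact, parametric description of them; and
audio-ML practitioners who want physiologically motivated spectro-temporal
features with a controlled synthetic test bed.

## The model

The stimulus window preceding each response bin is flattened to
**s** ∈ ℝᴰ (21 Bark channels × 50 frames of 2 ms; D = 1050). With binned
responses *r*, the regularized, whitened spike-triggered average solves

    (SᵀS/N + λI) h = Sᵀr/N,

with λ chosen by 5-fold cross-validated prediction correlation. The STRF is
cleaned by a bootstrap significance mask (1000 × 20% subsamples, per-
coefficient z-test at p < 0.05) and insular-pixel removal.

Matching pursuit then rewrites the patch over a dictionary of complex
Gabor atoms g(t,f) = e^{2πi ω_t t} e^{2πi ω_s f} h(t;b_t) h(f;b_s)
(Hann envelopes; real and imaginary parts used as separate unit-norm
atoms; modulations cover 0–125 Hz × 0–0.25 cyc/Bark). Each iteration
subtracts the best-correlated shifted atom until the reconstruction
correlation reaches θ. Per atom,

    κ_ω = (|ω_t| + |ω_s|) / √(ω_t² + ω_s²)  ∈ [1, √2],

is 1 for purely temporal or purely spectral atoms and √2 for diagonal
ones; a decomposition's κ is the mean over its entries, and
η_j = Σ |γ_ijk| accumulates each atom's absolute weights over all
decompositions.

## Worked example

Simulate an LNP neuron with a known Gabor filter, estimate its STRF back,
and decompose the estimate (about two minutes, most of it bootstrap
masking):

```r
library(strfgabor)

truth  <- gabor_atom(omega_t = 62.5, omega_s = 0, b_t = 32, b_s = 21)
neuron <- lnp_neuron(truth, target_rate = 20)

stim <- generate_ripple_stimulus(ripple_config(duration_s = 30, seed = 1))
resp <- lnp_respond(neuron, stim, n_repeats = 10, seed = 2)
print(resp)
#> Spike response: 10 repetitions x 14951 bins (2 ms), mean rate 20.42 spikes/s

ens  <- make_ensemble(stim, resp)
strf <- estimate_strf(ens, ridge_config(n_boot = 300, seed = 3))
print(strf)
#> STRF: 21 x 50, lambda = 2.184, cv correlation = 0.552, 16.8% coefficients retained
cor(as.vector(strf$patch), as.vector(Re(truth$patch)))
#> [1] 0.984

bank <- build_gabor_bank()
dec  <- mp_decompose(strf$patch, bank, theta = 0.8)
print(dec)
#> MP decomposition: 1 atoms, final correlation 0.9837 (theta = 0.8), kappa = 1.0000
dec$entries[, c("omega_t", "omega_s", "dt", "gamma", "correlation")]
#>   omega_t omega_s dt      gamma correlation
#> 1    62.5       0  0 0.01046141   0.9837145
```

Reading the output: the cross-validated prediction correlation (0.55) is
limited by Poisson spiking noise, yet the masked estimate correlates at
0.98 with the true filter; matching pursuit needs a single atom, picks the
dictionary entry with exactly the ground-truth modulation frequencies at
zero shift, and κ = 1 correctly labels the filter purely temporal.

A thin command-line front-end over the same functions is installed at
`inst/cli/strftools.R` (`spectrogram`, `bank`, `estimate`, `mp`,
`simulate` subcommands).

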