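#' Ripple stimulus configuration
#'
#' Parameters of the synthetic ripple ensemble used to probe model neurons.
#' The stimulus emulates an ensemble of distinct short ripple presentations:
#' it is generated in consecutive segments (default 1 s), each a fresh
#' superposition of `n_components` spectro-temporal ripples whose modulation
#' frequencies are drawn uniformly within the configured bounds and whose
#' amplitudes are tapered as `(1 + |w_t|/w_t_max)^-taper_t *
#' (1 + |w_s|/w_s_max)^-taper_s`. The default exponents (1 temporal, 2
#' spectral) encode the anisotropy of conspecific-song modulation spectra:
#' natural song carries temporal modulation energy out to fast rates but is
#' spectrally smooth, with steeply decaying spectral-modulation power.
#' Bounds must stay within half the Nyquist modulation rates of the
#' 2 ms / 1 Bark grid.
#'
#' @param duration_s Total stimulus duration in seconds.
#' @param max_temporal_mod Largest temporal modulation (Hz).
#' @param max_spectral_mod Largest spectral modulation magnitude (cyc/Bark);
#'   both ripple orientations are drawn.
#' @param n_components Number of superimposed ripples per segment.
#' @param segment_s Segment length in seconds; components are redrawn each
#'   segment.
#' @param taper_t,taper_s Amplitude taper exponents along the temporal and
#'   spectral modulation axes.
#' @param n_channels,frame_period_ms Spectrogram geometry.
#' @param seed RNG seed for reproducible stimuli.
#' @return Object of class `ripple_config`.
#' @export
ripple_config <- function(duration_s = 120, max_temporal_mod = 125,
                          max_spectral_mod = 0.25, n_components = 30,
                          segment_s = 1, taper_t = 1, taper_s = 2,
                          n_channels = 21, frame_period_ms = 2,
                          seed = NULL) {
  if (n_components < 1) stop("n_components must be >= 1")
  t_half_nyq <- 1000 / (2 * frame_period_ms) / 2
  s_half_nyq <- 0.25
  if (max_temporal_mod > t_half_nyq + 1e-9 || max_spectral_mod > s_half_nyq + 1e-9) {
    stop("modulation bounds exceed half the Nyquist rates of the grid")
  }
  if (segment_s <= 0) stop("segment_s must be positive")
  structure(
    list(duration_s = duration_s, max_temporal_mod = max_temporal_mod,
         max_spectral_mod = max_spectral_mod,
         n_components = as.integer(n_components),
         segment_s = segment_s, taper_t = taper_t, taper_s = taper_s,
         n_channels = as.integer(n_channels),
         frame_period_ms = frame_period_ms, seed = seed),
    class = "ripple_config"
  )
}

#' Generate a ripple-like Bark-domain stimulus
#'
#' Concatenation of segments, each a superposition of `n_components`
#' ripples `a cos(2 pi (w_t t + w_s f) + phi)` over the channels x frames
#' grid, with a positive offset so all values are nonnegative. Fully
#' deterministic given the config seed.
#'
#' @param config A [ripple_config()].
#' @return A `bark_spectrogram`-classed object (synthetic; no waveform
#'   behind it).
#' @export
generate_ripple_stimulus <- function(config = ripple_config()) {
  n_frames <- round(config$duration_s * 1000 / config$frame_period_ms)
  seg_frames <- max(1L, round(config$segment_s * 1000 / config$frame_period_ms))
  f_bark <- seq_len(config$n_channels) - 1
  values <- matrix(0, config$n_channels, n_frames)
  with_seed(config$seed, {
    start <- 1L
    while (start <= n_frames) {
      stop_at <- min(start + seg_frames - 1L, n_frames)
      t_s <- (start:stop_at - 1) * config$frame_period_ms / 1000
      seg <- matrix(0, config$n_channels, length(t_s))
      for (m in seq_len(config$n_components)) {
        wt <- stats::runif(1, 0, config$max_temporal_mod)
        ws <- stats::runif(1, -config$max_spectral_mod, config$max_spectral_mod)
        phi <- stats::runif(1, 0, 2 * pi)
        a <- (1 + wt / config$max_temporal_mod)^(-config$taper_t) *
          (1 + abs(ws) / config$max_spectral_mod)^(-config$taper_s)
        # cos(alpha_t + beta_f) expanded so the ripple is a rank-2 outer sum
        at <- 2 * pi * wt * t_s + phi
        bf <- 2 * pi * ws * f_bark
        seg <- seg + a * (outer(cos(bf), cos(at)) - outer(sin(bf), sin(at)))
      }
      values[, start:stop_at] <- seg
      start <- stop_at + 1L
    }
  })
  values <- values - min(values)
  structure(
    list(values = values,
         channel_centers = f_bark + 0.5,
         frame_period_ms = config$frame_period_ms,
         config = config),
    class = "bark_spectrogram"
  )
}

#' Linear–nonlinear–Poisson model neuron
#'
#' A fixed linear spectro-temporal filter followed by a static nonlinearity
#' and Poisson spike generation. The default nonlinearity is rectified
#' linear with its threshold at the median of the linear drive and its gain
#' solved so the mean firing rate equals `target_rate`.
#'
#' @param filter Real channels x frames matrix (the ground-truth STRF), or a
#'   [gabor_atom()] (its real part is used).
#' @param nonlinearity `"rectlin"` or `"exp"`.
#' @param target_rate Mean firing rate in spikes/s (> 0).
#' @param gain Optional fixed gain; `gain = 0` yields a drive-independent
#'   neuron firing at `target_rate`. For `"exp"`, the exponent slope (in
#'   units of drive standard deviations) before rate rescaling.
#' @param threshold Optional fixed threshold for `"rectlin"` (default: the
#'   median drive).
#' @return Object of class `lnp_neuron`.
#' @export
lnp_neuron <- function(filter, nonlinearity = c("rectlin", "exp"),
                       target_rate = 20, gain = NULL, threshold = NULL) {
  nonlinearity <- match.arg(nonlinearity)
  if (inherits(filter, "gabor_atom")) filter <- Re(filter$patch)
  if (!is.matrix(filter) || !all(is.finite(filter))) {
    stop("filter must be a finite numeric matrix")
  }
  if (target_rate <= 0) stop("target_rate must be positive")
  structure(
    list(filter = filter, nonlinearity = nonlinearity,
         target_rate = target_rate, gain = gain, threshold = threshold),
    class = "lnp_neuron"
  )
}

# Linear drive: valid 2D correlation of the stimulus with the filter along
# time; one value per frame from the first fully-covered window onward.
lnp_drive <- function(filter, values) {
  nc <- nrow(filter)
  nf <- ncol(filter)
  if (nc != nrow(values)) stop("filter channel count must match the stimulus")
  n <- ncol(values) - nf + 1L
  if (n < 1) stop("stimulus shorter than the filter")
  drive <- numeric(n)
  for (k in seq_len(nf)) {
    drive <- drive + as.vector(crossprod(filter[, k], values[, k:(k + n - 1L), drop = FALSE]))
  }
  drive
}

lnp_rate <- function(neuron, drive) {
  if (!is.null(neuron$gain) && neuron$gain == 0) {
    return(rep(neuron$target_rate, length(drive)))
  }
  if (neuron$nonlinearity == "rectlin") {
    thr <- if (is.null(neuron$threshold)) stats::median(drive) else neuron$threshold
    v <- pmax(drive - thr, 0)
    if (mean(v) == 0) return(rep(neuron$target_rate, length(drive)))
    rate <- neuron$target_rate * v / mean(v)
  } else {
    slope <- if (is.null(neuron$gain)) 1 else neuron$gain
    s <- stats::sd(drive)
    z <- if (s > 0) (drive - mean(drive)) / s else drive * 0
    v <- exp(slope * z)
    rate <- neuron$target_rate * v / mean(v)
  }
  if (any(rate < 0)) stop("internal error: nonlinearity produced negative rates")
  rate
}

#' Simulate spike responses of an LNP neuron
#'
#' Computes the linear drive of the neuron's filter over the stimulus,
#' passes it through the static nonlinearity (rescaled to the target mean
#' rate), and draws independent Poisson spike counts per frame-period bin
#' for each stimulus repetition.
#'
#' @param neuron An [lnp_neuron()].
#' @param stimulus A `bark_spectrogram` (real or synthetic).
#' @param n_repeats Number of stimulus repetitions (default 10).
#' @param seed RNG seed.
#' @return Object of class `spike_response`: integer `counts`
#'   (repetitions x frames, aligned to the frames from the first full
#'   filter window onward), `rate` (spikes/s per bin), `frame_period_ms`,
#'   `offset` (number of leading stimulus frames without a count).
#' @export
lnp_respond <- function(neuron, stimulus, n_repeats = 10, seed = NULL) {
  drive <- lnp_drive(neuron$filter, stimulus$values)
  rate <- lnp_rate(neuron, drive)
  dt <- stimulus$frame_period_ms / 1000
  counts <- with_seed(seed, {
    matrix(stats::rpois(n_repeats * length(rate), rep(rate * dt, each = n_repeats)),
           nrow = n_repeats)
  })
  structure(
    list(counts = counts, rate = rate, drive = drive,
         frame_period_ms = stimulus$frame_period_ms,
         offset = ncol(neuron$filter) - 1L,
         n_repeats = n_repeats),
    class = "spike_response"
  )
}

#' @export
print.spike_response <- function(x, ...) {
  cat(sprintf(
    "Spike response: %d repetitions x %d bins (%g ms), mean rate %.2f spikes/s\n",
    nrow(x$counts), ncol(x$counts), x$frame_period_ms,
    mean(x$counts) / (x$frame_period_ms / 1000)))
  invisible(x)
}

filter_category <- function(omega_t, omega_s) {
  if (omega_t == 0 && omega_s == 0) "dc"
  else if (omega_s == 0) "temporal"
  else if (omega_t == 0) "spectral"
  else "mixed"
}

#' Filter-recovery experiment with simulated LNP neurons
#'
#' For each ground-truth filter: simulate spike responses to a shared
#' ripple stimulus, estimate the STRF back by cross-validated ridge reverse
#' correlation, and report the Pearson correlation between estimate and
#' ground truth. The stimulus ensemble, its fold Gram matrices and their
#' eigendecompositions are computed once and shared across neurons.
#'
#' @param filters List of ground-truth filters: [gabor_atom()]s or real
#'   channels x frames matrices. Gabor atoms contribute real and imaginary
#'   parts only via `Re`; pass matrices (e.g. `Im(atom$patch)`) for other
#'   parts.
#' @param stim_config A [ripple_config()].
#' @param estimator_config A [ridge_config()]; `n_boot = 0` by default usage
#'   keeps the experiment to penalty selection + ridge fit.
#' @param n_repeats Stimulus repetitions per neuron.
#' @param target_rate Mean firing rate of each simulated neuron (spikes/s).
#' @param seed Base seed; neuron `i` uses `seed + i`.
#' @param high_mod_cutoff Fraction of the modulation Nyquist band above
#'   which energy counts as "high modulation" for the washed-out metric.
#' @return Data frame: one row per filter with its modulation parameters,
#'   `category` (purely temporal / purely spectral / mixed / dc),
#'   `recovery_correlation`, selected `lambda`, `cv_correlation`, and the
#'   high-modulation energy ratio `highmod_ratio` (estimate / truth).
#'   Failed estimations yield `NA` rows rather than errors.
#' @export
recovery_experiment <- function(filters,
                                stim_config = ripple_config(),
                                estimator_config = ridge_config(n_boot = 0),
                                n_repeats = 10,
                                target_rate = 20,
                                seed = 1,
                                high_mod_cutoff = 0.5) {
  stim <- generate_ripple_stimulus(stim_config)
  fl <- lapply(filters, function(f) if (inherits(f, "gabor_atom")) Re(f$patch) else f)
  n_frames <- ncol(fl[[1]])
  S <- build_design(stim$values, n_frames)
  mu <- colMeans(S)
  S <- sweep(S, 2, mu)
  machine <- cv_machine(S, estimator_config$n_folds)

  rows <- vector("list", length(filters))
  for (i in seq_along(fl)) {
    row <- data.frame(
      filter = i,
      omega_t = NA_real_, omega_s = NA_real_, category = NA_character_,
      recovery_correlation = NA_real_, lambda = NA_real_,
      cv_correlation = NA_real_, highmod_ratio = NA_real_
    )
    if (inherits(filters[[i]], "gabor_atom")) {
      row$omega_t <- filters[[i]]$omega_t
      row$omega_s <- filters[[i]]$omega_s
      row$category <- filter_category(row$omega_t, row$omega_s)
    }
    res <- try({
      neuron <- lnp_neuron(fl[[i]], target_rate = target_rate)
      resp <- lnp_respond(neuron, stim, n_repeats = n_repeats, seed = seed + i)
      ens <- structure(
        list(S = S, r = colMeans(resp$counts),
             n_channels = nrow(fl[[i]]), n_frames = n_frames, col_means = mu),
        class = "stimulus_ensemble"
      )
      cfg <- estimator_config
      cfg$n_boot <- 0L
      est <- estimate_strf(ens, cfg, machine = machine)
      row$recovery_correlation <- stats::cor(as.vector(est$patch), as.vector(fl[[i]]))
      row$lambda <- est$lambda
      row$cv_correlation <- est$cv_correlation
      row$highmod_ratio <- highmod_energy(est$patch, high_mod_cutoff) /
        max(highmod_energy(fl[[i]], high_mod_cutoff), .Machine$double.eps)
      NULL
    }, silent = TRUE)
    rows[[i]] <- row
  }
  do.call(rbind, rows)
}

# Energy of a patch in the upper half of the 2D modulation band (along both
# axes jointly): used to quantify the "washed-out" character of estimates.
highmod_energy <- function(patch, cutoff = 0.5) {
  P <- Mod(stats::fft(patch))^2
  nr <- nrow(patch)
  nc <- ncol(patch)
  fr <- pmin(0:(nr - 1), nr - 0:(nr - 1)) / (nr / 2)
  fc <- pmin(0:(nc - 1), nc - 0:(nc - 1)) / (nc / 2)
  hi <- outer(fr > cutoff, rep(TRUE, nc)) | outer(rep(TRUE, nr), fc > cutoff)
  sum(P[hi])
}
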