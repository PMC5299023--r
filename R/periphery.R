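#' Peripheral front-end configuration
#'
#' Parameters of the Bark-scaled spectrogram front-end: short-time DFT of the
#' waveform followed by trapezoid summation into 1-Bark-wide channels and
#' cubic-root amplitude compression. The defaults (16 kHz audio, 4 ms Hann
#' windows, 2 ms hop, 128-point DFT, 1 Bark bandwidth, exponent 1/3) yield a
#' 21-channel spectrogram with a 2 ms frame period.
#'
#' @param sample_rate Sampling rate in Hz.
#' @param window_ms Analysis window length in ms.
#' @param shift_ms Frame shift (hop) in ms; the stated "overlap" convention is
#'   hop = shift, overlap = window - hop.
#' @param dft_size DFT length in samples (frames are zero-padded up to this).
#' @param bark_bandwidth Channel bandwidth in Bark.
#' @param compression_exponent Exponent applied to band power (1/3 = cubic
#'   root of power).
#' @return An object of class `periphery_config`.
#' @export
periphery_config <- function(sample_rate = 16000,
                             window_ms = 4,
                             shift_ms = 2,
                             dft_size = 128,
                             bark_bandwidth = 1,
                             compression_exponent = 1 / 3) {
  win_samples <- round(window_ms * sample_rate / 1000)
  hop_samples <- round(shift_ms * sample_rate / 1000)
  if (hop_samples > win_samples) stop("frame shift must not exceed window length")
  if (dft_size < win_samples) stop("dft_size must be at least the window length in samples")
  if (bark_bandwidth <= 0) stop("bark_bandwidth must be positive")
  structure(
    list(
      sample_rate = sample_rate,
      window_ms = window_ms,
      shift_ms = shift_ms,
      dft_size = as.integer(dft_size),
      bark_bandwidth = bark_bandwidth,
      compression_exponent = compression_exponent,
      window_samples = as.integer(win_samples),
      hop_samples = as.integer(hop_samples)
    ),
    class = "periphery_config"
  )
}

#' Hertz to Bark
#'
#' Zwicker–Terhardt closed form,
#' `z = 13 atan(0.00076 f) + 3.5 atan((f/7500)^2)`.
#' Maps 0 Hz to 0 Bark, is strictly increasing, and places 8 kHz at
#' approximately 21.27 Bark, so exactly 21 one-Bark channels cover the
#' 0–8 kHz band of 16 kHz audio.
#'
#' @param frequency Frequency in Hz (vectorized, must be >= 0).
#' @return Critical-band rate in Bark.
#' @export
bark_scale <- function(frequency) {
  if (any(!is.finite(frequency)) || any(frequency < 0)) {
    stop("frequency must be finite and nonnegative")
  }
  13 * atan(0.00076 * frequency) + 3.5 * atan((frequency / 7500)^2)
}

# Trapezoid channel weight at Bark position z for a channel centered at
# `center` with half-height bandwidth `bw`: unit plateau for |z-c| <= bw/4,
# linear flanks reaching zero at |z-c| = 3 bw/4, so adjacent channels at
# 1-bandwidth spacing cross at half height.
trapezoid_weight <- function(z, center, bw) {
  pmin(pmax((0.75 * bw - abs(z - center)) / (bw / 2), 0), 1)
}

# Channel centers: (k - 1/2) * bw for k = 1, 2, ... while the plateau stays
# inside the analysis band. 21 channels at the defaults.
bark_channel_centers <- function(config) {
  z_max <- bark_scale(config$sample_rate / 2)
  bw <- config$bark_bandwidth
  k <- seq_len(floor((z_max - bw / 4) / bw + 0.5))
  (k - 0.5) * bw
}

#' Bark-scaled compressed spectrogram
#'
#' Computes the time–frequency representation all downstream stages consume:
#' Hann-windowed short-time power spectra, summed into trapezoid Bark bands,
#' then compressed by `power^(1/3)`.
#'
#' @param audio Mono waveform (numeric vector).
#' @param sample_rate Sampling rate of `audio` in Hz; must equal the
#'   configured rate — no implicit resampling.
#' @param config A [periphery_config()].
#' @return Object of class `bark_spectrogram` with elements `values`
#'   (channels x frames, nonnegative), `channel_centers` (Bark),
#'   `frame_period_ms`, and `config`.
#' @export
bark_spectrogram <- function(audio, sample_rate = 16000,
                             config = periphery_config()) {
  if (!is.numeric(audio) || is.matrix(audio)) stop("audio must be a mono numeric vector")
  if (sample_rate != config$sample_rate) {
    stop(sprintf("audio sample rate (%g) does not match config (%g); resample first",
                 sample_rate, config$sample_rate))
  }
  win <- config$window_samples
  hop <- config$hop_samples
  if (length(audio) < win) stop("audio shorter than one analysis window")

  n_frames <- (length(audio) - win) %/% hop + 1L
  starts <- (seq_len(n_frames) - 1L) * hop
  idx <- outer(seq_len(win), starts, `+`)
  frames <- matrix(audio[idx], nrow = win)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(win) - 1L) / win) # periodic Hann
  frames <- frames * w

  padded <- matrix(0, nrow = config$dft_size, ncol = n_frames)
  padded[seq_len(win), ] <- frames
  spec <- stats::mvfft(padded)
  n_bins <- config$dft_size %/% 2L + 1L
  power <- Mod(spec[seq_len(n_bins), , drop = FALSE])^2

  bin_freq <- (seq_len(n_bins) - 1L) * config$sample_rate / config$dft_size
  bin_bark <- bark_scale(bin_freq)
  centers <- bark_channel_centers(config)
  W <- t(vapply(centers, function(cz) {
    trapezoid_weight(bin_bark, cz, config$bark_bandwidth)
  }, numeric(n_bins)))

  values <- (W %*% power)^config$compression_exponent
  structure(
    list(
      values = values,
      channel_centers = centers,
      frame_period_ms = config$shift_ms,
      config = config
    ),
    class = "bark_spectrogram"
  )
}

#' @export
print.bark_spectrogram <- function(x, ...) {
  cat(sprintf("Bark spectrogram: %d channels x %d frames, %g ms frame period\n",
              nrow(x$values), ncol(x$values), x$frame_period_ms))
  invisible(x)
}

#' @export
plot.bark_spectrogram <- function(x, ...) {
  t_ms <- (seq_len(ncol(x$values)) - 1) * x$frame_period_ms
  graphics::image(t_ms, x$channel_centers, t(x$values),
                  xlab = "time (ms)", ylab = "frequency (Bark)",
                  main = "Bark spectrogram", useRaster = TRUE, ...)
  invisible(x)
}
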