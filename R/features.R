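#' Spectro-temporal filter features by 2D filtering
#'
#' Correlates a Bark spectrogram with a set of spectro-temporal filters at
#' every spectral alignment. Each filter is slid across the 21 channels
#' (edge rows clipped), producing one output channel per alignment; along
#' time the correlation is causal and same-length (zero padding before the
#' first frame), so the value at frame `t` sees only frames `<= t`. Complex
#' filters contribute their real part.
#'
#' @param spectrogram A [bark_spectrogram()] or channels x frames matrix.
#' @param filters List of filter patches (numeric or complex matrices,
#'   [gabor_atom()]s, or `strf` objects), or a [build_gabor_bank()] (its
#'   complex atoms' real parts are used).
#' @param decimate Integer mean-pooling factor along time (1 = none); e.g. 5
#'   converts the 2 ms frame grid to 10 ms.
#' @return Object of class `feature_matrix`: `values` (frames x dims),
#'   `labels` (filter id and output channel per column), `frame_period_ms`.
#' @export
filter_features <- function(spectrogram, filters, decimate = 1) {
  values <- if (inherits(spectrogram, "bark_spectrogram")) spectrogram$values else spectrogram
  nc <- nrow(values)
  if (inherits(filters, "gabor_bank")) filters <- filters$atoms
  fl <- lapply(filters, function(f) {
    if (inherits(f, "gabor_atom")) f <- f$patch
    if (inherits(f, "strf")) f <- f$patch
    if (is.complex(f)) f <- Re(f)
    if (!is.matrix(f)) stop("each filter must be a matrix, gabor_atom, or strf")
    if (nrow(f) > nc) stop("filter has more channels than the spectrogram")
    f
  })
  n_frames <- max(vapply(fl, ncol, integer(1)))

  padded <- cbind(matrix(0, nc, n_frames - 1L), values)
  W <- build_design(padded, n_frames)

  cols <- vector("list", length(fl) * nc)
  labs <- vector("list", length(fl) * nc)
  idx <- 0L
  for (j in seq_along(fl)) {
    f <- fl[[j]]
    h <- nrow(f)
    lf <- ncol(f)
    center <- ceiling((h + 1) / 2)
    for (ch in seq_len(nc)) {
      emb <- matrix(0, nc, n_frames)
      rows_out <- (ch - center + 1L):(ch - center + h)
      keep <- rows_out >= 1L & rows_out <= nc
      emb[rows_out[keep], (n_frames - lf + 1L):n_frames] <- f[keep, , drop = FALSE]
      idx <- idx + 1L
      cols[[idx]] <- as.vector(emb)
      labs[[idx]] <- data.frame(filter = j, channel = ch)
    }
  }
  F_mat <- do.call(cbind, cols)
  out <- W %*% F_mat
  labels <- do.call(rbind, labs)
  period <- if (inherits(spectrogram, "bark_spectrogram")) spectrogram$frame_period_ms else NA_real_

  if (decimate > 1) {
    n_pool <- nrow(out) %/% decimate
    if (n_pool < 1) stop("decimation factor larger than the feature length")
    grp <- rep(seq_len(n_pool), each = decimate)
    out <- rowsum(out[seq_along(grp), , drop = FALSE], grp) / decimate
    period <- period * decimate
  }
  structure(
    list(values = out, labels = labels, frame_period_ms = period),
    class = "feature_matrix"
  )
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("Feature matrix: %d frames x %d dimensions (%s ms frame period)\n",
              nrow(x$values), ncol(x$values),
              format(x$frame_period_ms)))
  invisible(x)
}

#' Spectral width of a filter
#'
#' For Gabor filters, the full width (in channels) at which the spectral
#' Hann envelope has decayed to 1/e of its peak — in closed form,
#' `width = b_s * acos(2/e - 1) / pi`. For STRFs, the length of the
#' smallest contiguous channel span containing at least 90% of the squared
#' coefficient energy, grown outward from the energy centroid (ties toward
#' lower channels).
#'
#' @param filter A [gabor_atom()] (`kind = "gabor"`) or a real matrix /
#'   `strf` (`kind = "strf"`).
#' @param kind `"gabor"` or `"strf"`.
#' @param energy_fraction Energy coverage for the STRF rule.
#' @return Width in channels (Gabor widths are capped at the patch height).
#' @export
spectral_width <- function(filter, kind = c("gabor", "strf"),
                           energy_fraction = 0.9) {
  kind <- match.arg(kind)
  if (kind == "gabor") {
    if (!inherits(filter, "gabor_atom")) {
      stop("kind = \"gabor\" requires a gabor_atom (the envelope width b_s is needed)")
    }
    w <- filter$b_s * acos(2 / exp(1) - 1) / pi / filter$channel_spacing
    return(min(w, filter$n_channels))
  }
  m <- if (inherits(filter, "strf")) filter$patch else filter
  if (inherits(m, "gabor_atom")) m <- Re(m$patch)
  e <- rowSums(m^2)
  tot <- sum(e)
  if (tot == 0) stop("zero filter: spectral width undefined")
  centroid <- round(sum(seq_along(e) * e) / tot)
  centroid <- min(max(centroid, 1L), length(e))
  lo <- hi <- centroid
  acc <- e[centroid]
  while (acc < energy_fraction * tot) {
    e_lo <- if (lo > 1) e[lo - 1] else -Inf
    e_hi <- if (hi < length(e)) e[hi + 1] else -Inf
    if (e_lo >= e_hi) {
      lo <- lo - 1
      acc <- acc + e[lo]
    } else {
      hi <- hi + 1
      acc <- acc + e[hi]
    }
  }
  as.integer(hi - lo + 1)
}

#' Channel subsampling by filter width
#'
#' Greedy bottom-up scan: channel 1 is always kept, and each further
#' channel is kept only if its distance to the last kept channel is at
#' least a quarter of the filter's spectral width. Removes the highly
#' correlated outputs of spectrally wide filters.
#'
#' @param n_channels Number of output channels.
#' @param width Filter spectral width in channels (> 0).
#' @return Integer vector of retained channel indices.
#' @export
subsample_channels <- function(n_channels, width) {
  stop_if_not_scalar_number(width, "width")
  if (width <= 0) stop("width must be positive")
  kept <- 1L
  last <- 1L
  for (ch in seq_len(n_channels)[-1]) {
    if (ch - last >= width / 4) {
      kept <- c(kept, ch)
      last <- ch
    }
  }
  kept
}

#' Apply width-based channel subsampling to a feature matrix
#'
#' @param features A [filter_features()] result.
#' @param widths Numeric vector of spectral widths, one per filter.
#' @return A reduced `feature_matrix`.
#' @export
subsample_features <- function(features, widths) {
  n_filters <- max(features$labels$filter)
  if (length(widths) != n_filters) stop("one width per filter required")
  keep <- logical(nrow(features$labels))
  for (j in seq_len(n_filters)) {
    chans <- subsample_channels(sum(features$labels$filter == j), widths[j])
    keep[features$labels$filter == j & features$labels$channel %in% chans] <- TRUE
  }
  features$values <- features$values[, keep, drop = FALSE]
  features$labels <- features$labels[keep, , drop = FALSE]
  features
}

#' PCA decorrelation fit on training features
#'
#' Fits a principal-component rotation on the training matrix only,
#' projects train (and optionally test) onto the components needed to
#' reach the requested cumulative variance, and returns the cumulative
#' explained-variance curve.
#'
#' @param train Training matrix (rows = observations) or `feature_matrix`.
#' @param test Optional test matrix projected with the training rotation.
#' @param variance_target Fraction of variance to retain, in (0, 1].
#' @return List: `train`, `test` (scores), `n_components`,
#'   `cum_variance` (non-decreasing, reaching 1 at full rank), `rotation`,
#'   `center`.
#' @export
pca_decorrelate <- function(train, test = NULL, variance_target = 0.99) {
  if (inherits(train, "feature_matrix")) train <- train$values
  if (inherits(test, "feature_matrix")) test <- test$values
  if (variance_target <= 0 || variance_target > 1) {
    stop("variance_target must be in (0, 1]")
  }
  if (nrow(train) < 2) stop("need at least two training rows for PCA")
  pc <- stats::prcomp(train, center = TRUE, scale. = FALSE)
  v <- pc$sdev^2
  cum <- cumsum(v) / sum(v)
  k <- which(cum >= variance_target - 1e-12)[1]
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  project <- function(m) sweep(m, 2, pc$center) %*% rot
  list(
    train = project(train),
    test = if (is.null(test)) NULL else project(test),
    n_components = k,
    cum_variance = cum,
    rotation = rot,
    center = pc$center
  )
}

# --- MFCC baseline ---------------------------------------------------------

mel_scale <- function(f) 2595 * log10(1 + f / 700)
mel_inverse <- function(m) 700 * (10^(m / 2595) - 1)

mel_filterbank <- function(n_filters, n_fft, sample_rate) {
  n_bins <- n_fft %/% 2 + 1
  edges <- mel_inverse(seq(mel_scale(0), mel_scale(sample_rate / 2),
                           length.out = n_filters + 2))
  bin_freq <- (seq_len(n_bins) - 1) * sample_rate / n_fft
  fb <- matrix(0, n_filters, n_bins)
  for (j in seq_len(n_filters)) {
    lo <- edges[j]; cen <- edges[j + 1]; hi <- edges[j + 2]
    up <- (bin_freq - lo) / (cen - lo)
    down <- (hi - bin_freq) / (hi - cen)
    fb[j, ] <- pmax(0, pmin(up, down))
  }
  fb
}

# Orthonormal DCT-II matrix (n_out x n_in).
dct_matrix <- function(n_out, n_in) {
  M <- outer(0:(n_out - 1), seq_len(n_in), function(k, j) {
    cos(pi * k * (2 * j - 1) / (2 * n_in))
  })
  M * sqrt(2 / n_in) * ifelse(0:(n_out - 1) == 0, sqrt(1 / 2), 1)
}

# Linear-slope ("delta") filter over a (2K+1)-point window with replicated
# edges: slope_t = sum_k k x_{t+k} / sum_k k^2.
delta_filter <- function(x, K) {
  n <- nrow(x)
  pad <- rbind(x[rep(1, K), , drop = FALSE], x, x[rep(n, K), , drop = FALSE])
  out <- matrix(0, n, ncol(x))
  for (k in seq_len(K)) {
    out <- out + k * (pad[(K + 1 + k):(K + n + k), , drop = FALSE] -
                        pad[(K + 1 - k):(K + n - k), , drop = FALSE])
  }
  out / (2 * sum(seq_len(K)^2))
}

#' MFCC baseline features
#'
#' HTK-style mel-frequency cepstra: 25 ms periodic-Hann frames with 10 ms
#' shift, 23 triangular mel filters over 0 to Nyquist, log compression,
#' orthonormal DCT-II. The first 13 coefficients are kept with c0 replaced
#' by the frame log-energy; 7-point linear-slope deltas and 9-point
#' linear-slope delta-deltas complete the 39-dimensional vector.
#'
#' @param audio Mono waveform.
#' @param sample_rate Sampling rate in Hz (16 kHz dialect).
#' @return A `feature_matrix` with 39 columns and a 10 ms frame period.
#' @export
mfcc_features <- function(audio, sample_rate = 16000) {
  win <- round(0.025 * sample_rate)
  hop <- round(0.010 * sample_rate)
  if (length(audio) < win) stop("audio shorter than one MFCC frame")
  n_fft <- 2^ceiling(log2(win))
  n_frames <- (length(audio) - win) %/% hop + 1L
  starts <- (seq_len(n_frames) - 1L) * hop
  idx <- outer(seq_len(win), starts, `+`)
  frames <- matrix(audio[idx], nrow = win)
  energy <- colSums(frames^2)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(win) - 1) / win)
  frames <- frames * w
  padded <- matrix(0, n_fft, n_frames)
  padded[seq_len(win), ] <- frames
  power <- Mod(stats::mvfft(padded)[seq_len(n_fft %/% 2 + 1), , drop = FALSE])^2

  fb <- mel_filterbank(23, n_fft, sample_rate)
  logmel <- log(pmax(fb %*% power, .Machine$double.eps))
  cep <- t(dct_matrix(13, 23) %*% logmel)
  cep[, 1] <- log(pmax(energy, .Machine$double.eps))

  d <- delta_filter(cep, 3)   # 7-point slope
  dd <- delta_filter(d, 4)    # 9-point slope of the deltas
  values <- cbind(cep, d, dd)
  structure(
    list(values = values,
         labels = data.frame(
           filter = rep(1:3, each = 13),
           channel = rep(1:13, times = 3)
         ),
         frame_period_ms = 10),
    class = "feature_matrix"
  )
}

# --- Synthetic event corpus ------------------------------------------------

#' Synthetic acoustic event corpus specification
#'
#' Describes a reproducible corpus of short synthetic sound events whose
#' classes differ primarily in their modulation signatures (harmonic tone
#' complexes, AM tones, FM sweeps, click trains, noise bursts, AM noise),
#' plus optional noisy test mixtures at given SNRs.
#'
#' @param classes Class names among the built-in generators.
#' @param n_train,n_test Events per class.
#' @param snr_list SNRs (dB) at which noisy copies of the test set are
#'   produced; empty for clean-only.
#' @param noise_kind `"stationary"` (white Gaussian) or `"modulated"`
#'   (slow sinusoidal amplitude modulation of white noise).
#' @param duration_s Event duration in seconds.
#' @param sample_rate Sampling rate in Hz.
#' @param seed Corpus seed; the whole corpus is a pure function of the spec.
#' @return Object of class `corpus_spec`.
#' @export
corpus_spec <- function(classes = c("tone_complex", "am_tone", "fm_sweep",
                                    "click_train", "noise_burst", "am_noise"),
                        n_train = 12, n_test = 8,
                        snr_list = numeric(0),
                        noise_kind = c("stationary", "modulated"),
                        duration_s = 0.5, sample_rate = 16000, seed = 1) {
  known <- c("tone_complex", "am_tone", "fm_sweep", "click_train",
             "noise_burst", "am_noise")
  if (!all(classes %in% known)) {
    stop("unknown class; available: ", paste(known, collapse = ", "))
  }
  if (length(classes) < 2) stop("need at least two classes")
  structure(
    list(classes = classes, n_train = n_train, n_test = n_test,
         snr_list = snr_list, noise_kind = match.arg(noise_kind),
         duration_s = duration_s, sample_rate = sample_rate, seed = seed),
    class = "corpus_spec"
  )
}

event_generator <- function(class, n, sr) {
  t <- (seq_len(n) - 1) / sr
  ramp <- pmin(1, pmin(seq_len(n), rev(seq_len(n))) / (0.01 * sr))
  x <- switch(
    class,
    tone_complex = {
      f0 <- stats::runif(1, 180, 320)
      rowSums(sapply(1:5, function(h) sin(2 * pi * h * f0 * t + stats::runif(1, 0, 2 * pi)) / h))
    },
    am_tone = {
      fc <- stats::runif(1, 800, 2000)
      fm <- stats::runif(1, 30, 70)
      (1 + 0.9 * sin(2 * pi * fm * t)) * sin(2 * pi * fc * t)
    },
    fm_sweep = {
      f1 <- stats::runif(1, 400, 800)
      f2 <- f1 * stats::runif(1, 3, 5)
      if (stats::runif(1) < 0.5) { tmp <- f1; f1 <- f2; f2 <- tmp }
      sin(2 * pi * (f1 * t + (f2 - f1) / (2 * max(t)) * t^2))
    },
    click_train = {
      rate <- stats::runif(1, 20, 40)
      x <- numeric(n)
      pos <- round(seq(stats::runif(1, 1, sr / rate), n, by = sr / rate))
      x[pos[pos <= n]] <- 1
      stats::filter(x, stats::dnorm(seq(-3, 3, length.out = 9)), sides = 2,
                    method = "convolution") |> as.numeric() |> (\(v) { v[is.na(v)] <- 0; v })()
    },
    noise_burst = {
      env <- numeric(n)
      n_bursts <- sample(2:4, 1)
      for (b in seq_len(n_bursts)) {
        c0 <- stats::runif(1, 0.1, 0.9) * n
        env <- env + exp(-((seq_len(n) - c0)^2) / (2 * (0.02 * sr)^2))
      }
      stats::rnorm(n) * env
    },
    am_noise = {
      fm <- stats::runif(1, 30, 70)
      stats::rnorm(n) * (1 + 0.9 * sin(2 * pi * fm * t))
    }
  )
  x <- x * ramp
  x / max(sqrt(mean(x^2)), .Machine$double.eps) * 0.1
}

corpus_noise <- function(kind, n, sr) {
  x <- stats::rnorm(n)
  if (kind == "modulated") {
    fm <- stats::runif(1, 4, 8)
    t <- (seq_len(n) - 1) / sr
    x <- x * (0.2 + 0.8 * abs(sin(2 * pi * fm * t)))
  }
  x
}

#' Mix signal and noise at a prescribed SNR
#'
#' Scales the noise so that `10 log10(P_signal / P_noise)` equals `snr_db`
#' over the signal support.
#'
#' @param signal,noise Equal-length waveforms.
#' @param snr_db Target signal-to-noise ratio in dB.
#' @return The mixture waveform.
#' @export
mix_at_snr <- function(signal, noise, snr_db) {
  p_s <- mean(signal^2)
  if (p_s == 0) stop("zero-power signal: SNR undefined")
  p_n <- mean(noise^2)
  if (p_n == 0) stop("zero-power noise")
  signal + noise * sqrt(p_s / (10^(snr_db / 10)) / p_n)
}

#' Generate a synthetic labeled event corpus
#'
#' Draws `n_train` + `n_test` events per class with randomized per-event
#' parameters, plus noisy copies of the test set at each requested SNR.
#' Fully reproducible from the spec seed.
#'
#' @param spec A [corpus_spec()].
#' @return List with `train` and `test` (each: `audio` list and `labels`
#'   factor), `test_noisy` (named by SNR), `sample_rate`, and `spec`.
#' @export
synth_event_corpus <- function(spec = corpus_spec()) {
  n <- round(spec$duration_s * spec$sample_rate)
  make_set <- function(count) {
    audio <- list()
    labels <- character(0)
    for (cl in spec$classes) {
      for (i in seq_len(count)) {
        audio[[length(audio) + 1L]] <- event_generator(cl, n, spec$sample_rate)
        labels <- c(labels, cl)
      }
    }
    list(audio = audio, labels = factor(labels, levels = spec$classes))
  }
  with_seed(spec$seed, {
    train <- make_set(spec$n_train)
    test <- make_set(spec$n_test)
    test_noisy <- list()
    for (snr in spec$snr_list) {
      noisy <- lapply(test$audio, function(x) {
        mix_at_snr(x, corpus_noise(spec$noise_kind, n, spec$sample_rate), snr)
      })
      test_noisy[[format(snr)]] <- list(audio = noisy, labels = test$labels)
    }
    list(train = train, test = test, test_noisy = test_noisy,
         sample_rate = spec$sample_rate, spec = spec)
  })
}

#' Pool a frame-level feature matrix into one event vector
#'
#' Per-event mean and standard deviation of every feature dimension.
#'
#' @param features A `feature_matrix` or frames x dims matrix.
#' @return Numeric vector of length 2 x dims.
#' @export
pool_features <- function(features) {
  m <- if (inherits(features, "feature_matrix")) features$values else features
  c(colMeans(m), apply(m, 2, stats::sd))
}

#' Event-level feature extraction over an audio set
#'
#' Applies a frame-level feature extractor to every event and pools each
#' result with [pool_features()].
#'
#' @param audio_list List of waveforms.
#' @param extractor Function mapping a waveform to a `feature_matrix` (or
#'   matrix).
#' @return Events x (2 x dims) matrix.
#' @export
pooled_features <- function(audio_list, extractor) {
  t(vapply(audio_list, function(x) pool_features(extractor(x)),
           numeric(length(pool_features(extractor(audio_list[[1]]))))))
}

# --- Classification harness ------------------------------------------------

svm_decision_values <- function(model, x) {
  p <- stats::predict(model, x, decision.values = TRUE)
  dv <- attr(p, "decision.values")
  # orient so larger = more "target"
  if (grepl("^rest/", colnames(dv)[1])) -as.vector(dv) else as.vector(dv)
}

fit_one_vs_all <- function(x, y, cost, gamma) {
  lapply(levels(y), function(cl) {
    yb <- factor(ifelse(y == cl, "target", "rest"), levels = c("target", "rest"))
    e1071::svm(x, yb, type = "C-classification", kernel = "radial",
               cost = cost, gamma = gamma, scale = FALSE)
  })
}

predict_one_vs_all <- function(models, x, classes) {
  dv <- sapply(models, function(m) svm_decision_values(m, x))
  if (is.null(dim(dv))) dv <- matrix(dv, nrow = 1)
  factor(classes[max.col(dv)], levels = classes)
}

#' One-vs-all SVM classification with winner-take-all decoding
#'
#' Trains one radial-kernel support-vector machine per class against the
#' rest, decodes test events by the largest decision value, and reports
#' accuracy and the confusion matrix. The SVM penalty and kernel radius are
#' chosen by grid search with k-fold cross-validation on the training set.
#' Features are standardized with training-set statistics.
#'
#' @param train_x,train_y Training events x dims matrix and labels.
#' @param test_x,test_y Test set.
#' @param cost_grid Penalty values searched.
#' @param gamma_grid Kernel radii searched; default scales `1/dims` by
#'   (1/4, 1, 4).
#' @param n_folds Cross-validation folds for the grid search.
#' @param seed Seed for fold assignment.
#' @return List: `accuracy`, `confusion`, `best_cost`, `best_gamma`,
#'   `cv_table`, `predicted`.
#' @export
classify_events <- function(train_x, train_y, test_x, test_y,
                            cost_grid = c(1, 10, 100), gamma_grid = NULL,
                            n_folds = 5, seed = 1) {
  train_y <- droplevels(as.factor(train_y))
  test_y <- factor(test_y, levels = levels(train_y))
  if (nlevels(train_y) < 2) stop("training set must contain at least two classes")
  mu <- colMeans(train_x)
  sdv <- apply(train_x, 2, stats::sd)
  sdv[sdv == 0] <- 1
  zs <- function(m) sweep(sweep(m, 2, mu), 2, sdv, `/`)
  xtr <- zs(train_x)
  xte <- zs(test_x)
  if (is.null(gamma_grid)) gamma_grid <- 1 / ncol(xtr) * c(0.25, 1, 4)

  grid <- expand.grid(cost = cost_grid, gamma = gamma_grid)
  folds <- with_seed(seed, sample(rep(seq_len(n_folds), length.out = nrow(xtr))))
  grid$cv_accuracy <- NA_real_
  for (g in seq_len(nrow(grid))) {
    acc <- numeric(n_folds)
    for (k in seq_len(n_folds)) {
      tr <- folds != k
      if (nlevels(droplevels(train_y[tr])) < nlevels(train_y)) {
        acc[k] <- NA
        next
      }
      models <- fit_one_vs_all(xtr[tr, , drop = FALSE], train_y[tr],
                               grid$cost[g], grid$gamma[g])
      pred <- predict_one_vs_all(models, xtr[!tr, , drop = FALSE], levels(train_y))
      acc[k] <- mean(pred == train_y[!tr])
    }
    grid$cv_accuracy[g] <- mean(acc, na.rm = TRUE)
  }
  best <- which.max(grid$cv_accuracy)
  models <- fit_one_vs_all(xtr, train_y, grid$cost[best], grid$gamma[best])
  pred <- predict_one_vs_all(models, xte, levels(train_y))
  list(
    accuracy = mean(pred == test_y),
    confusion = table(truth = test_y, predicted = pred),
    best_cost = grid$cost[best],
    best_gamma = grid$gamma[best],
    cv_table = grid,
    predicted = pred
  )
}
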