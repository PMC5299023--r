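test_that("a single-pixel filter reproduces the spectrogram and zeros map to zeros", {
  set.seed(60)
  vals <- matrix(abs(rnorm(21 * 120)), 21, 120)
  fm <- filter_features(vals, list(matrix(1, 1, 1)))
  expect_identical(dim(fm$values), c(120L, 21L))
  expect_equal(fm$values, t(vals), tolerance = 1e-12)
  fm0 <- filter_features(matrix(0, 21, 80), list(matrix(rnorm(21 * 10), 21, 10)))
  expect_true(all(fm0$values == 0))
})

test_that("2D filtering is linear in the spectrogram", {
  set.seed(61)
  X <- matrix(rnorm(21 * 60), 21, 60)
  Y <- matrix(rnorm(21 * 60), 21, 60)
  filt <- list(Re(gabor_atom(62.5, 0.125, b_t = 32, b_s = 16)$patch))
  fX <- filter_features(X, filt)$values
  fY <- filter_features(Y, filt)$values
  fXY <- filter_features(3 * X - 2 * Y, filt)$values
  expect_equal(fXY, 3 * fX - 2 * fY, tolerance = 1e-10)
})

test_that("52 filters produce 1092 feature dimensions before subsampling", {
  set.seed(62)
  filters <- replicate(52, matrix(rnorm(21 * 10), 21, 10), simplify = FALSE)
  fm <- filter_features(matrix(abs(rnorm(21 * 60)), 21, 60), filters)
  expect_identical(ncol(fm$values), 1092L)
  expect_identical(nrow(unique(fm$labels)), 1092L)
})

test_that("temporal decimation mean-pools the feature frames", {
  vals <- matrix(abs(rnorm(21 * 100)), 21, 100)
  sp <- structure(list(values = vals, channel_centers = 1:21, frame_period_ms = 2),
                  class = "bark_spectrogram")
  fm1 <- filter_features(sp, list(matrix(1, 1, 1)))
  fm5 <- filter_features(sp, list(matrix(1, 1, 1)), decimate = 5)
  expect_identical(nrow(fm5$values), 20L)
  expect_identical(fm5$frame_period_ms, 10)
  expect_equal(fm5$values[1, ], colMeans(fm1$values[1:5, ]), tolerance = 1e-12)
})

test_that("Gabor spectral width matches a numerical solve of the 1/e point", {
  a <- gabor_atom(0, 0.125, b_t = 100, b_s = 16)
  w <- spectral_width(a, kind = "gabor")
  # independent oracle: solve hann_envelope(x, b_s) = 1/e numerically
  root <- uniroot(function(x) hann_envelope(x, 16) - exp(-1), c(0, 8))$root
  expect_equal(w, 2 * root, tolerance = 1e-6)
  expect_error(spectral_width(matrix(1, 3, 3), kind = "gabor"), "gabor_atom")
})

test_that("STRF spectral width follows the 90% contiguous-energy rule", {
  m1 <- matrix(0, 21, 10)
  m1[7, ] <- rnorm(10)
  expect_identical(spectral_width(m1, kind = "strf"), 1L)
  m2 <- matrix(0, 21, 10)
  m2[6:15, ] <- 1                      # uniform energy over 10 channels
  expect_identical(spectral_width(m2, kind = "strf"), 9L)
  expect_error(spectral_width(matrix(0, 21, 10), kind = "strf"), "zero filter")
})

test_that("channel subsampling keeps all channels for narrow filters and 4 for the widest", {
  expect_identical(subsample_channels(21, 4), 1:21)
  expect_identical(subsample_channels(21, 3.2), 1:21)
  kept <- subsample_channels(21, 21)
  expect_identical(kept, c(1L, 7L, 13L, 19L))
  expect_identical(subsample_channels(21, 21), kept) # deterministic
  expect_error(subsample_channels(21, 0), "positive")
})

test_that("subsampled feature dimensionality shrinks only for wide filters", {
  set.seed(63)
  filters <- replicate(5, matrix(rnorm(21 * 10), 21, 10), simplify = FALSE)
  fm <- filter_features(matrix(abs(rnorm(21 * 50)), 21, 50), filters)
  narrow <- subsample_features(fm, widths = rep(4, 5))
  expect_identical(ncol(narrow$values), 105L)   # all retained
  wide <- subsample_features(fm, widths = rep(21, 5))
  expect_identical(ncol(wide$values), 20L)      # 4 per filter
})

test_that("PCA decorrelation reaches full variance at full rank and halves under duplication", {
  set.seed(64)
  base <- matrix(rnorm(200 * 10), 200, 10)
  dup <- cbind(base, base)                       # duplicated columns
  indep <- matrix(rnorm(200 * 20), 200, 20)
  p_dup <- pca_decorrelate(dup, variance_target = 0.99)
  p_ind <- pca_decorrelate(indep, variance_target = 0.99)
  expect_lte(p_dup$n_components * 2, p_ind$n_components + 1)
  expect_true(all(diff(p_dup$cum_variance) >= -1e-12))
  expect_equal(max(p_dup$cum_variance), 1, tolerance = 1e-10)

  rank1 <- outer(rnorm(50), rnorm(8))
  expect_identical(pca_decorrelate(rank1, variance_target = 0.99)$n_components, 1L)

  tr <- matrix(rnorm(40), 20, 2)
  te <- matrix(rnorm(10), 5, 2)
  p <- pca_decorrelate(tr, te, variance_target = 1)
  expect_identical(dim(p$test), c(5L, p$n_components))
  expect_error(pca_decorrelate(tr, variance_target = 0), "variance_target")
})

test_that("MFCCs are 39-dimensional at a 10 ms frame period with sane deltas", {
  x <- fixture_noise(8000, seed = 65)
  fm <- mfcc_features(x, 16000)
  expect_identical(ncol(fm$values), 39L)
  expect_identical(fm$frame_period_ms, 10)
  expect_error(mfcc_features(numeric(100), 16000), "shorter")

  # constant-amplitude signal: deltas vanish away from the edges
  tone <- sin(2 * pi * 1000 * (0:15999) / 16000)
  ft <- mfcc_features(tone, 16000)$values
  interior <- 10:(nrow(ft) - 10)
  expect_lt(max(abs(ft[interior, 14:39])), 1e-6)

  # time reversal negates the interior delta trajectories of a chirp
  t <- (0:15999) / 16000
  chirp <- sin(2 * pi * (300 * t + 1200 * t^2))
  f_fwd <- mfcc_features(chirp, 16000)$values
  f_rev <- mfcc_features(rev(chirp), 16000)$values
  d_fwd <- f_fwd[interior, 14:26]
  # frame t of the reversed signal sees (approximately) original frame N+1-t
  d_rev_mapped <- f_rev[nrow(f_rev) + 1 - interior, 14:26]
  expect_gt(cor(as.vector(d_fwd), as.vector(-d_rev_mapped)), 0.9)
})

test_that("the synthetic corpus is reproducible and SNR mixing is exact", {
  spec <- corpus_spec(n_train = 2, n_test = 1, seed = 66)
  c1 <- synth_event_corpus(spec)
  c2 <- synth_event_corpus(spec)
  expect_identical(c1$train$audio, c2$train$audio)
  expect_identical(c1$train$labels, c2$train$labels)
  expect_identical(length(c1$train$audio), 12L)

  set.seed(67)
  sig <- sin(2 * pi * 440 * (0:7999) / 16000)
  noise <- rnorm(8000)
  for (snr in c(-5, 0, 10)) {
    mix <- mix_at_snr(sig, noise, snr)
    measured <- 10 * log10(mean(sig^2) / mean((mix - sig)^2))
    expect_lt(abs(measured - snr), 0.1)
  }
  expect_error(mix_at_snr(numeric(100), noise[1:100], 0), "zero-power")
})

test_that("classes are separable in Gabor feature space: between-class distance exceeds within-class", {
  spec <- corpus_spec(n_train = 3, n_test = 1, seed = 68, duration_s = 0.35)
  corpus <- synth_event_corpus(spec)
  extractor <- function(x) {
    filter_features(bark_spectrogram(x, 16000), default_bank, decimate = 5)
  }
  X <- pooled_features(corpus$train$audio, extractor)
  X <- scale(X)
  X[is.na(X)] <- 0
  y <- corpus$train$labels
  centroid <- apply(X, 2, function(col) tapply(col, y, mean))
  within <- mean(sapply(seq_len(nrow(X)), function(i) {
    sqrt(sum((X[i, ] - centroid[as.integer(y[i]), ])^2))
  }))
  dmat <- as.matrix(dist(centroid))
  between <- mean(dmat[upper.tri(dmat)])
  expect_gt(between, within)
})

test_that("the SVM harness is perfect on separable data and near chance on shuffled labels", {
  set.seed(70)
  centers <- matrix(c(0, 0, 6, 0, 0, 6, 6, 6), 4, 2, byrow = TRUE)
  make <- function(n) {
    y <- factor(rep(paste0("c", 1:4), each = n))
    x <- centers[rep(1:4, each = n), ] + matrix(rnorm(8 * n, sd = 0.3), 4 * n, 2)
    list(x = x, y = y)
  }
  tr <- make(12)
  te <- make(6)
  res <- classify_events(tr$x, tr$y, te$x, te$y, cost_grid = c(1, 10))
  expect_identical(res$accuracy, 1)
  expect_identical(dim(res$confusion), c(4L, 4L))

  sh <- classify_events(tr$x, sample(tr$y), te$x, te$y, cost_grid = 1)
  expect_lte(sh$accuracy, 0.6)
  expect_error(classify_events(tr$x, factor(rep("a", 48)), te$x, te$y),
               "two classes")
})
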