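#' Stimulus/response ensemble for reverse correlation
#'
#' Wraps an N x D matrix of spectro-temporal stimulus vectors (each row a
#' flattened channels x frames window, channel-fastest) and the length-N
#' response vector. Columns are mean-centered at construction, matching the
#' zero-mean stimulus assumption of the spike-triggered average.
#'
#' @param vectors N x D numeric matrix of stimulus windows.
#' @param responses Length-N numeric response values.
#' @param n_channels,n_frames Patch geometry encoded in the columns
#'   (D = n_channels * n_frames).
#' @return Object of class `stimulus_ensemble` with centered `S`, `r`,
#'   geometry, and the removed column means.
#' @export
stimulus_ensemble <- function(vectors, responses, n_channels = 21,
                              n_frames = ncol(vectors) / n_channels) {
  if (!is.matrix(vectors) || nrow(vectors) == 0) stop("vectors must be a non-empty matrix")
  if (length(responses) != nrow(vectors)) stop("responses must have one value per stimulus row")
  if (ncol(vectors) != n_channels * n_frames) {
    stop("ncol(vectors) must equal n_channels * n_frames")
  }
  mu <- colMeans(vectors)
  structure(
    list(
      S = sweep(vectors, 2, mu),
      r = as.numeric(responses),
      n_channels = as.integer(n_channels),
      n_frames = as.integer(n_frames),
      col_means = mu
    ),
    class = "stimulus_ensemble"
  )
}

#' @export
print.stimulus_ensemble <- function(x, ...) {
  cat(sprintf("Stimulus ensemble: N = %d samples, D = %d (%d channels x %d frames)\n",
              nrow(x$S), ncol(x$S), x$n_channels, x$n_frames))
  invisible(x)
}

# Sliding-window design matrix: row n is the flattened window of frames
# n .. n+n_frames-1 (channel-fastest), i.e. the 100 ms of stimulus ending at
# the response bin it is paired with.
build_design <- function(values, n_frames) {
  nc <- nrow(values)
  nt <- ncol(values)
  if (nt < n_frames) stop("spectrogram shorter than one analysis window")
  n <- nt - n_frames + 1L
  S <- matrix(0, n, nc * n_frames)
  for (k in seq_len(n_frames)) {
    S[, ((k - 1L) * nc + 1L):(k * nc)] <- t(values[, k:(k + n - 1L), drop = FALSE])
  }
  S
}

#' Assemble an ensemble from a spectrogram and a binned response
#'
#' Pairs each response bin with the `n_frames`-frame stimulus window ending
#' at that bin (the 100 ms preceding the response at the default geometry).
#'
#' @param spectrogram A [bark_spectrogram()] (or a channels x frames matrix).
#' @param response Either a [lnp_respond()] spike response (repetitions are
#'   averaged), a length `T` per-frame vector (the first `n_frames - 1`
#'   frames are dropped), or a length `T - n_frames + 1` aligned vector.
#' @param n_frames Window length in frames (default 50 = 100 ms at 2 ms).
#' @return A [stimulus_ensemble()].
#' @export
make_ensemble <- function(spectrogram, response, n_frames = 50) {
  values <- if (inherits(spectrogram, "bark_spectrogram")) spectrogram$values else spectrogram
  S <- build_design(values, n_frames)
  n <- nrow(S)
  if (inherits(response, "spike_response")) {
    r <- colMeans(response$counts)
    if (length(r) != n) stop("spike response length does not match the stimulus windows")
  } else if (length(response) == ncol(values)) {
    r <- response[n_frames:ncol(values)]
  } else if (length(response) == n) {
    r <- response
  } else {
    stop("response length matches neither the frame count nor the window count")
  }
  stimulus_ensemble(S, r, n_channels = nrow(values), n_frames = n_frames)
}

#' Estimator configuration
#'
#' @param lambda_grid Ridge penalties to search; `NULL` for the default
#'   logarithmic grid `10^(-4..4)` times the mean Gram diagonal.
#' @param n_folds Cross-validation folds (contiguous blocks, so overlapping
#'   stimulus windows do not leak between train and test).
#' @param n_boot Bootstrap replicates for significance masking (0 disables).
#' @param boot_fraction Fraction of samples drawn (without replacement) per
#'   replicate.
#' @param alpha Two-sided significance level of the coefficient test.
#' @param min_correlation Inclusion threshold on the cross-validated
#'   prediction correlation.
#' @param seed Seed for the bootstrap resampling.
#' @return Object of class `ridge_config`.
#' @export
ridge_config <- function(lambda_grid = NULL, n_folds = 5, n_boot = 1000,
                         boot_fraction = 0.2, alpha = 0.05,
                         min_correlation = 0.25, seed = NULL) {
  if (!is.null(lambda_grid) && any(lambda_grid < 0)) stop("lambda values must be >= 0")
  if (boot_fraction <= 0 || boot_fraction > 1) stop("boot_fraction must be in (0, 1]")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  structure(
    list(lambda_grid = lambda_grid, n_folds = as.integer(n_folds),
         n_boot = as.integer(n_boot), boot_fraction = boot_fraction,
         alpha = alpha, min_correlation = min_correlation, seed = seed),
    class = "ridge_config"
  )
}

default_lambda_grid <- function(ensemble) {
  g <- sum(ensemble$S^2) / (nrow(ensemble$S) * ncol(ensemble$S))
  g * 10^seq(-4, 4)
}

#' Spike-triggered average
#'
#' The N-sample average `(1/N) sum_n s_n r_n`; the proportionality of the
#' reverse-correlation definition is fixed to equality with the mean.
#'
#' @param ensemble A [stimulus_ensemble()].
#' @return Length-D coefficient vector.
#' @export
sta <- function(ensemble) {
  as.vector(crossprod(ensemble$S, ensemble$r)) / nrow(ensemble$S)
}

#' Ridge-regularized (whitened) spike-triggered average
#'
#' Solves `(S'S/N + lambda I) h = S'r / N`. For `lambda = 0` with a
#' rank-deficient Gram matrix the pseudo-inverse is used with a warning.
#' Large `lambda` shrinks the solution toward the direction of the plain
#' spike-triggered average. The dual (kernel) form is used automatically
#' when N < D.
#'
#' @param ensemble A [stimulus_ensemble()].
#' @param lambda Ridge penalty (>= 0).
#' @return Length-D coefficient vector.
#' @export
ridge_sta <- function(ensemble, lambda) {
  stop_if_not_scalar_number(lambda, "lambda")
  if (lambda < 0) stop("lambda must be >= 0")
  S <- ensemble$S
  n <- nrow(S)
  d <- ncol(S)
  if (n >= d) {
    G <- crossprod(S) / n
    b <- as.vector(crossprod(S, ensemble$r)) / n
    if (lambda == 0) {
      e <- eigen(G, symmetric = TRUE)
      tol <- max(e$values) * d * .Machine$double.eps
      pos <- e$values > tol
      if (!all(pos)) warning("singular Gram matrix at lambda = 0: using pseudo-inverse")
      as.vector(e$vectors[, pos, drop = FALSE] %*%
                  ((crossprod(e$vectors[, pos, drop = FALSE], b)) / e$values[pos]))
    } else {
      as.vector(solve(G + diag(lambda, d), b))
    }
  } else {
    K <- tcrossprod(S)
    if (lambda == 0) {
      e <- eigen(K, symmetric = TRUE)
      tol <- max(e$values, 0) * n * .Machine$double.eps
      pos <- e$values > tol
      warning("underdetermined system at lambda = 0: minimum-norm pseudo-inverse solution")
      alpha <- e$vectors[, pos, drop = FALSE] %*%
        (crossprod(e$vectors[, pos, drop = FALSE], ensemble$r) / e$values[pos])
      as.vector(crossprod(S, alpha))
    } else {
      alpha <- solve(K + diag(n * lambda, n), ensemble$r)
      as.vector(crossprod(S, alpha))
    }
  }
}

# Cross-validation machinery shared across responses on the same stimulus:
# contiguous fold blocks, per-fold train Gram eigendecompositions, plus the
# full-data eigendecomposition. Cost is independent of how many neurons'
# responses are subsequently analyzed.
cv_machine <- function(S, n_folds = 5) {
  n <- nrow(S)
  fold_id <- rep(seq_len(n_folds), each = ceiling(n / n_folds))[seq_len(n)]
  Gk <- vector("list", n_folds)
  idx <- vector("list", n_folds)
  for (k in seq_len(n_folds)) {
    idx[[k]] <- which(fold_id == k)
    Gk[[k]] <- crossprod(S[idx[[k]], , drop = FALSE])
  }
  G_tot <- Reduce(`+`, Gk)
  eig <- vector("list", n_folds)
  for (k in seq_len(n_folds)) {
    n_train <- n - length(idx[[k]])
    eig[[k]] <- eigen((G_tot - Gk[[k]]) / n_train, symmetric = TRUE)
  }
  eig_full <- eigen(G_tot / n, symmetric = TRUE)
  list(n = n, n_folds = n_folds, idx = idx, eig = eig, eig_full = eig_full)
}

ridge_solve_eig <- function(eig, b, lambda) {
  as.vector(eig$vectors %*% (crossprod(eig$vectors, b) / (eig$values + lambda)))
}

#' Select the ridge penalty by cross-validated prediction correlation
#'
#' K-fold cross-validation over a penalty grid: for each fold and penalty
#' the estimate is fit on the training folds and the Pearson correlation
#' between predicted (`s . h`) and observed responses on the held-out fold
#' is recorded. The penalty with the highest mean correlation wins; exact
#' ties break toward the larger (more regularized) penalty. Folds are
#' contiguous blocks. Folds with constant held-out responses are skipped
#' with a warning.
#'
#' @param ensemble A [stimulus_ensemble()].
#' @param config A [ridge_config()].
#' @param machine Optional precomputed [cv_machine()] for `ensemble$S`.
#' @return List with `lambda` (selected), `cv_correlation` (its mean
#'   held-out correlation), and `table` (per-penalty means).
#' @export
select_lambda <- function(ensemble, config = ridge_config(), machine = NULL) {
  grid <- config$lambda_grid
  if (is.null(grid)) grid <- default_lambda_grid(ensemble)
  if (length(grid) == 0) stop("empty lambda grid")
  grid <- sort(unique(grid))
  if (is.null(machine)) machine <- cv_machine(ensemble$S, config$n_folds)
  S <- ensemble$S
  r <- ensemble$r
  cors <- matrix(NA_real_, machine$n_folds, length(grid))
  skipped <- integer(0)
  for (k in seq_len(machine$n_folds)) {
    test <- machine$idx[[k]]
    if (stats::sd(r[test]) == 0) {
      skipped <- c(skipped, k)
      next
    }
    b <- as.vector(crossprod(S[-test, , drop = FALSE], r[-test])) / (machine$n - length(test))
    for (g in seq_along(grid)) {
      h <- ridge_solve_eig(machine$eig[[k]], b, grid[g])
      pred <- as.vector(S[test, , drop = FALSE] %*% h)
      if (stats::sd(pred) == 0) next
      cors[k, g] <- stats::cor(pred, r[test])
    }
  }
  if (length(skipped) > 0) {
    warning(sprintf("%d fold(s) had constant held-out responses and were skipped: %s",
                    length(skipped), paste(skipped, collapse = ", ")))
  }
  mean_cor <- colMeans(cors, na.rm = TRUE)
  mean_cor[is.nan(mean_cor)] <- -Inf
  best <- max(mean_cor)
  lambda_star <- max(grid[mean_cor == best]) # tie-break toward stronger shrinkage
  list(lambda = lambda_star,
       cv_correlation = best,
       table = data.frame(lambda = grid, cv_correlation = mean_cor))
}

new_strf <- function(patch, mask, lambda, cv_correlation = NA_real_,
                     included = NA) {
  structure(
    list(patch = patch, mask = mask, lambda = lambda,
         cv_correlation = cv_correlation, included = included),
    class = "strf"
  )
}

#' @export
print.strf <- function(x, ...) {
  cat(sprintf(
    "STRF: %d x %d, lambda = %.4g, cv correlation = %.3f, %.1f%% coefficients retained\n",
    nrow(x$patch), ncol(x$patch), x$lambda, x$cv_correlation,
    100 * mean(x$mask)))
  invisible(x)
}

#' @export
plot.strf <- function(x, ...) {
  lim <- max(abs(x$patch))
  graphics::image(t(x$patch), zlim = c(-lim, lim),
                  col = grDevices::hcl.colors(64, "Blue-Red 3"),
                  xlab = "time (window fraction)", ylab = "channel fraction",
                  main = "STRF", useRaster = TRUE, ...)
  invisible(x)
}

#' Bootstrap significance masking of STRF coefficients
#'
#' Repeatedly re-estimates the ridge STA from random 20% subsamples of the
#' response bins (drawn without replacement), then keeps only coefficients
#' whose subsample mean differs significantly from zero in a two-sided
#' z-test. The subsample spread is rescaled by `sqrt(f / (1 - f))` to
#' estimate the full-sample sampling deviation before testing, which keeps
#' the test calibrated (null keep-rate approximately `alpha`). Masked
#' coefficients are set to exactly 0; the retained values come from the
#' full-data estimate at `lambda`.
#'
#' @param ensemble A [stimulus_ensemble()].
#' @param lambda Ridge penalty (typically the cross-validated choice).
#' @param config A [ridge_config()]; uses `n_boot`, `boot_fraction`,
#'   `alpha`, `seed`.
#' @return An `strf` object (patch, logical mask, lambda).
#' @export
bootstrap_mask <- function(ensemble, lambda, config = ridge_config()) {
  S <- ensemble$S
  r <- ensemble$r
  n <- nrow(S)
  d <- ncol(S)
  f <- config$boot_fraction
  nsub <- max(2L, round(f * n))
  h_full <- ridge_sta(ensemble, lambda)

  H <- matrix(0, config$n_boot, d)
  with_seed(config$seed, {
    for (b in seq_len(config$n_boot)) {
      take <- sample.int(n, nsub)
      Ss <- S[take, , drop = FALSE]
      rs <- r[take]
      if (nsub < d) {
        alpha_v <- solve(tcrossprod(Ss) + diag(nsub * lambda, nsub), rs)
        H[b, ] <- as.vector(crossprod(Ss, alpha_v))
      } else {
        H[b, ] <- as.vector(solve(crossprod(Ss) / nsub + diag(lambda, d),
                                  crossprod(Ss, rs) / nsub))
      }
    }
  })
  mu <- colMeans(H)
  sdv <- apply(H, 2, stats::sd)
  sd_full <- sdv * sqrt(f / (1 - f))
  crit <- stats::qnorm(1 - config$alpha / 2)
  keep <- ifelse(sd_full == 0, mu != 0, abs(mu / sd_full) > crit)

  patch <- unvec_patch(h_full, ensemble$n_channels, ensemble$n_frames)
  mask <- unvec_patch(keep, ensemble$n_channels, ensemble$n_frames)
  patch[!mask] <- 0
  new_strf(patch, mask, lambda)
}

#' Remove insular pixels from an STRF
#'
#' Any non-zero coefficient whose existing 8-connected neighbors (fewer at
#' edges and corners) are all zero is regarded as an isolated artifact and
#' set to zero, in a single pass. Idempotent.
#'
#' @param strf An `strf` object or a numeric matrix.
#' @return Same type as the input, cleaned.
#' @export
remove_insular_pixels <- function(strf) {
  m <- if (inherits(strf, "strf")) strf$patch else strf
  nr <- nrow(m)
  nc <- ncol(m)
  pad <- matrix(0, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- m
  nz <- pad != 0
  neighbor_nz <- matrix(0L, nr, nc)
  for (dr in -1:1) {
    for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      neighbor_nz <- neighbor_nz + nz[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
    }
  }
  cleaned <- m
  cleaned[m != 0 & neighbor_nz == 0L] <- 0
  if (inherits(strf, "strf")) {
    strf$patch <- cleaned
    strf$mask <- strf$mask & cleaned != 0
    strf
  } else {
    cleaned
  }
}

#' Predict responses from an STRF
#'
#' Linear prediction `r_hat_n = s_n . h` for every stimulus window.
#'
#' @param strf An `strf` object (or a patch matrix).
#' @param ensemble A [stimulus_ensemble()] with matching geometry.
#' @return Length-N numeric vector.
#' @export
predict_response <- function(strf, ensemble) {
  h <- if (inherits(strf, "strf")) vec_patch(strf$patch) else as.vector(strf)
  if (length(h) != ncol(ensemble$S)) stop("STRF and ensemble shapes are incompatible")
  as.vector(ensemble$S %*% h)
}

#' Full STRF estimation pipeline
#'
#' Cross-validated penalty selection, full-data ridge STA, bootstrap
#' significance masking, and insular-pixel cleanup. The returned STRF
#' carries the selected penalty, the held-out prediction correlation, and
#' whether it passes the inclusion threshold (`cv_correlation >=
#' min_correlation`).
#'
#' @param ensemble A [stimulus_ensemble()].
#' @param config A [ridge_config()]. Set `n_boot = 0` to skip masking.
#' @param machine Optional precomputed [cv_machine()].
#' @return An `strf` object.
#' @export
estimate_strf <- function(ensemble, config = ridge_config(), machine = NULL) {
  sel <- select_lambda(ensemble, config, machine)
  if (config$n_boot > 0) {
    out <- bootstrap_mask(ensemble, sel$lambda, config)
  } else {
    patch <- unvec_patch(ridge_sta(ensemble, sel$lambda),
                         ensemble$n_channels, ensemble$n_frames)
    out <- new_strf(patch, matrix(TRUE, ensemble$n_channels, ensemble$n_frames),
                    sel$lambda)
  }
  out <- remove_insular_pixels(out)
  out$cv_correlation <- sel$cv_correlation
  out$included <- is.finite(sel$cv_correlation) &&
    sel$cv_correlation >= config$min_correlation
  out
}
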