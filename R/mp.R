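# Shift a patch by (dt frames, ds channels), zero-filling; callers restrict
# shifts so the support stays inside the patch, making translates exact.
shift_patch <- function(m, dt = 0, ds = 0) {
  out <- matrix(0, nrow(m), ncol(m))
  src_r <- seq_len(nrow(m))
  src_c <- seq_len(ncol(m))
  dst_r <- src_r + ds
  dst_c <- src_c + dt
  ok_r <- dst_r >= 1 & dst_r <= nrow(m)
  ok_c <- dst_c >= 1 & dst_c <= ncol(m)
  out[dst_r[ok_r], dst_c[ok_c]] <- m[src_r[ok_r], src_c[ok_c]]
  out
}

#' Expand a Gabor bank into a shifted matching-pursuit dictionary
#'
#' Each real dictionary atom of the bank is translated along time (and
#' optionally along frequency) to every position at which its envelope
#' support still fits inside the patch, so every dictionary element is an
#' exact unit-norm translate. Full-height/full-width atoms admit only the
#' zero shift.
#'
#' @param bank A [build_gabor_bank()] object.
#' @param spectral_shifts Also translate along the channel axis
#'   (default `FALSE`: full-height atoms, as for MP on 21-band STRFs).
#' @return A list with `mat` (D x M matrix of flattened shifted atoms) and
#'   `info` (per-column metadata: atom, part, shifts, modulations).
#' @export
expand_dictionary <- function(bank, spectral_shifts = FALSE) {
  nc <- bank$config$n_channels
  nf <- bank$config$n_frames
  cols <- list()
  info <- list()
  for (j in seq_len(ncol(bank$dict))) {
    a <- matrix(bank$dict[, j], nc, nf)
    nz_c <- which(colSums(abs(a)) > 0)
    nz_r <- which(rowSums(abs(a)) > 0)
    dts <- seq.int(1L - min(nz_c), nf - max(nz_c))
    dss <- if (spectral_shifts) seq.int(1L - min(nz_r), nc - max(nz_r)) else 0L
    for (ds in dss) {
      for (dt in dts) {
        cols[[length(cols) + 1L]] <- as.vector(shift_patch(a, dt, ds))
        info[[length(info) + 1L]] <- c(j, dt, ds)
      }
    }
  }
  meta <- do.call(rbind, info)
  di <- bank$dict_info[meta[, 1], c("atom_id", "part", "omega_t", "omega_s")]
  out_info <- data.frame(
    column = seq_len(nrow(meta)),
    dict_col = meta[, 1],
    atom_id = di$atom_id, part = di$part,
    omega_t = di$omega_t, omega_s = di$omega_s,
    dt = meta[, 2], ds = meta[, 3],
    row.names = NULL
  )
  list(mat = do.call(cbind, cols), info = out_info)
}

#' Greedy two-dimensional matching pursuit over a Gabor dictionary
#'
#' At each iteration the (atom, part, shift) whose inner product with the
#' current residual is largest in magnitude is selected; its projection
#' (weight x shifted atom) is subtracted from the residual and added to the
#' reconstruction. Iterations stop once the Pearson correlation between the
#' target and the cumulative reconstruction reaches `theta`, or after
#' `max_iter` iterations (flagged via `reached_theta`).
#'
#' @param target Real channels x frames matrix (e.g. an STRF patch); must be
#'   non-zero and match the bank geometry.
#' @param bank A [build_gabor_bank()] object.
#' @param theta Termination correlation in (0, 1].
#' @param max_iter Iteration cap.
#' @param spectral_shifts Passed to [expand_dictionary()].
#' @param expanded Optional precomputed [expand_dictionary()] result (reused
#'   across many targets).
#' @return Object of class `mp_decomposition`: `entries` (one row per
#'   iteration: atom, part, shifts, modulation frequencies, weight `gamma`,
#'   running correlation), `residual`, `reconstruction`, `corr_track`,
#'   `n_iter`, `kappa`, `reached_theta`.
#' @export
mp_decompose <- function(target, bank, theta = 0.8, max_iter = 50,
                         spectral_shifts = FALSE, expanded = NULL) {
  if (!is.matrix(target) || !is.numeric(target)) stop("target must be a numeric matrix")
  nc <- bank$config$n_channels
  nf <- bank$config$n_frames
  if (!all(dim(target) == c(nc, nf))) {
    stop(sprintf("target must be %d x %d to match the bank", nc, nf))
  }
  if (all(target == 0)) stop("target is all zero; nothing to decompose")
  if (!is.numeric(theta) || length(theta) != 1 || theta <= 0 || theta > 1) {
    stop("theta must lie in (0, 1]")
  }
  if (is.null(expanded)) expanded <- expand_dictionary(bank, spectral_shifts)
  D <- expanded$mat
  info <- expanded$info

  tv <- as.vector(target)
  res <- tv
  recon <- numeric(length(tv))
  entries <- vector("list", max_iter)
  corr_track <- numeric(0)
  reached <- FALSE

  for (i in seq_len(max_iter)) {
    ip <- as.vector(crossprod(D, res))
    j <- which.max(abs(ip))
    gamma <- ip[j]
    if (gamma == 0) break # residual orthogonal to the whole dictionary
    res <- res - gamma * D[, j]
    recon <- recon + gamma * D[, j]
    corr <- suppressWarnings(stats::cor(tv, recon))
    if (is.na(corr)) corr <- 0
    corr_track <- c(corr_track, corr)
    entries[[i]] <- data.frame(
      iter = i,
      column = j,
      dict_col = info$dict_col[j],
      atom_id = info$atom_id[j], part = info$part[j],
      omega_t = info$omega_t[j], omega_s = info$omega_s[j],
      dt = info$dt[j], ds = info$ds[j],
      gamma = gamma, correlation = corr
    )
    if (corr >= theta) {
      reached <- TRUE
      break
    }
  }
  entries <- do.call(rbind, entries[!vapply(entries, is.null, logical(1))])
  if (is.null(entries) || nrow(entries) == 0) {
    stop("matching pursuit selected no atoms (dictionary orthogonal to target)")
  }
  dec <- structure(
    list(
      entries = entries,
      residual = matrix(res, nc, nf),
      reconstruction = matrix(recon, nc, nf),
      corr_track = corr_track,
      n_iter = nrow(entries),
      theta = theta,
      reached_theta = reached,
      frame_period_ms = bank$config$frame_period_ms,
      channel_spacing = bank$config$channel_spacing
    ),
    class = "mp_decomposition"
  )
  dec$kappa <- kappa_decomposition(dec)
  dec
}

#' @export
print.mp_decomposition <- function(x, ...) {
  cat(sprintf(
    "MP decomposition: %d atoms, final correlation %.4f (theta = %g%s), kappa = %.4f\n",
    x$n_iter, utils::tail(x$corr_track, 1), x$theta,
    if (x$reached_theta) "" else ", NOT reached", x$kappa))
  invisible(x)
}

#' Reconstruct a patch from a matching-pursuit decomposition
#'
#' Sums `gamma` x shifted atom over the decomposition entries using the bank
#' the decomposition references.
#'
#' @param dec An [mp_decompose()] result (its `entries` may also be an edited
#'   subset).
#' @param bank The bank the entries reference.
#' @return Real channels x frames matrix.
#' @export
reconstruct <- function(dec, bank) {
  nc <- bank$config$n_channels
  nf <- bank$config$n_frames
  out <- matrix(0, nc, nf)
  e <- dec$entries
  if (is.null(e) || nrow(e) == 0) return(out)
  if (any(e$dict_col > ncol(bank$dict)) || any(e$dict_col < 1)) {
    stop("decomposition references atoms unknown to this bank")
  }
  for (i in seq_len(nrow(e))) {
    a <- matrix(bank$dict[, e$dict_col[i]], nc, nf)
    out <- out + e$gamma[i] * shift_patch(a, e$dt[i], e$ds[i])
  }
  out
}

#' Diagonality index of a modulation vector
#'
#' L1 norm of the L2-normalized modulation vector
#' `(|w_t| + |w_s|) / sqrt(w_t^2 + w_s^2)`: 1 for purely temporal or purely
#' spectral modulations, sqrt(2) for fully diagonal ones (|w_t| = |w_s|).
#' Scale-invariant, so any consistent pair of units may be used. A zero
#' vector (DC atom) has no orientation; by policy it is assigned 1 with a
#' warning.
#'
#' @param omega_t,omega_s Temporal and spectral modulation frequencies.
#' @return Value in \[1, sqrt(2)\].
#' @export
kappa_atom <- function(omega_t, omega_s) {
  stop_if_not_scalar_number(omega_t, "omega_t")
  stop_if_not_scalar_number(omega_s, "omega_s")
  n2 <- sqrt(omega_t^2 + omega_s^2)
  if (n2 == 0) {
    warning("zero modulation vector (DC atom): kappa defined as 1 by policy")
    return(1)
  }
  (abs(omega_t) + abs(omega_s)) / n2
}

# Per-entry kappa values of a decomposition, on modulations normalized to
# cycles per sample (omega_t * frame period, omega_s * channel spacing).
entry_kappas <- function(dec) {
  ot <- abs(dec$entries$omega_t) * dec$frame_period_ms / 1000
  os <- abs(dec$entries$omega_s) * dec$channel_spacing
  n2 <- sqrt(ot^2 + os^2)
  ifelse(n2 == 0, 1, (ot + os) / n2)
}

#' Diagonality of a matching-pursuit decomposition
#'
#' Arithmetic mean of the per-atom diagonality indices over all iterations,
#' with modulation frequencies expressed in cycles per sample so the two
#' axes are commensurate. DC atoms contribute 1.
#'
#' @param dec An [mp_decompose()] result.
#' @return Mean kappa in \[1, sqrt(2)\].
#' @export
kappa_decomposition <- function(dec) {
  if (is.null(dec$entries) || nrow(dec$entries) == 0) {
    stop("empty decomposition: kappa undefined")
  }
  mean(entry_kappas(dec))
}

#' Atom importance over a set of decompositions
#'
#' For each real dictionary atom, the sum of absolute matching-pursuit
#' weights it received over all iterations of all decompositions.
#'
#' @param decs List of [mp_decompose()] results referencing `bank`.
#' @param bank The shared [build_gabor_bank()].
#' @return Data frame with one row per real dictionary atom: `atom_id`,
#'   `part`, `omega_t`, `omega_s`, `eta` (zero for never-selected atoms),
#'   and `n_strfs` as an attribute.
#' @export
atom_importance <- function(decs, bank) {
  out <- bank$dict_info[, c("column", "atom_id", "part", "omega_t", "omega_s")]
  out$eta <- 0
  for (dec in decs) {
    e <- dec$entries
    for (i in seq_len(nrow(e))) {
      k <- e$dict_col[i]
      out$eta[k] <- out$eta[k] + abs(e$gamma[i])
    }
  }
  attr(out, "n_strfs") <- length(decs)
  out
}

#' Histogram of atoms-per-decomposition
#'
#' @param decs List of [mp_decompose()] results.
#' @return Named integer vector: counts of decompositions by number of
#'   entries (empty for an empty list).
#' @export
atom_count_histogram <- function(decs) {
  if (length(decs) == 0) return(table(integer(0)))
  table(vapply(decs, function(d) d$n_iter, integer(1)))
}

#' Mean diagonality as a function of the reconstruction threshold
#'
#' Decomposes each target once at the largest threshold and, exploiting the
#' greedy determinism of matching pursuit (lower-threshold runs are prefixes
#' of higher-threshold runs), reads off the mean kappa over targets at every
#' threshold in `theta_grid`.
#'
#' @param targets List of channels x frames matrices.
#' @param bank A [build_gabor_bank()].
#' @param theta_grid Increasing thresholds within (0, 1).
#' @param max_iter Iteration cap per decomposition.
#' @param spectral_shifts Passed to [expand_dictionary()].
#' @return Data frame with columns `theta` and `kappa` (mean over targets).
#' @export
kappa_vs_theta <- function(targets, bank, theta_grid, max_iter = 50,
                           spectral_shifts = FALSE) {
  if (is.unsorted(theta_grid, strictly = TRUE) ||
      any(theta_grid <= 0) || any(theta_grid >= 1)) {
    stop("theta_grid must be strictly increasing within (0, 1)")
  }
  expanded <- expand_dictionary(bank, spectral_shifts)
  kap <- matrix(NA_real_, length(targets), length(theta_grid))
  for (k in seq_along(targets)) {
    dec <- mp_decompose(targets[[k]], bank, theta = max(theta_grid),
                        max_iter = max_iter, expanded = expanded)
    kv <- entry_kappas(dec)
    for (g in seq_along(theta_grid)) {
      n <- match(TRUE, dec$corr_track >= theta_grid[g])
      if (is.na(n)) n <- dec$n_iter
      kap[k, g] <- mean(kv[seq_len(n)])
    }
  }
  data.frame(theta = theta_grid, kappa = colMeans(kap))
}
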