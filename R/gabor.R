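#' Hann envelope
#'
#' Center-peaked Hann window of total support `b`:
#' `0.5 + 0.5 cos(2 pi x / b)` for `|x| < b/2`, zero elsewhere. Its maximum
#' is 1 at `x = 0` and its half-height width is `b/2`.
#'
#' @param x Axis coordinate(s), same units as `b`.
#' @param b Envelope support width (> 0).
#' @return Envelope values in \[0, 1\].
#' @export
hann_envelope <- function(x, b) {
  stop_if_not_scalar_number(b, "b")
  if (b <= 0) stop("envelope width b must be positive")
  ifelse(abs(x) < b / 2, 0.5 + 0.5 * cos(2 * pi * x / b), 0)
}

#' Complex spectro-temporal Gabor atom
#'
#' Separable product of complex sinusoidal carriers and Hann envelopes along
#' the time and frequency axes of a channels x frames patch:
#' `g(t, f) = exp(2 pi i w_t t) exp(2 pi i w_s f) h(t; b_t) h(f; b_s)`.
#' The patch is centered: the envelope peak sits mid-patch and the patch is
#' exactly zero outside the envelope support.
#'
#' @param omega_t Temporal modulation frequency in Hz.
#' @param omega_s Spectral modulation frequency in cycles/Bark.
#' @param b_t Temporal envelope support in ms.
#' @param b_s Spectral envelope support in Bark.
#' @param n_channels,n_frames Patch shape (default 21 x 50).
#' @param frame_period_ms Temporal sample spacing (ms).
#' @param channel_spacing Spectral sample spacing (Bark).
#' @param allow_truncation If `FALSE` (default), an envelope wider than the
#'   patch is an error.
#' @return Object of class `gabor_atom` with the complex `patch` and its
#'   parameters.
#' @export
gabor_atom <- function(omega_t, omega_s, b_t, b_s,
                       n_channels = 21, n_frames = 50,
                       frame_period_ms = 2, channel_spacing = 1,
                       allow_truncation = FALSE) {
  for (nm in c("omega_t", "omega_s", "b_t", "b_s")) {
    stop_if_not_scalar_number(get(nm), nm)
  }
  if (b_t <= 0 || b_s <= 0) stop("envelope widths must be positive")
  if (!allow_truncation &&
      (b_t > n_frames * frame_period_ms || b_s > n_channels * channel_spacing)) {
    stop("envelope wider than the patch; set allow_truncation = TRUE to clip")
  }

  t_ms <- (seq_len(n_frames) - (n_frames + 1) / 2) * frame_period_ms
  f_bark <- (seq_len(n_channels) - (n_channels + 1) / 2) * channel_spacing
  env_t <- hann_envelope(t_ms, b_t)
  env_s <- hann_envelope(f_bark, b_s)
  car_t <- exp(2i * pi * omega_t * t_ms / 1000)
  car_s <- exp(2i * pi * omega_s * f_bark)

  patch <- outer(env_s * car_s, env_t * car_t)
  structure(
    list(
      patch = patch,
      omega_t = omega_t, omega_s = omega_s, b_t = b_t, b_s = b_s,
      n_channels = n_channels, n_frames = n_frames,
      frame_period_ms = frame_period_ms, channel_spacing = channel_spacing
    ),
    class = "gabor_atom"
  )
}

#' @export
print.gabor_atom <- function(x, ...) {
  cat(sprintf(
    "Gabor atom: omega_t = %g Hz, omega_s = %g cyc/Bark, b_t = %g ms, b_s = %g Bark (%d x %d)\n",
    x$omega_t, x$omega_s, x$b_t, x$b_s, x$n_channels, x$n_frames))
  invisible(x)
}

# Realize one real-valued dictionary atom from a complex Gabor: take the
# requested part, remove its mean *within the envelope support* (zero-sum
# filters; outside-support zeros are untouched), normalize to unit Euclidean
# norm. Returns NULL when the part is numerically zero (e.g. the imaginary
# part of the DC atom).
realize_part <- function(atom, part = c("real", "imag"), tol = 1e-12) {
  part <- match.arg(part)
  m <- if (part == "real") Re(atom$patch) else Im(atom$patch)
  support <- Mod(atom$patch) > 0
  if (sqrt(sum(m^2)) < tol) return(NULL)
  m[support] <- m[support] - mean(m[support])
  nrm <- sqrt(sum(m^2))
  if (nrm < tol) return(NULL)
  m / nrm
}

# Constant-Q envelope width for a carrier frequency: `periods` full carrier
# cycles within the half-height width b/2, capped at the patch extent.
# omega in cycles per axis unit; returns width in axis units.
constant_q_width <- function(omega, periods, cap) {
  if (omega == 0) return(cap)
  min(2 * periods / omega, cap)
}

# Modulation grid along one axis: descend from the maximum by 1/spacing_factor
# until the constant-Q envelope first hits the patch cap (that entry is kept,
# then the descent stops), and always include 0.
modulation_grid <- function(omega_max, periods, cap, spacing_factor) {
  grid <- numeric(0)
  om <- omega_max
  while (om > 0) {
    grid <- c(grid, om)
    if (2 * periods / om >= cap) break
    om <- om / spacing_factor
  }
  sort(unique(c(0, grid)))
}

#' Build the Gabor filter bank
#'
#' Constructs a bank of complex Gabor atoms whose modulation frequencies
#' uniformly cover the modulation plane up to `max_temporal_mod` Hz and
#' `max_spectral_mod` cycles/Bark (each half the corresponding Nyquist rate
#' of the default 2 ms / 1 Bark resolution). The grid is geometric with ratio
#' `spacing_factor`, descending from the maxima until the constant-Q envelope
#' (one carrier period within the half-height width by default) is capped by
#' the 21-band x 100 ms patch; purely temporal, purely spectral and DC
#' (envelope-only) atoms are always included, and mixed atoms come in both
#' diagonal orientations (negative spectral modulation). Each complex atom is
#' additionally realized as separate real and imaginary real-valued dictionary
#' atoms, zero-sum within their support and normalized to unit norm.
#'
#' @param max_temporal_mod Largest temporal modulation (Hz).
#' @param max_spectral_mod Largest spectral modulation (cycles/Bark).
#' @param spacing_factor Geometric ratio between adjacent modulation grid
#'   points (default 2, one octave).
#' @param periods Carrier periods within the envelope half-height width
#'   (constant-Q parameter).
#' @param n_channels,n_frames,frame_period_ms,channel_spacing Patch geometry.
#' @return Object of class `gabor_bank`: `atoms` (list of [gabor_atom()]),
#'   `table` (per-atom parameters), `dict` (matrix whose columns are the
#'   flattened real atoms), `dict_info` (per-column metadata), `config`.
#' @export
build_gabor_bank <- function(max_temporal_mod = 125,
                             max_spectral_mod = 0.25,
                             spacing_factor = 2,
                             periods = 1,
                             n_channels = 21, n_frames = 50,
                             frame_period_ms = 2, channel_spacing = 1) {
  t_nyq <- 1000 / (2 * frame_period_ms)      # Hz
  s_nyq <- 1 / (2 * channel_spacing)         # cyc/Bark
  if (max_temporal_mod > t_nyq / 2 + 1e-9 || max_spectral_mod > s_nyq / 2 + 1e-9) {
    stop("bank maxima must not exceed half the Nyquist modulation rates")
  }
  cap_t <- n_frames * frame_period_ms        # ms
  cap_s <- n_channels * channel_spacing      # Bark
  # temporal omega in cycles/ms for the width formula
  grid_t <- modulation_grid(max_temporal_mod / 1000, periods, cap_t, spacing_factor) * 1000
  grid_s <- modulation_grid(max_spectral_mod, periods, cap_s, spacing_factor)

  combos <- expand.grid(omega_t = grid_t, omega_s = grid_s)
  neg <- subset(combos, combos$omega_t > 0 & combos$omega_s > 0)
  if (nrow(neg) > 0) {
    neg$omega_s <- -neg$omega_s
    combos <- rbind(combos, neg)
  }

  atoms <- vector("list", nrow(combos))
  tab <- combos
  tab$id <- seq_len(nrow(combos))
  tab$b_t <- NA_real_
  tab$b_s <- NA_real_
  for (i in seq_len(nrow(combos))) {
    ot <- combos$omega_t[i]
    os <- combos$omega_s[i]
    b_t <- constant_q_width(abs(ot) / 1000, periods, cap_t)
    b_s <- constant_q_width(abs(os), periods, cap_s)
    tab$b_t[i] <- b_t
    tab$b_s[i] <- b_s
    atoms[[i]] <- gabor_atom(ot, os, b_t, b_s, n_channels, n_frames,
                             frame_period_ms, channel_spacing)
  }

  cols <- list()
  info <- list()
  for (i in seq_along(atoms)) {
    for (part in c("real", "imag")) {
      v <- realize_part(atoms[[i]], part)
      if (is.null(v)) next
      cols[[length(cols) + 1L]] <- as.vector(v)
      info[[length(info) + 1L]] <- data.frame(
        atom_id = i, part = part,
        omega_t = atoms[[i]]$omega_t, omega_s = atoms[[i]]$omega_s,
        b_t = atoms[[i]]$b_t, b_s = atoms[[i]]$b_s
      )
    }
  }
  dict <- do.call(cbind, cols)
  dict_info <- do.call(rbind, info)
  dict_info$column <- seq_len(nrow(dict_info))

  structure(
    list(
      atoms = atoms,
      table = tab[, c("id", "omega_t", "omega_s", "b_t", "b_s")],
      dict = dict,
      dict_info = dict_info,
      config = list(
        max_temporal_mod = max_temporal_mod,
        max_spectral_mod = max_spectral_mod,
        spacing_factor = spacing_factor, periods = periods,
        n_channels = n_channels, n_frames = n_frames,
        frame_period_ms = frame_period_ms, channel_spacing = channel_spacing
      )
    ),
    class = "gabor_bank"
  )
}

#' @export
print.gabor_bank <- function(x, ...) {
  cat(sprintf(
    "Gabor bank: %d complex atoms (%d real dictionary atoms), |omega_t| <= %g Hz, |omega_s| <= %g cyc/Bark\n",
    length(x$atoms), ncol(x$dict),
    max(abs(x$table$omega_t)), max(abs(x$table$omega_s))))
  invisible(x)
}
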