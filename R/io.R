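# Text serialization: matrices as CSV, metadata as a JSON sidecar. `path` is
# a prefix; files `<path>.csv` and `<path>.json` are written.

write_matrix_csv <- function(m, path) {
  utils::write.table(m, path, sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

read_matrix_csv <- function(path) {
  as.matrix(utils::read.table(path, sep = ",", header = FALSE))
}

#' Write / read a Bark spectrogram as CSV + JSON sidecar
#'
#' @param x A `bark_spectrogram`.
#' @param path Path prefix; `<path>.csv` (values) and `<path>.json`
#'   (channel centers, frame period) are produced.
#' @return `path`, invisibly.
#' @export
write_bark_spectrogram <- function(x, path) {
  write_matrix_csv(x$values, paste0(path, ".csv"))
  jsonlite::write_json(
    list(channel_centers = x$channel_centers,
         frame_period_ms = x$frame_period_ms),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_bark_spectrogram
#' @export
read_bark_spectrogram <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  m <- read_matrix_csv(paste0(path, ".csv"))
  dimnames(m) <- NULL
  structure(
    list(values = m, channel_centers = meta$channel_centers,
         frame_period_ms = meta$frame_period_ms, config = NULL),
    class = "bark_spectrogram"
  )
}

#' Write / read an STRF as CSV + JSON sidecar
#'
#' @param x An `strf` object.
#' @param path Path prefix; `<path>.csv` (patch) and `<path>.json`
#'   (lambda, cv correlation, mask density) are produced.
#' @return `path`, invisibly.
#' @export
write_strf <- function(x, path) {
  write_matrix_csv(x$patch, paste0(path, ".csv"))
  jsonlite::write_json(
    list(lambda = x$lambda, cv_correlation = x$cv_correlation,
         mask_density = mean(x$mask), included = x$included),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_strf
#' @export
read_strf <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  m <- read_matrix_csv(paste0(path, ".csv"))
  dimnames(m) <- NULL
  new_strf(m, m != 0, meta$lambda, meta$cv_correlation, meta$included)
}

#' Write a matching-pursuit decomposition as JSON
#'
#' @param dec An [mp_decompose()] result.
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
write_decomposition <- function(dec, path) {
  jsonlite::write_json(
    list(entries = dec$entries, corr_track = dec$corr_track,
         n_iter = dec$n_iter, kappa = dec$kappa, theta = dec$theta,
         reached_theta = dec$reached_theta),
    path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}
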