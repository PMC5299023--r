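#' Read a mono PCM WAV file
#'
#' Minimal RIFF/WAVE reader for the 16 kHz mono recordings this package
#' consumes. Only uncompressed integer PCM (8/16/24/32 bit) is supported;
#' samples are returned as doubles in \[-1, 1\].
#'
#' @param path Path to a `.wav` file.
#' @return A list with `samples` (numeric vector) and `sample_rate` (Hz).
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  riff <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1L, size = 4L, endian = "little"))
  wave <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", size)
      fmt <- list(
        audio_format = readBin(body[1:2], "integer", 1L, 2L, endian = "little"),
        n_channels   = readBin(body[3:4], "integer", 1L, 2L, endian = "little"),
        sample_rate  = readBin(body[5:8], "integer", 1L, 4L, endian = "little"),
        bits         = readBin(body[15:16], "integer", 1L, 2L, endian = "little")
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
    } else {
      invisible(readBin(con, "raw", size))
    }
    if (size %% 2L == 1L) invisible(readBin(con, "raw", 1L)) # chunk padding
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stop("missing fmt/data chunk in ", path)
  if (fmt$audio_format != 1L) stop("only uncompressed PCM WAV is supported")
  if (fmt$n_channels != 1L) stop("only mono WAV is supported")

  bytes <- fmt$bits %/% 8L
  n <- length(data_raw) %/% bytes
  x <- switch(
    as.character(fmt$bits),
    "8"  = (as.numeric(readBin(data_raw, "integer", n, 1L, signed = FALSE)) - 128) / 128,
    "16" = readBin(data_raw, "integer", n, 2L, signed = TRUE, endian = "little") / 32768,
    "24" = {
      m <- matrix(as.integer(data_raw[seq_len(n * 3L)]), nrow = 3L)
      v <- m[1, ] + 256 * m[2, ] + 65536 * m[3, ]
      v <- ifelse(v >= 8388608, v - 16777216, v)
      v / 8388608
    },
    "32" = readBin(data_raw, "integer", n, 4L, signed = TRUE, endian = "little") / 2147483648,
    stop("unsupported PCM bit depth: ", fmt$bits)
  )
  list(samples = as.numeric(x), sample_rate = fmt$sample_rate)
}

#' Write a mono 16-bit PCM WAV file
#'
#' @param samples Numeric vector in \[-1, 1\] (values are clipped).
#' @param sample_rate Sampling rate in Hz.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, sample_rate, path) {
  x <- pmin(pmax(samples, -1), 32767 / 32768)
  pcm <- as.integer(round(x * 32768))
  n_bytes <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4L, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(1L, con, size = 2L, endian = "little")            # PCM
  writeBin(1L, con, size = 2L, endian = "little")            # mono
  writeBin(as.integer(sample_rate), con, size = 4L, endian = "little")
  writeBin(as.integer(sample_rate * 2L), con, size = 4L, endian = "little")
  writeBin(2L, con, size = 2L, endian = "little")            # block align
  writeBin(16L, con, size = 2L, endian = "little")           # bits
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(n_bytes), con, size = 4L, endian = "little")
  writeBin(pcm, con, size = 2L, endian = "little")
  invisible(path)
}
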