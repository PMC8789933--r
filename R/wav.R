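#' Read a RIFF/WAVE audio file
#'
#' Minimal WAV reader covering the formats produced by digital stethoscopes
#' and common converters: PCM 16-bit, PCM 24-bit and IEEE float 32-bit,
#' mono or multi-channel. Chunks other than `fmt ` and `data` are skipped.
#'
#' @param path Path to a `.wav` file.
#' @return A list with `samples` (numeric matrix, one column per channel,
#'   amplitudes in `[-1, 1]` for PCM) and `fs` (sampling rate in Hz).
#' @keywords internal
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAVE file: ", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a RIFF/WAVE file: ", path)

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (length(size) == 0) break
    if (identical(id, "fmt ")) {
      raw <- readBin(con, "raw", size)
      fmt <- list(
        format   = readBin(raw[1:2], "integer", 1, 2, signed = FALSE, endian = "little"),
        channels = readBin(raw[3:4], "integer", 1, 2, signed = FALSE, endian = "little"),
        fs       = readBin(raw[5:8], "integer", 1, 4, endian = "little"),
        bits     = readBin(raw[15:16], "integer", 1, 2, signed = FALSE, endian = "little")
      )
      # WAVE_FORMAT_EXTENSIBLE: actual format code sits in the subformat GUID
      if (fmt$format == 65534L && size >= 40) {
        fmt$format <- readBin(raw[25:26], "integer", 1, 2, signed = FALSE, endian = "little")
      }
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
    } else {
      invisible(readBin(con, "raw", size + (size %% 2)))
      next
    }
    if (size %% 2 == 1) invisible(readBin(con, "raw", 1))
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stop("corrupt WAV file (missing fmt/data chunk): ", path)
  if (length(data_raw) == 0) stop("zero-length audio in ", path)

  bytes_per <- fmt$bits %/% 8L
  n_frames <- length(data_raw) %/% (bytes_per * fmt$channels)
  if (n_frames < 1) stop("zero-length audio in ", path)
  usable <- data_raw[seq_len(n_frames * bytes_per * fmt$channels)]

  x <- if (fmt$format == 3L && fmt$bits == 32L) {
    readBin(usable, "double", n = n_frames * fmt$channels, size = 4, endian = "little")
  } else if (fmt$format == 1L && fmt$bits == 16L) {
    readBin(usable, "integer", n = n_frames * fmt$channels, size = 2,
            signed = TRUE, endian = "little") / 32768
  } else if (fmt$format == 1L && fmt$bits == 24L) {
    m <- matrix(as.integer(usable), nrow = 3)
    v <- m[1, ] + 256 * m[2, ] + 65536 * m[3, ]
    v <- ifelse(v >= 8388608, v - 16777216, v)
    v / 8388608
  } else {
    stop("unsupported WAV encoding (format ", fmt$format, ", ", fmt$bits, " bits)")
  }
  list(samples = matrix(x, ncol = fmt$channels, byrow = TRUE), fs = fmt$fs)
}

#' Write a mono (or multi-channel) WAV file
#'
#' @param samples Numeric vector or matrix (columns = channels), amplitudes
#'   nominally in `[-1, 1]`.
#' @param fs Sampling rate in Hz.
#' @param path Output path.
#' @param bits 16 (PCM) or 32 (IEEE float).
#' @keywords internal
write_wav <- function(samples, fs, path, bits = 16L) {
  if (is.vector(samples)) samples <- matrix(samples, ncol = 1)
  stopifnot(bits %in% c(16L, 32L), fs > 0)
  channels <- ncol(samples)
  interleaved <- as.vector(t(samples))
  bytes_per <- bits %/% 8L
  data_size <- length(interleaved) * bytes_per
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(if (bits == 32L) 3L else 1L, con, 2, endian = "little")
  writeBin(as.integer(channels), con, 2, endian = "little")
  writeBin(as.integer(fs), con, 4, endian = "little")
  writeBin(as.integer(fs * channels * bytes_per), con, 4, endian = "little")
  writeBin(as.integer(channels * bytes_per), con, 2, endian = "little")
  writeBin(as.integer(bits), con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, 4, endian = "little")
  if (bits == 32L) {
    writeBin(interleaved, con, size = 4, endian = "little")
  } else {
    q <- as.integer(round(pmax(pmin(interleaved, 1), -1) * 32767))
    writeBin(q, con, size = 2, endian = "little")
  }
  invisible(path)
}
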