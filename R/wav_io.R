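#' Read a RIFF/WAVE audio file
#'
#' Minimal reader for the two encodings cry corpora use in practice:
#' integer PCM (8/16/24/32 bit) and IEEE float (32/64 bit). Stereo input is
#' averaged to mono with a warning; samples are returned as doubles in
#' \[-1, 1\].
#'
#' @param path Path to a `.wav` file.
#' @return A list with `samples` (numeric vector in \[-1, 1\]),
#'   `sample_rate` (Hz) and `bit_depth`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))

  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) {
    stop("not a RIFF file: ", path, call. = FALSE)
  }
  readBin(con, "integer", 1, 4, endian = "little") # total size, unused
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) {
    stop("not a WAVE file: ", path, call. = FALSE)
  }

  fmt <- NULL
  data_raw <- NULL
  # chunk walk: ids/sizes are little-endian, chunks are word-aligned
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (length(size) == 0) break
    if (identical(id, "fmt ")) {
      fmt_raw <- readBin(con, "raw", size)
      fmt <- list(
        audio_format = sum(as.integer(fmt_raw[1:2]) * c(1L, 256L)),
        n_channels   = sum(as.integer(fmt_raw[3:4]) * c(1L, 256L)),
        sample_rate  = sum(as.integer(fmt_raw[5:8]) * c(1, 256, 65536, 16777216)),
        bit_depth    = sum(as.integer(fmt_raw[15:16]) * c(1L, 256L))
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
    } else {
      readBin(con, "raw", size)
    }
    if (size %% 2 == 1) readBin(con, "raw", 1) # pad byte
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) {
    stop("WAV file missing fmt or data chunk: ", path, call. = FALSE)
  }
  if (!fmt$audio_format %in% c(1L, 3L)) {
    stop("unsupported WAV encoding (format tag ", fmt$audio_format, "): ",
         path, call. = FALSE)
  }
  is_float <- fmt$audio_format == 3L

  x <- if (is_float) {
    readBin(data_raw, "double", n = length(data_raw) / (fmt$bit_depth / 8),
            size = fmt$bit_depth / 8, endian = "little")
  } else {
    switch(
      as.character(fmt$bit_depth),
      "8"  = (as.integer(readBin(data_raw, "integer", n = length(data_raw),
                                 size = 1, signed = FALSE)) - 128) / 128,
      "16" = readBin(data_raw, "integer", n = length(data_raw) / 2,
                     size = 2, signed = TRUE, endian = "little") / 32768,
      "24" = read_pcm24(data_raw),
      "32" = readBin(data_raw, "integer", n = length(data_raw) / 4,
                     size = 4, endian = "little") / 2147483648,
      stop("unsupported PCM bit depth: ", fmt$bit_depth, call. = FALSE)
    )
  }

  if (fmt$n_channels > 1) {
    warning("averaging ", fmt$n_channels, "-channel audio to mono: ",
            basename(path), call. = FALSE)
    x <- colMeans(matrix(x, nrow = fmt$n_channels))
  }
  list(samples = as.numeric(x), sample_rate = as.integer(fmt$sample_rate),
       bit_depth = as.integer(fmt$bit_depth))
}

read_pcm24 <- function(raw) {
  b <- as.integer(raw)
  n <- length(b) / 3L
  v <- b[seq(1, by = 3, length.out = n)] +
    b[seq(2, by = 3, length.out = n)] * 256 +
    b[seq(3, by = 3, length.out = n)] * 65536
  v <- ifelse(v >= 8388608, v - 16777216, v)
  v / 8388608
}

#' Write a mono 16-bit PCM WAV file
#'
#' @param samples Numeric vector; values are clipped to \[-1, 1\].
#' @param sample_rate Sampling rate in Hz.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, sample_rate, path) {
  stopifnot(is.numeric(samples), length(samples) > 0, sample_rate > 0)
  x <- pmin(1, pmax(-1, samples))
  pcm <- as.integer(round(x * 32767))
  n_bytes <- length(pcm) * 2L

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")                  # PCM
  writeBin(1L, con, size = 2, endian = "little")                  # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * 2), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")                  # block align
  writeBin(16L, con, size = 2, endian = "little")                 # bit depth
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}
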