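#' Read a RIFF/WAVE audio file
#'
#' Minimal WAV reader for uncompressed PCM (8/16/24/32-bit integer) and
#' 32-bit IEEE float files. Samples are rescaled to `[-1, 1]`; multi-channel
#' files are downmixed to mono by averaging channels.
#'
#' @param path Path to a `.wav` file.
#' @return A [waveform] with `source_id` set to the file name.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4, useBytes = TRUE) != "RIFF") stop("not a RIFF file")
  readBin(con, "integer", 1, 4, endian = "little")
  if (readChar(con, 4, useBytes = TRUE) != "WAVE") stop("not a WAVE file")
  fmt <- NULL
  samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (id == "fmt ") {
      fmt <- list(
        audio_format = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE),
        channels     = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE),
        sample_rate  = readBin(con, "integer", 1, 4, endian = "little"),
        byte_rate    = readBin(con, "integer", 1, 4, endian = "little"),
        block_align  = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE),
        bits         = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE)
      )
      if (size > 16) readBin(con, "raw", size - 16)
    } else if (id == "data") {
      if (is.null(fmt)) stop("malformed WAV: data chunk before fmt chunk")
      samples <- read_wav_data(con, size, fmt)
      break
    } else {
      readBin(con, "raw", size + (size %% 2)) # skip unknown chunk (padded)
    }
  }
  if (is.null(samples)) stop("no data chunk found in WAV file")
  if (fmt$channels > 1) {
    samples <- rowMeans(matrix(samples, ncol = fmt$channels, byrow = TRUE))
  }
  waveform(samples, sample_rate = fmt$sample_rate, source_id = basename(path))
}

read_wav_data <- function(con, size, fmt) {
  bits <- fmt$bits
  if (fmt$audio_format == 3) {
    if (bits != 32) stop("only 32-bit float WAV supported")
    return(readBin(con, "numeric", size / 4, 4, endian = "little"))
  }
  if (fmt$audio_format != 1) stop("unsupported WAV audio format ", fmt$audio_format)
  if (bits == 8) {
    raw <- as.integer(readBin(con, "raw", size))
    (raw - 128) / 128
  } else if (bits == 16) {
    readBin(con, "integer", size / 2, 2, endian = "little") / 32768
  } else if (bits == 24) {
    raw <- as.integer(readBin(con, "raw", size))
    b <- matrix(raw, nrow = 3)
    v <- b[1, ] + 256 * b[2, ] + 65536 * b[3, ]
    v[v >= 8388608] <- v[v >= 8388608] - 16777216
    v / 8388608
  } else if (bits == 32) {
    readBin(con, "integer", size / 4, 4, endian = "little") / 2147483648
  } else {
    stop("unsupported PCM bit depth ", bits)
  }
}

#' Write a mono waveform as 16-bit PCM WAV
#'
#' Companion to [read_wav()], mainly for round-trip tests and exporting
#' synthetic stimuli. Samples are clipped to `[-1, 1]`.
#'
#' @param w A [waveform].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(w, path) {
  stopifnot(inherits(w, "waveform"))
  s <- pmin(1, pmax(-1, w$samples))
  pcm <- as.integer(round(s * 32767))
  n_bytes <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")              # PCM
  writeBin(1L, con, size = 2, endian = "little")              # mono
  writeBin(as.integer(w$sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(w$sample_rate * 2), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")              # block align
  writeBin(16L, con, size = 2, endian = "little")             # bits
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}
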