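# Minimal RIFF/WAVE reader and writer.
#
# Supports the formats lung-sound corpora actually use: PCM 16- or 24-bit and
# IEEE float 32-bit, mono or stereo (stereo is downmixed by averaging).
# Samples are returned as doubles in [-1, 1].

#' Read a WAV file
#'
#' @param path Path to a `.wav` file (PCM 16/24-bit or 32-bit float).
#' @return A list with `samples` (numeric vector in `[-1, 1]`, mono —
#'   multi-channel input is downmixed by channel averaging) and
#'   `sample_rate` (Hz).
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) abort(paste0("WAV file not found: ", path))
  raw <- readBin(path, what = "raw", n = file.info(path)$size)
  if (length(raw) < 44 ||
      rawToChar(raw[1:4]) != "RIFF" || rawToChar(raw[9:12]) != "WAVE") {
    abort(paste0("Not a RIFF/WAVE file: ", path))
  }
  u16 <- function(b) sum(as.integer(b) * c(1, 256))
  u32 <- function(b) sum(as.numeric(b) * c(1, 256, 65536, 16777216))
  pos <- 13L
  fmt <- NULL
  data <- NULL
  while (pos + 8 <= length(raw)) {
    id <- rawToChar(raw[pos:(pos + 3)])
    size <- u32(raw[(pos + 4):(pos + 7)])
    body <- raw[(pos + 8):min(pos + 7 + size, length(raw))]
    if (id == "fmt ") fmt <- body
    if (id == "data") { data <- body; break }
    pos <- pos + 8L + size + (size %% 2)   # chunks are word-aligned
  }
  if (is.null(fmt) || is.null(data)) abort("WAV file lacks fmt/data chunks.")
  audio_format <- u16(fmt[1:2])
  n_channels <- u16(fmt[3:4])
  sample_rate <- u32(fmt[5:8])
  bits <- u16(fmt[15:16])
  if (audio_format == 65534 && length(fmt) >= 26) {
    audio_format <- u16(fmt[25:26])      # WAVE_FORMAT_EXTENSIBLE subformat tag
  }
  samples <- if (audio_format == 3 && bits == 32) {
    readBin(data, what = "double", size = 4, n = length(data) %/% 4,
            endian = "little")
  } else if (audio_format == 1 && bits == 16) {
    readBin(data, what = "integer", size = 2, n = length(data) %/% 2,
            signed = TRUE, endian = "little") / 32768
  } else if (audio_format == 1 && bits == 24) {
    n <- length(data) %/% 3
    b <- matrix(as.integer(data[seq_len(3 * n)]), nrow = 3)
    v <- b[1, ] + 256 * b[2, ] + 65536 * b[3, ]
    v <- ifelse(v >= 8388608, v - 16777216, v)
    v / 8388608
  } else {
    abort(sprintf("Unsupported WAV encoding (format %d, %d bits).",
                  audio_format, bits))
  }
  if (n_channels > 1) {
    n <- length(samples) %/% n_channels
    samples <- rowMeans(matrix(samples[seq_len(n * n_channels)],
                               ncol = n_channels, byrow = TRUE))
  }
  list(samples = as.numeric(samples), sample_rate = sample_rate)
}

#' Write a mono 16-bit PCM WAV file
#'
#' @param samples Numeric vector in `[-1, 1]`; values outside are clipped.
#' @param sample_rate Sampling rate in Hz.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, sample_rate, path) {
  stopifnot(is.numeric(samples), length(samples) > 0, sample_rate > 0)
  pcm <- as.integer(pmin(pmax(round(samples * 32768), -32768), 32767))
  data_size <- 2L * length(pcm)
  con <- file(path, "wb")
  on.exit(close(con))
  w32 <- function(v) writeBin(as.integer(v), con, size = 4, endian = "little")
  w16 <- function(v) writeBin(as.integer(v), con, size = 2, endian = "little")
  writeChar("RIFF", con, eos = NULL)
  w32(36 + data_size)
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  w32(16); w16(1); w16(1)                 # PCM, mono
  w32(sample_rate)
  w32(sample_rate * 2)                    # byte rate
  w16(2); w16(16)                         # block align, bits
  writeChar("data", con, eos = NULL)
  w32(data_size)
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}
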