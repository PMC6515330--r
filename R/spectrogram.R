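#' Spectrogram parameters
#'
#' Parameters of the cropped log-magnitude spectrogram image used as the
#' detector input representation: a short-time Fourier transform with
#' 4096-sample segments overlapping by 3200 samples (hop 896 samples,
#' about 20 ms at 44.1 kHz), keeping only frequency bins whose centre lies
#' strictly below 2000 Hz — the band that carries normal lung-sound energy.
#' Magnitudes are expressed in dB relative to the file maximum and clipped at
#' `log_floor_db`.
#'
#' @param sample_rate Sampling rate in Hz.
#' @param segment_length STFT segment length in samples.
#' @param overlap Overlap between successive segments in samples;
#'   `hop = segment_length - overlap`.
#' @param max_frequency Keep only bins with centre frequency strictly below
#'   this value (Hz).
#' @param log_floor_db Lower clip for the dB scale (dB relative to the file
#'   maximum; negative).
#' @param window Taper name; only `"hann"` is provided.
#' @return A list of class `spectrogram_params`.
#' @export
spectrogram_params <- function(sample_rate = 44100,
                               segment_length = 4096,
                               overlap = 3200,
                               max_frequency = 2000,
                               log_floor_db = -80,
                               window = "hann") {
  if (overlap <= 0 || overlap >= segment_length) {
    abort("`overlap` must satisfy 0 < overlap < segment_length.")
  }
  if (max_frequency <= 0 || max_frequency > sample_rate / 2) {
    abort("`max_frequency` must lie in (0, sample_rate/2].")
  }
  if (!identical(window, "hann")) abort("Only the 'hann' window is supported.")
  structure(
    list(
      sample_rate = sample_rate,
      segment_length = as.integer(segment_length),
      overlap = as.integer(overlap),
      hop = as.integer(segment_length - overlap),
      max_frequency = max_frequency,
      log_floor_db = log_floor_db,
      window = window
    ),
    class = "spectrogram_params"
  )
}

#' Compute the cropped log-magnitude spectrogram of a waveform
#'
#' Computes the magnitude STFT (Hann window, no padding: the first frame
#' starts at sample 1), drops every frequency bin at or above
#' `params$max_frequency`, and converts magnitudes to dB relative to the
#' maximum, clipped at `params$log_floor_db`. For a waveform of `N` samples
#' the image has `floor((N - segment_length)/hop) + 1` columns; at the
#' defaults a 10 s recording at 44.1 kHz gives a 186 x 488 image.
#'
#' @param waveform Numeric vector of mono samples (length >=
#'   `segment_length`, all finite).
#' @param params A [spectrogram_params()] object.
#' @return An object of class `spectrogram_image`: list with `values`
#'   (matrix, rows = frequency bins low to high, columns = time frames),
#'   `frame_times` (frame-centre times in seconds), `bin_frequencies` (Hz),
#'   `n_samples`, and `params`.
#' @export
compute_spectrogram <- function(waveform, params = spectrogram_params()) {
  waveform <- as.numeric(waveform)
  if (any(!is.finite(waveform))) abort("Waveform contains non-finite samples.")
  n <- length(waveform)
  if (n < params$segment_length) {
    abort(sprintf("Waveform too short: %d samples < segment_length %d.",
                  n, params$segment_length))
  }
  sg <- signal::specgram(
    waveform,
    n = params$segment_length,
    Fs = params$sample_rate,
    window = signal::hanning(params$segment_length),
    overlap = params$overlap
  )
  mag <- abs(sg$S)
  keep <- sg$f < params$max_frequency
  mag <- mag[keep, , drop = FALSE]
  peak <- max(mag)
  values <- if (peak > 0) {
    pmax(20 * log10(pmax(mag, .Machine$double.xmin) / peak), params$log_floor_db)
  } else {
    matrix(params$log_floor_db, nrow = nrow(mag), ncol = ncol(mag))
  }
  n_col <- ncol(values)
  frame_times <- ((seq_len(n_col) - 1) * params$hop + params$segment_length / 2) /
    params$sample_rate
  structure(
    list(
      values = values,
      frame_times = frame_times,
      bin_frequencies = sg$f[keep],
      n_samples = n,
      params = params
    ),
    class = "spectrogram_image"
  )
}

#' @export
print.spectrogram_image <- function(x, ...) {
  cat(sprintf(
    "<spectrogram_image> %d bins x %d frames, %.1f-%.1f Hz, %.2f s\n",
    nrow(x$values), ncol(x$values),
    min(x$bin_frequencies), max(x$bin_frequencies),
    x$n_samples / x$params$sample_rate
  ))
  invisible(x)
}

#' @export
dim.spectrogram_image <- function(x) dim(x$values)

#' Export a spectrogram as a three-channel PNG image
#'
#' Min-max scales the log-magnitudes to 8-bit grey and replicates the single
#' channel into three (the convention used when feeding spectrograms to
#' image-pretrained detectors). Low frequencies sit at the bottom of the
#' image. A spectrogram with zero dynamic range maps to 0 everywhere.
#'
#' @param spec A `spectrogram_image`.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_spectrogram_png <- function(spec, path) {
  v <- spec$values
  rng <- range(v)
  g <- if (diff(rng) > 0) (v - rng[1]) / diff(rng) else matrix(0, nrow(v), ncol(v))
  g <- g[rev(seq_len(nrow(g))), , drop = FALSE]   # low frequencies at bottom
  arr <- array(g, dim = c(nrow(g), ncol(g), 3))
  png::writePNG(arr, target = path)
  invisible(path)
}

#' Map between time and spectrogram columns
#'
#' Columns are 1-based; column `c` is centred at
#' `((c - 1) * hop + segment_length/2) / sample_rate` seconds.
#' `time_to_column()` returns the column whose centre is nearest to `t`,
#' clamped to the valid range, so detector pixel boxes can be converted to
#' time spans and back.
#'
#' @param spec A `spectrogram_image`.
#' @param t Time in seconds, within `[0, duration]`.
#' @param column Column index in `1..ncol`.
#' @return `time_to_column()`: integer column index; `column_to_time()`:
#'   time in seconds.
#' @export
time_to_column <- function(spec, t) {
  duration <- spec$n_samples / spec$params$sample_rate
  if (any(t < 0 | t > duration)) {
    abort(sprintf("Time out of range [0, %.6g].", duration))
  }
  p <- spec$params
  raw <- (t * p$sample_rate - p$segment_length / 2) / p$hop + 1
  pmin(pmax(as.integer(round(raw)), 1L), ncol(spec$values))
}

#' @rdname time_to_column
#' @export
column_to_time <- function(spec, column) {
  if (any(column < 1 | column > ncol(spec$values))) {
    abort(sprintf("Column out of range [1, %d].", ncol(spec$values)))
  }
  p <- spec$params
  ((column - 1) * p$hop + p$segment_length / 2) / p$sample_rate
}

#' Number of STFT frames for a signal length
#'
#' Closed form `floor((n_samples - segment_length)/hop) + 1`, valid for
#' `n_samples >= segment_length`.
#'
#' @param n_samples Signal length in samples.
#' @param params A [spectrogram_params()].
#' @return Integer frame count.
#' @export
n_spectrogram_frames <- function(n_samples, params = spectrogram_params()) {
  if (any(n_samples < params$segment_length)) {
    abort("n_samples must be >= segment_length.")
  }
  as.integer((n_samples - params$segment_length) %/% params$hop + 1)
}
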