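#' Baseline band-energy breathing-phase detector
#'
#' A deliberately simple, non-learned detector that makes the full pipeline
#' (detection, post-processing, agreement evaluation) runnable on any
#' recording: it band-passes the audio to the lung-sound band, computes a
#' smoothed energy envelope, extracts candidate phases by hysteresis
#' thresholding, and labels candidates by alternation — the louder parity of
#' the alternating sequence is called inspiration, since chest-wall
#' expiration is quieter and can be nearly silent. Each candidate's
#' confidence is its mean envelope normalised by the file's maximum envelope,
#' an energy ratio rather than a calibrated probability.
#'
#' Any scored detector (e.g. a learned object detector over spectrogram
#' images) can stand in for this baseline as long as it returns the same
#' annotation-tibble contract: intervals within `[0, duration]` with
#' confidences in `[0, 1]`.
#'
#' @param band Band-pass edges in Hz.
#' @param smooth_window Envelope smoothing window in seconds.
#' @param on_frac,off_frac Hysteresis thresholds as fractions of the maximum
#'   envelope: a candidate must reach `on_frac` and extends while the
#'   envelope stays at or above `off_frac`.
#' @param min_duration Discard candidates shorter than this (seconds).
#' @return `detector_config()`: a list of class `detector_config`.
#' @export
detector_config <- function(band = c(100, 1500),
                            smooth_window = 0.15,
                            on_frac = 0.15,
                            off_frac = 0.08,
                            min_duration = 0.25) {
  stopifnot(length(band) == 2, band[1] > 0, band[1] < band[2],
            smooth_window > 0, on_frac > off_frac, off_frac > 0,
            min_duration >= 0)
  structure(
    list(band = band, smooth_window = smooth_window,
         on_frac = on_frac, off_frac = off_frac,
         min_duration = min_duration),
    class = "detector_config"
  )
}

#' @rdname detector_config
#' @param waveform Numeric vector of mono samples, at least 1 s long.
#' @param sample_rate Sampling rate in Hz.
#' @param config A [detector_config()].
#' @param recording_id,source_id Identifiers stamped onto the output.
#' @return `detect_phases()`: an annotation tibble whose every row carries a
#'   confidence; empty (but with the correct duration recorded) for silent
#'   input. Deterministic: identical input and config give identical output.
#' @examples
#' prof <- breathing_profile(duration = 10, cycle_jitter_sd = 0)
#' sched <- generate_schedule(prof, seed = 1, recording_id = "sim")
#' wave <- synthesize_audio(sched, prof, seed = 1)
#' detect_phases(wave, prof$sample_rate, recording_id = "sim")
#' @export
detect_phases <- function(waveform, sample_rate,
                          config = detector_config(),
                          recording_id = "recording",
                          source_id = "baseline_detector") {
  waveform <- as.numeric(waveform)
  if (length(waveform) < sample_rate) {
    abort("Waveform must be at least 1 s long.")
  }
  duration <- length(waveform) / sample_rate
  if (all(waveform == 0)) {
    return(empty_annotations(recording_id, source_id, duration))
  }
  nyq <- sample_rate / 2
  bf <- signal::butter(4, pmin(config$band, nyq * 0.99) / nyq, type = "pass")
  y <- signal::filtfilt(bf, waveform)
  env <- sqrt(pmax(rolling_mean(y^2, max(1L, round(config$smooth_window * sample_rate))), 0))
  peak <- max(env)
  if (peak <= 0) {
    return(empty_annotations(recording_id, source_id, duration))
  }
  on_thr <- config$on_frac * peak
  off_thr <- config$off_frac * peak
  r <- rle(env >= off_thr)
  ends_idx <- cumsum(r$lengths)
  starts_idx <- ends_idx - r$lengths + 1L
  cand <- which(r$values)
  keep <- logical(length(cand))
  for (k in seq_along(cand)) {
    i0 <- starts_idx[cand[k]]
    i1 <- ends_idx[cand[k]]
    keep[k] <- (i1 - i0 + 1L) >= config$min_duration * sample_rate &&
      max(env[i0:i1]) >= on_thr
  }
  cand <- cand[keep]
  if (length(cand) == 0) {
    return(empty_annotations(recording_id, source_id, duration))
  }
  starts <- (starts_idx[cand] - 1) / sample_rate
  ends <- ends_idx[cand] / sample_rate
  mean_env <- vapply(
    seq_along(cand),
    function(k) mean(env[starts_idx[cand[k]]:ends_idx[cand[k]]]),
    numeric(1)
  )
  conf <- pmin(pmax(mean_env / peak, 0), 1)
  # Alternation labelling: candidates alternate phase; whichever parity is
  # louder on average is inspiration (the louder member of each adjacent
  # pair). A lone candidate is inspiration.
  n <- length(cand)
  odd <- seq(1, n, by = 2)
  even <- if (n > 1) seq(2, n, by = 2) else integer(0)
  odd_is_insp <- length(even) == 0 || mean(mean_env[odd]) >= mean(mean_env[even])
  phase <- rep("expiration", n)
  phase[if (odd_is_insp) odd else even] <- "inspiration"
  phase_annotations(
    start = starts, end = pmin(ends, duration), phase = phase,
    confidence = conf, recording_id = recording_id,
    source_id = source_id, duration = duration
  )
}

# Centered rolling mean via cumulative sums (O(n)); edges use the available
# part of the window.
rolling_mean <- function(x, k) {
  n <- length(x)
  if (k <= 1L || n == 0) return(x)
  half <- k %/% 2
  cs <- c(0, cumsum(x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}
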