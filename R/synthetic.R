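#' Breathing profile for the synthetic lung-sound generator
#'
#' The generator emulates chest-wall auscultation recordings: breathing
#' cycles of alternating inspiration and expiration separated by pauses,
#' inspiration louder than expiration (chest-wall expiration can be nearly
#' silent), band-limited noise-like sound, and 10-15 s recordings at
#' 44.1 kHz. Defaults describe an adult breathing deeper than normal with an
#' open mouth: 15 breaths/min, inspiration:expiration duration ratio 1:1.5,
#' 15% of each cycle silent, expiration at 0.4 of the inspiration amplitude.
#'
#' @param respiratory_rate Breaths per minute.
#' @param ie_ratio Expiration duration divided by inspiration duration.
#' @param pause_fraction Fraction of each cycle that is silent (split into a
#'   post-inspiration and a post-expiration pause).
#' @param expiration_gain Expiration amplitude relative to inspiration, in
#'   `(0, 1]`. Use [silent_expiration_profile()] for the near-silent case.
#' @param cycle_jitter_sd Gaussian SD (seconds) added independently to each
#'   phase duration.
#' @param duration Recording length in seconds.
#' @param sample_rate Sampling rate in Hz.
#' @return A list of class `breathing_profile`.
#' @export
breathing_profile <- function(respiratory_rate = 15,
                              ie_ratio = 1.5,
                              pause_fraction = 0.15,
                              expiration_gain = 0.4,
                              cycle_jitter_sd = 0.1,
                              duration = 15,
                              sample_rate = 44100) {
  stopifnot(respiratory_rate > 0, ie_ratio > 0,
            pause_fraction >= 0, pause_fraction < 1,
            expiration_gain > 0, expiration_gain <= 1,
            cycle_jitter_sd >= 0, duration > 0, sample_rate > 0)
  cycle <- 60 / respiratory_rate
  insp <- cycle * (1 - pause_fraction) / (1 + ie_ratio)
  if (insp <= 0) abort("Infeasible profile: nonpositive inspiration length.")
  structure(
    list(
      respiratory_rate = respiratory_rate, ie_ratio = ie_ratio,
      pause_fraction = pause_fraction, expiration_gain = expiration_gain,
      cycle_jitter_sd = cycle_jitter_sd, duration = duration,
      sample_rate = sample_rate
    ),
    class = "breathing_profile"
  )
}

#' @rdname breathing_profile
#' @export
silent_expiration_profile <- function(...) {
  breathing_profile(expiration_gain = 0.05, ...)
}

#' Generate a ground-truth breathing-phase schedule
#'
#' Lays out alternating inspiration/expiration events separated by pauses,
#' starting with inspiration, with independent Gaussian jitter on each phase
#' duration, truncated at the recording end. Deterministic given `seed`.
#'
#' @param profile A [breathing_profile()].
#' @param seed Integer seed.
#' @param recording_id,source_id Identifiers for the output tibble.
#' @return An annotation tibble satisfying the human-style invariants.
#' @export
generate_schedule <- function(profile, seed = 1,
                              recording_id = "sim",
                              source_id = "truth") {
  cycle <- 60 / profile$respiratory_rate
  breath <- cycle * (1 - profile$pause_fraction)
  insp0 <- breath / (1 + profile$ie_ratio)
  exp0 <- breath - insp0
  pause <- cycle * profile$pause_fraction / 2
  if (insp0 <= 0 || exp0 <= 0) {
    abort("Infeasible profile: nonpositive derived phase lengths.")
  }
  starts <- numeric(0); ends <- numeric(0); phase <- character(0)
  with_local_seed(seed, {
    t <- 0
    repeat {
      for (ph in c("inspiration", "expiration")) {
        base <- if (ph == "inspiration") insp0 else exp0
        len <- max(base + rnorm(1, 0, profile$cycle_jitter_sd), 0.2 * base)
        if (t >= profile$duration) break
        starts <- c(starts, t)
        ends <- c(ends, min(t + len, profile$duration))
        phase <- c(phase, ph)
        t <- t + len + pause
      }
      if (t >= profile$duration) break
    }
  })
  keep <- ends - starts >= 0.05
  phase_annotations(
    start = starts[keep], end = ends[keep], phase = phase[keep],
    recording_id = recording_id, source_id = source_id,
    duration = profile$duration
  )
}

#' Synthesize lung-sound-like audio for a phase schedule
#'
#' Band-limited (100-1200 Hz) Gaussian noise, amplitude-modulated by a
#' smooth envelope: full gain during inspiration, `expiration_gain` during
#' expiration, and a -40 dB noise floor during pauses. The envelope is
#' smoothed over 20 ms so phase edges are not clicks. Deterministic given
#' `seed`; the waveform has exactly `round(duration * sample_rate)` samples,
#' peak-normalised to 0.9.
#'
#' @param schedule Annotation tibble from [generate_schedule()].
#' @param profile The [breathing_profile()] used to generate it.
#' @param seed Integer seed.
#' @return Numeric waveform vector.
#' @export
synthesize_audio <- function(schedule, profile, seed = 1) {
  sr <- profile$sample_rate
  n <- round(profile$duration * sr)
  gain <- rep(0.01, n)                       # -40 dB pause floor
  for (i in seq_len(nrow(schedule))) {
    i0 <- max(1L, floor(schedule$start[i] * sr) + 1L)
    i1 <- min(n, ceiling(schedule$end[i] * sr))
    g <- if (schedule$phase[i] == "inspiration") 1 else profile$expiration_gain
    gain[i0:i1] <- g
  }
  gain <- rolling_mean(gain, max(1L, round(0.02 * sr)))
  wave <- with_local_seed(seed, {
    noise <- rnorm(n)
    bf <- signal::butter(2, c(100, 1200) / (sr / 2), type = "pass")
    signal::filtfilt(bf, noise)
  })
  wave <- wave * gain
  wave / max(abs(wave)) * 0.9
}

#' Annotator noise model
#'
#' Models an imperfect human annotator: independent Gaussian jitter on every
#' phase boundary, a probability of missing a phase entirely, and a Poisson
#' number of spurious short phases inserted into silent gaps.
#'
#' @param boundary_jitter_sd SD of the boundary jitter in seconds.
#' @param miss_prob Probability that a phase is dropped.
#' @param spurious_rate Expected number of spurious phases per recording.
#' @return A list of class `annotator_noise`.
#' @export
annotator_noise <- function(boundary_jitter_sd = 0.05,
                            miss_prob = 0,
                            spurious_rate = 0) {
  stopifnot(boundary_jitter_sd >= 0, miss_prob >= 0, miss_prob <= 1,
            spurious_rate >= 0)
  structure(
    list(boundary_jitter_sd = boundary_jitter_sd,
         miss_prob = miss_prob, spurious_rate = spurious_rate),
    class = "annotator_noise"
  )
}

#' Simulate an imperfect annotator
#'
#' Applies an [annotator_noise()] model to ground-truth annotations:
#' boundaries are jittered (clipped so intervals stay valid, inside the
#' recording, and non-overlapping), phases are dropped at `miss_prob`, and
#' spurious 0.15-0.4 s phases are inserted into silent gaps. With zero
#' noise the output equals the input. Deterministic given `seed`; handles
#' multi-recording tibbles (each recording gets an independent substream).
#'
#' @param truth Annotation tibble (human-style).
#' @param noise An [annotator_noise()].
#' @param seed Integer seed.
#' @param source_id Source identifier stamped on the output.
#' @return An annotation tibble.
#' @export
corrupt_annotations <- function(truth, noise, seed = 1,
                                source_id = "sim_annotator") {
  truth <- validate_annotations(truth)
  recs <- unique(truth$recording_id)
  out <- purrr::map_dfr(seq_along(recs), function(k) {
    g <- truth[truth$recording_id == recs[k], , drop = FALSE]
    corrupt_one(g, noise, seed = derive_seed(seed, 7919, k),
                source_id = source_id)
  })
  validate_annotations(out)
}

corrupt_one <- function(g, noise, seed, source_id) {
  dur <- g$duration[1]
  rec <- g$recording_id[1]
  with_local_seed(seed, {
    keep <- runif(nrow(g)) >= noise$miss_prob
    g <- g[keep, , drop = FALSE]
    s <- g$start + rnorm(nrow(g), 0, noise$boundary_jitter_sd)
    e <- g$end + rnorm(nrow(g), 0, noise$boundary_jitter_sd)
    s <- pmax(s, 0)
    e <- pmin(e, dur)
    # Keep intervals valid: a jitter that inverts an interval collapses it
    # back around its midpoint with a 50 ms minimum length.
    mid <- (s + e) / 2
    bad <- e - s < 0.05
    s[bad] <- pmax(mid[bad] - 0.025, 0)
    e[bad] <- pmin(mid[bad] + 0.025, dur)
    # Keep the sequence non-overlapping: clip each overlap at its midpoint.
    ph <- g$phase
    if (length(s) > 1) {
      o <- order(s, e)
      s <- s[o]; e <- e[o]; ph <- ph[o]
      for (i in seq_len(length(s) - 1)) {
        if (s[i + 1] < e[i]) {
          cut <- (s[i + 1] + e[i]) / 2
          e[i] <- cut
          s[i + 1] <- cut
        }
      }
    }
    # Final left-to-right sweep: heavy jitter can leave an interval reaching
    # past its next-but-one neighbour; enforce non-overlap and drop slivers.
    keep2 <- rep(TRUE, length(s))
    cursor <- 0
    for (i in seq_along(s)) {
      s[i] <- max(s[i], cursor)
      if (e[i] - s[i] < 0.02) keep2[i] <- FALSE else cursor <- e[i]
    }
    s <- s[keep2]; e <- e[keep2]; ph <- ph[keep2]
    # Spurious phases land in silent gaps of at least 0.5 s.
    n_spur <- rpois(1, noise$spurious_rate)
    if (n_spur > 0) {
      occupied <- iv_merge(iv_matrix(s, e))
      gaps <- iv_complement(occupied, dur)
      gaps <- gaps[gaps[, 2] - gaps[, 1] >= 0.5, , drop = FALSE]
      for (q in seq_len(n_spur)) {
        if (nrow(gaps) == 0) break
        gi <- sample.int(nrow(gaps), 1)
        len <- runif(1, 0.15, 0.4)
        lo <- gaps[gi, 1]
        hi <- gaps[gi, 2] - len
        if (hi <= lo) next
        st <- runif(1, lo, hi)
        s <- c(s, st); e <- c(e, st + len)
        ph <- c(ph, sample(phase_levels(), 1))
        gaps <- gaps[-gi, , drop = FALSE]
      }
    }
    if (length(s) == 0) {
      empty_annotations(rec, source_id, dur)
    } else {
      phase_annotations(
        start = s, end = e, phase = ph,
        recording_id = rec, source_id = source_id, duration = dur
      )
    }
  })
}

#' Simulate a corpus of recordings with truth and imperfect annotators
#'
#' Generates `n_files` ground-truth schedules (and, optionally, their audio
#' waveforms) from one breathing profile, plus one corrupted annotation set
#' per named [annotator_noise()] model.
#'
#' @param n_files Number of recordings.
#' @param profile A [breathing_profile()].
#' @param annotators Named list of [annotator_noise()] models.
#' @param seed Integer seed; every file and annotator derives its own
#'   substream from it.
#' @param audio Also synthesize waveforms (slower; needed only when running
#'   a detector).
#' @return A list with `truth` (annotation tibble over all files),
#'   `annotations` (tibble including truth and every simulated annotator),
#'   `audio` (named list of waveforms, or `NULL`), and `profile`.
#' @export
simulate_corpus <- function(n_files = 10,
                            profile = breathing_profile(),
                            annotators = list(),
                            seed = 1,
                            audio = FALSE) {
  ids <- sprintf("sim%03d", seq_len(n_files))
  truth <- purrr::map_dfr(seq_len(n_files), function(i) {
    generate_schedule(profile, seed = derive_seed(seed, 131, i),
                      recording_id = ids[i])
  })
  ann <- truth
  if (length(annotators) > 0) {
    stopifnot(!is.null(names(annotators)), all(nzchar(names(annotators))))
    for (nm in names(annotators)) {
      ann <- dplyr::bind_rows(
        ann,
        corrupt_annotations(truth, annotators[[nm]],
                            seed = derive_seed(seed, 977, match(nm, names(annotators))),
                            source_id = nm)
      )
    }
  }
  waves <- NULL
  if (audio) {
    waves <- lapply(seq_len(n_files), function(i) {
      synthesize_audio(truth[truth$recording_id == ids[i], , drop = FALSE],
                       profile, seed = derive_seed(seed, 131, i))
    })
    names(waves) <- ids
  }
  list(truth = truth, annotations = ann, audio = waves, profile = profile)
}

# Deterministic 32-bit-safe substream seed derivation.
derive_seed <- function(seed, mult, i) {
  as.integer((as.numeric(seed) + as.numeric(mult) * i) %% 2147483629)
}

# Run code with a local RNG state: seeds deterministically, restores the
# caller's stream afterwards.
with_local_seed <- function(seed, code) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
  )
  set.seed(as.integer(as.numeric(seed) %% 2147483629))
  code
}
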