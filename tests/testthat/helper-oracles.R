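# Independent oracles and random fixture generators used across the suite.

# Dense-grid oracle for the continuous-time confusion measures: classify the
# midpoint of every `step`-wide cell. Accurate to one grid step per interval
# boundary.
grid_confusion <- function(a, b, total, step = 0.001) {
  t <- seq(step / 2, total, by = step)
  in_set <- function(m) {
    hit <- rep(FALSE, length(t))
    for (i in seq_len(nrow(m))) hit <- hit | (t >= m[i, 1] & t < m[i, 2])
    hit
  }
  ia <- in_set(a)
  ib <- in_set(b)
  list(
    tp = sum(ia & ib) * step,
    fp = sum(ia & !ib) * step,
    tn = sum(!ia & !ib) * step,
    fn = sum(!ia & ib) * step
  )
}

# Exhaustive optimal one-to-one matching between two sets of same-class
# boxes: maximises matched-pair count, then total Jaccard. Recursion over
# a-boxes; feasible for <= 6 boxes per side.
brute_force_match <- function(ar, br, threshold = 0.5) {
  na <- nrow(ar)
  nb <- nrow(br)
  if (na == 0 || nb == 0) return(list(count = 0, total_j = 0))
  jac <- outer(seq_len(na), seq_len(nb), function(i, j) {
    lungphase::interval_jaccard(ar$start[i], ar$end[i], br$start[j], br$end[j])
  })
  best <- c(count = 0, total_j = 0)
  recurse <- function(i, used_b, count, total_j) {
    if (i > na) {
      if (count > best[["count"]] ||
          (count == best[["count"]] && total_j > best[["total_j"]])) {
        best <<- c(count = count, total_j = total_j)
      }
      return(invisible())
    }
    recurse(i + 1, used_b, count, total_j)          # leave a-box i unmatched
    for (j in seq_len(nb)) {
      if (!used_b[j] && jac[i, j] > threshold) {
        used_b[j] <- TRUE
        recurse(i + 1, used_b, count + 1, total_j + jac[i, j])
        used_b[j] <- FALSE
      }
    }
  }
  recurse(1, rep(FALSE, nb), 0, 0)
  list(count = best[["count"]], total_j = best[["total_j"]])
}

# Random human-style (non-overlapping) annotation set.
random_human_set <- function(seed, recording_id = "rec", source_id = "A",
                             duration = 15, max_events = 8) {
  set.seed(seed)
  n <- sample.int(max_events, 1)
  edges <- sort(runif(2 * n, 0, duration))
  starts <- edges[seq(1, 2 * n, by = 2)]
  ends <- edges[seq(2, 2 * n, by = 2)]
  keep <- ends - starts > 0.05
  if (!any(keep)) {
    return(phase_annotations(0.5, 1.5, "i", recording_id = recording_id,
                             source_id = source_id, duration = duration))
  }
  phase_annotations(
    start = starts[keep], end = ends[keep],
    phase = sample(c("inspiration", "expiration"), sum(keep), replace = TRUE),
    recording_id = recording_id, source_id = source_id, duration = duration
  )
}

# Random scored (possibly overlapping) detector-style boxes.
random_scored_boxes <- function(seed, recording_id = "rec",
                                source_id = "det", duration = 15,
                                max_events = 10) {
  set.seed(seed)
  n <- sample.int(max_events, 1)
  starts <- runif(n, 0, duration - 1)
  lens <- runif(n, 0.3, 3)
  phase_annotations(
    start = starts, end = pmin(starts + lens, duration),
    phase = sample(c("inspiration", "expiration"), n, replace = TRUE),
    confidence = round(runif(n), 3),
    recording_id = recording_id, source_id = source_id, duration = duration
  )
}

# Random detector-like scored boxes: a breathing-like alternating layout with
# small boundary errors, plus near-duplicate boxes (heavy same-class overlap)
# and low-confidence spurious proposals. This is the geometry post-processing
# is specified over: residual overlaps between successive phases are small.
random_detector_boxes <- function(seed, recording_id = "rec",
                                  source_id = "det", duration = 15) {
  set.seed(seed)
  truth <- generate_schedule(
    breathing_profile(duration = duration),
    seed = seed + 999, recording_id = recording_id, source_id = source_id
  )
  jit <- function(v, sd) v + rnorm(length(v), 0, sd)
  start <- jit(truth$start, 0.08)
  end <- jit(truth$end, 0.08)
  phase <- truth$phase
  conf <- runif(nrow(truth), 0.5, 1)
  # near-duplicates of some boxes
  dup <- which(runif(nrow(truth)) < 0.4)
  start <- c(start, jit(truth$start[dup], 0.1))
  end <- c(end, jit(truth$end[dup], 0.1))
  phase <- c(phase, truth$phase[dup])
  conf <- c(conf, runif(length(dup)))
  # low-confidence spurious proposals anywhere
  n_spur <- rpois(1, 2)
  if (n_spur > 0) {
    s <- runif(n_spur, 0, duration - 1)
    start <- c(start, s)
    end <- c(end, s + runif(n_spur, 0.3, 1.5))
    phase <- c(phase, sample(c("inspiration", "expiration"), n_spur, TRUE))
    conf <- c(conf, runif(n_spur, 0, 0.49))
  }
  ok <- start >= 0 & end <= duration & end - start > 0.05
  phase_annotations(start[ok], end[ok], phase[ok],
                    confidence = round(conf[ok], 3),
                    recording_id = recording_id, source_id = source_id,
                    duration = duration)
}

# Annotation tibble comparison that ignores post-processing metadata.
strip_meta <- function(x) {
  attr(x, "stage_counts") <- NULL
  as.data.frame(tibble::as_tibble(x))
}

# Random non-overlapping single-class boxes (the geometry box matching is
# defined on: annotators and post-processed detectors never self-overlap).
random_disjoint_boxes <- function(seed, n_max = 6, duration = 12,
                                  source_id = "A") {
  set.seed(seed)
  n <- sample.int(n_max, 1)
  edges <- sort(runif(2 * n, 0, duration))
  starts <- edges[seq(1, 2 * n, by = 2)]
  ends <- edges[seq(2, 2 * n, by = 2)]
  keep <- ends - starts > 0.1
  if (!any(keep)) { starts <- 0.5; ends <- 2; keep <- TRUE }
  phase_annotations(starts[keep], ends[keep], rep("i", sum(keep)),
                    confidence = 0.9, recording_id = "r",
                    source_id = source_id, duration = duration)
}

# TRUE if any pair of rows of one (recording, source) group overlaps.
has_overlapping_pair <- function(x, tol = 1e-9) {
  any(vapply(split(x, paste(x$recording_id, x$source_id)), function(g) {
    if (nrow(g) < 2) return(FALSE)
    for (i in seq_len(nrow(g) - 1)) {
      for (j in (i + 1):nrow(g)) {
        if (min(g$end[i], g$end[j]) - max(g$start[i], g$start[j]) > tol) {
          return(TRUE)
        }
      }
    }
    FALSE
  }, logical(1)))
}
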