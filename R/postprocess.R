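#' Post-processing configuration for scored detections
#'
#' Three assumptions clean up raw scored detections: (1) proposals below 50%
#' confidence are noise and are pruned (strictly below — a confidence of
#' exactly 0.50 survives); (2) same-class detections overlapping by more than
#' 50% are duplicates of one breathing phase, and only the highest-confidence
#' one is kept; (3) small residual overlaps between successive phases
#' (typically under 10%) are boundary errors, fixed by shrinking both phases
#' in equal amounts until they abut.
#'
#' @param confidence_threshold Detections with confidence strictly below this
#'   are pruned. Default 0.5.
#' @param duplicate_overlap_threshold Same-class pairs whose overlap exceeds
#'   this are duplicates. Default 0.5.
#' @param overlap_measure How pairwise overlap is measured for duplicate
#'   suppression: `"jaccard"` (intersection over union, default) or
#'   `"min_fraction"` (intersection over the shorter box).
#' @return A list of class `postprocess_config`.
#' @export
postprocess_config <- function(confidence_threshold = 0.5,
                               duplicate_overlap_threshold = 0.5,
                               overlap_measure = c("jaccard", "min_fraction")) {
  if (confidence_threshold <= 0 || confidence_threshold >= 1 ||
      duplicate_overlap_threshold <= 0 || duplicate_overlap_threshold >= 1) {
    abort("Post-processing thresholds must lie in (0, 1).")
  }
  structure(
    list(
      confidence_threshold = confidence_threshold,
      duplicate_overlap_threshold = duplicate_overlap_threshold,
      overlap_measure = match.arg(overlap_measure)
    ),
    class = "postprocess_config"
  )
}

#' Post-process scored breathing-phase detections
#'
#' `postprocess_detections()` runs the full chain
#' [prune_low_confidence()] -> [remove_duplicates()] -> [shrink_overlaps()]
#' per `(recording_id, source_id)` group and returns a non-overlapping
#' ("human-style") annotation tibble with the per-stage removal counts
#' attached (retrieve them with [stage_counts()] or `glance()`). The chain is
#' idempotent: post-processing its own output changes nothing.
#'
#' @param x Annotation tibble of scored detections (every row must carry a
#'   confidence).
#' @param config A [postprocess_config()].
#' @return The cleaned annotation tibble, with a `stage_counts` attribute.
#' @examples
#' det <- phase_annotations(
#'   start = c(0, 0.5, 5.0), end = c(4, 4, 8),
#'   phase = c("i", "i", "e"), confidence = c(0.9, 0.7, 0.6),
#'   recording_id = "rec", source_id = "det", duration = 10
#' )
#' out <- postprocess_detections(det)
#' stage_counts(out)
#' @export
postprocess_detections <- function(x, config = postprocess_config()) {
  x <- validate_annotations(x)
  n_input <- nrow(x)
  pruned <- prune_low_confidence(x, config)
  deduped <- remove_duplicates(pruned, config)
  out <- shrink_overlaps(deduped)
  counts <- tibble(
    n_input = n_input,
    n_pruned = n_input - nrow(pruned),
    n_suppressed = nrow(pruned) - nrow(deduped),
    n_output = nrow(out)
  )
  attr(out, "stage_counts") <- counts
  class(out) <- c("postprocessed_annotations", class(out))
  out
}

#' @rdname postprocess_detections
#' @export
stage_counts <- function(x) {
  attr(x, "stage_counts") %||%
    abort("No stage counts: not the output of postprocess_detections().")
}

#' @rdname postprocess_detections
#' @export
glance.postprocessed_annotations <- function(x, ...) stage_counts(x)

#' @rdname postprocess_detections
#' @export
prune_low_confidence <- function(x, config = postprocess_config()) {
  x <- validate_annotations(x)
  if (anyNA(x$confidence)) {
    abort("All detections must carry a confidence before pruning.")
  }
  dplyr::filter(x, .data$confidence >= config$confidence_threshold)
}

#' @rdname postprocess_detections
#' @export
remove_duplicates <- function(x, config = postprocess_config()) {
  x <- validate_annotations(x)
  if (anyNA(x$confidence)) {
    abort("All detections must carry a confidence for duplicate removal.")
  }
  if (nrow(x) == 0) return(x)
  kept <- dplyr::group_modify(
    dplyr::group_by(x, .data$recording_id, .data$source_id, .data$phase),
    function(g, key) suppress_duplicates_group(g, config)
  )
  out <- dplyr::ungroup(kept)
  out <- out[, annotation_columns]
  validate_annotations(out)
}

# Greedy non-maximum suppression within one recording/source/class group:
# process boxes in descending confidence (ties: earlier start); each kept box
# suppresses later boxes overlapping it above the threshold.
suppress_duplicates_group <- function(g, config) {
  o <- order(-g$confidence, g$start, g$end)
  g <- g[o, , drop = FALSE]
  keep <- logical(nrow(g))
  for (i in seq_len(nrow(g))) {
    ov <- FALSE
    for (j in which(keep)) {
      m <- pair_overlap(g$start[i], g$end[i], g$start[j], g$end[j],
                        config$overlap_measure)
      if (m > config$duplicate_overlap_threshold) { ov <- TRUE; break }
    }
    keep[i] <- !ov
  }
  g[keep, setdiff(names(g), c("recording_id", "source_id", "phase")), drop = FALSE]
}

pair_overlap <- function(s1, e1, s2, e2, measure) {
  inter <- max(0, min(e1, e2) - max(s1, s2))
  if (inter <= 0) return(0)
  switch(measure,
    jaccard = inter / (max(e1, e2) - min(s1, s2)),
    min_fraction = inter / min(e1 - s1, e2 - s2)
  )
}

#' @rdname postprocess_detections
#' @export
shrink_overlaps <- function(x) {
  x <- validate_annotations(x)
  if (nrow(x) == 0) return(x)
  out <- dplyr::group_modify(
    dplyr::group_by(x, .data$recording_id, .data$source_id),
    function(g, key) shrink_group(g, key)
  )
  out <- dplyr::ungroup(out)[, annotation_columns]
  validate_annotations(out)
}

# Single left-to-right sweep: each overlapping successive pair gives up half
# the overlap on each side, so the two boxes abut. Boxes are sorted by start
# (ties: earlier end first).
shrink_group <- function(g, key) {
  g <- g[order(g$start, g$end), , drop = FALSE]
  s <- g$start
  e <- g$end
  for (i in seq_len(nrow(g) - 1)) {
    d <- e[i] - s[i + 1]
    if (d > 0) {
      if (d / 2 >= e[i] - s[i] || d / 2 >= e[i + 1] - s[i + 1]) {
        abort(sprintf(
          "Cannot shrink boxes %d and %d of recording '%s' (overlap %.3g s would invert a box); remove duplicates first.",
          i, i + 1, key$recording_id, d
        ))
      }
      e[i] <- e[i] - d / 2
      s[i + 1] <- s[i + 1] + d / 2
    }
  }
  g$start <- s
  g$end <- e
  g[, setdiff(names(g), c("recording_id", "source_id")), drop = FALSE]
}
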