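#' Breathing-phase annotation tables
#'
#' Throughout the package an *annotation set* is an ordinary tibble with one
#' row per breathing-phase event ("box") and the columns
#'
#' * `recording_id` — identifier of the sound file,
#' * `source_id` — who produced the annotation (an annotator or a detector),
#' * `start`, `end` — event span in seconds, interpreted as the half-open
#'   interval `[start, end)` so that abutting phases are measure-disjoint,
#' * `phase` — `"inspiration"` or `"expiration"`,
#' * `confidence` — detector score in `[0, 1]`, `NA` for human annotations,
#' * `duration` — total length of the recording in seconds.
#'
#' `phase_annotations()` builds such a tibble for a single recording and
#' source; `validate_annotations()` checks the invariants (spans inside
#' `[0, duration]`, `start < end`, known phase labels, confidences in range,
#' rows sorted by start, and — for human-style sets, i.e. sets whose
#' confidences are all `NA` — pairwise non-overlapping events) and errors with
#' an informative message when one fails. Detector output may overlap before
#' post-processing, which is why overlap is only policed for human-style sets.
#'
#' @param start,end Numeric vectors of event boundaries in seconds.
#' @param phase Character vector of phase labels (normalised via
#'   [normalize_phase()]).
#' @param confidence Optional numeric vector of detector confidences.
#' @param recording_id,source_id Identifiers for the recording and the
#'   annotation source.
#' @param duration Recording length in seconds; defaults to `max(end)`.
#' @return A tibble as described above, sorted by
#'   `(recording_id, source_id, start, end)`.
#' @examples
#' phase_annotations(
#'   start = c(0, 2), end = c(1.4, 3.6),
#'   phase = c("i", "e"), recording_id = "rec01",
#'   source_id = "annotator1", duration = 15
#' )
#' @export
phase_annotations <- function(start, end, phase,
                              confidence = NA_real_,
                              recording_id = "recording",
                              source_id = "source",
                              duration = NULL) {
  if (length(start) == 0) {
    if (is.null(duration)) {
      abort("`duration` must be given for an empty annotation set.")
    }
    return(empty_annotations(recording_id, source_id, duration))
  }
  duration <- duration %||% max(end)
  x <- tibble(
    recording_id = as.character(recording_id),
    source_id = as.character(source_id),
    start = as.numeric(start),
    end = as.numeric(end),
    phase = normalize_phase(phase),
    confidence = as.numeric(confidence),
    duration = as.numeric(duration)
  )
  x <- dplyr::arrange(x, .data$recording_id, .data$source_id, .data$start, .data$end)
  validate_annotations(x)
}

#' @rdname phase_annotations
#' @export
empty_annotations <- function(recording_id = character(),
                              source_id = character(),
                              duration = numeric()) {
  n <- max(length(recording_id), length(source_id), length(duration), 0L)
  if (n == 0) {
    return(tibble(
      recording_id = character(), source_id = character(),
      start = numeric(), end = numeric(), phase = character(),
      confidence = numeric(), duration = numeric()
    ))
  }
  tibble(
    recording_id = as.character(recording_id),
    source_id = as.character(source_id),
    start = numeric(0), end = numeric(0), phase = character(0),
    confidence = numeric(0), duration = as.numeric(duration)
  )[0, ]
}

annotation_columns <- c(
  "recording_id", "source_id", "start", "end", "phase", "confidence", "duration"
)

#' @rdname phase_annotations
#' @param x A data frame of annotations.
#' @export
validate_annotations <- function(x) {
  x <- as_tibble(x)
  missing_cols <- setdiff(annotation_columns, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "Annotation table is missing column(s): ",
      paste(missing_cols, collapse = ", "), "."
    ))
  }
  if (nrow(x) == 0) return(x)
  bad <- !x$phase %in% phase_levels()
  if (any(bad)) {
    abort(paste0(
      "Unknown phase label(s): ",
      paste(unique(x$phase[bad]), collapse = ", "),
      ". Use normalize_phase() or a label mapping."
    ))
  }
  if (any(!is.finite(x$start)) || any(!is.finite(x$end))) {
    abort("Annotation starts and ends must be finite numbers.")
  }
  if (any(x$start < 0)) abort("Annotation starts must be >= 0.")
  if (any(x$start >= x$end)) {
    i <- which(x$start >= x$end)[1]
    abort(sprintf("Annotation row %d has start >= end (%g >= %g).",
                  i, x$start[i], x$end[i]))
  }
  if (any(x$end > x$duration + 1e-9)) {
    i <- which(x$end > x$duration + 1e-9)[1]
    abort(sprintf("Annotation row %d ends at %g s, after the recording end (%g s).",
                  i, x$end[i], x$duration[i]))
  }
  conf <- x$confidence[!is.na(x$confidence)]
  if (any(conf < 0 | conf > 1)) {
    abort("Confidences must lie in [0, 1].")
  }
  # Human-style sets (no confidences at all) must not self-overlap.
  grp <- split(seq_len(nrow(x)), paste(x$recording_id, x$source_id, sep = "\r"))
  for (idx in grp) {
    if (length(unique(x$duration[idx])) > 1) {
      abort(sprintf(
        "Recording '%s' has inconsistent durations for source '%s'.",
        x$recording_id[idx[1]], x$source_id[idx[1]]
      ))
    }
    if (all(is.na(x$confidence[idx])) && length(idx) > 1) {
      o <- idx[order(x$start[idx], x$end[idx])]
      if (any(x$start[o][-1] < x$end[o][-length(o)] - 1e-9)) {
        abort(sprintf(
          "Human-sourced set for recording '%s', source '%s' has overlapping intervals.",
          x$recording_id[idx[1]], x$source_id[idx[1]]
        ))
      }
    }
  }
  dplyr::arrange(x, .data$recording_id, .data$source_id, .data$start, .data$end)
}

phase_levels <- function() c("inspiration", "expiration")

#' Phase label mapping
#'
#' Annotators encode breathing phases differently ("i", "insp", "Inspiration",
#' ...). `phase_label_map()` returns the default mapping used by the readers;
#' `normalize_phase()` applies a mapping, case-insensitively, and errors
#' listing any label it cannot place.
#'
#' @param labels Character vector of raw labels.
#' @param map Named list with elements `inspiration` and `expiration`, each a
#'   character vector of accepted spellings.
#' @return `normalize_phase()`: character vector of canonical labels.
#' @export
phase_label_map <- function() {
  list(
    inspiration = c("inspiration", "i", "insp"),
    expiration = c("expiration", "e", "exp")
  )
}

#' @rdname phase_label_map
#' @export
normalize_phase <- function(labels, map = phase_label_map()) {
  lab <- tolower(trimws(as.character(labels)))
  out <- rep(NA_character_, length(lab))
  out[lab %in% tolower(map$inspiration)] <- "inspiration"
  out[lab %in% tolower(map$expiration)] <- "expiration"
  if (anyNA(out)) {
    abort(paste0(
      "Phase label(s) outside the configured mapping: ",
      paste(unique(labels[is.na(out)]), collapse = ", "), "."
    ))
  }
  out
}

# TRUE for labels that map to a phase, FALSE for background labels.
is_phase_label <- function(labels, map = phase_label_map()) {
  lab <- tolower(trimws(as.character(labels)))
  lab %in% tolower(c(map$inspiration, map$expiration))
}

# Split an annotation tibble into a named list of per-(recording, source)
# tibbles, preserving empty groups is impossible for plain tibbles, so
# callers that need empty sets carry durations separately.
annotation_groups <- function(x) {
  split(x, paste(x$recording_id, x$source_id, sep = "\r"), drop = TRUE)
}

# Durations per recording_id from an annotation tibble (first occurrence wins;
# validate_annotations already enforced per-source consistency).
recording_durations <- function(x) {
  d <- dplyr::distinct(x, .data$recording_id, .data$duration)
  dup <- duplicated(d$recording_id)
  if (any(dup)) {
    abort(paste0(
      "Recording(s) with conflicting durations across sources: ",
      paste(unique(d$recording_id[dup]), collapse = ", "), "."
    ))
  }
  d
}
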