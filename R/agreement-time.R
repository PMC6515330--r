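#' Merged phase regions of an annotation set
#'
#' The continuous-time agreement measures work on *regions*: the union of all
#' event spans of the selected class(es) for a recording, merged into
#' disjoint `[start, end)` spans. Abutting inspiration and expiration events
#' merge under `scope = "both"`.
#'
#' @param x Annotation tibble (a single recording, or use `recording`).
#' @param scope `"both"` (any breathing phase), `"inspiration"`, or
#'   `"expiration"`.
#' @param recording Optional recording id to select from a multi-recording
#'   tibble.
#' @return A tibble with columns `start`, `end`, sorted and disjoint.
#' @export
phase_region <- function(x, scope = c("both", "inspiration", "expiration"),
                         recording = NULL) {
  scope <- match.arg(scope)
  x <- validate_annotations(x)
  if (!is.null(recording)) x <- x[x$recording_id == recording, , drop = FALSE]
  if (scope != "both") x <- x[x$phase == scope, , drop = FALSE]
  m <- iv_merge(iv_matrix(x$start, x$end))
  tibble(start = unname(m[, 1]), end = unname(m[, 2]))
}

#' Continuous-time confusion durations between two annotations
#'
#' Treats the first source's phase region as the set `A` and the second's as
#' `B` and measures, exactly (by interval sweep, no time discretisation):
#' true positives `|A n B|`, false positives `|A - B|`, true negatives
#' `|!A n !B|`, and false negatives `|!A - !B| = |B - A|`, where `!` is the
#' complement within `[0, total]`. Note the orientation: `A` is the *human*
#' annotation and `B` the *prediction*, so a span only the human marked
#' counts as a false positive. This mirrors the evaluation convention this
#' package implements; `orientation = "conventional"` swaps the roles of `A`
#' and `B` (equivalently, swaps fp and fn) to recover the usual screening
#' convention.
#'
#' The four durations always sum to `total`.
#'
#' @param a,b Annotation tibbles over the same recordings (`a` plays the
#'   human/reference role `A`).
#' @param scope Phase scope, see [phase_region()].
#' @param orientation `"paper"` keeps `fp = |A - B|`; `"conventional"` swaps
#'   the roles of the two sources.
#' @param durations Optional tibble (`recording_id`, `duration`) naming the
#'   recordings to evaluate; a source with no events for a listed recording
#'   contributes an empty region. When `NULL`, the recording sets of `a` and
#'   `b` must coincide.
#' @return A tibble with one row per recording: `recording_id`, `tp`, `fp`,
#'   `tn`, `fn`, `total` (all in seconds).
#' @examples
#' a <- phase_annotations(0, 4, "i", recording_id = "r", duration = 10)
#' b <- phase_annotations(2, 6, "i", recording_id = "r",
#'                        source_id = "det", duration = 10)
#' time_confusion(a, b)  # tp 2, fp 2, fn 2, tn 4
#' @export
time_confusion <- function(a, b,
                           scope = c("both", "inspiration", "expiration"),
                           orientation = c("paper", "conventional"),
                           durations = NULL) {
  scope <- match.arg(scope)
  orientation <- match.arg(orientation)
  a <- validate_annotations(a)
  b <- validate_annotations(b)
  durations <- pair_durations(a, b, durations)
  out <- purrr::map_dfr(seq_len(nrow(durations)), function(k) {
    r <- durations$recording_id[k]
    total <- durations$duration[k]
    ra <- region_matrix(a, r, scope, total)
    rb <- region_matrix(b, r, scope, total)
    tc <- confusion_from_regions(ra, rb, total)
    tibble(recording_id = r, !!!tc)
  })
  if (orientation == "conventional") {
    out <- dplyr::rename(out, fp = "fn", fn = "fp")
    out <- out[, c("recording_id", "tp", "fp", "tn", "fn", "total")]
  }
  out
}

# Durations table for a pair of sources; errors on unpaired recordings when
# no explicit durations are supplied.
pair_durations <- function(a, b, durations = NULL) {
  if (!is.null(durations)) {
    stopifnot(all(c("recording_id", "duration") %in% names(durations)))
    return(durations[, c("recording_id", "duration")])
  }
  da <- recording_durations(a)
  db <- recording_durations(b)
  only_a <- setdiff(da$recording_id, db$recording_id)
  only_b <- setdiff(db$recording_id, da$recording_id)
  if (length(only_a) + length(only_b) > 0) {
    abort(paste0(
      "Unpaired recording(s): ",
      paste(c(only_a, only_b), collapse = ", "),
      ". Supply `durations` to evaluate recordings one source leaves empty."
    ))
  }
  m <- dplyr::inner_join(da, db, by = "recording_id",
                         suffix = c("_a", "_b"))
  bad <- abs(m$duration_a - m$duration_b) > 1e-6
  if (any(bad)) {
    abort(paste0(
      "Recording(s) with mismatched durations between sources: ",
      paste(m$recording_id[bad], collapse = ", "), "."
    ))
  }
  tibble(recording_id = m$recording_id, duration = m$duration_a)
}

region_matrix <- function(x, recording, scope, total) {
  x <- x[x$recording_id == recording, , drop = FALSE]
  if (scope != "both") x <- x[x$phase == scope, , drop = FALSE]
  if (nrow(x) > 0 && any(x$end > total + 1e-9)) {
    abort(sprintf("Region exceeds [0, %g] for recording '%s'.",
                  total, recording))
  }
  iv_clip(iv_merge(iv_matrix(x$start, x$end)), total)
}

confusion_from_regions <- function(ra, rb, total) {
  tp <- iv_measure(iv_intersect(ra, rb))
  fp <- iv_measure(ra) - tp                    # |A - B|
  fn <- iv_measure(rb) - tp                    # |B - A| = |!A - !B|
  tn <- total - (iv_measure(ra) + iv_measure(rb) - tp)
  list(tp = tp, fp = fp, tn = tn, fn = fn, total = total)
}

#' Sensitivity and specificity from continuous-time confusion durations
#'
#' `sensitivity = tp / (tp + fn)` and `specificity = tn / (tn + fp)`, applied
#' row-wise to the output of [time_confusion()]. A zero denominator gives
#' `NA` (undefined, excluded from averages) rather than an error.
#'
#' @param tc A tibble with columns `tp`, `fp`, `tn`, `fn`.
#' @return Numeric vector, `NA` where undefined.
#' @export
sensitivity <- function(tc) {
  denom <- tc$tp + tc$fn
  ifelse(denom > 0, tc$tp / denom, NA_real_)
}

#' @rdname sensitivity
#' @export
specificity <- function(tc) {
  denom <- tc$tn + tc$fp
  ifelse(denom > 0, tc$tn / denom, NA_real_)
}

#' Corpus-level continuous-time agreement summary
#'
#' Computes per-recording sensitivity and specificity for the inspiration,
#' expiration and both-phase scopes and averages them (unweighted) over the
#' recordings where they are defined. The both-phase scope is the
#' union-region computation; the mean of the two per-class averages is
#' reported alongside as scope `"class_mean"`.
#'
#' @inheritParams time_confusion
#' @return A tibble with one row per scope: `scope`, `mean_sensitivity`,
#'   `mean_specificity`, `n_files`, `n_defined_sens`, `n_defined_spec`.
#' @export
corpus_summary <- function(a, b, orientation = c("paper", "conventional"),
                           durations = NULL) {
  orientation <- match.arg(orientation)
  scopes <- c("inspiration", "expiration", "both")
  rows <- purrr::map_dfr(scopes, function(sc) {
    tc <- time_confusion(a, b, scope = sc, orientation = orientation,
                         durations = durations)
    se <- sensitivity(tc)
    sp <- specificity(tc)
    tibble(
      scope = sc,
      mean_sensitivity = mean(se, na.rm = TRUE),
      mean_specificity = mean(sp, na.rm = TRUE),
      n_files = nrow(tc),
      n_defined_sens = sum(!is.na(se)),
      n_defined_spec = sum(!is.na(sp))
    )
  })
  class_mean <- tibble(
    scope = "class_mean",
    mean_sensitivity = mean(rows$mean_sensitivity[1:2]),
    mean_specificity = mean(rows$mean_specificity[1:2]),
    n_files = rows$n_files[1],
    n_defined_sens = NA_integer_,
    n_defined_spec = NA_integer_
  )
  dplyr::bind_rows(rows, class_mean)
}
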