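#' Jaccard index of time intervals
#'
#' Intersection length over union length of two `[start, end)` intervals;
#' 0 for disjoint intervals, 1 iff identical. Vectorised.
#'
#' @param a_start,a_end,b_start,b_end Interval boundaries in seconds.
#' @return Numeric vector in `[0, 1]`.
#' @examples
#' interval_jaccard(0, 2, 1, 3)  # 1/3
#' @export
interval_jaccard <- function(a_start, a_end, b_start, b_end) {
  inter <- pmax(0, pmin(a_end, b_end) - pmax(a_start, b_start))
  uni <- (a_end - a_start) + (b_end - b_start) - inter
  ifelse(uni > 0, inter / uni, 0)
}

#' Match annotation boxes between two sources
#'
#' Box-level agreement counts a pair of boxes as agreeing when they are of
#' the same phase class and their Jaccard index exceeds the threshold.
#' Matching is one-to-one within each recording and class: candidate pairs
#' above the threshold are accepted greedily in descending Jaccard (ties
#' broken by earlier start in `a`, then in `b`), each box used at most once.
#'
#' @param a,b Annotation tibbles over the same recordings.
#' @param threshold Jaccard threshold (strict); default 0.5.
#' @return A tibble of matched pairs: `recording_id`, `phase`,
#'   `a_start`, `a_end`, `b_start`, `b_end`, `jaccard`.
#' @export
match_boxes <- function(a, b, threshold = 0.5) {
  a <- validate_annotations(a)
  b <- validate_annotations(b)
  recs <- union(unique(a$recording_id), unique(b$recording_id))
  out <- purrr::map_dfr(recs, function(r) {
    ar <- a[a$recording_id == r, , drop = FALSE]
    br <- b[b$recording_id == r, , drop = FALSE]
    purrr::map_dfr(phase_levels(), function(ph) {
      match_boxes_class(ar[ar$phase == ph, ], br[br$phase == ph, ], r, ph, threshold)
    })
  })
  if (nrow(out) == 0) {
    out <- tibble(
      recording_id = character(), phase = character(),
      a_start = numeric(), a_end = numeric(),
      b_start = numeric(), b_end = numeric(), jaccard = numeric()
    )
  }
  out
}

match_boxes_class <- function(ar, br, recording_id, phase, threshold) {
  if (nrow(ar) == 0 || nrow(br) == 0) return(NULL)
  cand <- tidyr::expand_grid(i = seq_len(nrow(ar)), j = seq_len(nrow(br)))
  cand$jaccard <- interval_jaccard(
    ar$start[cand$i], ar$end[cand$i], br$start[cand$j], br$end[cand$j]
  )
  cand <- cand[cand$jaccard > threshold, , drop = FALSE]
  cand <- cand[order(-cand$jaccard, ar$start[cand$i], br$start[cand$j]), ,
               drop = FALSE]
  used_i <- logical(nrow(ar))
  used_j <- logical(nrow(br))
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    i <- cand$i[k]; j <- cand$j[k]
    if (!used_i[i] && !used_j[j]) {
      keep[k] <- TRUE
      used_i[i] <- TRUE
      used_j[j] <- TRUE
    }
  }
  cand <- cand[keep, , drop = FALSE]
  if (nrow(cand) == 0) return(NULL)
  tibble(
    recording_id = recording_id, phase = phase,
    a_start = ar$start[cand$i], a_end = ar$end[cand$i],
    b_start = br$start[cand$j], b_end = br$end[cand$j],
    jaccard = cand$jaccard
  )
}

#' Box-level percentage agreement between two annotation sources
#'
#' For each phase class, and pooled over both classes, counts the one-to-one
#' matched pairs (see [match_boxes()]) and expresses them as a percentage of
#' the box count. The denominator is symmetric by default — the mean of the
#' two sources' box counts — so the statistic treats annotators
#' interchangeably; `"a"` (reference count) and `"max"` are available as
#' alternatives. Counts are pooled over all recordings; `by_file = TRUE`
#' instead averages per-file percentages. When both sources have zero boxes
#' the agreement is 100 by convention.
#'
#' @inheritParams match_boxes
#' @param denominator `"mean"`, `"a"`, or `"max"`.
#' @param by_file Average per-file percentages instead of pooling counts.
#' @return A tibble with one row per scope (`inspiration`, `expiration`,
#'   `both`): `matched`, `boxes_a`, `boxes_b`, `percent`.
#' @examples
#' a <- phase_annotations(c(0, 2), c(1.5, 3.5), c("i", "e"),
#'                        recording_id = "r", source_id = "A", duration = 5)
#' percent_agreement(a, a)
#' @export
percent_agreement <- function(a, b, threshold = 0.5,
                              denominator = c("mean", "a", "max"),
                              by_file = FALSE) {
  denominator <- match.arg(denominator)
  a <- validate_annotations(a)
  b <- validate_annotations(b)
  matches <- match_boxes(a, b, threshold)
  recs <- union(unique(a$recording_id), unique(b$recording_id))
  per_file <- purrr::map_dfr(recs, function(r) {
    purrr::map_dfr(c(phase_levels(), "both"), function(ph) {
      in_scope <- function(x) {
        x$recording_id == r & (ph == "both" | x$phase == ph)
      }
      tibble(
        recording_id = r, phase = ph,
        matched = sum(in_scope(matches)),
        boxes_a = sum(in_scope(a)),
        boxes_b = sum(in_scope(b))
      )
    })
  })
  agreement_percent <- function(matched, boxes_a, boxes_b) {
    denom <- switch(denominator,
      mean = (boxes_a + boxes_b) / 2,
      a = boxes_a,
      max = pmax(boxes_a, boxes_b)
    )
    ifelse(boxes_a + boxes_b == 0, 100, 100 * matched / denom)
  }
  if (by_file) {
    per_file$percent <- agreement_percent(
      per_file$matched, per_file$boxes_a, per_file$boxes_b
    )
    out <- dplyr::summarise(
      dplyr::group_by(per_file, .data$phase),
      matched = sum(.data$matched),
      boxes_a = sum(.data$boxes_a),
      boxes_b = sum(.data$boxes_b),
      percent = mean(.data$percent),
      .groups = "drop"
    )
  } else {
    out <- dplyr::summarise(
      dplyr::group_by(per_file, .data$phase),
      matched = sum(.data$matched),
      boxes_a = sum(.data$boxes_a),
      boxes_b = sum(.data$boxes_b),
      .groups = "drop"
    )
    out$percent <- agreement_percent(out$matched, out$boxes_a, out$boxes_b)
  }
  out[match(c("inspiration", "expiration", "both"), out$phase), ]
}
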