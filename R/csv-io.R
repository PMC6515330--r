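#' Read and write annotation CSV files
#'
#' The CSV dialect is comma-separated with a `.` decimal separator and the
#' exact header `recording_id,source_id,start_s,end_s,phase,confidence,duration_s`.
#' A blank `confidence` field means "no confidence" (a human annotation);
#' `read_annotations_csv()` validates every row against the annotation
#' invariants and reports the offending data row number on failure.
#'
#' @param path Path to a CSV file.
#' @return `read_annotations_csv()`: one annotation tibble covering all
#'   `(recording_id, source_id)` groups in the file, sorted by recording,
#'   source and start time.
#' @export
read_annotations_csv <- function(path) {
  if (!file.exists(path)) abort(paste0("Annotation CSV not found: ", path))
  expected <- c("recording_id", "source_id", "start_s", "end_s",
                "phase", "confidence", "duration_s")
  first_line <- readLines(path, n = 1)
  header <- if (length(first_line)) strsplit(first_line, ",")[[1]] else character()
  if (!identical(trimws(header), expected)) {
    abort(paste0(
      "Annotation CSV must have header exactly: ",
      paste(expected, collapse = ","), "."
    ))
  }
  x <- readr::read_csv(
    path,
    col_types = readr::cols(
      recording_id = readr::col_character(),
      source_id = readr::col_character(),
      start_s = readr::col_double(),
      end_s = readr::col_double(),
      phase = readr::col_character(),
      confidence = readr::col_double(),
      duration_s = readr::col_double()
    ),
    progress = FALSE
  )
  if (!identical(names(x), expected)) {
    abort(paste0(
      "Annotation CSV must have header exactly: ",
      paste(expected, collapse = ","), "."
    ))
  }
  if (nrow(x) == 0) return(empty_annotations())
  for (i in seq_len(nrow(x))) {
    row_check <- function(ok, msg) {
      if (!ok) abort(sprintf("Annotation CSV row %d: %s", i, msg))
    }
    row_check(is.finite(x$start_s[i]) && is.finite(x$end_s[i]),
              "start_s and end_s must be numbers.")
    row_check(x$start_s[i] >= 0, "start_s must be >= 0.")
    row_check(x$start_s[i] < x$end_s[i],
              sprintf("start_s >= end_s (%g >= %g).", x$start_s[i], x$end_s[i]))
    row_check(is.finite(x$duration_s[i]) && x$duration_s[i] > 0,
              "duration_s must be a positive number.")
    row_check(x$end_s[i] <= x$duration_s[i] + 1e-9,
              sprintf("end_s (%g) exceeds duration_s (%g).",
                      x$end_s[i], x$duration_s[i]))
    row_check(is_phase_label(x$phase[i]),
              sprintf("unknown phase label '%s'.", x$phase[i]))
    row_check(is.na(x$confidence[i]) ||
                (x$confidence[i] >= 0 && x$confidence[i] <= 1),
              "confidence must be blank or in [0, 1].")
  }
  out <- tibble(
    recording_id = x$recording_id,
    source_id = x$source_id,
    start = x$start_s,
    end = x$end_s,
    phase = normalize_phase(x$phase),
    confidence = x$confidence,
    duration = x$duration_s
  )
  validate_annotations(out)
}

#' @rdname read_annotations_csv
#' @param x Annotation tibble (any number of recordings and sources).
#' @return `write_annotations_csv()`: `path`, invisibly.
#' @export
write_annotations_csv <- function(x, path) {
  x <- validate_annotations(x)
  out <- tibble(
    recording_id = x$recording_id,
    source_id = x$source_id,
    start_s = x$start,
    end_s = x$end,
    phase = x$phase,
    confidence = x$confidence,
    duration_s = x$duration
  )
  out <- dplyr::arrange(out, .data$recording_id, .data$source_id, .data$start_s)
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}
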