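#' Read breathing-phase annotations from a Praat TextGrid
#'
#' Parses a Praat TextGrid file (long or short text dialect, UTF-8) and turns
#' the named interval tier into an annotation tibble. Tier intervals whose
#' label maps to a phase class become events; empty or unmapped-but-blank
#' labels are background and are dropped; a non-empty label that is neither a
#' phase nor blank is an error (it usually means the wrong tier was chosen).
#'
#' @param path Path to a TextGrid file.
#' @param tier Name of the interval tier holding the phase labels.
#' @param recording_id Identifier for the recording; defaults to the file name
#'   without extension.
#' @param source_id Identifier for the annotator.
#' @param duration Recording length in seconds; defaults to the tier's `xmax`.
#' @param label_map Phase label mapping, see [phase_label_map()].
#' @return An annotation tibble (see [phase_annotations()]).
#' @export
read_textgrid <- function(path, tier = "phase",
                          recording_id = NULL,
                          source_id = "annotator",
                          duration = NULL,
                          label_map = phase_label_map()) {
  if (!file.exists(path)) abort(paste0("TextGrid file not found: ", path))
  recording_id <- recording_id %||% sub("\\.[^.]*$", "", basename(path))
  tg <- parse_textgrid(readLines(path, encoding = "UTF-8", warn = FALSE))
  names_avail <- vapply(tg, `[[`, character(1), "name")
  hit <- which(names_avail == tier)
  if (length(hit) == 0) {
    abort(paste0(
      "TextGrid has no interval tier named '", tier, "'. Available: ",
      paste(names_avail, collapse = ", "), "."
    ))
  }
  t <- tg[[hit[1]]]
  duration <- duration %||% t$xmax
  iv <- t$intervals
  labelled <- nzchar(trimws(iv$text))
  iv <- iv[labelled, , drop = FALSE]
  if (nrow(iv) == 0) {
    return(empty_annotations(recording_id, source_id, duration))
  }
  bad <- !is_phase_label(iv$text, label_map)
  if (any(bad)) {
    abort(paste0(
      "Tier '", tier, "' has label(s) outside the phase mapping: ",
      paste(unique(iv$text[bad]), collapse = ", "), "."
    ))
  }
  phase_annotations(
    start = iv$xmin, end = iv$xmax,
    phase = normalize_phase(iv$text, label_map),
    recording_id = recording_id, source_id = source_id,
    duration = duration
  )
}

#' Write an annotation set as a Praat TextGrid
#'
#' Emits a long-format TextGrid with a single interval tier spanning
#' `[0, duration]`; gaps between phases are intervals with an empty label.
#' The set must be non-overlapping (post-process detector output first).
#'
#' @param x Annotation tibble for a single recording and source.
#' @param path Output file path.
#' @param tier Name of the interval tier to write.
#' @param duration Recording length, only needed when `x` has no rows.
#' @return `path`, invisibly.
#' @export
write_textgrid <- function(x, path, tier = "phase", duration = NULL) {
  x <- validate_annotations(x)
  if (nrow(x) > 0 &&
      (length(unique(x$recording_id)) > 1 || length(unique(x$source_id)) > 1)) {
    abort("write_textgrid() writes one recording/source at a time.")
  }
  dur <- if (nrow(x) > 0) x$duration[1] else duration %||% NA_real_
  if (!is.finite(dur)) {
    abort("Cannot write an empty annotation table without a `duration`.")
  }
  x <- dplyr::arrange(x, .data$start)
  if (nrow(x) > 1 && any(x$start[-1] < x$end[-nrow(x)] - 1e-12)) {
    abort("TextGrid tiers cannot hold overlapping intervals; post-process first.")
  }
  # Build the full tier including background gaps.
  xmin <- numeric(0); xmax <- numeric(0); text <- character(0)
  cursor <- 0
  for (i in seq_len(nrow(x))) {
    if (x$start[i] > cursor + 1e-12) {
      xmin <- c(xmin, cursor); xmax <- c(xmax, x$start[i]); text <- c(text, "")
    }
    xmin <- c(xmin, x$start[i]); xmax <- c(xmax, x$end[i]); text <- c(text, x$phase[i])
    cursor <- x$end[i]
  }
  if (cursor < dur - 1e-12 || length(xmin) == 0) {
    xmin <- c(xmin, cursor); xmax <- c(xmax, dur); text <- c(text, "")
  }
  num <- function(v) formatC(v, format = "fg", digits = 17)
  lines <- c(
    'File type = "ooTextFile"',
    'Object class = "TextGrid"',
    "",
    "xmin = 0",
    paste0("xmax = ", num(dur)),
    "tiers? <exists>",
    "size = 1",
    "item []:",
    "    item [1]:",
    '        class = "IntervalTier"',
    paste0('        name = "', tier, '"'),
    "        xmin = 0",
    paste0("        xmax = ", num(dur)),
    paste0("        intervals: size = ", length(xmin))
  )
  for (i in seq_along(xmin)) {
    lines <- c(
      lines,
      paste0("        intervals [", i, "]:"),
      paste0("            xmin = ", num(xmin[i])),
      paste0("            xmax = ", num(xmax[i])),
      paste0('            text = "', gsub('"', '""', text[i]), '"')
    )
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

# --- TextGrid parsing ------------------------------------------------------
# Returns a list of interval tiers: list(name, xmin, xmax,
# intervals = tibble(xmin, xmax, text)). Praat's two text dialects are
# supported: the long form has "key = value" lines, the short form bare
# values in a fixed order. Point tiers are skipped.

parse_textgrid <- function(lines) {
  if (length(lines) < 3) abort("Not a TextGrid file (too short).")
  if (!grepl("ooTextFile", lines[1]) || !any(grepl("TextGrid", lines[2]))) {
    abort("Not a TextGrid file (missing ooTextFile/TextGrid header).")
  }
  if (any(grepl("^\\s*xmin\\s*=", lines[-(1:2)]))) {
    parse_textgrid_long(lines)
  } else {
    parse_textgrid_short(lines)
  }
}

tg_unquote <- function(s) {
  s <- sub('^\\s*"', "", s)
  s <- sub('"\\s*$', "", s)
  gsub('""', '"', s)
}

parse_textgrid_long <- function(lines) {
  val <- function(line) trimws(sub("^[^=]*=", "", line))
  tier_starts <- grep('class\\s*=\\s*"(IntervalTier|TextTier)"', lines)
  tiers <- list()
  for (k in seq_along(tier_starts)) {
    i0 <- tier_starts[k]
    i1 <- if (k < length(tier_starts)) tier_starts[k + 1] - 1 else length(lines)
    block <- lines[i0:i1]
    if (!grepl("IntervalTier", block[1])) next
    name <- tg_unquote(val(block[grep("^\\s*name\\s*=", block)[1]]))
    xmin_t <- as.numeric(val(block[grep("^\\s*xmin\\s*=", block)[1]]))
    xmax_t <- as.numeric(val(block[grep("^\\s*xmax\\s*=", block)[1]]))
    xm <- grep("^\\s*xmin\\s*=", block)
    xx <- grep("^\\s*xmax\\s*=", block)
    tx <- grep("^\\s*text\\s*=", block)
    # First xmin/xmax belong to the tier itself; each interval contributes one
    # xmin, xmax, text triple (text lines may in principle span lines; Praat
    # phase labels never do, so single-line texts are assumed).
    n <- length(tx)
    ivs <- tibble(
      xmin = as.numeric(vapply(block[xm[-1]], val, character(1))),
      xmax = as.numeric(vapply(block[xx[-1]], val, character(1))),
      text = vapply(block[tx], function(l) tg_unquote(val(l)), character(1))
    )
    if (nrow(ivs) != n) abort("Malformed TextGrid interval tier.")
    tiers[[length(tiers) + 1]] <- list(
      name = name, xmin = xmin_t, xmax = xmax_t, intervals = ivs
    )
  }
  if (length(tiers) == 0) abort("TextGrid contains no interval tiers.")
  tiers
}

parse_textgrid_short <- function(lines) {
  toks <- trimws(lines[-(1:2)])
  toks <- toks[nzchar(toks)]
  # toks: xmin xmax <exists> ntiers then per tier: class name xmin xmax n (triples)
  if (length(toks) < 4) abort("Malformed short TextGrid.")
  pos <- 3L                      # skip global xmin, xmax
  if (grepl("exists", toks[pos])) pos <- pos + 1L
  ntier <- as.integer(toks[pos]); pos <- pos + 1L
  tiers <- list()
  for (t in seq_len(ntier)) {
    cls <- tg_unquote(toks[pos]); pos <- pos + 1L
    name <- tg_unquote(toks[pos]); pos <- pos + 1L
    xmin_t <- as.numeric(toks[pos]); pos <- pos + 1L
    xmax_t <- as.numeric(toks[pos]); pos <- pos + 1L
    n <- as.integer(toks[pos]); pos <- pos + 1L
    if (identical(cls, "IntervalTier")) {
      xmin <- numeric(n); xmax <- numeric(n); text <- character(n)
      for (i in seq_len(n)) {
        xmin[i] <- as.numeric(toks[pos]); pos <- pos + 1L
        xmax[i] <- as.numeric(toks[pos]); pos <- pos + 1L
        text[i] <- tg_unquote(toks[pos]); pos <- pos + 1L
      }
      tiers[[length(tiers) + 1]] <- list(
        name = name, xmin = xmin_t, xmax = xmax_t,
        intervals = tibble(xmin = xmin, xmax = xmax, text = text)
      )
    } else {
      pos <- pos + 2L * n        # point tier: time + mark per point
    }
  }
  if (length(tiers) == 0) abort("TextGrid contains no interval tiers.")
  tiers
}
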