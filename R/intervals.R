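# Exact interval-set algebra on [start, end) spans.
#
# All functions take and return two-column numeric matrices (start, end) with
# rows sorted by start and pairwise disjoint ("canonical" form). This is the
# computational core of the continuous-time agreement measures: durations are
# computed by an exact sweep, never by discretising time onto a grid.

iv_matrix <- function(start, end) {
  m <- cbind(start = as.numeric(start), end = as.numeric(end))
  m[m[, 1] < m[, 2], , drop = FALSE]
}

iv_empty <- function() {
  matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("start", "end")))
}

# Union-merge arbitrary spans into canonical form. Abutting spans ([a,b), [b,c))
# merge into one: under the closed-open convention they cover [a,c) exactly.
iv_merge <- function(m) {
  if (nrow(m) == 0) return(iv_empty())
  m <- m[order(m[, 1], m[, 2]), , drop = FALSE]
  starts <- m[1, 1]
  ends <- m[1, 2]
  if (nrow(m) > 1) {
    for (i in 2:nrow(m)) {
      k <- length(ends)
      if (m[i, 1] <= ends[k]) {
        ends[k] <- max(ends[k], m[i, 2])
      } else {
        starts <- c(starts, m[i, 1])
        ends <- c(ends, m[i, 2])
      }
    }
  }
  iv_matrix(starts, ends)
}

# Intersection of two canonical interval sets (two-pointer sweep).
iv_intersect <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) return(iv_empty())
  out_s <- numeric(0)
  out_e <- numeric(0)
  i <- 1L
  j <- 1L
  while (i <= nrow(a) && j <= nrow(b)) {
    lo <- max(a[i, 1], b[j, 1])
    hi <- min(a[i, 2], b[j, 2])
    if (lo < hi) {
      out_s <- c(out_s, lo)
      out_e <- c(out_e, hi)
    }
    if (a[i, 2] <= b[j, 2]) i <- i + 1L else j <- j + 1L
  }
  iv_matrix(out_s, out_e)
}

# Complement of a canonical set within [0, total].
iv_complement <- function(m, total) {
  if (nrow(m) == 0) return(iv_matrix(0, total))
  edges <- c(0, as.vector(t(m)), total)
  starts <- edges[seq(1, length(edges) - 1, by = 2)]
  ends <- edges[seq(2, length(edges), by = 2)]
  iv_matrix(starts, ends)
}

# Set difference a \ b.
iv_setdiff <- function(a, b, total) {
  if (nrow(a) == 0) return(iv_empty())
  iv_intersect(a, iv_complement(b, total))
}

# Clip a canonical set to [0, total].
iv_clip <- function(m, total) {
  if (nrow(m) == 0) return(m)
  s <- pmax(m[, 1], 0)
  e <- pmin(m[, 2], total)
  iv_matrix(s, e)
}

iv_measure <- function(m) {
  if (nrow(m) == 0) return(0)
  sum(m[, 2] - m[, 1])
}
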