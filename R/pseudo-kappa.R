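#' Continuous-time pseudo-kappa between two annotation sources
#'
#' A continuous-time analogue of Cohen's kappa for interval annotations.
#' Observed agreement `po` is the duration-weighted fraction of time the two
#' sources agree, pooled over the corpus: `sum(tp + tn) / sum(total)`.
#' Chance agreement `pe` breaks the link between annotation and sound
#' structure by re-pairing each first-source annotation with a second-source
#' annotation from a *different* recording (a random derangement of the
#' pairing), computing the same pooled agreement, and averaging over
#' `n_shuffles` repetitions; recordings of unequal length are truncated to
#' the shorter one. Then `kappa = (po - pe) / (1 - pe)`.
#'
#' Confidence intervals are non-parametric bootstrap percentile intervals:
#' recordings are resampled with replacement `n_bootstrap` times and the
#' whole statistic (including `pe`) recomputed on each resample.
#'
#' The label follows the usual interpretation scale: 0 no agreement,
#' (0, 0.20] slight, (0.20, 0.40] fair, (0.40, 0.60] moderate,
#' (0.60, 0.80] substantial, (0.80, 1] almost perfect agreement.
#'
#' @inheritParams time_confusion
#' @param n_shuffles Number of random re-pairings used to estimate chance
#'   agreement.
#' @param n_bootstrap Number of bootstrap resamples for the confidence
#'   interval.
#' @param seed Integer seed; mandatory for reproducibility.
#' @param conf_level Bootstrap interval coverage (default 0.95, i.e. the
#'   2.5/97.5 percentiles).
#' @return An object of class `pseudo_kappa`: a list with `po`, `pe`,
#'   `kappa`, `ci_low`, `ci_high`, `interpretation`, `scope`, `n_files`,
#'   `n_shuffles`, `n_bootstrap`, `seed`. `tidy()`/`glance()` return it as a
#'   one-row tibble.
#' @examples
#' prof <- breathing_profile(duration = 10)
#' truth <- purrr::map_dfr(1:4, function(i)
#'   generate_schedule(prof, seed = i, recording_id = paste0("r", i)))
#' noisy <- corrupt_annotations(truth,
#'   annotator_noise(boundary_jitter_sd = 0.1), seed = 9)
#' pseudo_kappa(truth, noisy, n_shuffles = 20, n_bootstrap = 50, seed = 1)
#' @export
pseudo_kappa <- function(a, b,
                         scope = c("both", "inspiration", "expiration"),
                         n_shuffles = 100,
                         n_bootstrap = 1000,
                         seed = 1,
                         conf_level = 0.95,
                         durations = NULL) {
  scope <- match.arg(scope)
  a <- validate_annotations(a)
  b <- validate_annotations(b)
  durations <- pair_durations(a, b, durations)
  durations <- durations[order(durations$recording_id), , drop = FALSE]
  n <- nrow(durations)
  if (n < 2) abort("pseudo_kappa needs at least 2 paired recordings.")

  # Precompute the n x n cross-pairing agreement table: agr[i, j] is the
  # agreement duration (|A_i n B_j| + |!A_i n !B_j|) when recording i's
  # first-source annotation is paired with recording j's second-source
  # annotation, both truncated to the shorter duration tot[i, j]. All
  # shuffles and bootstrap resamples are then pure table lookups.
  regions_a <- lapply(seq_len(n), function(i) {
    region_matrix(a, durations$recording_id[i], scope, durations$duration[i])
  })
  regions_b <- lapply(seq_len(n), function(i) {
    region_matrix(b, durations$recording_id[i], scope, durations$duration[i])
  })
  agr <- matrix(0, n, n)
  tot <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      total <- min(durations$duration[i], durations$duration[j])
      ra <- iv_clip(regions_a[[i]], total)
      rb <- iv_clip(regions_b[[j]], total)
      tc <- confusion_from_regions(ra, rb, total)
      agr[i, j] <- tc$tp + tc$tn
      tot[i, j] <- total
    }
  }
  diag_idx <- cbind(seq_len(n), seq_len(n))

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(as.integer(seed))

  pooled_agreement <- function(idx, perm = seq_along(idx)) {
    pairs <- cbind(idx, idx[perm])
    sum(agr[pairs]) / sum(tot[pairs])
  }
  chance_agreement <- function(idx) {
    mean(vapply(seq_len(n_shuffles), function(s) {
      pooled_agreement(idx, random_derangement(length(idx)))
    }, numeric(1)))
  }
  kappa_of <- function(idx) {
    po <- pooled_agreement(idx)
    pe <- chance_agreement(idx)
    k <- if (pe < 1) (po - pe) / (1 - pe) else NA_real_
    c(po = po, pe = pe, kappa = k)
  }

  full <- kappa_of(seq_len(n))
  if (is.na(full[["kappa"]])) {
    warn("Chance agreement is 1; pseudo-kappa is undefined for this corpus.")
  }
  boot <- vapply(seq_len(n_bootstrap), function(b) {
    kappa_of(sample.int(n, n, replace = TRUE))[["kappa"]]
  }, numeric(1))
  boot <- boot[is.finite(boot)]
  alpha <- (1 - conf_level) / 2
  ci <- if (length(boot) > 0) {
    quantile(boot, c(alpha, 1 - alpha), names = FALSE)
  } else {
    c(NA_real_, NA_real_)
  }

  structure(
    list(
      po = unname(full[["po"]]),
      pe = unname(full[["pe"]]),
      kappa = unname(full[["kappa"]]),
      ci_low = ci[1],
      ci_high = ci[2],
      interpretation = kappa_interpretation(full[["kappa"]]),
      scope = scope,
      n_files = n,
      n_shuffles = n_shuffles,
      n_bootstrap = n_bootstrap,
      conf_level = conf_level,
      seed = seed
    ),
    class = "pseudo_kappa"
  )
}

# Uniform random derangement (permutation without fixed points) by rejection.
random_derangement <- function(n) {
  if (n < 2) abort("A derangement needs n >= 2.")
  repeat {
    p <- sample.int(n)
    if (!any(p == seq_len(n))) return(p)
  }
}

#' Interpretation label for a kappa value
#'
#' Bins are half-open on the left so the printed range boundaries
#' (0.20, 0.40, 0.60, 0.80) fall into the lower category.
#'
#' @param kappa Numeric vector of kappa values.
#' @return Character vector of labels.
#' @examples
#' kappa_interpretation(c(0, 0.15, 0.75, 0.9))
#' @export
kappa_interpretation <- function(kappa) {
  labels <- c("no agreement", "slight agreement", "fair agreement",
              "moderate agreement", "substantial agreement",
              "almost perfect agreement")
  out <- as.character(cut(kappa, breaks = c(-Inf, 0, 0.2, 0.4, 0.6, 0.8, Inf),
                          labels = labels, right = TRUE))
  out[is.na(kappa)] <- NA_character_
  out
}

#' @export
print.pseudo_kappa <- function(x, ...) {
  cat(sprintf(
    paste0(
      "Continuous-time pseudo-kappa (%s scope, %d recordings)\n",
      "  observed agreement po = %.4f\n",
      "  chance agreement   pe = %.4f  (%d shuffles)\n",
      "  kappa = %.4f  [%.4f, %.4f] (%d%% bootstrap percentile, %d resamples)\n",
      "  interpretation: %s\n"
    ),
    x$scope, x$n_files, x$po, x$pe, x$n_shuffles,
    x$kappa, x$ci_low, x$ci_high,
    round(100 * x$conf_level), x$n_bootstrap, x$interpretation
  ))
  invisible(x)
}

#' @rdname pseudo_kappa
#' @param x A `pseudo_kappa` object.
#' @param ... Unused.
#' @export
tidy.pseudo_kappa <- function(x, ...) {
  tibble(
    scope = x$scope, po = x$po, pe = x$pe, kappa = x$kappa,
    ci_low = x$ci_low, ci_high = x$ci_high,
    interpretation = x$interpretation
  )
}

#' @rdname pseudo_kappa
#' @export
glance.pseudo_kappa <- function(x, ...) {
  tibble(
    kappa = x$kappa, ci_low = x$ci_low, ci_high = x$ci_high,
    n_files = x$n_files, n_shuffles = x$n_shuffles,
    n_bootstrap = x$n_bootstrap, seed = x$seed
  )
}
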