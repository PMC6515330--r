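test_that("phase regions merge abutting and overlapping spans into disjoint unions", {
  x <- phase_annotations(c(0, 1), c(1, 2), c("i", "e"),
                         recording_id = "r", duration = 5)
  both <- phase_region(x, "both")
  expect_equal(nrow(both), 1)
  expect_equal(c(both$start, both$end), c(0, 2))
  insp <- phase_region(x, "inspiration")
  expect_equal(c(insp$start, insp$end), c(0, 1))
  only_e <- phase_annotations(2, 3, "e", recording_id = "r", duration = 5)
  expect_equal(nrow(phase_region(only_e, "inspiration")), 0)
  # merged measure agrees with a dense-grid count on random overlapping spans
  set.seed(31)
  for (k in 1:10) {
    n <- sample.int(10, 1)
    s <- runif(n, 0, 9)
    det <- phase_annotations(s, pmin(s + runif(n, 0.1, 3), 10),
                             sample(c("i", "e"), n, TRUE),
                             confidence = 0.9, recording_id = "r", duration = 10)
    reg <- phase_region(det, "both")
    m <- as.matrix(reg)
    expect_false(has_overlapping_pair(
      dplyr::mutate(reg, recording_id = "r", source_id = "x")
    ))
    g <- grid_confusion(m, m, 10, step = 0.001)
    expect_equal(sum(reg$end - reg$start), g$tp, tolerance = 0.001 * (2 * n + 2))
  }
})

test_that("confusion durations follow the set definitions and conserve total time", {
  a <- phase_annotations(0, 4, "i", recording_id = "r", duration = 10)
  b <- phase_annotations(2, 6, "i", recording_id = "r",
                         source_id = "B", duration = 10)
  tc <- time_confusion(a, b)
  expect_equal(tc$tp, 2)   # |A n B|
  expect_equal(tc$fp, 2)   # |A - B|: human-only time counts against, not for
  expect_equal(tc$fn, 2)   # |B - A|
  expect_equal(tc$tn, 4)   # |!A n !B|
  expect_equal(tc$tp + tc$fp + tc$tn + tc$fn, tc$total, tolerance = 1e-12)
  # identity: A = B
  tcs <- time_confusion(a, a)
  expect_equal(tcs$fp, 0); expect_equal(tcs$fn, 0)
  expect_equal(tcs$tp, 4); expect_equal(tcs$tn, 6)
  # the conventional orientation swaps fp and fn
  conv <- time_confusion(a, b, orientation = "conventional")
  expect_equal(conv$fp, tc$fn)
  expect_equal(conv$fn, tc$fp)
})

test_that("exact sweep agrees with the dense-grid oracle on random pairs", {
  for (seed in 1:25) {
    a <- random_human_set(seed, "r", "A", duration = 12)
    b <- random_human_set(seed + 500, "r", "B", duration = 12)
    tc <- time_confusion(a, b)
    g <- grid_confusion(
      as.matrix(phase_region(a, "both")),
      as.matrix(phase_region(b, "both")), 12, step = 0.001
    )
    tol <- 0.001 * 2 * (nrow(a) + nrow(b) + 1)
    expect_equal(tc$tp, g$tp, tolerance = tol)
    expect_equal(tc$fp, g$fp, tolerance = tol)
    expect_equal(tc$tn, g$tn, tolerance = tol)
    expect_equal(tc$fn, g$fn, tolerance = tol)
    expect_equal(tc$tp + tc$fp + tc$tn + tc$fn, 12, tolerance = 1e-9)
  }
})

test_that("sensitivity and specificity are the stated ratios with 0/0 undefined", {
  tc <- tibble::tibble(tp = 2, fp = 2, tn = 4, fn = 2)
  expect_equal(sensitivity(tc), 0.5)
  expect_equal(specificity(tc), 4 / 6)
  a <- phase_annotations(1, 3, "i", recording_id = "r", duration = 10)
  self <- time_confusion(a, a)
  expect_equal(sensitivity(self), 1)
  expect_equal(specificity(self), 1)
  degenerate <- tibble::tibble(tp = 0, fp = 1, tn = 9, fn = 0)
  expect_true(is.na(sensitivity(degenerate)))
})

test_that("unpaired recordings or mismatched durations are rejected, durations= resolves them", {
  a <- phase_annotations(0, 1, "i", recording_id = "r1", duration = 10)
  b <- phase_annotations(0, 1, "i", recording_id = "r2",
                         source_id = "B", duration = 10)
  expect_error(time_confusion(a, b), "Unpaired")
  durs <- tibble::tibble(recording_id = c("r1", "r2"), duration = c(10, 10))
  tc <- time_confusion(a, b, durations = durs)
  expect_equal(nrow(tc), 2)
  expect_equal(tc$fp[tc$recording_id == "r1"], 1)  # b empty there
  b2 <- phase_annotations(0, 1, "i", recording_id = "r1",
                          source_id = "B", duration = 12)
  expect_error(time_confusion(a, b2), "mismatched durations")
})

test_that("corpus summary averages per-file values over defined files only", {
  a <- dplyr::bind_rows(
    phase_annotations(0, 5, "i", recording_id = "f1", duration = 10),
    phase_annotations(0, 4, "i", recording_id = "f2", duration = 10)
  )
  # f1: perfect agreement; f2: b covers everything -> specificity undefined
  b <- dplyr::bind_rows(
    phase_annotations(0, 5, "i", recording_id = "f1", source_id = "B", duration = 10),
    phase_annotations(0, 10, "i", recording_id = "f2", source_id = "B", duration = 10)
  )
  s <- corpus_summary(a, b)
  both <- s[s$scope == "both", ]
  expect_equal(both$n_defined_spec, 1)
  expect_equal(both$mean_specificity, 1)     # only f1 counts
  expect_equal(both$n_files, 2)
  expect_true("class_mean" %in% s$scope)
  # two files with sensitivities 0.9 and 1.0 average to 0.95
  a2 <- dplyr::bind_rows(
    phase_annotations(0, 9, "i", recording_id = "g1", duration = 20),
    phase_annotations(0, 10, "i", recording_id = "g2", duration = 20)
  )
  b2 <- dplyr::bind_rows(
    phase_annotations(0, 10, "i", recording_id = "g1", source_id = "B", duration = 20),
    phase_annotations(0, 10, "i", recording_id = "g2", source_id = "B", duration = 20)
  )
  s2 <- corpus_summary(a2, b2)
  expect_equal(s2$mean_sensitivity[s2$scope == "both"], 0.95)
})
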