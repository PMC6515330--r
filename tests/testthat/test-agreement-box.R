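test_that("interval Jaccard index: bounded, symmetric, 1 iff identical", {
  expect_equal(interval_jaccard(0, 2, 1, 3), 1 / 3)
  expect_equal(interval_jaccard(0, 2, 0, 2), 1)
  expect_equal(interval_jaccard(0, 1, 2, 3), 0)
  set.seed(8)
  for (k in 1:50) {
    a <- sort(runif(2)); b <- sort(runif(2))
    j1 <- interval_jaccard(a[1], a[2], b[1], b[2])
    j2 <- interval_jaccard(b[1], b[2], a[1], a[2])
    expect_equal(j1, j2)
    expect_true(j1 >= 0 && j1 <= 1)
    if (j1 == 1) expect_equal(a, b)
  }
})

test_that("box matching is one-to-one, class-respecting, above-threshold", {
  a <- phase_annotations(0, 2, "i", recording_id = "r", duration = 5)
  b <- phase_annotations(0.2, 2.1, "i", recording_id = "r",
                         source_id = "B", duration = 5)
  expect_equal(nrow(match_boxes(a, b)), 1)
  b_wrong <- phase_annotations(0, 2, "e", recording_id = "r",
                               source_id = "B", duration = 5)
  expect_equal(nrow(match_boxes(a, b_wrong)), 0)
  # two candidates for one box: the larger-Jaccard partner wins
  b2 <- phase_annotations(c(0, 0.2), c(1.9, 2.1), c("i", "i"),
                          confidence = c(0.9, 0.9),
                          recording_id = "r", source_id = "B", duration = 5)
  m <- match_boxes(a, b2)
  expect_equal(nrow(m), 1)
  expect_equal(m$b_start, 0)   # Jaccard 1.9/2 beats 1.8/2.1
})

test_that("greedy matching equals exhaustive optimal matching on random instances", {
  for (seed in 1:120) {
    a <- random_disjoint_boxes(seed, source_id = "A")
    b <- random_disjoint_boxes(seed + 4000, source_id = "B")
    expect_equal(nrow(match_boxes(a, b)), brute_force_match(a, b)$count)
  }
})

test_that("matched-pair count is symmetric in the two sources", {
  for (seed in c(21, 22, 23)) {
    a <- random_scored_boxes(seed, source_id = "A")
    b <- random_scored_boxes(seed + 100, source_id = "B")
    expect_equal(nrow(match_boxes(a, b)), nrow(match_boxes(b, a)))
  }
})

test_that("percentage agreement uses the symmetric mean-count denominator", {
  # 3 inspirations vs 2, both of the 2 matched -> 100 * 2 / 2.5 = 80
  a <- phase_annotations(c(0, 3, 6), c(1, 4, 7), rep("i", 3),
                         recording_id = "r", source_id = "A", duration = 10)
  b <- phase_annotations(c(0.05, 3.05), c(1, 4), rep("i", 2),
                         recording_id = "r", source_id = "B", duration = 10)
  res <- percent_agreement(a, b)
  expect_equal(res$percent[res$phase == "inspiration"], 80)
  expect_equal(res$matched[res$phase == "both"], 2)
  # self-agreement is 100 in every scope; empty scopes are 100 by convention
  self <- percent_agreement(a, a)
  expect_equal(self$percent, c(100, 100, 100))
  expect_equal(self$percent[self$phase == "expiration"], 100)
  # disjoint sources agree 0%
  far <- phase_annotations(c(8), c(9), "i",
                           recording_id = "r", source_id = "B", duration = 10)
  expect_equal(percent_agreement(a, far)$percent[1], 0)
})

test_that("alternative denominators and per-file averaging are exposed", {
  a <- dplyr::bind_rows(
    phase_annotations(0, 1, "i", recording_id = "r1", source_id = "A", duration = 5),
    phase_annotations(c(0, 2), c(1, 3), c("i", "i"), recording_id = "r2",
                      source_id = "A", duration = 5)
  )
  b <- dplyr::bind_rows(
    phase_annotations(0, 1, "i", recording_id = "r1", source_id = "B", duration = 5),
    phase_annotations(0, 0.9, "i", recording_id = "r2", source_id = "B", duration = 5)
  )
  pooled <- percent_agreement(a, b)
  expect_equal(pooled$percent[pooled$phase == "inspiration"], 100 * 2 / 2.5)
  ref <- percent_agreement(a, b, denominator = "a")
  expect_equal(ref$percent[ref$phase == "inspiration"], 100 * 2 / 3)
  per_file <- percent_agreement(a, b, by_file = TRUE)
  expect_equal(per_file$percent[per_file$phase == "inspiration"],
               mean(c(100, 100 * 1 / 1.5)))
})
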