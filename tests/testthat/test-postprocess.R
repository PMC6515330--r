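mk_boxes <- function(start, end, phase, conf, id = "r", dur = 10) {
  phase_annotations(start, end, phase, confidence = conf,
                    recording_id = id, source_id = "det", duration = dur)
}

test_that("confidence pruning is strictly 'below threshold': exactly 0.5 survives", {
  x <- mk_boxes(c(0, 2, 4), c(1, 3, 5), c("i", "e", "i"), c(0.6, 0.5, 0.49))
  kept <- prune_low_confidence(x)
  expect_equal(kept$confidence, c(0.6, 0.5))
  expect_equal(nrow(prune_low_confidence(mk_boxes(0, 1, "i", 0.1))), 0)
  expect_equal(prune_low_confidence(kept), kept)   # idempotent
  human <- phase_annotations(0, 1, "i", duration = 5)
  expect_error(prune_low_confidence(human), "confidence")
})

test_that("duplicate suppression keeps the highest-confidence same-class box", {
  x <- mk_boxes(c(0, 0.5), c(4, 4), c("i", "i"), c(0.9, 0.7))
  out <- remove_duplicates(x)
  expect_equal(nrow(out), 1)
  expect_equal(out$confidence, 0.9)
  # different classes never suppress each other
  y <- mk_boxes(c(0, 0), c(4, 4), c("i", "e"), c(0.9, 0.7))
  expect_equal(nrow(remove_duplicates(y)), 2)
})

test_that("greedy suppression follows descending confidence through chains", {
  # A-B and B-C overlap above 0.5 but A-C do not: A suppresses B, C survives
  a <- c(0, 1, 2)
  b <- c(4, 5, 6)
  expect_gt(interval_jaccard(a[1], b[1], a[2], b[2]), 0.5)
  expect_gt(interval_jaccard(a[2], b[2], a[3], b[3]), 0.5)
  expect_lt(interval_jaccard(a[1], b[1], a[3], b[3]), 0.5)
  x <- mk_boxes(a, b, rep("i", 3), c(0.9, 0.8, 0.7))
  out <- remove_duplicates(x)
  expect_equal(sort(out$confidence), c(0.7, 0.9))
})

test_that("overlap shrinking splits each overlap equally and leaves disjoint input alone", {
  x <- mk_boxes(c(0, 5.0), c(5.2, 8.0), c("i", "e"), c(0.9, 0.8))
  out <- shrink_overlaps(x)
  expect_equal(out$end[1], 5.1)
  expect_equal(out$start[2], 5.1)
  disjoint <- mk_boxes(c(0, 6), c(5, 8), c("i", "e"), c(0.9, 0.8))
  expect_equal(shrink_overlaps(disjoint)$start, disjoint$start)
  # left-to-right three-box sweep
  x3 <- mk_boxes(c(0, 2.0, 4.0), c(2.2, 4.1, 6.0), c("i", "e", "i"),
                 c(0.9, 0.8, 0.7))
  out3 <- shrink_overlaps(x3)
  expect_equal(out3$start, c(0, 2.1, 4.05))
  expect_equal(out3$end, c(2.1, 4.05, 6.0))
  # a shrink that would invert a box is an error naming the pair
  tiny <- mk_boxes(c(0, 0.1), c(2, 0.3), c("i", "e"), c(0.9, 0.8))
  expect_error(shrink_overlaps(tiny), "boxes 1 and 2")
})

test_that("the full chain removes, suppresses and shrinks with reconciling counts", {
  for (seed in 1:25) {
    x <- random_detector_boxes(seed)
    out <- postprocess_detections(x, postprocess_config())
    counts <- stage_counts(out)
    expect_equal(counts$n_input,
                 counts$n_pruned + counts$n_suppressed + counts$n_output)
    expect_false(has_overlapping_pair(out))
    expect_true(all(out$confidence >= 0.5))
    again <- postprocess_detections(out, postprocess_config())
    expect_equal(strip_meta(again), strip_meta(out))
  }
  e <- postprocess_detections(
    phase_annotations(numeric(0), numeric(0), character(0), duration = 5)
  )
  expect_equal(nrow(e), 0)
  expect_equal(stage_counts(e)$n_input, 0)
  expect_equal(glance(e), stage_counts(e))
})

test_that("min-fraction overlap measure is available as a config switch", {
  # inner box fully inside a long one: Jaccard small, min-fraction 1
  x <- mk_boxes(c(0, 1), c(8, 2), c("i", "i"), c(0.9, 0.8))
  expect_equal(nrow(remove_duplicates(x, postprocess_config())), 2)
  cfg <- postprocess_config(overlap_measure = "min_fraction")
  expect_equal(nrow(remove_duplicates(x, cfg)), 1)
})
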