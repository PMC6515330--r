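test_that("schedules alternate phases starting with inspiration and fit the recording", {
  prof <- breathing_profile()
  sch <- generate_schedule(prof, seed = 4)
  n_insp <- sum(sch$phase == "inspiration")
  expect_true(n_insp >= 3 && n_insp <= 4)     # 15 breaths/min over 15 s
  expect_equal(sch$phase[1], "inspiration")
  expect_true(all(sch$phase[-1] != sch$phase[-nrow(sch)]))
  expect_true(all(sch$start[-1] >= sch$end[-nrow(sch)]))
  expect_true(all(sch$end <= prof$duration))
  # zero jitter makes all inspiration durations identical
  sch0 <- generate_schedule(breathing_profile(cycle_jitter_sd = 0), seed = 4)
  insp_len <- with(sch0[sch0$phase == "inspiration" & sch0$end < 15, ],
                   end - start)
  expect_equal(diff(range(insp_len)), 0, tolerance = 1e-12)
})

test_that("generation is deterministic per seed and differs across seeds", {
  prof <- breathing_profile()
  expect_identical(generate_schedule(prof, seed = 5),
                   generate_schedule(prof, seed = 5))
  expect_false(identical(generate_schedule(prof, seed = 5)$start,
                         generate_schedule(prof, seed = 6)$start))
  sch <- generate_schedule(prof, seed = 5)
  expect_identical(synthesize_audio(sch, prof, seed = 5),
                   synthesize_audio(sch, prof, seed = 5))
})

test_that("audio loudness orders inspiration > expiration > pause", {
  prof <- breathing_profile()
  sch <- generate_schedule(prof, seed = 8)
  wave <- synthesize_audio(sch, prof, seed = 8)
  expect_equal(length(wave), round(prof$duration * prof$sample_rate))
  sr <- prof$sample_rate
  rms_in <- function(m) {
    idx <- unlist(lapply(seq_len(nrow(m)), function(i) {
      seq(max(1, floor(m[i, 1] * sr) + 1), min(length(wave), floor(m[i, 2] * sr)))
    }))
    sqrt(mean(wave[idx]^2))
  }
  insp <- as.matrix(phase_region(sch, "inspiration"))
  expi <- as.matrix(phase_region(sch, "expiration"))
  pause <- as.matrix(dplyr::filter(
    tibble::as_tibble(lungphase:::iv_complement(
      as.matrix(phase_region(sch, "both")), prof$duration
    )), end - start > 0.2
  ))
  expect_gt(rms_in(insp), rms_in(expi))
  expect_gt(rms_in(expi), rms_in(pause))
  # equal gains make the two phases equally loud within 10%
  prof_eq <- breathing_profile(expiration_gain = 1)
  sch_eq <- generate_schedule(prof_eq, seed = 9)
  wv <- synthesize_audio(sch_eq, prof_eq, seed = 9)
  wave <- wv
  r_i <- rms_in(as.matrix(phase_region(sch_eq, "inspiration")))
  r_e <- rms_in(as.matrix(phase_region(sch_eq, "expiration")))
  expect_lt(abs(r_i - r_e) / r_i, 0.10)
})

test_that("zero annotator noise is the identity; miss_prob 1 leaves only spurious phases", {
  truth <- generate_schedule(breathing_profile(), seed = 12)
  same <- corrupt_annotations(truth, annotator_noise(0, 0, 0), seed = 3)
  expect_equal(same$start, truth$start)
  expect_equal(same$end, truth$end)
  expect_equal(same$phase, truth$phase)
  gone <- corrupt_annotations(truth, annotator_noise(0, 1, 0), seed = 3)
  expect_equal(nrow(gone), 0)
  spur <- corrupt_annotations(truth, annotator_noise(0, 1, 3), seed = 3)
  if (nrow(spur) > 0) {
    expect_true(all(spur$end - spur$start <= 0.4 + 1e-9))
  }
})

test_that("boundary jitter increases disagreement time on average", {
  prof <- breathing_profile(duration = 15)
  truth <- purrr::map_dfr(1:4, function(i) {
    generate_schedule(prof, seed = 40 + i, recording_id = sprintf("r%d", i))
  })
  err_at <- function(sigma) {
    mean(vapply(1:20, function(rep) {
      noisy <- corrupt_annotations(
        truth, annotator_noise(boundary_jitter_sd = sigma), seed = 100 * rep
      )
      tc <- time_confusion(
        truth, noisy,
        durations = tibble::tibble(
          recording_id = unique(truth$recording_id), duration = 15
        )
      )
      sum(tc$fp + tc$fn)
    }, numeric(1)))
  }
  errs <- vapply(c(0, 0.15, 0.5), err_at, numeric(1))
  expect_equal(errs[1], 0)
  expect_true(all(diff(errs) > 0))
})

test_that("simulate_corpus stitches truth, annotators and audio together", {
  corp <- simulate_corpus(
    n_files = 3,
    profile = breathing_profile(duration = 10),
    annotators = list(
      careful = annotator_noise(0.03),
      sloppy = annotator_noise(0.2, miss_prob = 0.1, spurious_rate = 1)
    ),
    seed = 21, audio = TRUE
  )
  expect_equal(length(unique(corp$truth$recording_id)), 3)
  expect_setequal(unique(corp$annotations$source_id),
                  c("truth", "careful", "sloppy"))
  expect_equal(names(corp$audio), sprintf("sim%03d", 1:3))
  expect_equal(length(corp$audio[[1]]), 10 * 44100)
  # reproducible end to end
  corp2 <- simulate_corpus(
    n_files = 3, profile = breathing_profile(duration = 10),
    annotators = list(careful = annotator_noise(0.03),
                      sloppy = annotator_noise(0.2, 0.1, 1)),
    seed = 21, audio = FALSE
  )
  expect_equal(corp$annotations, corp2$annotations)
})
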