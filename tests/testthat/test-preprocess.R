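test_that("band-stop removes the mains tone and passes the signal band", {
  fs <- 1000
  t <- seq(0, 20, by = 1 / fs)
  bs <- filter_spec("bandstop", 59, 61)
  # evaluate on the interior to keep filtfilt edge transients out of the RMS
  core <- seq(round(length(t) * 0.1), round(length(t) * 0.9))
  x60 <- sin(2 * pi * 60 * t)
  y60 <- apply_filter(x60, fs, bs)
  expect_lt(sqrt(mean(y60[core]^2)) / sqrt(mean(x60[core]^2)), 0.05)
  x10 <- sin(2 * pi * 10 * t)
  y10 <- apply_filter(x10, fs, bs)
  expect_equal(sqrt(mean(y10[core]^2)) / sqrt(mean(x10[core]^2)), 1,
               tolerance = 0.01)
  expect_equal(apply_filter(rep(0, 5000), fs, bs), rep(0, 5000))
})

test_that("filtering is idempotent in the pass band", {
  fs <- 1000
  t <- seq(0, 10, by = 1 / fs)
  core <- seq(round(length(t) * 0.1), round(length(t) * 0.9))
  bp <- filter_spec("bandpass", 1, 100)
  x <- sin(2 * pi * 10 * t) + 0.5 * sin(2 * pi * 25 * t)
  y1 <- apply_filter(x, fs, bp)
  y2 <- apply_filter(y1, fs, bp)
  expect_equal(sqrt(mean(y2[core]^2)) / sqrt(mean(y1[core]^2)), 1,
               tolerance = 0.02)
})

test_that("invalid filter configurations raise errors", {
  expect_error(filter_spec("bandpass", 100, 1), "low_hz")
  expect_error(apply_filter(rnorm(5000), 150, filter_spec("bandpass", 1, 100)),
               "Nyquist")
  expect_error(apply_filter(rnorm(10), 1000, filter_spec("bandpass", 1, 100)),
               "too short")
  expect_error(apply_filter(c(rnorm(5000), NA), 1000,
                            filter_spec("bandpass", 1, 100)), "non-finite")
})

test_that("the 3-35 Hz band-pass is applied to cycling recordings only", {
  x <- rnorm(4000)
  rest <- condition_signal(x, 1000, "rest")
  cyc <- condition_signal(x, 1000, "cycling")
  expect_length(attr(rest, "filters"), 2)
  expect_length(attr(cyc, "filters"), 3)
  all3 <- condition_signal(x, 1000, "rest", apply_335_to_all = TRUE)
  expect_length(attr(all3, "filters"), 3)
  expect_length(rest, length(x))

  spec <- cohort_spec(n_subjects = 2, duration = 2, seed = 1,
                      artifact_rate = 0)
  coh <- condition_recordings(generate_cohort(spec))
  expect_true(all(coh$signals$n_filters[coh$signals$state == "rest"] == 2))
  expect_true(all(coh$signals$n_filters[coh$signals$state == "cycling"] == 3))
})

test_that("jump detection flags injected steps and nothing else", {
  withr::with_seed(2, {
    x <- rnorm(5000)
    x[2501:5000] <- x[2501:5000] + 50 * sd(x)
    flags <- detect_jump_artifacts(x, z_thresh = 8)
    expect_identical(flags, 2500L)
  })
  expect_message(out <- detect_jump_artifacts(rep(0, 1000)), "constant")
  expect_length(out, 0)
})

test_that("clean synthetic channels stay unflagged at the default threshold", {
  # false-positive check: 100 artifact-free channels
  spec <- cohort_spec(n_subjects = 13, duration = 2, seed = 21,
                      artifact_rate = 0)
  n_flagged <- 0
  n_total <- 0
  for (sid in sprintf("S%02d", 1:13)) {
    rec <- generate_recording(spec, sid, "rest", "open")
    for (x in rec$signal) {
      n_total <- n_total + 1
      if (length(detect_jump_artifacts(x, z_thresh = 8)) > 0) {
        n_flagged <- n_flagged + 1
      }
      if (n_total >= 100) break
    }
    if (n_total >= 100) break
  }
  expect_lt(n_flagged / n_total, 0.01)
})

test_that("segmentation follows the floor rule and conserves samples", {
  s1 <- segment_signal(rnorm(1000), 100)
  expect_equal(nrow(s1), 100)
  expect_true(all(lengths(s1$samples) == 10))
  expect_equal(attr(s1, "discarded"), 0)

  s2 <- segment_signal(rnorm(1005), 100)
  expect_true(all(lengths(s2$samples) == 10))
  expect_equal(attr(s2, "discarded"), 5)

  expect_error(segment_signal(rnorm(50), 100), "shorter")

  # conservation property over random lengths
  withr::with_seed(8, {
    for (rep in 1:10) {
      len <- sample(200:5000, 1)
      np <- sample(2:100, 1)
      x <- rnorm(len)
      s <- segment_signal(x, np)
      seg_len <- lengths(s$samples)[1]
      expect_equal(np * seg_len + attr(s, "discarded"), len)
      expect_identical(unlist(s$samples, use.names = FALSE),
                       x[seq_len(np * seg_len)])
    }
  })
})

test_that("subject-level exclusion drops whole subjects, recording-level only recordings", {
  spec <- cohort_spec(n_subjects = 4, duration = 2, seed = 31,
                      artifact_rate = 0.5)
  coh <- generate_cohort(spec)
  flagged_subjects <- unique(coh$manifest$subject[coh$manifest$artifact])
  expect_gt(length(flagged_subjects), 0)

  sc <- screen_artifacts(coh, level = "subject")
  expect_setequal(unique(sc$signals$subject),
                  setdiff(coh$manifest$subject, flagged_subjects))

  rc <- screen_artifacts(coh, level = "recording")
  kept <- dplyr::distinct(rc$signals, subject, state, eyes)
  expect_equal(nrow(kept), sum(!coh$manifest$artifact))
})
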