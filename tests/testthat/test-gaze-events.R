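test_that("resampling decimates to the target rate and propagates blinks", {
  t <- 0:999
  tr <- gaze_trace(t, rep(3, 1000), rep(-2, 1000))
  out <- resample_gaze(tr, 200)
  expect_equal(nrow(out), 200)
  expect_equal(attr(out, "rate_hz"), 200)
  expect_true(all(out$x == 3 & out$y == -2))

  ramp <- gaze_trace(t, t / 100, rep(0, 1000))
  out <- resample_gaze(ramp, 200)
  expect_equal(out$x, t[seq(1, 1000, by = 5)] / 100)

  v <- rep(TRUE, 1000); v[101:140] <- FALSE   # 40 ms blink
  tr <- gaze_trace(t, rep(0, 1000), rep(0, 1000), v)
  out <- resample_gaze(tr, 200)
  expect_equal(sum(!out$valid), 8)
})

test_that("non-uniform time stamps are rejected with a gap report", {
  t <- c(0:10, 12:20)
  expect_error(gaze_trace(t, seq_along(t), seq_along(t)), "non-uniform")
})

test_that("blink interpolation is linear and leaves boundary spans alone", {
  tr <- gaze_trace(0:4, c(1, 1, NA, 3, 3), c(0, 0, NA, 0, 0),
                   c(TRUE, TRUE, FALSE, TRUE, TRUE))
  out <- interpolate_blinks(tr)
  expect_equal(out$x[3], 2)
  expect_true(all(out$valid))

  tr <- gaze_trace(0:5, c(0, NA, NA, NA, 4, 4), rep(0, 6),
                   c(TRUE, FALSE, FALSE, FALSE, TRUE, TRUE))
  out <- interpolate_blinks(tr)
  expect_equal(out$x[2:4], c(1, 2, 3))

  clean <- gaze_trace(0:9, 0:9 / 10, rep(0, 10))
  expect_identical(interpolate_blinks(clean), clean)

  tr <- gaze_trace(0:4, c(NA, NA, 1, 1, 1), rep(0, 5),
                   c(FALSE, FALSE, TRUE, TRUE, TRUE))
  out <- suppressMessages(interpolate_blinks(tr))
  expect_false(any(out$valid[1:2]))
})

test_that("saccade detection applies the velocity and amplitude criteria", {
  t200 <- seq(0, 995, by = 5)
  still <- gaze_trace(t200, rep(1, 200), rep(2, 200))
  expect_equal(nrow(detect_saccades(still)), 0)

  st <- step_trace(list(c(0, 0), c(10, 0)))
  tr <- resample_gaze(st$trace, 200)
  sac <- detect_saccades(tr)
  expect_equal(nrow(sac), 1)
  expect_equal(sac$amplitude, 10, tolerance = 0.05)
  expect_gt(sac$peak_vel, 300)

  ## a 0.5 deg step fails the amplitude criterion however fast
  st2 <- step_trace(list(c(0, 0), c(0.5, 0)), step_ms = 20)
  tr2 <- resample_gaze(st2$trace, 200)
  expect_equal(nrow(detect_saccades(tr2)), 0)
})

test_that("raising the velocity threshold never adds saccades", {
  set.seed(4)
  st <- step_trace(list(c(0, 0), c(8, 2), c(-5, 1), c(3, -6)))
  tr <- resample_gaze(st$trace, 200)
  counts <- vapply(c(30, 50, 80, 150, 400),
                   function(v) nrow(detect_saccades(tr, vel_thresh = v)),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("fixations tile the trace and short ones are flagged", {
  st <- step_trace(list(c(0, 0), c(10, 0), c(0, 5)), hold_ms = 350)
  tr <- resample_gaze(st$trace, 200)
  sac <- detect_saccades(tr)
  fix <- extract_fixations(tr, sac)
  expect_equal(nrow(fix), nrow(sac) + 1)
  expect_true(all(fix$included[fix$duration >= 200]))
  expect_true(is.na(fix$next_saccade[nrow(fix)]))
  ## tiling: fixation and saccade intervals partition the trace
  ivals <- rbind(cbind(fix$t_on, fix$t_off), cbind(sac$t_on, sac$t_off))
  ivals <- ivals[order(ivals[, 1]), ]
  expect_equal(ivals[-1, 1], ivals[-nrow(ivals), 2])

  short <- step_trace(list(c(0, 0), c(5, 0), c(10, 0)), hold_ms = 150)
  tr2 <- resample_gaze(short$trace, 200)
  fix2 <- extract_fixations(tr2, detect_saccades(tr2))
  expect_false(any(fix2$included[fix2$duration < 200]))
})

test_that("planted events are recovered with small onset error", {
  set.seed(11)
  pos <- lapply(1:12, function(i) runif(2, -15, 15))
  ## ensure all steps exceed 1 deg
  for (i in 2:12) while (sqrt(sum((pos[[i]] - pos[[i - 1]])^2)) < 2)
    pos[[i]] <- runif(2, -15, 15)
  st <- step_trace(pos, hold_ms = 320)
  tr <- resample_gaze(st$trace, 200)
  sac <- detect_saccades(tr)
  fix <- extract_fixations(tr, sac)
  hits <- vapply(st$onsets, function(o) any(abs(sac$t_on - o) <= 10),
                 logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("mean-shift finds the dominant mode and rejects exact ties", {
  set.seed(2)
  pts <- rbind(matrix(rnorm(100, 5, 0.1), 50, 2),
               matrix(rnorm(6, 0, 0.05), 3, 2))
  res <- mean_shift_mode(pts)
  expect_false(res$rejected)
  expect_equal(as.numeric(res$mode), c(5, 5), tolerance = 0.1)

  single <- mean_shift_mode(matrix(c(1.5, -2), 1, 2))
  expect_equal(single$mode, c(1.5, -2))

  two <- rbind(matrix(rnorm(50, 0, 0.05), 25, 2),
               matrix(rnorm(50, 10, 0.05), 25, 2))
  expect_true(mean_shift_mode(two)$rejected)
})

test_that("saccade-goal labels follow the direction cones", {
  expect_equal(label_saccade_goal(30, rf_phi = 30, rf_R = 8), "in")
  expect_equal(label_saccade_goal(210, rf_phi = 30, rf_R = 8), "opposite")
  expect_equal(label_saccade_goal(120.001, rf_phi = 30, rf_R = 8), "other")
  expect_error(label_saccade_goal(0, rf_phi = 0, rf_R = 1.5), "eccentricity")

  ## reflecting the RF through the fixation point swaps in and opposite
  set.seed(5)
  dirs <- runif(200, -180, 180)
  a <- label_saccade_goal(dirs, rf_phi = 40, rf_R = 10)
  b <- label_saccade_goal(dirs, rf_phi = 40 + 180, rf_R = 10)
  expect_equal(a == "in", b == "opposite")
  expect_equal(a == "opposite", b == "in")
})
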