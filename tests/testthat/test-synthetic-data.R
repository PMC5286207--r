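test_that("rendering is deterministic and events carry model saliency", {
  geom <- small_geom()
  ev <- data.frame(onset = 0, duration = 1000, x = 10, y = 5,
                   kind = "moving-dot", intensity = 1, size = 3,
                   dir = 0, speed = 10)
  script <- scene_script(ev, 1000, geom, bg_level = 0.3)
  f1 <- render_clip(script, fps = 60, seed = 9)
  f2 <- render_clip(script, fps = 60, seed = 9)
  expect_identical(f1, f2)

  expect_error(scene_script(transform(ev, x = 60), 1000, geom), "screen")

  ## the model's saliency peak tracks the dot
  cfg <- small_cfg()
  g <- test_grid()
  ## model steps at 200 Hz reuse display frames at 60 fps
  t_ms <- attr(f1, "t_ms")
  steps <- seq(0, 40, by = 5)
  frames <- lapply(steps, function(t) f1[[max(which(t_ms <= t))]])
  out <- run_model(frames, cbind(0, 0)[rep(1, length(frames)), ], geom, g, cfg)
  last <- out[[length(out)]]
  expect_false(is.null(last))
  peak <- which.max(last$saliency)
  dot_x <- 10 + 10 * 0.040                      # dot position at t = 40 ms
  d <- sqrt((g$x[peak] - dot_x)^2 + (g$y[peak] - 5)^2)
  expect_lt(d, 2)
})

test_that("a colour event drives the chromatic channel hardest", {
  geom <- small_geom()
  ev <- data.frame(onset = 0, duration = 1000, x = -8, y = 0,
                   kind = "colour-disk", intensity = 1, size = 4)
  script <- scene_script(ev, 1000, geom, bg_level = 0.3)
  fr <- render_clip(script, fps = 60, seed = 3)[[1]]
  cfg <- small_cfg()
  g <- test_grid()
  out <- run_model(rep(list(fr), 9), cbind(0, 0)[rep(1, 9), ], geom, g, cfg)
  hi <- out[[9]]$high
  unit <- grid_unit_at(g, -8, 0)
  chroma <- max(hi[, , "rg"][unit], hi[, , "by"][unit])
  expect_gt(chroma, hi[, , "motion"][unit])
})

test_that("simulated gaze follows the stated fixation statistics", {
  set.seed(77)
  dur <- pmin(pmax(rlnorm(10000, 5.428, 0.446), 60), 1500)
  q <- quantile(dur, c(0.025, 0.975))
  expect_gt(q[1], 80); expect_lt(q[2], 600)

  geom <- small_geom()
  script <- random_scene_script(30, 20000, geom, seed = 5)
  ## p = 1: saccade endpoints sit on scripted event positions
  sim1 <- simulate_gaze(script, p = 1, seed = 6)
  tr1 <- sim1$truth
  with_target <- tr1[!is.na(tr1$target_event) & seq_len(nrow(tr1)) > 1, ]
  err <- sqrt((with_target$x - script$events$x[with_target$target_event])^2 +
              (with_target$y - script$events$y[with_target$target_event])^2)
  expect_lt(median(err), 1.5)
  ## p = 0: endpoints spread over the screen instead
  sim0 <- simulate_gaze(script, p = 0, seed = 6)
  expect_gt(stats::sd(sim0$truth$x), 5)
})

test_that("simulated spikes follow the planted rate model", {
  ## gain 0: homogeneous Poisson, exponential ISIs
  spec0 <- synthetic_neuron_spec(layer_class = "SCs", baseline = 30, gain = 0,
                                 seed = 3)
  sal <- runif(20000)
  sp0 <- simulate_spikes(spec0, sal, NULL)
  isi <- diff(sp0)
  ks <- stats::ks.test(isi, "pexp", rate = 30 / 1000)
  expect_gt(ks$p.value, 0.01)

  ## determinism under the seed
  expect_identical(as.numeric(simulate_spikes(spec0, sal, NULL)),
                   as.numeric(sp0))

  ## positive gain: detectable rank correlation in nearly all seeds
  det <- vapply(1:20, function(i) {
    spec <- synthetic_neuron_spec(layer_class = "SCs", seed = 2000 + i)
    ses <- synthetic_session(spec, n_fix = 300, seed = 2100 + i)
    s <- ses$samples[ses$samples$included, ]
    ct <- per_neuron_correlation(s$saliency, s$rate, min_n = 65)
    ct$rho > 0 && ct$p < 0.05
  }, logical(1))
  expect_gte(mean(det), 0.95)

  ## planted 75 ms latency is recovered by the MI alignment
  spec75 <- synthetic_neuron_spec(layer_class = "SCs", latency = 75, seed = 11)
  ses <- synthetic_session(spec75, n_fix = 600, seed = 12)
  d <- spike_density(ses$spikes, c(0, max(ses$t) + 5), kernel = "gaussian")
  nn <- min(length(ses$saliency), length(d$rate))
  prof <- mi_delay(ses$saliency[seq_len(nn)], d$rate[seq_len(nn)])
  expect_lte(abs(prof$delay - 75), 10)
})

test_that("a miniature session is fully reproducible from its ground truth", {
  spec <- synthetic_neuron_spec(rf_R = 8, rf_phi = 30, layer_class = "SCi",
                                baseline = 15, gain = 50, latency = 50,
                                goal_gain = 8, seed = 42)
  a <- synthetic_session(spec, n_fix = 20, seed = 9)
  b <- synthetic_session(spec, n_fix = 20, seed = 9)
  expect_identical(a$samples, b$samples)
  expect_identical(a$spikes, b$spikes)

  ## window rates recomputed by brute force from the spike list
  hand <- vapply(a$samples$t_on, function(o)
    sum(a$spikes >= o & a$spikes < o + 200) / 0.2, numeric(1))
  expect_equal(a$samples$rate, hand)

  ## the planted rate is zero-gain outside goal-in fixations (SCi gating)
  rate <- attr(a$spikes, "rate")
  out_idx <- which(a$goal != "in")
  expect_true(all(rate[out_idx] == 15))
})
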