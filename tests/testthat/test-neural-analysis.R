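test_that("spike density behaves like a causal unit-mass EPSP filter", {
  d0 <- spike_density(numeric(0), c(0, 1000))
  expect_true(all(d0$rate == 0))

  d1 <- spike_density(500, c(0, 1000))
  expect_true(all(d1$rate[d1$t < 500] == 0))        # causal
  peak_t <- d1$t[which.max(d1$rate)]
  expect_gt(peak_t, 500); expect_lt(peak_t, 530)    # 5 ms rise, 20 ms decay
  expect_equal(sum(d1$rate) * d1$dt / 1000, 1, tolerance = 0.01)

  d2 <- spike_density(c(200, 800), c(0, 1200))
  expect_equal(max(d2$rate), max(d1$rate), tolerance = 1e-6)
  expect_equal(sum(d2$rate) * d2$dt / 1000, 2, tolerance = 0.01)
})

test_that("neuron classification separates visual and visuomotor cells", {
  make_trials <- function(n, vis_burst, mot_burst, seed) {
    set.seed(seed)
    stim <- lapply(1:n, function(i) {
      base <- runif(rpois(1, 6), -100, 300)
      burst <- if (vis_burst) runif(rpois(1, 8), 45, 110) else numeric(0)
      sort(c(base, burst))
    })
    sacc <- lapply(1:n, function(i) {
      base <- runif(rpois(1, 6), -200, 100)
      burst <- if (mot_burst) runif(rpois(1, 8), -20, 20) else numeric(0)
      sort(c(base, burst))
    })
    list(stim = stim, sacc = sacc)
  }
  v <- make_trials(30, TRUE, FALSE, 1)
  cv <- classify_neuron(v$stim, v$sacc)
  expect_equal(cv$layer_class, "SCs")
  vm <- make_trials(30, TRUE, TRUE, 2)
  cvm <- classify_neuron(vm$stim, vm$sacc)
  expect_equal(cvm$layer_class, "SCi")
  flat <- make_trials(30, FALSE, FALSE, 3)
  cf <- classify_neuron(flat$stim, flat$sacc)
  expect_true(cf$excluded)
  few <- make_trials(5, TRUE, FALSE, 4)
  expect_true(classify_neuron(few$stim, few$sacc)$excluded)
})

test_that("0-1 rescaling uses the post-event window and is scale free", {
  t <- seq(0, 500, by = 5)
  ramp <- seq_along(t)
  n <- normalize_rate(ramp, t)
  expect_equal(range(n), c(0, 1))
  flat <- normalize_rate(rep(4, length(t)), t)
  expect_true(all(flat == 0) && attr(flat, "flat"))
  expect_equal(as.numeric(normalize_rate(10 * ramp, t)), as.numeric(n))
})

test_that("rank correlation detects a planted saliency gain", {
  set.seed(12)
  sal <- runif(200)
  mono <- per_neuron_correlation(sal, exp(3 * sal), min_n = 65)
  expect_equal(mono$rho, 1)
  null <- per_neuron_correlation(sal, rnorm(200), min_n = 65)
  expect_lt(abs(null$rho), 0.2)
  expect_error(per_neuron_correlation(runif(30), runif(30)), "at least")

  ## population of gained neurons: r distribution shifted right of zero
  rhos <- vapply(1:20, function(i) {
    set.seed(100 + i)
    spec <- synthetic_neuron_spec(layer_class = "SCs", seed = 100 + i)
    ses <- synthetic_session(spec, n_fix = 120, seed = 200 + i)
    s <- ses$samples[ses$samples$included, ]
    per_neuron_correlation(s$saliency, s$rate, min_n = 50)$rho
  }, numeric(1))
  expect_lt(stats::binom.test(sum(rhos > 0), 20, alternative = "greater")$p.value,
            0.05)
})

test_that("tertile assignment is balanced with stable ties", {
  for (n in c(9, 10, 11, 65)) {
    f <- assign_tertiles(runif(n))
    expect_lte(diff(range(table(f))), 1)
  }
  tied <- assign_tertiles(rep(1, 9))
  expect_equal(as.vector(table(tied)), c(3, 3, 3))
  expect_equal(as.character(tied[1:3]), rep("low", 3))
})

test_that("tertile curves recover a planted monotone saliency gain", {
  set.seed(21)
  pop <- lapply(1:8, function(i) {
    spec <- synthetic_neuron_spec(layer_class = "SCs", seed = 300 + i)
    synthetic_session(spec, n_fix = 250, seed = 400 + i)
  })
  tc <- tertile_curves(pop, "fixation")
  m <- colMeans(tc$epoch)
  expect_true(m["high"] > m["medium"] && m["medium"] > m["low"])

  ## zero-gain control: no ordering beyond noise
  pop0 <- lapply(1:8, function(i) {
    spec <- synthetic_neuron_spec(layer_class = "SCs", gain = 0, seed = 500 + i)
    synthetic_session(spec, n_fix = 250, seed = 600 + i)
  })
  tc0 <- tertile_curves(pop0, "fixation")
  d <- colMeans(tc0$epoch)
  expect_lt(abs(d["high"] - d["low"]), 2)

  ## single-neuron epoch mean matches a hand computation
  ses <- pop[[1]]
  s <- ses$samples[ses$samples$included, ]
  tert <- assign_tertiles(s$saliency)
  on <- s$t_on[tert == "high"]
  hand <- mean(vapply(on, function(o) {
    sel <- ses$density$t >= o & ses$density$t < o + 200
    mean(ses$density$rate[sel])
  }, numeric(1)))
  expect_equal(unname(tc$epoch[1, "high"]), hand, tolerance = 0.02)
})

test_that("the goal split shows gating only for visuomotor populations", {
  scs <- lapply(1:10, function(i) {
    spec <- synthetic_neuron_spec(layer_class = "SCs", seed = 700 + i)
    synthetic_session(spec, n_fix = 250, seed = 800 + i)
  })
  sci <- lapply(1:10, function(i) {
    spec <- synthetic_neuron_spec(layer_class = "SCi", goal_gain = 10,
                                  seed = 900 + i)
    synthetic_session(spec, n_fix = 250, seed = 1000 + i)
  })
  gs <- goal_split_analysis(scs, "fixation")
  gi <- goal_split_analysis(sci, "fixation")
  expect_lt(gs$tests$p_in, 0.05)
  expect_lt(gs$tests$p_opp, 0.05)
  expect_lt(gi$tests$p_in, 0.05)
  expect_gt(gi$tests$p_opp, 0.05)

  ## swapping the goal labels swaps the in/opposite condition means
  swapped <- scs
  for (i in seq_along(swapped)) {
    g <- swapped[[i]]$samples$goal
    swapped[[i]]$samples$goal <-
      ifelse(g == "in", "opposite", ifelse(g == "opposite", "in", g))
  }
  gsw <- goal_split_analysis(swapped, "fixation")
  expect_equal(gsw$epoch[, "high_in"], gs$epoch[, "high_opp"])
  expect_equal(gsw$epoch[, "low_opp"], gs$epoch[, "low_in"])

  ## saccade-aligned variant runs and keeps the SCs effect
  gsa <- goal_split_analysis(scs, "saccade")
  expect_lt(gsa$tests$p_in, 0.05)
})

test_that("feature dependence separates combined from tuned drive", {
  comb <- lapply(1:8, function(i) {
    spec <- synthetic_neuron_spec(layer_class = "SCs", seed = 1100 + i)
    synthetic_session(spec, n_fix = 250, seed = 1200 + i)
  })
  fd <- feature_dependence(comb)
  expect_true(all(colMeans(fd$matrix) > 0))
  expect_true(all(fd$significant))

  mot <- lapply(1:8, function(i) {
    spec <- synthetic_neuron_spec(layer_class = "SCs", seed = 1300 + i)
    synthetic_session(spec, n_fix = 250, seed = 1400 + i,
                      feature_mode = "motion")
  })
  fdm <- feature_dependence(mot)
  cm <- colMeans(fdm$matrix)
  expect_equal(names(which.max(cm)), "motion")

  zero <- lapply(1:8, function(i) {
    spec <- synthetic_neuron_spec(layer_class = "SCs", gain = 0, seed = 1500 + i)
    synthetic_session(spec, n_fix = 250, seed = 1600 + i)
  })
  fdz <- feature_dependence(zero)
  expect_lt(max(abs(colMeans(fdz$matrix))), 0.1)
})

test_that("epoch means are insensitive to sub-kernel spike jitter", {
  spec <- synthetic_neuron_spec(layer_class = "SCs", seed = 1700)
  ses <- synthetic_session(spec, n_fix = 200, seed = 1800)
  set.seed(1900)
  jit <- sort(pmax(ses$spikes + runif(length(ses$spikes), -1, 1), 0))
  total <- max(ses$t) + 5
  dj <- spike_density(jit, c(0, total), kernel = "epsp")
  sesj <- ses; sesj$density <- dj
  tc <- tertile_curves(list(ses), "fixation")
  tcj <- tertile_curves(list(sesj), "fixation")
  expect_lt(max(abs(tc$epoch - tcj$epoch) / tc$epoch), 0.01)
})

test_that("rank-sum detection of a small planted RT advantage has power", {
  hits <- vapply(1:20, function(i) {
    set.seed(i)
    lo <- rlnorm(2000, log(314), 0.35)
    hi <- rlnorm(2000, log(299), 0.35)
    stats::wilcox.test(hi, lo, alternative = "less")$p.value < 0.05
  }, logical(1))
  expect_gt(mean(hits), 0.9)
})
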