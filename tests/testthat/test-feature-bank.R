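test_that("DoG construction has the designed ratio and null response", {
  d <- make_dog(5, 6.7)
  expect_equal(d$sigma_s / d$sigma_c, 6.7)
  g <- test_grid()
  uni <- matrix(0.6, 100, 100)
  resp <- dog_response(uni, g, 6.7, ppd = 1)
  expect_lt(max(abs(resp)), 1e-10)
})

test_that("disk-diameter sweeps peak at the designed optimal size", {
  tun <- dog_size_tuning(10, K = 6.7, ppd = 8, field_deg = 30)
  expect_equal(tun$preferred, tun$S_design, tolerance = 0.05)
  tun2 <- dog_size_tuning(25, K = 3.2, ppd = 4, field_deg = 70)
  expect_equal(tun2$preferred, tun2$S_design, tolerance = 0.05)
})

test_that("the eccentricity size law interpolates the two anchors", {
  expect_equal(eccentricity_size_law(0), 0.75)
  expect_equal(eccentricity_size_law(40), 5)
  expect_equal(eccentricity_size_law(20), 2.875)
})

test_that("chromatic maps are double-opponent and size tuned", {
  g <- test_grid()
  cfg <- small_cfg()
  P <- 100
  grey <- structure(list(lum = matrix(0.5, P, P), rg = matrix(0, P, P),
                         by = matrix(0, P, P), ppd = 1, t = 0),
                    class = "retinal_frame")
  m0 <- chromatic_luminance_maps(grey, g, cfg)
  expect_lt(max(abs(m0)), 1e-10)
  expect_equal(dimnames(m0)[[3]], c("lum", "rg", "by"))

  ## red disk on green surround at a unit's RF centre: rg responds and the
  ## response is invariant to swapping the colours (|DoG| double opponency)
  unit <- grid_unit_at(g, 15, 0)
  S <- g$S[unit]
  disk <- disk_plane(S, centre = c(15, 0), ppd = 1, field_deg = 100)
  rgplus <- grey
  rgplus$rg <- 0.2 * disk - 0.1
  rgminus <- grey
  rgminus$rg <- -(0.2 * disk - 0.1)
  a <- chromatic_luminance_maps(rgplus, g, cfg)
  b <- chromatic_luminance_maps(rgminus, g, cfg)
  expect_gt(a[, , "rg"][unit], 0.01)
  expect_equal(a[, , "rg"], b[, , "rg"], tolerance = 1e-10)

  ## size tuning: optimal disk beats a 3x larger disk
  big <- grey; big$lum <- 0.5 + 0.3 * disk_plane(3 * S, c(15, 0), 1, 100)
  opt <- grey; opt$lum <- 0.5 + 0.3 * disk
  r_opt <- chromatic_luminance_maps(opt, g, cfg)[, , "lum"][unit]
  r_big <- chromatic_luminance_maps(big, g, cfg)[, , "lum"][unit]
  expect_gte(r_opt, r_big)
})

test_that("spatiotemporal maps separate orientation, flicker and motion", {
  g <- test_grid()
  cfg <- small_cfg()
  P <- 100
  xs <- matrix(seq_len(P), P, P, byrow = TRUE)
  ys <- matrix(seq_len(P), P, P)

  ## static uniform sequence: everything silent
  st0 <- spatiotemporal_energy(replicate(9, matrix(0.5, P, P), simplify = FALSE),
                               g, cfg, ppd = 1)
  expect_lt(max(abs(st0$ori)), 1e-8)
  expect_lt(max(abs(st0$flicker)), 1e-8)
  expect_lt(max(abs(st0$motion_fwd)), 1e-8)

  ## a localized static 45 deg grating patch: the 45 deg orientation map
  ## wins at the unit under the patch; opponent motion cancels
  patch <- disk_plane(10, centre = c(12, 0), ppd = 1, field_deg = 100)
  probe <- grid_unit_at(g, 12, 0)
  ## row index grows downward, so a +45 deg (up-right) grating varies
  ## along (xs - ys)
  gr45 <- 0.5 + 0.4 * patch * sin(2 * pi * 0.15 * (xs - ys) / sqrt(2))
  st <- spatiotemporal_energy(replicate(9, gr45, simplify = FALSE),
                              g, cfg, ppd = 1)
  e45 <- st$ori[, , "ori45_s1"][probe]
  e135 <- st$ori[, , "ori135_s1"][probe]
  expect_gt(e45, e135 * 1.5)
  opp <- opponent_motion(st)
  expect_lt(max(abs(opp)), 0.03 * max(st$ori))

  ## rightward-drifting grating patch: rightward-preferring raw maps
  ## exceed leftward at the matched configuration
  buf <- lapply(1:9, function(i)
    0.5 + 0.4 * patch * sin(2 * pi * 0.15 * (xs - i)))
  stm <- spatiotemporal_energy(buf, g, cfg, ppd = 1)
  i0 <- which(stm$labels$mot == "mot0_v1_s1")
  expect_gt(stm$motion_fwd[, , i0][probe], stm$motion_bwd[, , i0][probe])
  oppm <- opponent_motion(stm)
  expect_gt(oppm[, , "mot0_v1_s1_fwd"][probe], 0)
  expect_equal(oppm[, , "mot0_v1_s1_bwd"][probe], 0)

  ## flickering patch drives the flicker channel at its site
  fbuf <- lapply(1:9, function(i) 0.5 + 0.3 * (-1)^i * patch)
  stf <- spatiotemporal_energy(fbuf, g, cfg, ppd = 1)
  expect_gt(stf$flicker[probe], 1e-6)
})

test_that("opponent motion cancels matched responses and counts 48", {
  st <- list(motion_fwd = array(2, c(4, 4, 24)),
             motion_bwd = array(2, c(4, 4, 24)),
             labels = list(mot = sprintf("m%02d", 1:24)))
  opp <- opponent_motion(st)
  expect_equal(dim(opp)[3], 48)
  expect_true(all(opp == 0))
})

test_that("the competition operator preserves lone peaks, suppresses crowds", {
  cfg <- sc_config()
  z <- matrix(0, 200, 200)
  expect_true(all(competition_operator(z, cfg) == 0))

  one <- z; one[100, 100] <- 1
  out1 <- competition_operator(one, cfg)
  expect_equal(which.max(out1), which.max(one))
  expect_gt(max(out1), 0)

  many <- z
  many[seq(20, 180, by = 16), 100] <- 1
  many[100, seq(20, 180, by = 16)] <- 1
  out_many <- competition_operator(many, cfg)
  expect_lt(max(out_many), max(out1))
  expect_true(all(out_many >= 0))
})

test_that("activation-field pooling sums a circular neighbourhood", {
  imp <- matrix(0, 50, 50); imp[25, 25] <- 1
  p <- pool_activation_field(imp, 3)
  expect_equal(sum(p > 0), 29)            # radius-3 disc footprint
  uni <- matrix(2, 50, 50)
  expect_true(all(abs(pool_activation_field(uni, 3)[5:45, 5:45] - 58) < 1e-12))
})

test_that("the configured bank instantiates exactly 60 + 6 maps", {
  g <- test_grid()
  cfg <- small_cfg()
  set.seed(31)
  buf <- grey_buffer(cfg, modify = function(pl, i)
    pl + 0.2 * matrix(runif(length(pl)), nrow(pl)))
  st <- feature_stack(buf, g, cfg)
  expect_equal(dim(st$low)[3], 60)
  expect_equal(as.vector(table(feature_groups(st))), c(1, 1, 1, 8, 1, 48))
  expect_true(all(st$low >= 0))
  hi <- combine_high_level(st)
  expect_equal(dim(hi)[3], 6)
})

test_that("contrast scaling does not decrease the luminance-contrast peak", {
  g <- test_grid()
  cfg <- small_cfg()
  base <- disk_plane(3, centre = c(12, 0), ppd = 1, field_deg = 100)
  lo <- dog_response(0.5 + 0.2 * base, g, cfg$K_chrom, 1, rectify = "abs")
  hi <- dog_response(0.5 + 0.4 * base, g, cfg$K_chrom, 1, rectify = "abs")
  expect_gte(max(hi), max(lo))
})
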