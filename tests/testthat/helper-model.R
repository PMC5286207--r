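## shared fixtures, built once per test run

.helper_env <- new.env()

test_fit <- function() {
  if (is.null(.helper_env$fit))
    .helper_env$fit <- fit_resampling_params(n_restarts = 25, seed = 20170124)
  .helper_env$fit
}

test_grid <- function() {
  if (is.null(.helper_env$grid))
    .helper_env$grid <- build_sc_grid(test_fit())
  .helper_env$grid
}

## small screen for image tests: 2 px/deg, same 82 x 52 deg aspect
small_geom <- function() screen_geometry(164, 104, 82, 52)

## coarse model configuration used in end-to-end tests
small_cfg <- function() sc_config(px_per_deg = 1, decimations = 1)

## uniform-grey retinal buffer with one modifier applied to the lum planes
grey_buffer <- function(cfg = small_cfg(), level = 0.5,
                        modify = function(plane, i) plane) {
  P <- cfg$field_deg * cfg$px_per_deg
  lapply(1:9, function(i) {
    pl <- modify(matrix(level, P, P), i)
    structure(list(lum = pl, rg = matrix(0, P, P), by = matrix(0, P, P),
                   ppd = cfg$px_per_deg, t = i * 5),
              class = "retinal_frame")
  })
}

## 1 kHz gaze trace following a piecewise-constant position schedule with
## smooth saccadic steps; returns the trace plus the planted event times
step_trace <- function(positions, hold_ms = 400, step_ms = 30) {
  t <- c(); x <- c(); y <- c()
  cur <- positions[[1]]
  tms <- 0
  onsets <- c()
  for (k in seq_along(positions)) {
    nh <- hold_ms
    t <- c(t, tms + seq_len(nh) - 1)
    x <- c(x, rep(cur[1], nh)); y <- c(y, rep(cur[2], nh))
    tms <- tms + nh
    if (k < length(positions)) {
      nxt <- positions[[k + 1]]
      frac <- (1 - cos(pi * seq_len(step_ms) / step_ms)) / 2
      t <- c(t, tms + seq_len(step_ms) - 1)
      x <- c(x, cur[1] + frac * (nxt[1] - cur[1]))
      y <- c(y, cur[2] + frac * (nxt[2] - cur[2]))
      onsets <- c(onsets, tms)
      tms <- tms + step_ms
      cur <- nxt
    }
  }
  list(trace = gaze_trace(t, x, y), onsets = onsets)
}
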