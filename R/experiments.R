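#' Planted-latency recovery experiment
#'
#' Generates synthetic neuron sessions with known response latencies drawn
#' from 25-125 ms, runs the mutual-information delay estimator on the
#' ground-truth RF saliency series and the Gaussian-smoothed spike
#' density, and reports how often the latency is recovered within
#' +/- 10 ms.  Each case uses a full session (default 600 fixations,
#' about three minutes of viewing), matching the practice of estimating
#' the delay over all clips of a recording session.
#'
#' @param n_cases number of synthetic neuron-clips.
#' @param n_fix fixations per session.
#' @param seed master seed.
#' @param tol recovery tolerance, ms.
#' @return list with `results` (data frame: `true`, `recovered`) and
#'   `fraction` recovered within `tol`.
#' @export
planted_lag_recovery <- function(n_cases = 100, n_fix = 600, seed = 1,
                                 tol = 10) {
  res <- t(vapply(seq_len(n_cases), function(i) {
    set.seed(seed * 10000 + i)
    lag_true <- sample(seq(25, 125, 5), 1)
    spec <- synthetic_neuron_spec(layer_class = "SCs", latency = lag_true,
                                  seed = seed * 10000 + i)
    ses <- synthetic_session(spec, n_fix = n_fix, seed = seed * 20000 + i)
    d <- spike_density(ses$spikes, c(0, max(ses$t) + 5), kernel = "gaussian")
    nn <- min(length(ses$saliency), length(d$rate))
    prof <- mi_delay(ses$saliency[seq_len(nn)], d$rate[seq_len(nn)])
    c(true = lag_true, recovered = prof$delay)
  }, numeric(2)))
  res <- as.data.frame(res)
  list(results = res,
       fraction = mean(abs(res$recovered - res$true) <= tol))
}

#' Saccade-goal signature recovery experiment
#'
#' Runs the fixation-aligned saliency x saccade-goal analysis on
#' independently seeded synthetic populations and asks, per run, whether
#' the qualitative population signature is recovered: a significant
#' saliency effect in both goal conditions for the visual (SCs-like)
#' neurons, and a saliency effect only in the goal-in condition for the
#' visuomotor (SCi-like) neurons.
#'
#' @param n_runs number of seeded runs.
#' @param n_scs,n_sci,n_fix population parameters.
#' @param seed master seed.
#' @param alpha test level.
#' @return list with `runs` (data frame of per-run p values and flags)
#'   and `fraction` of runs showing the full signature.
#' @export
signature_recovery <- function(n_runs = 20, n_scs = 30, n_sci = 25,
                               n_fix = 300, seed = 1, alpha = 0.05) {
  runs <- lapply(seq_len(n_runs), function(r) {
    pop <- synthetic_population(n_scs, n_sci, n_fix, seed = seed * 100 + r)
    cls <- vapply(pop, `[[`, "", "layer_class")
    gs_s <- goal_split_analysis(pop[cls == "SCs"], "fixation")
    gs_i <- goal_split_analysis(pop[cls == "SCi"], "fixation")
    data.frame(run = r,
               scs_p_in = gs_s$tests$p_in, scs_p_opp = gs_s$tests$p_opp,
               sci_p_in = gs_i$tests$p_in, sci_p_opp = gs_i$tests$p_opp)
  })
  runs <- do.call(rbind, runs)
  runs$scs_both <- runs$scs_p_in < alpha & runs$scs_p_opp < alpha
  runs$sci_gated <- runs$sci_p_in < alpha & runs$sci_p_opp >= alpha
  runs$signature <- runs$scs_both & runs$sci_gated
  list(runs = runs, fraction = mean(runs$signature))
}

#' Behavioural saliency experiment
#'
#' Simulates salience-seeking free viewing over scripted scenes with a
#' fixed RF, collects per-fixation RF saliency, next-saccade goal and
#' fixation duration, and runs the behavioural analysis: frequency of
#' RF-directed saccades and their reaction times at high versus low RF
#' saliency.
#'
#' @param n_clips number of scripted clips.
#' @param clip_ms clip duration, ms.
#' @param n_events scripted events per clip.
#' @param rf `c(R, phi)` of the observed neuron's RF, degrees.
#' @param p salience-seeking probability.
#' @param seed master seed.
#' @return the [behavioural_saliency()] result, with the pooled `samples`
#'   attached.
#' @export
behavioural_experiment <- function(n_clips = 40, clip_ms = 45000,
                                   n_events = 150, rf = c(8, 45), p = 0.8,
                                   seed = 1) {
  geom <- screen_geometry()
  samples <- do.call(rbind, lapply(seq_len(n_clips), function(ci) {
    script <- random_scene_script(n_events, clip_ms, geom,
                                  seed = seed * 100 + ci)
    sim <- simulate_gaze(script, p = p, seed = seed * 100 + ci, rf = rf)
    data.frame(neuron = 1L, saliency = sim$truth$s_rf,
               goal = sim$truth$goal, duration = sim$truth$duration,
               included = TRUE)
  }))
  out <- behavioural_saliency(samples)
  out$samples <- samples
  out
}
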