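# scsaliency

Does the midbrain carry a visual saliency map?  Answering that question
during free viewing of dynamic natural scenes requires a *computational*
definition of saliency at every place and time in the stimulus — and, for
the superior colliculus (SC), one computed in the SC's own gaze-centred,
log-polar coordinates.  `scsaliency` provides both halves of that
programme for R users in visual and oculomotor neuroscience:

1. **The model.**  A feed-forward saliency model on a 200 × 200
   space-variant SC grid.  Frames are shifted to retinal coordinates at
   200 Hz, embedded in a black 100° × 100° surround, converted to DKL
   opponent planes, and read through eccentricity-dependent
   difference-of-Gaussian (DoG) receptive fields: a detector with optimal
   stimulus size S and surround/centre ratio K uses unit-mass Gaussians

       sigma_c = S * sqrt(K^2 - 1) / (4 K sqrt(ln K)),  sigma_s = K * sigma_c,

   with S growing linearly from 0.75° at the fovea to 5° at 40°
   eccentricity (K = 6.7 for luminance/colour, 3.2 for spatiotemporal
   channels).  Sixty low-level maps (1 luminance + 1 red–green + 1
   blue–yellow + 8 orientation + 1 flicker + 48 opponent motion) pass a
   long-range competition operator and radius-3 activation-field pooling,
   combine into six high-level features, and — after square-root
   compression — into a feature-agnostic saliency response.  The
   visual ↔ SC geometry is the complex-log mapping
   u = B_u ln(|z + A|/A), v = B_v arg(z + A) (A = 3°, B_u = 1.4 mm,
   B_v = 1.8 mm/rad), with an analytically exact inverse and a fitted
   square-grid resampling for image processing.

2. **The analysis pipeline.**  Gaze segmentation (50 °/s and 1° saccade
   criteria, 200 ms fixation cutoff, mean-shift drift correction),
   EPSP-kernel spike densities, SCs/SCi classification, per-fixation RF
   saliency (mean over the point-image RF boundary, 0–200 ms saccade-free
   window), Spearman correlations, saliency-tertile curves, saccade-goal
   (in/opposite the RF) splits with per-bin divergence tests,
   feature-dependence matrices, and behavioural effects (frequency and
   reaction time of RF-directed saccades by saliency).

Because such recordings are not publicly deposited, a synthetic-data
module generates video, fixation–saccade gaze and inhomogeneous-Poisson
spike trains with full ground truth (gains, latencies, goal gating), so
every claim the pipeline makes can be tested as parameter recovery.

## Worked example

```r
library(scsaliency)

## fit the space-variant resampling to the conformal mapping, build the grid
fit  <- fit_resampling_params(n_restarts = 200, seed = 1)
grid <- build_sc_grid(fit)
grid
#> <sc_grid> 200 x 200 units, eccentricity 0.05-70.8 deg, pool radius 3 px
#>   variable-resolution constants: a=3.307 b=0.32 c=59.16

## size tuning of the 40-deg unit's DoG, by numerical disk sweep
tun <- dog_size_tuning(40, K = 6.7)
sprintf("preferred disk diameter at 40 deg: %.2f deg (design 5 deg)", tun$preferred)
#> "preferred disk diameter at 40 deg: 5.12 deg (design 5 deg)"

## activation field of the 10-deg unit, by probe-position sweep
af <- activation_field_sweep(10, grid, sc_config())
sprintf("activation-field diameter at 10 deg: %.2f deg (design ~2 deg)", af$diameter)
#> "activation-field diameter at 10 deg: 2.11 deg (design ~2 deg)"

## a synthetic SCs neuron: saliency-rate correlation and latency recovery
spec <- synthetic_neuron_spec(rf_R = 12, rf_phi = 30, layer_class = "SCs",
                              latency = 80, seed = 1)
ses  <- synthetic_session(spec, n_fix = 600, seed = 1)
s    <- ses$samples[ses$samples$included, ]
ct   <- per_neuron_correlation(s$saliency, s$rate)
sprintf("saliency-rate Spearman rho = %.2f (p = %.1e, n = %d fixations)",
        ct$rho, ct$p, ct$n)
#> "saliency-rate Spearman rho = 0.25 (p = 6.3e-07, n = 373 fixations)"

d    <- spike_density(ses$spikes, c(0, max(ses$t) + 5), kernel = "gaussian")
nn   <- min(length(ses$saliency), length(d$rate))
prof <- mi_delay(ses$saliency[seq_len(nn)], d$rate[seq_len(nn)])
sprintf("MI-optimal delay: %d ms (planted latency 80 ms)", prof$delay)
#> "MI-optimal delay: 85 ms (planted latency 80 ms)"
```

The correlation is positive and highly significant because the neuron's
rate was generated as baseline + gain × lagged RF saliency; the
mutual-information alignment recovers the planted 80 ms latency on the
5 ms delay grid.

Population-level recovery experiments are packaged as functions:
`signature_recovery()` (SCs neurons show the saliency effect for saccades
both into and opposite the RF; SCi neurons only for saccades into the
RF), `planted_lag_recovery()` (latency recovery across 100 synthetic
neurons), and `behavioural_experiment()` (more, and faster, RF-directed
saccades when RF saliency is high).

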