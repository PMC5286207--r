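Package: scsaliency
Title: Space-Variant Saliency Modelling and Fixation-Locked Analysis of
    Superior Colliculus Activity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Implements a biologically tuned computational saliency model in
    gaze-centred, log-polar superior colliculus (SC) coordinates, together
    with the analysis pipeline that links model-predicted saliency to the
    firing of SC neurons during free viewing of dynamic scenes.  The model
    converts video frames to retinal (gaze-centred) DKL colour planes,
    resamples them through a fitted space-variant transform onto a 200 x 200
    model SC grid, computes 60 low-level feature maps (luminance and colour
    double-opponency, oriented edges, flicker and opponent motion) through
    eccentricity-dependent difference-of-Gaussian receptive fields, and
    combines them into six high-level feature maps and a saliency response.
    The analysis side segments gaze traces into saccades and fixations,
    builds fixation-locked spike density functions, and computes saliency
    tertile curves, saccade-goal splits, per-feature dependence profiles and
    behavioural saliency effects.  A synthetic-data generator produces video,
    gaze and Poisson spike trains with known ground truth for end-to-end
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
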