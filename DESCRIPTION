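Package: saccadapt
Title: Visuomotor Gain Learning Models for Saccadic Adaptation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: State-space modelling of saccadic adaptation in which three
    visuomotor gains - a visual gain mapping retinal input to perceived
    target position, a motor gain (inverse model) mapping target percept to
    motor command, and a corollary-discharge gain (forward dynamics model)
    mapping the motor command copy to a computed displacement of visual
    space - learn trial by trial by delta-rule gradient descent on either a
    visual prediction error or a postdictive motor error. Provides the
    closed-form forward model of the probe observables (pre-saccadic
    localization, saccade vector, post-saccadic localization relative to
    landing), gain estimation from probe-block medians, robust trial
    filtering, bounded weighted least-squares fitting of learning rates,
    residual-standard-error model comparison, fixed-point and Jacobian
    stability analysis of the learning dynamics, and a synthetic session
    generator for end-to-end parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
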