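Package: diffeffector
Title: Differentiable Biomechanical Effectors Controlled by Recurrent Policies
Version: 0.1.0
Authors@R:
    person("Repo", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Planar musculoskeletal effectors (a point-mass and a two-joint,
    six-muscle arm) with Hill-type and linear piecewise muscle actuators,
    muscle-path geometry and moment arms, delayed noise-corrupted sensory
    feedback, and a gated recurrent unit (GRU) policy trained end-to-end by
    backpropagation through the effector physics. Includes a small
    reverse-mode automatic-differentiation tape, reaching and postural task
    environments with curl-field and mechanical perturbations, and scripted
    protocols for curl-field adaptation, perturbation generalization,
    preferential-movement-direction analysis, and passive-drift mapping.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
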