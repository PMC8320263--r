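Package: kinesia
Title: Simulated Neurological Examination of Upper-Limb Motor Control
    Under Active Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates two bedside neurological exams -- the biceps tendon
    tap and a three-target upper-limb coordination task -- with a
    hierarchical active-inference model of motor control.  A continuous
    generative model of three-joint arm dynamics is inverted by
    generalized (variational) filtering in generalized coordinates of
    motion, with action generated through a spinal reflex-arc gradient.
    Two discrete Markov-decision-process levels plan sequences of
    attracting points via expected free energy, and talk to the
    continuous level through Bayesian model averaging and Bayesian model
    reduction.  Named computational lesions -- overestimated sensory
    precision, overestimated smoothness of fluctuations, attenuated
    policy precision, and attenuated hierarchical likelihood precision --
    reproduce the clinical phenomenology of hyperreflexia, pendular
    reflexes with dysmetria, hypokinesia, and perseverative loss of motor
    set.  Exam trajectories are scored with clinical metrics (reflex
    amplitude and settling, endpoint error, overshoot, movement onset
    latency) and exported as plain-text tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
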