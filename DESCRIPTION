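Package: setshiftr
Title: Simulation and Scoring of the Rodent Attentional Set-Shifting Task
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the seven-stage rodent attentional set-shifting task
    (ASST): counterbalanced task-schedule generation with latin-square pair
    assignment and run-length constraints, an attention-weighted
    reinforcement-learning agent simulator with strain presets
    (spontaneously hypertensive, Wistar-Kyoto and Sprague-Dawley profiles)
    and methylphenidate dose transforms, trial scoring with the
    perseverative/regressive/never-reinforced error taxonomy, and the
    accompanying statistical battery (mixed repeated-measures ANOVA with
    Greenhouse-Geisser and Huynh-Feldt sphericity corrections, Fisher LSD
    post-hoc tests, paired t contrasts and Pearson correlations).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    car,
    withr
Config/testthat/edition: 3
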