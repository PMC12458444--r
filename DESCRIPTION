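Package: invbehave
Title: Behavioral Phenotyping and Genotype-by-Environment Inference for
    Inversion Genotypes in Drosophila
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies Drosophila melanogaster behavior from 1-D tube
    tracking trajectories (sleep bouts of at least five minutes of
    inactivity, baseline locomotor speed, startle-response duration and
    magnitude, and food-zone occupancy) and tests for effects of the
    In(2L)t chromosomal inversion, sex, and temperature with nested
    linear mixed-model ladders compared by likelihood-ratio tests, with
    gated post-hoc pairwise t-tests between genotypes. Includes a
    stochastic trajectory simulator (alternating sleep/wake renewal
    process with a mean-reverting bounded walk and exponential-decay
    startle kinetics) so the full pipeline is testable without raw
    tracking data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
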