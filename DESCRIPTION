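Package: quartetri
Title: Matched-Quartet Factorial Designs and Randomization Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Design and analysis of 2x2 factorial field experiments that use
    ex-ante matched quartet blocking. Provides greedy nearest-neighbour
    matching of experimental units into blocks of four on standardized
    baseline covariates, random within-block allocation of the four factorial
    arms, linear probability models with block fixed effects for main and
    prior-knowledge interaction effects, and randomization inference over the
    within-block permutation null (exact enumeration or Monte-Carlo
    sampling). Includes a synthetic-data generator that emulates the baseline
    and outcome tables such designs produce, so the whole design-and-inference
    chain can be validated by simulation, plus a replication pipeline that
    reproduces treatment-effect tables from an outcome file.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    tools,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
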