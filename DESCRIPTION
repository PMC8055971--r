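Package: epal
Title: Epsilon-PAL Pareto Active Learning for Discrete Materials Design Spaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Multiobjective active learning for discrete candidate libraries
    using the epsilon-PAL algorithm: Gaussian-process confidence
    hyperrectangles classify every candidate as epsilon-accurate
    Pareto-optimal or confidently discarded, while a coefficient-of-variation
    acquisition rule picks the next oracle evaluation. Includes full-factorial
    generation and featurization of coarse-grained polymer sequence design
    spaces, intrinsic-coregionalization (ICM) Gaussian-process surrogates with
    Matern-5/2 kernels and missing-label support, exact (d <= 3) and
    Monte-Carlo hypervolume indicators with hypervolume-error benchmarking
    against a random-search baseline, a noisy three-objective polymer
    pseudo-simulator for desk-scale experiments, and an elitist genetic
    algorithm that inverts the trained surrogates to propose novel sequences
    via a feature back-tracing decoder.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
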