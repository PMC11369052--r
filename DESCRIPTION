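Package: critbdm
Title: Multi-Type Critical Birth-Death-Mutation Processes
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Exact stochastic simulation and exact, numerical and asymptotic
    solutions for n-type critical birth-death processes with consecutive
    mutations, a model of error-induced extinction (EEX) in microbial and
    tumour cell populations.  Provides closed-form single-type and two-type
    results (the latter in terms of modified Bessel functions), numerical
    solution of the coupled survival, type-presence and arrival-time ODE
    systems for arbitrary numbers of types, extraction of probability mass
    functions from generating functions by FFT contour inversion,
    large-time scaling laws (survival exponents chi_n = 2^(1-n), matched
    asymptotic expansions, confluent-hypergeometric scaling densities,
    algebraic tails), and genetic-diversity summaries such as the Shannon
    index and the expected number of co-existing types.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    graphics,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
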