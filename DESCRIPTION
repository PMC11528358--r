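Package: sisage
Title: SIS Epidemics on Uncertainty-Aware Social Networks with Social Ageing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates endemic susceptible-infected-susceptible (SIS)
    pathogen spread over weighted grooming networks whose edge weights carry
    Bayesian sampling uncertainty, with optional linear immunosenescence in
    susceptibility, infection duration and infection severity. Provides a
    synthetic generator for age-structured group-year observation data, a
    conjugate count edge model yielding posterior network draws, weighted
    centrality measures (strength, closeness, thresholded degree), a fast
    discrete-time SIS simulator, and mixed-model summaries that quantify the
    protective effect of declining social centrality in old age on
    accumulated infection cost.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    lme4,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
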