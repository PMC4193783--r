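Package: pottsort
Title: Cellular Potts Simulations of Tissue Patterning by Cell Sorting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Two-dimensional Cellular Potts Model of tissue patterning by
    cell sorting under chemotaxis and differential adhesion. Cells carrying
    one of several fates move on a bounded lattice by Metropolis Monte Carlo
    dynamics driven by a three-term energy (differential contact energy, an
    area constraint, and a chemotactic coupling to a morphogen field). The
    morphogen gradient is either a closed-form exponential or a stochastic
    reaction-diffusion field integrated by implicit Euler. Includes
    probabilistic fate specification with a tunable error ratio, sorting
    metrics (cluster counts, fractions of correct and stable runs, sorting
    times, size variation, cell speeds, cluster lifetimes, boundary-crossing
    times), ensemble scenario runners, and ggplot2 visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    Matrix,
    methods,
    stats,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
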