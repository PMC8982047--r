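Package: haplodfe
Title: Haplotype-Based Inference of Selection Coefficients and the
    Distribution of Fitness Effects
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Likelihood-based inference of the population-scaled selection
    coefficient 4Ns, the distribution of fitness effects of variants segregating
    at a given sample frequency (DFEf), and the distribution of fitness effects
    of new mutations (DFE), from the lengths of pairwise identity-by-state
    haplotype tracts around low-frequency derived alleles.  Includes a
    forward-in-time Wright-Fisher simulator under the Poisson Random Field
    model, importance sampling of allele-frequency trajectories conditioned on
    a present-day sample frequency, a structured coalescent simulator with
    recombination conditional on an allele-frequency trajectory, composite
    likelihood estimation over a grid of candidate selection coefficients, and
    rejection-ABC inference of piecewise-constant demographic models from the
    identity-by-state tracts of putatively neutral variants.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
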