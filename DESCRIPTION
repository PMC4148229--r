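Package: namhr
Title: Joint Linkage and Association Mapping of Hypersensitive-Response
    Modifiers in Nested Association Mapping Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for dissecting quantitative variation in the maize
    hypersensitive defense response (and similar multi-family trials) with
    a nested association mapping (NAM) design: derivation of lesion traits
    from repeated severity ratings (standardized area under the disease
    progress curve, mutant/wild-type ratio traits), least-squares line
    means, variance components and line-mean heritability, parent-of-origin
    genotype correction with a Viterbi hidden Markov model, imputation onto
    a uniform centimorgan grid, physical-distance-weighted projection of
    dense founder variants onto recombinant inbred lines, joint multi-family
    stepwise QTL mapping with permutation thresholds, model refinement,
    founder allele-effect estimation, support intervals and digenic
    epistasis scans, and residual-based genome-wide association with
    subagging and resample model inclusion probabilities (RMIP). A
    synthetic NAM population generator makes every stage testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
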