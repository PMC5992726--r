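Package: methylHMM
Title: Methylation Calling and Imputation from Bisulfite Sequencing with a
    Distance-Aware Hidden Markov Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Calls, imputes and recalibrates cytosine methylation from
    whole-genome bisulfite sequencing read counts.  A two-state (unmethylated /
    methylated) hidden Markov model with context-specific binomial emissions
    and distance-dependent transition probabilities is fitted by a modified
    Baum-Welch algorithm, yielding posterior methylation status calls and
    recalibrated methylation levels for every cytosine in the genome,
    including uncovered positions, together with an estimate of the bisulfite
    conversion rate.  Includes cytosine context extraction from a reference
    genome, CGmap input, a binomial-test baseline caller with neighbourhood
    imputation, saturation (downsampling) analysis, genome-wide methylation
    summaries, meta-feature enrichment profiles and a synthetic methylome
    generator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    minpack.lm,
    Biostrings,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
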