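Package: dosagefold
Title: Per-Cell Normalization of Whole-Genome-Duplication Dosage Effects on
    the Metabolome
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify the immediate dosage effects of whole genome
    duplication (autopolyploidy) on untargeted metabolomes. Implements a
    three-step feature quality filter (group presence, within-group relative
    standard deviation, interquartile range) with log2(x+1) normalization,
    per-feature differential-abundance statistics with strain-by-ploidy
    classification and ploidy-specific (presence/absence) calls, Bayesian
    inference of tetraploid-to-diploid relative cell density from mixed-ploidy
    flow-cytometry nucleus counts (a logit-scale nonlinear regression fitted
    by adaptive Metropolis MCMC), a no-intercept Bayesian dry-to-fresh mass
    regression, and the renormalization of per-dry-mass metabolite fold
    changes to per-cell fold changes with dosage-compensation classes. A
    seeded synthetic-data generator emulating the mixed-ploidy study design
    makes every stage testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    optparse
Config/testthat/edition: 3
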