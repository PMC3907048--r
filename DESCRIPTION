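Package: erdesign
Title: Design and Power Analysis of Evolve-and-Resequence Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Forward Wright-Fisher simulation of selection on standing
    variation in whole genomes, tailored to evolve-and-resequence (E&R)
    experiments: generation of synthetic founder populations with
    window-resolved diversity and recombination, multiplicative fecundity
    selection on an arbitrary set of beneficial loci, Pool-Seq sampling of
    allele counts, detection of selected sites with the
    Cochran-Mantel-Haenszel test across replicates, and evaluation of
    experimental designs (replication, population size, duration, founder
    diversity) by ROC curves and partial AUC.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    optparse,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
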