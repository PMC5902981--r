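Package: edsim
Title: Stochastic Simulation of Genomic Selection with Zygote Genome Editing
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Monte Carlo simulator of closed livestock breeding programs that
    combine truncation genomic selection on a polygenic trait with zygote
    genome editing of a single biallelic locus (such as the polled locus in
    dairy cattle). Animals carry true breeding values with inbreeding-adjusted
    Mendelian sampling, pseudo-estimated breeding values of chosen reliability,
    and a monogenic genotype that enters a linear selection index. Editing of
    zygotes from targeted matings converts undesired alleles with a per-allele
    success probability and exposes subjected zygotes to a survival risk.
    The package tracks allele-frequency trajectories, time to fixation,
    polygenic selection response, pedigree inbreeding via generation-wise
    propagation of the additive relationship matrix, editing-procedure counts,
    and the cost-benefit of fixing the desired allele.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
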