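Package: pgtlink
Title: Bayesian Haplotype Linkage Analysis for Preimplantation Genetic
    Testing of Monogenic Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes each IVF embryo's posterior probability of carrying a
    known familial disease allele from shallow single-cell sequencing data.
    Heterozygous SNVs flanking the causal mutation are chained through a
    recombination-aware two-state Bayesian recursion; per-sample genotype
    posteriors absorb whole-genome-amplification noise (allele dropout,
    spurious alleles, base miscalls). The carrier parent's disease-carrying
    and normal haplotypes are phased from a proband sample or, proband-free,
    by cross-validating alleles transmitted to four or more embryos or sperm
    cells. Includes a seeded family simulator (meiosis with Poisson
    crossovers, amplification noise, shallow reads) so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    vcfR,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
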