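Package: quartetcall
Title: Joint Bayesian Genotyping of Tumor-Normal-Parent Quartets
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Joint genotype inference for quartets of related sequencing
    samples: father, mother, and a patient's matched normal and tumor.
    A Bayesian model links the six hidden diploid genotypes (parents,
    mutated parental germlines, child normal, child tumor) through
    Hardy-Weinberg-style priors with a heterozygosity adjustment,
    Jukes-Cantor germline and somatic substitution kernels, Mendelian
    inheritance, tumor-purity read mixtures, and Phred-scaled base-call
    errors. Per-locus read likelihoods are factorized into a compact
    partial-likelihood store so that genotype posteriors, de novo and
    somatic mutation probabilities are computed in O(G^3) per locus, and
    all model parameters (reference divergence, heterozygosity, mutation
    rates, tumor purity, quality calibration) are trained by
    expectation-maximization. Includes a generative quartet simulator,
    a pileup reader, a VCF v4.1 writer with greedy ambiguity-aware
    genotype calls, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation
Config/testthat/edition: 3
RoxygenNote: 7.3.3
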