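Package: mmbscan
Title: Male Mutation Bias Estimation and Sex Chromosome Turnover Dating
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates the strength of male mutation bias (alpha, the
    male-to-female mutation rate ratio) from X-linked, Y-linked and
    autosomal substitution rates using Miyata's equations with a
    nonparametric intron-by-site double bootstrap, and dates ancestral
    sex-chromosome turnovers by comparing observed synonymous branch
    lengths against sequences simulated under scenarios in which lineages
    retained an ancestral X chromosome for a known number of million
    years. Includes Tamura-Nei (TN93) pairwise distances, a fourfold
    degenerate site synonymous-rate proxy, least-squares branch lengths on
    a fixed topology, alignment filters (first-intron and exon-flank
    removal, CpG and ambiguous-column masks), codon bootstrap with
    median-consensus trees, autosomal-rate correction of X-linked branch
    lengths, and a synthetic-data generator with known truth for
    parameter-recovery studies.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils,
    tools,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    phangorn
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
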