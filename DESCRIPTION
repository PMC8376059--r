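Package: ydegen
Title: Diagnosing Y-Chromosome Degeneration from Population Sequencing Coverage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting genetic degeneration of a Y (or W) chromosome
    from low-coverage population sequencing of both sexes. Reads per-gene
    coverage tables, normalizes each individual by its autosomal median, and
    computes male/female (M/F), male/autosome and female/autosome coverage
    ratios per population and pooled. Assigns sexes to unsexed individuals from
    their X/autosome coverage ratio, classifies genes as hemizygous, diploid or
    duplicated, tests region contrasts, assesses cross-population consistency
    of calls, and locates the pseudoautosomal boundary by least-squares
    change-point detection against the expected 0.5/1 coverage levels.
    Estimates synonymous and nonsynonymous divergence between paired coding
    sequences with Nei-Gojobori (1986) counting, Jukes-Cantor correction and
    codon-bootstrap confidence intervals, and converts synonymous divergence to
    generations. Classifies marker sex-linkage from brood genotypes (progeny
    sexing via dam-allele hemizygosity, paternal-X deduction, paternity
    clustering, recombinant scoring) and from population samples (male-specific
    alleles, male homozygosity). A synthetic-data generator produces coverage
    datasets, broods and diverged coding-sequence pairs with the statistical
    structure the analysis assumes, so the whole pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    seqinr
Config/testthat/edition: 3
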