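Package: wolfmtdna
Title: Haplotype Networks, Expansion Statistics and Ancient-DNA Frequency
    Tests for mtDNA Control-Region Data
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Population-genetic toolkit for short mitochondrial control-region
    alignments, built around the question of whether a once-common European
    wolf mtDNA haplogroup was replaced in frequency by another. Collapses
    aligned sequences into haplotypes, classifies variable sites, computes
    diversity summaries (haplotype diversity, nucleotide diversity, s/d),
    Fu's Fs with an Ewens-sampling S' and a coalescent null, mismatch
    distributions with a sudden-expansion least-squares fit and Harpending's
    raggedness test, statistical-parsimony (TCS-style) haplotype networks
    with a probabilistic connection limit and haplogroup partitioning,
    hypergeometric rarefaction with an asymptotic richness extrapolation,
    and exact binomial tests comparing ancient and modern haplogroup
    frequencies. Includes a seeded Hudson-style coalescent generator for
    two-haplogroup, serially sampled synthetic datasets so the whole
    pipeline is testable without sequence downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
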