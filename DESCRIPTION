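Package: cgrmf
Title: Multifractal Analysis of Genome Sequences via Chaos Game
    Representation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates the generalized (Renyi) dimension spectrum Dq of
    DNA sequences by box counting over their Chaos Game Representation,
    and derives the mass exponent tau(q) and the multifractality degree
    (max Dq - min Dq) per fixed-length genome fragment.  Includes genome
    fragmentation from FASTA input, per-fragment counting of annotated
    sequence features (Alu and other interspersed repeats, CpG islands,
    genes, exons, SNPs) from interval files, regression and binning of
    multifractality against feature densities, threshold classification
    of fragments, hierarchical clustering of chromosome-averaged spectra,
    and region averaging.  A synthetic-genome generator with closed-form
    multifractal oracles makes every stage testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    graphics,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
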