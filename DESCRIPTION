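Package: plastrearr
Title: Plastome Rearrangement, Repeat and Gene-Transfer Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Comparative analysis of conifer chloroplast genomes at
    gene-order resolution. Implements signed circular permutation algebra
    with exact Hannenhalli-Pevzner reversal distances, optimal inversion
    scenarios and parsimony trees with reconstructed ancestral gene orders;
    traces oriented repeat copies through inversion scenarios to model how
    tandem repeats are split into dispersed inverted repeats; screens
    sequences for microsatellites (MISA-style thresholds) and for tandem
    repeats of at least 30 bp unit length at 90 percent identity; and
    analyses nuclear copies of plastid genes (ORF discovery, intron
    detection by genomic-versus-transcript comparison, upstream motif
    scans, protein identity). Ground-truth synthetic data generators make
    every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    ape,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
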