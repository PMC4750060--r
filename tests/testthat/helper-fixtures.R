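# shared helpers: small random objects under fixed seeds

rand_scperm <- function(n) scperm(sample(n) * sample(c(-1L, 1L), n, replace = TRUE))

rand_inversion <- function(n) {
  repeat {
    ij <- sort(sample(0:n, 2L))
    if (!(ij[1] == 0L && ij[2] == n)) return(ij)
  }
}

# a 2-gene toy GenBank file; returns the path
write_toy_genbank <- function(path = tempfile(fileext = ".gb")) {
  writeLines(c(
    "LOCUS       TOY1 120 bp    DNA     circular PLN 01-JAN-2020",
    "DEFINITION  toy two-gene genome",
    "ACCESSION   TOY1",
    "FEATURES             Location/Qualifiers",
    "     gene            5..34",
    '                     /gene="geneA"',
    "     gene            complement(61..96)",
    '                     /gene="geneB"',
    "ORIGIN",
    paste0("        1 ", paste(rep("acgtacgtgc", 6), collapse = " ")),
    paste0("       61 ", paste(rep("acgtacgtgc", 6), collapse = " ")),
    "//"), path)
  path
}
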