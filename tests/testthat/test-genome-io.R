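# GenBank/FASTA/TSV I/O, composition statistics and sequence extraction.

test_that("a minimal GenBank record parses with derived introns", {
  path <- write_toy_genbank()
  g <- parse_genbank(path)
  expect_s3_class(g, "annotated_genome")
  expect_identical(g$id, "TOY1")
  expect_true(g$circular)
  expect_identical(nchar(g$seq), 120L)
  expect_identical(nrow(g$features), 2L)
  expect_identical(g$features$strand, c("+", "-"))

  gb <- tempfile(fileext = ".gb")
  writeLines(c(
    "LOCUS       J1 240 bp    DNA     circular PLN 01-JAN-2020",
    "ACCESSION   J1",
    "FEATURES             Location/Qualifiers",
    "     gene            join(10..20,115..130)",
    '                     /gene="abc"',
    "ORIGIN",
    paste0(sprintf("%9d ", seq(1, 240, 60)),
           vapply(1:4, function(i)
             paste(rep("acgtacgtgc", 6), collapse = " "), character(1))),
    "//"), gb)
  g2 <- parse_genbank(gb)
  intr <- g2$features[g2$features$kind == "intron", ]
  expect_identical(nrow(intr), 1L)
  expect_identical(c(intr$start, intr$end), c(21L, 114L))
  expect_identical(sum(g2$features$kind == "gene"), 2L)  # one per exon
})

test_that("malformed records and illegal bases are rejected informatively", {
  bad <- tempfile()
  writeLines(c("LOCUS       X 10 bp", "FEATURES",
               "     gene            join(oops)", "ORIGIN",
               "        1 acgtacgtgc", "//"), bad)
  expect_error(parse_genbank(bad), "join\\(oops\\)")
  expect_error(annotated_genome("x", "ACGTRY"), "outside")
  expect_error(annotated_genome("x", ""), "non-empty")
})

test_that("write -> parse round trip preserves sequence and features", {
  syn <- synth_genome(n_genes = 6, seed = 3, genome_length = 9000)
  g <- syn$genome
  gbp <- tempfile(fileext = ".gb")
  write_genbank(g, gbp)
  g2 <- parse_genbank(gbp)
  expect_identical(g2$seq, g$seq)
  cols <- c("kind", "start", "end", "strand")
  f1 <- g$features[do.call(order, g$features[cols]), cols]
  f2 <- g2$features[do.call(order, g2$features[cols]), cols]
  rownames(f1) <- rownames(f2) <- NULL
  expect_identical(f1, f2)

  # FASTA + feature table round trip
  fp <- tempfile(fileext = ".fa"); tp <- tempfile(fileext = ".tsv")
  write_genome_fasta(g, fp); write_feature_table(g, tp)
  g3 <- read_genome_fasta(fp)
  expect_identical(g3$seq, g$seq)
  fe <- read_feature_table(tp)
  expect_identical(fe, g$features)
})

test_that("gc_content follows its definition and reverse-complement invariance", {
  expect_identical(gc_content("GCGC"), 1)
  expect_identical(gc_content("ATAT"), 0)
  expect_identical(gc_content("ACGTN"), 0.5)   # N out of the denominator
  expect_identical(format_gc(0.35425), "35.43")  # half-up
  expect_identical(format_gc(0.5), "50.00")
  set.seed(21)
  for (t in 1:10) {
    s <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE), collapse = "")
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    expect_equal(gc_content(s), gc_content(rc))
  }
  expect_error(gc_content(annotated_genome("x", "ACGT", circular = FALSE),
                          c(2, 1)), "linear")
  # wrap-around region on a circular genome is legal
  expect_equal(gc_content(annotated_genome("x", "GGAT"), c(4, 1)), 0.5)
})

test_that("feature extraction honors strand and circular wrap-around", {
  g <- annotated_genome("x", "ACGTACGT", features = data.frame(
    name = c("f1", "f2", "wrap"), kind = "gene",
    start = c(1L, 1L, 7L), end = c(4L, 4L, 2L),
    strand = c("+", "-", "+"), stringsAsFactors = FALSE))
  expect_identical(extract_feature_seq(g, "f1"), "ACGT")
  expect_identical(extract_feature_seq(g, "f2"), "ACGT")  # palindrome
  expect_identical(extract_feature_seq(g, "wrap"), "GTAC")
  expect_error(extract_feature_seq(g, "nope"), "available")
})

test_that("hamming_diff reports counts and positions and is a metric", {
  expect_identical(hamming_diff("ACGT", "ACGT")$count, 0L)
  d <- hamming_diff("AAAA", "AATA")
  expect_identical(d$count, 1L)
  expect_identical(d$positions, 3L)
  expect_error(hamming_diff("AC", "ACG"), "length")
  set.seed(22)
  for (t in 1:20) {
    mk <- function() paste(sample(c("A", "C", "G", "T"), 30, TRUE), collapse = "")
    a <- mk(); b <- mk(); c <- mk()
    expect_identical(hamming_diff(a, b)$count, hamming_diff(b, a)$count)
    expect_lte(hamming_diff(a, c)$count,
               hamming_diff(a, b)$count + hamming_diff(b, c)$count)
  }
})

test_that("gene_order produces the planted permutation and handles errors", {
  g <- annotated_genome("x", strrep("ACGT", 25), features = data.frame(
    name = c("g1", "g2", "g3"), kind = "gene",
    start = c(10L, 40L, 70L), end = c(20L, 50L, 80L),
    strand = c("+", "+", "+"), stringsAsFactors = FALSE))
  expect_identical(as.integer(gene_order(g, c("g1", "g2", "g3"))), 1:3)
  # read from the opposite strand: reflection-equivalent permutation
  g2 <- g; g2$features$strand <- "-"
  g2$features$start <- 100L - g$features$end + 1L
  g2$features$end <- 100L - g$features$start + 1L
  p1 <- canonicalize(gene_order(g, c("g1", "g2", "g3")))
  p2 <- canonicalize(gene_order(g2, c("g1", "g2", "g3")))
  expect_identical(as.integer(p1), as.integer(p2))
  expect_error(gene_order(g, c("g1", "gX")), "not found")

  # round trip through a synthetic genome built from a known permutation
  syn <- synth_genome(n_genes = 8, seed = 9, genome_length = 12000)
  genes <- unique(syn$genome$features$name[syn$genome$features$kind == "gene"])
  p <- gene_order(syn$genome, genes)
  fe <- syn$genome$features[syn$genome$features$kind == "gene", ]
  fe <- fe[match(genes, fe$name), ]
  expected <- order(fe$start) # genes listed in coordinate order
  expect_identical(abs(as.integer(p)), as.integer(expected))
  expect_identical(as.integer(sign(as.integer(p))),
                   ifelse(fe$strand[expected] == "+", 1L, -1L))
})
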