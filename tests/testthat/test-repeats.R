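# SSR and tandem-repeat screens.

test_that("find_ssrs reports maximal primitive runs above the thresholds", {
  loci <- find_ssrs("GGCTTAAAAAAAAAAAAGTC")
  expect_identical(nrow(loci), 1L)
  expect_identical(loci$motif, "A")
  expect_identical(loci$copies, 12L)
  expect_identical(c(loci$start, loci$end), c(6L, 17L))

  expect_identical(nrow(find_ssrs(strrep("A", 9))), 0L)   # threshold edge
  expect_identical(find_ssrs(strrep("A", 10))$copies, 10L)

  di <- find_ssrs(paste0("GGC", strrep("AT", 5), "GCC"))
  expect_identical(di$motif, "AT")
  expect_identical(di$unit_len, 2L)                       # never reported as mono

  # primitivity: (A)12 must not additionally surface as AA/AAA/AAAA
  expect_identical(nrow(find_ssrs(paste0("GC", strrep("A", 12), "TG"))), 1L)
  expect_identical(nrow(find_ssrs("")), 0L)

  # spans reproduce the source substring exactly
  s <- paste0("CCGT", strrep("GAT", 5), "AACC", strrep("T", 11), "GAC")
  loci <- find_ssrs(s)
  for (r in seq_len(nrow(loci))) {
    span <- substring(s, loci$start[r], loci$end[r])
    expect_identical(span, strrep(loci$motif[r], loci$copies[r]))
    expect_identical(nchar(span), loci$unit_len[r] * loci$copies[r])
  }
})

test_that("find_ssrs is reverse-complement symmetric", {
  set.seed(31)
  syn <- synth_genome(n_genes = 4,
                      planted_ssrs = list(list(motif = "A", copies = 12),
                                          list(motif = "CT", copies = 6),
                                          list(motif = "GGA", copies = 4)),
                      seed = 31, genome_length = 8000)
  s <- syn$genome$seq
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  f1 <- find_ssrs(s)
  f2 <- find_ssrs(rc)
  expect_identical(nrow(f1), nrow(f2))
  L <- nchar(s)
  mirrored <- data.frame(start = L - f2$end + 1L, end = L - f2$start + 1L)
  expect_setequal(paste(f1$start, f1$end), paste(mirrored$start, mirrored$end))
})

test_that("SSR screen has perfect precision and recall on planted genomes", {
  for (sd in c(42, 7, 99)) {
    syn <- synth_genome(
      n_genes = 10,
      planted_ssrs = list(list(motif = "A", copies = 12, region = "IGS"),
                          list(motif = "T", copies = 10, region = "IGS"),
                          list(motif = "AT", copies = 6, region = "CDS"),
                          list(motif = "GAT", copies = 5, region = "intron"),
                          list(motif = "ATCG", copies = 4, region = "CDS")),
      seed = sd, genome_length = 20000)
    found <- find_ssrs(syn$genome)
    truth <- syn$ssr_truth
    expect_identical(nrow(found), nrow(truth))
    key <- function(d) paste(d$motif, d$start, d$end)
    expect_setequal(key(found), key(truth))
    cls <- classify_ssr_regions(found, syn$genome)
    m <- match(key(cls), key(truth))
    expect_identical(cls$region_class, truth$region_class[m])
  }
})

test_that("region classification applies coding > intron > IGS precedence", {
  g <- annotated_genome("x", strrep("ACGT", 50), features = data.frame(
    name = c("g1", "g1", "g1-intron1", "g1"),
    kind = c("gene", "CDS", "intron", "CDS"),
    start = c(21L, 21L, 61L, 101L), end = c(140L, 60L, 100L, 140L),
    strand = "+", stringsAsFactors = FALSE))
  loci <- data.frame(motif = "A", unit_len = 1L, copies = 10L,
                     start = c(30L, 70L, 150L), end = c(39L, 79L, 159L))
  cls <- classify_ssr_regions(loci, g)
  expect_identical(cls$region_class, c("CDS", "intron", "IGS"))
})

test_that("tandem screen recovers planted arrays exactly and honors its floors", {
  syn <- synth_genome(
    n_genes = 8,
    planted_tandems = list(list(unit_len = 40, copies = 3, identity = 1.0),
                           list(unit_len = 35, copies = 2, identity = 1.0),
                           list(unit_len = 60, copies = 2, identity = 1.0)),
    seed = 42, genome_length = 20000)
  tr <- find_tandem_repeats(syn$genome)
  truth <- syn$tandem_truth
  expect_identical(nrow(tr), nrow(truth))
  expect_setequal(paste(tr$start, tr$end, tr$unit_len),
                  paste(truth$start, truth$end, truth$unit_len))
  expect_true(all(tr$identity == 1))

  # identity floor: 0.85 arrays stay unreported, 0.95 arrays are found
  lo <- synth_genome(planted_tandems = list(
    list(unit_len = 40, copies = 2, identity = 0.85)), seed = 5,
    genome_length = 8000)
  expect_identical(nrow(find_tandem_repeats(lo$genome)), 0L)
  hi <- synth_genome(planted_tandems = list(
    list(unit_len = 40, copies = 3, identity = 0.95)), seed = 6,
    genome_length = 8000)
  hits <- find_tandem_repeats(hi$genome)
  expect_identical(nrow(hits), 1L)
  # degenerate copies: the array must be found at its locus (boundary
  # columns carrying substitutions may be trimmed, so coordinates are
  # only guaranteed for perfect arrays)
  ov <- min(hits$end, hi$tandem_truth$end) - max(hits$start, hi$tandem_truth$start) + 1
  expect_gte(ov / (hi$tandem_truth$end - hi$tandem_truth$start + 1), 0.5)
  expect_identical(hits$unit_len, hi$tandem_truth$unit_len)

  expect_error(find_tandem_repeats("ACGT", min_unit = 0), "min_unit")
  # clean background: no plants, no calls
  clean <- synth_genome(n_genes = 5, seed = 8, genome_length = 10000)
  expect_identical(nrow(find_tandem_repeats(clean$genome)), 0L)
  expect_identical(nrow(find_ssrs(clean$genome)), 0L)
})
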