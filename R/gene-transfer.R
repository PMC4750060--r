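# Analysis of nuclear copies of plastid genes: ORF discovery and
# translation, intron detection by genomic-versus-transcript comparison,
# upstream promoter-motif scanning and protein identity.
#
# Offset convention: the A of the translation-start ATG is +1 and the
# base immediately 5' of it is -1 (there is no offset 0). An intron
# whose insertion point lies between the bases at offsets -65 and -64
# is reported with upstream_offset -65 and downstream_offset -64.

GENETIC_CODE_STOPS <- c("TAA", "TAG", "TGA")

translate_orf <- function(nt) {
  aa <- Biostrings::translate(Biostrings::DNAString(nt))
  as.character(aa)
}

#' Longest open reading frame of a transcript
#'
#' Scans the three forward frames (transcript orientation is known) for
#' the longest ATG-to-stop ORF under the standard genetic code.
#'
#' @param transcript nucleotide string.
#' @param min_codons ORFs shorter than this raise a warning (the best
#'   available ORF is still returned); default 50.
#' @return The protein string (stop excluded), with attributes `start`
#'   and `end` (1-based nucleotide coordinates of the ORF on the
#'   transcript, stop codon included).
#' @examples
#' longest_orf("ATGAAATGA")   # "MK"
#' @export
longest_orf <- function(transcript, min_codons = 50L) {
  s <- toupper(transcript)
  L <- nchar(s)
  best <- NULL
  for (frame in 0:2) {
    starts <- integer(0)
    i <- frame + 1L
    open_at <- NA_integer_
    while (i + 2L <= L) {
      codon <- substring(s, i, i + 2L)
      if (is.na(open_at) && codon == "ATG") open_at <- i
      if (!is.na(open_at) && codon %in% GENETIC_CODE_STOPS) {
        len <- i + 2L - open_at + 1L
        if (is.null(best) || len > best$len)
          best <- list(start = open_at, end = i + 2L, len = len)
        open_at <- NA_integer_
      }
      i <- i + 3L
    }
  }
  if (is.null(best))
    stop("no ATG...stop open reading frame found")
  n_codons <- best$len / 3L - 1L
  if (n_codons < min_codons)
    warning("longest ORF has only ", n_codons, " codons (< ", min_codons, ")")
  prot <- translate_orf(substring(s, best$start, best$end - 3L))
  structure(prot, start = best$start, end = best$end)
}

#' Detect introns by genomic-versus-transcript comparison
#'
#' Aligns the genomic copy of a gene against its spliced transcript
#' (affine gaps, free end gaps so untranscribed flanking sequence stays
#' outside the alignment); every maximal gap in the transcript row is
#' an intron, reported with genomic coordinates and with offsets
#' relative to the translation start of the transcript ORF. Exonic
#' mismatches (candidate RNA-editing sites) are reported rather than
#' treated as errors. Splice sites are taken purely from the alignment;
#' GT..AG conformance is annotated, not enforced.
#'
#' @param genomic nucleotide string of the genomic (intron-containing)
#'   copy.
#' @param transcript nucleotide string of the spliced transcript.
#' @param min_orf_codons passed to [longest_orf()].
#' @return A `gene_structure`: list with `orf_start`/`orf_end` (genomic
#'   coordinates), `orf_protein`, `introns` (data.frame `start`, `end`,
#'   `length` on the genomic copy, `upstream_offset`/`downstream_offset`
#'   relative to the translation start, `gt_ag` flag), `utr5_len`,
#'   `utr3_len` and `mismatch_sites` (genomic positions of exon
#'   mismatches; none expected for a faithful nuclear copy).
#' @export
find_introns <- function(genomic, transcript, min_orf_codons = 50L) {
  g <- toupper(genomic)
  tr <- toupper(transcript)
  # overlap (free end-gap) alignment: the transcribed region is embedded
  # in the genomic copy, and untranscribed flanks (promoter region,
  # downstream DNA) must stay outside the alignment rather than surface
  # as spurious terminal "introns"
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(g), Biostrings::DNAString(tr), type = "overlap",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 2, mismatch = -3, baseOnly = FALSE),
    gapOpening = 8, gapExtension = 0.2)
  ga <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  ta <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]

  g_off <- Biostrings::start(Biostrings::pattern(al)) - 1L
  t_off <- Biostrings::start(Biostrings::subject(al)) - 1L
  gpos <- g_off + cumsum(ga != "-")     # genomic coordinate per column
  tpos <- t_off + cumsum(ta != "-")     # transcript coordinate per column

  # introns: maximal runs of gap in the transcript row
  r <- rle(ta == "-")
  col <- cumsum(c(1L, r$lengths))
  introns <- data.frame(start = integer(), end = integer(),
                        length = integer(), upstream_offset = integer(),
                        downstream_offset = integer(), gt_ag = logical(),
                        stringsAsFactors = FALSE)
  orf <- longest_orf(tr, min_codons = min_orf_codons)
  orf_t_start <- attr(orf, "start")
  orf_t_end <- attr(orf, "end")
  t_offset <- function(tp) {
    # offset of the transcript base tp relative to translation start
    if (tp >= orf_t_start) tp - orf_t_start + 1L else tp - orf_t_start
  }
  for (k in seq_along(r$lengths)) {
    if (!r$values[k]) next
    c1 <- col[k]
    c2 <- col[k] + r$lengths[k] - 1L
    # gap runs touching an alignment end are untranscribed flanking
    # sequence (promoter region, downstream DNA), not introns
    if (c1 == 1L || c2 == length(ta)) next
    gs <- gpos[c1]
    ge <- gpos[c2]
    # transcript base preceding / following the insertion point
    before <- if (c1 > 1L) tpos[c1 - 1L] else t_off
    after <- before + 1L
    introns[nrow(introns) + 1L, ] <- list(
      start = gs, end = ge, length = ge - gs + 1L,
      upstream_offset = if (before >= 1L) t_offset(before) else NA_integer_,
      downstream_offset = t_offset(after),
      gt_ag = substring(g, gs, gs + 1L) == "GT" &&
        substring(g, ge - 1L, ge) == "AG")
  }
  # exon mismatches (both rows aligned, letters differ) and genomic-row gaps
  mm <- which(ga != "-" & ta != "-" & ga != ta)
  # map ORF to genomic coordinates
  orf_cols_start <- which(tpos == orf_t_start & ta != "-")[1]
  orf_cols_end <- which(tpos == orf_t_end & ta != "-")[1]
  structure(list(
    orf_start = gpos[orf_cols_start],
    orf_end = gpos[orf_cols_end],
    orf_protein = as.character(orf),
    introns = introns,
    utr5_len = orf_t_start - 1L,
    utr3_len = nchar(tr) - orf_t_end,
    mismatch_sites = gpos[mm]), class = "gene_structure")
}

#' @export
print.gene_structure <- function(x, ...) {
  cat("<gene_structure> ORF ", x$orf_start, "..", x$orf_end, " (",
      nchar(x$orf_protein), " aa), 5'UTR ", x$utr5_len, " bp, 3'UTR ",
      x$utr3_len, " bp, ", nrow(x$introns), " intron(s)\n", sep = "")
  if (nrow(x$introns)) {
    for (k in seq_len(nrow(x$introns)))
      cat(sprintf("  intron %d: %d..%d (%d bp) at offsets %d/%d%s\n", k,
                  x$introns$start[k], x$introns$end[k], x$introns$length[k],
                  x$introns$upstream_offset[k], x$introns$downstream_offset[k],
                  if (x$introns$gt_ag[k]) " [GT..AG]" else ""))
  }
  if (length(x$mismatch_sites))
    cat("  exon mismatches at:", paste(x$mismatch_sites, collapse = ", "), "\n")
  invisible(x)
}

#' Scan upstream sequence for a promoter motif
#'
#' Exact-match scan of the region upstream of the translation start;
#' occurrences are reported as negative offsets of the motif's 5' base
#' (base -1 is immediately 5' of the ATG).
#'
#' @param genomic nucleotide string containing the gene and its upstream
#'   region.
#' @param orf_start 1-based position of the A of the translation-start
#'   ATG on `genomic`.
#' @param motif motif to search for (default `"TATA"`).
#' @param window how far upstream to scan, in bp; truncated with a
#'   warning if less sequence is available.
#' @return Integer vector of negative offsets (empty if absent).
#' @export
scan_promoter <- function(genomic, orf_start, motif = "TATA", window = 2000L) {
  s <- toupper(genomic)
  if (orf_start < 2L) return(integer(0))
  from <- orf_start - window
  if (from < 1L) {
    warning("window truncated to the ", orf_start - 1L,
            " bp of available upstream sequence")
    from <- 1L
  }
  up <- substring(s, from, orf_start - 1L)
  m <- nchar(motif)
  if (nchar(up) < m) return(integer(0))
  # overlapping occurrences ("TATATA" holds two TATA boxes)
  starts <- seq_len(nchar(up) - m + 1L)
  hits <- starts[substring(up, starts, starts + m - 1L) == toupper(motif)]
  if (!length(hits)) return(integer(0))
  as.integer(hits) + from - 1L - orf_start
}

#' Percent identity of two protein sequences
#'
#' Global alignment (BLOSUM62, affine gaps); identity is matches over
#' aligned columns, gap columns counting as mismatches (no end-gap
#' forgiveness), so identical sequences -- and only those -- score 1.
#'
#' @param protA,protB protein strings.
#' @param gap_opening,gap_extension affine gap parameters.
#' @return Fraction in `[0, 1]`.
#' @examples
#' percent_identity("MKV", "MRV")  # 2/3
#' @export
percent_identity <- function(protA, protB, gap_opening = 10, gap_extension = 0.5) {
  if (!nzchar(protA) || !nzchar(protB)) stop("empty protein sequence")
  if (protA == protB) return(1)
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(protA), Biostrings::AAString(protB), type = "global",
    substitutionMatrix = "BLOSUM62",
    gapOpening = gap_opening, gapExtension = gap_extension)
  pa <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  sum(pa == pb & pa != "-") / length(pa)
}
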