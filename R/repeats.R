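# Repeat screens: MISA-dialect microsatellite (SSR) detection and a
# deterministic seed-and-extend tandem-repeat finder with the thresholds
# used for plastome surveys (unit >= 30 bp, adjacent-copy identity >=
# 90%, >= 2 copies).

#' Default MISA-style SSR thresholds
#'
#' Minimum copy number per motif length: 10 for mononucleotide, 5 for
#' dinucleotide, 4 for tri- to hexanucleotide motifs.
#' @return Named integer vector, names "1".."6".
#' @export
ssr_default_thresholds <- function() {
  stats::setNames(c(10L, 5L, 4L, 4L, 4L, 4L), as.character(1:6))
}

#' Find simple sequence repeats (microsatellites)
#'
#' Reports maximal perfect tandem runs of primitive 1-6 bp motifs whose
#' copy number meets the per-motif-length threshold. A run is reported
#' once, under its primitive motif ("AAAA" is a mononucleotide run, never
#' a dinucleotide one), truncated to whole copies so that
#' `end - start + 1 == unit_len * copies`. Motifs are reported as found;
#' strand complements are not merged.
#'
#' @param seq nucleotide string (or [annotated_genome]).
#' @param thresholds named vector mapping motif length ("1".."6") to the
#'   minimum copy number; defaults to [ssr_default_thresholds()].
#' @return data.frame with columns `motif`, `unit_len`, `copies`,
#'   `start`, `end`, sorted by `start`.
#' @examples
#' find_ssrs("GGCTTAAAAAAAAAAAAGTC")  # one (A)12 locus
#' @export
find_ssrs <- function(seq, thresholds = ssr_default_thresholds()) {
  if (inherits(seq, "annotated_genome")) seq <- seq$seq
  seq <- toupper(seq)
  out <- data.frame(motif = character(), unit_len = integer(),
                    copies = integer(), start = integer(), end = integer(),
                    stringsAsFactors = FALSE)
  L <- nchar(seq)
  if (L == 0L) return(out)
  ch <- strsplit(seq, "")[[1]]
  for (p in 1:6) {
    min_copies <- as.integer(thresholds[[as.character(p)]])
    if (is.na(min_copies)) next
    if (L < p * min_copies) next
    eq <- ch[seq_len(L - p)] == ch[(p + 1L):L]  # eq[i]: s[i] == s[i+p]
    # maximal runs of TRUE
    r <- rle(eq)
    pos <- cumsum(c(1L, r$lengths))
    for (k in seq_along(r$lengths)) {
      if (!r$values[k]) next
      run_start <- pos[k]              # first i with s[i] == s[i+p]
      run_len <- r$lengths[k]
      region_len <- run_len + p        # bases run_start .. run_start+run_len-1+p
      copies <- region_len %/% p
      if (copies < min_copies) next
      motif <- substring(seq, run_start, run_start + p - 1L)
      if (!is_primitive(motif)) next
      if (grepl("N", motif, fixed = TRUE)) next
      out[nrow(out) + 1L, ] <- list(motif = motif, unit_len = p,
                                    copies = copies, start = run_start,
                                    end = run_start + p * copies - 1L)
    }
  }
  out <- unique(out)
  out[order(out$start, out$unit_len), , drop = FALSE]
}

is_primitive <- function(motif) {
  p <- nchar(motif)
  if (p == 1L) return(TRUE)
  for (d in seq_len(p - 1L)) {
    if (p %% d != 0L) next
    if (identical(strrep(substring(motif, 1L, d), p %/% d), motif))
      return(FALSE)
  }
  TRUE
}

#' Classify SSR loci by genomic region
#'
#' Assigns each locus the region class covering its start position, with
#' precedence coding exon (CDS/tRNA/rRNA) > intron > intergenic spacer
#' (IGS).
#'
#' @param loci data.frame from [find_ssrs()].
#' @param genome an [annotated_genome] with CDS/tRNA/rRNA (and intron)
#'   features.
#' @return `loci` with an added `region_class` column
#'   (`"CDS"`/`"intron"`/`"IGS"`).
#' @export
classify_ssr_regions <- function(loci, genome) {
  fe <- genome$features
  covers <- function(row, pos) {
    if (row$end >= row$start) pos >= row$start & pos <= row$end
    else pos >= row$start | pos <= row$end   # wrap-around
  }
  cls <- vapply(loci$start, function(pos) {
    in_kind <- function(kinds) {
      any(vapply(seq_len(nrow(fe)), function(r)
        fe$kind[r] %in% kinds && covers(fe[r, ], pos), logical(1)))
    }
    if (nrow(fe) == 0L) return("IGS")
    if (in_kind(c("CDS", "tRNA", "rRNA"))) "CDS"
    else if (in_kind("intron")) "intron"
    else "IGS"
  }, character(1))
  loci$region_class <- cls
  loci
}

#' Find tandem repeats of long units
#'
#' Deterministic seed-and-extend detector for tandem arrays of units of
#' at least `min_unit` bp: candidate periods are proposed where identical
#' `k`-mers recur at a spacing in range, the array is extended maximally
#' at that period, adjacent copies are verified by global alignment
#' (match = 1, mismatch = 0, gap columns count as mismatches) against the
#' identity floor, and nested or redundant overlapping calls are removed,
#' keeping the call with the most copies, then the smallest unit.
#'
#' @param seq nucleotide string (or [annotated_genome]).
#' @param min_unit minimum unit length in bp (default 30).
#' @param min_identity minimum adjacent-copy identity (default 0.90).
#' @param min_copies minimum number of copies (default 2).
#' @param k seed k-mer length (default 13).
#' @param max_unit largest period considered (default 1000).
#' @return data.frame with columns `start`, `end`, `unit_len`, `copies`,
#'   `identity`, `consensus`.
#' @export
find_tandem_repeats <- function(seq, min_unit = 30L, min_identity = 0.90,
                                min_copies = 2, k = 13L, max_unit = 1000L) {
  if (inherits(seq, "annotated_genome")) seq <- seq$seq
  if (min_unit < 1L) stop("min_unit must be >= 1")
  seq <- toupper(seq)
  L <- nchar(seq)
  empty <- data.frame(start = integer(), end = integer(),
                      unit_len = integer(), copies = numeric(),
                      identity = numeric(), consensus = character(),
                      stringsAsFactors = FALSE)
  if (L < 2L * min_unit) return(empty)
  ch <- strsplit(seq, "")[[1]]

  # candidate periods from repeated k-mer spacings
  kmers <- substring(seq, seq_len(L - k + 1L), k:L)
  ord <- order(kmers)
  sk <- kmers[ord]
  dup <- sk[-1L] == sk[-length(sk)]
  cand_periods <- integer(0)
  if (any(dup)) {
    grp <- cumsum(!c(TRUE, dup))
    for (g in split(ord, grp)) {
      if (length(g) < 2L) next
      d <- diff(sort(g))
      cand_periods <- c(cand_periods, d[d >= min_unit & d <= max_unit])
    }
    cand_periods <- sort(unique(cand_periods))
  }
  if (!length(cand_periods)) return(empty)

  calls <- empty
  for (d in cand_periods) {
    eq <- ch[seq_len(L - d)] == ch[(d + 1L):L]
    # merge TRUE-runs separated by short FALSE-runs (substitutions in a
    # copy interrupt the self-match); the gap is bounded both by the
    # identity budget and by an absolute cap, since chance matches occur
    # at 1/4 per column and an uncapped gap would chain them into
    # genome-spanning clusters at large periods
    tol <- max(0L, min(8L, floor((1 - min_identity) * d)))
    r <- rle(eq)
    # positions of runs
    starts <- cumsum(c(1L, r$lengths))[seq_along(r$lengths)]
    ends <- starts + r$lengths - 1L
    keep <- r$values | (r$lengths <= tol)
    # merge consecutive kept runs
    kk <- rle(keep)
    ks <- cumsum(c(1L, kk$lengths))[seq_along(kk$lengths)]
    eval_region <- function(runs) {
      a <- runs$s[1]
      b <- runs$e[nrow(runs)]
      if (b - a + 1L < d * (min_copies - 1L)) return(NULL)
      reg_start <- a
      reg_end <- min(b + d, L)
      copies <- (reg_end - reg_start + 1L) / d
      if (copies < min_copies) return(NULL)
      n_full <- floor(copies)
      idents <- vapply(seq_len(n_full - 1L), function(cidx) {
        u1 <- substring(seq, reg_start + (cidx - 1L) * d,
                        reg_start + cidx * d - 1L)
        u2 <- substring(seq, reg_start + cidx * d,
                        reg_start + (cidx + 1L) * d - 1L)
        alignment_identity(u1, u2)
      }, numeric(1))
      tail_len <- reg_end - (reg_start + n_full * d) + 1L
      if (tail_len >= 1L) {
        # a fractional trailing copy must match the corresponding prefix
        # of the previous copy too, or it is flank sequence
        u1 <- substring(seq, reg_start + (n_full - 1L) * d,
                        reg_start + (n_full - 1L) * d + tail_len - 1L)
        u2 <- substring(seq, reg_start + n_full * d, reg_end)
        idents <- c(idents, alignment_identity(u1, u2))
      }
      list(start = reg_start, end = reg_end, copies = copies,
           ident = min(idents))
    }
    for (q in seq_along(kk$lengths)) {
      if (!kk$values[q]) next
      ridx <- ks[q]:(ks[q] + kk$lengths[q] - 1L)
      # chance matches at period d occur at 1/4 per column and merge
      # into the cluster whenever they sit within the mismatch
      # tolerance of each other, so first strip boundary match-runs
      # shorter than 4 columns (cheap index arithmetic, no subsetting),
      # then demand that what remains spans at least one unit and is
      # mostly matching before any alignment work is spent on it
      vv <- r$values[ridx]; ll <- r$lengths[ridx]
      ss <- starts[ridx]; ee <- ends[ridx]
      lo <- 1L; hi <- length(vv)
      repeat {
        while (lo <= hi && !vv[lo]) lo <- lo + 1L
        while (hi >= lo && !vv[hi]) hi <- hi - 1L
        if (lo < hi && ll[lo] < 4L) { lo <- lo + 1L; next }
        if (hi > lo && ll[hi] < 4L) { hi <- hi - 1L; next }
        break
      }
      if (lo > hi) next
      span <- ee[hi] - ss[lo] + 1L
      sum_true <- sum(ll[lo:hi][vv[lo:hi]])
      if (span < d * (min_copies - 1L) - 2L * tol) next
      if (sum_true < 0.7 * span) next
      runs <- data.frame(val = vv[lo:hi], len = ll[lo:hi],
                         s = ss[lo:hi], e = ee[lo:hi])
      # enumerate trim states that peel remaining short (< k) boundary
      # match-runs and keep the one with the best identity, then the
      # longest region
      trimmable <- function(rr, from_left) {
        depth <- 0L
        while (depth < 8L && nrow(rr) > 2L) {
          lenb <- if (from_left) rr$len[1] else rr$len[nrow(rr)]
          if (lenb >= k) break
          rr <- if (from_left) rr[-(1:2), ] else rr[-((nrow(rr) - 1L):nrow(rr)), ]
          depth <- depth + 1L
        }
        depth
      }
      cur <- NULL
      for (li in 0:trimmable(runs, TRUE)) {
        rl <- runs
        if (li > 0L) rl <- rl[-seq_len(2L * li), ]
        for (ri in 0:trimmable(rl, FALSE)) {
          rr <- rl
          if (ri > 0L) rr <- rr[seq_len(nrow(rr) - 2L * ri), ]
          cand <- eval_region(rr)
          if (is.null(cand)) next
          if (is.null(cur) || cand$ident > cur$ident ||
              (cand$ident == cur$ident && cand$end - cand$start > cur$end - cur$start))
            cur <- cand
        }
      }
      if (is.null(cur) || cur$ident < min_identity) next
      calls[nrow(calls) + 1L, ] <- list(
        start = cur$start, end = cur$end, unit_len = d,
        copies = round(cur$copies, 2), identity = round(cur$ident, 4),
        consensus = substring(seq, cur$start, cur$start + d - 1L))
    }
  }
  if (!nrow(calls)) return(empty)
  # remove nested/redundant overlapping calls: keep most copies, then
  # smallest unit
  calls <- calls[order(-calls$copies, calls$unit_len, calls$start), , drop = FALSE]
  kept <- empty
  for (r in seq_len(nrow(calls))) {
    ov <- FALSE
    if (nrow(kept)) {
      ov <- any(pmin(kept$end, calls$end[r]) - pmax(kept$start, calls$start[r]) >= 0)
    }
    if (!ov) kept[nrow(kept) + 1L, ] <- calls[r, ]
  }
  kept[order(kept$start), , drop = FALSE]
}

# identity of a global pairwise alignment: matches / aligned columns,
# gap columns counting as mismatches
alignment_identity <- function(a, b) {
  if (a == b) return(1)
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = 0, baseOnly = FALSE),
    gapOpening = 2, gapExtension = 1)
  pa <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  sum(pa == pb & pa != "-") / length(pa)
}
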