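# Ground-truth generators: random signed circular permutations, planted
# inversion histories, annotated genomes with planted SSRs and tandem
# arrays on a repeat-free background, and genomic/transcript gene pairs
# with planted introns. Every generator is deterministic per seed and
# returns exact truth tables, so detector precision and recall can be
# asserted exactly.

#' Random signed circular permutation
#'
#' Uniform over raw arrangements (order and signs); not canonicalized,
#' so every block is negative in half of the draws.
#'
#' @param n number of blocks (>= 3).
#' @param seed integer seed.
#' @return An [scperm].
#' @export
random_permutation <- function(n, seed) {
  if (n < 3L) stop("n must be >= 3")
  set.seed(seed)
  scperm(sample(n) * sample(c(-1L, 1L), n, replace = TRUE))
}

#' Evolve a permutation by random inversions
#'
#' Applies `k` uniformly drawn inversions (junction pairs), recording
#' the history; if repeat `copies` are supplied (as for
#' [repeat_config()]), the configuration is traced alongside with
#' default cut slots.
#'
#' @param p source [scperm].
#' @param k number of inversions (>= 0).
#' @param seed integer seed.
#' @param copies optional copies list for [repeat_config()].
#' @return A `planted_history`: list with `seed`, `source`, `inversions`
#'   (list of `list(i, j, slots)`), `result`, and when copies are given
#'   `trace` (stepwise configurations) and `config` (final).
#' @export
evolve <- function(p, k, seed, copies = NULL) {
  if (k < 0L) stop("k must be >= 0")
  set.seed(seed)
  n <- length(p)
  w <- p
  cfg <- if (!is.null(copies)) repeat_config(p, copies) else NULL
  trace <- if (!is.null(cfg)) list(cfg) else NULL
  invs <- list()
  for (s in seq_len(k)) {
    repeat {
      ij <- sort(sample(0:n, 2L))
      if (!(ij[1] == 0L && ij[2] == n) && ij[1] != ij[2]) break
    }
    invs[[s]] <- list(i = ij[1], j = ij[2], slots = c(NA, NA))
    w <- apply_inversion(w, ij[1], ij[2])
    if (!is.null(cfg)) {
      cfg <- apply_inversion_traced(cfg, ij[1], ij[2])
      trace[[length(trace) + 1L]] <- cfg
    }
  }
  structure(list(seed = seed, source = p, inversions = invs, result = w,
                 trace = trace, config = cfg),
            class = "planted_history")
}

#' @export
print.planted_history <- function(x, ...) {
  cat("<planted_history> ", length(x$inversions), " inversion(s), seed ",
      x$seed, "\n", sep = "")
  invisible(x)
}

# Background sequence in which every k-mer is unique, so no tandem
# structure of unit >= k can occur by chance.
random_unique_kmer_seq <- function(len, k = 13L) {
  bases <- c("A", "C", "G", "T")
  seen <- new.env(hash = TRUE, parent = emptyenv())
  out <- character(len)
  i <- 1L
  stalls <- 0L
  while (i <= len) {
    placed <- FALSE
    for (b in sample(bases)) {
      if (i >= k) {
        km <- paste(c(out[(i - k + 1L):(i - 1L)], b), collapse = "")
        if (!is.null(seen[[km]])) next
        out[i] <- b
        seen[[km]] <- TRUE
        placed <- TRUE
        break
      } else {
        out[i] <- b
        placed <- TRUE
        break
      }
    }
    if (placed) {
      i <- i + 1L
    } else {
      # dead end: back up one base and retry (rare at plastome scale)
      stalls <- stalls + 1L
      if (stalls > 1000L) stop("cannot extend unique k-mer background")
      i <- i - 1L
    }
  }
  paste(out, collapse = "")
}

other_base <- function(avoid) {
  sample(setdiff(c("A", "C", "G", "T"), avoid), 1L)
}

#' Synthesize an annotated genome with planted repeats
#'
#' Builds a circular genome whose background has every `k`-mer unique
#' (so tandem structure above the seed length cannot occur by chance),
#' lays out `n_genes` gene/CDS features separated by intergenic spacers
#' (every fourth gene carries an intron), plants the requested SSR runs
#' and tandem arrays at non-overlapping positions with flanking bases
#' chosen so runs cannot extend, and finally mutates away any background
#' SSR that arose by chance outside the planted spans. Truth tables give
#' exact coordinates.
#'
#' Plant specifications: `planted_ssrs` entries are
#' `list(motif =, copies =, region = optional "CDS"/"intron"/"IGS",
#' start = optional)`; `planted_tandems` entries are `list(unit_len =,
#' copies =, identity = 1.0, region =, start =)` (integer copies).
#'
#' @param n_genes number of gene features.
#' @param planted_ssrs,planted_tandems plant specification lists.
#' @param seed integer seed.
#' @param genome_length total length in bp.
#' @param id genome identifier.
#' @return List with `genome` (an [annotated_genome]), `ssr_truth` and
#'   `tandem_truth` data.frames.
#' @export
synth_genome <- function(n_genes = 20L, planted_ssrs = list(),
                         planted_tandems = list(), seed = 1L,
                         genome_length = 20000L, id = "SYNTH1") {
  set.seed(seed)
  # feature layout: gene of 600-1200 bp, IGS gap of 200-500 bp
  features <- data.frame(name = character(), kind = character(),
                         start = integer(), end = integer(),
                         strand = character(), stringsAsFactors = FALSE)
  pos <- 1L + sample(100:300, 1L)
  for (g in seq_len(n_genes)) {
    glen <- sample(600:1200, 1L)
    if (pos + glen > genome_length - 200L) break
    strand <- sample(c("+", "-"), 1L)
    nm <- paste0("gene", g)
    if (g %% 4L == 0L && glen > 500L) {
      # two exons with an intron between
      e1 <- floor(glen * 0.4)
      ilen <- sample(80:150, 1L)
      e2 <- glen - e1 - ilen
      features[nrow(features) + 1L, ] <- list(nm, "gene", pos, pos + glen - 1L, strand)
      features[nrow(features) + 1L, ] <- list(nm, "CDS", pos, pos + e1 - 1L, strand)
      features[nrow(features) + 1L, ] <- list(paste0(nm, "-intron1"), "intron",
                                              pos + e1, pos + e1 + ilen - 1L, strand)
      features[nrow(features) + 1L, ] <- list(nm, "CDS", pos + e1 + ilen,
                                              pos + glen - 1L, strand)
    } else {
      features[nrow(features) + 1L, ] <- list(nm, "gene", pos, pos + glen - 1L, strand)
      features[nrow(features) + 1L, ] <- list(nm, "CDS", pos, pos + glen - 1L, strand)
    }
    pos <- pos + glen + sample(200:500, 1L)
  }
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)

  ch <- strsplit(random_unique_kmer_seq(genome_length), "")[[1]]

  region_intervals <- function(region) {
    if (region == "IGS") {
      # complement of gene spans, away from the origin
      genes <- features[features$kind == "gene", , drop = FALSE]
      genes <- genes[order(genes$start), , drop = FALSE]
      lo <- c(1L, genes$end + 1L)
      hi <- c(genes$start - 1L, genome_length)
      ok <- hi - lo > 40L
      cbind(lo[ok], hi[ok])
    } else {
      fe <- features[features$kind == if (region == "CDS") "CDS" else "intron", ,
                     drop = FALSE]
      cbind(fe$start, fe$end)
    }
  }

  occupied <- matrix(integer(0), ncol = 2)
  claim <- function(s, e) {
    if (nrow(occupied) &&
        any(pmin(occupied[, 2], e + 1L) - pmax(occupied[, 1], s - 1L) >= 0))
      return(FALSE)
    occupied <<- rbind(occupied, c(s, e))
    TRUE
  }
  place <- function(len, region, start) {
    if (!is.null(start)) {
      if (!claim(start, start + len - 1L))
        stop("planted repeats overlap at position ", start)
      return(start)
    }
    iv <- if (is.null(region)) matrix(c(2L, genome_length - len - 1L), ncol = 2)
          else region_intervals(region)
    for (tries in 1:200) {
      r <- iv[sample(nrow(iv), 1L), , drop = FALSE]
      if (r[2] - r[1] + 1L < len + 2L) next
      s <- sample(r[1]:(r[2] - len + 1L), 1L)
      if (s < 2L || s + len > genome_length) next
      if (claim(s, s + len - 1L)) return(s)
    }
    stop("could not place a planted repeat of length ", len,
         if (!is.null(region)) paste0(" in region ", region))
  }

  ssr_truth <- data.frame(motif = character(), unit_len = integer(),
                          copies = integer(), start = integer(),
                          end = integer(), region_class = character(),
                          stringsAsFactors = FALSE)
  for (sp in planted_ssrs) {
    motif <- toupper(sp$motif)
    p <- nchar(motif)
    len <- p * sp$copies
    s <- place(len, sp$region, sp$start)
    run <- strsplit(strrep(motif, sp$copies), "")[[1]]
    ch[s:(s + len - 1L)] <- run
    # flanks must not extend the run at its own period
    ch[s - 1L] <- other_base(c(substring(motif, p, p), ch[s - 1L + p]))
    if (s + len <= genome_length)
      ch[s + len] <- other_base(c(substring(motif, 1L, 1L), ch[s + len - p]))
    ssr_truth[nrow(ssr_truth) + 1L, ] <-
      list(motif, p, as.integer(sp$copies), s, s + len - 1L,
           if (is.null(sp$region)) NA_character_ else sp$region)
  }

  tandem_truth <- data.frame(start = integer(), end = integer(),
                             unit_len = integer(), copies = integer(),
                             identity = numeric(), stringsAsFactors = FALSE)
  for (tp in planted_tandems) {
    d <- tp$unit_len
    cc <- tp$copies
    idy <- if (is.null(tp$identity)) 1.0 else tp$identity
    len <- d * cc
    s <- place(len, tp$region, tp$start)
    unit <- sample(c("A", "C", "G", "T"), d, replace = TRUE)
    arr <- rep(unit, cc)
    n_mut <- round((1 - idy) * d)
    if (n_mut > 0L) {
      for (ci in 2:cc) {
        at <- sample(2:(d - 1L), n_mut)
        for (a in at) {
          idx <- (ci - 1L) * d + a
          arr[idx] <- other_base(arr[idx])
        }
      }
    }
    ch[s:(s + len - 1L)] <- arr
    ch[s - 1L] <- other_base(c(ch[s - 1L + d], ch[s - 1L]))
    if (s + len <= genome_length)
      ch[s + len] <- other_base(c(ch[s + len - d], ch[s + len]))
    tandem_truth[nrow(tandem_truth) + 1L, ] <-
      list(s, s + len - 1L, as.integer(d), as.integer(cc), idy)
  }

  # scrub chance SSRs outside planted spans
  seqstr <- paste(ch, collapse = "")
  for (pass in 1:20) {
    found <- find_ssrs(seqstr)
    extra <- found[!(found$start %in% ssr_truth$start &
                       found$end %in% ssr_truth$end), , drop = FALSE]
    if (nrow(ssr_truth))
      extra <- extra[!vapply(seq_len(nrow(extra)), function(r)
        any(extra$start[r] <= ssr_truth$end & extra$end[r] >= ssr_truth$start),
        logical(1)), , drop = FALSE]
    if (!nrow(extra)) break
    for (r in seq_len(nrow(extra))) {
      mid <- extra$start[r] + (extra$end[r] - extra$start[r]) %/% 2L
      ch[mid] <- other_base(c(ch[mid], ch[mid + extra$unit_len[r]],
                              ch[mid - extra$unit_len[r]]))
    }
    seqstr <- paste(ch, collapse = "")
  }

  genome <- annotated_genome(id = id, seq = seqstr, circular = TRUE,
                             features = features)
  if (nrow(ssr_truth))
    ssr_truth$region_class <- classify_ssr_regions(
      ssr_truth[, c("motif", "unit_len", "copies", "start", "end")], genome)$region_class
  list(genome = genome, ssr_truth = ssr_truth, tandem_truth = tandem_truth)
}

#' Synthesize a genomic/transcript gene pair with planted introns
#'
#' The transcript is 5' UTR + ORF (ATG, non-stop codons, stop) + 3' UTR;
#' the genomic copy is the transcript with the specified introns
#' inserted (and an optional upstream region carrying a planted TATA
#' box). Intron boundary bases are chosen to differ from the adjacent
#' exon bases, so the gap placement in a genomic-versus-transcript
#' alignment is unambiguous and truth coordinates are exact; the 5' UTR
#' is generated ATG-free so no chance upstream start codon can extend
#' the planted ORF.
#'
#' Intron specification: `list(length =, at =)` where `at` is the offset
#' (translation-start convention, -1 = immediately 5' of the ATG) of the
#' exon base immediately 5' of the insertion point; `at = -65` plants an
#' intron between the bases at offsets -65 and -64.
#'
#' @param intron_specs list of intron specifications.
#' @param seed integer seed.
#' @param utr5_len,utr3_len UTR lengths on the transcript (bp).
#' @param orf_codons protein length in amino acids (ATG included).
#' @param upstream_len extra genomic sequence 5' of the transcribed
#'   region.
#' @param tata_at optional offset for a planted TATA box (e.g. -1599);
#'   requires sufficient `upstream_len`/`utr5_len`; the upstream region
#'   is generated free of other TATA matches.
#' @return List with `genomic`, `transcript`, and `truth` (list:
#'   `orf_start` on the genomic copy, `orf_t_start` on the transcript,
#'   `protein`, `introns` data.frame with genomic `start`, `end`,
#'   `length`, `upstream_offset`, `downstream_offset`).
#' @export
synth_gene_pair <- function(intron_specs = list(), seed = 1L,
                            utr5_len = 120L, orf_codons = 212L,
                            utr3_len = 100L, upstream_len = 0L,
                            tata_at = NULL) {
  stopifnot(all(vapply(intron_specs, function(x) x$length >= 1L, logical(1))))
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  codons <- apply(expand.grid(bases, bases, bases), 1, paste, collapse = "")
  sense <- setdiff(codons, c(GENETIC_CODE_STOPS, "ATG"))
  orf <- paste0("ATG", paste(sample(sense, orf_codons - 1L, replace = TRUE),
                             collapse = ""), "TAA")
  rand_nt <- function(k) paste(sample(bases, k, replace = TRUE), collapse = "")
  # the 5' UTR must not contain an ATG: a chance upstream start codon in
  # frame with the planted ORF would extend it and shift every offset
  utr5 <- ""
  if (utr5_len > 0L) {
    repeat {
      utr5 <- rand_nt(utr5_len)
      if (!grepl("ATG", utr5, fixed = TRUE)) break
    }
  }
  transcript <- paste0(utr5, orf, rand_nt(utr3_len))
  orf_t_start <- utr5_len + 1L

  # insertion point (transcript position after which the intron sits)
  spec_pos <- vapply(intron_specs, function(x) {
    at <- x$at
    p <- if (at < 0L) orf_t_start + at else orf_t_start + at - 1L
    if (p < 1L || p >= nchar(transcript))
      stop("intron offset ", at, " outside the transcript")
    as.integer(p)
  }, integer(1))
  ord <- order(spec_pos)
  intron_specs <- intron_specs[ord]
  spec_pos <- spec_pos[ord]
  if (anyDuplicated(spec_pos)) stop("introns share an insertion point")

  tch <- strsplit(transcript, "")[[1]]
  gparts <- character(0)
  truth <- data.frame(start = integer(), end = integer(), length = integer(),
                      upstream_offset = integer(), downstream_offset = integer(),
                      stringsAsFactors = FALSE)
  gpos <- 0L
  prev <- 1L
  t_off <- function(tp) if (tp >= orf_t_start) tp - orf_t_start + 1L else tp - orf_t_start
  for (k in seq_along(intron_specs)) {
    ilen <- intron_specs[[k]]$length
    exon <- paste(tch[prev:spec_pos[k]], collapse = "")
    intr <- strsplit(rand_nt(ilen), "")[[1]]
    # unambiguous boundaries: first base differs from the next exon base,
    # last base differs from the previous exon base
    intr[1L] <- other_base(c(tch[spec_pos[k] + 1L], intr[1L]))
    intr[ilen] <- other_base(c(tch[spec_pos[k]], intr[ilen]))
    gparts <- c(gparts, exon, paste(intr, collapse = ""))
    gpos <- gpos + nchar(exon)
    truth[nrow(truth) + 1L, ] <- list(gpos + 1L, gpos + ilen, ilen,
                                      t_off(spec_pos[k]),
                                      t_off(spec_pos[k] + 1L))
    gpos <- gpos + ilen
    prev <- spec_pos[k] + 1L
  }
  gparts <- c(gparts, paste(tch[prev:length(tch)], collapse = ""))
  gene_seq <- paste(gparts, collapse = "")

  upstream <- ""
  if (upstream_len > 0L) {
    repeat {
      upstream <- rand_nt(upstream_len)
      if (!grepl("TATA", upstream, fixed = TRUE)) break
    }
  }
  intron_before_orf <- sum(truth$length[truth$upstream_offset < 0L])
  orf_g_start <- upstream_len + utr5_len + intron_before_orf + 1L
  if (!is.null(tata_at)) {
    at <- abs(tata_at)
    s <- orf_g_start - at          # genomic position of the motif's 5' base
    if (s < 1L) stop("tata_at lies outside the generated sequence")
    up <- strsplit(paste0(upstream, gene_seq), "")[[1]]
    up[s:(s + 3L)] <- c("T", "A", "T", "A")
    full <- paste(up, collapse = "")
  } else {
    full <- paste0(upstream, gene_seq)
  }
  truth$start <- as.integer(truth$start + upstream_len)
  truth$end <- as.integer(truth$end + upstream_len)
  truth$length <- as.integer(truth$length)
  truth$upstream_offset <- as.integer(truth$upstream_offset)
  truth$downstream_offset <- as.integer(truth$downstream_offset)

  list(genomic = full, transcript = transcript,
       truth = list(orf_start = as.integer(orf_g_start),
                    orf_t_start = as.integer(orf_t_start),
                    protein = translate_orf(substring(orf, 1L, nchar(orf) - 3L)),
                    introns = truth))
}
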