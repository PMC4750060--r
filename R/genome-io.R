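# Annotated circular genomes: GenBank flat-file parsing, FASTA/TSV
# round-trips, composition statistics and sequence extraction.
# Coordinates are 1-based inclusive throughout (GenBank convention);
# features on circular genomes may wrap the origin (end < start).

FEATURE_KINDS <- c("gene", "CDS", "tRNA", "rRNA", "intron", "IGS")

#' Construct an annotated genome
#'
#' @param id accession-like identifier string.
#' @param seq nucleotide string over `A`, `C`, `G`, `T`, `N`
#'   (case-insensitive; stored upper-case). Other ambiguity codes are
#'   rejected.
#' @param circular logical; plastomes are circular.
#' @param features `data.frame` with columns `name`, `kind` (one of
#'   gene, CDS, tRNA, rRNA, intron, IGS), `start`, `end` (1-based
#'   inclusive) and `strand` (`+`/`-`). A wrap-around feature on a
#'   circular genome has `end < start`.
#' @return An object of class `annotated_genome`.
#' @export
annotated_genome <- function(id, seq, circular = TRUE, features = NULL) {
  seq <- toupper(seq)
  if (!nzchar(seq)) stop("sequence must be non-empty")
  if (grepl("[^ACGTN]", seq))
    stop("sequence contains characters outside {A,C,G,T,N}: ",
         paste(unique(strsplit(gsub("[ACGTN]", "", seq), "")[[1]]), collapse = ""))
  if (is.null(features)) {
    features <- data.frame(name = character(), kind = character(),
                           start = integer(), end = integer(),
                           strand = character(), stringsAsFactors = FALSE)
  }
  stopifnot(all(c("name", "kind", "start", "end", "strand") %in% names(features)))
  if (nrow(features)) {
    if (!all(features$kind %in% FEATURE_KINDS))
      stop("unknown feature kind(s): ",
           paste(setdiff(features$kind, FEATURE_KINDS), collapse = ", "))
    if (!all(features$strand %in% c("+", "-")))
      stop("strand must be '+' or '-'")
    len <- nchar(seq)
    bad <- features$start < 1 | features$start > len |
      features$end < 1 | features$end > len
    if (any(bad))
      stop("feature(s) outside [1, ", len, "]: ",
           paste(features$name[bad], collapse = ", "))
    if (!circular && any(features$end < features$start))
      stop("wrap-around features require a circular genome")
  }
  structure(list(id = id, seq = seq, circular = circular,
                 features = features),
            class = "annotated_genome")
}

#' @export
print.annotated_genome <- function(x, ...) {
  cat("<annotated_genome> ", x$id, ": ", nchar(x$seq), " bp, ",
      if (x$circular) "circular" else "linear", ", ",
      nrow(x$features), " feature(s)\n", sep = "")
  invisible(x)
}

genome_length <- function(genome) nchar(genome$seq)

#' Parse a GenBank flat file
#'
#' Reads LOCUS (length, topology), ACCESSION/DEFINITION, the FEATURES
#' table (gene, CDS, tRNA, rRNA records; `complement()` and `join()`
#' locations) and the ORIGIN sequence. A `join()` location yields one
#' feature per exon plus a derived `intron` feature between consecutive
#' exons. Feature names are taken from the `/gene=` qualifier.
#'
#' @param path path to a GenBank flat file.
#' @return An [annotated_genome].
#' @export
parse_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("empty GenBank file: ", path)
  locus <- grep("^LOCUS", lines, value = TRUE)
  if (!length(locus)) stop("malformed GenBank record: no LOCUS line")
  circular <- grepl("circular", locus[1], ignore.case = TRUE)
  acc_line <- grep("^(ACCESSION|LOCUS)", lines, value = TRUE)
  id <- strsplit(trimws(sub("^(ACCESSION|LOCUS)", "", acc_line[length(acc_line)])),
                 "[[:space:]]+")[[1]][1]
  def_line <- grep("^DEFINITION", lines, value = TRUE)
  definition <- if (length(def_line))
    trimws(sub("^DEFINITION", "", def_line[1])) else ""

  fstart <- grep("^FEATURES", lines)
  ostart <- grep("^ORIGIN", lines)
  if (!length(ostart)) stop("malformed GenBank record: no ORIGIN section")
  oend <- grep("^//", lines)
  oend <- if (length(oend)) oend[1] else length(lines) + 1L

  seq_lines <- lines[(ostart[1] + 1L):(oend - 1L)]
  seq <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))

  features <- data.frame(name = character(), kind = character(),
                         start = integer(), end = integer(),
                         strand = character(), stringsAsFactors = FALSE)
  if (length(fstart)) {
    fl <- lines[(fstart[1] + 1L):(ostart[1] - 1L)]
    # group into feature records: a new record starts at indent 5 with a key
    rec_start <- grep("^ {5}\\S", fl)
    for (ri in seq_along(rec_start)) {
      a <- rec_start[ri]
      b <- if (ri < length(rec_start)) rec_start[ri + 1L] - 1L else length(fl)
      block <- fl[a:b]
      key <- sub("^ {5}(\\S+).*", "\\1", block[1])
      if (!key %in% c("gene", "CDS", "tRNA", "rRNA")) next
      # location may continue over lines until the first qualifier
      qual_at <- grep("^ {21}/", block)
      loc_end <- if (length(qual_at)) qual_at[1] - 1L else length(block)
      loc <- paste(c(sub("^ {5}\\S+\\s*", "", block[1]),
                     trimws(block[seq_len(loc_end)[-1]])), collapse = "")
      loc <- gsub("[[:space:]]", "", loc)
      gene_q <- grep('^ {21}/gene="', block, value = TRUE)
      name <- if (length(gene_q))
        sub('^ {21}/gene="([^"]*)".*', "\\1", gene_q[1]) else key
      pl <- parse_location(loc, line = block[1])
      for (k in seq_len(nrow(pl$exons))) {
        features[nrow(features) + 1L, ] <-
          list(name = name, kind = key,
               start = pl$exons$start[k], end = pl$exons$end[k],
               strand = pl$strand)
      }
      if (nrow(pl$exons) > 1L) {
        ex <- pl$exons[order(pl$exons$start), ]
        for (k in seq_len(nrow(ex) - 1L)) {
          features[nrow(features) + 1L, ] <-
            list(name = paste0(name, "-intron", k), kind = "intron",
                 start = ex$end[k] + 1L, end = ex$start[k + 1L] - 1L,
                 strand = pl$strand)
        }
      }
    }
  }
  g <- annotated_genome(id = id, seq = seq, circular = circular,
                        features = features)
  attr(g, "definition") <- definition
  g
}

parse_location <- function(loc, line = loc) {
  strand <- "+"
  x <- loc
  if (grepl("^complement\\(", x)) {
    strand <- "-"
    x <- sub("^complement\\((.*)\\)$", "\\1", x)
  }
  if (grepl("^join\\(", x)) {
    x <- sub("^join\\((.*)\\)$", "\\1", x)
  }
  parts <- strsplit(x, ",")[[1]]
  m <- regmatches(parts, regexec("^<?(\\d+)\\.\\.>?(\\d+)$|^(\\d+)$", parts))
  starts <- integer(0); ends <- integer(0)
  for (mm in m) {
    if (!length(mm))
      stop("cannot parse feature location in line: ", line)
    if (nzchar(mm[2])) {
      starts <- c(starts, as.integer(mm[2])); ends <- c(ends, as.integer(mm[3]))
    } else if (nzchar(mm[4])) {
      starts <- c(starts, as.integer(mm[4])); ends <- c(ends, as.integer(mm[4]))
    } else stop("cannot parse feature location in line: ", line)
  }
  list(strand = strand,
       exons = data.frame(start = starts, end = ends))
}

#' Write an annotated genome as a GenBank flat file
#'
#' Emits a minimal but standard-conforming record (LOCUS, DEFINITION,
#' ACCESSION, FEATURES with `/gene=` qualifiers, ORIGIN). Derived intron
#' features are not written (they are re-derived from `join()` exons on
#' parsing); exon pairs of the same gene/kind are written as `join()`
#' locations.
#'
#' @param genome an [annotated_genome].
#' @param path output path.
#' @param definition optional DEFINITION text.
#' @export
write_genbank <- function(genome, path, definition = NULL) {
  if (is.null(definition))
    definition <- attr(genome, "definition")
  if (is.null(definition))
    definition <- paste(genome$id, "synthetic annotated genome")
  len <- genome_length(genome)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("LOCUS       %s %d bp    DNA     %s PLN %s",
                     genome$id, len,
                     if (genome$circular) "circular" else "linear",
                     format(Sys.Date(), "%d-%b-%Y")), con)
  writeLines(paste0("DEFINITION  ", definition), con)
  writeLines(paste0("ACCESSION   ", genome$id), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  fe <- genome$features
  fe <- fe[fe$kind != "intron", , drop = FALSE]
  if (nrow(fe)) {
    grp <- paste(fe$name, fe$kind, fe$strand, sep = "\r")
    for (g in unique(grp)) {
      rows <- fe[grp == g, , drop = FALSE]
      rows <- rows[order(rows$start), , drop = FALSE]
      locs <- sprintf("%d..%d", rows$start, rows$end)
      loc <- if (nrow(rows) > 1L)
        paste0("join(", paste(locs, collapse = ","), ")") else locs
      if (rows$strand[1] == "-") loc <- paste0("complement(", loc, ")")
      writeLines(sprintf("     %-16s%s", rows$kind[1], loc), con)
      writeLines(sprintf('                     /gene="%s"', rows$name[1]), con)
    }
  }
  writeLines("ORIGIN", con)
  s <- genome$seq
  i <- 1L
  while (i <= len) {
    chunk <- substring(s, i, min(i + 59L, len))
    tens <- substring(chunk, seq(1, nchar(chunk), 10),
                      pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    writeLines(sprintf("%9d %s", i, paste(tolower(tens), collapse = " ")), con)
    i <- i + 60L
  }
  writeLines("//", con)
  invisible(path)
}

#' FASTA and feature-table I/O
#'
#' `write_genome_fasta`/`read_genome_fasta` handle the sequence;
#' `write_feature_table`/`read_feature_table` handle a TSV with columns
#' name, kind, start, end, strand. Together they round-trip an
#' [annotated_genome] exactly.
#'
#' @param genome an [annotated_genome].
#' @param path file path.
#' @export
write_genome_fasta <- function(genome, path) {
  x <- Biostrings::DNAStringSet(genome$seq)
  names(x) <- genome$id
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @param circular topology flag to attach on reading.
#' @rdname write_genome_fasta
#' @export
read_genome_fasta <- function(path, circular = TRUE) {
  x <- Biostrings::readDNAStringSet(path)
  annotated_genome(id = names(x)[1], seq = as.character(x[[1]]),
                   circular = circular)
}

#' @rdname write_genome_fasta
#' @export
write_feature_table <- function(genome, path) {
  utils::write.table(genome$features, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_genome_fasta
#' @export
read_feature_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE,
                    colClasses = c("character", "character", "integer",
                                   "integer", "character"))
}

#' GC content of a genome or region
#'
#' `(G + C) / (A + C + G + T)`; `N` bases are excluded from the
#' denominator. Use [format_gc()] for the 2-decimal half-up percentage
#' used in published composition tables.
#'
#' @param genome an [annotated_genome] or a plain nucleotide string.
#' @param region optional `c(start, end)` 1-based inclusive interval
#'   (wrap-around allowed on circular genomes).
#' @return Fraction in `[0, 1]`.
#' @export
gc_content <- function(genome, region = NULL) {
  s <- if (inherits(genome, "annotated_genome")) genome$seq else toupper(genome)
  if (!is.null(region)) {
    circ <- !inherits(genome, "annotated_genome") || genome$circular
    s <- subseq_circular(s, region[1], region[2], circular = circ)
  }
  if (!nzchar(s)) stop("empty region")
  counts <- table(factor(strsplit(s, "")[[1]], levels = c("A", "C", "G", "T", "N")))
  denom <- sum(counts[c("A", "C", "G", "T")])
  if (denom == 0) stop("region contains no unambiguous bases")
  as.numeric((counts["G"] + counts["C"]) / denom)
}

#' @param frac a fraction from [gc_content()].
#' @rdname gc_content
#' @export
format_gc <- function(frac) {
  # round half-up at 2 decimals of the percentage
  sprintf("%.2f", floor(frac * 10000 + 0.5) / 100)
}

subseq_circular <- function(s, start, end, circular = TRUE) {
  len <- nchar(s)
  if (start < 1 || start > len || end < 1 || end > len)
    stop("region outside [1, ", len, "]")
  if (end >= start) return(substring(s, start, end))
  if (!circular) stop("end < start on a linear sequence")
  paste0(substring(s, start, len), substring(s, 1, end))
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Extract the sequence of a feature
#'
#' Minus-strand features are reverse-complemented; wrap-around features
#' (`end < start`) on circular genomes are concatenated across the
#' origin.
#'
#' @param genome an [annotated_genome].
#' @param feature a feature name (must match exactly one row of
#'   `genome$features`) or a one-row data.frame / list with `start`,
#'   `end`, `strand`.
#' @return Nucleotide string.
#' @export
extract_feature_seq <- function(genome, feature) {
  if (is.character(feature)) {
    hit <- which(genome$features$name == feature)
    if (!length(hit))
      stop("unknown feature '", feature, "'; available: ",
           paste(unique(genome$features$name), collapse = ", "))
    if (length(hit) > 1L)
      stop("feature name '", feature, "' is ambiguous (", length(hit),
           " matches); pass a row of genome$features instead")
    feature <- genome$features[hit, ]
  }
  s <- subseq_circular(genome$seq, feature$start, feature$end,
                       circular = genome$circular)
  if (feature$strand == "-") s <- revcomp(s)
  s
}

#' Hamming comparison of equal-length sequences
#'
#' @param seqA,seqB equal-length nucleotide (or any character) strings.
#' @return list with `count` and 1-based `positions` of mismatches.
#' @export
hamming_diff <- function(seqA, seqB) {
  if (nchar(seqA) != nchar(seqB))
    stop("sequences differ in length (", nchar(seqA), " vs ", nchar(seqB),
         "); align first")
  a <- strsplit(toupper(seqA), "")[[1]]
  b <- strsplit(toupper(seqB), "")[[1]]
  pos <- which(a != b)
  list(count = length(pos), positions = pos)
}

#' Signed gene order of an annotated genome
#'
#' Orders the listed genes by start coordinate and signs them by strand,
#' producing a signed circular permutation -- a shared-gene-order
#' fallback for locally collinear blocks when a whole-genome aligner is
#' not available. Gene ids are the positions in `gene_names` (1-based),
#' so several genomes ordered against the same list are directly
#' comparable.
#'
#' @param genome an [annotated_genome].
#' @param gene_names character vector; each must occur exactly once among
#'   the genome's `gene` features (disambiguate duplicated genes with
#'   copy suffixes first).
#' @return An [scperm].
#' @export
gene_order <- function(genome, gene_names) {
  fe <- genome$features[genome$features$kind == "gene", , drop = FALSE]
  idx <- lapply(gene_names, function(g) which(fe$name == g))
  n_hit <- lengths(idx)
  if (any(n_hit == 0L))
    stop("gene(s) not found: ", paste(gene_names[n_hit == 0L], collapse = ", "))
  if (any(n_hit > 1L))
    stop("gene(s) occur more than once (add copy suffixes): ",
         paste(gene_names[n_hit > 1L], collapse = ", "))
  rows <- fe[unlist(idx), , drop = FALSE]
  ord <- order(rows$start)
  ids <- seq_along(gene_names)[ord]
  signs <- ifelse(rows$strand[ord] == "+", 1L, -1L)
  scperm(ids * signs)
}
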