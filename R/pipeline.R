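# End-to-end orchestration: run the analysis stages described by a flat
# configuration document and write machine-readable reports.

PIPELINE_STAGES <- c("stats", "ssr", "tandem", "rearr", "trace", "accd")

PIPELINE_KEYS <- c("stages", "outdir", "seed", "genome", "genome_synth",
                   "permutations", "ssr_thresholds", "tandem_min_unit",
                   "tandem_min_identity", "trace_fixture", "accd_genomic",
                   "accd_transcript", "promoter_motif", "promoter_window",
                   "verbose")

#' Run the comparative plastome analysis pipeline
#'
#' Executes the requested stages in dependency order (genome statistics,
#' SSR screen, tandem-repeat screen, rearrangement distances/tree,
#' trnQ-repeat tracing, nuclear-gene analysis) and writes one TSV/JSON
#' artifact per stage plus a `report.json` echoing the configuration
#' (with its md5 hash and package version) for provenance. Reruns with
#' the same configuration and seed produce identical outputs.
#'
#' Configuration keys: `stages` (subset of stats, ssr, tandem, rearr,
#' trace, accd), `outdir`, `seed`, `genome` (GenBank path) or
#' `genome_synth` (arguments for [synth_genome()]), `permutations`
#' (GRIMM file path) for the rearr stage, `trace_fixture`
#' ("taxus"/"cunninghamia") for the trace stage, `accd_genomic` /
#' `accd_transcript` (FASTA paths) for the accd stage, plus optional
#' `ssr_thresholds`, `tandem_min_unit`, `tandem_min_identity`,
#' `promoter_motif`, `promoter_window`, `verbose`. Unknown keys are
#' rejected.
#'
#' @param config named list, or path to a JSON file holding one.
#' @return Invisibly, a list of per-stage results (also written to
#'   `outdir`).
#' @export
run_pipeline <- function(config) {
  cfg_path <- NULL
  if (is.character(config) && length(config) == 1L) {
    cfg_path <- config
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  unknown <- setdiff(names(config), PIPELINE_KEYS)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  stages <- config[["stages"]]
  if (is.null(stages)) stages <- c("stats", "ssr", "tandem")
  bad <- setdiff(stages, PIPELINE_STAGES)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  outdir <- if (is.null(config[["outdir"]])) "." else config[["outdir"]]
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- if (is.null(config[["seed"]])) 1L else as.integer(config[["seed"]])
  verbose <- isTRUE(config[["verbose"]])
  logmsg <- function(stage, ...) {
    if (verbose)
      message(format(Sys.time(), "%H:%M:%S"), " [", stage, "] ", ...)
  }

  results <- list()
  genome <- NULL
  need_genome <- any(c("stats", "ssr", "tandem") %in% stages)
  if (need_genome) {
    if (!is.null(config[["genome"]])) {
      genome <- parse_genbank(config[["genome"]])
    } else if (!is.null(config[["genome_synth"]])) {
      args <- as.list(config[["genome_synth"]])
      if (is.null(args$seed)) args$seed <- seed
      synth <- do.call(synth_genome, args)
      genome <- synth$genome
      results$genome_truth <- synth[c("ssr_truth", "tandem_truth")]
    } else {
      stop("stage(s) ", paste(intersect(stages, c("stats", "ssr", "tandem")),
                              collapse = "/"),
           " need a 'genome' or 'genome_synth' entry")
    }
  }

  run_stage <- function(stage, fun) {
    logmsg(stage, "start")
    tryCatch(fun(), error = function(e)
      stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  if ("stats" %in% stages) {
    results$stats <- run_stage("stats", function() {
      st <- genome_stats(genome)
      jsonlite::write_json(st, file.path(outdir, "stats.json"),
                           auto_unbox = TRUE, digits = NA)
      st
    })
  }
  if ("ssr" %in% stages) {
    results$ssr <- run_stage("ssr", function() {
      th <- if (!is.null(config[["ssr_thresholds"]]))
        stats::setNames(as.integer(config[["ssr_thresholds"]]),
                        names(config[["ssr_thresholds"]]))
      else ssr_default_thresholds()
      loci <- classify_ssr_regions(find_ssrs(genome, th), genome)
      utils::write.table(loci, file.path(outdir, "ssr.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      loci
    })
  }
  if ("tandem" %in% stages) {
    results$tandem <- run_stage("tandem", function() {
      mu <- if (is.null(config[["tandem_min_unit"]])) 30L else config[["tandem_min_unit"]]
      mi <- if (is.null(config[["tandem_min_identity"]])) 0.90
            else config[["tandem_min_identity"]]
      tr <- find_tandem_repeats(genome, min_unit = mu, min_identity = mi)
      utils::write.table(tr, file.path(outdir, "tandem.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      tr
    })
  }
  if ("rearr" %in% stages) {
    results$rearr <- run_stage("rearr", function() {
      if (is.null(config[["permutations"]]))
        stop("rearr stage needs a 'permutations' GRIMM file")
      perms <- read_grimm(config[["permutations"]])
      D <- distance_matrix(perms)
      utils::write.table(D, file.path(outdir, "distance_matrix.tsv"),
                         sep = "\t", quote = FALSE, col.names = NA)
      tree <- mgr_tree(perms)
      write_rearr_newick(tree, file.path(outdir, "tree.nwk"))
      list(distances = D, tree = tree)
    })
  }
  if ("trace" %in% stages) {
    results$trace <- run_stage("trace", function() {
      fx <- if (is.null(config[["trace_fixture"]])) "taxus" else config[["trace_fixture"]]
      tr <- switch(fx,
        taxus = trace_scenario(trnq_config_sciadopitys(),
                               trnq_scenario_to_taxus()),
        cunninghamia = trace_scenario(trnq_config_a25(),
                                      trnq_scenario_to_cunninghamia()),
        stop("unknown trace_fixture: ", fx))
      fin <- tr[[length(tr)]]
      out <- data.frame(
        step = seq_along(tr) - 1L,
        arrangement = vapply(tr, function(cf)
          paste(utils::capture.output(print(cf)), collapse = ""), character(1)),
        loci = vapply(tr, count_repeat_loci, integer(1),
                      label_prefix = "trnQ"),
        stringsAsFactors = FALSE)
      utils::write.table(out, file.path(outdir, "trace.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      list(steps = tr, classification = classify_arrangement(fin, "trnQ"),
           loci = count_repeat_loci(fin, "trnQ"))
    })
  }
  if ("accd" %in% stages) {
    results$accd <- run_stage("accd", function() {
      if (is.null(config[["accd_genomic"]]) || is.null(config[["accd_transcript"]]))
        stop("accd stage needs 'accd_genomic' and 'accd_transcript' FASTA paths")
      gseq <- as.character(Biostrings::readDNAStringSet(config[["accd_genomic"]])[[1]])
      tseq <- as.character(Biostrings::readDNAStringSet(config[["accd_transcript"]])[[1]])
      gs <- find_introns(gseq, tseq)
      motif <- if (is.null(config[["promoter_motif"]])) "TATA" else config[["promoter_motif"]]
      win <- if (is.null(config[["promoter_window"]])) 2000L else config[["promoter_window"]]
      hits <- scan_promoter(gseq, gs$orf_start, motif = motif, window = win)
      jsonlite::write_json(
        list(orf_protein_length = nchar(gs$orf_protein),
             introns = gs$introns, promoter_hits = hits),
        file.path(outdir, "accd.json"), auto_unbox = TRUE, digits = NA)
      list(structure = gs, promoter_hits = hits)
    })
  }

  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  tmp <- tempfile()
  writeLines(cfg_json, tmp)
  report <- list(
    package_version = as.character(utils::packageVersion("plastrearr")),
    config = config,
    config_md5 = unname(tools::md5sum(tmp)),
    seed = seed,
    stages_run = stages)
  unlink(tmp)
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(results)
}

#' Composition statistics of an annotated genome
#'
#' Genome length and GC content overall and per region class
#' (protein-coding, tRNA, rRNA, introns, intergenic spacers), the
#' layout of published plastome composition tables.
#'
#' @param genome an [annotated_genome].
#' @return Named list of statistics (`gc_*` entries are percentages
#'   formatted half-up to 2 decimals).
#' @export
genome_stats <- function(genome) {
  len <- genome_length(genome)
  fe <- genome$features
  class_gc <- function(kinds) {
    rows <- fe[fe$kind %in% kinds, , drop = FALSE]
    if (!nrow(rows)) return(NA_character_)
    s <- paste(vapply(seq_len(nrow(rows)), function(r)
      extract_feature_seq(genome, rows[r, ]), character(1)), collapse = "")
    format_gc(gc_content(s))
  }
  covered <- rep(FALSE, len)
  for (r in seq_len(nrow(fe))) {
    if (!fe$kind[r] %in% c("gene", "CDS", "tRNA", "rRNA", "intron")) next
    if (fe$end[r] >= fe$start[r]) covered[fe$start[r]:fe$end[r]] <- TRUE
    else covered[c(fe$start[r]:len, 1:fe$end[r])] <- TRUE
  }
  igs <- paste(strsplit(genome$seq, "")[[1]][!covered], collapse = "")
  list(id = genome$id,
       length_bp = len,
       n_features = nrow(fe),
       gc_genome = format_gc(gc_content(genome)),
       gc_cds = class_gc("CDS"),
       gc_trna = class_gc("tRNA"),
       gc_rrna = class_gc("rRNA"),
       gc_intron = class_gc("intron"),
       gc_igs = if (nzchar(igs)) format_gc(gc_content(igs)) else NA_character_)
}
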