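# Orchestration: discover -> annotate -> smallrna stages with a declarative
# config, per-stage logging, report files and a machine-readable run summary.

#' Run configuration
#'
#' @param genome Path to the genome FASTA (or an in-memory genome object).
#' @param trnascan Optional tRNAscan-SE tabular file of anchors.
#' @param reads Optional small-RNA FASTA/FASTQ.
#' @param genes Optional GFF3 of gene models.
#' @param clusters Optional BED of externally called piRNA clusters (skips
#'   the internal density caller).
#' @param consensus Optional consensus FASTA (skips discovery in
#'   [run_annotate()]).
#' @param out Output directory.
#' @param seed Integer seed (used by `simulate`, recorded in the summary).
#' @param discovery A [discovery_config()].
#' @param scoring A [scoring_scheme()].
#' @param read_length_bounds Length filter for small reads.
#' @param cluster_window,cluster_min_unique,cluster_min_density Parameters of
#'   the density-based cluster caller.
#' @return A list of class `run_config`.
#' @export
run_config <- function(genome = NULL, trnascan = NULL, reads = NULL,
                       genes = NULL, clusters = NULL, consensus = NULL,
                       out = "sinescout_out", seed = 1L,
                       discovery = discovery_config(),
                       scoring = scoring_scheme(),
                       read_length_bounds = c(26L, 31L),
                       cluster_window = 5000L, cluster_min_unique = 5L,
                       cluster_min_density = 0.002) {
  structure(as.list(environment()), class = "run_config")
}

.log_stage <- function(...) message("[sinescout] ", sprintf(...))

.load_genome_cfg <- function(config) {
  if (is.null(config$genome)) stop("run: no genome configured", call. = FALSE)
  if (is.character(config$genome) && !file.exists(config$genome)) {
    stop("run: genome FASTA not found: ", config$genome, call. = FALSE)
  }
  as_genome(config$genome)
}

#' Discovery stage
#'
#' Anchors -> windows -> clusters -> boundaries -> consensus models; writes
#' `consensus.fa`, `clusters.tsv` and `anchors.bed` under `config$out`.
#'
#' @param config A [run_config()].
#' @return Invisibly, the [discover_families()] result.
#' @export
run_discover <- function(config) {
  genome <- .load_genome_cfg(config)
  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
  anchors <- NULL
  if (!is.null(config$trnascan)) {
    anchors <- read_trnascan(config$trnascan)
    .log_stage("anchors: %d (tRNAscan)", nrow(anchors))
  }
  disc <- discover_families(genome, anchors, config$discovery, config$scoring)
  .log_stage("anchors: %d, windows: %d, clusters: %d, families: %d (%d rejected)",
             nrow(disc$anchors), nrow(disc$windows), length(disc$clusters),
             length(disc$models), nrow(disc$rejected))
  if (length(disc$models) > 0L) {
    write_consensus_fasta(disc$models, file.path(config$out, "consensus.fa"))
  } else {
    writeLines(character(0), file.path(config$out, "consensus.fa"))
  }
  ab <- disc$anchors
  ab$name <- ab$source
  write_bed(data.frame(contig = ab$contig, start = ab$anchor_pos,
                       end = ab$anchor_pos + 1L, name = ab$source,
                       strand = ab$strand),
            file.path(config$out, "anchors.bed"))
  rows <- lapply(disc$models, function(m) {
    data.frame(family = m$name, length = m$length, members = m$n_members,
               tss_offset = m$tss_offset, head_end = m$head_end,
               tail = m$tail$kind,
               flags = paste(m$flags, collapse = ";"))
  })
  tab <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(family = character(0), length = integer(0),
               members = integer(0), tss_offset = integer(0),
               head_end = integer(0), tail = character(0), flags = character(0))
  utils::write.table(tab, file.path(config$out, "clusters.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(disc)
}

.models_from_fasta <- function(path, config) {
  seqs <- read_fasta(path)
  models <- list()
  for (i in seq_along(seqs)) {
    nm <- strsplit(names(seqs)[i], "|", fixed = TRUE)[[1L]][1L]
    cons <- as.character(seqs[[i]])
    if (nchar(cons) < config$discovery$min_length) {
      warning("consensus ", nm, " shorter than ", config$discovery$min_length,
              " bp; family skipped")
      next
    }
    ph <- scan_promoters(stats::setNames(cons, "consensus"))
    ph <- ph[ph$strand == "+", , drop = FALSE]
    ph <- if (nrow(ph) > 0L) ph[order(ph$abox_start), ][1L, , drop = FALSE] else NULL
    models[[length(models) + 1L]] <- structure(list(
      name = nm, consensus = cons, length = nchar(cons), promoter = ph,
      tss_offset = if (!is.null(ph)) ph$abox_start[1L] else NA_integer_,
      head_end = if (!is.null(ph)) min(nchar(cons), ph$bbox_end[1L] + config$discovery$head_pad)
                 else 0L,
      tail = classify_tail(cons), n_members = NA_integer_,
      member_loci = NULL, flags = character(0)), class = "sine_model")
  }
  models
}

#' Annotation stage
#'
#' Copies at 80/90% identity, TSDs, tails, age profiles, dimers; writes
#' `copies.bed`, `copies.tsv`, `age_profile.tsv` and `dimers.tsv`.
#'
#' @param config A [run_config()]; consensus comes from `config$consensus`
#'   or a prior [run_discover()] result passed as `disc`.
#' @param disc Optional [discover_families()] result.
#' @return Invisibly, the [annotate_families()] result (plus `models`).
#' @export
run_annotate <- function(config, disc = NULL) {
  genome <- .load_genome_cfg(config)
  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
  models <- if (!is.null(disc)) disc$models
            else if (!is.null(config$consensus)) .models_from_fasta(config$consensus, config)
            else .models_from_fasta(file.path(config$out, "consensus.fa"), config)
  if (length(models) == 0L) {
    .log_stage("annotate: no families to annotate")
    return(invisible(list(models = models)))
  }
  ann <- annotate_families(genome, models, config$scoring)
  all80 <- do.call(rbind, c(ann$copies80, list(make.row.names = FALSE)))
  .log_stage("annotate: %d families, %d copies at 80%%, %d dimers",
             length(models), nrow(all80), nrow(ann$dimers))
  write_bed(all80, file.path(config$out, "copies.bed"))
  utils::write.table(all80, file.path(config$out, "copies.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(ann$age, file.path(config$out, "age_profile.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(ann$dimers, file.path(config$out, "dimers.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  ann$models <- models
  invisible(ann)
}

#' Small-RNA stage
#'
#' Length filter -> genome mapping -> cluster calling (or ingestion) ->
#' SINE-related pool -> per-gene counts and per-consensus coverage; writes
#' `gene_counts.tsv`, `pirna_clusters.bed`, `pool.fa` and
#' `consensus_coverage.bedgraph`.
#'
#' @param config A [run_config()] with `reads` set.
#' @param ann Optional [run_annotate()] result (models + copies).
#' @return Invisibly: list(reads, hits, clusters, pool, counts).
#' @export
run_smallrna <- function(config, ann = NULL) {
  genome <- .load_genome_cfg(config)
  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
  if (is.null(config$reads)) stop("run_smallrna: no reads configured", call. = FALSE)
  raw <- read_small_reads(config$reads)
  reads <- filter_lengths(raw, config$read_length_bounds[1],
                          config$read_length_bounds[2])
  .log_stage("reads: %d raw, %d unique in [%d,%d] nt",
             length(raw), nrow(reads), config$read_length_bounds[1],
             config$read_length_bounds[2])
  hits <- map_exact(reads, genome)
  clusters <- if (!is.null(config$clusters)) read_bed(config$clusters) else
    call_clusters(hits, stats::setNames(Biostrings::width(genome), names(genome)),
                  window = config$cluster_window,
                  min_unique = config$cluster_min_unique,
                  min_density = config$cluster_min_density)
  .log_stage("genome hits: %d, clusters: %d", nrow(hits), nrow(clusters))
  write_bed(clusters, file.path(config$out, "pirna_clusters.bed"))
  pool <- reads; counts <- NULL
  if (!is.null(ann) && length(ann$models) > 0L) {
    db <- build_copy_db(genome, ann$models, ann$copies80, config$scoring)
    pool <- select_sine_related(reads, hits, clusters, db)
    .log_stage("SINE-related pool: %d unique / %d total reads",
               attr(pool, "n_unique"), attr(pool, "n_total"))
    write_fasta(stats::setNames(pool$seq,
                                sprintf("pool%05d_x%d", seq_len(nrow(pool)),
                                        pool$multiplicity)),
                file.path(config$out, "pool.fa"))
    # per-consensus coverage track (pileup of pool hits on each consensus)
    cons <- stats::setNames(vapply(ann$models, `[[`, "", "consensus"),
                            vapply(ann$models, `[[`, "", "name"))
    chits <- map_exact(pool, cons)
    cov <- list()
    for (nm in names(cons)) {
      depth <- integer(nchar(cons[[nm]]))
      hh <- chits[chits$target == nm, , drop = FALSE]
      for (r in seq_len(nrow(hh))) {
        idx <- (hh$offset[r] + 1L):(hh$offset[r] + nchar(hh$seq[r]))
        depth[idx] <- depth[idx] + hh$multiplicity[r]
      }
      cov[[length(cov) + 1L]] <- data.frame(
        contig = nm, pos = seq_along(depth) - 1L, depth = depth)
    }
    write_bedgraph(do.call(rbind, cov),
                   file.path(config$out, "consensus_coverage.bedgraph"))
  }
  if (!is.null(config$genes)) {
    genes <- read_gff3_genes(config$genes)
    pool_hits <- if (!is.null(ann) && length(ann$models) > 0L) {
      hits[hits$seq %in% pool$seq, , drop = FALSE]
    } else hits
    counts <- count_by_gene(pool_hits, genes)
    validate_count_records(counts)
    .log_stage("gene counts: %d genes, %d exon-overlap violations",
               nrow(counts), attr(counts, "exon_violations"))
    write_count_report(counts, file.path(config$out, "gene_counts.tsv"))
  } else {
    .log_stage("no gene models provided; counts stage skipped")
  }
  invisible(list(reads = reads, hits = hits, clusters = clusters,
                 pool = pool, counts = counts))
}

#' Simulation stage
#' @param config A [run_config()]; `seed` drives the simulator.
#' @param sim_cfg Optional [sim_config()] override.
#' @return Invisibly, the written `sine_sim`.
#' @export
run_simulate <- function(config, sim_cfg = NULL) {
  if (is.null(sim_cfg)) {
    extra <- if (!is.null(config$sim)) config$sim else list()
    sim_cfg <- do.call(sim_config, c(list(seed = config$seed), extra))
  }
  sim <- simulate_genome(sim_cfg)
  sim <- simulate_reads(sim, sim_cfg)
  write_sim(sim, config$out)
  .log_stage("simulated %d bp genome, %d copies, %d reads -> %s",
             sum(Biostrings::width(sim$genome)), nrow(sim$manifest$copies),
             length(sim$reads_expanded), config$out)
  invisible(sim)
}

#' Full pipeline
#'
#' discover -> annotate -> smallrna, with a JSON run summary.
#' @param config A [run_config()].
#' @return Invisibly: list(discover, annotate, smallrna).
#' @export
run_all <- function(config) {
  disc <- run_discover(config)
  ann <- run_annotate(config, disc)
  sm <- if (!is.null(config$reads)) run_smallrna(config, ann) else NULL
  summary <- list(
    seed = config$seed,
    n_anchors = nrow(disc$anchors), n_windows = nrow(disc$windows),
    n_clusters = length(disc$clusters), n_families = length(disc$models),
    families = lapply(disc$models, function(m) {
      list(name = m$name, length = m$length, tss_offset = m$tss_offset,
           tail = m$tail$kind)
    }),
    n_copies80 = if (!is.null(ann$copies80)) sum(vapply(ann$copies80, nrow, 1L)) else 0L,
    n_clusters_pirna = if (!is.null(sm)) nrow(sm$clusters) else NA,
    n_genes_counted = if (!is.null(sm) && !is.null(sm$counts)) nrow(sm$counts) else NA
  )
  jsonlite::write_json(summary, file.path(config$out, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(list(discover = disc, annotate = ann, smallrna = sm))
}

#' Command-line entry point
#'
#' `sinescout simulate|discover|annotate|smallrna|all [options]` -- see
#' `exec/sinescout`.  Options mirror [run_config()]; a JSON config file may
#' supply any of them, with command-line flags taking precedence.
#'
#' @param args Character vector of command-line arguments.
#' @return Integer exit status (0 success, 2 usage/input error).
#' @export
sinescout_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: sinescout simulate|discover|annotate|smallrna|all [--config FILE] [--genome FA] [--reads FA] [--genes GFF3] [--trnascan TSV] [--seed N] [--out DIR]"
  if (length(args) < 1L || args[1L] %in% c("-h", "--help")) {
    message(usage); return(if (length(args) < 1L) 2L else 0L)
  }
  cmd <- args[1L]
  if (!cmd %in% c("simulate", "discover", "annotate", "smallrna", "all")) {
    message("unknown command: ", cmd, "\n", usage); return(2L)
  }
  spec <- list(
    optparse::make_option("--config", type = "character", default = NULL),
    optparse::make_option("--genome", type = "character", default = NULL),
    optparse::make_option("--reads", type = "character", default = NULL),
    optparse::make_option("--genes", type = "character", default = NULL),
    optparse::make_option("--trnascan", type = "character", default = NULL),
    optparse::make_option("--clusters", type = "character", default = NULL),
    optparse::make_option("--consensus", type = "character", default = NULL),
    optparse::make_option("--seed", type = "integer", default = NULL),
    optparse::make_option("--out", type = "character", default = NULL))
  opt <- tryCatch(
    optparse::parse_args(optparse::OptionParser(option_list = spec),
                         args = args[-1L]),
    error = function(e) { message(conditionMessage(e)); NULL })
  if (is.null(opt)) return(2L)
  cfg <- run_config()
  if (!is.null(opt$config)) {
    file_cfg <- jsonlite::read_json(opt$config, simplifyVector = TRUE)
    for (k in names(file_cfg)) cfg[[k]] <- file_cfg[[k]]
  }
  for (k in c("genome", "reads", "genes", "trnascan", "clusters", "consensus",
              "seed", "out")) {
    if (!is.null(opt[[k]])) cfg[[k]] <- opt[[k]]
  }
  status <- tryCatch({
    switch(cmd,
           simulate = run_simulate(cfg),
           discover = run_discover(cfg),
           annotate = run_annotate(cfg, disc = NULL),
           smallrna = {
             ann <- tryCatch(run_annotate(cfg, disc = NULL), error = function(e) NULL)
             run_smallrna(cfg, ann)
           },
           all = run_all(cfg))
    0L
  }, error = function(e) {
    message("sinescout ", cmd, ": ", conditionMessage(e))
    2L
  })
  status
}
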