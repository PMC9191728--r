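# The piRNA arm: 26-31-nt length filtering, tRNA-head masking, zero-mismatch
# strand-aware mapping, per-gene intron counting, and a simplified
# density-based piRNA-cluster caller.

#' Read small-RNA reads from FASTA or FASTQ
#'
#' Format is detected from the first non-empty character (`>` FASTA, `@`
#' FASTQ).  Quality strings are ignored; reads are returned as plain
#' uppercase character strings.  Adapter trimming and pair merging are
#' assumed to have happened upstream.
#'
#' @param path Path to a FASTA or FASTQ file.
#' @return Character vector of read sequences.
#' @export
read_small_reads <- function(path) {
  if (!file.exists(path)) stop("reads file not found: ", path)
  con <- file(path, "r"); on.exit(close(con))
  first <- ""
  while (first == "") first <- trimws(readLines(con, n = 1L))
  close(con); on.exit()
  fmt <- if (startsWith(first, "@")) "fastq" else "fasta"
  x <- Biostrings::readBStringSet(path, format = fmt)
  toupper(as.character(x))
}

#' Length-filter and collapse small reads
#'
#' Keeps reads of length `lo`..`hi`, drops reads with characters outside
#' `ACGTN` (counted in the `dropped_invalid` attribute), and collapses
#' identical sequences into one record with a multiplicity equal to the
#' occurrence count.
#'
#' @param reads Character vector of read sequences (or a `small_reads`
#'   data.frame, returned unchanged after re-filtering).
#' @param lo,hi Inclusive length bounds (canonical piRNA range 26-31 nt).
#' @return Data.frame of class `small_reads` (`seq`, `multiplicity`), sorted
#'   by multiplicity (desc) then sequence; attributes `dropped_length` and
#'   `dropped_invalid` count discards.
#' @export
filter_lengths <- function(reads, lo = 26L, hi = 31L) {
  if (is.data.frame(reads)) {
    mult <- reads$multiplicity
    reads <- rep(reads$seq, mult)
  }
  reads <- toupper(reads)
  valid <- grepl("^[ACGTN]*$", reads)
  n_invalid <- sum(!valid)
  reads <- reads[valid]
  len_ok <- nchar(reads) >= lo & nchar(reads) <= hi
  n_len <- sum(!len_ok)
  reads <- reads[len_ok]
  if (length(reads) == 0L) {
    out <- data.frame(seq = character(0), multiplicity = integer(0))
  } else {
    tb <- table(reads)
    out <- data.frame(seq = names(tb), multiplicity = as.integer(tb),
                      stringsAsFactors = FALSE)
    out <- out[order(-out$multiplicity, out$seq), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "dropped_length") <- n_len
  attr(out, "dropped_invalid") <- n_invalid
  class(out) <- c("small_reads", "data.frame")
  out
}

#' Remove the tRNA-derived head from a model or copy sequence
#'
#' tRNA-derived 5' heads also occur in TE-independent tRNA genes, whose
#' abundant PIWI-independent fragments would contaminate SINE piRNA counts;
#' the copy database therefore excludes everything 5' of `head_end`.
#'
#' @param model A `sine_model`, or a character sequence together with
#'   `head_end`.
#' @param head_end Optional override of the model's head end (0-based).
#' @return The body+tail sequence (positions `head_end`.. of the input).
#' @export
mask_trna <- function(model, head_end = NULL) {
  if (is.character(model)) {
    seq <- model
    if (is.null(head_end)) stop("mask_trna: head_end required for a bare sequence")
  } else {
    seq <- model$consensus
    if (is.null(head_end)) head_end <- model$head_end
  }
  if (head_end >= nchar(seq)) {
    stop("mask_trna: head_end (", head_end, ") >= sequence length (", nchar(seq), ")")
  }
  substr(seq, head_end + 1L, nchar(seq))
}

#' Build the masked genomic copy database
#'
#' One entry per genomic copy (>= 80% identity), extracted element-sense,
#' with the tRNA-head region removed.  The head boundary on each copy is
#' located by projecting the consensus `head_end` through the
#' consensus-to-copy alignment rather than by fixed offset, so diverged
#' copies are masked correctly.  Copies entirely inside the head region are
#' excluded (recorded in the `excluded` attribute).
#'
#' @param genome Genome object.
#' @param models Named list of `sine_model`s (or list; names from `$name`).
#' @param copies80 Named list (by family) of `genomic_copies` at the 0.80
#'   threshold, e.g. `annotate_families()$copies80`.
#' @param scoring A [scoring_scheme()].
#' @return Named character vector of masked sequences; names are
#'   `family:contig:start-end` (0-based half-open).
#' @export
build_copy_db <- function(genome, models, copies80,
                          scoring = scoring_scheme()) {
  genome <- as_genome(genome)
  nm <- vapply(models, function(m) m$name, "")
  names(models) <- nm
  db <- character(0)
  excluded <- character(0)
  for (fam in names(copies80)) {
    model <- models[[fam]]
    if (is.null(model)) next
    cp <- copies80[[fam]]
    for (r in seq_len(nrow(cp))) {
      cseq <- genome_slice(genome, cp$contig[r], cp$start[r], cp$end[r], cp$strand[r])
      if (nchar(cseq) == 0L) next
      aln <- align_glocal(model$consensus, cseq, scoring)
      cut <- project_position(aln, model$head_end)
      id <- sprintf("%s:%s:%d-%d", fam, cp$contig[r], cp$start[r], cp$end[r])
      if (cut >= nchar(cseq)) {
        excluded <- c(excluded, id)
        next
      }
      db[[id]] <- substr(cseq, cut + 1L, nchar(cseq))
    }
  }
  db <- db[!duplicated(names(db))]
  attr(db, "excluded") <- excluded
  db
}

#' Map reads to targets with zero mismatches
#'
#' Reports every occurrence of each read, or of its reverse complement, as an
#' exact substring of any target (orientation `F` for sense, `R` for reverse
#' complement).  Multi-target and multi-offset hits are all reported; reads
#' containing `N` cannot match (N never matches) and are skipped.
#'
#' @param reads A `small_reads` data.frame (or character vector, collapsed
#'   first).
#' @param targets Named character vector or `DNAStringSet` of target
#'   sequences.
#' @return Data.frame of class `exact_hits`: `seq`, `multiplicity`,
#'   `target`, `offset` (0-based start in the target), `orientation`.
#' @export
map_exact <- function(reads, targets) {
  if (!is.data.frame(reads)) reads <- filter_lengths(reads, lo = 1L, hi = .Machine$integer.max)
  if (methods::is(targets, "DNAStringSet")) {
    tg <- targets
  } else {
    tg <- Biostrings::DNAStringSet(toupper(targets))
  }
  if (is.null(names(tg))) names(tg) <- paste0("t", seq_along(tg))
  empty <- data.frame(seq = character(0), multiplicity = integer(0),
                      target = character(0), offset = integer(0),
                      orientation = character(0))
  class(empty) <- c("exact_hits", "data.frame")
  ok <- !grepl("N", reads$seq, fixed = TRUE) & nchar(reads$seq) > 0L
  reads <- reads[ok, , drop = FALSE]
  if (nrow(reads) == 0L || length(tg) == 0L) return(empty)
  out <- list()
  for (ori in c("F", "R")) {
    seqs <- if (ori == "F") reads$seq else revcomp(reads$seq)
    byw <- split(seq_len(nrow(reads)), nchar(seqs))
    for (grp in byw) {
      pd <- Biostrings::PDict(Biostrings::DNAStringSet(seqs[grp]))
      for (ti in seq_along(tg)) {
        if (length(tg[[ti]]) < nchar(seqs[grp[1L]])) next
        mh <- Biostrings::matchPDict(pd, tg[[ti]])
        nh <- S4Vectors::elementNROWS(mh)
        if (sum(nh) == 0L) next
        pos <- unlist(IRanges::start(mh), use.names = FALSE) - 1L
        ridx <- rep(grp, nh)
        out[[length(out) + 1L]] <- data.frame(
          seq = reads$seq[ridx], multiplicity = reads$multiplicity[ridx],
          target = names(tg)[ti], offset = pos, orientation = ori,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$target, res$offset, res$orientation, res$seq), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("exact_hits", "data.frame")
  res
}

#' Per-gene strand-split intron counts
#'
#' Takes genome-coordinate exact hits (targets were contigs) and gene models,
#' and counts, for each gene, the reads whose hits fall entirely inside an
#' intron -- split by orientation and weighted by read multiplicity.  A read
#' is counted once per gene and orientation regardless of how many intron
#' offsets it matches.  Hits overlapping an exon are excluded from the counts
#' and reported in the `exon_violations` attribute (expected to be empty for
#' piRNA pools derived from intronic SINE copies).
#'
#' @param hits An `exact_hits` data.frame whose `target` column holds contig
#'   names and `offset` genomic positions.
#' @param genes A `gene_models` object from [read_gff3_genes()] or
#'   [simulate_genome()].
#' @return Data.frame of class `count_records`: gene metadata plus `forward`,
#'   `reverse`, `total`, sorted by total (desc).  Genes with no hits are
#'   omitted.
#' @export
count_by_gene <- function(hits, genes) {
  g <- genes$genes
  ex <- genes$exons
  recs <- list()
  viol <- 0L
  for (r in seq_len(nrow(g))) {
    sel <- hits$target == g$contig[r] &
      hits$offset >= g$start[r] &
      (hits$offset + nchar(hits$seq)) <= g$end[r]
    if (!any(sel)) next
    h <- hits[sel, , drop = FALSE]
    gex <- ex[ex$gene_id == g$gene_id[r], , drop = FALSE]
    hs <- h$offset; he <- h$offset + nchar(h$seq)
    in_exon <- rep(FALSE, nrow(h))
    for (q in seq_len(nrow(gex))) {
      in_exon <- in_exon | (pmin(he, gex$end[q]) - pmax(hs, gex$start[q]) > 0L)
    }
    viol <- viol + sum(h$multiplicity[in_exon] *
                         !duplicated(paste(h$seq, h$orientation)[in_exon]))
    h <- h[!in_exon, , drop = FALSE]
    if (nrow(h) == 0L) next
    h <- h[!duplicated(paste(h$seq, h$orientation)), , drop = FALSE]
    fwd <- sum(h$multiplicity[h$orientation == "F"])
    rev <- sum(h$multiplicity[h$orientation == "R"])
    recs[[length(recs) + 1L]] <- data.frame(
      contig = g$contig[r], strand = g$strand[r], start = g$start[r],
      end = g$end[r], gene_id = g$gene_id[r], gene_name = g$gene_name[r],
      forward = fwd, reverse = rev, total = fwd + rev,
      stringsAsFactors = FALSE)
  }
  out <- if (length(recs) > 0L) do.call(rbind, recs) else
    data.frame(contig = character(0), strand = character(0),
               start = integer(0), end = integer(0), gene_id = character(0),
               gene_name = character(0), forward = integer(0),
               reverse = integer(0), total = integer(0))
  out <- out[order(-out$total, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "exon_violations") <- viol
  class(out) <- c("count_records", "data.frame")
  out
}

#' Call read-dense clusters on the genome (proTRAC-style proxy)
#'
#' A deliberately simple density caller standing in for a dedicated
#' piRNA-cluster tool: sliding windows with at least `min_unique` distinct
#' mapped sequences and a read density of at least `min_density` reads/bp are
#' merged (gap < `window`) into cluster intervals.  Externally called cluster
#' BED files can be ingested instead via [read_bed()].
#'
#' @param hits Genome-coordinate `exact_hits`.
#' @param contig_lengths Named integer vector of contig lengths.
#' @param window Window and merge-gap size (bp).
#' @param step Window step (bp).
#' @param min_unique Minimum distinct read sequences per window.
#' @param min_density Minimum summed multiplicity per bp.
#' @return Data.frame: contig, start, end (0-based half-open).
#' @export
call_clusters <- function(hits, contig_lengths, window = 5000L, step = 1000L,
                          min_unique = 5L, min_density = 0.002) {
  out <- list()
  for (contig in names(contig_lengths)) {
    h <- hits[hits$target == contig, , drop = FALSE]
    if (nrow(h) == 0L) next
    h <- h[!duplicated(paste(h$seq, h$offset, h$orientation)), , drop = FALSE]
    L <- contig_lengths[[contig]]
    starts <- seq.int(0L, max(0L, L - 1L), by = step)
    ord <- order(h$offset)
    pos <- h$offset[ord]; seqs <- h$seq[ord]; mult <- h$multiplicity[ord]
    lo <- findInterval(starts - 1L, pos) + 1L
    hi <- findInterval(starts + window - 1L, pos)
    pass <- logical(length(starts))
    for (i in seq_along(starts)) {
      if (hi[i] < lo[i]) next
      idx <- lo[i]:hi[i]
      if (length(unique(seqs[idx])) < min_unique) next
      if (sum(mult[idx]) / window < min_density) next
      pass[i] <- TRUE
    }
    if (!any(pass)) next
    ws <- starts[pass]; we <- pmin(L, ws + window)
    merged <- list(c(ws[1L], we[1L]))
    for (i in seq_along(ws)[-1L]) {
      last <- merged[[length(merged)]]
      if (ws[i] - last[2L] < window) {
        merged[[length(merged)]] <- c(last[1L], max(last[2L], we[i]))
      } else {
        merged[[length(merged) + 1L]] <- c(ws[i], we[i])
      }
    }
    out[[length(out) + 1L]] <- data.frame(
      contig = contig,
      start = vapply(merged, `[`, 1, 1L), end = vapply(merged, `[`, 1, 2L),
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) {
    return(data.frame(contig = character(0), start = integer(0), end = integer(0)))
  }
  do.call(rbind, out)
}

#' Select the SINE-related read pool
#'
#' Restricts reads to those with at least one genomic hit inside a called
#' (or ingested) cluster interval, then keeps the sub-pool with at least one
#' zero-mismatch hit in the masked copy database, expanded back to full
#' multiplicity.  The operation is idempotent.
#'
#' @param reads A `small_reads` data.frame.
#' @param genome_hits Genome-coordinate `exact_hits` for the same reads.
#' @param clusters Cluster intervals (contig, start, end).
#' @param copy_db Masked copy database from [build_copy_db()].
#' @return A `small_reads` subset; attributes `n_unique` and `n_total` give
#'   the pool size in unique sequences and in summed multiplicity.
#' @export
select_sine_related <- function(reads, genome_hits, clusters, copy_db) {
  in_cluster <- rep(FALSE, nrow(genome_hits))
  for (r in seq_len(nrow(clusters))) {
    in_cluster <- in_cluster | (
      genome_hits$target == clusters$contig[r] &
        genome_hits$offset >= clusters$start[r] &
        (genome_hits$offset + nchar(genome_hits$seq)) <= clusters$end[r])
  }
  cluster_seqs <- unique(genome_hits$seq[in_cluster])
  sub <- reads[reads$seq %in% cluster_seqs, , drop = FALSE]
  if (nrow(sub) > 0L && length(copy_db) > 0L) {
    db_hits <- map_exact(sub, copy_db)
    sub <- sub[sub$seq %in% unique(db_hits$seq), , drop = FALSE]
  } else {
    sub <- sub[0L, , drop = FALSE]
  }
  rownames(sub) <- NULL
  attr(sub, "n_unique") <- nrow(sub)
  attr(sub, "n_total") <- sum(sub$multiplicity)
  class(sub) <- c("small_reads", "data.frame")
  sub
}

#' Validate per-gene count records
#'
#' Checks the structural invariants of a count table: `total == forward +
#' reverse` on every row, non-negative counts, 1-based inclusive coordinate
#' sanity (`start <= end`).
#'
#' @param records A `count_records` data.frame (internal, 0-based) or a
#'   table read back by [read_count_report()] (1-based).
#' @return `TRUE` invisibly; stops with a description of the first violated
#'   invariant otherwise.
#' @export
validate_count_records <- function(records) {
  if (nrow(records) == 0L) return(invisible(TRUE))
  if (any(records$forward < 0L | records$reverse < 0L)) {
    stop("negative strand count")
  }
  bad <- which(records$total != records$forward + records$reverse)
  if (length(bad) > 0L) {
    stop("total != forward + reverse for ", records$gene_id[bad[1L]])
  }
  if (any(records$start > records$end)) stop("start > end in count records")
  invisible(TRUE)
}
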