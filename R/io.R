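# Annotation I/O: GFF3 gene models (genes with exon children; introns
# derived), BED intervals, Table-style count reports and bedGraph tracks.
# Internal coordinates are 0-based half-open; GFF3 and count reports are
# 1-based inclusive on disk, BED and bedGraph 0-based half-open.

.gene_models <- function(genes, exons) {
  genes <- genes[order(genes$contig, genes$start), , drop = FALSE]
  rownames(genes) <- NULL
  rownames(exons) <- NULL
  structure(list(genes = genes, exons = exons), class = "gene_models")
}

#' Derive the introns of a gene model set
#' @param genes A `gene_models` object.
#' @return Data.frame: gene_id, contig, start, end (0-based half-open).
#' @export
gene_introns <- function(genes) {
  out <- list()
  for (r in seq_len(nrow(genes$genes))) {
    gid <- genes$genes$gene_id[r]
    ex <- genes$exons[genes$exons$gene_id == gid, , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    if (nrow(ex) < 2L) next
    out[[length(out) + 1L]] <- data.frame(
      gene_id = gid, contig = genes$genes$contig[r],
      start = ex$end[-nrow(ex)], end = ex$start[-1L],
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) {
    return(data.frame(gene_id = character(0), contig = character(0),
                      start = integer(0), end = integer(0)))
  }
  do.call(rbind, out)
}

#' Read gene models from GFF3
#'
#' Expects `gene` features with `exon` children (`Parent` or `gene_id`
#' attributes); introns are derived as the span minus the exons.
#'
#' @param path GFF3 file path.
#' @return A `gene_models` object: `$genes` (gene_id, gene_name, contig,
#'   start, end, strand; 0-based half-open) and `$exons`.
#' @export
read_gff3_genes <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)
  ids <- if (!is.null(md$ID)) as.character(md$ID) else NA_character_
  parents <- if (!is.null(md$Parent)) {
    vapply(md$Parent, function(p) if (length(p) > 0L) as.character(p[1L]) else NA_character_, "")
  } else rep(NA_character_, length(gr))
  gsel <- type == "gene"
  genes <- data.frame(
    gene_id = ids[gsel],
    gene_name = if (!is.null(md$Name)) as.character(md$Name)[gsel] else ids[gsel],
    contig = as.character(GenomicRanges::seqnames(gr))[gsel],
    start = GenomicRanges::start(gr)[gsel] - 1L,
    end = GenomicRanges::end(gr)[gsel],
    strand = as.character(GenomicRanges::strand(gr))[gsel],
    stringsAsFactors = FALSE)
  genes$strand[!genes$strand %in% c("+", "-")] <- "+"
  esel <- type == "exon"
  exons <- data.frame(
    gene_id = parents[esel],
    contig = as.character(GenomicRanges::seqnames(gr))[esel],
    start = GenomicRanges::start(gr)[esel] - 1L,
    end = GenomicRanges::end(gr)[esel],
    stringsAsFactors = FALSE)
  .gene_models(genes, exons)
}

#' Write gene models to GFF3
#' @param genes A `gene_models` object (0-based internal coordinates).
#' @param path Output path.
#' @export
write_gff3_genes <- function(genes, path) {
  lines <- c("##gff-version 3",
             "# coordinates: 1-based inclusive (GFF3 convention)")
  g <- genes$genes
  for (r in seq_len(nrow(g))) {
    lines <- c(lines, paste(
      g$contig[r], "sinescout", "gene", g$start[r] + 1L, g$end[r], ".",
      g$strand[r], ".", sprintf("ID=%s;Name=%s", g$gene_id[r], g$gene_name[r]),
      sep = "\t"))
    ex <- genes$exons[genes$exons$gene_id == g$gene_id[r], , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    for (q in seq_len(nrow(ex))) {
      lines <- c(lines, paste(
        g$contig[r], "sinescout", "exon", ex$start[q] + 1L, ex$end[q], ".",
        g$strand[r], ".",
        sprintf("ID=%s.e%d;Parent=%s", g$gene_id[r], q, g$gene_id[r]),
        sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write intervals as BED6
#' @param df Data.frame with contig, start, end (0-based half-open) and
#'   optionally name, score, strand columns.
#' @param path Output path.
#' @export
write_bed <- function(df, path) {
  name <- if (!is.null(df$name)) df$name else
    if (!is.null(df$family)) df$family else "."
  score <- if (!is.null(df$score)) df$score else
    if (!is.null(df$identity)) round(1000 * df$identity) else 0L
  strand <- if (!is.null(df$strand)) df$strand else "."
  lines <- c("# BED6; coordinates 0-based half-open",
             paste(df$contig, df$start, df$end, name, score, strand, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED file of intervals
#' @param path BED path (first three columns used).
#' @return Data.frame: contig, start, end (0-based half-open).
#' @export
read_bed <- function(path) {
  x <- utils::read.table(path, sep = "\t", comment.char = "#",
                         stringsAsFactors = FALSE)
  data.frame(contig = as.character(x[[1L]]), start = as.integer(x[[2L]]),
             end = as.integer(x[[3L]]), stringsAsFactors = FALSE)
}

#' Write a per-gene count report (Table-style layout)
#'
#' Columns: Contig ID, Strand, Start, End, Gene ID, Gene full name,
#' Reads count, F, R -- coordinates 1-based inclusive, rows sorted by total
#' count descending.
#'
#' @param records A `count_records` data.frame (0-based internal).
#' @param path Output path.
#' @export
write_count_report <- function(records, path) {
  hdr <- c("# per-gene SINE-related small-RNA counts",
           "# coordinates: 1-based inclusive; F/R = forward / reverse-complement hits",
           paste("Contig.ID", "Strand", "Start", "End", "Gene.ID",
                 "Gene.full.name", "Reads.count", "F", "R", sep = "\t"))
  body <- paste(records$contig, records$strand, records$start + 1L,
                records$end, records$gene_id, records$gene_name,
                records$total, records$forward, records$reverse, sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a per-gene count report
#'
#' Accepts the layout written by [write_count_report()] as well as the
#' combined `total (F - x; R - y)` single-column variant used in published
#' tables.
#'
#' @param path Report path.
#' @return A `count_records` data.frame (coordinates converted back to
#'   0-based half-open).
#' @export
read_count_report <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                         stringsAsFactors = FALSE, check.names = TRUE)
  if (!"F" %in% names(x) && ncol(x) >= 7L) {
    # combined "3557 (F-1798; R-1759)" style column
    comb <- as.character(x[[7L]])
    num <- function(p) as.integer(gsub("[^0-9]", "", regmatches(comb, regexpr(p, comb))))
    x$Reads.count <- as.integer(sub("^\\s*(\\d+).*$", "\\1", comb))
    x$F <- num("F[^0-9]*[0-9]+")
    x$R <- num("R[^0-9]*[0-9]+")
  }
  out <- data.frame(
    contig = as.character(x[[1L]]), strand = as.character(x[[2L]]),
    start = as.integer(x[[3L]]) - 1L, end = as.integer(x[[4L]]),
    gene_id = as.character(x[[5L]]), gene_name = as.character(x[[6L]]),
    forward = x$F, reverse = x$R, total = x$Reads.count,
    stringsAsFactors = FALSE)
  class(out) <- c("count_records", "data.frame")
  out
}

#' Write a per-base coverage track as bedGraph
#' @param cov Data.frame: contig, pos (0-based), depth.
#' @param path Output path.
#' @export
write_bedgraph <- function(cov, path) {
  lines <- "# bedGraph; coordinates 0-based half-open"
  for (contig in unique(cov$contig)) {
    cc <- cov[cov$contig == contig, , drop = FALSE]
    cc <- cc[order(cc$pos), , drop = FALSE]
    if (nrow(cc) == 0L) next
    brk <- c(TRUE, diff(cc$pos) != 1L | diff(cc$depth) != 0L)
    grp <- cumsum(brk)
    for (g in split(seq_len(nrow(cc)), grp)) {
      lines <- c(lines, paste(contig, cc$pos[g[1L]], cc$pos[g[length(g)]] + 1L,
                              cc$depth[g[1L]], sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write family consensus sequences with structured headers
#'
#' Header layout: `name|length|tss_offset|tail_kind`.
#'
#' @param models List of `sine_model`s.
#' @param path Output path.
#' @export
write_consensus_fasta <- function(models, path) {
  seqs <- vapply(models, function(m) m$consensus, "")
  names(seqs) <- vapply(models, function(m) {
    sprintf("%s|%d|%d|%s", m$name, m$length, m$tss_offset, m$tail$kind)
  }, "")
  write_fasta(seqs, path)
}
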