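# RNA polymerase III type-2 promoter scanning (A box + B box), ingestion of
# external tRNA predictions, and measurement of the TSS-to-A-box offset.

#' Canonical Pol III internal promoter boxes
#'
#' The 11-bp A-box and B-box consensus motifs of type-2 RNA polymerase III
#' promoters, in IUPAC code.
#' @export
ABOX_PATTERN <- "TRGYNNARNNG"

#' @rdname ABOX_PATTERN
#' @export
BBOX_PATTERN <- "RGTTCRANTCC"

BOX_LEN <- 11L

#' Scan a genome for Pol III type-2 promoter structures
#'
#' Finds every A-box/B-box pair, on both strands, where each 11-bp box matches
#' its canonical IUPAC motif with at most `max_mismatch_per_box` substitutions
#' and the spacing between the A-box end and the B-box start lies within
#' `spacing_bounds`.  The default of one tolerated substitution per box
#' reflects the observation that functional tRNA-head SINEs rarely carry more
#' than one substitution inside either box.
#'
#' @param genome Genome (`DNAStringSet`, named character vector or FASTA path).
#' @param max_mismatch_per_box Maximum substitutions tolerated per box.
#' @param spacing_bounds Length-2 integer vector: allowed bp between A-box end
#'   and B-box start (default `c(25, 70)`, slightly wider than the canonical
#'   ~30-60 bp to tolerate the approximation).
#' @param abox,bbox IUPAC motifs for the two boxes.
#' @return A data.frame of class `promoter_hits`, one row per A/B pair, with
#'   plus-strand 0-based half-open box intervals, the strand, the spacing and
#'   the per-box mismatch counts.  `anchor_pos` is the plus-strand coordinate
#'   of the strand-aware first base of the A box (the natural anchor for
#'   window extraction).  Sorted by contig, then coordinate.
#' @export
scan_promoters <- function(genome, max_mismatch_per_box = 1L,
                           spacing_bounds = c(25L, 70L),
                           abox = ABOX_PATTERN, bbox = BBOX_PATTERN) {
  genome <- as_genome(genome)
  stopifnot(length(spacing_bounds) == 2L, spacing_bounds[1] <= spacing_bounds[2])
  res <- list()
  for (contig in names(genome)) {
    L <- length(genome[[contig]])
    fwd <- as.character(genome[[contig]])
    for (strand in c("+", "-")) {
      s <- if (strand == "+") fwd else revcomp(fwd)
      pa <- iupac_profile(s, abox)
      pb <- iupac_profile(s, bbox)
      apos <- which(pa <= max_mismatch_per_box) - 1L   # 0-based, strand-local
      bpos <- which(pb <= max_mismatch_per_box) - 1L
      if (length(apos) == 0L || length(bpos) == 0L) next
      # pair every B start b with A starts a where b - (a + 11) in bounds
      hits <- vector("list", length(bpos))
      for (i in seq_along(bpos)) {
        b <- bpos[i]
        lo <- b - BOX_LEN - spacing_bounds[2]
        hi <- b - BOX_LEN - spacing_bounds[1]
        sel <- apos[apos >= lo & apos <= hi]
        if (length(sel) == 0L) next
        hits[[i]] <- data.frame(a = sel, b = b)
      }
      hits <- do.call(rbind, hits)
      if (is.null(hits) || nrow(hits) == 0L) next
      if (strand == "+") {
        abox_start <- hits$a; bbox_start <- hits$b
        anchor <- hits$a
      } else {
        # strand-local [x, x+11) on minus maps to plus [L-x-11, L-x)
        abox_start <- L - hits$a - BOX_LEN
        bbox_start <- L - hits$b - BOX_LEN
        anchor <- L - hits$a - 1L     # plus coord of the A box's 5'-most base on '-'
      }
      res[[length(res) + 1L]] <- data.frame(
        contig = contig, strand = strand,
        abox_start = abox_start, abox_end = abox_start + BOX_LEN,
        bbox_start = bbox_start, bbox_end = bbox_start + BOX_LEN,
        spacing = hits$b - hits$a - BOX_LEN,
        abox_mismatches = pa[hits$a + 1L],
        bbox_mismatches = pb[hits$b + 1L],
        anchor_pos = anchor,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- if (length(res) > 0L) do.call(rbind, res) else
    data.frame(contig = character(0), strand = character(0),
               abox_start = integer(0), abox_end = integer(0),
               bbox_start = integer(0), bbox_end = integer(0),
               spacing = integer(0), abox_mismatches = integer(0),
               bbox_mismatches = integer(0), anchor_pos = integer(0))
  out <- out[order(out$contig, pmin(out$abox_start, out$bbox_start), out$strand), ,
             drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("promoter_hits", "data.frame")
  out
}

#' Convert promoter hits to anchor records
#'
#' @param hits A `promoter_hits` data.frame from [scan_promoters()].
#' @return An `anchor_hits` data.frame (contig, anchor_pos, strand, source,
#'   mismatch total) suitable for [extract_windows()].
#' @export
promoter_anchors <- function(hits) {
  out <- data.frame(
    contig = hits$contig, anchor_pos = hits$anchor_pos, strand = hits$strand,
    source = rep("promoter_scan", nrow(hits)),
    box_mismatches = hits$abox_mismatches + hits$bbox_mismatches,
    stringsAsFactors = FALSE
  )
  class(out) <- c("anchor_hits", "data.frame")
  out
}

#' Read tRNA predictions in tRNAscan-SE tabular format
#'
#' Parses the standard tabular output (three header lines, then one row per
#' prediction with 1-based inclusive coordinates; minus-strand rows have
#' begin > end).  Coordinates are converted to the package's 0-based
#' convention and `anchor_pos` is the strand-aware first base of the tRNA.
#'
#' @param path Path to a tRNAscan-SE tabular file.
#' @return An `anchor_hits` data.frame (source `"trnascan"`).
#' @export
read_trnascan <- function(path) {
  if (!file.exists(path)) stop("tRNAscan file not found: ", path)
  lines <- readLines(path)
  # drop the standard 3-line header (name/border lines); be tolerant if absent
  body <- grep("^-+\\s|^Sequence|^Name\\s|^\\s*$", lines, invert = TRUE)
  rows <- list()
  for (i in body) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    if (length(f) < 4L) stop("read_trnascan: unparsable row at line ", i, ": ", lines[i])
    begin <- suppressWarnings(as.integer(f[3L]))
    end <- suppressWarnings(as.integer(f[4L]))
    if (is.na(begin) || is.na(end)) {
      stop("read_trnascan: non-numeric coordinates at line ", i, ": ", lines[i])
    }
    strand <- if (begin <= end) "+" else "-"
    anchor <- begin - 1L            # works for both strands: 5'-most base, 0-based
    rows[[length(rows) + 1L]] <- data.frame(
      contig = f[1L], anchor_pos = anchor, strand = strand,
      source = "trnascan", box_mismatches = NA_integer_,
      stringsAsFactors = FALSE
    )
  }
  out <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(contig = character(0), anchor_pos = integer(0),
               strand = character(0), source = character(0),
               box_mismatches = integer(0))
  rownames(out) <- NULL
  class(out) <- c("anchor_hits", "data.frame")
  out
}

#' Measure the TSS-to-A-box offset of an element
#'
#' Returns the distance in bp from the element's 5' end (its transcription
#' start) to the first base of its A box.  The "eleven-nucleotide rule" is a
#' property to be measured, never enforced: this function only reports the
#' offset.
#'
#' @param element_seq The element sequence (consensus or copy), 5' end first.
#' @param promoter A single-row `promoter_hits` data.frame located on
#'   `element_seq` (plus strand, element coordinates).
#' @return Integer offset in bp (A-box start minus element start).
#' @export
measure_tss_offset <- function(element_seq, promoter) {
  stopifnot(nrow(promoter) == 1L)
  off <- promoter$abox_start[1L]
  if (off < 0L || promoter$abox_end[1L] > nchar(element_seq)) {
    stop("measure_tss_offset: A box lies outside the element")
  }
  as.integer(off)
}
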