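# Core discovery algorithm: extract promoter/tRNA-anchored 1-kb windows,
# single-linkage cluster them by local-alignment similarity, call element
# boundaries from column conservation, and build family consensus sequences.

#' Discovery parameters
#'
#' @param window_length Window length W downstream of the anchor (bp).
#' @param upstream_pad Pad U upstream of the anchor (bp).  The element's 5'
#'   end lies upstream of the tRNA/A-box anchor (typically 11 bp to the A
#'   box), so windows start `U` bp before the anchor.
#' @param min_identity Minimum pairwise local-alignment identity for a
#'   cluster edge.
#' @param min_overlap Minimum alignment length (columns) for a cluster edge.
#' @param min_members Minimum number of distinct genomic loci per cluster.
#' @param max_anchor_shift Maximum implied anchor offset (bp) between two
#'   windows joined by an edge.
#' @param boundary_conservation Smoothed modal-base fraction threshold for
#'   boundary calling.
#' @param boundary_window Smoothing window (columns).
#' @param boundary_match_run Consecutive-match run length used to refine
#'   element ends from the member alignments.
#' @param min_length Minimum element (consensus) length in bp.
#' @param head_pad bp past the B-box end included in the tRNA-like head.
#' @param min_shared_kmers Seed prefilter: candidate window pairs must share
#'   at least this many distinct 12-mers before an alignment is attempted.
#' @param max_failed_aligns Per-window cap on failed edge alignments;
#'   windows that keep failing (degenerate copies below the identity
#'   threshold) stop consuming alignment budget.
#' @param cluster_align_span Only the first `cluster_align_span` bp of each
#'   window are pairwise-aligned during clustering.  Anchoring places the
#'   element at the window start, and canonical SINEs stay under ~600 bp,
#'   so the default (650) sees the whole element; raise it when hunting
#'   longer elements.
#' @param max_mismatch_per_box,spacing_bounds Passed to [scan_promoters()]
#'   when no anchors are supplied.
#' @param name_prefix Prefix for family names.
#' @return A list of class `discovery_config`.
#' @export
discovery_config <- function(window_length = 1000L, upstream_pad = 30L,
                             min_identity = 0.90, min_overlap = 150L,
                             min_members = 3L, max_anchor_shift = 5L,
                             boundary_conservation = 0.6, boundary_window = 20L,
                             boundary_match_run = 8L, min_length = 150L,
                             head_pad = 15L, min_shared_kmers = 10L,
                             max_failed_aligns = 6L,
                             cluster_align_span = 650L,
                             max_mismatch_per_box = 1L,
                             spacing_bounds = c(25L, 70L),
                             name_prefix = "SINE") {
  structure(as.list(environment()), class = "discovery_config")
}

#' Extract anchored windows
#'
#' One window per anchor: the slice from `U` bp upstream of the anchor to
#' `W` bp downstream, clipped at contig ends.  Minus-strand windows are
#' reverse-complemented so every returned sequence reads element-sense with
#' the anchor near the 5' end.
#'
#' @param genome Genome object (see [as_genome()]).
#' @param anchors An `anchor_hits` data.frame ([promoter_anchors()] or
#'   [read_trnascan()]).
#' @param W,U Window length and upstream pad (bp).
#' @return A data.frame of class `anchor_windows`: one row per anchor with
#'   the plus-strand interval, the element-sense sequence, the anchor offset
#'   within the sequence, and a truncation flag.
#' @export
extract_windows <- function(genome, anchors, W = 1000L, U = 30L) {
  genome <- as_genome(genome)
  n <- nrow(anchors)
  out <- data.frame(
    window_id = character(n), contig = anchors$contig,
    strand = anchors$strand, anchor_pos = anchors$anchor_pos,
    start = integer(n), end = integer(n), anchor_offset = integer(n),
    truncated = logical(n), source = anchors$source,
    box_mismatches = anchors$box_mismatches, seq = character(n),
    stringsAsFactors = FALSE
  )
  for (i in seq_len(n)) {
    contig <- anchors$contig[i]
    L <- length(genome[[contig]])
    p <- anchors$anchor_pos[i]
    if (anchors$strand[i] == "+") {
      s0 <- p - U; e0 <- p + W
    } else {
      s0 <- p + 1L - W; e0 <- p + 1L + U
    }
    s <- max(0L, s0); e <- min(L, e0)
    out$start[i] <- s; out$end[i] <- e
    out$truncated[i] <- (s != s0) || (e != e0)
    out$anchor_offset[i] <- if (anchors$strand[i] == "+") p - s else (e - 1L) - p
    out$seq[i] <- genome_slice(genome, contig, s, e, anchors$strand[i])
  }
  ord <- order(out$contig, out$start, out$strand)
  out <- out[ord, , drop = FALSE]
  out$window_id <- sprintf("w%04d", seq_len(n))
  rownames(out) <- NULL
  class(out) <- c("anchor_windows", "data.frame")
  out
}

# distinct 12-mer codes of a sequence (base-4 encoding; windows touching an N
# are skipped).  Doubles hold 4^12 exactly.
.kmer_codes <- function(seq, k = 12L) {
  v <- match(strsplit(toupper(seq), "", fixed = TRUE)[[1L]], c("A", "C", "G", "T")) - 1
  n <- length(v) - k + 1L
  if (is.na(n) || n < 1L) return(numeric(0))
  code <- numeric(n)
  ok <- rep(TRUE, n)
  for (j in seq_len(k)) {
    d <- v[j:(j + n - 1L)]
    ok <- ok & !is.na(d)
    d[is.na(d)] <- 0
    code <- code * 4 + d
  }
  unique(code[ok])
}

# union-find
.uf_new <- function(n) seq_len(n)
.uf_find <- function(uf, i) { while (uf[i] != i) { uf[i] <- uf[uf[i]]; i <- uf[i] }; i }

# collapse windows whose anchors essentially coincide (same contig and
# strand, anchor positions within max_shift bp -- e.g. an A box paired with
# two nearby B boxes); keeps one representative (tRNA-scan anchors preferred,
# then fewest box mismatches, then leftmost).  Windows with genuinely
# distinct anchors at one locus stay separate: the anchor-shift edge filter
# keeps them from cross-linking, and shadow/redundancy suppression removes
# the parallel clusters they may form.
.dedupe_loci <- function(windows, max_shift = 5L) {
  n <- nrow(windows)
  if (n <= 1L) return(windows)
  keep <- logical(n)
  key <- paste(windows$contig, windows$strand)
  for (grp in split(seq_len(n), key)) {
    grp <- grp[order(windows$anchor_pos[grp])]
    ap <- windows$anchor_pos[grp]
    comp_id <- cumsum(c(TRUE, diff(ap) > max_shift))
    for (comp in split(seq_along(grp), comp_id)) {
      idx <- grp[comp]
      pref <- order(windows$source[idx] != "trnascan",
                    ifelse(is.na(windows$box_mismatches[idx]), 0L,
                           windows$box_mismatches[idx]),
                    windows$start[idx])
      keep[idx[pref[1L]]] <- TRUE
    }
  }
  windows[keep, , drop = FALSE]
}

#' Cluster anchored windows into candidate families
#'
#' Single-linkage clustering over the graph whose edges join window pairs
#' with a local alignment of identity at least `min_identity` spanning at
#' least `min_overlap` columns, whose implied anchor offset is at most
#' `max_anchor_shift` bp.  Windows covering the same genomic locus are first
#' collapsed to one representative, so cluster membership counts distinct
#' loci.  Clusters with fewer than `min_members` members are discarded.
#' A shared-12-mer prefilter skips hopeless pairs; pairs already joined by
#' transitivity are not re-aligned (single linkage only needs connectivity).
#'
#' @param windows An `anchor_windows` data.frame.
#' @param config A [discovery_config()].
#' @param scoring A [scoring_scheme()].
#' @return A list of `candidate_cluster` objects, ordered by the leftmost
#'   member coordinate; each holds the member windows, the passing edges
#'   (with identities, overlaps and shifts) computed on the way.
#' @export
cluster_windows <- function(windows, config = discovery_config(),
                            scoring = scoring_scheme()) {
  if (nrow(windows) == 0L) return(list())
  windows <- .dedupe_loci(windows, max_shift = config$max_anchor_shift)
  windows <- windows[order(windows$contig, windows$start, windows$strand), , drop = FALSE]
  rownames(windows) <- NULL
  n <- nrow(windows)
  kl <- lapply(windows$seq, .kmer_codes)
  # sparse shared-kmer counts
  lens <- lengths(kl)
  if (sum(lens) > 0L) {
    all_codes <- unlist(kl, use.names = FALSE)
    cid <- match(all_codes, unique(all_codes))
    M <- Matrix::sparseMatrix(i = rep(seq_len(n), lens), j = cid, x = 1)
    S <- Matrix::tcrossprod(M)
    S <- methods::as(methods::as(S, "generalMatrix"), "TsparseMatrix")
    pi_ <- S@i + 1L; pj <- S@j + 1L; px <- S@x
    sel <- pi_ < pj & px >= config$min_shared_kmers
    cand <- data.frame(i = pi_[sel], j = pj[sel], shared = px[sel])
  } else {
    cand <- data.frame(i = integer(0), j = integer(0), shared = numeric(0))
  }
  # best-supported pairs first: components condense quickly and weaker pairs
  # are skipped by transitivity; a per-window cap on failed alignments keeps
  # degenerate (sub-threshold) windows from exhausting the alignment budget
  cand <- cand[order(-cand$shared, cand$i, cand$j), , drop = FALSE]
  uf <- .uf_new(n)
  fails <- integer(n)
  max_fail <- config$max_failed_aligns
  comp_fails <- new.env(parent = emptyenv())   # failed component pairs
  edges <- list()
  for (r in seq_len(nrow(cand))) {
    i <- cand$i[r]; j <- cand$j[r]
    ri <- .uf_find(uf, i); rj <- .uf_find(uf, j)
    if (ri == rj) next
    if (fails[i] >= max_fail || fails[j] >= max_fail) next
    ck <- paste(min(ri, rj), max(ri, rj))
    nf <- if (is.null(comp_fails[[ck]])) 0L else comp_fails[[ck]]
    if (nf >= 3L) next
    span <- config$cluster_align_span
    aln <- align_local(substr(windows$seq[i], 1L, span),
                       substr(windows$seq[j], 1L, span), scoring,
                       with_strings = FALSE)
    ok_edge <- aln$identity >= config$min_identity &&
      aln$aligned_length >= config$min_overlap
    shift <- Inf
    if (ok_edge) {
      shift <- abs((windows$anchor_offset[i] - aln$query_span[1]) -
                   (windows$anchor_offset[j] - aln$target_span[1]))
    }
    if (!ok_edge || shift > config$max_anchor_shift) {
      comp_fails[[ck]] <- nf + 1L
      if (!ok_edge) { fails[i] <- fails[i] + 1L; fails[j] <- fails[j] + 1L }
      next
    }
    uf[.uf_find(uf, j)] <- .uf_find(uf, i)
    edges[[length(edges) + 1L]] <- data.frame(
      i = windows$window_id[i], j = windows$window_id[j],
      identity = aln$identity, overlap = aln$aligned_length, shift = shift
    )
  }
  edges <- if (length(edges) > 0L) do.call(rbind, edges) else
    data.frame(i = character(0), j = character(0), identity = numeric(0),
               overlap = integer(0), shift = integer(0))
  roots <- vapply(seq_len(n), function(i) .uf_find(uf, i), 1L)
  clusters <- list()
  for (comp in split(seq_len(n), roots)) {
    if (length(comp) < config$min_members) next
    mem <- windows[comp, , drop = FALSE]
    rownames(mem) <- NULL
    esel <- edges[edges$i %in% mem$window_id & edges$j %in% mem$window_id, , drop = FALSE]
    clusters[[length(clusters) + 1L]] <- structure(
      list(members = mem, edges = esel, config = config), class = "candidate_cluster")
  }
  if (length(clusters) > 1L) {
    first <- vapply(clusters, function(cl) min(cl$members$start), 1L)
    fcon <- vapply(clusters, function(cl) cl$members$contig[which.min(cl$members$start)], "")
    clusters <- clusters[order(fcon, first)]
  }
  clusters
}

#' @export
print.candidate_cluster <- function(x, ...) {
  cat(sprintf("<candidate_cluster: %d members, %d edges, %s:%d..>\n",
              nrow(x$members), nrow(x$edges), x$members$contig[1L], x$members$start[1L]))
  invisible(x)
}

# Star alignment of a cluster: every member locally aligned to the center
# (the member with the highest summed edge identity), projected onto center
# columns.  Member insertions relative to the center are dropped; a member
# deletion shows as "-"; uncovered columns are NA.
.star_align <- function(cluster, scoring = scoring_scheme()) {
  mem <- cluster$members
  n <- nrow(mem)
  idsum <- stats::setNames(numeric(n), mem$window_id)
  for (r in seq_len(nrow(cluster$edges))) {
    e <- cluster$edges[r, ]
    idsum[e$i] <- idsum[e$i] + e$identity
    idsum[e$j] <- idsum[e$j] + e$identity
  }
  center <- which.max(idsum)            # ties: first (leftmost, by ordering)
  clen <- nchar(mem$seq[center])
  mat <- matrix(NA_character_, nrow = n, ncol = clen)
  pos <- matrix(NA_integer_, nrow = n, ncol = clen)   # member pos (1-based)
  cseq <- strsplit(mem$seq[center], "", fixed = TRUE)[[1L]]
  mat[center, ] <- cseq
  pos[center, ] <- seq_len(clen)
  # emat/epos additionally carry a bounded ungapped extension beyond each
  # member's local-alignment ends, so a terminal mismatch (e.g. the center's
  # first base mutated in one copy) does not erase member evidence at
  # boundary columns.  The extension feeds only the TSD vote and the
  # consensus content; conservation and match-run trimming use the pure
  # alignment-supported mat/pos (extension chars at flank columns would
  # inflate flank conservation and shift the coarse boundaries).
  ext <- 40L
  emat <- mat; epos <- pos
  for (i in seq_len(n)) {
    if (i == center) next
    aln <- align_local(mem$seq[i], mem$seq[center], scoring)
    if (aln$aligned_length == 0L) next
    qc <- strsplit(aln$query_aln, "", fixed = TRUE)[[1L]]
    tc <- strsplit(aln$target_aln, "", fixed = TRUE)[[1L]]
    mchars <- strsplit(mem$seq[i], "", fixed = TRUE)[[1L]]
    tpos <- aln$target_span[1]
    qpos <- aln$query_span[1]
    for (k in seq_along(tc)) {
      if (qc[k] != "-") qpos <- qpos + 1L
      if (tc[k] != "-") {
        mat[i, tpos + 1L] <- qc[k]
        emat[i, tpos + 1L] <- qc[k]
        if (qc[k] != "-") {
          pos[i, tpos + 1L] <- qpos
          epos[i, tpos + 1L] <- qpos
        }
        tpos <- tpos + 1L
      }
    }
    for (k in seq_len(min(ext, aln$target_span[1], aln$query_span[1]))) {
      emat[i, aln$target_span[1] - k + 1L] <- mchars[aln$query_span[1] - k + 1L]
      epos[i, aln$target_span[1] - k + 1L] <- aln$query_span[1] - k + 1L
    }
    for (k in seq_len(min(ext, clen - aln$target_span[2],
                          length(mchars) - aln$query_span[2]))) {
      emat[i, aln$target_span[2] + k] <- mchars[aln$query_span[2] + k]
      epos[i, aln$target_span[2] + k] <- aln$query_span[2] + k
    }
  }
  list(center = center, mat = mat, pos = pos, emat = emat, epos = epos,
       center_seq = cseq)
}

# Exact boundary refinement by target-site duplication voting.  A freshly
# inserted element is flanked by a mismatch-free 10-15-bp direct repeat; in
# each member window we look for an exact repeat pair whose left instance
# ends, and right instance starts, near the coarse boundaries, and let the
# members vote (in center-column coordinates).  Returns c(start_col, end_col)
# 1-based inclusive, or NULL when fewer than `min_votes` members agree.
.tsd_vote <- function(star, member_seqs, cs0, ce0, wiggle = 15L,
                      min_len = 10L, max_len = 15L, min_votes = 2L,
                      max_members = 25L, cons = NULL) {
  n <- nrow(star$mat)
  use <- seq_len(min(n, max_members))
  votes <- list()
  # conversions prefer the alignment-supported projection; the ungapped
  # extension is only a fallback for columns the local alignment does not
  # reach (e.g. a terminal mismatch in the center copy)
  pmat <- star$pos
  emat <- if (!is.null(star$epos)) star$epos else star$pos
  nc <- ncol(pmat)
  # member<->center coordinates are converted through a local diagonal
  # offset measured at anchor columns ~25 bp INSIDE the element, where the
  # mapping is unambiguous.  A position-map lookup at the boundary itself is
  # unreliable: the local aligner occasionally places a spurious gap inside
  # the (mismatch-rich) TSD region, shifting the map by one base exactly
  # where the vote needs it.
  diag_at <- function(i, col0) {
    for (cc in c(col0, (col0 - 8L):(col0 + 8L))) {
      if (cc >= 1L && cc <= nc && !is.na(pmat[i, cc])) return(pmat[i, cc] - cc)
    }
    NA_integer_
  }
  for (i in use) {
    s <- member_seqs[i]
    L <- nchar(s)
    d1 <- diag_at(i, min(nc, cs0 + 25L))
    d2 <- diag_at(i, max(1L, ce0 - 25L))
    if (is.na(d1) || is.na(d2)) next
    p1 <- cs0 + d1; p2 <- ce0 + d2
    if (p1 < 1L || p2 > L) next
    # candidate pairs at every length: a shifted sub-repeat of the true TSD
    # is systematic across members, so the decision is taken globally by
    # (vote count, then repeat length), not per member
    for (len in seq.int(max_len, min_len)) {
      ls <- (p1 - wiggle):(p1 + wiggle)       # candidate element start positions
      ls <- ls[ls - len >= 1L & ls <= L]
      rs <- (p2 - wiggle):(p2 + wiggle)       # candidate element end positions
      rs <- rs[rs >= 1L & rs + len <= L]
      if (length(ls) == 0L || length(rs) == 0L) next
      lseq <- substring(s, ls - len, ls - 1L)
      rseq <- substring(s, rs + 1L, rs + len)
      eq <- outer(lseq, rseq, "==")
      if (!any(eq)) next
      idx <- which(eq, arr.ind = TRUE)
      if (nrow(idx) > 8L) idx <- idx[seq_len(8L), , drop = FALSE]
      for (k in seq_len(nrow(idx))) {
        c1 <- ls[idx[k, 1L]] - d1
        c2 <- rs[idx[k, 2L]] - d2
        if (c1 < 1L || c2 > nc || c2 <= c1) next
        votes[[length(votes) + 1L]] <- data.frame(
          member = i, c1 = c1, c2 = c2, len = len)
      }
    }
  }
  if (length(votes) == 0L) return(NULL)
  votes <- do.call(rbind, votes)
  votes <- votes[!duplicated(votes[, c("member", "c1", "c2")]), , drop = FALSE]
  key <- paste(votes$c1, votes$c2)
  count <- tapply(votes$member, key, function(x) length(unique(x)))
  lenmax <- tapply(votes$len, key, max)
  # total repeat evidence: the true pair collects each member's full TSD
  # length; any shifted sub-pair collects strictly less from strictly fewer
  # members, and chance one-base extensions collect from few members
  score <- tapply(votes$len, key, sum)
  pos <- do.call(rbind, strsplit(names(count), " "))
  agg <- data.frame(c1 = as.integer(pos[, 1L]), c2 = as.integer(pos[, 2L]),
                    count = as.integer(count), len = as.integer(lenmax),
                    score = as.integer(score))
  # boundary-evidence penalty: just outside a true boundary lie the TSDs
  # (different per member, unconserved columns), just inside the element
  # (conserved).  A one-base-shifted pair -- possible when every member's
  # flank coincides with the adjacent element base -- fails this check.
  agg$penalty <- 0L
  if (!is.null(cons)) {
    nc <- length(cons)
    colcons <- function(i) ifelse(i >= 1L & i <= nc, cons[pmax(pmin(i, nc), 1L)], 0)
    agg$penalty <- (colcons(agg$c1 - 1L) >= 0.6) + (colcons(agg$c2 + 1L) >= 0.6) +
      (colcons(agg$c1) < 0.6) + (colcons(agg$c2) < 0.6)
  }
  agg <- agg[order(-agg$score, agg$penalty, -agg$count, -agg$len,
                   abs(agg$c1 - cs0) + abs(agg$c2 - ce0)), , drop = FALSE]
  if (agg$count[1L] < min_votes) return(NULL)
  c(agg$c1[1L], agg$c2[1L])
}

# per-column modal-base fraction (gaps and uncovered positions are never
# modal; denominator is the full member count)
.conservation <- function(mat) {
  n <- nrow(mat)
  apply(mat, 2L, function(col) {
    col <- col[!is.na(col) & col != "-"]
    if (length(col) == 0L) return(0)
    max(tabulate(match(col, c("A", "C", "G", "T")), nbins = 4L)) / n
  })
}

#' Call element boundaries within a cluster
#'
#' Coarse boundaries come from the conservation rule: the run of
#' columns whose smoothed (centered window) modal-base fraction stays at or
#' above `boundary_conservation`, anchored at the cluster's anchor column.
#' Ends are then refined from the member alignments: each member's aligned
#' span is trimmed back to its outermost run of `boundary_match_run`
#' consecutive matches to the center near the coarse bounds, and the element
#' spans the union of the trimmed spans.  Clusters whose conserved run is
#' shorter than `min_length` are rejected (an absent marker with a `reason` attribute, see [is_absent()]).
#'
#' @param cluster A `candidate_cluster`.
#' @param config A [discovery_config()].
#' @param scoring A [scoring_scheme()].
#' @return A list of class `cluster_boundary` with `start` and `end` (0-based
#'   half-open, center coordinates), flags, and the cached star alignment.
#' @export
call_boundary <- function(cluster, config = cluster$config,
                          scoring = scoring_scheme()) {
  if (is.null(config)) config <- discovery_config()
  star <- .star_align(cluster, scoring)
  mat <- star$mat
  cons <- .conservation(mat)
  sm <- as.numeric(stats::filter(cons, rep(1 / config$boundary_window,
                                           config$boundary_window), sides = 2L))
  sm[is.na(sm)] <- cons[is.na(sm)]
  ok <- sm >= config$boundary_conservation
  if (!any(ok)) {
    return(.absent("conservation never reaches threshold"))
  }
  runs <- rle(ok)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  anchor_col <- cluster$members$anchor_offset[star$center] + 1L
  hit <- which(runs$values & starts <= anchor_col & ends >= anchor_col)
  if (length(hit) == 0L) {
    tr <- which(runs$values)
    hit <- tr[which.max(runs$lengths[tr])]
  }
  run_start <- starts[hit]; run_end <- ends[hit]
  flags <- character(0)
  if (run_end - run_start + 1L < config$min_length) {
    return(.absent(sprintf(
      "conserved run too short (%d < %d)", run_end - run_start + 1L, config$min_length)))
  }
  if (mean(cons >= 0.95) > 0.95) {
    flags <- c(flags, "no divergence observed - possible segmental duplication")
    run_end <- ncol(mat)
  }
  # refinement 1: trimmed member spans near the coarse bounds
  slack <- 15L
  lo <- max(1L, run_start - slack); hi <- min(ncol(mat), run_end + slack)
  smin <- integer(0); emax <- integer(0)
  K <- config$boundary_match_run
  for (i in seq_len(nrow(mat))) {
    if (i == star$center) next
    mv <- !is.na(mat[i, ]) & mat[i, ] == star$center_seq
    mv[seq_len(lo - 1L)] <- FALSE
    if (hi < length(mv)) mv[(hi + 1L):length(mv)] <- FALSE
    r <- rle(mv)
    re <- cumsum(r$lengths); rs <- re - r$lengths + 1L
    good <- which(r$values & r$lengths >= K)
    if (length(good) == 0L) next
    smin <- c(smin, rs[good[1L]])
    emax <- c(emax, re[good[length(good)]])
  }
  # outermost trimmed spans, robustly: members with a mutation in their
  # terminal match run trim inward, a rare chance flank run trims outward;
  # the 10th/90th percentile (type 1: equals min/max for small clusters)
  # ignores lone outward outliers without giving up the outermost evidence
  el_start <- if (length(smin) > 0L)
    as.integer(stats::quantile(smin, 0.1, type = 1L)) else run_start
  el_end <- if (length(emax) > 0L)
    as.integer(stats::quantile(emax, 0.9, type = 1L)) else run_end
  if ("no divergence observed - possible segmental duplication" %in% flags) {
    el_end <- ncol(mat)
  }
  if (el_end - el_start + 1L < config$min_length) {
    return(.absent("refined element shorter than minimum length"))
  }
  # refinement 2: TSD voting -- exact when members carry intact target-site
  # duplications (fresh insertions).  Centered first on the trimmed bounds,
  # then on the coarse conservation-run bounds: either centering can be the
  # one within voting range when smoothing or trimming drifted.
  if (length(flags) == 0L) {
    tv <- .tsd_vote(star, cluster$members$seq, el_start, el_end, cons = cons)
    if (is.null(tv) && (abs(el_start - run_start) > 5L ||
                        abs(el_end - run_end) > 5L)) {
      tv <- .tsd_vote(star, cluster$members$seq, run_start, run_end, cons = cons)
    }
    if (!is.null(tv) && tv[2L] - tv[1L] + 1L >= config$min_length) {
      el_start <- tv[1L]; el_end <- tv[2L]
      flags <- c(flags, "tsd_refined")
    }
  }
  structure(list(start = el_start - 1L, end = el_end, flags = flags,
                 center = star$center, star = star),
            class = "cluster_boundary")
}

#' Build a family consensus from a cluster and its boundary
#'
#' Column-wise majority consensus over the star alignment, restricted to the
#' boundary span.  A column is emitted iff fewer than half the members have a
#' gap (or are uncovered) there; ties are broken in the fixed base order
#' A < C < G < T.  The promoter is re-detected on the consensus and the
#' TSS-to-A-box offset recorded; a consensus with no promoter, or shorter
#' than the minimum element length, is rejected (an absent marker with a
#' `reason` attribute, see [is_absent()]).
#'
#' @param cluster A `candidate_cluster`.
#' @param boundary A `cluster_boundary` from [call_boundary()].
#' @param name Family name.
#' @param config A [discovery_config()].
#' @return An object of class `sine_model`.
#' @export
build_consensus <- function(cluster, boundary, name = "SINE",
                            config = cluster$config) {
  if (is.null(config)) config <- discovery_config()
  if (is_absent(boundary)) stop("build_consensus: boundary is absent")
  mat <- if (!is.null(boundary$star$emat)) boundary$star$emat else boundary$star$mat
  cols <- seq.int(boundary$start + 1L, boundary$end)
  n <- nrow(mat)
  bases <- c("A", "C", "G", "T")
  out <- character(0)
  for (cc in cols) {
    col <- mat[, cc]
    gapish <- sum(is.na(col) | col == "-")
    if (gapish * 2L >= n) next
    counts <- tabulate(match(col[!is.na(col) & col != "-"], bases), nbins = 4L)
    out <- c(out, bases[which.max(counts)])   # which.max -> first max: A<C<G<T
  }
  consensus <- paste(out, collapse = "")
  if (nchar(consensus) < config$min_length) {
    return(.absent(sprintf(
      "consensus shorter than %d bp", config$min_length)))
  }
  ph <- scan_promoters(stats::setNames(consensus, "consensus"),
                       max_mismatch_per_box = config$max_mismatch_per_box,
                       spacing_bounds = config$spacing_bounds)
  ph <- ph[ph$strand == "+", , drop = FALSE]
  if (nrow(ph) == 0L) {
    return(.absent("no promoter on consensus"))
  }
  # best-matching boxes first (the genuine promoter is near-canonical);
  # among equals the 5'-most wins
  ph <- ph[order(ph$abox_mismatches + ph$bbox_mismatches, ph$abox_start), ,
           drop = FALSE][1L, , drop = FALSE]
  tss_offset <- measure_tss_offset(consensus, ph)
  head_end <- min(nchar(consensus), ph$bbox_end[1L] + config$head_pad)
  tail <- classify_tail(consensus)
  loci <- cluster$members[, c("contig", "start", "end", "strand", "window_id")]
  structure(list(
    name = name, consensus = consensus, length = nchar(consensus),
    promoter = ph, tss_offset = tss_offset, head_end = head_end,
    tail = tail, n_members = nrow(cluster$members), member_loci = loci,
    flags = boundary$flags
  ), class = "sine_model")
}

#' @export
print.sine_model <- function(x, ...) {
  cat(sprintf("<sine_model %s: %d bp, %d members, tss_offset %d, head_end %d, tail %s>\n",
              x$name, x$length, x$n_members, x$tss_offset, x$head_end, x$tail$kind))
  invisible(x)
}

# Suppress "shadow" clusters: secondary promoter-like hits inside an element
# (either sense) produce a parallel cluster over the same genomic copies,
# anchored away from the true promoter and therefore truncated.  Among
# models whose member loci largely overlap, keep the longest consensus
# (degenerate no-divergence models last, then membership).
.suppress_shadows <- function(models) {
  n <- length(models)
  if (n <= 1L) return(models)
  uf <- .uf_new(n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      a <- models[[i]]$member_loci; b <- models[[j]]$member_loci
      hits <- 0L
      for (r in seq_len(nrow(a))) {
        sel <- b$contig == a$contig[r] &
          pmin(b$end, a$end[r]) - pmax(b$start, a$start[r]) >= 200L
        if (any(sel)) hits <- hits + 1L
      }
      if (hits >= 0.5 * min(nrow(a), nrow(b))) {
        ra <- .uf_find(uf, i); rb <- .uf_find(uf, j)
        if (ra != rb) uf[rb] <- ra
      }
    }
  }
  roots <- vapply(seq_len(n), function(i) .uf_find(uf, i), 1L)
  keep <- .pick_representatives(models, roots)
  models[keep]
}

# one representative per redundancy component: TSD-pinned boundaries beat
# unpinned ones (a shadow cluster lacks at least one flanking TSD in its
# windows and cannot refine), then membership, then length; degenerate
# no-divergence models last
.pick_representatives <- function(models, roots) {
  n <- length(models)
  keep <- logical(n)
  for (comp in split(seq_len(n), roots)) {
    sizes <- vapply(comp, function(i) models[[i]]$n_members, 1L)
    lens <- vapply(comp, function(i) models[[i]]$length, 1L)
    flagged <- vapply(comp, function(i)
      any(grepl("no divergence", models[[i]]$flags)), TRUE)
    refined <- vapply(comp, function(i)
      "tsd_refined" %in% models[[i]]$flags, TRUE)
    keep[comp[order(flagged, !refined, -sizes, -lens)][1L]] <- TRUE
  }
  keep
}

# Merge models that describe the same element: copies whose primary promoter
# was destroyed by mutation can be rediscovered through a secondary internal
# promoter hit, yielding a second model with non-overlapping member loci but
# a near-identical consensus.  A model rediscovered through a downstream
# secondary promoter is necessarily 5'-truncated, so among redundant models
# the longest consensus wins (degenerate no-divergence models last, then
# membership as tie-break).
.merge_redundant <- function(models, min_identity = 0.90, min_cover = 0.8,
                             scoring = scoring_scheme()) {
  n <- length(models)
  if (n <= 1L) return(models)
  uf <- .uf_new(n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (.uf_find(uf, i) == .uf_find(uf, j)) next
      minlen <- min(models[[i]]$length, models[[j]]$length)
      aln <- align_local(models[[i]]$consensus, models[[j]]$consensus, scoring,
                         with_strings = FALSE)
      if (aln$identity < min_identity || aln$aligned_length < min_cover * minlen) {
        # opposite-sense shadows: compare against the reverse complement too
        aln <- align_local(revcomp(models[[i]]$consensus),
                           models[[j]]$consensus, scoring, with_strings = FALSE)
      }
      if (aln$identity >= min_identity && aln$aligned_length >= min_cover * minlen) {
        uf[.uf_find(uf, j)] <- .uf_find(uf, i)
      }
    }
  }
  roots <- vapply(seq_len(n), function(i) .uf_find(uf, i), 1L)
  models[.pick_representatives(models, roots)]
}

#' Run the full discovery stage
#'
#' Anchors (from a supplied tRNA-prediction table, else a genome-wide
#' promoter scan) are expanded to windows, clustered, boundary-called, and
#' summarized as consensus models.  Shadow clusters arising from secondary
#' promoter-like hits inside an element are suppressed; surviving families
#' are named in genomic order.
#'
#' @param genome Genome object.
#' @param anchors Optional `anchor_hits`; when `NULL`, [scan_promoters()]
#'   provides them.
#' @param config A [discovery_config()].
#' @param scoring A [scoring_scheme()].
#' @return A list with `models` (list of `sine_model`), `clusters`,
#'   `windows`, `anchors` and `rejected` (data.frame of cluster rejection
#'   reasons).
#' @export
discover_families <- function(genome, anchors = NULL,
                              config = discovery_config(),
                              scoring = scoring_scheme()) {
  genome <- as_genome(genome)
  if (is.null(anchors)) {
    anchors <- promoter_anchors(scan_promoters(
      genome, max_mismatch_per_box = config$max_mismatch_per_box,
      spacing_bounds = config$spacing_bounds))
  }
  windows <- extract_windows(genome, anchors,
                             W = config$window_length, U = config$upstream_pad)
  clusters <- cluster_windows(windows, config, scoring)
  models <- list(); rejected <- list()
  for (k in seq_along(clusters)) {
    b <- call_boundary(clusters[[k]], config, scoring)
    if (is_absent(b)) {
      rejected[[length(rejected) + 1L]] <- data.frame(
        cluster = k, reason = attr(b, "reason"))
      next
    }
    m <- build_consensus(clusters[[k]], b, name = sprintf("cl%03d", k), config)
    if (is_absent(m)) {
      rejected[[length(rejected) + 1L]] <- data.frame(
        cluster = k, reason = attr(m, "reason"))
      next
    }
    m$cluster_index <- k
    models[[length(models) + 1L]] <- m
  }
  models <- .suppress_shadows(models)
  models <- .merge_redundant(models, scoring = scoring)
  for (i in seq_along(models)) {
    models[[i]]$name <- sprintf("%s_%d", config$name_prefix, i)
  }
  rejected <- if (length(rejected) > 0L) do.call(rbind, rejected) else
    data.frame(cluster = integer(0), reason = character(0))
  list(models = models, clusters = clusters, windows = windows,
       anchors = anchors, rejected = rejected)
}
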