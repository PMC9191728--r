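# Genome-wide characterization of SINE families: full-length copy
# enumeration at 80/90% identity, age statistics, target-site-duplication
# detection, tail classification and dimer detection.

#' Enumerate full-length genomic copies of a family
#'
#' Seed-and-verify scan: candidate loci are found from shared 12-mers between
#' the consensus and the genome (both strands), grouped by diagonal, and each
#' candidate window is verified by a semi-global alignment of the full-length
#' consensus ([align_glocal()]).  With `k = 12` and at least `min_seeds`
#' shared seeds per locus, a >=150-bp consensus cannot miss a copy above 90%
#' identity: at 10% divergence the expected spacing between intact 12-mers is
#' far below 150/2 bp, and the oracle tests enforce parity down to 80%.
#' Overlapping candidate loci are resolved best-first (higher identity wins;
#' ties leftmost).
#'
#' @param genome Genome object.
#' @param model A `sine_model` (or any list with `name` and `consensus`).
#' @param min_identity Identity threshold, conventionally 0.80 or 0.90.
#' @param scoring A [scoring_scheme()].
#' @param k Seed k-mer length.
#' @param min_seeds Minimum shared seeds per candidate locus.
#' @param margin Extra bp around a candidate locus given to the verifier.
#' @return A data.frame of class `genomic_copies`: family, contig, 0-based
#'   half-open locus, strand, identity, truncation flag.
#' @export
scan_copies <- function(genome, model, min_identity = 0.80,
                        scoring = scoring_scheme(), k = 12L, min_seeds = 2L,
                        margin = 30L) {
  genome <- as_genome(genome)
  cons <- toupper(model$consensus)
  L <- nchar(cons)
  if (L < 150L) stop("scan_copies: consensus shorter than 150 bp")
  cand <- list()
  for (strand in c("+", "-")) {
    q <- if (strand == "+") cons else revcomp(cons)
    noff <- L - k + 1L
    km <- Biostrings::DNAStringSet(substring(q, seq_len(noff), seq_len(noff) + k - 1L))
    keep <- !grepl("N", as.character(km), fixed = TRUE)
    if (!any(keep)) next
    pd <- Biostrings::PDict(km[keep])
    offs <- (seq_len(noff) - 1L)[keep]
    for (contig in names(genome)) {
      mh <- Biostrings::matchPDict(pd, genome[[contig]])
      nh <- S4Vectors::elementNROWS(mh)
      if (sum(nh) == 0L) next
      pos <- unlist(IRanges::start(mh), use.names = FALSE) - 1L
      ko <- rep(offs, nh)
      diag <- pos - ko
      ord <- order(diag, pos)
      diag <- diag[ord]
      grp <- cumsum(c(TRUE, diff(diag) > 20L))
      for (g in split(seq_along(diag), grp)) {
        if (length(unique(diag[g])) + 0L < 1L) next
        if (length(g) < min_seeds) next
        d0 <- min(diag[g])
        cand[[length(cand) + 1L]] <- data.frame(
          contig = contig, strand = strand,
          wstart = d0 - margin, wend = max(diag[g]) + L + margin,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(cand) == 0L) return(.empty_copies(model$name))
  cand <- unique(do.call(rbind, cand))
  hits <- list()
  for (r in seq_len(nrow(cand))) {
    contig <- cand$contig[r]
    Lc <- length(genome[[contig]])
    ws <- max(0L, cand$wstart[r]); we <- min(Lc, cand$wend[r])
    if (we - ws < 0.5 * L) next
    tgt <- genome_slice(genome, contig, ws, we, "+")
    q <- if (cand$strand[r] == "+") cons else revcomp(cons)
    aln <- align_glocal(q, tgt, scoring, with_strings = FALSE)
    if (aln$identity < min_identity) next
    hits[[length(hits) + 1L]] <- data.frame(
      family = model$name, contig = contig,
      start = ws + aln$target_span[1], end = ws + aln$target_span[2],
      strand = cand$strand[r], identity = aln$identity,
      truncated = (cand$wstart[r] < 0L) || (cand$wend[r] > Lc),
      stringsAsFactors = FALSE
    )
  }
  if (length(hits) == 0L) return(.empty_copies(model$name))
  hits <- do.call(rbind, hits)
  hits <- hits[order(-hits$identity, hits$contig, hits$start), , drop = FALSE]
  keep <- logical(nrow(hits))
  taken <- list()
  for (r in seq_len(nrow(hits))) {
    contig <- hits$contig[r]
    tk <- taken[[contig]]
    ovl <- FALSE
    if (!is.null(tk)) {
      ovl <- any(pmin(tk$end, hits$end[r]) - pmax(tk$start, hits$start[r]) > 0L)
    }
    if (!ovl) {
      keep[r] <- TRUE
      taken[[contig]] <- rbind(tk, hits[r, c("start", "end")])
    }
  }
  out <- hits[keep, , drop = FALSE]
  out <- out[order(out$contig, out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("genomic_copies", "data.frame")
  out
}

.empty_copies <- function(family) {
  out <- data.frame(family = character(0), contig = character(0),
                    start = integer(0), end = integer(0), strand = character(0),
                    identity = numeric(0), truncated = logical(0))
  class(out) <- c("genomic_copies", "data.frame")
  out
}

#' Copy-number age profile of a family
#'
#' The fraction of high-identity copies (>= 90%) among all copies (>= 80%)
#' proxies a family's evolutionary youth.  Truncated copies (contig-end
#' overlaps) are excluded from both counts.
#'
#' @param copies80,copies90 `genomic_copies` for the same family at the 0.80
#'   and 0.90 thresholds.
#' @return One-row data.frame: family, n80, n90, young_fraction (0, flagged,
#'   when n80 is 0).
#' @export
age_profile <- function(copies80, copies90) {
  fam <- unique(c(copies80$family, copies90$family))
  if (length(fam) > 1L) stop("age_profile: copies from more than one family")
  if (length(fam) == 0L) fam <- NA_character_
  n80 <- sum(!copies80$truncated)
  n90 <- sum(!copies90$truncated)
  data.frame(family = fam, n80 = n80, n90 = n90,
             young_fraction = if (n80 > 0L) n90 / n80 else 0,
             degenerate = n80 == 0L)
}

#' Detect the target-site duplication flanking a copy
#'
#' Searches for the longest direct repeat (length `min_len`..`max_len`, at
#' most `max_mismatch` substitutions) whose left instance ends at, and right
#' instance starts at, the copy boundaries -- each allowed to sit up to
#' `max_offset` bp away to tolerate imprecise boundary calls.  Among equal
#' lengths the pair closest to the copy ends wins.
#'
#' @param genome Genome object.
#' @param locus One-row data.frame or list with `contig`, `start`, `end`
#'   (0-based half-open).
#' @param min_len,max_len TSD length bounds (canonically 10-15 bp).
#' @param max_mismatch Tolerated substitutions between the two instances.
#' @param max_offset Max bp between a repeat instance and the copy boundary.
#' @return A list of class `tsd_pair` (left/right 0-based intervals, sequence
#'   of the left instance, length, mismatches) or an absent marker (see
#'   [is_absent()]) with a `reason` attribute.
#' @export
detect_tsd <- function(genome, locus, min_len = 10L, max_len = 15L,
                       max_mismatch = 0L, max_offset = 3L) {
  genome <- as_genome(genome)
  contig <- as.character(locus$contig[1L])
  s <- as.integer(locus$start[1L]); e <- as.integer(locus$end[1L])
  Lc <- length(genome[[contig]])
  need <- max_len + max_offset
  if (s < need || Lc - e < need) {
    return(.absent("insufficient flank"))
  }
  left_fl <- genome_slice(genome, contig, s - need, s, "+")
  right_fl <- genome_slice(genome, contig, e, e + need, "+")
  lf <- strsplit(left_fl, "", fixed = TRUE)[[1L]]
  rf <- strsplit(right_fl, "", fixed = TRUE)[[1L]]
  for (len in seq.int(max_len, min_len)) {
    best <- NULL
    for (dtot in 0:(2L * max_offset)) {
      for (loff in 0:min(dtot, max_offset)) {
        roff <- dtot - loff
        if (roff > max_offset) next
        # left instance: ends loff bp before the copy start
        li <- need - loff - len
        if (li < 0L) next
        lseq <- lf[(li + 1L):(li + len)]
        rseq <- rf[(roff + 1L):(roff + len)]
        mm <- sum(lseq != rseq | lseq == "N")
        if (mm <= max_mismatch) {
          best <- list(loff = loff, roff = roff, mm = mm,
                       lseq = paste(lseq, collapse = ""))
          break
        }
      }
      if (!is.null(best)) break
    }
    if (!is.null(best)) {
      lstart <- s - best$loff - len
      rstart <- e + best$roff
      return(structure(list(
        left = c(lstart, lstart + len), right = c(rstart, rstart + len),
        seq = best$lseq, length = len, mismatches = best$mm,
        contig = contig), class = "tsd_pair"))
    }
  }
  .absent("no direct repeat of 10-15 bp at the copy ends")
}

# lexicographically minimal rotation (unit <= 6, brute force is fine)
.min_rotation <- function(unit) {
  n <- nchar(unit)
  rots <- vapply(seq_len(n), function(i) {
    paste0(substr(unit, i, n), substr(unit, 1, i - 1L))
  }, "")
  sort(rots)[1L]
}

# smallest period of a string (unit primitivity test)
.smallest_period <- function(s) {
  n <- nchar(s)
  for (p in seq_len(n)) {
    if (n %% p == 0L && s == paste(rep(substr(s, 1, p), n / p), collapse = "")) return(p)
  }
  n
}

#' Classify the 3' tail of a consensus
#'
#' Reports the maximal perfect tandem repeat (unit 1-6 bp, >= `min_repeats`
#' repeats, total span >= `min_span` bp) inside the 3'-terminal
#' `search_window`.  Because a tail is a terminal structure, runs are
#' accepted by chaining from the 3' end: a run qualifies if it ends within
#' `end_slack` bp of the terminus or of an already-accepted run; this keeps
#' chance micro-repeats inside the body from masquerading as tails while
#' still seeing heterogeneous tails made of adjacent tandem blocks.  Units
#' are canonicalized by lexicographically minimal rotation (so `GTTA` ==
#' `TTAG`); unit `A` yields kind `polyA`; two or more distinct qualifying
#' units yield `mixed`; none found yields `none`.
#'
#' @param consensus Consensus sequence (>= 150 bp for real elements, not
#'   enforced here).
#' @param search_window 3'-terminal span searched (bp).
#' @param min_repeats Minimum tandem repeat count.
#' @param max_unit Maximum repeat unit length (bp).
#' @param min_span Minimum total tandem span (bp).
#' @param end_slack Maximum distance (bp) between the run end and the 3'
#'   terminus.
#' @return A list of class `tail_annotation`: kind (`polyA`, `STR`, `mixed`,
#'   `none`), canonical unit, unit count, 0-based span within the consensus.
#' @export
classify_tail <- function(consensus, search_window = 60L, min_repeats = 3L,
                          max_unit = 6L, min_span = 8L, end_slack = 15L) {
  consensus <- toupper(consensus)
  L <- nchar(consensus)
  w0 <- max(0L, L - search_window)
  s <- substr(consensus, w0 + 1L, L)
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  runs <- list()
  for (u in seq_len(min(max_unit, floor(n / 2)))) {
    eqv <- chars[seq_len(n - u)] == chars[(u + 1L):n]
    r <- rle(eqv)
    re <- cumsum(r$lengths); rs <- re - r$lengths + 1L
    for (i in which(r$values)) {
      span_len <- r$lengths[i] + u          # total tandem span in bp
      reps <- floor(span_len / u)
      if (reps < min_repeats) next
      if (span_len < min_span) next
      unit <- substr(s, rs[i], rs[i] + u - 1L)
      if (.smallest_period(unit) < u) next  # keep primitive units only
      runs[[length(runs) + 1L]] <- data.frame(
        start = rs[i] - 1L, end = rs[i] - 1L + span_len,
        unit = .min_rotation(unit), unit_len = u, count = reps,
        span = span_len, stringsAsFactors = FALSE)
    }
  }
  if (length(runs) == 0L) {
    return(structure(list(kind = "none", unit = NA_character_, unit_count = 0L,
                          span = c(NA_integer_, NA_integer_)),
                     class = "tail_annotation"))
  }
  runs <- do.call(rbind, runs)
  # chain from the 3' terminus: accept runs reaching the end (or an already
  # accepted run) within end_slack bp
  runs <- runs[order(-runs$end, -runs$span), , drop = FALSE]
  frontier <- n
  acc <- NULL
  for (r in seq_len(nrow(runs))) {
    if (runs$end[r] < frontier - end_slack) next
    ov <- if (is.null(acc)) -1 else
      pmin(acc$end, runs$end[r]) - pmax(acc$start, runs$start[r])
    if (any(ov > 0.5 * pmin(if (is.null(acc)) Inf else acc$span, runs$span[r]))) next
    acc <- rbind(acc, runs[r, , drop = FALSE])
    frontier <- min(frontier, runs$start[r])
  }
  if (is.null(acc)) {
    return(structure(list(kind = "none", unit = NA_character_, unit_count = 0L,
                          span = c(NA_integer_, NA_integer_)),
                     class = "tail_annotation"))
  }
  acc <- acc[order(-acc$span, acc$unit_len, acc$start), , drop = FALSE]
  units <- unique(acc$unit)
  main <- acc[1L, ]
  kind <- if (length(units) > 1L) "mixed"
          else if (main$unit == "A") "polyA"
          else "STR"
  structure(list(kind = kind, unit = main$unit,
                 unit_count = as.integer(main$count),
                 span = c(w0 + main$start, w0 + main$end)),
            class = "tail_annotation")
}

#' @export
print.tail_annotation <- function(x, ...) {
  cat(sprintf("<tail: %s unit=%s x%d>\n", x$kind,
              ifelse(is.na(x$unit), "-", x$unit), x$unit_count))
  invisible(x)
}

#' Detect dimeric (composite) families
#'
#' For each candidate composite consensus, tests whether it is covered at
#' least `min_coverage` by a prefix aligning to one family and a suffix
#' aligning to another (each at `min_identity`), with at most `max_junction`
#' bp of gap or overlap at the junction.
#'
#' @param models List of `sine_model` objects (>= 2).
#' @param min_identity Minimum local-alignment identity for each part.
#' @param min_coverage Minimum fraction of the composite covered by the two
#'   parts.
#' @param max_junction Maximum junction gap/overlap (bp).
#' @param scoring A [scoring_scheme()].
#' @return Data.frame: composite, part1 (5'), part2 (3'), breakpoint (0-based
#'   position in the composite), coverage.
#' @export
detect_dimers <- function(models, min_identity = 0.80, min_coverage = 0.90,
                          max_junction = 30L, scoring = scoring_scheme()) {
  out <- list()
  nm <- vapply(models, function(m) m$name, "")
  for (k in seq_along(models)) {
    Lk <- models[[k]]$length
    parts <- list()
    for (i in seq_along(models)) {
      if (i == k) next
      aln <- align_local(models[[i]]$consensus, models[[k]]$consensus, scoring,
                         with_strings = FALSE)
      if (aln$identity < min_identity || aln$aligned_length < 50L) next
      parts[[length(parts) + 1L]] <- data.frame(
        part = nm[i], tstart = aln$target_span[1], tend = aln$target_span[2])
    }
    if (length(parts) < 1L) next
    parts <- do.call(rbind, parts)
    for (a in seq_len(nrow(parts))) {
      for (b in seq_len(nrow(parts))) {
        pa <- parts[a, ]; pb <- parts[b, ]
        if (pa$tstart > max_junction) next              # part1 must be a prefix
        if (Lk - pb$tend > max_junction) next           # part2 must be a suffix
        if (pb$tend <= pa$tend || pb$tstart <= pa$tstart) next
        junction <- pb$tstart - pa$tend                 # gap (+) or overlap (-)
        if (abs(junction) > max_junction) next
        covered <- (pa$tend - pa$tstart) + (pb$tend - pb$tstart) -
          max(0L, -junction)
        if (covered < min_coverage * Lk) next
        out[[length(out) + 1L]] <- data.frame(
          composite = nm[k], part1 = pa$part, part2 = pb$part,
          breakpoint = as.integer(round((pa$tend + pb$tstart) / 2)),
          coverage = covered / Lk, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(composite = character(0), part1 = character(0),
                      part2 = character(0), breakpoint = integer(0),
                      coverage = numeric(0)))
  }
  unique(do.call(rbind, out))
}

#' Full annotation of a set of families against a genome
#'
#' Runs the copy scan at both thresholds, computes age profiles, detects the
#' TSD of every non-truncated copy, classifies tails and reports dimers.
#'
#' @param genome Genome object.
#' @param models List of `sine_model`s.
#' @param scoring A [scoring_scheme()].
#' @param tsd_max_offset Passed to [detect_tsd()] (boundary-call slack).
#' @return A list: `copies80`, `copies90` (each a `genomic_copies` with a
#'   `tsd_seq`/`tsd_len` column on copies80), `age` (data.frame), `dimers`.
#' @export
annotate_families <- function(genome, models, scoring = scoring_scheme(),
                              tsd_max_offset = 12L) {
  genome <- as_genome(genome)
  c80 <- list(); c90 <- list(); age <- list()
  for (m in models) {
    a80 <- scan_copies(genome, m, 0.80, scoring)
    a90 <- a80[a80$identity >= 0.90, , drop = FALSE]
    tsd_seq <- rep(NA_character_, nrow(a80))
    tsd_len <- rep(NA_integer_, nrow(a80))
    for (r in seq_len(nrow(a80))) {
      t <- detect_tsd(genome, a80[r, ], max_offset = tsd_max_offset)
      if (!is_absent(t)) { tsd_seq[r] <- t$seq; tsd_len[r] <- t$length }
    }
    a80$tsd_seq <- tsd_seq; a80$tsd_len <- tsd_len
    c80[[m$name]] <- a80; c90[[m$name]] <- a90
    age[[m$name]] <- age_profile(a80[, setdiff(names(a80), c("tsd_seq", "tsd_len"))], a90)
  }
  list(copies80 = c80, copies90 = c90,
       age = do.call(rbind, c(age, list(make.row.names = FALSE))),
       dimers = if (length(models) >= 2L) detect_dimers(models, scoring = scoring)
                else data.frame())
}
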