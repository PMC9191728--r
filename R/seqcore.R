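# Sequence I/O, coordinate conventions, degenerate-motif matching and the
# pairwise alignment primitives shared by every other module.
#
# Conventions used throughout the package:
#   * internal coordinates are 0-based, half-open [start, end);
#   * GFF3 and Table-style reports are emitted 1-based inclusive, BED 0-based;
#   * genomes are Biostrings::DNAStringSet objects, uppercased on ingestion;
#   * N never matches any pattern base and always scores as a mismatch.

# "absent" results (no TSD, rejected cluster, ...) are empty lists carrying
# a `reason` attribute; NULL cannot hold attributes in modern R.
.absent <- function(reason) structure(list(), reason = reason, class = "absent")

#' Is a result absent (or a cluster rejected)?
#'
#' Operations that may legitimately fail ([detect_tsd()], [call_boundary()],
#' [build_consensus()]) return an empty object carrying a `reason` attribute;
#' this predicate tests for it (and treats `NULL` as absent too).
#'
#' @param x Any object.
#' @return `TRUE` if `x` is `NULL` or an absent/rejected marker.
#' @export
is_absent <- function(x) is.null(x) || (is.list(x) && length(x) == 0L)

#' @rdname is_absent
#' @return `absent_reason`: the reason string (or `NA`).
#' @export
absent_reason <- function(x) {
  r <- attr(x, "reason")
  if (is.null(r)) NA_character_ else r
}

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# 15 x 256 logical lookup: does byte b satisfy IUPAC code r?  A plain N in the
# subject never satisfies anything (including pattern N), per package policy.
.iupac_lookup <- local({
  codes <- names(IUPAC_SETS)
  m <- matrix(FALSE, nrow = length(codes), ncol = 256, dimnames = list(codes, NULL))
  for (cd in codes) {
    for (b in IUPAC_SETS[[cd]]) m[cd, utf8ToInt(b) + 1L] <- TRUE
  }
  m
})

#' Read a FASTA file into a genome object
#'
#' Wraps [Biostrings::readDNAStringSet()], uppercases every record, keeps the
#' input order and validates that no record is empty.  Header text after the
#' first whitespace is dropped so sequence names are single tokens.
#'
#' @param path Path to a (multi-)FASTA file.
#' @return A [Biostrings::DNAStringSet] with one element per record.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  x <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fasta"),
    error = function(e) stop("malformed FASTA '", path, "': ", conditionMessage(e))
  )
  if (length(x) == 0L) stop("malformed FASTA '", path, "': no records")
  names(x) <- sub("\\s.*$", "", names(x))
  if (any(names(x) == "")) stop("malformed FASTA '", path, "': empty header")
  empty <- which(Biostrings::width(x) == 0L)
  if (length(empty) > 0L) {
    stop("empty sequence in '", path, "' (record ", names(x)[empty[1L]], ")")
  }
  # DNAStringSet normalizes case; force through toupper for safety on the
  # character path used elsewhere.
  x
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector or `DNAStringSet`.
#' @param path Output path.
#' @param width Line-wrap width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (is.character(seqs)) {
    if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
    seqs <- Biostrings::DNAStringSet(seqs)
  }
  Biostrings::writeXStringSet(seqs, path, width = width)
  invisible(path)
}

#' Coerce a genome argument to a DNAStringSet
#' @param genome `DNAStringSet`, named character vector, or FASTA path.
#' @return A named `DNAStringSet`.
#' @export
as_genome <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) {
    g <- genome
  } else if (is.character(genome) && length(genome) == 1L && file.exists(genome) &&
             !grepl("^[ACGTNacgtn]+$", genome)) {
    g <- read_fasta(genome)
  } else {
    g <- Biostrings::DNAStringSet(toupper(genome))
  }
  if (is.null(names(g))) names(g) <- paste0("contig", seq_along(g))
  g
}

#' Reverse complement
#'
#' Involution over the IUPAC DNA alphabet; N maps to N.  Errors on characters
#' outside the IUPAC alphabet.
#'
#' @param seq Character vector of DNA strings.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(seq) {
  out <- tryCatch(
    as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(toupper(seq)))),
    error = function(e) stop("revcomp: non-IUPAC character in input: ", conditionMessage(e))
  )
  unname(out)
}

#' Match a window against an IUPAC degenerate pattern
#'
#' @param pattern IUPAC pattern (e.g. the canonical A-box `TRGYNNARNNG`).
#' @param window Plain DNA string of the same length.
#' @return `TRUE` iff every window base lies in the expansion of the
#'   corresponding code.  An `N` in the window never matches.
#' @export
iupac_match <- function(pattern, window) {
  iupac_mismatches(pattern, window) == 0L
}

#' Count mismatches against an IUPAC pattern
#'
#' @inheritParams iupac_match
#' @return Integer count of positions whose window base is outside the code's
#'   expansion.
#' @export
iupac_mismatches <- function(pattern, window) {
  pattern <- toupper(pattern); window <- toupper(window)
  if (nchar(pattern) != nchar(window)) {
    stop("iupac_match: pattern length ", nchar(pattern),
         " != window length ", nchar(window))
  }
  pc <- strsplit(pattern, "", fixed = TRUE)[[1L]]
  if (!all(pc %in% rownames(.iupac_lookup))) {
    stop("iupac_match: invalid IUPAC code in pattern: ",
         paste(setdiff(pc, rownames(.iupac_lookup)), collapse = ","))
  }
  wb <- utf8ToInt(window) + 1L
  sum(!.iupac_lookup[cbind(match(pc, rownames(.iupac_lookup)), wb)])
}

#' Sliding mismatch profile of an IUPAC pattern over a sequence
#'
#' Vectorized scan used by the promoter module: position i (0-based) of the
#' result is the number of pattern violations of the window starting there.
#'
#' @param seq DNA string.
#' @param pattern IUPAC pattern.
#' @return Integer vector of length `nchar(seq) - nchar(pattern) + 1` (empty
#'   when the sequence is shorter than the pattern).
#' @export
iupac_profile <- function(seq, pattern) {
  seq <- toupper(seq); pattern <- toupper(pattern)
  k <- nchar(pattern); L <- nchar(seq)
  if (L < k) return(integer(0))
  pc <- strsplit(pattern, "", fixed = TRUE)[[1L]]
  bytes <- utf8ToInt(seq) + 1L
  n <- L - k + 1L
  mm <- integer(n)
  for (j in seq_len(k)) {
    row <- .iupac_lookup[pc[j], ]
    mm <- mm + !row[bytes[j:(j + n - 1L)]]
  }
  mm
}

#' Alignment scoring scheme
#'
#' The default mirrors the package-wide convention: match +1, mismatch -1,
#' linear gap -2 per gap column (no opening cost).  `N` is scored as a
#' mismatch against everything, including another `N`.
#'
#' @param match,mismatch,gap Per-column scores; `gap` must be negative.
#' @param gap_open Additional gap opening cost (0 = linear gaps).
#' @return An object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(match = 1, mismatch = -1, gap = -2, gap_open = 0) {
  stopifnot(match > 0, mismatch < 0, gap < 0, gap_open <= 0)
  bases <- c("A", "C", "G", "T", "N")
  mat <- matrix(mismatch, 5L, 5L, dimnames = list(bases, bases))
  diag(mat) <- match
  mat["N", "N"] <- mismatch
  structure(list(match = match, mismatch = mismatch, gap = gap,
                 gap_open = gap_open, matrix = mat),
            class = "scoring_scheme")
}

# fast path: match/column counts via Biostrings C accessors, no aligned
# strings.  Only exact for N-free inputs (N==N would count as a match).
.aln_result_fast <- function(pa) {
  ncol_aln <- Biostrings::nchar(pa)
  matches <- Biostrings::nmatch(pa)
  structure(list(
    score = Biostrings::score(pa),
    aligned_length = ncol_aln,
    matches = matches,
    identity = if (ncol_aln > 0L) matches / ncol_aln else 0,
    query_span = c(IRanges::start(Biostrings::pattern(pa)) - 1L,
                   IRanges::end(Biostrings::pattern(pa))),
    target_span = c(IRanges::start(Biostrings::subject(pa)) - 1L,
                    IRanges::end(Biostrings::subject(pa))),
    query_aln = NULL, target_aln = NULL
  ), class = "alignment_result")
}

.aln_result <- function(pa, qlen, tlen) {
  sc <- Biostrings::score(pa)
  p <- as.character(Biostrings::alignedPattern(pa))
  s <- as.character(Biostrings::alignedSubject(pa))
  pc <- strsplit(p, "", fixed = TRUE)[[1L]]
  sc2 <- strsplit(s, "", fixed = TRUE)[[1L]]
  ncol_aln <- length(pc)
  matches <- sum(pc == sc2 & pc != "-" & pc != "N")
  qs <- IRanges::start(Biostrings::pattern(pa)) - 1L
  qe <- IRanges::end(Biostrings::pattern(pa))
  ts <- IRanges::start(Biostrings::subject(pa)) - 1L
  te <- IRanges::end(Biostrings::subject(pa))
  structure(list(
    score = sc,
    aligned_length = ncol_aln,
    matches = matches,
    identity = if (ncol_aln > 0L) matches / ncol_aln else 0,
    query_span = c(qs, qe),
    target_span = c(ts, te),
    query_aln = p,
    target_aln = s
  ), class = "alignment_result")
}

.empty_aln <- function() {
  structure(list(score = 0, aligned_length = 0L, matches = 0L, identity = 0,
                 query_span = c(0L, 0L), target_span = c(0L, 0L),
                 query_aln = "", target_aln = ""),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("<alignment: score %.1f, %d cols, identity %.3f, query [%d,%d), target [%d,%d)>\n",
              x$score, x$aligned_length, x$identity,
              x$query_span[1], x$query_span[2],
              x$target_span[1], x$target_span[2]))
  invisible(x)
}

.pairwise <- function(a, b, type, scoring) {
  Biostrings::pairwiseAlignment(
    pattern = a, subject = b, type = type,
    substitutionMatrix = scoring$matrix,
    gapOpening = -scoring$gap_open, gapExtension = -scoring$gap
  )
}

#' Optimal local (Smith-Waterman) alignment
#'
#' @param a,b Non-empty DNA strings.
#' @param scoring A [scoring_scheme()].
#' @param with_strings Keep the aligned (gapped) strings on the result?
#'   Setting `FALSE` skips their extraction (much faster; N-free inputs
#'   only -- falls back to the full path when an N is present).
#' @return An `alignment_result` with score, column count, match count,
#'   identity (matches / alignment columns including internal gaps) and the
#'   0-based half-open spans of both sequences.  When no positively scoring
#'   local alignment exists the empty alignment (identity 0) is returned.
#' @export
align_local <- function(a, b, scoring = scoring_scheme(), with_strings = TRUE) {
  a <- toupper(a); b <- toupper(b)
  if (nchar(a) == 0L || nchar(b) == 0L) stop("align_local: empty input sequence")
  pa <- .pairwise(a, b, "local", scoring)
  if (Biostrings::score(pa) <= 0) return(.empty_aln())
  if (!with_strings && !grepl("N", a, fixed = TRUE) && !grepl("N", b, fixed = TRUE)) {
    return(.aln_result_fast(pa))
  }
  .aln_result(pa, nchar(a), nchar(b))
}

#' Semi-global ("glocal") alignment: query end-to-end, free target ends
#'
#' Used for full-length copy detection: the whole query (consensus) must be
#' aligned, while the target may contribute any substring.
#'
#' @inheritParams align_local
#' @param query,target Non-empty DNA strings.
#' @return An `alignment_result`; `query_span` always covers the full query.
#' @export
align_glocal <- function(query, target, scoring = scoring_scheme(),
                         with_strings = TRUE) {
  query <- toupper(query); target <- toupper(target)
  if (nchar(query) == 0L || nchar(target) == 0L) stop("align_glocal: empty input sequence")
  pa <- .pairwise(query, target, "global-local", scoring)
  if (!with_strings && !grepl("N", query, fixed = TRUE) &&
      !grepl("N", target, fixed = TRUE)) {
    return(.aln_result_fast(pa))
  }
  .aln_result(pa, nchar(query), nchar(target))
}

#' Project a query position through an alignment onto the target
#'
#' Walks the aligned strings of an `alignment_result` and returns the target
#' position (0-based) corresponding to a query position; positions falling in
#' a target gap map to the next covered target position.
#'
#' @param aln An `alignment_result`.
#' @param qpos 0-based query position (may be a vector).
#' @return Integer vector of 0-based target positions (clamped to the
#'   aligned target span).
#' @export
project_position <- function(aln, qpos) {
  pc <- strsplit(aln$query_aln, "", fixed = TRUE)[[1L]]
  sc <- strsplit(aln$target_aln, "", fixed = TRUE)[[1L]]
  qcur <- aln$query_span[1]; tcur <- aln$target_span[1]
  qmap <- integer(0)
  for (i in seq_along(pc)) {
    if (pc[i] != "-") {
      qmap[qcur + 1L] <- tcur
      qcur <- qcur + 1L
    }
    if (sc[i] != "-") tcur <- tcur + 1L
  }
  out <- integer(length(qpos))
  for (i in seq_along(qpos)) {
    q <- qpos[i]
    if (q < aln$query_span[1]) out[i] <- aln$target_span[1]
    else if (q >= aln$query_span[2]) out[i] <- aln$target_span[2]
    else out[i] <- qmap[q + 1L]
  }
  out
}

#' Extract a 0-based half-open slice of a contig
#' @param genome A `DNAStringSet`.
#' @param contig Contig name.
#' @param start,end 0-based half-open bounds (clamped to the contig).
#' @param strand `"+"` or `"-"`; minus returns the reverse complement.
#' @return Character DNA string.
#' @export
genome_slice <- function(genome, contig, start, end, strand = "+") {
  g <- genome[[contig]]
  L <- length(g)
  start <- max(0L, as.integer(start)); end <- min(L, as.integer(end))
  if (end <= start) return("")
  s <- as.character(Biostrings::subseq(g, start + 1L, end))
  if (strand == "-") revcomp(s) else s
}
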