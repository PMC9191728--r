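# Planted-copy fixtures and the ungapped sliding-window scan oracle, shared
# by the annotate unit tests and the acceptance suite.

make_model <- function(consensus, name = "fam_t") {
  structure(list(name = name, consensus = consensus,
                 length = nchar(consensus), head_end = 60L,
                 tss_offset = 11L, tail = classify_tail(consensus),
                 promoter = NULL, n_members = 3L, member_loci = NULL,
                 flags = character(0)), class = "sine_model")
}

# plant copies of a consensus into a random genome at given identities
# (substitution-only, alternating strands)
plant_genome <- function(consensus, identities, glen = 60000L, seed = 1L) {
  set.seed(seed)
  L <- nchar(consensus)
  gap <- floor((glen - length(identities) * L) / (length(identities) + 1L))
  pieces <- character(0); truth <- list()
  pos <- 0L
  for (i in seq_along(identities)) {
    pieces <- c(pieces, random_dna(gap))
    pos <- pos + gap
    nsub <- round((1 - identities[i]) * L)
    strand <- if (i %% 2 == 0L) "-" else "+"
    cp <- mutate_subs(consensus, nsub)
    pieces <- c(pieces, if (strand == "+") cp else revcomp(cp))
    truth[[i]] <- data.frame(start = pos, end = pos + L, strand = strand,
                             identity = 1 - nsub / L)
    pos <- pos + L
  }
  pieces <- c(pieces, random_dna(glen - pos))
  list(genome = c(ctg = paste(pieces, collapse = "")),
       truth = do.call(rbind, truth))
}

# ungapped sliding-window oracle: all loci where the consensus matches at
# min_identity, greedy best-first overlap resolution (mirrors the package's
# copy-scan semantics for substitution-only plants)
oracle_scan <- function(genome_seq, consensus, min_identity) {
  L <- nchar(consensus)
  hits <- list()
  for (strand in c("+", "-")) {
    q <- if (strand == "+") consensus else revcomp(consensus)
    qv <- strsplit(q, "", fixed = TRUE)[[1L]]
    gv <- strsplit(genome_seq, "", fixed = TRUE)[[1L]]
    n <- length(gv) - L + 1L
    matches <- integer(n)
    for (k in seq_len(L)) {
      matches <- matches + (gv[k:(k + n - 1L)] == qv[k])
    }
    idx <- which(matches / L >= min_identity)
    if (length(idx) > 0L) {
      hits[[strand]] <- data.frame(start = idx - 1L, end = idx - 1L + L,
                                   strand = strand, identity = matches[idx] / L)
    }
  }
  out <- do.call(rbind, hits)
  if (is.null(out)) return(out)
  out <- out[order(-out$identity, out$start), ]
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))) {
    if (!keep[i]) next
    ov <- keep & seq_len(nrow(out)) > i &
      pmin(out$end, out$end[i]) - pmax(out$start, out$start[i]) > 0L
    keep[ov] <- FALSE
  }
  out[keep, ]
}
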