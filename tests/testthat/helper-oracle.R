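# Independent quadratic dynamic-programming oracles, written against the
# scoring definition only (match +1, mismatch -1, linear gap -2 by default)
# and deliberately sharing no code with the package's alignment path.

oracle_score_matrix <- function(a, b, match = 1, mismatch = -1, gap = -2,
                                mode = c("local", "glocal")) {
  mode <- match.arg(mode)
  av <- strsplit(toupper(a), "", fixed = TRUE)[[1L]]
  bv <- strsplit(toupper(b), "", fixed = TRUE)[[1L]]
  n <- length(av); m <- length(bv)
  H <- matrix(0, n + 1L, m + 1L)
  if (mode == "glocal") {
    # query (rows) must be consumed end-to-end; target ends are free
    H[, 1L] <- gap * (0:n)
    H[1L, ] <- 0
  }
  for (i in seq_len(n)) {
    s <- ifelse(bv == av[i] & av[i] != "N", match, mismatch)
    for (j in seq_len(m)) {
      v <- max(H[i, j] + s[j], H[i, j + 1L] + gap, H[i + 1L, j] + gap)
      if (mode == "local") v <- max(v, 0)
      H[i + 1L, j + 1L] <- v
    }
  }
  H
}

# optimal local alignment score (Smith-Waterman)
oracle_local_score <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  max(oracle_score_matrix(a, b, match, mismatch, gap, "local"))
}

# optimal semi-global score: full query, any target substring
oracle_glocal_score <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  H <- oracle_score_matrix(a, b, match, mismatch, gap, "glocal")
  max(H[nrow(H), ])
}

# local alignment identity via full traceback (used on small cases)
oracle_local_identity <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  av <- strsplit(toupper(a), "", fixed = TRUE)[[1L]]
  bv <- strsplit(toupper(b), "", fixed = TRUE)[[1L]]
  n <- length(av); m <- length(bv)
  H <- oracle_score_matrix(a, b, match, mismatch, gap, "local")
  best <- which(H == max(H), arr.ind = TRUE)[1L, ]
  i <- best[1L] - 1L; j <- best[2L] - 1L
  matches <- 0L; cols <- 0L
  while (i > 0L && j > 0L && H[i + 1L, j + 1L] > 0) {
    s <- if (av[i] == bv[j] && av[i] != "N") match else mismatch
    if (H[i + 1L, j + 1L] == H[i, j] + s) {
      matches <- matches + (av[i] == bv[j] && av[i] != "N")
      cols <- cols + 1L; i <- i - 1L; j <- j - 1L
    } else if (H[i + 1L, j + 1L] == H[i, j + 1L] + gap) {
      cols <- cols + 1L; i <- i - 1L
    } else {
      cols <- cols + 1L; j <- j - 1L
    }
  }
  if (cols == 0L) 0 else matches / cols
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

mutate_subs <- function(seq, nsub) {
  v <- strsplit(seq, "", fixed = TRUE)[[1L]]
  pos <- sample(length(v), nsub)
  for (p in pos) v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1L)
  paste(v, collapse = "")
}
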