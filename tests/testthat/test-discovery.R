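# Window extraction, clustering, boundary calling, consensus building.

test_that("extract_windows arithmetic, truncation and strand handling", {
  set.seed(2)
  s <- random_dna(10000)
  g <- c(ctg = s)
  anchors <- data.frame(contig = "ctg", anchor_pos = c(500L, 9900L, 700L),
                        strand = c("+", "+", "-"), source = "promoter_scan",
                        box_mismatches = 0L)
  w <- extract_windows(g, anchors, W = 1000L, U = 30L)
  w <- w[order(w$anchor_pos), ]
  # plus-strand anchor at 500: [470, 1500)
  expect_equal(c(w$start[1L], w$end[1L]), c(470L, 1500L))
  expect_false(w$truncated[1L])
  expect_equal(w$anchor_offset[1L], 30L)
  expect_equal(w$seq[1L], substr(s, 471, 1500))
  # minus-strand anchor near the contig start: clamped at 0, flagged
  expect_equal(c(w$start[2L], w$end[2L]), c(0L, 731L))
  expect_true(w$truncated[2L])
  expect_equal(w$seq[2L], revcomp(substr(s, 1L, 731L)))
  expect_equal(w$anchor_offset[2L], 30L)
  # anchor near the contig end: truncated and flagged
  expect_true(w$truncated[3L])
  expect_equal(w$end[3L], 10000L)
})

# build windows with a planted element for clustering tests; each "copy"
# carries its own mismatch-free 10-15-bp target-site duplication, like a
# real insertion
planted_windows <- function(n_copies, element, n_random = 0L, seed = 1L,
                            flank = 700L, shift = integer(n_copies)) {
  set.seed(seed)
  seqs <- character(0); anchors <- integer(0)
  for (i in seq_len(n_copies)) {
    tsd <- random_dna(sample(10:15, 1L))
    lead <- 19L + shift[i] - nchar(tsd)
    seqs <- c(seqs, paste0(random_dna(lead), tsd, element, tsd,
                           random_dna(flank - shift[i] - nchar(tsd))))
    anchors <- c(anchors, 30L)
  }
  for (i in seq_len(n_random)) {
    seqs <- c(seqs, random_dna(nchar(seqs[1L])))
    anchors <- c(anchors, 30L)
  }
  n <- length(seqs)
  w <- data.frame(
    window_id = sprintf("w%04d", seq_len(n)), contig = "ctg",
    strand = "+", anchor_pos = seq_len(n) * 5000L,
    start = seq_len(n) * 5000L - 30L, end = seq_len(n) * 5000L - 30L + nchar(seqs),
    anchor_offset = anchors, truncated = FALSE, source = "promoter_scan",
    box_mismatches = 0L, seq = seqs, stringsAsFactors = FALSE)
  class(w) <- c("anchor_windows", "data.frame")
  w
}

test_that("cluster_windows groups shared elements and ignores noise", {
  set.seed(10)
  element <- random_dna(300)
  w <- planted_windows(5L, element, n_random = 4L)
  # mutate each element copy slightly (~3%) so members differ
  for (i in 1:5) {
    piece <- substr(w$seq[i], 20L, 319L)
    w$seq[i] <- paste0(substr(w$seq[i], 1L, 19L), mutate_subs(piece, 9L),
                       substr(w$seq[i], 320L, nchar(w$seq[i])))
  }
  cl <- cluster_windows(w)
  expect_length(cl, 1L)
  expect_equal(nrow(cl[[1L]]$members), 5L)
  expect_true(all(cl[[1L]]$edges$identity >= 0.90))
  expect_true(all(cl[[1L]]$edges$overlap >= 150L))
})

test_that("clusters below min_members are discarded", {
  set.seed(11)
  w <- planted_windows(2L, random_dna(300), n_random = 3L)
  expect_length(cluster_windows(w), 0L)
})

test_that("distinct families yield distinct clusters with no cross-membership", {
  set.seed(12)
  e1 <- random_dna(300); e2 <- random_dna(300)
  w1 <- planted_windows(4L, e1, seed = 21L)
  w2 <- planted_windows(4L, e2, seed = 22L)
  w2$anchor_pos <- w2$anchor_pos + 100000L
  w2$start <- w2$start + 100000L; w2$end <- w2$end + 100000L
  w <- rbind(w1, w2)
  class(w) <- c("anchor_windows", "data.frame")
  w$window_id <- sprintf("w%04d", seq_len(nrow(w)))
  cl <- cluster_windows(w)
  expect_length(cl, 2L)
  sizes <- sort(vapply(cl, function(c) nrow(c$members), 1L))
  expect_equal(sizes, c(4L, 4L))
  ids1 <- cl[[1L]]$members$anchor_pos
  ids2 <- cl[[2L]]$members$anchor_pos
  expect_length(intersect(ids1, ids2), 0L)
})

test_that("anchor shift above the limit blocks edges", {
  set.seed(13)
  element <- random_dna(300)
  # three windows, one anchored 20 bp off inside the element
  w <- planted_windows(3L, element, shift = c(0L, 0L, 20L))
  cl <- cluster_windows(w)
  # the shifted window cannot join; 2 members < min_members -> no cluster
  expect_length(cl, 0L)
})

test_that("clustering is order-independent", {
  set.seed(14)
  e1 <- random_dna(280)
  w <- planted_windows(4L, e1, n_random = 3L)
  cl1 <- cluster_windows(w)
  perm <- sample(nrow(w))
  wp <- w[perm, ]
  class(wp) <- c("anchor_windows", "data.frame")
  cl2 <- cluster_windows(wp)
  key <- function(cl) lapply(cl, function(c) sort(c$members$anchor_pos))
  expect_equal(key(cl1), key(cl2))
})

test_that("call_boundary finds a planted element end within 10 bp", {
  set.seed(15)
  element <- random_dna(300)
  w <- planted_windows(5L, element)
  for (i in 1:5) {   # 3% divergence
    piece <- substr(w$seq[i], 20L, 319L)
    w$seq[i] <- paste0(substr(w$seq[i], 1L, 19L), mutate_subs(piece, 9L),
                       substr(w$seq[i], 320L, nchar(w$seq[i])))
  }
  cl <- cluster_windows(w)
  b <- call_boundary(cl[[1L]])
  expect_false(is_absent(b))
  expect_lt(abs(b$start - 19L), 10L)
  expect_lt(abs(b$end - 319L), 10L)
})

test_that("identical full-length windows are flagged as possible segmental duplication", {
  set.seed(16)
  seqs <- rep(random_dna(1030), 3L)
  w <- planted_windows(3L, "ACGT")   # scaffold, then overwrite seqs
  w$seq <- seqs
  w$end <- w$start + nchar(seqs)
  cl <- cluster_windows(w)
  b <- call_boundary(cl[[1L]])
  expect_true(any(grepl("no divergence", b$flags)))
  expect_equal(b$end, 1030L)
})

test_that("build_consensus recovers the majority sequence", {
  set.seed(17)
  abox <- "TGGCTTAGAGG"; bbox <- "GGTTCGAATCC"
  element <- paste0(random_dna(11), abox, random_dna(40), bbox,
                    random_dna(160), strrep("TTAG", 6L))
  w <- planted_windows(4L, element)
  # one member carries a single substitution at element position 30
  v <- strsplit(w$seq[2L], "", fixed = TRUE)[[1L]]
  pos <- 19L + 30L
  v[pos] <- setdiff(c("A", "C", "G", "T"), v[pos])[1L]
  w$seq[2L] <- paste(v, collapse = "")
  cl <- cluster_windows(w)
  b <- call_boundary(cl[[1L]])
  m <- build_consensus(cl[[1L]], b, name = "fam_t")
  expect_s3_class(m, "sine_model")
  # majority rules: the lone substitution does not reach the consensus
  expect_equal(m$consensus, element)
  expect_equal(m$tss_offset, 11L)
  expect_equal(m$tail$kind, "STR")
  expect_equal(m$tail$unit, "AGTT")  # minimal rotation of TTAG
})

test_that("simulator round trip: every planted family recovered once, boundaries tight", {
  sim <- shared_sim()
  disc <- shared_discovery()
  fams <- sim$manifest$families
  expect_length(disc$models, length(fams))
  planted <- sort(unname(vapply(fams, `[[`, 1L, "length")))
  called <- sort(unname(vapply(disc$models, `[[`, 1L, "length")))
  expect_true(all(abs(planted - called) <= 10L))
  # consensus within 1% of the planted master: the best-matching family
  # aligns with matches covering >= 99% of the shorter sequence
  for (m in disc$models) {
    best <- max(vapply(fams, function(f) {
      aln <- align_local(m$consensus, f$master, with_strings = FALSE)
      aln$matches / min(m$length, f$length)
    }, 1))
    expect_gte(best, 0.99)
  }
})

test_that("every emitted model satisfies the SINE structure criteria", {
  disc <- shared_discovery()
  ann <- shared_annotation()
  for (m in disc$models) {
    expect_gte(m$length, 150L)                        # minimum length
    expect_equal(nrow(m$promoter), 1L)                # Pol III promoter present
    expect_gte(m$n_members, 3L)                       # >= 3 genomic copies
    expect_gte(m$tss_offset, 0L)
    cp <- ann$copies80[[m$name]]
    expect_gte(sum(!cp$truncated), 3L)
    expect_gt(sum(!is.na(cp$tsd_len)), 0L)            # TSD-flanked copies exist
  }
})
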