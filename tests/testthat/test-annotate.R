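# Copy scanning, age profiles, TSDs, tails, dimers.
# (make_model / plant_genome / oracle_scan live in helper-plant.R)

test_that("scan_copies matches planted copies and the sliding oracle", {
  set.seed(30)
  consensus <- random_dna(300)
  pg <- plant_genome(consensus, c(0.95, 0.95, 0.95, 0.95, 0.95, 0.95, 0.95,
                                  0.85, 0.85, 0.85), seed = 31L)
  model <- make_model(consensus)
  c90 <- scan_copies(pg$genome, model, 0.90)
  c80 <- scan_copies(pg$genome, model, 0.80)
  expect_equal(nrow(c90), 7L)
  expect_equal(nrow(c80), 10L)
  # loci and identities equal the independent ungapped oracle
  o80 <- oracle_scan(pg$genome[["ctg"]], consensus, 0.80)
  o80 <- o80[order(o80$start), ]
  expect_equal(c80$start, o80$start)
  expect_equal(c80$end, o80$end)
  expect_equal(c80$strand, o80$strand)
  expect_equal(c80$identity, o80$identity, tolerance = 1e-9)
})

test_that("random genomes produce no copies at either threshold", {
  set.seed(32)
  consensus <- random_dna(250)
  model <- make_model(consensus)
  for (seed in 1:3) {
    set.seed(seed * 97L)
    g <- c(ctg = random_dna(50000))
    expect_equal(nrow(scan_copies(g, model, 0.80)), 0L)
  }
})

test_that("scan at 0.90 is a subset of scan at 0.80", {
  sim <- shared_sim()
  disc <- shared_discovery()
  for (m in disc$models) {
    c80 <- scan_copies(sim$genome, m, 0.80)
    c90 <- scan_copies(sim$genome, m, 0.90)
    k80 <- paste(c80$contig, c80$start, c80$end)
    k90 <- paste(c90$contig, c90$start, c90$end)
    expect_true(all(k90 %in% k80))
    # re-verification: every reported copy realigns at threshold
    for (r in seq_len(min(nrow(c80), 10L))) {
      tgt <- genome_slice(sim$genome, c80$contig[r], c80$start[r] - 20L,
                          c80$end[r] + 20L)
      q <- if (c80$strand[r] == "+") m$consensus else revcomp(m$consensus)
      expect_gte(align_glocal(q, tgt, with_strings = FALSE)$identity, 0.80)
    }
  }
})

test_that("age_profile arithmetic and degenerate flag", {
  c80 <- data.frame(family = "f", truncated = rep(FALSE, 100))
  c90 <- data.frame(family = "f", truncated = rep(FALSE, 40))
  a <- age_profile(c80, c90)
  expect_equal(a$young_fraction, 0.40)
  a2 <- age_profile(c80[1:5, ], c80[1:5, ])
  expect_equal(a2$young_fraction, 1)
  a3 <- age_profile(c80[0, ], c90[0, ])
  expect_equal(a3$young_fraction, 0)
  expect_true(a3$degenerate)
  expect_error(age_profile(data.frame(family = c("a", "b"),
                                      truncated = FALSE), c90),
               "more than one family")
})

test_that("detect_tsd finds planted duplications and honors thresholds", {
  set.seed(33)
  tsd <- "GGATTACCGGAT"      # 12-mer
  copy <- random_dna(200)
  g <- c(ctg = paste0(random_dna(50), tsd, copy, tsd, random_dna(50)))
  locus <- data.frame(contig = "ctg", start = 62L, end = 262L)
  t <- detect_tsd(g, locus)
  expect_equal(t$length, 12L)
  expect_equal(t$seq, tsd)
  expect_equal(t$left, c(50L, 62L))
  expect_equal(t$right, c(262L, 274L))
  # 8-bp identical flank is below min_len
  g2 <- c(ctg = paste0(random_dna(50), "ACGTACGT", copy, "ACGTACGT",
                       random_dna(50)))
  locus2 <- data.frame(contig = "ctg", start = 58L, end = 258L)
  expect_true(is_absent(detect_tsd(g2, locus2)))
  # insufficient flank
  g3 <- c(ctg = paste0("ACGT", copy, random_dna(60)))
  absent3 <- detect_tsd(g3, data.frame(contig = "ctg", start = 4L, end = 204L))
  expect_true(is_absent(absent3))
  expect_match(absent_reason(absent3), "insufficient flank")
})

test_that("simulator TSDs are recovered exactly at truth loci", {
  sim <- shared_sim()
  cp <- sim$manifest$copies
  for (r in seq_len(nrow(cp))) {
    t <- detect_tsd(sim$genome, cp[r, ], max_offset = 0L)
    expect_false(is_absent(t), info = cp$copy_id[r])
    expect_equal(t$length, cp$tsd_len[r], info = cp$copy_id[r])
    expect_equal(t$seq, cp$tsd_seq[r], info = cp$copy_id[r])
    expect_equal(t$mismatches, 0L)
  }
})

test_that("classify_tail recognizes STR, polyA, none and mixed", {
  base <- random_dna(160)
  t1 <- classify_tail(paste0(base, strrep("TTAG", 4L)))
  expect_equal(t1$kind, "STR")
  expect_equal(t1$unit, "AGTT")
  expect_equal(t1$unit_count, 4L)
  t2 <- classify_tail(paste0(base, strrep("A", 12L)))
  expect_equal(t2$kind, "polyA")
  expect_equal(t2$unit_count, 12L)
  t3 <- classify_tail(paste0(base, "ACGTACGATCGT"))
  expect_equal(t3$kind, "none")
  t4 <- classify_tail(paste0(base, strrep("CA", 6L), strrep("TTAG", 4L)))
  expect_equal(t4$kind, "mixed")
  # canonicalization: GTTA runs report the same unit as TTAG runs
  t5 <- classify_tail(paste0(base, "G", strrep("TTAG", 4L)))
  expect_equal(t5$unit, "AGTT")
})

test_that("detect_dimers flags constructed composites only", {
  set.seed(34)
  m1 <- make_model(paste0(random_dna(239), strrep("TTAG", 4)), "p1")
  m2 <- make_model(paste0(random_dna(240), strrep("CA", 8)), "p2")
  dimer <- make_model(paste0(m1$consensus, m2$consensus), "dim")
  d <- detect_dimers(list(m1, m2, dimer))
  expect_equal(nrow(d), 1L)
  expect_equal(d$composite, "dim")
  expect_equal(d$part1, "p1")
  expect_equal(d$part2, "p2")
  expect_lt(abs(d$breakpoint - m1$length), 15L)
  expect_equal(nrow(detect_dimers(list(m1, m2))), 0L)
  # 5% diverged dimer still detected
  dim2 <- make_model(mutate_subs(paste0(m1$consensus, m2$consensus), 25L), "dim2")
  d2 <- detect_dimers(list(m1, m2, dim2))
  expect_true("dim2" %in% d2$composite)
})
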