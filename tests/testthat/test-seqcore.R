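# Sequence I/O, motif matching and the alignment primitives.

test_that("read_fasta parses, uppercases and validates", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "acgt"), f)
  x <- read_fasta(f)
  expect_equal(length(x), 1L)
  expect_equal(names(x), "a")
  expect_equal(as.character(x[[1L]]), "ACGT")

  writeLines(c(">a", "AC", "GT", ">b", "NNN"), f)
  x <- read_fasta(f)
  expect_equal(unname(Biostrings::width(x)), c(4L, 3L))

  writeLines(c(">a", ""), f)
  expect_error(read_fasta(f), "empty sequence.*a")
})

test_that("revcomp handles IUPAC and N, and is an involution", {
  expect_equal(revcomp("ACGT"), "ACGT")
  expect_equal(revcomp("AAAC"), "GTTT")
  expect_equal(revcomp("ANT"), "ANT")
  expect_error(revcomp("ACGX"), "non-IUPAC")
  set.seed(7)
  seqs <- vapply(1:10000, function(i) random_dna(sample(5:60, 1L)), "")
  expect_identical(revcomp(revcomp(seqs)), seqs)
})

test_that("iupac_match follows code expansions", {
  expect_true(iupac_match("TRGYNNARNNG", "TGGCAAAGTTG"))
  expect_true(iupac_match("RGTTCRANTCC", "GGTTCGAATCC"))
  expect_false(iupac_match("TRGYNNARNNG", "TTGCAAAGTTG"))  # pos 2: R != T
  expect_error(iupac_match("TRG", "TRGY"), "length")
  # window N never matches, even pattern N
  expect_false(iupac_match("N", "N"))
  expect_equal(iupac_mismatches("TRGYNNARNNG", "TGGCAAAGTTG"), 0L)
  expect_equal(iupac_mismatches("TRGYNNARNNG", "TTGCAAAGTTG"), 1L)
})

test_that("iupac_profile equals per-window iupac_mismatches", {
  set.seed(3)
  s <- random_dna(300)
  pat <- "TRGYNNARNNG"
  prof <- iupac_profile(s, pat)
  expect_length(prof, 300 - 11 + 1)
  idx <- sample(length(prof), 40)
  manual <- vapply(idx, function(i)
    iupac_mismatches(pat, substr(s, i, i + 10L)), 1L)
  expect_equal(prof[idx], manual)
})

test_that("align_local basics", {
  a <- align_local("ACGT", "ACGT")
  expect_equal(a$identity, 1)
  expect_equal(a$aligned_length, 4L)
  b <- align_local("ACGTACGT", "TTTACGTACGTTTT")
  expect_equal(b$identity, 1)
  expect_equal(b$aligned_length, 8L)
  expect_equal(b$target_span, c(3L, 11L))
  expect_error(align_local("", "ACGT"), "empty")
  # no positive-scoring alignment -> empty result
  z <- align_local("AAAA", "CCCC")
  expect_equal(z$identity, 0)
  expect_equal(z$aligned_length, 0L)
})

test_that("align_local matches the independent DP oracle on planted substitutions", {
  set.seed(42)
  for (rep in 1:5) {
    a <- random_dna(200)
    b <- mutate_subs(a, 10L)
    aln <- align_local(a, b)
    expect_equal(aln$score, oracle_local_score(a, b))
    expect_equal(aln$identity, oracle_local_identity(a, b), tolerance = 1e-9)
  }
})

test_that("align_glocal aligns the query end-to-end with free target ends", {
  a <- align_glocal("ACGTACGT", "GGACGTACGTGG")
  expect_equal(a$identity, 1)
  expect_equal(a$target_span, c(2L, 10L))
  expect_equal(a$query_span, c(0L, 8L))
  q <- "ACGTACGTAC"
  t <- paste0("GGGG", mutate_subs(q, 1L), "GGGG")
  expect_equal(align_glocal(q, t)$identity, 0.9)
})

test_that("alignment engines agree with the DP oracle on random pairs <= 60 bp", {
  set.seed(101)
  for (rep in 1:120) {
    a <- random_dna(sample(5:60, 1L))
    b <- random_dna(sample(5:60, 1L))
    expect_equal(align_local(a, b)$score, oracle_local_score(a, b),
                 info = paste(a, b))
    expect_equal(align_glocal(a, b)$score, oracle_glocal_score(a, b),
                 info = paste(a, b))
  }
})

test_that("identity bounds hold and identity 1 implies equal spans", {
  set.seed(5)
  for (rep in 1:60) {
    a <- random_dna(sample(10:80, 1L))
    b <- if (rep %% 3 == 0) a else random_dna(sample(10:80, 1L))
    aln <- align_local(a, b)
    expect_gte(aln$identity, 0)
    expect_lte(aln$identity, 1)
    expect_lte(aln$matches, aln$aligned_length)
    if (aln$aligned_length > 0L) {
      qa <- substr(a, aln$query_span[1] + 1L, aln$query_span[2])
      ta <- substr(b, aln$target_span[1] + 1L, aln$target_span[2])
      if (aln$identity == 1) expect_identical(qa, ta)
    }
  }
})

test_that("fast alignment path equals the string path", {
  set.seed(9)
  for (rep in 1:25) {
    a <- random_dna(120); b <- mutate_subs(a, sample(0:20, 1L))
    full <- align_local(a, b)
    fast <- align_local(a, b, with_strings = FALSE)
    expect_equal(fast$score, full$score)
    expect_equal(fast$matches, full$matches)
    expect_equal(fast$aligned_length, full$aligned_length)
    g1 <- align_glocal(a, b); g2 <- align_glocal(a, b, with_strings = FALSE)
    expect_equal(g2$identity, g1$identity)
  }
})

test_that("project_position maps query onto target through gaps", {
  aln <- align_glocal("ACGTACGT", "GGACGTACGTGG")
  expect_equal(project_position(aln, c(0L, 4L, 7L)), c(2L, 6L, 9L))
})

test_that("genome_slice respects bounds and strand", {
  g <- as_genome(c(chr = "ACGTACGTAC"))
  expect_equal(genome_slice(g, "chr", 2, 6), "GTAC")
  expect_equal(genome_slice(g, "chr", 2, 6, "-"), revcomp("GTAC"))
  expect_equal(genome_slice(g, "chr", -5, 3), "ACG")
  expect_equal(genome_slice(g, "chr", 8, 99), "AC")
})
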