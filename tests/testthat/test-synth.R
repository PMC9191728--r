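# The synthetic-data generator and its ground-truth manifest.

tiny_cfg <- function(seed = 21L, ...) {
  sim_config(seed = seed, genome_length = 2e5, n_contigs = 1L,
             copy_counts = c(4L, 6L), divergence_max = c(0.02, 0.05),
             degenerate_fraction = 0, n_genes = 2L,
             n_sine_reads = 80L, n_background_reads = 20L,
             n_decoy_reads = 20L, ...)
}

test_that("simulate_genome is byte-deterministic given the seed", {
  s1 <- simulate_genome(tiny_cfg())
  s2 <- simulate_genome(tiny_cfg())
  expect_identical(as.character(s1$genome), as.character(s2$genome))
  expect_identical(s1$manifest$copies, s2$manifest$copies)
  s3 <- simulate_genome(tiny_cfg(seed = 22L))
  expect_false(identical(as.character(s1$genome), as.character(s3$genome)))
})

test_that("zero-divergence copies are exact master substrings with intact TSDs", {
  cfg <- tiny_cfg()
  cfg$divergence_max <- c(0, 0)
  sim <- simulate_genome(cfg)
  cp <- sim$manifest$copies
  for (r in seq_len(nrow(cp))) {
    fam <- sim$manifest$families[[cp$family[r]]]
    extracted <- genome_slice(sim$genome, cp$contig[r], cp$start[r],
                              cp$end[r], cp$strand[r])
    expect_identical(extracted, fam$master)
    # TSD instances flank the copy on the plus strand
    left <- genome_slice(sim$genome, cp$contig[r],
                         cp$start[r] - cp$tsd_len[r], cp$start[r])
    right <- genome_slice(sim$genome, cp$contig[r], cp$end[r],
                          cp$end[r] + cp$tsd_len[r])
    expect_identical(left, cp$tsd_seq[r])
    expect_identical(right, cp$tsd_seq[r])
  }
})

test_that("planted structure obeys the stated invariants", {
  sim <- shared_sim()
  man <- sim$manifest
  for (f in man$families) {
    expect_gte(f$length, 150L)
    expect_equal(f$tss_offset, 11L)
    expect_equal(f$abox, c(11L, 22L))
    abox_seq <- substr(f$master, 12L, 22L)
    bbox_seq <- substr(f$master, f$bbox[1L] + 1L, f$bbox[2L])
    expect_true(iupac_match(ABOX_PATTERN, abox_seq))
    expect_true(iupac_match(BBOX_PATTERN, bbox_seq))
    expect_gte(f$spacing, 30L); expect_lte(f$spacing, 60L)
  }
  cp <- man$copies
  expect_true(all(cp$tsd_len >= 10L & cp$tsd_len <= 15L))
  expect_true(all(cp$divergence >= 0 & cp$divergence <= 0.35))
  # loci pairwise disjoint
  cp <- cp[order(cp$contig, cp$start), ]
  same <- cp$contig[-1L] == cp$contig[-nrow(cp)]
  expect_true(all(cp$start[-1L][same] >= cp$end[-nrow(cp)][same]))
  # mutated identity bookkeeping
  expect_equal(cp$identity,
               1 - round(cp$divergence * nchar(cp$seq)) / nchar(cp$seq))
})

test_that("capacity violations error out before writing", {
  cfg <- tiny_cfg()
  cfg$genome_length <- 1e4
  expect_error(simulate_genome(cfg), "too small")
})

test_that("intron copies are placed inside introns of distinct genes", {
  sim <- shared_sim()
  cp <- sim$manifest$copies
  ig <- cp[!is.na(cp$gene_id), ]
  expect_equal(nrow(ig), length(sim$manifest$families))
  expect_equal(anyDuplicated(ig$gene_id), 0L)
  expect_equal(anyDuplicated(ig$family), 0L)
  introns <- gene_introns(sim$genes)
  for (r in seq_len(nrow(ig))) {
    sel <- introns$gene_id == ig$gene_id[r] &
      introns$start <= ig$start[r] & introns$end >= ig$end[r]
    expect_true(any(sel), info = ig$copy_id[r])
  }
})

test_that("read generation respects origins and orientation bookkeeping", {
  sim <- shared_sim()
  reads <- sim$manifest$reads
  expect_true(all(nchar(reads$seq) >= 26L & nchar(reads$seq) <= 31L))
  sine <- reads[reads$origin == "sine", ]
  fams <- sim$manifest$families
  cp <- sim$manifest$copies
  idx <- sample(nrow(sine), 25L)
  for (r in idx) {
    copy <- cp[cp$copy_id == sine$copy_id[r], ]
    probe <- if (sine$orientation[r] == "F") sine$seq[r] else revcomp(sine$seq[r])
    expect_true(grepl(probe, copy$seq, fixed = TRUE), info = sine$copy_id[r])
    # never from the head
    head_part <- substr(copy$seq, 1L, fams[[copy$family]]$head_end)
    expect_false(grepl(probe, head_part, fixed = TRUE))
  }
  # decoys come from heads only
  dec <- reads[reads$origin == "decoy", ]
  for (r in sample(nrow(dec), 15L)) {
    copy <- cp[cp$copy_id == dec$copy_id[r], ]
    head_part <- substr(copy$seq, 1L, fams[[copy$family]]$head_end)
    expect_true(grepl(dec$seq[r], head_part, fixed = TRUE))
  }
  # background reads never occur in gene spans (either orientation)
  bg <- reads[reads$origin == "background", ]
  spans <- vapply(seq_len(nrow(sim$genes$genes)), function(i) {
    g <- sim$genes$genes[i, ]
    genome_slice(sim$genome, g$contig, g$start, g$end)
  }, "")
  for (r in sample(nrow(bg), 15L)) {
    expect_false(any(vapply(spans, function(s)
      grepl(bg$seq[r], s, fixed = TRUE) ||
        grepl(revcomp(bg$seq[r]), s, fixed = TRUE), TRUE)))
  }
})

test_that("background-only genomes yield zero families", {
  for (sd in c(101L, 202L, 303L)) {
    cfg <- sim_config(seed = sd, genome_length = 2e5, n_contigs = 1L,
                      copy_counts = c(0L, 0L), divergence_max = c(0, 0),
                      n_genes = 2L, n_sine_reads = 0L,
                      n_background_reads = 0L, n_decoy_reads = 0L)
    sim <- simulate_genome(cfg)
    disc <- discover_families(sim$genome)
    expect_length(disc$models, 0L)
  }
})

test_that("write_sim emits the standard files round-trippably", {
  dir <- tempfile("simout")
  sim <- shared_sim()
  write_sim(sim, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "genome.fa", "genes.gff3", "reads.fa", "manifest.json", "copies.tsv")))))
  g <- read_fasta(file.path(dir, "genome.fa"))
  expect_identical(as.character(g), as.character(sim$genome))
  gm <- read_gff3_genes(file.path(dir, "genes.gff3"))
  expect_equal(gm$genes$gene_id, sim$genes$genes$gene_id)
  expect_equal(gm$genes$start, sim$genes$genes$start)
  expect_equal(gm$exons$start, sim$genes$exons$start)
  reads <- read_small_reads(file.path(dir, "reads.fa"))
  expect_length(reads, length(sim$reads_expanded))
  unlink(dir, recursive = TRUE)
})
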