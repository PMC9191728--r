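# Length filtering, head masking, zero-mismatch mapping, gene counting,
# cluster calling, pool selection.

test_that("filter_lengths drops out-of-range reads and collapses duplicates", {
  reads <- c("A", strrep("A", 25), strrep("C", 26), strrep("G", 31),
             strrep("T", 32), rep(strrep("AC", 14), 5))
  f <- filter_lengths(reads)
  expect_equal(sum(f$multiplicity), 7L)              # 26-mer, 31-mer, 5x 28-mer
  expect_equal(nrow(f), 3L)
  expect_equal(f$multiplicity[f$seq == strrep("AC", 14)], 5L)
  expect_equal(attr(f, "dropped_length"), 3L)
  bad <- filter_lengths(c(strrep("X", 28), strrep("A", 28)))
  expect_equal(attr(bad, "dropped_invalid"), 1L)
  expect_equal(nrow(filter_lengths(character(0))), 0L)
})

test_that("mask_trna removes the head and validates bounds", {
  seq <- random_dna(306)
  expect_equal(mask_trna(seq, head_end = 80L), substr(seq, 81, 306))
  expect_equal(nchar(mask_trna(seq, head_end = 80L)), 226L)
  expect_equal(mask_trna(seq, head_end = 0L), seq)
  expect_error(mask_trna(seq, head_end = 306L), "head_end")
})

test_that("map_exact reports every occurrence in both orientations", {
  set.seed(50)
  tgt <- c(t1 = random_dna(5000))
  read <- substr(tgt[["t1"]], 1001, 1028)
  reads <- filter_lengths(c(read, revcomp(read)))
  h <- map_exact(reads, tgt)
  expect_equal(nrow(h), 2L)
  expect_setequal(h$orientation, c("F", "R"))
  expect_equal(unique(h$offset), 1000L)
  # every hit re-verifies character-for-character
  for (r in seq_len(nrow(h))) {
    sub <- substr(tgt[[h$target[r]]], h$offset[r] + 1L,
                  h$offset[r] + nchar(h$seq[r]))
    expect_true(sub == h$seq[r] || sub == revcomp(h$seq[r]))
  }
})

test_that("map_exact equals a naive substring-scan oracle", {
  set.seed(51)
  tgt <- c(t1 = random_dna(10000))
  # reads: some sliced from the target (with repeats), some random
  reads <- c(vapply(1:40, function(i) {
    s <- sample(9970, 1L); substr(tgt[["t1"]], s, s + sample(25:30, 1L))
  }, ""), vapply(1:40, function(i) random_dna(sample(26:31, 1L)), ""))
  rc <- filter_lengths(reads)
  hits <- map_exact(rc, tgt)
  naive <- list()
  for (r in seq_len(nrow(rc))) {
    for (ori in c("F", "R")) {
      pat <- if (ori == "F") rc$seq[r] else revcomp(rc$seq[r])
      offs <- gregexpr(pat, tgt[["t1"]], fixed = TRUE)[[1L]]
      # gregexpr misses overlapping occurrences; step through manually
      offs <- integer(0); from <- 1L
      repeat {
        p <- regexpr(pat, substr(tgt[["t1"]], from, nchar(tgt[["t1"]])),
                     fixed = TRUE)
        if (p < 0L) break
        offs <- c(offs, from + p - 2L)
        from <- from + p
      }
      for (o in offs) {
        naive[[length(naive) + 1L]] <- data.frame(
          seq = rc$seq[r], target = "t1", offset = o, orientation = ori)
      }
    }
  }
  naive <- do.call(rbind, naive)
  naive <- naive[order(naive$target, naive$offset, naive$orientation, naive$seq), ]
  expect_equal(nrow(hits), nrow(naive))
  expect_equal(hits$offset, naive$offset)
  expect_equal(hits$seq, naive$seq)
  expect_equal(hits$orientation, naive$orientation)
})

test_that("count_by_gene weights by multiplicity, splits strands, excludes exons", {
  glen <- 3000L
  set.seed(52)
  gseq <- random_dna(glen)
  genome_hits <- function(reads_df) map_exact(reads_df, c(chr = gseq))
  genes <- sinescout:::.gene_models(
    data.frame(gene_id = "g1", gene_name = "gene one", contig = "chr",
               start = 100L, end = 2900L, strand = "+"),
    data.frame(gene_id = "g1", contig = "chr",
               start = c(100L, 2500L), end = c(400L, 2900L)))
  intronic <- substr(gseq, 1001, 1028)     # inside the intron [400, 2500)
  exonic <- substr(gseq, 151, 178)         # inside exon 1
  reads <- data.frame(seq = c(intronic, revcomp(intronic), exonic),
                      multiplicity = c(7L, 2L, 3L))
  class(reads) <- c("small_reads", "data.frame")
  cnt <- count_by_gene(genome_hits(reads), genes)
  expect_equal(nrow(cnt), 1L)
  expect_equal(cnt$forward, 7L)
  expect_equal(cnt$reverse, 2L)
  expect_equal(cnt$total, 9L)
  expect_equal(attr(cnt, "exon_violations"), 3L)
  validate_count_records(cnt)
})

test_that("call_clusters finds dense regions and merges windows", {
  set.seed(53)
  g <- random_dna(100000)
  # 50 distinct reads from one 3-kb region
  reads <- vapply(1:50, function(i) {
    s <- 40000L + sample(2970L, 1L); substr(g, s, s + 27L)
  }, "")
  rc <- filter_lengths(reads)
  hits <- map_exact(rc, c(chr = g))
  cl <- call_clusters(hits, c(chr = 100000L))
  expect_equal(nrow(cl), 1L)
  expect_lte(cl$start, 40000L)
  expect_gte(cl$end, 42900L)
  # sparse background below the density threshold: no clusters
  sparse <- vapply(1:8, function(i) {
    s <- sample(99000L, 1L); substr(g, s, s + 27L)
  }, "")
  h2 <- map_exact(filter_lengths(sparse), c(chr = g))
  expect_equal(nrow(call_clusters(h2, c(chr = 100000L), min_unique = 5L,
                                  min_density = 0.002)), 0L)
  # two dense regions far apart give two clusters
  reads2 <- c(reads, vapply(1:50, function(i) {
    s <- 80000L + sample(2970L, 1L); substr(g, s, s + 27L)
  }, ""))
  h3 <- map_exact(filter_lengths(reads2), c(chr = g))
  expect_equal(nrow(call_clusters(h3, c(chr = 100000L))), 2L)
})

test_that("select_sine_related keeps cluster reads matching the masked db, idempotently", {
  set.seed(54)
  g <- random_dna(50000)
  copy_body <- substr(g, 20000, 20400)
  head_region <- substr(g, 19800, 19999)
  db <- c(`fam:chr:19800-20400` = copy_body)    # masked: body only
  body_reads <- vapply(1:30, function(i) {
    s <- sample(370L, 1L); substr(copy_body, s, s + 27L)
  }, "")
  head_reads <- vapply(1:10, function(i) {
    s <- sample(170L, 1L); substr(head_region, s, s + 27L)
  }, "")
  reads <- filter_lengths(c(body_reads, head_reads))
  hits <- map_exact(reads, c(chr = g))
  clusters <- data.frame(contig = "chr", start = 19000L, end = 21000L)
  pool <- select_sine_related(reads, hits, clusters, db)
  expect_true(all(pool$seq %in% c(body_reads, revcomp(body_reads))))
  expect_false(any(pool$seq %in% head_reads))    # tRNA-head reads excluded
  expect_equal(attr(pool, "n_total"), sum(pool$multiplicity))
  pool2 <- select_sine_related(pool, hits, clusters, db)
  expect_equal(pool2$seq, pool$seq)              # idempotent
  expect_true(all(pool$seq %in% reads$seq))      # subset of cluster reads
})

test_that("build_copy_db masks heads through the alignment, excludes head-only copies", {
  sim <- shared_sim()
  disc <- shared_discovery()
  ann <- shared_annotation()
  db <- build_copy_db(sim$genome, disc$models, ann$copies80)
  expect_gt(length(db), 0L)
  # no masked entry contains a long exact chunk of its family's head
  models <- disc$models
  names(models) <- vapply(models, `[[`, "", "name")
  for (id in names(db)[seq_len(min(10L, length(db)))]) {
    fam <- strsplit(id, ":", fixed = TRUE)[[1L]][1L]
    head_seq <- substr(models[[fam]]$consensus, 1L, models[[fam]]$head_end)
    expect_false(grepl(substr(head_seq, 20L, 60L), db[[id]], fixed = TRUE))
  }
})

test_that("per-gene counts equal the simulator manifest exactly", {
  sim <- shared_sim()
  cfg <- shared_cfg()
  reads <- filter_lengths(sim$reads_expanded)
  hits <- map_exact(reads, sim$genome)
  cnt <- count_by_gene(hits, sim$genes)
  validate_count_records(cnt)
  truth <- sim$manifest$gene_truth
  expect_equal(nrow(cnt), nrow(truth))
  m <- match(truth$gene_id, cnt$gene_id)
  expect_false(anyNA(m))
  expect_equal(cnt$forward[m], truth$forward)
  expect_equal(cnt$reverse[m], truth$reverse)
  expect_equal(cnt$total[m], truth$total)
  expect_equal(attr(cnt, "exon_violations"), 0L)
})

test_that("decoy (tRNA-head) reads never hit the masked copy database", {
  sim <- shared_sim()
  disc <- shared_discovery()
  ann <- shared_annotation()
  db <- build_copy_db(sim$genome, disc$models, ann$copies80)
  decoys <- sim$manifest$reads[sim$manifest$reads$origin == "decoy", ]
  dec <- filter_lengths(rep(decoys$seq, decoys$multiplicity))
  hits <- map_exact(dec, db)
  expect_equal(nrow(hits), 0L)
})

test_that("the bundled worked-example count table is internally consistent", {
  path <- system.file("extdata", "bgermanica_top20_gene_counts.tsv",
                      package = "sinescout")
  tab <- read_count_report(path)
  expect_equal(nrow(tab), 20L)
  expect_silent(validate_count_records(tab))
  expect_true(all(tab$total == tab$forward + tab$reverse))
  expect_equal(tab$total, sort(tab$total, decreasing = TRUE))
  expect_equal(tab$total[1L], 3557L)
  expect_equal(tab$forward[1L], 1798L)
  expect_equal(tab$reverse[1L], 1759L)
})
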