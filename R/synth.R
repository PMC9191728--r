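# Seeded synthetic-data generator: a multi-megabase genome with planted
# tRNA-head SINE families (canonical A/B boxes, random bodies, poly(A)/STR
# tails, graded copy divergence, 10-15-bp TSDs, a subset of copies inside
# introns of synthetic genes) plus 26-31-nt small-RNA reads with a full
# ground-truth manifest.

.DNA <- c("A", "C", "G", "T")

.random_dna <- function(n) paste(sample(.DNA, n, replace = TRUE), collapse = "")

# concrete instance of an IUPAC pattern
.sample_iupac <- function(pattern) {
  pc <- strsplit(pattern, "", fixed = TRUE)[[1L]]
  paste(vapply(pc, function(cd) sample(IUPAC_SETS[[cd]], 1L), ""), collapse = "")
}

# substitution-only mutation: round(d * L) positions changed to a different
# base, so identity to the source is exactly 1 - round(d*L)/L
.mutate <- function(seq, divergence) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  L <- length(chars)
  nsub <- round(divergence * L)
  if (nsub > 0L) {
    pos <- sample.int(L, nsub)
    for (p in pos) chars[p] <- sample(setdiff(.DNA, chars[p]), 1L)
  }
  paste(chars, collapse = "")
}

#' Simulation configuration
#'
#' Defaults describe the world the pipeline assumes: a 2-Mb genome over two
#' contigs; four families with copy counts 3/10/30/100 whose young copies
#' diverge up to 2/4/6/8% (small families young, mirroring the observed age
#' structure where the rarest family is the most recent); an additional
#' `degenerate_fraction` of copies at 10-18% divergence providing the
#' 80%-but-not-90% identity class; 10-15-bp TSDs; one intron-resident copy
#' per family, each in a distinct 4-exon gene (so a read from one family maps
#' into exactly one gene); and 26-31-nt reads from copy bodies on both
#' strands plus random background and tRNA-head decoys.
#'
#' @param seed Integer RNG seed (drives every random choice).
#' @param genome_length Total genome size (bp), split over `n_contigs`.
#' @param n_contigs Number of contigs.
#' @param copy_counts Integer vector, one entry per family.
#' @param divergence_max Per-family upper bound of young-copy divergence.
#' @param degenerate_fraction Fraction of copies drawn at 10-18% divergence.
#' @param body_length_range Range of random body lengths (bp).
#' @param tail_units Pool of tail repeat units (family i uses unit i,
#'   recycled); `"A"` yields a poly(A) tail.
#' @param tail_repeats_range Range of tandem repeat counts.
#' @param tsd_len_range TSD length range (bp), canonically 10-15.
#' @param min_copy_spacing Minimum bp between insertion points, kept above
#'   the discovery window span so neighbouring copies never share a window.
#' @param n_genes Number of synthetic 4-exon genes.
#' @param exon_length_range,intron_length_range Gene geometry (bp); introns
#'   exceed 1 kb so full-length copies fit.
#' @param intron_copies_per_family Copies planted inside gene introns (at
#'   most one per family, each family in its own gene).
#' @param n_sine_reads,n_background_reads,n_decoy_reads Read counts.
#' @param read_length_range Read length range (nt), canonically 26-31.
#' @param forward_fraction Probability a SINE-derived read is sense.
#' @param multiplicity_max Read multiplicities are uniform on
#'   1..`multiplicity_max`.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, genome_length = 2e6, n_contigs = 2L,
                       copy_counts = c(3L, 10L, 30L, 100L),
                       divergence_max = c(0.02, 0.04, 0.06, 0.08),
                       degenerate_fraction = 0.25,
                       body_length_range = c(120L, 260L),
                       tail_units = c("A", "TTAG", "CA", "ACCTTT", "TGGAA", "TCAGA"),
                       tail_repeats_range = c(5L, 8L),
                       tsd_len_range = c(10L, 15L),
                       min_copy_spacing = 1200L,
                       n_genes = 8L, exon_length_range = c(200L, 400L),
                       intron_length_range = c(1200L, 2500L),
                       intron_copies_per_family = 1L,
                       n_sine_reads = 1500L, n_background_reads = 400L,
                       n_decoy_reads = 200L,
                       read_length_range = c(26L, 31L),
                       forward_fraction = 0.5, multiplicity_max = 4L) {
  cfg <- as.list(environment())
  cfg$n_families <- length(copy_counts)
  stopifnot(length(divergence_max) == cfg$n_families,
            all(divergence_max >= 0), all(divergence_max <= 0.35),
            degenerate_fraction >= 0, degenerate_fraction <= 1,
            all(copy_counts >= 0), intron_copies_per_family <= 1L)
  if (intron_copies_per_family > 0L && n_genes < cfg$n_families) {
    stop("sim_config: need at least one gene per family for intron plants")
  }
  structure(cfg, class = "sim_config")
}

# one family master: 11-bp lead (the eleven-nucleotide rule by construction),
# exact A box, 30-60-bp spacer, exact B box, short linker completing the
# tRNA-like head, random body, tandem tail
.make_family <- function(idx, config) {
  abox <- .sample_iupac(ABOX_PATTERN)
  bbox <- .sample_iupac(BBOX_PATTERN)
  spacing <- sample(30:60, 1L)
  linker <- sample(10:20, 1L)
  unit <- config$tail_units[((idx - 1L) %% length(config$tail_units)) + 1L]
  reps <- sample(config$tail_repeats_range[1]:config$tail_repeats_range[2], 1L)
  # tails are a real structural feature: keep the tandem span >= 10 bp even
  # for short units (a 5-bp poly(A) would be indistinguishable from noise)
  if (reps * nchar(unit) < 10L) {
    reps <- as.integer(ceiling(10L / nchar(unit))) + sample(0:4, 1L)
  }
  body_len <- sample(config$body_length_range[1]:config$body_length_range[2], 1L)
  lead <- .random_dna(11L)
  head <- paste0(lead, abox, .random_dna(spacing), bbox, .random_dna(linker))
  master <- paste0(head, .random_dna(body_len), paste(rep(unit, reps), collapse = ""))
  list(name = sprintf("fam%d", idx), master = master, length = nchar(master),
       abox = c(11L, 22L), bbox = c(22L + spacing, 33L + spacing),
       spacing = spacing, head_end = nchar(head), tss_offset = 11L,
       tail_unit = unit, tail_repeats = reps)
}

#' Simulate a genome with planted SINE families and genes
#'
#' Deterministic given `config$seed`.  Builds family masters, plants genes
#' and then SINE copies (mutated per copy divergence, inserted with a
#' duplicated 10-15-bp target site, a configured subset inside gene introns),
#' and records the complete ground truth.
#'
#' @param config A [sim_config()].
#' @return A list of class `sine_sim`: `genome` (`DNAStringSet`), `genes`
#'   (a `gene_models`), and `manifest` (families, copies with element-sense
#'   sequences, genes, config echo).
#' @export
simulate_genome <- function(config = sim_config()) {
  set.seed(config$seed)
  fams <- lapply(seq_len(config$n_families), .make_family, config = config)
  names(fams) <- vapply(fams, `[[`, "", "name")
  # capacity check before any assembly
  max_copy <- max(vapply(fams, `[[`, 1L, "length"))
  total_insert <- sum(rep(vapply(fams, `[[`, 1L, "length"), config$copy_counts) +
                        2L * config$tsd_len_range[2])
  gene_len_max <- 4L * config$exon_length_range[2] + 3L * config$intron_length_range[2]
  if (total_insert + config$n_genes * gene_len_max > 0.6 * config$genome_length) {
    stop("simulate_genome: genome too small for requested plants (",
         total_insert, " bp of insertions into ", config$genome_length, " bp)")
  }
  clen <- rep(floor(config$genome_length / config$n_contigs), config$n_contigs)
  contig_names <- sprintf("ctg%02d", seq_len(config$n_contigs))
  backbone <- lapply(clen, .random_dna)
  names(backbone) <- contig_names

  # --- genes in backbone coordinates -------------------------------------
  genes <- list(); exons <- list()
  gctg <- rep_len(seq_len(config$n_contigs), config$n_genes)
  next_free <- rep(1000L, config$n_contigs)
  for (gi in seq_len(config$n_genes)) {
    ci <- gctg[gi]
    ex_len <- sample(config$exon_length_range[1]:config$exon_length_range[2], 4L,
                     replace = TRUE)
    in_len <- sample(config$intron_length_range[1]:config$intron_length_range[2], 3L,
                     replace = TRUE)
    glen <- sum(ex_len) + sum(in_len)
    gstart <- next_free[ci] + sample(1000:20000, 1L)
    if (gstart + glen > clen[ci] - 1000L) {
      stop("simulate_genome: genome too small for requested genes")
    }
    next_free[ci] <- gstart + glen
    bnd <- gstart + cumsum(c(0L, rbind(ex_len, c(in_len, 0L))[seq_len(7L)]))
    gid <- sprintf("gene%02d", gi)
    genes[[gi]] <- data.frame(
      gene_id = gid, gene_name = sprintf("synthetic gene %d", gi),
      contig = contig_names[ci], start = gstart, end = gstart + glen,
      strand = sample(c("+", "-"), 1L), stringsAsFactors = FALSE)
    exons[[gi]] <- data.frame(
      gene_id = gid, contig = contig_names[ci],
      start = bnd[c(1L, 3L, 5L, 7L)], end = bnd[c(2L, 4L, 6L, 8L)],
      stringsAsFactors = FALSE)
  }
  genes <- do.call(rbind, genes); exons <- do.call(rbind, exons)

  # --- copy placement in backbone coordinates ----------------------------
  events <- list()
  intron_gene <- if (config$intron_copies_per_family > 0L) {
    sample(genes$gene_id, config$n_families)
  } else character(0)
  for (fi in seq_len(config$n_families)) {
    fam <- fams[[fi]]
    ncp <- config$copy_counts[fi]
    if (ncp == 0L) next
    degen <- stats::runif(ncp) < config$degenerate_fraction
    div <- ifelse(degen, stats::runif(ncp, 0.10, 0.18),
                  stats::runif(ncp, 0, config$divergence_max[fi]))
    in_gene <- rep(NA_character_, ncp)
    if (config$intron_copies_per_family > 0L) {
      # the intron-resident copy is a young one (it seeds the piRNA counts)
      young <- which(!degen)
      tgt <- if (length(young) > 0L) young[1L] else 1L
      in_gene[tgt] <- intron_gene[fi]
    }
    for (k in seq_len(ncp)) {
      events[[length(events) + 1L]] <- data.frame(
        family = fam$name, divergence = div[k],
        strand = sample(c("+", "-"), 1L),
        tsd_len = sample(config$tsd_len_range[1]:config$tsd_len_range[2], 1L),
        gene_id = in_gene[k], stringsAsFactors = FALSE)
    }
  }
  events <- if (length(events) > 0L) do.call(rbind, events) else
    data.frame(family = character(0), divergence = numeric(0),
               strand = character(0), tsd_len = integer(0),
               gene_id = character(0))
  ev_ci <- integer(nrow(events)); ev_pos <- integer(nrow(events))
  occupied <- lapply(seq_len(config$n_contigs), function(i) {
    cbind(genes$start[genes$contig == contig_names[i]] - 100L,
          genes$end[genes$contig == contig_names[i]] + 100L)
  })
  for (r in seq_len(nrow(events))) {
    flen <- fams[[events$family[r]]]$length
    if (!is.na(events$gene_id[r])) {
      g <- which(genes$gene_id == events$gene_id[r])
      ci <- match(genes$contig[g], contig_names)
      gex <- exons[exons$gene_id == events$gene_id[r], , drop = FALSE]
      gex <- gex[order(gex$start), ]
      ok <- FALSE
      for (try in seq_len(200L)) {
        ii <- sample(3L, 1L)   # which intron
        is_ <- gex$end[ii] + 100L; ie <- gex$start[ii + 1L] - 100L - flen -
          events$tsd_len[r]
        if (ie <= is_) next
        p <- sample(is_:ie, 1L)
        clash <- any(ev_ci == ci & abs(ev_pos - p) < (max_copy + config$min_copy_spacing) &
                       seq_len(nrow(events)) < r)
        if (!clash) { ok <- TRUE; break }
      }
      if (!ok) stop("simulate_genome: could not place intron copy (gene too crowded)")
      ev_ci[r] <- ci; ev_pos[r] <- p
    } else {
      ok <- FALSE
      for (try in seq_len(500L)) {
        ci <- sample(config$n_contigs, 1L, prob = clen)
        p <- sample(seq.int(300L, clen[ci] - 300L - flen - events$tsd_len[r]), 1L)
        occ <- occupied[[ci]]
        in_gene <- nrow(occ) > 0L && any(p < occ[, 2L] & (p + flen) > occ[, 1L])
        clash <- any(ev_ci == ci & abs(ev_pos - p) < (max_copy + config$min_copy_spacing) &
                       seq_len(nrow(events)) < r)
        if (!in_gene && !clash) { ok <- TRUE; break }
      }
      if (!ok) stop("simulate_genome: genome too small for requested plants")
      ev_ci[r] <- ci; ev_pos[r] <- p
    }
  }
  events$contig <- contig_names[ev_ci]
  events$bpos <- ev_pos
  # mutated element-sense sequences (drawn in a fixed order for determinism)
  events$seq <- vapply(seq_len(nrow(events)), function(r) {
    .mutate(fams[[events$family[r]]]$master, events$divergence[r])
  }, "")

  # --- assembly with coordinate remapping --------------------------------
  out_seq <- character(config$n_contigs)
  copies <- list()
  for (ci in seq_len(config$n_contigs)) {
    ev <- events[events$contig == contig_names[ci], , drop = FALSE]
    ev <- ev[order(ev$bpos), , drop = FALSE]
    pieces <- character(0)
    cursor <- 0L; shift <- 0L
    bb <- backbone[[ci]]
    starts <- integer(nrow(ev)); ends <- integer(nrow(ev)); tsds <- character(nrow(ev))
    for (r in seq_len(nrow(ev))) {
      p <- ev$bpos[r]; t <- ev$tsd_len[r]
      tsd <- substr(bb, p + 1L, p + t)
      oriented <- if (ev$strand[r] == "+") ev$seq[r] else revcomp(ev$seq[r])
      pieces <- c(pieces, substr(bb, cursor + 1L, p + t), oriented, tsd)
      starts[r] <- p + t + shift
      ends[r] <- starts[r] + nchar(oriented)
      tsds[r] <- tsd
      shift <- shift + nchar(oriented) + t
      cursor <- p + t
    }
    pieces <- c(pieces, substr(bb, cursor + 1L, nchar(bb)))
    out_seq[ci] <- paste(pieces, collapse = "")
    if (nrow(ev) > 0L) {
      ev$start <- starts; ev$end <- ends; ev$tsd_seq <- tsds
      copies[[length(copies) + 1L]] <- ev
    }
    # remap gene coordinates on this contig
    insp <- ev$bpos + ev$tsd_len
    insw <- (ev$end - ev$start) + ev$tsd_len
    remap <- function(x) {
      x + vapply(x, function(xx) sum(insw[insp <= xx]), 1L)
    }
    gsel <- genes$contig == contig_names[ci]
    genes$start[gsel] <- remap(genes$start[gsel])
    genes$end[gsel] <- remap(genes$end[gsel])
    esel <- exons$contig == contig_names[ci]
    exons$start[esel] <- remap(exons$start[esel])
    exons$end[esel] <- remap(exons$end[esel])
  }
  if (length(copies) > 0L) {
    copies <- do.call(rbind, copies)
    copies$copy_id <- sprintf("%s_c%03d", copies$family,
                              stats::ave(seq_len(nrow(copies)), copies$family,
                                         FUN = seq_along))
    copies$identity <- 1 - round(copies$divergence *
                                   nchar(copies$seq)) / nchar(copies$seq)
    copies <- copies[, c("copy_id", "family", "contig", "start", "end",
                         "strand", "divergence", "identity", "tsd_seq",
                         "tsd_len", "gene_id", "seq")]
    rownames(copies) <- NULL
  } else {
    copies <- data.frame(copy_id = character(0), family = character(0),
                         contig = character(0), start = integer(0),
                         end = integer(0), strand = character(0),
                         divergence = numeric(0), identity = numeric(0),
                         tsd_seq = character(0), tsd_len = integer(0),
                         gene_id = character(0), seq = character(0))
  }
  genome <- Biostrings::DNAStringSet(stats::setNames(out_seq, contig_names))
  gm <- .gene_models(genes, exons)
  structure(list(
    genome = genome, genes = gm,
    manifest = list(config = unclass(config), families = fams,
                    copies = copies, genes = gm)
  ), class = "sine_sim")
}

#' @export
print.sine_sim <- function(x, ...) {
  cat(sprintf("<sine_sim: %d contigs (%d bp), %d families, %d copies, %d genes>\n",
              length(x$genome), sum(Biostrings::width(x$genome)),
              length(x$manifest$families), nrow(x$manifest$copies),
              nrow(x$genes$genes)))
  invisible(x)
}

#' Simulate small-RNA reads from a planted genome
#'
#' SINE-derived reads are sampled from copy bodies (never heads) in both
#' orientations; decoys from the tRNA-like head regions; background reads
#' are random and rejection-sampled so that neither they nor their reverse
#' complements occur in any gene span (making per-gene truth counts exact).
#' For every distinct read sequence the generator records, by direct
#' substring scan of the intron sequences, which genes it hits in which
#' orientation -- the ground truth that [count_by_gene()] must reproduce.
#'
#' @param sim A `sine_sim` from [simulate_genome()].
#' @param config The same [sim_config()].
#' @return The `sine_sim` with `manifest$reads` (per sampled read: seq,
#'   multiplicity, origin, family, copy_id, orientation), `manifest$gene_truth`
#'   (per gene: expected forward/reverse/total) and `reads_expanded` (the raw
#'   library, one entry per occurrence) filled in.
#' @export
simulate_reads <- function(sim, config = sim_config()) {
  set.seed(config$seed + 7919L)
  cp <- sim$manifest$copies
  fams <- sim$manifest$families
  rlr <- config$read_length_range
  draw_len <- function() sample(rlr[1]:rlr[2], 1L)
  reads <- list()
  if (nrow(cp) > 0L && config$n_sine_reads > 0L) {
    pick <- sample(nrow(cp), config$n_sine_reads, replace = TRUE)
    for (i in pick) {
      fam <- fams[[cp$family[i]]]
      rl <- draw_len()
      lo <- fam$head_end; hi <- nchar(cp$seq[i]) - rl
      if (hi < lo) next
      s <- sample(lo:hi, 1L)
      frag <- substr(cp$seq[i], s + 1L, s + rl)
      ori <- if (stats::runif(1) < config$forward_fraction) "F" else "R"
      reads[[length(reads) + 1L]] <- data.frame(
        seq = if (ori == "F") frag else revcomp(frag),
        multiplicity = sample(config$multiplicity_max, 1L),
        origin = "sine", family = cp$family[i], copy_id = cp$copy_id[i],
        orientation = ori, stringsAsFactors = FALSE)
    }
  }
  if (nrow(cp) > 0L && config$n_decoy_reads > 0L) {
    pick <- sample(nrow(cp), config$n_decoy_reads, replace = TRUE)
    for (i in pick) {
      fam <- fams[[cp$family[i]]]
      rl <- draw_len()
      hi <- fam$head_end - rl
      if (hi < 0L) next
      s <- sample(0:hi, 1L)
      frag <- substr(cp$seq[i], s + 1L, s + rl)
      reads[[length(reads) + 1L]] <- data.frame(
        seq = frag, multiplicity = sample(config$multiplicity_max, 1L),
        origin = "decoy", family = cp$family[i], copy_id = cp$copy_id[i],
        orientation = "F", stringsAsFactors = FALSE)
    }
  }
  # intron sequences (final coordinates) for truth scans and rejection
  introns <- gene_introns(sim$genes)
  intron_seq <- vapply(seq_len(nrow(introns)), function(r) {
    genome_slice(sim$genome, introns$contig[r], introns$start[r],
                 introns$end[r], "+")
  }, "")
  span_seq <- vapply(seq_len(nrow(sim$genes$genes)), function(r) {
    g <- sim$genes$genes[r, ]
    genome_slice(sim$genome, g$contig, g$start, g$end, "+")
  }, "")
  if (config$n_background_reads > 0L) {
    made <- 0L
    while (made < config$n_background_reads) {
      frag <- .random_dna(draw_len())
      rc <- revcomp(frag)
      if (any(vapply(span_seq, function(s)
        grepl(frag, s, fixed = TRUE) || grepl(rc, s, fixed = TRUE), TRUE))) next
      reads[[length(reads) + 1L]] <- data.frame(
        seq = frag, multiplicity = sample(config$multiplicity_max, 1L),
        origin = "background", family = NA_character_, copy_id = NA_character_,
        orientation = "F", stringsAsFactors = FALSE)
      made <- made + 1L
    }
  }
  reads <- if (length(reads) > 0L) do.call(rbind, reads) else
    data.frame(seq = character(0), multiplicity = integer(0),
               origin = character(0), family = character(0),
               copy_id = character(0), orientation = character(0))
  # gene truth at the distinct-sequence level (matches count_by_gene exactly)
  uniq <- stats::aggregate(multiplicity ~ seq, data = reads, FUN = sum)
  truth <- list()
  for (g in unique(introns$gene_id)) {
    iseq <- intron_seq[introns$gene_id == g]
    fwd <- 0L; rev <- 0L
    for (r in seq_len(nrow(uniq))) {
      sq <- uniq$seq[r]; rc <- revcomp(sq)
      if (any(vapply(iseq, function(s) grepl(sq, s, fixed = TRUE), TRUE))) {
        fwd <- fwd + uniq$multiplicity[r]
      }
      if (any(vapply(iseq, function(s) grepl(rc, s, fixed = TRUE), TRUE))) {
        rev <- rev + uniq$multiplicity[r]
      }
    }
    if (fwd + rev > 0L) {
      truth[[length(truth) + 1L]] <- data.frame(
        gene_id = g, forward = fwd, reverse = rev, total = fwd + rev,
        stringsAsFactors = FALSE)
    }
  }
  truth <- if (length(truth) > 0L) do.call(rbind, truth) else
    data.frame(gene_id = character(0), forward = integer(0),
               reverse = integer(0), total = integer(0))
  sim$manifest$reads <- reads
  sim$manifest$gene_truth <- truth[order(-truth$total, truth$gene_id), , drop = FALSE]
  sim$reads_expanded <- rep(reads$seq, reads$multiplicity)
  sim
}

#' Write simulator outputs to a directory
#'
#' Emits `genome.fa`, `genes.gff3`, `reads.fa` (one record per read
#' occurrence) and `manifest.json` (+ `copies.tsv`).
#'
#' @param sim A `sine_sim` (ideally after [simulate_reads()]).
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_sim <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(sim$genome, file.path(dir, "genome.fa"))
  write_gff3_genes(sim$genes, file.path(dir, "genes.gff3"))
  if (!is.null(sim$reads_expanded)) {
    reads <- stats::setNames(sim$reads_expanded,
                             sprintf("read%06d", seq_along(sim$reads_expanded)))
    write_fasta(reads, file.path(dir, "reads.fa"))
  }
  man <- sim$manifest
  man$genes <- list(genes = man$genes$genes, exons = man$genes$exons)
  utils::write.table(man$copies, file.path(dir, "copies.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(man, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}
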