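# Shared small simulation fixture, built once per test run.  A 400-kb
# single-contig genome with three families is large enough to exercise the
# whole pipeline yet cheap enough to reuse across test files.

small_sim_config <- function(seed = 11L) {
  sim_config(seed = seed, genome_length = 4e5, n_contigs = 1L,
             copy_counts = c(3L, 8L, 20L),
             divergence_max = c(0.02, 0.05, 0.08),
             degenerate_fraction = 0,
             n_genes = 3L,
             n_sine_reads = 300L, n_background_reads = 60L,
             n_decoy_reads = 60L)
}

.sim_cache <- new.env(parent = emptyenv())

shared_sim <- function() {
  if (is.null(.sim_cache$sim)) {
    cfg <- small_sim_config()
    sim <- simulate_genome(cfg)
    sim <- simulate_reads(sim, cfg)
    .sim_cache$sim <- sim
    .sim_cache$cfg <- cfg
  }
  .sim_cache$sim
}

shared_cfg <- function() {
  invisible(shared_sim())
  .sim_cache$cfg
}

shared_discovery <- function() {
  if (is.null(.sim_cache$disc)) {
    .sim_cache$disc <- discover_families(shared_sim()$genome)
  }
  .sim_cache$disc
}

shared_annotation <- function() {
  if (is.null(.sim_cache$ann)) {
    .sim_cache$ann <- annotate_families(shared_sim()$genome,
                                        shared_discovery()$models)
  }
  .sim_cache$ann
}
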