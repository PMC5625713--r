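# Shared fixtures, built once per test session and cached in-process.
# Everything is generated in code; no binary fixtures on disk.

.fx_cache <- new.env(parent = emptyenv())

fx <- function(name, build) {
  if (!exists(name, envir = .fx_cache)) {
    assign(name, build(), envir = .fx_cache)
  }
  get(name, envir = .fx_cache)
}

run_dataset <- function(cfg) {
  gn <- build_genome(cfg)
  sim <- simulate_reads(gn$genome, gn$truth, cfg)
  batch <- align_batch(sim$reads, gn$genome)
  screen <- run_all_types(batch$unmapped, gn$genome, stranded = cfg$stranded)
  ag <- screen$hyper_reads[
    screen$hyper_reads$mismatch_type %in% c("A>G", "T>C"), , drop = FALSE]
  list(cfg = cfg, genome = gn$genome, truth = sim$truth, reads = sim$reads,
       batch = batch, screen = screen, ag = ag,
       sites = collapse_sites(ag, stranded = cfg$stranded))
}

# mid-size noiseless dataset for routine module tests
fx_small <- function() fx("small", function() {
  run_dataset(sim_config(genome_length = 30000, n_reads = 5000,
                         seq_error_rate = 0, snp_rate = 0, seed = 7))
})

# acceptance-scale noiseless dataset (criteria on recovery and dsRNA linkage)
fx_noiseless <- function() fx("noiseless", function() {
  run_dataset(sim_config(genome_length = 50000, n_reads = 20000,
                         seq_error_rate = 0, snp_rate = 0, seed = 101))
})

# tiny deterministic genome for IO / alignment unit tests
fx_tiny_genome <- function() fx("tiny_genome", function() {
  withr::with_seed(123, c(
    chrA = random_dna(600, 0.5),
    chrB = random_dna(250, 0.4)
  ))
})

# a minimal hand-built hyper-read row (columns as emitted by detect_type)
hyper_row <- function(read_id, type, chrom, aln_start, strand, gpos,
                      read_len = 80L) {
  gpos <- as.integer(sort(gpos))
  tibble::tibble(
    read_id = read_id, mismatch_type = type, chrom = chrom,
    aln_start = as.integer(aln_start),
    aln_end = as.integer(aln_start + read_len),
    strand = strand, n_candidates = length(gpos),
    other_mismatches = 0L,
    cluster_start = gpos[1], cluster_end = gpos[length(gpos)] + 1L,
    candidate_gpos = list(gpos),
    candidate_offsets = list(gpos - as.integer(aln_start))
  )
}
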