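#' Configure an end-to-end run
#'
#' Bundles the simulation (or input paths), detection, quantification,
#' dsRNA and annotation settings for [run_pipeline()].
#'
#' @param out_dir Output directory (created if absent).
#' @param sim A [sim_config()] used to generate the dataset, or `NULL`
#'   when `genome_fasta`/`reads_fastq` are supplied.
#' @param genome_fasta,reads_fastq Optional input paths used instead of
#'   simulation; both must exist.
#' @param stranded Library strandedness; defaults to the simulation's.
#' @param opts A [detect_opts()].
#' @param max_mm Initial-pass mismatch budget.
#' @param flank dsRNA search flank (bases).
#' @param n_windows Windows sampled for the genomic dsRNA potential.
#' @param seed Seed for stages with sampling (dsRNA potential); the
#'   simulation uses its own seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, sim = sim_config(), genome_fasta = NULL,
                            reads_fastq = NULL, stranded = NULL,
                            opts = detect_opts(), max_mm = 3L,
                            flank = 2000L, n_windows = 1000L, seed = 1L) {
  if (is.null(sim)) {
    if (is.null(genome_fasta) || is.null(reads_fastq)) {
      abort("either `sim` or both `genome_fasta` and `reads_fastq` must be given")
    }
    if (!file.exists(genome_fasta)) {
      abort(sprintf("genome FASTA not found: '%s'", genome_fasta))
    }
    if (!file.exists(reads_fastq)) {
      abort(sprintf("reads FASTQ not found: '%s'", reads_fastq))
    }
  }
  structure(list(
    out_dir = out_dir, sim = sim, genome_fasta = genome_fasta,
    reads_fastq = reads_fastq,
    stranded = if (is.null(stranded)) {
      if (is.null(sim)) FALSE else sim$stranded
    } else isTRUE(stranded),
    opts = opts, max_mm = as.integer(max_mm), flank = as.integer(flank),
    n_windows = check_count(n_windows, "n_windows", 0L),
    seed = check_count(seed, "seed", 0L)
  ), class = "pipeline_config")
}

stage_msg <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the full hyper-editing analysis
#'
#' simulate (or load) -> initial alignment -> twelve-type cluster
#' detection -> quantification -> motif profiling -> dsRNA structure
#' search -> annotation -> report. All outputs are deterministic given the
#' configuration, so two runs with the same config produce byte-identical
#' files.
#'
#' @param config A [pipeline_config()].
#' @return (Invisibly) a `hyperedit_run` list with every stage's result;
#'   [glance()] summarises it in one row.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$out_dir, ...)

  if (!is.null(config$sim)) {
    stage_msg("simulate", "genome %d bp, %d reads (seed %d)",
              config$sim$genome_length, config$sim$n_reads, config$sim$seed)
    gn <- build_genome(config$sim)
    sim <- simulate_reads(gn$genome, gn$truth, config$sim)
    genome <- gn$genome; truth <- sim$truth; reads <- sim$reads
    write_fasta(genome, out("genome.fa"))
    write_fastq(reads, out("reads.fastq"))
    write_bed(mutate(truth$repeats, name = .data$family), out("repeats.bed"))
    write_bed(truth$transcripts[truth$transcripts$coding, ], out("coding.bed"))
    readr::write_tsv(truth$reads |>
                       select(-"edit_genomic_pos", -"edit_read_offset",
                              -"error_read_offset"),
                     out("truth_reads.tsv"))
  } else {
    stage_msg("load", "genome '%s', reads '%s'",
              config$genome_fasta, config$reads_fastq)
    genome <- read_fasta(config$genome_fasta)
    reads <- read_fastq(config$reads_fastq)
    truth <- NULL
  }

  batch <- align_batch(reads, genome, max_mm = config$max_mm,
                       k = config$opts$k)
  stage_msg("align", "%d reads: %d mapped (%.1f%%), %d unmapped, %d mapped bases",
            nrow(reads), nrow(batch$mapped),
            if (nrow(reads)) 100 * nrow(batch$mapped) / nrow(reads) else 0,
            nrow(batch$unmapped), batch$mapped_bases)

  screen <- run_all_types(batch$unmapped, genome, stranded = config$stranded,
                          opts = config$opts)
  tp <- signal_pair_types(config$stranded)
  ag_reads <- screen$hyper_reads[
    screen$hyper_reads$mismatch_type %in% tp$signal, , drop = FALSE]
  stage_msg("detect", "%d hyper-edited reads rescued (%d A-to-G-family)",
            nrow(screen$hyper_reads), nrow(ag_reads))
  readr::write_tsv(screen$report, out("type_screen.tsv"))

  report <- signal_report(screen, batch, stranded = config$stranded,
                          label = basename(config$out_dir))
  sites <- collapse_sites(ag_reads, stranded = config$stranded)
  write_sites(sites, out("sites_A_to_G.bed"))
  spec <- specificity(screen$report, stranded = config$stranded)
  stage_msg("quantify", "signal %.2f events/Mb, specificity %.3f",
            report$normalized_signal, spec)

  cluster_spans <- tibble(chrom = ag_reads$chrom,
                          start = ag_reads$cluster_start,
                          end = ag_reads$cluster_end,
                          strand = site_span_strand(ag_reads, config$stranded))
  profile <- if (nrow(sites) > 0) {
    build_profile(sites, genome, cluster_spans)
  } else NULL
  if (!is.null(profile)) {
    readr::write_tsv(tidy(profile), out("motif_profile.tsv"))
    stage_msg("motif", "%d usable sites, upstream-G enrichment %.2f",
              profile$n_sites, upstream_depletion(profile))
  }

  loci <- if (nrow(ag_reads)) {
    gr <- GenomicRanges::reduce(as_granges(
      tibble(chrom = ag_reads$chrom, start = ag_reads$cluster_start,
             end = ag_reads$cluster_end)))
    tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
           start = GenomicRanges::start(gr) - 1L,
           end = GenomicRanges::end(gr))
  } else tibble(chrom = character(), start = integer(), end = integer())
  partner_hits <- bind_rows(lapply(seq_len(nrow(loci)), function(i) {
    find_dsrna_partner(loci[i, ], genome, flank = config$flank)
  }))
  control_hits <- bind_rows(lapply(seq_len(nrow(loci)), function(i) {
    control_same_strand(loci[i, ], genome, flank = config$flank)
  }))
  potential <- if (config$n_windows > 0) {
    genomic_dsrna_potential(genome, config$n_windows, flank = config$flank,
                            seed = config$seed)
  } else NA_real_
  enrich <- if (nrow(partner_hits) && nrow(sites)) {
    dsrna_editing_enrichment(partner_hits, sites, genome)
  } else NA_real_
  stage_msg("dsrna", "%d/%d loci with reverse partner, %d/%d same-strand control, potential %.4f",
            nrow(partner_hits), nrow(loci), nrow(control_hits), nrow(loci),
            potential)
  readr::write_tsv(bind_rows(partner_hits, control_hits), out("dsrna_hits.tsv"))

  repeats_bed <- if (!is.null(truth)) {
    mutate(truth$repeats, name = .data$family)
  } else tibble(chrom = character(), start = integer(), end = integer(),
                name = character())
  coding_bed <- if (!is.null(truth)) {
    truth$transcripts[truth$transcripts$coding, ]
  } else tibble(chrom = character(), start = integer(), end = integer())
  ov_rep <- overlap_fraction(sites, repeats_bed)
  ov_cod <- overlap_fraction(sites, coding_bed)
  expr <- unedited_expression(ag_reads, batch$alignments,
                              stranded = config$stranded)
  stage_msg("annotate", "%.1f%% of sites in repeats, %.1f%% in coding, %.0f%% of loci edited-only",
            100 * ov_rep$fraction, 100 * ov_cod$fraction,
            100 * (expr$fraction_loci_edited_only %||% NA_real_))
  readr::write_tsv(expr$site_levels, out("site_levels.tsv"))

  summary <- tibble(
    label = report$label,
    source_reads = nrow(reads),
    pct_aligned = if (nrow(reads)) 100 * nrow(batch$mapped) / nrow(reads) else NA_real_,
    hyper_reads = report$hyper_reads,
    editing_events = report$editing_events,
    unique_sites = report$unique_sites,
    pct_A_to_G_of_all_types = report$pct_A_to_G_of_all_types,
    pct_in_coding = 100 * ov_cod$fraction,
    pct_in_repeats = 100 * ov_rep$fraction,
    normalized_signal = report$normalized_signal,
    false_positive_signal = report$false_positive_signal
  )
  write_summary(summary, out("summary.tsv"))
  stage_msg("report", "summary written to %s", out("summary.tsv"))

  res <- structure(list(
    config = config, genome = genome, truth = truth, reads = reads,
    batch = batch, screen = screen, report = report, sites = sites,
    specificity = spec, profile = profile, loci = loci,
    dsrna_partners = partner_hits, dsrna_controls = control_hits,
    dsrna_potential = potential, dsrna_enrichment = enrich,
    overlap_repeats = ov_rep, overlap_coding = ov_cod,
    expression = expr, summary = summary
  ), class = "hyperedit_run")
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a

site_span_strand <- function(ag_reads, stranded) {
  if (!nrow(ag_reads)) return(character(0))
  if (stranded) {
    ag_reads$strand
  } else {
    # cluster strand inferred from the mismatch type, as for sites
    ifelse(ag_reads$mismatch_type == "A>G", "+", "-")
  }
}

#' @export
print.hyperedit_run <- function(x, ...) {
  cat("<hyperedit_run>\n")
  print(glance(x))
  invisible(x)
}

#' @describeIn run_pipeline One-row summary of a pipeline run.
#' @param x A `hyperedit_run`.
#' @param ... Unused.
#' @export
glance.hyperedit_run <- function(x, ...) {
  tibble(
    source_reads = x$summary$source_reads,
    pct_aligned = x$summary$pct_aligned,
    hyper_reads = x$summary$hyper_reads,
    editing_events = x$summary$editing_events,
    unique_sites = x$summary$unique_sites,
    normalized_signal = x$summary$normalized_signal,
    specificity = x$specificity,
    pct_in_repeats = x$summary$pct_in_repeats,
    pct_in_coding = x$summary$pct_in_coding,
    fraction_loci_edited_only = x$expression$fraction_loci_edited_only,
    dsrna_partner_rate = if (nrow(x$loci)) nrow(x$dsrna_partners) / nrow(x$loci) else NA_real_,
    dsrna_control_rate = if (nrow(x$loci)) nrow(x$dsrna_controls) / nrow(x$loci) else NA_real_,
    dsrna_potential = x$dsrna_potential,
    dsrna_enrichment = x$dsrna_enrichment
  )
}
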