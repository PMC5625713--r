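#' Fraction of sites overlapping an annotation
#'
#' A site overlaps when it falls inside at least one interval, regardless
#' of frame or strand. Also reports per-label site counts (e.g. per repeat
#' family).
#'
#' @param sites Site tibble (`chrom`, `pos`).
#' @param intervals Interval tibble (`chrom`, `start`, `end`, optional
#'   `name`), 0-based half-open.
#' @return List: `fraction` (sites inside any interval) and `by_label`
#'   (tibble of per-label site counts).
#' @export
overlap_fraction <- function(sites, intervals) {
  if (!nrow(sites)) {
    return(list(fraction = 0,
                by_label = tibble(label = character(), n_sites = integer())))
  }
  if (!nrow(intervals)) {
    return(list(fraction = 0,
                by_label = tibble(label = character(), n_sites = integer())))
  }
  sgr <- points_as_granges(sites)
  igr <- as_granges(intervals)
  GenomicRanges::strand(igr) <- "*"
  ov <- GenomicRanges::findOverlaps(sgr, igr, ignore.strand = TRUE)
  frac <- length(unique(S4Vectors::queryHits(ov))) / nrow(sites)
  labels <- if ("name" %in% names(intervals)) {
    intervals$name
  } else if ("label" %in% names(intervals)) {
    intervals$label
  } else rep(".", nrow(intervals))
  by_label <- tibble(label = labels[S4Vectors::subjectHits(ov)],
                     site = S4Vectors::queryHits(ov)) |>
    distinct() |>
    dplyr::count(.data$label, name = "n_sites")
  list(fraction = frac, by_label = by_label)
}

site_tier <- function(level) {
  dplyr::case_when(
    level > 0.3 ~ "strong",
    level >= 0.01 ~ "moderate",
    TRUE ~ "weak"
  )
}

#' Do hyper-edited loci express unedited transcripts?
#'
#' Merges the detected cluster spans into loci and asks, per locus,
#' whether any initially-mapped read overlaps it; a locus supported by no
#' such read is "edited-only" — all transcripts expressed from it are
#' extensively edited. Per-site editing levels (edited reads over all
#' covering reads, both passes, duplicate read ids counted once) are
#' tiered: strong (> 30\%), moderate (1-30\%), weak (< 1\%).
#'
#' @param hyper_reads Hyper-edited read tibble from [run_all_types()] (the
#'   A-to-G family).
#' @param alignments Initial-pass alignment tibble from [align_batch()].
#' @param stranded Library strandedness (passed to [collapse_sites()]).
#' @return List: `loci` (per-locus counts and the `edited_only` flag),
#'   `site_levels` (per-site coverage, level and tier),
#'   `fraction_loci_edited_only`, `fraction_sites_edited_only`.
#' @export
unedited_expression <- function(hyper_reads, alignments, stranded = FALSE) {
  empty <- list(
    loci = tibble(chrom = character(), start = integer(), end = integer(),
                  n_initial_reads = integer(), n_hyper_reads = integer(),
                  edited_only = logical()),
    site_levels = tibble(chrom = character(), pos = integer(),
                         edited = integer(), total = integer(),
                         level = numeric(), tier = character()),
    fraction_loci_edited_only = NA_real_,
    fraction_sites_edited_only = NA_real_
  )
  if (!nrow(hyper_reads)) return(empty)

  init <- alignments[alignments$mapped %in% TRUE, , drop = FALSE]
  init <- distinct(init, .data$read_id, .keep_all = TRUE)

  spans <- tibble(chrom = hyper_reads$chrom, start = hyper_reads$cluster_start,
                  end = hyper_reads$cluster_end)
  loci_gr <- GenomicRanges::reduce(as_granges(spans))
  init_gr <- GenomicRanges::GRanges(
    init$chrom, IRanges::IRanges(init$start + 1L, init$start + init$aln_len))
  hyper_gr <- as_granges(tibble(chrom = hyper_reads$chrom,
                                start = hyper_reads$aln_start,
                                end = hyper_reads$aln_end))
  n_init <- GenomicRanges::countOverlaps(loci_gr, init_gr, ignore.strand = TRUE)
  n_hyper <- GenomicRanges::countOverlaps(loci_gr, hyper_gr, ignore.strand = TRUE)
  loci <- tibble(
    chrom = as.character(GenomicRanges::seqnames(loci_gr)),
    start = GenomicRanges::start(loci_gr) - 1L,
    end = GenomicRanges::end(loci_gr),
    n_initial_reads = n_init, n_hyper_reads = n_hyper,
    edited_only = n_init == 0L
  )

  sites <- collapse_sites(hyper_reads, stranded = stranded)
  sgr <- points_as_granges(sites)

  # initial reads carrying the same mismatch at a site count as edited
  init_mm <- bind_rows(lapply(seq_len(nrow(init)), function(i) {
    mm <- parse_mismatches(init$mismatches[i])
    if (!nrow(mm)) return(NULL)
    tibble(chrom = init$chrom[i], pos = init$start[i] + mm$offset,
           ref = mm$ref, alt = mm$alt)
  }))
  edited_init <- if (nrow(sites) && nrow(init_mm)) {
    ag <- init_mm[paste0(init_mm$ref, ">", init_mm$alt) %in% c("A>G", "T>C"), ]
    if (nrow(ag)) dplyr::count(ag, .data$chrom, .data$pos, name = "n_init_edited")
    else NULL
  } else NULL

  cov_init <- GenomicRanges::countOverlaps(sgr, init_gr, ignore.strand = TRUE)
  cov_hyper <- GenomicRanges::countOverlaps(sgr, hyper_gr, ignore.strand = TRUE)
  site_levels <- sites |>
    mutate(n_init_cov = cov_init, n_hyper_cov = cov_hyper)
  site_levels <- if (!is.null(edited_init)) {
    left_join(site_levels, edited_init, by = c("chrom", "pos"))
  } else mutate(site_levels, n_init_edited = NA_integer_)
  site_levels <- site_levels |>
    mutate(
      n_init_edited = dplyr::coalesce(.data$n_init_edited, 0L),
      edited = .data$support + .data$n_init_edited,
      total = .data$n_init_cov + .data$n_hyper_cov,
      level = ifelse(.data$total > 0, .data$edited / .data$total, NA_real_),
      tier = site_tier(.data$level)
    ) |>
    select("chrom", "pos", "strand", "mismatch_type", "edited", "total",
           "level", "tier")

  in_edited_only <- IRanges::overlapsAny(
    sgr, loci_gr[loci$edited_only], ignore.strand = TRUE)
  list(
    loci = loci,
    site_levels = site_levels,
    fraction_loci_edited_only = mean(loci$edited_only),
    fraction_sites_edited_only = if (nrow(sites)) mean(in_edited_only) else NA_real_
  )
}

#' Minimum edited fraction of a hyper-edited duplex
#'
#' The per-read site threshold, applied to both strands of the duplex when
#' `double_strand = TRUE`, divided by the read length: the lower bound on
#' the fraction of base pairs edited in a hyper-edited dsRNA region
#' (10\% for four sites at 80 bp).
#'
#' @param read_length Read length in bases (> 0).
#' @param min_sites Site threshold (see [min_sites()]).
#' @param double_strand Count edits on both strands of the duplex.
#' @return Fraction in \[0, 1\].
#' @export
min_edited_fraction <- function(read_length, min_sites, double_strand = TRUE) {
  stopifnot(read_length > 0)
  min_sites * (if (isTRUE(double_strand)) 2 else 1) / read_length
}
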