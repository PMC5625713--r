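#' Minimum candidate sites for a hyper-edited call
#'
#' A read is called hyper-edited when its candidate-type mismatches reach
#' 5\% of its length — four sites for an 80-bp read. The default rounds the
#' 5\% fraction up (`ceiling(min_frac * L)`), which reproduces the
#' four-sites-at-80-bp rule; `strict = TRUE` instead requires strictly more
#' than `min_frac * L` sites (the smallest integer exceeding it).
#'
#' @param read_length Read length in bases (>= 20).
#' @param min_frac Fraction of the read length (default 0.05).
#' @param strict Use the strictly-greater-than reading.
#' @return Integer site threshold.
#' @export
min_sites <- function(read_length, min_frac = 0.05, strict = FALSE) {
  read_length <- check_count(read_length, "read_length", 20L)
  x <- min_frac * read_length
  if (strict) {
    as.integer(floor(x + 1e-9)) + 1L
  } else {
    as.integer(ceiling(x - 1e-9))
  }
}

#' Detection options for hyper-edited read calling
#'
#' Clean-read filters applied on top of the site-count threshold: a cap on
#' non-candidate mismatches (`max_other_frac` of the read length, at least
#' 1), rejection of reads whose candidate sites all fall in the first or
#' last `end_decile` of the read (junction/end-of-read artifacts), and a
#' minimum mean base quality at candidate sites when qualities are
#' informative.
#'
#' @param min_frac Site-count threshold as a fraction of read length.
#' @param strict Strict (`>`) reading of the threshold; see [min_sites()].
#' @param max_other_frac Cap on non-candidate mismatches as a fraction of
#'   read length (cap is `max(1, floor(max_other_frac * L))`).
#' @param end_decile Terminal fraction of the read used by the edge filter.
#' @param min_qual Minimum mean Phred quality at candidate sites.
#' @param trim_to If set, reads longer than this are trimmed from their
#'   start (the 3' end is kept) before detection, for cross-dataset
#'   comparability.
#' @param k Seed length for the transformed index.
#' @param max_mm Transformed-space mismatch budget; `NULL` scales it from
#'   the read length via [max_mm_scaled()] plus the candidate allowance
#'   (candidate mismatches vanish in transformed space, so the budget only
#'   covers the rest).
#' @return A `detect_opts` list.
#' @export
detect_opts <- function(min_frac = 0.05, strict = FALSE, max_other_frac = 0.025,
                        end_decile = 0.1, min_qual = 25, trim_to = NULL,
                        k = 16L, max_mm = 3L) {
  structure(list(min_frac = min_frac, strict = strict,
                 max_other_frac = max_other_frac, end_decile = end_decile,
                 min_qual = min_qual, trim_to = trim_to,
                 k = check_count(k, "k", 1L), max_mm = as.integer(max_mm)),
            class = "detect_opts")
}

empty_hyper_reads <- function() {
  tibble(read_id = character(), mismatch_type = character(), chrom = character(),
         aln_start = integer(), aln_end = integer(), strand = character(),
         n_candidates = integer(), other_mismatches = integer(),
         cluster_start = integer(), cluster_end = integer(),
         candidate_gpos = list(), candidate_offsets = list())
}

mean_qual_at <- function(qual, offsets) {
  if (is.na(qual) || !nzchar(qual)) return(Inf)
  q <- utf8ToInt(qual) - 33L
  if (length(unique(q)) == 1L) return(Inf)  # uninformative constant qualities
  mean(q[offsets + 1L])
}

# Detect dense clusters of one reference-forward mismatch type among
# unmapped reads realigned in the transformed alphabet.
detect_forward_type <- function(unmapped, genome, from, to, opts) {
  if (!nrow(unmapped)) return(empty_hyper_reads())
  reads <- unmapped
  if (!is.null(opts$trim_to)) {
    long <- nchar(reads$seq) > opts$trim_to
    reads$seq[long] <- substr(reads$seq[long],
                              nchar(reads$seq[long]) - opts$trim_to + 1L,
                              nchar(reads$seq[long]))
    if ("qual" %in% names(reads)) {
      reads$qual[long] <- substr(reads$qual[long],
                                 nchar(reads$qual[long]) - opts$trim_to + 1L,
                                 nchar(reads$qual[long]))
    }
  }
  index <- build_index(genome, k = opts$k, scheme = transform_scheme(from, to))
  aln <- align_tbl(cpp_align_reads(index$ptr, reads$read_id, reads$seq,
                                   opts$max_mm))
  keep <- aln$mapped %in% TRUE & aln$unique %in% TRUE
  if (!any(keep)) return(empty_hyper_reads())
  aln <- aln[keep, , drop = FALSE]
  reads <- reads[keep, , drop = FALSE]
  quals <- if ("qual" %in% names(reads)) reads$qual else rep(NA_character_, nrow(reads))

  rows <- vector("list", nrow(aln))
  for (i in seq_len(nrow(aln))) {
    L <- nchar(reads$seq[i])
    mm <- parse_mismatches(aln$mismatches[i])
    cand <- mm[mm$ref == from & mm$alt == to, , drop = FALSE]
    thr <- min_sites(L, opts$min_frac, opts$strict)
    if (nrow(cand) < thr) next
    other <- nrow(mm) - nrow(cand)
    if (other > max(1L, as.integer(floor(opts$max_other_frac * L + 1e-9)))) next
    edge <- as.integer(ceiling(opts$end_decile * L - 1e-9))
    if (all(cand$offset < edge) || all(cand$offset >= L - edge)) next
    # quality offsets are in read space; minus-strand alignments report
    # offsets in reference-forward order
    read_off <- if (aln$strand[i] == "-") L - 1L - cand$offset else cand$offset
    if (mean_qual_at(quals[i], read_off) < opts$min_qual) next
    gpos <- aln$start[i] + sort(cand$offset)
    rows[[i]] <- tibble(
      read_id = aln$read_id[i], mismatch_type = paste0(from, ">", to),
      chrom = aln$chrom[i], aln_start = aln$start[i], aln_end = aln$start[i] + L,
      strand = aln$strand[i], n_candidates = nrow(cand),
      other_mismatches = other,
      cluster_start = gpos[1], cluster_end = gpos[length(gpos)] + 1L,
      candidate_gpos = list(as.integer(gpos)),
      candidate_offsets = list(as.integer(sort(cand$offset)))
    )
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty_hyper_reads()) else bind_rows(rows)
}

#' Detect hyper-edited reads for one mismatch type
#'
#' Realigns initially unmapped reads after collapsing the alphabet for the
#' given type, recovers native mismatches at each unique placement, and
#' keeps reads whose candidate-type mismatches form a dense cluster passing
#' the clean-read filters. In stranded mode the type is interpreted in
#' transcript orientation: a minus-strand alignment whose reference-forward
#' mismatches are the complementary type is reported under `type`.
#'
#' @param unmapped Read tibble (`read_id`, `seq`, optional `qual`) from the
#'   initial pass's unmapped set.
#' @param genome Named character vector of sequences.
#' @param type Ordered mismatch type, e.g. `"A>G"`.
#' @param stranded Library strandedness.
#' @param opts A [detect_opts()].
#' @return Tibble of hyper-edited reads with candidate site positions and
#'   the genomic cluster span (first to last candidate site).
#' @export
detect_type <- function(unmapped, genome, type = "A>G", stranded = FALSE,
                        opts = detect_opts()) {
  stopifnot(type %in% mismatch_types())
  from <- substr(type, 1L, 1L); to <- substr(type, 3L, 3L)
  if (!stranded) {
    return(detect_forward_type(unmapped, genome, from, to, opts))
  }
  fwd <- detect_forward_type(unmapped, genome, from, to, opts)
  fwd <- fwd[fwd$strand == "+", , drop = FALSE]
  ct <- comp_type(type)
  rev <- detect_forward_type(unmapped, genome, substr(ct, 1L, 1L),
                             substr(ct, 3L, 3L), opts)
  rev <- rev[rev$strand == "-", , drop = FALSE]
  rev$mismatch_type <- rep(type, nrow(rev))
  bind_rows(fwd, rev)
}

#' Run the twelve-mismatch-type specificity screen
#'
#' Executes detection for every ordered mismatch type with identical
#' parameters. Since non-A-to-G editing is essentially absent, the
#' abundance of non-A-to-G clusters measures the false-positive rate of
#' the screen.
#'
#' @inheritParams detect_type
#' @return List: `hyper_reads` (one tibble, all types; in stranded mode
#'   types are transcript-oriented) and `report` (the type-screen tibble:
#'   per type, hyper-read count, editing events, unique sites).
#' @export
run_all_types <- function(unmapped, genome, stranded = FALSE,
                          opts = detect_opts()) {
  types <- mismatch_types()
  per_type <- lapply(types, function(t) {
    from <- substr(t, 1L, 1L); to <- substr(t, 3L, 3L)
    detect_forward_type(unmapped, genome, from, to, opts)
  })
  hyper <- bind_rows(per_type)
  if (stranded && nrow(hyper)) {
    flip <- hyper$strand == "-"
    hyper$mismatch_type[flip] <- comp_type(hyper$mismatch_type[flip])
  }
  counts <- lapply(types, function(t) {
    h <- hyper[hyper$mismatch_type == t, , drop = FALSE]
    n_sites <- if (nrow(h)) {
      nrow(distinct(tibble(chrom = rep(h$chrom, lengths(h$candidate_gpos)),
                           pos = unlist(h$candidate_gpos))))
    } else 0L
    tibble(mismatch_type = t, n_reads = nrow(h),
           n_events = sum(h$n_candidates), n_sites = n_sites)
  })
  list(hyper_reads = hyper, report = bind_rows(counts))
}

#' Collapse hyper-edited reads to unique genomic sites
#'
#' Aggregates candidate sites over reads into unique genomic positions
#' with read support. In unstranded mode each type is first canonicalised
#' to its complement-pair representative with an inferred strand (a T-to-C
#' cluster is an A-to-G cluster on the minus strand), and a position
#' supported by both orientations is merged into one site (flagged
#' strand-unresolved).
#'
#' @param hyper_reads Tibble from [detect_type()] / [run_all_types()].
#' @param stranded Library strandedness. When `TRUE` the read's alignment
#'   strand is the transcript strand and types are already
#'   transcript-oriented.
#' @return Site tibble: `chrom`, `pos` (0-based), `strand`,
#'   `mismatch_type`, `support`, `strand_resolved`.
#' @export
collapse_sites <- function(hyper_reads, stranded = FALSE) {
  if (!nrow(hyper_reads)) {
    return(tibble(chrom = character(), pos = integer(), strand = character(),
                  mismatch_type = character(), support = integer(),
                  strand_resolved = logical()))
  }
  long <- tibble(
    chrom = rep(hyper_reads$chrom, lengths(hyper_reads$candidate_gpos)),
    pos = unlist(hyper_reads$candidate_gpos),
    type = rep(hyper_reads$mismatch_type, lengths(hyper_reads$candidate_gpos)),
    aln_strand = rep(hyper_reads$strand, lengths(hyper_reads$candidate_gpos))
  )
  if (stranded) {
    long$site_type <- long$type
    long$site_strand <- long$aln_strand
  } else {
    ct <- comp_type(long$type)
    canon <- ifelse(long$type <= ct, long$type, ct)
    long$site_strand <- ifelse(long$type == canon, "+", "-")
    long$site_type <- canon
  }
  long |>
    group_by(.data$chrom, .data$pos, .data$site_type) |>
    summarise(
      support = n(),
      strand_resolved = length(unique(.data$site_strand)) == 1L,
      strand = if (length(unique(.data$site_strand)) == 1L) {
        .data$site_strand[1]
      } else {
        names(sort(table(.data$site_strand), decreasing = TRUE))[1]
      },
      .groups = "drop"
    ) |>
    dplyr::rename(mismatch_type = "site_type") |>
    select("chrom", "pos", "strand", "mismatch_type", "support",
           "strand_resolved") |>
    arrange(.data$chrom, .data$pos)
}
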