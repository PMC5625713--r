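#' Local alignment scoring parameters
#'
#' The scoring regime of the pairwise dsRNA search: match +2, mismatch -3,
#' affine gaps (a gap of length g costs `gap_open + g * gap_extend`), a
#' shared-word prefilter of length `word_size`, low-complexity filtering
#' off.
#'
#' @param match Match reward (> 0).
#' @param mismatch Mismatch penalty (< 0).
#' @param gap_open Gap opening cost (default 5).
#' @param gap_extend Per-base gap extension cost (default 2).
#' @param word_size No alignment is reported unless query and subject
#'   share an exact word of this length (default 7).
#' @return A `local_align_params` list.
#' @export
local_align_params <- function(match = 2, mismatch = -3, gap_open = 5,
                               gap_extend = 2, word_size = 7L) {
  if (match <= 0 || mismatch >= 0) {
    abort("`match` must be positive and `mismatch` negative")
  }
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend, word_size = as.integer(word_size)),
            class = "local_align_params")
}

#' Best local alignment between two sequences
#'
#' Full affine-gap Smith-Waterman, deterministic given its inputs.
#' Identity is computed over aligned columns with gaps counted as
#' mismatches. Coordinates are 0-based half-open within each sequence.
#'
#' @param query,subject Non-empty DNA strings.
#' @param params A [local_align_params()].
#' @return One-row tibble: `score`, `identity`, `aligned_length`,
#'   `n_match`, `gaps`, `q_start`, `q_end`, `s_start`, `s_end`. A row of
#'   score 0 means no alignment passed the word prefilter.
#' @export
local_align <- function(query, subject, params = local_align_params()) {
  stopifnot(inherits(params, "local_align_params"))
  res <- cpp_sw_local(query, subject, params$match, params$mismatch,
                      params$gap_open, params$gap_extend, params$word_size)
  as_tibble(res[c("score", "identity", "aligned_length", "n_match", "gaps",
                  "q_start", "q_end", "s_start", "s_end")])
}

empty_hits <- function() {
  tibble(chrom = character(), q_start = integer(), q_end = integer(),
         partner_start = integer(), partner_end = integer(),
         orientation = character(), identity = numeric(),
         aligned_length = integer(), coverage_of_query = numeric(),
         score = numeric())
}

flank_region <- function(genome, chrom, start, end, flank) {
  glen <- nchar(genome[[chrom]])
  rs <- max(0L, start - flank)
  re <- min(glen, end + flank)
  list(rs = rs, re = re, seq = substr(genome[[chrom]], rs + 1L, re))
}

#' Search for a reverse-orientation dsRNA partner of a cluster
#'
#' Aligns the cluster sequence against the reverse complement of its
#' flanking genomic region (`flank` bases either side). A hit requires at
#' least `min_identity` identity along at least `min_cov` of the cluster
#' length. A reverse-orientation partner overlapping the query's own locus
#' is a legitimate self-folding (palindrome) hit and is kept.
#'
#' @param cluster List or one-row tibble with `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param genome Named character vector of sequences.
#' @param flank Flank size in bases (default 2000; truncated at sequence
#'   ends).
#' @param min_identity Minimum alignment identity (default 0.65).
#' @param min_cov Minimum fraction of the cluster length covered by the
#'   alignment's query span (default 0.80).
#' @param params A [local_align_params()].
#' @return A `DsRNAHit` tibble with 0 or 1 rows.
#' @export
find_dsrna_partner <- function(cluster, genome, flank = 2000L,
                               min_identity = 0.65, min_cov = 0.80,
                               params = local_align_params()) {
  chrom <- cluster$chrom[1]; start <- cluster$start[1]; end <- cluster$end[1]
  stopifnot(start >= 0, end <= nchar(genome[[chrom]]), start < end)
  query <- substr(genome[[chrom]], start + 1L, end)
  reg <- flank_region(genome, chrom, start, end, flank)
  subject <- revcomp(reg$seq)
  hit <- local_align(query, subject, params)
  if (hit$score <= 0) return(empty_hits())
  cov <- (hit$q_end - hit$q_start) / (end - start)
  if (is.na(hit$identity) || hit$identity < min_identity || cov < min_cov) {
    return(empty_hits())
  }
  rlen <- reg$re - reg$rs
  tibble(
    chrom = chrom, q_start = start, q_end = end,
    partner_start = reg$rs + rlen - hit$s_end,
    partner_end = reg$rs + rlen - hit$s_start,
    orientation = "reverse", identity = hit$identity,
    aligned_length = hit$aligned_length, coverage_of_query = cov,
    score = hit$score
  )
}

overlap_len <- function(a1, a2, b1, b2) max(0L, min(a2, b2) - max(a1, b1))

#' Same-strand control search
#'
#' The identical flank search without reverse-complementing, quantifying
#' how often a similar sequence that cannot base-pair with the transcript
#' lies nearby. The trivial self-hit is excluded: a best alignment whose
#' partner overlaps the query span by more than half is discarded and the
#' search repeated with the query span hard-masked.
#'
#' @inheritParams find_dsrna_partner
#' @return A `DsRNAHit` tibble with 0 or 1 rows (`orientation`
#'   `"same-strand-control"`).
#' @export
control_same_strand <- function(cluster, genome, flank = 2000L,
                                min_identity = 0.65, min_cov = 0.80,
                                params = local_align_params()) {
  chrom <- cluster$chrom[1]; start <- cluster$start[1]; end <- cluster$end[1]
  stopifnot(start >= 0, end <= nchar(genome[[chrom]]), start < end)
  query <- substr(genome[[chrom]], start + 1L, end)
  reg <- flank_region(genome, chrom, start, end, flank)

  attempt <- function(subject) {
    hit <- local_align(query, subject, params)
    if (hit$score <= 0) return(NULL)
    hit
  }
  hit <- attempt(reg$seq)
  if (!is.null(hit)) {
    p_start <- reg$rs + hit$s_start; p_end <- reg$rs + hit$s_end
    if (overlap_len(p_start, p_end, start, end) > (end - start) / 2) {
      masked <- reg$seq
      substr(masked, start - reg$rs + 1L, end - reg$rs) <-
        strrep("N", end - start)
      hit <- attempt(masked)
    }
  }
  if (is.null(hit)) return(empty_hits())
  cov <- (hit$q_end - hit$q_start) / (end - start)
  if (is.na(hit$identity) || hit$identity < min_identity || cov < min_cov) {
    return(empty_hits())
  }
  tibble(
    chrom = chrom, q_start = start, q_end = end,
    partner_start = reg$rs + hit$s_start, partner_end = reg$rs + hit$s_end,
    orientation = "same-strand-control", identity = hit$identity,
    aligned_length = hit$aligned_length, coverage_of_query = cov,
    score = hit$score
  )
}

#' Genome-wide dsRNA-forming potential
#'
#' Samples random windows and reports the fraction with a highly similar
#' (identity above `min_identity` over at least `min_len` bases)
#' reverse-oriented partner in the flanking region — the background
#' propensity of a genome to form editable duplexes. Windows with more
#' than 10\% N are resampled. The word prefilter uses 13-mers here: any
#' qualifying hit (>=40 bp at >95\% identity allows at most 2 mismatches)
#' must contain an exact 13-mer by pigeonhole.
#'
#' @param genome Named character vector of sequences.
#' @param n_windows Number of windows to sample (>= 1).
#' @param window Window length (default 50).
#' @param flank Flank size (default 2000).
#' @param min_identity Identity threshold, exceeded strictly (default 0.95).
#' @param min_len Minimum aligned length (default 40).
#' @param seed Integer seed for window sampling.
#' @param params A [local_align_params()]; the word size is raised to 13
#'   for this search.
#' @return Fraction of windows with a qualifying reverse-oriented partner.
#' @export
genomic_dsrna_potential <- function(genome, n_windows, window = 50L,
                                    flank = 2000L, min_identity = 0.95,
                                    min_len = 40L, seed = 1L,
                                    params = local_align_params(word_size = 13L)) {
  n_windows <- check_count(n_windows, "n_windows", 1L)
  lens <- nchar(genome)
  if (all(lens < window)) abort("`window` is longer than every sequence")
  withr::local_seed(seed)
  ok_chrom <- names(genome)[lens >= window]
  hits <- 0L
  for (i in seq_len(n_windows)) {
    for (try in 1:50) {
      chrom <- if (length(ok_chrom) == 1L) ok_chrom else {
        sample(ok_chrom, 1L, prob = lens[ok_chrom] - window + 1L)
      }
      s <- sample.int(lens[[chrom]] - window + 1L, 1L) - 1L
      win <- substr(genome[[chrom]], s + 1L, s + window)
      n_frac <- lengths(regmatches(win, gregexpr("N", win))) / window
      if (n_frac <= 0.1) break
    }
    reg <- flank_region(genome, chrom, s, s + window, flank)
    hit <- local_align(win, revcomp(reg$seq), params)
    if (hit$score > 0 && !is.na(hit$identity) &&
        hit$identity > min_identity && hit$aligned_length >= min_len) {
      hits <- hits + 1L
    }
  }
  hits / n_windows
}

#' Enrichment of editing inside predicted dsRNA regions
#'
#' Ratio of the unique-site density inside the predicted dsRNA regions
#' (union of query and partner intervals of the hits) to the density
#' outside.
#'
#' @param hits `DsRNAHit` tibble (reverse-orientation hits).
#' @param sites Site tibble (`chrom`, `pos`).
#' @param genome Named character vector (supplies total genome size).
#' @return Fold-change (possibly `Inf` when no site falls outside);
#'   `NA` with a warning when there are no sites or no dsRNA regions.
#' @export
dsrna_editing_enrichment <- function(hits, sites, genome) {
  if (!nrow(sites)) {
    warn("no sites; dsRNA editing enrichment is undefined")
    return(NA_real_)
  }
  if (!nrow(hits)) {
    warn("no dsRNA hits; dsRNA editing enrichment is undefined")
    return(NA_real_)
  }
  regions <- bind_rows(
    tibble(chrom = hits$chrom, start = hits$q_start, end = hits$q_end),
    tibble(chrom = hits$chrom, start = hits$partner_start, end = hits$partner_end)
  )
  gr <- GenomicRanges::reduce(as_granges(regions))
  in_bp <- sum(IRanges::width(gr))
  total_bp <- sum(nchar(genome))
  out_bp <- total_bp - in_bp
  inside <- IRanges::overlapsAny(points_as_granges(sites), gr)
  n_in <- sum(inside); n_out <- sum(!inside)
  dens_in <- n_in / in_bp
  if (out_bp == 0) return(Inf)
  dens_out <- n_out / out_bp
  if (dens_out == 0) return(Inf)
  dens_in / dens_out
}
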