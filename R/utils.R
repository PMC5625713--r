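BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' Vectorised over its input; non-ACGT characters map to `N`.
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x))
  if (!length(x)) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(toupper(x))))
}

comp_base <- function(x) chartr("ACGTN", "TGCAN", x)

# complement of an ordered mismatch type, e.g. "A>G" -> "T>C"
comp_type <- function(type) {
  from <- substr(type, 1L, 1L)
  to <- substr(type, 3L, 3L)
  paste0(comp_base(from), ">", comp_base(to))
}

#' The 12 ordered mismatch types
#'
#' All ordered pairs of distinct bases, written `"X>Y"` for a reference base
#' X read as Y. Screening all 12 with identical parameters gauges the
#' specificity of cluster detection: only `A>G` (and `T>C` in unstranded
#' libraries) is expected from A-to-I editing.
#'
#' @return Character vector of length 12.
#' @export
mismatch_types <- function() {
  grid <- expand.grid(from = BASES, to = BASES, stringsAsFactors = FALSE)
  grid <- grid[grid$from != grid$to, ]
  sort(paste0(grid$from, ">", grid$to))
}

#' Random DNA sequence
#'
#' Draws i.i.d. bases at a given GC content, using the current RNG state.
#'
#' @param n Sequence length.
#' @param gc GC fraction (default 0.5).
#' @return A single DNA string.
#' @export
random_dna <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(BASES, n, replace = TRUE, prob = p), collapse = "")
}

#' Randomly substitute bases of a sequence
#'
#' Each base is replaced by a uniformly chosen different base with
#' probability `rate`, using the current RNG state — the divergence model
#' of the repeat-family simulator.
#'
#' @param seq A DNA string.
#' @param rate Per-base substitution probability.
#' @return The mutated string.
#' @export
mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(ch)) < rate)
  for (i in hit) {
    ch[i] <- sample(setdiff(BASES, ch[i]), 1L)
  }
  paste(ch, collapse = "")
}

check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a single number in [0, 1]", name))
  }
  x
}

check_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x)) {
    abort(sprintf("`%s` must be a single integer >= %d", name, min))
  }
  as.integer(x)
}

# intervals as GRanges (internal 0-based half-open -> IRanges 1-based closed)
as_granges <- function(df, seqlengths = NULL) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = if ("strand" %in% names(df)) {
      ifelse(df$strand %in% c("+", "-"), df$strand, "*")
    } else "*"
  )
}

points_as_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$pos + 1L, width = 1L)
  )
}
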