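#' Define an alphabet transform for realignment
#'
#' Rewriting one base as another (e.g. every A as G) in both reads and
#' reference collapses the alphabet so that mismatches of that exact type
#' vanish, letting heavily edited reads align where they otherwise could
#' not — the bisulfite-style trick at the heart of hyper-editing rescue.
#'
#' @param from,to Distinct single bases.
#' @return A `transform_scheme` list.
#' @export
transform_scheme <- function(from, to) {
  from <- toupper(from); to <- toupper(to)
  if (!from %in% BASES || !to %in% BASES || from == to) {
    abort("`from` and `to` must be distinct bases among A, C, G, T")
  }
  structure(list(from = from, to = to), class = "transform_scheme")
}

scheme_from_type <- function(type) {
  transform_scheme(substr(type, 1L, 1L), substr(type, 3L, 3L))
}

#' Build an exact-match k-mer index over a genome
#'
#' Indexes the forward strand of the (optionally transformed) genome.
#' Reverse-strand placements are found by aligning the read's reverse
#' complement, with the transform applied after strand resolution, so the
#' twelve-mismatch-type screen is symmetric.
#'
#' @param genome Named character vector of sequences.
#' @param k Seed length (default 16).
#' @param scheme Optional [transform_scheme()]; `NULL` for the native
#'   alphabet.
#' @return A `kmer_index` object.
#' @export
build_index <- function(genome, k = 16L, scheme = NULL) {
  stopifnot(is.character(genome), !is.null(names(genome)))
  k <- check_count(k, "k", 1L)
  if (k > min(nchar(genome))) {
    abort("`k` is larger than the shortest chromosome")
  }
  from <- if (is.null(scheme)) "" else scheme$from
  to <- if (is.null(scheme)) "" else scheme$to
  ptr <- cpp_build_index(names(genome), unname(genome), k, from, to)
  structure(list(ptr = ptr, k = k, scheme = scheme,
                 chrom_names = names(genome),
                 chrom_lengths = setNames(nchar(genome), names(genome))),
            class = "kmer_index")
}

#' @export
print.kmer_index <- function(x, ...) {
  info <- cpp_index_info(x$ptr)
  cat(sprintf("<kmer_index> k=%d, %d sequence(s), %s distinct k-mers%s\n",
              info$k, length(info$names), format(info$n_kmers, big.mark = ","),
              if (nzchar(info$transform_from)) {
                sprintf(", transform %s->%s", info$transform_from, info$transform_to)
              } else ""))
  invisible(x)
}

#' Look up a k-mer in an index
#'
#' @param index A [build_index()] object.
#' @param kmer A string of length `k`.
#' @return Tibble with `chrom` and 0-based `pos` of each exact occurrence
#'   on the indexed (forward) strand.
#' @export
index_lookup <- function(index, kmer) {
  stopifnot(inherits(index, "kmer_index"))
  hits <- cpp_index_lookup(index$ptr, kmer)
  tibble(chrom = index$chrom_names[hits$chrom_i], pos = hits$pos)
}

#' Distinct k-mers present in an index
#'
#' Intended for inspection on small genomes.
#'
#' @param index A [build_index()] object.
#' @return Character vector of distinct indexed k-mers.
#' @export
index_kmers <- function(index) {
  stopifnot(inherits(index, "kmer_index"))
  sort(cpp_index_kmers(index$ptr))
}

#' Mismatch budget scaled to read length
#'
#' @param read_length Read length in bases.
#' @return `max(1, floor(0.04 * read_length))`, the default initial-pass
#'   budget at typical read lengths (3 at 80 bp).
#' @export
max_mm_scaled <- function(read_length) {
  max(1L, as.integer(floor(0.04 * read_length + 1e-9)))
}

parse_mismatches <- function(s) {
  if (is.na(s) || !nzchar(s)) {
    return(tibble(offset = integer(), ref = character(), alt = character()))
  }
  parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], "[:>]")
  tibble(
    offset = as.integer(vapply(parts, `[`, character(1), 1L)),
    ref = vapply(parts, `[`, character(1), 2L),
    alt = vapply(parts, `[`, character(1), 3L)
  )
}

align_tbl <- function(df) {
  out <- as_tibble(df)
  out$read_id <- as.character(out$read_id)
  out$chrom <- as.character(out$chrom)
  out$strand <- as.character(out$strand)
  out$mismatches <- as.character(out$mismatches)
  out
}

#' Align a single read
#'
#' Gapless end-to-end placement by minimum mismatch count in the indexed
#' (possibly transformed) alphabet, found by pigeonhole seed tiling: a read
#' with at most `max_mm` mismatches is guaranteed at least one exact seed
#' among `max_mm + 1` non-overlapping tiles. The guarantee is exhaustive
#' when `read length >= (max_mm + 1) * k`; shorter reads fall back to fewer
#' tiles and placements with many mismatches may be missed. Both strands
#' are searched; `unique` is `FALSE` when the best placement is tied.
#'
#' @param read A read sequence (single string).
#' @param index A [build_index()] object.
#' @param max_mm Maximum mismatches (in the indexed alphabet) to accept.
#' @param read_id Identifier for the output row.
#' @return One-row tibble: `read_id`, `mapped`, `chrom`, `start` (0-based),
#'   `strand`, `mm_transformed`, `unique`, `n_native_mm`, `mismatches`
#'   (native-alphabet list, encoded `"offset:ref>alt;..."` with offsets in
#'   reference-forward order).
#' @export
align_read <- function(read, index, max_mm = 3L, read_id = "read") {
  stopifnot(inherits(index, "kmer_index"), is.character(read), length(read) == 1L)
  align_tbl(cpp_align_reads(index$ptr, read_id, read, as.integer(max_mm)))
}

#' Align a batch of reads and partition them
#'
#' The initial alignment pass: reads placed within the mismatch budget are
#' "mapped"; the remainder — including reads defeated by dense editing —
#' are handed to the transformed-alphabet rescue. `mapped_bases` (the sum
#' of mapped read lengths) is the denominator of the normalized
#' hyper-editing signal.
#'
#' @param reads Tibble with `read_id`, `seq` (and optionally `qual`).
#' @param genome Named character vector of sequences.
#' @param max_mm Mismatch budget (default 3).
#' @param k Seed length (default 16).
#' @return List: `alignments` (tibble, all reads), `mapped`, `unmapped`
#'   (subsets of `reads`), `mapped_bases`.
#' @export
align_batch <- function(reads, genome, max_mm = 3L, k = 16L) {
  if (!nrow(reads)) {
    return(list(alignments = align_tbl(cpp_align_reads(
      build_index(genome, k)$ptr, character(0), character(0), max_mm)),
      mapped = reads, unmapped = reads, mapped_bases = 0))
  }
  index <- build_index(genome, k = k, scheme = NULL)
  aln <- align_tbl(cpp_align_reads(index$ptr, reads$read_id, reads$seq,
                                   as.integer(max_mm)))
  is_mapped <- aln$mapped %in% TRUE
  list(
    alignments = aln,
    mapped = reads[is_mapped, , drop = FALSE],
    unmapped = reads[!is_mapped, , drop = FALSE],
    mapped_bases = sum(nchar(reads$seq[is_mapped]))
  )
}
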