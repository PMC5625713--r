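#' Read a genome FASTA
#'
#' Sequences are uppercased on read (soft-masking is carried separately via
#' repeat intervals, not case). Names are truncated at the first whitespace.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(x))
  names(seqs) <- sub("\\s.*$", "", names(x))
  seqs
}

#' Write a genome FASTA
#'
#' @param genome Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width (default 60).
#' @export
write_fasta <- function(genome, path, width = 60L) {
  lines <- character(0)
  for (nm in names(genome)) {
    seq <- genome[[nm]]
    starts <- seq.int(1L, nchar(seq), by = width)
    lines <- c(lines, paste0(">", nm),
               substring(seq, starts, pmin(starts + width - 1L, nchar(seq))))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read single-end reads from FASTQ (Phred+33)
#'
#' @param path Path to an uncompressed or gzipped FASTQ file.
#' @return A tibble with columns `read_id`, `seq`, `qual`. An empty file
#'   yields an empty tibble.
#' @export
read_fastq <- function(path) {
  if (file.exists(path) && file.size(path) == 0) {
    return(tibble(read_id = character(), seq = character(), qual = character()))
  }
  x <- withCallingHandlers(
    tryCatch(
      Biostrings::readQualityScaledDNAStringSet(path),
      error = function(e) abort(sprintf("malformed FASTQ '%s': %s", path,
                                        conditionMessage(e)))
    ),
    # harmless constructor chatter about (empty) metadata columns
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  tibble(
    read_id = sub("\\s.*$", "", names(x)),
    seq = unname(toupper(as.character(x))),
    qual = unname(as.character(Biostrings::quality(x)))
  )
}

#' Write reads to FASTQ (Phred+33)
#'
#' @param reads Tibble with `read_id`, `seq`, `qual`.
#' @param path Output path.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("read_id", "seq", "qual") %in% names(reads)))
  # the constructor chatters about dropping (empty) metadata columns
  x <- withCallingHandlers(
    Biostrings::QualityScaledDNAStringSet(
      Biostrings::DNAStringSet(setNames(reads$seq, reads$read_id)),
      Biostrings::PhredQuality(reads$qual)
    ),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  Biostrings::writeQualityScaledXStringSet(x, path)
  invisible(path)
}

#' Read BED intervals (0-based half-open)
#'
#' Accepts 3 to 6 columns (chrom, start, end, name, score, strand). Missing
#' columns are filled with `"."`/`NA`. Mixed line endings are tolerated.
#'
#' @param path Path to a BED file.
#' @return Tibble with columns `chrom`, `start`, `end`, `name`, `score`,
#'   `strand`.
#' @export
read_bed <- function(path) {
  empty <- tibble(chrom = character(), start = integer(), end = integer(),
                  name = character(), score = character(), strand = character())
  if (file.exists(path) && file.size(path) == 0) return(empty)
  lines <- readLines(path)
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(empty)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 3L)
  if (length(bad)) {
    abort(sprintf("malformed BED record at line %d of '%s' (fewer than 3 fields)",
                  bad[1], path))
  }
  get <- function(i, default) {
    vapply(fields, function(f) if (length(f) >= i) f[i] else default, character(1))
  }
  out <- tibble(
    chrom = get(1L, NA_character_),
    start = suppressWarnings(as.integer(get(2L, NA_character_))),
    end = suppressWarnings(as.integer(get(3L, NA_character_))),
    name = get(4L, "."),
    score = get(5L, "."),
    strand = get(6L, ".")
  )
  bad <- which(is.na(out$start) | is.na(out$end) | out$start < 0 | out$start >= out$end)
  if (length(bad)) {
    abort(sprintf("malformed BED record at line %d of '%s' (bad coordinates)",
                  bad[1], path))
  }
  out
}

#' Write BED intervals (0-based half-open, 6 columns)
#'
#' @param intervals Tibble with at least `chrom`, `start`, `end`; optional
#'   `name`, `score`, `strand`.
#' @param path Output path.
#' @export
write_bed <- function(intervals, path) {
  n <- nrow(intervals)
  df <- tibble(
    chrom = as.character(intervals$chrom),
    start = as.integer(intervals$start),
    end = as.integer(intervals$end),
    name = if ("name" %in% names(intervals)) as.character(intervals$name) else rep(".", n),
    score = if ("score" %in% names(intervals)) as.character(intervals$score) else rep(".", n),
    strand = if ("strand" %in% names(intervals)) as.character(intervals$strand) else rep(".", n)
  )
  readr::write_tsv(df, path, col_names = FALSE, escape = "none")
  invisible(path)
}

#' Write unique editing sites as a BED-like table
#'
#' One row per unique site: chrom, start, end (= start + 1), mismatch type,
#' read support, strand.
#'
#' @param sites Site tibble from [collapse_sites()].
#' @param path Output path.
#' @export
write_sites <- function(sites, path) {
  write_bed(tibble(
    chrom = sites$chrom, start = sites$pos, end = sites$pos + 1L,
    name = sites$mismatch_type, score = as.character(sites$support),
    strand = sites$strand
  ), path)
}

#' Write a per-dataset summary table
#'
#' Tab-delimited, one row per dataset, mirroring the usual hyper-editing
#' report: source reads, percent aligned, hyper-edited reads, editing
#' events, unique sites (with percent A-to-G of all types), percent of
#' sites in coding regions and in repeats.
#'
#' @param summary A tibble (one row per dataset).
#' @param path Output path.
#' @export
write_summary <- function(summary, path) {
  readr::write_tsv(summary, path)
  invisible(path)
}

# MD tag from a sorted native mismatch list (offsets within the alignment,
# reference-forward order) for a gapless alignment of length L
md_tag <- function(offsets, ref_bases, L) {
  if (!length(offsets)) return(as.character(L))
  o <- order(offsets)
  offsets <- offsets[o]; ref_bases <- ref_bases[o]
  out <- character(0)
  prev <- -1L
  for (i in seq_along(offsets)) {
    out <- c(out, as.character(offsets[i] - prev - 1L), ref_bases[i])
    prev <- offsets[i]
  }
  paste0(paste(out, collapse = ""), L - prev - 1L)
}

#' Write gapless alignments as SAM
#'
#' Minimal single-end SAM emission: flags 0/16 only, MAPQ 255, full-length
#' match CIGAR, NM and MD tags populated. Sequences are emitted in
#' reference-forward orientation as SAM requires.
#'
#' @param alignments Alignment tibble (mapped rows are written).
#' @param reads Read tibble (`read_id`, `seq`, `qual`) the alignments came from.
#' @param genome Named character vector of reference sequences.
#' @param path Output path.
#' @export
write_sam <- function(alignments, reads, genome, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  for (nm in names(genome)) {
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", nm, nchar(genome[[nm]])), con)
  }
  aln <- alignments[alignments$mapped %in% TRUE, , drop = FALSE]
  if (!nrow(aln)) return(invisible(path))
  idx <- match(aln$read_id, reads$read_id)
  for (i in seq_len(nrow(aln))) {
    seq <- reads$seq[idx[i]]
    qual <- reads$qual[idx[i]]
    L <- nchar(seq)
    flag <- if (aln$strand[i] == "-") 16L else 0L
    if (flag == 16L) {
      seq <- revcomp(seq)
      qual <- paste(rev(strsplit(qual, "", fixed = TRUE)[[1]]), collapse = "")
    }
    mm <- parse_mismatches(aln$mismatches[i])
    writeLines(paste(
      aln$read_id[i], flag, aln$chrom[i], aln$start[i] + 1L, 255L,
      paste0(L, "M"), "*", 0L, 0L, seq, qual,
      paste0("NM:i:", nrow(mm)),
      paste0("MD:Z:", md_tag(mm$offset, mm$ref, L)),
      sep = "\t"
    ), con)
  }
  invisible(path)
}
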