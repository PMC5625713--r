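#' Specify a repeat family for genome simulation
#'
#' Repeat families provide the double-stranded-RNA-forming substrate that
#' ADAR hyper-editing requires: copies placed as reverse-complement
#' (inverted) pairs within a short flank can hybridise into a duplex when
#' co-transcribed, and palindromic copies (consensus approximately equal to
#' its own reverse complement) fold into a hairpin on their own.
#'
#' @param name Family label.
#' @param consensus_length Consensus length in bases.
#' @param copy_number Number of copies placed in the genome.
#' @param divergence Expected per-base substitution fraction between a copy
#'   and the consensus, in \[0, 0.35\].
#' @param palindromic If `TRUE` the consensus equals its own reverse
#'   complement (hairpin-forming family).
#' @param inverted_pair_fraction Fraction of copies placed as a
#'   reverse-complement partner pair within `pair_flank` bases.
#' @param pair_flank Maximum distance (bases) between the end of one pair
#'   member and the start of its partner (default 2000, the search flank
#'   used downstream).
#' @return A `repeat_family` list.
#' @export
repeat_family <- function(name, consensus_length = 300L, copy_number = 10L,
                          divergence = 0.1, palindromic = FALSE,
                          inverted_pair_fraction = 0, pair_flank = 2000L) {
  if (!is.numeric(divergence) || divergence < 0 || divergence > 0.35) {
    abort("`divergence` must be in [0, 0.35]")
  }
  check_fraction(inverted_pair_fraction, "inverted_pair_fraction")
  structure(list(
    name = as.character(name),
    consensus_length = check_count(consensus_length, "consensus_length", 2L),
    copy_number = check_count(copy_number, "copy_number", 0L),
    divergence = divergence,
    palindromic = isTRUE(palindromic),
    inverted_pair_fraction = inverted_pair_fraction,
    pair_flank = check_count(pair_flank, "pair_flank", 1L)
  ), class = "repeat_family")
}

#' Simulation configuration
#'
#' Defines the generative model: a random background genome carrying repeat
#' families, tiled into transcripts of 1-3 kb on both strands; reads sampled
#' uniformly from transcripts; a sampled transcript molecule is hyper-edited
#' with probability `p_transcript_edited`, in which case every adenosine of
#' its dsRNA-forming spans is deaminated independently with probability
#' `edit_rate_per_A`, modulated by the planted ADAR neighbour preference
#' (depletion when the upstream base is G; the downstream preference is set
#' by `motif_group`). Homozygous SNPs are applied to the genome copy reads
#' are drawn from (so they appear in all reads of a locus, unlike editing,
#' which is per-molecule); substitution sequencing errors are applied last.
#'
#' The default per-adenosine rate 0.3 reproduces the observed density of
#' hyper-edited duplexes, where on the order of 16% of base pairs (and so
#' roughly a third of adenosines per strand) are edited.
#'
#' @param genome_length Genome length in bases (single chromosome `chr1`).
#' @param gc_content Background GC fraction.
#' @param repeat_families List of [repeat_family()] specs.
#' @param n_reads Number of reads to simulate.
#' @param read_length Read length in bases (default 80).
#' @param edit_rate_per_A Per-adenosine editing probability within dsRNA
#'   spans of edited molecules.
#' @param p_transcript_edited Probability a sampled transcript molecule is
#'   hyper-edited.
#' @param motif_group `"downstream_G"` or `"downstream_A"`: which base is
#'   preferred immediately downstream (+1) of edited sites.
#' @param motif_strength Multiplicative boost on the editing probability
#'   when the +1 base matches the preferred base (non-preferred bases are
#'   correspondingly down-weighted).
#' @param upstream_G_depletion Multiplicative factor (< 1) on the editing
#'   probability when the -1 base is G.
#' @param seq_error_rate Per-base substitution sequencing-error probability.
#' @param snp_rate Per-base homozygous SNP probability.
#' @param stranded If `TRUE` reads are reported in transcript orientation;
#'   if `FALSE` the sequencing strand is random, so minus-strand edits
#'   appear as T-to-C mismatches against the reference.
#' @param transcript_length_range Length range (bases) of the transcripts
#'   the genome is tiled into.
#' @param coding_fraction Fraction of transcripts annotated as coding.
#' @param seed Integer seed; identical seeds give byte-identical output.
#' @return A `sim_config` list.
#' @export
sim_config <- function(genome_length = 50000L, gc_content = 0.42,
                       repeat_families = default_repeat_families(),
                       n_reads = 20000L, read_length = 80L,
                       edit_rate_per_A = 0.3, p_transcript_edited = 0.5,
                       motif_group = c("downstream_G", "downstream_A"),
                       motif_strength = 1.6,
                       upstream_G_depletion = 0.3,
                       seq_error_rate = 0.001, snp_rate = 5e-4,
                       stranded = FALSE,
                       transcript_length_range = c(1000L, 3000L),
                       coding_fraction = 0.2, seed = 1L) {
  motif_group <- match.arg(motif_group)
  cfg <- list(
    genome_length = check_count(genome_length, "genome_length", 1L),
    gc_content = check_fraction(gc_content, "gc_content"),
    repeat_families = repeat_families,
    n_reads = check_count(n_reads, "n_reads", 0L),
    read_length = check_count(read_length, "read_length", 20L),
    edit_rate_per_A = check_fraction(edit_rate_per_A, "edit_rate_per_A"),
    p_transcript_edited = check_fraction(p_transcript_edited, "p_transcript_edited"),
    motif_group = motif_group,
    motif_strength = motif_strength,
    upstream_G_depletion = upstream_G_depletion,
    seq_error_rate = check_fraction(seq_error_rate, "seq_error_rate"),
    snp_rate = check_fraction(snp_rate, "snp_rate"),
    stranded = isTRUE(stranded),
    transcript_length_range = as.integer(transcript_length_range),
    coding_fraction = check_fraction(coding_fraction, "coding_fraction"),
    seed = check_count(seed, "seed", 0L)
  )
  if (cfg$genome_length < 10L * cfg$read_length) {
    abort("`genome_length` must be at least 10 x read_length")
  }
  if (cfg$upstream_G_depletion < 0 || cfg$upstream_G_depletion > 1) {
    abort("`upstream_G_depletion` must be in [0, 1]")
  }
  structure(cfg, class = "sim_config")
}

#' Default repeat families
#'
#' One dispersed family placed mostly as inverted pairs (the classic
#' inverted-repeat dsRNA substrate) and one palindromic, hairpin-forming
#' family.
#'
#' @return List of [repeat_family()] specs.
#' @export
default_repeat_families <- function() {
  list(
    repeat_family("IRE1", consensus_length = 300L, copy_number = 10L,
                  divergence = 0.1, inverted_pair_fraction = 0.8),
    repeat_family("PAL1", consensus_length = 200L, copy_number = 4L,
                  divergence = 0.08, palindromic = TRUE)
  )
}

make_consensus <- function(fam, gc) {
  if (fam$palindromic) {
    half <- random_dna(ceiling(fam$consensus_length / 2), gc)
    cons <- paste0(half, revcomp(half))
    substr(cons, 1L, fam$consensus_length)
  } else {
    random_dna(fam$consensus_length, gc)
  }
}

# place `width` bases avoiding `occupied` intervals (tibble start/end,
# 0-based half-open); returns start or NA
place_slot <- function(width, genome_length, occupied, buffer = 50L, tries = 2000L) {
  if (width + 2L * buffer > genome_length) return(NA_integer_)
  for (i in seq_len(tries)) {
    s <- sample.int(genome_length - width - buffer, 1L) + buffer %/% 2L
    if (!nrow(occupied) ||
        !any(s < occupied$end + buffer & s + width > occupied$start - buffer)) {
      return(s)
    }
  }
  NA_integer_
}

#' Build a synthetic genome with repeat families and ground truth
#'
#' Generates the background sequence, places repeat-family copies (inverted
#' pairs, palindromic copies, and dispersed singles), tiles the genome into
#' transcripts on both strands, draws homozygous SNP positions, and records
#' everything in a truth table. dsRNA-forming spans are the union of (a)
#' both members of each inverted pair plus the intervening sequence and (b)
#' every palindromic-family copy.
#'
#' @param cfg A [sim_config()].
#' @return List with `genome` (named character vector) and `truth` (a
#'   `sim_truth` list of tibbles: `repeats`, `dsrna_spans`, `transcripts`,
#'   `snps`).
#' @export
build_genome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::local_seed(cfg$seed)
  G <- cfg$genome_length

  total_repeat <- sum(vapply(cfg$repeat_families, function(f) {
    f$copy_number * f$consensus_length * 1.5
  }, numeric(1)))
  if (total_repeat > G / 2) {
    abort("genome_length too small to host the requested repeat copies")
  }

  seq <- random_dna(G, cfg$gc_content)
  occupied <- tibble(start = integer(), end = integer())
  repeats <- list()
  spans <- list()
  copy_id <- 0L

  for (fam in cfg$repeat_families) {
    if (fam$copy_number == 0L) next
    cons <- make_consensus(fam, cfg$gc_content)
    len <- nchar(cons)
    n_paired <- round(fam$copy_number * fam$inverted_pair_fraction)
    if (n_paired %% 2L == 1L) n_paired <- n_paired - 1L
    n_pairs <- n_paired %/% 2L
    n_single <- fam$copy_number - 2L * n_pairs

    for (p in seq_len(n_pairs)) {
      max_gap <- max(100L, fam$pair_flank - len)
      gap <- sample(100:max_gap, 1L)
      width <- 2L * len + gap
      s <- place_slot(width, G, occupied)
      if (is.na(s)) abort("genome_length too small to host the requested repeat copies")
      occupied <- bind_rows(occupied, tibble(start = s, end = s + width))
      a <- mutate_seq(cons, fam$divergence)
      b <- revcomp(mutate_seq(cons, fam$divergence))
      substr(seq, s + 1L, s + len) <- a
      substr(seq, s + gap + len + 1L, s + width) <- b
      repeats <- c(repeats, list(
        tibble(chrom = "chr1", start = s, end = s + len, strand = "+",
               family = fam$name, copy_id = copy_id + 1L, pair_id = sprintf("%s_pair%d", fam$name, p)),
        tibble(chrom = "chr1", start = s + gap + len, end = s + width, strand = "-",
               family = fam$name, copy_id = copy_id + 2L, pair_id = sprintf("%s_pair%d", fam$name, p))
      ))
      copy_id <- copy_id + 2L
      spans <- c(spans, list(tibble(chrom = "chr1", start = s, end = s + width,
                                    kind = "inverted_pair",
                                    pair_id = sprintf("%s_pair%d", fam$name, p))))
    }
    for (sgl in seq_len(n_single)) {
      s <- place_slot(len, G, occupied)
      if (is.na(s)) abort("genome_length too small to host the requested repeat copies")
      occupied <- bind_rows(occupied, tibble(start = s, end = s + len))
      strand <- sample(c("+", "-"), 1L)
      copy <- mutate_seq(cons, fam$divergence)
      if (strand == "-") copy <- revcomp(copy)
      substr(seq, s + 1L, s + len) <- copy
      copy_id <- copy_id + 1L
      repeats <- c(repeats, list(
        tibble(chrom = "chr1", start = s, end = s + len, strand = strand,
               family = fam$name, copy_id = copy_id, pair_id = NA_character_)
      ))
      if (fam$palindromic) {
        spans <- c(spans, list(tibble(chrom = "chr1", start = s, end = s + len,
                                      kind = "palindrome", pair_id = NA_character_)))
      }
    }
  }

  repeats <- if (length(repeats)) bind_rows(repeats) else {
    tibble(chrom = character(), start = integer(), end = integer(),
           strand = character(), family = character(), copy_id = integer(),
           pair_id = character())
  }
  spans <- if (length(spans)) bind_rows(spans) else {
    tibble(chrom = character(), start = integer(), end = integer(),
           kind = character(), pair_id = character())
  }

  # tile into transcripts on both strands
  tx <- list()
  pos <- 0L
  while (pos < G) {
    len <- sample(cfg$transcript_length_range[1]:cfg$transcript_length_range[2], 1L)
    end <- min(pos + len, G)
    if (end - pos >= cfg$read_length) {
      tx <- c(tx, list(tibble(chrom = "chr1", start = pos, end = end,
                              strand = sample(c("+", "-"), 1L),
                              coding = runif(1) < cfg$coding_fraction)))
    }
    pos <- end
  }
  transcripts <- bind_rows(tx)

  n_snp <- rbinom(1L, G, cfg$snp_rate)
  snp_pos <- if (n_snp > 0) sort(sample.int(G, n_snp) - 1L) else integer(0)
  ref <- if (n_snp > 0) substring(seq, snp_pos + 1L, snp_pos + 1L) else character(0)
  alt <- vapply(ref, function(r) sample(setdiff(BASES, r), 1L), character(1),
                USE.NAMES = FALSE)
  snps <- tibble(chrom = rep("chr1", n_snp), pos = snp_pos, ref = ref, alt = alt)

  truth <- structure(list(
    repeats = repeats, dsrna_spans = spans, transcripts = transcripts,
    snps = snps, reads = NULL, sites = NULL
  ), class = "sim_truth")
  list(genome = c(chr1 = seq), truth = truth)
}

apply_snps <- function(genome, snps) {
  for (nm in unique(snps$chrom)) {
    s <- snps[snps$chrom == nm, ]
    ch <- strsplit(genome[[nm]], "", fixed = TRUE)[[1]]
    ch[s$pos + 1L] <- s$alt
    genome[[nm]] <- paste(ch, collapse = "")
  }
  genome
}

# per-site editing probability given transcript-strand context bases
edit_prob <- function(base_rate, up, down, cfg) {
  pref <- if (cfg$motif_group == "downstream_G") "G" else "A"
  w <- ifelse(down == pref, cfg$motif_strength, 0.8)
  p <- base_rate * w
  p[up == "G"] <- p[up == "G"] * cfg$upstream_G_depletion
  pmin(p, 1)
}

#' Simulate RNA-seq reads with planted hyper-editing
#'
#' Reads are drawn uniformly from transcripts on both strands of the
#' SNP-applied genome. A read's source molecule is hyper-edited with
#' probability `p_transcript_edited`; edits convert adenosines of the
#' transcribed strand to G within dsRNA-forming spans, at
#' `edit_rate_per_A` modulated by the planted neighbour preferences.
#' Sequencing errors are applied after editing. In unstranded mode the
#' reported sequence is the (random) sequencing strand, so minus-strand
#' edits appear as T-to-C against the reference.
#'
#' @param genome Named character vector from [build_genome()].
#' @param truth `sim_truth` from [build_genome()].
#' @param cfg The same [sim_config()].
#' @return List with `reads` (tibble: `read_id`, `seq`, `qual`) and the
#'   updated `truth` (gains `reads` and `sites` tibbles).
#' @export
simulate_reads <- function(genome, truth, cfg) {
  stopifnot(inherits(cfg, "sim_config"), inherits(truth, "sim_truth"))
  withr::local_seed(cfg$seed + 1L)
  n <- cfg$n_reads
  L <- cfg$read_length
  tx <- truth$transcripts
  if (!nrow(tx) || n == 0L) {
    if (!nrow(tx)) warn("no transcribed regions; returning an empty read set")
    truth$reads <- empty_truth_reads()
    truth$sites <- tibble(chrom = character(), pos = integer(), strand = character())
    return(list(reads = tibble(read_id = character(), seq = character(),
                               qual = character()), truth = truth))
  }
  gseq <- apply_snps(genome, truth$snps)

  tx <- tx[tx$end - tx$start >= L, ]
  ti <- sample.int(nrow(tx), n, replace = TRUE,
                   prob = tx$end - tx$start - L + 1L)
  start <- tx$start[ti] + floor(runif(n) * (tx$end[ti] - tx$start[ti] - L + 1L))
  start <- as.integer(start)
  tstrand <- tx$strand[ti]
  chrom <- tx$chrom[ti]
  fwd <- substring(gseq[["chr1"]], start + 1L, start + L)

  edited_mol <- runif(n) < cfg$p_transcript_edited
  edit_gpos <- vector("list", n)

  spans <- truth$dsrna_spans
  if (nrow(spans) && cfg$edit_rate_per_A > 0 && any(edited_mol)) {
    gch <- strsplit(gseq[["chr1"]], "", fixed = TRUE)[[1]]
    # which reads overlap a dsRNA span at all
    rd_gr <- IRanges::IRanges(start + 1L, start + L)
    sp_gr <- IRanges::IRanges(spans$start + 1L, spans$end)
    ov <- IRanges::overlapsAny(rd_gr, sp_gr)
    span_mask <- rep(FALSE, nchar(gseq[["chr1"]]))
    for (i in seq_len(nrow(spans))) {
      span_mask[(spans$start[i] + 1L):spans$end[i]] <- TRUE
    }
    for (i in which(edited_mol & ov)) {
      pos1 <- (start[i] + 1L):(start[i] + L)          # 1-based genomic
      pos1 <- pos1[span_mask[pos1]]
      base_needed <- if (tstrand[i] == "+") "A" else "T"
      pos1 <- pos1[gch[pos1] == base_needed]
      # exclude chromosome-boundary sites (no context)
      pos1 <- pos1[pos1 > 1L & pos1 < length(gch)]
      if (!length(pos1)) next
      if (tstrand[i] == "+") {
        up <- gch[pos1 - 1L]; down <- gch[pos1 + 1L]
      } else {
        up <- comp_base(gch[pos1 + 1L]); down <- comp_base(gch[pos1 - 1L])
      }
      p <- edit_prob(cfg$edit_rate_per_A, up, down, cfg)
      hit <- pos1[runif(length(pos1)) < p]
      if (!length(hit)) next
      ch <- strsplit(fwd[i], "", fixed = TRUE)[[1]]
      off <- hit - start[i]                            # 1-based within read
      ch[off] <- ifelse(tstrand[i] == "+", "G", "C")
      fwd[i] <- paste(ch, collapse = "")
      edit_gpos[[i]] <- as.integer(hit - 1L)           # 0-based genomic
    }
  }

  # orientation of the reported sequence relative to the forward reference
  seq_strand <- if (cfg$stranded) tstrand else sample(c("+", "-"), n, replace = TRUE)
  seqs <- fwd
  minus <- seq_strand == "-"
  if (any(minus)) {
    seqs[minus] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(fwd[minus]))
    )
  }

  # sequencing errors (substitutions only), after editing
  err_off <- vector("list", n)
  if (cfg$seq_error_rate > 0) {
    n_err <- rbinom(n, L, cfg$seq_error_rate)
    for (i in which(n_err > 0)) {
      off <- sample.int(L, n_err[i])
      ch <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
      for (o in off) ch[o] <- sample(setdiff(BASES, ch[o]), 1L)
      seqs[i] <- paste(ch, collapse = "")
      err_off[[i]] <- sort(as.integer(off - 1L))
    }
  }

  read_id <- sprintf("read%06d", seq_len(n))
  n_edits <- lengths(edit_gpos)
  edit_read_off <- lapply(seq_len(n), function(i) {
    g <- edit_gpos[[i]]
    if (!length(g)) return(integer(0))
    if (seq_strand[i] == "+") g - start[i] else start[i] + L - 1L - g
  })

  truth$reads <- tibble(
    read_id = read_id, chrom = chrom, start = start, end = start + L,
    transcript_strand = tstrand, sequenced_strand = seq_strand,
    edited = edited_mol & n_edits > 0L, n_edits = n_edits,
    edit_genomic_pos = edit_gpos, edit_read_offset = edit_read_off,
    error_read_offset = lapply(err_off, function(x) if (is.null(x)) integer(0) else x)
  )
  site_tbl <- truth$reads |>
    dplyr::select("chrom", "transcript_strand", "edit_genomic_pos") |>
    tidyr::unnest_longer("edit_genomic_pos", values_to = "pos") |>
    distinct(.data$chrom, .data$pos, strand = .data$transcript_strand)
  truth$sites <- arrange(site_tbl, .data$chrom, .data$pos)

  list(reads = tibble(read_id = read_id, seq = seqs, qual = strrep("?", L)),
       truth = truth)
}

empty_truth_reads <- function() {
  tibble(read_id = character(), chrom = character(), start = integer(),
         end = integer(), transcript_strand = character(),
         sequenced_strand = character(), edited = logical(),
         n_edits = integer(), edit_genomic_pos = list(),
         edit_read_offset = list(), error_read_offset = list())
}

#' Generate an ADAR-null control dataset
#'
#' The identical generative process with the editing rate forced to zero —
#' the in-silico analogue of profiling an organism without ADAR enzymes.
#' Downstream, A-to-G cluster counts should be statistically
#' indistinguishable from the other mismatch types.
#'
#' @param cfg A [sim_config()]; `edit_rate_per_A` is overridden to 0.
#' @return List with `genome`, `truth`, `reads`.
#' @export
adar_null_control <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  cfg$edit_rate_per_A <- 0
  gn <- build_genome(cfg)
  sim <- simulate_reads(gn$genome, gn$truth, cfg)
  list(genome = gn$genome, truth = sim$truth, reads = sim$reads)
}
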