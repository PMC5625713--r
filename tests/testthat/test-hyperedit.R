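test_that("min_sites reproduces the printed thresholds at both readings", {
  expect_identical(min_sites(80), 4L)
  expect_identical(min_sites(100), 5L)
  expect_identical(min_sites(20), 1L)
  expect_identical(min_sites(80, strict = TRUE), 5L)
  expect_identical(min_sites(100, strict = TRUE), 6L)
  expect_identical(min_sites(20, strict = TRUE), 2L)
  expect_error(min_sites(10), "read_length")
})

test_that("min_sites matches exact rational arithmetic for all read lengths", {
  # binary floating point must not shift the threshold (0.05 * 80 > 4 in
  # double precision); compare against integer arithmetic on 5L/100
  for (L in 20:300) {
    exact_ceil <- (5L * L) %/% 100L + as.integer((5L * L) %% 100L > 0L)
    exact_strict <- (5L * L) %/% 100L + 1L
    expect_identical(min_sites(L), exact_ceil)
    expect_identical(min_sites(L, strict = TRUE), exact_strict)
  }
})

test_that("min_sites is nondecreasing in read length", {
  v <- vapply(20:300, min_sites, integer(1))
  expect_true(all(diff(v) >= 0))
})

test_that("detect_type finds a planted A>G cluster and records its span", {
  g <- fx_tiny_genome()
  r <- substr(g[["chrA"]], 101, 180)
  ch <- strsplit(r, "")[[1]]
  a_pos <- which(ch == "A")
  a_pos <- a_pos[a_pos > 8 & a_pos <= 72][1:5]  # clear of the end deciles
  ch[a_pos] <- "G"
  reads <- tibble::tibble(read_id = "h1", seq = paste(ch, collapse = ""),
                          qual = strrep("I", 80))
  hr <- detect_type(reads, g, "A>G")
  expect_identical(nrow(hr), 1L)
  expect_identical(hr$mismatch_type, "A>G")
  expect_identical(hr$n_candidates, 5L)
  expect_identical(hr$other_mismatches, 0L)
  expect_identical(hr$candidate_gpos[[1]], 100L + a_pos - 1L)
  expect_identical(hr$cluster_start, min(100L + a_pos - 1L))
  expect_identical(hr$cluster_end, max(100L + a_pos - 1L) + 1L)
  expect_identical(hr$aln_start, 100L)
  expect_identical(hr$aln_end, 180L)
  # no cluster of an unrelated type
  expect_identical(nrow(detect_type(reads, g, "C>T")), 0L)
  # three sites are below the 80-bp threshold of four
  ch2 <- strsplit(r, "")[[1]]
  ch2[a_pos[1:3]] <- "G"
  reads3 <- tibble::tibble(read_id = "h2", seq = paste(ch2, collapse = ""),
                           qual = strrep("I", 80))
  expect_identical(nrow(detect_type(reads3, g, "A>G")), 0L)
})

test_that("clean-read filters reject edge-confined, noisy and low-quality clusters", {
  g <- fx_tiny_genome()
  # plant a run of adenosines at the start of the window so the edge filter
  # has something to reject
  substr(g[["chrA"]], 101, 106) <- "AAAAAA"
  base <- substr(g[["chrA"]], 101, 180)

  plant <- function(offsets1, extra = NULL, qual = strrep("I", 80)) {
    ch <- strsplit(base, "")[[1]]
    stopifnot(all(ch[offsets1] == "A"))
    ch[offsets1] <- "G"
    if (!is.null(extra)) {
      for (p in extra) ch[p] <- chartr("ACGT", "GTAC", ch[p])
    }
    tibble::tibble(read_id = "r", seq = paste(ch, collapse = ""), qual = qual)
  }
  a_pos <- which(strsplit(base, "")[[1]] == "A")
  mid <- a_pos[a_pos > 8 & a_pos <= 72]

  # all candidate sites inside the first decile (offsets 0-7) -> rejected
  head_sites <- 1:4
  expect_identical(nrow(detect_type(plant(head_sites), g, "A>G")), 0L)

  # same number of sites in the read body -> accepted
  expect_identical(nrow(detect_type(plant(mid[1:4]), g, "A>G")), 1L)

  # too many non-candidate mismatches -> rejected (cap is max(1, 2) = 2 at 80 bp)
  nonA <- setdiff(which(!strsplit(base, "")[[1]] %in% "A"), c(mid[1:5], a_pos))
  noisy <- plant(mid[1:5], extra = nonA[c(10, 20, 30)])
  expect_identical(nrow(detect_type(noisy, g, "A>G")), 0L)
  ok_noise <- plant(mid[1:5], extra = nonA[c(10, 20)])
  expect_identical(nrow(detect_type(ok_noise, g, "A>G")), 1L)

  # low quality at candidate sites -> rejected when qualities are informative
  q <- strsplit(strrep("I", 80), "")[[1]]
  q[mid[1:5]] <- "#"            # Q2 at every candidate
  q[1] <- "J"                   # make the string non-constant (informative)
  lowq <- plant(mid[1:5], qual = paste(q, collapse = ""))
  expect_identical(nrow(detect_type(lowq, g, "A>G")), 0L)
  # constant qualities are uninformative and do not filter
  allsame <- plant(mid[1:5], qual = strrep("#", 80))
  expect_identical(nrow(detect_type(allsame, g, "A>G")), 1L)
})

test_that("minus-strand clusters report reference-forward types (unstranded)", {
  g <- fx_tiny_genome()
  fwd <- substr(g[["chrA"]], 201, 280)
  ch <- strsplit(fwd, "")[[1]]
  t_pos <- which(ch == "T")
  t_pos <- t_pos[t_pos > 8 & t_pos <= 72][1:5]
  ch[t_pos] <- "C"              # T>C on the forward reference
  read_minus <- revcomp(paste(ch, collapse = ""))  # sequenced from minus strand
  reads <- tibble::tibble(read_id = "m", seq = read_minus, qual = strrep("I", 80))
  hr <- detect_type(reads, g, "T>C")
  expect_identical(nrow(hr), 1L)
  expect_identical(hr$strand, "-")
  expect_identical(hr$candidate_gpos[[1]], 200L + t_pos - 1L)
  # the same read carries no A>G cluster in reference-forward terms
  expect_identical(nrow(detect_type(reads, g, "A>G")), 0L)
})

test_that("stranded detection re-types minus-strand alignments", {
  # a minus-strand transcript edited at adenosines shows T>C on the forward
  # reference; in stranded mode it must be reported as A>G
  g <- fx_tiny_genome()
  fwd <- substr(g[["chrA"]], 201, 280)
  ch <- strsplit(fwd, "")[[1]]
  t_pos <- which(ch == "T")
  t_pos <- t_pos[t_pos > 8 & t_pos <= 72][1:5]
  ch[t_pos] <- "C"
  read_minus <- revcomp(paste(ch, collapse = ""))
  reads <- tibble::tibble(read_id = "m", seq = read_minus, qual = strrep("I", 80))
  hr <- detect_type(reads, g, "A>G", stranded = TRUE)
  expect_identical(nrow(hr), 1L)
  expect_identical(hr$mismatch_type, "A>G")
  expect_identical(hr$strand, "-")
  screen <- run_all_types(reads, g, stranded = TRUE)
  expect_identical(screen$report$n_reads[screen$report$mismatch_type == "A>G"], 1L)
  expect_identical(sum(screen$report$n_reads), 1L)
})

test_that("run_all_types screens all 12 types symmetrically", {
  d <- fx_small()
  rep <- d$screen$report
  expect_identical(rep$mismatch_type, mismatch_types())
  expect_identical(sum(rep$n_reads), nrow(d$screen$hyper_reads))
  # in a noiseless unstranded dataset only the A>G/T>C pair fires
  firing <- rep$mismatch_type[rep$n_reads > 0]
  expect_true(all(firing %in% c("A>G", "T>C")))
  expect_gt(sum(rep$n_reads), 100)
  # every hyper read carries at least min_sites(80) = 4 candidates
  expect_true(all(d$screen$hyper_reads$n_candidates >= 4L))
  # n_events is the candidate total, n_sites the distinct positions
  ag <- d$screen$hyper_reads[d$screen$hyper_reads$mismatch_type == "A>G", ]
  expect_identical(rep$n_events[rep$mismatch_type == "A>G"],
                   sum(ag$n_candidates))
  expect_identical(
    rep$n_sites[rep$mismatch_type == "A>G"],
    nrow(dplyr::distinct(tibble::tibble(
      chrom = rep(ag$chrom, lengths(ag$candidate_gpos)),
      pos = unlist(ag$candidate_gpos))))
  )
})

test_that("candidate sites are uniformly distributed across read positions", {
  # editing has no positional preference within a read, so pooled candidate
  # offsets should be uniform (chi-square over deciles)
  d <- fx_noiseless()
  offs <- unlist(d$ag$candidate_offsets)
  expect_gt(length(offs), 2000)
  bins <- table(cut(offs, breaks = seq(0, 80, by = 8), right = FALSE,
                    include.lowest = TRUE))
  p <- stats::chisq.test(bins)$p.value
  expect_gt(p, 0.001)
})

test_that("collapse_sites aggregates support and canonicalises strands", {
  # two A>G reads sharing a site, plus a T>C read at the same position:
  # unstranded collapse merges them into one A>G site, strand-unresolved
  hr <- dplyr::bind_rows(
    hyper_row("r1", "A>G", "chr1", 100L, "+", c(110L, 120L, 130L, 140L)),
    hyper_row("r2", "A>G", "chr1", 105L, "+", c(120L, 130L, 140L, 150L)),
    hyper_row("r3", "T>C", "chr1", 108L, "-", c(120L, 125L, 133L, 141L))
  )
  sites <- collapse_sites(hr)
  expect_true(all(sites$mismatch_type == "A>G"))  # T>C canonicalised
  s120 <- sites[sites$pos == 120L, ]
  expect_identical(s120$support, 3L)
  expect_false(s120$strand_resolved)
  s110 <- sites[sites$pos == 110L, ]
  expect_identical(s110$support, 1L)
  expect_true(s110$strand_resolved)
  expect_identical(s110$strand, "+")
  s125 <- sites[sites$pos == 125L, ]
  expect_identical(s125$strand, "-")  # T>C cluster = minus-strand A>G site
  expect_identical(sum(sites$support), 12L)

  # stranded mode keeps the alignment strand and reported type
  sst <- collapse_sites(hr, stranded = TRUE)
  expect_true("T>C" %in% sst$mismatch_type)

  empty <- collapse_sites(hr[0, ])
  expect_identical(nrow(empty), 0L)
  expect_named(empty, c("chrom", "pos", "strand", "mismatch_type",
                        "support", "strand_resolved"))
})

test_that("trim_to shortens long reads from the 5' end before detection", {
  g <- fx_tiny_genome()
  r <- substr(g[["chrA"]], 101, 200)  # 100 bp
  ch <- strsplit(r, "")[[1]]
  a_pos <- which(ch[31:90] == "A") + 30L  # sites in the retained 3' part
  a_pos <- a_pos[1:5]
  ch[a_pos] <- "G"
  reads <- tibble::tibble(read_id = "long", seq = paste(ch, collapse = ""),
                          qual = strrep("I", 100))
  hr <- detect_type(reads, g, "A>G", opts = detect_opts(trim_to = 80L))
  expect_identical(nrow(hr), 1L)
  expect_identical(hr$aln_end - hr$aln_start, 80L)
  expect_identical(hr$candidate_gpos[[1]], 100L + a_pos - 1L)
})
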