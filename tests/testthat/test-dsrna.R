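test_that("local_align scores identity and divergence as expected", {
  withr::with_seed(71, s <- random_dna(200, 0.5))
  self <- local_align(s, s)
  expect_identical(self$score, 400)        # 200 matches x 2
  expect_identical(self$identity, 1)
  expect_identical(self$aligned_length, 200L)
  expect_identical(self$gaps, 0L)
  expect_identical(self$q_start, 0L)
  expect_identical(self$q_end, 200L)

  withr::with_seed(72, m <- mutate_seq(s, 0.3))
  div <- local_align(s, m)
  expect_lt(div$identity, 1)
  expect_gt(div$identity, 0.5)
  # symmetric scoring regime -> symmetric best score
  expect_identical(local_align(s, m)$score, local_align(m, s)$score)

  expect_error(local_align_params(match = -1, mismatch = -3), "positive")
  expect_error(local_align_params(match = 2, mismatch = 1), "negative")
})

test_that("local_align equals the full affine-gap DP oracle", {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                  baseOnly = TRUE)
  params <- local_align_params(word_size = 1L)  # disable the word gate
  withr::with_seed(73, {
    for (i in 1:12) {
      lq <- sample(60:300, 1)
      q <- random_dna(lq, 0.5)
      s <- if (i %% 3 == 0) random_dna(sample(60:300, 1), 0.5) else {
        paste0(random_dna(30, 0.5),
               mutate_seq(substr(q, 5, min(lq, 5 + 150)), 0.15),
               random_dna(30, 0.5))
      }
      ours <- local_align(q, s, params)$score
      ref <- Biostrings::score(Biostrings::pairwiseAlignment(
        q, s, type = "local", substitutionMatrix = mat,
        gapOpening = 5, gapExtension = 2))
      expect_equal(ours, ref)
    }
  })
})

test_that("the word prefilter gates dissimilar pairs to a zero-score row", {
  hit <- local_align("AAAAAAAAAA", "CCCCCCCCCC",
                     local_align_params(word_size = 4L))
  expect_identical(hit$score, 0)
  expect_identical(hit$aligned_length, 0L)
})

test_that("find_dsrna_partner locates a planted inverted copy exactly", {
  withr::with_seed(81, {
    bgL <- random_dna(700, 0.45)
    mid <- random_dna(300, 0.45)
    bgR <- random_dna(700, 0.45)
    x <- random_dna(150, 0.45)
  })
  # x at 700..850, revcomp(x) at 1150..1300
  g <- c(chr1 = paste0(bgL, x, mid, revcomp(x), bgR))
  cl <- tibble::tibble(chrom = "chr1", start = 700L, end = 850L)
  hit <- find_dsrna_partner(cl, g)
  expect_identical(nrow(hit), 1L)
  expect_identical(hit$orientation, "reverse")
  expect_identical(hit$identity, 1)
  expect_gte(hit$coverage_of_query, 1)
  expect_identical(hit$partner_start, 1150L)
  expect_identical(hit$partner_end, 1300L)

  # a diverged partner still qualifies above 65% identity
  withr::with_seed(82, xd <- mutate_seq(x, 0.15))
  g2 <- c(chr1 = paste0(bgL, x, mid, revcomp(xd), bgR))
  hit2 <- find_dsrna_partner(cl, g2)
  expect_identical(nrow(hit2), 1L)
  expect_gte(hit2$identity, 0.65)
  expect_lt(hit2$identity, 1)

  # no partner within the flank -> no hit
  withr::with_seed(83, far <- random_dna(2050, 0.45))
  g3 <- c(chr1 = paste0(bgL, x, far, revcomp(x), bgR))
  expect_identical(nrow(find_dsrna_partner(tibble::tibble(
    chrom = "chr1", start = 700L, end = 850L), g3)), 0L)
})

test_that("a palindromic cluster is its own reverse-orientation partner", {
  withr::with_seed(84, {
    half <- random_dna(80, 0.45)
    pad <- random_dna(400, 0.45)
    pad2 <- random_dna(400, 0.45)
  })
  pal <- paste0(half, revcomp(half))
  g <- c(chr1 = paste0(pad, pal, pad2))
  cl <- tibble::tibble(chrom = "chr1", start = 400L, end = 560L)
  hit <- find_dsrna_partner(cl, g)
  expect_identical(nrow(hit), 1L)
  expect_identical(hit$identity, 1)
  # the partner is the cluster itself read in reverse orientation
  expect_identical(hit$partner_start, 400L)
  expect_identical(hit$partner_end, 560L)
})

test_that("the same-strand control masks the trivial self-hit", {
  withr::with_seed(85, {
    bg1 <- random_dna(500, 0.45)
    bg2 <- random_dna(500, 0.45)
    bg3 <- random_dna(500, 0.45)
    x <- random_dna(150, 0.45)
  })
  # direct (same-orientation) copies -> the control fires
  g_direct <- c(chr1 = paste0(bg1, x, bg2, x, bg3))
  cl <- tibble::tibble(chrom = "chr1", start = 500L, end = 650L)
  hit <- control_same_strand(cl, g_direct)
  expect_identical(nrow(hit), 1L)
  expect_identical(hit$orientation, "same-strand-control")
  expect_identical(hit$partner_start, 1150L)
  expect_identical(hit$partner_end, 1300L)

  # a lone copy: the only similar sequence is the query itself -> masked, no hit
  g_lone <- c(chr1 = paste0(bg1, x, bg2, bg3))
  expect_identical(nrow(control_same_strand(cl, g_lone)), 0L)

  # an inverted copy does not fire the same-strand control
  g_inv <- c(chr1 = paste0(bg1, x, bg2, revcomp(x), bg3))
  expect_identical(nrow(control_same_strand(cl, g_inv)), 0L)
})

test_that("genomic dsRNA potential is ~0 for random sequence and detects planted pairs", {
  withr::with_seed(86, g_rand <- c(chr1 = random_dna(12000, 0.45)))
  pot0 <- genomic_dsrna_potential(g_rand, 300, seed = 1)
  expect_identical(pot0, 0)

  # plant perfect inverted pairs over ~10% of a genome
  withr::with_seed(87, {
    parts <- character(0)
    for (i in 1:4) {
      x <- random_dna(150, 0.45)
      parts <- c(parts, random_dna(1100, 0.45), x, random_dna(300, 0.45),
                 revcomp(x), random_dna(1100, 0.45))
    }
    g_pairs <- c(chr1 = paste(parts, collapse = ""))
  })
  pot1 <- genomic_dsrna_potential(g_pairs, 400, seed = 2)
  frac_planted <- 4 * 2 * 150 / nchar(g_pairs[["chr1"]])
  expect_gt(pot1, frac_planted / 3)
  expect_lt(pot1, frac_planted * 3)

  # deterministic given the seed, invalid window counts rejected
  expect_identical(pot1, genomic_dsrna_potential(g_pairs, 400, seed = 2))
  expect_error(genomic_dsrna_potential(g_rand, 0), "n_windows")
  expect_error(genomic_dsrna_potential(c(chr1 = "ACGT"), 10), "window")
})

test_that("dsrna_editing_enrichment computes the density ratio", {
  g <- c(chr1 = strrep("A", 10000))
  hits <- tibble::tibble(chrom = "chr1", q_start = 1000L, q_end = 1500L,
                         partner_start = 2000L, partner_end = 2500L,
                         orientation = "reverse", identity = 1,
                         aligned_length = 500L, coverage_of_query = 1,
                         score = 1000)
  sites <- tibble::tibble(chrom = "chr1",
                          pos = c(1100L, 1200L, 2100L, 5000L))
  # 3 sites in 1000 bp vs 1 site in 9000 bp -> 27x
  expect_equal(dsrna_editing_enrichment(hits, sites, g), 27)
  # all sites inside -> infinite enrichment
  expect_identical(dsrna_editing_enrichment(hits, sites[1:3, ], g), Inf)
  expect_warning(e <- dsrna_editing_enrichment(hits, sites[0, ], g), "no sites")
  expect_true(is.na(e))
  expect_warning(e2 <- dsrna_editing_enrichment(hits[0, ], sites, g), "no dsRNA hits")
  expect_true(is.na(e2))
})

test_that("editing is enriched in predicted dsRNA regions of the simulated data", {
  d <- fx_small()
  gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
    d$ag$chrom, IRanges::IRanges(d$ag$cluster_start + 1L, d$ag$cluster_end)))
  loci <- tibble::tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
                         start = GenomicRanges::start(gr) - 1L,
                         end = GenomicRanges::end(gr))
  hits <- dplyr::bind_rows(lapply(seq_len(nrow(loci)), function(i)
    find_dsrna_partner(loci[i, ], d$genome)))
  expect_gt(nrow(hits), 0)
  expect_true(all(hits$identity >= 0.65))
  expect_true(all(hits$coverage_of_query >= 0.8))
  enrich <- dsrna_editing_enrichment(hits, d$sites, d$genome)
  expect_gt(enrich, 2)
})
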