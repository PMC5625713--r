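test_that("transform_scheme validates and rewrites as expected", {
  s <- transform_scheme("a", "g")
  expect_identical(s$from, "A")
  expect_identical(s$to, "G")
  expect_error(transform_scheme("A", "A"), "distinct")
  expect_error(transform_scheme("A", "N"), "distinct bases")
})

test_that("the k-mer index stores exact forward-strand occurrences", {
  g <- c(chr1 = "ACGTACGTACGTAAAA", chr2 = "TTTTACGTACGT")
  idx <- build_index(g, k = 8)
  hits <- index_lookup(idx, "ACGTACGT")
  expect_identical(hits$chrom, c("chr1", "chr1", "chr2"))
  expect_identical(hits$pos, c(0L, 4L, 4L))
  expect_identical(nrow(index_lookup(idx, "GGGGGGGG")), 0L)
  expect_true("AAAACGTA" %in% index_kmers(idx) == FALSE) # sanity: not present
  expect_true("CGTACGTA" %in% index_kmers(idx))
  expect_error(build_index(g, k = 20), "shortest")
})

test_that("a transformed index collapses the from-base before matching", {
  g <- c(chr1 = "AAGAAGAAGAAG")
  idx <- build_index(g, k = 6, scheme = transform_scheme("A", "G"))
  # every k-mer becomes all-G after A->G
  expect_identical(index_kmers(idx), "GGGGGG")
})

test_that("align_read recovers planted placements, strand and mismatch lists", {
  g <- fx_tiny_genome()
  idx <- build_index(g, k = 16)

  r <- substr(g[["chrA"]], 201, 280)
  a <- align_read(r, idx, read_id = "exact")
  expect_true(a$mapped)
  expect_identical(a$chrom, "chrA")
  expect_identical(a$start, 200L)
  expect_identical(a$strand, "+")
  expect_identical(a$mm_transformed, 0L)
  expect_identical(a$n_native_mm, 0L)
  expect_true(a$unique)

  # two planted substitutions are reported at their offsets, ref>alt
  r2 <- r
  old5 <- substr(r2, 6, 6); substr(r2, 6, 6) <- chartr("ACGT", "GTAC", old5)
  old40 <- substr(r2, 41, 41); substr(r2, 41, 41) <- chartr("ACGT", "GTAC", old40)
  a2 <- align_read(r2, idx)
  expect_identical(a2$start, 200L)
  expect_identical(a2$n_native_mm, 2L)
  mm <- strsplit(a2$mismatches, ";")[[1]]
  expect_identical(mm[1], paste0("5:", old5, ">", substr(r2, 6, 6)))
  expect_identical(mm[2], paste0("40:", old40, ">", substr(r2, 41, 41)))

  # reverse-strand placement; mismatch offsets are reference-forward
  r3 <- revcomp(r2)
  a3 <- align_read(r3, idx)
  expect_identical(a3$strand, "-")
  expect_identical(a3$start, 200L)
  expect_identical(a3$mismatches, a2$mismatches)

  # a read over the mismatch budget stays unmapped
  r4 <- r
  for (p in c(5L, 25L, 45L, 65L)) {
    substr(r4, p, p) <- chartr("ACGT", "GTAC", substr(r4, p, p))
  }
  expect_false(align_read(r4, idx, max_mm = 3)$mapped)
  expect_true(align_read(r4, idx, max_mm = 4)$mapped)
})

test_that("tied best placements are flagged non-unique", {
  dup <- withr::with_seed(5, random_dna(80, 0.5))
  pad <- withr::with_seed(6, random_dna(40, 0.5))
  g <- c(chr1 = paste0(pad, dup, pad, dup, pad))
  idx <- build_index(g)
  a <- align_read(dup, idx)
  expect_true(a$mapped)
  expect_false(a$unique)
})

test_that("seed-and-extend equals an exhaustive scan when the pigeonhole bound holds", {
  # L = 80 >= (max_mm + 1) * k = 64, so every placement with <= 3 mismatches
  # must be found; verified against Biostrings' exhaustive edit-distance scan
  g <- fx_tiny_genome()
  idx <- build_index(g, k = 16)
  L <- 80L

  oracle <- function(read, max_mm) {
    res <- list()
    for (nm in names(g)) {
      subj <- Biostrings::DNAString(g[[nm]])
      n <- nchar(g[[nm]]) - L + 1L
      for (str in c("+", "-")) {
        pat <- Biostrings::DNAString(if (str == "+") read else revcomp(read))
        ed <- Biostrings::neditStartingAt(pat, subj, starting.at = seq_len(n),
                                          fixed = TRUE)
        res[[paste(nm, str)]] <- ed
      }
    }
    best <- min(vapply(res, min, numeric(1)))
    hits <- do.call(rbind, lapply(names(res), function(k) {
      w <- which(res[[k]] == best)
      if (!length(w)) NULL else data.frame(key = k, pos = w - 1L)
    }))
    list(best = best, hits = hits)
  }

  withr::with_seed(17, {
    for (i in 1:40) {
      nm <- sample(names(g), 1)
      s <- sample.int(nchar(g[[nm]]) - L, 1)
      r <- mutate_seq(substr(g[[nm]], s, s + L - 1), sample(c(0, 0.02, 0.1), 1))
      if (runif(1) < 0.5) r <- revcomp(r)
      a <- align_read(r, idx, max_mm = 3)
      o <- oracle(r, 3)
      if (o$best <= 3) {
        expect_true(a$mapped)
        expect_identical(a$mm_transformed, as.integer(o$best))
        expect_true(paste(a$chrom, a$strand) %in% o$hits$key)
        expect_true(a$start %in% o$hits$pos[o$hits$key == paste(a$chrom, a$strand)])
        expect_identical(a$unique, nrow(o$hits) == 1L)
      } else {
        expect_false(a$mapped)
      }
    }
  })
})

test_that("transformed-space alignment equals aligning chartr-rewritten sequences", {
  g <- fx_tiny_genome()
  scheme <- transform_scheme("A", "G")
  idx_t <- build_index(g, k = 12, scheme = scheme)
  g_x <- vapply(g, function(s) chartr("A", "G", s), character(1))
  idx_x <- build_index(g_x, k = 12)
  withr::with_seed(23, {
    for (i in 1:20) {
      s <- sample.int(nchar(g[["chrA"]]) - 80, 1)
      r <- mutate_seq(substr(g[["chrA"]], s, s + 79), 0.03)
      a_t <- align_read(r, idx_t, max_mm = 2)
      a_x <- align_read(chartr("A", "G", r), idx_x, max_mm = 2)
      expect_identical(a_t[c("mapped", "chrom", "start", "strand",
                             "mm_transformed", "unique")],
                       a_x[c("mapped", "chrom", "start", "strand",
                             "mm_transformed", "unique")])
    }
  })
})

test_that("a heavily edited read fails the native pass but maps after A->G collapse", {
  g <- fx_tiny_genome()
  r <- substr(g[["chrA"]], 301, 380)
  ch <- strsplit(r, "")[[1]]
  a_pos <- which(ch == "A")[1:6]
  ch[a_pos] <- "G"
  edited <- paste(ch, collapse = "")
  expect_false(align_read(edited, build_index(g), max_mm = 3)$mapped)
  a <- align_read(edited, build_index(g, scheme = transform_scheme("A", "G")),
                  max_mm = 3)
  expect_true(a$mapped)
  expect_identical(a$start, 300L)
  expect_identical(a$mm_transformed, 0L)  # A>G mismatches vanish when collapsed
  expect_identical(a$n_native_mm, 6L)     # ...but are recovered natively
  mm <- strsplit(a$mismatches, ";")[[1]]
  expect_true(all(grepl("A>G$", mm)))
  expect_identical(as.integer(sub(":.*", "", mm)), a_pos - 1L)
})

test_that("align_batch partitions reads and counts mapped bases", {
  g <- fx_tiny_genome()
  good <- substr(g[["chrA"]], 1, 60)
  bad <- strrep("ACGT", 15)  # repetitive, absent from the genome
  reads <- tibble::tibble(read_id = c("g", "b"), seq = c(good, bad),
                          qual = strrep("I", 60))
  batch <- align_batch(reads, g, max_mm = 2, k = 12)
  expect_identical(batch$mapped$read_id, "g")
  expect_identical(batch$unmapped$read_id, "b")
  expect_identical(batch$mapped_bases, 60L)
  expect_identical(nrow(batch$alignments), 2L)

  empty <- align_batch(reads[0, ], g)
  expect_identical(empty$mapped_bases, 0)
  expect_identical(nrow(empty$alignments), 0L)
})

test_that("max_mm_scaled applies the 4%-of-length rule", {
  expect_identical(max_mm_scaled(80), 3L)
  expect_identical(max_mm_scaled(100), 4L)
  expect_identical(max_mm_scaled(25), 1L)
  expect_identical(max_mm_scaled(10), 1L)  # floor at 1
})
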