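context_bases <- function(genome, chrom, pos, strand) {
  # -1 (upstream) and +1 (downstream) neighbours in edited-strand orientation
  seq <- genome[[chrom]]
  if (strand == "+") {
    c(up = substr(seq, pos, pos), down = substr(seq, pos + 2L, pos + 2L))
  } else {
    c(up = comp_base(substr(seq, pos + 2L, pos + 2L)),
      down = comp_base(substr(seq, pos, pos)))
  }
}

tally_contexts <- function(genome, df) {
  counts <- matrix(0L, nrow = 4L, ncol = 2L,
                   dimnames = list(BASES, c("-1", "+1")))
  for (i in seq_len(nrow(df))) {
    ctx <- context_bases(genome, df$chrom[i], df$pos[i], df$strand[i])
    if (ctx[["up"]] %in% BASES) {
      counts[ctx[["up"]], "-1"] <- counts[ctx[["up"]], "-1"] + 1L
    }
    if (ctx[["down"]] %in% BASES) {
      counts[ctx[["down"]], "+1"] <- counts[ctx[["down"]], "+1"] + 1L
    }
  }
  counts
}

# adenosines of the edited strand inside cluster spans, excluding `exclude`
span_adenosines <- function(genome, spans, exclude) {
  out <- list()
  key <- paste(exclude$chrom, exclude$pos, exclude$strand)
  for (i in seq_len(nrow(spans))) {
    seq <- genome[[spans$chrom[i]]]
    s <- spans$start[i]; e <- spans$end[i]
    bases <- strsplit(substr(seq, s + 1L, e), "", fixed = TRUE)[[1]]
    want <- if (spans$strand[i] == "+") "A" else "T"
    pos <- s + which(bases == want) - 1L
    if (length(pos)) {
      out[[length(out) + 1L]] <- tibble(chrom = spans$chrom[i], pos = pos,
                                        strand = spans$strand[i])
    }
  }
  if (!length(out)) {
    return(tibble(chrom = character(), pos = integer(), strand = character()))
  }
  bg <- distinct(bind_rows(out))
  bg[!(paste(bg$chrom, bg$pos, bg$strand) %in% key), , drop = FALSE]
}

#' Neighbour-preference profile around edited sites
#'
#' Tallies the bases one position upstream (-1) and one downstream (+1) of
#' unique edited sites, in edited-strand orientation (the site itself is
#' excluded), and the same for background adenosines. Enrichment is the
#' per-position base fraction at sites divided by the background fraction.
#' The default background is the unedited adenosines within the detected
#' cluster spans, which controls for the local composition of edited
#' regions; `background = "genome"` uses all adenosines genome-wide (both
#' strands).
#'
#' @param sites Strand-resolved site tibble (`chrom`, `pos`, `strand`).
#'   Sites at sequence boundaries are skipped.
#' @param genome Named character vector of sequences.
#' @param cluster_spans Tibble of cluster spans (`chrom`, `start`, `end`,
#'   `strand`), typically the per-read cluster spans of the detected
#'   hyper-edited reads; required for the `"cluster"` background.
#' @param background `"cluster"` or `"genome"`.
#' @param min_confident Profiles built from fewer usable sites are flagged
#'   low-confidence (default 50).
#' @return A `motif_profile` object: count, background and enrichment
#'   matrices (4 bases x positions -1/+1), plus `n_sites` and
#'   `low_confidence`.
#' @export
build_profile <- function(sites, genome, cluster_spans = NULL,
                          background = c("cluster", "genome"),
                          min_confident = 50L) {
  background <- match.arg(background)
  usable <- sites[sites$pos > 0L &
                    sites$pos < nchar(genome[sites$chrom]) - 1L, , drop = FALSE]
  counts <- tally_contexts(genome, usable)

  if (background == "cluster") {
    if (is.null(cluster_spans)) {
      abort("`cluster_spans` is required for the cluster background")
    }
    bg_pos <- span_adenosines(genome, cluster_spans, usable)
  } else {
    bg_pos <- bind_rows(lapply(names(genome), function(nm) {
      ch <- strsplit(genome[[nm]], "", fixed = TRUE)[[1]]
      bind_rows(
        tibble(chrom = nm, pos = which(ch == "A") - 1L, strand = "+"),
        tibble(chrom = nm, pos = which(ch == "T") - 1L, strand = "-")
      )
    }))
    bg_pos <- bg_pos[!(paste(bg_pos$chrom, bg_pos$pos, bg_pos$strand) %in%
                         paste(usable$chrom, usable$pos, usable$strand)), ]
  }
  bg_pos <- bg_pos[bg_pos$pos > 0L &
                     bg_pos$pos < nchar(genome[bg_pos$chrom]) - 1L, , drop = FALSE]
  bg_counts <- tally_contexts(genome, bg_pos)

  freq <- sweep(counts, 2L, pmax(colSums(counts), 1L), "/")
  bg_freq <- sweep(bg_counts, 2L, pmax(colSums(bg_counts), 1L), "/")
  enrichment <- freq / bg_freq
  enrichment[bg_freq == 0] <- NA_real_

  structure(list(counts = counts, background = bg_counts,
                 enrichment = enrichment, n_sites = nrow(usable),
                 low_confidence = nrow(usable) < min_confident),
            class = "motif_profile")
}

#' @export
print.motif_profile <- function(x, ...) {
  cat(sprintf("<motif_profile> %d sites%s\n", x$n_sites,
              if (x$low_confidence) " (low confidence)" else ""))
  cat("enrichment (site freq / background freq):\n")
  print(round(x$enrichment, 3))
  invisible(x)
}

#' @describeIn build_profile Tidy a motif profile into a long tibble.
#' @param x A `motif_profile`.
#' @param ... Unused.
#' @export
tidy.motif_profile <- function(x, ...) {
  tidyr::expand_grid(base = BASES, position = c("-1", "+1")) |>
    mutate(
      count = x$counts[cbind(.data$base, .data$position)],
      background = x$background[cbind(.data$base, .data$position)],
      enrichment = x$enrichment[cbind(.data$base, .data$position)]
    )
}

#' Upstream-G depletion of a motif profile
#'
#' ADAR avoids a guanosine immediately 5' of the edited adenosine; values
#' below 1 for the G enrichment at -1 reproduce that depletion.
#'
#' @param profile A [build_profile()] result.
#' @return The enrichment of G at position -1 (`NA` with a warning when
#'   the background has no G at -1).
#' @export
upstream_depletion <- function(profile) {
  stopifnot(inherits(profile, "motif_profile"))
  if (profile$background["G", "-1"] == 0) {
    warn("background has no G at -1; upstream depletion is undefined")
    return(NA_real_)
  }
  unname(profile$enrichment["G", "-1"])
}

profile_vector <- function(p) {
  v <- as.vector(p$enrichment)
  names(v) <- paste0(rep(BASES, 2), rep(c("@-1", "@+1"), each = 4))
  v[!is.finite(v) | v <= 0] <- 1
  # enrichment ratios are multiplicative: a 2-fold depletion (0.5) should be
  # as far from neutral (1) as a 2-fold enrichment (2), so cluster on log2
  log2(v)
}

#' Cluster neighbour-preference profiles across datasets
#'
#' Agglomerative clustering (average linkage, Euclidean distance) on the
#' 8-dimensional log2-enrichment vectors, cut at `k` groups. Identical
#' profiles are split deterministically in input (label) order.
#'
#' @param profiles Named list of [build_profile()] results (>= 2).
#' @param k Number of groups (default 2).
#' @return A `motif_clustering` object with the group assignment and the
#'   `hclust` linkage; [tidy()] returns the assignment tibble.
#' @export
cluster_profiles <- function(profiles, k = 2L) {
  if (length(profiles) < 2L) abort("at least 2 profiles are required")
  if (is.null(names(profiles)) || any(!nzchar(names(profiles)))) {
    abort("`profiles` must be a named list")
  }
  mat <- do.call(rbind, lapply(profiles, profile_vector))
  rownames(mat) <- names(profiles)
  hc <- hclust(dist(mat), method = "average")
  k <- min(k, nrow(mat))
  groups <- cutree(hc, k = k)
  structure(list(
    groups = tibble(label = names(profiles), group = unname(groups[names(profiles)])),
    hclust = hc, k = k, matrix = mat
  ), class = "motif_clustering")
}

#' @export
print.motif_clustering <- function(x, ...) {
  cat(sprintf("<motif_clustering> %d profiles in %d groups\n",
              nrow(x$groups), x$k))
  print(x$groups)
  invisible(x)
}

#' @describeIn cluster_profiles Tidy the group assignment.
#' @param x A `motif_clustering`.
#' @param ... Unused.
#' @export
tidy.motif_clustering <- function(x, ...) x$groups
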