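#' Normalized hyper-editing signal
#'
#' Editing events per million mapped bases — the cross-dataset comparison
#' metric.
#'
#' @param events Number of candidate mismatches in detected clusters.
#' @param mapped_bases Total mapped bases (initial pass plus rescued
#'   hyper-edited reads).
#' @return `events * 1e6 / mapped_bases`.
#' @export
normalized_signal <- function(events, mapped_bases) {
  if (!is.numeric(mapped_bases) || any(mapped_bases <= 0)) {
    abort("`mapped_bases` must be positive; the signal is undefined otherwise")
  }
  events * 1e6 / mapped_bases
}

signal_pair_types <- function(stranded) {
  if (stranded) {
    list(signal = "A>G", fp = "G>A")
  } else {
    list(signal = c("A>G", "T>C"), fp = c("G>A", "C>T"))
  }
}

#' Build a signal report for one dataset
#'
#' Aggregates a type-screen run into the per-dataset quantities: editing
#' events, mapped bases (initial pass plus rescued hyper-edited read
#' bases), the normalized signal, unique sites, the percentage of
#' unique sites that are A-to-G across all twelve types, and the same
#' normalization applied to G-to-A clusters as the expected false-positive
#' signal. In unstranded mode the A-to-G signal pools A>G with T>C and the
#' false-positive signal pools G>A with C>T.
#'
#' @param screen Result of [run_all_types()].
#' @param batch Result of [align_batch()] (the initial pass).
#' @param stranded Library strandedness.
#' @param label Dataset label.
#' @return One-row tibble (a `SignalReport` row).
#' @export
signal_report <- function(screen, batch, stranded = FALSE, label = "dataset") {
  tp <- signal_pair_types(stranded)
  rep <- screen$report
  hyper <- screen$hyper_reads
  sig_reads <- hyper[hyper$mismatch_type %in% tp$signal, , drop = FALSE]
  events <- sum(rep$n_events[rep$mismatch_type %in% tp$signal])
  rescued_bases <- sum(sig_reads$aln_end - sig_reads$aln_start)
  mapped_bases <- batch$mapped_bases + rescued_bases
  total_sites <- sum(rep$n_sites)
  sig_sites <- sum(rep$n_sites[rep$mismatch_type %in% tp$signal])
  fp_events <- sum(rep$n_events[rep$mismatch_type %in% tp$fp])
  tibble(
    label = label,
    hyper_reads = nrow(sig_reads),
    editing_events = events,
    mapped_bases = mapped_bases,
    normalized_signal = if (mapped_bases > 0) events * 1e6 / mapped_bases else NA_real_,
    unique_sites = sig_sites,
    pct_A_to_G_of_all_types = if (total_sites > 0) 100 * sig_sites / total_sites else NA_real_,
    false_positive_signal = if (mapped_bases > 0) fp_events * 1e6 / mapped_bases else NA_real_
  )
}

#' Specificity of the type screen
#'
#' The fraction of unique cluster sites belonging to A-to-G mismatch
#' clusters (pooled with T-to-C for unstranded libraries) over all twelve
#' types.
#'
#' @param report Type-screen report tibble from [run_all_types()].
#' @param stranded Library strandedness.
#' @return Fraction in \[0, 1\], or `NA` (with a warning) when no sites of
#'   any type were found.
#' @export
specificity <- function(report, stranded = FALSE) {
  tp <- signal_pair_types(stranded)
  total <- sum(report$n_sites)
  if (total == 0) {
    warn("no unique sites of any type; specificity is undefined")
    return(NA_real_)
  }
  sum(report$n_sites[report$mismatch_type %in% tp$signal]) / total
}

#' Consistency of a null screen with no A-to-G excess
#'
#' Chi-square goodness of fit of the per-type hyper-read counts against a
#' uniform distribution over the twelve types. When no clusters of any
#' type exist — the expected outcome for an ADAR-null dataset at realistic
#' error rates — the data are maximally consistent with the null and p = 1
#' is returned with a note.
#'
#' @param report Type-screen report tibble.
#' @return Tibble with `p_value`, `total`, `a_to_g`, `note`.
#' @export
type_screen_null_check <- function(report) {
  counts <- report$n_reads
  total <- sum(counts)
  ag <- report$n_reads[report$mismatch_type == "A>G"]
  if (total == 0) {
    return(tibble(p_value = 1, total = 0L, a_to_g = 0L,
                  note = "no clusters of any type"))
  }
  p <- suppressWarnings(chisq.test(counts, p = rep(1 / 12, 12))$p.value)
  tibble(p_value = p, total = total, a_to_g = ag, note = NA_character_)
}

#' Rank datasets by normalized hyper-editing signal
#'
#' @param reports A list of [signal_report()] rows or a tibble of them.
#' @return Tibble sorted by decreasing `normalized_signal`, with a `rank`
#'   column and the false-positive column alongside.
#' @export
compare_datasets <- function(reports) {
  tbl <- if (is.data.frame(reports)) reports else bind_rows(reports)
  if (!nrow(tbl)) return(mutate(tbl, rank = integer(0)))
  tbl |>
    arrange(desc(.data$normalized_signal)) |>
    mutate(rank = row_number()) |>
    select("rank", dplyr::everything())
}

#' Aggregate biological replicates
#'
#' Mean and standard error of the normalized signal across replicate
#' signal reports sharing a label.
#'
#' @param reports Tibble of [signal_report()] rows (several per label).
#' @return Tibble with per-label mean, SE and replicate count.
#' @export
aggregate_replicates <- function(reports) {
  reports |>
    group_by(.data$label) |>
    summarise(
      n_replicates = n(),
      mean_signal = mean(.data$normalized_signal),
      se_signal = stats::sd(.data$normalized_signal) / sqrt(n()),
      mean_false_positive = mean(.data$false_positive_signal),
      .groups = "drop"
    )
}
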