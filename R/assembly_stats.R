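#' N50 of a set of sequence lengths
#'
#' With lengths sorted in descending order, N50 is the length at which the
#' running cumulative sum first reaches at least half of the total length.
#' It is always an element of the input multiset; no interpolation is done.
#'
#' @param lengths Vector of positive integer lengths.
#' @return The N50, an integer.
#' @examples
#' n50(c(4, 3, 3, 2, 2, 2))  # total 16, half 8, cumsum 4,7,10 -> 3
#' @export
n50 <- function(lengths) {
  if (length(lengths) == 0) stop("n50 of an empty length set", call. = FALSE)
  stopifnot(all(lengths > 0))
  srt <- sort(as.numeric(lengths), decreasing = TRUE)
  idx <- which(cumsum(srt) >= sum(srt) / 2)[1L]
  as.integer(srt[idx])
}

#' Summarize an assembly of transcripts
#'
#' Computes the unigene-level summary statistics reported for de novo
#' transcriptome assemblies: sequence count, total and mean length, N50,
#' longest sequence, the fraction of sequences strictly longer than a cutoff,
#' and a fixed-width binned length distribution.
#'
#' Bins are `[k*w + 1, (k+1)*w]` for bin width `w`; lengths above
#' `bin_ceiling` are pooled into one open-ended final bin.
#'
#' @param records Tibble of transcripts as from [read_fasta()], or a vector
#'   of lengths.
#' @param cutoff Length cutoff in bp for `frac_over_cutoff` (strict `>`;
#'   default 500).
#' @param bin_width Histogram bin width in bp (default 100).
#' @param bin_ceiling Lengths above this go into the final open-ended bin
#'   (default 3000).
#' @return An object of class `assembly_summary`: a list with `n_sequences`,
#'   `total_length`, `mean_length`, `n50`, `max_length`, `cutoff`,
#'   `frac_over_cutoff`, and `bins` (tibble: `bin_start`, `bin_end`, `label`,
#'   `count`).
#' @export
summarize_assembly <- function(records, cutoff = 500, bin_width = 100,
                               bin_ceiling = 3000) {
  lengths <- if (is.data.frame(records)) records$length else as.integer(records)
  if (length(lengths) == 0) stop("empty assembly", call. = FALSE)
  stopifnot(all(lengths >= 1), bin_width >= 1, bin_ceiling >= bin_width)
  n_bins <- ceiling(bin_ceiling / bin_width)
  bin_start <- (seq_len(n_bins + 1) - 1L) * bin_width + 1L
  bin_end <- c(seq_len(n_bins) * bin_width, NA_integer_)  # last bin open-ended
  idx <- pmin((lengths - 1L) %/% bin_width + 1L, n_bins + 1L)
  counts <- tabulate(idx, nbins = n_bins + 1L)
  label <- c(sprintf("%d-%d", bin_start[seq_len(n_bins)], bin_end[seq_len(n_bins)]),
             sprintf(">%d", n_bins * bin_width))
  structure(
    list(
      n_sequences = length(lengths),
      total_length = sum(as.numeric(lengths)),
      mean_length = mean(lengths),
      n50 = n50(lengths),
      max_length = max(lengths),
      cutoff = cutoff,
      frac_over_cutoff = mean(lengths > cutoff),
      bins = tibble(bin_start = bin_start, bin_end = bin_end,
                    label = label, count = counts)
    ),
    class = "assembly_summary"
  )
}

#' @export
print.assembly_summary <- function(x, ...) {
  cat(sprintf(
    "Assembly summary: %d sequences, total %.0f bp\n  mean %.1f bp | N50 %d bp | longest %d bp | %.2f%% over %d bp\n",
    x$n_sequences, x$total_length, x$mean_length, x$n50, x$max_length,
    100 * x$frac_over_cutoff, x$cutoff))
  invisible(x)
}

#' Plot the binned length distribution of an assembly
#'
#' @param summary An [summarize_assembly()] result.
#' @return A ggplot object (bar chart of sequence counts per length bin).
#' @export
plot_length_distribution <- function(summary) {
  stopifnot(inherits(summary, "assembly_summary"))
  df <- summary$bins
  df$label <- factor(df$label, levels = df$label)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$label, y = .data$count)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "Sequence length (bp)", y = "Number of sequences") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}
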