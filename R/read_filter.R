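#' Thresholds for raw-read removal
#'
#' Bundles the three removal rules applied to raw reads before assembly:
#' reads with an adapter match of more than `adapter_min_excess_bp` bases,
#' reads with more than `max_n_fraction` ambiguous (`N`) bases, and reads
#' where more than `max_lowq_fraction` of bases have quality strictly below
#' `lowq_cutoff`. All three "more than" comparisons are strict: a read sitting
#' exactly at a threshold is kept.
#'
#' @param adapter_seq Adapter DNA sequence to match against (required; no
#'   default ships as ground truth).
#' @param adapter_min_excess_bp Longest tolerated exact adapter match, in bp
#'   (default 9; a 10+ bp match removes the read).
#' @param max_n_fraction Maximum tolerated fraction of `N` bases (default 0.03).
#' @param max_lowq_fraction Maximum tolerated fraction of low-quality bases
#'   (default 0.50).
#' @param lowq_cutoff Phred score below which a base counts as low-quality
#'   (default 3, i.e. Q < 3).
#' @return An object of class `filter_thresholds`.
#' @export
filter_thresholds <- function(adapter_seq,
                              adapter_min_excess_bp = 9,
                              max_n_fraction = 0.03,
                              max_lowq_fraction = 0.5,
                              lowq_cutoff = 3) {
  adapter_seq <- normalize_seq(adapter_seq)
  stopifnot(is.character(adapter_seq), length(adapter_seq) == 1, nzchar(adapter_seq))
  assert_dna(adapter_seq, "adapter")
  stopifnot(adapter_min_excess_bp >= 0,
            max_n_fraction >= 0, max_n_fraction <= 1,
            max_lowq_fraction >= 0, max_lowq_fraction <= 1,
            lowq_cutoff >= 0)
  structure(
    list(adapter_seq = adapter_seq,
         adapter_min_excess_bp = as.integer(adapter_min_excess_bp),
         max_n_fraction = max_n_fraction,
         max_lowq_fraction = max_lowq_fraction,
         lowq_cutoff = as.integer(lowq_cutoff)),
    class = "filter_thresholds"
  )
}

#' @export
print.filter_thresholds <- function(x, ...) {
  cat("Read-removal thresholds:\n",
      sprintf("  adapter match      > %d bp (adapter: %s)\n",
              x$adapter_min_excess_bp, x$adapter_seq),
      sprintf("  N fraction         > %g\n", x$max_n_fraction),
      sprintf("  low-quality (Q<%d) > %g\n", x$lowq_cutoff, x$max_lowq_fraction),
      sep = "")
  invisible(x)
}

#' Longest exact common substring between a read and an adapter
#'
#' The adapter rule is operationalized as the length of the longest exact
#' common substring between read and adapter (the study names no adapter
#' sequence or aligner, so exact matching is the deterministic choice).
#'
#' @param read_seq Read sequence (single string).
#' @param adapter_seq Adapter sequence (single string).
#' @return Integer length of the longest shared substring (0 if none).
#' @export
adapter_match_length <- function(read_seq, adapter_seq) {
  stopifnot(length(read_seq) == 1, length(adapter_seq) == 1,
            nzchar(read_seq), nzchar(adapter_seq))
  m <- nchar(adapter_seq)
  kmax <- min(nchar(read_seq), m)
  # Scan lengths from longest down; adapters are short so the substring set
  # per length is small.
  for (k in kmax:1) {
    subs <- unique(substring(adapter_seq, 1:(m - k + 1), k:m))
    hit <- vapply(subs, function(s) grepl(s, read_seq, fixed = TRUE), logical(1))
    if (any(hit)) return(k)
  }
  0L
}

# Vectorized per-read rule evaluation shared by filter_read / filter_fastq.
# Returns character vector: NA (keep) or the first failing rule among
# "adapter", "n", "quality" -- fixed order used only for attribution.
evaluate_rules <- function(seq, quals, t) {
  len <- nchar(seq)
  if (any(len == 0)) stop("zero-length read", call. = FALSE)
  adapter_fail <- vapply(seq, function(s) {
    adapter_match_length(s, t$adapter_seq) > t$adapter_min_excess_bp
  }, logical(1), USE.NAMES = FALSE)
  n_count <- nchar(seq) - nchar(gsub("N", "", seq, fixed = TRUE))
  n_fail <- n_count / len > t$max_n_fraction
  lowq_fail <- mapply(function(q, l) sum(q < t$lowq_cutoff) / l, quals, len) >
    t$max_lowq_fraction
  rule <- rep(NA_character_, length(seq))
  rule[lowq_fail] <- "quality"
  rule[n_fail] <- "n"
  rule[adapter_fail] <- "adapter"
  rule
}

#' Keep/remove decision for a single read
#'
#' Applies the three removal rules to one read. Rules are evaluated in the
#' fixed order adapter, N, quality; the order affects only which rule a
#' removal is attributed to, never the decision itself.
#'
#' @param seq Read sequence (single string).
#' @param quals Integer vector of per-base Phred scores.
#' @param thresholds A [filter_thresholds()] object.
#' @return A list with `keep` (logical) and `rule` (`NA` if kept, otherwise
#'   one of `"adapter"`, `"n"`, `"quality"`).
#' @export
filter_read <- function(seq, quals, thresholds) {
  stopifnot(inherits(thresholds, "filter_thresholds"),
            length(seq) == 1, length(quals) == nchar(seq))
  seq <- normalize_seq(seq)
  assert_dna(seq, "read")
  rule <- evaluate_rules(seq, list(quals), thresholds)
  list(keep = is.na(rule), rule = rule)
}

#' Filter a set of reads (or read pairs)
#'
#' Applies [filter_read()] decisions to every read; for paired input a pair
#' is dropped when either mate fails. Removal means the whole read (pair) is
#' discarded, never trimmed. Counts in the report attribute each removed
#' unit to its first failing rule (adapter before N before quality; for a
#' pair, the highest-priority failing rule across both mates).
#'
#' @param reads Tibble of reads as from [read_fastq()].
#' @param thresholds A [filter_thresholds()] object.
#' @param mates Optional tibble of second mates, aligned row-for-row with
#'   `reads`.
#' @return A list with `kept` (tibble), `kept_mates` (tibble or `NULL`),
#'   `rules` (per-unit attribution, `NA` = kept) and `report` (list with
#'   `n_input`, `n_removed_adapter`, `n_removed_n`, `n_removed_quality`,
#'   `n_kept`; counts are per read, or per pair for paired input).
#' @export
filter_fastq <- function(reads, thresholds, mates = NULL) {
  stopifnot(inherits(thresholds, "filter_thresholds"),
            all(c("seq", "quals") %in% names(reads)))
  if (!is.null(mates)) {
    if (nrow(mates) != nrow(reads)) {
      stop("paired input: mate files have different read counts", call. = FALSE)
    }
  }
  n <- nrow(reads)
  if (n == 0) {
    report <- list(n_input = 0L, n_removed_adapter = 0L, n_removed_n = 0L,
                   n_removed_quality = 0L, n_kept = 0L)
    return(list(kept = reads, kept_mates = mates, rules = character(0),
                report = report))
  }
  rule1 <- evaluate_rules(reads$seq, reads$quals, thresholds)
  rule <- rule1
  if (!is.null(mates)) {
    rule2 <- evaluate_rules(mates$seq, mates$quals, thresholds)
    prio <- c(adapter = 1L, n = 2L, quality = 3L)
    pick <- function(a, b) {
      if (is.na(a)) return(b)
      if (is.na(b)) return(a)
      if (prio[[a]] <= prio[[b]]) a else b
    }
    rule <- mapply(pick, rule1, rule2, USE.NAMES = FALSE)
  }
  keep <- is.na(rule)
  report <- list(
    n_input = n,
    n_removed_adapter = sum(rule == "adapter", na.rm = TRUE),
    n_removed_n = sum(rule == "n", na.rm = TRUE),
    n_removed_quality = sum(rule == "quality", na.rm = TRUE),
    n_kept = sum(keep)
  )
  list(kept = reads[keep, , drop = FALSE],
       kept_mates = if (is.null(mates)) NULL else mates[keep, , drop = FALSE],
       rules = rule,
       report = report)
}
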