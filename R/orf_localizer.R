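REGION_LEVELS <- c("FIVE_UTR", "CDS", "THREE_UTR", "NO_ORF")

#' Longest open reading frame of a transcript
#'
#' Scans the three forward frames for ATG-to-stop open reading frames and
#' returns the longest with at least `min_codons` codons (the stop codon is
#' included in the span and the codon count). Forward frames only: assembled
#' unigenes are treated as sense-strand transcripts, with antisense structure
#' handled by the i-motif pattern at the scanning stage. ORFs without an
#' in-frame stop before the transcript end are not accepted, which keeps the
#' UTR/CDS/UTR partition well-defined. Ties are broken by smallest start,
#' then smallest frame.
#'
#' @param seq A single DNA string.
#' @param min_codons Minimum ORF length in codons, stop included (default 50).
#' @return A list with `has_orf` (logical), and when `has_orf` is `TRUE`:
#'   `orf_start` (0-based, at the A of ATG), `orf_end` (exclusive, just past
#'   the stop codon) and `frame` (0, 1 or 2).
#' @export
find_longest_orf <- function(seq, min_codons = 50) {
  stopifnot(length(seq) == 1, min_codons >= 1)
  seq <- normalize_seq(seq)
  assert_dna(seq)
  n <- nchar(seq)
  no_orf <- list(has_orf = FALSE, orf_start = NA_integer_,
                 orf_end = NA_integer_, frame = NA_integer_)
  if (n < 3L * min_codons) return(no_orf)
  atg <- find_all(seq, "ATG")
  stops <- sort(c(find_all(seq, "TAA"), find_all(seq, "TAG"), find_all(seq, "TGA")))
  best <- NULL
  for (f in 0:2) {
    a <- atg[(atg - 1L) %% 3L == f]
    s <- stops[(stops - 1L) %% 3L == f]
    if (length(a) == 0 || length(s) == 0) next
    # first in-frame stop at or after each ATG + 3
    idx <- findInterval(a + 3L - 0.5, s) + 1L
    ok <- idx <= length(s)
    a <- a[ok]; idx <- idx[ok]
    if (length(a) == 0) next
    stop_pos <- s[idx]
    span <- stop_pos + 3L - a            # length in nt, stop included
    keep <- span >= 3L * min_codons
    a <- a[keep]; stop_pos <- stop_pos[keep]; span <- span[keep]
    for (k in seq_along(a)) {
      cand <- list(start = a[k], end = stop_pos[k] + 3L, span = span[k], frame = f)
      if (is.null(best) ||
          cand$span > best$span ||
          (cand$span == best$span && (cand$start < best$start ||
            (cand$start == best$start && cand$frame < best$frame)))) {
        best <- cand
      }
    }
  }
  if (is.null(best)) return(no_orf)
  list(has_orf = TRUE, orf_start = best$start - 1L, orf_end = best$end - 1L,
       frame = best$frame)
}

# 1-based start positions of all (possibly overlapping) occurrences of a
# fixed trinucleotide.
find_all <- function(seq, codon) {
  m <- gregexpr(codon, seq, fixed = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m)
}

#' Annotate longest ORFs for a set of transcripts
#'
#' @param records Tibble of transcripts as from [read_fasta()].
#' @param min_codons Minimum ORF length in codons (see [find_longest_orf()]).
#' @return A tibble with one row per transcript: `transcript_id`, `has_orf`,
#'   `orf_start`, `orf_end`, `frame`, `length`.
#' @export
annotate_orfs <- function(records, min_codons = 50) {
  stopifnot(is.data.frame(records), all(c("id", "seq") %in% names(records)))
  rows <- lapply(seq_len(nrow(records)), function(i) {
    o <- find_longest_orf(records$seq[i], min_codons)
    tibble(transcript_id = records$id[i], has_orf = o$has_orf,
           orf_start = o$orf_start, orf_end = o$orf_end, frame = o$frame,
           length = nchar(records$seq[i]))
  })
  dplyr::bind_rows(rows)
}

#' Classify a hit interval as 5' UTR, CDS or 3' UTR
#'
#' The longest ORF partitions a transcript of length `L` into
#' `[0, orf_start)`, `[orf_start, orf_end)` and `[orf_end, L)`. A hit is
#' assigned to the region containing the majority of its bases; ties break
#' toward the 5'-most region. Transcripts without an accepted ORF yield
#' `NO_ORF`.
#'
#' @param start,end Hit interval, 0-based half-open.
#' @param orf One row of [annotate_orfs()] output (or the list from
#'   [find_longest_orf()] plus a `length` element).
#' @return One of `"FIVE_UTR"`, `"CDS"`, `"THREE_UTR"`, `"NO_ORF"`.
#' @export
classify_region <- function(start, end, orf) {
  stopifnot(end > start, start >= 0)
  if (!isTRUE(orf$has_orf[[1]])) return("NO_ORF")
  L <- orf$length[[1]]
  s <- orf$orf_start[[1]]; e <- orf$orf_end[[1]]
  stopifnot(end <= L)
  ov <- c(
    FIVE_UTR = max(0, min(end, s) - max(start, 0)),
    CDS = max(0, min(end, e) - max(start, s)),
    THREE_UTR = max(0, min(end, L) - max(start, e))
  )
  names(ov)[which.max(ov)]  # which.max takes the first (5'-most) on ties
}

#' Attach region labels to a hit table
#'
#' Joins hits with per-transcript ORF annotations and labels each hit by
#' majority overlap.
#'
#' @param hits Hit tibble from [scan_transcripts()].
#' @param orfs ORF tibble from [annotate_orfs()].
#' @return `hits` with added columns `orf_start`, `orf_end`, `frame`,
#'   `has_orf` and `region`.
#' @export
localize_hits <- function(hits, orfs) {
  stopifnot("transcript_id" %in% names(hits),
            all(c("transcript_id", "has_orf", "length") %in% names(orfs)))
  missing <- setdiff(unique(hits$transcript_id), orfs$transcript_id)
  if (length(missing)) {
    stop("hits reference transcripts absent from the ORF table: ",
         missing[1L], call. = FALSE)
  }
  out <- dplyr::left_join(hits, orfs, by = "transcript_id")
  region <- character(nrow(out))
  for (i in seq_len(nrow(out))) {
    region[i] <- classify_region(out$start[i], out$end[i],
                                 out[i, c("has_orf", "orf_start", "orf_end",
                                          "length")])
  }
  out$region <- region
  out
}
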