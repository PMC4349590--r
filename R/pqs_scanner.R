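#' Tract/loop pattern for quadruplex-type motifs
#'
#' Describes the classical putative-quadruplex pattern `(G3+ L1-7)3+ G3+`:
#' at least `min_repeat_units + 1` tracts of `g_run_min` or more guanines,
#' separated by loops of `loop_min` to `loop_max` unrestricted bases. The
#' same geometry with cytosine tracts describes the i-motif on the
#' complementary strand.
#'
#' Loop bases are unrestricted (any of A/C/G/T/N, including G), mirroring the
#' `.` of the regex form `G{3,}.{1,7}G{3,}.{1,7}G{3,}.{1,7}G{3,}`; no
#' "loop must not extend a tract" correction is applied.
#'
#' @param g_run_min Minimum tract length (default 3).
#' @param loop_min,loop_max Loop length bounds in bp (defaults 1 and 7).
#' @param min_repeat_units Minimum number of (tract, loop) repeat units before
#'   the final tract (default 3, i.e. at least 4 tracts).
#' @return An object of class `pqs_pattern`.
#' @export
pqs_pattern <- function(g_run_min = 3, loop_min = 1, loop_max = 7,
                        min_repeat_units = 3) {
  stopifnot(g_run_min >= 2, loop_min >= 1, loop_min <= loop_max,
            min_repeat_units >= 1)
  structure(
    list(g_run_min = as.integer(g_run_min),
         loop_min = as.integer(loop_min),
         loop_max = as.integer(loop_max),
         min_repeat_units = as.integer(min_repeat_units)),
    class = "pqs_pattern"
  )
}

#' @export
print.pqs_pattern <- function(x, ...) {
  cat(sprintf("PQS pattern: (G%d+ L%d-%d)%d+ G%d+  (>= %d tracts)\n",
              x$g_run_min, x$loop_min, x$loop_max, x$min_repeat_units,
              x$g_run_min, x$min_repeat_units + 1L))
  invisible(x)
}

# PCRE form of the pattern for a given tract base.
pqs_regex <- function(p, base = "G") {
  sprintf("%s{%d,}(?:.{%d,%d}%s{%d,}){%d,}",
          base, p$g_run_min, p$loop_min, p$loop_max, base, p$g_run_min,
          p$min_repeat_units)
}

# run_from[i]: length of the maximal run of `base` starting at 1-based i.
base_run_lengths <- function(chars, base) {
  n <- length(chars)
  run <- integer(n)
  if (n == 0) return(run)
  run[n] <- as.integer(chars[n] == base)
  if (n > 1) {
    for (i in (n - 1):1) run[i] <- if (chars[i] == base) run[i + 1] + 1L else 0L
  }
  run
}

#' Parse a string as a complete tract/loop motif
#'
#' Recursive-descent parser that attempts to decompose `seq` *in its
#' entirety* into tracts and loops under pattern `p`. Greedy order (maximal
#' tract, then longest loop first) with full backtracking, so a valid
#' decomposition is found whenever one exists. This parser is the reference
#' validator used by the brute-force enumerator and by the synthetic-data
#' generator's suppression check; it shares no code with the scanner's
#' matching engines.
#'
#' @param seq Candidate motif string.
#' @param p A [pqs_pattern()].
#' @param base Tract base, `"G"` for quadruplex or `"C"` for i-motif.
#' @return `NULL` if `seq` is not a complete motif, otherwise a list with
#'   integer vectors `tract_lengths` and `loop_lengths`.
#' @export
parse_quadruplex <- function(seq, p = pqs_pattern(), base = "G") {
  n <- nchar(seq)
  g <- p$g_run_min
  t_min <- p$min_repeat_units + 1L
  if (n < t_min * g + (t_min - 1L) * p$loop_min) return(NULL)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  run <- base_run_lengths(chars, base)
  failed <- new.env(parent = emptyenv())  # (pos, capped tract count) -> TRUE
  descend <- function(pos, ntracts) {
    if (run[pos] < g) return(NULL)
    key <- paste0(pos, "_", min(ntracts, t_min))
    if (!is.null(failed[[key]])) return(NULL)
    for (a in seq.int(run[pos], g)) {
      after <- pos + a            # first position after the tract
      if (after == n + 1L) {
        if (ntracts + 1L >= t_min) {
          return(list(tract_lengths = a, loop_lengths = integer(0)))
        }
        next
      }
      for (l in seq.int(p$loop_max, p$loop_min)) {
        nxt <- after + l
        if (nxt + g - 1L > n) next
        sub <- descend(nxt, ntracts + 1L)
        if (!is.null(sub)) {
          return(list(tract_lengths = c(a, sub$tract_lengths),
                      loop_lengths = c(l, sub$loop_lengths)))
        }
      }
    }
    failed[[key]] <- TRUE
    NULL
  }
  descend(1L, 0L)
}

# Exhaustive interval enumeration: memoized reachability over tract starts.
# Returns 0-based half-open (start, end) pairs, sorted by start then end.
pqs_exhaustive_intervals <- function(seq, p, base = "G") {
  n <- nchar(seq)
  g <- p$g_run_min
  t_need <- p$min_repeat_units + 1L
  empty <- data.frame(start = integer(0), end = integer(0))
  if (n < t_need * g) return(empty)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  run <- base_run_lengths(chars, base)
  memo <- new.env(parent = emptyenv())
  # reach(i, r): ends (1-based inclusive) of all parses whose next tract
  # starts at i, with r tracts (capped) still required.
  reach <- function(i, r) {
    key <- paste0(i, "_", r)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    ends <- integer(0)
    r2 <- max(r - 1L, 0L)
    for (a in seq.int(g, run[i])) {
      after <- i + a
      if (r2 == 0L) ends <- c(ends, after - 1L)
      for (l in seq.int(p$loop_min, p$loop_max)) {
        j <- after + l
        if (j + g - 1L > n) break
        if (run[j] >= g) ends <- c(ends, reach(j, r2))
      }
    }
    ends <- sort.int(unique(ends))
    memo[[key]] <- ends
    ends
  }
  starts <- which(run >= g)
  out_start <- integer(0); out_end <- integer(0)
  for (i in starts) {
    ends <- reach(i, t_need)
    if (length(ends)) {
      out_start <- c(out_start, rep.int(i - 1L, length(ends)))
      out_end <- c(out_end, ends)
    }
  }
  ord <- order(out_start, out_end)
  data.frame(start = out_start[ord], end = out_end[ord])
}

# Default (regex-style) intervals: leftmost, non-overlapping, greedy.
pqs_default_intervals <- function(seq, p, base = "G") {
  m <- gregexpr(pqs_regex(p, base), seq, perl = TRUE)[[1]]
  if (m[1] == -1) return(data.frame(start = integer(0), end = integer(0)))
  len <- attr(m, "match.length")
  data.frame(start = as.integer(m) - 1L, end = as.integer(m) + len - 1L)
}

# Shared hit-table constructor: decompose each interval with the reference
# parser and assemble the tibble.
build_hits <- function(seq, intervals, p, base, motif_label) {
  k <- nrow(intervals)
  matched <- substring(seq, intervals$start + 1L, intervals$end)
  decomp <- lapply(matched, parse_quadruplex, p = p, base = base)
  stopifnot(!vapply(decomp, is.null, logical(1)))
  tibble(
    motif = rep(motif_label, k),
    start = as.integer(intervals$start),
    end = as.integer(intervals$end),
    matched_seq = matched,
    n_tracts = vapply(decomp, function(d) length(d$tract_lengths), integer(1)),
    tract_lengths = lapply(decomp, `[[`, "tract_lengths"),
    loop_lengths = lapply(decomp, `[[`, "loop_lengths")
  )
}

empty_hits <- function() {
  tibble(motif = character(0), start = integer(0), end = integer(0),
         matched_seq = character(0), n_tracts = integer(0),
         tract_lengths = list(), loop_lengths = list())
}

#' Find putative G-quadruplex-forming sequences
#'
#' Scans a DNA string for the quadruplex tract/loop pattern. In `"default"`
#' mode, matches follow standard regex semantics: left-to-right,
#' non-overlapping, greedy (each match absorbs maximal G-runs and as many
#' repeat units as possible), so one long G-rich region yields a single
#' maximal hit. In `"exhaustive"` mode, every `(start, end)` substring that
#' parses as tracts-and-loops is returned, including overlapping and nested
#' intervals.
#'
#' @param seq A single normalized DNA string (A/C/G/T/N).
#' @param pattern A [pqs_pattern()].
#' @param mode `"default"` or `"exhaustive"`.
#' @return A tibble of hits with columns `motif`, `start` (0-based
#'   inclusive), `end` (exclusive), `matched_seq`, `n_tracts`,
#'   `tract_lengths` and `loop_lengths` (list columns).
#' @examples
#' find_g4("GGGAGGGAGGGAGGG")
#' @export
find_g4 <- function(seq, pattern = pqs_pattern(),
                    mode = c("default", "exhaustive")) {
  mode <- match.arg(mode)
  stopifnot(length(seq) == 1)
  seq <- normalize_seq(seq)
  assert_dna(seq)
  iv <- if (mode == "default") {
    pqs_default_intervals(seq, pattern, "G")
  } else {
    pqs_exhaustive_intervals(seq, pattern, "G")
  }
  if (nrow(iv) == 0) return(empty_hits())
  build_hits(seq, iv, pattern, "G", "G4")
}

#' Find putative i-motif-forming sequences
#'
#' The i-motif is the C-rich mirror of the G-quadruplex: the same tract/loop
#' geometry with cytosine tracts, arising because assembled ESTs may be
#' antisense. Implemented as a G4 scan of the reverse complement with
#' coordinates mapped back to the given strand (for an interval `[s, e)` on a
#' sequence of length `L`, the mapped interval is `[L - e, L - s)`), which is
#' equivalent to matching the C-based pattern on the given strand.
#'
#' @inheritParams find_g4
#' @return A tibble of hits (see [find_g4()]) with `motif = "IMOTIF"`;
#'   `matched_seq` and tract/loop decompositions refer to the given strand.
#' @examples
#' find_imotif("CCCACCCACCCACCC")
#' @export
find_imotif <- function(seq, pattern = pqs_pattern(),
                        mode = c("default", "exhaustive")) {
  mode <- match.arg(mode)
  stopifnot(length(seq) == 1)
  seq <- normalize_seq(seq)
  assert_dna(seq)
  len <- nchar(seq)
  h <- find_g4(reverse_complement(seq), pattern, mode)
  if (nrow(h) == 0) return(empty_hits())
  out <- tibble(
    motif = rep("IMOTIF", nrow(h)),
    start = len - h$end,
    end = len - h$start,
    matched_seq = substring(seq, len - h$end + 1L, len - h$start),
    n_tracts = h$n_tracts,
    tract_lengths = lapply(h$tract_lengths, rev),
    loop_lengths = lapply(h$loop_lengths, rev)
  )
  out[order(out$start, out$end), , drop = FALSE]
}

#' Brute-force enumeration of all motif intervals
#'
#' Reference enumerator: tests every substring of `seq` with
#' [parse_quadruplex()] and reports all that parse completely. Candidate
#' substrings are prefiltered to those beginning and ending with a full
#' tract, which every valid parse must. Quadratic and meant for validation
#' and fixture construction, not production scanning.
#'
#' @inheritParams parse_quadruplex
#' @return A tibble with 0-based half-open `start` and `end` columns, sorted.
#' @export
pqs_brute_force <- function(seq, p = pqs_pattern(), base = "G") {
  seq <- normalize_seq(seq)
  assert_dna(seq)
  n <- nchar(seq)
  g <- p$g_run_min
  t_min <- p$min_repeat_units + 1L
  min_len <- t_min * g + (t_min - 1L) * p$loop_min
  out <- tibble(start = integer(0), end = integer(0))
  if (n < min_len) return(out)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  run <- base_run_lengths(chars, base)
  # rev_run[e]: run of `base` ending at e
  rev_run <- integer(n)
  rev_run[1] <- as.integer(chars[1] == base)
  if (n > 1) {
    for (i in 2:n) rev_run[i] <- if (chars[i] == base) rev_run[i - 1] + 1L else 0L
  }
  starts <- which(run >= g)
  tract_ends <- which(rev_run >= g)
  res_s <- integer(0); res_e <- integer(0)
  for (i in starts) {
    for (e in tract_ends[tract_ends >= i + min_len - 1L]) {
      if (!is.null(parse_quadruplex(substr(seq, i, e), p, base))) {
        res_s <- c(res_s, i - 1L)
        res_e <- c(res_e, e)
      }
    }
  }
  ord <- order(res_s, res_e)
  tibble(start = res_s[ord], end = res_e[ord])
}

#' Scan a set of transcripts for G4 and/or i-motif hits
#'
#' @param records Tibble of transcripts as from [read_fasta()].
#' @param pattern A [pqs_pattern()].
#' @param motif Which motif class(es) to scan for.
#' @param mode Scan mode, as in [find_g4()].
#' @return A tibble of hits with a leading `transcript_id` column.
#' @export
scan_transcripts <- function(records, pattern = pqs_pattern(),
                             motif = c("both", "g4", "imotif"),
                             mode = c("default", "exhaustive")) {
  motif <- match.arg(motif)
  mode <- match.arg(mode)
  stopifnot(is.data.frame(records), all(c("id", "seq") %in% names(records)))
  per_record <- lapply(seq_len(nrow(records)), function(i) {
    parts <- list()
    if (motif %in% c("both", "g4")) {
      parts$g4 <- find_g4(records$seq[i], pattern, mode)
    }
    if (motif %in% c("both", "imotif")) {
      parts$im <- find_imotif(records$seq[i], pattern, mode)
    }
    h <- dplyr::bind_rows(parts)
    if (nrow(h)) h <- dplyr::mutate(h, transcript_id = records$id[i],
                                    .before = 1)
    h
  })
  hits <- dplyr::bind_rows(per_record)
  if (nrow(hits) == 0) {
    hits <- dplyr::mutate(empty_hits(), transcript_id = character(0),
                          .before = 1)
  }
  hits
}

#' Count unigenes carrying at least one motif
#'
#' A transcript with many hits counts once; co-occurrence of both classes on
#' one transcript counts once per class when filtered by class.
#'
#' @param hits Hit tibble from [scan_transcripts()] (needs `transcript_id`).
#' @param motif_class Optional class filter, `"G4"` or `"IMOTIF"`.
#' @return Integer count of distinct transcripts.
#' @export
count_pqs_unigenes <- function(hits, motif_class = NULL) {
  stopifnot("transcript_id" %in% names(hits))
  if (!is.null(motif_class)) {
    hits <- hits[hits$motif == motif_class, , drop = FALSE]
  }
  dplyr::n_distinct(hits$transcript_id)
}
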