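# Independent oracles used to validate package operations. These deliberately
# share no code with the implementations they check.

rand_dna <- function(n, gc = 0.5, with_n = 0) {
  bases <- c("A", "C", "G", "T", "N")
  prob <- c((1 - gc) / 2 * (1 - with_n), gc / 2 * (1 - with_n),
            gc / 2 * (1 - with_n), (1 - gc) / 2 * (1 - with_n), with_n)
  paste(sample(bases, n, replace = TRUE, prob = prob), collapse = "")
}

# Longest common substring by the classic O(n*m) dynamic program.
oracle_lcs_dp <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  best <- 0L
  prev <- integer(length(y))
  for (i in seq_along(x)) {
    cur <- integer(length(y))
    for (j in seq_along(y)) {
      if (x[i] == y[j]) {
        cur[j] <- if (j == 1L) 1L else prev[j - 1L] + 1L
        if (cur[j] > best) best <- cur[j]
      }
    }
    prev <- cur
  }
  best
}

# All motif intervals by anchored-regex validation of every candidate
# substring (0-based half-open). Candidates are limited to substrings that
# begin and end with a full tract, which any match must.
oracle_pqs_intervals <- function(seq, base = "G", g = 3, lmin = 1, lmax = 7,
                                 units = 3) {
  n <- nchar(seq)
  rx <- sprintf("^%s{%d,}(?:.{%d,%d}%s{%d,}){%d,}$", base, g, lmin, lmax,
                base, g, units)
  tract <- strrep(base, g)
  min_len <- (units + 1L) * g + units * lmin
  out <- list()
  k <- 0L
  for (i in seq_len(n)) {
    if (substr(seq, i, i + g - 1L) != tract) next
    j <- i + min_len - 1L
    while (j <= n) {
      if (substr(seq, j - g + 1L, j) == tract &&
          grepl(rx, substr(seq, i, j), perl = TRUE)) {
        k <- k + 1L
        out[[k]] <- c(i - 1L, j)
      }
      j <- j + 1L
    }
  }
  if (k == 0L) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  m <- do.call(rbind, out)
  df <- data.frame(start = m[, 1], end = m[, 2])
  df[order(df$start, df$end), , drop = FALSE]
}

# N50 straight from the definition: descending sort, first length where the
# running total reaches half the assembly.
oracle_n50 <- function(lengths) {
  s <- sort(lengths, decreasing = TRUE)
  tot <- sum(as.numeric(s))
  acc <- 0
  for (x in s) {
    acc <- acc + x
    if (acc >= tot / 2) return(as.integer(x))
  }
}

# Longest ORF by literal enumeration: every frame, every ATG, walk codons to
# the first stop. Returns list(has_orf, orf_start, orf_end, frame), 0-based.
oracle_longest_orf <- function(seq, min_codons) {
  n <- nchar(seq)
  stops <- c("TAA", "TAG", "TGA")
  best <- NULL
  for (f in 0:2) {
    if (f + 1L > n - 2L) next
    starts <- seq(f + 1L, n - 2L, by = 3L)
    for (a in starts) {
      if (substr(seq, a, a + 2L) != "ATG") next
      p <- a + 3L
      while (p + 2L <= n) {
        if (substr(seq, p, p + 2L) %in% stops) {
          span <- p + 3L - a
          if (span >= 3L * min_codons &&
              (is.null(best) || span > best$span ||
               (span == best$span && a < best$a))) {
            best <- list(a = a, end = p + 3L, span = span, frame = f)
          }
          break
        }
        p <- p + 3L
      }
    }
  }
  if (is.null(best)) {
    return(list(has_orf = FALSE, orf_start = NA_integer_,
                orf_end = NA_integer_, frame = NA_integer_))
  }
  list(has_orf = TRUE, orf_start = best$a - 1L, orf_end = best$end - 1L,
       frame = best$frame)
}

interval_key <- function(df) paste(df$start, df$end, sep = ":")

make_quals <- function(n, q = 40L) rep(q, n)
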