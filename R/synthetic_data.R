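#' Generate pattern-free background transcripts
#'
#' Draws i.i.d. bases at the requested GC content and rejection-resamples
#' each sequence until the brute-force checker ([pqs_brute_force()], which
#' shares no matching code with the scanner) finds zero G4 and zero i-motif
#' intervals. Deterministic for a fixed seed.
#'
#' @param n Number of transcripts.
#' @param length Transcript length in bp (scalar or vector of length `n`).
#' @param gc GC content in (0, 1).
#' @param seed Integer seed.
#' @param pattern A [pqs_pattern()] used by the suppression check.
#' @param max_tries Rejection budget per sequence.
#' @param id_prefix Prefix for generated transcript ids.
#' @return A tibble with columns `id`, `seq`, `length`.
#' @export
generate_background <- function(n, length = 300, gc = 0.5, seed = 1,
                                pattern = pqs_pattern(), max_tries = 1000,
                                id_prefix = "synth") {
  stopifnot(n >= 1, gc > 0, gc < 1, all(length >= 1))
  len <- rep_len(as.integer(length), n)
  set.seed(seed)
  seqs <- vapply(seq_len(n), function(i) {
    draw_suppressed(len[i], gc, pattern, max_tries)
  }, character(1))
  tibble(id = sprintf("%s_%04d", id_prefix, seq_len(n)),
         seq = seqs, length = nchar(seqs))
}

# One pattern-free sequence, by rejection.
draw_suppressed <- function(len, gc, pattern, max_tries) {
  prob <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  for (try in seq_len(max_tries)) {
    s <- paste(sample(names(prob), len, replace = TRUE, prob = prob),
               collapse = "")
    if (nrow(pqs_brute_force(s, pattern, "G")) == 0 &&
        nrow(pqs_brute_force(s, pattern, "C")) == 0) {
      return(s)
    }
  }
  stop("could not draw a pattern-free sequence in ", max_tries,
       " tries; lower gc", call. = FALSE)
}

#' Build the literal string for a motif plant
#'
#' Tracts are pure G (or C for i-motif); loop positions are filled with `A`.
#' A G/A (or C/A) string contains no ATG, no stop codon and no tract of the
#' opposite base, so planting it can neither create cross-class hits nor add
#' start/stop codons to a constructed ORF.
#'
#' @param motif_class `"G4"` or `"IMOTIF"`.
#' @param tract_lengths Integer vector of tract lengths (each >= pattern
#'   minimum; at least 4 tracts for the default pattern).
#' @param loop_lengths Integer vector of loop lengths, one fewer than tracts.
#' @return The motif string.
#' @export
motif_string <- function(motif_class, tract_lengths, loop_lengths) {
  stopifnot(motif_class %in% c("G4", "IMOTIF"),
            length(tract_lengths) == length(loop_lengths) + 1L)
  base <- if (motif_class == "G4") "G" else "C"
  parts <- character(2L * length(tract_lengths) - 1L)
  parts[seq(1, length(parts), by = 2)] <- strrep(base, tract_lengths)
  if (length(loop_lengths)) {
    parts[seq(2, length(parts), by = 2)] <- strrep("A", loop_lengths)
  }
  paste(parts, collapse = "")
}

#' Specify one motif plant
#'
#' @param motif_class `"G4"` or `"IMOTIF"`.
#' @param n_tracts Number of tracts (>= 4 for the default pattern).
#' @param tract_length Tract length (scalar, recycled over tracts).
#' @param loop_lengths Loop lengths (scalar recycled, or one per loop), each
#'   within the pattern's loop bounds.
#' @param transcript Target transcript id, or `NA` to place at random.
#' @param offset 0-based plant offset within the transcript, or `NA` for
#'   random placement.
#' @param target_region `NA`, or one of `"FIVE_UTR"`, `"CDS"`, `"THREE_UTR"`
#'   for region-targeted planting into ORF-bearing transcripts.
#' @return A one-row tibble describing the plant.
#' @export
motif_plant_spec <- function(motif_class, n_tracts = 4, tract_length = 3,
                             loop_lengths = 1, transcript = NA,
                             offset = NA, target_region = NA) {
  stopifnot(motif_class %in% c("G4", "IMOTIF"), n_tracts >= 2)
  loops <- rep_len(as.integer(loop_lengths), n_tracts - 1L)
  tibble(motif_class = motif_class, n_tracts = as.integer(n_tracts),
         tract_length = as.integer(tract_length),
         loop_lengths = list(loops),
         transcript = as.character(transcript),
         offset = as.integer(offset),
         target_region = as.character(target_region))
}

#' Plant motifs into transcripts
#'
#' Splices motif strings into transcript sequences, replacing background
#' bases (length-preserving, so coordinates planned in advance stay valid).
#' Placement is random where `offset`/`transcript` are `NA`; two plants on
#' the same transcript may not overlap. For region-targeted plants,
#' `orfs` must carry the constructed ORF coordinates and the random offset is
#' drawn inside the requested region (plants never touch the start or stop
#' codon).
#'
#' @param transcripts Tibble as from [generate_background()].
#' @param specs Tibble of plant specs (rows from [motif_plant_spec()]).
#' @param seed Integer seed for random placement.
#' @param orfs Optional ORF tibble ([annotate_orfs()] layout) required when
#'   any spec has a `target_region`.
#' @return A list with `transcripts` (sequences after planting) and `truth`
#'   (tibble: `transcript_id`, `start`, `end`, `motif_class`,
#'   `target_region`).
#' @export
plant_motifs <- function(transcripts, specs, seed = 1, orfs = NULL) {
  stopifnot(is.data.frame(transcripts), nrow(transcripts) >= 1,
            is.data.frame(specs), nrow(specs) >= 1)
  set.seed(seed)
  seqs <- transcripts$seq
  names(seqs) <- transcripts$id
  occupied <- lapply(seqs, function(x) integer(0))  # planted positions per tx
  truth <- vector("list", nrow(specs))
  for (k in seq_len(nrow(specs))) {
    sp <- specs[k, ]
    mstr <- motif_string(sp$motif_class,
                         rep_len(sp$tract_length, sp$n_tracts),
                         sp$loop_lengths[[1]])
    mlen <- nchar(mstr)
    tid <- sp$transcript
    if (is.na(tid)) tid <- sample(transcripts$id, 1L)
    L <- nchar(seqs[[tid]])
    region <- sp$target_region
    if (!is.na(region)) {
      if (is.null(orfs)) {
        stop("region-targeted plant requires an `orfs` table", call. = FALSE)
      }
      o <- orfs[orfs$transcript_id == tid, ]
      if (nrow(o) != 1 || !isTRUE(o$has_orf)) {
        stop("transcript '", tid, "' has no constructed ORF", call. = FALSE)
      }
      bounds <- switch(region,
        FIVE_UTR = c(0L, o$orf_start),
        CDS = c(o$orf_start + 3L, o$orf_end - 3L),  # spare start/stop codons
        THREE_UTR = c(o$orf_end, L),
        stop("unknown target_region: ", region, call. = FALSE))
    } else {
      bounds <- c(0L, L)
    }
    if (bounds[2] - bounds[1] < mlen) {
      stop("motif of ", mlen, " bp does not fit in ", region, " of '", tid,
           "'", call. = FALSE)
    }
    off <- sp$offset
    placed <- FALSE
    for (attempt in seq_len(200L)) {
      cand <- if (!is.na(off)) off else {
        bounds[1] + sample.int(bounds[2] - bounds[1] - mlen + 1L, 1L) - 1L
      }
      span <- (cand + 1L):(cand + mlen)
      if (!any(span %in% occupied[[tid]])) {
        off <- cand
        placed <- TRUE
        break
      }
      if (!is.na(sp$offset)) break  # explicit offset that collides
    }
    if (!placed) {
      stop("planted intervals overlap on transcript '", tid, "'",
           call. = FALSE)
    }
    substr(seqs[[tid]], off + 1L, off + mlen) <- mstr
    occupied[[tid]] <- c(occupied[[tid]], (off + 1L):(off + mlen))
    truth[[k]] <- tibble(transcript_id = tid, start = off,
                         end = off + mlen, motif_class = sp$motif_class,
                         target_region = region)
  }
  out <- transcripts
  out$seq <- unname(seqs[transcripts$id])
  out$length <- nchar(out$seq)
  list(transcripts = out, truth = dplyr::bind_rows(truth))
}

#' Generate pattern-free transcripts carrying a constructed ORF
#'
#' Builds suppressed backgrounds and then installs a known ORF: an ATG at
#' `orf_start`, a TAA stop ending at `orf_end`, and all in-frame internal
#' stop codons resampled away. Candidates where the installed ORF is not the
#' unique longest ORF (a competing ATG-to-stop span elsewhere can be longer
#' by chance) are rejected and redrawn, so [find_longest_orf()] is guaranteed
#' to recover the constructed coordinates.
#'
#' @param n Number of transcripts.
#' @param length Transcript length in bp.
#' @param orf_start,orf_end Constructed ORF interval, 0-based half-open;
#'   `orf_end - orf_start` must be a positive multiple of 3.
#' @param gc GC content of the background.
#' @param seed Integer seed.
#' @param min_codons ORF acceptance floor used in the dominance check.
#' @param pattern A [pqs_pattern()] for the suppression check.
#' @param max_tries Rejection budget per transcript.
#' @param id_prefix Prefix for transcript ids.
#' @return A list with `transcripts` (tibble) and `orfs` (tibble in
#'   [annotate_orfs()] layout, the constructed coordinates).
#' @export
generate_orf_transcripts <- function(n, length = 900, orf_start = 240,
                                     orf_end = 690, gc = 0.5, seed = 1,
                                     min_codons = 50,
                                     pattern = pqs_pattern(),
                                     max_tries = 1000,
                                     id_prefix = "synth_orf") {
  stopifnot((orf_end - orf_start) %% 3 == 0,
            orf_end - orf_start >= 3 * min_codons,
            orf_end <= length, orf_start >= 0)
  set.seed(seed)
  seqs <- character(n)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      s <- draw_suppressed(length, gc, pattern, max_tries)
      s <- install_orf(s, orf_start, orf_end)
      o <- find_longest_orf(s, min_codons)
      if (isTRUE(o$has_orf) && o$orf_start == orf_start &&
          o$orf_end == orf_end &&
          nrow(pqs_brute_force(s, pattern, "G")) == 0 &&
          nrow(pqs_brute_force(s, pattern, "C")) == 0) {
        seqs[i] <- s
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      stop("could not construct a dominant ORF in ", max_tries, " tries",
           call. = FALSE)
    }
  }
  ids <- sprintf("%s_%04d", id_prefix, seq_len(n))
  list(
    transcripts = tibble(id = ids, seq = seqs, length = nchar(seqs)),
    orfs = tibble(transcript_id = ids, has_orf = TRUE,
                  orf_start = as.integer(orf_start),
                  orf_end = as.integer(orf_end),
                  frame = as.integer(orf_start %% 3), length = nchar(seqs))
  )
}

# Overwrite the ORF scaffold into a background: ATG ... (no in-frame stops,
# stops resampled to CAA/CAG/CGA) ... TAA. Codon rewrites use C as the first
# base, which cannot seed a G-tract.
install_orf <- function(s, orf_start, orf_end) {
  substr(s, orf_start + 1L, orf_start + 3L) <- "ATG"
  substr(s, orf_end - 2L, orf_end) <- "TAA"
  pos <- orf_start + 3L  # 0-based codon starts of internal codons
  while (pos + 3L <= orf_end - 3L) {
    codon <- substr(s, pos + 1L, pos + 3L)
    if (codon %in% c("TAA", "TAG", "TGA")) {
      substr(s, pos + 1L, pos + 1L) <- "C"
    }
    pos <- pos + 3L
  }
  s
}

#' Simulate ORF-bearing transcripts with region-targeted motif plants
#'
#' Convenience generator for localization studies: each transcript carries a
#' constructed ORF ([generate_orf_transcripts()]) and one motif planted into
#' a designated region. Because a planted motif can overwrite a background
#' stop codon and thereby lengthen a competing reading frame, every
#' transcript is re-verified after planting (the constructed ORF must still
#' be the unique longest) and redrawn if not, so classification ground truth
#' is exact by construction.
#'
#' @param n Number of transcripts (one plant each).
#' @param regions Character vector recycled over transcripts:
#'   `"FIVE_UTR"`, `"CDS"` or `"THREE_UTR"`.
#' @param motif_classes Character vector recycled over transcripts: `"G4"` or
#'   `"IMOTIF"`.
#' @param length,orf_start,orf_end,gc,min_codons,pattern Passed to
#'   [generate_orf_transcripts()].
#' @param seed Integer seed.
#' @param max_tries Redraw budget per transcript.
#' @return A list with `transcripts`, `orfs` (constructed coordinates) and
#'   `truth` (plant intervals with `target_region`).
#' @export
simulate_region_plants <- function(n, regions = c("FIVE_UTR", "CDS", "THREE_UTR"),
                                   motif_classes = c("G4", "IMOTIF"),
                                   length = 900, orf_start = 240,
                                   orf_end = 690, gc = 0.5, seed = 1,
                                   min_codons = 50, pattern = pqs_pattern(),
                                   max_tries = 50) {
  regions <- rep_len(regions, n)
  motif_classes <- rep_len(motif_classes, n)
  txs <- vector("list", n)
  orfs <- vector("list", n)
  truths <- vector("list", n)
  for (i in seq_len(n)) {
    done <- FALSE
    for (try in seq_len(max_tries)) {
      sub_seed <- (seed + 7919L * i + 104729L * (try - 1L)) %% .Machine$integer.max
      gen <- generate_orf_transcripts(1, length = length,
                                      orf_start = orf_start,
                                      orf_end = orf_end, gc = gc,
                                      seed = sub_seed,
                                      min_codons = min_codons,
                                      pattern = pattern,
                                      id_prefix = sprintf("synth_orf_%04d", i))
      spec <- motif_plant_spec(motif_classes[i],
                               n_tracts = 4, tract_length = pattern$g_run_min,
                               loop_lengths = 2,
                               transcript = gen$transcripts$id[1],
                               target_region = regions[i])
      planted <- plant_motifs(gen$transcripts, spec, seed = sub_seed + 1L,
                              orfs = gen$orfs)
      o <- find_longest_orf(planted$transcripts$seq[1], min_codons)
      if (isTRUE(o$has_orf) && o$orf_start == orf_start &&
          o$orf_end == orf_end) {
        txs[[i]] <- planted$transcripts
        orfs[[i]] <- gen$orfs
        truths[[i]] <- planted$truth
        done <- TRUE
        break
      }
    }
    if (!done) {
      stop("could not plant into '", regions[i],
           "' while keeping the constructed ORF dominant", call. = FALSE)
    }
  }
  list(transcripts = dplyr::bind_rows(txs), orfs = dplyr::bind_rows(orfs),
       truth = dplyr::bind_rows(truths))
}

#' Generate paired reads with labeled filter-rule violations
#'
#' Samples read pairs from transcripts at high base quality and plants, in
#' selected pairs, exactly one violation of one removal rule: an exact
#' adapter insert longer than the tolerated match, an N fraction strictly
#' above the N threshold, or a low-quality fraction strictly above the
#' quality threshold. Each violating pair carries its violation on mate 1;
#' all other reads are rejection-checked to violate nothing, so the truth
#' labels are exact. Quality values are flat (40 for clean bases, 2 for
#' planted low-quality bases): the generator emulates rule boundaries, not a
#' sequencer error profile.
#'
#' @param transcripts Tibble of source transcripts (all at least
#'   `read_length` long).
#' @param n_reads Number of read pairs.
#' @param read_length Read length in bp.
#' @param frac_adapter,frac_n,frac_lowq Fractions of pairs violating each
#'   rule (must sum to at most 1).
#' @param adapter_seq Adapter sequence; inserts of
#'   `thresholds$adapter_min_excess_bp + 3` bp are planted.
#' @param thresholds A [filter_thresholds()] object defining the boundaries
#'   to breach (its `adapter_seq` must equal `adapter_seq`).
#' @param seed Integer seed.
#' @return A list with `r1`, `r2` (read tibbles as from [read_fastq()]) and
#'   `truth` (tibble: `pair_id`, `violation` in
#'   `"none"/"adapter"/"n"/"quality"`).
#' @export
generate_reads <- function(transcripts, n_reads, read_length = 100,
                           frac_adapter = 0.1, frac_n = 0.1, frac_lowq = 0.1,
                           adapter_seq = "AGATCGGAAGAGC",
                           thresholds = filter_thresholds(adapter_seq),
                           seed = 1) {
  stopifnot(frac_adapter + frac_n + frac_lowq <= 1,
            identical(thresholds$adapter_seq, normalize_seq(adapter_seq)))
  if (any(transcripts$length < read_length)) {
    stop("read_length exceeds the length of some transcripts", call. = FALSE)
  }
  set.seed(seed)
  n_ad <- round(frac_adapter * n_reads)
  n_n <- round(frac_n * n_reads)
  n_lq <- round(frac_lowq * n_reads)
  labels <- sample(c(rep("adapter", n_ad), rep("n", n_n),
                     rep("quality", n_lq),
                     rep("none", n_reads - n_ad - n_n - n_lq)))
  q_hi <- 40L
  q_lo <- thresholds$lowq_cutoff - 1L
  is_clean <- function(s) {
    !grepl("N", s, fixed = TRUE) &&
      adapter_match_length(s, thresholds$adapter_seq) <=
        thresholds$adapter_min_excess_bp
  }
  draw_clean <- function(revcomp = FALSE) {
    # window free of N and of disqualifying adapter overlap
    for (try in 1:200) {
      tx <- transcripts[sample.int(nrow(transcripts), 1L), ]
      pos <- sample.int(tx$length - read_length + 1L, 1L)
      s <- substr(tx$seq, pos, pos + read_length - 1L)
      if (revcomp) s <- reverse_complement(s)
      if (is_clean(s)) return(s)
    }
    stop("could not draw a clean read window", call. = FALSE)
  }
  mutate_read <- function(s, label) {
    quals <- rep(q_hi, read_length)
    if (label == "adapter") {
      ins_len <- min(nchar(thresholds$adapter_seq),
                     thresholds$adapter_min_excess_bp + 3L)
      at <- sample.int(read_length - ins_len + 1L, 1L)
      substr(s, at, at + ins_len - 1L) <- substr(thresholds$adapter_seq, 1L,
                                                 ins_len)
    } else if (label == "n") {
      k <- floor(thresholds$max_n_fraction * read_length) + 1L
      at <- sample.int(read_length, k)
      for (j in at) substr(s, j, j) <- "N"
    } else if (label == "quality") {
      k <- floor(thresholds$max_lowq_fraction * read_length) + 1L
      quals[sample.int(read_length, k)] <- q_lo
    }
    list(seq = s, quals = quals)
  }
  r1 <- vector("list", n_reads)
  r2 <- vector("list", n_reads)
  for (i in seq_len(n_reads)) {
    m1 <- mutate_read(draw_clean(), labels[i])
    m2 <- list(seq = draw_clean(revcomp = TRUE),
               quals = rep(q_hi, read_length))
    r1[[i]] <- m1
    r2[[i]] <- m2
  }
  pair_ids <- sprintf("read_%05d", seq_len(n_reads))
  mk <- function(lst, mate) {
    tibble(id = paste0(pair_ids, "/", mate),
           seq = vapply(lst, `[[`, character(1), "seq"),
           quals = lapply(lst, `[[`, "quals"),
           length = read_length)
  }
  list(r1 = mk(r1, 1L), r2 = mk(r2, 2L),
       truth = tibble(pair_id = pair_ids, violation = labels))
}
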