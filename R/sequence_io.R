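#' @importFrom rlang .data
#' @importFrom tibble tibble
NULL

# Alphabet after ingest normalization: DNA plus the ambiguity placeholder N.
DNA_ALPHABET <- c("A", "C", "G", "T", "N")

#' Validate a DNA character vector
#'
#' Checks that every element of `seq` uses only the A/C/G/T/N alphabet
#' (uppercase). Used internally by every operation that consumes sequence.
#'
#' @param seq Character vector of sequences.
#' @param what Label used in the error message.
#' @return Invisibly, `seq`.
#' @keywords internal
assert_dna <- function(seq, what = "sequence") {
  bad <- grepl("[^ACGTN]", seq)
  if (any(bad)) {
    offender <- seq[bad][1L]
    ch <- regmatches(offender, regexpr("[^ACGTN]", offender))
    stop(sprintf("illegal character '%s' in %s (allowed: A,C,G,T,N)", ch, what),
         call. = FALSE)
  }
  invisible(seq)
}

# Uppercase and map RNA U to T; EST/unigene data are cDNA so patterns are
# scanned on the DNA alphabet.
normalize_seq <- function(seq) {
  chartr("U", "T", toupper(seq))
}

#' Read transcripts from a FASTA file
#'
#' Reads a (possibly gzipped) FASTA file of assembled transcripts/unigenes.
#' Sequences are normalized on ingest: lowercase is uppercased and RNA `U` is
#' mapped to `T`. IUPAC ambiguity codes other than `N` are rejected rather
#' than silently remapped, because the quadruplex scan semantics for them are
#' undefined.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id`, `seq` and `length`, one row per record,
#'   in file order.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">u1", "ggga"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  ids <- names(set)
  seqs <- normalize_seq(as.character(set))
  if (length(set) > 0) {
    ids <- sub("\\s.*$", "", ids)  # FASTA id = first whitespace-delimited token
    if (any(!nzchar(ids))) {
      stop("FASTA record ", which(!nzchar(ids))[1L], " has an empty header",
           call. = FALSE)
    }
    if (anyDuplicated(ids)) {
      stop("duplicate FASTA id: ", ids[duplicated(ids)][1L], call. = FALSE)
    }
    empty <- !nzchar(seqs)
    if (any(empty)) {
      stop("FASTA record '", ids[empty][1L], "' has an empty sequence",
           call. = FALSE)
    }
    for (i in seq_along(seqs)) assert_dna(seqs[i], paste0("record '", ids[i], "'"))
  }
  tibble(id = as.character(ids), seq = unname(seqs), length = nchar(unname(seqs)))
}

#' Write transcripts to a FASTA file
#'
#' @param records Tibble with columns `id` and `seq` (as from [read_fasta()]).
#' @param path Output path.
#' @param width Line-wrap width in columns (default 60).
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(records, path, width = 60) {
  stopifnot(is.data.frame(records), all(c("id", "seq") %in% names(records)))
  set <- Biostrings::BStringSet(records$seq)
  names(set) <- records$id
  Biostrings::writeXStringSet(set, path, format = "fasta", width = width)
  invisible(path)
}

#' Read sequencing reads from a FASTQ file
#'
#' Reads 4-line FASTQ records and decodes per-base Phred quality scores as
#' `utf8(char) - phred_offset`.
#'
#' @param path Path to a FASTQ file (plain or gzipped).
#' @param phred_offset ASCII offset of the quality encoding, 33 (Sanger /
#'   CASAVA >= 1.8) or 64 (older Illumina).
#' @return A tibble with columns `id`, `seq`, `quals` (list column of integer
#'   vectors) and `length`.
#' @export
read_fastq <- function(path, phred_offset = 33) {
  if (!phred_offset %in% c(33L, 64L)) {
    stop("phred_offset must be 33 or 64", call. = FALSE)
  }
  if (!file.exists(path)) stop("FASTQ file not found: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path, format = "fastq", with.qualities = TRUE)
  ids <- sub("\\s.*$", "", names(set))
  qset <- S4Vectors::mcols(set)$qualities
  # the parser NUL-pads short quality strings to the read width (and errors
  # itself on over-long ones); padded bytes mean a length mismatch
  bad <- vapply(seq_along(qset),
                function(i) any(as.integer(qset[[i]]) == 0L), logical(1))
  if (any(bad)) {
    stop("FASTQ record '", ids[bad][1L],
         "': quality string length differs from sequence length", call. = FALSE)
  }
  seqs <- normalize_seq(as.character(set))
  qstr <- as.character(qset)
  for (i in seq_along(seqs)) assert_dna(seqs[i], paste0("read '", ids[i], "'"))
  quals <- lapply(qstr, function(q) {
    if (!nzchar(q)) return(integer(0))
    utf8ToInt(q) - as.integer(phred_offset)
  })
  out_of_range <- vapply(quals, function(q) any(q < 0L | q > 93L), logical(1))
  if (any(out_of_range)) {
    stop("FASTQ record '", ids[out_of_range][1L],
         "': decoded quality outside [0, 93]; wrong phred_offset?",
         call. = FALSE)
  }
  tibble(id = unname(ids), seq = unname(seqs), quals = unname(quals),
         length = nchar(unname(seqs)))
}

#' Write reads to a FASTQ file
#'
#' @param reads Tibble with columns `id`, `seq` and `quals` (list column of
#'   integer Phred scores), as from [read_fastq()].
#' @param path Output path.
#' @param phred_offset Quality encoding offset (33 or 64).
#' @return Invisibly, `path`.
#' @export
write_fastq <- function(reads, path, phred_offset = 33) {
  stopifnot(all(c("id", "seq", "quals") %in% names(reads)))
  qstr <- vapply(reads$quals, function(q) {
    if (length(q) == 0) "" else intToUtf8(q + as.integer(phred_offset))
  }, character(1))
  set <- Biostrings::BStringSet(reads$seq)
  names(set) <- reads$id
  Biostrings::writeXStringSet(set, path, format = "fastq",
                              qualities = Biostrings::BStringSet(qstr))
  invisible(path)
}

#' Reverse complement of DNA sequences
#'
#' Standard Watson-Crick complement, reversed; `N` maps to `N`. Assembled
#' ESTs may represent the antisense strand, which is why the scanner treats
#' C-rich (i-motif) patterns as the mirror of G-rich ones.
#'
#' @param seq Character vector of A/C/G/T/N sequences.
#' @return Character vector of reverse complements.
#' @examples
#' reverse_complement("GGGA")  # "TCCC"
#' @export
reverse_complement <- function(seq) {
  seq <- normalize_seq(seq)
  assert_dna(seq)
  out <- character(length(seq))
  nonempty <- nzchar(seq)
  if (any(nonempty)) {
    rc <- Biostrings::reverseComplement(Biostrings::DNAStringSet(seq[nonempty]))
    out[nonempty] <- as.character(rc)
  }
  out
}
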