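#' Write a hit table as BED6
#'
#' Coordinates stay 0-based half-open (BED convention). `score` carries the
#' number of tracts; strand is `+` for G4 and `-` for i-motif (the C-rich
#' pattern marks putative antisense structure).
#'
#' @param hits Hit tibble from [scan_transcripts()] (optionally localized).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_hits_bed <- function(hits, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# BED6: transcript, start, end, name, n_tracts, strand", con)
  if (nrow(hits)) {
    bed <- data.frame(
      chrom = hits$transcript_id,
      start = hits$start,
      end = hits$end,
      name = sprintf("%s_%d", tolower(hits$motif), seq_len(nrow(hits))),
      score = hits$n_tracts,
      strand = ifelse(hits$motif == "G4", "+", "-")
    )
    utils::write.table(bed, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Write a hit table as TSV
#'
#' Adds 1-based inclusive coordinate columns (`start_1based`, `end_1based`)
#' next to the 0-based half-open ones, and flattens the tract/loop
#' decompositions to comma-separated strings.
#'
#' @inheritParams write_hits_bed
#' @return Invisibly, `path`.
#' @export
write_hits_tsv <- function(hits, path) {
  flat <- function(col) vapply(col, paste, character(1), collapse = ",")
  df <- as.data.frame(hits[setdiff(names(hits),
                                   c("tract_lengths", "loop_lengths"))])
  df$start_1based <- hits$start + 1L
  df$end_1based <- hits$end
  df$tract_lengths <- if (nrow(hits)) flat(hits$tract_lengths) else character(0)
  df$loop_lengths <- if (nrow(hits)) flat(hits$loop_lengths) else character(0)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Assemble a pipeline configuration
#'
#' @param fasta Path to the transcript/unigene FASTA (required).
#' @param fastq1,fastq2 Optional raw-read FASTQ paths; when given, the read
#'   filter stage runs (paired if `fastq2` is set).
#' @param adapter_seq Adapter sequence for the filter stage (required when
#'   reads are given).
#' @param out_dir Output directory (created if absent).
#' @param thresholds A [filter_thresholds()] object, built from `adapter_seq`
#'   by default.
#' @param pattern A [pqs_pattern()].
#' @param motif,mode Scan options, as in [scan_transcripts()].
#' @param min_codons ORF acceptance floor for localization.
#' @param cutoff,bin_width,bin_ceiling Assembly-summary options.
#' @param phred_offset FASTQ quality encoding offset.
#' @return A `pipeline_config` list, validated.
#' @export
pipeline_config <- function(fasta, out_dir, fastq1 = NULL, fastq2 = NULL,
                            adapter_seq = NULL,
                            thresholds = if (!is.null(adapter_seq))
                              filter_thresholds(adapter_seq) else NULL,
                            pattern = pqs_pattern(),
                            motif = "both", mode = "default",
                            min_codons = 50, cutoff = 500, bin_width = 100,
                            bin_ceiling = 3000, phred_offset = 33) {
  if (!file.exists(fasta)) stop("missing input FASTA: ", fasta, call. = FALSE)
  for (fq in c(fastq1, fastq2)) {
    if (!is.null(fq) && !file.exists(fq)) {
      stop("missing input FASTQ: ", fq, call. = FALSE)
    }
  }
  if (!is.null(fastq1) && is.null(thresholds)) {
    stop("read filtering requested but no adapter/thresholds given",
         call. = FALSE)
  }
  structure(
    list(fasta = fasta, fastq1 = fastq1, fastq2 = fastq2,
         thresholds = thresholds, pattern = pattern, motif = motif,
         mode = mode, min_codons = min_codons, cutoff = cutoff,
         bin_width = bin_width, bin_ceiling = bin_ceiling,
         phred_offset = phred_offset, out_dir = out_dir),
    class = "pipeline_config"
  )
}

#' Run the full pipeline: filter, stats, scan, localize
#'
#' Stage order is fixed: (1) optional raw-read filtering with a JSON report;
#' (2) assembly summary of the transcript FASTA; (3) G4/i-motif scan with
#' BED6 and TSV output; (4) longest-ORF localization of every hit; (5) a
#' top-level JSON summary with per-class unigene counts. All outputs are
#' plain files under `cfg$out_dir`; re-running the same config on the same
#' inputs reproduces them byte-identically. Progress is logged to stderr.
#'
#' @param cfg A [pipeline_config()].
#' @return Invisibly, the run summary (named list) written to `summary.json`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(cfg$out_dir, f)
  stage <- function(msg) message(sprintf("[quadscan %s] %s",
                                         format(Sys.time(), "%H:%M:%S"), msg))
  summary <- list()

  if (!is.null(cfg$fastq1)) {
    stage(paste("filtering reads:", cfg$fastq1))
    r1 <- read_fastq(cfg$fastq1, cfg$phred_offset)
    r2 <- if (!is.null(cfg$fastq2)) read_fastq(cfg$fastq2, cfg$phred_offset)
    res <- filter_fastq(r1, cfg$thresholds, mates = r2)
    write_fastq(res$kept, out("filtered_1.fastq"), cfg$phred_offset)
    if (!is.null(res$kept_mates)) {
      write_fastq(res$kept_mates, out("filtered_2.fastq"), cfg$phred_offset)
    }
    write_json_report(res$report, out("filter_report.json"))
    summary$filter <- res$report
  }

  stage(paste("summarizing assembly:", cfg$fasta))
  tx <- read_fasta(cfg$fasta)
  asm <- summarize_assembly(tx, cutoff = cfg$cutoff,
                            bin_width = cfg$bin_width,
                            bin_ceiling = cfg$bin_ceiling)
  asm_json <- asm[setdiff(names(asm), "bins")]
  write_json_report(asm_json, out("assembly_summary.json"))
  utils::write.table(asm$bins[, c("label", "count")], out("length_hist.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  summary$assembly <- asm_json

  stage(sprintf("scanning %d transcripts (%s, %s mode)", nrow(tx),
                cfg$motif, cfg$mode))
  hits <- scan_transcripts(tx, cfg$pattern, motif = cfg$motif, mode = cfg$mode)
  write_hits_bed(hits, out("hits.bed"))
  write_hits_tsv(hits, out("hits.tsv"))

  stage("localizing hits to 5'UTR/CDS/3'UTR")
  orfs <- annotate_orfs(tx, min_codons = cfg$min_codons)
  annotated <- localize_hits(hits, orfs)
  write_hits_tsv(annotated, out("hits_annotated.tsv"))

  summary$pqs <- list(
    n_hits = nrow(hits),
    g4_unigene_count = count_pqs_unigenes(hits, "G4"),
    imotif_unigene_count = count_pqs_unigenes(hits, "IMOTIF"),
    region_counts = as.list(table(factor(annotated$region,
                                         levels = REGION_LEVELS)))
  )
  write_json_report(summary, out("summary.json"))
  stage("done")
  invisible(summary)
}
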