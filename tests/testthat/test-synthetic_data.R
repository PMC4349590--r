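test_that("background generation is deterministic and pattern-free", {
  a <- generate_background(10, 300, gc = 0.4, seed = 7)
  b <- generate_background(10, 300, gc = 0.4, seed = 7)
  expect_identical(a, b)
  expect_false(identical(a, generate_background(10, 300, gc = 0.4, seed = 8)))
  for (s in a$seq) {
    expect_equal(nrow(oracle_pqs_intervals(s, "G")), 0L)
    expect_equal(nrow(oracle_pqs_intervals(s, "C")), 0L)
  }
})

test_that("background base composition matches the requested GC content", {
  bg <- generate_background(50, 2000, gc = 0.4, seed = 99)
  all_seq <- paste(bg$seq, collapse = "")
  n <- nchar(all_seq)
  gc_obs <- (n - nchar(gsub("[GC]", "", all_seq))) / n
  se <- sqrt(0.4 * 0.6 / n)
  expect_lt(abs(gc_obs - 0.4), 3 * se)
})

test_that("motif strings parse under the anchored pattern for both classes", {
  g4 <- motif_string("G4", c(3, 4, 5, 3), c(1, 7, 2))
  expect_equal(nchar(g4), 25L)
  expect_true(grepl("^G{3,}(?:.{1,7}G{3,}){3,}$", g4, perl = TRUE))
  im <- motif_string("IMOTIF", rep(3, 4), rep(1, 3))
  expect_true(grepl("^C{3,}(?:.{1,7}C{3,}){3,}$", im, perl = TRUE))
  expect_error(motif_string("G4", rep(3, 4), rep(1, 4)), "length")
})

test_that("planting is length-preserving with exact truth coordinates", {
  bg <- generate_background(4, 300, seed = 11)
  specs <- dplyr::bind_rows(
    motif_plant_spec("G4", n_tracts = 4, tract_length = 3, loop_lengths = 1,
                     transcript = bg$id[1], offset = 10),
    motif_plant_spec("IMOTIF", n_tracts = 4, tract_length = 3,
                     loop_lengths = 2, transcript = bg$id[2])
  )
  res <- plant_motifs(bg, specs, seed = 2)
  expect_equal(res$truth$start[1], 10L)
  expect_equal(res$truth$end[1], 25L)
  expect_equal(res$transcripts$length, bg$length)
  expect_equal(substr(res$transcripts$seq[1], 11, 25), "GGGAGGGAGGGAGGG")
  # untouched transcripts unchanged
  expect_equal(res$transcripts$seq[3:4], bg$seq[3:4])
  # planted i-motif parses as a C-tract motif
  im <- with(res$truth[2, ], substr(res$transcripts$seq[2], start + 1, end))
  expect_true(grepl("^C{3,}(?:.{1,7}C{3,}){3,}$", im, perl = TRUE))

  # overlapping explicit plants error out
  clash <- dplyr::bind_rows(
    motif_plant_spec("G4", transcript = bg$id[1], offset = 10),
    motif_plant_spec("G4", transcript = bg$id[1], offset = 12)
  )
  expect_error(plant_motifs(bg, clash, seed = 1), "overlap")
})

test_that("region-targeted plants land in their region and need an ORF table", {
  sim <- simulate_region_plants(6, seed = 5)
  expect_equal(nrow(sim$truth), 6L)
  ann <- localize_hits(
    scan_transcripts(sim$transcripts, mode = "exhaustive"),
    annotate_orfs(sim$transcripts)
  )
  for (k in seq_len(nrow(sim$truth))) {
    tr <- sim$truth[k, ]
    match <- ann[ann$transcript_id == tr$transcript_id &
                   ann$start == tr$start & ann$end == tr$end, ]
    expect_equal(nrow(match), 1L)
    expect_equal(match$region, tr$target_region)
    expect_equal(match$motif, tr$motif_class)
  }

  bg <- generate_background(2, 300, seed = 3)
  spec <- motif_plant_spec("G4", transcript = bg$id[1], target_region = "CDS")
  expect_error(plant_motifs(bg, spec, seed = 1), "orfs")
})

test_that("generated reads carry exactly their labeled violation", {
  bg <- generate_background(10, 300, seed = 41)
  th <- filter_thresholds("AGATCGGAAGAGC")
  rd <- generate_reads(bg, 200, read_length = 100, frac_adapter = 0.1,
                       frac_n = 0.1, frac_lowq = 0.1, seed = 17,
                       thresholds = th)
  expect_equal(nrow(rd$r1), 200L)
  res <- filter_fastq(rd$r1, th, mates = rd$r2)
  rules <- ifelse(is.na(res$rules), "none", res$rules)
  expect_equal(rules, rd$truth$violation)
  expect_equal(res$report$n_removed_adapter, sum(rd$truth$violation == "adapter"))
  expect_equal(res$report$n_removed_n, sum(rd$truth$violation == "n"))
  expect_equal(res$report$n_removed_quality, sum(rd$truth$violation == "quality"))

  # no violations requested: everything passes
  clean <- generate_reads(bg, 50, frac_adapter = 0, frac_n = 0, frac_lowq = 0,
                          seed = 19, thresholds = th)
  expect_equal(filter_fastq(clean$r1, th, mates = clean$r2)$report$n_kept, 50L)

  expect_error(generate_reads(bg, 10, read_length = 400, thresholds = th),
               "read_length exceeds")
})

test_that("read generation is byte-identical under a fixed seed", {
  bg <- generate_background(5, 300, seed = 53)
  th <- filter_thresholds("AGATCGGAAGAGC")
  a <- generate_reads(bg, 30, seed = 4, thresholds = th)
  b <- generate_reads(bg, 30, seed = 4, thresholds = th)
  f1 <- withr::local_tempfile(fileext = ".fq")
  f2 <- withr::local_tempfile(fileext = ".fq")
  write_fastq(a$r1, f1)
  write_fastq(b$r1, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(a$truth, b$truth)
})
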