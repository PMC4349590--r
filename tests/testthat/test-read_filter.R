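adapter <- "AGATCGGAAGAGCACACGTCTGAACTCCAG"  # TruSeq-like, 30 nt
th <- filter_thresholds(adapter)

test_that("adapter_match_length equals the dynamic-programming oracle", {
  # flanks chosen so they cannot extend the embedded 12-mer
  read <- paste0(strrep("A", 40), substr(adapter, 5, 16), strrep("A", 40))
  expect_equal(adapter_match_length(read, adapter), 12L)
  expect_lte(adapter_match_length(strrep("T", 50), "ACGCA"), 1L)

  set.seed(17)
  for (i in 1:30) {
    r <- rand_dna(100)
    expect_equal(adapter_match_length(r, adapter), oracle_lcs_dp(r, adapter))
  }
})

test_that("each removal rule is strict at its boundary", {
  len <- 100L
  base <- strrep("TA", 50)  # shares no 3-mer with the adapter
  q <- make_quals(len)

  # N rule: 4/100 removed, 3/100 kept
  with_n <- function(k) paste0(strrep("N", k), substr(base, k + 1, len))
  expect_false(filter_read(with_n(4), q, th)$keep)
  expect_equal(filter_read(with_n(4), q, th)$rule, "n")
  expect_true(filter_read(with_n(3), q, th)$keep)

  # quality rule: 26/50 low-Q removed, 25/50 kept
  s50 <- substr(base, 1, 50)
  expect_false(filter_read(s50, c(rep(2, 26), rep(40, 24)), th)$keep)
  expect_equal(filter_read(s50, c(rep(2, 26), rep(40, 24)), th)$rule, "quality")
  expect_true(filter_read(s50, c(rep(2, 25), rep(40, 25)), th)$keep)
  # Q exactly at the cutoff does not count as low-quality
  expect_true(filter_read(s50, rep(3, 50), th)$keep)

  # adapter rule: exactly 9 bp match kept, 10 bp removed
  r9 <- paste0(substr(adapter, 1, 9), substr(base, 10, len))
  stopifnot(oracle_lcs_dp(r9, adapter) == 9)
  expect_true(filter_read(r9, q, th)$keep)
  r10 <- paste0(substr(adapter, 1, 10), substr(base, 11, len))
  stopifnot(oracle_lcs_dp(r10, adapter) == 10)
  expect_false(filter_read(r10, q, th)$keep)
  expect_equal(filter_read(r10, q, th)$rule, "adapter")

  expect_error(filter_read("", integer(0), th), "zero-length")
})

test_that("attribution follows the fixed adapter > N > quality order", {
  len <- 100L
  seq <- paste0(substr(adapter, 1, 12), strrep("N", 10), strrep("A", len - 22))
  r <- filter_read(seq, rep(0, len), th)  # violates all three rules
  expect_equal(r$rule, "adapter")
  seq2 <- paste0(strrep("N", 10), strrep("A", len - 10))
  expect_equal(filter_read(seq2, rep(0, len), th)$rule, "n")
})

make_reads <- function(seqs, q = 40) {
  tibble::tibble(id = sprintf("r%d", seq_along(seqs)), seq = seqs,
                 quals = lapply(nchar(seqs), make_quals, q = q),
                 length = nchar(seqs))
}

test_that("filter_fastq drops a pair when either mate fails and reports counts", {
  set.seed(5)
  clean <- vapply(rep(80, 4), rand_dna, character(1), gc = 0.1)
  bad_n <- paste0(strrep("N", 10), strrep("A", 70))
  r1 <- make_reads(c(clean[1], clean[2]))
  r2 <- make_reads(c(clean[3], bad_n))
  res <- filter_fastq(r1, th, mates = r2)
  expect_equal(res$report$n_input, 2L)
  expect_equal(res$report$n_kept, 1L)
  expect_equal(res$report$n_removed_n, 1L)
  expect_equal(res$kept$id, "r1")
  expect_equal(res$kept_mates$id, "r1")

  expect_error(filter_fastq(r1, th, mates = r2[1, ]), "different read counts")
})

test_that("filtering is idempotent, order-invariant, and identity on clean input", {
  set.seed(23)
  seqs <- c(vapply(rep(90, 15), rand_dna, character(1), gc = 0.1),
            paste0(strrep("N", 9), strrep("A", 81)),
            paste0(substr(adapter, 1, 15), strrep("A", 75)))
  reads <- make_reads(seqs)
  reads$quals[[3]] <- rep(0L, 90)  # one low-quality read
  res <- filter_fastq(reads, th)
  expect_equal(res$report$n_kept + res$report$n_removed_adapter +
                 res$report$n_removed_n + res$report$n_removed_quality,
               res$report$n_input)

  # idempotence
  res2 <- filter_fastq(res$kept, th)
  expect_equal(res2$report$n_kept, res2$report$n_input)
  expect_equal(res2$kept, res$kept)

  # permutation invariance of the kept set
  perm <- sample(nrow(reads))
  res3 <- filter_fastq(reads[perm, ], th)
  expect_setequal(res3$kept$id, res$kept$id)

  # clean input passes through untouched
  clean <- make_reads(vapply(rep(60, 5), rand_dna, character(1), gc = 0.1))
  res4 <- filter_fastq(clean, th)
  expect_equal(res4$kept, clean)
  expect_equal(res4$report$n_kept, 5L)
})
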