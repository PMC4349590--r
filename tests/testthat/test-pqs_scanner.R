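p <- pqs_pattern()

# Random sequence with a few motif strings spliced in, to guarantee hits.
seeded_motif_seq <- function(len = 150) {
  s <- rand_dna(len, gc = 0.45)
  m <- motif_string(sample(c("G4", "IMOTIF"), 1),
                    sample(3:5, 4, replace = TRUE),
                    sample(1:7, 3, replace = TRUE))
  at <- sample(len - nchar(m), 1)
  substr(s, at, at + nchar(m) - 1) <- m
  s
}

test_that("the minimal pattern instance yields one fully decomposed hit", {
  h <- find_g4("GGGAGGGAGGGAGGG", p)
  expect_equal(nrow(h), 1L)
  expect_equal(h$start, 0L)
  expect_equal(h$end, 15L)
  expect_equal(h$tract_lengths[[1]], c(3L, 3L, 3L, 3L))
  expect_equal(h$loop_lengths[[1]], c(1L, 1L, 1L))
  expect_equal(h$matched_seq, "GGGAGGGAGGGAGGG")
})

test_that("a loop longer than 7 nt breaks the pattern; loops may contain G and N", {
  expect_equal(nrow(find_g4("GGGAAAAAAAAGGGAGGGAGGG", p)), 0L)
  expect_equal(nrow(find_g4("GGGNGGGNGGGNGGG", p)), 1L)
  # 5 G-tracts: the default scan returns one maximal hit with G-bearing loops
  h <- find_g4("GGGAGGGAGGGAGGGAGGG", p)
  expect_equal(nrow(h), 1L)
  expect_equal(h$end - h$start, 19L)
})

test_that("default-mode matches are non-overlapping and left-to-right", {
  two <- paste0("GGGAGGGAGGGAGGG", strrep("T", 10), "GGGTGGGTGGGTGGG")
  h <- find_g4(two, p)
  expect_equal(nrow(h), 2L)
  expect_equal(h$start, c(0L, 25L))
  expect_true(all(h$start[-1] >= h$end[-nrow(h)]))
})

test_that("exhaustive mode equals the anchored-regex substring oracle", {
  set.seed(61)
  for (i in 1:60) {
    s <- seeded_motif_seq()
    got <- find_g4(s, p, mode = "exhaustive")
    want <- oracle_pqs_intervals(s, "G")
    expect_equal(interval_key(got), interval_key(want))
  }
})

test_that("every returned matched_seq re-validates under the anchored pattern", {
  set.seed(71)
  rx <- "^G{3,}(?:.{1,7}G{3,}){3,}$"
  for (i in 1:25) {
    s <- seeded_motif_seq()
    for (mode in c("default", "exhaustive")) {
      h <- find_g4(s, p, mode)
      if (nrow(h)) {
        expect_true(all(grepl(rx, h$matched_seq, perl = TRUE)))
        expect_equal(h$end - h$start, nchar(h$matched_seq))
        expect_equal(
          mapply(function(t, l) sum(t) + sum(l), h$tract_lengths, h$loop_lengths),
          nchar(h$matched_seq))
        expect_true(all(h$n_tracts >= 4))
      }
    }
  }
})

test_that("default-mode hit intervals are a subset of exhaustive-mode hits", {
  set.seed(83)
  for (i in 1:40) {
    s <- seeded_motif_seq(200)
    def <- find_g4(s, p, "default")
    exh <- find_g4(s, p, "exhaustive")
    expect_true(all(interval_key(def) %in% interval_key(exh)))
  }
})

test_that("i-motif detection equals the C-base brute force and strand duality holds", {
  h <- find_imotif("CCCACCCACCCACCC", p)
  expect_equal(nrow(h), 1L)
  expect_equal(h$start, 0L)
  expect_equal(h$end, 15L)
  expect_equal(h$motif, "IMOTIF")
  expect_equal(nrow(find_imotif("GGGAGGGAGGGAGGG", p)), 0L)

  set.seed(97)
  for (i in 1:30) {
    s <- seeded_motif_seq()
    # independent route: enumerate C-tract motifs directly on the forward strand
    want <- oracle_pqs_intervals(s, "C")
    got <- find_imotif(s, p, "exhaustive")
    expect_equal(interval_key(got), interval_key(want))
    # duality: mapped G4 intervals of the reverse complement
    L <- nchar(s)
    g4rc <- find_g4(reverse_complement(s), p, "exhaustive")
    mapped <- data.frame(start = L - g4rc$end, end = L - g4rc$start)
    mapped <- mapped[order(mapped$start, mapped$end), ]
    expect_equal(interval_key(got), interval_key(mapped))
  }
})

test_that("unigene counting collapses hit multiplicity per class", {
  hits <- tibble::tibble(
    transcript_id = c("t1", "t1", "t1", "t2", "t2"),
    motif = c("G4", "G4", "IMOTIF", "G4", "G4")
  )
  expect_equal(count_pqs_unigenes(hits), 2L)
  expect_equal(count_pqs_unigenes(hits, "G4"), 2L)
  expect_equal(count_pqs_unigenes(hits, "IMOTIF"), 1L)
  expect_equal(count_pqs_unigenes(hits[0, ]), 0L)
})

test_that("scan_transcripts attaches transcript ids and honors the motif filter", {
  tx <- tibble::tibble(
    id = c("a", "b", "c"),
    seq = c("GGGAGGGAGGGAGGG", "CCCACCCACCCACCC", strrep("AT", 30)),
    length = c(15L, 15L, 60L)
  )
  hits <- scan_transcripts(tx, p)
  expect_equal(sort(unique(hits$transcript_id)), c("a", "b"))
  expect_equal(nrow(scan_transcripts(tx, p, motif = "g4")), 1L)
  expect_equal(nrow(scan_transcripts(tx[3, ], p)), 0L)
})
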