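acgt_pwm <- function() {
  counts <- matrix(1, 4, 4, dimnames = list(c("A", "C", "G", "T"), NULL))
  counts["A", 1] <- 97
  counts["C", 2] <- 97
  counts["G", 3] <- 97
  counts["T", 4] <- 97
  pwm_from_counts(counts, pseudocount = 0)
}

test_that("JASPAR parsing produces the expected log-odds matrix", {
  path <- system.file("extdata", "oct4_sox2_synthetic.jaspar",
                      package = "ptmpipe")
  pw <- read_jaspar(path)
  expect_equal(pw$width, 15)
  expect_equal(pwm_consensus(pw), "CATTGTTATGCAAAT")
  # column probabilities derive from counts + pseudocount over background
  expect_equal(unname(pw$weights["C", 1]),
               log2(((82 + 0.25) / (100 + 1)) / 0.25), tolerance = 1e-12)
})

test_that("pwm_scan finds a planted site with the hand-summed score", {
  pw <- acgt_pwm()
  hits <- pwm_scan("AAACGTAA", pw, score_threshold = 4)
  fwd <- hits[hits$strand == "+", ]
  expect_equal(fwd$offset, 2)
  expect_equal(fwd$score, sum(diag(pw$weights[c("A", "C", "G", "T"), ])),
               tolerance = 1e-12)
})

test_that("reverse-strand hits are scored on the reverse complement", {
  pw <- acgt_pwm()
  # revcomp(ACGT) == ACGT, so use an asymmetric motif: consensus ACGG
  counts <- matrix(1, 4, 4, dimnames = list(c("A", "C", "G", "T"), NULL))
  counts["A", 1] <- 97; counts["C", 2] <- 97
  counts["G", 3] <- 97; counts["G", 4] <- 97
  pw2 <- pwm_from_counts(counts, pseudocount = 0)
  # CCGT is the reverse complement of ACGG
  hits <- pwm_scan("TTCCGTTT", pw2, threshold_frac = 0.9)
  expect_equal(hits$strand, "-")
  expect_equal(hits$offset, 2)
  expect_equal(hits$score, pwm_max_score(pw2), tolerance = 1e-12)
})

test_that("forward hits on a sequence mirror reverse hits on its complement", {
  pw <- read_jaspar(system.file("extdata", "oct4_sox2_synthetic.jaspar",
                                package = "ptmpipe"))
  withr::with_seed(23, {
    seq <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  })
  seq <- paste0(substr(seq, 1, 120), pwm_consensus(pw), substr(seq, 136, 300))
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  f <- pwm_scan(seq, pw, threshold_frac = 0.7)
  r <- pwm_scan(rc, pw, threshold_frac = 0.7)
  flip <- function(h, len, w) sort((len - w) - h$offset)
  expect_equal(sort(r$offset),
               flip(f, nchar(seq), pw$width))
  expect_equal(sort(f$score), sort(r$score), tolerance = 1e-12)
})

test_that("pwm_scan respects thresholds, N windows and short sequences", {
  pw <- acgt_pwm()
  expect_equal(nrow(pwm_scan("AAACGTAA", pw,
                             score_threshold = pwm_max_score(pw) + 1)), 0)
  expect_equal(nrow(pwm_scan("ACN", pw, score_threshold = -100)), 0)
  # windows containing N are skipped, flanking windows still scored
  hits <- pwm_scan("ACGTNACGT", pw, threshold_frac = 0.99)
  expect_equal(hits$offset[hits$strand == "+"], c(0, 5))
})

test_that("motif_fraction is exact on constructed peak sets", {
  pw <- read_jaspar(system.file("extdata", "oct4_sox2_synthetic.jaspar",
                                package = "ptmpipe"))
  sim <- gen_chip(genome_length = 20000, n_chroms = 1, n_true_regions = 10,
                  motif = pw, motif_fraction_true = 0.5,
                  n_chip_tags = 1000, n_input_tags = 1000, seed = 77)
  mf <- motif_fraction(sim$truth, sim$genome, pw)
  expect_equal(attr(mf, "fraction"), 0.5)
  expect_identical(mf$has_motif, sim$truth$has_motif)
  expect_equal(glance(mf)$fraction, 0.5)
  expect_error(motif_fraction(sim$truth[0, ], sim$genome, pw), "Empty")
})
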