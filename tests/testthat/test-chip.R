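toy_sizes <- tibble::tibble(chrom = "chr1", size = 400L)

test_that("dedupe_and_subsample collapses duplicates and is seed-reproducible", {
  tags <- tibble::tibble(
    chrom = "chr1",
    pos = c(10L, 10L, 20L, 30L, 30L),
    strand = c("+", "+", "-", "+", "+")
  )
  all3 <- dedupe_and_subsample(tags, 3)
  expect_equal(nrow(all3), 3)
  expect_equal(nrow(dplyr::distinct(all3)), 3)
  a <- dedupe_and_subsample(tags, 2, seed = 9)
  b <- dedupe_and_subsample(tags, 2, seed = 9)
  expect_identical(a, b)
  expect_error(dedupe_and_subsample(tags, 4), "only 3 unique")
})

test_that("tag_density counts tags within the dilated bin window", {
  one <- tibble::tibble(chrom = "chr1", pos = 100L, strand = "+")
  tr <- tag_density(one, toy_sizes, bin_size = 20, flank = 75,
                    normalize_to = 1)
  # bin [80,100) has window [5,175): contains position 100
  expect_equal(tr$value[tr$start == 80], 1)
  # bin [0,20) has window [-75,95): misses a tag at 200
  far <- tibble::tibble(chrom = "chr1", pos = 200L, strand = "+")
  tr2 <- tag_density(far, toy_sizes, bin_size = 20, flank = 75,
                     normalize_to = 1)
  expect_equal(tr2$value[tr2$start == 0], 0)
})

test_that("uniform tags give window-length counts away from edges", {
  uni <- tibble::tibble(chrom = "chr1", pos = 0:399, strand = "+")
  tr <- tag_density(uni, toy_sizes, bin_size = 20, flank = 75,
                    normalize_to = 400) # normalize_to = total: raw counts
  interior <- tr$value[tr$start >= 80 & tr$start < 300]
  expect_true(all(interior == 20 + 2 * 75))
})

test_that("track length and normalization contracts hold", {
  withr::with_seed(4, {
    tags <- tibble::tibble(chrom = "chr1",
                           pos = sample.int(400, 200, replace = TRUE) - 1L,
                           strand = "+")
  })
  tr <- tag_density(tags, toy_sizes, bin_size = 30)
  expect_equal(nrow(tr), ceiling(400 / 30))
  # doubling normalize_to doubles every value
  tr2 <- tag_density(tags, toy_sizes, bin_size = 30, normalize_to = 2e7)
  expect_equal(tr2$value, 2 * tr$value)
  expect_error(
    tag_density(tibble::tibble(chrom = "chr1", pos = 500L, strand = "+"),
                toy_sizes),
    "0 <= pos"
  )
})

test_that("subtract_input is exact self-annihilation and preserves sign", {
  withr::with_seed(8, {
    tags <- tibble::tibble(chrom = "chr1",
                           pos = sample.int(400, 300, replace = TRUE) - 1L,
                           strand = sample(c("+", "-"), 300, TRUE))
  })
  x <- tag_density(tags, toy_sizes)
  expect_true(all(subtract_input(x, x)$value == 0))
  zero <- x
  zero$value <- 0
  expect_equal(subtract_input(x, zero)$value, x$value)
  # input exceeding chip leaves negative values in place
  big <- x
  big$value <- x$value + 5
  expect_true(all(subtract_input(x, big)$value == -5))
  other <- tag_density(tags, toy_sizes, bin_size = 40)
  expect_error(subtract_input(x, other), "mismatched")
})

test_that("call_peaks thresholds, merges across small gaps, drops short runs", {
  mk_track <- function(values) {
    structure(
      tibble::tibble(chrom = "chr1",
                     start = seq(0, by = 20, length.out = length(values)),
                     end = seq(20, by = 20, length.out = length(values)),
                     value = values),
      bin_size = 20, flank = 75, normalize_to = 1e7,
      class = c("signal_track", class(tibble::tibble()))
    )
  }
  single <- call_peaks(mk_track(c(0, 0, rep(10, 5), 0, 0)), threshold = 5)
  expect_equal(nrow(single), 1)
  expect_equal(single$end - single$start, 100)

  # two runs separated by one sub-threshold bin merge at merge_gap 40
  gap <- call_peaks(mk_track(c(10, 10, 0, 10, 10)), threshold = 5,
                    merge_gap = 40, min_width = 20)
  expect_equal(nrow(gap), 1)
  expect_equal(c(gap$start, gap$end), c(0, 100))
  # but stay separate when the gap rule is stricter
  sep <- call_peaks(mk_track(c(10, 10, 0, 10, 10)), threshold = 5,
                    merge_gap = 20, min_width = 20)
  expect_equal(nrow(sep), 2)

  expect_equal(nrow(call_peaks(mk_track(rep(1, 10)), threshold = 5)), 0)
})

test_that("peak_overlap handles half-open boundaries and partitions exhaustively", {
  a <- tibble::tibble(chrom = "chr1", start = 0, end = 100)
  b <- tibble::tibble(chrom = "chr1", start = 50, end = 150)
  ov <- peak_overlap(a, b)
  expect_equal(nrow(ov$shared_a), 1)
  # half-open: [0,100) and [100,200) do not overlap
  c <- tibble::tibble(chrom = "chr1", start = 100, end = 200)
  ov2 <- peak_overlap(a, c)
  expect_equal(nrow(ov2$shared_a), 0)
  expect_equal(nrow(ov2$specific_a), 1)
})

test_that("peak_overlap agrees with the all-pairs brute-force oracle", {
  withr::with_seed(17, {
    for (k in 1:10) {
      a <- random_peaks(sample(1:50, 1))
      b <- random_peaks(sample(1:50, 1))
      ov <- peak_overlap(a, b)
      oracle <- overlap_oracle(a, b)
      expect_equal(nrow(ov$shared_a), length(oracle$shared_a))
      expect_equal(nrow(ov$shared_b), length(oracle$shared_b))
      expect_equal(nrow(ov$shared_a) + nrow(ov$specific_a), nrow(a))
      expect_equal(dplyr::bind_rows(ov$shared_a, ov$specific_a) |>
                     dplyr::arrange(chrom, start, end),
                   dplyr::arrange(a, chrom, start, end))
    }
  })
})
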