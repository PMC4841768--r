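test_that("generators are bit-reproducible for a fixed seed", {
  panel <- sox2_tad_isoforms("wildtype")
  a <- gen_ms1_run(panel$isoforms, panel$fractions, noise_cv = 0.01, seed = 5)
  b <- gen_ms1_run(panel$isoforms, panel$fractions, noise_cv = 0.01, seed = 5)
  expect_identical(a, b)
  expect_identical(gen_apms(n_background = 20, seed = 5),
                   gen_apms(n_background = 20, seed = 5))
  expect_identical(gen_chip(genome_length = 5000, n_true_regions = 3,
                            n_chip_tags = 500, n_input_tags = 500, seed = 5),
                   gen_chip(genome_length = 5000, n_true_regions = 3,
                            n_chip_tags = 500, n_input_tags = 500, seed = 5))
  expect_identical(gen_expression(n_genes = 50, n_up = 5, n_down = 5, seed = 5),
                   gen_expression(n_genes = 50, n_up = 5, n_down = 5, seed = 5))
})

test_that("gen_ms1_run truth matches requested composition", {
  panel <- sox2_tad_isoforms("S248A")
  sim <- gen_ms1_run(panel$isoforms, panel$fractions, total_area = 5e7,
                     seed = 2)
  expect_equal(sim$truth$fraction, unname(panel$fractions))
  expect_equal(sum(sim$truth$area), 5e7)
  expect_error(
    gen_ms1_run(panel$isoforms, c(0.5, 0.4, 0.2), seed = 1),
    "sum to 1"
  )
})

test_that("gen_apms honors missingness and validates rates", {
  full <- gen_apms(n_background = 30, missing_rate = 0, seed = 3)
  expect_false(any(is.na(full$intensities$intensity)))
  some <- gen_apms(n_background = 200, missing_rate = 0.2, seed = 3)
  miss <- mean(is.na(some$intensities$intensity))
  expect_gt(miss, 0.15)
  expect_lt(miss, 0.25)
  expect_error(gen_apms(missing_rate = 1.2), "missing_rate")
  expect_error(
    gen_apms(specific_interactors = tibble::tibble(
      protein = "X", fold = -1, differential_fold = 1
    )),
    "positive"
  )
})

test_that("gen_chip places regions in bounds and embeds the exact motif count", {
  pw <- read_jaspar(system.file("extdata", "oct4_sox2_synthetic.jaspar",
                                package = "ptmpipe"))
  sim <- gen_chip(genome_length = 30000, n_chroms = 2, n_true_regions = 12,
                  motif = pw, motif_fraction_true = 0.25,
                  n_chip_tags = 2000, n_input_tags = 2000, seed = 6)
  expect_true(all(sim$truth$start >= 0))
  expect_true(all(sim$truth$end <= 30000))
  expect_equal(sum(sim$truth$has_motif), 3) # 0.25 * 12 exactly
  for (r in which(sim$truth$has_motif)) {
    seqs <- substr(sim$genome[[sim$truth$chrom[r]]],
                   sim$truth$start[r] + 1, sim$truth$end[r])
    expect_true(grepl(pwm_consensus(pw), seqs, fixed = TRUE))
  }
  expect_error(gen_chip(genome_length = 100, region_width = 200),
               "exceed")
})

test_that("null ChIP (no enrichment) yields essentially no called peaks", {
  sim <- gen_chip(genome_length = 50000, n_chroms = 1, n_true_regions = 5,
                  enrichment_fold = 1, n_chip_tags = 10000,
                  n_input_tags = 10000, seed = 14)
  chip <- tag_density(sim$chip, sim$sizes, normalize_to = 1e6)
  input <- tag_density(sim$input, sim$sizes, normalize_to = 1e6)
  net <- subtract_input(chip, input)
  pk <- call_peaks(net)
  # at the default threshold essentially nothing is called: any stray peaks
  # cover a vanishing share of the genome
  expect_lt(sum(pk$end - pk$start), 0.02 * 50000)
})

test_that("noiseless expression simulation is recovered exactly", {
  sim <- gen_expression(n_genes = 120, n_up = 15, n_down = 10, fold = 2,
                        log2_noise_sd = 0, seed = 8)
  res <- de_filter(sim$matrix)
  expect_equal(sum(res$class == "up"), 15)
  expect_equal(sum(res$class == "down"), 10)
  called_up <- res$gene[res$class == "up"]
  expect_setequal(called_up, sim$truth$gene[sim$truth$class_truth == "up"])
})
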