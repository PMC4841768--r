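test_that("rollup excludes bait-region and homologous peptides", {
  peps <- tibble::tibble(
    protein = c("SOX2", "SOX2", "SOX2", "OTHER", "OTHER"),
    peptide = c("tad_pep", "p2", "p3", "shared", "own"),
    sample = "FLAG_WT_1",
    intensity = c(500, 300, 200, 50, 70),
    homologous = c(FALSE, FALSE, FALSE, TRUE, FALSE),
    pep_start = c(240, 100, 150, 10, 30),
    pep_end = c(260, 110, 160, 20, 40)
  )
  out <- rollup_protein_intensity(peps, bait_protein = "SOX2",
                                  bait_exclusion = c(235, 265))
  expect_equal(out$intensity[out$protein == "SOX2"], 500) # 300 + 200
  expect_equal(out$intensity[out$protein == "OTHER"], 70) # homolog dropped

  # without an exclusion region the bait is a plain sum
  plain <- rollup_protein_intensity(peps)
  expect_equal(plain$intensity[plain$protein == "SOX2"], 1000)

  # a protein whose only peptide is homologous has no row, not a zero
  only_hom <- tibble::tibble(
    protein = "GHOST", peptide = "shared", sample = "s1",
    intensity = 10, homologous = TRUE
  )
  expect_equal(nrow(rollup_protein_intensity(only_hom)), 0)
})

test_that("specificity calls strong enrichment over a flat background", {
  ratios <- c(rep(1, 19), 16)
  toy <- toy_intensity_table(ratios)
  res <- specificity_score(toy$intensities, toy$meta,
                           flag_tags = "FLAG_WT")
  expect_equal(median(res$normalized), 0, tolerance = 1e-9)
  expect_true(res$specific[res$protein == "P20"])
  expect_false(any(res$specific[res$protein != "P20"]))
  # requiring the call in both bait lines behaves the same on this table
  both <- specificity_score(toy$intensities, toy$meta)
  expect_equal(specific_interactors(both), "P20")
})

test_that("degenerate ratio tables warn and make no specific calls", {
  toy <- toy_intensity_table(rep(2, 5))
  expect_warning(
    res <- specificity_score(toy$intensities, toy$meta, flag_tags = "FLAG_WT"),
    "identical"
  )
  expect_false(any(res$specific))
})

test_that("interactome scores are invariant to global intensity rescaling", {
  sim <- gen_apms(
    n_background = 50,
    specific_interactors = tibble::tibble(protein = "PARP1", fold = 16,
                                          differential_fold = 4),
    seed = 31
  )
  scaled <- dplyr::mutate(sim$intensities, intensity = intensity * 7.3)
  a <- specificity_score(sim$intensities, sim$meta)
  b <- specificity_score(scaled, sim$meta)
  expect_equal(a$ratio, b$ratio, tolerance = 1e-12)
  expect_equal(a$z, b$z, tolerance = 1e-12)
  expect_identical(a$specific, b$specific)
  da <- differential_score(sim$intensities, sim$meta)
  db <- differential_score(scaled, sim$meta)
  expect_equal(da$z, db$z, tolerance = 1e-12)
  expect_identical(da$class, db$class)
})

test_that("differential scoring: no effect gives shared, 4-fold gives raw log2 of 2", {
  toy <- toy_intensity_table(rep(1, 6))
  # a table with zero spread in the ratio of ratios is degenerate by design
  expect_warning(df <- differential_score(toy$intensities, toy$meta),
                 "Zero variance")
  expect_true(all(df$ratio == 0))
  expect_true(all(df$class == "shared"))

  # one protein 4-fold higher in the mutant co-IP
  tab <- toy_intensity_table(rep(1, 6))
  tab$intensities <- dplyr::mutate(
    tab$intensities,
    intensity = ifelse(protein == "P01" & grepl("FLAG_S248A", sample),
                       intensity * 4, intensity)
  )
  df2 <- differential_score(tab$intensities, tab$meta)
  expect_equal(df2$ratio[df2$protein == "P01"], 2)
})

test_that("row order never changes scores or calls", {
  sim <- gen_apms(n_background = 40, seed = 13)
  shuffled <- dplyr::slice_sample(sim$intensities,
                                  n = nrow(sim$intensities))
  a <- dplyr::arrange(specificity_score(sim$intensities, sim$meta), protein, tag)
  b <- dplyr::arrange(specificity_score(shuffled, sim$meta), protein, tag)
  expect_equal(a$z, b$z)
  expect_identical(a$specific, b$specific)
  da <- dplyr::arrange(differential_score(sim$intensities, sim$meta), protein)
  db <- dplyr::arrange(differential_score(shuffled, sim$meta), protein)
  expect_equal(da$z, db$z)
  expect_identical(da$class, db$class)
})

test_that("targeted top-2 picks the two most intense non-homologous peptides", {
  meta <- tibble::tibble(
    sample = c("FLAG_WT_1", "FLAG_S248A_1", "FLAG_WT_2", "FLAG_S248A_2",
               "FLAG_WT_3", "FLAG_S248A_3"),
    tag = rep(c("FLAG_WT", "FLAG_S248A"), 3),
    replicate = rep(1:3, each = 2)
  )
  # per-replicate enrichments 0.8, 1.0, 3.0 -> median 1.0
  enr <- c(0.8, 1.0, 3.0)
  rows <- purrr::pmap(list(rep = 1:3), function(rep) {
    tibble::tibble(
      protein = "MBD3",
      peptide = c("hom_top", "pepA", "pepB", "pepC"),
      sample = paste0("FLAG_WT_", rep),
      intensity = c(1e6, 100, 80, 10),
      homologous = c(TRUE, FALSE, FALSE, FALSE)
    )
  })
  wt <- purrr::list_rbind(rows)
  mut <- wt
  mut$sample <- sub("FLAG_WT", "FLAG_S248A", wt$sample)
  mut$intensity <- wt$intensity *
    2^enr[as.integer(sub(".*_", "", wt$sample))]
  res <- targeted_top2(dplyr::bind_rows(wt, mut), meta)
  expect_equal(res$peptides, "pepA;pepB") # homologous top peptide skipped
  expect_equal(res$median_enrichment, 1.0, tolerance = 1e-9)
  expect_equal(res$n_replicates, 3)

  # fewer than two eligible peptides: skipped with a warning
  lone <- tibble::tibble(protein = "X", peptide = "only",
                         sample = "FLAG_WT_1", intensity = 5,
                         homologous = FALSE)
  expect_warning(out <- targeted_top2(lone, meta), "skipped")
  expect_equal(nrow(out), 0)
})
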