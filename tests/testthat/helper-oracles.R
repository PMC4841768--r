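# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Textbook one-sample t on paired differences: t = mean(d) / (sd(d)/sqrt(n)),
# two-sided p from the t distribution with n - 1 df.
paired_t_oracle <- function(x, y) {
  d <- log2(y) - log2(x)
  n <- length(d)
  t_stat <- mean(d) / (sd(d) / sqrt(n))
  list(t = t_stat, p = 2 * pt(-abs(t_stat), df = n - 1))
}

# All-pairs brute-force overlap partition of half-open interval sets.
overlap_oracle <- function(a, b) {
  hit_a <- vapply(seq_len(nrow(a)), function(i) {
    any(a$chrom[i] == b$chrom & a$start[i] < b$end & b$start < a$end[i])
  }, logical(1))
  hit_b <- vapply(seq_len(nrow(b)), function(j) {
    any(b$chrom[j] == a$chrom & b$start[j] < a$end & a$start < b$end[j])
  }, logical(1))
  list(shared_a = which(hit_a), shared_b = which(hit_b))
}

random_peaks <- function(n, chroms = c("chr1", "chr2"), span = 10000) {
  starts <- sample.int(span - 200, n, replace = TRUE)
  tibble::tibble(
    chrom = sample(chroms, n, replace = TRUE),
    start = starts,
    end = starts + sample.int(150, n, replace = TRUE)
  ) |> dplyr::arrange(chrom, start)
}

# Minimal long intensity table: one protein per row of `ratios`, FLAG
# intensity = ratio * HA intensity, identical across replicates.
toy_intensity_table <- function(ratios, n_replicates = 2, ha = 1000) {
  proteins <- sprintf("P%02d", seq_along(ratios))
  meta <- tidyr::expand_grid(
    tag = c("FLAG_WT", "FLAG_S248A", "HA_control"),
    replicate = seq_len(n_replicates)
  )
  meta$sample <- paste0(meta$tag, "_", meta$replicate)
  grid <- tidyr::expand_grid(protein = proteins, sample = meta$sample)
  grid <- dplyr::left_join(grid, meta, by = "sample")
  grid$intensity <- ifelse(grid$tag == "HA_control", ha,
                           ha * ratios[match(grid$protein, proteins)])
  list(intensities = grid[, c("protein", "sample", "intensity")],
       meta = meta[, c("sample", "tag", "replicate")])
}
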