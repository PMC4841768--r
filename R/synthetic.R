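#' Default TAD-peptide isoform panels
#'
#' Isoform definitions and study-condition compositions for the SOX2
#' transactivation-domain (TAD) tryptic peptide, the quantified unit of the
#' stoichiometry pipeline. The sequence is a placeholder tryptic peptide
#' (`GAQPVSMALGSTGVNTAR`) carrying Ser/Ser/Thr at the relative offsets of
#' S248, S253 and T258; site indices are zero-based. The wild-type panel
#' has four populations: unmodified (33.2% of total signal), singly
#' O-GlcNAcylated at S248 (44.1%), phosphorylated at S253 (10.9%) and
#' doubly modified GlcNAc-S248 + phospho-S253 (11.8%). The S248A panel
#' (alanine at the S248 position, no GlcNAc-S248 form) has phospho-S253 at
#' 18.7% of total; its unmodified (66.0%) and GlcNAc-T258 (15.3%) shares
#' are illustrative defaults.
#'
#' @param variant `"wildtype"` or `"S248A"`.
#' @return List with `isoforms` (definition tibble for
#'   [quantify_isoforms()]) and `fractions` (named, summing to 1).
#' @export
sox2_tad_isoforms <- function(variant = c("wildtype", "S248A")) {
  variant <- match.arg(variant)
  if (variant == "wildtype") {
    seq <- "GAQPVSMALGSTGVNTAR"
    defs <- tibble(
      label = c("unmodified", "GlcNAc-S248", "phospho-S253",
                "GlcNAc-S248+phospho-S253"),
      sequence = seq,
      mods = c("", "5:HexNAc", "10:Phospho", "5:HexNAc;10:Phospho"),
      charges = "2;3",
      rt_start = c(29, 25, 27, 23),
      rt_end = c(31, 27, 29, 25)
    )
    fractions <- c(`unmodified` = 0.332, `GlcNAc-S248` = 0.441,
                   `phospho-S253` = 0.109,
                   `GlcNAc-S248+phospho-S253` = 0.118)
  } else {
    seq <- "GAQPVAMALGSTGVNTAR"
    defs <- tibble(
      label = c("unmodified", "GlcNAc-T258", "phospho-S253"),
      sequence = seq,
      mods = c("", "15:HexNAc", "10:Phospho"),
      charges = "2;3",
      rt_start = c(29, 25, 27),
      rt_end = c(31, 27, 29)
    )
    fractions <- c(`unmodified` = 0.660, `GlcNAc-T258` = 0.153,
                   `phospho-S253` = 0.187)
  }
  list(isoforms = defs, fractions = fractions)
}

#' Simulate an MS1 run with known isoform stoichiometry
#'
#' Builds a centroided MS1 run in which each PTM isoform elutes as a
#' Gaussian-shaped chromatographic peak at its theoretical m/z (one
#' centroid per listed charge state per scan), with integrated area equal
#' to `fraction x total_area` split equally across charge states.
#' Multiplicative log-normal intensity noise with coefficient of variation
#' `noise_cv` is applied per centroid, and uniform background centroids are
#' added away from all targets. Real elution peaks tail; Gaussians suffice
#' here because the integrator is shape-agnostic.
#'
#' @param isoforms Isoform definition tibble (see [sox2_tad_isoforms()]);
#'   each isoform's rt window should cover its elution peak.
#' @param fractions Ground-truth fractions, one per isoform (named by label
#'   or in definition order); must be non-negative and sum to 1.
#' @param peak_rt_centers Elution apex per isoform in minutes (default: the
#'   midpoint of each rt window). Isobaric isoforms need distinct windows.
#' @param peak_width Gaussian SD of the elution profile in minutes
#'   (default 0.2).
#' @param total_area Total integrated signal across isoforms (default 1e8).
#' @param noise_cv Coefficient of variation of multiplicative intensity
#'   noise (default 0).
#' @param scan_interval Scan spacing in minutes (default 0.02).
#' @param n_background Background centroids per scan (default 5).
#' @param seed Integer seed, or `NULL`.
#' @return List with `run` (an [ms1_run()]) and `truth` (tibble `label`,
#'   `fraction`, `rt_center`, `area`).
#' @export
gen_ms1_run <- function(isoforms, fractions, peak_rt_centers = NULL,
                        peak_width = 0.2, total_area = 1e8, noise_cv = 0,
                        scan_interval = 0.02, n_background = 5,
                        seed = NULL) {
  isoforms <- as_tibble(isoforms)
  if (!is.null(names(fractions))) {
    stopifnot(setequal(names(fractions), isoforms$label))
    fractions <- fractions[isoforms$label]
  }
  stopifnot(length(fractions) == nrow(isoforms))
  if (any(fractions < 0) || abs(sum(fractions) - 1) > 1e-9) {
    abort("`fractions` must be non-negative and sum to 1.")
  }
  centers <- peak_rt_centers %||% ((isoforms$rt_start + isoforms$rt_end) / 2)
  if (!is.null(names(centers))) centers <- centers[isoforms$label]

  targets <- isoform_targets(isoforms)
  # isobaric isoforms must elute apart, as in the real chromatography
  for (i in seq_len(nrow(isoforms))) {
    for (j in seq_len(nrow(isoforms))) {
      if (i >= j) next
      mz_i <- targets$mz[targets$label == isoforms$label[i]]
      mz_j <- targets$mz[targets$label == isoforms$label[j]]
      isobaric <- any(outer(mz_i, mz_j, function(x, y) abs(x - y) < 1e-4))
      if (isobaric && abs(centers[i] - centers[j]) < 4 * peak_width) {
        abort(paste0("Isobaric isoforms with overlapping elution: ",
                     isoforms$label[i], " and ", isoforms$label[j]))
      }
    }
  }

  build <- function() {
    grid <- seq(min(isoforms$rt_start), max(isoforms$rt_end),
                by = scan_interval)
    sdlog <- if (noise_cv > 0) sqrt(log(1 + noise_cv^2)) else 0
    rows <- map(seq_len(nrow(isoforms)), function(i) {
      tg <- filter(targets, .data$label == isoforms$label[i])
      area_z <- fractions[i] * total_area / nrow(tg)
      list_rbind(map(seq_len(nrow(tg)), function(k) {
        mu <- area_z * dnorm(grid, centers[i], peak_width)
        noise <- if (sdlog > 0) exp(rnorm(length(grid), 0, sdlog)) else 1
        tibble(rt = grid, mz = tg$mz[k], intensity = mu * noise)
      }))
    })
    signal <- list_rbind(rows)
    signal <- filter(signal, .data$intensity > 0)
    bg <- if (n_background > 0) {
      n_bg <- n_background * length(grid)
      mz_bg <- runif(n_bg, 400, 1600)
      # keep background off every target m/z
      for (t_mz in unique(targets$mz)) {
        near <- abs(mz_bg - t_mz) < t_mz * 50e-6
        while (any(near)) {
          mz_bg[near] <- runif(sum(near), 400, 1600)
          near <- abs(mz_bg - t_mz) < t_mz * 50e-6
        }
      }
      tibble(
        rt = rep(grid, each = n_background),
        mz = mz_bg,
        intensity = rexp(n_bg, rate = 1) * total_area * 1e-6
      )
    } else {
      NULL
    }
    ms1_run(bind_rows(signal, bg), scan_times = grid)
  }
  run <- if (is.null(seed)) build() else withr::with_seed(seed, build())
  list(
    run = run,
    truth = tibble(label = isoforms$label, fraction = unname(fractions),
                   rt_center = unname(centers),
                   area = unname(fractions) * total_area)
  )
}

#' Simulate an AP-MS co-IP experiment
#'
#' Generates protein- and peptide-level LFQ tables for a FLAG wild-type
#' bait line, a FLAG mutant bait line and an HA-tagged control line, with
#' `n_replicates` replicates each. Background proteins have FLAG/HA ratio
#' centered at 1; spiked interactors are enriched `fold`-times over HA in
#' both FLAG lines and additionally scaled by `differential_fold` in the
#' mutant line. Intensities are log-normal (base abundance) with
#' multiplicative log2-normal replicate noise; values are dropped missing
#' at `missing_rate`. Each protein carries three peptides splitting its
#' intensity; one peptide pair shared between the first two background
#' proteins is flagged homologous.
#'
#' @param n_background Number of background (non-interacting) proteins.
#' @param specific_interactors Tibble with columns `protein`, `fold`,
#'   `differential_fold`, or `NULL` for a pure-background (null) table.
#' @param log2_noise_sd SD of per-sample log2 noise (default 0.5).
#' @param n_replicates Replicates per line (default 2).
#' @param missing_rate Probability a measurement is missing (default 0).
#' @param seed Integer seed, or `NULL`.
#' @return List with `intensities` (long protein table), `peptides` (long
#'   peptide table), `meta` (sample metadata) and `truth`.
#' @export
gen_apms <- function(n_background = 200, specific_interactors = NULL,
                     log2_noise_sd = 0.5, n_replicates = 2,
                     missing_rate = 0, seed = NULL) {
  if (missing_rate < 0 || missing_rate >= 1) {
    abort("`missing_rate` must be in [0, 1).")
  }
  spec <- if (is.null(specific_interactors)) {
    tibble(protein = character(), fold = double(), differential_fold = double())
  } else {
    as_tibble(specific_interactors)
  }
  if (nrow(spec) > 0 && any(spec$fold <= 0 | spec$differential_fold <= 0)) {
    abort("Folds must be positive.")
  }
  truth <- bind_rows(
    tibble(protein = sprintf("BG%04d", seq_len(n_background)),
           fold = 1, differential_fold = 1),
    spec
  ) %>%
    mutate(
      specific_truth = .data$fold > 1,
      class_truth = case_when(
        .data$differential_fold > 1 ~ "S248A_preferring",
        .data$differential_fold < 1 ~ "WT_preferring",
        TRUE ~ "shared"
      )
    )

  meta <- tidyr::expand_grid(
    tag = c("FLAG_WT", "FLAG_S248A", "HA_control"),
    replicate = seq_len(n_replicates)
  ) %>%
    mutate(sample = paste0(.data$tag, "_", .data$replicate)) %>%
    select("sample", "tag", "replicate")

  build <- function() {
    base <- exp(rnorm(nrow(truth), log(1e7), 1))
    grid <- tidyr::expand_grid(
      i = seq_len(nrow(truth)), sample = meta$sample
    ) %>%
      left_join(meta, by = "sample") %>%
      mutate(
        protein = truth$protein[.data$i],
        mu = base[.data$i] * case_when(
          .data$tag == "HA_control" ~ 1,
          .data$tag == "FLAG_WT" ~ truth$fold[.data$i],
          TRUE ~ truth$fold[.data$i] * truth$differential_fold[.data$i]
        ),
        intensity = .data$mu * 2^rnorm(n(), 0, log2_noise_sd)
      )
    if (missing_rate > 0) {
      drop <- runif(nrow(grid)) < missing_rate
      grid$intensity[drop] <- NA_real_
    }
    intensities <- select(grid, "protein", "sample", "intensity")

    # peptide layer: three peptides per protein with fixed per-protein splits
    splits <- map(seq_len(nrow(truth)), function(i) {
      w <- runif(3, 0.5, 1.5)
      w / sum(w)
    })
    peptides <- grid %>%
      mutate(split = splits[.data$i]) %>%
      tidyr::unnest_longer("split", indices_to = "pep_idx") %>%
      mutate(
        peptide = paste0(.data$protein, "_pep", .data$pep_idx),
        intensity = .data$intensity * .data$split,
        homologous = FALSE
      ) %>%
      select("protein", "peptide", "sample", "intensity", "homologous")
    if (n_background >= 2) {
      shared <- grid %>%
        filter(.data$i <= 2) %>%
        mutate(peptide = "SHARED_pep", homologous = TRUE,
               intensity = .data$intensity * 0.1) %>%
        select("protein", "peptide", "sample", "intensity", "homologous")
      peptides <- bind_rows(peptides, shared)
    }
    list(intensities = intensities, peptides = peptides)
  }
  tabs <- if (is.null(seed)) build() else withr::with_seed(seed, build())
  c(tabs, list(meta = meta, truth = truth))
}

#' Simulate a ChIP-seq experiment on a toy genome
#'
#' Draws a random genome, places non-overlapping enriched regions, embeds a
#' motif consensus in a stated fraction of them, and samples single-position
#' ChIP tags from a background-plus-enrichment mixture (enriched regions
#' receive `enrichment_fold` times the background per-bp tag rate) and
#' input tags uniformly. Tags are single-position events; no fragment-size
#' model is applied.
#'
#' @param genome_length Length of each chromosome in bp.
#' @param n_chroms Number of chromosomes.
#' @param n_true_regions Number of enriched regions.
#' @param region_width Width of each enriched region in bp (default 200).
#' @param enrichment_fold Tag-rate fold enrichment inside regions.
#' @param n_chip_tags,n_input_tags Tag counts drawn for ChIP and input.
#' @param motif A `pwm`, a consensus string, or `NULL` for no embedding.
#' @param motif_fraction_true Fraction of regions receiving an embedded
#'   consensus (exact count, default 0.5).
#' @param seed Integer seed, or `NULL`.
#' @return List with `genome` (named character vector), `sizes`, `chip`
#'   and `input` tag tibbles, and `truth` (regions with `has_motif`).
#' @export
gen_chip <- function(genome_length = 1e5, n_chroms = 2, n_true_regions = 20,
                     region_width = 200, enrichment_fold = 20,
                     n_chip_tags = 20000, n_input_tags = 20000,
                     motif = NULL, motif_fraction_true = 0.5, seed = NULL) {
  if (region_width > genome_length) {
    abort("Regions exceed the chromosome bounds.")
  }
  consensus <- if (inherits(motif, "pwm")) pwm_consensus(motif) else motif
  build <- function() {
    chroms <- paste0("chr", seq_len(n_chroms))
    genome <- setNames(map_chr(chroms, function(ch) {
      paste(sample(c("A", "C", "G", "T"), genome_length, replace = TRUE),
            collapse = "")
    }), chroms)
    sizes <- tibble(chrom = chroms, size = as.integer(genome_length))

    # non-overlapping regions via per-chromosome rejection sampling
    regions <- NULL
    per_chrom <- table(sample(chroms, n_true_regions, replace = TRUE))
    for (ch in names(per_chrom)) {
      k <- per_chrom[[ch]]
      repeat {
        starts <- sort(sample.int(genome_length - region_width, k))
        if (k == 1 || all(diff(starts) > region_width)) break
      }
      regions <- bind_rows(regions, tibble(
        chrom = ch, start = starts, end = starts + region_width
      ))
    }
    n_with <- round(motif_fraction_true * nrow(regions))
    with_motif <- sample(seq_len(nrow(regions)), n_with)
    regions$has_motif <- seq_len(nrow(regions)) %in% with_motif
    if (!is.null(consensus)) {
      for (r in which(regions$has_motif)) {
        at <- regions$start[r] + (region_width - nchar(consensus)) %/% 2
        substr(genome[[regions$chrom[r]]], at + 1,
               at + nchar(consensus)) <- consensus
      }
    }

    sample_tags <- function(n, enriched) {
      bg_weight <- n_chroms * genome_length
      extra <- if (enriched) (enrichment_fold - 1) * region_width * nrow(regions) else 0
      in_region <- runif(n) < extra / (bg_weight + extra)
      n_reg <- sum(in_region)
      uni_chrom <- sample(chroms, n - n_reg, replace = TRUE)
      uni_pos <- sample.int(genome_length, n - n_reg, replace = TRUE) - 1L
      reg_idx <- sample.int(nrow(regions), n_reg, replace = TRUE)
      reg_pos <- regions$start[reg_idx] +
        sample.int(region_width, n_reg, replace = TRUE) - 1L
      tibble(
        chrom = c(uni_chrom, regions$chrom[reg_idx]),
        pos = as.integer(c(uni_pos, reg_pos)),
        strand = sample(c("+", "-"), n, replace = TRUE)
      ) %>% arrange(.data$chrom, .data$pos)
    }
    list(
      genome = genome, sizes = sizes,
      chip = sample_tags(n_chip_tags, enriched = TRUE),
      input = sample_tags(n_input_tags, enriched = FALSE),
      truth = regions
    )
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}

#' Write a toy genome to FASTA
#'
#' @param genome Named character vector of chromosome sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path)
  invisible(path)
}

#' Simulate a paired expression experiment
#'
#' Generates a paired two-condition expression matrix with `n_up` genes up-
#' and `n_down` genes down-regulated at the stated fold in the test
#' condition and the remainder null. Each gene has a latent log2 abundance
#' and a shared per-pair effect (the paired structure); independent log2
#' noise of SD `log2_noise_sd` is added to every measurement.
#'
#' @param n_genes Total number of genes.
#' @param n_up,n_down Numbers of truly up-/down-regulated genes.
#' @param fold True fold change of regulated genes (default 2).
#' @param n_pairs Number of replicate pairs (default 3).
#' @param log2_noise_sd Measurement noise SD in log2 units (default 0.25).
#' @param seed Integer seed, or `NULL`.
#' @return List with `matrix` (long tibble for [de_filter()]) and `truth`
#'   (`gene`, `class_truth`, `fold`).
#' @export
gen_expression <- function(n_genes = 2000, n_up = 320, n_down = 344,
                           fold = 2, n_pairs = 3, log2_noise_sd = 0.25,
                           seed = NULL) {
  if (n_up + n_down > n_genes) abort("n_up + n_down must not exceed n_genes.")
  truth <- tibble(
    gene = sprintf("G%05d", seq_len(n_genes)),
    class_truth = c(rep("up", n_up), rep("down", n_down),
                    rep("null", n_genes - n_up - n_down)),
    fold = c(rep(fold, n_up), rep(1 / fold, n_down),
             rep(1, n_genes - n_up - n_down))
  )
  build <- function() {
    base <- rnorm(n_genes, 8, 2)
    pair_eff <- rnorm(n_pairs, 0, 0.5)
    grid <- tidyr::expand_grid(i = seq_len(n_genes), pair = seq_len(n_pairs))
    wt <- 2^(base[grid$i] + pair_eff[grid$pair] +
               rnorm(nrow(grid), 0, log2_noise_sd))
    s2 <- 2^(base[grid$i] + pair_eff[grid$pair] + log2(truth$fold[grid$i]) +
               rnorm(nrow(grid), 0, log2_noise_sd))
    bind_rows(
      tibble(gene = truth$gene[grid$i], condition = "WT",
             pair = grid$pair, value = wt),
      tibble(gene = truth$gene[grid$i], condition = "S248A",
             pair = grid$pair, value = s2)
    )
  }
  mat <- if (is.null(seed)) build() else withr::with_seed(seed, build())
  list(matrix = mat, truth = truth)
}
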