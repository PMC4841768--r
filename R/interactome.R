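#' Read AP-MS tables
#'
#' `read_intensity_tsv()` reads a wide protein-level LFQ table (first column
#' `protein`, one column per sample) into long form. `read_sample_meta_tsv()`
#' reads sample metadata with columns `sample`, `tag` (one of `FLAG_WT`,
#' `FLAG_S248A`, `HA_control`) and `replicate`. `read_peptides_tsv()` reads a
#' long peptide table with columns `protein`, `peptide`, `sample`,
#' `intensity`, `homologous` (logical: peptide shared across proteins) and
#' optionally `pep_start`, `pep_end` (1-based residue coordinates in the
#' parent protein).
#'
#' @param path Path to the TSV file.
#' @return A tibble in the long layout used by the scoring functions.
#' @name apms_io
NULL

#' @rdname apms_io
#' @export
read_intensity_tsv <- function(path) {
  wide <- readr::read_tsv(path, show_col_types = FALSE)
  tidyr::pivot_longer(wide, -"protein", names_to = "sample",
                      values_to = "intensity")
}

#' @rdname apms_io
#' @export
read_sample_meta_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    sample = readr::col_character(),
                    tag = readr::col_character(),
                    replicate = readr::col_integer()
                  ))
}

#' @rdname apms_io
#' @export
read_peptides_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Roll peptide intensities up to protein level
#'
#' Protein intensity is the sum of its non-homologous peptide intensities
#' per sample. Peptides flagged homologous (shared across proteins)
#' contribute to no protein. For the bait protein, peptides overlapping the
#' excluded residue interval (e.g. the modified transactivation-domain
#' peptide, whose signal is split across PTM proteoforms) are removed before
#' summation. Proteins left with no surviving peptide have no row in the
#' output (missing intensity, not zero).
#'
#' @param peptides Long peptide tibble (see [read_peptides_tsv()]).
#' @param bait_protein Identifier of the bait, or `NULL`.
#' @param bait_exclusion Length-2 numeric `(start, end)` residue interval
#'   (1-based, inclusive) excluded from the bait's quantitation, or `NULL`.
#' @return Long tibble `protein`, `sample`, `intensity`.
#' @export
rollup_protein_intensity <- function(peptides, bait_protein = NULL,
                                     bait_exclusion = NULL) {
  peptides <- as_tibble(peptides)
  stopifnot(all(c("protein", "peptide", "sample", "intensity") %in% names(peptides)))
  if (!"homologous" %in% names(peptides)) peptides$homologous <- FALSE
  kept <- filter(peptides, !.data$homologous)
  if (!is.null(bait_exclusion)) {
    if (is.null(bait_protein)) abort("`bait_exclusion` requires `bait_protein`.")
    if (!all(c("pep_start", "pep_end") %in% names(kept))) {
      abort("`bait_exclusion` requires `pep_start`/`pep_end` peptide coordinates.")
    }
    kept <- filter(kept, !(
      .data$protein == bait_protein &
        .data$pep_start <= bait_exclusion[2] &
        .data$pep_end >= bait_exclusion[1]
    ))
  }
  kept %>%
    filter(!is.na(.data$intensity)) %>%
    group_by(.data$protein, .data$sample) %>%
    summarise(intensity = sum(.data$intensity), .groups = "drop")
}

mean_log2_ratio <- function(num, den, method) {
  # num, den: intensity vectors over replicates (NAs already removed)
  if (method == "ratio_of_means") {
    log2(mean(num) / mean(den))
  } else {
    # mean over all replicate pairings of log2(num_i / den_j)
    mean(log2(num)) - mean(log2(den))
  }
}

tag_intensities <- function(intensities, meta) {
  inner_join(as_tibble(intensities), as_tibble(meta), by = "sample") %>%
    filter(!is.na(.data$intensity), .data$intensity > 0)
}

#' Call bait-specific interactors from FLAG/HA enrichment
#'
#' For each protein and each FLAG-tagged bait line, computes the log2 ratio
#' of its LFQ intensity in the FLAG purifications over the HA-tagged
#' control purifications, normalizes ratios by their global median, and
#' calls a protein specific in that line when its normalized ratio exceeds
#' the mean by `sd_threshold` standard deviations (enrichment side only:
#' depleted proteins are not interactors). A protein absent from every HA
#' sample is given a floor intensity equal to the `na_floor_quantile`
#' quantile of observed HA intensities, so bait-specific preys with no
#' control signal remain scoreable; proteins absent from every FLAG sample
#' of a line are not scored in that line.
#'
#' @param intensities Long protein tibble (`protein`, `sample`,
#'   `intensity`); zero or `NA` intensity is treated as missing.
#' @param meta Sample metadata (`sample`, `tag`, `replicate`).
#' @param sd_threshold Number of standard deviations above the mean
#'   required for a specific call (default 2).
#' @param flag_tags FLAG bait tags scored (default both lines); a protein's
#'   overall `specific` call in [specific_interactors()] requires the call
#'   in every listed line.
#' @param ha_tag Control tag (default `"HA_control"`).
#' @param ratio_method `"ratio_of_means"` (default: log2 of the ratio of
#'   replicate-mean intensities) or `"mean_of_ratios"` (mean log2 ratio over
#'   all replicate pairings).
#' @param na_floor_quantile Quantile of observed HA intensities used as the
#'   missing-control floor (default 0.01).
#' @return Tibble of class `specificity_result`, one row per (protein,
#'   flag line): `protein`, `tag`, `ratio`, `normalized`, `z`, `specific`.
#' @export
specificity_score <- function(intensities, meta, sd_threshold = 2,
                              flag_tags = c("FLAG_WT", "FLAG_S248A"),
                              ha_tag = "HA_control",
                              ratio_method = c("ratio_of_means", "mean_of_ratios"),
                              na_floor_quantile = 0.01) {
  ratio_method <- match.arg(ratio_method)
  dat <- tag_intensities(intensities, meta)
  ha <- filter(dat, .data$tag == ha_tag)
  if (nrow(ha) == 0) abort("No control (HA) intensities found.")
  ha_floor <- quantile(ha$intensity, na_floor_quantile, names = FALSE)

  per_tag <- map(flag_tags, function(ft) {
    flag <- filter(dat, .data$tag == ft)
    scored <- flag %>%
      group_by(.data$protein) %>%
      summarise(flag_int = list(.data$intensity), .groups = "drop") %>%
      left_join(
        ha %>% group_by(.data$protein) %>%
          summarise(ha_int = list(.data$intensity), .groups = "drop"),
        by = "protein"
      ) %>%
      mutate(
        ha_int = map(.data$ha_int, function(v) if (is.null(v)) ha_floor else v),
        ratio = map2(.data$flag_int, .data$ha_int, mean_log2_ratio,
                     method = ratio_method) %>% map_dbl(1)
      )
    if (nrow(scored) < 3) abort("Need >= 3 scored proteins.")
    scored <- mutate(scored, tag = ft,
                     normalized = .data$ratio - median(.data$ratio))
    s <- sd(scored$normalized)
    if (s == 0) {
      warn(paste0("All ratios identical in ", ft, ": no specific calls."))
      scored <- mutate(scored, z = NA_real_, specific = FALSE)
    } else {
      scored <- mutate(scored,
                       z = (.data$normalized - mean(.data$normalized)) / s,
                       specific = .data$z >= sd_threshold)
    }
    select(scored, "protein", "tag", "ratio", "normalized", "z", "specific")
  })
  out <- list_rbind(per_tag)
  structure(out, sd_threshold = sd_threshold, flag_tags = flag_tags,
            ratio_method = ratio_method,
            class = c("specificity_result", class(out)))
}

#' Proteins called specific in every scored bait line
#'
#' @param x A `specificity_result`.
#' @return Character vector of protein identifiers.
#' @export
specific_interactors <- function(x) {
  stopifnot(inherits(x, "specificity_result"))
  tags <- attr(x, "flag_tags")
  as_tibble(x) %>%
    group_by(.data$protein) %>%
    summarise(ok = sum(.data$specific) == length(tags), .groups = "drop") %>%
    filter(.data$ok) %>%
    pull("protein")
}

#' Classify differential interactors by ratio-of-ratios z-score
#'
#' For each protein quantified in both FLAG lines, computes the log2 ratio
#' of its mutant-line enrichment over its wild-type-line enrichment; the HA
#' control cancels, so this is log2(S248A intensity) - log2(WT intensity)
#' (averaged over replicates per `ratio_method`). Values are normalized by
#' their global median and converted to z-scores with the sample standard
#' deviation; proteins with z above `z_threshold` prefer the mutant bait,
#' below `-z_threshold` the wild-type bait, and are otherwise shared.
#'
#' @inheritParams specificity_score
#' @param z_threshold z-score magnitude for a differential call
#'   (default 1.5).
#' @param wt_tag,mut_tag Tags of the two compared bait lines.
#' @return Tibble of class `differential_result`: `protein`, `ratio`
#'   (raw log2 ratio of ratios), `normalized`, `z`, `fold_change`
#'   (`2^ratio`), `class` (`WT_preferring`, `S248A_preferring`, `shared`).
#' @export
differential_score <- function(intensities, meta, z_threshold = 1.5,
                               wt_tag = "FLAG_WT", mut_tag = "FLAG_S248A",
                               ratio_method = c("ratio_of_means", "mean_of_ratios")) {
  ratio_method <- match.arg(ratio_method)
  dat <- tag_intensities(intensities, meta)
  by_prot <- dat %>%
    filter(.data$tag %in% c(wt_tag, mut_tag)) %>%
    group_by(.data$protein, .data$tag) %>%
    summarise(ints = list(.data$intensity), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "tag", values_from = "ints") %>%
    filter(!map_lgl(.data[[wt_tag]], is.null),
           !map_lgl(.data[[mut_tag]], is.null))
  if (nrow(by_prot) < 3) abort("Need >= 3 proteins quantified in both lines.")
  scored <- mutate(
    by_prot,
    ratio = map2(.data[[mut_tag]], .data[[wt_tag]], mean_log2_ratio,
                 method = ratio_method) %>% map_dbl(1),
    normalized = .data$ratio - median(.data$ratio)
  )
  s <- sd(scored$normalized)
  if (s == 0) {
    warn("Zero variance of log ratios: all proteins classified shared.")
    scored <- mutate(scored, z = NA_real_, class = "shared")
  } else {
    scored <- mutate(
      scored,
      z = (.data$normalized - mean(.data$normalized)) / s,
      class = case_when(
        .data$z > z_threshold ~ "S248A_preferring",
        .data$z < -z_threshold ~ "WT_preferring",
        TRUE ~ "shared"
      )
    )
  }
  out <- scored %>%
    mutate(fold_change = 2^.data$ratio) %>%
    select("protein", "ratio", "normalized", "z", "fold_change", "class")
  structure(out, z_threshold = z_threshold, ratio_method = ratio_method,
            class = c("differential_result", class(out)))
}

#' Targeted top-2 peptide enrichment
#'
#' For each listed protein, selects its two non-homologous peptides with the
#' highest total intensity across all samples, computes per-replicate
#' enrichment as the log2 ratio of the two peptides' summed intensity in the
#' mutant line over the wild-type line, and reports the median enrichment
#' across replicates. Proteins with fewer than two eligible peptides are
#' skipped with a warning.
#'
#' @param peptides Long peptide tibble (see [read_peptides_tsv()]).
#' @param meta Sample metadata (`sample`, `tag`, `replicate`).
#' @param proteins Protein identifiers to score (default: all in
#'   `peptides`).
#' @param wt_tag,mut_tag Tags of the compared lines.
#' @return Tibble `protein`, `median_enrichment`, `n_replicates`,
#'   `peptides` (the two selected sequences, `;`-joined).
#' @export
targeted_top2 <- function(peptides, meta, proteins = NULL,
                          wt_tag = "FLAG_WT", mut_tag = "FLAG_S248A") {
  peptides <- as_tibble(peptides)
  if (!"homologous" %in% names(peptides)) peptides$homologous <- FALSE
  proteins <- proteins %||% unique(peptides$protein)
  dat <- inner_join(peptides, as_tibble(meta), by = "sample") %>%
    filter(!is.na(.data$intensity))

  rows <- map(proteins, function(p) {
    pp <- filter(dat, .data$protein == p, !.data$homologous)
    totals <- pp %>%
      group_by(.data$peptide) %>%
      summarise(total = sum(.data$intensity), .groups = "drop") %>%
      arrange(dplyr::desc(.data$total))
    if (nrow(totals) < 2) {
      warn(paste0("Protein ", p, " has < 2 eligible peptides; skipped."))
      return(NULL)
    }
    top2 <- head(totals$peptide, 2)
    per_rep <- pp %>%
      filter(.data$peptide %in% top2, .data$tag %in% c(wt_tag, mut_tag)) %>%
      group_by(.data$replicate, .data$tag) %>%
      summarise(sum_int = sum(.data$intensity), .groups = "drop") %>%
      tidyr::pivot_wider(names_from = "tag", values_from = "sum_int") %>%
      filter(!is.na(.data[[wt_tag]]), !is.na(.data[[mut_tag]])) %>%
      mutate(enrichment = log2(.data[[mut_tag]] / .data[[wt_tag]]))
    tibble(
      protein = p,
      median_enrichment = median(per_rep$enrichment),
      n_replicates = nrow(per_rep),
      peptides = paste(top2, collapse = ";")
    )
  })
  list_rbind(rows)
}

#' Write interactome scoring results to TSV
#'
#' @param x A `specificity_result` or `differential_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scores_tsv <- function(x, path) {
  readr::write_tsv(as_tibble(x), path)
  invisible(path)
}
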