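#' Per-isoform stoichiometry from integrated areas
#'
#' Converts integrated XIC areas into the fraction of total signal carried
#' by each PTM isoform (PTM occupancy). Rows whose fraction falls below
#' `loq_fraction` are flagged as below the limit of quantitation but are
#' retained both in the table and in the normalization — low-abundance forms
#' are reported as unreliable, never silently dropped.
#'
#' @param areas Tibble/data frame with columns `label` and `area`
#'   (non-negative), or a named numeric vector of areas.
#' @param loq_fraction Fraction of total signal below which an isoform is
#'   flagged below-LOQ (default 0.01, i.e. 1% of total).
#' @return A tibble of class `stoich_tbl` with columns `label`, `area`,
#'   `fraction`, `below_loq`.
#' @examples
#' stoichiometry(c(unmodified = 332, `GlcNAc-S248` = 441,
#'                 `phospho-S253` = 109, doubly = 118))
#' @export
stoichiometry <- function(areas, loq_fraction = 0.01) {
  if (is.numeric(areas) && !is.null(names(areas))) {
    areas <- tibble(label = names(areas), area = unname(areas))
  }
  areas <- as_tibble(areas)
  stopifnot(all(c("label", "area") %in% names(areas)))
  if (any(areas$area < 0)) abort("Areas must be non-negative.")
  total <- sum(areas$area)
  if (total <= 0) abort("All areas are zero: no quantifiable signal.")
  out <- mutate(
    areas[, c("label", "area")],
    fraction = .data$area / total,
    below_loq = .data$fraction < loq_fraction
  )
  structure(out, loq_fraction = loq_fraction,
            class = c("stoich_tbl", class(out)))
}

parse_mods <- function(spec) {
  if (is.na(spec) || !nzchar(spec)) {
    return(tibble(site = integer(), kind = character()))
  }
  parts <- strsplit(strsplit(spec, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
  tibble(
    site = as.integer(map_chr(parts, 1)),
    kind = map_chr(parts, 2)
  )
}

parse_charges <- function(spec) {
  as.integer(strsplit(as.character(spec), ";", fixed = TRUE)[[1]])
}

#' Read isoform definitions from TSV
#'
#' Tab-separated columns: `label`, `sequence`, `mods`
#' (`site:kind;site:kind`, zero-based sites, empty for unmodified),
#' `charges` (`;`-separated positive integers), `rt_start`, `rt_end`
#' (minutes).
#'
#' @param path Path to the TSV file.
#' @return A tibble of isoform definitions as consumed by
#'   [quantify_isoforms()].
#' @export
read_isoforms_tsv <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           label = readr::col_character(),
                           sequence = readr::col_character(),
                           mods = readr::col_character(),
                           charges = readr::col_character(),
                           rt_start = readr::col_double(),
                           rt_end = readr::col_double()
                         ))
  tbl$mods[is.na(tbl$mods)] <- ""
  tbl
}

#' Write a stoichiometry table to TSV
#'
#' @param x A `stoich_tbl` from [stoichiometry()] or [quantify_isoforms()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stoichiometry_tsv <- function(x, path) {
  readr::write_tsv(as_tibble(x), path)
  invisible(path)
}

isoform_targets <- function(isoforms) {
  rows <- pmap(isoforms, function(label, sequence, mods, charges,
                                  rt_start, rt_end, ...) {
    mods_tbl <- if (is.data.frame(mods)) as_tibble(mods) else parse_mods(mods)
    zs <- if (is.numeric(charges)) as.integer(charges) else parse_charges(charges)
    tibble(
      label = label,
      charge = zs,
      mz = map_dbl(zs, function(z) {
        compute_isoform_mz(modified_peptide(sequence, mods_tbl, z, label))
      }),
      rt_start = rt_start,
      rt_end = rt_end
    )
  })
  list_rbind(rows)
}

#' Quantify PTM isoform stoichiometry from an MS1 run
#'
#' For each isoform definition, extracts one XIC per charge state at the
#' theoretical m/z within `tolerance_ppm`, restricted to the isoform's
#' retention-time window, integrates each trace
#' (baseline-subtracted trapezoid), sums areas across charge states, and
#' normalizes to fractions of total signal. Positional isomers with
#' indistinguishable m/z (isobaric isoforms, e.g. the two singly
#' O-GlcNAcylated forms of one peptide) must be given disjoint
#' retention-time windows; overlapping windows for an isobaric pair are
#' rejected.
#'
#' @param run An [ms1_run()].
#' @param isoforms Isoform definition tibble (see [read_isoforms_tsv()]);
#'   `mods` may be a spec string or a nested data frame, `charges` a
#'   `;`-string or integer vector.
#' @param tolerance_ppm XIC mass tolerance in ppm (default 10).
#' @param loq_fraction Below-LOQ flag threshold passed to [stoichiometry()].
#' @return A `stoich_tbl` (label, area, fraction, below_loq), one row per
#'   isoform in input order.
#' @export
quantify_isoforms <- function(run, isoforms, tolerance_ppm = 10,
                              loq_fraction = 0.01) {
  isoforms <- as_tibble(isoforms)
  if (nrow(isoforms) == 0) abort("`isoforms` must be non-empty.")
  targets <- isoform_targets(isoforms)

  # isobaric isoforms sharing an extraction window cannot be separated
  labs <- unique(targets$label)
  if (length(labs) > 1) {
    for (i in seq_along(labs)[-length(labs)]) {
      for (j in seq((i + 1), length(labs))) {
        a <- filter(targets, .data$label == labs[i])
        b <- filter(targets, .data$label == labs[j])
        tol <- outer(a$mz, b$mz, function(x, y) abs(x - y) <= x * tolerance_ppm * 1e-6)
        rt_olap <- a$rt_start[1] < b$rt_end[1] & b$rt_start[1] < a$rt_end[1]
        if (any(tol) && rt_olap) {
          abort(paste0(
            "Isobaric isoforms with overlapping rt windows: ",
            labs[i], " and ", labs[j],
            "; give them disjoint rt windows."
          ))
        }
      }
    }
  }

  areas <- targets %>%
    mutate(area = pmap_dbl(list(.data$mz, .data$rt_start, .data$rt_end),
                           function(mz, s, e) {
                             integrate_area(extract_xic(run, mz, tolerance_ppm, c(s, e)))
                           })) %>%
    group_by(.data$label) %>%
    summarise(area = sum(.data$area), .groups = "drop")

  # restore the caller's isoform order
  areas <- areas[match(unique(isoforms$label), areas$label), ]
  stoichiometry(areas, loq_fraction = loq_fraction)
}

#' @export
#' @method autoplot stoich_tbl
#' @rdname quantify_isoforms
#' @param x A `stoich_tbl`.
#' @param ... Unused.
autoplot.stoich_tbl <- function(x, ...) {
  dat <- as_tibble(x)
  dat$label <- factor(dat$label, levels = dat$label)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$label, y = 100 * .data$fraction,
                                    fill = .data$below_loq)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey30", `TRUE` = "firebrick"),
                               name = "below LOQ") +
    ggplot2::labs(x = NULL, y = "% of total signal") +
    ggplot2::theme_minimal()
}
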