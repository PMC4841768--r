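#' Differential-expression filter: fold change + paired t-test
#'
#' For each gene, measurements paired by replicate are compared between the
#' two conditions with a two-sided paired t-test on log2 values (a
#' one-sample t on the per-pair log2 differences). The fold change is the
#' geometric mean of per-pair ratios (mutant over wild type), i.e.
#' `2^mean(log2 differences)`; an arithmetic-mean alternative is available.
#' A gene is called `up` when FC >= `fc_cutoff` and p < `alpha`, `down`
#' when FC <= 1/`fc_cutoff` and p < `alpha`, otherwise `unchanged`.
#'
#' Degenerate inputs: pairs identical in every replicate give FC 1 and
#' class `unchanged`; zero variance of differences with nonzero mean is a
#' 0-limit p-value, reported as `p = 0` with `zero_var = TRUE`.
#'
#' @param matrix Long expression tibble with columns `gene`, `condition`,
#'   `pair` (replicate-pair index) and `value` (> 0, linear scale).
#' @param fc_cutoff Fold-change gate (default 1.5).
#' @param alpha Raw p-value gate (default 0.05). No multiple-testing
#'   correction is applied to the calls; BH q-values can be added with
#'   `adjust = TRUE` as an extra column.
#' @param conditions Length-2 character: reference then test condition
#'   (fold change is test over reference).
#' @param fc_method `"geometric"` (default) or `"arithmetic"` mean of
#'   per-pair ratios.
#' @param adjust Add a BH-adjusted `q` column (default `FALSE`; calls are
#'   unaffected).
#' @return Tibble of class `de_result`: `gene`, `fold_change`, `t`, `p`,
#'   `class`, `zero_var` (+ `q` if requested).
#' @export
de_filter <- function(matrix, fc_cutoff = 1.5, alpha = 0.05,
                      conditions = c("WT", "S248A"),
                      fc_method = c("geometric", "arithmetic"),
                      adjust = FALSE) {
  fc_method <- match.arg(fc_method)
  matrix <- as_tibble(matrix)
  stopifnot(all(c("gene", "condition", "pair", "value") %in% names(matrix)))
  if (any(matrix$value <= 0)) abort("Expression values must be positive.")
  wide <- matrix %>%
    filter(.data$condition %in% conditions) %>%
    tidyr::pivot_wider(names_from = "condition", values_from = "value")
  ref <- conditions[1]
  tst <- conditions[2]
  if (any(is.na(wide[[ref]]) | is.na(wide[[tst]]))) {
    abort("Every replicate pair must have both conditions.")
  }

  res <- wide %>%
    group_by(.data$gene) %>%
    summarise(
      n_pairs = n(),
      ratios = list(.data[[tst]] / .data[[ref]]),
      diffs = list(log2(.data[[tst]]) - log2(.data[[ref]])),
      .groups = "drop"
    )
  if (any(res$n_pairs < 2)) abort("Need >= 2 replicate pairs per gene.")

  scored <- res %>%
    mutate(
      fold_change = if (fc_method == "geometric") {
        map_dbl(.data$diffs, ~ 2^mean(.x))
      } else {
        map_dbl(.data$ratios, mean)
      },
      stats = map(.data$diffs, function(d) {
        # treat sub-ulp spread as zero variance (pairs identical up to rounding)
        if (sd(d) <= 1e-12 * max(1, abs(mean(d)))) {
          if (abs(mean(d)) <= 1e-12) {
            tibble(t = 0, p = 1, zero_var = FALSE)
          } else {
            tibble(t = sign(mean(d)) * Inf, p = 0, zero_var = TRUE)
          }
        } else {
          tt <- t.test(d)
          tibble(t = unname(tt$statistic), p = tt$p.value, zero_var = FALSE)
        }
      })
    ) %>%
    tidyr::unnest("stats") %>%
    mutate(class = case_when(
      .data$fold_change >= fc_cutoff & .data$p < alpha ~ "up",
      .data$fold_change <= 1 / fc_cutoff & .data$p < alpha ~ "down",
      TRUE ~ "unchanged"
    )) %>%
    select("gene", "fold_change", "t", "p", "class", "zero_var")
  if (adjust) scored$q <- p.adjust(scored$p, method = "BH")
  structure(scored, fc_cutoff = fc_cutoff, alpha = alpha,
            conditions = conditions,
            class = c("de_result", class(scored)))
}

#' @export
glance.de_result <- function(x, ...) {
  tibble(
    n_genes = nrow(x),
    n_up = sum(x$class == "up"),
    n_down = sum(x$class == "down"),
    fc_cutoff = attr(x, "fc_cutoff"),
    alpha = attr(x, "alpha")
  )
}

#' @export
#' @method autoplot de_result
#' @rdname de_filter
#' @param x A `de_result`.
#' @param ... Unused.
autoplot.de_result <- function(x, ...) {
  dat <- mutate(as_tibble(x), neglog_p = -log10(pmax(.data$p, 1e-300)))
  ggplot2::ggplot(dat, ggplot2::aes(x = log2(.data$fold_change),
                                    y = .data$neglog_p,
                                    colour = .data$class)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(
      up = "firebrick", down = "steelblue", unchanged = "grey60"
    )) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p") +
    ggplot2::theme_minimal()
}

#' Relative quantitation by the delta-Cq method
#'
#' `delta_cq()` returns `2^-(cq_gene - cq_ref)`, the expression of a gene
#' relative to a reference gene from qPCR quantification cycles
#' (vectorized). `delta_cq_table()` applies it to a long Cq table against a
#' named reference gene, per sample.
#'
#' @param cq_gene,cq_ref Finite quantification-cycle values.
#' @return Relative expression (1 when the Cq values are equal).
#' @examples
#' delta_cq(25, 22) # 2^-3 = 0.125
#' @export
delta_cq <- function(cq_gene, cq_ref) {
  stopifnot(all(is.finite(cq_gene)), all(is.finite(cq_ref)))
  2^(-(cq_gene - cq_ref))
}

#' @rdname delta_cq
#' @param cq Tibble with columns `gene`, `sample`, `cq`.
#' @param ref_gene Reference gene identifier (e.g. `"GusB"`).
#' @export
delta_cq_table <- function(cq, ref_gene) {
  cq <- as_tibble(cq)
  stopifnot(all(c("gene", "sample", "cq") %in% names(cq)))
  ref <- filter(cq, .data$gene == ref_gene)
  if (nrow(ref) == 0) abort(paste0("Reference gene not found: ", ref_gene))
  cq %>%
    filter(.data$gene != ref_gene) %>%
    left_join(select(ref, "sample", ref_cq = "cq"), by = "sample") %>%
    mutate(rel_expression = delta_cq(.data$cq, .data$ref_cq))
}

#' Read a long expression matrix from TSV
#'
#' Expects columns `gene`, `condition`, `pair`, `value`.
#'
#' @param path Path to the TSV file.
#' @return A long expression tibble for [de_filter()].
#' @export
read_expression_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}
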