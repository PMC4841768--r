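#' Tidy and summarize pipeline results
#'
#' All result objects are tibbles already; `tidy()` strips the result class
#' (returning a plain tibble) and `glance()` returns a one-row summary of
#' the fit-level quantities: thresholds, call counts, and dispersion of the
#' normalized ratios.
#'
#' @param x A result object.
#' @param ... Unused.
#' @return A tibble.
#' @name tidiers
NULL

strip_result <- function(x) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), c("stoich_tbl", "specificity_result",
                                      "differential_result", "de_result",
                                      "motif_fraction", "signal_track"))
  out
}

#' @rdname tidiers
#' @export
tidy.stoich_tbl <- function(x, ...) strip_result(x)

#' @rdname tidiers
#' @export
tidy.specificity_result <- function(x, ...) strip_result(x)

#' @rdname tidiers
#' @export
tidy.differential_result <- function(x, ...) strip_result(x)

#' @rdname tidiers
#' @export
tidy.de_result <- function(x, ...) strip_result(x)

#' @rdname tidiers
#' @export
tidy.motif_fraction <- function(x, ...) strip_result(x)

#' @rdname tidiers
#' @export
glance.stoich_tbl <- function(x, ...) {
  tibble(
    n_isoforms = nrow(x),
    total_area = sum(x$area),
    n_below_loq = sum(x$below_loq),
    loq_fraction = attr(x, "loq_fraction")
  )
}

#' @rdname tidiers
#' @export
glance.specificity_result <- function(x, ...) {
  as_tibble(x) %>%
    group_by(.data$tag) %>%
    summarise(
      n_scored = n(),
      n_specific = sum(.data$specific, na.rm = TRUE),
      sd_normalized = sd(.data$normalized),
      .groups = "drop"
    ) %>%
    mutate(sd_threshold = attr(x, "sd_threshold"))
}

#' @rdname tidiers
#' @export
glance.differential_result <- function(x, ...) {
  tibble(
    n_scored = nrow(x),
    n_wt_preferring = sum(x$class == "WT_preferring"),
    n_s248a_preferring = sum(x$class == "S248A_preferring"),
    sd_normalized = sd(x$normalized),
    z_threshold = attr(x, "z_threshold")
  )
}

#' @rdname tidiers
#' @export
#' @method autoplot differential_result
autoplot.differential_result <- function(x, ...) {
  ggplot2::ggplot(as_tibble(x),
                  ggplot2::aes(x = .data$normalized, fill = .data$class)) +
    ggplot2::geom_histogram(bins = 50) +
    ggplot2::scale_fill_manual(values = c(
      WT_preferring = "steelblue", S248A_preferring = "firebrick",
      shared = "grey60"
    )) +
    ggplot2::labs(x = "median-normalized log2 ratio of ratios", y = "proteins") +
    ggplot2::theme_minimal()
}

#' @rdname tidiers
#' @export
#' @method autoplot specificity_result
autoplot.specificity_result <- function(x, ...) {
  ggplot2::ggplot(as_tibble(x),
                  ggplot2::aes(x = .data$normalized, fill = .data$specific)) +
    ggplot2::geom_histogram(bins = 50) +
    ggplot2::facet_wrap(~tag) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick"),
                               name = "specific") +
    ggplot2::labs(x = "median-normalized log2 FLAG/HA", y = "proteins") +
    ggplot2::theme_minimal()
}
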