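#' Read and write aligned tag positions (BED6)
#'
#' Tags are the mapped 5' positions of sequenced ChIP fragment ends, stored
#' as a tibble with columns `chrom`, `pos` (0-based) and `strand`. In BED6
#' input the tag position is `start` for `+` records and `end - 1` for `-`
#' records (the 5' end of the aligned read). `read_chrom_sizes()` reads a
#' two-column `chrom<TAB>size` table.
#'
#' @param path Path to the file.
#' @return `read_tags_bed()`: a tibble `chrom`, `pos`, `strand`;
#'   `read_chrom_sizes()`: a tibble `chrom`, `size`.
#' @name tag_io
NULL

#' @rdname tag_io
#' @export
read_tags_bed <- function(path) {
  bed <- readr::read_tsv(path, col_names = c("chrom", "start", "end",
                                             "name", "score", "strand"),
                         show_col_types = FALSE,
                         col_types = "ciicdc")
  tibble(
    chrom = bed$chrom,
    pos = if_else(bed$strand == "-", bed$end - 1L, bed$start),
    strand = bed$strand
  )
}

#' @rdname tag_io
#' @param tags Tag tibble (`chrom`, `pos`, `strand`).
#' @export
write_tags_bed <- function(tags, path) {
  bed <- tibble(
    chrom = tags$chrom, start = tags$pos, end = tags$pos + 1L,
    name = ".", score = 0, strand = tags$strand
  )
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

#' @rdname tag_io
#' @export
read_chrom_sizes <- function(path) {
  readr::read_tsv(path, col_names = c("chrom", "size"),
                  show_col_types = FALSE, col_types = "ci")
}

validate_tags <- function(tags, sizes) {
  missing <- setdiff(unique(tags$chrom), sizes$chrom)
  if (length(missing) > 0) {
    abort(paste0("Tags on chromosomes absent from the sizes table: ",
                 paste(missing, collapse = ", ")))
  }
  joined <- left_join(tags, sizes, by = "chrom")
  if (any(joined$pos < 0 | joined$pos >= joined$size)) {
    abort("Tag positions must satisfy 0 <= pos < chromosome length.")
  }
  invisible(tags)
}

#' Deduplicate and subsample tags
#'
#' Collapses tags identical in (chromosome, position, strand) to one record
#' and draws exactly `n` of the unique tags uniformly without replacement.
#' Sampling is reproducible for a fixed `seed`. Equalizing library depth by
#' subsampling to a common count (e.g. 10 million unique tags per dataset)
#' makes ChIP and input densities directly comparable before subtraction.
#'
#' @param tags Tag tibble (`chrom`, `pos`, `strand`).
#' @param n Number of unique tags to retain.
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @return Tag tibble of `n` unique tags.
#' @export
dedupe_and_subsample <- function(tags, n, seed = NULL) {
  uniq <- distinct(as_tibble(tags), .data$chrom, .data$pos, .data$strand)
  if (n > nrow(uniq)) {
    abort(sprintf("Requested %d tags but only %d unique tags are available.",
                  n, nrow(uniq)))
  }
  draw <- function() uniq[sample.int(nrow(uniq), n), ]
  out <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  arrange(out, .data$chrom, .data$pos)
}

#' Binned, depth-normalized tag density
#'
#' Partitions each chromosome into `bin_size` bp bins and counts the tags
#' within `flank` bp of each bin: with `flank_from = "edges"` (default) the
#' counting window is the bin dilated by `flank` on each side,
#' `[start - flank, end + flank)`; with `"center"` it is
#' `[center - flank, center + flank)`. Counts from both strands are pooled.
#' Raw counts are scaled by `normalize_to / total tags`, so tracks built
#' from libraries of different depth are comparable.
#'
#' @param tags Tag tibble (`chrom`, `pos`, `strand`).
#' @param sizes Chromosome sizes tibble (`chrom`, `size`).
#' @param bin_size Bin width in bp (default 20).
#' @param flank Flank in bp added around each bin (default 75).
#' @param normalize_to Tag count the track is normalized to (default 1e7).
#' @param flank_from `"edges"` or `"center"` (see above).
#' @return Tibble of class `signal_track` with columns `chrom`, `start`,
#'   `end`, `value`, one row per bin, and attributes `bin_size`, `flank`,
#'   `normalize_to`. Values may be negative after [subtract_input()].
#' @export
tag_density <- function(tags, sizes, bin_size = 20, flank = 75,
                        normalize_to = 1e7,
                        flank_from = c("edges", "center")) {
  flank_from <- match.arg(flank_from)
  if (bin_size <= 0) abort("`bin_size` must be > 0.")
  if (flank < 0) abort("`flank` must be >= 0.")
  tags <- as_tibble(tags)
  validate_tags(tags, sizes)
  total <- nrow(tags)
  if (total == 0) warn("Empty tag set: returning an all-zero track.")
  scale <- if (total == 0) 0 else normalize_to / total

  per_chrom <- map(seq_len(nrow(sizes)), function(i) {
    chrom <- sizes$chrom[i]
    len <- sizes$size[i]
    starts <- seq.int(0L, len - 1L, by = bin_size)
    pos <- sort(tags$pos[tags$chrom == chrom])
    if (flank_from == "edges") {
      lo <- starts - flank
      hi <- starts + bin_size + flank
    } else {
      centers <- starts + bin_size / 2
      lo <- centers - flank
      hi <- centers + flank
    }
    counts <- findInterval(hi - 0.5, pos) - findInterval(lo - 0.5, pos)
    tibble(chrom = chrom, start = starts,
           end = pmin(starts + bin_size, len),
           value = counts * scale)
  })
  out <- list_rbind(per_chrom)
  structure(out, bin_size = bin_size, flank = flank,
            normalize_to = normalize_to,
            class = c("signal_track", class(out)))
}

#' Subtract a matched input track from a ChIP track
#'
#' Elementwise subtraction of the depth-normalized input (background)
#' density from the ChIP density. Both tracks must share the same bins and
#' normalization count. Negative values are retained: they are informative
#' background fluctuation, not an error.
#'
#' @param chip,input `signal_track` objects over the same genome and bins.
#' @return A `signal_track` of the differences.
#' @export
subtract_input <- function(chip, input) {
  stopifnot(inherits(chip, "signal_track"), inherits(input, "signal_track"))
  same <- identical(attr(chip, "bin_size"), attr(input, "bin_size")) &&
    identical(attr(chip, "normalize_to"), attr(input, "normalize_to")) &&
    nrow(chip) == nrow(input) &&
    identical(chip$chrom, input$chrom) && identical(chip$start, input$start)
  if (!same) abort("Tracks have mismatched bins or normalization.")
  out <- mutate(as_tibble(chip), value = .data$value - input$value)
  structure(out, bin_size = attr(chip, "bin_size"),
            flank = attr(chip, "flank"),
            normalize_to = attr(chip, "normalize_to"),
            class = class(chip))
}

#' Threshold-and-merge peak calling on a signal track
#'
#' A deliberately simple caller used to turn the subtracted density track
#' into intervals: maximal runs of bins with value at or above `threshold`
#' become candidate peaks, runs separated by less than `merge_gap` bp are
#' merged, and merged runs shorter than `min_width` bp are discarded.
#' Externally called peaks (BED) are accepted everywhere a peak set is
#' consumed, so any dedicated caller can be substituted upstream.
#'
#' @param track A `signal_track`.
#' @param threshold Minimum bin value; default `NULL` uses
#'   mean + 2 standard deviations of all bin values.
#' @param min_width Minimum peak width in bp (default two bins).
#' @param merge_gap Runs closer than this many bp are merged (default two
#'   bins).
#' @return Peak tibble `chrom`, `start`, `end`, `score` (maximum bin value),
#'   half-open 0-based intervals, sorted within chromosome.
#' @export
call_peaks <- function(track, threshold = NULL, min_width = NULL,
                       merge_gap = NULL) {
  stopifnot(inherits(track, "signal_track"))
  bin <- attr(track, "bin_size")
  min_width <- min_width %||% (2 * bin)
  merge_gap <- merge_gap %||% (2 * bin)
  threshold <- threshold %||% (mean(track$value) + 2 * sd(track$value))
  if (threshold <= 0) abort("`threshold` must be > 0.")

  per_chrom <- map(unique(track$chrom), function(ch) {
    tr <- filter(as_tibble(track), .data$chrom == ch)
    above <- tr$value >= threshold
    if (!any(above)) return(NULL)
    r <- rle(above)
    ends_idx <- cumsum(r$lengths)
    starts_idx <- ends_idx - r$lengths + 1L
    keep <- r$values
    runs <- tibble(
      start = tr$start[starts_idx[keep]],
      end = tr$end[ends_idx[keep]]
    )
    # merge runs separated by < merge_gap bp
    merged_start <- runs$start[1]
    merged_end <- runs$end[1]
    acc <- list()
    if (nrow(runs) > 1) {
      for (k in 2:nrow(runs)) {
        if (runs$start[k] - merged_end < merge_gap) {
          merged_end <- runs$end[k]
        } else {
          acc[[length(acc) + 1]] <- c(merged_start, merged_end)
          merged_start <- runs$start[k]
          merged_end <- runs$end[k]
        }
      }
    }
    acc[[length(acc) + 1]] <- c(merged_start, merged_end)
    peaks <- tibble(
      chrom = ch,
      start = map_dbl(acc, 1),
      end = map_dbl(acc, 2)
    )
    peaks <- filter(peaks, .data$end - .data$start >= min_width)
    if (nrow(peaks) == 0) return(NULL)
    peaks$score <- map_dbl(seq_len(nrow(peaks)), function(k) {
      max(tr$value[tr$start >= peaks$start[k] & tr$start < peaks$end[k]])
    })
    peaks
  })
  out <- list_rbind(per_chrom)
  if (is.null(out) || nrow(out) == 0) {
    out <- tibble(chrom = character(), start = double(), end = double(),
                  score = double())
  }
  arrange(out, .data$chrom, .data$start)
}

#' Write a signal track as bedGraph
#'
#' @param track A `signal_track`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  readr::write_tsv(as_tibble(track)[, c("chrom", "start", "end", "value")],
                   path, col_names = FALSE)
  invisible(path)
}

#' Read peaks from BED (3 or more columns)
#'
#' @param path Path to a BED3+ file (0-based half-open intervals).
#' @return Peak tibble `chrom`, `start`, `end` (+ `score` if present).
#' @export
read_peaks_bed <- function(path) {
  first <- readr::read_tsv(path, col_names = FALSE, n_max = 1,
                           show_col_types = FALSE)
  nms <- c("chrom", "start", "end", "name", "score", "strand")[seq_len(ncol(first))]
  bed <- readr::read_tsv(path, col_names = nms, show_col_types = FALSE)
  keep <- intersect(c("chrom", "start", "end", "score"), names(bed))
  arrange(as_tibble(bed)[, keep], .data$chrom, .data$start)
}

#' Write peaks as BED
#'
#' @param peaks Peak tibble (`chrom`, `start`, `end`, optional `score`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peaks_bed <- function(peaks, path) {
  out <- tibble(
    chrom = peaks$chrom, start = peaks$start, end = peaks$end,
    name = paste0("peak_", seq_len(nrow(peaks))),
    score = if ("score" %in% names(peaks)) peaks$score else 0
  )
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' Partition two peak sets by overlap
#'
#' A peak is shared when it overlaps any peak of the other set by at least
#' one base (half-open intervals: `[0,100)` and `[100,200)` do not
#' overlap). The partition is exhaustive and exclusive within each set.
#'
#' @param a,b Peak tibbles (`chrom`, `start`, `end`).
#' @return A list of class `peak_overlap` with tibbles `shared_a`,
#'   `shared_b`, `specific_a`, `specific_b`.
#' @export
peak_overlap <- function(a, b) {
  a <- arrange(as_tibble(a), .data$chrom, .data$start)
  b <- arrange(as_tibble(b), .data$chrom, .data$start)
  stopifnot(all(a$start < a$end), all(b$start < b$end))
  gr <- function(p) GenomicRanges::GRanges(
    p$chrom, IRanges::IRanges(start = p$start + 1, end = p$end)
  )
  if (nrow(a) == 0 || nrow(b) == 0) {
    hit_a <- logical(nrow(a))
    hit_b <- logical(nrow(b))
  } else {
    ov <- GenomicRanges::findOverlaps(gr(a), gr(b))
    hit_a <- seq_len(nrow(a)) %in% S4Vectors::queryHits(ov)
    hit_b <- seq_len(nrow(b)) %in% S4Vectors::subjectHits(ov)
  }
  structure(
    list(
      shared_a = a[hit_a, ], shared_b = b[hit_b, ],
      specific_a = a[!hit_a, ], specific_b = b[!hit_b, ]
    ),
    class = "peak_overlap"
  )
}

#' @export
print.peak_overlap <- function(x, ...) {
  cat(sprintf(
    "<peak_overlap> shared: %d / %d; specific: %d (a), %d (b)\n",
    nrow(x$shared_a), nrow(x$shared_b), nrow(x$specific_a), nrow(x$specific_b)
  ))
  invisible(x)
}

#' @export
tidy.peak_overlap <- function(x, ...) {
  bind_rows(
    mutate(x$shared_a, set = "a", class = "shared"),
    mutate(x$specific_a, set = "a", class = "specific"),
    mutate(x$shared_b, set = "b", class = "shared"),
    mutate(x$specific_b, set = "b", class = "specific")
  )
}

#' @export
glance.peak_overlap <- function(x, ...) {
  tibble(
    shared_a = nrow(x$shared_a), shared_b = nrow(x$shared_b),
    specific_a = nrow(x$specific_a), specific_b = nrow(x$specific_b)
  )
}

#' @export
#' @method autoplot signal_track
#' @rdname tag_density
#' @param x A `signal_track`.
#' @param ... Unused.
autoplot.signal_track <- function(x, ...) {
  ggplot2::ggplot(as_tibble(x),
                  ggplot2::aes(x = .data$start, y = .data$value)) +
    ggplot2::geom_step() +
    ggplot2::facet_wrap(~chrom, scales = "free_x", ncol = 1) +
    ggplot2::labs(x = "position (bp)", y = "normalized tag density") +
    ggplot2::theme_minimal()
}
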