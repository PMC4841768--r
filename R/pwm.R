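#' Position weight matrices
#'
#' A PWM is stored as a list with a 4 x width matrix of per-position
#' log2-odds base weights (rows A, C, G, T) and the background base
#' frequencies the odds are taken against. `read_jaspar()` parses the
#' JASPAR text format (a `>` header line followed by four rows of counts,
#' with or without the `A [ ... ]` bracket style) into a count matrix and
#' converts it with `pwm_from_counts()`.
#'
#' @param counts 4 x width numeric matrix of base counts or probabilities,
#'   rows named A, C, G, T.
#' @param background Background base frequencies (length 4, summing to 1).
#' @param pseudocount Added to every count before normalization
#'   (default 0.25).
#' @param name Motif name.
#' @return An object of class `pwm`.
#' @export
pwm_from_counts <- function(counts, background = rep(0.25, 4),
                            pseudocount = 0.25, name = "motif") {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == 4, ncol(counts) >= 1)
  if (is.null(rownames(counts))) rownames(counts) <- c("A", "C", "G", "T")
  counts <- counts[c("A", "C", "G", "T"), , drop = FALSE]
  if (any(background <= 0) || abs(sum(background) - 1) > 1e-6) {
    abort("`background` must be positive frequencies summing to 1.")
  }
  probs <- sweep(counts + pseudocount, 2,
                 colSums(counts + pseudocount), "/")
  weights <- log2(sweep(probs, 1, background, "/"))
  structure(
    list(weights = weights, background = background, name = name,
         width = ncol(weights)),
    class = "pwm"
  )
}

#' @rdname pwm_from_counts
#' @param path Path to a JASPAR-format text file.
#' @export
read_jaspar <- function(path, background = rep(0.25, 4),
                        pseudocount = 0.25) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  header <- grep("^>", lines)
  if (length(header) != 1 || length(lines) < header + 4) {
    abort("Expected one '>' header followed by four base rows.")
  }
  name <- trimws(sub("^>\\s*", "", lines[header]))
  rows <- lines[(header + 1):(header + 4)]
  parse_row <- function(line) {
    base <- toupper(substr(trimws(line), 1, 1))
    nums <- gsub("^[ACGTacgt]\\s*\\[?|\\]\\s*$", "", trimws(line))
    vals <- as.numeric(strsplit(trimws(nums), "\\s+")[[1]])
    list(base = base, vals = vals)
  }
  parsed <- map(rows, parse_row)
  counts <- do.call(rbind, map(parsed, "vals"))
  rownames(counts) <- map_chr(parsed, "base")
  pwm_from_counts(counts, background, pseudocount, name = name)
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm> %s, width %d (log2-odds weights)\n", x$name, x$width))
  print(round(x$weights, 2))
  invisible(x)
}

#' Maximum achievable log-odds score of a PWM
#'
#' @param pwm A [pwm_from_counts()] object.
#' @return Sum over positions of the best base weight.
#' @export
pwm_max_score <- function(pwm) sum(apply(pwm$weights, 2, max))

#' Consensus sequence of a PWM (best base per position)
#'
#' @param pwm A `pwm`.
#' @return Character string of length `pwm$width`.
#' @export
pwm_consensus <- function(pwm) {
  paste(rownames(pwm$weights)[apply(pwm$weights, 2, which.max)],
        collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

score_windows <- function(seq_chars, pwm) {
  w <- pwm$width
  n <- length(seq_chars) - w + 1
  if (n < 1) return(numeric(0))
  idx <- match(seq_chars, c("A", "C", "G", "T"))
  scores <- numeric(n)
  for (j in seq_len(w)) {
    scores <- scores + pwm$weights[cbind(idx[j:(j + n - 1)], j)]
  }
  scores  # windows containing N (or other letters) score NA
}

#' Scan a DNA sequence with a PWM on both strands
#'
#' Scores every width-length window of `sequence` with the PWM's log2-odds
#' weights on the forward strand, and scores the reverse strand by scanning
#' the reverse complement; reverse-strand offsets are reported in forward
#' coordinates (0-based offset of the window's leftmost base). Windows
#' containing `N` are skipped. Hits are windows scoring at or above
#' `score_threshold`.
#'
#' @param sequence DNA string over A, C, G, T, N.
#' @param pwm A `pwm`.
#' @param score_threshold Minimum log2-odds score, or `NULL` to use
#'   `threshold_frac * pwm_max_score(pwm)`.
#' @param threshold_frac Fraction of the maximum achievable score used when
#'   `score_threshold` is `NULL` (default 0.8).
#' @return Tibble `offset` (0-based), `strand` (`+`/`-`), `score`, ordered
#'   by offset. Empty when the sequence is shorter than the motif.
#' @export
pwm_scan <- function(sequence, pwm, score_threshold = NULL,
                     threshold_frac = 0.8) {
  stopifnot(inherits(pwm, "pwm"))
  score_threshold <- score_threshold %||% (threshold_frac * pwm_max_score(pwm))
  sequence <- toupper(sequence)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  w <- pwm$width
  if (length(chars) < w) {
    return(tibble(offset = integer(), strand = character(), score = double()))
  }
  fwd <- score_windows(chars, pwm)
  rev_chars <- strsplit(revcomp(sequence), "", fixed = TRUE)[[1]]
  rev <- score_windows(rev_chars, pwm)
  # window at reverse-complement offset i covers forward offset L - w - i
  n <- length(fwd)
  hits <- bind_rows(
    tibble(offset = which(!is.na(fwd) & fwd >= score_threshold) - 1L,
           strand = "+") %>%
      mutate(score = fwd[.data$offset + 1L]),
    tibble(offset = n - which(!is.na(rev) & rev >= score_threshold),
           strand = "-") %>%
      mutate(score = rev[n - .data$offset])
  )
  arrange(hits, .data$offset, .data$strand)
}

#' Fraction of peaks containing a motif match
#'
#' Extracts each peak's sequence from the genome and scans it with the PWM
#' on both strands; a peak counts as motif-containing when it has at least
#' one window scoring at or above the threshold. Reports the proportion of
#' motif-containing peaks together with the per-peak hit flags.
#'
#' @param peaks Peak tibble (`chrom`, `start`, `end`), 0-based half-open,
#'   within genome bounds.
#' @param genome A named `Biostrings::DNAStringSet`, a named character
#'   vector of chromosome sequences, or a FASTA file path.
#' @inheritParams pwm_scan
#' @return Tibble of class `motif_fraction` with per-peak columns `chrom`,
#'   `start`, `end`, `has_motif`, `n_hits`; the overall proportion is in
#'   attribute `fraction` (also via [glance()]).
#' @export
motif_fraction <- function(peaks, genome, pwm, score_threshold = NULL,
                           threshold_frac = 0.8) {
  peaks <- as_tibble(peaks)
  if (nrow(peaks) == 0) abort("Empty peak set: no fraction to compute.")
  if (is.character(genome) && length(genome) == 1 && file.exists(genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
  }
  get_seq <- function(chrom, start, end) {
    if (inherits(genome, "DNAStringSet")) {
      chr <- genome[[chrom]]
      if (end > length(chr)) abort("Peak exceeds chromosome bounds.")
      as.character(Biostrings::subseq(chr, start + 1, end))
    } else {
      chr <- genome[[chrom]]
      if (end > nchar(chr)) abort("Peak exceeds chromosome bounds.")
      substr(chr, start + 1, end)
    }
  }
  score_threshold <- score_threshold %||% (threshold_frac * pwm_max_score(pwm))
  hits <- pmap_dbl(peaks[, c("chrom", "start", "end")],
                   function(chrom, start, end) {
                     nrow(pwm_scan(get_seq(chrom, start, end), pwm,
                                   score_threshold))
                   })
  out <- mutate(peaks, n_hits = as.integer(hits), has_motif = hits > 0)
  structure(out, fraction = mean(out$has_motif),
            score_threshold = score_threshold,
            class = c("motif_fraction", class(out)))
}

#' @export
glance.motif_fraction <- function(x, ...) {
  tibble(
    n_peaks = nrow(x),
    n_with_motif = sum(x$has_motif),
    fraction = attr(x, "fraction"),
    score_threshold = attr(x, "score_threshold")
  )
}
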