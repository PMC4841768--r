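#' Monoisotopic residue and modification masses
#'
#' Standard monoisotopic masses (Da) of the twenty amino-acid residues
#' (as incorporated in a peptide chain, i.e. minus water), plus the
#' modification deltas used throughout: O-GlcNAc (HexNAc, +203.079373 Da on
#' Ser/Thr) and phosphorylation (+79.966331 Da on Ser/Thr/Tyr).
#'
#' @format A named numeric vector of residue masses in daltons.
#' @keywords internal
#' @name masses
NULL

RESIDUE_MASS <- c(
  G = 57.02146374, A = 71.03711379, S = 87.03202841, P = 97.05276385,
  V = 99.06841392, T = 101.04767847, C = 103.00918448, L = 113.08406398,
  I = 113.08406398, N = 114.04292744, D = 115.02694302, Q = 128.05857751,
  K = 128.09496302, E = 129.04259309, M = 131.04048461, H = 137.05891186,
  F = 147.06841392, R = 156.10111102, Y = 163.06332853, W = 186.07931295
)

MOD_DELTA <- c(HexNAc = 203.079373, Phospho = 79.966331)
MOD_TARGETS <- list(HexNAc = c("S", "T"), Phospho = c("S", "T", "Y"))

MASS_WATER <- 18.010565
MASS_PROTON <- 1.007276466

#' Construct a site-localized modified peptide
#'
#' A modified peptide is the unit whose theoretical m/z and extracted ion
#' chromatogram (XIC) are computed: a residue sequence plus zero or more
#' site-localized modifications and a charge state. Site indices are
#' zero-based positions in `sequence`. HexNAc (O-GlcNAc) sites must be S or
#' T; Phospho sites must be S, T or Y; no two modifications may share a
#' site.
#'
#' @param sequence Uppercase one-letter amino-acid string.
#' @param modifications Tibble or data frame with columns `site` (zero-based
#'   integer index) and `kind` (`"HexNAc"` or `"Phospho"`), or `NULL` for an
#'   unmodified peptide.
#' @param charge Positive integer charge state.
#' @param label Free-text isoform name (defaults to a generated one).
#' @return An object of class `modified_peptide`.
#' @examples
#' modified_peptide("GAQPVSMALGSTGVNTAR",
#'   modifications = data.frame(site = 5, kind = "HexNAc"), charge = 2
#' )
#' @export
modified_peptide <- function(sequence, modifications = NULL, charge = 2L,
                             label = NULL) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  residues <- strsplit(sequence, "", fixed = TRUE)[[1]]
  unknown <- setdiff(unique(residues), names(RESIDUE_MASS))
  if (length(unknown) > 0) {
    abort(paste0(
      "Unknown residue letter(s) in peptide sequence: ",
      paste(unknown, collapse = ", ")
    ))
  }
  if (!is.numeric(charge) || length(charge) != 1L || charge < 1 ||
      charge != round(charge)) {
    abort("`charge` must be a positive integer.")
  }
  if (is.null(modifications)) {
    modifications <- tibble(site = integer(), kind = character())
  }
  modifications <- as_tibble(modifications)
  stopifnot(all(c("site", "kind") %in% names(modifications)))
  modifications$site <- as.integer(modifications$site)
  if (anyDuplicated(modifications$site)) {
    abort("No two modifications may share a site index.")
  }
  if (any(modifications$site < 0 | modifications$site >= length(residues))) {
    abort("Modification site index out of range for the sequence.")
  }
  bad_kind <- setdiff(modifications$kind, names(MOD_DELTA))
  if (length(bad_kind) > 0) {
    abort(paste0("Unknown modification kind: ", paste(bad_kind, collapse = ", ")))
  }
  ok_res <- map_lgl(seq_len(nrow(modifications)), function(i) {
    residues[modifications$site[i] + 1L] %in% MOD_TARGETS[[modifications$kind[i]]]
  })
  if (!all(ok_res)) {
    bad <- modifications[!ok_res, ]
    abort(paste0(
      "Modification on incompatible residue: ",
      paste(sprintf("%s at site %d (%s)", bad$kind, bad$site,
                    residues[bad$site + 1L]), collapse = "; ")
    ))
  }
  structure(
    list(
      sequence = sequence,
      modifications = modifications[order(modifications$site), ],
      charge = as.integer(charge),
      label = label %||% paste0(sequence, "/", charge, "+")
    ),
    class = "modified_peptide"
  )
}

#' @export
print.modified_peptide <- function(x, ...) {
  mods <- if (nrow(x$modifications) == 0) {
    "unmodified"
  } else {
    paste(sprintf("%s@%d", x$modifications$kind, x$modifications$site),
          collapse = ", ")
  }
  cat(sprintf(
    "<modified_peptide> %s [%s] %d+ (%s)\n",
    x$sequence, mods, x$charge, x$label
  ))
  invisible(x)
}

#' Theoretical monoisotopic m/z of a PTM isoform
#'
#' Computes `(M + z * m_proton) / z` where the neutral monoisotopic mass M is
#' the sum of residue masses plus one water plus the modification deltas
#' (HexNAc +203.079373 Da, Phospho +79.966331 Da).
#'
#' @param peptide A [modified_peptide()].
#' @return The m/z value in thomson (Th).
#' @examples
#' compute_isoform_mz(modified_peptide("PEPTIDER", charge = 2))
#' @export
compute_isoform_mz <- function(peptide) {
  stopifnot(inherits(peptide, "modified_peptide"))
  residues <- strsplit(peptide$sequence, "", fixed = TRUE)[[1]]
  neutral <- sum(RESIDUE_MASS[residues]) + MASS_WATER +
    sum(MOD_DELTA[peptide$modifications$kind])
  (neutral + peptide$charge * MASS_PROTON) / peptide$charge
}
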