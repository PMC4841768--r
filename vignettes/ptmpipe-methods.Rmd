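---
title: "Methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptmpipe)
```

This vignette is the package's account of the science behind each stage:
what is being modelled, which parameters matter, what the synthetic data
do and do not emulate, and where the design was genuinely open.

## PTM-proteoform stoichiometry from MS1 XICs

### Model

A peptide that can carry O-GlcNAc (HexNAc, +203.079373 Da) and/or
phosphate (+79.966331 Da) exists in the cell as a mixture of proteoforms.
In label-free MS1 quantitation each proteoform is observed as a
chromatographic peak at its theoretical m/z,

$$m/z = \frac{\sum_i m_{\mathrm{res},i} + m_{\mathrm{H_2O}} + \sum_k \Delta_k + z\, m_{\mathrm{H^+}}}{z},$$

and its relative abundance (occupancy) is its share of the total
extracted-ion-chromatogram area over all proteoforms of that peptide:
$f_i = A_i / \sum_j A_j$. The approach assumes the proteoforms ionize
comparably (no electrospray suppression differences) — an assumption that
must be validated per peptide with synthetic standards, and which the
pipeline takes as given.

Masses are fixed monoisotopic constants (water 18.010565 Da, proton
1.007276466 Da, standard residue masses). The mass table was
cross-checked against an independent proteomics mass calculator in the
test suite.

### XIC extraction and integration

* `tolerance_ppm` (default **10 ppm**): the high-resolution MS1 matching
  window; a centroid contributes when
  $|m/z - \mathrm{target}|/\mathrm{target} \le 10^{-6}\,\mathrm{tol}$.
  Every scan in the retention-time window contributes a point (zero when
  nothing matches), so traces are dense and integrable.
* Integration is a baseline-subtracted trapezoid with the baseline set to
  the window minimum, clipped below at zero. Vendor chromatographic-area
  algorithms (e.g. the ICIS integrator) are proprietary; the trapezoid is
  reproducible, documented, shape-agnostic, and agrees with a dense
  Riemann-sum oracle to better than 0.1% on smooth peaks in the tests.
  Because the baseline is proportional to the (shared) peak shape, it
  cancels in the fractions.
* Positional isomers with identical mass (GlcNAc-S248 vs GlcNAc-T258)
  cannot be separated by m/z; the caller must supply disjoint
  retention-time windows, mirroring their chromatographic separation.
  Overlapping windows for an isobaric pair are an error, not a silent
  merge. Charge states are listed per isoform and their areas summed; the
  split across charges is irrelevant to the fractions.
* `loq_fraction` (default **0.01**): isoforms below 1% of total signal are
  flagged below the limit of quantitation. The threshold is a
  package-level convention (the source data report a doubly phosphorylated
  form only as "below the limit of quantitation" without defining one);
  flagged rows stay in the table and in the normalization.

### Study-condition compositions

`sox2_tad_isoforms()` encodes the two quantified compositions of the SOX2
transactivation-domain (TAD) tryptic peptide: wild type — unmodified
33.2%, GlcNAc-S248 44.1%, phospho-S253 10.9%, doubly modified
GlcNAc-S248+phospho-S253 11.8% — and the S248A mutant, where only the
phospho-S253 share (18.7%) is an established value; the unmodified
(66.0%) and GlcNAc-T258 (15.3%) shares of the mutant panel are
illustrative defaults chosen once to complete a plausible composition.
The exact TAD peptide sequence is published only in graphical form, so
the panels use the placeholder tryptic sequence `GAQPVSMALGSTGVNTAR`
with Ser/Ser/Thr at the relative offsets of S248/S253/T258; because
occupancy is a ratio of areas at whatever m/z the sequence implies, the
placeholder changes nothing about the recovery behaviour.

## AP-MS interactome scoring

Protein-level LFQ intensities from FLAG-bait purifications are compared
against an HA-tagged control purification of the same bait.

* **Roll-up**: protein intensity is the sum of its non-homologous peptide
  intensities; peptides shared between proteins count for neither. For
  the bait itself, peptides overlapping the modified region (the TAD) are
  excluded so that PTM-dependent signal splitting across proteoforms does
  not distort the bait's protein-level quantity. A protein with no
  surviving peptides is missing, not zero.
* **Specificity**: $r = \log_2(\mathrm{FLAG}/\mathrm{HA})$ per protein,
  median-normalized over all scored proteins, called specific at
  $r' \ge \bar{r'} + 2\,\mathrm{SD}$. The call is one-sided: depletion
  does not make an interactor. With two bait lines the overall call
  requires the 2-SD call in each line independently. "Average ratio" is
  interpreted as the ratio of replicate means (log2 of mean FLAG over mean
  HA); a mean-of-log-ratios alternative is available via `ratio_method`
  since the two differ under noise and the source wording is ambiguous.
* **Missing values**: a protein absent from every HA sample receives a
  floor equal to the 1st percentile of observed HA intensities (standard
  AP-MS practice; keeps bait-specific preys scoreable without infinite
  ratios); proteins absent from all FLAG samples of a line are not scored
  there.
* **Differential calls**: $d = \log_2\frac{S248A/HA}{WT/HA}
  = \log_2 S248A - \log_2 WT$ (the control cancels), median-normalized,
  z-scored with the sample (n−1) standard deviation over scored proteins,
  and classified at $|z| > 1.5$. Under a pure-noise null the expected
  call rate is $2(1-\Phi(1.5)) \approx 13.4\%$, which the test suite
  verifies by simulation; the z rule is a relative-outlier detector, not
  an error-rate guarantee. Fold change is reported alongside rather than
  gated on, since the fold corresponding to a given z depends on the
  dataset's spread.
* **Targeted top-2**: for complex subunits, the two most intense
  non-homologous peptides are summed per replicate and the median
  log2(S248A/WT) enrichment across replicates reported.

All scores depend on intensities only through ratios, so they are exactly
invariant under global rescaling — a property the tests assert.

## ChIP-seq signal, overlap and motifs

* Tags are 5′ positions of aligned fragment ends; uniqueness is
  (chromosome, position, strand), and `dedupe_and_subsample()` draws a
  fixed number of unique tags (conventionally 10⁷; generalized so toy
  genomes are testable) to equalize library depth before comparison. No
  fragment shift is applied (none is defined for the source protocol);
  positions can be shifted upstream by the caller if desired.
* `tag_density()` counts tags within 75 bp of each 20 bp bin — read as
  the bin dilated by 75 bp on each side (a 170 bp window); a
  bin-center-based alternative is available via `flank_from` since the
  phrase admits both readings. Counts are scaled by
  `normalize_to / total`, and the matched input track is subtracted
  bin-wise; negative values are retained as genuine background
  fluctuation.
* The threshold/merge peak caller (runs of bins ≥ threshold, gaps <
  `merge_gap` merged, short runs dropped) is plumbing: the upstream peak
  caller of the original analysis is unnamed, and externally called BED
  peaks are accepted everywhere a peak set is consumed. The default
  threshold (mean + 2 SD of the track) is a pragmatic outlier rule for
  the strongly enriched synthetic tracks, not a calibrated error rate.
* Peak overlap uses half-open intervals and a 1 bp overlap criterion,
  implemented over GenomicRanges and verified exactly against an
  all-pairs brute-force oracle on 100 random interval sets.
* PWM scanning scores every window on both strands with log2-odds
  weights (counts + 0.25 pseudocount over a uniform background by
  default); windows containing N are skipped, and reverse-strand hits are
  reported at forward coordinates. The default hit threshold is 80% of
  the PWM's maximum achievable score — the match threshold of the
  original de novo motif analysis is not recoverable, so the default is a
  stringent, configurable convention. The shipped
  `oct4_sox2_synthetic.jaspar` matrix is a synthetic composite
  octamer+HMG motif constructed for tests and examples; it is **not** a
  database matrix.

## Expression filters

`de_filter()` mirrors a fold-change-plus-raw-p filter: paired t-test on
log2 values (the scale of the original array test is unstated; log2 is
the standard choice and makes the pairing additive), two-sided, FC as the
geometric mean of per-pair ratios (`2^mean(Δlog2)`, with an
arithmetic-mean alternative), classification at FC ≥ 1.5 and p < 0.05.
No multiple-testing correction is applied to the calls, mirroring the
filter it reproduces; BH q-values can be added as a column. Zero-variance
differences with nonzero mean are reported as the p → 0 limit with a
`zero_var` flag (spread below ~1e-12 in log2 units is treated as zero to
absorb floating-point rounding); identical pairs give p = 1 and class
`unchanged`. `delta_cq()` implements `2^-(Cq_gene - Cq_ref)`.

## Synthetic-data generators

The generators define the study conditions under which everything is
tested:

* `gen_ms1_run()`: Gaussian elution profiles (SD 0.2 min) sampled every
  0.02 min, one centroid per charge state per scan at the exact
  theoretical m/z, multiplicative log-normal noise (CV 1% in the recovery
  experiments), and uniform background centroids kept 50 ppm away from
  every target. Real peaks tail and real centroids wobble in m/z; neither
  matters to a shape-agnostic integrator with a ppm window, which is what
  the round-trip tests demonstrate — they do not demonstrate robustness
  to co-eluting interference or detector saturation.
* `gen_apms()`: log-normal base abundances (meanlog log 10⁷, sdlog 1),
  FLAG/HA ratios centered at 1 for background, spiked interactors at a
  stated fold (16 in the end-to-end test) with a differential factor
  between bait lines (4), log2-normal replicate noise of SD 0.5, two
  replicates per line — the scale of a typical co-IP duplicate design.
  Real AP-MS missingness is intensity-dependent; the generator drops
  values uniformly at random.
* `gen_chip()`: uniform background tags with enriched regions at a fold
  increase of the per-bp rate (20-fold over 200 bp regions in tests),
  uniform input, motif consensus embedded in an exact fraction of the
  regions. There is no fragment-length, mappability or GC model; the
  generator exercises density/subtraction/overlap semantics, not aligner
  realism.
* `gen_expression()`: gene-level log2 abundances with shared per-pair
  effects (the paired structure), regulated genes at an exact fold. With
  zero noise the DE filter recovers the regulated sets exactly; with
  noise it calibrates the type-I error.

All generators are bit-reproducible for a fixed seed; the `truth` tables
they return are sufficient to score recall and precision of every
downstream call.

## Problem sizes and runtime

The test and acceptance workloads were sized to be comfortable on a
single CPU: MS1 runs of ~400 scans, AP-MS tables of 200–1000 proteins,
toy genomes of 2 × 100 kb with 20 k tags, and 2000-gene expression
matrices. The complete test suite runs in under half a minute; the
acceptance script in a few seconds.

## Known limitations

* No spectrum identification, site localization, isotope envelopes or
  match-between-runs: the stoichiometry pipeline starts from identified
  isoform definitions with caller-supplied retention-time windows.
* The specificity/differential z rules assume the background dominates
  the scored set; with many true interactors the mean/SD inflate and
  calls become conservative (the masking inherent to outlier rules).
* The peak caller is intentionally naive; for real data, use a dedicated
  caller and feed the BED peaks into the overlap and motif stages.
* PWM scanning reports marginal per-window hits; overlapping hits on the
  two strands of a palindromic site count as one peak hit but two scan
  hits.
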