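# ptmpipe

Tidy pipelines for studying how a post-translational modification (PTM)
reshapes a transcription factor's behaviour — built around the O-GlcNAc /
phosphorylation proteoform biology of SOX2 in mouse embryonic stem cells,
but applicable to any peptide-centric PTM stoichiometry problem. The
package covers four desk-scale computations that normally live in four
different toolchains:

1. **PTM-proteoform stoichiometry from MS1 XICs.** Each modified peptide
   isoform (e.g. the SOX2 transactivation-domain peptide carrying O-GlcNAc
   at S248, phosphate at S253, both, or neither) has a theoretical
   monoisotopic m/z
   `(M + z·m_H⁺)/z`, with `M = Σ residue masses + H₂O + Σ Δ_mod`
   (Δ_HexNAc = +203.079373 Da, Δ_Phospho = +79.966331 Da). An extracted
   ion chromatogram (XIC) sums centroid intensity within a ppm window
   (default 10 ppm) of that m/z per scan; baseline-subtracted trapezoidal
   integration gives each isoform's area, and PTM occupancy is
   `f_i = A_i / Σ_j A_j`, with isoforms under a limit-of-quantitation
   fraction flagged (never dropped).
2. **AP-MS interactome scoring.** From label-free quantitation (LFQ)
   intensities of FLAG-bait versus HA-control purifications: specificity is
   `r = log2(FLAG/HA)`, median-normalized, called at mean + 2 SD
   (enrichment side); differential interaction between two bait proteoforms
   is the ratio of ratios `d = log2((S248A/HA)/(WT/HA))`, median-normalized,
   z-scored, called at |z| > 1.5. Includes peptide→protein roll-up with
   bait-region exclusion and targeted top-2-peptide enrichment.
3. **ChIP-seq signal and motifs.** Unique-tag subsampling to a fixed depth,
   tag density in 75 bp-dilated 20 bp bins normalized to 10⁷ tags, matched
   input subtraction, a simple threshold/merge peak caller, exact half-open
   peak-set overlap partitioning, and log-odds PWM scanning (both strands)
   to compute the fraction of peaks containing a motif.
4. **Expression filters.** Differential expression by fold-change ≥ 1.5
   plus paired t-test p < 0.05 on log2 values, and RT-qPCR relative
   quantitation by `2^-(ΔCq)`.

Every stage has a seeded synthetic-data generator with serialized ground
truth (`gen_ms1_run()`, `gen_apms()`, `gen_chip()`, `gen_expression()`),
so the whole pipeline is testable without any external data.

All user-facing functions take a data frame first and return tibbles;
results carry `tidy()`, `glance()` and `autoplot()` methods.

## Worked example

Simulate an MS1 run at the wild-type TAD-peptide composition and
re-quantify it:

```r
library(ptmpipe)

panel <- sox2_tad_isoforms("wildtype")
sim <- gen_ms1_run(panel$isoforms, panel$fractions, noise_cv = 0.01, seed = 1)
quantify_isoforms(sim$run, panel$isoforms, tolerance_ppm = 10)
#> # A tibble: 4 × 4
#>   label                         area fraction below_loq
#> 1 unmodified               33197558.    0.332 FALSE
#> 2 GlcNAc-S248              44038871.    0.441 FALSE
#> 3 phospho-S253             10907568.    0.109 FALSE
#> 4 GlcNAc-S248+phospho-S253 11807605.    0.118 FALSE
```

The recovered fractions match the generating composition (33.2 / 44.1 /
10.9 / 11.8% of total TAD-peptide signal) to well under one percentage
point at 1% multiplicative noise. `below_loq` flags isoforms whose share
falls under the quantitation limit (default 1%).

Score a synthetic co-IP with one 16-fold-enriched interactor that prefers
the S248A proteoform 4-fold:

```r
sim2 <- gen_apms(
  n_background = 200,
  specific_interactors = tibble::tibble(
    protein = "PARP1", fold = 16, differential_fold = 4),
  seed = 1
)
sp <- specificity_score(sim2$intensities, sim2$meta)
specific_interactors(sp)
#> [1] "BG0048" "PARP1"

dz <- differential_score(sim2$intensities, sim2$meta)
dplyr::filter(dz, protein == "PARP1")
#>   protein ratio normalized     z fold_change class
#> 1 PARP1    1.69       1.67  3.08        3.22 S248A_preferring
```

`PARP1` is called specific in both bait lines and classified
S248A-preferring (z = 3.08 > 1.5); one of 200 background proteins slips
through the 2-SD gate, consistent with its one-sided ~2% false-positive
rate.

A thin command-line wrapper over the same functions lives at
`inst/cli/ptmpipe.R`:

```sh
Rscript inst/cli/ptmpipe.R simulate kind=ms1 seed=4 --out simdir
Rscript inst/cli/ptmpipe.R ptm_quant run_file=simdir/ms1_run.tsv \
    isoforms_file=simdir/isoforms.tsv ppm=10 --out quantdir
```

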