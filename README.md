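# poolscreen

Simulation and analysis of pooled shRNA survival screens.

## The problem

In a pooled lentiviral shRNA screen, tens of thousands of hairpin constructs
are delivered into a cell population (at low MOI, so most cells carry one
integration), the population is split into an untreated *reference* arm and a
*treated* arm placed under a selective pressure, and the genomic integrations
are sequenced. Hairpins that protect cells from the pressure rise in relative
abundance in the treated arm; hairpins that sensitize them drop. `poolscreen`
implements the full computational path of such an enrichment screen for
libraries organized as multiple pools with 4–7 hairpins per gene spread over
distinct pools, plus a counter-screen subtraction step that removes genes
conferring generic (pressure-unspecific) death resistance:

1. **Library design & budget** — synthetic pooled libraries with unique,
   Hamming-separated barcodes (`design_library`, `validate_library`), and the
   wet-lab arithmetic: cells to seed = ⌈n·coverage/MOI⌉, gDNA mass per
   specimen (`coverage_calculator`).
2. **Screen simulation** — negative-binomial counts with log-normal baseline
   skew and planted log2 selection effects (`simulate_screen_counts`), and
   FASTQ emission with an unassignable spike-in fraction and optional
   substitution errors (`emit_fastq`).
3. **Quantification** — mismatch-tolerant fixed-offset barcode matching of
   FASTQ reads against a library pool (`quantify`, `merge_columns`), with a
   per-sample read-conservation invariant (assigned + unassigned = total).
4. **Differential representation** — CPM normalization (`cpm`), moderated
   method-of-moments NB dispersion (`estimate_dispersion`), and an exact
   conditional negative-binomial test per shRNA with per-pool
   Benjamini–Hochberg control (`test_shrna`, `screen_differential`):
   conditioning on the two-arm total *t* of size-adjusted counts, the
   reference-arm total follows the conditional law of two independent NB
   variables with sizes n₁/φ and n₂/φ; the two-sided p-value is the mass of
   all splits no more probable than the observed one.
5. **Hit calling** — a gene is a hit iff ≥2 member shRNAs are enriched
   (FDR < 0.05, log2FC > 0) in **distinct pools**, at least one with
   log2FC ≥ 1, and **no** member shRNA is significantly depleted
   (`call_hits`); counter-screen hits are subtracted at the gene level
   (`subtract_counter_screen`).
6. **Over-representation** — exact hypergeometric upper-tail test of the
   final hit list against GMT gene sets, BH-adjusted, significant at
   FDR < 0.1 (`enrich`).

`run_pipeline()` orchestrates all stages from a YAML config and writes
deterministic TSV outputs; `inst/cli/poolscreen.R` is a thin command-line
wrapper (`design`, `budget`, `count`, `subtract`, `enrich`, `run-all`, ...).

## Worked example

A 120-gene, 5-pool screen with four genes planted at a log2 selection effect
of 2.5 on every member hairpin:

```r
library(poolscreen)

lib <- design_library(n_genes = 120, per_gene_min = 4, per_gene_max = 5,
                      n_pools = 5, seed = 20)
coverage_calculator(n_shrnas = 9570)
#> Screen design budget
#>   9570 shRNAs at 1000x coverage, MOI 0.3 -> seed 31,900,000 cells
#>   8 PCR replicates x 825 ng gDNA -> 6.6 ug per specimen

eff <- effect_profile(lib, gene_effects = c(GENE00001 = 2.5, GENE00002 = 2.5,
                                            GENE00004 = 2.5, GENE00042 = 2.5))
cfg  <- simulation_config(sequencing_depth = 5e5, dispersion = 0.1, seed = 21)
arms <- simulate_screen_counts(lib, eff, cfg)
res  <- screen_differential(arms$reference, arms$treated, lib)
head(res[order(res$fdr), c("shrna_id", "gene_id", "pool", "log2fc", "fdr")], 3)
#>  shrna_id   gene_id pool   log2fc          fdr
#>  SH000004 GENE00001    4 3.263313 5.034910e-14
#>  SH000009 GENE00002    5 2.243897 5.993385e-10
#>  SH000018 GENE00004    5 2.417910 1.097045e-09

calls <- call_hits(res, lib, hit_criteria())
subset(calls, is_hit)$gene_id
#> [1] "GENE00001" "GENE00002" "GENE00004" "GENE00042"
```

Exactly the four planted genes are called: each has ≥2 enriched hairpins in
distinct pools, a strongest log2FC above 1, and no depleted member. Testing
the hit list against the shipped synthetic gene sets:

```r
gmt <- system.file("extdata", "synthetic_gene_sets.gmt", package = "poolscreen")
enr <- enrich(subset(calls, is_hit)$gene_id, read_gmt(gmt),
              universe = unique(lib$constructs$gene_id))
enr[1, c("term_id", "k", "K", "n", "N", "p_value", "fdr")]
#>              term_id k K n   N      p_value         fdr
#>  SET_METAL_TRANSPORT 3 6 4 120 0.0002793816 0.001117527
```

Three of the four hits fall in the 6-gene metal-transport set
(p = P(X ≥ 3) under the hypergeometric with K = 6, n = 4, N = 120), which
survives FDR < 0.1.

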