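---
title: "Models and methods behind poolscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind poolscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolscreen)
```

`poolscreen` analyses pooled shRNA enrichment screens: a library of hairpin
constructs is transduced into cells at low MOI, the population is split into
an untreated reference arm and a treated arm, and hairpin abundance is read
out by sequencing. This vignette explains the generative model the package
simulates, the statistics it computes, the design choices that were
genuinely open, and what the test suite does and does not establish about
real screens.

## The library model

A library is a table of constructs: `shrna_id`, `gene_id`, `pool`,
`barcode`. The design constraints mirror genome-wide pooled GIPZ-style
libraries: each gene carries between `per_gene_min` and `per_gene_max`
hairpins (defaults 4 and 7), a gene's hairpins occupy **distinct** pools,
and with `equal_pools` every pool holds exactly the same number of
constructs. At full scale (18,205 genes, 10 pools, 95,700 constructs) the
designer produces 9,570 constructs per pool.

Two construction choices were open:

* **Per-gene counts.** Only the range and the total are constrained, so
  counts are drawn uniformly from the range and then repaired by ±1
  adjustments on randomly chosen genes until the total matches. The repair
  touches genes uniformly at random, so no systematic bias in which genes
  get more hairpins is introduced.
* **Pool assignment.** Each gene's $k$ constructs are assigned to its $k$
  least-filled pools (ties broken by pool index). This greedy rule has an
  invariant worth stating: if pool loads span at most 1 before a gene is
  placed, they span at most 1 afterwards — placing into the least-filled
  pools first can only lift the minimum. Equal pools therefore fall out
  exactly whenever the total is divisible by the number of pools; no
  backtracking is needed.

**Barcodes** are uniform random sequences of length 22 with pairwise
Hamming distance ≥ 3, enforced by rejection. Distance 3 makes
single-mismatch read assignment unambiguous by construction: the distance-1
neighbourhoods of two barcodes cannot intersect. Verifying the distance for
95,700 barcodes naively is quadratic; instead each barcode is split into
three segments and bucketed by each segment — two barcodes within distance
2 must agree exactly on at least one segment (pigeonhole), so only
bucket-mates are ever compared.

## Screen-design arithmetic

`coverage_calculator()` encodes the standard wet-lab budget: cells to seed
$= \lceil n_\text{shRNA} \times \text{coverage} / \text{MOI} \rceil$
(defaults: 1000 copies per hairpin, MOI 0.3 so that most transduced cells
carry a single integration), and gDNA per specimen $=$ PCR replicates
$\times$ mass per replicate (defaults 8 × 825 ng = 6.6 µg).

## The count simulator

For each pool, baseline construct abundances are drawn log-normally
(`abundance_sdlog`, default 0.5 — a standard model of pooled-library skew)
and normalized to proportions $p_i$. Reference-arm samples draw counts

$$y_{ij} \sim \mathrm{NB}\!\left(\mu = D\,p_i,\ \phi\right), \qquad
\mathrm{Var}(y) = \mu + \phi\mu^2,$$

with $D$ the expected sequencing depth per sample (default $5\times10^6$,
a realistic per-sample yield for a ~10,000-construct pool) and $\phi$ the
dispersion (default 0.1, a typical between-replicate value for screen
counts; $\phi = 0$ gives Poisson draws). Treated-arm proportions are
$p_i 2^{e_i}$ renormalized, where $e_i$ is the construct's planted log2
selection effect from `effect_profile()`. Renormalization matters: planting
strong positive effects necessarily dilutes every neutral construct, just
as real selection does, so neutral hairpins in a heavily selected pool show
mild negative fold changes. Three replicates per arm (the screen's gDNA
specimens per pool) are the default.

`emit_fastq()` writes one read per counted molecule: a constant 10-nt 5'
flank, the barcode, and constant filler padded to `read_length` (default
75 nt). Unassignable reads are modelled as uniform random sequences
appended at $\lceil f/(1-f) \times n_\text{assigned}\rceil$ for spike-in
fraction $f$ (default 0.10), so the spike-in is the stated fraction of all
reads; random sequences suffice because only their unassignability matters
downstream — no actual phiX genome fragments are used. The default per-base
substitution error rate is 0: the default configuration isolates the
spike-in as the only source of unassignable reads, and sequencing errors
are an explicit opt-in (`error_rate`). All generators are bit-reproducible
given their seed.

What the simulator does **not** model: PCR amplification bias, apoptotic
cell removal, integration-site effects, index hopping, or quality-score
variation (qualities are constant). Passing tests therefore demonstrate
correctness of the analysis under a clean NB generative model, not
robustness to those artefacts.

## Quantification

Reads are assigned by Hamming matching of the barcode window (fixed offset,
default 10) against one pool's barcodes, with `max_mismatches` 0 or 1.
Mismatch-1 mode is only permitted when the pool passes the pairwise
distance ≥ 3 check, and is implemented by a precomputed distance-≤1
neighbourhood table in which any variant reachable from two barcodes is
marked ambiguous and never assigned; ambiguous reads are discarded, never
fractionally assigned, keeping counts integral. An offset-scan mode (try
every offset, demand a single distinct barcode hit) handles reads with
unknown barcode position. Each sample column records `unassigned` and
`total_reads`, and the conservation invariant
`sum(assigned) + unassigned = total` is asserted at construction of every
count object.

## Differential representation

Counts are normalized to CPM ($10^6 \times$ column proportion). Fold change
is pseudocount-stabilized,
$\log_2\frac{\overline{\mathrm{CPM}}_\text{trt} + c}{\overline{\mathrm{CPM}}_\text{ref} + c}$
with $c = 0.5$ CPM, bounding fold changes for zero counts.

**Dispersion.** Counts are scaled to the geometric-mean library size; per
shRNA, a method-of-moments estimate $(v - m)/m^2$ is pooled across arms by
degrees of freedom, then shrunk toward the common (all-shRNA mean)
dispersion with a prior weight of 10 pseudo-degrees of freedom and floored
at $10^{-8}$. With 3 + 3 replicates a raw estimate has only 4 df, so the
shrinkage dominates unless the data argue otherwise; under a constant-$\phi$
simulation the common value is accurate and the moderation is nearly free.
With one replicate per arm the per-shRNA estimate does not exist and the
common dispersion (computed across arms, which conservatively absorbs
treatment effects) is used with a warning.

**The exact test.** For each shRNA the size-adjusted counts are summed per
arm and rounded, giving $(s_1, s_2)$ with total $t$. Under the null of
equal proportional representation, $S_1 \mid S_1 + S_2 = t$ follows the
conditional law of two independent NB variables with sizes $n_1/\phi$ and
$n_2/\phi$ and common per-replicate mean — a negative hypergeometric with
masses $\propto \binom{k + n_1/\phi - 1}{k}\binom{t-k+n_2/\phi-1}{t-k}$.
The two-sided p-value is the total mass of all splits whose probability
does not exceed the observed split's (mass-ordering). For $\phi < 10^{-6}$
the Poisson limit is used and the conditional law is binomial — this also
sidesteps the precision loss of `lgamma` differences at huge shape
parameters. Identical counts in both arms give $p = 1$; all-zero shRNAs are
flagged and given $p = 1$, $\log_2\mathrm{FC} = 0$.

The test is implemented in-package rather than delegated: exact
conditioning makes small-count behaviour testable against independent
oracles (a product-mass enumeration using `dnbinom`, a rejection-sampling
Monte-Carlo of the conditional law, and edgeR's exact test with the
`smallp` rejection region as an external cross-check). Under a null
simulation at the screen's scale (2,000 shRNAs, 3 vs 3, depth
$5\times10^6$, $\phi = 0.1$) the observed size is ≈ 0.05–0.06.

**Multiplicity.** BH adjustment is applied *within each pool*: each pool is
its own experiment with its own 3 + 3 specimens, so pools are the
experimental units. "Enriched" means FDR < 0.05 with positive fold change;
"depleted", FDR < 0.05 with negative fold change, with no magnitude
requirement for depletion.

## Gene-level hit calling

A gene is a hit iff **all** of: (i) at least `min_enriched` (default 2)
member shRNAs enriched; (ii) those enriched shRNAs occupy at least
`min_enriched` distinct pools; (iii) the strongest enriched member has
$\log_2\mathrm{FC} \ge 1$ (read as log base 2, i.e. enriched more than
two-fold, applied as ≥); (iv) no member shRNA is significantly depleted.
Every violated rule is reported, not only the first; genes with fewer than
`min_enriched` library constructs are flagged `insufficient_constructs`.

One property of this rule is worth knowing: raising the FDR threshold is
**not** a pure relaxation while the depletion veto is active, because a
looser threshold also admits newly significant depleted shRNAs which can
disqualify a former hit. Monotonicity in the thresholds holds with the veto
disabled, and holds for the fold-change and count thresholds in general;
the test suite asserts exactly that.

Counter-screen subtraction operates on gene-level hit lists (set
difference, sorted for deterministic serialization): genes that are also
hits under a generic lethal pressure are removed as unspecific.

## Over-representation

The final hit list is tested against user-supplied GMT gene sets by the
exact hypergeometric upper tail $P(X \ge k)$, with set members intersected
with the universe first; the universe defaults to all genes in the library
design — the gene space the screen actually interrogated. BH is applied
across all supplied terms (no ontology-hierarchy correction), significant
at FDR < 0.1. Because some established annotation services score
over-representation with an EASE-adjusted statistic (the tail computed on
$k - 1$), that variant is available behind `ease = TRUE`; the standard tail
is the default since no published variant is universally specified. A small
synthetic gene-set fixture ships in `inst/extdata/`.

## Numerical and degenerate-input choices

* Dispersion floor $10^{-8}$; Poisson/binomial branch below $\phi = 10^{-6}$.
* Mass-ordering ties at the observed split's probability are included using
  a $1 + 10^{-10}$ relative tolerance, so exact ties count as "as extreme".
* Zero-depth simulations yield all-zero counts; empty count vectors emit
  valid empty FASTQ; zero-sum CPM columns are an error naming the sample.
* Sample order after merging is canonical (condition, replicate, id), so
  results are invariant to input order.
* All randomness is seeded; pipeline sub-stages derive fixed offsets from
  the run seed, and identical config + seed reproduces byte-identical
  tables.

## Problem sizes used by the shipped checks

The test suite exercises the full-scale library design (95,700 constructs)
but runs the statistical simulations at reduced, statistically adequate
sizes chosen once: the null-size check at 2,000 shRNAs × 3 vs 3 at depth
$5\times10^6$; power monotonicity at 500 shRNAs with 40 planted; end-to-end
recovery on a 120-gene, 5-pool screen at ~5,000 reads per shRNA over 10
seeds; the unassignable-read fraction on a single >100,000-read sample.
The acceptance script mirrors the last of these.

## Known limitations

* The exact test conditions on *rounded* size-adjusted totals; with very
  unequal library sizes the rounding perturbs small counts (the same
  compromise as classic exact-test equalization).
* The moderated dispersion assumes exchangeable shRNAs; strong
  mean-dispersion trends are not modelled (no trended fit).
* Quantification assumes one barcode per read at a known (or scannable)
  offset; indels are not tolerated, only substitutions.
* The simulator's spike-in is unassignable by construction (random
  sequences); collision with a real barcode at length 22 has probability
  $\approx 4^{-22} \cdot 3L$ per read and is ignored.
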