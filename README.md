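# coexmod

Stage-resolved weighted gene co-expression network analysis for bulk
RNA-seq time courses — the setting where each library is a single
individual (an embryo sampled on consecutive days of development), samples
are few and biologically heterogeneous, and the question is which groups of
genes move together across stages, which traits they track, and whether any
apparent module is really an unrecorded covariate such as sex.

## What it computes

Given a genes × samples count matrix with gene lengths and sample metadata
(day, replicate, clade), `coexmod` builds a **signed-hybrid weighted
co-expression network** and dissects it:

- **Filtering & normalization** — library-size-aware CPM abundance filter
  (≥ 5 counts at median depth), variance filter, TMM normalization,
  `log2(CPM + 0.5)` expression values; plus RPKM binning
  (>0–5 / >5–50 / >50), stage-core gene sets, and assembly-completeness
  arithmetic.
- **Network** — biweight midcorrelation with side-specific outlier capping
  (`maxPOutliers = 0.1`); soft power β chosen by the scale-free topology
  criterion (signed R² target 0.85) with a sample-size guideline fallback;
  adjacency `a_ij = cor_ij^β · 1(cor_ij > 0)`; topological overlap
  `TOM_ij = (Σ_u a_iu a_uj + a_ij)/(min(k_i,k_j) + 1 − a_ij)`.
- **Modules** — average-linkage clustering of `1 − TOM`, dynamic branch
  cut (height-profile variant, minimum module size 50), eigengene merging
  at correlation 0.9, module–trait correlation with BH control, hub genes
  (kME > 0.9, p < 10⁻⁶).
- **Hidden covariates** — exhaustive scan of all `2^(n−1) − 1` sample
  bipartitions (16,383 at n = 15) against module eigengenes, Bonferroni
  corrected.
- **Sample structure** — complete-linkage clustering on correlation
  distance with multiscale bootstrap support (BP and AU values), classical
  MDS.
- **Enrichment** — hypergeometric over-representation with BH control,
  Wallenius noncentral test with isotonic length-bias weights, GOSlim-style
  rollups.
- **Synthetic data** — a negative-binomial simulator that plants modules
  with stage-shaped eigengene trajectories and a hidden sex-like binary
  covariate, so every claim above is testable without external data.

Results are tibbles (or carry `tidy()`/`glance()` methods) and the main
result types have `autoplot()` methods; everything chains with the pipe.

## Worked example

A full synthetic run: 2,300 genes (three planted 100-gene modules with
early-high, late-high and mid-switch trajectories plus 2,000 flat
background genes) across 15 single-embryo libraries covering days 1–9.

```r
library(coexmod)
library(dplyr)

run <- run_pipeline(coex_config(seed = 1, sim = sim_config(seed = 1),
                                boot_b = 200))
run
#> <coex_run>
#>   genes: 2300 -> 2300 (abundance) -> 273 (variance)
#>   beta = 9; modules: 3 -> 3 after merging; 208 hub genes
```

The variance filter strips the flat background (2,300 → 273 genes); the
scale-free criterion finds no trustworthy crossing on three-block data and
falls back to the guideline power β = 9; the dynamic cut then recovers
exactly the three planted modules. The module–trait table shows which
modules track the developmental axis:

```r
tidy(run$module_trait) |> filter(fdr < 0.05) |> arrange(p)
#> # A tibble: 4 × 6
#>   module trait      r           p         fdr     n
#>   <chr>  <chr>  <dbl>       <dbl>       <dbl> <int>
#> 1 ME3    day    0.944 0.000000130 0.000000389    15
#> 2 ME1    day   -0.898 0.00000547  0.00000820     15
#> 3 ME3    clade  0.880 0.0000149   0.0000448      15
#> 4 ME1    clade -0.802 0.000323    0.000485       15
```

ME3 (the late-rising module) climbs with day (r = 0.94); ME1 (the
early-high module) falls (r = −0.90); both also track the early/late clade
split. The bipartition scan reports, per module, the best of all 16,383
two-group splits with a Bonferroni-adjusted p-value (multiplier
16,383 × 3 = 49,149 here) — on this run the two day-linked modules flag
the early/late boundary split, and when a `covariate_linked` module is
planted its best split recovers the hidden labeling exactly. Against the
planted truth:

```r
truth <- run$truth$module[rownames(run$expr$values)]
adjusted_rand_index(truth, run$modules$labels)
#> [1] 0.887
```

Small self-contained computations work standalone, e.g. the completeness
summary used for assembly QC tallies:

```r
completeness_summary(complete = 235, partial = 10, missing = 3)$recovered_pct
#> [1] 98.79
```

See `vignette("coexpression-methods")` for the models, parameter
rationales, and limitations, and `inst/scripts/coexmod-run.R` for a thin
command-line wrapper around `run_pipeline()` driven by a YAML config.

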