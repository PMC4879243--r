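# islandmark

Window-based ChIP-seq island calling with dual controls, genome feature
annotation, tag-density metaprofiles, interval-overlap accounting, and
integration with WT/knockout expression into a direct-target gene list —
plus a synthetic-data generator with planted truth so the whole chain is
testable without any sequencing downloads.

## Who this is for

Analysts studying a DNA-binding factor (or histone mark) profiled by
ChIP-seq in a wild-type and a knockout background, who want to go from
mapped tag positions to:

1. significant enriched **islands** called against one or two control
   samples (input DNA and/or the knockout ChIP),
2. where those islands fall (promoter / exon / intron / intergenic, CpG
   islands, another mark's islands),
3. average binding **profiles** around TSSs, CpG-island centres and along
   scaled gene bodies, and
4. a **direct-target** gene list: genes both bound within their extended
   gene body (10 kb upstream of the TSS plus the gene span) and changed at
   least twofold between WT and knockout.

## The model in brief

Tags (5' positions of uniquely mapped reads) are summarized in `w = 200` bp
windows. Under the background, window counts are Poisson with mean
λ = *Tw/L* (*T* tags, genome length *L*). Windows with
P(X ≥ count) < *p₀* = 0.2 are eligible; eligible windows at most
`g = 200` bp apart merge into candidate islands scored by
Σ −ln P(X ≥ cᵢ; λ). Each island's ChIP count is then tested against a
Poisson mean derived from each control — the depth-scaled control count,
floored at the genome-wide background expectation for the island's length —
with Benjamini–Hochberg correction across islands and an island FDR of
10⁻⁵. With two controls an island must pass against both. Expression
integration classifies genes by log2(KO/WT) at a twofold threshold and
intersects with binding. Details, defaults and design rationale are in the
methods vignette (`vignettes/islandmark-methods.Rmd`).

## Worked example

Everything below is generated from one seed; no external files.

```r
library(islandmark)

cfg    <- sim_config(seed = 1)          # 2 x 5 Mb, 500 genes, 2e5 tags/sample
genome <- simulate_genome(cfg)          # genes, CpGIs, planted truth
chip   <- simulate_chip_tags(genome, cfg, "treatment", "chip_wt")
ko     <- simulate_chip_tags(genome, cfg, "control",   "chip_ko")
input  <- simulate_chip_tags(genome, cfg, "control",   "input")
chip
#> <tag_set> chip_wt: 208409 tags (50 bp) on 2 chromosome(s)

islands <- call_islands(chip, list(ko, input), caller_params(),
                        genome$chrom_sizes)
nrow(islands)
#> [1] 50
islands[1:3, c("chrom", "start", "end", "score", "n_chip", "q_1", "q_2")]
#> # A tibble: 3 × 7
#>   chrom  start    end score n_chip       q_1       q_2
#>   <chr>  <int>  <int> <dbl>  <int>     <dbl>     <dbl>
#> 1 chr1  159400 160600  289.    206 8.15e-110 6.11e-110
#> 2 chr1  285400 286600  237.    188 5.32e- 94 5.02e- 94
#> 3 chr1  559400 560800  274.    212 3.48e-103 3.22e-103
```

Fifty islands are called; each spans whole 200-bp windows, carries its
additive score, ChIP tag count and a BH q-value per control. Against the
planted truth (50 one-kb intervals at 10-fold enrichment) recovery is
perfect at this seed:

```r
island_recovery_stats(islands, genome$truth$enriched)[c("recall", "precision")]
#> $recall
#> [1] 1
#> $precision
#> [1] 1
```

Feature annotation shows the islands sit at promoters, far above the
genome baseline — the planted configuration:

```r
partition <- build_partition(genome$genes, genome$chrom_sizes)
peak_feature_distribution(islands, partition)
#> # A tibble: 4 × 4
#>   label      peak_count peak_fraction genome_fraction
#>   <chr>           <int>         <dbl>           <dbl>
#> 1 promoter           50             1          0.0955
#> 2 exon                0             0          0.0390
#> 3 intron              0             0          0.506
#> 4 intergenic          0             0          0.360
```

Integration with the simulated WT/KO expression table applies the
direct-target rule (bound within 10 kb upstream + gene body, ≥ twofold
change):

```r
expr <- simulate_expression(genome, cfg)
dt   <- call_direct_targets(islands, genome$genes, expr, genome$chrom_sizes)
dt$summary
#> # A tibble: 1 × 6
#>   n_genes n_bound n_bound_and_changed n_down  n_up fraction_down
#>     <int>   <int>               <int>  <int> <int>         <dbl>
#> 1     500      77                  41     34     7         0.829
```

Of 500 genes, 77 are bound, 41 of those change at least twofold, and 83%
of the changed ones go down — recovering the planted 85%-down truth within
sampling noise.

`run_pipeline(default_run_config("out", seed = 1))` runs all stages at
once and writes BED/TSV outputs plus an MD5-checksummed manifest;
`report_summary("out")` tabulates a finished run. A thin command-line
wrapper with per-stage subcommands lives at `inst/cli/islandmark.R`.

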