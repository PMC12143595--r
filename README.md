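# chromlayers

Layered multi-omics classification of transcription-factor binding sites.

## What this package is for

A pioneer transcription factor binds thousands of sites in the genome, but
its regulatory output differs wildly between them: some sites sit in
already-open chromatin, some become accessible only upon activation, some
gain enhancer histone marks without ever opening, and only a minority drive
new transcription. `chromlayers` is for analysts who have (or want to
prototype against) condition-contrasted data at a fixed set of binding
sites — accessibility fragments (ATAC-type), histone-mark fragments
(CUT&Tag-type), 5′-end transcription-start reads (CAGE-type), a
binding-signal library, a chromatin-state segmentation and RE annotations —
and want the site-level picture assembled into classification layers:

* **accessibility transition** between control and treated
  (`constitutively_open` / `opened` / `constitutively_closed` /
  `putatively_closed`),
* **collapsed chromatin state** (promoter / enhancer / transcription /
  quiescent, from an 18-state segmentation),
* **TSS status** (`induced` / `uninduced` / `none`, induced meaning an
  overlapping TSS with log2FC > 0.5),
* **response-element class** (canonical / noncanonical / none).

Around the classification sit the quantitative pieces:

* a **negative-binomial differential test** for region counts with
  median-of-ratios normalization, method-of-moments dispersion shrunk
  toward the across-region median, a Wald statistic on
  `log2FC = log2((μ_t + ½)/(μ_c + ½))`, and Benjamini–Hochberg FDR;
  classification at `|log2FC| > 1`, `FDR < 0.1`;
* **nucleosome profiling** from mono-nucleosome (180–240 bp) fragments:
  anchored mean-occupancy profiles and an eviction score (mean occupancy
  change within ±73 bp of the RE) plus a flank cross-correlation shift lag;
* **CTSS density** around canonical RE centers: per-region normalized
  density over ±200 bp (regions with < 5 reads dropped), averaged per
  condition and chromatin state, with mode detection — the structure of
  interest being initiation both *at* the RE and ~50 bp from it;
* an **occupancy→transcription response model**
  `y = a + (b − a)/(1 + exp(−(log10 x − x0)/k))` whose midpoint `x0`
  estimates the binding-occupancy threshold for productive transcription;
* **enhancer–gene linking** through provided association pairs with a
  2.5 kb promoter-proximal distance filter and joint TSS/gene significance
  thresholds (TSS log2FC > 1 & FDR < 0.1; gene log2FC > 0.5 & FDR < 0.05).

A ground-truthed simulator (`simulate_multiome`) generates every input the
pipeline consumes — including the two ATAC fragment-size classes, positioned
nucleosomes, a TSS-offset mixture at {0, +50} bp, negative-binomial
replicate noise and wired enhancer–gene pairs — so the whole analysis runs
and is tested without any external download. See the methods vignette
(`vignettes/chromlayers-methods.Rmd`) for the models, defaults and
limitations.

## Worked example

```r
library(chromlayers)

cfg <- sim_config(seed = 11)          # 500 sites, 4+4 replicates, 1e5 frags/library
sim <- simulate_multiome(cfg)
data_dir <- file.path(tempdir(), "demo_data")
write_dataset(sim, data_dir)

res <- run_pipeline(pipeline_config(data_dir, file.path(tempdir(), "demo_out"),
                                    seed = 11))

res$summary_layers$axis$accessibility
#>                    level count fraction percent
#> 1: constitutively_closed   218    0.436      44
#> 2:   constitutively_open   141    0.282      28
#> 3:                opened   140    0.280      28
#> 4:     putatively_closed     1    0.002       0

res$sigmoid
#> occupancy_fit: a=-0.966 b=2.07 x0=2.68 k=0.0757 | r2=0.687 rho=0.768 (p=1.73e-98) n=500

res$density$modes
#> [1]  0 50
res$nucleosome$scores$opened$eviction
#> [1] 1.694
head(res$links$candidates)
#> [1] "gene_002" "gene_003" "gene_004" "gene_005" "gene_006" "gene_007"
```

Reading the output: 28% of simulated sites were open before treatment and a
further 28% opened upon it (this run's generator draw); the occupancy→
transcription relation is strongly monotone (Spearman ρ = 0.77) and
sigmoid-shaped (r² = 0.69); transcription initiation concentrates at the RE
center (0 bp) and ~50 bp from it; opened sites lose nucleosome occupancy at
the RE under treatment (positive eviction score); and the linking stage
returns the genes wired to induced, bound enhancers. Per-site labels land
in `site_layers.tsv`, profiles and links in their own TSV files, and a
summary JSON plus run manifest in the output directory. A thin CLI over the
same functions is installed at `exec/chromlayers` inside the package
(subcommands `simulate`, `run`, `count`, `diff`, `layers`, `nucprofile`,
`ctssdensity`, `link`).

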