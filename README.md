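# refugia

Spatial population genomics of post-glacial range expansion.

Species that rode out the last glacial maximum (LGM) in a restricted
refugium and then recolonised their range leave a predictable footprint in
their genomes: heterozygosity declines with distance from the refuge,
runs of homozygosity (ROH) from serial founder events accumulate toward
the expansion front, restricted dispersal produces isolation by distance
(IBD), and drift at the front reshapes the frequency spectrum of
deleterious variants. `refugia` implements this analysis chain for diploid
genotype data, end to end, for researchers working on phylogeography,
landscape genomics and conservation genetics:

* **genio** — VCF/CSV/ASCII-grid I/O, the genotype–variant–sample data
  model, MAF filtering and PLINK-style (`indep-pairwise 50 10 0.2`) LD
  pruning;
* **diversity** — per-individual heterozygosity, windowed ROH detection,
  the 5 kb–1 Mb ROH band, and tract age dating via `g = 100 / (2 L_cM)`;
* **load** — derived-allele genetic load: `Pn/(Pn+Ps)`,
  `(Pn·f̄n)/(Ps·f̄s)`, and loss-of-function allele dosage, per individual
  or per population;
* **differentiation** — Weir–Cockerham (1984) FST, `FST/(1−FST)`
  linearization, great-circle distances, and a seeded permutation Mantel
  test (`ibd_test()` runs the whole IBD analysis);
* **spatial** — empirical variograms, weighted-least-squares variogram
  fitting, ordinary kriging onto a lon/lat grid, refuge-centre extraction
  from a binary presence raster (e.g. an LGM ecological-niche-model
  output), and distance-gradient correlation tests with
  Benjamini–Hochberg FDR;
* **simdata** — a forward-in-time serial-founder expansion simulator
  (Rcpp) whose haplotypes are founder-interval mosaics seeded with
  standing ancestral variation, emitting VCF + sample CSV + presence
  rasters with the statistical structure the analysis assumes;
* **pipeline** — `run_pipeline()` drives every stage from one YAML/JSON
  config with a global seed and writes CSVs, rasters and a JSON manifest.

## Worked example

Simulate an expansion out of a north-eastern refuge on an 8 × 8 deme grid
(100 diploids per deme, 5 founders per colonization, migration 0.01) and
run the analysis:

```r
library(refugia)

sim <- simulate_expansion(sim_config(seed = 1))
sim
#> Serial-founder range-expansion simulation
#>   grid 8 x 8, origin (1, 8), N = 100, K = 5, m = 0.01
#>   128 sampled individuals, 13767 segregating sites, 570 generations

gs     <- sim$data
center <- refuge_center(sim$presence_lgm)   # (95 E, 36 N): the refuge deme

het  <- heterozygosity(gs)
roh  <- roh_summary(detect_roh(gs), ids = gs$samples$sample_id)
load <- individual_load(gs)

stats_df <- data.frame(heterozygosity = het, roh_count = roh$roh_count,
                       ratio_ns = load$ratio_ns,
                       freq_ratio = load$freq_ratio,
                       lof_dosage = load$lof_dosage)
gradient_table(stats_df, gs$samples$lon, gs$samples$lat, center)
#>       statistic       r        p       q   n
#>  heterozygosity -0.2714 0.001947 0.00487 128
#>       roh_count  0.3179 0.000255 0.00128 128
#>        ratio_ns -0.1692 0.056187 0.07023 128
#>      freq_ratio -0.1730 0.050847 0.07023 128
#>      lof_dosage -0.0801 0.368633 0.36863 128

ibd <- ibd_test(gs, seed = 1)
sprintf("Mantel r = %.3f, p = %.4f (%d sites, %d LD-pruned SNPs)",
        ibd$r, ibd$p, ibd$n_sites, ibd$n_snps_used)
#> "Mantel r = 0.496, p = 0.0001 (64 sites, 441 LD-pruned SNPs)"
```

Heterozygosity falls (r = −0.27, q = 0.005) and the 5 kb–1 Mb ROH count
rises (r = +0.32, q = 0.001) with distance from the refuge centre — the
founder-effect gradient — and the low-migration expansion shows strong
isolation by distance. Re-running with `migration = 0.25` erases the IBD
signal while the diversity gradient persists, the classic contrast between
dispersal-limited and vagile co-distributed species. Kriging
(`fit_variogram()` + `ordinary_krige()`) interpolates any of these
per-individual statistics onto a map; `write_sim_outputs()` round-trips
everything through standard formats.

The same analysis runs from files (VCF with `AA`/`CLASS` INFO tags, sample
CSV, presence raster) through `run_pipeline()`:

```r
run_pipeline(system.file("extdata", "demo_config.yaml", package = "refugia"),
             output_dir = "demo_out")
```

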