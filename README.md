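# msatpop

Population-genetic analysis of codominant diploid **microsatellite**
genotypes scored from gel band sizes — the workhorse data of livestock
diversity and conservation surveys. The package is aimed at researchers
characterising breed structure from SSR markers: it takes a genotype table
(CSV or GenePop), or raw band migrations plus a DNA ladder, and produces
the standard battery of breed-level statistics, differentiation analyses,
neutrality tests and per-locus dendrograms — plus a seeded simulator so
every stage can be validated without access to unpublished raw data.

What it computes:

* **Diversity per breed × locus** — observed/effective allele counts
  (N<sub>o</sub>, N<sub>e</sub> = 1/Σp²), observed/expected heterozygosity
  (H<sub>o</sub>, H<sub>e</sub> = 1 − Σp², Nei-corrected by default),
  Botstein's PIC, and the inbreeding coefficient F = 1 − H<sub>o</sub>/H<sub>e</sub>,
  with mean ± SE breed summaries.
* **Hierarchical F-statistics per locus** — Nei's gene-diversity
  decomposition H<sub>I</sub>, H<sub>S</sub>, H<sub>T</sub> giving
  F<sub>IS</sub> = 1 − H<sub>I</sub>/H<sub>S</sub>,
  F<sub>ST</sub> = 1 − H<sub>S</sub>/H<sub>T</sub>,
  F<sub>IT</sub> = 1 − H<sub>I</sub>/H<sub>T</sub> (Wright's identity
  (1−F<sub>IS</sub>)(1−F<sub>ST</sub>) = (1−F<sub>IT</sub>) holds exactly),
  and island-model gene flow N<sub>m</sub> = (1−F<sub>ST</sub>)/(4F<sub>ST</sub>).
  A Weir–Cockerham estimator is available for sensitivity.
* **Ewens–Watterson neutrality** — the deviate
  D = (E[F<sub>null</sub>] − Σp̂²)/sd[F<sub>null</sub>] against the Ewens
  sampling formula conditioned on sample size and allele count, via exact
  closed-form moments, full partition enumeration, or seeded Monte Carlo.
* **Per-locus trees** — UPGMA dendrograms from Nei's standard distance
  (breed level) or Dice band sharing (individual level), written as Newick.
* **Gel sizing** — log-linear ladder calibration with R² QC, allele
  binning, and one-band/two-band genotype calling.
* **Simulation** — Balding–Nichols genotypes at a target F<sub>ST</sub>
  and F<sub>IS</sub> (defaulting to a seven-breed, 14-locus survey design
  with F<sub>ST</sub> = 0.22), and synthetic band tables with ladder.

Everything is tibble-in/tibble-out and pipe-friendly; fitted objects have
`tidy()`/`glance()` methods and result types have `autoplot()`/`plot_*()`
companions. See `vignette("msatpop-methods")` for the models, estimator
choices and their assumptions.

## Worked example

Simulate the default seven-breed design and run the full analysis:

```r
library(msatpop)

geno <- simulate_genotypes(seed = 42)   # 526 rabbits, 7 breeds, 14 loci

diversity_summary(geno) |>
  dplyr::select(population, No_mean, Ne_mean, Ho_mean, He_mean, PIC_mean, F_mean)
#>   population No_mean Ne_mean Ho_mean He_mean PIC_mean   F_mean
#> 1 AR            4.14    2.33   0.516   0.501    0.448 -0.0328
#> 2 BB            4.29    2.31   0.506   0.516    0.458  0.0137
#> 3 CH            4.36    2.33   0.517   0.505    0.455 -0.00585
#> 4 JAB           4.21    2.48   0.498   0.498    0.453 -0.00104
#> 5 NZW           4.43    2.29   0.488   0.504    0.449  0.0216
#> 6 RB            3.93    2.40   0.535   0.537    0.474 -0.00656
#> 7 WB            4.07    2.63   0.592   0.551    0.494 -0.0775
```

Each row summarises one breed over its 14 loci (mean over loci; `_se`
columns, not shown, give the n−1-over-√loci standard errors). `F_mean`
near zero says genotype frequencies sit close to Hardy–Weinberg within
breeds — as simulated, since `fis = 0`.

```r
ft <- fstats_table(geno)
ft$summary
#>   statistic    mean      se n_loci
#> 1 FIS       -0.0102 0.00941     14
#> 2 FIT        0.175  0.0213      14
#> 3 FST        0.184  0.0187      14
#> 4 Nm         1.62   0.507       14
```

Mean F<sub>ST</sub> ≈ 0.18 recovers the simulated differentiation (target
0.22 deflates by the weighted-mean factor ≈ 0.83 inherent to
frequency-decomposition estimators at seven finite populations; the
methods vignette derives this), labelling the breeds as highly
differentiated (> 0.15) with on the order of 1–2 effective migrants per
generation between them.

```r
neutrality_table(neutrality_test(geno))$summary
#>   population  mean    se n_defined
#> 1 AR         0.528 0.247        14
#> ...

write_newick(locus_tree(geno, "L01"))
#> (WB:0.2639509359,(AR:0.05226497787,((BB:0.001023486768,JAB:0.001023486768):...
```

Positive breed-mean deviates reflect the even, allele-rich spectra the
neutral Balding–Nichols model produces; real surveys show negative means
in breeds that drifted through small flocks. `run_msat_pipeline(geno,
"out/", seed = 1, tree_loci = "L01")` writes all of the above as TSVs
(undefined cells as `-`) plus Newick files, with a `# key=value`
provenance header; reruns are byte-identical.

The package also ships reported reference statistics from a seven-breed
rabbit survey (`reported_rabbit_stats()`) used by the test suite for
internal-consistency validation — e.g. `gene_flow()` reproduces the
reported N<sub>m</sub> column from the reported F<sub>ST</sub> values at
three decimals, 13 of 13.

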