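# hapdemog

Population-genetic and spatial-statistical analysis of two-marker
phylogeography surveys: maternally inherited plastid sequence data analysed
for haplotype structure, molecular diversity and demographic history, and a
nuclear dominant-marker (AFLP) panel analysed for multivariate structure and
its geographic and bioclimatic correlates. The package is aimed at plant
phylogeographers working with systems like a Eurasian perennial crucifer
whose range spans an old, diverse Caucasus/Irano-Turanian gene pool and a
younger derived European one — settings where the questions are: how many
plastid haplotypes are there and how are they related, when did each gene
pool expand, and how much of the nuclear genetic structure is explained by
ancestry, space and climate?

## What it computes

* **Haplotypes** — alignment reading, masking of homopolymer length
  variation (slippage noise in poly-A/T/G runs), collapsing to haplotypes
  with deterministic `H1…` naming, and per-region frequency tables.
* **Diversity** — segregating sites `S`, Nei's unbiased haplotype diversity
  `Hd = n/(n−1)(1 − Σp²)`, nucleotide diversity `π` (per site; printed as
  percent) and `k̄`, and Tajima's
  `D = (k̄ − S/a₁)/√(e₁S + e₂S(S−1))`, undefined at `S = 0`.
* **Networks** — statistical-parsimony haplotype networks with a 95%
  connection limit; links beyond the limit split gene pools into separate
  components; multi-step links gain inferred intermediate nodes.
* **Demography** — the mismatch distribution under the sudden (stepwise)
  expansion model
  `F_i = F̂_i(θ₁) + e^{−τ(θ₁+1)/θ₁} Σ_l τ^l/l! (F̂_{i−l}(θ₀) − F̂_{i−l}(θ₁))`,
  fitted by least squares (SSD); goodness of fit (SSD, Harpending's
  raggedness) and CIs for `τ` by parametric bootstrap over a coalescent
  simulator with one instantaneous size change; conversion of `τ` to
  calendar time via `T = τ/2u`, `u = μkg`.
* **AFLP QC and ordination** — replicate genotyping error rate,
  Brown–Forsythe homogeneity-of-variance screening of fragment counts,
  `μ ± 2σ` fragment-count filtering against post-2002 reference material,
  Euclidean distances, PCoA with broken-stick assessment, per-region band
  statistics, one-level AMOVA (`Φ_ST` by permutation), and Evanno ΔK
  post-processing of clustering log-likelihoods.
* **Partial RDA** — genotype axes against nine orthogonalised degree-3
  spatial polynomials and climate covariates with the gene pool as a
  conditioning term; permutation tests (residuals of the reduced model),
  gated forward selection at α = 0.01, VIF, per-axis tests, and an exact
  conditional/constrained/residual variance partition.
* **Synthetic data** — generators for coalescent sequence sets with two
  planted gene pools, AFLP matrices with replicate noise and herbarium-style
  degradation, and landscapes with an exactly planted RDA variance
  partition; these drive every test.

## Worked example

Simulate a study-scale two-pool dataset, collapse haplotypes, summarise
diversity and run the mismatch analysis for the refuge-area group:

```r
library(hapdemog)

spec <- synthetic_spec(42)
sq   <- make_sequence_dataset(spec)
aln  <- mask_homopolymer_variation(sq$alignment)
hset <- collapse_haplotypes(aln)

group_summary(aln, hset, "region")
#>                     group  n   S  h    Hd pi_percent     D
#> 1 Caucasus-Irano-Turanian 25 136 25 1.000     0.9334 -2.41
#> 2                  Europe 52  71 38 0.931     0.1831 -2.88
#> 3             Scandinavia 41  16 13 0.505     0.0548 -2.49
#> 4           North America 19  16 14 0.912     0.1114 -2.38

cit <- subset_alignment(aln,
         aln$meta$sample_id[aln$meta$region == "Caucasus-Irano-Turanian"])
fit <- mismatch_analysis(cit, rate_model(), B = 1000, seed = 1)
fit
#> sudden-expansion fit: tau=10.85 theta0=3.436 theta1=281.4 SSD=0.001499 HRag=0.003467
#>   bootstrap: p(SSD)=0.922 p(HRag)=0.977 tau 95% CI [8.29, 20.8]
```

Each diversity row reads as one published-style table row: the refuge-area
group is the most diverse (every sequence its own haplotype at these
simulation settings, π ≈ 0.93% per site), the recently colonised regions
the least; the strongly negative `D` values reflect the simulated
expansions. The mismatch fit recovers the generating `τ = 11.34` within its
bootstrap CI; `p(SSD) = 0.92` means the sudden-expansion model is not
rejected. Converting with the calibrated rate
(`μ = 2.004e-9`, `k = 1512`, `g = 2`):

```r
expansion_time(fit$tau, rate_model()) / 1e6
#> [1] 0.8949...   # My since expansion began
```

`run_pipeline(pipeline_config(...))` chains the stages (haplotypes →
diversity → network → mismatch → optional AFLP) with per-stage seeds, TSV
outputs and a checksummed JSON manifest.

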