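---
title: "Haplotype networks, mismatch demography and spatial genetic structure with hapdemog"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haplotype networks, mismatch demography and spatial genetic structure with hapdemog}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hapdemog)
```

# Scope

`hapdemog` implements the statistical chain of a classic two-marker-system
phylogeography study: maternally inherited plastid sequences analysed for
haplotype structure, diversity and demographic history, and a nuclear
dominant-marker (AFLP) panel analysed for multivariate structure and its
geographic/bioclimatic correlates. The motivating system is a Eurasian
perennial crucifer with two deeply diverged plastid gene pools — an old,
diverse refuge-area pool in the Caucasus/Irano-Turanian region and a younger
derived European pool — whose recent range expansion makes the demographic
and spatial questions interesting. Everything downstream of raw marker
scoring is covered; alignment, peak calling and Bayesian divergence dating
are upstream inputs.

Because raw study data are not bundled, a first-class synthetic-data module
generates every input the chain consumes, with known truth, at the study's
scale. All tests and the acceptance script run on these generators.

# Plastid haplotypes

## Homopolymer masking

Plastid mononucleotide runs (poly-A/T/G/C) gain and lose repeat units by
replication slippage at rates orders of magnitude above the substitution
rate, so run-length differences carry no phylogeographic signal. A variable
alignment column is excluded when its non-missing states are exactly one
base plus the gap character *and* the column sits, in at least one sequence,
inside a run of that base of length at least `min_run`. Substitutions inside
runs (two different bases) are always kept: the masking rule targets indel
scoring, not SNPs. The run-length threshold is not dictated by the biology —
slippage accelerates with run length, and three is the shortest run for
which slippage is commonly reported — so `min_run = 3` is the default and
the parameter is exposed. Masking is a pure function of the sequences and
therefore idempotent.

## Collapsing and naming

Sequences identical over unmasked sites form a haplotype; ids are assigned
`H1, H2, ...` in order of first appearance in the input, which makes the
labelling reproducible run to run. Missing bases (`N`) are handled by a
unique-compatibility rule: a sequence with `N`s joins an existing haplotype
only if it is compatible with exactly one; multi-way compatibility is
ambiguous, triggers a warning, and the sequence founds its own haplotype
(the conservative choice — it can split a true haplotype but never merges
two distinct ones).

# Diversity statistics

Per group the package reports sample size `n`, segregating sites `S`,
haplotype count `h`, Nei's unbiased haplotype diversity
`Hd = n/(n-1) (1 - sum p_i^2)`, nucleotide diversity and Tajima's `D`.
Two conventions deserve explicit statement:

* **Units of nucleotide diversity.** `pi` is stored as a per-site fraction;
  the table writer prints `100 * pi` (percent per site), the convention
  under which published regional tables of this kind are mutually consistent
  with their printed `D` values. `k_bar` (mean pairwise differences per
  sequence) is reported alongside; for complete alignments
  `k_bar = pi * L`.
* **Missing data.** Pairs are compared over their mutually scored unmasked
  sites (pairwise deletion), with per-pair length normalisation for `pi`.
  This follows the practice of retaining accessions with partial sequence
  rather than dropping columns globally.

Tajima's `D` uses the standard coefficients
(`a1 = sum 1/i`, ..., `e2 = c2/(a1^2+a2)`) and is undefined — reported as
`NA`, printed as an em dash — when `S = 0`; zero would wrongly suggest a
neutral-equilibrium result. Reproducing published `D` values from printed
`(n, S, pi)` is limited by the 3-decimal rounding of `pi`; an error of
0.0005 in `pi` percent moves `D` by up to about 0.02, which is the tolerance
the tests use.

# Statistical-parsimony networks

Haplotype pairs are linked in increasing order of mutational distance.
Links longer than the 95% connection limit are refused, which is what splits
deeply diverged gene pools into separate network components. Within a
distance class, all links that joined distinct components at the start of
the class are retained, so equal-distance alternatives appear as
reticulations rather than being resolved arbitrarily; ties are ordered by
combined haplotype frequency and then lexicographically, making the output
independent of input order. A k-step link is materialised with k-1 inferred
intermediate nodes.

The connection limit is the largest number of steps `j` at which the
probability that `j` visible differences reflect exactly `j` mutations is
still at least 0.95. The estimator models the true number of mutations
separating a random pair as geometric (the neutral coalescent pairwise
distribution), with its mean estimated from the pair itself by Jukes-Cantor
correction, and models multiple hits by uniform occupancy of sites; the
reported probability is the posterior `P(mutations = j | j visible)`. This
is a from-first-principles construction in the spirit of the classical
statistical-parsimony procedure rather than a line-by-line port of any
particular program; it satisfies the expected limits (`alpha -> 0` gives the
step cap, the limit is non-decreasing in alignment length) and gives 12
steps for a 1512-bp alignment at 95%, a value pinned by a regression test.
The limit is an internal quantity here: published network figures do not
print it, so no external target exists.

# Mismatch-distribution demography

## Model

For a population whose scaled mutation parameter jumped from `theta0` to
`theta1` at `tau` mutational time units in the past, the distribution of
pairwise differences is

```
F_i = Fhat_i(theta1) + exp(-tau (theta1+1)/theta1) *
      sum_{l=0}^{i} tau^l/l! * (Fhat_{i-l}(theta0) - Fhat_{i-l}(theta1))
```

with `Fhat_i(theta) = theta^i/(1+theta)^(i+1)` the equilibrium geometric.
At `tau = 0` this collapses to the equilibrium at `theta0`; for large `tau`
and small `theta0` it approaches a Poisson wave centred at `tau`. Both
limits are exercised in the tests. Observed histograms run over classes
`0..d` (d = largest observed difference); model mass beyond `d` is folded
into the last class by default so the compared vectors are both simplexes
(renormalisation is available by flag).

## Fitting and uncertainty

`(tau, theta0, theta1)` are estimated by minimising the sum of squared
deviations (SSD) between observed and model frequencies, with a
deterministic 3x3x3 grid of starting points feeding a Nelder-Mead search on
square-root-transformed parameters (which enforces nonnegativity without
hard constraint logic); ties are broken by lower SSD, then lower `tau`.
`theta1` is capped at 99999, the conventional stand-in for an effectively
infinite post-expansion size. Refitting frequencies generated by the model
itself recovers the parameters to SSD below 1e-15, the self-consistency
check the test suite pins at 1e-8.

Goodness of fit uses the parametric bootstrap: `B = 1000` coalescent
datasets are simulated at the fitted parameters and sample size, each is
refit, and `p_SSD` (and analogously `p_HRag` for Harpending's raggedness
`r = sum (x_{i+1}-x_i)^2`, trailing zero class included) is the fraction of
simulated statistics at least as large as the observed one. The 2.5% and
97.5% quantiles of the bootstrap `tau` estimates give the confidence
interval. All of this is seeded and bit-reproducible.

The simulator draws a standard coalescent genealogy with one instantaneous
size change on the mutational clock (units chosen so that a pair separated
for time `nu` accumulates `nu` expected differences, i.e. the change sits at
`tau`), Poisson mutations on branches, and infinite-sites placement at
distinct positions. Constant-size runs reproduce `E[k_bar] = theta` and
`E[S] = theta a1` within Monte Carlo error, the oracle the tests check at
`theta = 5, n = 20` over 2000 replicates. The fitting and bootstrap loops
are implemented in C++ (Rcpp) since calibration experiments need on the
order of 10^5 simulate-and-refit cycles.

## Time conversion

With `u = mu * k * g` the per-haplotype per-generation mutation rate
(`mu` substitutions/site/year, `k` sites, `g` years/generation), the model
relation is `tau = 2 u T` with `T` in generations. The package's default,
"paper-compatible" conversion reports `T_years = tau / (2 mu k g)`; the
dimensionally strict alternative (`T` generations times `g` years) is
`T_years = tau / (2 mu k)` and is available as `convention = "strict"`.
The two differ by the factor `g`. The default is the convention under which
published expansion times of the motivating system (0.93 and 0.23 My for
`tau` = 11.34 and 2.84 with `mu = 2.004e-9`, `k = 1512`, `g = 2`) are
reproduced; the discrepancy between the stated "time in generations" and
times printed in years is inherited from the source literature, and the
package makes it explicit rather than silently choosing. Similarly, the
calibrated rate for this marker set is quoted in different places as
2.004e-9 and 2.004e-10; only the former reproduces the printed times, so it
is the default and both are accepted via configuration. `rate_from_calibration`
implements the generic `mu = d/(2t)` estimator from a clade pair's
divergence and split age.

# AFLP quality control and ordination

* **Replicate error rate**: mismatching scored loci over mutually scored
  loci, pooled over all replicate pairs. The estimator is unbiased for a
  symmetric per-locus flip probability, which the tests verify by
  simulation at the study-scale rate of about 1%.
* **Degradation screening**: herbarium-derived DNA loses AFLP fragments.
  Homogeneity of variance of per-sample fragment counts between old and
  recent material is tested with the Brown-Forsythe statistic (one-way
  ANOVA on absolute deviations from group medians — the median-centred
  Levene variant, robust to non-normal counts).
* **Fragment-count filter**: mean and SD of fragment counts are estimated
  from the reference material (collected in or after 2003, the boundary
  year the source protocol implies) and samples outside `mu ± 2 sd` are
  removed. The band is two-sided: degradation only loses fragments, but
  scoring artifacts can add them. Removal and re-estimation iterate to a
  fixed point, which makes the filter idempotent — the first iteration is
  the classical single pass, and later iterations act only when removed
  samples had inflated the reference SD.
* **PCoA**: Gower double-centering of `-d^2/2` and eigendecomposition, with
  plain Euclidean distance on 0/1 profiles as the default dissimilarity.
  Negative eigenvalues (possible for non-Euclidean input) are reported but
  excluded from the explained-variance denominator; "positive" means above
  `1e-8` times the leading eigenvalue. Axes are judged against the
  broken-stick expectation `b_k = (1/p) sum_{i=k}^p 1/i`.
* **AMOVA**: one-level variance decomposition from squared distances with
  `Phi_ST` tested by label permutation, `p = (#(perm >= obs)+1)/(B+1)`.
* **Evanno delta-K**: second difference of the clustering log-probability
  across K normalised by the replicate SD. Replicate runs at different K
  are unpaired, so the mean absolute second difference is computed from the
  means; boundary K and zero-variance K are undefined (warned, `NA`).
  The MCMC clustering itself is external — only its log-probability table
  is consumed.

# Partial redundancy analysis

The genotype response (significant PCoA axes) is regressed on spatial and
bioclimatic predictors with the plastid gene pool as a conditioning
variable, separating ancient lineage structure from contemporary spatial
trend. Spatial predictors are the nine degree-3 monomials of Z-standardised
longitude and latitude (`x, y, x^2, xy, y^2, x^3, x^2y, xy^2, y^3`),
orthogonalised sequentially in that fixed order and scaled to unit SD;
degenerate columns are dropped with a warning. Climate covariates are
treated as opaque named columns — no semantics are asserted for them — and
screened for pairwise |r| >= 0.5, a report rather than an automatic drop.

Both response and predictors are residualised on the condition (plus
intercept); the constrained variance is the variance of the fitted values
of that residualised regression, so conditional + constrained + residual
equals the total exactly at machine precision. Significance uses
permutation of residuals under the reduced model (rows of the
condition-residualised response are permuted), the standard scheme for
partial ordination tests; simple row permutation is available by flag.
P-values use `(count+1)/(n_perm+1)`.

Forward selection considers spatial and climate main terms plus all
spatial-by-climate interactions. Each step tests every remaining candidate
conditional on the already-selected terms and the condition, and admits the
largest-F candidate with permutation `p <= alpha` (`alpha = 0.01`,
1000 permutations by default). Before any step runs, an omnibus test of the
full candidate set must itself pass `alpha`: with about fifty candidates,
per-candidate testing alone would admit a spurious term in a large fraction
of null datasets, and the global gate — the usual double-stopping guard in
constrained-ordination model selection — restores the nominal error rate.
The null calibration test demands a spurious selection in at most 5% of 100
no-signal landscapes, and the gate is what makes that attainable.

Variance inflation factors are `1/(1-R^2)` from regressing each selected
term on the others with the condition included; aliased columns report
`Inf`. Per-axis tests are marginal with earlier axes moved into the
conditioning set.

# The synthetic-data module

The generators define the study conditions used throughout the tests:

* **Sequences**: four groups emulating the regional design — refuge-area
  pool (n = 25, `tau` = 11.34), derived European pool (n = 52,
  `tau` = 2.84), and two recently colonised regions (n = 41, 19) drawn from
  the derived pool — over L = 1512 sites, with the two pools separated by
  10 planted fixed differences. Within-group variation is coalescent under
  each group's expansion history; `theta1 = 1000` represents the
  effectively unbounded post-expansion size. Pool labels are embedded in
  the metadata as truth.
* **AFLP**: 404 loci, 134 samples in two pools plus 50 replicate copies.
  Band presence follows the dominant-marker convention
  (`1 - (1-p)^2` under Hardy-Weinberg with Beta-distributed null-allele
  frequencies); replicates flip loci at 0.011, the published error-rate
  scale; samples collected before 2003 lose bands (1 to 0 only, the
  herbarium mechanism) with probability linear in their age before the
  cutoff (0.0015/year by default — chosen to leave a realistic two-thirds
  of samples after filtering; power checks plant a steeper slope
  explicitly).
* **Landscape**: n = 400 samples with uniform coordinates, a binary
  condition, four noise climate columns and a degree-2 spatial surface;
  the response is a sum of sequentially orthogonalised components scaled so
  the planted variance fractions (default 25% condition / 25% spatial /
  50% noise, echoing the structure of the published partition) hold exactly
  in-sample. The degree-2 surface leaves the degree-3 candidate terms as
  true negatives for selection.

What the generators do **not** emulate: marker ascertainment bias, spatial
autocorrelation of sampling and climate (climate columns are independent
noise unless given weight), linked selection, recombination, and
population-level pedigree structure. Passing tests therefore demonstrate
correctness of the statistical machinery under its own model assumptions,
not robustness to the full messiness of field data.

# Problem sizes and numerical choices

Calibration experiments run at: 100 coalescent datasets
(n = 25, L = 1512) with B = 1000 bootstrap replicates each for `tau`
recovery and CI coverage; 200 datasets with B = 199 for goodness-of-fit
calibration; 2000 constant-size replicates for the coalescent oracle; 100
null landscapes (n = 100, 199 permutations) for selection calibration.
These sizes give Monte Carlo error comfortably inside the asserted bands
while keeping a full run on a single core in the low minutes.

Other numerical conventions: optimizer tie-breaks (lowest SSD, then lowest
`tau`); strict-positivity threshold for eigenvalues at `1e-8` of the
leading one; degenerate mismatch histograms (all pairs identical) fit
`tau = 0` and are flagged rather than erroring; p-values never return
exactly zero.

# Known limitations

* The connection-limit estimator is a principled reconstruction, not a port
  of the legacy program's code path; absolute agreement with that program's
  limits is not guaranteed (only the qualitative behaviour and the pinned
  regression value are).
* The mismatch model is the sudden (stepwise) demographic expansion; the
  spatial-expansion variant and other neutrality statistics (e.g. Fu's Fs)
  are out of scope.
* AMOVA is one-level (among/within groups); hierarchical designs are not
  implemented.
* The RDA permutation engine treats the condition as fixed; exchangeability
  is assumed within the whole sample.
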