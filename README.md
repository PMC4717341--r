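# divload

Does a symbiont species' mitochondrial genetic diversity scale with the
typical size of its infrapopulations — the number of conspecific
symbionts living on one host individual? `divload` implements the
species-level analysis chain for testing this in host–symbiont systems
such as feather mites on passerine birds, where infrapopulation size is
the practical census-size surrogate for $N_e$ and COI is the workhorse
marker. It is written for population geneticists and evolutionary
ecologists working with multi-species symbiont surveys: one aligned COI
FASTA, one host/sample metadata table, one table of median loads in —
species-level estimates, tests and diagnostics out.

## What it computes

Per species, from an alignment of $n$ sequences and $L$ sites
(IUPAC ambiguities, `N` and `-` treated as missing under pairwise
deletion):

* mean pairwise differences $\hat k$ and nucleotide diversity
  $\pi = \operatorname{mean}_{i<j}\, d_{ij} / L_{ij}$;
* segregating sites $S$;
* Tajima's $D = (\hat k - S/a_1)\big/\sqrt{e_1 S + e_2 S(S-1)}$ with a
  two-sided normal p-value;
* the Ramos-Onsins–Rozas expansion statistic
  $R_2 = \sqrt{\tfrac1n\sum_i (U_i - \hat k/2)^2}\,\big/\,S$, with a
  lower-tail p-value from coalescent simulations conditioned on the
  observed $n$ and $S$;
* minimum-spanning haplotype networks with equal-weight alternative
  links, per-bird haplotype composition, and a `star_score` diagnostic
  for star-like versus reticulated structure.

Because symbionts transmit vertically, mites from one bird are kin; the
species-level estimator `divload()` therefore resamples: 100 iterations
of (i) one randomly chosen mite per bird, (ii) recomputed per-species
statistics, (iii) loads jittered on $\mathrm{Uniform}(M/2, M)$ to absorb
survey overcounting, (iv) a Gaussian identity-link GLM of $\pi$ on load,
weighted by per-species sample size. Iteration averages, empirical 95%
intervals, per-species significance percentages (`**` above 95%, `*`
above 75%), an intraclass-correlation repeatability diagnostic and
rank-correlation/locality robustness checks complete the analysis. A
coalescent-based generator (`simulate_system()`) produces synthetic
vertically transmitted systems with known truth for validation and
power analysis.

## Worked example

```r
library(divload)

sys <- simulate_system(default_preset(), seed = 42)   # 17 synthetic species
fit <- divload(sys$datasets, iterations = 100, r2_reps = 200, seed = 1)
fit
#> Diversity ~ infrapopulation size (resampled weighted Gaussian GLM)
#>   17 species, 100 iterations (seed 1)
#>   mean F = 11.62 (95% CI 3.86-24.75), df = 15, mean P = 0.015
#>   mean deviance explained = 40% (95% CI 20-62%)
#>   fixed-load GLM: F = 12.22, df = 15, P = 0.00325, deviance explained = 45%
```

Species diversity rises with median load and the weighted GLM explains
about 40% of the deviance on average across iterations. The per-species
table shows what drives it — and what departs from it:

```r
summary(fit)
#>  species  n If S_full median_load mean_pi mean_D mean_R2 R2_sig
#>     sp01 30  6      6         5.0 0.00548   0.82    0.25      0
#>     ...
#>     sp09 35  7      4        15.8 0.00100  -1.18    0.26      7
#>     sp12 50 10      7        24.3 0.00241  -0.63    0.14     20
#>     ...
#>     sp16 35  7     67        43.3 0.04040   0.13    0.21      0
#>     sp17 40  8     41        50.0 0.01510  -0.64    0.16      4
```

`sp09` and `sp12` are the preset's recent-expansion species: diversity
far below their loads' expectation, the analogue of star-like species in
real surveys. Excluding them (`divload(..., exclude = c("sp09",
"sp12"))`) raises the mean deviance explained. Repeatability of
per-infrapopulation diversity across species:

```r
repeatability_diversity(sys$datasets)
#> ICC repeatability R = 0.481 (95% CI 0.301-0.703); 17 groups, 147 observations
```

and a haplotype network for one species:

```r
d  <- sys$datasets[["sp12"]]
ht <- collapse_haplotypes(d$alignment, d$metadata)
nw <- build_network(ht)
network_summary(nw, ht)
#>   n_haplotypes haplotype_diversity max_within_bird_sharing star_score
#> 1            8           0.7591837                       5  0.5714286
plot(nw, table = ht)   # nodes sized by frequency, pies by host bird
```

Real data enter through `read_alignment()`, `read_metadata()`,
`read_loads()` and `build_species_datasets()`; the fitted object answers
`summary()`, `coef()`, `plot()`, `predict()`, `fitted()` and
`residuals()`.

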