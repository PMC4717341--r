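---
title: "Methods: mitochondrial diversity and infrapopulation size in host-symbiont systems"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mitochondrial diversity and infrapopulation size}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific question

Neutral theory predicts that genetic diversity scales with effective
population size, $N_e$. For symbionts that live their whole life on a host
individual — feather mites on passerine birds are the motivating system —
the census size of a species is hard to observe, but the *infrapopulation
size* (the number of conspecific symbionts on one infected host) is a
routinely collected field measurement. `divload` asks, for a set of
symbiont species each living on its own host species: does species-wide
mitochondrial (COI) nucleotide diversity increase with the species'
median infrapopulation size?

Two features of these systems complicate the naive regression:

* **Vertical transmission.** Mites colonise chicks from their parents, so
  mites sampled from one bird are often close kin sharing haplotypes.
  Treating every sequenced mite as an independent draw from the species
  gene pool pseudo-replicates the data and biases diversity downward.
* **Load uncertainty.** Wing-mite counts pool all mite species present on
  a bird, so a species' recorded median load is an upper bound for the
  focal species.

The package's estimator addresses both by resampling: in each of (by
default) 100 iterations it keeps a single randomly chosen mite per bird,
recomputes every species' diversity from that one-per-host subsample,
draws each species' load uniformly from $[M/2, M]$, and fits a weighted
Gaussian identity-link GLM of diversity on load. Iteration averages, not
any single fit, are reported.

# Statistics computed per species

For an alignment of $n$ sequences and $L$ sites:

* **Mean pairwise differences** $\hat k$: pairwise-deletion difference
  counts summed over all $\binom{n}{2}$ pairs, divided by the number of
  pairs. A site enters a pair's comparison only when both sequences carry
  an unambiguous A/C/G/T; IUPAC ambiguity codes, `N` and `-` are treated
  as missing, never as a fifth state.
* **Nucleotide diversity** $\pi$: the mean over pairs of
  $d_{ij}/L_{ij}$ with $L_{ij}$ the number of compared sites for the
  pair. With complete data this reduces exactly to $\hat k / L$; under
  missing data it remains a per-site quantity. Pairs with no comparable
  site are dropped with a warning.
* **Segregating sites** $S$: columns with at least two distinct
  unambiguous bases.
* **Tajima's D**: $(\hat k - S/a_1)/\sqrt{e_1 S + e_2 S (S-1)}$ with the
  standard constants; the p-value treats D as standard normal,
  two-sided. D is reported as `NA` (undefined, never imputed as zero)
  when $S = 0$ and also when $n \le 3$, where the $e_1, e_2$ variance
  constants vanish identically and the statistic is $0/0$.
* **Ramos-Onsins–Rozas $R_2$**:
  $\sqrt{\tfrac1n \sum_i (U_i - \hat k/2)^2}\,/\,S$, where $U_i$ counts
  the segregating sites at which sequence $i$ carries a base found in no
  other sequence (so at a site where $n-1$ sequences share the derived
  base, the lone ancestral sequence holds the singleton). Low $R_2$
  signals population expansion. Significance comes from a lower-tail
  Monte-Carlo p-value against a standard neutral constant-size coalescent
  conditioned on the observed $n$ and $S$ (fixed-$S$ mutation dropping:
  exponential waiting times at rate $j(j-1)/2$, uniformly random merges,
  exactly $S$ mutations placed with probability proportional to branch
  length). Conditioning on $S$ rather than on an estimated $\theta$
  matches the statistic's original calibration and avoids a nuisance
  estimate. The p-value uses the $(r+1)/(B+1)$ correction so it is never
  exactly zero; 1000 replicates by default.

All undefined cases propagate as `NA` through the pipeline; they are
skipped in averages and significance counts, never replaced by zeros.

# The resampling estimator

`divload()` runs, per iteration and species, under its own deterministic
seed sub-stream derived from the master seed, the iteration number and
the species name — so excluding a species never perturbs the draws of
the others, and a seeded run is bit-reproducible.

The per-iteration regression weights each species by its total number of
sequenced mites (the only sample-size measure carried by the data), via
the `weights` argument of a Gaussian `glm`. The reported quantities per
iteration are the slope, intercept, weighted null and residual deviance,
deviance explained $1 - D_{res}/D_{null}$, and
$F = (D_{null}-D_{res})/(D_{res}/(n_{obs}-2))$ on $(1, n_{obs}-2)$
degrees of freedom. Across iterations the package reports means and
empirical 95% intervals (2.5/97.5 percentiles of the 100 values;
percentiles avoid a normality assumption that the skewed per-iteration
F and p values would violate). A secondary fixed-load GLM — per-species
mean diversity against the unjittered recorded medians — is always
fitted and backs the `predict`, `fitted` and `residuals` methods.

Per-species tests are summarised as the percentage of iterations with
$p \le \alpha$ ($\alpha = 0.05$ by default); species above 95% are marked
`**`, above 75% `*` (strict inequalities; the same rule is applied to
Tajima's D and to $R_2$).

Two diagnostics accompany the fit:

* **Repeatability (ICC).** One-way ANOVA intraclass correlation of
  per-infrapopulation diversity grouped by species, with the
  unbalanced-design correction
  $n_0 = (N - \sum n_i^2/N)/(a-1)$ and Searle-type F-bound confidence
  limits. High repeatability means infrapopulations of a species agree
  about its diversity, so the species-level estimate is not driven by a
  few hosts.
* **Robustness checks.** (a) Spearman rank correlation between mean
  infrapopulation diversity and the subsampled species-level estimate;
  (b) a paired t-test across species of diversity with versus without a
  designated locality subset (e.g. a distant sampling region). The
  locality check is reported as skipped when the exclusion set is empty
  or removes nothing — a degenerate paired test is never forced. The
  published analysis this design follows reports its paired test with a
  Welch-like fractional df, which is inconsistent with a paired design;
  this package implements the standard paired t-test and leaves the
  discrepancy documented here rather than reverse-engineering the
  original call.

# Haplotype networks

Sequences are collapsed into haplotypes by greedy first-occurrence
matching, ignoring positions where either sequence is ambiguous (the
relation is not transitive under missing data, so greedy assignment in
input order makes the result deterministic). The network is the minimum
spanning tree on pairwise Hamming distances, built with edges sorted by
(weight, smaller index, larger index) so ties are stable; every non-tree
pair whose distance equals the bottleneck (maximum edge weight on its
tree path) is kept as an equal-weight alternative link, because each such
link could replace that bottleneck edge in another minimum spanning
tree — these are the reticulations that distinguish an equilibrium
species from a star-like one. The summary reports Nei haplotype
diversity, the maximum number of conspecific mites sharing a haplotype
within one bird (the vertical-transmission signature), and `star_score`:
the fraction of non-hub haplotypes attached directly to the modal
haplotype. `star_score` is this package's own diagnostic, introduced to
quantify the star-like versus reticulated contrast; it never enters the
regression.

# The synthetic-data generator

`simulate_species()` emulates a vertically transmitted infrapopulation
sample with a two-phase coalescent. Within each bird the $m$ sampled
mites descend from at most $f$ founder lineages (assignment uniform at
random; founders are distinct when $f \ge m$, so $f = m$ recovers the
unstructured baseline with $E[\pi] = \theta$, and $f = 1$ makes all
mites of a bird identical). Within-bird coalescence is treated as
instantaneous: the founder-event bottleneck is what produces the
observed within-bird haplotype sharing, and a full two-timescale
simulator would add parameters the data cannot inform. Founder lineages
across birds then follow a neutral coalescent — constant-size, or with
a recent $g$-fold expansion at time $\tau$ (coalescence rate multiplied
by $g$ beyond $\tau$), the simplest history that yields star-like
genealogies and depressed $R_2$. Mutations are Poisson on branches
(mean $=$ length $\times\ \theta/2 \times L$) at distinct uniform
positions — quasi-infinite sites on $L$ positions, no back-mutation; a
species drawing more mutations than sites is an error instructing a
larger $L$ or smaller $\theta$.

## The default preset and how it was chosen

`default_preset()` fixes the study conditions used by the package's own
validation experiments: 17 species; median loads log-spaced from 5 to 50
mites per bird; 6–12 birds per species with 5 mites sampled from each;
$f = 2$ founders per bird (strong kin structure, as seen in real
within-bird haplotype sharing); diversity scaling
$\theta = 2.8\times10^{-4} \cdot M^{1.3}$ per site; and two
recent-expansion species ($g = 30$, $\tau = 0.05$) placed at mid-range
loads. The scaling constants were set by a design power analysis run
before the validation experiments were frozen: the preset is required to
make the diversity–load effect recoverable in at least 95% of full
pipeline runs, and a weaker slope (e.g. $\beta = 1$) leaves the
single-genealogy coalescent noise — whose coefficient of variation in
$\pi$ is irreducibly around 0.5 per species, whatever the within-species
sample size — too large for that. The realised per-site diversity spans
roughly 0.002–0.045, the order of magnitude of COI surveys in these
systems. The expansion species sit at mid-range loads so that they are
low-diversity *outliers* relative to the trend; excluding them then
increases the deviance explained, the behaviour expected of star-like
species in real data. No quantitative transmission or founder parameters
exist for these systems; the defaults are illustrative of the mechanism,
not calibrated to any organism.

What passing tests on this generator do **not** show about real data:
the generator draws every species from the neutral model that the
neutrality tests assume, has no selection, recombination, migration,
geographic structure, back-mutation, sequencing error or alignment
error, and models load uncertainty exactly as the jitter the pipeline
assumes. Agreement between estimator and generator is therefore a check
of internal correctness and calibration, not of the biological model.

# Numerical choices and degenerate inputs

* Sites are 0-based internally and 1-based in every report; sequences
  are upper-cased on read and `U` is mapped to `T` before parsing.
* Alignments are validated as non-ragged with unique ids; species with
  fewer than 2 sequences, or fewer than 2 birds at subsampling time, are
  excluded with warnings; the regression requires at least 3 species.
* $\pi$ with all pairs incomparable, D with $S = 0$ or $n \le 3$, and
  $R_2$ with $S = 0$ are `NA`, and significance percentages count only
  defined iterations.
* Monte-Carlo p-values are never 0 by construction; all p-values lie in
  $(0, 1]$.
* MST ties are broken deterministically by haplotype index; haplotype
  numbering follows first occurrence in the input.

# Problem sizes used in validation

The package's own test experiments use: 200 random alignments
($n \le 10$, $L \le 50$) against brute-force oracles; 10,000 coalescent
replicates for the tree-length expectation ($n = 10$,
$E = 2\sum_{i<10} 1/i \approx 5.658$); 1000 neutral datasets
($n = 20$, $S = 20$, 200 null replicates each) for the $R_2$ type-I
error, accepted in $[0.03, 0.07]$; 100 independent full pipeline runs
(17 species, 100 iterations each) for effect recovery under
$\beta = 1.3$ and false-positive control under $\beta = 0$; and 50
matched equilibrium/expansion species pairs for the star-likeness
contrast. These sizes give Monte-Carlo standard errors comfortably
below the tolerances they are tested against.

# Known limitations

* The regression is correlative; the package deliberately offers no
  causal or phylogenetic interpretation (no PGLS — the motivating
  analysis found no phylogenetic signal in diversity, and a host
  phylogeny is outside this package's inputs).
* The $R_2$ null conditions on $n$ and $S$; for data with very few
  segregating sites the test has little power, and species-level
  significance percentages should be read with $S$ in view.
* Under heavy within-host kin structure the full-sample (unsubsampled)
  statistics are biased by design; only the one-per-host resampled
  estimates are meant for species-level inference.
* The Hamming-distance network treats every substitution equally; no
  model-corrected distances are used at these shallow divergences.
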