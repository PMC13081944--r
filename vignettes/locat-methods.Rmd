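---
title: "Detecting localized marker genes: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting localized marker genes: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(locat)
```

## The problem

In a low-dimensional embedding of single cells, a gene can be locally
*enriched* without being a usable marker: it may peak in one region yet stay
detectably expressed everywhere else. `locat` operationalises a stricter
notion — **localization** — as the conjunction of two testable properties:

* **concentration**: the gene's expression density accumulates into compact
  regions of the embedding, beyond what prevalence-matched random expression
  would produce; and
* **depletion**: the gene's expressing cells are selectively absent from
  regions that hold a substantial share of the background cell density.

Only genes with evidence for *both* are called localized. The distinction
matters in practice: broadly expressed genes with a local peak pass
enrichment-only criteria but cannot demarcate a population.

## Density model

Both the background cell density $f_0(x)$ and each gene's expression density
$f_g(x)$ are weighted Gaussian mixture models (WGMMs) over the embedding
coordinates, fitted by EM with per-observation weights that sum to one
(uniform weights for the background, the gene's normalized expression for
$f_g$). Covariances are full (embeddings are low-dimensional, typically 2–8
components of a PCA) and regularized by adding $10^{-6}\times$ the median
coordinate variance to the diagonal. EM stops when the relative change of the
weighted log-likelihood falls below $10^{-6}$ or after 200 iterations; the
weighted log-likelihood is non-decreasing across iterations, and the test
suite asserts this invariant.

Model complexity is chosen by a BIC variant that accounts for unequal
weights: the weighted mean log-likelihood is scaled by Kish's effective
sample size $n_\mathrm{eff} = (\sum_c w_c)^2 / \sum_c w_c^2$, and the
parameter penalty uses $\log n_\mathrm{eff}$. With uniform weights this is
the ordinary BIC. The background is fitted once per dataset over a grid of
component counts (default $1..10$), and the density values are averaged over
several refits (default 5) at the selected count to stabilise them. Gene
models scan $k = 1..k_{\max}(g)$ with the support-adaptive cap
$k_{\max}(g) = \mathrm{clamp}(\lfloor n_\mathrm{eff}(g)/20 \rfloor, 1, 10)$:
very sparse genes are forced to a single component, well-supported multimodal
genes can use several.

## Concentration score

For gene $g$ with prevalence $\pi_g$ (fraction of expressing cells), each
cell contributes the bounded, prevalence-scaled density contrast
$\gamma_{g,c} = \pi_g (1-\pi_g)\,(f_g - f_0)/(f_g + f_0)$, and the raw
statistic $z_g$ is the expression-weighted mean of $\gamma_{g,c}$ over
expressing cells. The prevalence factor stabilises sparse genes and
down-weights near-ubiquitous ones; $|\gamma| \le \pi(1-\pi) \le 1/4$ always.

Because $z_g$ drifts with prevalence even under the null, significance is
calibrated against **randomized pseudo-genes**: at each of several prevalence
levels, random cell subsets receive weights resampled from real genes of
similar prevalence, are pushed through the same gene-density fit, and yield a
null location $\mu(\pi)$ and scale $\sigma(\pi)$ (median and
$1.4826\cdot\mathrm{MAD}$; a mean/sd option exists). These curves are
interpolated linearly in $\log \pi$ with constant extrapolation, and
$Z_g = (z_g - \mu(\pi_g))/\sigma(\pi_g)$ gives the one-sided p-value
$p_{c,g} = 1 - \Phi(Z_g)$. Genes with prevalence above `max_freq` (default
0.9) are reported untested.

The calibration grid spans the prevalences of the genes actually under test
(clamped to $[0.005, \mathrm{max\_freq}]$), with 12 log-spaced levels and 100
pseudo-genes per level by default. Spanning only the observed range, rather
than always reaching `max_freq`, avoids spending most of the runtime on
high-prevalence pseudo-genes that no tested gene would ever be interpolated
against.

## Depletion score

For a contrast threshold $\lambda \ge 1$ the depletion region
$\Gamma_\lambda = \{c : f_0(x_c) > \lambda f_g(x_c)\}$ collects cells where
background density dominates the gene density. Two masses are compared: the
model-based background share $\beta_0(\lambda)$ (fraction of total $f_0$
inside the region) and the empirical expressing-cell share
$\beta_g(\lambda)$ (each expressing cell counts equally by default;
expression weighting is optional). Under the null that expressing cells
follow the background, $\beta_g \approx \beta_0$; localized genes have
$\beta_g \ll \beta_0$.

The one-sided tail probability uses a beta-binomial with overdispersion
$\rho_{bb} = 0.02$ and an effective trial count
$n_\mathrm{trials} = \mathrm{round}(\min(0.6\, n_\mathrm{eff},\ n_\mathrm{cells}))$
— Kish's $n_\mathrm{eff}$ of the gene weights, shrunk because $f_g$ and
$f_0$ share cells and neighbouring cells are correlated. Rounding is R's
round-half-even. With $\rho_{bb} = 0$ the test reduces to a binomial tail.
The scan covers 16 geometric contrasts from 1.25 to 100; a contrast is
admissible when the region carries enough background mass
($\beta_0 \ge 0.05$), enough effective evidence
($n_\mathrm{eff}\beta_0 \ge 10$), a non-negligible deficit
($\beta_0 - \beta_g \ge 0.01$), and an observed mass consistent with the
contrast ratio ($\beta_g < (\beta_0/\lambda)(1 - 0.05)$). The depletion
p-value is the minimum admissible tail probability with a Šidák-form
correction over the number of admissible contrasts — approximate, since the
scan is correlated; with no admissible contrast the p-value is 1. All four
admissibility thresholds are exposed in `depletion_control()`.

## Combination, penalties, smoothing

Concentration and depletion p-values are combined with a Cauchy combination,
$T_g = \tan((\tfrac12 - p_c)\pi) + \tan((\tfrac12 - p_d)\pi)$ and
$p_{loc} = \tfrac12 - \arctan(T_g)/\pi$, which stays valid under dependence
between the two tests. The sum form (no $1/2$ averaging) is deliberate and is
the default; `average = TRUE` gives the conventional variant. Inputs are
clipped into $[10^{-15}, 1 - 10^{-15}]$ before the tangent.

Two conservative penalties then stabilise small or poorly separated genes:
a sparsity factor $h^{(size)} = 1 - e^{-1/(n_g+1)}$ and a sensitivity factor
$h^{(sens)} = 1 - $ (fraction of expressing cells where $f_g > f_0$,
evaluated against the averaged background). The adjusted score
$p_g = 1 - (1-p_{loc})(1-\alpha_{size}h^{(size)})(1-\alpha_{sens}h^{(sens)})$
satisfies $p_g \ge p_{loc}$, so penalties can only reduce significance. Both
coefficients default to $0.5$ and are exposed; with these defaults the final
p-value of even an overwhelmingly localized gene floors at roughly
$0.5(1 - \mathrm{frac\ dominated})$ plus a small sparsity term, which is what
keeps very diffuse genes from ever reaching significance. Finally a monotone
smoothing map spreads scores above 0.99 apart without letting them reach 1;
it preserves ranks and leaves everything at or below 0.99 untouched.

## Secondary tests

* **Likelihood-ratio test** (`likelihood_ratio_test()`): per-cell-normalized
  log-likelihood ratio of $f_g$ versus $f_0$ over expressing cells, against a
  $\chi^2$ with $\max(1, k_0 - k_g + 1)$ degrees of freedom. The per-cell
  normalization keeps the statistic comparable across prevalences but bounds
  its power — it is a baseline, not the primary criterion.
* **Permutation diagnostic** (`permutation_pvalue()`): rank-stratified
  within-bin weight shuffling plus i.i.d. Exponential(1) weight noise
  (Bayesian-bootstrap style), refit, and add-one empirical p-value. Because
  every replicate is a noised copy of the observed gene, extremeness is
  compared on the Cauchy combination statistic with strict inequality; the
  construction is intentionally permissive and is offered as a diagnostic
  for candidate genes, not a calibrated test.
* **Spectral baseline** (`spectral_rh()`): Rayleigh smoothness on the kNN
  graph's normalized Laplacian plus Shannon entropy of squared projections
  onto the leading eigenvectors (default 96), each standardized against
  per-gene permutation nulls and summed; lower means more localized.
* **Rank calibration** (`empirical_rank_pvalues()`): $p = \mathrm{rank}/(N+1)$
  with average ties, for methods that report scores rather than p-values.

## Module discovery, nDA, temporal patterns

Co-expression modules: binarize at $t = 0$, test every gene pair's overlap
with an upper-tail hypergeometric test at raw $\alpha = 0.05$ (a BH option
exists but is off, matching the raw-threshold convention), build the binary
gene graph, partition with Louvain at resolution 1, and drop communities
below 5 genes.

Neighborhood differential abundance: local group fractions over $k \in
\{15, 40, 75\}$ nearest neighbours (query cell excluded, to avoid
self-label leakage), mapped through an antisymmetric Bayes-factor transform
to $[-1, 1]$, then aggregated by a ridge-regularized logistic fit with
balanced class weights whose fitted probabilities are rescaled to $[-1, 1]$.
With balanced weights an uninformative score matrix collapses to 0; the
unweighted option collapses to $2q_1 - 1$.

Temporal patterns: genes localized in at least one of $T$ timepoints are
assigned to one of $2^T - 1$ patterns; observed pattern frequencies are
contrasted with the independence expectation (product of marginals,
renormalized over admissible patterns), $\delta$ per pattern, with a Monte
Carlo null (default 10,000 resamples) and an overall chi-square test.
Replicate p-values combine by geometric mean.

## The synthetic benchmark and what it does (not) show

`gaussian_background()` draws the study backdrop: 1,500 cells i.i.d. from a
standard 2-D Gaussian. `simulate_localized_gene()` plants a gene by drawing
its expressing cells uniformly from the cells inside a ball of given
**dispersion radius** around a mode center, assigning lognormal(0, 0.5)
magnitudes. Design choices worth stating explicitly:

* **Truncated-ball support.** Inside the ball, cells express; outside, the
  gene is truly absent. Small radii therefore produce both concentration and
  genuine depletion, and growing the radius merges the pattern into the
  background — mirroring how the radius sweep is described against both the
  localization test and the likelihood-ratio baseline. In the
  radius-to-zero limit the expressing cells are exactly the nearest
  neighbours of the center.
* **Random mode centers.** Centers default to the positions of uniformly
  chosen background cells. A localized subpopulation generically sits away
  from the embedding's center of mass; centering every replicate on the
  density mode would be the single degenerate configuration in which
  depletion is weakest.
* **Per-cell jitter.** Jitter (a percentage of the per-axis background
  range) displaces each expressing cell's target position independently, so
  modes become progressively more diffuse; displacing only the mode centers
  would relocate compact clumps without ever spreading them, leaving every
  density-ratio test at full power.
* **Perturbations.** `perturb_gene()` subsamples expressing cells
  (retaining `round((1-level)*n)` of them) or redistributes a fraction of
  them onto random background cells with the expressing count held fixed.

`benchmark_power()` pairs all grid levels within a replicate: one background
draw, one background fit, and one concentration calibration are shared
across levels, which both mirrors a paired design and keeps sweeps fast. At
benchmark scale the pipeline runs with `benchmark_control()`: background
`k_grid` 1:3 and 3 averaged refits (the background is a single Gaussian by
construction), gene-model cap 5, calibration with 4 grid points bracketing
the tested prevalences and 50 pseudo-genes each. The radius, jitter and
sample-size sweeps use 20 replicates per level; the template-perturbation
sweeps use 12 (their template carries 250 expressing cells, the costliest
fits in the suite, and the assertions are property-based monotonicity
checks). Package-level defaults (`locat_control()`) remain the full-size
ones.

What passing these benchmarks does *not* show: real embeddings have
non-Gaussian, multi-scale structure, library-size and dropout artifacts, and
correlated genes; the generator models none of these (no count model, no
dropout). The benchmarks validate the statistical machinery under controlled
ground truth, not performance on any particular tissue.

## Numerical choices and degenerate inputs

* Densities are floored at $10^{-300}$ so ratios stay finite; p-values are
  clipped away from 0 and 1 before tangent transforms; the Šidák step uses
  `expm1`/`log1p` to survive tail probabilities near the double minimum.
* Round-half-even (R's `round`) for effective trials and observed counts.
* Genes with zero expressing cells are untestable (error at the single-gene
  surface, `NA` rows in the pipeline); constant genes are untestable in the
  spectral baseline.
* Pseudo-gene magnitude pools fall back to all nonzero values when no real
  gene has prevalence within a factor 1.5 of the target level.
* The EM initialisation samples distinct support points with probability
  proportional to weight; every stochastic step derives its seed from the
  master seed, so identical configurations reproduce byte-identical tables.
* Ties in `write_locat_results()` order break on the gene identifier.

## Known limitations

* The depletion scan's multiplicity correction treats admissible contrasts
  as independent; they are not, and the correction is approximate by
  construction.
* The sensitivity penalty couples the final p-value to the geometry of the
  fitted gene density; for genes whose support straddles the background
  density mode the penalty dominates well before the component tests lose
  significance.
* The permutation diagnostic is anti-conservative by design (its null
  preserves most of the observed structure) and should be read as a
  robustness check on candidate genes.
* HDF5 single-cell containers are not read directly; export to an MTX
  triplet or dense table first.

## A worked call

```{r example, eval = FALSE}
sim <- simulate_dataset(n_cells = 1500, d = 2, n_localized = 1, n_null = 5,
                        radius = 0.3, n_expressing = 100, seed = 42)
fit <- locat(sim$expr, sim$embedding, control = benchmark_control(seed = 42))
tidy(fit)
glance(fit)
autoplot(fit)
```
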