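# locat

Clustering-free detection of **localized marker genes** in single-cell
embeddings.

A gene can be locally enriched in an embedding — a visible peak — and still be
expressed across the whole manifold, which makes it useless as a population
marker. `locat` calls a gene *localized* only when two conditions hold
jointly on a low-dimensional embedding `X` (cells × d, typically a few PCA
components) with a normalized expression matrix `W` (genes × cells):

1. **Concentration.** With weighted-Gaussian-mixture densities `f_g` (gene)
   and `f_0` (background), the prevalence-scaled contrast
   `γ_gc = π_g(1−π_g) · (f_g−f_0)/(f_g+f_0)` is averaged with expression
   weights over expressing cells, standardized against prevalence-matched
   randomized pseudo-genes, and tested one-sided: `p_c = 1 − Φ(Z_g)`.
2. **Depletion.** For contrasts `λ ≥ 1`, the region
   `Γ_λ = {c : f_0 > λ f_g}` is tested for under-representation of
   expressing cells with a beta-binomial lower tail (`ρ_bb = 0.02`) whose
   trial count is Kish's effective sample size of the gene weights, scaled
   by 0.6; the scan over λ is Šidák-corrected.

The two p-values merge through a Cauchy combination
(`T = tan((½−p_c)π) + tan((½−p_d)π)`), are conservatively penalized for
sparse support and for gene densities that fail to dominate the background
at expressing cells, and are smoothed near 1. Per-gene output includes the
final localization p-value `p̃_g`, the component p-values, the adjusted
concentration z-score, the selected mixture size `K_g`, a BIC-style
parsimony score, support and prevalence.

Around the core test the package provides co-expression module discovery
(hypergeometric gene graphs + Louvain), multiscale neighborhood differential
abundance, likelihood-ratio and permutation diagnostics, a spectral
smoothness baseline, rank-based empirical p-values, replicate combination and
temporal-pattern statistics, and a synthetic benchmark suite with controlled
ground truth.

## Worked example

Plant one localized gene (100 expressing cells drawn from a compact
neighbourhood of a 1,500-cell Gaussian background) plus five
prevalence-matched null genes, and run the pipeline:

```r
library(locat)

sim <- simulate_dataset(n_cells = 1500, d = 2, n_localized = 1, n_null = 5,
                        radius = 0.3, n_expressing = 100, seed = 42)
fit <- locat(sim$expr, sim$embedding, control = benchmark_control(seed = 42))
tidy(fit)
#> # A tibble: 6 × 11
#>   gene_id p_tilde     p_loc p_conc    p_depl z_conc k_components bic_like n_expr
#>   <chr>     <dbl>     <dbl>  <dbl>     <dbl>  <dbl>        <int>    <dbl>  <int>
#> 1 loc001   0.0248 9.99e-16   0     4.78e-9   46.8              1     110.    100
#> 2 null001  0.997  1.000e+ 0  0.305 1          0.510            1     466.    100
#> 3 null002  0.997  1.000e+ 0  0.680 1         -0.468            1     452.    100
#> # … null003–null005 similar
```

The planted gene is called localized (`p̃ = 0.0248`): its concentration
z-score is 46.8 standard deviations above the prevalence-matched null and
its expressing cells are significantly depleted from high-background-density
regions (`p_depl ≈ 5e-9`). The five null genes — random supports of the same
prevalence — end near 1. `glance(fit)` summarises the run;
`autoplot(fit)` draws prevalence against `−log10 p̃`;
`write_locat_results(tidy(fit), "results.tsv")` writes the sorted table.

Power sweeps with ground truth (radius, sample size, jitter, template
perturbations) run through one call:

```r
bench <- benchmark_power("radius", grid = seq(0.3, 3, length.out = 10),
                         n_replicates = 20, methods = c("locat", "lrt"),
                         seed = 1)
bench$crossing
#> # A tibble: 2 × 2
#>   method crossing_level
#>   <chr>           <dbl>
#> 1 locat             1.5
#> 2 lrt               0.9
```

The localization test keeps its median p-value below 0.05 until the
dispersion radius reaches ~1.5 embedding units, while the likelihood-ratio
baseline fades by ~0.9.

A thin command-line front end is installed at `exec/locat`
(`locat run|simulate|modules|nda|diff|subset-embed`).

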