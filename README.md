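# parafd

Functional alpha and beta diversity of parasites and their hosts.

`parafd` is an R package for a question in parasite biogeography: across
the regions of a biogeographic realm, is the functional diversity of a
parasite assemblage (here, fleas) driven by the functional diversity of
its hosts (small mammals), by the off-host environment, or both? It
implements the complete inference chain for both the *alpha* (within
region) and *beta* (between regions) sides of that question, plus a
synthetic realm generator with known ground truth so every stage can be
validated end to end.

## The methods

**Functional trees.** Species are described by mixed-type traits
(continuous, ordinal, nominal, binary). Traits are prepared —
ln-transformation where flagged, standardization to zero mean and unit
variance, dummy coding of nominal levels — and pairwise Gower distances

d(i,j) = (1/p) Σₖ |xᵢₖ − xⱼₖ| / rangeₖ

feed a neighbour-joining tree whose branches act as functional
diversity units (FDUs).

**Alpha components.** A region's species induce a minimal spanning
subtree; its branch lengths ℓ₁…ℓ_B give

- functional richness = Σ ℓᵦ
- functional divergence = mean ℓᵦ
- functional regularity = dispersion of ℓᵦ, reported both as the raw
  variance and as the bounded evenness 1/(1 + CV²).

**Comparative regression.** Regions sharing species are not independent
observations. A pseudo-phylogeny of regions is built from combined flea
+ host composition (Bray–Curtis → complete linkage → ultrametric tree
with leaf depth = merge height/2), and each flea component is regressed
on the matching host component plus three environmental PC1 composites
by generalized least squares under Brownian motion on that tree,

β̂ = (XᵀC⁻¹X)⁻¹ XᵀC⁻¹ y,  C = shared root-to-ancestor depths,

with forward stepwise selection (AICc) and a Moran's *I* test
(inverse-distance weights, E[I] = −1/(n−1)) on the residuals.

**Beta side.** Between-region functional dissimilarity is branch-based
Ochiai: with a, b, c the branch-length totals of shared and unique
root-path branch sets, d = 1 − a/√((a+b)(a+c)). Flea functional
dissimilarity is then modelled by generalized dissimilarity modelling:
monotone order-3 I-spline transforms of host functional dissimilarity,
environmental composites and great-circle distance, link
μ = 1 − exp(−η), binomial-form deviance minimized by iteratively
reweighted non-negative least squares. Predictor importance is the
percent decrease in deviance explained under matrix permutation.

## Worked example

```r
library(parafd)

realm <- simulate_realm(n_regions = 30, n_hosts = 50, n_fleas = 40,
                        theta_match = 0.9, seed = 1)
res <- run_realm_analysis(realm, run_config(seed = 1, n_perm = 100))
res
#> realm_analysis
#>   PGLS richness    selected: host (AIC 0.27, Moran p = 0.799)
#>   PGLS divergence  selected: temperature, host (AIC -264.66, Moran p = 0.670)
#>   PGLS regularity  selected: (intercept only) (AIC -94.73, Moran p = 0.869)
#>   GDM: 36.2% deviance explained; importance ranking: host_fd > temperature > geo_dist > vegetation > precipitation

res$pgls$richness$fit
#> pgls_fit: n = 30, logLik = 2.864, AIC = 0.272, sigma2 = 0.1753
#>             estimate     se       t      p
#> (Intercept)  -0.0996 0.7222 -0.1379 0.8913
#> host          0.6080 0.2891  2.1032 0.0446

res$importance
#> gdm_importance: 100 permutations (seed 1), full DE 36.2%, model p = 0.000
#>       predictor importance    p
#> 1    vegetation      -1.82 0.98
#> 2   temperature       9.61 0.00
#> 3 precipitation      -1.87 0.99
#> 4       host_fd      87.63 0.00
#> 5      geo_dist      -0.64 0.98
```

At strong flea–host coupling (`theta_match = 0.9`) the pipeline
recovers what it should: flea functional richness increases with host
functional richness (PGLS slope 0.61, p = 0.045, no residual spatial
autocorrelation), and host functional turnover dominates the GDM
importance table (87.6% vs ≤ 10% for every environmental gradient),
with permuting it being the only change that significantly degrades the
model.

A command-line wrapper over the same functions lives in
`inst/scripts/parafd-cli.R` (subcommands `simulate`, `prep-traits`,
`build-tree`, `alpha`, `region-tree`, `pgls`, `beta`, `gdm`, `varimp`).

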