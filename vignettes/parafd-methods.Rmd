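---
title: "Methods: tree-based functional diversity of parasites and hosts"
author: "parafd"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tree-based functional diversity of parasites and hosts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(parafd)
```

`parafd` asks whether the functional diversity of a parasite assemblage
tracks the functional diversity of its hosts, and how much the off-host
environment contributes, at the scale of regions within a biogeographic
realm. This vignette is the package's own account of the models it
fits, the parameters that matter, the numerical choices taken where
several were defensible, and what the validation suite does and does
not demonstrate.

## From traits to functional trees

Trait tables are mixed-type, with a schema declaring each trait
continuous, ordinal, nominal or binary. Preparation
(`prepare_traits()`) ln-transforms flagged continuous traits (used for
strongly right-skewed quantities such as geographic range size),
converts ordinal traits to integer ranks along their declared level
ordering, standardizes continuous and ordinal columns to zero mean and
unit *sample* variance (n − 1 denominator; recorded in the output
metadata), and expands a nominal trait with k levels into k 0/1 dummy
columns. Ordinal traits are ranked-then-scaled rather than
dummy-coded because they carry order information that dummy coding
would discard; only nominal traits are dummy-coded.

`gower_distance()` is the range-normalized mean absolute difference
over the *prepared* columns, so dummy columns contribute symmetric
mismatch terms and the measure is insensitive to affine rescaling of
any raw input column. Zero-range columns carry no information and are
skipped, reducing the divisor p. Whether one should hand the Gower
routine raw factors or processed columns is a genuinely open choice;
we fix processed columns and flag the convention in the object
metadata. Missing trait values are an error rather than being handled
by pairwise deletion: the generator never produces them and silent
deletion changes the effective weighting of traits between pairs.

The functional tree is neighbour joining (`nj_build()`, delegating to
the standard Saitou–Nei implementation in `ape`). NJ can return
slightly negative branch lengths on non-additive input; these are
clamped to zero and the clamped mass is recorded, since all downstream
quantities are sums of branch lengths and must stay non-negative. On
exactly additive input the reconstruction is exact (verified to 1e−8 on
random additive trees). The trifurcating node ape stores as the root
of the unrooted NJ tree is retained as the reference root wherever a
rooted decomposition is needed.

## Alpha components

For a region with species set S, `induced_branches()` returns the
minimal spanning subtree of S (an edge belongs iff removing it
separates members of S). With branch lengths ℓ₁…ℓ_B:
richness = Σℓ, divergence = mean ℓ, and regularity is the dispersion
of ℓ. The dispersion is reported twice, deliberately. The raw
population variance of branch lengths is the literal definition of the
regularity component in the tree-based framework, but it *decreases*
when a community is more regular, while the concept (and the bounded
evenness measures in the toolkits this framework comes from) runs the
other way. We therefore also report evenness = 1/(1 + CV²) ∈ (0, 1],
which is 1 exactly when all branch lengths are equal, and let the
regression stage choose via `run_config(regularity_metric = )`, with
evenness the default because it preserves the reading "higher = more
regular". Singleton regions induce no branches: richness is 0 and the
other components are NA with an explicit `singleton` flag; they are
excluded from the regression stage with a note rather than imputed.

An independent brute-force oracle (`alpha_oracle()`) recomputes the
components by enumerating the union of all leaf-pair paths
edge-by-edge; the suite checks agreement to 1e−10 relative error on
random 20-leaf trees.

## The region pseudo-phylogeny and PGLS

Regions within a realm share species, so their diversity values are
not independent. Following standard practice in comparative analysis,
non-independence is modelled as Brownian motion on a tree — here not a
phylogeny but a dendrogram of regions: flea and host incidence
matrices are concatenated, Bray–Curtis dissimilarity (for 0/1 rows,
1 − 2a/(2a + b + c)) is clustered by complete linkage, and the
dendrogram becomes an ultrametric tree. Dendrogram-to-tree height
conventions differ between tools; ours is fixed by requiring that the
patristic distance between two regions equal their cophenetic merge
height, which the `ape` conversion (leaf depth = merge height/2)
satisfies and the suite verifies to 1e−10. Tied merge heights are
broken in input order for determinism; identical regions merge at
height zero, giving zero-length branches, which the covariance
construction tolerates.

`bm_covariance()` sets C_ij to the root depth of the most recent
common ancestor. `pgls_fit()` is exact generalized least squares:
β̂ = (XᵀC⁻¹X)⁻¹XᵀC⁻¹y via Cholesky whitening, σ² by maximum
likelihood (r'C⁻¹r/n), coefficient t tests with the unbiased (n − k)
residual variance, and AIC = 2(k + 1) − 2logLik counting σ². Only
plain Brownian motion is fitted — no Pagel's λ or OU transformation —
matching the plain usage this analysis style calls for. A numerically
singular C (possible with duplicated regions) receives a diagonal
jitter of 1e−10 · mean(diag(C)), logged.

Forward stepwise selection starts from the intercept-only model and
adds the candidate with the largest criterion decrease. The default
criterion is **AICc**, not plain AIC. This is a deliberate design
choice: realms have 15–36 regions and up to five parameters, so
n/k is far below 40, the regime where uncorrected AIC is known to
over-admit spurious predictors. In simulation at n = 30 with three
pure-noise candidates, plain AIC admits each noise predictor in
roughly 17–20% of replicates while AICc keeps it near 11–13% without
measurable loss of power for a standardized effect of 0.8 (selected in
essentially 100% of replicates either way). Plain AIC remains
available via `criterion = "AIC"`.

Residual spatial autocorrelation is tested with Moran's I. The
weighting scheme is not dictated by the method, so it is a
configuration switch (`inverse_distance`, the default, or symmetric
4-nearest-neighbour adjacency), always row-standardized, with
great-circle distances on a sphere of radius 6371 km. The expectation
is −1/(n − 1) exactly; the variance uses the kurtosis-corrected
randomization formula and the p-value the two-sided normal
approximation. The approximation is adequate for region counts in the
realm range provided centres are not nearly coincident (coincident
centres are an error suggesting jitter — a single dominant
inverse-distance weight invalidates the normal tail).

## Beta side: branch-based Ochiai and GDM

Between-region functional dissimilarity replaces species with
branches: region r's branch set K_r holds every branch on a
root-to-leaf path of a present species, and with branch-length totals
a (shared), b, c (unique), dissimilarity is the complement of the
Ochiai similarity a/√((a+b)(a+c)) — the incidence-data member of the
Gower–Legendre S12 family, taken without any square-root transform
(logged in metadata). The decomposition depends on the root; we use
the NJ construction root by default and expose
`reroot = "midpoint"` to probe sensitivity, without resolving it —
the choice is reported, not hidden. An independent oracle that builds
each region's branch set from explicit root-to-tip node paths checks
the implementation to 1e−12.

The GDM relates flea functional dissimilarity d to predictors through
μ = 1 − exp(−η), η = a0 + Σ_p Σ_{k=1..3} c_pk · b_pk, with every
coefficient ≥ 0. Each predictor gets three order-3 (piecewise
quadratic) I-splines with knots at the 0/50/100th percentiles of its
observed values — three splines because the analysis framework this
models reports exactly three I-spline coefficients per predictor.
Scalar predictors (the environmental PC1 composites) enter as site
values whose basis difference |I_k(x_i) − I_k(x_j)| forms the model
term; distance-type predictors (host functional dissimilarity,
geographic distance) pass their pair value through their own I-spline
transform with knots on the distance distribution. Whether the
original analysis style entered environmental variables as site values
or as precomputed distance matrices is not recoverable; we use site
values, the convention of the reference GDM implementation for scalar
gradients.

Fitting minimizes the binomial-form deviance
D = Σ 2[d·ln(d/μ) + (1−d)·ln((1−d)/(1−μ))] (limit terms at d ∈ {0,1})
by iteratively reweighted non-negative least squares on the link
scale: working response z = η + (d − μ)/(1 − μ), weights
(1 − μ)/μ, inner solver `pracma::lsqnonneg`, initialized at
μ = (d + mean(d))/2, converged when |ΔD| < 1e−8 (cap 100 iterations;
non-convergence returns the last iterate, flagged). μ is clamped to
[1e−10, 1 − 1e−10] inside the deviance and weights. A constant
response (null deviance ≈ 0) short-circuits to the null model with
all coefficients zero; constant predictors are dropped with a
warning. The non-negativity constraint makes every fitted transform
non-decreasing with f(min) = 0 by construction, so a predictor's
coefficient sum is the height of its transform — the total turnover
attributable to that gradient.

Importance (`var_importance()`) permutes region identities for one
predictor at a time — site values for scalars, rows and columns
jointly for matrices, which preserves the predictor's internal
structure — refits, and reports the mean percent decrease in deviance
explained (default 100 permutations; at least 50). The permutation
p-value is the fraction of permutations matching or beating the full
model; model-level significance applies one shared permutation to all
predictors per iteration, leaving the response fixed. Importances can
be slightly negative by chance and are reported as computed.

## The synthetic realm generator

`simulate_realm()` provides the ground-truth world every stage is
tested against. It emulates the shape of regional survey data — 15–36
regions (default 30), tens of host (50) and flea (40) species, binary
incidence, region centres on a jittered grid spanning 20° × 40° so
great-circle geometry is non-trivial, and three environmental
categories (vegetation, temperature, precipitation) each observed
through two noisy raw variables so the PC1-composite stage does real
work.

Its coupling model, in brief: hosts carry mixed traits; host occupancy
is logistic with niche coefficients over the three observed gradients
*and two hidden spatial factors*, with only the hidden channel
trait-structured (coefficients a linear map of the host's continuous
traits) and a logit scale making presence nearly deterministic given
the niche. Each flea has a preferred host-trait profile; compatibility
is a threshold on Euclidean distance in standardized host-trait space,
the threshold being the global 25% quantile of all flea–host distances
(mean host range ≈ a quarter of the pool; a flea with no host under
the threshold gets its nearest). Flea traits mix the compatible-host
mean profile with independent noise at weight `theta_match`; flea
occupancy requires at least one compatible host present and then
tracks the fraction of its compatible hosts present with sharpness
scaled by `theta_match`, times an environmental filter
exp(−`theta_env`·(temperature gradient − optimum)²).

Three design points deserve comment. First, `theta_match` scales the
occupancy tracking as well as the trait mixing: if it scaled traits
only, flea/host species counts would stay coupled at `theta_match = 0`
(through host availability) and decoupled recovery tests would be
impossible — a single coupling dial for "functional structure" must
govern both composition and traits. Second, routing the
trait-structure of host niches through *hidden* factors is what makes
host functional turnover a genuine, irreplaceable signal: if host
composition were trait-filtered along the observed gradients, the
environmental composites would explain flea turnover directly and the
host predictor would carry no unique information; hidden
trait-structured filtering is also the realistic case (hosts respond
to much that is not measured). Third, defaults `theta_match = 0.7`,
`theta_env = 0.25` place the generator in the regime the real system
occupies — host-dominated turnover with weaker, realm-variable
environmental effects; under strong coupling (0.9) host functional
dissimilarity ranks first in the importance table in essentially every
realization, the qualitative signature the pipeline should recover.

What the generator does *not* emulate: abundance (the measures here
are incidence-based by design), phylogenies and phylogenetic signal,
trait missingness, spatially autocorrelated sampling effort, or
realm-to-realm heterogeneity in trait pools. Passing recovery tests
on this generator therefore shows the pipeline is correct and
well-calibrated under a known trait-matching world; it does not show
the real world satisfies those assumptions.

Realizations violating the incidence invariants (an empty region, a
species present nowhere) are redrawn up to 100 times with the retry
count recorded in the truth report; persistent failure (e.g. an
extreme `theta_env`) is an error rather than a silently degenerate
dataset.

## Validation scope and problem sizes

The test suite validates each stage against an independent oracle
(closed forms for 3-taxon NJ, path-union enumeration for alpha,
explicit branch tables for Ochiai, matrix algebra for GLS, numerical
integration for I-splines, `vegan`'s Gower and `ape`'s Moran's I as
cross-checks) and the whole chain by simulation: NJ exactness on 200
random additive trees; PGLS slope recovery and 95% CI coverage over
500 Brownian replicates on a 30-region pseudo-tree; stepwise
power/false-selection over 200 replicates; Moran's I calibration
against 2000 residual permutations and 200 null datasets; GDM
self-consistency on noise-free data from known models (deviance
explained ≥ 99%, spline heights within 10%); importance calibration
over 100 null simulations and host-dominance recovery over 100
simulated realms (20 regions each, 50 permutations per predictor).
These sizes keep the full suite to a few minutes while holding
Monte-Carlo error well inside the asserted bands.

## Known limitations

- The rooting of the functional tree affects the branch-based beta
  decomposition; the package exposes midpoint rerooting but takes no
  position on which is "right".
- GDM spline count and knot placement are fixed (3 splines,
  0/50/100th percentiles); no model selection across spline
  configurations, no prediction to unsampled sites, and no bootstrap
  confidence bands for the splines.
- Moran's I p-values rely on a normal approximation; for very small
  region counts (< ~10) or highly concentrated weights a permutation
  p would be preferable.
- The evenness transform 1/(1 + CV²) is one of several bounded
  regularity measures; conclusions about regularity should be checked
  against the raw variance, which is always reported alongside.
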