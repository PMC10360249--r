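---
title: "Small-area disease risk mapping with BYM models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Small-area disease risk mapping with BYM models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Health systems often record consultations at the *facility* where care was
delivered, not at the patient's place of residence. Estimating the
small-area risk of a common condition such as acute respiratory infection
(ARI) from such records requires two steps: (i) re-distributing
facility-level counts over census areas, and (ii) modelling the resulting
area rates with a spatial regression that shares information between
neighbouring areas. `bymrisk` implements both, plus the diagnostics and
decision rules that typically accompany them, and a synthetic-city
generator that makes every stage testable against a known truth.

# The model

For area $i$ with population $pop_i$ and covariates $X_i$, counts follow

$$y_i \sim \mathrm{Poisson}(\lambda_i), \qquad
\log \lambda_i = \alpha + X_i\beta + \log(pop_i) + u_i + st_i,$$

the Besag-York-Mollié (BYM) convolution: $u_i \sim N(0, 1/\tau_u)$ iid,
and $st$ an intrinsic conditional autoregressive (ICAR) field over the
areal adjacency graph, with conditional law

$$st_i \mid st_{-i} \sim N\!\left(\tfrac{1}{\#N(i)}\textstyle\sum_{j \in N(i)} st_j,\;
\tfrac{1}{\tau_{st}\,\#N(i)}\right),$$

where $N(i)$ are the areas sharing a boundary with $i$. The ICAR density
is improper (invariant to constant shifts), so a sum-to-zero constraint on
$st$ identifies the intercept. Hyperpriors are logGamma on the two
log-precisions — equivalently Gamma on the precisions — with the
default pairing logGamma(0.1, 0.1) on $\log\tau_u$ and
logGamma(0.001, 0.001) on $\log\tau_{st}$; the two symbols differ only
typographically in the source analysis, so the pairing is a configuration
key (`prior_u`, `prior_st`), not a hard-coded assumption. Fixed effects
get vague $N(0, 1/0.001)$ priors. Exponentiated coefficients are
per-unit relative risks, which is why covariates enter unscaled.

# Inference engine

The posterior is sampled by adaptive Metropolis-within-Gibbs (Rcpp), the
engine family used by CARBayes for the same model:

* single-site random-walk updates for $\alpha$, $\beta_j$, $u_i$, $st_i$,
  with proposal scales tuned during burn-in to a 35–50% acceptance window;
* conjugate Gibbs draws for $\tau_u \mid u \sim \Gamma(a + n/2,\, b + \sum u_i^2/2)$
  and $\tau_{st} \mid st \sim \Gamma(a + (n-1)/2,\, b + \sum_{i\sim j}(st_i - st_j)^2/2)$;
* a hard sum-to-zero constraint: $st$ is recentred every sweep and its mean
  transferred into $\alpha$ (the model is invariant under this shift, so no
  soft penalty is needed);
* internal standardisation of the design matrix for mixing, with draws
  mapped back to the per-unit scale and the Gaussian prior applied on the
  per-unit scale.

Single-site updates alone cross the ridges of this posterior very slowly.
With one observation per area, $X\beta + u + st$ is pointwise exchangeable
with the random effects, and the convolution splits total spatial variance
between $u$ and $st$ only through the priors. Three likelihood-invariant
Metropolis moves fix this:

* **$\alpha/u$ and $\beta_j/u$ ridge moves** — shift the fixed effect by
  $d$ and subtract the compensating amount from $u$; the likelihood cancels
  and only prior terms enter the acceptance ratio.
* **$\beta_j/st$ ridge move** — same, compensating through $st$ (the
  centred design keeps $\sum st = 0$); this matters because spatially
  smooth covariates compete directly with the ICAR field.
* **$u/st$ swap** — $u' = u + d\,st$, $st' = (1-d)\,st$, which preserves
  $u + st$ and trades variance between the fields; the Jacobian on the
  $(n-1)$-dimensional constrained subspace is $(1-d)^{n-1}$.

All are ordinary Metropolis proposals on the exact posterior. With them, a
460-area fit (4 chains x 16,000 iterations, the default) takes seconds and
recovers
generating coefficients with |bias| < 0.01 on the exp scale. Convergence is
summarised by split-$\hat R$ on the intercept, coefficients and
log-precisions; values above 1.05 trigger a warning, and the model-selection
ledger refuses to "choose" candidates above a configurable gate
(default 1.1). The precisions remain the slowest-mixing parameters — the
usual BYM behaviour — so long runs are advisable when the spatial variance
fraction itself is of interest.

The deviance information criterion uses
$p_D = \bar D - D(\hat\eta)$ with $\hat\eta$ the posterior mean of the
per-area linear predictor; differences below 2 are reported as
equivalent fit.

# Geometry and adjacency

Polygons are planar (projected metres; no geodesy). Queen contiguity means
the boundaries come within a snap tolerance of touching (point contact
suffices); rook requires a shared segment of positive length. The snap
tolerance defaults to $10^{-6}$ of the map diagonal — the source analysis
names queen contiguity but no tolerance, so it is explicit and
configurable. Five comparison schemes are provided for the preliminary
model selection (queen, rook, symmetrised k-nearest-neighbour with k = 6,
a centroid distance band whose default radius is the smallest leaving no
island, and second-order queen); the five actually used in the original
analysis are not enumerated there, so this menu is a stand-in of standard
candidates. Moran's I uses binary weights with $S_0$ normalisation and
two-sided permutation inference with the $(\#\mathrm{extreme}+1)/(B+1)$
correction against the analytical null expectation $-1/(n-1)$.

# Rate allocation

Each health service gets a zone: its home area plus queen neighbours to a
graph radius of 1 (primary) or 2 (intermediate), or the whole city
(high-complexity); radii are configuration keys because the source method
describes the tiers but not the radii, and zones overlap since several
services can serve one area. Weights within a zone are population shares,
so allocated cases are conserved exactly. Allocated cases are fractional
and stay fractional everywhere except the Poisson likelihood boundary,
where they are rounded half-to-even. Migrant-exclusive services contribute
to the overall rate *and* to a separate migrant rate whose denominator is
the total area population (no migrant population denominator exists).
A service exactly on a boundary goes to the containing area with the
lexicographically smallest id.

# The synthetic city

The generator emulates a mid-sized city of irregular census sections:

* **Lattice** — Voronoi tessellation of uniform points in a 7.2 km square
  (about 114,000 m² per area at the default 460), queen adjacency.
* **Populations** — lognormal, median 1,500, $\sigma_{\log} = 0.5$,
  floor 50: plausible for ~788k people over ~460 sections; population only
  enters through the offset.
* **Covariates** — unit-variance ICAR fields plus white noise
  (sd 0.4), affinely mapped to published-table-like ranges: migrant
  consultation rate 0–13 per 100, population under 15 between 10–30%,
  poverty index 0–86, economically-active index 35–70, population over 65
  between 5–25% (the published over-65 summary row is internally
  inconsistent and was not copied). This construction guarantees the
  positive Moran's I the screening stage expects.
* **Effects** — $\tau_u = 25$ (sd 0.2) and $\tau_{st} = 4$; ICAR draws are
  exact, via the spectral decomposition of the graph Laplacian with zero
  mass on the null eigenvector.
* **Intercept** — calibrated so the realised citywide expected rate is
  exactly 0.25 cases/person-year, matching the published mean rate of
  25.77 per 100.
* **Ground-truth coefficients** — exp(β) = 1.25 per unit migrant rate,
  1.08 per % under 15, 1.04 per poverty unit, zero elsewhere: the
  published effect sizes, reused as recoverable truth.
* **Services** — about one primary facility per 8 areas, one intermediate
  per 50, two high-complexity; case scattering prefers primary care with
  attraction weights 10 : 3 : 1, since ARI consultations are
  overwhelmingly primary-care visits. Counts are multinomially scattered
  to the services covering each area, so consultations conserve cases
  exactly.
* **Determinism** — one global seed; every stage derives its own seed from
  it by fixed offsets, and a regenerated city is identical bit for bit.

## What a green test does and does not establish

The generator produces smooth covariate fields, exact model counts and
clean service coverage. Real data differ: covariates are measured with
error, counts carry reporting artefacts, and facility catchments are not
graph-radius zones. Green recovery tests therefore validate the
*machinery* — they do not certify that the published point estimates would
be reproduced, and the published headline numbers (DIC, coefficient table,
hotspot counts) derive from confidential records that are not reproducible
here.

One limitation deserves emphasis. Zone re-allocation is a
population-share smooth over each service's zone. Information about the
area of origin is destroyed by facility-level aggregation, and no
weighting scheme can undo it: on synthetic cities the Spearman correlation
between allocated and true per-area cases is about 0.5 at the defaults and
stays near 0.65 even with one primary service per area. Consequently,
coefficient recovery is evaluated on the model path (true per-area counts);
fitting to re-allocated counts attenuates exp(β) = 1.25 to roughly 1.03.
Any real analysis built on this allocation method inherits the same
attenuation — a caveat worth carrying into interpretation.

# Risk mapping

Relative risks are posterior summaries of $\exp(u_i + st_i)$ — marginal
random effects only, so they measure residual area risk relative to the
citywide baseline after covariate adjustment. The exceedance probability
$\Pr(RR_i > 1.5 \mid y)$ with a 0.8 reporting threshold mirrors the
published decision rule; both are configuration keys. A hotspot is an area
with $RR > 1$ whose neighbours *all* have $RR > 1$ (the strictest reading
of "surrounded by"; a fractional rule is available), evaluated on the
posterior mean RR; perimeter areas are judged over their existing
neighbours only, and islands are never hot- or coldspots.

# Model selection

`compare_candidates()` reproduces the preliminary protocol: fit each
candidate (different priors, adjacency schemes, or covariate sets) on the
same data and seed, rank by DIC, flag differences under 2 as equivalent,
and exclude non-converged fits from the choice. The four default
hyperprior candidates — logGamma pairs (1, 0.01), (0.1, 0.1),
(0.001, 0.001), (1, 0.1) applied symmetrically — are a plausible
non-informative menu; the original four are not enumerated in the source.
`backward_eliminate()` drops, one at a time, the covariate whose credible
interval crosses 1 with the largest two-sided posterior tail probability,
refits until all survivors are credible, then re-adds all subsets of the
dropped covariates (capped at $2^5$) to check whether conclusions change,
and compares reduced against full model by the DIC < 2 rule. A covariate
whose interval excludes 1 is never dropped.

# Numerical choices

* Quintile coding is by rank with ties broken by canonical area order, so
  bin sizes differ by at most one and binning is idempotent under monotone
  transforms. The model consumes the continuous per-area PM10 average by
  default (a single-coefficient pollutant term), with quintile codes
  available by configuration; the source is ambiguous between the two.
* IDW power defaults to 2 (the common default of the GIS tool used for
  the original interpolation), evaluated at polygon centroids
  (`n_sample_points = 1`): with three stations the surface is smooth and
  the centroid is cheap and deterministic.
* VIF is computed by least squares of each covariate on the others;
  exact dependence reports `Inf` rather than failing. The flag threshold
  is 5.
* Canonical ordering: areas are sorted lexicographically by id once, in
  the lattice constructor; every vector and matrix downstream uses that
  order, which is what makes fits invariant to input ordering.
* Seeds stay below $2^{31}$; stage seeds are derived from the global seed
  by fixed affine offsets modulo a large prime.

# Known limitations

No age/sex standardisation (the source data lacked it too); no geodetic
coordinates; no zero-inflation or negative-binomial extension; the
nested-Laplace engine of the original analysis is not reimplemented — the
model density is the contract, and MCMC samples the same posterior. DIC
comparisons at small MCMC sizes carry Monte Carlo noise of the same order
as the equivalence band; use long runs for ledger decisions that matter.
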