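---
title: "Non-linear multilevel SEM mixtures: model, estimation, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Non-linear multilevel SEM mixtures: model, estimation, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mlsemm)
```

## The model

`mlsemm` works with two-level structural equation models in which both the
within level (individuals $i$ nested in clusters $k$) and the between level
(the clusters themselves) carry a full latent-variable model, and both
levels may be finite mixtures of such models.

At level 1, for an individual in latent class $C_{ik}=c$ of a cluster in
class $D_k=d$:

$$
y^{*}_{ik} = \nu_{1cd} + \Lambda_{1cd}\, f_1(\eta_{1ik}) +
             K_{1cd}\, g_1(x_{1ik}) + \epsilon_{1ik}, \qquad
\epsilon_{1ik} \sim N(0, \Theta_{1cd})
$$
$$
\eta_{1ik} = \alpha_{cd} + B_{1cd}\, F_1(\eta_{1ik}) +
             \Gamma_{1cd}\, G_1(x_{1ik}) + \zeta_{1ik}, \qquad
\zeta_{1ik} \sim N(0, \Psi_{1cd})
$$

with an analogous measurement/structural pair at level 2 for the cluster
latent vector $\eta_{2k}$ and cluster indicators $z_k$. Class membership
follows multinomial-logit models in observed covariates,
$\Pr(C_{ik}=c) \propto \exp(a_c + b_c' h_1(x_{1ik}))$ and likewise for
$D_k$. Any level-1 structural intercept or slope can be promoted to a
cluster random effect: it is removed from the parameter vector and read
from a position of $\eta_{2k}$ instead, which is how a random intercept
"travels" from the within model to the between model where latent
predictors, interactions, and mixtures explain it.

The functions $f, F, g, G, h$ are *function sets*: ordered collections of
terms drawn from a small language — linear terms, integer powers, pairwise
products (interactions), and truncated powers $(v-\xi)_+^p$. A cubic
spline with knots $\xi_1 < \xi_2$ is the set
$(v,\ v^2,\ v^3,\ (v-\xi_1)_+^3,\ (v-\xi_2)_+^3)$; the assembled piecewise
cubic is $C^2$ at each knot by construction. We use the truncated-power
basis rather than B-splines so that each coefficient remains directly
interpretable against published tables for this parameterization, at the
cost of poorer numerical conditioning (see *Ridge moves* below). Knots are
always user-fixed, never data-adaptive, and basis columns are not centered
by default — centering would change the meaning of the reported
coefficients. Constants are unrepresentable in the term language: freeing
an intercept inside a function set would destroy the identification of the
model's intercept parameters.

Observed indicators attach to the latent responses through links:
`identity` for continuous data, `ordered` for ordinal data (thresholds on
an underlying normal response, estimated by data augmentation), and
`poisson_log` for counts. Count indicators are supported in simulation
only; their estimation would need a non-conjugate augmentation scheme that
is out of scope here.

## Identification checks

`validate_identification()` runs necessary (not sufficient) checks:

1. every latent variable needs a scaling constraint (the default convention
   fixes the first loading of each latent at 1, which also keeps every
   conditional update conjugate), and for every measured latent either the
   latent intercept or an indicator intercept must be fixed;
2. the covariate sets $g$ and $G$ of a level must be term-disjoint —
   otherwise the same covariate effect would be estimated twice in one
   equation — while the latent sets $f$ and $F$ must merely differ (they
   routinely share linear terms, e.g. when spline bases include the linear
   term that also carries the loadings); only *active* terms (those with a
   free or non-zero coefficient) participate in either check;
3. level-2 exogenous latent predictors need measured scaling constraints of
   their own;
4. mixture reference classes are pinned at zero and any model with more
   than one class must carry an ordering constraint on exactly one
   intercept block.

The structural system must be recursive: a topological order over the
active terms of $F$ is required and cycles are rejected. The formal model
notation would allow simultaneity, but no recursive-conditionals sampler
can target such a system, so we rule it out rather than guess at semantics.

## Simulation

`simulate_dataset()` follows the generative order: level-2 class, level-2
latents (exogenous entries Gaussian per class, endogenous entries solved
recursively), cluster indicators; then per individual the level-1 class,
latents, indicators, and links. One master seed spawns an independent
substream per cluster, so enlarging a design extends the data without
reshuffling what was already generated. Covariate generators are user
hooks (standard normal by default) because covariates are "observed but
unexplained" in this model class. The generation truth (classes, latent
values, latent responses) is retained for recovery studies but never
written into the CSV exports.

`apply_mar_mask()` imposes missingness whose probability is logistic in a
fully observed covariate (or flat), calibrated to a target marginal rate —
missing at random by construction, which is the mechanism the estimator's
imputation step assumes.

The packaged example model (`twolevel_spline_fixture()`) is an
educational-assessment-style configuration: three pupil-level constructs
with three indicators each, latent cubic splines (knots at 2 and 3) from
two predictors into math skill, a school-level random math intercept
explained by two measured school constructs and their interaction, and a
two-class school-level mixture with heavily overlapping classes
(proportions 0.532/0.468, latent mean gaps about 0.17–0.19 against latent
SDs near 0.5). Cluster sizes are 1 + Poisson(6), matching a
many-small-clusters school survey design. Its generating values are
realistic published-scale estimates for a model of this structure, so
simulation studies run under conditions a real analysis would face —
including the weak identification that comes with them.

## Estimation

`run_gibbs()` is a Metropolis-within-Gibbs sampler with these blocks per
iteration:

* **Augmentation.** Ordinal indicators: truncated-normal draws of the
  underlying responses within their category's threshold interval, and
  uniform conditional draws of interior thresholds; the first cut point is
  fixed at 0 and the indicator's residual variance at 1 (the usual
  ordered-probit scale convention — the model statement alone fixes
  neither). Missing cells: normal imputation given the current latents
  (requiring a diagonal residual block for the affected indicator).
* **Latent variables.** In fully linear models, exact multivariate-normal
  draws per individual/cluster. Otherwise, each *conditionally linear*
  coordinate — one in which every active term is linear, which includes
  all interaction terms — gets an exact univariate Gaussian draw obtained
  by numerically extracting the linear residual representation; the
  remaining coordinates (those under powers or splines) move by joint
  random-walk Metropolis. Random coefficients are always conditionally
  linear in the cluster latents, so random-intercept and interaction
  structures mix through exact draws.
* **Classes.** $D_k$ and $C_{ik}$ from their multinomial full conditionals
  (prior logit probability times complete-data likelihood), sampled with
  log-sum-exp stabilization via the Gumbel-argmax identity. The number of
  level-1 classes is taken as common across level-2 classes; per-$d$
  counts would turn this update into a variable-dimension move.
* **Coefficients.** Row-wise conjugate Bayesian regressions. When a
  residual covariance block couples several rows, the row's regression
  conditions on the other rows' residuals (exact Gibbs). The designated
  class-ordered intercept block is parameterized as a base value plus
  positive increments: the base gets a normal conditional, each increment
  a truncated-normal conditional under its half-normal prior, so class
  order is strict in *every* draw and label switching cannot occur.
* **Precisions.** Wishart full conditionals per covariance block (the 1x1
  case is the familiar inverse-gamma option for diagonal residual
  matrices).
* **Mixture logits.** Random-walk Metropolis under independent normal
  priors; at the cluster level the proposal is evaluated against the
  likelihood with the class labels summed out (see below).
* **Mixing accelerators** (see *Weak identification and extra kernels*).

Random-walk step sizes adapt toward an acceptance rate of 0.3 during
burn-in only, so the post-burn-in kernel is fixed and detailed balance
holds for retained draws.

### Priors

Coefficient entries get normal priors with variance $H_0 \times s^2_r$,
where $s^2_r$ is a per-row data scale (indicator column variance or latent
proxy variance) fixed once before sampling. Keeping the scale fixed —
rather than conditioning on the current residual variance — makes the
joint prior coherent across the conjugate updates and the Metropolis
moves. Defaults: $H_0 = 10$ for coefficients (prior SD about three
residual SDs), a half-normal with multiplier $H_{0\Delta} = 1$ for ordered
class increments, and SD 2.5 for mixture logits. The tighter defaults on
the mixture side are deliberate: with heavily overlapping classes, a
nearly flat prior lets an emptied class wander arbitrarily far before
being repopulated, and flat priors on quasi-collinear spline bases allow
unbounded drift along near-ridge directions; weakly informative priors are
standard practice for exactly these situations. All of this is adjustable
through `prior_spec()`.

### Weak identification and extra kernels

Three slow directions dominate the posterior geometry of realistic
configurations, and plain one-block-at-a-time Gibbs crosses each of them
far too slowly for desk-scale studies (we observed chains that still
disagreed after 8,000 iterations while agreeing on everything else). The
sampler therefore carries four additional kernels, each a valid
Metropolis or partially collapsed Gibbs move on the exact posterior:

* **Ridge recentering.** A truncated-power basis has no intercept column,
  but over a bounded data range its columns combine into a nearly constant
  function, which trades off against the downstream intercept — in a
  random-intercept model, against the whole vector of cluster effects and
  their level-2 mean. One symmetric Metropolis move per (endogenous row,
  spline variable) pair shifts the basis coefficients along a precomputed
  least-squares-constant direction by $c$ while shifting the compensating
  intercept by $-c$; the direction is a fixed function of the data, so
  only the level-1 structural likelihood and the shifted priors enter the
  ratio.
* **Factor scale moves.** The split of an indicator block's variance
  between loadings, latent variance, and residual variances
  ($\lambda^2\psi + \theta$) is pinned only by the fixed scaling loading.
  A multiplicative move rescales a latent's deviations by $\phi$, its
  disturbance row/column by $\phi$, free loadings by $1/\phi$, and shifts
  free intercepts so every compensated row's fit is exactly unchanged;
  the Jacobian of the map and the Wishart/normal prior ratios enter the
  acceptance probability.
* **Class-marginal mixture updates.** With heavily overlapping classes,
  logit coefficients and ordered class-mean increments conditioned on the
  current labels move only as fast as the labels do. Both are therefore
  proposed against the likelihood with the cluster labels summed out
  (log-sum-exp over classes), and the labels are refreshed from their
  full conditional immediately afterwards — a standard partially
  collapsed scheme.
* **Collapsed random-outcome regression.** When a cluster random effect
  is a pure outcome (no indicators of its own, no downstream terms), the
  coefficients of its structural equation are drawn with the random
  effect integrated out: the precision-weighted cluster means of the
  mapped level-1 residuals are exact Gaussian pseudo-observations with
  variance $\psi_{2,uu} + \psi_{1,rr}/n_k$, and the random-effect column
  is re-drawn from its full conditional right after.

Without these kernels the convergence diagnostic stays far above its 1.2
threshold at any feasible iteration count for the packaged example; with
them, three chains of a few thousand iterations suffice.

### Diagnostics and comparison

`epsr()` implements the classic non-split multi-chain potential scale
reduction, with convergence conventionally declared below 1.2;
byte-identical chains report exactly 1. `posterior_summary()` reports the
mean, posterior SD (as `se`), $t = $ mean/SD, and 2.5/50/97.5 percentiles,
pooled across chains. `dic()` uses the deviance that is *marginal over the
latent classes* (log-sum-exp over both class variables) but *conditional
on the continuous latent variables*, with $p_D = \bar D - D(\bar\theta)$
evaluated at the posterior means of parameters and latents; the variant is
recorded in the result because DIC is not unique in mixture models.
`relabel()` provides post-hoc relabeling by class means or proportions for
draws produced without the ordering constraint; when the constraint was
active it is the identity.

`marginal_loglik_small()` is a deliberately independent cross-check: it
evaluates the observed-data likelihood of tiny models (at most 3 latent
dimensions, 2 classes per level, 50 clusters) by nested Gauss-Hermite
quadrature in disturbance space, where the recursive structural map has
unit Jacobian so non-linear structural functions are handled exactly on
the grid. The grid is not adaptively recentered, so roughly twice the
nodes of an adaptive scheme are needed: with 80 nodes per dimension it
matches closed-form Gaussian likelihoods to about $10^{-6}$ on the scales
we test. Combined with a parameter grid it yields quadrature posteriors
against which the sampler is verified end to end.

## What the tests do and do not show

The test suite verifies the machinery on data generated by the package's
own simulator: exact conditionals against analytic posteriors
(hierarchical normal–normal), sampler-vs-quadrature agreement on a tiny
non-linear model, moment recovery of the simulator, classification against
a brute-force Bayes oracle, strict class ordering, EPSR behavior, DIC
parsimony when a mixture is superfluous, and parameter recovery on the
packaged model with and without 10% missingness. Problem sizes are scaled
to what a careful desk study would use — recovery runs use K = 100
clusters of mean size 7 with 3 chains of 4,000 iterations each (half
burn-in), replicated twice plus once under missingness; the mixture
DIC comparison uses 10 replications of K = 80 clusters; the quadrature
oracle runs at n around 50.
Passing these tests shows the algorithms target the stated posterior under
the stated model. It does not show that the model fits any particular real
dataset, that parcels or links are appropriate for a given survey, or that
the necessary identification checks are sufficient for exotic
specifications.

## Known limitations

* Count and logistic measurement models are simulation-only.
* Random factor loadings and random mixture-logit coefficients are not
  estimated.
* The level-2 measurement block of a small-K mixture model (here, 100
  clusters with overlapping classes) is genuinely data-weak; its loadings
  and intercepts carry wide, slowly mixing posteriors, which is a property
  of the design rather than of the sampler.
* Non-recursive (simultaneous) structural systems are rejected.
* The DIC variant conditions on continuous latents; comparing it against a
  fully marginal DIC from other software is not meaningful. More
  importantly, this variant under-penalizes mixture components: a
  superfluous second class can fit the realized random-effect sample
  in-sample with a gain of the same order as its ~2-point complexity
  penalty, so DIC comparisons between class counts discriminate only
  weakly (our simulations find the parsimonious model preferred in about
  six of ten mixture-free replications, not reliably more). This is the
  well-documented difficulty of DIC in mixture models; treat such
  comparisons as suggestive, never decisive.
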