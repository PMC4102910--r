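# mlsemm

Non-linear multilevel structural equation mixture models: specification,
simulation, and Bayesian (Metropolis-within-Gibbs) estimation.

## What this solves, and for whom

Clustered social-science data — pupils in schools, patients in clinics —
often need all three of the following at once: latent variables measured by
multiple indicators, *non-linear* structural relations among those latent
variables (interactions, polynomials, splines), and non-normality or
unobserved heterogeneity captured by finite mixtures. Standard SEM software
covers each piece separately; `mlsemm` implements the combined model for
methodologists and applied researchers who want to simulate from it, fit
it, and check what designs can actually recover.

The model couples a within (individual) level and a between (cluster)
level. At level 1, class-conditional measurement and structural models

$$y^*_{ik} = \nu_1 + \Lambda_1 f_1(\eta_{1ik}) + K_1 g_1(x_{1ik}) + \epsilon_{1ik},
\qquad
\eta_{1ik} = \alpha + B_1 F_1(\eta_{1ik}) + \Gamma_1 G_1(x_{1ik}) + \zeta_{1ik},$$

where the function sets $f_1, F_1, g_1, G_1$ contain linear terms, powers,
pairwise products, and truncated powers $(v-\xi)_+^p$ (so latent cubic
splines and interactions are first-class citizens). An analogous pair
governs the cluster latents $\eta_{2k}$ and cluster indicators $z_k$. Any
level-1 intercept or slope can be a cluster random effect: it becomes a
coordinate of $\eta_{2k}$, where latent cluster predictors, their
interactions, and a cluster-level mixture explain it. Class memberships
follow multinomial-logit models; indicators may be continuous, ordinal
(estimated via threshold augmentation), or counts (simulation only).
Estimation is Bayesian with conjugate updates wherever the model is
linear-in-parameters, exact Gaussian draws for conditionally linear latent
coordinates, random-walk Metropolis elsewhere, and ordered-increment priors
that make mixture label switching impossible by construction.

## A worked example

The packaged example model is an educational-assessment-style two-level
design: three pupil constructs (attitude toward reading, experienced
teaching strategies, math skill) with three indicators each, latent cubic
splines (knots at 2 and 3) from the first two into math skill, and a
school-level random math intercept explained by two latent school
characteristics, their interaction, and a two-class school mixture.

```r
library(mlsemm)

spec <- twolevel_spline_fixture()
validate_identification(spec)
#> identification report: PASS
#>   rule 1: 11/11 checks pass
#>   rule 2: 5/5 checks pass
#>   rule 3: 2/2 checks pass
#>   rule 4: 3/3 checks pass

data <- simulate_fixture(spec, K = 100, seed = 42)
data
#> <mlsem data> 714 individuals in 100 clusters; 9 y, 6 z indicators

fit <- run_gibbs(spec, data,
                 settings = sampler_settings(chains = 3, iterations = 4000,
                                             burn_in = 2000, seed = 9))
summ <- posterior_summary(fit)
print(summ[summ$parameter %in%
             c("L2.B.3.1", "L2.B.3.2", "L2.B.3.3", "L2.mu.3"), ])
#>  parameter   mean    se      t   q2.5    q50 q97.5
#>    L2.mu.3  0.123 0.716  0.172 -1.265  0.118 1.578
#>   L2.B.3.1  0.234 0.246  0.950 -0.222  0.223 0.740
#>   L2.B.3.2  0.151 0.243  0.621 -0.291  0.142 0.658
#>   L2.B.3.3 -0.123 0.119 -1.035 -0.368 -0.120 0.095
round(max(epsr(fit)), 3)
#> [1] 1.162
```

The three `L2.B.3.*` rows are the school-level effects of the two latent
school characteristics and of their interaction on the random math
intercept; the generating values were 0.558, 0.442, and -0.289, and each
95% interval covers its generating value. The intervals are wide and the
point estimates attenuated: with 100 schools and heavily overlapping
mixture classes, the school-level part of this design carries little
information, and the posterior honestly says so. `L2.mu.3` is the
intercept of that equation — in a spline model its posterior is
additionally widened because a truncated-power basis can almost reproduce
a constant, a weak identification the sampler bridges with a dedicated
ridge move (see the vignette). `epsr()` reports the multi-chain
potential-scale-reduction convergence diagnostic (converged below 1.2 by
convention).

Models can equally be declared in YAML (`read_model_config()` /
`write_model_config()`), datasets exchanged as two CSV files
(`write_dataset()` / `read_dataset()`), and everything driven from a shell
via the thin CLI in `inst/cli/mlsemm` (subcommands `simulate`, `fit`,
`diagnose`, `summarize`, `fixture`).

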