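test_that("identical seeds give identical draws", {
  spec <- nn_model()
  d <- simulate_dataset(spec, 10, cluster_size_plan(n = 4), seed = 2)
  st <- sampler_settings(chains = 2, iterations = 80, burn_in = 40,
                         seed = 123)
  dr1 <- run_gibbs(spec, d, settings = st)
  dr2 <- run_gibbs(spec, d, settings = st)
  expect_identical(dr1$draws, dr2$draws)
  expect_identical(dr1$deviance, dr2$deviance)
})

test_that("misidentified models are refused before sampling", {
  g <- function_spec(list(term_linear(1)), arity = 1)
  meas <- measurement_spec(
    f = lin1(1), lambda = cbind(c(1, 0.8)),
    lambda_free = cbind(c(FALSE, TRUE)),
    nu = c(0, 0), nu_free = cbind(c(FALSE, TRUE)),
    theta = c(0.3, 0.3), g = g, kappa = cbind(c(0.2, 0.2)),
    kappa_free = cbind(c(TRUE, TRUE)))
  struct <- structural_spec(
    F = lin1(1), B = matrix(0, 1, 1), B_free = matrix(FALSE, 1, 1),
    alpha = 0, psi = 0.5, G = g, gamma = matrix(0.1, 1, 1),
    gamma_free = matrix(TRUE, 1, 1))
  spec <- model_spec(meas, struct)
  d <- simulate_dataset(spec, 10, cluster_size_plan(n = 3), seed = 1)
  expect_error(run_gibbs(spec, d), "identification")
})

test_that("well-separated cluster classes are recovered almost surely", {
  spec <- mix2_model(gap = 5 * sqrt(0.4))
  d <- simulate_dataset(spec, 400, cluster_size_plan(n = 8), seed = 31)
  expect_true(length(unique(d$truth$D)) == 2)
  # white-box: run a few full update cycles from the generating parameters
  fit <- mlsemm:::prep_fit(spec, d)
  fit$data <- d
  set.seed(99)
  st <- mlsemm:::init_state(fit, default_priors(), sampler_settings(), 1)
  st$spec <- fit$spec   # generating parameter values
  votes <- matrix(0L, fit$K, 2)
  for (i in 1:60) {
    st <- mlsemm:::update_eta1(st, fit)
    st <- mlsemm:::update_eta2(st, fit)
    st <- mlsemm:::update_classes(st, fit)
    if (i > 10) votes[cbind(seq_len(fit$K), st$D)] <-
        votes[cbind(seq_len(fit$K), st$D)] + 1L
  }
  map <- max.col(votes)
  # brute-force oracle: exact per-cluster class posterior from the
  # closed-form marginal y_k ~ N(mu_d 1, psi2 J + (psi1 + theta) I)
  s2 <- 0.3 + 0.2
  oracle <- vapply(seq_len(fit$K), function(k) {
    yk <- d$y[d$cluster == k, 1]
    S <- matrix(0.4, length(yk), length(yk)) + diag(s2, length(yk))
    ll <- vapply(c(1, 1 + 5 * sqrt(0.4)), function(m)
      mvtnorm_logdens(yk, rep(m, length(yk)), S), 0)
    which.max(ll)
  }, 0L)
  confident <- vapply(seq_len(fit$K), function(k) {
    yk <- d$y[d$cluster == k, 1]
    S <- matrix(0.4, length(yk), length(yk)) + diag(s2, length(yk))
    ll <- vapply(c(1, 1 + 5 * sqrt(0.4)), function(m)
      mvtnorm_logdens(yk, rep(m, length(yk)), S), 0)
    abs(diff(ll)) > log(9)
  }, TRUE)
  # the sampler reproduces the oracle on every confidently classified
  # cluster, and the oracle itself recovers the generating classes there
  expect_gt(mean(map[confident] == oracle[confident]), 0.99)
  expect_gt(mean(oracle[confident] == d$truth$D[confident]), 0.99)
  expect_gt(mean(confident), 0.95)
})

test_that("posterior class probabilities reduce to the prior when classes tie", {
  spec <- mix2_model(gap = 0, psi1 = 0.3)
  # both classes identical and a2 = 0.8: conditional must equal the prior
  spec$l2$mix$a$values[[1]][2, 1] <- 0.8
  d <- simulate_dataset(spec, 2000, cluster_size_plan(n = 2), seed = 17)
  fit <- mlsemm:::prep_fit(spec, d)
  fit$data <- d
  set.seed(5)
  st <- mlsemm:::init_state(fit, default_priors(), sampler_settings(), 1)
  st$spec <- fit$spec
  st <- mlsemm:::update_classes(st, fit)
  p_expected <- exp(0.8) / (1 + exp(0.8))
  expect_lt(abs(mean(st$D == 2) - p_expected), 0.03)
})

test_that("Metropolis acceptance lands in the target band after adaptation", {
  spec <- twolevel_spline_fixture()
  d <- simulate_fixture(spec, K = 40, seed = 12)
  dr <- run_gibbs(spec, d, settings = sampler_settings(
    chains = 1, iterations = 500, burn_in = 300, seed = 2,
    deviance_every = 50))
  acc <- dr$accept[[1]]$eta1
  expect_gt(acc, 0.2)
  expect_lt(acc, 0.5)
})

test_that("precision draws concentrate on the residual mean square", {
  set.seed(21)
  cs <- mlsemm:::cov_spec(diag(2, 3), blocks = list(1:2, 3))
  E <- matrix(rnorm(6000 * 3), 6000, 3) %*% chol(diag(c(1.5, 0.7, 2.2)))
  pri <- default_priors()
  draws <- replicate(200, {
    cs2 <- mlsemm:::draw_cov(cs, E, rep(1L, 6000), rep(1L, 6000), 1L, pri)
    diag(mlsemm:::cov_get(cs2))
  })
  post_mean <- rowMeans(draws)
  emp <- colMeans(E^2)
  expect_lt(max(abs(post_mean / emp - 1)), 0.02)
})

test_that("empty classes fall back to prior draws for their precisions", {
  cs <- mlsemm:::cov_spec(matrix(1), vary = "d", n_groups = 2L)
  E <- matrix(rnorm(500, 0, 3), 500, 1)
  pri <- default_priors()
  set.seed(3)
  d2 <- replicate(300, {
    cs2 <- mlsemm:::draw_cov(cs, E, rep(1L, 500), rep(1L, 500), 1L, pri)
    cs2$values[[2]][1, 1]
  })
  # group 2 never sees data: draws follow the prior (scale 0.5, df 3),
  # i.e. an inverse gamma with mean 0.5 / (3 - 2)
  expect_lt(abs(median(d2) - 0.5 / qchisq(0.5, 3)) /
              (0.5 / qchisq(0.5, 3)), 0.35)
  d1 <- replicate(50, {
    cs2 <- mlsemm:::draw_cov(cs, E, rep(1L, 500), rep(1L, 500), 1L, pri)
    cs2$values[[1]][1, 1]
  })
  expect_lt(abs(mean(d1) - 9), 1.5)
})

test_that("ordinal indicators are estimated through augmentation", {
  spec <- factor_model(free = "none")
  spec$y_links[[1]] <- indicator_spec("ordered", n_categories = 3,
                                      thresholds = c(0, 0.8))
  spec <- model_spec(
    measurement_spec(f = lin1(1), lambda = cbind(c(1, 0.8, 1.2)),
                     lambda_free = cbind(c(FALSE, TRUE, FALSE)),
                     nu = c(0, 0.3, -0.2),
                     nu_free = cbind(c(TRUE, FALSE, FALSE)),
                     theta = c(1, 0.4, 0.5),
                     theta_free = c(FALSE, FALSE, FALSE)),
    structural_spec(F = lin1(1), B = matrix(0, 1, 1),
                    B_free = matrix(FALSE, 1, 1), alpha = 0.5,
                    alpha_free = matrix(FALSE, 1, 1),
                    psi = 0.8, psi_free = FALSE),
    y_links = list(indicator_spec("ordered", n_categories = 3,
                                  thresholds = c(0, 0.8)),
                   indicator_spec(), indicator_spec()))
  d <- simulate_dataset(spec, 120, cluster_size_plan(n = 4), seed = 14)
  expect_true(all(d$y[, 1] %in% 1:3))
  dr <- run_gibbs(spec, d, settings = sampler_settings(
    chains = 2, iterations = 400, burn_in = 200, seed = 8,
    deviance_every = 20))
  s <- posterior_summary(dr)
  tau2 <- s[s$parameter == "tau.y1.2", ]
  expect_gt(tau2$mean, 0)          # above the fixed first cut point
  expect_lt(abs(tau2$mean - 0.8), 0.35)
  lam <- s[s$parameter == "L1.lambda.2.1", ]
  expect_lt(abs(lam$mean - 0.8), 0.3)
})

test_that("missing-at-random cells are imputed inside the sampler", {
  spec <- nn_model()
  d <- simulate_dataset(spec, 40, cluster_size_plan(n = 6), seed = 3)
  dm <- apply_mar_mask(d, 0.15, seed = 4)
  dr <- run_gibbs(spec, dm, settings = sampler_settings(
    chains = 2, iterations = 500, burn_in = 250, seed = 5,
    deviance_every = 25))
  s <- posterior_summary(dr)
  expect_lt(abs(s$mean[s$parameter == "L2.mu.1"] - 1), 0.5)
  # masking widens the posterior relative to complete data
  dr0 <- run_gibbs(spec, d, settings = sampler_settings(
    chains = 2, iterations = 500, burn_in = 250, seed = 5,
    deviance_every = 25))
  s0 <- posterior_summary(dr0)
  expect_gt(s$se[1], 0.8 * s0$se[1])
})

test_that("the factor-scale kernel leaves the factor-model posterior honest", {
  # the scale move trades loading, latent-variance, and residual scale;
  # if its Jacobian or prior bookkeeping were wrong, loadings and psi
  # would drift systematically. Check recovery at moderate n.
  spec <- factor_model()
  d <- simulate_dataset(spec, 150, cluster_size_plan(n = 4), seed = 9)
  st <- sampler_settings(chains = 2, iterations = 1200, burn_in = 500,
                         seed = 3, deviance_every = 100)
  fitted <- run_gibbs(spec, d, settings = st)
  expect_false(anyNA(fitted$accept[[1]]$fscale))
  full <- posterior_summary(fitted)
  truth <- parameter_values(spec)
  rownames(full) <- full$parameter
  for (p in c("L1.lambda.2.1", "L1.lambda.3.1", "L1.psi.1.1",
              "L1.alpha.1")) {
    expect_lt(abs(full[p, "mean"] - truth[p]) / max(full[p, "se"], 0.02), 4)
  }
})

test_that("cluster order does not change the posterior", {
  spec <- nn_model()
  d <- simulate_dataset(spec, 16, cluster_size_plan(n = 5), seed = 20)
  # permute cluster blocks
  perm <- sample(16)
  ord <- order(match(d$cluster, perm))
  d2 <- d
  d2$y <- d$y[ord, , drop = FALSE]
  d2$cluster <- match(d$cluster, perm)[ord]
  d2$z <- d$z[perm, , drop = FALSE]
  d2$x2 <- d$x2[perm, , drop = FALSE]
  d2$y_miss <- d$y_miss[ord, , drop = FALSE]
  d2$z_miss <- d$z_miss[perm, , drop = FALSE]
  d2$truth <- NULL
  st <- sampler_settings(chains = 2, iterations = 450, burn_in = 225,
                         seed = 2, deviance_every = 50)
  m1 <- posterior_summary(run_gibbs(spec, d, settings = st))$mean
  m2 <- posterior_summary(run_gibbs(spec, d2, settings = st))$mean
  expect_lt(abs(m1 - m2), 0.06)
})
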