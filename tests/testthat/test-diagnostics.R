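fake_draws <- function(chains, pnames = colnames(chains[[1]])) {
  structure(list(draws = chains, deviance = rep(list(NA_real_),
                                                length(chains)),
                 parameters = pnames, accept = list(), settings = NULL,
                 spec = NULL, latent_means = NULL, data_dims = NULL),
            class = "mlsem_draws")
}

test_that("EPSR is exactly 1 for identical chains and flags separation", {
  set.seed(1)
  x <- matrix(rnorm(2000), 1000, 2, dimnames = list(NULL, c("a", "b")))
  expect_equal(unname(epsr(list(x, x))), c(1, 1))
  # two chains offset by 5 within-chain SDs
  y <- x
  y[, 1] <- y[, 1] + 5 * sd(x[, 1])
  e <- epsr(list(x, y))
  expect_gt(e["a"], 1.2)
  expect_lt(e["b"], 1.05)
  # direct formula evaluation as the oracle
  n <- nrow(x)
  W <- mean(c(var(x[, 1]), var(y[, 1])))
  B <- n * var(c(mean(x[, 1]), mean(y[, 1])))
  expect_equal(unname(e["a"]), sqrt(((n - 1) / n * W + B / n) / W))
  expect_error(epsr(list(x)), "2 chains")
})

test_that("EPSR of well-mixed chains stays near 1", {
  set.seed(4)
  chains <- replicate(3, matrix(rnorm(1e4), ncol = 1,
                                dimnames = list(NULL, "p")),
                      simplify = FALSE)
  e <- epsr(chains)
  expect_gte(e, 1 - 1e-12)
  expect_lt(e, 1.05)
})

test_that("posterior summaries report mean, SE, t, and percentiles", {
  x <- matrix(0.5, 100, 1, dimnames = list(NULL, "c"))
  s <- posterior_summary(list(x))
  expect_equal(s$mean, 0.5)
  expect_equal(s$se, 0)
  expect_equal(s$q2.5, 0.5)
  expect_true(is.infinite(s$t) && s$t > 0)

  set.seed(2)
  z <- matrix(rnorm(1e5), ncol = 1, dimnames = list(NULL, "z"))
  s2 <- posterior_summary(list(z))
  expect_lt(abs(s2$q2.5 - (-1.96)), 0.02)
  expect_lt(abs(s2$q50 - 0), 0.02)
  expect_lt(abs(s2$q97.5 - 1.96), 0.02)

  # t-value convention: posterior mean over posterior SD
  w <- as.numeric(scale(rnorm(5000))) * 0.101 + 0.558
  s3 <- posterior_summary(list(matrix(w, ncol = 1,
                                      dimnames = list(NULL, "b3"))))
  expect_equal(s3$t, 0.558 / 0.101, tolerance = 1e-6)

  # pooling is invariant to chain order
  a <- matrix(rnorm(500), ncol = 1, dimnames = list(NULL, "p"))
  b <- matrix(rnorm(500), ncol = 1, dimnames = list(NULL, "p"))
  expect_equal(posterior_summary(list(a, b)),
               posterior_summary(list(b, a)))
})

test_that("quadrature marginal likelihood matches closed forms", {
  # no latent influence: pin the latent scale to (nearly) zero so the
  # marginal is a plain Gaussian likelihood
  spec <- factor_model(free = "none")
  d <- simulate_dataset(spec, 30, cluster_size_plan(n = 1), seed = 5)
  ll_q <- marginal_loglik_small(spec, d, nodes = 80)
  lam <- c(1, 0.8, 1.2)
  S <- 0.8 * lam %*% t(lam) + diag(c(0.3, 0.4, 0.5))
  mu <- c(0, 0.3, -0.2) + lam * 0.5
  Si <- solve(S)
  ld <- determinant(S)$modulus
  ll_c <- sum(apply(d$y, 1, function(yy)
    -0.5 * (3 * log(2 * pi) + ld + t(yy - mu) %*% Si %*% (yy - mu))))
  expect_lt(abs(ll_q - ll_c), 1e-6)
})

test_that("quadrature converges in the node count and guards its scope", {
  spec <- quad_model()
  d <- simulate_dataset(spec, 25, cluster_size_plan(n = 2), seed = 9)
  l120 <- marginal_loglik_small(spec, d, nodes = 120)
  l240 <- marginal_loglik_small(spec, d, nodes = 240)
  expect_lt(abs(l240 - l120), 1e-4)
  big <- twolevel_spline_fixture()
  dbig <- simulate_fixture(big, K = 10, seed = 1)
  expect_error(marginal_loglik_small(big, dbig), "3 latent dimensions")
})

test_that("DIC decomposes exactly and penalizes duplicated classes", {
  spec <- mix2_model(gap = 0.8)
  d <- simulate_dataset(spec, 60, cluster_size_plan(n = 6), seed = 13)
  dr <- run_gibbs(spec, d, settings = sampler_settings(
    chains = 2, iterations = 400, burn_in = 200, seed = 3,
    deviance_every = 4))
  out <- dic(dr, data = d)
  expect_equal(out$dic, out$D_hat + 2 * out$pD, tolerance = 1e-8)
  expect_equal(out$dic, out$D_bar + out$pD, tolerance = 1e-8)
  expect_gt(out$pD, 0)
})

test_that("relabeling restores monotone class means after permutation", {
  spec <- mix2_model(gap = 1)
  d <- simulate_dataset(spec, 50, cluster_size_plan(n = 6), seed = 23)
  dr <- run_gibbs(spec, d, settings = sampler_settings(
    chains = 2, iterations = 300, burn_in = 150, seed = 4,
    deviance_every = 30))
  # constraint was active: relabel must be the identity
  expect_identical(relabel(dr)$draws, dr$draws)
  # artificially permute half the draws
  drp <- dr
  cols <- c("L2.mu.1.d1", "L2.mu.1.d2")
  for (ch in seq_along(drp$draws)) {
    n <- nrow(drp$draws[[ch]])
    flip <- seq_len(n) %% 2 == 0
    tmp <- drp$draws[[ch]][flip, cols[1]]
    drp$draws[[ch]][flip, cols[1]] <- drp$draws[[ch]][flip, cols[2]]
    drp$draws[[ch]][flip, cols[2]] <- tmp
    drp$draws[[ch]][flip, "mixD.a.2"] <- -drp$draws[[ch]][flip, "mixD.a.2"]
  }
  fixed <- relabel(drp)
  for (ch in seq_along(fixed$draws)) {
    expect_true(all(fixed$draws[[ch]][, "L2.mu.1.d2"] >
                      fixed$draws[[ch]][, "L2.mu.1.d1"]))
  }
  # single class: no-op
  spec1 <- mix2_model(n_classes = 1L)
  d1 <- simulate_dataset(spec1, 20, cluster_size_plan(n = 4), seed = 2)
  dr1 <- run_gibbs(spec1, d1, settings = sampler_settings(
    chains = 2, iterations = 150, burn_in = 75, seed = 5,
    deviance_every = 20))
  expect_identical(relabel(dr1)$draws, dr1$draws)
})

test_that("the diagnostics report combines EPSR, acceptance, and DIC", {
  spec <- nn_model()
  d <- simulate_dataset(spec, 20, cluster_size_plan(n = 4), seed = 6)
  dr <- run_gibbs(spec, d, settings = sampler_settings(
    chains = 2, iterations = 300, burn_in = 150, seed = 7,
    deviance_every = 10))
  rep <- diagnostics_report(dr, data = d)
  expect_true(is.numeric(rep$epsr))
  expect_equal(rep$converged, all(rep$epsr < 1.2))
  expect_true(rep$dic$pD > 0 || abs(rep$dic$pD) < 5)
})
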