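test_that("class probabilities follow the multinomial logit", {
  mix <- mixture_spec(2)
  expect_equal(as.numeric(class_probs(mix)), c(0.5, 0.5))
  mix2 <- mixture_spec(2, a = c(log(3), 0))
  # reference class pinned at 0, so a = (0, -log 3): softmax arithmetic
  expect_equal(as.numeric(class_probs(mixture_spec(2, a = c(0, -log(3))))),
               c(0.75, 0.25))
  h <- function_spec(list(term_linear(1)), arity = 1)
  mix3 <- mixture_spec(3, h = h, a = c(0, 0.4, -0.2),
                       b = rbind(0, 1.2, -0.5))
  set.seed(2)
  X <- matrix(rnorm(50), 50, 1)
  p <- class_probs(mix3, X)
  expect_equal(rowSums(p), rep(1, 50))
  expect_true(all(p > 0 & p < 1))
})

test_that("simulated class frequencies match their probabilities", {
  mix <- mixture_spec(2, a = c(0, log(0.468 / 0.532)))
  set.seed(11)
  cls <- draw_class(mix, matrix(0, 1e5, 0))
  expect_lt(abs(mean(cls == 1) - 0.532), 0.005)
})

test_that("simulation is reproducible and clusters use substreams", {
  spec <- nn_model()
  d1 <- simulate_dataset(spec, 12, cluster_size_plan(n = 4), seed = 5)
  d2 <- simulate_dataset(spec, 12, cluster_size_plan(n = 4), seed = 5)
  expect_identical(d1, d2)
  # extending the cluster count leaves existing clusters untouched
  d3 <- simulate_dataset(spec, 15, cluster_size_plan(n = 4), seed = 5)
  expect_equal(d3$y[d3$cluster <= 12, , drop = FALSE], d1$y)
  expect_equal(d3$truth$eta2[1:12, , drop = FALSE], d1$truth$eta2)
})

test_that("the noise-free limit follows the deterministic mean path", {
  spec <- nn_model(mu = 2, psi1 = 1e-12, theta = 1e-12, psi2 = 1e-12)
  d <- simulate_dataset(spec, 5, cluster_size_plan(n = 3), seed = 1)
  expect_equal(as.numeric(d$y), rep(2, 15), tolerance = 1e-4)
})

test_that("interaction effects propagate through the generative path", {
  # with Prob = Soc = c fixed (zero latent variance), the random intercept
  # mean is mu3 + (b3+b4) c + b5 c^2
  spec <- twolevel_spline_fixture(n_classes = 1)
  spec$l2$struct$psi$values[[1]][1:2, 1:2] <- diag(1e-12, 2)
  cc <- 2.0
  spec$l2$struct$alpha$values[[1]][1:2, 1] <- cc
  set.seed(3)
  d <- simulate_dataset(spec, 400, cluster_size_plan(n = 2), seed = 3)
  expected <- -0.365 + (0.558 + 0.442) * cc - 0.289 * cc^2
  got <- mean(d$truth$eta2[, 3])
  se <- sd(d$truth$eta2[, 3]) / sqrt(400)
  expect_lt(abs(got - expected), 3 * se)
})

test_that("ordered links bin the latent responses at the thresholds", {
  spec <- factor_model()
  spec$y_links[[1]] <- indicator_spec("ordered", n_categories = 3,
                                      thresholds = c(0, 1))
  spec$pmap <- mlsemm:::build_pmap(spec)
  d <- simulate_dataset(spec, 50, cluster_size_plan(n = 4), seed = 8)
  ys <- d$truth$ystar[, 1]
  expect_equal(unname(d$y[, 1]),
               as.numeric(cut(ys, c(-Inf, 0, 1, Inf), labels = FALSE)))
  expect_true(all(d$y[, 1] %in% 1:3))
})

test_that("count indicators draw from the log-linked Poisson", {
  spec <- factor_model()
  spec$y_links[[2]] <- indicator_spec("poisson_log")
  d <- simulate_dataset(spec, 300, cluster_size_plan(n = 5), seed = 9)
  counts <- d$y[, 2]
  expect_true(all(counts >= 0 & counts == floor(counts)))
  # marginal mean of a log-normal-rate Poisson: E[exp(ystar)]
  expect_lt(abs(mean(counts) - mean(exp(d$truth$ystar[, 2]))), 0.4)
})

test_that("MAR masking hits its target rate and stays MAR", {
  g <- function_spec(list(term_linear(1)), arity = 1)
  spec <- factor_model()
  # add a covariate so masking can depend on it
  spec2 <- model_spec(
    measurement_spec(f = lin1(1), lambda = cbind(c(1, 0.8, 1.2)),
                     lambda_free = cbind(c(FALSE, TRUE, TRUE)),
                     nu = c(0, 0.3, -0.2),
                     nu_free = cbind(c(FALSE, TRUE, TRUE)),
                     theta = c(0.3, 0.4, 0.5),
                     g = g, kappa = cbind(c(0, 0, 0.5)),
                     kappa_free = cbind(c(FALSE, FALSE, TRUE))),
    structural_spec(F = lin1(1), B = matrix(0, 1, 1),
                    B_free = matrix(FALSE, 1, 1), alpha = 0.5,
                    psi = 0.8))
  d <- simulate_dataset(spec2, 700, cluster_size_plan(n = 5), seed = 4)
  expect_identical(apply_mar_mask(d, 0), d)
  dm <- apply_mar_mask(d, 0.1, predictor = 1, seed = 6)
  expect_lt(abs(mean(dm$y_miss) - 0.1), 0.01)
  expect_true(all(is.na(dm$y[dm$y_miss])))
  # masking probability varies with the covariate (MAR, not MCAR)
  rate_hi <- mean(dm$y_miss[d$x1[, 1] > 0.5, ])
  rate_lo <- mean(dm$y_miss[d$x1[, 1] < -0.5, ])
  expect_gt(rate_hi, rate_lo)
  # masking again at rate 0 keeps existing mask (idempotent on masked cells)
  expect_identical(apply_mar_mask(dm, 0), dm)
})

test_that("single draws agree with the vectorized generator", {
  spec <- twolevel_spline_fixture()
  set.seed(10)
  l2 <- draw_level2(spec, d = 2)
  expect_length(l2$eta2, 3)
  expect_length(l2$z, 6)
  l1 <- draw_level1(spec, c = 1, d = 2, eta2 = l2$eta2)
  expect_length(l1$y, 9)
  # the random intercept flows from eta2 into the Math equation:
  # with all level-1 noise removed, Math equals alpha3 plus spline terms
  spec0 <- twolevel_spline_fixture()
  spec0$l1$struct$psi$values[[1]] <- diag(1e-14, 3)
  l1b <- draw_level1(spec0, 1, 2, eta2 = c(2, 2, 5))
  Fb <- eval_function(spec0$l1$struct$F, l1b$eta1)
  expect_equal(l1b$eta1[3],
               5 + sum(pb_get(spec0$l1$struct$B)[3, ] * Fb),
               tolerance = 1e-5)
})
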