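# Small model builders shared across tests. All models are constructed in
# code; no stored fixtures.

lin1 <- function(m) function_spec(lapply(seq_len(m), term_linear), arity = m)

# hierarchical normal-normal: one indicator, one level-1 latent whose
# intercept is a cluster random effect with mean mu; all variances fixed
nn_model <- function(mu = 1, psi1 = 0.3, theta = 0.2, psi2 = 0.5,
                     mu_free = TRUE) {
  f1 <- lin1(1)
  meas1 <- measurement_spec(
    f = f1, lambda = matrix(1, 1, 1), lambda_free = matrix(FALSE, 1, 1),
    nu = 0, nu_free = matrix(FALSE, 1, 1),
    theta = theta, theta_free = FALSE)
  struct1 <- structural_spec(
    F = f1, B = matrix(0, 1, 1), B_free = matrix(FALSE, 1, 1),
    alpha = 0, psi = psi1, psi_free = FALSE)
  struct2 <- structural_spec(
    F = lin1(1), B = matrix(0, 1, 1), B_free = matrix(FALSE, 1, 1),
    alpha = mu, alpha_free = matrix(mu_free, 1, 1),
    psi = psi2, psi_free = FALSE)
  model_spec(level1_measurement = meas1, level1_structural = struct1,
             level2_structural = struct2,
             random = random_coef("alpha", 1, eta2 = 1))
}

# single-level one-factor model with three indicators (no level 2)
factor_model <- function(loadings = c(1, 0.8, 1.2), nu = c(0, 0.3, -0.2),
                         theta = c(0.3, 0.4, 0.5), alpha = 0.5, psi = 0.8,
                         free = "all") {
  J <- length(loadings)
  lam_free <- cbind(c(FALSE, rep(TRUE, J - 1L)))
  nu_free <- cbind(c(FALSE, rep(TRUE, J - 1L)))
  if (free == "none") {
    lam_free[] <- FALSE; nu_free[] <- FALSE
  }
  meas1 <- measurement_spec(
    f = lin1(1), lambda = cbind(loadings), lambda_free = lam_free,
    nu = nu, nu_free = nu_free,
    theta = theta, theta_free = rep(free == "all", J))
  struct1 <- structural_spec(
    F = lin1(1), B = matrix(0, 1, 1), B_free = matrix(FALSE, 1, 1),
    alpha = alpha, alpha_free = matrix(free == "all", 1, 1),
    psi = psi, psi_free = free == "all")
  model_spec(level1_measurement = meas1, level1_structural = struct1)
}

# tiny non-linear model: one latent measured by y1 (linear, scaling) and
# y2 (linear + quadratic); the quadratic loading is the only free parameter
quad_model <- function(lq = 0.4) {
  f1 <- function_spec(list(term_linear(1), term_power(1, 2)), arity = 1)
  meas1 <- measurement_spec(
    f = f1,
    lambda = rbind(c(1, 0), c(0.8, lq)),
    lambda_free = rbind(c(FALSE, FALSE), c(FALSE, TRUE)),
    nu = c(0, 0), nu_free = matrix(FALSE, 2, 1),
    theta = c(0.3, 0.3), theta_free = c(FALSE, FALSE))
  struct1 <- structural_spec(
    F = lin1(1), B = matrix(0, 1, 1), B_free = matrix(FALSE, 1, 1),
    alpha = 0.4, alpha_free = matrix(FALSE, 1, 1),
    psi = 0.7, psi_free = FALSE)
  model_spec(level1_measurement = meas1, level1_structural = struct1)
}

# cluster-level random intercept whose mean carries a 2-class mixture
# (level-2 mixture necessity experiments); gap = class separation
mix2_model <- function(gap = 0, n_classes = 2L, psi1 = 0.3, theta = 0.2,
                       psi2 = 0.4, base = 1) {
  f1 <- lin1(1)
  meas1 <- measurement_spec(
    f = f1, lambda = matrix(1, 1, 1), lambda_free = matrix(FALSE, 1, 1),
    nu = 0, nu_free = matrix(FALSE, 1, 1), theta = theta,
    theta_free = TRUE)
  struct1 <- structural_spec(
    F = f1, B = matrix(0, 1, 1), B_free = matrix(FALSE, 1, 1),
    alpha = 0, psi = psi1, psi_free = TRUE)
  mu_d <- if (n_classes == 2L) list(cbind(base), cbind(base + gap))
  else cbind(base)
  struct2 <- structural_spec(
    F = lin1(1), B = matrix(0, 1, 1), B_free = matrix(FALSE, 1, 1),
    alpha = mu_d, alpha_free = matrix(TRUE, 1, 1),
    psi = psi2, psi_free = TRUE,
    vary = if (n_classes == 2L) c(alpha = "d"))
  model_spec(level1_measurement = meas1, level1_structural = struct1,
             level2_structural = struct2,
             level2_mixture = mixture_spec(n_classes),
             random = random_coef("alpha", 1, eta2 = 1))
}

quiet_fit <- function(spec, data, ...) {
  suppressMessages(run_gibbs(spec, data, ...))
}

mvtnorm_logdens <- function(y, mu, S) {
  R <- chol(S)
  z <- backsolve(R, y - mu, transpose = TRUE)
  -0.5 * (length(y) * log(2 * pi) + sum(z^2)) - sum(log(diag(R)))
}
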