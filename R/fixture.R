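#' Two-level spline/interaction example model
#'
#' A fully parameterized educational-assessment-style model used throughout
#' the package's tests and documentation. Within schools, a pupil's latent
#' math skill is predicted by two latent traits (attitude toward reading,
#' experienced teaching strategies), each entering through a latent cubic
#' spline with knots at 2 and 3; all three constructs carry three continuous
#' indicators. The math intercept is a school-level random effect explained
#' by two latent school characteristics (structural problems, social
#' environment), their interaction, and a two-class mixture on the school
#' level that captures non-normality of the school-level predictors.
#'
#' The generating parameter values are realistic published-scale posterior
#' means for a model of this structure (factor loadings near 1, small
#' spline coefficients, interaction effect -0.289, class proportions
#' 0.532/0.468 with latent mean gaps of about 0.17-0.19).
#'
#' @param n_classes number of school-level mixture classes (1 or 2); the
#'   one-class variant is used for mixture-necessity comparisons.
#' @return an `mlsem_spec`.
#' @examples
#' spec <- twolevel_spline_fixture()
#' validate_identification(spec)
#' @export
twolevel_spline_fixture <- function(n_classes = 2L) {
  n_classes <- as.integer(n_classes)
  stopifnot(n_classes %in% c(1L, 2L))
  simple <- function(loads) {
    # block-diagonal loading matrix from per-factor loading vectors
    J <- sum(lengths(loads))
    out <- matrix(0, J, length(loads))
    fr <- matrix(FALSE, J, length(loads))
    r <- 0L
    for (f in seq_along(loads)) {
      idx <- r + seq_along(loads[[f]])
      out[idx, f] <- loads[[f]]
      fr[idx, f] <- c(FALSE, rep(TRUE, length(loads[[f]]) - 1L))
      r <- r + length(loads[[f]])
    }
    list(lambda = out, free = fr)
  }

  # ---- level 1: Att, Strat -> Math through cubic splines ----
  l1_load <- simple(list(c(1, 1.141, 0.997), c(1, 0.687, 1.213),
                         c(1, 0.754, 0.553)))
  nu1 <- c(0, -1.078, -0.409, 0, 0.411, -0.419, 0, 0.058, 0.340)
  nu1_free <- rep(c(FALSE, TRUE, TRUE), 3)
  F1 <- function_spec(c(spline_terms(1, c(2, 3), 3, arity = 3)$terms,
                        spline_terms(2, c(2, 3), 3, arity = 3)$terms),
                      arity = 3)
  B1 <- rbind(0, 0, c(0.005, 0.009, -0.005, 0.046, -0.164,
                      -0.070, 0.079, -0.017, 0.007, 0.018))
  B1_free <- rbind(rep(FALSE, 10), rep(FALSE, 10), rep(TRUE, 10))
  psi1 <- matrix(0, 3, 3)
  psi1[1:2, 1:2] <- matrix(c(0.506, 0.072, 0.072, 0.250), 2)
  psi1[3, 3] <- 0.041
  meas1 <- measurement_spec(
    f = function_spec(lapply(1:3, term_linear), arity = 3),
    lambda = l1_load$lambda, lambda_free = l1_load$free,
    nu = nu1, nu_free = cbind(nu1_free),
    theta = c(0.147, 0.198, 0.212, 0.212, 0.323, 0.219, 0.066, 0.047,
              0.049))
  struct1 <- structural_spec(
    F = F1, B = B1, B_free = B1_free,
    alpha = c(2.856, 2.700, 0),
    alpha_free = cbind(c(TRUE, TRUE, FALSE)),
    psi = psi1, psi_blocks = list(1:2, 3))

  # ---- level 2: Prob, Soc -> random math intercept, with interaction ----
  l2_load <- simple(list(c(1, 1.029, 0.700), c(1, 1.002, 0.794)))
  nu2 <- c(0, 0.759, 0.603, 0, -0.024, 0.279)
  nu2_free <- rep(c(FALSE, TRUE, TRUE), 2)
  F2 <- function_spec(list(term_linear(1), term_linear(2),
                           term_product(1, 2)), arity = 3)
  B2 <- rbind(0, 0, c(0.558, 0.442, -0.289))
  B2_free <- rbind(rep(FALSE, 3), rep(FALSE, 3), rep(TRUE, 3))
  psi2 <- matrix(0, 3, 3)
  psi2[1:2, 1:2] <- matrix(c(0.291, 0.007, 0.007, 0.239), 2)
  psi2[3, 3] <- 0.051
  mu_d <- if (n_classes == 2L) {
    list(cbind(c(1.921, 1.938, -0.365)), cbind(c(2.107, 2.091, -0.365)))
  } else {
    cbind(c(2.0, 2.0, -0.365))
  }
  meas2 <- measurement_spec(
    f = function_spec(lapply(1:2, term_linear), arity = 3),
    lambda = l2_load$lambda, lambda_free = l2_load$free,
    nu = nu2, nu_free = cbind(nu2_free),
    theta = c(0.415, 0.723, 0.366, 0.183, 0.130, 0.176))
  struct2 <- structural_spec(
    F = F2, B = B2, B_free = B2_free,
    alpha = mu_d, alpha_free = cbind(c(TRUE, TRUE, TRUE)),
    psi = psi2, psi_blocks = list(1:2, 3),
    vary = if (n_classes == 2L) c(alpha = "d") else NULL,
    vary_rows = if (n_classes == 2L) list(alpha = 1:2) else NULL)

  mixD <- if (n_classes == 2L) {
    # class proportions (0.532, 0.468): a2 = log(0.468/0.532)
    mixture_spec(2L, a = c(0, log(0.468 / 0.532)))
  } else {
    mixture_spec(1L)
  }

  model_spec(
    level1_measurement = meas1, level1_structural = struct1,
    level2_measurement = meas2, level2_structural = struct2,
    level2_mixture = mixD,
    random = random_coef("alpha", 3, eta2 = 3),
    names = list(eta1 = c("Att", "Strat", "Math"),
                 eta2 = c("Prob", "Soc", "AlphaMath"),
                 y = paste0("y", 1:9), z = paste0("z", 1:6)))
}

#' Simulate a dataset from the example model
#'
#' Cluster sizes are drawn as 1 + Poisson(6) (mean 7), matching the
#' many-small-clusters design typical of school samples.
#'
#' @param spec the fixture model (default [twolevel_spline_fixture()]).
#' @param K number of schools.
#' @param seed integer seed.
#' @return an `mlsem_data`.
#' @export
simulate_fixture <- function(spec = twolevel_spline_fixture(), K = 100,
                             seed = 1L) {
  set.seed(as.integer(seed))
  sizes <- 1L + rpois(K, 6)
  simulate_dataset(spec, K, cluster_size_plan(sizes = sizes), seed = seed)
}
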