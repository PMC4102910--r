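test_that("check_disjoint_terms detects shared covariate terms", {
  A <- function_spec(list("v1", "v1^2"), arity = 1)
  B <- function_spec(list("v1", "v1^2"), arity = 1)
  expect_false(check_disjoint_terms(A, B))
  expect_false(check_disjoint_terms(B, A))  # symmetry
  expect_true(check_disjoint_terms(function_spec(list("v1"), 1),
                                   function_spec(list("v1^2"), 1)))
  expect_true(check_disjoint_terms(empty_function(1),
                                   function_spec(list("v1"), 1)))
  expect_error(check_disjoint_terms(function_spec(list("v1"), 1),
                                    function_spec(list("v2"), 2)),
               "different variable spaces")
})

test_that("the packaged two-level model passes all identification rules", {
  rep <- validate_identification(twolevel_spline_fixture())
  expect_true(attr(rep, "ok"))
  expect_setequal(unique(rep$rule), 1:4)
})

test_that("shared covariate terms in g and G fail rule 2 naming the term", {
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
  spec <- model_spec(meas, struct, names = list(x1 = "x11"))
  rep <- validate_identification(spec)
  bad <- rep[!rep$pass, ]
  expect_true(any(grepl("disjoint.g1", bad$check)))
  expect_true(any(grepl("x11", bad$detail)))
})

test_that("single-class models need no ordering constraint", {
  rep <- validate_identification(factor_model())
  r4 <- rep[rep$rule == 4, ]
  expect_true(all(r4$pass))
  expect_false("ordering.constraint" %in% r4$check)
})

test_that("parameter_index names are stable and exclude constrained entries", {
  spec <- twolevel_spline_fixture()
  pn <- parameter_index(spec)
  expect_true(all(paste0("L1.B.3.", 1:10) %in% pn))
  expect_true(all(c("L2.B.3.1", "L2.B.3.2", "L2.B.3.3") %in% pn))
  expect_true(all(c("L2.mu.1.d1", "L2.mu.1.d2", "L2.mu.2.d1",
                    "L2.mu.2.d2", "L2.mu.3") %in% pn))
  expect_true("mixD.a.2" %in% pn)
  # scaling loadings (fixed at 1) and the random intercept are absent
  expect_false("L1.lambda.1.1" %in% pn)
  expect_false("L1.alpha.3" %in% pn)
  expect_false(anyDuplicated(pn) > 0)
  # one-class model lists no logit parameters
  expect_false(any(grepl("^mix", parameter_index(factor_model()))))
})

test_that("pack/unpack of the free-parameter vector is the identity", {
  for (spec in list(twolevel_spline_fixture(), factor_model(),
                    nn_model())) {
    th <- mlsemm:::collect_params(spec)
    set.seed(7)
    th2 <- th + rnorm(length(th), 0, 0.1)
    spec2 <- mlsemm:::unpack_params(spec, th2)
    expect_equal(mlsemm:::collect_params(spec2), th2)
    # and the report is pure: same spec, same report
    expect_identical(validate_identification(spec),
                     validate_identification(spec))
  }
})

test_that("non-recursive structural systems are rejected", {
  F2 <- lin1(2)
  meas <- measurement_spec(
    f = lin1(2), lambda = rbind(c(1, 0), c(0, 1)),
    lambda_free = matrix(FALSE, 2, 2), nu = c(0, 0),
    nu_free = matrix(FALSE, 2, 1), theta = c(0.2, 0.2))
  struct <- structural_spec(
    F = F2, B = rbind(c(0, 0.5), c(0.5, 0)),
    B_free = rbind(c(FALSE, TRUE), c(TRUE, FALSE)),
    alpha = c(0, 0), psi = c(0.5, 0.5))
  expect_error(model_spec(meas, struct), "not recursive")
})

test_that("the mixture reference class is pinned at zero", {
  mx <- mixture_spec(3, a = c(5, 1, 2))
  expect_equal(mx$a[1], 0)
  h <- function_spec(list(term_linear(1)), arity = 1)
  mx2 <- mixture_spec(2, h = h, b = rbind(3, 1.5))
  expect_equal(mx2$b[1, ], 0)
})
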