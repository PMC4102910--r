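test_that("term constructors enforce their invariants", {
  expect_error(term_power(1, 0), "exponent")
  expect_error(term_tpower(1, 2, 0), "degree")
  expect_error(term_product(2, 2), "distinct")
  expect_s3_class(term_power(1, 1), "mlsem_term")
  expect_equal(term_power(1, 1)$kind, "linear")
})

test_that("term equality ignores product order and compares all fields", {
  expect_true(term_equal(term_product(1, 2), term_product(2, 1)))
  expect_false(term_equal(term_power(1, 2), term_power(1, 3)))
  expect_false(term_equal(term_tpower(1, 2, 3), term_tpower(1, 3, 3)))
  expect_false(term_equal(term_linear(1), term_power(1, 2)))
  expect_true(term_equal(term_tpower(2, 2.5, 3), term_tpower(2, 2.5, 3)))
})

test_that("term strings parse and serialize losslessly", {
  vars <- c("Att", "Strat")
  cases <- list(term_linear(2), term_power(1, 3), term_product(1, 2),
                term_tpower(1, 2, 3))
  for (tm in cases) {
    back <- parse_term(format_term(tm, vars), vars)[[1]]
    expect_true(term_equal(tm, back))
  }
  sp <- parse_term("spline(Att, knots=[2,3], degree=3)", vars)
  expect_length(sp, 5)
  expect_true(term_equal(sp[[4]], term_tpower(1, 2, 3)))
  expect_error(parse_term("unknown_var", vars), "unknown variable")
})

test_that("spline_terms builds the truncated-power basis", {
  fs <- spline_terms(1, knots = c(2, 3), degree = 3)
  expect_equal(fs$out_dim, 5L)
  expect_equal(spline_terms(1, numeric(0), 1)$out_dim, 1L)
  fs2 <- spline_terms(1, 0, 2)
  expect_true(term_equal(fs2$terms[[3]], term_tpower(1, 0, 2)))
  expect_error(spline_terms(1, c(3, 2), 3), "increasing")
})

test_that("eval_term computes truncated powers and products", {
  expect_equal(eval_term(term_tpower(1, 2, 3), 4), 8)
  expect_equal(eval_term(term_tpower(1, 3, 3), 2), 0)
  expect_equal(eval_term(term_product(1, 2), c(2, 3)), 6)
  expect_equal(eval_term(term_power(1, 2), -3), 9)
})

test_that("eval_function reproduces hand-computed basis rows", {
  att_basis <- spline_terms(1, c(2, 3), 3)
  expect_equal(eval_function(att_basis, 2), c(2, 4, 8, 0, 0))
  expect_equal(eval_function(att_basis, 4), c(4, 16, 64, 8, 1))
  F2 <- function_spec(list(term_linear(1), term_linear(2),
                           term_product(1, 2)), arity = 2)
  expect_equal(eval_function(F2, c(1, 1)), c(1, 1, 1))
  expect_error(eval_function(F2, 1), "expected 2")
})

test_that("eval_basis agrees with eval_function row by row", {
  set.seed(1)
  fs <- function_spec(list(term_linear(1), term_power(2, 2),
                           term_product(1, 3), term_tpower(3, 0.5, 2)),
                      arity = 3)
  X <- matrix(rnorm(60), 20, 3)
  B <- eval_basis(fs, X)
  for (i in c(1, 7, 20))
    expect_equal(B[i, ], eval_function(fs, X[i, ]))
})

test_that("assembled splines are C2 at the knots and cubic below them", {
  fs <- spline_terms(1, c(2, 3), 3)
  eps <- 1e-6
  # the component born at each knot contributes nothing to the value or the
  # first/second finite differences as eps -> 0: it is eps^3 at knot + eps
  for (knot in c(2, 3)) {
    tterm <- term_tpower(1, knot, 3)
    expect_lt(abs(eval_term(tterm, knot + eps) - eval_term(tterm, knot)),
              1e-6)
    d_right <- (eval_term(tterm, knot + eps) - eval_term(tterm, knot)) / eps
    d_left <- (eval_term(tterm, knot) - eval_term(tterm, knot - eps)) / eps
    expect_lt(abs(d_right - d_left), 1e-6)
    dd <- (eval_term(tterm, knot + eps) - 2 * eval_term(tterm, knot) +
             eval_term(tterm, knot - eps)) / eps^2
    expect_lt(abs(dd), 1e-5)
  }
  # assembled spline with published-scale coefficients: continuous value
  # and first differences across both knots within 1e-6
  beta <- c(0.005, 0.009, -0.005, 0.046, -0.164)
  s <- function(v) sum(beta * eval_function(fs, v))
  for (knot in c(2, 3)) {
    expect_lt(abs(s(knot + eps) - s(knot)), 1e-6)
    expect_lt(abs(s(knot) - s(knot - eps)), 1e-6)
    d_right <- (s(knot + eps) - s(knot)) / eps
    d_left <- (s(knot) - s(knot - eps)) / eps
    expect_lt(abs(d_right - d_left), 1e-6)
  }
  # below the first knot the spline equals the plain cubic exactly
  set.seed(42)
  for (rep in 1:5) {
    b <- rnorm(5)
    s2 <- function(v) sum(b * eval_function(fs, v))
    for (v in seq(0, 1.99, length.out = 7))
      expect_equal(s2(v), b[1] * v + b[2] * v^2 + b[3] * v^3,
                   tolerance = 1e-12)
  }
})

test_that("function sets reject duplicates, constants are unrepresentable", {
  expect_error(function_spec(list(term_linear(1), term_linear(1)), 1),
               "duplicate")
  expect_error(function_spec(list(term_linear(2)), arity = 1), "beyond")
})
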