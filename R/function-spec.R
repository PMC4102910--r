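#' Function sets: ordered collections of terms
#'
#' A function set is the "smooth polynomial function" object of the model:
#' it maps a variable vector (latent variables or covariates) to the vector
#' of its evaluated terms. Function sets appear in the measurement models
#' (f1, f2, g1, g2), the structural models (F1, F2, G1, G2), and the
#' mixture-logit models (h1, h2).
#'
#' @param terms list of `mlsem_term` objects (or term syntax strings, see
#'   [parse_term()]); duplicates are rejected.
#' @param arity dimension of the input vector the terms index into.
#' @param vars optional variable names used when parsing strings and when
#'   printing.
#' @return an object of class `mlsem_fnspec` with fields `terms`, `arity`,
#'   `out_dim`, `vars`.
#' @examples
#' fs <- function_spec(list("v1", "v1^2"), arity = 1)
#' eval_function(fs, 3)   # c(3, 9)
#' @export
function_spec <- function(terms, arity, vars = NULL) {
  if (inherits(terms, "mlsem_term")) terms <- list(terms)
  terms <- unlist(lapply(terms, function(t) {
    if (is.character(t)) parse_term(t, vars) else list(t)
  }), recursive = FALSE)
  if (!all(vapply(terms, inherits, TRUE, "mlsem_term")))
    stop("all terms must be mlsem_term objects or term strings", call. = FALSE)
  arity <- as.integer(arity)
  used <- unlist(lapply(terms, `[[`, "var"))
  if (length(used) && max(used) > arity)
    stop("term references variable index beyond arity ", arity, call. = FALSE)
  n <- length(terms)
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n)) {
      if (term_equal(terms[[i]], terms[[j]]))
        stop("duplicate term in function set: ", format_term(terms[[i]]),
             call. = FALSE)
    }
  }
  structure(list(terms = terms, arity = arity, out_dim = n, vars = vars),
            class = "mlsem_fnspec")
}

#' An empty function set (no terms)
#' @param arity input dimension.
#' @export
#' @rdname function_spec
empty_function <- function(arity = 0L) {
  function_spec(list(), arity = arity)
}

#' @export
print.mlsem_fnspec <- function(x, ...) {
  cat("<function set> arity", x$arity, "->", x$out_dim, "terms:",
      paste(vapply(x$terms, format_term, "", vars = x$vars), collapse = ", "),
      "\n")
  invisible(x)
}

#' Truncated-power spline basis terms
#'
#' Returns the function set \eqn{(v, v^2, \dots, v^p, (v-\xi_1)_+^p, \dots,
#' (v-\xi_q)_+^p)} for one variable: a degree-`degree` polynomial plus one
#' truncated power per knot, yielding a piecewise polynomial that is
#' \eqn{C^{p-1}} at every knot. No intercept term is included.
#'
#' @param var variable index the spline applies to.
#' @param knots strictly increasing numeric vector of knot locations (may be
#'   empty, giving a plain polynomial).
#' @param degree positive integer degree.
#' @param arity input dimension of the resulting function set (defaults to
#'   `var`).
#' @return an `mlsem_fnspec`.
#' @examples
#' spline_terms(1, knots = c(2, 3), degree = 3)   # 5 terms
#' @export
spline_terms <- function(var, knots, degree, arity = var) {
  degree <- as.integer(degree)
  if (degree < 1L) stop("degree must be >= 1", call. = FALSE)
  if (length(knots) > 1 && any(diff(knots) <= 0))
    stop("knots must be strictly increasing", call. = FALSE)
  poly <- lapply(seq_len(degree), function(p) term_power(var, p))
  trunc <- lapply(knots, function(k) term_tpower(var, k, degree))
  function_spec(c(poly, trunc), arity = arity)
}

#' Evaluate a single term
#'
#' @param term an `mlsem_term`.
#' @param values numeric vector the term indexes into.
#' @return numeric scalar.
#' @export
eval_term <- function(term, values) {
  switch(term$kind,
    linear = values[term$var],
    power = values[term$var]^term$exponent,
    product = values[term$var[1]] * values[term$var[2]],
    truncated_power = max(values[term$var] - term$knot, 0)^term$degree)
}

#' Evaluate a function set at one point
#'
#' @param fspec an `mlsem_fnspec`.
#' @param values numeric vector of length `fspec$arity`.
#' @return numeric vector of length `fspec$out_dim` (term order preserved).
#' @export
eval_function <- function(fspec, values) {
  if (length(values) != fspec$arity)
    stop("eval_function: expected ", fspec$arity, " values, got ",
         length(values), call. = FALSE)
  vapply(fspec$terms, eval_term, numeric(1), values = values)
}

#' Evaluate a function set on the rows of a matrix
#'
#' Vectorized companion of [eval_function()]: row `i` of the result is the
#' function set evaluated at row `i` of `x`.
#'
#' @param fspec an `mlsem_fnspec`.
#' @param x numeric matrix with `fspec$arity` columns.
#' @return numeric matrix, `nrow(x)` by `fspec$out_dim`.
#' @export
eval_basis <- function(fspec, x) {
  if (!is.matrix(x)) x <- as.matrix(x)
  nt <- fspec$out_dim
  if (nt == 0L) return(matrix(0, nrow(x), 0L))
  if (ncol(x) != fspec$arity)
    stop("eval_basis: expected ", fspec$arity, " columns, got ", ncol(x),
         call. = FALSE)
  out <- matrix(0, nrow(x), nt)
  terms <- fspec$terms
  for (t in seq_len(nt)) {
    tm <- terms[[t]]
    out[, t] <- switch(tm$kind,
      linear = x[, tm$var],
      power = x[, tm$var]^tm$exponent,
      product = x[, tm$var[1L]] * x[, tm$var[2L]],
      truncated_power = {
        v <- x[, tm$var] - tm$knot
        v[v < 0] <- 0
        v^tm$degree
      })
  }
  out
}

# variable indices a term depends on
term_vars <- function(term) term$var

# TRUE when the term is linear in every variable it references
term_is_linear <- function(term) term$kind == "linear"

fnspec_is_linear <- function(fspec) {
  all(vapply(fspec$terms, term_is_linear, TRUE))
}
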