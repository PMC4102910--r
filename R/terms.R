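#' Term constructors for polynomial, interaction, and spline function sets
#'
#' A term is the atomic building block of a function set ([function_spec()]):
#' a linear term \eqn{v}, a power \eqn{v^p}, a product \eqn{v_a v_b}, or a
#' truncated power \eqn{(v-\xi)_+^p} used in spline bases. Terms never encode
#' a constant; intercepts live in the model's intercept vectors so that they
#' remain identified.
#'
#' @param var variable index (1-based) into the vector the function set is
#'   evaluated on (latent variables or covariates).
#' @param exponent positive integer power.
#' @param var1,var2 the two distinct variable indices of a product term.
#' @param knot real knot location \eqn{\xi}.
#' @param degree positive integer degree of the truncated power.
#' @return an object of class `mlsem_term`.
#' @examples
#' term_tpower(1, knot = 2, degree = 3)  # (v - 2)_+^3
#' @name terms
NULL

#' @rdname terms
#' @export
term_linear <- function(var) {
  new_term("linear", var = as.integer(var))
}

#' @rdname terms
#' @export
term_power <- function(var, exponent) {
  exponent <- as.integer(exponent)
  if (exponent < 1L) stop("power term requires exponent >= 1", call. = FALSE)
  if (exponent == 1L) return(term_linear(var))
  new_term("power", var = as.integer(var), exponent = exponent)
}

#' @rdname terms
#' @export
term_product <- function(var1, var2) {
  var1 <- as.integer(var1); var2 <- as.integer(var2)
  if (var1 == var2)
    stop("product term references two distinct variables; use term_power",
         call. = FALSE)
  # multiplication commutes: store in canonical (sorted) order
  new_term("product", var = sort(c(var1, var2)))
}

#' @rdname terms
#' @export
term_tpower <- function(var, knot, degree) {
  degree <- as.integer(degree)
  if (degree < 1L) stop("truncated power term requires degree >= 1", call. = FALSE)
  new_term("truncated_power", var = as.integer(var),
           knot = as.numeric(knot), degree = degree)
}

new_term <- function(kind, var, exponent = NULL, knot = NULL, degree = NULL) {
  if (any(var < 1L)) stop("term variable index must be >= 1", call. = FALSE)
  structure(list(kind = kind, var = var, exponent = exponent,
                 knot = knot, degree = degree),
            class = "mlsem_term")
}

#' Term equality
#'
#' Two terms are equal when they have the same kind, reference the same
#' variables (product order is ignored), and share exponent, knot, and degree.
#'
#' @param a,b `mlsem_term` objects.
#' @return logical scalar.
#' @export
term_equal <- function(a, b) {
  stopifnot(inherits(a, "mlsem_term"), inherits(b, "mlsem_term"))
  if (a$kind != b$kind) return(FALSE)
  if (!identical(a$var, b$var)) return(FALSE)
  identical(a$exponent, b$exponent) &&
    identical(a$degree, b$degree) &&
    isTRUE(all.equal(c(a$knot, -Inf), c(b$knot, -Inf), tolerance = 0))
}

#' @export
print.mlsem_term <- function(x, ...) {
  cat(format_term(x), "\n")
  invisible(x)
}

#' Serialize a term to its string syntax
#'
#' The inverse of [parse_term()]: `v3`, `v1^2`, `v1*v2`, `tp(v1, knot=2, degree=3)`.
#' Variable names can be substituted via `vars`.
#'
#' @param term an `mlsem_term`.
#' @param vars optional character vector of variable names.
#' @return character scalar.
#' @export
format_term <- function(term, vars = NULL) {
  nm <- function(i) if (is.null(vars)) paste0("v", i) else vars[i]
  switch(term$kind,
    linear = nm(term$var),
    power = paste0(nm(term$var), "^", term$exponent),
    product = paste0(nm(term$var[1]), "*", nm(term$var[2])),
    truncated_power = sprintf("tp(%s, knot=%s, degree=%d)", nm(term$var),
                              format(term$knot, digits = 15), term$degree))
}

#' Parse term syntax strings
#'
#' Accepts the syntax emitted by [format_term()] plus the `spline()`
#' shorthand, e.g. `"eta1"`, `"eta1^2"`, `"eta1*eta2"`,
#' `"tp(eta1, knot=2, degree=3)"`, and
#' `"spline(eta1, knots=[2,3], degree=3)"` (which expands to several terms).
#'
#' @param text character scalar.
#' @param vars character vector mapping variable names to indices; plain
#'   `v<k>` indices are always accepted.
#' @return a list of `mlsem_term` objects (length > 1 only for `spline()`).
#' @export
parse_term <- function(text, vars = NULL) {
  s <- gsub(" ", "", text)
  varidx <- function(tok) {
    if (!is.null(vars) && tok %in% vars) return(match(tok, vars))
    if (grepl("^v[0-9]+$", tok)) return(as.integer(sub("^v", "", tok)))
    stop("unknown variable '", tok, "' in term '", text, "'", call. = FALSE)
  }
  if (grepl("^spline\\(", s)) {
    m <- regmatches(s, regexec(
      "^spline\\(([^,]+),knots=\\[([^]]*)\\],degree=([0-9]+)\\)$", s))[[1]]
    if (length(m) == 0) stop("malformed spline() term: ", text, call. = FALSE)
    knots <- if (nzchar(m[3])) as.numeric(strsplit(m[3], ",")[[1]]) else numeric(0)
    return(spline_terms(varidx(m[2]), knots, as.integer(m[4]))$terms)
  }
  if (grepl("^tp\\(", s)) {
    m <- regmatches(s, regexec(
      "^tp\\(([^,]+),knot=([-0-9.eE+]+),degree=([0-9]+)\\)$", s))[[1]]
    if (length(m) == 0) stop("malformed tp() term: ", text, call. = FALSE)
    return(list(term_tpower(varidx(m[2]), as.numeric(m[3]), as.integer(m[4]))))
  }
  if (grepl("\\*", s)) {
    p <- strsplit(s, "*", fixed = TRUE)[[1]]
    if (length(p) != 2) stop("malformed product term: ", text, call. = FALSE)
    return(list(term_product(varidx(p[1]), varidx(p[2]))))
  }
  if (grepl("\\^", s)) {
    p <- strsplit(s, "^", fixed = TRUE)[[1]]
    return(list(term_power(varidx(p[1]), as.integer(p[2]))))
  }
  list(term_linear(varidx(s)))
}
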