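# Internal parameter-block representation.
#
# A coefficient block (intercept vector, loading matrix, regression matrix,
# logit coefficients) is stored as a list of numeric matrices -- one per
# mixture "group" -- plus a logical free-mask shared by all groups. The
# `vary` flag states which class indices the block depends on:
#   "none" (shared), "c" (level-1 class), "d" (level-2 class),
#   "cd" (both; group index = (d-1)*Cstar + c).
# Covariance blocks additionally carry a block partition of their rows; each
# partition block is either wholly free (sampled) or wholly fixed.

pblock <- function(values, free = NULL, vary = "none", n_groups = 1L,
                   nrow = NULL, ncol = NULL, vary_rows = NULL) {
  if (!is.list(values)) {
    values <- as.matrix(values)
    if (!is.null(nrow)) stopifnot(base::nrow(values) == nrow,
                                  base::ncol(values) == ncol)
    values <- rep(list(values), n_groups)
  } else {
    values <- lapply(values, as.matrix)
    if (length(values) != n_groups)
      stop("expected ", n_groups, " class-specific matrices, got ",
           length(values), call. = FALSE)
  }
  dims <- dim(values[[1]])
  if (!all(vapply(values, function(v) identical(dim(v), dims), TRUE)))
    stop("class-specific matrices must share dimensions", call. = FALSE)
  if (is.null(free)) free <- matrix(TRUE, dims[1], dims[2])
  free <- matrix(as.logical(free), dims[1], dims[2])
  stopifnot(vary %in% c("none", "c", "d", "cd"))
  # row-level class variation: rows not listed in vary_rows are tied
  # across class groups (their group-1 value is authoritative)
  if (vary == "none" || n_groups == 1L) {
    row_vary <- rep(FALSE, dims[1])
  } else if (is.null(vary_rows)) {
    row_vary <- rep(TRUE, dims[1])
  } else {
    row_vary <- seq_len(dims[1]) %in% as.integer(vary_rows)
  }
  if (n_groups > 1L && any(!row_vary)) {
    for (g in seq.int(2L, n_groups))
      values[[g]][!row_vary, ] <- values[[1L]][!row_vary, , drop = FALSE]
  }
  structure(list(values = values, free = free, vary = vary,
                 n_groups = as.integer(n_groups), row_vary = row_vary),
            class = "mlsem_pblock")
}

# number of groups implied by a vary flag
pb_ngroups <- function(vary, Cstar, Dstar) {
  switch(vary, none = 1L, c = Cstar, d = Dstar, cd = Cstar * Dstar)
}

# group index for class pair (c, d) under a vary flag
pb_group <- function(vary, c, d, Cstar) {
  switch(vary, none = rep(1L, length(c)), c = c, d = d,
         cd = (d - 1L) * Cstar + c)
}

pb_get <- function(pb, g = 1L) pb$values[[g]]

pb_set <- function(pb, g, values) {
  pb$values[[g]] <- values
  pb
}

# Covariance specification: positive-definite matrix with a block partition.
cov_spec <- function(values, blocks = NULL, free = NULL, vary = "none",
                     n_groups = 1L) {
  if (!is.list(values)) {
    values <- as.matrix(values)
    values <- rep(list(values), n_groups)
  }
  values <- lapply(values, as.matrix)
  p <- nrow(values[[1]])
  if (is.null(blocks)) blocks <- as.list(seq_len(p))
  blocks <- lapply(blocks, as.integer)
  covered <- as.integer(sort(unlist(blocks)))
  if (!identical(covered, seq_len(p)))
    stop("covariance blocks must partition 1..", p, call. = FALSE)
  if (is.null(free)) free <- rep(TRUE, length(blocks))
  free <- as.logical(free)
  stopifnot(length(free) == length(blocks))
  for (v in values) {
    if (!isSymmetric(unname(v), tol = 1e-8))
      stop("covariance matrix must be symmetric", call. = FALSE)
    for (b in blocks) {
      ev <- eigen(v[b, b, drop = FALSE], symmetric = TRUE,
                  only.values = TRUE)$values
      if (any(ev <= 0))
        stop("covariance block not positive definite", call. = FALSE)
    }
    off <- v
    for (b in blocks) off[b, b] <- 0
    if (any(off != 0))
      stop("covariance entries outside the declared blocks must be zero",
           call. = FALSE)
  }
  structure(list(values = values, blocks = blocks, free = free, vary = vary,
                 n_groups = as.integer(n_groups), dim = p),
            class = "mlsem_covspec")
}

cov_get <- function(cs, g = 1L) cs$values[[g]]

cov_set_block <- function(cs, g, b, mat) {
  idx <- cs$blocks[[b]]
  cs$values[[g]][idx, idx] <- mat
  cs
}

# TRUE when every block of the covariance is 1x1 (diagonal matrix)
cov_is_diagonal <- function(cs) all(lengths(cs$blocks) == 1L)

# Block-diagonal multivariate-normal log density for residual rows E (n x p);
# returns the n-vector of log densities. `cs_val` is the covariance matrix.
ldmvnorm_blocks <- function(E, cs_val, blocks) {
  n <- nrow(E)
  if (ncol(E) == 0L) return(numeric(n))
  out <- numeric(n)
  for (b in blocks) {
    S <- cs_val[b, b, drop = FALSE]
    if (length(b) == 1L) {
      out <- out - 0.5 * (log(2 * pi * S[1, 1]) + E[, b]^2 / S[1, 1])
    } else {
      R <- chol(S)
      z <- E[, b, drop = FALSE] %*% backsolve(R, diag(length(b)))
      out <- out - 0.5 * (length(b) * log(2 * pi)) -
        sum(log(diag(R))) - 0.5 * rowSums(z * z)
    }
  }
  out
}
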