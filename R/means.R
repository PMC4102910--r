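# Model-implied conditional means, vectorized over units (rows).
#
# These helpers power both the simulator and the sampler likelihoods. All
# take the latent/covariate matrices for n units plus the class indices
# (c, d) per unit, and loop only over the distinct class groups of each
# parameter block.

# per-row group index for a block
row_groups <- function(vary, cvec, dvec, Cstar, n) {
  if (vary == "none") return(rep(1L, n))
  pb_group(vary, cvec, dvec, Cstar)
}

# add `pb`-type block contribution basis %*% t(value_g) per class group
add_block <- function(acc, basis, pb, cvec, dvec, Cstar) {
  if (ncol(basis) == 0L || nrow(pb$free) == 0L) return(acc)
  if (pb$n_groups == 1L || pb$vary == "none")
    return(acc + basis %*% t(pb$values[[1L]]))
  g <- pb_group(pb$vary, cvec, dvec, Cstar)
  for (gg in unique(g)) {
    rows <- which(g == gg)
    acc[rows, ] <- acc[rows, , drop = FALSE] +
      basis[rows, , drop = FALSE] %*% t(pb$values[[gg]])
  }
  acc
}

# add intercept column-block (p x 1) per class group
add_intercept <- function(acc, pb, cvec, dvec, Cstar) {
  if (nrow(pb$free) == 0L) return(acc)
  if (pb$n_groups == 1L || pb$vary == "none")
    return(acc + rep(pb$values[[1L]][, 1], each = nrow(acc)))
  g <- pb_group(pb$vary, cvec, dvec, Cstar)
  for (gg in unique(g)) {
    rows <- which(g == gg)
    acc[rows, ] <- acc[rows, , drop = FALSE] +
      matrix(pb$values[[gg]][, 1], length(rows), nrow(pb$free), byrow = TRUE)
  }
  acc
}

# random-coefficient substitutions: rand is a list of entries
# list(block, row, col, values = n-vector) applied to the structural mean
apply_random <- function(acc, Fb, Gb, rand) {
  for (e in rand) {
    acc[, e$row] <- acc[, e$row] + switch(e$block,
      alpha = e$values,
      B = Fb[, e$col] * e$values,
      gamma = Gb[, e$col] * e$values)
  }
  acc
}

# build the per-unit random-coefficient entry list from eta2 rows
rand_entries <- function(spec, eta2_rows) {
  if (!nrow(spec$random)) return(list())
  lapply(seq_len(nrow(spec$random)), function(r) {
    e <- spec$random[r, ]
    list(block = e$block, row = e$row, col = e$col,
         values = eta2_rows[, e$eta2])
  })
}

# measurement mean: nu + Lambda f(eta) + K g(x)
meas_mean <- function(lvl, eta, x, cvec, dvec, Cstar) {
  n <- nrow(eta)
  J <- lvl$J
  acc <- matrix(0, n, J)
  if (J == 0L) return(acc)
  acc <- add_intercept(acc, lvl$meas$nu, cvec, dvec, Cstar)
  acc <- add_block(acc, eval_basis(lvl$meas$f, eta), lvl$meas$lambda,
                   cvec, dvec, Cstar)
  acc <- add_block(acc, eval_basis(lvl$meas$g, x), lvl$meas$kappa,
                   cvec, dvec, Cstar)
  acc
}

# structural mean: alpha + B F(eta) + Gamma G(x), evaluated at the given
# eta (used for residuals; for generation use solve_structural). `Fb` may
# supply a precomputed basis for `eta` (the spline basis is the costly
# part and callers often evaluate it once per iteration).
struct_mean <- function(lvl, eta, x, cvec, dvec, Cstar, rand = list(),
                        Fb = NULL) {
  n <- nrow(eta)
  m <- lvl$m
  acc <- matrix(0, n, m)
  if (m == 0L) return(acc)
  if (is.null(Fb)) Fb <- eval_basis(lvl$struct$F, eta)
  Gb <- eval_basis(lvl$struct$G, x)
  acc <- add_intercept(acc, lvl$struct$alpha, cvec, dvec, Cstar)
  acc <- add_block(acc, Fb, lvl$struct$B, cvec, dvec, Cstar)
  acc <- add_block(acc, Gb, lvl$struct$gamma, cvec, dvec, Cstar)
  apply_random(acc, Fb, Gb, rand)
}

# generate eta from disturbances by walking the topological order
solve_structural <- function(lvl, zeta, x, cvec, dvec, Cstar,
                             rand = list()) {
  n <- nrow(zeta)
  m <- lvl$m
  eta <- matrix(0, n, m)
  if (m == 0L) return(eta)
  Gb <- eval_basis(lvl$struct$G, x)
  galpha <- row_groups(lvl$struct$alpha$vary, cvec, dvec, Cstar, n)
  gB <- row_groups(lvl$struct$B$vary, cvec, dvec, Cstar, n)
  gG <- row_groups(lvl$struct$gamma$vary, cvec, dvec, Cstar, n)
  for (v in lvl$topo$order) {
    mu_v <- numeric(n)
    for (gg in unique(galpha))
      mu_v[galpha == gg] <- lvl$struct$alpha$values[[gg]][v, 1]
    Fb <- eval_basis(lvl$struct$F, eta)   # columns for later vars are junk,
    for (gg in unique(gB)) {              # but their B entries are zero
      rows <- gB == gg
      bv <- lvl$struct$B$values[[gg]][v, ]
      if (any(bv != 0))
        mu_v[rows] <- mu_v[rows] + Fb[rows, , drop = FALSE] %*% bv
    }
    if (ncol(Gb) > 0) {
      for (gg in unique(gG)) {
        rows <- gG == gg
        gv <- lvl$struct$gamma$values[[gg]][v, ]
        if (any(gv != 0))
          mu_v[rows] <- mu_v[rows] + Gb[rows, , drop = FALSE] %*% gv
      }
    }
    for (e in rand) {
      if (e$row != v) next
      mu_v <- mu_v + switch(e$block,
        alpha = e$values,
        B = Fb[, e$col] * e$values,
        gamma = Gb[, e$col] * e$values)
    }
    eta[, v] <- mu_v + zeta[, v]
  }
  eta
}

# draw n rows from N(0, S) for each class group of a covariance spec
draw_disturbance <- function(cs, cvec, dvec, Cstar, n) {
  p <- cs$dim
  out <- matrix(0, n, p)
  if (p == 0L) return(out)
  g <- row_groups(cs$vary, cvec, dvec, Cstar, n)
  for (gg in unique(g)) {
    rows <- which(g == gg)
    S <- cs$values[[gg]]
    z <- matrix(rnorm(length(rows) * p), length(rows), p)
    out[rows, ] <- z %*% chol(S)
  }
  out
}

# log density of residual rows under a (possibly class-varying) covariance
resid_loglik <- function(E, cs, cvec, dvec, Cstar) {
  n <- nrow(E)
  if (ncol(E) == 0L) return(numeric(n))
  if (cs$n_groups == 1L || cs$vary == "none")
    return(ldmvnorm_blocks(E, cs$values[[1L]], cs$blocks))
  g <- pb_group(cs$vary, cvec, dvec, Cstar)
  out <- numeric(n)
  for (gg in unique(g)) {
    rows <- which(g == gg)
    out[rows] <- ldmvnorm_blocks(E[rows, , drop = FALSE], cs$values[[gg]],
                                 cs$blocks)
  }
  out
}
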