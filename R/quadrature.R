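# Gauss-Hermite quadrature evaluation of the marginal likelihood for tiny
# models. Serves as a brute-force oracle for the sampler: the observed-data
# likelihood integrates the continuous latent variables out by nested
# quadrature (clusters outside, individuals inside) and sums the discrete
# classes exactly.

# Golub-Welsch nodes/weights for integrals against the N(0,1) density
gh_nodes <- function(n) {
  if (n == 1L) return(list(x = 0, w = 1))
  i <- seq_len(n - 1L)
  a <- sqrt(i / 2)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1L)] <- a
  J[cbind(i + 1L, i)] <- a
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(x = sqrt(2) * e$values[ord], w = e$vectors[1, ord]^2)
}

# tensor-product grid over p dimensions: list(points T x p, log weights T)
gh_grid <- function(nodes, p) {
  gh <- gh_nodes(nodes)
  if (p == 0L) return(list(points = matrix(0, 1, 0), lw = 0))
  idx <- do.call(expand.grid, rep(list(seq_len(nodes)), p))
  pts <- matrix(gh$x[as.matrix(idx)], nrow(idx), p)
  lw <- rowSums(matrix(log(gh$w)[as.matrix(idx)], nrow(idx), p))
  list(points = pts, lw = lw)
}

#' Marginal log-likelihood of a tiny model by quadrature
#'
#' Evaluates the observed-data log-likelihood -- the product over clusters
#' of the class-mixed integral over the cluster latents of the product over
#' individuals of the class-mixed integral over the individual latents --
#' by nested Gauss-Hermite quadrature in disturbance space (the recursive
#' structural map has unit Jacobian, so nonlinear structural functions are
#' handled exactly on the grid). Intended as an independent cross-check for
#' the sampler on small problems; it refuses models beyond its scope.
#'
#' @param spec an `mlsem_spec` with at most 3 total latent dimensions, at
#'   most 2 classes per level, and identity links.
#' @param data an `mlsem_data` with at most 50 clusters and no missing
#'   cells.
#' @param nodes quadrature nodes per latent dimension.
#' @return log-likelihood (numeric scalar).
#' @export
marginal_loglik_small <- function(spec, data, nodes = 40) {
  stopifnot(inherits(spec, "mlsem_spec"), inherits(data, "mlsem_data"))
  if (spec$m + spec$U > 3L)
    stop("quadrature oracle supports at most 3 latent dimensions",
         call. = FALSE)
  if (spec$Cstar > 2L || spec$Dstar > 2L)
    stop("quadrature oracle supports at most 2 classes per level",
         call. = FALSE)
  if (nrow(data$z) > 50L)
    stop("quadrature oracle supports at most 50 clusters", call. = FALSE)
  if (any(data$y_miss) || any(data$z_miss) || anyNA(data$y))
    stop("quadrature oracle requires complete data", call. = FALSE)
  for (lk in c(spec$y_links, spec$z_links))
    if (lk$link != "identity")
      stop("quadrature oracle supports identity links only", call. = FALSE)

  K <- nrow(data$z)
  N <- nrow(data$y)
  cluster <- data$cluster
  x1 <- data$x1; x2 <- data$x2
  lpD <- log(class_probs(spec$l2$mix, x2))           # K x Dstar
  lpC <- log(class_probs(spec$l1$mix, x1))           # N x Cstar
  g2 <- gh_grid(nodes, spec$U)
  g1 <- gh_grid(nodes, spec$m)
  T2 <- nrow(g2$points); T1 <- nrow(g1$points)

  per_d <- matrix(-Inf, K, spec$Dstar)
  for (d in seq_len(spec$Dstar)) {
    Dd <- rep(d, K)
    ones <- rep(1L, K)
    L2 <- if (spec$U > 0L)
      chol(spec$l2$struct$psi$values[[
        pb_group(spec$l2$struct$psi$vary, 1L, d, 1L)]]) else NULL
    M2 <- matrix(-Inf, K, T2)
    for (t2 in seq_len(T2)) {
      zeta2 <- if (spec$U > 0L)
        matrix(drop(t(L2) %*% g2$points[t2, ]), K, spec$U, byrow = TRUE)
      else matrix(0, K, 0)
      eta2 <- solve_structural(spec$l2, zeta2, x2, ones, Dd, 1L)
      lz <- if (spec$L > 0L) {
        Ez <- data$z - meas_mean(spec$l2, eta2, x2, ones, Dd, 1L)
        resid_loglik(Ez, spec$l2$meas$theta, ones, Dd, 1L)
      } else numeric(K)
      # individual-level integral given this eta2
      eta2exp <- eta2[cluster, , drop = FALSE]
      rand <- rand_entries(spec, eta2exp)
      Ai <- matrix(-Inf, N, spec$Cstar)
      for (cc in seq_len(spec$Cstar)) {
        Cc <- rep(cc, N)
        Dexp <- rep(d, N)
        L1 <- if (spec$m > 0L)
          chol(spec$l1$struct$psi$values[[
            pb_group(spec$l1$struct$psi$vary, cc, d, spec$Cstar)]]) else NULL
        M1 <- matrix(-Inf, N, T1)
        for (t1 in seq_len(T1)) {
          zeta1 <- if (spec$m > 0L)
            matrix(drop(t(L1) %*% g1$points[t1, ]), N, spec$m, byrow = TRUE)
          else matrix(0, N, 0)
          eta1 <- solve_structural(spec$l1, zeta1, x1, Cc, Dexp,
                                   spec$Cstar, rand)
          Ey <- data$y - meas_mean(spec$l1, eta1, x1, Cc, Dexp, spec$Cstar)
          M1[, t1] <- g1$lw[t1] +
            resid_loglik(Ey, spec$l1$meas$theta, Cc, Dexp, spec$Cstar)
        }
        Ai[, cc] <- lpC[, cc] + lse_rows(M1)
      }
      li <- lse_rows(Ai)
      M2[, t2] <- g2$lw[t2] + lz + rowsum_vec(li, cluster, K)
    }
    per_d[, d] <- lpD[, d] + lse_rows(M2)
  }
  sum(lse_rows(per_d))
}
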