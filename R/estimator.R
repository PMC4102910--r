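# Metropolis-within-Gibbs sampler.
#
# Update cycle per iteration:
#   1. data augmentation: ordinal utilities, thresholds, missing cells
#   2. latent variables eta1 (per individual) and eta2 (per cluster):
#      exact multivariate-normal draws in linear models, random-walk
#      Metropolis otherwise
#   3. latent classes C (individuals) and D (clusters) from their
#      multinomial full conditionals
#   4. coefficient blocks from conjugate normal conditionals (Bayesian
#      regression row by row, conditioning on the other residual rows of a
#      correlated block); the designated class-ordered intercept block uses
#      the base + positive-increment parameterization
#   5. covariance blocks from Wishart (inverse-gamma for 1x1) conditionals
#   6. mixture-logit coefficients by random-walk Metropolis
# Step sizes adapt toward the target acceptance rate during burn-in only.

# ---- likelihood pieces --------------------------------------------------

unit_ll1 <- function(spec, ystar, eta1, x1, C, Dexp, rand, Fb = NULL) {
  E_m <- ystar - meas_mean(spec$l1, eta1, x1, C, Dexp, spec$Cstar)
  E_s <- eta1 - struct_mean(spec$l1, eta1, x1, C, Dexp, spec$Cstar, rand,
                            Fb = Fb)
  resid_loglik(E_m, spec$l1$meas$theta, C, Dexp, spec$Cstar) +
    resid_loglik(E_s, spec$l1$struct$psi, C, Dexp, spec$Cstar)
}

cluster_ll2 <- function(spec, zstar, eta2, x2, D) {
  ones <- rep(1L, length(D))
  E_m <- zstar - meas_mean(spec$l2, eta2, x2, ones, D, 1L)
  E_s <- eta2 - struct_mean(spec$l2, eta2, x2, ones, D, 1L)
  resid_loglik(E_m, spec$l2$meas$theta, ones, D, 1L) +
    resid_loglik(E_s, spec$l2$struct$psi, ones, D, 1L)
}

# ---- latent-variable updates -------------------------------------------

# per-unit quadratic-form pair against a block covariance:
# a = rowSums(S Sigma^-1 S), b = rowSums(R0 Sigma^-1 S)
qf_pair <- function(R0, S, cs, cvec, dvec, Cstar) {
  n <- nrow(R0)
  a <- numeric(n); b <- numeric(n)
  if (ncol(R0) == 0L) return(list(a = a, b = b))
  g <- if (cs$n_groups == 1L || cs$vary == "none") rep(1L, n)
  else pb_group(cs$vary, cvec, dvec, Cstar)
  for (gg in unique(g)) {
    rows <- which(g == gg)
    Sigma <- cs$values[[gg]]
    for (bl in cs$blocks) {
      if (length(bl) == 1L) {
        w <- 1 / Sigma[bl, bl]
        a[rows] <- a[rows] + S[rows, bl]^2 * w
        b[rows] <- b[rows] + R0[rows, bl] * S[rows, bl] * w
      } else {
        Si <- chol2inv(chol(Sigma[bl, bl, drop = FALSE]))
        SS <- S[rows, bl, drop = FALSE] %*% Si
        a[rows] <- a[rows] + rowSums(SS * S[rows, bl, drop = FALSE])
        b[rows] <- b[rows] + rowSums(SS * R0[rows, bl, drop = FALSE])
      }
    }
  }
  list(a = a, b = b)
}

update_eta1 <- function(st, fit) {
  spec <- st$spec
  if (spec$m == 0L) return(st)
  if (spec$l1$linear && all(spec$random$block == "alpha"))
    return(update_eta1_exact(st, fit))
  n <- fit$N
  Dexp <- st$D[fit$cluster]
  rand <- rand_entries(spec, st$eta2[fit$cluster, , drop = FALSE])
  x1 <- fit$data$x1
  lvl <- spec$l1
  # exact Gaussian draws for conditionally linear coordinates
  Fb_c <- if (lvl$coord_basis_const) st$F1b
  for (u in which(lvl$lin_coords)) {
    e0 <- st$eta1; e0[, u] <- 0
    e1 <- e0; e1[, u] <- 1
    Rm0 <- st$ystar - meas_mean(lvl, e0, x1, st$C, Dexp, spec$Cstar)
    Sm <- (st$ystar - meas_mean(lvl, e1, x1, st$C, Dexp, spec$Cstar)) - Rm0
    Rs0 <- e0 - struct_mean(lvl, e0, x1, st$C, Dexp, spec$Cstar, rand,
                            Fb = Fb_c)
    Ss <- (e1 - struct_mean(lvl, e1, x1, st$C, Dexp, spec$Cstar, rand,
                            Fb = Fb_c)) - Rs0
    qm <- qf_pair(Rm0, Sm, lvl$meas$theta, st$C, Dexp, spec$Cstar)
    qs <- qf_pair(Rs0, Ss, lvl$struct$psi, st$C, Dexp, spec$Cstar)
    a <- qm$a + qs$a
    b <- -(qm$b + qs$b)
    st$eta1[, u] <- rnorm(n, b / a, sqrt(1 / a))
  }
  nl <- which(!lvl$lin_coords)
  if (length(nl)) {
    cur <- unit_ll1(spec, st$ystar, st$eta1, x1, st$C, Dexp, rand,
                    Fb = Fb_c)
    step <- st$steps$eta1 * st$steps$scale1
    prop <- st$eta1
    prop[, nl] <- prop[, nl, drop = FALSE] +
      matrix(rnorm(n * length(nl)), n) *
      matrix(step[nl], n, length(nl), byrow = TRUE)
    pll <- unit_ll1(spec, st$ystar, prop, x1, st$C, Dexp, rand)
    acc <- log(runif(n)) < pll - cur
    st$eta1[acc, ] <- prop[acc, , drop = FALSE]
    st$acc$eta1 <- st$acc$eta1 + c(sum(acc), n)
  }
  st$F1b <- eval_basis(lvl$struct$F, st$eta1)
  st
}

# linear measurement/structural model: exact Gaussian conditional
update_eta1_exact <- function(st, fit) {
  spec <- st$spec
  m <- spec$m
  Dexp <- st$D[fit$cluster]
  x1 <- fit$data$x1
  gb <- eval_basis(spec$l1$meas$g, x1)
  Gb <- eval_basis(spec$l1$struct$G, x1)
  gcd <- (Dexp - 1L) * spec$Cstar + st$C
  for (g in sort(unique(gcd))) {
    rows <- which(gcd == g)
    cc <- ((g - 1L) %% spec$Cstar) + 1L
    dd <- ((g - 1L) %/% spec$Cstar) + 1L
    gg <- function(pb) pb_group(pb$vary, cc, dd, spec$Cstar)
    lam <- spec$l1$meas$lambda$values[[gg(spec$l1$meas$lambda)]]
    Lam <- linear_map(spec$l1$meas$f, lam, m)
    B <- spec$l1$struct$B$values[[gg(spec$l1$struct$B)]]
    Blin <- linear_map(spec$l1$struct$F, B, m)
    ImB <- diag(m) - Blin
    Psi <- spec$l1$struct$psi$values[[
      pb_group(spec$l1$struct$psi$vary, cc, dd, spec$Cstar)]]
    Th <- spec$l1$meas$theta$values[[
      pb_group(spec$l1$meas$theta$vary, cc, dd, spec$Cstar)]]
    Psi_i <- chol2inv(chol(Psi))
    Th_i <- chol2inv(chol(Th))
    P0 <- t(ImB) %*% Psi_i %*% ImB
    Vprec <- P0 + t(Lam) %*% Th_i %*% Lam
    Rv <- chol(Vprec)
    # per-unit prior mean (I-B)^{-1} (alpha_i + Gamma G(x))
    alpha <- spec$l1$struct$alpha$values[[gg(spec$l1$struct$alpha)]][, 1]
    A <- matrix(alpha, length(rows), m, byrow = TRUE)
    if (ncol(Gb) > 0) {
      gam <- spec$l1$struct$gamma$values[[gg(spec$l1$struct$gamma)]]
      A <- A + Gb[rows, , drop = FALSE] %*% t(gam)
    }
    if (nrow(spec$random)) {
      for (r in seq_len(nrow(spec$random))) {
        e <- spec$random[r, ]
        A[, e$row] <- A[, e$row] + st$eta2[fit$cluster[rows], e$eta2]
      }
    }
    mu <- t(solve(ImB, t(A)))
    # measurement information
    nu <- spec$l1$meas$nu$values[[gg(spec$l1$meas$nu)]][, 1]
    Yc <- st$ystar[rows, , drop = FALSE] -
      matrix(nu, length(rows), spec$J, byrow = TRUE)
    if (ncol(gb) > 0) {
      kap <- spec$l1$meas$kappa$values[[gg(spec$l1$meas$kappa)]]
      Yc <- Yc - gb[rows, , drop = FALSE] %*% t(kap)
    }
    bmat <- Yc %*% Th_i %*% Lam
    mean <- t(backsolve(Rv, forwardsolve(t(Rv), t(mu %*% P0 + bmat))))
    z <- matrix(rnorm(length(rows) * m), length(rows), m)
    st$eta1[rows, ] <- mean + t(backsolve(Rv, t(z)))
  }
  st$acc$eta1 <- st$acc$eta1 + c(fit$N, fit$N)
  st$F1b <- eval_basis(spec$l1$struct$F, st$eta1)
  st
}

# map a coefficient matrix over a purely linear function set to a
# coefficient matrix over the raw variables
linear_map <- function(fspec, coef, m) {
  out <- matrix(0, nrow(coef), m)
  for (t in seq_len(fspec$out_dim))
    out[, fspec$terms[[t]]$var] <- out[, fspec$terms[[t]]$var] + coef[, t]
  out
}

update_eta2 <- function(st, fit) {
  spec <- st$spec
  if (spec$U == 0L) return(st)
  if (spec$l2$linear && all(spec$random$block == "alpha"))
    return(update_eta2_exact(st, fit))
  K <- fit$K
  x2 <- fit$data$x2
  x1 <- fit$data$x1
  has_rand <- nrow(spec$random) > 0
  Dexp <- st$D[fit$cluster]
  ones <- rep(1L, K)
  lvl <- spec$l2
  # level-1 contribution of a candidate eta2 matrix, per cluster
  l1_part <- function(eta2) {
    if (!has_rand) return(numeric(K))
    rand <- rand_entries(spec, eta2[fit$cluster, , drop = FALSE])
    E_s <- st$eta1 - struct_mean(spec$l1, st$eta1, x1, st$C, Dexp,
                                 spec$Cstar, rand, Fb = st$F1b)
    rowsum_vec(resid_loglik(E_s, spec$l1$struct$psi, st$C, Dexp,
                            spec$Cstar), fit$cluster, K)
  }
  # exact coordinate draws (conditionally linear coordinates; random
  # coefficients are always linear in the cluster latents)
  for (u in which(lvl$lin_coords))
    st$eta2[, u] <- eta2_coord_draw(st, fit, u)
  nl <- which(!lvl$lin_coords)
  if (length(nl)) {
    cur <- cluster_ll2(spec, st$zstar, st$eta2, x2, st$D) + l1_part(st$eta2)
    step <- st$steps$eta2 * st$steps$scale2
    prop <- st$eta2
    prop[, nl] <- prop[, nl, drop = FALSE] +
      matrix(rnorm(K * length(nl)), K) *
      matrix(step[nl], K, length(nl), byrow = TRUE)
    pll <- cluster_ll2(spec, st$zstar, prop, x2, st$D) + l1_part(prop)
    acc <- log(runif(K)) < pll - cur
    st$eta2[acc, ] <- prop[acc, , drop = FALSE]
    st$acc$eta2 <- st$acc$eta2 + c(sum(acc), K)
  }
  st
}

# exact Gaussian draw of one conditionally linear eta2 coordinate,
# vectorized over clusters
eta2_coord_draw <- function(st, fit, u) {
  spec <- st$spec
  lvl <- spec$l2
  K <- fit$K
  x2 <- fit$data$x2
  x1 <- fit$data$x1
  ones <- rep(1L, K)
  Dexp <- st$D[fit$cluster]
  # level-1 terms involve this coordinate only when a random coefficient
  # reads from it
  has_rand <- nrow(spec$random) > 0 && u %in% spec$random$eta2
  e0 <- st$eta2; e0[, u] <- 0
  e1 <- e0; e1[, u] <- 1
  Rm0 <- st$zstar - meas_mean(lvl, e0, x2, ones, st$D, 1L)
  Sm <- (st$zstar - meas_mean(lvl, e1, x2, ones, st$D, 1L)) - Rm0
  Rs0 <- e0 - struct_mean(lvl, e0, x2, ones, st$D, 1L)
  Ss <- (e1 - struct_mean(lvl, e1, x2, ones, st$D, 1L)) - Rs0
  qm <- qf_pair(Rm0, Sm, lvl$meas$theta, ones, st$D, 1L)
  qs <- qf_pair(Rs0, Ss, lvl$struct$psi, ones, st$D, 1L)
  a <- qm$a + qs$a
  b <- -(qm$b + qs$b)
  if (has_rand) {
    r0 <- rand_entries(spec, e0[fit$cluster, , drop = FALSE])
    r1 <- rand_entries(spec, e1[fit$cluster, , drop = FALSE])
    Rl0 <- st$eta1 - struct_mean(spec$l1, st$eta1, x1, st$C, Dexp,
                                 spec$Cstar, r0, Fb = st$F1b)
    Sl <- (st$eta1 - struct_mean(spec$l1, st$eta1, x1, st$C, Dexp,
                                 spec$Cstar, r1, Fb = st$F1b)) - Rl0
    ql <- qf_pair(Rl0, Sl, spec$l1$struct$psi, st$C, Dexp, spec$Cstar)
    a <- a + rowsum_vec(ql$a, fit$cluster, K)
    b <- b - rowsum_vec(ql$b, fit$cluster, K)
  }
  rnorm(K, b / a, sqrt(1 / a))
}

update_eta2_exact <- function(st, fit) {
  spec <- st$spec
  U <- spec$U
  x2 <- fit$data$x2
  g2b <- eval_basis(spec$l2$meas$g, x2)
  G2b <- eval_basis(spec$l2$struct$G, x2)
  # level-1 contribution through mapped random intercepts
  has_rand <- nrow(spec$random) > 0
  if (has_rand) {
    Dexp <- st$D[fit$cluster]
    mean0 <- struct_mean(spec$l1, st$eta1, fit$data$x1, st$C, Dexp,
                         spec$Cstar, rand = list())
    Z0 <- st$eta1 - mean0
    rrows <- spec$random$row
  }
  for (d in sort(unique(st$D))) {
    ks <- which(st$D == d)
    gv <- function(pb) pb$values[[pb_group(pb$vary, 1L, d, 1L)]]
    lam <- gv(spec$l2$meas$lambda)
    Lam <- if (spec$L > 0) linear_map(spec$l2$meas$f, lam, U) else
      matrix(0, 0, U)
    B <- gv(spec$l2$struct$B)
    ImB <- diag(U) - linear_map(spec$l2$struct$F, B, U)
    Psi_i <- chol2inv(chol(spec$l2$struct$psi$values[[
      pb_group(spec$l2$struct$psi$vary, 1L, d, 1L)]]))
    P0 <- t(ImB) %*% Psi_i %*% ImB
    Plik <- if (spec$L > 0) {
      Th_i <- chol2inv(chol(spec$l2$meas$theta$values[[
        pb_group(spec$l2$meas$theta$vary, 1L, d, 1L)]]))
      t(Lam) %*% Th_i %*% Lam
    } else matrix(0, U, U)
    alpha <- gv(spec$l2$struct$alpha)[, 1]
    A <- matrix(alpha, length(ks), U, byrow = TRUE)
    if (ncol(G2b) > 0)
      A <- A + G2b[ks, , drop = FALSE] %*% t(gv(spec$l2$struct$gamma))
    mu <- t(solve(ImB, t(A)))
    if (spec$L > 0) {
      nu <- gv(spec$l2$meas$nu)[, 1]
      Zc <- st$zstar[ks, , drop = FALSE] -
        matrix(nu, length(ks), spec$L, byrow = TRUE)
      if (ncol(g2b) > 0)
        Zc <- Zc - g2b[ks, , drop = FALSE] %*% t(gv(spec$l2$meas$kappa))
      bz <- Zc %*% Th_i %*% Lam
    } else bz <- matrix(0, length(ks), U)
    for (ii in seq_along(ks)) {
      k <- ks[ii]
      Prand <- matrix(0, U, U)
      brand <- numeric(U)
      if (has_rand) {
        rows <- fit$cl_rows[[k]]
        for (i in rows) {
          Pi <- chol2inv(chol(spec$l1$struct$psi$values[[
            pb_group(spec$l1$struct$psi$vary, st$C[i], d, spec$Cstar)]]))
          sub <- Pi[rrows, rrows, drop = FALSE]
          eidx <- spec$random$eta2
          Prand[eidx, eidx] <- Prand[eidx, eidx] + sub
          brand[eidx] <- brand[eidx] +
            as.numeric(Pi[rrows, , drop = FALSE] %*% Z0[i, ])
        }
      }
      Vp <- P0 + Plik + Prand
      Rv <- chol(Vp)
      rhs <- as.numeric(P0 %*% mu[ii, ]) + bz[ii, ] + brand
      mean <- backsolve(Rv, forwardsolve(t(Rv), rhs))
      st$eta2[k, ] <- mean + backsolve(Rv, rnorm(U))
    }
  }
  st$acc$eta2 <- st$acc$eta2 + c(fit$K, fit$K)
  st
}

rowsum_vec <- function(x, grp, K) {
  out <- numeric(K)
  s <- rowsum(x, grp)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

# ---- class updates ------------------------------------------------------

update_classes <- function(st, fit) {
  spec <- st$spec
  # individuals
  if (spec$Cstar > 1L) {
    x1 <- fit$data$x1
    Dexp <- st$D[fit$cluster]
    rand <- rand_entries(spec, st$eta2[fit$cluster, , drop = FALSE])
    lp <- log(class_probs(spec$l1$mix, x1))
    for (cc in seq_len(spec$Cstar)) {
      Cc <- rep(cc, fit$N)
      lp[, cc] <- lp[, cc] + unit_ll1(spec, st$ystar, st$eta1, x1, Cc,
                                      Dexp, rand, Fb = st$F1b)
    }
    st$C <- gumbel_argmax(lp)
  }
  # clusters
  if (spec$Dstar > 1L) {
    x2 <- fit$data$x2
    lp <- log(class_probs(spec$l2$mix, x2))
    for (dd in seq_len(spec$Dstar)) {
      Dd <- rep(dd, fit$K)
      lp[, dd] <- lp[, dd] + cluster_ll2(spec, st$zstar, st$eta2, x2, Dd)
      if (fit$l1_depends_d) {
        x1 <- fit$data$x1
        rand <- rand_entries(spec, st$eta2[fit$cluster, , drop = FALSE])
        ll1 <- unit_ll1(spec, st$ystar, st$eta1, x1, st$C,
                        rep(dd, fit$N), rand, Fb = st$F1b)
        lp[, dd] <- lp[, dd] + rowsum_vec(ll1, fit$cluster, fit$K)
      }
    }
    st$D <- gumbel_argmax(lp)
  }
  st
}

# categorical draws from unnormalized log probabilities, row-wise
gumbel_argmax <- function(lp) {
  g <- -log(-log(matrix(runif(length(lp)), nrow(lp))))
  max.col(lp + g, ties.method = "first")
}

# ---- data augmentation --------------------------------------------------

update_augmented <- function(st, fit) {
  spec <- st$spec
  if (length(fit$y_ordered) || fit$any_y_miss) {
    Dexp <- st$D[fit$cluster]
    M <- meas_mean(spec$l1, st$eta1, fit$data$x1, st$C, Dexp, spec$Cstar)
    for (j in fit$y_ordered) {
      lk <- spec$y_links[[j]]
      cuts <- c(-Inf, lk$thresholds, Inf)
      cat_obs <- fit$data$y[, j]
      obs <- !fit$y_miss[, j]
      lo <- cuts[cat_obs[obs]]
      hi <- cuts[cat_obs[obs] + 1L]
      st$ystar[obs, j] <- rtnorm_vec(M[obs, j], 1, lo, hi)
      # threshold conditionals (uniform between adjacent utilities)
      if (lk$n_categories > 2L) {
        tau <- lk$thresholds
        for (s in 2:(lk$n_categories - 1L)) {
          below <- st$ystar[obs, j][cat_obs[obs] == s]
          above <- st$ystar[obs, j][cat_obs[obs] == s + 1L]
          lo_s <- max(c(below, tau[s - 1L]))
          hi_s <- min(c(above, if (s < lk$n_categories - 1L) tau[s + 1L]))
          tau[s] <- runif(1, lo_s, hi_s)
        }
        st$spec$y_links[[j]]$thresholds <- tau
        spec <- st$spec
      }
    }
    if (fit$any_y_miss) {
      vtheta <- unit_res_var(spec$l1$meas$theta, st$C, Dexp, spec$Cstar)
      idx <- which(fit$y_miss, arr.ind = TRUE)
      st$ystar[idx] <- M[idx] +
        rnorm(nrow(idx)) * sqrt(vtheta[idx])
    }
  }
  if (length(fit$z_ordered) || fit$any_z_miss) {
    ones <- rep(1L, fit$K)
    M <- meas_mean(spec$l2, st$eta2, fit$data$x2, ones, st$D, 1L)
    for (l in fit$z_ordered) {
      lk <- spec$z_links[[l]]
      cuts <- c(-Inf, lk$thresholds, Inf)
      cat_obs <- fit$data$z[, l]
      obs <- !fit$z_miss[, l]
      st$zstar[obs, l] <- rtnorm_vec(M[obs, l], 1, cuts[cat_obs[obs]],
                                     cuts[cat_obs[obs] + 1L])
      if (lk$n_categories > 2L) {
        tau <- lk$thresholds
        for (s in 2:(lk$n_categories - 1L)) {
          below <- st$zstar[obs, l][cat_obs[obs] == s]
          above <- st$zstar[obs, l][cat_obs[obs] == s + 1L]
          tau[s] <- runif(1, max(c(below, tau[s - 1L])),
                          min(c(above, if (s < lk$n_categories - 1L)
                            tau[s + 1L])))
        }
        st$spec$z_links[[l]]$thresholds <- tau
        spec <- st$spec
      }
    }
    if (fit$any_z_miss) {
      vtheta <- unit_res_var(spec$l2$meas$theta, ones, st$D, 1L)
      idx <- which(fit$z_miss, arr.ind = TRUE)
      st$zstar[idx] <- M[idx] + rnorm(nrow(idx)) * sqrt(vtheta[idx])
    }
  }
  st
}

# matrix of per-unit residual variances (diagonal entries) for a covariance
unit_res_var <- function(cs, cvec, dvec, Cstar) {
  n <- length(cvec)
  g <- row_groups(cs$vary, cvec, dvec, Cstar, n)
  out <- matrix(0, n, cs$dim)
  for (gg in unique(g))
    out[g == gg, ] <- matrix(diag(cs$values[[gg]]), sum(g == gg), cs$dim,
                             byrow = TRUE)
  out
}

# vectorized truncated-normal draws on (lo, hi)
rtnorm_vec <- function(mean, sd, lo, hi) {
  plo <- pnorm(lo, mean, sd)
  phi <- pnorm(hi, mean, sd)
  # guard the extreme tails
  plo <- pmin(plo, 1 - 1e-12)
  phi <- pmax(phi, plo + 1e-12)
  u <- plo + runif(length(mean)) * (phi - plo)
  q <- qnorm(u, mean, sd)
  pmin(pmax(q, lo + 1e-10), hi - 1e-10)
}

# scalar positive-truncated normal (Robert's exponential rejection in the
# far tail)
rtnorm_pos <- function(m, s) {
  lo <- pnorm(0, m, s)
  if (lo < 1 - 1e-10) {
    x <- qnorm(runif(1, lo, 1), m, s)
    if (is.finite(x) && x > 0) return(x)
  }
  mu <- -m / s
  a <- (mu + sqrt(mu^2 + 4)) / 2
  repeat {
    z <- mu + rexp(1, a)
    if (runif(1) <= exp(-(z - a)^2 / 2)) return(m + s * z)
  }
}
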