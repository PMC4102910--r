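# Conjugate coefficient updates, precision updates, mixture-logit updates,
# complete-data deviance, and the sampler driver.

safe_chol <- function(S) {
  tryCatch(chol(S), error = function(e) {
    chol(S + diag(1e-8 * mean(diag(S)) + 1e-10, nrow(S)))
  })
}

# Bayesian linear regression draw with known heteroscedastic variances:
# y_i = x_i' beta + e_i, e_i ~ N(0, var_i), beta ~ N(m0, v0 I)
conj_reg <- function(y, X, var_i, m0, v0) {
  p <- ncol(X)
  Xw <- X / var_i
  A <- crossprod(Xw, X) + diag(1 / v0, p)
  b <- crossprod(Xw, y) + m0 / v0
  R <- chol(A)
  mean <- backsolve(R, forwardsolve(t(R), b))
  as.numeric(mean + backsolve(R, rnorm(p)))
}

update_coefficients <- function(st, fit, priors) {
  st <- update_part_coefs(st, fit, priors, 1L, "meas")
  st <- update_part_coefs(st, fit, priors, 1L, "struct")
  if (st$spec$U > 0L) {
    st <- update_part_coefs(st, fit, priors, 2L, "meas")
    st <- update_part_coefs(st, fit, priors, 2L, "struct")
  }
  st
}

update_part_coefs <- function(st, fit, priors, level, part) {
  spec <- st$spec
  lvl <- if (level == 1L) spec$l1 else spec$l2
  nresp <- if (part == "meas") lvl$J else lvl$m
  if (nresp == 0L) return(st)
  if (level == 1L) {
    uc <- st$C; ud <- st$D[fit$cluster]; x <- fit$data$x1
    eta <- st$eta1
    resp <- if (part == "meas") st$ystar else st$eta1
    rand <- rand_entries(spec, st$eta2[fit$cluster, , drop = FALSE])
  } else {
    uc <- rep(1L, fit$K); ud <- st$D; x <- fit$data$x2
    eta <- st$eta2
    resp <- if (part == "meas") st$zstar else st$eta2
    rand <- list()
  }
  n <- nrow(resp)
  if (part == "meas") {
    bnames <- c("nu", "lambda", "kappa")
    bas <- list(nu = matrix(1, n, 1), lambda = eval_basis(lvl$meas$f, eta),
                kappa = eval_basis(lvl$meas$g, x))
    po <- lvl$meas
    cs <- lvl$meas$theta
  } else {
    bnames <- c("alpha", "B", "gamma")
    bas <- list(alpha = matrix(1, n, 1),
                B = if (level == 1L && !is.null(st$F1b)) st$F1b
                else eval_basis(lvl$struct$F, eta),
                gamma = eval_basis(lvl$struct$G, x))
    po <- lvl$struct
    cs <- lvl$struct$psi
  }
  names(bas) <- bnames

  M <- if (part == "meas") meas_mean(lvl, eta, x, uc, ud, spec$Cstar)
  else struct_mean(lvl, eta, x, uc, ud, spec$Cstar, rand, Fb = bas$B)
  E <- resp - M
  gcv <- row_groups(cs$vary, uc, ud, spec$Cstar, n)

  ob <- spec$ordered_block
  ob_here <- !is.null(ob) && ob$level == level &&
    ((ob$block == "alpha" && part == "struct") ||
       (ob$block == "nu" && part == "meas"))
  ob_bn <- if (ob_here) ob$block else ""

  for (r in seq_len(nresp)) {
    any_free <- any(vapply(bnames, function(bn) any(po[[bn]]$free[r, ]),
                           TRUE))
    if (!any_free) next
    # conditional residual variance given the other rows of the block
    bi <- which(vapply(cs$blocks, function(b) r %in% b, TRUE))
    o <- setdiff(cs$blocks[[bi]], r)
    var_i <- numeric(n); cmu <- numeric(n)
    for (gg in unique(gcv)) {
      u <- gcv == gg
      S <- cs$values[[gg]]
      if (length(o)) {
        w <- solve(S[o, o, drop = FALSE], S[o, r])
        var_i[u] <- S[r, r] - sum(S[r, o] * w)
        cmu[u] <- E[u, o, drop = FALSE] %*% w
      } else var_i[u] <- S[r, r]
    }
    for (bn in bnames) {
      pb <- po[[bn]]
      cols <- which(pb$free[r, ])
      is_ord <- ob_here && bn == ob_bn && pb$n_groups > 1L && pb$row_vary[r]
      if (!length(cols) && !is_ord) next
      pmn <- if (bn == "lambda") priors$loading_mean else priors$coef_mean
      ps_r <- fit$ps[[paste0("l", level, "_", part)]][r]
      if (is_ord) {
        gvec_o <- pb_group(pb$vary, uc, ud, spec$Cstar)
        vals_old <- vapply(seq_len(pb$n_groups), function(g)
          pb$values[[g]][r, 1], 0)
        pb <- ordered_intercept_draw(pb, r, resp[, r], M[, r], cmu, var_i,
                                     gvec_o, priors, ps_r)
        vals_new <- vapply(seq_len(pb$n_groups), function(g)
          pb$values[[g]][r, 1], 0)
        M[, r] <- M[, r] + (vals_new - vals_old)[gvec_o]
      } else if (length(cols)) {
        shared <- pb$n_groups > 1L && !pb$row_vary[r]
        gvec <- if (pb$n_groups == 1L || shared) rep(1L, n)
        else pb_group(pb$vary, uc, ud, spec$Cstar)
        X <- bas[[bn]][, cols, drop = FALSE]
        v0 <- ps_r * priors$H0
        for (g in unique(gvec)) {
          u <- which(gvec == g)
          beta_cur <- pb$values[[g]][r, cols]
          partial <- M[u, r] - X[u, , drop = FALSE] %*% beta_cur
          yt <- resp[u, r] - partial - cmu[u]
          beta_new <- conj_reg(yt, X[u, , drop = FALSE], var_i[u], pmn, v0)
          gset <- if (shared) seq_len(pb$n_groups) else g
          for (g2 in gset) pb$values[[g2]][r, cols] <- beta_new
          M[u, r] <- M[u, r] +
            X[u, , drop = FALSE] %*% (beta_new - beta_cur)
        }
      }
      po[[bn]] <- pb
    }
    E[, r] <- resp[, r] - M[, r]
  }
  if (level == 1L) {
    if (part == "meas") st$spec$l1$meas <- po else st$spec$l1$struct <- po
  } else {
    if (part == "meas") st$spec$l2$meas <- po else st$spec$l2$struct <- po
  }
  st
}

# class-ordered intercepts: value_g = base + sum of positive increments;
# the base gets a normal conditional, each increment a positive-truncated
# normal conditional (half-normal prior)
ordered_intercept_draw <- function(pb, r, resp_r, M_r, cmu, var_i, gvec,
                                   priors, ps_r) {
  G <- pb$n_groups
  vals <- vapply(seq_len(G), function(g) pb$values[[g]][r, 1], 0)
  resp_all <- resp_r - (M_r - vals[gvec]) - cmu
  v0 <- ps_r * priors$H0
  v0d <- ps_r * priors$H0_delta
  # base intercept: conditional on the increments
  off <- vals[gvec] - vals[1]
  prec <- sum(1 / var_i) + 1 / v0
  mu <- (sum((resp_all - off) / var_i) + priors$coef_mean / v0) / prec
  base_new <- rnorm(1, mu, sqrt(1 / prec))
  vals <- vals - vals[1] + base_new
  for (t in seq_len(G - 1L)) {
    u <- which(gvec > t)
    delta_t <- vals[t + 1L] - vals[t]
    if (length(u)) {
      resid <- resp_all[u] - (vals[gvec[u]] - delta_t)
      prec <- sum(1 / var_i[u]) + 1 / v0d
      mu <- sum(resid / var_i[u]) / prec
      dnew <- rtnorm_pos(mu, sqrt(1 / prec))
    } else {
      dnew <- abs(rnorm(1, 0, sqrt(v0d)))
    }
    vals[(t + 1L):G] <- vals[(t + 1L):G] + (dnew - delta_t)
  }
  for (g in seq_len(G)) pb$values[[g]][r, 1] <- vals[g]
  pb
}

# ---- ridge recentering move --------------------------------------------
# Symmetric Metropolis move along the precomputed near-constant direction
# of a spline/polynomial basis: basis coefficients shift by c*w while the
# compensating intercept (fixed, or the mapped cluster random effect plus
# its level-2 mean) shifts by -c. Level-2 residuals are unchanged by
# construction, so the ratio involves only the level-1 structural
# likelihood and the priors of the shifted coefficients.
update_ridge <- function(st, fit, priors) {
  if (!length(fit$ridge)) return(st)
  spec <- st$spec
  Dexp <- st$D[fit$cluster]
  x1 <- fit$data$x1
  for (i in seq_along(fit$ridge)) {
    mv <- fit$ridge[[i]]
    cdelta <- rnorm(1, 0, st$steps$ridge[i])
    rand <- rand_entries(spec, st$eta2[fit$cluster, , drop = FALSE])
    E <- st$eta1 - struct_mean(spec$l1, st$eta1, x1, st$C, Dexp,
                               spec$Cstar, rand, Fb = st$F1b)
    ll_cur <- sum(resid_loglik(E, spec$l1$struct$psi, st$C, Dexp,
                               spec$Cstar))
    sp2 <- spec
    Bv <- sp2$l1$struct$B
    b_old <- Bv$values[[1]][mv$row, mv$cols]
    b_new <- b_old + cdelta * mv$w
    for (g in seq_len(Bv$n_groups)) Bv$values[[g]][mv$row, mv$cols] <- b_new
    sp2$l1$struct$B <- Bv
    eta2p <- st$eta2
    if (mv$type == "eta2") {
      eta2p[, mv$u] <- eta2p[, mv$u] - cdelta
      al <- sp2$l2$struct$alpha
      m_old <- al$values[[1]][mv$u, 1]
      for (g in seq_len(al$n_groups))
        al$values[[g]][mv$u, 1] <- al$values[[g]][mv$u, 1] - cdelta
      sp2$l2$struct$alpha <- al
      v0m <- fit$ps$l2_struct[mv$u] * priors$H0
    } else {
      al <- sp2$l1$struct$alpha
      m_old <- al$values[[1]][mv$row, 1]
      for (g in seq_len(al$n_groups))
        al$values[[g]][mv$row, 1] <- al$values[[g]][mv$row, 1] - cdelta
      sp2$l1$struct$alpha <- al
      v0m <- fit$ps$l1_struct[mv$row] * priors$H0
    }
    randp <- rand_entries(sp2, eta2p[fit$cluster, , drop = FALSE])
    Ep <- st$eta1 - struct_mean(sp2$l1, st$eta1, x1, st$C, Dexp,
                                spec$Cstar, randp, Fb = st$F1b)
    ll_prop <- sum(resid_loglik(Ep, sp2$l1$struct$psi, st$C, Dexp,
                                spec$Cstar))
    v0B <- fit$ps$l1_struct[mv$row] * priors$H0
    lpr <- sum(dnorm(b_new, priors$coef_mean, sqrt(v0B), log = TRUE)) -
      sum(dnorm(b_old, priors$coef_mean, sqrt(v0B), log = TRUE)) +
      dnorm(m_old - cdelta, priors$coef_mean, sqrt(v0m), log = TRUE) -
      dnorm(m_old, priors$coef_mean, sqrt(v0m), log = TRUE)
    if (log(runif(1)) < ll_prop - ll_cur + lpr) {
      st$spec <- sp2
      st$eta2 <- eta2p
      spec <- sp2
      st$acc$ridge[i, ] <- st$acc$ridge[i, ] + c(1, 1)
    } else {
      st$acc$ridge[i, ] <- st$acc$ridge[i, ] + c(0, 1)
    }
  }
  st
}

# ---- collapsed random-outcome coefficient update ------------------------
# Conjugate draw of (mu_u, B2 row u, Gamma2 row u) with the random-effect
# column eta2[, u] integrated out, followed by an exact refresh of that
# column (partially collapsed Gibbs).
update_collapsed <- function(st, fit, priors) {
  if (!length(fit$collapse)) return(st)
  spec <- st$spec
  x1 <- fit$data$x1
  x2 <- fit$data$x2
  K <- fit$K
  Dexp <- st$D[fit$cluster]
  for (mv in fit$collapse) {
    # level-1 pseudo-observations: precision-weighted cluster means of the
    # mapped row's residuals (excluding the random intercept itself)
    rand_other <- Filter(function(e) !(e$block == "alpha" &&
                                         e$row == mv$r),
                         rand_entries(spec,
                                      st$eta2[fit$cluster, , drop = FALSE]))
    mean_no <- struct_mean(spec$l1, st$eta1, x1, st$C, Dexp, spec$Cstar,
                           rand_other, Fb = st$F1b)
    resid_r <- st$eta1[, mv$r] - mean_no[, mv$r]
    v1 <- unit_res_var(spec$l1$struct$psi, st$C, Dexp,
                       spec$Cstar)[, mv$r]
    wk <- rowsum_vec(1 / v1, fit$cluster, K)
    mk <- rowsum_vec(resid_r / v1, fit$cluster, K) / wk
    psi2_uu <- vapply(seq_len(K), function(k)
      spec$l2$struct$psi$values[[pb_group(spec$l2$struct$psi$vary, 1L,
                                          st$D[k], 1L)]][mv$u, mv$u], 0)
    var_k <- psi2_uu + 1 / wk
    # design: intercept (if free) + free B columns + free Gamma columns
    F2b <- eval_basis(spec$l2$struct$F, st$eta2)
    G2b <- eval_basis(spec$l2$struct$G, x2)
    X <- cbind(if (mv$mu_free) rep(1, K),
               F2b[, mv$cols_B, drop = FALSE],
               G2b[, mv$cols_G, drop = FALSE])
    if (is.null(X) || ncol(X) == 0L) next
    # offset: mean of row u under current parameters minus the free part
    ones <- rep(1L, K)
    mu_row <- struct_mean(spec$l2, st$eta2, x2, ones, st$D, 1L)[, mv$u]
    al <- spec$l2$struct$alpha
    beta_cur <- c(if (mv$mu_free) al$values[[1]][mv$u, 1],
                  spec$l2$struct$B$values[[1]][mv$u, mv$cols_B],
                  spec$l2$struct$gamma$values[[1]][mv$u, mv$cols_G])
    offset <- mu_row - as.numeric(X %*% beta_cur)
    v0 <- fit$ps$l2_struct[mv$u] * priors$H0
    beta_new <- conj_reg(mk - offset, X, var_k, priors$coef_mean, v0)
    p <- 0L
    if (mv$mu_free) {
      p <- 1L
      for (g in seq_len(al$n_groups)) al$values[[g]][mv$u, 1] <- beta_new[1]
      spec$l2$struct$alpha <- al
    }
    if (length(mv$cols_B)) {
      Bv <- spec$l2$struct$B
      for (g in seq_len(Bv$n_groups))
        Bv$values[[g]][mv$u, mv$cols_B] <- beta_new[p + seq_along(mv$cols_B)]
      spec$l2$struct$B <- Bv
      p <- p + length(mv$cols_B)
    }
    if (length(mv$cols_G)) {
      Gv <- spec$l2$struct$gamma
      for (g in seq_len(Gv$n_groups))
        Gv$values[[g]][mv$u, mv$cols_G] <- beta_new[p + seq_along(mv$cols_G)]
      spec$l2$struct$gamma <- Gv
    }
    st$spec <- spec
    # refresh the collapsed random-effect column from its full conditional
    st$eta2[, mv$u] <- eta2_coord_draw(st, fit, mv$u)
  }
  st
}

# ---- factor scale moves -------------------------------------------------
update_fscale <- function(st, fit, priors) {
  if (!length(fit$fscale)) return(st)
  for (i in seq_along(fit$fscale)) {
    mv <- fit$fscale[[i]]
    spec <- st$spec
    lvl <- if (mv$level == 1) spec$l1 else spec$l2
    if (mv$level == 1) {
      uc <- st$C; ud <- st$D[fit$cluster]; x <- fit$data$x1
      eta <- st$eta1; star <- st$ystar
      rand <- rand_entries(spec, st$eta2[fit$cluster, , drop = FALSE])
    } else {
      uc <- rep(1L, fit$K); ud <- st$D; x <- fit$data$x2
      eta <- st$eta2; star <- st$zstar
      rand <- list()
    }
    n <- nrow(eta)
    level_ll <- function(sp, lvl2, eta2m, Fb = NULL) {
      E_m <- star - meas_mean(lvl2, eta2m, x, uc, ud, sp$Cstar)
      E_s <- eta2m - struct_mean(lvl2, eta2m, x, uc, ud, sp$Cstar, rand,
                                 Fb = Fb)
      sum(resid_loglik(E_m, lvl2$meas$theta, uc, ud, sp$Cstar)) +
        sum(resid_loglik(E_s, lvl2$struct$psi, uc, ud, sp$Cstar))
    }
    # cross-level term when a level-2 latent feeds level-1 random effects
    cross_ll <- function(sp, eta2m) {
      if (mv$level != 2 || !(mv$v %in% sp$random$eta2)) return(0)
      r2 <- rand_entries(sp, eta2m[fit$cluster, , drop = FALSE])
      E_s <- st$eta1 - struct_mean(sp$l1, st$eta1, fit$data$x1, st$C,
                                   st$D[fit$cluster], sp$Cstar, r2,
                                   Fb = st$F1b)
      sum(resid_loglik(E_s, sp$l1$struct$psi, st$C, st$D[fit$cluster],
                       sp$Cstar))
    }
    eps <- rnorm(1, 0, st$steps$fscale[i])
    phi <- exp(eps)
    m_v <- struct_mean(lvl, eta, x, uc, ud, spec$Cstar, rand)[, mv$v]
    m0 <- mean(m_v)
    eta_p <- eta
    eta_p[, mv$v] <- m_v + (eta[, mv$v] - m_v) * phi
    lvl_p <- lvl
    lam <- lvl_p$meas$lambda
    lam_old <- lam$values[[1]][mv$lam_rows, mv$col]
    lam$values[[1]][mv$lam_rows, mv$col] <- lam_old / phi
    lvl_p$meas$lambda <- lam
    nub <- lvl_p$meas$nu
    nu_old <- nub$values[[1]][mv$nu_rows, 1]
    lam_nu <- lam_old[match(mv$nu_rows, mv$lam_rows)]
    nub$values[[1]][mv$nu_rows, 1] <- nu_old + lam_nu * m0 * (1 - 1 / phi)
    lvl_p$meas$nu <- nub
    psi <- lvl_p$struct$psi
    S <- psi$values[[1]]
    S_old_blk <- S[mv$blk, mv$blk, drop = FALSE]
    S[mv$v, ] <- S[mv$v, ] * phi
    S[, mv$v] <- S[, mv$v] * phi
    psi$values[[1]] <- S
    lvl_p$struct$psi <- psi
    sp2 <- spec
    if (mv$level == 1) sp2$l1 <- lvl_p else sp2$l2 <- lvl_p

    Fb_cur <- if (mv$level == 1) st$F1b
    ll_cur <- level_ll(spec, lvl, eta, Fb = Fb_cur) + cross_ll(spec, eta)
    ll_prop <- level_ll(sp2, lvl_p, eta_p) + cross_ll(sp2, eta_p)
    # priors on transformed parameters
    ps_lam <- fit$ps[[paste0("l", mv$level, "_meas")]][mv$lam_rows]
    v0_lam <- ps_lam * priors$H0
    ps_nu <- fit$ps[[paste0("l", mv$level, "_meas")]][mv$nu_rows]
    v0_nu <- ps_nu * priors$H0
    lpr <- sum(dnorm(lam_old / phi, priors$loading_mean, sqrt(v0_lam),
                     log = TRUE) -
                 dnorm(lam_old, priors$loading_mean, sqrt(v0_lam),
                       log = TRUE)) +
      sum(dnorm(nub$values[[1]][mv$nu_rows, 1], priors$coef_mean,
                sqrt(v0_nu), log = TRUE) -
            dnorm(nu_old, priors$coef_mean, sqrt(v0_nu), log = TRUE))
    # Wishart prior ratio for the scaled disturbance block
    p_blk <- length(mv$blk)
    df0 <- p_blk + priors$wishart_df_add
    S0 <- diag(priors$wishart_scale, p_blk)
    S_new_blk <- S[mv$blk, mv$blk, drop = FALSE]
    wish_lp <- function(Sb) {
      -0.5 * (df0 + p_blk + 1) * determinant(Sb)$modulus[1] -
        0.5 * sum(diag(S0 %*% chol2inv(safe_chol(Sb))))
    }
    lpr <- lpr + wish_lp(S_new_blk) - wish_lp(S_old_blk)
    # Jacobian: n latent values scale by phi, the psi row/column
    # contributes (p_blk + 1) powers of phi, free loadings 1/phi each
    logJ <- (n + p_blk + 1 - length(mv$lam_rows)) * eps
    if (log(runif(1)) < ll_prop - ll_cur + lpr + logJ) {
      st$spec <- sp2
      if (mv$level == 1) {
        st$eta1 <- eta_p
        st$F1b <- eval_basis(sp2$l1$struct$F, eta_p)
      } else st$eta2 <- eta_p
      st$acc$fscale[i, ] <- st$acc$fscale[i, ] + c(1, 1)
    } else {
      st$acc$fscale[i, ] <- st$acc$fscale[i, ] + c(0, 1)
    }
  }
  st
}

# ---- precision updates --------------------------------------------------

update_precisions <- function(st, fit, priors) {
  spec <- st$spec
  Dexp <- st$D[fit$cluster]
  rand <- rand_entries(spec, st$eta2[fit$cluster, , drop = FALSE])
  x1 <- fit$data$x1
  if (spec$J > 0L) {
    E <- st$ystar - meas_mean(spec$l1, st$eta1, x1, st$C, Dexp, spec$Cstar)
    st$spec$l1$meas$theta <- draw_cov(spec$l1$meas$theta, E, st$C, Dexp,
                                      spec$Cstar, priors)
  }
  if (spec$m > 0L) {
    E <- st$eta1 - struct_mean(spec$l1, st$eta1, x1, st$C, Dexp,
                               spec$Cstar, rand, Fb = st$F1b)
    st$spec$l1$struct$psi <- draw_cov(spec$l1$struct$psi, E, st$C, Dexp,
                                      spec$Cstar, priors)
  }
  if (spec$U > 0L) {
    ones <- rep(1L, fit$K)
    x2 <- fit$data$x2
    if (spec$L > 0L) {
      E <- st$zstar - meas_mean(spec$l2, st$eta2, x2, ones, st$D, 1L)
      st$spec$l2$meas$theta <- draw_cov(spec$l2$meas$theta, E, ones, st$D,
                                        1L, priors)
    }
    E <- st$eta2 - struct_mean(spec$l2, st$eta2, x2, ones, st$D, 1L)
    st$spec$l2$struct$psi <- draw_cov(spec$l2$struct$psi, E, ones, st$D,
                                      1L, priors)
  }
  st
}

draw_cov <- function(cs, E, cvec, dvec, Cstar, priors) {
  if (!any(cs$free)) return(cs)
  g <- row_groups(cs$vary, cvec, dvec, Cstar, nrow(E))
  for (gg in seq_len(cs$n_groups)) {
    u <- which(g == gg)
    for (b in seq_along(cs$blocks)) {
      if (!cs$free[b]) next
      ids <- cs$blocks[[b]]
      p <- length(ids)
      S0 <- diag(priors$wishart_scale, p)
      df0 <- p + priors$wishart_df_add
      CP <- if (length(u)) crossprod(E[u, ids, drop = FALSE])
      else matrix(0, p, p)
      Sc <- chol2inv(safe_chol(S0 + CP))
      W <- rWishart(1, df0 + length(u), Sc)[, , 1]
      cs$values[[gg]][ids, ids] <- chol2inv(safe_chol(W))
    }
  }
  cs
}

# ---- class-marginal mixture updates ------------------------------------
# Partially collapsed Metropolis updates for the level-2 mixture: the
# logit intercepts/slopes and the ordered class-mean increments are
# proposed against the likelihood with the class labels D summed out
# (log-sum-exp over classes of the cluster-level likelihood). The labels
# are refreshed from their full conditional immediately afterwards
# (update_classes follows in the cycle), which keeps the collapsed draws
# valid. With heavily overlapping classes this mixes the mixture block
# orders of magnitude faster than label-conditional draws alone.
update_mixture_marginal <- function(st, fit, priors) {
  spec <- st$spec
  if (spec$Dstar < 2L) return(st)
  x2 <- fit$data$x2
  K <- fit$K
  ones <- rep(1L, K)
  # class-conditional pieces; only the level-2 structural part reacts to
  # the ordered class-mean increments, so the rest is computed once
  L_fix <- matrix(0, K, spec$Dstar)
  for (d in seq_len(spec$Dstar)) {
    Dd <- rep(d, K)
    if (spec$L > 0L) {
      E_m <- st$zstar - meas_mean(spec$l2, st$eta2, x2, ones, Dd, 1L)
      L_fix[, d] <- resid_loglik(E_m, spec$l2$meas$theta, ones, Dd, 1L)
    }
  }
  if (fit$l1_depends_d) {
    x1 <- fit$data$x1
    rand <- rand_entries(spec, st$eta2[fit$cluster, , drop = FALSE])
    for (d in seq_len(spec$Dstar)) {
      ll1 <- unit_ll1(spec, st$ystar, st$eta1, x1, st$C,
                      rep(d, fit$N), rand)
      L_fix[, d] <- L_fix[, d] + rowsum_vec(ll1, fit$cluster, K)
    }
  }
  l_struct <- function(sp) {
    out <- matrix(0, K, spec$Dstar)
    for (d in seq_len(spec$Dstar)) {
      Dd <- rep(d, K)
      E_s <- st$eta2 - struct_mean(sp$l2, st$eta2, x2, ones, Dd, 1L)
      out[, d] <- resid_loglik(E_s, sp$l2$struct$psi, ones, Dd, 1L)
    }
    out
  }
  lmat <- function(sp) L_fix + l_struct(sp)
  marg_ll <- function(sp, L) {
    lp <- log(class_probs(sp$l2$mix, x2))
    sum(lse_rows(lp + L))
  }
  L_cur <- lmat(spec)

  # logit coefficients, marginal over D
  mix <- spec$l2$mix
  afree <- which(mix$a$free[, 1])
  bfree <- which(mix$b$free)
  if (length(afree) || length(bfree)) {
    a0 <- pb_get(mix$a)[, 1]; b0 <- pb_get(mix$b)
    lpr <- function(a, b) sum(dnorm(c(a[afree], b[bfree]), 0,
                                    priors$logit_sd, log = TRUE))
    step <- st$steps$logit2
    a1 <- a0; b1 <- b0
    a1[afree] <- a1[afree] + step * rnorm(length(afree))
    b1[bfree] <- b1[bfree] + step * rnorm(length(bfree))
    sp2 <- spec
    sp2$l2$mix$a$values[[1]][, 1] <- a1
    sp2$l2$mix$b$values[[1]] <- b1
    if (log(runif(1)) < marg_ll(sp2, L_cur) + lpr(a1, b1) -
        marg_ll(spec, L_cur) - lpr(a0, b0)) {
      st$spec <- sp2
      spec <- sp2
      st$acc$logit2 <- st$acc$logit2 + c(1, 1)
    } else {
      st$acc$logit2 <- st$acc$logit2 + c(0, 1)
    }
  }

  # ordered class-mean increments, marginal over D
  ob <- spec$ordered_block
  if (!is.null(ob) && ob$level == 2 && ob$block == "alpha") {
    al <- spec$l2$struct$alpha
    G <- al$n_groups
    rows <- which(al$row_vary & al$free[, 1])
    for (ri in seq_along(rows)) {
      r <- rows[ri]
      ps_r <- fit$ps$l2_struct[r]
      v0d <- ps_r * priors$H0_delta
      for (t in seq_len(G - 1L)) {
        idx <- (ri - 1L) * (G - 1L) + t
        step <- st$steps$delta[idx]
        vals <- vapply(seq_len(G), function(g) al$values[[g]][r, 1], 0)
        delta <- vals[t + 1L] - vals[t]
        dnew <- delta + step * rnorm(1)
        if (dnew > 0) {
          sp2 <- spec
          al2 <- sp2$l2$struct$alpha
          for (g in seq.int(t + 1L, G))
            al2$values[[g]][r, 1] <- al2$values[[g]][r, 1] + (dnew - delta)
          sp2$l2$struct$alpha <- al2
          lratio <- marg_ll(sp2, lmat(sp2)) - marg_ll(spec, L_cur) +
            dnorm(dnew, 0, sqrt(v0d), log = TRUE) -
            dnorm(delta, 0, sqrt(v0d), log = TRUE)
          if (log(runif(1)) < lratio) {
            st$spec <- sp2
            spec <- sp2
            L_cur <- lmat(spec)
            st$acc$delta[idx, ] <- st$acc$delta[idx, ] + c(1, 1)
            next
          }
        }
        st$acc$delta[idx, ] <- st$acc$delta[idx, ] + c(0, 1)
      }
    }
  }
  st
}

# ---- mixture-logit updates ---------------------------------------------

update_logit <- function(st, fit, priors) {
  # level-2 logits are handled by the class-marginal update
  for (level in 1L) {
    mix <- if (level == 1L) st$spec$l1$mix else st$spec$l2$mix
    G <- mix$n_classes
    if (G < 2L) next
    afree <- which(mix$a$free[, 1])
    bfree <- which(mix$b$free)
    if (!length(afree) && !length(bfree)) next
    cls <- if (level == 1L) st$C else st$D
    x <- if (level == 1L) fit$data$x1 else fit$data$x2
    hb <- eval_basis(mix$h, x)
    n <- length(cls)
    idx <- cbind(seq_len(n), cls)
    llfun <- function(a, b) {
      lin <- matrix(a, n, G, byrow = TRUE)
      if (ncol(hb) > 0L) lin <- lin + hb %*% t(b)
      mx <- lin[, 1]
      for (jj in 2:G) mx <- pmax(mx, lin[, jj])
      sum(lin[idx]) - sum(mx + log(rowSums(exp(lin - mx))))
    }
    a0 <- pb_get(mix$a)[, 1]; b0 <- pb_get(mix$b)
    lpr <- function(a, b) sum(dnorm(c(a[afree], b[bfree]), 0,
                                    priors$logit_sd, log = TRUE))
    cur <- llfun(a0, b0) + lpr(a0, b0)
    sname <- paste0("logit", level)
    step <- st$steps[[sname]]
    a1 <- a0; b1 <- b0
    a1[afree] <- a1[afree] + step * rnorm(length(afree))
    b1[bfree] <- b1[bfree] + step * rnorm(length(bfree))
    if (log(runif(1)) < llfun(a1, b1) + lpr(a1, b1) - cur) {
      mix$a$values[[1]][, 1] <- a1
      mix$b$values[[1]] <- b1
      if (level == 1L) st$spec$l1$mix <- mix else st$spec$l2$mix <- mix
      st$acc[[sname]] <- st$acc[[sname]] + c(1, 1)
    } else {
      st$acc[[sname]] <- st$acc[[sname]] + c(0, 1)
    }
  }
  st
}

# ---- complete-data deviance --------------------------------------------

lse_rows <- function(x) {
  mx <- x[, 1]
  if (ncol(x) > 1) for (jj in 2:ncol(x)) mx <- pmax(mx, x[, jj])
  mx + log(rowSums(exp(x - mx)))
}

# -2 log likelihood, marginal over latent classes but conditional on the
# continuous latent variables (and on augmented/imputed responses)
complete_deviance <- function(spec, fit, eta1, eta2, ystar, zstar,
                              Fb = NULL) {
  N <- fit$N; K <- fit$K
  x1 <- fit$data$x1; x2 <- fit$data$x2
  Cstar <- spec$Cstar; Dstar <- spec$Dstar
  lpD <- log(class_probs(spec$l2$mix, x2))
  lpC <- log(class_probs(spec$l1$mix, x1))
  rand <- rand_entries(spec, eta2[fit$cluster, , drop = FALSE])
  l1_for_d <- function(d) {
    A <- matrix(0, N, Cstar)
    for (cc in seq_len(Cstar)) {
      A[, cc] <- lpC[, cc] + unit_ll1(spec, ystar, eta1, x1,
                                      rep(cc, N), rep(d, N), rand,
                                      Fb = Fb)
    }
    lse_rows(A)
  }
  li_shared <- if (!fit$l1_depends_d) l1_for_d(1L) else NULL
  tot <- matrix(0, K, Dstar)
  for (d in seq_len(Dstar)) {
    ll2 <- cluster_ll2(spec, zstar, eta2, x2, rep(d, K))
    li <- if (is.null(li_shared)) l1_for_d(d) else li_shared
    tot[, d] <- lpD[, d] + ll2 + rowsum_vec(li, fit$cluster, K)
  }
  -2 * sum(lse_rows(tot))
}

# ---- driver -------------------------------------------------------------

adapt_steps <- function(st, settings) {
  for (nm in c("eta1", "eta2", "logit1", "logit2")) {
    a <- st$acc[[nm]]
    if (a[2] == 0) next
    rate <- a[1] / a[2]
    st$steps[[nm]] <- min(10, max(1e-3, st$steps[[nm]] *
                                    exp(0.8 * (rate - settings$target_accept))))
    st$acc[[nm]] <- c(0, 0)
  }
  for (nm in c("ridge", "delta", "fscale")) {
    for (i in seq_len(nrow(st$acc[[nm]]))) {
      a <- st$acc[[nm]][i, ]
      if (a[2] == 0) next
      st$steps[[nm]][i] <- min(20, max(1e-3, st$steps[[nm]][i] *
                                         exp(0.8 * (a[1] / a[2] -
                                                      settings$target_accept))))
    }
    if (nrow(st$acc[[nm]])) st$acc[[nm]][] <- 0
  }
  st
}

reset_acc <- function(st) {
  for (nm in c("eta1", "eta2", "logit1", "logit2"))
    st$acc[[nm]] <- c(0, 0)
  st$acc$ridge[] <- 0
  st$acc$delta[] <- 0
  st$acc$fscale[] <- 0
  st
}

#' Fit a model by Metropolis-within-Gibbs sampling
#'
#' Runs the full data-augmentation sampler: latent classes on both levels,
#' latent variables (exact normal draws in linear models, random-walk
#' Metropolis under non-linear structural functions), conjugate normal
#' draws for coefficient blocks, Wishart/inverse-gamma draws for covariance
#' blocks, ordered positive increments for the designated class-varying
#' intercept block (which rules out label switching by construction),
#' truncated-normal utilities and threshold draws for ordinal indicators,
#' and normal imputation for missing-at-random cells.
#'
#' @param spec an `mlsem_spec` that passes [validate_identification()].
#' @param data an `mlsem_data` (from [simulate_dataset()] or
#'   [read_dataset()]).
#' @param priors a [prior_spec()].
#' @param settings a [sampler_settings()].
#' @return an object of class `mlsem_draws`: per-chain matrices of retained
#'   parameter draws (columns named as in [parameter_index()]), per-chain
#'   deviance traces, Metropolis acceptance rates, and posterior means of
#'   the continuous latent variables.
#' @seealso [posterior_summary()], [epsr()], [dic()]
#' @export
run_gibbs <- function(spec, data, priors = default_priors(spec),
                      settings = sampler_settings()) {
  stopifnot(inherits(priors, "mlsem_priors"),
            inherits(settings, "mlsem_settings"))
  fit <- prep_fit(spec, data)
  fit$data <- data
  spec <- fit$spec
  pnames <- spec$pmap$name
  n_keep <- (settings$iterations - settings$burn_in) %/% settings$thin
  chains <- vector("list", settings$chains)
  devs <- vector("list", settings$chains)
  acc_out <- vector("list", settings$chains)
  eta1_sum <- matrix(0, fit$N, spec$m)
  eta2_sum <- matrix(0, fit$K, spec$U)
  ystar_sum <- matrix(0, fit$N, spec$J)
  zstar_sum <- matrix(0, fit$K, spec$L)
  n_acc <- 0L
  for (ch in seq_len(settings$chains)) {
    set.seed(cluster_seed(settings$seed, 1000003L + ch))
    st <- init_state(fit, priors, settings, ch)
    kept <- matrix(NA_real_, n_keep, length(pnames))
    dv <- rep(NA_real_, n_keep)
    kk <- 0L
    for (it in seq_len(settings$iterations)) {
      st <- update_augmented(st, fit)
      st <- update_eta1(st, fit)
      st <- update_eta2(st, fit)
      st <- update_mixture_marginal(st, fit, priors)
      st <- update_classes(st, fit)
      st <- update_coefficients(st, fit, priors)
      st <- update_collapsed(st, fit, priors)
      # the two auxiliary kernels alternate between iterations: each is a
      # valid kernel on its own, and every other iteration is plenty for
      # the slow directions they target
      if (it %% 2L == 0L) st <- update_ridge(st, fit, priors)
      else st <- update_fscale(st, fit, priors)
      st <- update_precisions(st, fit, priors)
      st <- update_logit(st, fit, priors)
      if (it <= settings$burn_in && it %% settings$adapt_every == 0L)
        st <- adapt_steps(st, settings)
      if (it == settings$burn_in) st <- reset_acc(st)
      if (it > settings$burn_in &&
          (it - settings$burn_in) %% settings$thin == 0L) {
        kk <- kk + 1L
        kept[kk, ] <- collect_params(st$spec)
        dv[kk] <- if ((kk - 1L) %% settings$deviance_every == 0L)
          complete_deviance(st$spec, fit, st$eta1, st$eta2, st$ystar,
                            st$zstar, Fb = st$F1b) else NA_real_
        eta1_sum <- eta1_sum + st$eta1
        eta2_sum <- eta2_sum + st$eta2
        ystar_sum <- ystar_sum + st$ystar
        zstar_sum <- zstar_sum + st$zstar
        n_acc <- n_acc + 1L
      }
    }
    colnames(kept) <- pnames
    chains[[ch]] <- kept
    devs[[ch]] <- dv
    mat_rate <- function(a) if (nrow(a) && all(a[, 2] > 0))
      a[, 1] / a[, 2] else NA_real_
    acc_out[[ch]] <- c(
      lapply(st$acc[c("eta1", "eta2", "logit1", "logit2")], function(a)
        if (a[2] > 0) a[1] / a[2] else NA_real_),
      list(ridge = mat_rate(st$acc$ridge),
           delta = mat_rate(st$acc$delta),
           fscale = mat_rate(st$acc$fscale)))
  }
  structure(list(
    draws = chains, deviance = devs, parameters = pnames,
    accept = acc_out, settings = settings, spec = spec,
    latent_means = list(eta1 = eta1_sum / n_acc, eta2 = eta2_sum / n_acc,
                        ystar = ystar_sum / n_acc,
                        zstar = zstar_sum / n_acc),
    data_dims = list(N = fit$N, K = fit$K)), class = "mlsem_draws")
}

#' @export
print.mlsem_draws <- function(x, ...) {
  cat(sprintf("<mlsem draws> %d chain(s) x %d retained iterations, %d parameters\n",
              length(x$draws), nrow(x$draws[[1]]), length(x$parameters)))
  acc <- x$accept[[1]]
  acc <- acc[vapply(acc, function(a) length(a) >= 1 && !anyNA(a), TRUE)]
  if (length(acc))
    cat("  acceptance:",
        paste(names(acc), vapply(acc, function(a)
          paste(sprintf("%.2f", a), collapse = "/"), ""), collapse = ", "),
        "\n")
  invisible(x)
}
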