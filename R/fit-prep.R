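# Data preparation and state initialization for the Gibbs sampler.

# validate the data against the model and build static caches
prep_fit <- function(spec, data) {
  stopifnot(inherits(spec, "mlsem_spec"), inherits(data, "mlsem_data"))
  rep <- validate_identification(spec)
  if (!attr(rep, "ok")) {
    bad <- rep[!rep$pass, ]
    stop("model failed identification checks: ",
         paste(bad$check, collapse = ", "), call. = FALSE)
  }
  if (ncol(data$y) != spec$J || ncol(data$z) != spec$L ||
      ncol(data$x1) != spec$Q || ncol(data$x2) != spec$V)
    stop("data dimensions do not match the model", call. = FALSE)
  for (lk in c(spec$y_links, spec$z_links)) {
    if (lk$link == "poisson_log")
      stop("count (Poisson) indicators are supported in simulation only",
           call. = FALSE)
  }
  K <- nrow(data$z)
  if (K < 1L || max(data$cluster) != K ||
      !all(sort(unique(data$cluster)) == seq_len(K)))
    stop("cluster ids must index every cluster row", call. = FALSE)

  y_miss <- data$y_miss | is.na(data$y)
  z_miss <- data$z_miss | is.na(data$z)
  # missing cells need a diagonal residual block for one-shot imputation
  chk_missing_diag <- function(miss, theta, what) {
    cols <- which(colSums(miss) > 0)
    for (j in cols) {
      b <- theta$blocks[[which(vapply(theta$blocks, function(b) j %in% b,
                                      TRUE))]]
      if (length(b) > 1L)
        stop("missing values in ", what, " indicator ", j,
             " require a diagonal residual block", call. = FALSE)
    }
  }
  chk_missing_diag(y_miss, spec$l1$meas$theta, "y")
  chk_missing_diag(z_miss, spec$l2$meas$theta, "z")

  # ordered indicators: fix the residual variance at 1, first cut point 0
  fix_ordered <- function(links, theta, what) {
    for (j in seq_along(links)) {
      lk <- links[[j]]
      if (lk$link != "ordered") next
      bi <- which(vapply(theta$blocks, function(b) j %in% b, TRUE))
      if (length(theta$blocks[[bi]]) > 1L)
        stop("ordered ", what, " indicator ", j,
             " requires a diagonal residual block", call. = FALSE)
      theta$free[bi] <- FALSE
      for (g in seq_len(theta$n_groups)) theta$values[[g]][j, j] <- 1
      links[[j]]$thresholds <- lk$thresholds - lk$thresholds[1]
    }
    list(links = links, theta = theta)
  }
  fy <- fix_ordered(spec$y_links, spec$l1$meas$theta, "y")
  spec$y_links <- fy$links; spec$l1$meas$theta <- fy$theta
  fz <- fix_ordered(spec$z_links, spec$l2$meas$theta, "z")
  spec$z_links <- fz$links; spec$l2$meas$theta <- fz$theta

  cl_rows <- split(seq_len(data$N), data$cluster)

  # fixed per-row prior scales: the coefficient prior variance is
  # H0 * scale(row), with the scale set once from the data (column
  # variances of the indicators / latent proxies), keeping the joint prior
  # coherent across the conjugate and Metropolis updates
  ys0 <- init_star(data$y, spec$y_links, y_miss)
  zs0 <- init_star(data$z, spec$z_links, z_miss)
  proxy1 <- latent_proxy(spec$l1, ys0)
  proxy2 <- latent_proxy(spec$l2, zs0)
  colvar <- function(m, floor = 0.1) {
    if (ncol(m) == 0L) return(numeric(0))
    pmax(apply(m, 2, var), floor)
  }
  ps <- list(l1_meas = colvar(ys0), l1_struct = colvar(proxy1),
             l2_meas = colvar(zs0), l2_struct = colvar(proxy2))

  # number of class-marginal increment moves (level-2 ordered block)
  n_delta <- 0L
  ob <- spec$ordered_block
  if (!is.null(ob) && ob$level == 2 && ob$block == "alpha") {
    al <- spec$l2$struct$alpha
    n_delta <- sum(al$row_vary & al$free[, 1]) * (al$n_groups - 1L)
  }

  list(spec = spec, K = K, N = data$N, ps = ps, n_delta = n_delta,
       ridge = build_ridge_moves(spec, proxy1),
       collapse = build_collapse_moves(spec),
       fscale = build_scale_moves(spec),
       cluster = data$cluster, cl_rows = cl_rows,
       n_k = as.integer(lengths(cl_rows)),
       y_miss = y_miss, z_miss = z_miss,
       any_y_miss = any(y_miss), any_z_miss = any(z_miss),
       y_ordered = which(vapply(spec$y_links, function(l)
         l$link == "ordered", TRUE)),
       z_ordered = which(vapply(spec$z_links, function(l)
         l$link == "ordered", TRUE)),
       # level-1 likelihood depends on d only through class-varying blocks
       l1_depends_d = any(vapply(
         list(spec$l1$meas$nu, spec$l1$meas$lambda, spec$l1$meas$kappa,
              spec$l1$struct$alpha, spec$l1$struct$B, spec$l1$struct$gamma),
         function(pb) pb$vary %in% c("d", "cd"), TRUE)) ||
         spec$l1$meas$theta$vary %in% c("d", "cd") ||
         spec$l1$struct$psi$vary %in% c("d", "cd"))
}

# Ridge recentering moves. A truncated-power (or polynomial) basis without
# an intercept can still represent near-constant functions over the data
# range, so the basis coefficients of a structural row and the row's
# intercept (or the cluster random intercept it maps to) form a weakly
# identified ridge that plain Gibbs traverses very slowly. For each
# (endogenous row, spline variable) pair we precompute the fixed coefficient
# direction w that best reproduces a constant over the observed predictor
# range, and the sampler adds a symmetric Metropolis move that shifts the
# basis coefficients by c*w while shifting the compensating intercept by
# -c. The direction is a fixed function of the data, so the move is a valid
# Metropolis kernel on the exact posterior.
build_ridge_moves <- function(spec, proxy1) {
  moves <- list()
  B <- spec$l1$struct$B
  Fs <- spec$l1$struct$F
  if (spec$m == 0L || B$vary != "none") return(moves)
  psi1 <- spec$l1$struct$psi
  blk_of <- function(cs, r) cs$blocks[[which(vapply(cs$blocks, function(b)
    r %in% b, TRUE))]]
  for (r in seq_len(spec$m)) {
    cols_free <- which(B$free[r, ])
    if (!length(cols_free)) next
    if (length(blk_of(psi1, r)) != 1L) next
    # partner intercept
    mapped <- spec$random[spec$random$block == "alpha" &
                            spec$random$row == r, ]
    if (nrow(mapped) == 1L) {
      u <- mapped$eta2
      refs_u <- function(fspec, pb) {
        if (fspec$out_dim == 0L) return(FALSE)
        act <- colSums(active_entries(pb)) > 0
        any(vapply(seq_len(fspec$out_dim), function(t)
          act[t] && u %in% term_vars(fspec$terms[[t]]), TRUE))
      }
      al2 <- spec$l2$struct$alpha
      ok <- !refs_u(spec$l2$meas$f, spec$l2$meas$lambda) &&
        !refs_u(spec$l2$struct$F, spec$l2$struct$B) &&
        al2$free[u, 1] && (al2$n_groups == 1L || !al2$row_vary[u]) &&
        length(blk_of(spec$l2$struct$psi, u)) == 1L
      partner <- if (ok) list(type = "eta2", u = u)
    } else {
      al1 <- spec$l1$struct$alpha
      partner <- if (al1$free[r, 1] && al1$vary == "none")
        list(type = "alpha", u = r)
    }
    if (is.null(partner)) next
    # group free columns by the single variable their term references
    tvars <- lapply(Fs$terms[cols_free], term_vars)
    singles <- lengths(tvars) == 1L
    for (v in unique(unlist(tvars[singles]))) {
      cols <- cols_free[singles & vapply(tvars, function(x)
        identical(x, v), TRUE)[singles]]
      nonlin <- any(vapply(Fs$terms[cols], function(t)
        t$kind != "linear", TRUE))
      if (length(cols) < 2L || !nonlin) next
      X <- eval_basis(Fs, proxy1)[, cols, drop = FALSE]
      w <- tryCatch(
        qr.solve(crossprod(X) + diag(1e-8, length(cols)), colSums(X)),
        error = function(e) NULL)
      if (is.null(w)) next
      moves[[length(moves) + 1L]] <- c(list(row = r, cols = cols, w = w),
                                       partner)
    }
  }
  moves
}

# Collapsed-outcome moves. When a cluster random effect eta2[u] has no own
# indicators and no downstream role (it is a pure outcome of the level-2
# structural model, fed by a level-1 intercept), the coefficients of its
# structural row can be drawn with eta2[u] integrated out: the per-cluster
# precision-weighted mean of the level-1 residuals is a Gaussian
# pseudo-observation of mu_u + B_u F2 + Gamma_u G2 with variance
# psi2_uu + psi1_rr / n_k. Collapsing removes the K-dimensional random
# effect from between the coefficients and the data, which is what makes
# the structural coefficients mix.
build_collapse_moves <- function(spec) {
  moves <- list()
  if (!nrow(spec$random)) return(moves)
  blk1 <- function(cs, r) length(cs$blocks[[which(vapply(cs$blocks,
    function(b) r %in% b, TRUE))]]) == 1L
  refs_u <- function(fspec, pb, u) {
    if (fspec$out_dim == 0L) return(FALSE)
    act <- colSums(active_entries(pb)) > 0
    any(vapply(seq_len(fspec$out_dim), function(t)
      act[t] && u %in% term_vars(fspec$terms[[t]]), TRUE))
  }
  al2 <- spec$l2$struct$alpha
  B2 <- spec$l2$struct$B
  ga2 <- spec$l2$struct$gamma
  for (i in which(spec$random$block == "alpha")) {
    r <- spec$random$row[i]
    u <- spec$random$eta2[i]
    ok <- blk1(spec$l1$struct$psi, r) && blk1(spec$l2$struct$psi, u) &&
      !refs_u(spec$l2$meas$f, spec$l2$meas$lambda, u) &&
      !refs_u(spec$l2$struct$F, spec$l2$struct$B, u) &&
      B2$vary == "none" &&
      (al2$n_groups == 1L || !al2$row_vary[u])
    if (!ok) next
    cols_B <- which(B2$free[u, ])
    cols_G <- which(ga2$free[u, ])
    moves[[length(moves) + 1L]] <- list(
      r = r, u = u, cols_B = cols_B, cols_G = cols_G,
      mu_free = al2$free[u, 1])
  }
  moves
}

# Factor scale moves. The scale split between a latent variable's variance,
# its free loadings, and the residual variances (lambda^2 psi + theta =
# observed variance) is identified only through the fixed scaling loading,
# and plain Gibbs walks that valley slowly. The scale move proposes
# phi = exp(eps): latent deviations (around the structural mean, which the
# move leaves invariant) scale by phi, the disturbance block row/column by
# phi, free loadings on the latent by 1/phi, and free indicator intercepts
# shift to keep their rows' fit exactly unchanged. The Jacobian of the
# deterministic map and the prior ratios enter the acceptance probability,
# so the move targets the exact posterior; the data resist only through
# the scaling indicator and through non-linear downstream terms.
build_scale_moves <- function(spec) {
  moves <- list()
  for (level in 1:2) {
    lvl <- if (level == 1) spec$l1 else spec$l2
    if (lvl$m == 0L || lvl$J == 0L) next
    psi <- lvl$struct$psi
    if (psi$vary != "none") next
    lam <- lvl$meas$lambda
    if (lam$vary != "none" || lvl$meas$nu$vary != "none") next
    for (v in seq_len(lvl$m)) {
      cols <- which(vapply(lvl$meas$f$terms, function(t)
        t$kind == "linear" && identical(t$var, v), TRUE))
      if (length(cols) != 1L) next
      col <- cols[1]
      lam_free_rows <- which(lam$free[, col])
      if (!length(lam_free_rows)) next
      bi <- which(vapply(psi$blocks, function(b) v %in% b, TRUE))
      if (!psi$free[bi]) next
      # free-loading rows must not also load on other latent columns
      # (the intercept compensation would no longer be exact)
      others <- active_entries(lam)[lam_free_rows, -col, drop = FALSE]
      if (any(others)) next
      nu_free_rows <- lam_free_rows[lvl$meas$nu$free[lam_free_rows, 1]]
      moves[[length(moves) + 1L]] <- list(
        level = level, v = v, col = col, blk = psi$blocks[[bi]],
        lam_rows = lam_free_rows, nu_rows = nu_free_rows)
    }
  }
  moves
}

# initial numeric ystar: observed values, ordered categories centered,
# missing cells at the column mean
init_star <- function(y, links, miss) {
  ys <- y
  for (j in seq_len(ncol(y))) {
    if (links[[j]]$link == "ordered") {
      tau <- links[[j]]$thresholds
      cuts <- c(tau[1] - 1, tau, tau[length(tau)] + 1)
      mids <- (cuts[-1] + cuts[-length(cuts)]) / 2
      ys[, j] <- mids[pmin(pmax(y[, j], 1), length(mids))]
    }
  }
  for (j in seq_len(ncol(ys))) {
    mj <- miss[, j]
    if (any(mj)) ys[mj, j] <- mean(ys[!mj, j])
  }
  ys
}

# data-driven proxy for each latent column: its scaling indicator when one
# exists, otherwise the mean of its active indicators, otherwise zero
latent_proxy <- function(lvl, ystar) {
  m <- lvl$m
  n <- nrow(ystar)
  out <- matrix(0, n, m)
  if (m == 0L || lvl$J == 0L) return(out)
  act <- active_entries(lvl$meas$lambda)
  for (v in seq_len(m)) {
    cols <- which(vapply(lvl$meas$f$terms, function(t)
      t$kind == "linear" && identical(t$var, v), TRUE))
    if (!length(cols)) next
    fixed <- integer(0)
    for (cc in cols)
      fixed <- c(fixed, which(!lvl$meas$lambda$free[, cc] &
                                pb_get(lvl$meas$lambda)[, cc] == 1))
    if (length(fixed)) {
      out[, v] <- ystar[, fixed[1]]
    } else {
      ind <- which(rowSums(act[, cols, drop = FALSE]) > 0)
      if (length(ind)) out[, v] <- rowMeans(ystar[, ind, drop = FALSE])
    }
  }
  out
}

# overdispersed chain start: free coefficients at rough moment-based values
# plus chain-specific jitter; free covariance blocks at scaled diagonals
init_state <- function(fit, priors, settings, chain) {
  spec <- fit$spec
  data <- fit$data
  jit <- function(n, s = 0.15) rnorm(n, 0, s)

  ystar <- init_star(data$y, spec$y_links, fit$y_miss)
  zstar <- init_star(data$z, spec$z_links, fit$z_miss)
  eta1 <- latent_proxy(spec$l1, ystar)
  eta2 <- latent_proxy(spec$l2, zstar)
  # random-coefficient positions start at the cluster mean of the mapped row
  if (nrow(spec$random)) {
    for (r in seq_len(nrow(spec$random))) {
      e <- spec$random[r, ]
      if (e$block == "alpha") {
        eta2[, e$eta2] <- as.numeric(
          tapply(eta1[, e$row], fit$cluster, mean))
      } else {
        eta2[, e$eta2] <- jit(fit$K, 0.2)
      }
    }
  }
  eta1 <- eta1 + matrix(jit(length(eta1), 0.1), nrow(eta1))
  if (length(eta2)) eta2 <- eta2 + matrix(jit(length(eta2), 0.1), nrow(eta2))

  C <- draw_class(spec$l1$mix, data$x1)
  D <- draw_class(spec$l2$mix, data$x2)

  init_level <- function(lvl, star, eta, n_units) {
    # measurement coefficients
    for (bn in c("nu", "lambda", "kappa")) {
      pb <- lvl$meas[[bn]]
      if (!any(pb$free)) next
      for (g in seq_len(pb$n_groups)) {
        v <- pb$values[[g]]
        idx <- which(pb$free, arr.ind = TRUE)
        for (r in seq_len(nrow(idx))) {
          i <- idx[r, 1]; j <- idx[r, 2]
          v[i, j] <- switch(bn,
            nu = mean(star[, i]) + jit(1, 0.3),
            lambda = 1 + jit(1, 0.2),
            kappa = jit(1, 0.2))
        }
        pb$values[[g]] <- v
      }
      lvl$meas[[bn]] <- sync_shared(pb)
    }
    # structural coefficients
    for (bn in c("alpha", "B", "gamma")) {
      pb <- lvl$struct[[bn]]
      if (!any(pb$free)) next
      for (g in seq_len(pb$n_groups)) {
        v <- pb$values[[g]]
        idx <- which(pb$free, arr.ind = TRUE)
        for (r in seq_len(nrow(idx))) {
          i <- idx[r, 1]; j <- idx[r, 2]
          v[i, j] <- if (bn == "alpha") mean(eta[, i]) + jit(1, 0.3)
          else jit(1, 0.1)
        }
        pb$values[[g]] <- v
      }
      lvl$struct[[bn]] <- sync_shared(pb)
    }
    # class-ordered intercept starts must be monotone: sort then separate
    # (done later for the designated block)
    # covariances: free blocks at half the proxy variance
    for (pn in c("theta", "psi")) {
      cs <- lvl$meas$theta
      cs <- lvl[[if (pn == "theta") "meas" else "struct"]][[pn]]
      src <- if (pn == "theta") star else eta
      if (!length(cs$blocks)) next
      for (g in seq_len(cs$n_groups)) {
        for (b in seq_along(cs$blocks)) {
          if (!cs$free[b]) next
          ids <- cs$blocks[[b]]
          vars <- pmax(apply(src[, ids, drop = FALSE], 2, var), 0.05)
          cs$values[[g]][ids, ids] <- diag(vars * runif(1, 0.4, 0.9),
                                           length(ids))
        }
      }
      lvl[[if (pn == "theta") "meas" else "struct"]][[pn]] <- cs
    }
    lvl
  }
  spec$l1 <- init_level(spec$l1, ystar, eta1, fit$N)
  if (spec$U > 0L) spec$l2 <- init_level(spec$l2, zstar, eta2, fit$K)

  # enforce monotone starting values on the ordered-increment block
  ob <- spec$ordered_block
  if (!is.null(ob)) {
    lvl <- if (ob$level == 1) "l1" else "l2"
    part <- if (ob$block == "alpha") "struct" else "meas"
    pb <- spec[[lvl]][[part]][[ob$block]]
    for (i in which(pb$row_vary & pb$free[, 1])) {
      vals <- sort(vapply(seq_len(pb$n_groups), function(g)
        pb$values[[g]][i, 1], 0))
      vals <- vals[1] + cumsum(c(0, pmax(diff(vals), 0.05)))
      for (g in seq_len(pb$n_groups)) pb$values[[g]][i, 1] <- vals[g]
    }
    spec[[lvl]][[part]][[ob$block]] <- pb
  }

  F1b <- eval_basis(spec$l1$struct$F, eta1)
  scale1 <- pmax(apply(eta1, 2, sd), 0.3)
  scale2 <- if (spec$U > 0L) pmax(apply(eta2, 2, sd), 0.3) else numeric(0)
  list(spec = spec, eta1 = eta1, eta2 = eta2, C = C, D = D,
       F1b = F1b, ystar = ystar, zstar = zstar,
       steps = list(eta1 = settings$step_eta1, eta2 = settings$step_eta2,
                    logit1 = settings$step_logit,
                    logit2 = settings$step_logit,
                    ridge = rep(0.5, length(fit$ridge)),
                    delta = rep(0.3, fit$n_delta),
                    fscale = rep(0.1, length(fit$fscale)),
                    scale1 = scale1, scale2 = scale2),
       acc = list(eta1 = c(0, 0), eta2 = c(0, 0), logit1 = c(0, 0),
                  logit2 = c(0, 0),
                  ridge = matrix(0, length(fit$ridge), 2),
                  delta = matrix(0, fit$n_delta, 2),
                  fscale = matrix(0, length(fit$fscale), 2)))
}

# keep tied rows equal across class groups
sync_shared <- function(pb) {
  if (pb$n_groups > 1L && any(!pb$row_vary)) {
    for (g in seq.int(2L, pb$n_groups))
      pb$values[[g]][!pb$row_vary, ] <-
        pb$values[[1L]][!pb$row_vary, , drop = FALSE]
  }
  pb
}
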