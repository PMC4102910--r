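#' Measurement model specification
#'
#' Declares how observed indicators measure the latent variables of one
#' level: \eqn{y^* = \nu + \Lambda f(\eta) + K g(x) + \epsilon},
#' \eqn{\epsilon \sim N(0, \Theta)}. Entries of \eqn{\nu}, \eqn{\Lambda},
#' and \eqn{K} are either free (sampled/estimated) or fixed at the supplied
#' value; fixed loadings of 1 are the usual scaling constraint.
#'
#' @param f function set mapping the latent vector to the loading columns.
#' @param lambda loading matrix (indicators x `f$out_dim`), or a list of such
#'   matrices when the block varies over mixture classes.
#' @param nu intercept vector (default all zero, free); or list per class.
#' @param theta residual covariance: a vector (diagonal), a matrix, or a list
#'   per class.
#' @param g optional function set over the covariates feeding `kappa`.
#' @param kappa covariate coefficient matrix (indicators x `g$out_dim`).
#' @param lambda_free,nu_free,kappa_free logical masks; `FALSE` entries are
#'   fixed at their supplied values. Defaults: all free except that a
#'   loading equal to 1 with all other loadings in its column equal to 0 is
#'   left free -- pass masks explicitly for scaling constraints.
#' @param theta_blocks partition of the indicators into residual covariance
#'   blocks (list of index vectors); default: all diagonal.
#' @param theta_free logical per block; fixed blocks are never updated.
#' @param vary named character vector, e.g. `c(nu = "d")`, stating which
#'   blocks vary over level-1 classes (`"c"`), level-2 classes (`"d"`), or
#'   both (`"cd"`).
#' @return an object of class `mlsem_measurement`.
#' @export
measurement_spec <- function(f, lambda, nu = NULL, theta, g = NULL,
                             kappa = NULL, lambda_free = NULL, nu_free = NULL,
                             kappa_free = NULL, theta_blocks = NULL,
                             theta_free = NULL, vary = NULL,
                             vary_rows = NULL) {
  J <- if (is.list(lambda) && !is.matrix(lambda)) nrow(lambda[[1]]) else
    nrow(as.matrix(lambda))
  if (is.null(nu)) nu <- rep(0, J)
  structure(list(f = f, g = g, lambda = lambda, nu = nu, kappa = kappa,
                 theta = theta, lambda_free = lambda_free, nu_free = nu_free,
                 kappa_free = kappa_free, theta_blocks = theta_blocks,
                 theta_free = theta_free, vary = vary,
                 vary_rows = vary_rows, n_ind = J),
            class = "mlsem_measurement")
}

#' Structural model specification
#'
#' Declares the relations among the latent variables of one level:
#' \eqn{\eta = \alpha + B F(\eta) + \Gamma G(x) + \zeta},
#' \eqn{\zeta \sim N(0, \Psi)}. A latent variable is endogenous when its row
#' of `B` contains an active (free or non-zero) entry; the system must be
#' recursive (no cycles through the terms of `F`).
#'
#' @param F function set over the latent vector feeding `B`.
#' @param B coefficient matrix (latents x `F$out_dim`), or list per class.
#' @param alpha intercept vector (latent means for exogenous rows); default
#'   zero, free.
#' @param psi disturbance covariance (vector for diagonal, matrix, or list).
#' @param G,gamma optional covariate function set and coefficients.
#' @param B_free,alpha_free,gamma_free logical masks (`FALSE` = fixed).
#' @param psi_blocks,psi_free covariance block partition and per-block free
#'   flags, as in [measurement_spec()].
#' @param vary named character vector of class-varying blocks.
#' @return an object of class `mlsem_structural`.
#' @export
structural_spec <- function(F, B, alpha = NULL, psi, G = NULL, gamma = NULL,
                            B_free = NULL, alpha_free = NULL,
                            gamma_free = NULL, psi_blocks = NULL,
                            psi_free = NULL, vary = NULL, vary_rows = NULL) {
  m <- if (is.list(B) && !is.matrix(B)) nrow(B[[1]]) else nrow(as.matrix(B))
  if (is.null(alpha)) alpha <- rep(0, m)
  structure(list(F = F, G = G, B = B, alpha = alpha, gamma = gamma,
                 psi = psi, B_free = B_free, alpha_free = alpha_free,
                 gamma_free = gamma_free, psi_blocks = psi_blocks,
                 psi_free = psi_free, vary = vary, vary_rows = vary_rows,
                 n_lat = m),
            class = "mlsem_structural")
}

#' Mixture (latent class) specification
#'
#' Multinomial-logit model for class membership:
#' \eqn{\Pr(class = t) \propto \exp(a_t + b_t' h(x))}. The first class is
#' the reference: its `a` and `b` are fixed at zero for identification.
#'
#' @param n_classes number of latent classes (>= 1).
#' @param h function set over the covariates (may be empty).
#' @param a logit intercepts (length `n_classes`; first entry forced to 0).
#' @param b logit slope matrix (`n_classes` x `h$out_dim`; first row forced
#'   to 0).
#' @return an object of class `mlsem_mixture`.
#' @export
mixture_spec <- function(n_classes, h = NULL, a = NULL, b = NULL) {
  n_classes <- as.integer(n_classes)
  if (n_classes < 1L) stop("n_classes must be >= 1", call. = FALSE)
  if (is.null(h)) h <- empty_function(0L)
  if (is.null(a)) a <- rep(0, n_classes)
  if (length(a) != n_classes) stop("length(a) != n_classes", call. = FALSE)
  if (is.null(b)) b <- matrix(0, n_classes, h$out_dim)
  b <- matrix(as.numeric(b), n_classes, h$out_dim)
  a[1] <- 0
  if (h$out_dim > 0) b[1, ] <- 0
  structure(list(n_classes = n_classes, h = h, a = as.numeric(a), b = b),
            class = "mlsem_mixture")
}

#' Indicator link specification
#'
#' Observation model for one indicator: `identity` (continuous normal),
#' `ordered` (ordinal via thresholds on an underlying normal variable), or
#' `poisson_log` (counts with log link; simulation only).
#'
#' @param link one of `"identity"`, `"ordered"`, `"poisson_log"`.
#' @param n_categories number of ordered categories (>= 2).
#' @param thresholds strictly increasing cut points of length
#'   `n_categories - 1`; the outer thresholds \eqn{-\infty, +\infty} are
#'   implicit. For estimation the first cut point is fixed at 0 and the
#'   indicator's residual variance at 1.
#' @return an object of class `mlsem_link`.
#' @export
indicator_spec <- function(link = c("identity", "ordered", "poisson_log"),
                           n_categories = NULL, thresholds = NULL) {
  link <- match.arg(link)
  if (link == "ordered") {
    if (is.null(n_categories) || n_categories < 2)
      stop("ordered link requires n_categories >= 2", call. = FALSE)
    n_categories <- as.integer(n_categories)
    if (is.null(thresholds)) thresholds <- seq(0, by = 1,
                                               length.out = n_categories - 1L)
    if (length(thresholds) != n_categories - 1L)
      stop("need n_categories - 1 thresholds", call. = FALSE)
    if (length(thresholds) > 1 && any(diff(thresholds) <= 0))
      stop("thresholds must be strictly increasing", call. = FALSE)
  } else if (!is.null(thresholds)) {
    stop(link, " link has no thresholds", call. = FALSE)
  }
  structure(list(link = link, n_categories = n_categories,
                 thresholds = as.numeric(thresholds)),
            class = "mlsem_link")
}

#' Random-coefficient map entry
#'
#' Promotes a level-1 structural parameter (an intercept `alpha[row]`, a
#' slope `B[row, col]`, or a covariate coefficient `gamma[row, col]`) to a
#' cluster-level latent variable: its value for cluster k is read from
#' position `eta2` of the level-2 latent vector instead of the fixed
#' parameter vector.
#'
#' @param block one of `"alpha"`, `"B"`, `"gamma"`.
#' @param row,col position within the level-1 structural block.
#' @param eta2 position in the level-2 latent vector holding the effect.
#' @return a one-row data frame.
#' @export
random_coef <- function(block = c("alpha", "B", "gamma"), row, col = 1L,
                        eta2) {
  block <- match.arg(block)
  data.frame(block = block, row = as.integer(row), col = as.integer(col),
             eta2 = as.integer(eta2), stringsAsFactors = FALSE)
}

#' Assemble a two-level non-linear SEM mixture model
#'
#' Combines measurement, structural, and mixture specifications for the
#' within (individual) and between (cluster) levels into one validated,
#' compiled model object. Level 2 may be omitted for single-level models.
#'
#' @param level1_measurement,level1_structural level-1 specification objects.
#' @param level1_mixture level-1 class model ([mixture_spec()]); default one
#'   class.
#' @param level2_measurement,level2_structural,level2_mixture level-2
#'   counterparts; all `NULL` for a single-level model.
#'   `level2_measurement` may be `NULL` while `level2_structural` is given
#'   (cluster latents without their own indicators, e.g. a lone random
#'   intercept).
#' @param random data frame of [random_coef()] rows (may be `NULL`).
#' @param y_links,z_links lists of [indicator_spec()] per indicator; default
#'   identity links.
#' @param ordered_block which class-varying intercept block carries the
#'   ordered-increment (anti label switching) constraint, as
#'   `list(level =, block =)` with block `"alpha"` (structural intercepts)
#'   or `"nu"` (measurement intercepts). Default: the first class-varying
#'   intercept block found, structural before measurement, level 2 before
#'   level 1.
#' @param names optional list of variable names: `eta1`, `eta2`, `y`, `z`,
#'   `x1`, `x2`.
#' @return an object of class `mlsem_spec`.
#' @export
model_spec <- function(level1_measurement, level1_structural,
                       level1_mixture = NULL,
                       level2_measurement = NULL, level2_structural = NULL,
                       level2_mixture = NULL,
                       random = NULL, y_links = NULL, z_links = NULL,
                       ordered_block = NULL, names = NULL) {
  if (is.null(level1_mixture)) level1_mixture <- mixture_spec(1L)
  if (is.null(level2_mixture)) level2_mixture <- mixture_spec(1L)
  Cstar <- level1_mixture$n_classes
  Dstar <- level2_mixture$n_classes

  l1 <- normalize_level(level1_measurement, level1_structural,
                        level1_mixture, Cstar = Cstar, Dstar = Dstar,
                        level = 1L)
  if (is.null(level2_structural)) {
    if (!is.null(level2_measurement))
      stop("level-2 measurement requires a level-2 structural model",
           call. = FALSE)
    if (Dstar > 1L)
      stop("a level-2 mixture requires a level-2 structural model",
           call. = FALSE)
    l2 <- empty_level()
  } else {
    if (is.null(level2_measurement)) {
      U <- level2_structural$n_lat
      level2_measurement <- measurement_spec(
        f = empty_function(U), lambda = matrix(0, 0, 0),
        nu = numeric(0), theta = matrix(0, 0, 0))
      level2_measurement$n_ind <- 0L
    }
    l2 <- normalize_level(level2_measurement, level2_structural,
                          level2_mixture, Cstar = 1L, Dstar = Dstar,
                          level = 2L)
  }

  if (is.null(random)) {
    random <- data.frame(block = character(0), row = integer(0),
                         col = integer(0), eta2 = integer(0))
  }
  spec <- structure(list(l1 = l1, l2 = l2, random = random,
                         Cstar = Cstar, Dstar = Dstar),
                    class = "mlsem_spec")
  spec$J <- l1$J; spec$m <- l1$m; spec$Q <- l1$Q
  spec$L <- l2$J; spec$U <- l2$m; spec$V <- l2$Q

  # random-coefficient map checks
  if (nrow(random)) {
    if (spec$U == 0L)
      stop("random coefficients require a level-2 structural model",
           call. = FALSE)
    if (anyDuplicated(random$eta2))
      stop("each level-2 position may absorb at most one random coefficient",
           call. = FALSE)
    for (r in seq_len(nrow(random))) {
      e <- random[r, ]
      if (e$eta2 < 1L || e$eta2 > spec$U)
        stop("random coefficient maps to eta2 position out of range",
             call. = FALSE)
      dims <- switch(e$block, alpha = c(spec$m, 1L),
                     B = dim(pb_get(spec$l1$struct$B)),
                     gamma = dim(pb_get(spec$l1$struct$gamma)))
      if (e$row > dims[1] || e$col > dims[2])
        stop("random coefficient position out of range", call. = FALSE)
      # mapped parameters leave the fixed-parameter vector
      pbname <- e$block
      spec$l1$struct[[pbname]]$free[e$row, e$col] <- FALSE
      for (g in seq_len(spec$l1$struct[[pbname]]$n_groups))
        spec$l1$struct[[pbname]]$values[[g]][e$row, e$col] <- 0
    }
  }

  # indicator links
  spec$y_links <- normalize_links(y_links, spec$J, "y")
  spec$z_links <- normalize_links(z_links, spec$L, "z")

  # variable names
  nm <- function(x, n, stem) {
    if (!is.null(x)) { stopifnot(length(x) == n); return(as.character(x)) }
    if (n == 0L) character(0) else paste0(stem, seq_len(n))
  }
  spec$names <- list(
    eta1 = nm(names$eta1, spec$m, "eta1_"),
    eta2 = nm(names$eta2, spec$U, "eta2_"),
    y = nm(names$y, spec$J, "y"), z = nm(names$z, spec$L, "z"),
    x1 = nm(names$x1, spec$Q, "x1_"), x2 = nm(names$x2, spec$V, "x2_"))

  spec <- compile_topology(spec)
  spec$ordered_block <- resolve_ordered_block(spec, ordered_block)
  spec$pmap <- build_pmap(spec)
  spec
}

# ---- internal: normalization -------------------------------------------

normalize_level <- function(meas, struct, mix, Cstar, Dstar, level) {
  stopifnot(inherits(meas, "mlsem_measurement"),
            inherits(struct, "mlsem_structural"),
            inherits(mix, "mlsem_mixture"))
  vary_of <- function(spec_vary, block) {
    v <- if (!is.null(spec_vary) && block %in% base::names(spec_vary))
      unname(spec_vary[[block]]) else "none"
    if (level == 2L && !v %in% c("none", "d"))
      stop("level-2 blocks can only vary over d", call. = FALSE)
    v
  }
  ng <- function(v) pb_ngroups(v, Cstar, Dstar)
  J <- meas$n_ind; m <- struct$n_lat
  f <- meas$f; g <- meas$g
  Fs <- struct$F; Gs <- struct$G
  if (f$arity != m || Fs$arity != m)
    stop("f and F must have arity equal to the number of latent variables",
         call. = FALSE)
  # covariate dimension: shared by g, G, h
  arities <- c(if (!is.null(g)) g$arity, if (!is.null(Gs)) Gs$arity,
               if (mix$h$out_dim > 0 || mix$h$arity > 0) mix$h$arity)
  Q <- if (length(arities)) {
    if (length(unique(arities)) > 1)
      stop("g, G, and h must share the covariate dimension", call. = FALSE)
    arities[1]
  } else 0L
  if (is.null(g)) g <- empty_function(Q)
  if (is.null(Gs)) Gs <- empty_function(Q)
  h <- if (mix$h$arity == 0L && Q > 0L) empty_function(Q) else mix$h

  vr <- function(spec_vary_rows, block) {
    if (!is.null(spec_vary_rows) && block %in% base::names(spec_vary_rows))
      spec_vary_rows[[block]] else NULL
  }
  mk <- function(x, free, v, nr, nc, rows = NULL) {
    pblock(x, free = free, vary = v, n_groups = ng(v), nrow = nr, ncol = nc,
           vary_rows = rows)
  }
  as_col <- function(x) {
    if (is.list(x) && !is.matrix(x)) lapply(x, function(e) cbind(as.numeric(e)))
    else cbind(as.numeric(x))
  }
  as_cov <- function(x) {
    one <- function(e) if (is.matrix(e)) e else diag(as.numeric(e),
                                                     length(e), length(e))
    if (is.list(x) && !is.matrix(x)) lapply(x, one) else one(x)
  }
  v_nu <- vary_of(meas$vary, "nu"); v_la <- vary_of(meas$vary, "lambda")
  v_ka <- vary_of(meas$vary, "kappa"); v_th <- vary_of(meas$vary, "theta")
  v_al <- vary_of(struct$vary, "alpha"); v_B <- vary_of(struct$vary, "B")
  v_ga <- vary_of(struct$vary, "gamma"); v_ps <- vary_of(struct$vary, "psi")

  kap <- if (is.null(meas$kappa)) matrix(0, J, g$out_dim) else meas$kappa
  gam <- if (is.null(struct$gamma)) matrix(0, m, Gs$out_dim) else struct$gamma
  kap_free <- if (is.null(meas$kappa) && is.null(meas$kappa_free))
    matrix(FALSE, J, g$out_dim) else meas$kappa_free
  gam_free <- if (is.null(struct$gamma) && is.null(struct$gamma_free))
    matrix(FALSE, m, Gs$out_dim) else struct$gamma_free

  out <- list(J = J, m = m, Q = Q)
  out$meas <- list(
    f = f, g = g,
    nu = mk(as_col(meas$nu), meas$nu_free, v_nu, J, 1L,
            vr(meas$vary_rows, "nu")),
    lambda = mk(meas$lambda, meas$lambda_free, v_la, J, f$out_dim,
                vr(meas$vary_rows, "lambda")),
    kappa = mk(kap, kap_free, v_ka, J, g$out_dim,
               vr(meas$vary_rows, "kappa")),
    theta = cov_spec(as_cov(meas$theta), blocks = meas$theta_blocks,
                     free = meas$theta_free, vary = v_th, n_groups = ng(v_th)))
  out$struct <- list(
    F = Fs, G = Gs,
    alpha = mk(as_col(struct$alpha), struct$alpha_free, v_al, m, 1L,
               vr(struct$vary_rows, "alpha")),
    B = mk(struct$B, struct$B_free, v_B, m, Fs$out_dim,
           vr(struct$vary_rows, "B")),
    gamma = mk(gam, gam_free, v_ga, m, Gs$out_dim,
               vr(struct$vary_rows, "gamma")),
    psi = cov_spec(as_cov(struct$psi), blocks = struct$psi_blocks,
                   free = struct$psi_free, vary = v_ps, n_groups = ng(v_ps)))
  if (out$meas$theta$dim != J) stop("theta dimension != indicator count",
                                    call. = FALSE)
  if (out$struct$psi$dim != m) stop("psi dimension != latent count",
                                    call. = FALSE)
  n_cl <- mix$n_classes
  a_free <- cbind(c(FALSE, rep(TRUE, n_cl - 1L)))
  b_free <- matrix(rep(c(FALSE, rep(TRUE, n_cl - 1L)), h$out_dim),
                   n_cl, h$out_dim)
  out$mix <- list(
    n_classes = n_cl, h = h,
    a = pblock(cbind(mix$a), free = a_free),
    b = pblock(matrix(mix$b, n_cl, h$out_dim), free = b_free))
  out
}

empty_level <- function() {
  list(J = 0L, m = 0L, Q = 0L,
       meas = list(f = empty_function(0L), g = empty_function(0L),
                   nu = pblock(matrix(0, 0, 1)),
                   lambda = pblock(matrix(0, 0, 0)),
                   kappa = pblock(matrix(0, 0, 0)),
                   theta = cov_spec(matrix(0, 0, 0), blocks = list())),
       struct = list(F = empty_function(0L), G = empty_function(0L),
                     alpha = pblock(matrix(0, 0, 1)),
                     B = pblock(matrix(0, 0, 0)),
                     gamma = pblock(matrix(0, 0, 0)),
                     psi = cov_spec(matrix(0, 0, 0), blocks = list())),
       mix = list(n_classes = 1L, h = empty_function(0L),
                  a = pblock(matrix(0, 1, 1), free = matrix(FALSE, 1, 1)),
                  b = pblock(matrix(0, 1, 0))))
}

normalize_links <- function(links, n, what) {
  if (is.null(links)) links <- replicate(n, indicator_spec("identity"),
                                         simplify = FALSE)
  if (inherits(links, "mlsem_link")) links <- rep(list(links), n)
  if (length(links) != n)
    stop("need one link specification per ", what, " indicator",
         call. = FALSE)
  stopifnot(all(vapply(links, inherits, TRUE, "mlsem_link")))
  links
}

# ---- internal: topology / recursivity ----------------------------------

# an entry of a pblock is "active" if free or non-zero in any class group
active_entries <- function(pb) {
  act <- pb$free
  for (g in seq_len(pb$n_groups)) act <- act | (pb$values[[g]] != 0)
  act
}

level_topology <- function(lvl, random = NULL, level = 1L) {
  m <- lvl$m
  if (m == 0L) return(list(endo = integer(0), exo = integer(0),
                           order = integer(0)))
  act <- active_entries(lvl$struct$B)
  if (!is.null(random) && level == 1L && nrow(random)) {
    rB <- random[random$block == "B", ]
    if (nrow(rB)) act[cbind(rB$row, rB$col)] <- TRUE
  }
  Fs <- lvl$struct$F
  dep <- matrix(FALSE, m, m)   # dep[v, w]: v depends on w
  for (t in seq_len(ncol(act))) {
    rows <- which(act[, t])
    if (!length(rows)) next
    for (w in term_vars(Fs$terms[[t]])) dep[rows, w] <- TRUE
  }
  endo <- which(rowSums(act) > 0)
  exo <- setdiff(seq_len(m), endo)
  # Kahn topological sort over endogenous variables
  order <- exo
  remaining <- endo
  depw <- dep
  depw[, ] <- dep
  while (length(remaining)) {
    ready <- remaining[vapply(remaining, function(v)
      !any(depw[v, remaining]), TRUE)]
    ready <- setdiff(ready, ready[depw[cbind(ready, ready)]])
    if (!length(ready))
      stop("structural system is not recursive: cycle among latent ",
           "variables ", paste(remaining, collapse = ", "), call. = FALSE)
    order <- c(order, ready)
    remaining <- setdiff(remaining, ready)
  }
  list(endo = endo, exo = exo, order = order)
}

compile_topology <- function(spec) {
  spec$l1$topo <- level_topology(spec$l1, spec$random, level = 1L)
  spec$l2$topo <- level_topology(spec$l2)
  spec$l1$linear <- fnspec_is_linear(spec$l1$struct$F) &&
    fnspec_is_linear(spec$l1$meas$f)
  spec$l2$linear <- fnspec_is_linear(spec$l2$struct$F) &&
    fnspec_is_linear(spec$l2$meas$f)
  # eta2 enters level 1 linearly only through intercept-type random effects
  spec$random_linear <- all(spec$random$block == "alpha")
  spec$l1$lin_coords <- cond_linear_coords(spec$l1)
  spec$l2$lin_coords <- cond_linear_coords(spec$l2)
  # the structural basis is unaffected by redrawing the conditionally
  # linear coordinates when no F-term references any of them
  basis_const <- function(lvl) {
    lin <- which(lvl$lin_coords)
    !any(vapply(lvl$struct$F$terms, function(t)
      any(term_vars(t) %in% lin), TRUE))
  }
  spec$l1$coord_basis_const <- basis_const(spec$l1)
  spec$l2$coord_basis_const <- basis_const(spec$l2)
  spec
}

# Which latent coordinates have exact Gaussian full conditionals: coordinate
# u qualifies when every active term referencing it is linear in it (a
# linear term, or a product with a different variable). Interaction models
# are conditionally linear in each coordinate; powers and splines are not.
cond_linear_coords <- function(lvl) {
  m <- lvl$m
  if (m == 0L) return(logical(0))
  ok <- rep(TRUE, m)
  chk <- function(fspec, pb) {
    if (fspec$out_dim == 0L) return()
    act <- colSums(active_entries(pb)) > 0
    for (t in seq_len(fspec$out_dim)) {
      if (!act[t]) next
      tm <- fspec$terms[[t]]
      if (tm$kind %in% c("power", "truncated_power"))
        ok[tm$var] <<- FALSE
    }
  }
  chk(lvl$meas$f, lvl$meas$lambda)
  chk(lvl$struct$F, lvl$struct$B)
  ok
}

resolve_ordered_block <- function(spec, ordered_block) {
  if (!is.null(ordered_block)) {
    stopifnot(ordered_block$level %in% c(1, 2),
              ordered_block$block %in% c("alpha", "nu"))
    lvl <- if (ordered_block$level == 1) spec$l1 else spec$l2
    part <- if (ordered_block$block == "alpha") lvl$struct else lvl$meas
    if (part[[ordered_block$block]]$vary == "none")
      stop("ordered_block must point at a class-varying intercept block",
           call. = FALSE)
    return(ordered_block)
  }
  cand <- list(list(level = 2, block = "alpha"), list(level = 2, block = "nu"),
               list(level = 1, block = "alpha"), list(level = 1, block = "nu"))
  for (cb in cand) {
    lvl <- if (cb$level == 1) spec$l1 else spec$l2
    part <- if (cb$block == "alpha") lvl$struct else lvl$meas
    if (part[[cb$block]]$vary != "none" && any(part[[cb$block]]$free))
      return(cb)
  }
  NULL
}

#' @export
print.mlsem_spec <- function(x, ...) {
  cat("<mlsem model>\n")
  cat(sprintf("  level 1: %d indicators, %d latent variables, %d covariates, %d class(es)\n",
              x$J, x$m, x$Q, x$Cstar))
  cat(sprintf("  level 2: %d indicators, %d latent variables, %d covariates, %d class(es)\n",
              x$L, x$U, x$V, x$Dstar))
  if (nrow(x$random))
    cat("  random coefficients:", nrow(x$random), "\n")
  cat("  free parameters:", nrow(x$pmap), "\n")
  invisible(x)
}
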