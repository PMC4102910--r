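#' Multinomial-logit class probabilities
#'
#' Softmax probabilities \eqn{\Pr(class=t) = \exp(a_t + b_t'h(x)) /
#' \sum_s \exp(a_s + b_s'h(x))}, computed with log-sum-exp stabilization.
#'
#' @param mix a [mixture_spec()] (or the corresponding component of a
#'   compiled model).
#' @param x covariate matrix (units x covariates) or a single vector.
#' @return matrix of probabilities, units x classes; rows sum to one.
#' @export
class_probs <- function(mix, x = NULL) {
  mm <- mix_matrices(mix)
  n_cl <- mm$n_classes
  if (is.null(x)) x <- matrix(0, 1, mm$h$arity)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  hb <- eval_basis(mm$h, x)
  lin <- matrix(mm$a, nrow(hb), n_cl, byrow = TRUE)
  if (ncol(hb) > 0) lin <- lin + hb %*% t(mm$b)
  mx <- apply(lin, 1, max)
  ex <- exp(lin - mx)
  ex / rowSums(ex)
}

mix_matrices <- function(mix) {
  if (inherits(mix, "mlsem_mixture")) {
    list(n_classes = mix$n_classes, h = mix$h, a = mix$a, b = mix$b)
  } else {
    list(n_classes = mix$n_classes, h = mix$h, a = pb_get(mix$a)[, 1],
         b = pb_get(mix$b))
  }
}

#' Draw latent class memberships
#'
#' @inheritParams class_probs
#' @return integer vector of class indices, one per row of `x`.
#' @export
draw_class <- function(mix, x = NULL) {
  p <- class_probs(mix, x)
  u <- runif(nrow(p))
  cp <- p
  if (ncol(p) > 1L) for (j in 2:ncol(p)) cp[, j] <- cp[, j - 1L] + p[, j]
  as.integer(1L + rowSums(u > cp))
}

#' Cluster size plan
#'
#' Either a fixed common size or an explicit vector of cluster sizes.
#'
#' @param n fixed size for every cluster.
#' @param sizes integer vector of per-cluster sizes (overrides `n`).
#' @return an object of class `mlsem_size_plan`.
#' @export
cluster_size_plan <- function(n = NULL, sizes = NULL) {
  if (is.null(sizes)) {
    stopifnot(!is.null(n), n >= 1)
    plan <- list(type = "fixed", n = as.integer(n))
  } else {
    sizes <- as.integer(sizes)
    if (any(sizes < 1L)) stop("all cluster sizes must be >= 1", call. = FALSE)
    plan <- list(type = "sizes", sizes = sizes)
  }
  structure(plan, class = "mlsem_size_plan")
}

plan_sizes <- function(plan, K) {
  if (plan$type == "fixed") return(rep(plan$n, K))
  if (length(plan$sizes) != K)
    stop("size plan lists ", length(plan$sizes), " clusters, need ", K,
         call. = FALSE)
  plan$sizes
}

# apply an indicator link to latent responses (columns of ystar)
apply_links <- function(ystar, links) {
  y <- ystar
  for (j in seq_along(links)) {
    lk <- links[[j]]
    if (lk$link == "identity") next
    if (lk$link == "ordered") {
      cuts <- c(-Inf, lk$thresholds, Inf)
      y[, j] <- as.numeric(cut(ystar[, j], cuts, labels = FALSE))
    } else if (lk$link == "poisson_log") {
      y[, j] <- rpois(nrow(ystar), exp(pmin(ystar[, j], 30)))
    }
  }
  y
}

# vectorized level-2 generation for given classes D and covariates x2
sim_level2 <- function(spec, D, x2) {
  K <- length(D)
  ones <- rep(1L, K)
  zeta2 <- draw_disturbance(spec$l2$struct$psi, ones, D, 1L, K)
  eta2 <- solve_structural(spec$l2, zeta2, x2, ones, D, 1L)
  zstar <- meas_mean(spec$l2, eta2, x2, ones, D, 1L)
  if (spec$L > 0L) {
    eps <- draw_disturbance(spec$l2$meas$theta, ones, D, 1L, K)
    zstar <- zstar + eps
  }
  list(eta2 = eta2, zstar = zstar, z = apply_links(zstar, spec$z_links))
}

# vectorized level-1 generation
sim_level1 <- function(spec, C, Dexp, eta2exp, x1) {
  n <- length(C)
  rand <- rand_entries(spec, eta2exp)
  zeta1 <- draw_disturbance(spec$l1$struct$psi, C, Dexp, spec$Cstar, n)
  eta1 <- solve_structural(spec$l1, zeta1, x1, C, Dexp, spec$Cstar, rand)
  ystar <- meas_mean(spec$l1, eta1, x1, C, Dexp, spec$Cstar) +
    draw_disturbance(spec$l1$meas$theta, C, Dexp, spec$Cstar, n)
  list(eta1 = eta1, ystar = ystar, y = apply_links(ystar, spec$y_links))
}

#' Generate one cluster-level realization
#'
#' Draws the level-2 latent vector for one cluster of class `d`: exogenous
#' entries from their class-d Gaussian, endogenous entries recursively from
#' the structural model, then the cluster indicators through the
#' measurement model and link functions.
#'
#' @param spec an `mlsem_spec`.
#' @param d level-2 class index.
#' @param x2 covariate vector for the cluster.
#' @return list with `eta2`, `zstar`, `z`.
#' @export
draw_level2 <- function(spec, d, x2 = NULL) {
  if (is.null(x2)) x2 <- numeric(spec$V)
  out <- sim_level2(spec, as.integer(d), matrix(x2, 1))
  lapply(out, drop)
}

#' Generate one individual-level realization
#'
#' @param spec an `mlsem_spec`.
#' @param c level-1 class index.
#' @param d level-2 class index of the individual's cluster.
#' @param eta2 the cluster's latent vector (supplies random coefficients).
#' @param x1 covariate vector for the individual.
#' @return list with `eta1`, `ystar`, `y`.
#' @export
draw_level1 <- function(spec, c, d, eta2 = NULL, x1 = NULL) {
  if (is.null(eta2)) eta2 <- numeric(spec$U)
  if (is.null(x1)) x1 <- numeric(spec$Q)
  out <- sim_level1(spec, as.integer(c), as.integer(d),
                    matrix(eta2, 1), matrix(x1, 1))
  lapply(out, drop)
}

#' Simulate a complete clustered dataset from a model
#'
#' Follows the generative order of the model: level-2 class, level-2
#' latents and indicators, then per individual the level-1 class, latents,
#' and indicators. One master seed spawns an independent substream per
#' cluster, so increasing `K` extends the data without reshuffling existing
#' clusters.
#'
#' @param spec an `mlsem_spec`.
#' @param K number of clusters.
#' @param plan a [cluster_size_plan()].
#' @param x1_gen,x2_gen covariate generators `function(n, p)` returning an
#'   `n x p` matrix; default standard normal.
#' @param seed integer master seed.
#' @return an object of class `mlsem_data`: matrices `y`, `z`, `x1`, `x2`,
#'   integer `cluster` ids, logical missingness masks `y_miss`/`z_miss`,
#'   and a `truth` record (`C`, `D`, `eta1`, `eta2`, `ystar`, `zstar`).
#' @export
simulate_dataset <- function(spec, K, plan, x1_gen = NULL, x2_gen = NULL,
                             seed = 1L) {
  stopifnot(inherits(spec, "mlsem_spec"))
  K <- as.integer(K)
  if (K < 1L) stop("K must be >= 1", call. = FALSE)
  if (is.null(x1_gen)) x1_gen <- function(n, p) matrix(rnorm(n * p), n, p)
  if (is.null(x2_gen)) x2_gen <- function(n, p) matrix(rnorm(n * p), n, p)
  sizes <- plan_sizes(plan, K)

  y <- matrix(NA_real_, sum(sizes), spec$J)
  x1 <- matrix(NA_real_, sum(sizes), spec$Q)
  eta1 <- matrix(NA_real_, sum(sizes), spec$m)
  ystar <- y
  C <- integer(sum(sizes))
  z <- matrix(NA_real_, K, spec$L)
  zstar <- z
  x2 <- matrix(NA_real_, K, spec$V)
  eta2 <- matrix(NA_real_, K, spec$U)
  D <- integer(K)
  cluster <- rep.int(seq_len(K), sizes)

  offset <- c(0L, cumsum(sizes))
  for (k in seq_len(K)) {
    set.seed(cluster_seed(seed, k))
    x2[k, ] <- x2_gen(1L, spec$V)
    D[k] <- draw_class(spec$l2$mix, x2[k, , drop = FALSE])
    l2 <- sim_level2(spec, D[k], x2[k, , drop = FALSE])
    eta2[k, ] <- l2$eta2
    zstar[k, ] <- l2$zstar
    z[k, ] <- l2$z
    rows <- (offset[k] + 1L):offset[k + 1L]
    nk <- sizes[k]
    x1[rows, ] <- x1_gen(nk, spec$Q)
    C[rows] <- draw_class(spec$l1$mix, x1[rows, , drop = FALSE])
    l1 <- sim_level1(spec, C[rows], rep(D[k], nk),
                     eta2[k, , drop = FALSE][rep(1L, nk), , drop = FALSE],
                     x1[rows, , drop = FALSE])
    eta1[rows, ] <- l1$eta1
    ystar[rows, ] <- l1$ystar
    y[rows, ] <- l1$y
  }
  setcn <- function(m, nm) { if (ncol(m) > 0) colnames(m) <- nm; m }
  y <- setcn(y, spec$names$y); x1 <- setcn(x1, spec$names$x1)
  z <- setcn(z, spec$names$z); x2 <- setcn(x2, spec$names$x2)
  structure(list(
    y = y, z = z, x1 = x1, x2 = x2, cluster = cluster,
    y_miss = matrix(FALSE, nrow(y), ncol(y)),
    z_miss = matrix(FALSE, nrow(z), ncol(z)),
    truth = list(C = C, D = D, eta1 = eta1, eta2 = eta2,
                 ystar = ystar, zstar = zstar),
    K = K, N = sum(sizes), seed = seed), class = "mlsem_data")
}

# deterministic per-cluster substream seed, kept below 2^31
cluster_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k * 16807) %% 2147483647)
}

#' @export
print.mlsem_data <- function(x, ...) {
  cat(sprintf("<mlsem data> %d individuals in %d clusters; %d y, %d z indicators\n",
              x$N, x$K, ncol(x$y), ncol(x$z)))
  nmiss <- sum(x$y_miss) + sum(x$z_miss)
  if (nmiss) cat("  missing cells:", nmiss, "\n")
  invisible(x)
}

#' Impose missing-at-random masking
#'
#' Masks individual-level indicator cells with a probability that depends
#' only on a fully observed covariate through a logistic model, preserving
#' the missing-at-random property. The marginal masking probability is
#' calibrated to `rate`. Already-masked cells stay masked.
#'
#' @param data an `mlsem_data`.
#' @param rate target marginal missingness proportion in `[0, 1)`.
#' @param predictor name (or index) of the `x1` column driving missingness;
#'   `NULL` gives covariate-independent masking.
#' @param slope logistic slope on the standardized predictor.
#' @param seed integer seed.
#' @return the dataset with an updated `y_miss` mask; masked `y` cells are
#'   set to `NA`.
#' @export
apply_mar_mask <- function(data, rate, predictor = NULL, slope = 1,
                           seed = 1L) {
  stopifnot(inherits(data, "mlsem_data"), rate >= 0, rate < 1)
  if (rate == 0) return(data)
  set.seed(as.integer(seed))
  n <- nrow(data$y); J <- ncol(data$y)
  if (is.null(predictor) || ncol(data$x1) == 0L) {
    lin <- rep(0, n)
  } else {
    v <- data$x1[, predictor]
    s <- sd(v)
    lin <- slope * (v - mean(v)) / (if (s > 0) s else 1)
  }
  # calibrate the intercept so the marginal rate matches `rate`
  f <- function(b0) mean(plogis(b0 + lin)) - rate
  b0 <- uniroot(f, c(-30, 30))$root
  p <- plogis(b0 + lin)
  mask <- matrix(runif(n * J) < p, n, J)
  data$y_miss <- data$y_miss | mask
  data$y[data$y_miss] <- NA_real_
  data
}
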