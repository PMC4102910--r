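#' Estimated potential scale reduction (EPSR)
#'
#' Classic multi-chain Gelman-Rubin statistic: with within-chain variance W
#' and between-chain variance B over n retained iterations,
#' \eqn{EPSR = \sqrt{((n-1)/n \cdot W + B/n) / W}}. Convergence is commonly
#' declared when all values fall below 1.2.
#'
#' @param draws an `mlsem_draws` object, or a list of chain matrices with
#'   identical column names.
#' @return named numeric vector of EPSR values, one per parameter.
#' @export
epsr <- function(draws) {
  chains <- if (inherits(draws, "mlsem_draws")) draws$draws else draws
  if (length(chains) < 2L)
    stop("EPSR needs at least 2 chains; rerun with chains >= 2",
         call. = FALSE)
  n <- nrow(chains[[1]])
  if (n < 10L) stop("EPSR needs at least 10 retained iterations",
                    call. = FALSE)
  means <- vapply(chains, colMeans, numeric(ncol(chains[[1]])))
  vars <- vapply(chains, function(ch) apply(ch, 2, var),
                 numeric(ncol(chains[[1]])))
  if (is.null(dim(means))) {
    means <- matrix(means, nrow = 1)
    vars <- matrix(vars, nrow = 1)
  }
  W <- rowMeans(vars)
  B <- n * apply(means, 1, var)
  out <- sqrt(((n - 1) / n * W + B / n) / W)
  out[B == 0] <- 1   # byte-identical chains (incl. zero-variance draws)
  names(out) <- colnames(chains[[1]])
  out
}

#' Posterior summary table
#'
#' Pools retained draws across chains and reports, per parameter, the
#' posterior mean, SE (posterior standard deviation), t-value (mean/SD),
#' and the 2.5, 50, and 97.5 percent percentiles (linear interpolation).
#'
#' @param draws an `mlsem_draws` or list of chain matrices.
#' @return a data frame of class `mlsem_summary` with columns `parameter`,
#'   `mean`, `se`, `t`, `q2.5`, `q50`, `q97.5`.
#' @export
posterior_summary <- function(draws) {
  chains <- if (inherits(draws, "mlsem_draws")) draws$draws else draws
  pooled <- do.call(rbind, chains)
  if (!nrow(pooled)) stop("no retained draws", call. = FALSE)
  mn <- colMeans(pooled)
  se <- apply(pooled, 2, sd)
  tv <- ifelse(se > 0, mn / se, sign(mn) * Inf)
  qs <- t(apply(pooled, 2, quantile, probs = c(0.025, 0.5, 0.975),
                names = FALSE))
  out <- data.frame(parameter = colnames(pooled), mean = mn, se = se,
                    t = tv, q2.5 = qs[, 1], q50 = qs[, 2], q97.5 = qs[, 3],
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("mlsem_summary", "data.frame")
  out
}

#' @export
summary.mlsem_draws <- function(object, ...) posterior_summary(object)

#' @export
print.mlsem_summary <- function(x, digits = 3, ...) {
  y <- x
  num <- vapply(y, is.numeric, TRUE)
  y[num] <- lapply(y[num], round, digits = digits)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}

# Monte Carlo standard error of a posterior mean by batch means
mcse <- function(x) {
  n <- length(x)
  nb <- max(2L, floor(sqrt(n)))
  bs <- floor(n / nb)
  bm <- vapply(seq_len(nb), function(b)
    mean(x[((b - 1L) * bs + 1L):(b * bs)]), 0)
  sd(bm) / sqrt(nb)
}

#' Deviance information criterion
#'
#' DIC = D-bar + pD with pD = D-bar - D(theta-bar), where the deviance
#' D = -2 log L uses the likelihood marginal over the latent classes
#' (log-sum-exp over both levels' class variables) but conditional on the
#' posterior draws of the continuous latent variables (evaluated at their
#' posterior means for D(theta-bar)). This conditional-on-latents,
#' marginal-over-classes variant is recorded in the result.
#'
#' @param draws an `mlsem_draws` from [run_gibbs()].
#' @param spec the model (defaults to the one stored in `draws`).
#' @param data the fitted dataset.
#' @return list with `dic`, `pD`, `D_bar`, `D_hat`, `variant`.
#' @export
dic <- function(draws, spec = draws$spec, data) {
  stopifnot(inherits(draws, "mlsem_draws"))
  fit <- prep_fit(spec, data)
  fit$data <- data
  spec <- fit$spec
  D_bar <- mean(unlist(draws$deviance), na.rm = TRUE)
  theta_bar <- colMeans(do.call(rbind, draws$draws))
  spec_hat <- unpack_params(spec, theta_bar[spec$pmap$name])
  lm <- draws$latent_means
  D_hat <- complete_deviance(spec_hat, fit, lm$eta1, lm$eta2, lm$ystar,
                             lm$zstar)
  pD <- D_bar - D_hat
  list(dic = D_bar + pD, pD = pD, D_bar = D_bar, D_hat = D_hat,
       variant = "class-marginal, conditional on continuous latents")
}

#' Post-hoc relabeling of mixture classes
#'
#' Reorders the class labels of each retained draw by an ordering rule:
#' increasing class means of the ordered intercept block (`"means"`) or
#' decreasing class proportions (`"proportions"`). When the sampler's
#' ordered-increment constraint was active the relabeling is the identity.
#' Ties break deterministically by class index.
#'
#' @param draws an `mlsem_draws`.
#' @param rule ordering rule.
#' @param level which level's classes to relabel (2 = cluster level).
#' @return the draws with relabeled class-specific columns.
#' @export
relabel <- function(draws, rule = c("means", "proportions"), level = 2) {
  rule <- match.arg(rule)
  spec <- draws$spec
  G <- if (level == 2) spec$Dstar else spec$Cstar
  if (G < 2L) return(draws)
  sfx <- if (level == 2) "d" else "c"
  pat <- paste0("\\.", sfx, "([0-9]+)$")
  pn <- draws$parameters
  classed <- grepl(pat, pn)
  base <- sub(pat, "", pn)
  cls <- integer(length(pn))
  cls[classed] <- as.integer(sub(paste0("^.*\\.", sfx), "", pn[classed]))
  # columns of the ordering key
  if (rule == "means") {
    ob <- spec$ordered_block
    if (is.null(ob)) stop("no ordered intercept block to order by",
                          call. = FALSE)
    lbl <- if (ob$level == 2 && ob$block == "alpha") "L2.mu"
    else paste0("L", ob$level, ".", ob$block)
    key_base <- unique(base[classed & startsWith(pn, lbl)])
  } else {
    key_base <- paste0(if (level == 2) "mixD" else "mixC", ".a")
  }
  mixlab <- paste0(if (level == 2) "mixD" else "mixC", ".")
  for (ch in seq_along(draws$draws)) {
    X <- draws$draws[[ch]]
    for (it in seq_len(nrow(X))) {
      key <- numeric(G)
      if (rule == "means") {
        for (g in seq_len(G)) {
          cols <- pn[classed & cls == g & base %in% key_base]
          key[g] <- mean(X[it, cols])
        }
        ord <- order(key, seq_len(G))
      } else {
        a <- c(0, X[it, pn[classed & base == key_base]])
        key <- exp(a - max(a)); key <- key / sum(key)
        ord <- order(-key, seq_len(G))
      }
      if (all(ord == seq_len(G))) next
      # permute class-specific structural/measurement parameters
      for (bb in unique(base[classed & !startsWith(base, mixlab)])) {
        cols <- vapply(seq_len(G), function(g)
          which(pn == paste0(bb, ".", sfx, g)), 0L)
        X[it, cols] <- X[it, cols[ord]]
      }
      # logit intercepts/slopes: re-reference after permutation
      acols <- pn[classed & base == paste0(mixlab, "a")]
      if (length(acols)) {
        a <- c(0, X[it, acols])
        a <- a[ord] - a[ord][1]
        X[it, acols] <- a[-1]
      }
    }
    draws$draws[[ch]] <- X
  }
  draws
}

#' Convergence and fit report
#'
#' @param draws an `mlsem_draws`.
#' @param data optionally, the fitted dataset (enables the DIC).
#' @param threshold EPSR convergence threshold.
#' @return list of class `mlsem_diag`: per-parameter EPSR, the maximum,
#'   a convergence flag, Metropolis acceptance summaries, and (with data)
#'   the DIC decomposition.
#' @export
diagnostics_report <- function(draws, data = NULL, threshold = 1.2) {
  e <- epsr(draws)
  out <- list(epsr = e, max_epsr = max(e), threshold = threshold,
              converged = all(e < threshold),
              accept = draws$accept)
  if (!is.null(data)) out$dic <- dic(draws, data = data)
  class(out) <- "mlsem_diag"
  out
}

#' Trace plots of retained draws
#'
#' One panel per parameter, chains overlaid, written to a PNG file (or the
#' active device when `file` is `NULL`).
#'
#' @param draws an `mlsem_draws`.
#' @param pars parameters to plot (default: the six with the highest EPSR).
#' @param file optional PNG path.
#' @return invisibly, the plotted parameter names.
#' @export
trace_plot <- function(draws, pars = NULL, file = NULL) {
  chains <- draws$draws
  if (is.null(pars)) {
    pars <- if (length(chains) >= 2) {
      names(sort(epsr(draws), decreasing = TRUE))[
        seq_len(min(6, length(draws$parameters)))]
    } else utils::head(draws$parameters, 6)
  }
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 180 * length(pars))
    on.exit(grDevices::dev.off())
  }
  op <- graphics::par(mfrow = c(length(pars), 1),
                      mar = c(2, 4, 1.5, 0.5))
  on.exit(graphics::par(op), add = TRUE)
  for (p in pars) {
    rng <- range(vapply(chains, function(X) range(X[, p]),
                        numeric(2)))
    graphics::plot(chains[[1]][, p], type = "l", ylim = rng, ylab = p,
                   xlab = "", col = 1)
    if (length(chains) > 1) {
      for (ch in 2:length(chains))
        graphics::lines(chains[[ch]][, p], col = ch)
    }
  }
  invisible(pars)
}

#' @export
print.mlsem_diag <- function(x, ...) {
  cat(sprintf("max EPSR: %.3f (threshold %.2f) -> converged: %s\n",
              x$max_epsr, x$threshold, x$converged))
  if (!is.null(x$dic))
    cat(sprintf("DIC: %.1f (pD = %.1f)\n", x$dic$dic, x$dic$pD))
  invisible(x)
}
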