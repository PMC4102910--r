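#' Prior specification for the Gibbs sampler
#'
#' Conjugate prior system: coefficient entries get normal priors whose
#' variance is the row's residual variance times `H0` (so the prior scales
#' with the data, and the conditional posterior stays normal); precision
#' blocks get Wishart priors (for 1x1 blocks the Wishart reduces to the
#' usual inverse-gamma option on a variance); multinomial-logit coefficients
#' get independent normals; ordered class increments get half-normal priors
#' on the positive half-line.
#'
#' @param H0 prior variance multiplier for coefficient blocks (larger =
#'   weaker).
#' @param H0_delta prior variance multiplier for the half-normal ordered
#'   class increments. Class separations are measured on the scale of the
#'   residual standard deviation, so a multiplier near 1 is weakly
#'   informative while still discouraging the unbounded class-mean
#'   excursions that occur when a mixture class empties.
#' @param coef_mean common prior mean for free coefficients.
#' @param loading_mean prior mean for free factor loadings (centered at 1,
#'   the scaling value).
#' @param wishart_df_add Wishart degrees of freedom are block dimension plus
#'   this (must keep df >= dimension).
#' @param wishart_scale the prior scale matrix is `wishart_scale` times the
#'   identity.
#' @param logit_sd prior standard deviation for mixture-logit coefficients.
#' @return an object of class `mlsem_priors`.
#' @export
prior_spec <- function(H0 = 10, H0_delta = 1, coef_mean = 0,
                       loading_mean = 1, wishart_df_add = 2,
                       wishart_scale = 0.5, logit_sd = 2.5) {
  stopifnot(H0 > 0, H0_delta > 0, wishart_df_add >= 0, wishart_scale > 0,
            logit_sd > 0)
  structure(list(H0 = H0, H0_delta = H0_delta, coef_mean = coef_mean,
                 loading_mean = loading_mean,
                 wishart_df_add = wishart_df_add,
                 wishart_scale = wishart_scale, logit_sd = logit_sd),
            class = "mlsem_priors")
}

#' @rdname prior_spec
#' @param spec an `mlsem_spec` (reserved for model-dependent defaults).
#' @export
default_priors <- function(spec = NULL) prior_spec()

#' Sampler settings
#'
#' @param chains number of independent chains.
#' @param iterations total iterations per chain.
#' @param burn_in iterations discarded (and used for step-size adaptation).
#' @param thin keep every `thin`-th post-burn-in draw.
#' @param seed master seed; chain c uses a seed derived from it.
#' @param adapt_every adaptation interval (iterations) during burn-in.
#' @param target_accept Metropolis target acceptance rate for the
#'   random-walk blocks (adapted toward during burn-in only, preserving
#'   detailed balance afterwards).
#' @param step_eta1,step_eta2,step_logit initial random-walk step sizes.
#' @param deviance_every evaluate the complete-data deviance on every
#'   `deviance_every`-th retained draw (thinning the deviance trace keeps
#'   long runs cheap without biasing the DIC).
#' @return an object of class `mlsem_settings`.
#' @export
sampler_settings <- function(chains = 3, iterations = 2000,
                             burn_in = floor(iterations / 2), thin = 1,
                             seed = 1L, adapt_every = 25,
                             target_accept = 0.3, step_eta1 = 0.4,
                             step_eta2 = 0.4, step_logit = 0.5,
                             deviance_every = 1L) {
  stopifnot(chains >= 1, burn_in < iterations, thin >= 1,
            target_accept > 0, target_accept < 1, deviance_every >= 1)
  structure(list(chains = as.integer(chains),
                 iterations = as.integer(iterations),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 seed = as.integer(seed), adapt_every = as.integer(adapt_every),
                 target_accept = target_accept, step_eta1 = step_eta1,
                 step_eta2 = step_eta2, step_logit = step_logit,
                 deviance_every = as.integer(deviance_every)),
            class = "mlsem_settings")
}
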