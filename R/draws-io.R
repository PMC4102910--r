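#' Write a draw archive
#'
#' Long-format CSV with columns `chain`, `iteration`, `parameter`, `value`.
#' The deviance trace is stored under the pseudo-parameter `.deviance`;
#' sampler settings and acceptance rates go to a YAML sidecar next to the
#' CSV (same path with extension `.meta.yaml`).
#'
#' @param draws an `mlsem_draws`.
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_draws <- function(draws, path) {
  stopifnot(inherits(draws, "mlsem_draws"))
  rows <- lapply(seq_along(draws$draws), function(ch) {
    X <- draws$draws[[ch]]
    n <- nrow(X)
    data.frame(chain = ch, iteration = rep(seq_len(n), ncol(X) + 1L),
               parameter = rep(c(colnames(X), ".deviance"), each = n),
               value = c(as.numeric(X), draws$deviance[[ch]]))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  meta <- list(parameters = draws$parameters,
               chains = length(draws$draws),
               settings = unclass(draws$settings),
               accept = lapply(draws$accept, function(a) lapply(a, unname)),
               data_dims = draws$data_dims)
  yaml::write_yaml(meta, paste0(path, ".meta.yaml"), precision = 12L)
  invisible(path)
}

#' Read a draw archive
#'
#' Inverse of [write_draws()]. The result supports [epsr()],
#' [posterior_summary()], and [relabel()]; the model-dependent pieces
#' (latent means for [dic()]) are not part of the archive.
#'
#' @param path CSV path written by [write_draws()].
#' @return an `mlsem_draws` (without `spec`/`latent_means`).
#' @export
read_draws <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  meta_path <- paste0(path, ".meta.yaml")
  meta <- if (file.exists(meta_path)) yaml::read_yaml(meta_path) else NULL
  chains <- sort(unique(df$chain))
  pnames <- if (!is.null(meta)) unlist(meta$parameters)
  else setdiff(unique(df$parameter), ".deviance")
  draws <- lapply(chains, function(ch) {
    sub <- df[df$chain == ch & df$parameter != ".deviance", ]
    n <- max(sub$iteration)
    X <- matrix(NA_real_, n, length(pnames), dimnames = list(NULL, pnames))
    X[cbind(sub$iteration, match(sub$parameter, pnames))] <- sub$value
    X
  })
  devs <- lapply(chains, function(ch) {
    sub <- df[df$chain == ch & df$parameter == ".deviance", ]
    sub$value[order(sub$iteration)]
  })
  structure(list(draws = draws, deviance = devs, parameters = pnames,
                 accept = meta$accept, settings = meta$settings,
                 spec = NULL, latent_means = NULL,
                 data_dims = meta$data_dims), class = "mlsem_draws")
}
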