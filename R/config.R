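#' Read a model configuration file
#'
#' Builds an [model_spec()] from a YAML document. The layout mirrors the
#' constructor arguments; function sets are written as term strings over
#' the declared variable names (`"Att"`, `"Att^2"`, `"Prob*Soc"`,
#' `"spline(Att, knots=[2,3], degree=3)"`). Matrices are written as lists
#' of rows; class-varying blocks list one value set per class under
#' `values` with a `vary` flag. See the file emitted by
#' [write_model_config()] for a complete example.
#'
#' @param path YAML file path.
#' @return an `mlsem_spec`.
#' @export
read_model_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  nms <- lapply(cfg$names, function(x) as.character(unlist(x)))
  for (f in c("eta1", "eta2", "y", "z", "x1", "x2"))
    if (is.null(nms[[f]])) nms[[f]] <- character(0)
  as_mat <- function(x, nr = NULL, nc = NULL) {
    if (is.null(x)) return(NULL)
    m <- if (is.list(x)) do.call(rbind, lapply(x, as.numeric))
    else matrix(as.numeric(x), ncol = 1)
    if (!is.null(nr) && nrow(m) == 1L && nr > 1L && ncol(m) == nr)
      m <- t(m)  # a single flat vector for a column block
    m
  }
  as_lgl <- function(x) {
    if (is.null(x)) return(NULL)
    if (is.list(x)) do.call(rbind, lapply(x, as.logical))
    else matrix(as.logical(x), ncol = 1)
  }
  get_fn <- function(strs, vars, arity) {
    if (is.null(strs) || !length(strs)) return(empty_function(arity))
    function_spec(as.list(strs), arity = arity, vars = vars)
  }
  block_values <- function(b, what = "values") {
    v <- b[[what]]
    if (!is.null(b$vary) && is.list(v) && is.list(v[[1]]))
      lapply(v, function(e) do.call(rbind, lapply(e, as.numeric)))
    else if (!is.null(b$vary) && is.list(v) &&
               all(vapply(v, is.numeric, TRUE)) && is.null(b$matrix))
      lapply(v, function(e) matrix(as.numeric(e), ncol = 1))
    else as_mat(v)
  }
  cov_values <- function(cv) {
    if (is.null(cv)) return(NULL)
    vals <- cv$values
    blocks <- if (!is.null(cv$blocks)) lapply(cv$blocks, as.integer)
    p <- if (!is.null(cv$dim)) cv$dim
    else if (!is.null(blocks)) max(unlist(blocks))
    else length(vals)
    out <- matrix(0, p, p)
    if (is.null(blocks)) blocks <- as.list(seq_len(p))
    for (bi in seq_along(blocks)) {
      ids <- blocks[[bi]]
      v <- vals[[bi]]
      out[ids, ids] <- if (length(ids) == 1L) as.numeric(v)
      else do.call(rbind, lapply(v, as.numeric))
    }
    list(values = out, blocks = blocks,
         free = if (!is.null(cv$free)) as.logical(cv$free))
  }
  read_level <- function(lc, latents, covs, level) {
    if (is.null(lc)) return(NULL)
    m <- length(latents)
    Q <- length(covs)
    f <- get_fn(lc$f, latents, m)
    g <- if (!is.null(lc$g)) get_fn(lc$g, covs, Q) else NULL
    Fs <- get_fn(lc$F, latents, m)
    Gs <- if (!is.null(lc$G)) get_fn(lc$G, covs, Q) else NULL
    th <- cov_values(lc$theta)
    ps <- cov_values(lc$psi)
    vary <- c()
    vary_rows_m <- list(); vary_rows_s <- list()
    vget <- function(b, nm) {
      if (!is.null(b$vary)) vary[nm] <<- b$vary
      if (!is.null(b$vary_rows)) {
        if (nm %in% c("alpha", "B", "gamma"))
          vary_rows_s[[nm]] <<- as.integer(b$vary_rows)
        else vary_rows_m[[nm]] <<- as.integer(b$vary_rows)
      }
    }
    for (nm in c("nu", "lambda", "kappa", "alpha", "B", "gamma"))
      if (!is.null(lc[[nm]])) vget(lc[[nm]], nm)
    meas <- if (is.null(lc$lambda)) NULL else measurement_spec(
      f = f, g = g,
      lambda = block_values(lc$lambda),
      lambda_free = as_lgl(lc$lambda$free),
      nu = block_values(lc$nu), nu_free = as_lgl(lc$nu$free),
      kappa = block_values(lc$kappa), kappa_free = as_lgl(lc$kappa$free),
      theta = th$values, theta_blocks = th$blocks, theta_free = th$free,
      vary = vary[names(vary) %in% c("nu", "lambda", "kappa")],
      vary_rows = if (length(vary_rows_m)) vary_rows_m)
    struct <- structural_spec(
      F = Fs, G = Gs,
      B = block_values(lc$B), B_free = as_lgl(lc$B$free),
      alpha = block_values(lc$alpha), alpha_free = as_lgl(lc$alpha$free),
      gamma = block_values(lc$gamma), gamma_free = as_lgl(lc$gamma$free),
      psi = ps$values, psi_blocks = ps$blocks, psi_free = ps$free,
      vary = vary[names(vary) %in% c("alpha", "B", "gamma")],
      vary_rows = if (length(vary_rows_s)) vary_rows_s)
    mix <- if (!is.null(lc$mixture)) {
      mixture_spec(lc$mixture$classes,
                   h = if (!is.null(lc$mixture$h))
                     get_fn(lc$mixture$h, covs, Q),
                   a = lc$mixture$a,
                   b = if (!is.null(lc$mixture$b)) as_mat(lc$mixture$b))
    }
    list(meas = meas, struct = struct, mix = mix)
  }
  read_links <- function(ls, n) {
    if (is.null(ls)) return(NULL)
    lapply(seq_len(n), function(j) {
      lk <- if (length(ls) == 1L) ls[[1]] else ls[[j]]
      indicator_spec(lk$link, n_categories = lk$n_categories,
                     thresholds = lk$thresholds)
    })
  }
  l1 <- read_level(cfg$level1, nms$eta1, nms$x1, 1L)
  l2 <- read_level(cfg$level2, nms$eta2, nms$x2, 2L)
  random <- if (!is.null(cfg$random)) {
    do.call(rbind, lapply(cfg$random, function(e) {
      row <- if (is.character(e$row)) match(e$row, nms$eta1) else e$row
      eta2 <- if (is.character(e$eta2)) match(e$eta2, nms$eta2) else e$eta2
      random_coef(e$block, row, e$col %||% 1L, eta2)
    }))
  }
  model_spec(
    level1_measurement = l1$meas, level1_structural = l1$struct,
    level1_mixture = l1$mix,
    level2_measurement = l2$meas, level2_structural = l2$struct,
    level2_mixture = l2$mix,
    random = random,
    y_links = read_links(cfg$links$y, length(nms$y)),
    z_links = read_links(cfg$links$z, length(nms$z)),
    ordered_block = cfg$ordered_block,
    names = nms)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a model configuration file
#'
#' Serializes a compiled model back to the YAML dialect accepted by
#' [read_model_config()]; `read_model_config(write_model_config(spec, f))`
#' reproduces the model.
#'
#' @param spec an `mlsem_spec`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_model_config <- function(spec, path) {
  stopifnot(inherits(spec, "mlsem_spec"))
  fmt_fn <- function(fs, vars) {
    if (fs$out_dim == 0L) return(NULL)
    vapply(fs$terms, format_term, "", vars = vars)
  }
  mat_rows <- function(m) lapply(seq_len(nrow(m)), function(i)
    as.numeric(m[i, ]))
  pb_out <- function(pb, col = FALSE) {
    if (nrow(pb$free) == 0L || ncol(pb$free) == 0L) return(NULL)
    vals <- if (pb$n_groups == 1L) {
      if (col) list(as.numeric(pb$values[[1]][, 1]))
      else mat_rows(pb$values[[1]])
    } else {
      lapply(pb$values, function(v)
        if (col) as.numeric(v[, 1]) else mat_rows(v))
    }
    if (pb$n_groups == 1L && !col) vals <- vals
    out <- list(values = if (pb$n_groups == 1L && col) vals[[1]] else vals,
                free = if (col) as.logical(pb$free[, 1])
                else lapply(seq_len(nrow(pb$free)), function(i)
                  as.logical(pb$free[i, ])))
    if (pb$vary != "none") {
      out$vary <- pb$vary
      if (any(!pb$row_vary)) out$vary_rows <- which(pb$row_vary)
    }
    out
  }
  cov_out <- function(cs) {
    if (cs$dim == 0L) return(NULL)
    list(dim = cs$dim,
         blocks = lapply(cs$blocks, as.integer),
         values = lapply(cs$blocks, function(b) {
           v <- cs$values[[1]][b, b, drop = FALSE]
           if (length(b) == 1L) as.numeric(v) else mat_rows(v)
         }),
         free = as.logical(cs$free))
  }
  lvl_out <- function(lvl, latents, covs) {
    if (lvl$m == 0L) return(NULL)
    out <- list(
      f = fmt_fn(lvl$meas$f, latents), g = fmt_fn(lvl$meas$g, covs),
      F = fmt_fn(lvl$struct$F, latents), G = fmt_fn(lvl$struct$G, covs),
      nu = pb_out(lvl$meas$nu, col = TRUE),
      lambda = pb_out(lvl$meas$lambda),
      kappa = pb_out(lvl$meas$kappa),
      theta = cov_out(lvl$meas$theta),
      alpha = pb_out(lvl$struct$alpha, col = TRUE),
      B = pb_out(lvl$struct$B),
      gamma = pb_out(lvl$struct$gamma),
      psi = cov_out(lvl$struct$psi))
    if (lvl$mix$n_classes > 1L) {
      out$mixture <- list(classes = lvl$mix$n_classes,
                          a = as.numeric(pb_get(lvl$mix$a)[, 1]),
                          h = fmt_fn(lvl$mix$h, covs))
      if (ncol(pb_get(lvl$mix$b)) > 0)
        out$mixture$b <- mat_rows(pb_get(lvl$mix$b))
    } else out$mixture <- list(classes = 1L)
    out[!vapply(out, is.null, TRUE)]
  }
  link_out <- function(links) {
    lapply(links, function(lk) {
      o <- list(link = lk$link)
      if (lk$link == "ordered") {
        o$n_categories <- lk$n_categories
        o$thresholds <- as.numeric(lk$thresholds)
      }
      o
    })
  }
  nm_out <- spec$names
  nm_out <- nm_out[lengths(nm_out) > 0]
  cfg <- list(
    names = nm_out,
    level1 = lvl_out(spec$l1, spec$names$eta1, spec$names$x1),
    level2 = lvl_out(spec$l2, spec$names$eta2, spec$names$x2),
    random = if (nrow(spec$random)) lapply(seq_len(nrow(spec$random)),
                                           function(r) as.list(spec$random[r, ])),
    links = list(y = link_out(spec$y_links), z = link_out(spec$z_links)),
    ordered_block = spec$ordered_block)
  cfg <- cfg[!vapply(cfg, is.null, TRUE)]
  yaml::write_yaml(cfg, path, precision = 12L)
  invisible(path)
}
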