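#' Are two function sets term-disjoint?
#'
#' Used by the identification checks: when the same covariate function set
#' feeds both the measurement and the structural model of one level, the two
#' coefficient sets are perfectly collinear and the model is not identified.
#'
#' @param A,B function sets ([function_spec()]) over the same variable space.
#' @return `TRUE` iff no term (same kind, variables, exponent/knot/degree)
#'   appears in both.
#' @export
check_disjoint_terms <- function(A, B) {
  stopifnot(inherits(A, "mlsem_fnspec"), inherits(B, "mlsem_fnspec"))
  if (A$out_dim > 0 && B$out_dim > 0 && A$arity != B$arity)
    stop("function sets are defined over different variable spaces",
         call. = FALSE)
  for (ta in A$terms) for (tb in B$terms) {
    if (term_equal(ta, tb)) return(FALSE)
  }
  TRUE
}

# equality of two function sets as term multisets
fnspec_identical <- function(A, B) {
  if (A$out_dim != B$out_dim) return(FALSE)
  used <- rep(FALSE, B$out_dim)
  for (ta in A$terms) {
    hit <- FALSE
    for (j in seq_len(B$out_dim)) {
      if (!used[j] && term_equal(ta, B$terms[[j]])) {
        used[j] <- TRUE; hit <- TRUE; break
      }
    }
    if (!hit) return(FALSE)
  }
  TRUE
}

#' Necessary identification checks
#'
#' Runs the four necessary identification rules on a compiled model and
#' returns a report (it never throws):
#' \enumerate{
#'   \item a scaling constraint for every latent variable (a fixed non-zero
#'     loading or a fixed latent variance), and for every measured latent
#'     either a fixed indicator intercept or a fixed latent intercept;
#'   \item the covariate function sets g/G of each level must be
#'     term-disjoint, the latent function sets f/F must not be identical,
#'     and no function set may contain a constant;
#'   \item every level-2 exogenous latent variable needs at least one
#'     indicator with a scaling constraint (directly or through the level-1
#'     parameter it drives as a random coefficient);
#'   \item reference-class logit coefficients are fixed at zero, and any
#'     model with more than one class must declare an ordering constraint on
#'     exactly one intercept block.
#' }
#'
#' @param spec an `mlsem_spec`.
#' @return a data frame of class `mlsem_validation` with columns `rule`,
#'   `check`, `pass`, `detail`; attribute `ok` is `TRUE` when all rows pass.
#' @export
validate_identification <- function(spec) {
  stopifnot(inherits(spec, "mlsem_spec"))
  rows <- list()
  add <- function(rule, check, pass, detail = "") {
    rows[[length(rows) + 1L]] <<- data.frame(
      rule = rule, check = check, pass = pass, detail = detail,
      stringsAsFactors = FALSE)
  }

  latent_scaled <- function(lvl, v, level) {
    f <- lvl$meas$f
    cols <- which(vapply(f$terms, function(t)
      t$kind == "linear" && identical(t$var, v), TRUE))
    la <- lvl$meas$lambda
    fixed_loading <- FALSE
    for (col in cols) {
      fixed_loading <- fixed_loading ||
        any(!la$free[, col] & pb_get(la)[, col] != 0)
    }
    bidx <- which(vapply(lvl$struct$psi$blocks, function(b) v %in% b, TRUE))
    fixed_var <- length(bidx) == 1 && !lvl$struct$psi$free[bidx]
    inherited <- level == 2L && v %in% spec$random$eta2
    fixed_loading || fixed_var || inherited
  }

  # rule 1: scaling and intercept constraints
  for (lv in 1:2) {
    lvl <- if (lv == 1) spec$l1 else spec$l2
    if (lvl$m == 0L) next
    for (v in seq_len(lvl$m)) {
      nmv <- if (lv == 1) spec$names$eta1[v] else spec$names$eta2[v]
      add(1L, paste0("scale.", nmv), latent_scaled(lvl, v, lv),
          paste0("latent '", nmv, "' needs a fixed loading or fixed variance"))
      # intercept side: not both the latent intercept and all indicator
      # intercepts free
      f <- lvl$meas$f
      cols <- which(vapply(f$terms, function(t)
        t$kind == "linear" && identical(t$var, v), TRUE))
      ind <- integer(0)
      for (col in cols)
        ind <- union(ind, which(active_entries(lvl$meas$lambda)[, col]))
      if (length(ind)) {
        a_free <- lvl$struct$alpha$free[v, 1]
        nu_all_free <- all(lvl$meas$nu$free[ind, 1])
        add(1L, paste0("intercept.", nmv), !(a_free && nu_all_free),
            paste0("latent '", nmv, "': fix its intercept or one indicator",
                   " intercept"))
      }
    }
  }

  # rule 2: disjoint covariate sets, unequal latent sets, no constants.
  # Only "active" terms matter: a term whose coefficient column is entirely
  # fixed at zero exerts no influence and cannot create collinearity.
  active_terms <- function(fspec, pb) {
    if (fspec$out_dim == 0L) return(fspec)
    act <- active_entries(pb)
    keep <- which(colSums(act) > 0)
    out <- fspec
    out$terms <- fspec$terms[keep]
    out$out_dim <- length(keep)
    out
  }
  name_shared <- function(A, B, vars) {
    shared <- character(0)
    for (ta in A$terms) for (tb in B$terms) {
      if (term_equal(ta, tb))
        shared <- c(shared, format_term(ta, vars))
    }
    unique(shared)
  }
  for (lv in 1:2) {
    lvl <- if (lv == 1) spec$l1 else spec$l2
    if (lvl$m == 0L) next
    xv <- if (lv == 1) spec$names$x1 else spec$names$x2
    g_act <- active_terms(lvl$meas$g, lvl$meas$kappa)
    G_act <- active_terms(lvl$struct$G, lvl$struct$gamma)
    shared <- name_shared(g_act, G_act, xv)
    add(2L, paste0("disjoint.g", lv, ".G", lv), length(shared) == 0L,
        if (length(shared)) paste0("term(s) in both g and G: ",
                                   paste(shared, collapse = ", ")) else "")
    f_act <- active_terms(lvl$meas$f, lvl$meas$lambda)
    F_act <- active_terms(lvl$struct$F, lvl$struct$B)
    add(2L, paste0("unequal.f", lv, ".F", lv),
        !(f_act$out_dim > 0 && fnspec_identical(f_act, F_act)),
        "f and F must not be identical term sets")
  }
  add(2L, "no.constants", TRUE,
      "term language admits no constant terms by construction")

  # rule 3: level-2 exogenous latents need measured scaling constraints
  if (spec$U > 0L) {
    for (v in spec$l2$topo$exo) {
      nmv <- spec$names$eta2[v]
      add(3L, paste0("l2.exo.", nmv), latent_scaled(spec$l2, v, 2L),
          paste0("level-2 exogenous latent '", nmv,
                 "' needs an indicator with a scaling constraint"))
    }
  }

  # rule 4: reference class fixed at zero; ordering constraint declared
  for (lv in 1:2) {
    mix <- if (lv == 1) spec$l1$mix else spec$l2$mix
    ok <- !mix$a$free[1, 1] && pb_get(mix$a)[1, 1] == 0 &&
      (ncol(mix$b$free) == 0 || (!any(mix$b$free[1, ]) &&
                                   all(pb_get(mix$b)[1, ] == 0)))
    add(4L, paste0("reference.class.", c("C", "D")[lv]), ok,
        "reference class logit coefficients must be fixed at zero")
  }
  if (spec$Cstar > 1L || spec$Dstar > 1L) {
    add(4L, "ordering.constraint", !is.null(spec$ordered_block),
        "mixture models need an ordered-increment constraint on one intercept block")
  }

  rep <- do.call(rbind, rows)
  class(rep) <- c("mlsem_validation", "data.frame")
  attr(rep, "ok") <- all(rep$pass)
  rep
}

#' @export
print.mlsem_validation <- function(x, ...) {
  cat("identification report:", if (attr(x, "ok")) "PASS" else "FAIL", "\n")
  for (r in sort(unique(x$rule))) {
    sub <- x[x$rule == r, ]
    cat(sprintf("  rule %d: %d/%d checks pass\n", r, sum(sub$pass),
                nrow(sub)))
    for (i in which(!sub$pass))
      cat("    FAIL ", sub$check[i], ": ", sub$detail[i], "\n", sep = "")
  }
  invisible(x)
}

# ---- parameter index / pack / unpack -----------------------------------

grp_suffix <- function(vary, g, Cstar) {
  switch(vary,
    none = "",
    c = paste0(".c", g),
    d = paste0(".d", g),
    cd = paste0(".c", ((g - 1L) %% Cstar) + 1L,
                ".d", ((g - 1L) %/% Cstar) + 1L))
}

build_pmap <- function(spec) {
  rows <- list()
  add <- function(name, path, g, i, j, kind, shared = FALSE) {
    rows[[length(rows) + 1L]] <<- data.frame(
      name = name, path = path, g = g, i = i, j = j, kind = kind,
      shared = shared, stringsAsFactors = FALSE)
  }
  coef_block <- function(pb, path, label, Cstar, scalar_col = FALSE) {
    idx <- which(pb$free, arr.ind = TRUE)
    if (!nrow(idx)) return(invisible())
    for (r in seq_len(nrow(idx))) {
      i <- idx[r, 1]; j <- idx[r, 2]
      base_nm <- if (scalar_col) paste0(label, ".", i)
      else paste0(label, ".", i, ".", j)
      if (pb$n_groups == 1L || !pb$row_vary[i]) {
        # row tied across classes: a single parameter
        add(base_nm, path, 1L, i, j, "coef", shared = pb$n_groups > 1L)
      } else {
        for (g in seq_len(pb$n_groups))
          add(paste0(base_nm, grp_suffix(pb$vary, g, Cstar)), path, g, i, j,
              "coef")
      }
    }
  }
  cov_block <- function(cs, path, label, Cstar) {
    for (g in seq_len(cs$n_groups)) {
      sfx <- grp_suffix(cs$vary, g, Cstar)
      for (b in seq_along(cs$blocks)) {
        if (!cs$free[b]) next
        ids <- cs$blocks[[b]]
        for (a1 in seq_along(ids)) for (a2 in seq_len(a1)) {
          add(paste0(label, ".", ids[a1], ".", ids[a2], sfx), path, g,
              ids[a1], ids[a2], "cov")
        }
      }
    }
  }
  lev <- function(lvl, pre, mixlab, Cstar) {
    lab <- function(b) paste0(pre, ".", b)
    coef_block(lvl$meas$nu, paste0(tolower(pre), ".meas.nu"), lab("nu"),
               Cstar, scalar_col = TRUE)
    coef_block(lvl$meas$lambda, paste0(tolower(pre), ".meas.lambda"),
               lab("lambda"), Cstar)
    coef_block(lvl$meas$kappa, paste0(tolower(pre), ".meas.kappa"),
               lab("kappa"), Cstar)
    cov_block(lvl$meas$theta, paste0(tolower(pre), ".meas.theta"),
              lab("theta"), Cstar)
    alab <- if (pre == "L2") "L2.mu" else paste0(pre, ".alpha")
    coef_block(lvl$struct$alpha, paste0(tolower(pre), ".struct.alpha"),
               alab, Cstar, scalar_col = TRUE)
    coef_block(lvl$struct$B, paste0(tolower(pre), ".struct.B"), lab("B"),
               Cstar)
    coef_block(lvl$struct$gamma, paste0(tolower(pre), ".struct.gamma"),
               lab("gamma"), Cstar)
    cov_block(lvl$struct$psi, paste0(tolower(pre), ".struct.psi"),
              lab("psi"), Cstar)
    coef_block(lvl$mix$a, paste0(tolower(pre), ".mix.a"),
               paste0(mixlab, ".a"), Cstar, scalar_col = TRUE)
    coef_block(lvl$mix$b, paste0(tolower(pre), ".mix.b"),
               paste0(mixlab, ".b"), Cstar)
  }
  lev(spec$l1, "L1", "mixC", spec$Cstar)
  lev(spec$l2, "L2", "mixD", 1L)
  # thresholds of ordered indicators (first cut point fixed at 0)
  for (j in seq_len(spec$J)) {
    lk <- spec$y_links[[j]]
    if (lk$link == "ordered" && lk$n_categories > 2L) {
      for (s in 2:(lk$n_categories - 1L))
        add(paste0("tau.y", j, ".", s), paste0("tau.y.", j), 1L, s, 1L,
            "tau")
    }
  }
  for (l in seq_len(spec$L)) {
    lk <- spec$z_links[[l]]
    if (lk$link == "ordered" && lk$n_categories > 2L) {
      for (s in 2:(lk$n_categories - 1L))
        add(paste0("tau.z", l, ".", s), paste0("tau.z.", l), 1L, s, 1L,
            "tau")
    }
  }
  if (!length(rows)) {
    return(data.frame(name = character(0), path = character(0),
                      g = integer(0), i = integer(0), j = integer(0),
                      kind = character(0), shared = logical(0),
                      stringsAsFactors = FALSE))
  }
  pm <- do.call(rbind, rows)
  if (anyDuplicated(pm$name)) stop("internal: duplicate parameter names")
  pm
}

# resolve "l1.meas.nu"-style path against a spec-like object
get_block <- function(spec, path) {
  p <- strsplit(path, ".", fixed = TRUE)[[1]]
  if (p[1] == "tau") {
    return(spec[[paste0(p[2], "_links")]][[as.integer(p[3])]])
  }
  spec[[p[1]]][[p[2]]][[p[3]]]
}

#' Ordered names of the free parameters of a model
#'
#' Deterministic, stable naming of every free parameter: level prefix,
#' block, row/column, and a class suffix for class-varying blocks (for
#' example `L2.mu.1.d2`). Fixed, constrained, and random-coefficient
#' entries are excluded; random coefficients appear only through their
#' level-2 means and variances.
#'
#' @param spec an `mlsem_spec`.
#' @return character vector.
#' @export
parameter_index <- function(spec) {
  stopifnot(inherits(spec, "mlsem_spec"))
  spec$pmap$name
}

#' Current values of the free parameters of a model
#'
#' Named vector in [parameter_index()] order; for a generating model this
#' is the ground truth of a simulation study.
#'
#' @param spec an `mlsem_spec`.
#' @return named numeric vector.
#' @export
parameter_values <- function(spec) {
  stopifnot(inherits(spec, "mlsem_spec"))
  collect_params(spec)
}

# pack the current values of all free parameters into a named vector
collect_params <- function(spec) {
  pm <- spec$pmap
  out <- numeric(nrow(pm))
  for (r in seq_len(nrow(pm))) {
    p <- strsplit(pm$path[r], ".", fixed = TRUE)[[1]]
    if (p[1] == "tau") {
      lk <- spec[[paste0(p[2], "_links")]][[as.integer(p[3])]]
      out[r] <- lk$thresholds[pm$i[r]]
    } else {
      blk <- spec[[p[1]]][[p[2]]][[p[3]]]
      out[r] <- blk$values[[pm$g[r]]][pm$i[r], pm$j[r]]
    }
  }
  names(out) <- pm$name
  out
}

# inverse of collect_params; returns the modified spec
unpack_params <- function(spec, theta) {
  pm <- spec$pmap
  stopifnot(length(theta) == nrow(pm))
  for (r in seq_len(nrow(pm))) {
    p <- strsplit(pm$path[r], ".", fixed = TRUE)[[1]]
    if (p[1] == "tau") {
      spec[[paste0(p[2], "_links")]][[as.integer(p[3])]]$thresholds[pm$i[r]] <-
        theta[r]
    } else {
      gs <- if (isTRUE(pm$shared[r]))
        seq_along(spec[[p[1]]][[p[2]]][[p[3]]]$values) else pm$g[r]
      for (g in gs) {
        spec[[p[1]]][[p[2]]][[p[3]]]$values[[g]][pm$i[r], pm$j[r]] <-
          theta[r]
        if (pm$kind[r] == "cov" && pm$i[r] != pm$j[r]) {
          spec[[p[1]]][[p[2]]][[p[3]]]$values[[g]][pm$j[r], pm$i[r]] <-
            theta[r]
        }
      }
    }
  }
  spec
}
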