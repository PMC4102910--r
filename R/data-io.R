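#' Write a dataset to CSV files
#'
#' Two-file layout: an individual-level table (`cluster_id`, indicator
#' columns, covariate columns) and a cluster-level table (`cluster_id`,
#' cluster indicators, cluster covariates). Missing cells are written as
#' empty fields. The generation truth record (classes and latent values),
#' when present, goes to a YAML sidecar.
#'
#' @param data an `mlsem_data`.
#' @param individual_csv,cluster_csv output paths.
#' @param truth_file optional path for the truth sidecar (`NULL` = skip).
#' @return invisibly, the paths written.
#' @export
write_dataset <- function(data, individual_csv, cluster_csv,
                          truth_file = NULL) {
  stopifnot(inherits(data, "mlsem_data"))
  ind <- data.frame(cluster_id = data$cluster)
  y <- data$y; y[data$y_miss] <- NA
  ind <- cbind(ind, as.data.frame(y), as.data.frame(data$x1))
  cl <- data.frame(cluster_id = seq_len(data$K))
  z <- data$z; z[data$z_miss] <- NA
  cl <- cbind(cl, as.data.frame(z), as.data.frame(data$x2))
  utils::write.csv(ind, individual_csv, row.names = FALSE, na = "")
  utils::write.csv(cl, cluster_csv, row.names = FALSE, na = "")
  if (!is.null(truth_file) && !is.null(data$truth)) {
    tr <- data$truth
    yaml::write_yaml(list(
      seed = data$seed,
      C = as.integer(tr$C), D = as.integer(tr$D),
      eta1 = apply(tr$eta1, 1, as.numeric, simplify = FALSE),
      eta2 = apply(tr$eta2, 1, as.numeric, simplify = FALSE)),
      truth_file)
  }
  invisible(c(individual_csv, cluster_csv))
}

#' Read a dataset from CSV files
#'
#' Validates the two-file layout against a model: both files need a
#' `cluster_id` column plus the model's declared indicator and covariate
#' columns; empty fields become missing-mask entries; every individual's
#' cluster id must resolve against the cluster table. Cluster ids are
#' treated as opaque labels and indexed by order of first appearance in the
#' cluster table.
#'
#' @param individual_csv,cluster_csv input paths.
#' @param spec the `mlsem_spec` the data are meant for.
#' @return an `mlsem_data`.
#' @export
read_dataset <- function(individual_csv, cluster_csv, spec) {
  stopifnot(inherits(spec, "mlsem_spec"))
  ind <- utils::read.csv(individual_csv, check.names = FALSE)
  cl <- utils::read.csv(cluster_csv, check.names = FALSE)
  for (df in list(ind, cl)) {
    if (!"cluster_id" %in% names(df))
      stop("both CSV files need a 'cluster_id' column", call. = FALSE)
  }
  getcols <- function(df, cols, what, n_expect, file) {
    miss <- setdiff(cols, names(df))
    if (length(miss))
      stop("missing ", what, " column(s) in ", file, ": ",
           paste(miss, collapse = ", "), call. = FALSE)
    m <- as.matrix(df[, cols, drop = FALSE])
    if (length(m) && !is.numeric(m)) {
      bad <- which(!vapply(df[cols], is.numeric, TRUE))
      stop("non-numeric ", what, " column in ", file, ": ",
           cols[bad[1]], call. = FALSE)
    }
    m
  }
  keys <- as.character(cl$cluster_id)
  if (anyDuplicated(keys))
    stop("duplicated cluster_id in the cluster table", call. = FALSE)
  idx <- match(as.character(ind$cluster_id), keys)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1]
    stop("individual row ", bad, " has cluster_id '",
         ind$cluster_id[bad], "' absent from the cluster table",
         call. = FALSE)
  }
  y <- getcols(ind, spec$names$y, "indicator", spec$J, individual_csv)
  x1 <- getcols(ind, spec$names$x1, "covariate", spec$Q, individual_csv)
  z <- getcols(cl, spec$names$z, "indicator", spec$L, cluster_csv)
  x2 <- getcols(cl, spec$names$x2, "covariate", spec$V, cluster_csv)
  if (anyNA(x1) || anyNA(x2))
    stop("covariates must be fully observed", call. = FALSE)
  structure(list(
    y = y, z = z, x1 = x1, x2 = x2, cluster = idx,
    y_miss = is.na(y), z_miss = is.na(z),
    truth = NULL, K = nrow(cl), N = nrow(ind),
    cluster_labels = keys, seed = NA_integer_), class = "mlsem_data")
}
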