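#' @title Multilevel data container
#'
#' @description Internal validated container for three-level data: responses
#' indexed by cluster and sub-cluster, plus design matrices at the three
#' levels.  Rows are reordered deterministically (clusters, then sub-clusters,
#' by sorted label; observations keep their input order within sub-cluster).
#'
#' @param cluster,subcluster character or factor identifiers, one per row;
#'   sub-cluster labels need only be unique within a cluster.
#' @param y nonnegative numeric response, one per row.
#' @param Z1,Z2,Z3 per-row numeric matrices of cluster-, sub-cluster- and
#'   observation-level covariates (may have zero columns).  Cluster-level
#'   columns must be constant within each cluster, and sub-cluster-level
#'   columns constant within each sub-cluster; an intercept column is allowed
#'   only in `Z3`, and only one.
#'
#' @return an object of class `cp_data`: the responses, collapsed design
#'   matrices (`Z1` with one row per cluster, `Z2` one per sub-cluster, `Z3`
#'   one per observation) and the index maps between the three levels.
#' @noRd
cp_data <- function(cluster, subcluster, y, Z1, Z2, Z3) {
  N <- length(y)
  cluster <- as.character(cluster)
  subcluster <- as.character(subcluster)
  if (length(cluster) != N || length(subcluster) != N)
    stop("'cluster', 'subcluster' and 'y' must have equal length")
  Z1 <- as_design(Z1, N, "Z1")
  Z2 <- as_design(Z2, N, "Z2")
  Z3 <- as_design(Z3, N, "Z3")

  if (anyNA(cluster) || anyNA(subcluster))
    stop("missing values in cluster or sub-cluster identifiers (rows ",
         toString(utils::head(which(is.na(cluster) | is.na(subcluster)), 5L)),
         ")")
  if (!is.numeric(y))
    stop("response 'y' must be numeric")
  if (anyNA(y))
    stop("missing response values in rows ",
         toString(utils::head(which(is.na(y)), 5L)))
  bad <- which(y < 0)
  if (length(bad))
    stop("negative response in row ", bad[1L], " (y = ", y[bad[1L]],
         "); responses must be nonnegative")
  for (nm in c("Z1", "Z2", "Z3")) {
    Z <- get(nm)
    if (anyNA(Z)) {
      j <- which(colSums(is.na(Z)) > 0)[1L]
      stop("missing values in covariate '", colnames(Z)[j], "'")
    }
  }

  ## deterministic ordering: cluster label, then sub-cluster label,
  ## observations in input order within sub-cluster
  ord <- order(cluster, subcluster)
  cluster <- cluster[ord]; subcluster <- subcluster[ord]; y <- y[ord]
  Z1 <- Z1[ord, , drop = FALSE]
  Z2 <- Z2[ord, , drop = FALSE]
  Z3 <- Z3[ord, , drop = FALSE]

  cl_f <- factor(cluster, levels = unique(cluster))
  sub_key <- paste(cluster, subcluster, sep = "\r")
  sub_f <- factor(sub_key, levels = unique(sub_key))
  obs_cluster <- as.integer(cl_f)
  obs_sub <- as.integer(sub_f)
  I <- nlevels(cl_f)
  M <- nlevels(sub_f)
  first_sub <- match(seq_len(M), obs_sub)
  first_cl <- match(seq_len(I), obs_cluster)
  sub_cluster <- obs_cluster[first_sub]

  check_constant(Z1, obs_cluster, cluster, "cluster")
  check_constant(Z2, obs_sub, paste(cluster, subcluster, sep = "/"),
                 "sub-cluster")

  Z1c <- Z1[first_cl, , drop = FALSE]
  Z2c <- Z2[first_sub, , drop = FALSE]
  rownames(Z1c) <- levels(cl_f)
  rownames(Z2c) <- NULL

  ## an intercept (any constant column) is only identifiable in Z3
  for (lv in list(list(Z1c, "cluster", I), list(Z2c, "sub-cluster", M))) {
    Z <- lv[[1L]]
    if (lv[[3L]] > 1L && ncol(Z) > 0L) {
      cst <- which(apply(Z, 2L, function(x) max(x) == min(x)))
      if (length(cst))
        stop("covariate '", colnames(Z)[cst[1L]], "' is constant across all ",
             lv[[2L]], "s and acts as an intercept; intercepts are only ",
             "allowed at the observation level")
    }
  }
  if (ncol(Z3) > 1L) {
    ones <- which(apply(Z3, 2L, function(x) all(x == 1)))
    if (length(ones) > 1L)
      stop("more than one intercept column in the observation-level design")
  }

  X <- cbind(Z1, Z2, Z3)
  if (ncol(X) == 0L)
    stop("no covariates at any level; at least an intercept is required")
  if (qr(X)$rank < ncol(X))
    stop("the stacked design matrix (cluster, sub-cluster, observation ",
         "columns combined) is rank deficient; remove redundant covariates")

  structure(list(
    y = y,
    cluster = cl_f,
    subcluster = subcluster,
    Z1 = Z1c, Z2 = Z2c, Z3 = Z3,
    obs_cluster = obs_cluster,
    obs_sub = obs_sub,
    sub_cluster = sub_cluster,
    sub_label = subcluster[first_sub],
    cluster_label = levels(cl_f),
    I = I, M = M, N = N,
    J = as.integer(tabulate(sub_cluster, I)),
    n = as.integer(tabulate(obs_sub, M)),
    order = ord
  ), class = "cp_data")
}

as_design <- function(Z, N, what) {
  if (is.null(Z)) Z <- matrix(numeric(0), N, 0L)
  Z <- as.matrix(Z)
  if (!is.numeric(Z) && ncol(Z) > 0L)
    stop("covariate matrix ", what, " must be numeric")
  if (nrow(Z) != N)
    stop("covariate matrix ", what, " has ", nrow(Z), " rows; expected ", N)
  if (is.null(colnames(Z)) && ncol(Z) > 0L)
    colnames(Z) <- paste0(what, seq_len(ncol(Z)))
  Z
}

check_constant <- function(Z, group, labels, what) {
  if (ncol(Z) == 0L) return(invisible())
  for (j in seq_len(ncol(Z))) {
    rng <- vapply(split(Z[, j], group), function(v) max(v) - min(v), 0)
    if (any(rng > 0)) {
      g <- which(rng > 0)[1L]
      lab <- labels[match(g, group)]
      stop("covariate '", colnames(Z)[j], "' is declared ", what,
           "-level but varies within ", what, " '", lab, "'")
    }
  }
  invisible()
}

#' Per-row design matrices from level formulas
#'
#' Builds the three per-row covariate matrices from an observation-level
#' model formula (with intercept) and optional intercept-free cluster- and
#' sub-cluster-level formulas.  Factors in the level formulas are expanded
#' with treatment contrasts and the intercept column is then dropped, so a
#' binary factor contributes a single dummy column.
#' @noRd
cp_model_matrices <- function(formula, cluster_formula, subcluster_formula,
                              data) {
  mf <- stats::model.frame(formula, data, na.action = stats::na.pass)
  y <- stats::model.response(mf)
  Z3 <- stats::model.matrix(attr(mf, "terms"), mf)
  drop_int <- function(f) {
    if (is.null(f)) return(NULL)
    mm <- stats::model.matrix(f, stats::model.frame(f, data,
                                                    na.action = stats::na.pass))
    mm[, colnames(mm) != "(Intercept)", drop = FALSE]
  }
  list(y = as.numeric(y), Z1 = drop_int(cluster_formula),
       Z2 = drop_int(subcluster_formula), Z3 = Z3)
}

#' Validate a long-format multilevel dataset
#'
#' Checks that a long-format data frame is a well-formed three-level dataset:
#' nonnegative responses with no missing values, covariates constant within
#' the level they are declared at, and a full-rank stacked design.
#'
#' @param data a data frame with one row per observation.
#' @param level_map named character vector or list mapping each covariate
#'   column to `"cluster"`, `"subcluster"` or `"observation"`.
#' @param cluster,subcluster,response names of the identifier and response
#'   columns.
#' @return invisibly, a list with the validated dimensions (`I` clusters,
#'   `M` sub-clusters, `N` observations and the per-sub-cluster sizes `n`).
#'   Validation failures raise an error naming the offending covariate or row.
#' @examples
#' sim <- cpmm_simulate(cpmm_design(I = 20), seed = 1)
#' validate_cpmm_data(sim$data, sim$level_map)
#' @export
validate_cpmm_data <- function(data, level_map, cluster = "cluster",
                               subcluster = "subcluster", response = "y") {
  level_map <- unlist(level_map)
  missing_cols <- setdiff(c(cluster, subcluster, response, names(level_map)),
                          names(data))
  if (length(missing_cols))
    stop("column(s) not found in data: ", toString(missing_cols))
  bad_lvl <- setdiff(level_map, c("cluster", "subcluster", "observation"))
  if (length(bad_lvl))
    stop("unknown level(s) in level map: ", toString(bad_lvl))
  pick <- function(lvl) {
    nms <- names(level_map)[level_map == lvl]
    if (!length(nms)) return(NULL)
    Z <- as.matrix(data[nms])
    storage.mode(Z) <- "double"
    Z
  }
  d <- cp_data(data[[cluster]], data[[subcluster]], data[[response]],
               pick("cluster"), pick("subcluster"),
               cbind("(Intercept)" = rep(1, nrow(data)), pick("observation")))
  invisible(list(I = d$I, M = d$M, N = d$N, J = d$J, n = d$n))
}
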