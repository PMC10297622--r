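## Orthodox best linear unbiased prediction of the random effects.
##
## The BLUP of a random effect W given the responses Y of its cluster is
##   What = E(W) + Cov(W, Y) Var(Y)^-1 (Y - E(Y)),
## the best predictor among all linear-in-Y unbiased predictors; it requires
## only the first two moments, not the full hierarchical distributions.
## Because the per-cluster covariance is diagonal plus low rank, the BLUPs
## and their prediction mean-squared errors admit closed forms, which the
## production path uses; cp_blup_dense() is the dense-algebra reference kept
## for verification.

#' Closed-form BLUPs and prediction MSEs
#'
#' Cluster level:
#'   Uhat_i = [mu_i + sigma2 mu_i sum_jk w_ij mu_ijk^(1-p) Y_ijk] /
#'            [1 + sigma2 mu_i sum_jk w_ij mu_ij mu_ijk^(2-p)]
#'   d(i)   = sigma2 mu_i^2 / (same denominator)
#' Sub-cluster level:
#'   Vhat_ij = rho2 w_ij mu_ij Uhat_i
#'             + tau2 mu_ij w_ij sum_k mu_ijk^(1-p) Y_ijk
#'   d(ij)   = rho2 w_ij tau2 mu_i mu_ij^2 + (rho2 w_ij mu_ij)^2 d(i)
#' All predictors are positive-coefficient combinations of nonnegative
#' responses, hence strictly positive; exact zeros in Y need no special
#' handling.
#' @noRd
cp_blup <- function(data, params, means) {
  p <- params$p
  t1p <- means$mu_ijk^(1 - p)
  A_ij <- rs(t1p * data$y, data$obs_sub)        # sum_k mu_ijk^(1-p) Y_ijk
  wA <- means$w_ij * A_ij
  wmS <- means$w_ij * means$mu_ij * means$S_ij
  den <- 1 + params$sigma2 * means$mu_i * rs(wmS, data$sub_cluster)
  U_hat <- (means$mu_i + params$sigma2 * means$mu_i *
              rs(wA, data$sub_cluster)) / den
  d_i <- params$sigma2 * means$mu_i^2 / den
  V_hat <- params$rho2 * means$w_ij * means$mu_ij * U_hat[data$sub_cluster] +
    params$tau2 * means$mu_ij * wA
  d_ij <- params$rho2 * means$w_ij * params$tau2 *
    means$mu_i[data$sub_cluster] * means$mu_ij^2 +
    (params$rho2 * means$w_ij * means$mu_ij)^2 * d_i[data$sub_cluster]
  list(U_hat = U_hat, V_hat = V_hat, d_i = d_i, d_ij = d_ij)
}

#' Dense-matrix BLUP reference
#'
#' Evaluates What = E(W) + Cov(W,Y) Var(Y)^-1 (Y - E(Y)) and
#' MSE = Var(W) - Cov(W,Y) Var(Y)^-1 Cov(Y,W) cluster by cluster with dense
#' linear algebra.  Clusters are independent, so no global solve is needed.
#' @noRd
cp_blup_dense <- function(data, params, means) {
  U_hat <- d_i <- numeric(data$I)
  V_hat <- d_ij <- numeric(data$M)
  for (i in seq_len(data$I)) {
    mom <- cp_re_moments(data, params, means, i)
    Vy <- cp_cluster_cov(data, params, means, i)
    EY <- cp_marginal_mean(data, means)[mom$idx]
    r <- data$y[mom$idx] - EY
    sol <- tryCatch(solve(Vy, cbind(r, mom$covUY, t(mom$covVY))),
                    error = function(e)
                      stop("singular marginal covariance in cluster '",
                           data$cluster_label[i], "'"))
    U_hat[i] <- mom$EU + sum(mom$covUY * sol[, 1L])
    d_i[i] <- mom$varU - sum(mom$covUY * sol[, 2L])
    V_hat[mom$subs] <- mom$EV + drop(mom$covVY %*% sol[, 1L])
    d_ij[mom$subs] <- diag(mom$covVV) -
      diag(mom$covVY %*% sol[, -(1:2), drop = FALSE])
  }
  list(U_hat = U_hat, V_hat = V_hat, d_i = d_i, d_ij = d_ij)
}

#' Random effect predictions from a fitted model
#'
#' Extracts the orthodox best linear unbiased predictors (BLUPs) of the
#' cluster-level effects \eqn{\hat U_i} and sub-cluster-level effects
#' \eqn{\hat V_{ij}} from a fitted [cpmm] model, together with their
#' prediction mean-squared errors \eqn{d(i) = E(\hat U_i - U_i)^2} and
#' \eqn{d(ij) = E(\hat V_{ij} - V_{ij})^2}.
#'
#' @param object a fitted model.
#' @param ... unused.
#' @return a data frame with one row per sub-cluster: `cluster`,
#'   `subcluster`, `U_hat`, `V_hat`, `d_i`, `d_ij` (cluster-level columns are
#'   repeated across the cluster's sub-clusters).
#' @examples
#' sim <- cpmm_simulate(cpmm_design(I = 30), seed = 1)
#' fit <- cpmm_sim_fit(sim)
#' head(blup(fit))
#' @export
blup <- function(object, ...) UseMethod("blup")

#' @rdname blup
#' @export
blup.cpmm <- function(object, ...) {
  b <- object$blup
  d <- object$cp_data
  data.frame(cluster = d$cluster_label[d$sub_cluster],
             subcluster = d$sub_label,
             U_hat = b$U_hat[d$sub_cluster],
             V_hat = b$V_hat,
             d_i = b$d_i[d$sub_cluster],
             d_ij = b$d_ij,
             stringsAsFactors = FALSE)
}
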