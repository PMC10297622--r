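## Optimal estimating equations for the regression coefficients.
##
## The estimating function stacks three blocks, one per level, each a sum of
## BLUP-standardised residuals weighted by the level's covariates:
##   psi1 = sum_i   Z_i    (Uhat_i - mu_i)            / (mu_i   sigma2)
##   psi2 = sum_ij  Z_ij   (Vhat_ij - Uhat_i mu_ij)   / (mu_ij  tau2)
##   psi3 = sum_ijk Z_ijk  mu_ijk^(1-p) (Y_ijk - Vhat_ij mu_ijk) / rho2
## and is identical to the global matrix form
##   psi = X' D Var(Y)^-1 (Y - E(Y)),   D = diag(E(Y)),
## whose sensitivity/variability matrices satisfy J = V = -S with
##   V = X' D Var(Y)^-1 D X  (the Godambe information).
## The solver exploits the diagonal + low-rank structure of the per-cluster
## covariance so that both psi and V are assembled with grouped sums only;
## cp_global_dense() is the dense reference implementation.

## stacked design matrix expanded to one row per observation
cp_X <- function(data) {
  cbind(data$Z1[data$obs_cluster, , drop = FALSE],
        data$Z2[data$obs_sub, , drop = FALSE],
        data$Z3)
}

#' Component-route estimating function
#'
#' @param by_cluster if `TRUE`, return the q x I matrix of per-cluster
#'   contributions (clusters are independent, so psi is their row sum).
#' @noRd
cp_score <- function(data, params, means, blup, by_cluster = FALSE) {
  r1 <- (blup$U_hat - means$mu_i) / (means$mu_i * params$sigma2)
  r2 <- (blup$V_hat - blup$U_hat[data$sub_cluster] * means$mu_ij) /
    (means$mu_ij * params$tau2)
  r3 <- means$mu_ijk^(1 - params$p) *
    (data$y - blup$V_hat[data$obs_sub] * means$mu_ijk) / params$rho2
  if (by_cluster) {
    p1 <- t(data$Z1 * r1)
    p2 <- if (ncol(data$Z2)) t(rowsum(data$Z2 * r2, data$sub_cluster)) else
      matrix(0, 0L, data$I)
    p3 <- t(rowsum(data$Z3 * r3, data$obs_cluster))
    out <- rbind(p1, p2, p3)
    dimnames(out) <- NULL
    return(out)
  }
  c(as.vector(crossprod(data$Z1, r1)),
    as.vector(crossprod(data$Z2, r2)),
    as.vector(crossprod(data$Z3, r3)))
}

#' Godambe information V = X' D Var(Y)^-1 D X via the structured inverse
#'
#' Per cluster, Var(Y) = C + sum_j u_j u_j' + a a' with
#'   C   = diag(rho2 mu_i mu_ij mu_ijk^p)
#'   u_j = sqrt(tau2 mu_i) mu_ij mu_ijk  (supported on sub-cluster j)
#'   a   = sqrt(sigma2) E(Y).
#' Woodbury gives Var(Y)^-1 = C^-1 - C^-1 [u a] K^-1 [u a]' C^-1 where K is
#' an arrowhead matrix (the u_j have disjoint support), so everything reduces
#' to sums over observations grouped by sub-cluster and cluster.
#' @noRd
cp_info <- function(data, params, means) {
  X <- cp_X(data)
  m1o <- means$mu_i[data$obs_cluster]
  m2o <- means$mu_ij[data$obs_sub]
  EY <- m1o * m2o * means$mu_ijk
  cinv <- 1 / (params$rho2 * m1o * m2o * means$mu_ijk^params$p)
  mm <- sqrt(params$tau2 * m1o) * m2o * means$mu_ijk       # u_j entries
  a <- sqrt(params$sigma2) * EY
  DXc <- X * (EY * cinv)                                   # C^-1 D X rows
  T1 <- crossprod(X * sqrt(EY^2 * cinv))
  Dw <- 1 / (params$rho2 * means$w_ij)                     # 1 + u_j'C^-1 u_j
  b <- rs(mm * a * cinv, data$obs_sub)                     # u_j' C^-1 a
  corner <- 1 + rs(a^2 * cinv, data$obs_cluster)
  s <- corner - rs(b^2 / Dw, data$sub_cluster)             # Schur complement
  Gsub <- rowsum(DXc * mm, data$obs_sub)                   # (DX)'C^-1 u_j
  Ga <- rowsum(DXc * a, data$obs_cluster)                  # (DX)'C^-1 a
  H <- rowsum(Gsub * (b / Dw), data$sub_cluster) - Ga
  V <- T1 - crossprod(Gsub / sqrt(Dw)) - crossprod(H / sqrt(s))
  dimnames(V) <- NULL
  0.5 * (V + t(V))
}

#' Dense-matrix estimating function and information (reference route)
#'
#' Assembles psi = X' D Var(Y)^-1 (Y - E(Y)) and
#' V = X' D Var(Y)^-1 D X cluster by cluster with dense solves, and returns
#' the Godambe triplet (J = V = -S).
#' @noRd
cp_global_dense <- function(data, params, means) {
  q <- ncol(data$Z1) + ncol(data$Z2) + ncol(data$Z3)
  psi <- numeric(q)
  V <- matrix(0, q, q)
  X <- cp_X(data)
  EYall <- cp_marginal_mean(data, means)
  for (i in seq_len(data$I)) {
    idx <- which(data$obs_cluster == i)
    Vy <- cp_cluster_cov(data, params, means, i)
    DX <- X[idx, , drop = FALSE] * EYall[idx]
    sol <- tryCatch(solve(Vy, cbind(data$y[idx] - EYall[idx], DX)),
                    error = function(e)
                      stop("singular marginal covariance in cluster '",
                           data$cluster_label[i], "'"))
    psi <- psi + as.vector(crossprod(DX, sol[, 1L]))
    V <- V + crossprod(DX, sol[, -1L, drop = FALSE])
  }
  V <- 0.5 * (V + t(V))
  dimnames(V) <- NULL
  list(psi = psi, S = -V, V = V, J = V)
}

#' One Newton scoring update beta* = beta - S^-1 psi = beta + V^-1 psi
#' @noRd
cp_scoring_step <- function(data, params, means, blup) {
  psi <- cp_score(data, params, means, blup)
  V <- cp_info(data, params, means)
  ch <- tryCatch(chol(V), error = function(e)
    stop("sensitivity matrix is not invertible; check the design matrix ",
         "for (near) rank deficiency"))
  delta <- backsolve(ch, backsolve(ch, psi, transpose = TRUE))
  list(beta = c(params$beta1, params$beta2, params$beta3) + delta,
       psi = psi, V = V, delta = delta)
}

#' Adjusted Pearson estimators of the dispersion parameters
#'
#' Moment estimators built from squared BLUP residuals plus additive bias
#' corrections involving the prediction MSEs; each estimator is exactly
#' unbiased for its target given the current regression coefficients:
#'   sigma2: mean over clusters of [(Uhat-mu_i)^2 + d(i)] / mu_i^2
#'   tau2:   cluster mean of sub-cluster means of
#'           [(Vhat - mu_ij Uhat)^2 + d(i) mu_ij^2 + d(ij)
#'            - 2 rho2 d(i) w_ij mu_ij^2] / (mu_i mu_ij^2)
#'   rho2:   cluster mean of sub-cluster means of observation means of
#'           [(Y - Vhat mu_ijk)^2 / mu_ijk^p + d(ij) mu_ijk^(2-p)] /
#'           (mu_i mu_ij)
#' @noRd
cp_dispersions <- function(data, params, means, blup) {
  m1s <- means$mu_i[data$sub_cluster]
  d_i_s <- blup$d_i[data$sub_cluster]
  sigma2 <- mean(((blup$U_hat - means$mu_i)^2 + blup$d_i) / means$mu_i^2)
  tsub <- ((blup$V_hat - means$mu_ij * blup$U_hat[data$sub_cluster])^2 +
             d_i_s * means$mu_ij^2 + blup$d_ij -
             2 * params$rho2 * d_i_s * means$w_ij * means$mu_ij^2) /
    (m1s * means$mu_ij^2)
  tau2 <- mean(rs(tsub, data$sub_cluster) / data$J)
  m1o <- means$mu_i[data$obs_cluster]
  m2o <- means$mu_ij[data$obs_sub]
  robs <- ((data$y - blup$V_hat[data$obs_sub] * means$mu_ijk)^2 /
             means$mu_ijk^params$p +
             blup$d_ij[data$obs_sub] * means$mu_ijk^(2 - params$p)) /
    (m1o * m2o)
  per_sub <- rs(robs, data$obs_sub) / data$n
  rho2 <- mean(rs(per_sub, data$sub_cluster) / data$J)
  c(sigma2 = sigma2, tau2 = tau2, rho2 = rho2)
}

#' Standard errors from the sensitivity matrix
#'
#' The asymptotic variance of the coefficient estimator is -S^-1 (equal to
#' V^-1 = J^-1 here); standard errors are the square roots of its diagonal.
#' @noRd
cp_standard_errors <- function(S) {
  negS <- -S
  ch <- tryCatch(chol(negS), error = function(e)
    stop("sensitivity matrix is not negative definite"))
  sqrt(diag(chol2inv(ch)))
}
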