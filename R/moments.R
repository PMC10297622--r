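## Mean structure and exact marginal moments of the three-level
## compound Poisson mixed model.
##
## Level means follow the log link:
##   mu_i   = exp(Z_i'    beta1)   (cluster)
##   mu_ij  = exp(Z_ij'   beta2)   (sub-cluster)
##   mu_ijk = exp(Z_ijk'  beta3)   (observation)
## so that E(Y_ijk) = mu_i * mu_ij * mu_ijk = exp(X_ijk' beta).

## largest |linear predictor| accepted before exp(); beyond this the means
## overflow/underflow double precision
.eta_max <- 700

cp_params <- function(beta1, beta2, beta3, sigma2, tau2, rho2, p) {
  if (!(p > 1 && p < 2)) stop("index parameter p must lie strictly in (1, 2)")
  if (any(c(sigma2, tau2, rho2) < 0))
    stop("dispersion parameters must be nonnegative")
  if (rho2 <= 0) stop("rho2 must be strictly positive")
  list(beta1 = as.numeric(beta1), beta2 = as.numeric(beta2),
       beta3 = as.numeric(beta3), sigma2 = sigma2, tau2 = tau2,
       rho2 = rho2, p = p)
}

## rowsum() down to a plain vector, groups 1..ng all present
rs <- function(x, g) {
  out <- rowsum(x, g, reorder = TRUE)
  dimnames(out) <- NULL
  if (ncol(out) == 1L) drop(out) else out
}

#' Level means and sub-cluster weights
#'
#' Computes mu_i, mu_ij, mu_ijk by the log link and the sub-cluster weights
#' w_ij = 1 / (rho2 + tau2 * mu_ij * sum_k mu_ijk^(2-p)), together with the
#' per-sub-cluster sums S_ij = sum_k mu_ijk^(2-p) reused throughout the
#' estimation.
#' @noRd
cp_means <- function(data, params) {
  eta1 <- unname(drop(data$Z1 %*% params$beta1))
  eta2 <- unname(drop(data$Z2 %*% params$beta2))
  eta3 <- unname(drop(data$Z3 %*% params$beta3))
  if (length(eta1) == 0L) eta1 <- numeric(data$I)
  if (length(eta2) == 0L) eta2 <- numeric(data$M)
  if (length(eta3) == 0L) eta3 <- numeric(data$N)
  eta_all <- c(eta1, eta2, eta3)
  if (any(!is.finite(eta_all)) || max(abs(eta_all)) > .eta_max)
    stop("linear predictor out of range (|eta| > ", .eta_max,
         "); consider centring/rescaling covariates")
  mu_i <- exp(eta1); mu_ij <- exp(eta2); mu_ijk <- exp(eta3)
  S_ij <- rs(mu_ijk^(2 - params$p), data$obs_sub)
  w_ij <- 1 / (params$rho2 + params$tau2 * mu_ij * S_ij)
  list(mu_i = mu_i, mu_ij = mu_ij, mu_ijk = mu_ijk, w_ij = w_ij, S_ij = S_ij)
}

## marginal mean E(Y_ijk) = mu_i mu_ij mu_ijk, one entry per observation
cp_marginal_mean <- function(data, means) {
  means$mu_i[data$obs_cluster] * means$mu_ij[data$obs_sub] * means$mu_ijk
}

#' Dense marginal covariance of one cluster's observations
#'
#' Entry (jk, tl) is
#'   sigma2 mu_i^2 mu_ij mu_it mu_ijk mu_itl
#'   + delta(t,j) tau2 mu_i mu_ij^2 mu_ijk mu_ijl
#'   + delta(t,j) delta(l,k) rho2 mu_i mu_ij mu_ijk^p,
#' i.e. a rank-one cluster term plus block-diagonal sub-cluster terms plus a
#' diagonal.  Rows/columns are ordered lexicographically (sub-cluster, then
#' observation), matching the container's row order.
#' @noRd
cp_cluster_cov <- function(data, params, means, i) {
  idx <- which(data$obs_cluster == i)
  sub <- data$obs_sub[idx]
  m1 <- means$mu_i[i]
  m2 <- means$mu_ij[sub]
  m3 <- means$mu_ijk[idx]
  EY <- m1 * m2 * m3
  V <- params$sigma2 * tcrossprod(EY)
  for (j in unique(sub)) {
    sel <- sub == j
    mm <- means$mu_ij[j] * m3[sel]
    V[sel, sel] <- V[sel, sel] + params$tau2 * m1 * tcrossprod(mm)
  }
  diag(V) <- diag(V) + params$rho2 * m1 * m2 * m3^params$p
  if (any(!is.finite(V))) stop("non-finite entries in marginal covariance")
  V
}

#' First and second moments of the random effects of one cluster
#'
#' Returns E(U_i), Var(U_i), E(V_ij), Cov(V_ij, V_it) and the
#' cross-covariances with the cluster's responses,
#'   Cov(U_i, Y_ijk)  = sigma2 mu_i^2 mu_ij mu_ijk,
#'   Cov(V_ij, Y_itl) = mu_itl * Cov(V_ij, V_it),
#' used by the dense-matrix BLUP oracle.
#' @noRd
cp_re_moments <- function(data, params, means, i) {
  idx <- which(data$obs_cluster == i)
  subs <- which(data$sub_cluster == i)
  sub_of_obs <- data$obs_sub[idx]
  m1 <- means$mu_i[i]
  m2s <- means$mu_ij[subs]
  m2 <- means$mu_ij[sub_of_obs]
  m3 <- means$mu_ijk[idx]
  covVV <- params$sigma2 * m1^2 * tcrossprod(m2s) +
    diag(params$tau2 * m1 * m2s^2, nrow = length(subs))
  jpos <- match(sub_of_obs, subs)
  ## Cov(V_ij, Y_itl) over sub-clusters j (rows) and observations tl (cols)
  covVY <- (params$sigma2 * m1^2 * tcrossprod(m2s, m2) +
              params$tau2 * m1 * (m2s^2) *
              outer(seq_along(subs), jpos, "==")) * rep(m3, each = length(subs))
  list(EU = m1, varU = params$sigma2 * m1^2,
       EV = m1 * m2s, covVV = covVV,
       covUY = params$sigma2 * m1^2 * m2 * m3,
       covVY = covVY,
       idx = idx, subs = subs)
}
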