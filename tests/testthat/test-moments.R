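test_that("zero coefficients give unit means and the closed-form weights", {
  set.seed(101)
  inst <- random_instance()
  pars <- inst$params
  pars$beta1 <- 0; pars$beta2 <- 0; pars$beta3 <- c(0, 0)
  m <- cpmixed:::cp_means(inst$d, pars)
  expect_equal(m$mu_i, rep(1, inst$d$I))
  expect_equal(m$mu_ij, rep(1, inst$d$M))
  expect_equal(m$mu_ijk, rep(1, inst$d$N))
  expect_equal(m$w_ij, 1 / (pars$rho2 + pars$tau2 * inst$d$n))

  pars$tau2 <- 0
  m0 <- cpmixed:::cp_means(inst$d, pars)
  expect_equal(m0$w_ij, rep(1 / pars$rho2, inst$d$M))
})

test_that("weights match an independent double-loop evaluation", {
  set.seed(102)
  for (r in 1:20) {
    inst <- random_instance()
    d <- inst$d; pars <- inst$params
    m <- cpmixed:::cp_means(d, pars)
    w_ref <- numeric(d$M)
    for (j in seq_len(d$M)) {
      s <- 0
      for (k in which(d$obs_sub == j)) s <- s + m$mu_ijk[k]^(2 - pars$p)
      w_ref[j] <- 1 / (pars$rho2 + pars$tau2 * m$mu_ij[j] * s)
    }
    expect_lt(max_rel_diff(m$w_ij, w_ref), 1e-12)
    expect_true(all(m$w_ij <= 1 / pars$rho2 + 1e-15))
  }
})

test_that("marginal mean: product form equals exp of the stacked predictor", {
  set.seed(103)
  for (r in 1:20) {
    inst <- random_instance()
    m <- cpmixed:::cp_means(inst$d, inst$params)
    prod_form <- cpmixed:::cp_marginal_mean(inst$d, m)
    X <- cpmixed:::cp_X(inst$d)
    beta <- c(inst$params$beta1, inst$params$beta2, inst$params$beta3)
    expect_lt(max_rel_diff(prod_form, exp(drop(X %*% beta))), 1e-12)
  }
})

test_that("marginal mean at a zero-covariate row is exp(intercept)", {
  ## first row carries all-zero covariates, so at the estimated
  ## intervention-study coefficients its mean reduces to exp(-1.2114);
  ## the remaining rows only keep the stacked design full rank
  set.seed(108)
  nr <- 16
  clu <- rep(c("c1", "c2", "c3", "c4"), each = 4)
  sub <- rep(c("s1", "s2"), 8)
  key <- paste(clu, sub)
  cl_vals <- function() c(0, stats::runif(3))[match(clu, unique(clu))]
  sub_vals <- function() c(0, stats::runif(7))[match(key, unique(key))]
  Z1 <- sapply(c(treatment = 1, gender_pr = 1, age_pr = 1),
               function(i) cl_vals())
  Z2 <- sapply(c(age_ad = 1, race_ad = 1, gender_ad = 1),
               function(i) sub_vals())
  Z3 <- cbind("(Intercept)" = rep(1, nr),
              months = c(0, stats::runif(nr - 1)),
              spring = c(0, stats::rbinom(nr - 1, 1, 0.5)),
              summer = c(0, stats::rbinom(nr - 1, 1, 0.5)))
  d <- cpmixed:::cp_data(clu, sub, stats::rgamma(nr, 1, 1), Z1, Z2, Z3)
  pars <- cpmixed:::cp_params(c(0.0110, 0.2310, -0.0165),
                              c(0.0403, 0.1148, 0.4058),
                              c(-1.2114, -0.0503, 0.0880, -0.0173),
                              0.1050, 0.3844, 0.6794, 1.55)
  m <- cpmixed:::cp_means(d, pars)
  EY <- cpmixed:::cp_marginal_mean(d, m)
  zero_row <- which(rowSums(abs(cbind(d$Z1[d$obs_cluster, ],
                                      d$Z2[d$obs_sub, ],
                                      d$Z3[, -1]))) == 0)
  expect_length(zero_row, 1L)
  expect_equal(EY[zero_row], exp(-1.2114))
})

test_that("linear predictor overflow raises a scaling error", {
  d <- cpmixed:::cp_data(c("c1", "c1"), c("s1", "s1"), c(1, 2),
                         NULL, NULL,
                         cbind("(Intercept)" = c(1, 1), x = c(0, 1e6)))
  pars <- cpmixed:::cp_params(numeric(0), numeric(0), c(0, 1),
                              0.1, 0.1, 1, 1.5)
  expect_error(cpmixed:::cp_means(d, pars), "rescaling")
})

test_that("marginal covariance has the stated structure and limits", {
  set.seed(104)
  inst <- random_instance(I = 2, maxJ = 3, maxn = 3)
  d <- inst$d; pars <- inst$params

  ## independence limit: sigma2 = tau2 = 0 with unit upper-level means
  p0 <- pars
  p0$sigma2 <- 0; p0$tau2 <- 0; p0$beta1 <- 0; p0$beta2 <- 0
  m0 <- cpmixed:::cp_means(d, p0)
  V0 <- cpmixed:::cp_cluster_cov(d, p0, m0, 1L)
  k1 <- which(d$obs_cluster == 1L)
  expect_equal(V0, diag(p0$rho2 * m0$mu_ijk[k1]^p0$p,
                        nrow = length(k1)))

  ## diagonal entries follow the three-term variance decomposition
  m <- cpmixed:::cp_means(d, pars)
  V <- cpmixed:::cp_cluster_cov(d, pars, m, 1L)
  m1 <- m$mu_i[1L]
  m2 <- m$mu_ij[d$obs_sub[k1]]
  m3 <- m$mu_ijk[k1]
  expect_equal(diag(V),
               pars$sigma2 * m1^2 * m2^2 * m3^2 +
                 pars$tau2 * m1 * m2^2 * m3^2 +
                 pars$rho2 * m1 * m2 * m3^pars$p)

  ## property sweep: symmetric positive definite for positive dispersions
  set.seed(105)
  for (r in 1:25) {
    inst <- random_instance()
    m <- cpmixed:::cp_means(inst$d, inst$params)
    for (i in seq_len(inst$d$I)) {
      Vi <- cpmixed:::cp_cluster_cov(inst$d, inst$params, m, i)
      expect_equal(Vi, t(Vi))
      expect_no_error(chol(Vi))
    }
  }
})

test_that("random-effect moments: degenerate and cross-cluster cases", {
  set.seed(106)
  inst <- random_instance(I = 3)
  pars <- inst$params
  pars$sigma2 <- 0
  m <- cpmixed:::cp_means(inst$d, pars)
  mom <- cpmixed:::cp_re_moments(inst$d, pars, m, 2L)
  expect_equal(mom$varU, 0)
  expect_equal(mom$EU, m$mu_i[2L])
  expect_equal(mom$EV, m$mu_i[2L] * m$mu_ij[inst$d$sub_cluster == 2L])
  ## with sigma2 = 0, V covariances reduce to the diagonal tau2 term
  expect_equal(mom$covVV,
               diag(pars$tau2 * m$mu_i[2L] *
                      m$mu_ij[inst$d$sub_cluster == 2L]^2,
                    nrow = sum(inst$d$sub_cluster == 2L)))
})

test_that("simulator moments match the covariance formula (Monte Carlo)", {
  ## one fixed cluster with 2 sub-clusters x 2 observations, replicated:
  ## empirical Cov(Y) must match the model covariance entrywise
  set.seed(107)
  R <- 2e5
  mu_i <- 1.2
  mu_ij <- c(0.8, 1.4)
  mu_ijk <- c(0.9, 1.6, 1.1, 0.7)
  sub_of_obs <- c(1L, 1L, 2L, 2L)
  s2 <- 0.105; t2 <- 0.3844; r2 <- 0.6794; p <- 1.55
  U <- rgamma_md(R, mu_i, s2)
  V1 <- rgamma_md(R, mu_ij[1] * U, t2 / U)
  V2 <- rgamma_md(R, mu_ij[2] * U, t2 / U)
  Vm <- cbind(V1, V1, V2, V2)
  Y <- sapply(1:4, function(k)
    rtweedie_cp(R, mu_ijk[k] * Vm[, k], r2 * Vm[, k]^(1 - p), p))

  ## model covariance via the packaged formula on a matching cp_data
  d <- cpmixed:::cp_data(rep("c1", 4), c("s1", "s1", "s2", "s2"), rep(1, 4),
                         NULL, NULL, cbind("(Intercept)" = rep(1, 4)))
  pars <- cpmixed:::cp_params(numeric(0), numeric(0), 0, s2, t2, r2, p)
  m <- cpmixed:::cp_means(d, pars)
  m$mu_i <- mu_i; m$mu_ij <- mu_ij; m$mu_ijk <- mu_ijk
  m$S_ij <- cpmixed:::rs(mu_ijk^(2 - p), d$obs_sub)
  m$w_ij <- 1 / (r2 + t2 * mu_ij * m$S_ij)
  Vmodel <- cpmixed:::cp_cluster_cov(d, pars, m, 1L)

  emp <- stats::cov(Y)
  ctr <- sweep(Y, 2, colMeans(Y))
  ## 10 distinct entries tested jointly: compare the largest |z| against a
  ## Bonferroni-adjusted three-sigma-equivalent family-wise bound
  z <- sapply(1:4, function(a) sapply(1:4, function(b)
    (emp[a, b] - Vmodel[a, b]) /
      (stats::sd(ctr[, a] * ctr[, b]) / sqrt(R))))
  expect_lt(max(abs(z[upper.tri(z, diag = TRUE)])),
            stats::qnorm(1 - stats::pnorm(-3) / 10))
  ## random-effect moments against the same draws
  expect_lt(abs(mean(U) - mu_i), 3 * stats::sd(U) / sqrt(R))
  expect_lt(abs(stats::var(U) - s2 * mu_i^2),
            3 * stats::sd((U - mean(U))^2) / sqrt(R))
  expect_lt(abs(mean(V2) - mu_i * mu_ij[2]), 3 * stats::sd(V2) / sqrt(R))
})
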