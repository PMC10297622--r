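test_that("score vanishes exactly at the degenerate conditional means", {
  ## degenerate hierarchy: U at mu_i, V at its conditional mean mu_ij U,
  ## Y at its conditional mean mu_ijk V -> every score block is exactly 0
  set.seed(301)
  inst <- random_instance()
  d <- inst$d
  m <- cpmixed:::cp_means(d, inst$params)
  U <- m$mu_i
  V <- m$mu_ij * U[d$sub_cluster]
  d$y <- m$mu_ijk * V[d$obs_sub]
  bl <- list(U_hat = U, V_hat = V)
  psi <- cpmixed:::cp_score(d, inst$params, m, bl)
  expect_equal(psi, rep(0, 4))
})

test_that("component-route score equals the Theorem-form matrix route", {
  set.seed(302)
  for (r in 1:100) {
    inst <- random_instance()
    m <- cpmixed:::cp_means(inst$d, inst$params)
    bl <- cpmixed:::cp_blup(inst$d, inst$params, m)
    psi_c <- cpmixed:::cp_score(inst$d, inst$params, m, bl)
    g <- cpmixed:::cp_global_dense(inst$d, inst$params, m)
    expect_lt(max(abs(psi_c - g$psi)) / max(abs(g$psi), 1e-8), 1e-8)
    ## per-cluster contributions sum to the total
    pc <- cpmixed:::cp_score(inst$d, inst$params, m, bl, by_cluster = TRUE)
    expect_equal(rowSums(pc), psi_c, tolerance = 1e-12)
  }
})

test_that("fast information matrix equals the dense route and J = V = -S", {
  set.seed(303)
  for (r in 1:50) {
    inst <- random_instance()
    m <- cpmixed:::cp_means(inst$d, inst$params)
    Vfast <- cpmixed:::cp_info(inst$d, inst$params, m)
    g <- cpmixed:::cp_global_dense(inst$d, inst$params, m)
    expect_lt(max(abs(Vfast - g$V)) / max(abs(g$V)), 1e-8)
    expect_identical(g$S, -g$V)
    expect_identical(g$J, g$V)
    expect_equal(Vfast, t(Vfast))
    expect_true(all(eigen(Vfast, symmetric = TRUE,
                          only.values = TRUE)$values > 0))
  }
})

test_that("responses at their marginal mean are a scoring fixed point", {
  set.seed(304)
  inst <- random_instance()
  d <- inst$d
  m <- cpmixed:::cp_means(d, inst$params)
  d$y <- cpmixed:::cp_marginal_mean(d, m)
  bl <- cpmixed:::cp_blup(d, inst$params, m)
  st <- cpmixed:::cp_scoring_step(d, inst$params, m, bl)
  expect_equal(max(abs(st$psi)), 0, tolerance = 1e-10)
  expect_equal(st$beta, c(inst$params$beta1, inst$params$beta2,
                          inst$params$beta3), tolerance = 1e-10)
})

test_that("dispersion updates match a naive double-loop re-summation", {
  set.seed(305)
  for (r in 1:10) {
    inst <- random_instance()
    d <- inst$d; pars <- inst$params
    m <- cpmixed:::cp_means(d, pars)
    bl <- cpmixed:::cp_blup(d, pars, m)
    got <- cpmixed:::cp_dispersions(d, pars, m, bl)

    I <- d$I
    s2 <- t2 <- r2 <- 0
    for (i in seq_len(I)) {
      s2 <- s2 + ((bl$U_hat[i] - m$mu_i[i])^2 + bl$d_i[i]) / m$mu_i[i]^2 / I
      subs <- which(d$sub_cluster == i)
      Ji <- length(subs)
      for (j in subs) {
        num <- (bl$V_hat[j] - m$mu_ij[j] * bl$U_hat[i])^2 +
          bl$d_i[i] * m$mu_ij[j]^2 + bl$d_ij[j] -
          2 * pars$rho2 * bl$d_i[i] * m$w_ij[j] * m$mu_ij[j]^2
        t2 <- t2 + num / (m$mu_i[i] * m$mu_ij[j]^2) / (I * Ji)
        obs <- which(d$obs_sub == j)
        nij <- length(obs)
        for (k in obs) {
          rk <- (d$y[k] - bl$V_hat[j] * m$mu_ijk[k])^2 /
            (m$mu_i[i] * m$mu_ij[j] * m$mu_ijk[k]^pars$p) +
            bl$d_ij[j] * m$mu_ijk[k]^(2 - pars$p) /
            (m$mu_i[i] * m$mu_ij[j])
          r2 <- r2 + rk / (I * Ji * nij)
        }
      }
    }
    expect_lt(max_rel_diff(got, c(s2, t2, r2)), 1e-10)
  }
})

test_that("dispersion estimate is zero for perfectly predicted effects", {
  set.seed(306)
  inst <- random_instance()
  d <- inst$d
  m <- cpmixed:::cp_means(d, inst$params)
  bl <- cpmixed:::cp_blup(d, inst$params, m)
  bl$U_hat <- m$mu_i
  bl$d_i <- rep(0, d$I)
  got <- cpmixed:::cp_dispersions(d, inst$params, m, bl)
  expect_equal(got[["sigma2"]], 0)
})

test_that("estimating function is unbiased at the truth (MC)", {
  set.seed(307)
  des <- cpmm_design(I = 3000, J_range = c(1, 3), n_range = c(1, 5))
  sim <- cpmm_simulate(des)
  d <- sim_cp_data(sim)
  pars <- cpmixed:::cp_params(des$beta1, des$beta2, des$beta3,
                              des$sigma2, des$tau2, des$rho2, des$p)
  m <- cpmixed:::cp_means(d, pars)
  bl <- cpmixed:::cp_blup(d, pars, m)
  pc <- cpmixed:::cp_score(d, pars, m, bl, by_cluster = TRUE)
  z <- rowMeans(pc) / (apply(pc, 1, stats::sd) / sqrt(ncol(pc)))
  expect_true(all(abs(z) < 3))
})

test_that("degenerate dispersions reproduce an independent Tweedie IRLS", {
  set.seed(308)
  des <- cpmm_design(model = "ctmm", I = 150, sigma2 = 1e-12, tau2 = 1e-12,
                     rho2 = 0.6, p = 1.5)
  sim <- cpmm_simulate(des)
  fit <- cpmm_sim_fit(sim, cpmm_control(update_dispersions = FALSE,
                                        sigma2 = 1e-12, tau2 = 1e-12,
                                        rho2 = 0.6))
  X <- stats::model.matrix(sim$formula, sim$data)
  ref <- irls_tweedie(X, sim$data$y, p = 1.5)
  expect_lt(max(abs(coef(fit) - ref)), 1e-6)
})

test_that("intercept-only degenerate fit returns log(mean(y))", {
  set.seed(309)
  y <- c(rgamma(30, 2, 2), 0, 0, 0)
  df <- data.frame(cluster = "c1", subcluster = "s1", y = y)
  fit <- cpmm(y ~ 1, df, cluster = "cluster", subcluster = "subcluster",
              p = 1.5,
              control = cpmm_control(update_dispersions = FALSE,
                                     sigma2 = 1e-12, tau2 = 1e-12,
                                     rho2 = 1))
  expect_equal(unname(coef(fit)), log(mean(y)), tolerance = 1e-8)
})

test_that("standard errors are sqrt of the diagonal of -S^-1", {
  expect_equal(cpmixed:::cp_standard_errors(matrix(-4, 1, 1)), 0.5)
  expect_error(cpmixed:::cp_standard_errors(matrix(4, 1, 1)),
               "negative definite")
  set.seed(310)
  inst <- random_instance()
  m <- cpmixed:::cp_means(inst$d, inst$params)
  g <- cpmixed:::cp_global_dense(inst$d, inst$params, m)
  expect_equal(cpmixed:::cp_standard_errors(g$S),
               unname(sqrt(diag(solve(g$V)))), tolerance = 1e-10)
})

test_that("optimal weighting beats working independence (PSD order)", {
  ## asymptotic variance of the optimally weighted estimating function,
  ## V^-1, is no larger than the sandwich variance of the naive
  ## independence-weighted moment estimator, on any fixed design
  set.seed(311)
  for (r in 1:2) {
    inst <- random_instance(I = 4, maxJ = 3, maxn = 4)
    d <- inst$d; pars <- inst$params
    m <- cpmixed:::cp_means(d, pars)
    X <- cpmixed:::cp_X(d)
    EY <- cpmixed:::cp_marginal_mean(d, m)
    cdiag <- pars$sigma2 * EY^2 +
      pars$tau2 * m$mu_i[d$obs_cluster] * (m$mu_ij[d$obs_sub] *
                                             m$mu_ijk)^2 +
      pars$rho2 * m$mu_i[d$obs_cluster] * m$mu_ij[d$obs_sub] *
        m$mu_ijk^pars$p
    DX <- X * EY
    A <- crossprod(DX, DX / cdiag)
    B <- matrix(0, ncol(X), ncol(X))
    for (i in seq_len(d$I)) {
      idx <- which(d$obs_cluster == i)
      Vy <- cpmixed:::cp_cluster_cov(d, pars, m, i)
      Wi <- DX[idx, , drop = FALSE] / cdiag[idx]
      B <- B + crossprod(Wi, Vy %*% Wi)
    }
    sandwich <- solve(A, B) %*% solve(A)
    Vopt <- solve(cpmixed:::cp_info(d, pars, m))
    ev <- eigen(sandwich - Vopt, symmetric = TRUE, only.values = TRUE)$values
    expect_true(all(ev > -1e-8 * max(abs(ev))))
  }
})

test_that("coefficient bias shrinks as the number of clusters grows", {
  set.seed(312)
  rmse <- sapply(c(50, 800), function(I) {
    des <- cpmm_design(I = I)
    err <- replicate(8, {
      sim <- cpmm_simulate(des)
      fit <- suppressWarnings(cpmm_sim_fit(sim))
      coef(fit)[c("gender_ad", "months")] -
        c(des$beta2["gender_ad"], des$beta3["months"])
    })
    sqrt(rowMeans(err^2))
  })
  expect_true(all(rmse[, 2] < rmse[, 1]))
})

test_that("accelerated and plain fixed-point iterations agree", {
  set.seed(315)
  sim <- cpmm_simulate(cpmm_design(I = 60))
  fit_acc <- suppressWarnings(cpmm_sim_fit(sim))
  fit_plain <- suppressWarnings(
    cpmm_sim_fit(sim, cpmm_control(accelerate = FALSE, max_iter = 600L)))
  expect_true(fit_plain$converged)
  expect_lt(max(abs(coef(fit_acc) - coef(fit_plain))), 1e-7)
  expect_lt(max(abs(fit_acc$dispersion - fit_plain$dispersion)), 1e-7)
  expect_lt(fit_acc$iterations, fit_plain$iterations)
})

test_that("covariate-independent special case: all upper-level means are 1", {
  set.seed(313)
  sim <- cpmm_simulate(cpmm_design(model = "ctmm", I = 120))
  fit <- suppressWarnings(cpmm_sim_fit(sim))
  expect_length(fit$beta$cluster, 0)
  expect_length(fit$beta$subcluster, 0)
  expect_equal(fit$means$mu_i, rep(1, fit$cp_data$I))
  expect_equal(fit$means$mu_ij, rep(1, fit$cp_data$M))
  ## ... so the marginal mean is exp(Z3 beta3) alone
  expect_equal(fitted(fit),
               unname(exp(drop(stats::model.matrix(sim$formula, sim$data) %*%
                                 fit$beta$observation))),
               tolerance = 1e-12)
})

test_that("fit converges and reports a coherent result object", {
  set.seed(314)
  sim <- cpmm_simulate(cpmm_design(I = 80))
  fit <- cpmm_sim_fit(sim)
  expect_true(fit$converged)
  expect_lt(fit$iterations, 200)
  ## at the reported optimum the estimating function is a numerical root
  m <- cpmixed:::cp_means(fit$cp_data, fit$params)
  bl <- cpmixed:::cp_blup(fit$cp_data, fit$params, m)
  expect_lt(max(abs(cpmixed:::cp_score(fit$cp_data, fit$params, m, bl))),
            fit$control$tol_score)
  expect_equal(unname(fit$se), sqrt(diag(solve(fit$godambe))))
  s <- summary(fit)
  expect_s3_class(s, "summary.cpmm")
  expect_equal(dim(s$coefficients), c(10L, 4L))
})
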