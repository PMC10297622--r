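## Shared fixtures: random small instances with arbitrary nonnegative
## responses (the BLUP/score identities hold for any y), plus independent
## oracle implementations kept deliberately naive.

## random parameters over the sweep used by the equivalence checks
random_params <- function(q1, q2, q3, p = sample(c(1.1, 1.5, 1.9), 1),
                          disp_range = c(0.01, 5)) {
  cpmixed:::cp_params(
    beta1 = stats::rnorm(q1, 0, 0.4),
    beta2 = stats::rnorm(q2, 0, 0.4),
    beta3 = c(stats::rnorm(1, 0, 0.5), stats::rnorm(q3 - 1, 0, 0.4)),
    sigma2 = stats::runif(1, disp_range[1], disp_range[2]),
    tau2 = stats::runif(1, disp_range[1], disp_range[2]),
    rho2 = stats::runif(1, disp_range[1], disp_range[2]),
    p = p)
}

## a small three-level instance: cp_data with one covariate per upper level,
## intercept + one covariate at observation level, and responses that are a
## zero-inflated gamma mixture (not from the model on purpose)
random_instance <- function(I = sample(2:5, 1), maxJ = 4, maxn = 5,
                            p = sample(c(1.1, 1.5, 1.9), 1),
                            zero_prob = 0.3, disp_range = c(0.01, 5)) {
  repeat {
    J <- sample.int(maxJ, I, replace = TRUE)
    M <- sum(J)
    sub_cluster <- rep.int(seq_len(I), J)
    n <- sample.int(maxn, M, replace = TRUE)
    N <- sum(n)
    obs_sub <- rep.int(seq_len(M), n)
    obs_cluster <- sub_cluster[obs_sub]
    z1 <- matrix(stats::runif(I, -1, 1), I, 1,
                 dimnames = list(NULL, "x1"))[obs_cluster, , drop = FALSE]
    z2 <- matrix(stats::runif(M, -1, 1), M, 1,
                 dimnames = list(NULL, "x2"))[obs_sub, , drop = FALSE]
    z3 <- cbind("(Intercept)" = rep(1, N), x3 = stats::runif(N, -1, 1))
    y <- stats::rgamma(N, shape = 1.2, rate = 1)
    y[stats::runif(N) < zero_prob] <- 0
    d <- tryCatch(cpmixed:::cp_data(sprintf("c%03d", obs_cluster),
                                    sprintf("s%03d", obs_sub), y,
                                    z1, z2, z3),
                  error = function(e) NULL)   # rare rank-deficient draw
    if (!is.null(d)) break
  }
  list(d = d, params = random_params(1, 1, 2, p = p,
                                     disp_range = disp_range))
}

## cp_data from a cpmm_simulate() result (same path the fitting front end
## uses)
sim_cp_data <- function(sim) {
  mm <- cpmixed:::cp_model_matrices(sim$formula, sim$cluster_formula,
                                    sim$subcluster_formula, sim$data)
  cpmixed:::cp_data(sim$data$cluster, sim$data$subcluster, mm$y,
                    mm$Z1, mm$Z2, mm$Z3)
}

## textbook IRLS for a quasi-likelihood Tweedie GLM with log link and
## variance function mu^p -- the independent oracle for the degenerate
## (no random effects) case
irls_tweedie <- function(X, y, p, tol = 1e-12, maxit = 200) {
  beta <- numeric(ncol(X))
  beta[1] <- log(mean(y) + 0.01)
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- exp(eta)
    w <- mu^2 / mu^p
    z <- eta + (y - mu) / mu
    beta_new <- drop(solve(crossprod(X, w * X), crossprod(X, w * z)))
    if (max(abs(beta_new - beta)) < tol) return(beta_new)
    beta <- beta_new
  }
  beta
}

max_rel_diff <- function(a, b) {
  max(abs(a - b) / pmax(abs(b), 1e-12))
}
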