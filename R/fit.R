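#' Fit a Tweedie compound Poisson mixed model with covariate-dependent
#' random effects
#'
#' @description
#' Fits a three-level model for a semicontinuous (nonnegative, zero-inflated)
#' response \eqn{Y_{ijk}} observed for observation \eqn{k} of sub-cluster
#' \eqn{j} of cluster \eqn{i}:
#' \itemize{
#'   \item cluster effects \eqn{U_i \sim} Gamma with mean
#'     \eqn{\mu_i = \exp(Z_i'\beta^{(1)})} and variance \eqn{\sigma^2\mu_i^2};
#'   \item sub-cluster effects \eqn{V_{ij} \mid U \sim} Gamma with mean
#'     \eqn{\mu_{ij} U_i} and variance \eqn{\tau^2 \mu_{ij}^2 U_i}, where
#'     \eqn{\mu_{ij} = \exp(Z_{ij}'\beta^{(2)})};
#'   \item responses \eqn{Y_{ijk} \mid V \sim} Tweedie compound Poisson with
#'     mean \eqn{\mu_{ijk} V_{ij}} and variance
#'     \eqn{\rho^2 \mu_{ijk}^p V_{ij}}, where
#'     \eqn{\mu_{ijk} = \exp(Z_{ijk}'\beta^{(3)})} and the index parameter
#'     \eqn{p} is fixed in \eqn{(1, 2)}.
#' }
#' Marginally \eqn{E(Y_{ijk}) = \mu_i \mu_{ij} \mu_{ijk} =
#' \exp(X_{ijk}'\beta)}, so covariates act at their own level while the
#' marginal mean stays log-linear.  Attaching cluster-level covariates
#' directly to observations (the conventional covariate-independent
#' arrangement, obtained here by leaving `cluster_formula` and
#' `subcluster_formula` empty) risks the ecological fallacy this model is
#' designed to avoid.
#'
#' Estimation iterates (i) a Newton scoring update of all regression blocks
#' from the optimal estimating equation \eqn{\psi(\beta) = X' D
#' \mathrm{Var}(Y)^{-1}(Y - E Y) = 0}, (ii) closed-form orthodox BLUP
#' prediction of the random effects, and (iii) adjusted Pearson moment
#' updates of \eqn{\sigma^2, \tau^2, \rho^2}, until both the parameters and
#' the estimating function have converged.  Standard errors come from the
#' inverse Godambe information, which for this estimating function equals
#' \eqn{-S^{-1}(\beta)}.
#'
#' @param formula observation-level model formula, `response ~ covariates`;
#'   the intercept belongs to this level.
#' @param data a data frame in long format, one row per observation.
#' @param cluster,subcluster names of the columns holding the cluster and
#'   sub-cluster identifiers (sub-cluster labels need only be unique within a
#'   cluster).
#' @param cluster_formula,subcluster_formula optional one-sided formulas for
#'   the covariates driving the cluster- and sub-cluster-level random-effect
#'   means.  They must be constant within their level; intercepts are dropped
#'   (the multiplicative decomposition is only identifiable with a single
#'   intercept, at the observation level).  `NULL` means no covariates at
#'   that level, i.e. covariate-independent random effects there.
#' @param p Tweedie index parameter, fixed in (1, 2).  The package does not
#'   estimate `p`; choose it externally (e.g. by profile likelihood in a
#'   marginal Tweedie GLM).
#' @param control a list from [cpmm_control()].
#'
#' @return an object of class `"cpmm"` with components `coefficients`,
#'   `se`, `vcov`, `dispersion` (`sigma2`, `tau2`, `rho2`), `p`, `blup`,
#'   `fitted.values`, `converged`, `iterations` and `trace`; see
#'   [summary.cpmm()], [blup()], [predict.cpmm()], [simulate.cpmm()].
#'
#' @examples
#' sim <- cpmm_simulate(cpmm_design(I = 60), seed = 7)
#' fit <- cpmm(y ~ months + spring + summer, data = sim$data,
#'             cluster = "cluster", subcluster = "subcluster",
#'             cluster_formula = ~ treatment + gender_pr + age_pr,
#'             subcluster_formula = ~ age_ad + race_ad + gender_ad,
#'             p = 1.55)
#' summary(fit)
#' @export
cpmm <- function(formula, data, cluster, subcluster,
                 cluster_formula = NULL, subcluster_formula = NULL,
                 p = 1.5, control = cpmm_control()) {
  cl <- match.call()
  if (!is.data.frame(data)) stop("'data' must be a data frame")
  for (nm in c(cluster, subcluster))
    if (!nm %in% names(data)) stop("identifier column '", nm,
                                   "' not found in data")
  mm <- cp_model_matrices(formula, cluster_formula, subcluster_formula, data)
  d <- cp_data(data[[cluster]], data[[subcluster]], mm$y,
               mm$Z1, mm$Z2, mm$Z3)
  fit <- cpmm_fit(d, p, control)
  fit$call <- cl
  fit$formula <- formula
  fit$cluster_formula <- cluster_formula
  fit$subcluster_formula <- subcluster_formula
  fit$terms <- list(obs = stats::terms(formula),
                    cluster = if (!is.null(cluster_formula))
                      stats::terms(cluster_formula),
                    subcluster = if (!is.null(subcluster_formula))
                      stats::terms(subcluster_formula))
  fit
}

#' Control parameters for [cpmm()]
#'
#' @param max_iter maximum number of outer iterations (each outer iteration
#'   is one scoring update, one BLUP pass and one dispersion update).
#' @param tol_param convergence tolerance on the maximum relative parameter
#'   change between outer iterations (relative to `max(|value|, 0.01)`).
#' @param tol_score convergence tolerance on the supremum norm of the
#'   estimating function.
#' @param update_dispersions if `FALSE`, the dispersion parameters are held
#'   at their initial values and only the regression coefficients are
#'   estimated.
#' @param sigma2,tau2 initial values for the cluster and sub-cluster
#'   dispersions.
#' @param rho2 initial value for the response dispersion; `NULL` initialises
#'   it from the Pearson statistic of an independence working model.
#' @param floor lower bound applied to dispersion updates; a nonpositive
#'   update is floored here with a warning (repeated flooring suggests the
#'   corresponding variance component is absent).
#' @param max_halvings maximum number of step halvings per scoring update.
#' @param accelerate apply a safeguarded Aitken delta-squared extrapolation
#'   to the dispersion fixed point once the iteration is in its linearly
#'   convergent regime.  The moment updates converge geometrically; the
#'   extrapolation typically cuts the iteration count severalfold and is
#'   rejected whenever it would leave the parameter space.
#' @param verbose print per-iteration progress.
#' @return a named list.
#' @export
cpmm_control <- function(max_iter = 200L, tol_param = 1e-8, tol_score = 1e-6,
                         update_dispersions = TRUE, sigma2 = 0.1, tau2 = 0.1,
                         rho2 = NULL, floor = 1e-10, max_halvings = 10L,
                         accelerate = TRUE, verbose = FALSE) {
  stopifnot(max_iter >= 1L, tol_param > 0, tol_score > 0,
            sigma2 >= 0, tau2 >= 0, is.null(rho2) || rho2 > 0, floor > 0)
  list(max_iter = as.integer(max_iter), tol_param = tol_param,
       tol_score = tol_score, update_dispersions = update_dispersions,
       sigma2 = sigma2, tau2 = tau2, rho2 = rho2, floor = floor,
       max_halvings = as.integer(max_halvings), accelerate = accelerate,
       verbose = verbose)
}

## the outer iteration: scoring -> BLUP -> dispersions, as one fixed-point
## sweep per iteration
cpmm_fit <- function(d, p, control) {
  if (!(p > 1 && p < 2)) stop("index parameter p must lie strictly in (1, 2)")
  q1 <- ncol(d$Z1); q2 <- ncol(d$Z2); q3 <- ncol(d$Z3)

  ## initial beta3 from a log-link quasi-Poisson working model ignoring the
  ## clustering; beta1, beta2 at zero; rho2 from the working-model Pearson
  ## statistic with variance function mu^p
  beta3 <- numeric(q3)
  rho2 <- control$rho2
  if (q3 > 0L) {
    g0 <- suppressWarnings(stats::glm.fit(d$Z3, d$y,
                                          family = stats::quasipoisson()))
    beta3 <- ifelse(is.na(g0$coefficients), 0, g0$coefficients)
    if (is.null(rho2)) {
      mu0 <- pmax(g0$fitted.values, 1e-8)
      rho2 <- max(sum((d$y - mu0)^2 / mu0^p) / max(1, d$N - q3), 1e-4)
    }
  } else if (is.null(rho2)) rho2 <- 1
  params <- cp_params(numeric(q1), numeric(q2), beta3,
                      control$sigma2, control$tau2, rho2, p)

  coef_names <- c(colnames(d$Z1), colnames(d$Z2), colnames(d$Z3))
  theta_old <- c(unlist(params[c("beta1", "beta2", "beta3")], use.names = FALSE),
                 params$sigma2, params$tau2, params$rho2)
  trace <- vector("list", control$max_iter)
  converged <- FALSE
  floored <- FALSE
  means <- cp_means(d, params)
  disp_hist <- NULL
  rel <- Inf

  for (it in seq_len(control$max_iter)) {
    bl <- cp_blup(d, params, means)
    st <- cp_scoring_step(d, params, means, bl)

    ## step halving when a full Newton step leaves the parameter space
    step <- 1
    for (h in 0:control$max_halvings) {
      beta_try <- c(params$beta1, params$beta2, params$beta3) +
        step * st$delta
      cand <- params
      cand$beta1 <- beta_try[seq_len(q1)]
      cand$beta2 <- beta_try[q1 + seq_len(q2)]
      cand$beta3 <- beta_try[q1 + q2 + seq_len(q3)]
      means_try <- tryCatch(cp_means(d, cand), error = function(e) NULL)
      if (!is.null(means_try) &&
          all(is.finite(cp_score(d, cand, means_try,
                                 cp_blup(d, cand, means_try)))))
        break
      means_try <- NULL
      step <- step / 2
    }
    if (is.null(means_try))
      stop("scoring step diverged (non-finite estimating function after ",
           control$max_halvings, " step halvings); last coefficient ",
           "estimates: ", toString(signif(c(params$beta1, params$beta2,
                                            params$beta3), 4)))
    params <- cand
    means <- means_try
    bl <- cp_blup(d, params, means)

    if (control$update_dispersions) {
      disp <- cp_dispersions(d, params, means, bl)
      if (any(disp[c("sigma2", "tau2")] < control$floor)) floored <- TRUE
      disp <- pmax(disp, control$floor)
      ## Aitken delta-squared extrapolation of the linearly convergent
      ## moment fixed point, safeguarded to stay in the parameter space
      disp_hist <- rbind(disp_hist, disp)
      if (nrow(disp_hist) > 3L) disp_hist <- disp_hist[-1L, , drop = FALSE]
      if (control$accelerate && nrow(disp_hist) == 3L && rel < 1e-2) {
        step1 <- disp_hist[2L, ] - disp_hist[1L, ]
        step2 <- disp_hist[3L, ] - disp_hist[2L, ]
        ratio <- step2 / step1
        den <- step2 - step1
        acc <- disp_hist[3L, ] - step2^2 / den
        ## extrapolate only along genuinely contracting components
        ## (successive differences decaying geometrically with the same
        ## sign); anything else risks overshooting into a limit cycle
        ok <- is.finite(acc) & is.finite(ratio) & ratio > 0 & ratio < 0.99 &
          acc > control$floor & acc < 5 * disp & acc > disp / 5
        if (any(ok)) {
          disp[ok] <- acc[ok]
          disp_hist <- NULL
        }
      }
      params$sigma2 <- disp[["sigma2"]]
      params$tau2 <- disp[["tau2"]]
      params$rho2 <- disp[["rho2"]]
      means <- cp_means(d, params)   # weights depend on the dispersions
      bl <- cp_blup(d, params, means)
    }

    psi <- cp_score(d, params, means, bl)
    theta <- c(params$beta1, params$beta2, params$beta3,
               params$sigma2, params$tau2, params$rho2)
    if (any(!is.finite(theta)))
      stop("parameter estimates diverged at iteration ", it,
           "; last finite values: ", toString(signif(theta_old, 4)))
    rel <- max(abs(theta - theta_old) / pmax(abs(theta_old), 1e-2))
    psi_inf <- max(abs(psi))
    trace[[it]] <- c(iter = it, sigma2 = params$sigma2, tau2 = params$tau2,
                     rho2 = params$rho2, max_rel_change = rel,
                     score_inf = psi_inf, step = step)
    if (control$verbose)
      message(sprintf("iter %3d  |psi|_inf = %.3e  rel change = %.3e",
                      it, psi_inf, rel))
    theta_old <- theta
    if (rel < control$tol_param && psi_inf < control$tol_score) {
      converged <- TRUE
      break
    }
  }
  if (floored)
    warning("a dispersion update was nonpositive and was floored at ",
            control$floor, "; the corresponding variance component may be ",
            "absent from the data")
  trace <- Filter(Negate(is.null), trace)
  if (!converged)
    warning("estimation did not converge in ", control$max_iter,
            " iterations (last max relative change ",
            signif(trace[[length(trace)]][["max_rel_change"]], 3),
            "); inspect the 'trace' component")

  V <- cp_info(d, params, means)
  ch <- chol(V)
  vcov <- chol2inv(ch)
  se <- sqrt(diag(vcov))
  coefficients <- stats::setNames(
    c(params$beta1, params$beta2, params$beta3), coef_names)
  dimnames(vcov) <- list(coef_names, coef_names)
  fitted <- cp_marginal_mean(d, means)[order(d$order)]

  structure(list(
    coefficients = coefficients,
    beta = list(cluster = stats::setNames(params$beta1, colnames(d$Z1)),
                subcluster = stats::setNames(params$beta2, colnames(d$Z2)),
                observation = stats::setNames(params$beta3, colnames(d$Z3))),
    se = stats::setNames(se, coef_names),
    vcov = vcov,
    godambe = V,
    sensitivity = -V,
    dispersion = c(sigma2 = params$sigma2, tau2 = params$tau2,
                   rho2 = params$rho2),
    p = p,
    params = params,
    means = means,
    blup = cp_blup(d, params, means),
    fitted.values = fitted,
    y = d$y[order(d$order)],
    cp_data = d,
    converged = converged,
    iterations = length(trace),
    trace = as.data.frame(do.call(rbind, trace)),
    control = control
  ), class = "cpmm")
}
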