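#' @export
print.cpmm <- function(x, digits = 4, ...) {
  cat("Tweedie compound Poisson mixed model",
      if (length(x$beta$cluster) || length(x$beta$subcluster))
        "with covariate-dependent random effects" else
          "with covariate-independent random effects", "\n")
  if (!is.null(x$call)) { cat("Call: "); print(x$call) }
  d <- x$cp_data
  cat(sprintf("%d clusters, %d sub-clusters, %d observations; p = %s\n",
              d$I, d$M, d$N, format(x$p)))
  cat("\nCoefficients:\n")
  print(round(x$coefficients, digits))
  cat("\nDispersions:  sigma2 =", signif(x$dispersion[["sigma2"]], digits),
      " tau2 =", signif(x$dispersion[["tau2"]], digits),
      " rho2 =", signif(x$dispersion[["rho2"]], digits), "\n")
  if (!x$converged)
    cat("WARNING: algorithm did not converge in", x$iterations,
        "iterations\n")
  invisible(x)
}

#' Summarise a fitted compound Poisson mixed model
#'
#' Produces the usual coefficient table (estimate, standard error from the
#' inverse Godambe information, Wald z and two-sided normal p-value),
#' grouped by the level each covariate acts at, plus the estimated
#' dispersion parameters.
#'
#' @param object a fitted `cpmm` model.
#' @param ... unused.
#' @return an object of class `summary.cpmm`.
#' @export
summary.cpmm <- function(object, ...) {
  est <- object$coefficients
  se <- object$se
  z <- est / se
  pv <- 2 * stats::pnorm(-abs(z))
  tab <- cbind(Estimate = est, `Std. Error` = se, `z value` = z,
               `Pr(>|z|)` = pv)
  lev <- rep(c("cluster", "subcluster", "observation"),
             c(length(object$beta$cluster), length(object$beta$subcluster),
               length(object$beta$observation)))
  structure(list(call = object$call, coefficients = tab, level = lev,
                 dispersion = object$dispersion, p = object$p,
                 converged = object$converged,
                 iterations = object$iterations,
                 dims = c(I = object$cp_data$I, M = object$cp_data$M,
                          N = object$cp_data$N)),
            class = "summary.cpmm")
}

#' @export
print.summary.cpmm <- function(x, digits = 4, ...) {
  cat("Tweedie compound Poisson mixed model (index p =", format(x$p), ")\n")
  if (!is.null(x$call)) { cat("Call: "); print(x$call) }
  cat(sprintf("%d clusters / %d sub-clusters / %d observations\n\n",
              x$dims[["I"]], x$dims[["M"]], x$dims[["N"]]))
  for (lvl in c("observation", "subcluster", "cluster")) {
    sel <- x$level == lvl
    if (!any(sel)) next
    cat(switch(lvl, observation = "Observation level:",
               subcluster = "Sub-cluster level:",
               cluster = "Cluster level:"), "\n")
    stats::printCoefmat(x$coefficients[sel, , drop = FALSE], digits = digits,
                        signif.stars = FALSE)
    cat("\n")
  }
  cat("Dispersion parameters:\n")
  print(round(x$dispersion, digits))
  cat("\nConverged:", x$converged, "in", x$iterations, "iterations\n")
  invisible(x)
}

#' @export
coef.cpmm <- function(object, ...) object$coefficients

#' @export
vcov.cpmm <- function(object, ...) object$vcov

#' @export
fitted.cpmm <- function(object, ...) object$fitted.values

#' Residuals of a fitted compound Poisson mixed model
#'
#' @param object a fitted `cpmm` model.
#' @param type `"pearson"` standardises the marginal residual by the
#'   marginal standard deviation of \eqn{Y_{ijk}}; `"response"` is
#'   \eqn{y - \hat E(Y)}; `"conditional"` standardises
#'   \eqn{y - \hat V_{ij}\mu_{ijk}} by the conditional standard deviation
#'   given the predicted sub-cluster effect.
#' @param ... unused.
#' @export
residuals.cpmm <- function(object,
                           type = c("pearson", "response", "conditional"),
                           ...) {
  type <- match.arg(type)
  d <- object$cp_data
  mns <- object$means
  inv <- order(d$order)
  m1 <- mns$mu_i[d$obs_cluster]; m2 <- mns$mu_ij[d$obs_sub]; m3 <- mns$mu_ijk
  r <- switch(type,
    response = d$y - m1 * m2 * m3,
    pearson = (d$y - m1 * m2 * m3) /
      sqrt(object$dispersion[["sigma2"]] * m1^2 * m2^2 * m3^2 +
             object$dispersion[["tau2"]] * m1 * m2^2 * m3^2 +
             object$dispersion[["rho2"]] * m1 * m2 * m3^object$p),
    conditional = {
      Vo <- object$blup$V_hat[d$obs_sub]
      (d$y - Vo * m3) / sqrt(object$dispersion[["rho2"]] * m3^object$p * Vo)
    })
  r[inv]
}

#' Marginal mean predictions
#'
#' Returns the marginal mean \eqn{\hat E(Y) = \exp(X'\hat\beta)} for the
#' fitted data or for new rows carrying the same covariate columns.
#'
#' @param object a fitted `cpmm` model.
#' @param newdata optional data frame; if omitted, fitted values are
#'   returned.
#' @param type `"response"` (mean scale) or `"link"` (linear predictor).
#' @param ... unused.
#' @export
predict.cpmm <- function(object, newdata = NULL,
                         type = c("response", "link"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    eta <- log(object$fitted.values)
    return(if (type == "link") eta else object$fitted.values)
  }
  tt <- stats::delete.response(object$terms$obs)
  Z3 <- stats::model.matrix(tt, stats::model.frame(tt, newdata))
  eta <- unname(drop(Z3 %*% object$beta$observation))
  for (part in c("cluster", "subcluster")) {
    trm <- object$terms[[part]]
    if (is.null(trm)) next
    mm <- stats::model.matrix(trm, stats::model.frame(trm, newdata))
    mm <- mm[, colnames(mm) != "(Intercept)", drop = FALSE]
    eta <- eta + unname(drop(mm %*% object$beta[[part]]))
  }
  if (type == "link") eta else exp(eta)
}

#' Simulate responses from a fitted model
#'
#' Draws new response vectors from the fitted hierarchy at the estimated
#' parameters, conditional on the observed design (same clusters,
#' sub-clusters and covariates).  Fresh random effects are drawn for every
#' replicate.
#'
#' @param object a fitted `cpmm` model.
#' @param nsim number of replicate response vectors.
#' @param seed optional seed, handled as in [stats::simulate()].
#' @param ... unused.
#' @return a data frame with `nsim` columns, rows in the original row order.
#' @export
simulate.cpmm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  d <- object$cp_data
  mns <- object$means
  inv <- order(d$order)
  out <- lapply(seq_len(nsim), function(s) {
    h <- cp_sample_hierarchy(mns$mu_i, mns$mu_ij, mns$mu_ijk,
                             d$sub_cluster, d$obs_sub,
                             object$dispersion[["sigma2"]],
                             object$dispersion[["tau2"]],
                             object$dispersion[["rho2"]], object$p)
    h$y[inv]
  })
  stats::setNames(as.data.frame(out), paste0("sim_", seq_len(nsim)))
}

#' Diagnostic plots
#'
#' `which = 1` plots the response histogram with the exact-zero point mass
#' drawn as a separate bar (the zero spike is the hallmark of semicontinuous
#' data); `which = 2` plots conditional Pearson residuals against fitted
#' marginal means.
#'
#' @param x a fitted `cpmm` model.
#' @param which which plot.
#' @param ... passed to the underlying plotting functions.
#' @export
plot.cpmm <- function(x, which = 1L, ...) {
  if (which == 1L) {
    y <- x$y
    pos <- y[y > 0]
    h <- graphics::hist(pos, plot = FALSE)
    ylim <- c(0, max(h$counts, sum(y == 0)))
    graphics::hist(pos, ylim = ylim, xlim = c(0, max(y)),
                   main = "Response distribution", xlab = "response", ...)
    graphics::rect(0, 0, diff(h$breaks[1:2]) / 4, sum(y == 0),
                   col = "grey30")
    graphics::legend("topright", legend = sprintf("exact zeros: %.1f%%",
                                                  100 * mean(y == 0)),
                     bty = "n")
  } else {
    graphics::plot(fitted(x), residuals(x, type = "conditional"),
                   xlab = "fitted marginal mean",
                   ylab = "conditional Pearson residual", ...)
    graphics::abline(h = 0, lty = 2)
  }
  invisible(x)
}
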