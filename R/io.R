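#' Read a long-format multilevel dataset
#'
#' Reads a comma-separated file (UTF-8, `.` decimal separator) with one row
#' per observation.  Required columns: `cluster`, `subcluster`, `y`;
#' remaining columns are covariates.  Identifiers are kept as opaque
#' strings.
#'
#' @param path path to the CSV file.
#' @return a data frame.
#' @export
read_cpmm_data <- function(path) {
  if (!file.exists(path)) stop("data file not found: ", path)
  hdr <- names(utils::read.csv(path, nrows = 1L))
  need <- c("cluster", "subcluster", "y")
  miss <- setdiff(need, hdr)
  if (length(miss)) stop("missing required column(s): ", toString(miss))
  id_classes <- stats::setNames(rep("character", 2L),
                                c("cluster", "subcluster"))
  dat <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = id_classes)
  if (!is.numeric(dat$y)) {
    bad <- which(is.na(suppressWarnings(as.numeric(dat$y))))
    stop("unparseable response values in column 'y', row(s) ",
         toString(utils::head(bad, 5L)))
  }
  if (anyNA(dat$y))
    stop("missing response values in column 'y', row(s) ",
         toString(utils::head(which(is.na(dat$y)), 5L)))
  for (nm in setdiff(names(dat), need))
    if (!is.numeric(dat[[nm]]) && !is.character(dat[[nm]]))
      stop("column '", nm, "' has unsupported type ", class(dat[[nm]])[1L])
  dat
}

#' Read a model configuration
#'
#' A configuration file (YAML or JSON, chosen by extension) with fields
#' `levels` (a map from covariate name to `cluster`, `subcluster` or
#' `observation`) and `p` (Tweedie index in (1, 2)); optional fields
#' `max_iter`, `tol_param`, `tol_score` override [cpmm_control()] defaults.
#'
#' @param path path to the configuration file.
#' @return a list with `level_map`, `p` and `control`.
#' @export
read_cpmm_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (is.null(cfg$levels) || !length(cfg$levels))
    stop("config must declare a 'levels' map")
  level_map <- unlist(cfg$levels)
  bad <- setdiff(level_map, c("cluster", "subcluster", "observation"))
  if (length(bad)) stop("unknown level(s) in config: ", toString(bad))
  p <- cfg$p
  if (is.null(p)) stop("config must fix the Tweedie index 'p'")
  if (!(p > 1 && p < 2)) stop("config 'p' must lie strictly in (1, 2)")
  ctrl_args <- cfg[intersect(names(cfg),
                             c("max_iter", "tol_param", "tol_score"))]
  list(level_map = level_map, p = p,
       control = do.call(cpmm_control, ctrl_args))
}

## formulas implied by a level map
level_map_formulas <- function(level_map) {
  at <- function(lvl) names(level_map)[level_map == lvl]
  obs <- at("observation"); clu <- at("cluster"); sub <- at("subcluster")
  list(formula = stats::reformulate(if (length(obs)) obs else "1",
                                    response = "y"),
       cluster_formula = if (length(clu)) stats::reformulate(clu),
       subcluster_formula = if (length(sub)) stats::reformulate(sub))
}

#' Fit a model from a data file and configuration
#'
#' File-based front end to [cpmm()]: reads a long-format CSV and a
#' configuration assigning each covariate to its level, and fits the model.
#'
#' @param data_path path to the data CSV (see [read_cpmm_data()]).
#' @param config_path path to the configuration (see [read_cpmm_config()]).
#' @param p optional override of the configured index parameter.
#' @return a fitted `cpmm` object.
#' @export
cpmm_fit_files <- function(data_path, config_path, p = NULL) {
  dat <- read_cpmm_data(data_path)
  cfg <- read_cpmm_config(config_path)
  missing_cov <- setdiff(names(cfg$level_map), names(dat))
  if (length(missing_cov))
    stop("covariate(s) in config but not in data: ", toString(missing_cov))
  f <- level_map_formulas(cfg$level_map)
  cpmm(f$formula, dat, cluster = "cluster", subcluster = "subcluster",
       cluster_formula = f$cluster_formula,
       subcluster_formula = f$subcluster_formula,
       p = if (is.null(p)) cfg$p else p, control = cfg$control)
}

#' Write fitted results
#'
#' Writes a machine-readable JSON report (coefficients grouped by level with
#' estimates, standard errors and two-sided normal p-values, the dispersion
#' parameters, and convergence information) and, optionally, an aligned
#' plain-text table next to it.
#'
#' @param fit a fitted `cpmm` model.
#' @param path output path for the JSON report.
#' @param text_path optional output path for the human-readable table.
#' @return invisibly, the report list.
#' @export
write_cpmm_results <- function(fit, path, text_path = NULL) {
  s <- summary(fit)
  tab <- s$coefficients
  by_level <- lapply(c(observation = "observation", subcluster = "subcluster",
                       cluster = "cluster"), function(lvl) {
    sel <- s$level == lvl
    if (!any(sel)) return(list())
    lapply(which(sel), function(i) list(
      name = rownames(tab)[i],
      estimate = unname(tab[i, "Estimate"]),
      std_error = unname(tab[i, "Std. Error"]),
      p_value = unname(tab[i, "Pr(>|z|)"])))
  })
  report <- list(
    model = if (length(fit$beta$cluster) || length(fit$beta$subcluster))
      "covariate-dependent" else "covariate-independent",
    p_index = fit$p,
    n = list(clusters = unname(s$dims[["I"]]),
             subclusters = unname(s$dims[["M"]]),
             observations = unname(s$dims[["N"]])),
    coefficients = by_level,
    dispersion = as.list(fit$dispersion),
    convergence = list(converged = fit$converged,
                       iterations = fit$iterations))
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  if (!is.null(text_path)) {
    txt <- utils::capture.output(print(s))
    writeLines(txt, text_path)
  }
  invisible(report)
}

#' Write the BLUP table
#'
#' One row per sub-cluster: identifiers, predicted random effects and their
#' prediction mean-squared errors (see [blup()]).
#'
#' @param fit a fitted `cpmm` model.
#' @param path output CSV path.
#' @export
write_cpmm_blup <- function(fit, path) {
  utils::write.csv(blup(fit), path, row.names = FALSE)
  invisible(path)
}

## minimal structural validation of a results file against the shipped
## field/type schema (inst/schema/cpmm-results-schema.json)
check_results_file <- function(path) {
  schema <- jsonlite::fromJSON(system.file("schema",
                                           "cpmm-results-schema.json",
                                           package = "cpmixed"),
                               simplifyVector = FALSE)
  rep <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  miss <- setdiff(unlist(schema$required), names(rep))
  if (length(miss)) stop("results file missing field(s): ", toString(miss))
  for (fld in names(schema$types)) {
    want <- schema$types[[fld]]
    ok <- switch(want,
                 number = is.numeric(rep[[fld]]),
                 object = is.list(rep[[fld]]),
                 string = is.character(rep[[fld]]))
    if (!isTRUE(ok))
      stop("results field '", fld, "' should be of type ", want)
  }
  invisible(TRUE)
}
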