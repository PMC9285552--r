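#' Linear prediction-equation specification
#'
#' A lightweight container for a fitted (or published) linear predictor of
#' daily CH4 emission or of the methane conversion factor. Covariate keys are
#' restricted to the panel variables: \code{LW} (kg), \code{DMI} (kg/day),
#' \code{ECM} (kg/day) and \code{CH4CO2} (breath ratio, L/L).
#'
#' @param name Short label, e.g. "eq2".
#' @param response One of \code{"CH4_L_per_day"}, \code{"MCF_J_per_100J"}.
#' @param intercept Intercept, response units.
#' @param coefficients Named numeric vector/list of slopes.
#' @param coefficient_se Named numeric vector/list of slope standard errors
#'   (optional, same names).
#' @param intercept_se Standard error of the intercept (optional).
#' @param adj_r2 Adjusted R-squared of the fit.
#' @param rmse Root mean square error, response units.
#' @return An object of class \code{equation_spec}.
#' @export
equation_spec <- function(name, response, intercept, coefficients,
                          coefficient_se = NULL, intercept_se = NA_real_,
                          adj_r2 = NA_real_, rmse = NA_real_) {
  response <- match.arg(response, c("CH4_L_per_day", "MCF_J_per_100J"))
  coefficients <- unlist(coefficients)
  allowed <- c("LW", "DMI", "ECM", "CH4CO2")
  bad <- setdiff(names(coefficients), allowed)
  if (length(bad)) {
    stop("unknown covariate key(s): ", paste(bad, collapse = ", "))
  }
  if (!is.null(coefficient_se)) {
    coefficient_se <- unlist(coefficient_se)[names(coefficients)]
  }
  # estimated fits on pure noise can have adj_r2 <= 0; only > 1 is impossible
  if (!is.na(adj_r2) && adj_r2 > 1) {
    stop("adj_r2 cannot exceed 1")
  }
  if (!is.na(rmse) && rmse <= 0) stop("rmse must be positive")
  structure(
    list(name = name, response = response,
         intercept = as.numeric(intercept),
         coefficients = coefficients,
         coefficient_se = coefficient_se,
         intercept_se = as.numeric(intercept_se),
         adj_r2 = as.numeric(adj_r2), rmse = as.numeric(rmse)),
    class = "equation_spec"
  )
}

#' @export
print.equation_spec <- function(x, ...) {
  terms <- paste0(
    sprintf("%+.4g ", x$coefficients), names(x$coefficients),
    collapse = " "
  )
  cat(sprintf("<equation_spec %s> %s = %.4g %s\n", x$name,
              x$response, x$intercept, terms))
  cat(sprintf("  adj R2 = %.3f, RMSE = %.3g\n", x$adj_r2, x$rmse))
  invisible(x)
}

#' Evaluate a prediction equation at covariate values
#'
#' @param spec An [equation_spec()].
#' @param covariates Named list or vector supplying every covariate the
#'   equation uses (extra entries are ignored). Values may be vectors of a
#'   common length.
#' @return Predicted response (vectorized over covariate vectors).
#' @examples
#' eqs <- load_equation_bundle()
#' evaluate_equation(eqs$eq7, list(DMI = 16.7))
#' @export
evaluate_equation <- function(spec, covariates) {
  stopifnot(inherits(spec, "equation_spec"))
  covariates <- lapply(as.list(covariates), as.numeric)
  missing <- setdiff(names(spec$coefficients), names(covariates))
  if (length(missing)) {
    stop("missing covariate(s): ", paste(missing, collapse = ", "))
  }
  out <- spec$intercept
  for (key in names(spec$coefficients)) {
    out <- out + spec$coefficients[[key]] * covariates[[key]]
  }
  unname(out)
}

#' Load a bundle of equation specifications from YAML
#'
#' With no argument, loads the package's published equation set: twelve
#' linear predictors (eq1-eq7 for daily CH4 in L/day, eq8-eq12 for MCF in
#' J/100 J GEI) developed on a 121-cow indirect-calorimetry panel.
#'
#' @param path YAML file in the dialect written by [write_equation_bundle()].
#' @return Named list of [equation_spec()] objects.
#' @export
load_equation_bundle <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "table2_equations.yaml",
                        package = "snifferch4", mustWork = TRUE)
  }
  raw <- yaml::read_yaml(path)
  specs <- lapply(raw$equations, function(e) {
    equation_spec(
      name = e$name, response = e$response, intercept = e$intercept,
      coefficients = e$coefficients, coefficient_se = e$coefficient_se,
      intercept_se = if (is.null(e$intercept_se)) NA_real_ else e$intercept_se,
      adj_r2 = if (is.null(e$adj_r2)) NA_real_ else e$adj_r2,
      rmse = if (is.null(e$rmse)) NA_real_ else e$rmse
    )
  })
  names(specs) <- vapply(specs, `[[`, "", "name")
  specs
}

#' Write a bundle of equation specifications to YAML
#'
#' Round-trippable with [load_equation_bundle()], so refitted equations can be
#' consumed wherever the published set is.
#'
#' @param specs List of [equation_spec()] objects.
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
write_equation_bundle <- function(specs, path) {
  as_plain <- function(s) {
    out <- list(
      name = s$name, response = s$response, intercept = s$intercept,
      coefficients = as.list(s$coefficients)
    )
    if (!is.null(s$coefficient_se)) {
      out$coefficient_se <- as.list(s$coefficient_se)
    }
    if (!is.na(s$intercept_se)) out$intercept_se <- s$intercept_se
    if (!is.na(s$adj_r2)) out$adj_r2 <- s$adj_r2
    if (!is.na(s$rmse)) out$rmse <- s$rmse
    out
  }
  yaml::write_yaml(list(equations = lapply(unname(specs), as_plain)), path)
  invisible(path)
}
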