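#' Develop a prediction equation by ordinary least squares
#'
#' Fits \code{response ~ covariates} by OLS on a cow panel and reports the
#' statistics the equation tables carry: coefficient standard errors,
#' adjusted R-squared, RMSE = sqrt(SSE / (n - p - 1)) (the regression's
#' root mean square error, not sqrt(SSE/n)), and variance inflation factors
#' computed as \code{1 / (1 - R2_j)} from regressing each covariate on the
#' others.
#'
#' @param data Cow panel with columns among \code{LW}, \code{DMI}, \code{ECM},
#'   \code{CH4CO2} plus the response column (\code{CH4} in L/day or
#'   \code{MCF} in J/100 J).
#' @param response \code{"CH4_L_per_day"} or \code{"MCF_J_per_100J"}.
#' @param covariates Character vector of covariate names.
#' @param name Label for the resulting [equation_spec()].
#' @return List of class \code{equation_fit}: \code{spec} (an
#'   [equation_spec()] with the estimates), \code{n}, \code{adj_r2},
#'   \code{rmse}, \code{vif} (named), \code{residuals}, \code{model}.
#' @export
fit_equation <- function(data, response = c("CH4_L_per_day",
                         "MCF_J_per_100J"), covariates, name = "fit") {
  response <- match.arg(response)
  ycol <- if (response == "CH4_L_per_day") "CH4" else "MCF"
  if (!ycol %in% names(data)) {
    stop("panel has no '", ycol, "' response column")
  }
  missing <- setdiff(covariates, names(data))
  if (length(missing)) {
    stop("panel lacks covariate(s): ", paste(missing, collapse = ", "))
  }
  used <- data[, c(ycol, covariates), drop = FALSE]
  if (anyNA(used)) stop("missing values in used columns")
  n <- nrow(used)
  p <- length(covariates)
  if (n <= p + 1) stop("need n > p + 1 observations")

  fml <- stats::as.formula(
    paste(ycol, "~", paste(covariates, collapse = " + ")))
  fit <- stats::lm(fml, data = used)
  if (anyNA(stats::coef(fit)) || fit$rank < p + 1) {
    stop("collinear (rank-deficient) design: ",
         paste(covariates, collapse = ", "))
  }
  sm <- summary(fit)
  coefs <- stats::coef(sm)

  vif <- vapply(covariates, function(j) {
    if (p == 1) return(1)
    r2j <- summary(stats::lm(
      stats::as.formula(paste(j, "~", paste(setdiff(covariates, j),
                                            collapse = " + "))),
      data = used))$r.squared
    1 / (1 - r2j)
  }, numeric(1))

  rmse <- sqrt(sum(stats::residuals(fit)^2) / (n - p - 1))
  spec <- equation_spec(
    name = name, response = response,
    intercept = coefs["(Intercept)", "Estimate"],
    coefficients = coefs[covariates, "Estimate"],
    coefficient_se = coefs[covariates, "Std. Error"],
    intercept_se = coefs["(Intercept)", "Std. Error"],
    adj_r2 = sm$adj.r.squared, rmse = rmse
  )
  structure(
    list(spec = spec, n = n, adj_r2 = sm$adj.r.squared, rmse = rmse,
         vif = vif, residuals = unname(stats::residuals(fit)), model = fit),
    class = "equation_fit"
  )
}

#' @export
print.equation_fit <- function(x, ...) {
  print(x$spec)
  cat(sprintf("  n = %d; max VIF = %.2f\n", x$n, max(x$vif)))
  invisible(x)
}

#' Linear mixed model for the time-after-eating effect
#'
#' Fits, by REML, the repeated-measures model for a per-visit response
#' (CH4/CO2 ratio by default): fixed effects of time after eating, diet,
#' and their interaction (diet reference level HF), random intercepts for
#' Latin square and cow within square. The residual covariance structure is
#' either independent or compound-symmetric within cow-period (an extra
#' random intercept per cow-period); \code{"auto"} picks the lower-AIC
#' structure on ML fits and refits the winner by REML.
#'
#' @param visits Visit-summary data frame: the response column, plus
#'   \code{time_after_eating} (h), \code{diet}, \code{square}, \code{cow_id}.
#' @param response One of \code{"ratio"}, \code{"ch4_corr"},
#'   \code{"co2_corr"}, \code{"eructation_rate"}.
#' @param cov_structure \code{"auto"}, \code{"independent"} or \code{"cs"}.
#' @param reference Diet reference level.
#' @param random_effects Set FALSE to fix all variance components at zero,
#'   reducing the model to fixed-effects OLS with the same term layout.
#' @return List of class \code{mixed_fit}: \code{fixed} (term, coefficient,
#'   SE, p, reference flag; reference-level rows are structural zeros),
#'   \code{varcomp} (square, cow-within-square, residual variances),
#'   \code{structure}, \code{singular} boundary flag, \code{diet_levels},
#'   and the underlying \code{model}.
#' @export
fit_time_model <- function(visits,
                           response = c("ratio", "ch4_corr", "co2_corr",
                                        "eructation_rate"),
                           cov_structure = c("auto", "independent", "cs"),
                           reference = "HF", random_effects = TRUE) {
  response <- match.arg(response)
  cov_structure <- match.arg(cov_structure)
  ycol <- switch(response, ratio = "ratio", ch4_corr = "mean_ch4_corr",
                 co2_corr = "mean_co2_corr",
                 eructation_rate = "eructation_rate")
  if (!ycol %in% names(visits)) stop("visits has no '", ycol, "' column")

  d <- data.frame(
    y = visits[[ycol]],
    time = visits$time_after_eating,
    diet = as.character(visits$diet),
    square = factor(visits$square),
    cow = factor(visits$cow_id)
  )
  d <- d[stats::complete.cases(d), ]
  levs <- unique(d$diet)
  d$diet <- factor(d$diet,
                   levels = c(intersect(reference, levs),
                              sort(setdiff(levs, reference))))

  multi_diet <- nlevels(d$diet) > 1
  fixed_rhs <- if (multi_diet) "time * diet" else "time"

  if (!random_effects) {
    # variance components fixed at zero: plain OLS with the same terms
    ols <- stats::lm(stats::as.formula(paste("y ~", fixed_rhs)), data = d)
    ct <- stats::coef(summary(ols))
    fixed <- data.frame(
      term = sub("^\\(Intercept\\)$", "intercept", rownames(ct)),
      coefficient = ct[, "Estimate"], se = ct[, "Std. Error"],
      p = ct[, "Pr(>|t|)"], reference = FALSE,
      row.names = NULL, stringsAsFactors = FALSE)
    if (multi_diet) {
      ref <- levels(d$diet)[1]
      fixed <- rbind(fixed, data.frame(
        term = c(paste0("time:diet", ref), paste0("diet", ref)),
        coefficient = 0, se = NA_real_, p = NA_real_, reference = TRUE,
        stringsAsFactors = FALSE))
    }
    return(structure(
      list(fixed = fixed,
           varcomp = data.frame(component = "residual",
                                variance = summary(ols)$sigma^2,
                                sd = summary(ols)$sigma,
                                stringsAsFactors = FALSE),
           structure = "independent", singular = FALSE,
           diet_levels = levels(d$diet), response = response,
           n = nrow(d), model = ols),
      class = "mixed_fit"))
  }

  fml <- stats::as.formula(paste(
    "y ~", fixed_rhs, "+ (1 | square) + (1 | square:cow)"))
  fml_cs <- stats::as.formula(paste(
    "y ~", fixed_rhs,
    "+ (1 | square) + (1 | square:cow) + (1 | square:cow:diet)"))

  fit_one <- function(f, reml) {
    suppressMessages(suppressWarnings(
      lmerTest::lmer(f, data = d, REML = reml)))
  }
  structure_used <- cov_structure
  if (cov_structure == "auto") {
    aic_ind <- stats::AIC(fit_one(fml, reml = FALSE))
    aic_cs <- tryCatch(stats::AIC(fit_one(fml_cs, reml = FALSE)),
                       error = function(e) Inf)
    structure_used <- if (aic_cs < aic_ind) "cs" else "independent"
  }
  model <- fit_one(if (structure_used == "cs") fml_cs else fml, reml = TRUE)

  sm <- suppressMessages(summary(model))
  ct <- stats::coef(sm)
  term_map <- function(nm) {
    nm <- sub("^\\(Intercept\\)$", "intercept", nm)
    nm
  }
  fixed <- data.frame(
    term = term_map(rownames(ct)),
    coefficient = ct[, "Estimate"],
    se = ct[, "Std. Error"],
    p = ct[, "Pr(>|t|)"],
    reference = FALSE,
    row.names = NULL, stringsAsFactors = FALSE
  )
  if (multi_diet) {
    ref <- levels(d$diet)[1]
    ref_rows <- data.frame(
      term = c(paste0("time:diet", ref), paste0("diet", ref)),
      coefficient = 0, se = NA_real_, p = NA_real_, reference = TRUE,
      stringsAsFactors = FALSE)
    fixed <- rbind(fixed, ref_rows)
  }

  vc <- as.data.frame(lme4::VarCorr(model))
  comp_name <- function(g) switch(g, square = "square",
                                  `square:cow` = "cow_within_square",
                                  `square:cow:diet` = "cow_period",
                                  Residual = "residual", g)
  varcomp <- data.frame(
    component = vapply(vc$grp, comp_name, ""),
    variance = vc$vcov, sd = vc$sdcor, stringsAsFactors = FALSE)

  structure(
    list(fixed = fixed, varcomp = varcomp, structure = structure_used,
         singular = lme4::isSingular(model),
         diet_levels = levels(d$diet), response = response,
         n = nrow(d), model = model),
    class = "mixed_fit"
  )
}

#' @export
print.mixed_fit <- function(x, ...) {
  cat(sprintf("Mixed model for %s (n = %d visits, %s residual structure%s)\n",
              x$response, x$n, x$structure,
              if (x$singular) ", boundary fit" else ""))
  print(x$fixed, digits = 4)
  cat("Variance components:\n")
  print(x$varcomp, digits = 4)
  invisible(x)
}

#' Regression through the origin
#'
#' Least-squares line with no intercept: slope = sum(xy) / sum(x^2). The
#' reported adjusted R-squared and RMSE follow the no-intercept convention
#' (total sum of squares about zero, n - 1 residual degrees of freedom).
#'
#' @param x Predictor (observed values in a predicted-vs-observed plot).
#' @param y Response (predicted values).
#' @return List of class \code{origin_regression}: \code{slope},
#'   \code{adj_r2}, \code{rmse}, \code{n}.
#' @export
regress_through_origin <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  sxx <- sum(x^2)
  if (sxx == 0) stop("all-zero x: through-origin slope undefined")
  slope <- sum(x * y) / sxx
  n <- length(x)
  res <- y - slope * x
  sse <- sum(res^2)
  r2 <- if (sum(y^2) > 0) 1 - sse / sum(y^2) else NA_real_
  adj_r2 <- if (n > 1) 1 - (1 - r2) * n / (n - 1) else NA_real_
  rmse <- if (n > 1) sqrt(sse / (n - 1)) else NA_real_
  structure(list(slope = slope, adj_r2 = adj_r2, rmse = rmse, n = n),
            class = "origin_regression")
}

#' @export
print.origin_regression <- function(x, ...) {
  cat(sprintf("Y = %.3gX (adj R2 = %.3f, RMSE = %.3g, n = %d)\n",
              x$slope, x$adj_r2, x$rmse, x$n))
  invisible(x)
}

#' Residual-versus-days-in-milk diagnostic
#'
#' Regresses prediction residuals (observed - predicted) on days in milk and
#' attaches a pointwise 95% prediction band; a systematic slope or points
#' outside the band indicate lactation-stage bias (e.g. overestimation of
#' CO2 output in early lactation when body fat is mobilized).
#'
#' @param observed,predicted Emission vectors, same length.
#' @param dim Days in milk, same length.
#' @param level Prediction-band coverage.
#' @return List: \code{slope}, \code{intercept}, \code{adj_r2}, \code{rmse},
#'   \code{p_slope}, \code{band} (data frame with dim, residual, fit, lwr,
#'   upr, outside), \code{n_outside}.
#' @export
residual_dim_diagnostic <- function(observed, predicted, dim, level = 0.95) {
  n <- length(observed)
  if (length(predicted) != n || length(dim) != n) {
    stop("observed, predicted and dim must have equal length")
  }
  if (n <= 3) stop("need more than 3 observations")
  d <- data.frame(residual = observed - predicted, dim = dim)
  fit <- stats::lm(residual ~ dim, data = d)
  sm <- summary(fit)
  pred <- stats::predict(fit, newdata = d, interval = "prediction",
                         level = level)
  band <- cbind(d, as.data.frame(pred))
  band$outside <- band$residual < band$lwr | band$residual > band$upr
  list(
    slope = unname(stats::coef(fit)["dim"]),
    intercept = unname(stats::coef(fit)["(Intercept)"]),
    adj_r2 = sm$adj.r.squared, rmse = sm$sigma,
    p_slope = stats::coef(sm)["dim", "Pr(>|t|)"],
    band = band, n_outside = sum(band$outside)
  )
}

#' Compare prediction methods against observed emissions
#'
#' For each method label, regresses predicted on observed through the origin
#' and tabulates slope, adjusted R-squared and RMSE — the summary behind
#' predicted-versus-observed evaluation plots.
#'
#' @param observed Observed emissions.
#' @param predicted Predicted emissions, aligned with \code{observed}.
#' @param labels Method label per element (recycled if length 1); NULL for a
#'   single unnamed method.
#' @return Data frame: method, slope, adj_r2, rmse, n.
#' @export
evaluate_predictions <- function(observed, predicted, labels = NULL) {
  if (length(observed) != length(predicted)) {
    stop("observed and predicted lengths differ")
  }
  if (is.null(labels)) labels <- "all"
  labels <- rep_len(as.character(labels), length(observed))
  out <- lapply(unique(labels), function(lab) {
    i <- labels == lab
    r <- regress_through_origin(observed[i], predicted[i])
    data.frame(method = lab, slope = r$slope, adj_r2 = r$adj_r2,
               rmse = r$rmse, n = r$n, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
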