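test_that("OLS equation development agrees with the normal-equations oracle", {
  set.seed(14)
  for (i in 1:20) {
    n <- sample(8:20, 1)
    p <- sample(1:3, 1)
    covs <- c("LW", "DMI", "ECM")[seq_len(p)]
    d <- as.data.frame(matrix(rnorm(n * p, 50, 10), n,
                              dimnames = list(NULL, covs)))
    d$CH4 <- rnorm(n, 400, 60)
    fit <- fit_equation(d, "CH4_L_per_day", covs)
    beta <- ols_oracle(cbind(1, as.matrix(d[covs])), d$CH4)
    est <- c(fit$spec$intercept, unname(fit$spec$coefficients))
    expect_lt(max(abs(est - beta) / pmax(abs(beta), 1e-8)), 1e-8)
    # rmse ties to the residuals by definition
    expect_equal(fit$rmse^2 * (n - p - 1), sum(fit$residuals^2))
    expect_true(all(fit$vif >= 1))
  }
})

test_that("noise-free panels refit exactly; collinear designs are rejected", {
  eqs <- load_equation_bundle()
  panel <- gen_cow_panel(panel_config(n = 60, noise_sd = 0, seed = 101))
  # lm warns about the (intentionally) perfect fit
  fit <- suppressWarnings(
    fit_equation(panel, "CH4_L_per_day", c("LW", "ECM", "CH4CO2")))
  expect_equal(max(abs(fit$residuals)), 0, tolerance = 1e-8)
  expect_equal(fit$adj_r2, 1, tolerance = 1e-12)
  expect_equal(unname(fit$spec$coefficients),
               unname(eqs$eq2$coefficients), tolerance = 1e-6)
  # perfectly collinear covariates
  bad <- panel
  bad$DMI <- 2 * bad$ECM
  expect_error(fit_equation(bad, "CH4_L_per_day", c("DMI", "ECM")),
               "collinear")
  expect_error(fit_equation(panel[1:3, ], "CH4_L_per_day",
                            c("LW", "ECM", "CH4CO2")), "n > p")
})

test_that("VIF is exactly 1 for orthogonal covariates and matches car::vif", {
  # orthogonal design: contrasts of a balanced factorial
  d <- expand.grid(LW = c(-1, 1), DMI = c(-1, 1), ECM = c(-1, 1))
  d <- d[rep(1:8, 3), ]
  set.seed(2)
  d$CH4 <- rnorm(24)
  fit <- fit_equation(d, "CH4_L_per_day", c("LW", "DMI", "ECM"))
  expect_equal(unname(fit$vif), c(1, 1, 1))
  # correlated design: agree with the standard implementation
  panel <- gen_cow_panel(panel_config(n = 121, seed = 8))
  f2 <- fit_equation(panel, "CH4_L_per_day", c("LW", "DMI", "ECM"))
  expect_equal(unname(f2$vif), unname(car::vif(f2$model)), tolerance = 1e-10)
})

test_that("the time-after-eating mixed model recovers generating coefficients", {
  visits <- gen_visit_table(seed = 424)
  fit <- fit_time_model(visits, "ratio")
  fx <- fit$fixed
  get <- function(term, col = "coefficient") fx[[col]][fx$term == term]
  expect_lt(abs(get("time") - (-0.0034)), 2 * get("time", "se"))
  expect_lt(abs(get("dietLF") - (-0.026)), 2 * get("dietLF", "se"))
  expect_lt(abs(get("dietMF") - (-0.016)), 2 * get("dietMF", "se"))
  # reference-level rows are structural zeros
  expect_equal(get("dietHF"), 0)
  expect_equal(get("time:dietHF"), 0)
  expect_true(fx$reference[fx$term == "dietHF"])
  # variance components are labelled and non-negative
  expect_setequal(
    setdiff(fit$varcomp$component, "cow_period"),
    c("square", "cow_within_square", "residual"))
  expect_true(all(fit$varcomp$variance >= 0))
})

test_that("zero-noise visits give exact recovery; zero random effects match OLS", {
  visits <- gen_visit_table(visits_per_cow_diet = 8, square_sd = 0,
                            cow_sd = 0, resid_sd = 1e-8, seed = 5)
  fit <- fit_time_model(visits, "ratio", cov_structure = "independent")
  fx <- fit$fixed
  expect_equal(fx$coefficient[fx$term == "time"], -0.0034,
               tolerance = 1e-4)
  expect_equal(fx$coefficient[fx$term == "dietLF"], -0.026,
               tolerance = 1e-4)
  # with no true random effects the REML fit hits the boundary and the
  # fixed effects coincide with the dummy-variable OLS oracle
  visits2 <- gen_visit_table(visits_per_cow_diet = 20, square_sd = 0,
                             cow_sd = 0, resid_sd = 0.005, seed = 6)
  fit2 <- fit_time_model(visits2, "ratio", cov_structure = "independent")
  d <- data.frame(y = visits2$ratio, time = visits2$time_after_eating,
                  diet = factor(visits2$diet,
                                levels = c("HF", "LF", "MF")))
  ols <- stats::coef(stats::lm(y ~ time * diet, data = d))
  fx2 <- fit2$fixed
  expect_true(fit2$singular)
  expect_equal(fx2$coefficient[fx2$term == "time"], unname(ols["time"]),
               tolerance = 1e-6)
  expect_equal(fx2$coefficient[fx2$term == "dietLF"],
               unname(ols["dietLF"]), tolerance = 1e-6)
})

test_that("a single diet level degrades to the time-only model", {
  visits <- gen_visit_table(diets = "HF",
                            diet_offsets = c(HF = 0),
                            interaction = c(HF = 0),
                            visits_per_cow_diet = 30, seed = 9)
  fit <- fit_time_model(visits, "ratio")
  expect_setequal(fit$fixed$term, c("intercept", "time"))
  expect_lt(abs(fit$fixed$coefficient[fit$fixed$term == "time"] -
                  (-0.0034)),
            2 * fit$fixed$se[fit$fixed$term == "time"])
})

test_that("through-origin regression matches its closed form", {
  r <- regress_through_origin(c(1, 2), c(2, 4))
  expect_equal(r$slope, 2)
  expect_equal(r$rmse, 0)
  # orthogonal x and y
  expect_equal(regress_through_origin(c(1, -1), c(1, 1))$slope, 0)
  expect_error(regress_through_origin(c(0, 0), c(1, 2)), "all-zero")
  # closed form = lm(y ~ x - 1) on random data, including adj R2 and RMSE
  set.seed(31)
  x <- runif(200, 1, 10)
  y <- 0.81 * x + rnorm(200, 0, 0.5)
  r2 <- regress_through_origin(x, y)
  lmfit <- summary(stats::lm(y ~ x - 1))
  expect_equal(r2$slope, unname(stats::coef(lmfit)[1, 1]))
  expect_equal(r2$adj_r2, lmfit$adj.r.squared)
  expect_equal(r2$rmse, lmfit$sigma)
  # Monte-Carlo oracle: slope near the generating attenuation
  set.seed(32)
  x3 <- runif(1000, 5, 15)
  y3 <- 0.81 * x3 + rnorm(1000, 0, 0.8)
  expect_lt(abs(regress_through_origin(x3, y3)$slope - 0.81), 0.02)
})

test_that("residual-vs-DIM diagnostic flags lactation-stage bias", {
  dim <- seq(10, 300, length.out = 60)
  # identically zero residuals: flat line, empty outside-band set
  z <- residual_dim_diagnostic(rep(500, 60), rep(500, 60), dim)
  expect_equal(z$slope, 0)
  expect_equal(z$n_outside, 0)
  # early-lactation overestimation (negative residuals before DIM 60)
  set.seed(44)
  obs <- rep(500, 60)
  pred <- obs + ifelse(dim < 60, 80, 0) + rnorm(60, 0, 10)
  d2 <- residual_dim_diagnostic(obs, pred, dim)
  expect_gt(d2$slope, 0)
  expect_error(residual_dim_diagnostic(1:3, 1:3, 1:3), "more than 3")
  # prediction-band coverage on Gaussian residuals is about 95%
  set.seed(45)
  n <- 4000
  dimv <- runif(n, 0, 300)
  res <- rnorm(n, 0, 50)
  cov95 <- 1 - residual_dim_diagnostic(res, rep(0, n), dimv)$n_outside / n
  expect_gt(cov95, 0.93)
  expect_lt(cov95, 0.97)
})

test_that("prediction evaluation tabulates per-method through-origin fits", {
  obs <- c(500, 600, 700, 800)
  tab <- evaluate_predictions(c(obs, obs), c(obs, 0.9 * obs),
                              labels = rep(c("identity", "scaled"), each = 4))
  expect_equal(tab$slope[tab$method == "identity"], 1)
  expect_equal(tab$rmse[tab$method == "identity"], 0)
  expect_equal(tab$slope[tab$method == "scaled"], 0.9)
  expect_error(evaluate_predictions(1:3, 1:4), "lengths differ")
})
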