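#' Configuration for the synthetic cow panel
#'
#' Defaults reproduce the statistical structure of the model-development
#' panel: n = 121 lactating Holsteins measured by indirect calorimetry, with
#' DMI 16.7 +/- 3.68 kg/day, ECM 27.4 +/- 6.78 kg/day, breath CH4/CO2 ratio
#' 0.088 +/- 0.0119, days in milk 147 +/- 69.1, and covariate correlations
#' r(LW,DMI) = 0.51, r(LW,ECM) = 0.32, r(DMI,ECM) = 0.80. Live weight
#' (not printed for the panel) defaults to Normal(650, 50) truncated to
#' [400, 900] kg, consistent with the feeding-trial cows; the ratio's
#' correlations with the other covariates default to 0.
#'
#' @param n Panel size.
#' @param means,sds Named numeric vectors over LW, DMI, ECM, CH4CO2.
#' @param r_lw_dmi,r_lw_ecm,r_dmi_ecm,r_lw_ratio,r_dmi_ratio,r_ecm_ratio
#'   Pairwise correlations.
#' @param dim_mean,dim_sd Days-in-milk distribution (truncated at 0).
#' @param lw_bounds Truncation bounds for live weight, kg.
#' @param gei_per_dmi Gross energy density of the diet, MJ/kg DM (sets GEI =
#'   DMI x this; typical rations run ~18.5).
#' @param true_equation [equation_spec()] generating CH4 from the covariates;
#'   defaults to the bundled eq2.
#' @param noise_sd Residual SD of CH4 about the equation surface, L/day
#'   (eq2's published RMSE, 40.8).
#' @param seed Seed (NULL = leave RNG state alone).
#' @return List of class \code{panel_config}.
#' @export
panel_config <- function(n = 121,
                         means = c(LW = 650, DMI = 16.7, ECM = 27.4,
                                   CH4CO2 = 0.088),
                         sds = c(LW = 50, DMI = 3.68, ECM = 6.78,
                                 CH4CO2 = 0.0119),
                         r_lw_dmi = 0.51, r_lw_ecm = 0.32, r_dmi_ecm = 0.80,
                         r_lw_ratio = 0, r_dmi_ratio = 0, r_ecm_ratio = 0,
                         dim_mean = 147, dim_sd = 69.1,
                         lw_bounds = c(400, 900), gei_per_dmi = 18.5,
                         true_equation = NULL, noise_sd = 40.8,
                         seed = 20210930) {
  if (is.null(true_equation)) {
    true_equation <- load_equation_bundle()$eq2
  }
  corr <- diag(4)
  dimnames(corr) <- list(names(means), names(means))
  corr["LW", "DMI"] <- corr["DMI", "LW"] <- r_lw_dmi
  corr["LW", "ECM"] <- corr["ECM", "LW"] <- r_lw_ecm
  corr["DMI", "ECM"] <- corr["ECM", "DMI"] <- r_dmi_ecm
  corr["LW", "CH4CO2"] <- corr["CH4CO2", "LW"] <- r_lw_ratio
  corr["DMI", "CH4CO2"] <- corr["CH4CO2", "DMI"] <- r_dmi_ratio
  corr["ECM", "CH4CO2"] <- corr["CH4CO2", "ECM"] <- r_ecm_ratio
  ev <- eigen(corr, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 1e-10)) stop("correlation matrix is not positive definite")
  if (any(sds <= 0)) stop("SDs must be positive")
  structure(
    list(n = n, means = means, sds = sds, corr = corr,
         dim_mean = dim_mean, dim_sd = dim_sd, lw_bounds = lw_bounds,
         gei_per_dmi = gei_per_dmi, true_equation = true_equation,
         noise_sd = noise_sd, seed = seed),
    class = "panel_config"
  )
}

#' Generate a synthetic cow panel with known true emissions
#'
#' Draws covariates from a truncated multivariate normal (rejection sampling
#' at the physiologic bounds: all variables positive, live weight within
#' \code{lw_bounds}) and simulates CH4 from the configured true equation plus
#' Gaussian noise. MCF is derived from the simulated CH4 and GEI, so the MCF
#' equations can be refit on the same panel.
#'
#' @param cfg A [panel_config()].
#' @return Data frame: cow_id, LW, DMI, ECM, CH4CO2, days_in_milk, gei,
#'   milk_yield, milk_fat, milk_protein, CH4_true (noise-free), CH4, MCF.
#' @export
gen_cow_panel <- function(cfg = panel_config()) {
  stopifnot(inherits(cfg, "panel_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  sigma <- diag(cfg$sds) %*% cfg$corr %*% diag(cfg$sds)
  ok <- function(m) {
    m[, 1] >= cfg$lw_bounds[1] & m[, 1] <= cfg$lw_bounds[2] &
      m[, 2] > 0 & m[, 3] > 0 & m[, 4] > 0
  }
  draws <- matrix(numeric(0), ncol = 4)
  while (nrow(draws) < cfg$n) {
    m <- MASS::mvrnorm(2 * cfg$n, mu = cfg$means, Sigma = sigma)
    draws <- rbind(draws, m[ok(m), , drop = FALSE])
  }
  draws <- draws[seq_len(cfg$n), , drop = FALSE]
  colnames(draws) <- names(cfg$means)

  dim_days <- pmax(stats::rnorm(cfg$n, cfg$dim_mean, cfg$dim_sd), 0)
  gei <- draws[, "DMI"] * cfg$gei_per_dmi
  # back out milk at typical composition so the milk fields are coherent
  fat <- 3.5
  protein <- 3.2
  milk <- draws[, "ECM"] / ((376 * fat + 209 * protein + 948) / 3138)

  covs <- as.data.frame(draws)
  ch4_true <- evaluate_equation(cfg$true_equation, covs)
  ch4 <- ch4_true + stats::rnorm(cfg$n, 0, cfg$noise_sd)

  data.frame(
    cow_id = sprintf("cow%03d", seq_len(cfg$n)),
    covs,
    days_in_milk = dim_days, gei = gei,
    milk_yield = milk, milk_fat = fat, milk_protein = protein,
    CH4_true = ch4_true, CH4 = ch4,
    MCF = compute_mcf(pmax(ch4, 0), gei),
    stringsAsFactors = FALSE
  )
}

#' Configuration for synthetic AMS breath traces
#'
#' Defaults describe a plausible milking visit: 8 min at the feed bin,
#' ambient background near 20 ppm CH4 / 600 ppm CO2, a breath plume raising
#' CO2 by ~2,500 ppm (comfortably above the 500-ppm head-position filter),
#' eructation spikes at 1.1/min with lognormal amplitude and a >= 10-s
#' refractory interval, head-away dropouts covering 15% of the visit, and a
#' linear decline of the latent ratio with time after eating (-0.0034/h)
#' with diet offsets (LF -0.026, MF -0.016, HF reference).
#'
#' @param visit_duration_s Visit length, s.
#' @param bg_ch4,bg_co2 Background concentrations, ppm.
#' @param breath_co2_excess Mean CO2 excess of breath over background, ppm.
#' @param eructation_rate True eructation rate, peaks/min.
#' @param spike_meanlog,spike_sdlog Lognormal spike-amplitude parameters
#'   (multiples of the baseline breath CH4 excess).
#' @param spike_width_s Gaussian spike half-width, s.
#' @param refractory_s Minimum spacing between eructations, s.
#' @param head_away_fraction Fraction of the visit with the head away from
#'   the bin (CO2 near background).
#' @param ratio_time_slope Latent-ratio decline per hour after eating.
#' @param diet_offsets Named additive diet offsets on the latent ratio.
#' @param base_ratio Latent ratio at 0 h after eating, HF diet.
#' @param noise_sd_ch4,noise_sd_co2 Analyzer noise SDs, ppm.
#' @param seed Seed (NULL = leave RNG state alone).
#' @return List of class \code{trace_config}.
#' @export
trace_config <- function(visit_duration_s = 480, bg_ch4 = 20, bg_co2 = 600,
                         breath_co2_excess = 2500, eructation_rate = 1.1,
                         spike_meanlog = log(3), spike_sdlog = 0.3,
                         spike_width_s = 2, refractory_s = 10,
                         head_away_fraction = 0.15,
                         ratio_time_slope = -0.0034,
                         diet_offsets = c(HF = 0, LF = -0.026, MF = -0.016),
                         base_ratio = 0.102,
                         noise_sd_ch4 = 2, noise_sd_co2 = 100,
                         seed = 20210930) {
  if (head_away_fraction < 0 || head_away_fraction >= 1) {
    stop("head_away_fraction must lie in [0, 1)")
  }
  if (eructation_rate < 0) stop("eructation_rate must be non-negative")
  structure(as.list(environment()), class = "trace_config")
}

# Eructation event times: Poisson-like renewal process with a hard
# refractory interval, so the long-run rate equals `rate_per_min` exactly.
gen_spike_times <- function(duration_s, rate_per_min, refractory_s) {
  if (rate_per_min <= 0) return(numeric())
  mean_gap <- 60 / rate_per_min
  if (mean_gap <= refractory_s) {
    stop("eructation rate incompatible with refractory interval")
  }
  times <- numeric()
  t <- stats::runif(1, 0, mean_gap)   # stationary-ish start
  while (t < duration_s) {
    times <- c(times, t)
    t <- t + refractory_s + stats::rexp(1, 1 / (mean_gap - refractory_s))
  }
  times
}

# Contiguous head-away blocks totalling exactly round(fraction * duration)
# seconds of the visit.
gen_head_away_mask <- function(duration_s, fraction, block_s = 30) {
  away <- logical(duration_s)
  target <- round(fraction * duration_s)
  guard <- 0
  while (sum(away) < target && guard < 200) {
    guard <- guard + 1
    len <- max(5, stats::rpois(1, block_s))
    start <- sample.int(duration_s - len + 1, 1)
    cells <- start:(start + len - 1)
    new <- cells[!away[cells]]
    room <- target - sum(away)
    if (length(new) > room) new <- new[seq_len(room)]
    away[new] <- TRUE
  }
  away
}

#' Generate one synthetic AMS visit trace with its ground truth
#'
#' The 1-Hz trace is background + a breath plume (CO2 excess above the
#' filter threshold except during head-away blocks) + eructation CH4 spikes
#' + analyzer noise. The CH4 excess is scaled so that, before noise, the
#' visit-mean CH4/CO2 excess over head-at-bin seconds equals the cow's
#' latent ratio exactly (eructations redistribute CH4 within the visit; they
#' do not add emission on top of the latent ratio).
#'
#' @param cow List with \code{cow_id}, \code{base_ratio} (cow-specific latent
#'   ratio at 0 h, HF scale) and \code{diet}.
#' @param cfg A [trace_config()].
#' @param time_after_eating Hours since the last eating bout.
#' @return List: \code{trace} (data frame t, ch4, co2, ppm),
#'   \code{truth} (latent_ratio, n_spikes, spike_times, head_away mask,
#'   time_after_eating).
#' @export
gen_ams_visit <- function(cow, cfg = trace_config(), time_after_eating = 0) {
  stopifnot(inherits(cfg, "trace_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  dur <- cfg$visit_duration_s
  diet <- as.character(cow$diet)
  if (!diet %in% names(cfg$diet_offsets)) {
    stop("diet '", diet, "' has no configured offset")
  }
  latent <- cow$base_ratio + cfg$ratio_time_slope * time_after_eating +
    cfg$diet_offsets[[diet]]
  if (latent <= 0) stop("latent ratio is non-positive under this config")

  tt <- seq_len(dur) - 1
  away <- gen_head_away_mask(dur, cfg$head_away_fraction)
  co2_excess <- ifelse(away, 0, cfg$breath_co2_excess)

  spikes <- gen_spike_times(dur, cfg$eructation_rate, cfg$refractory_s)
  shape <- rep(1, dur)
  if (length(spikes)) {
    amp <- stats::rlnorm(length(spikes), cfg$spike_meanlog, cfg$spike_sdlog)
    for (k in seq_along(spikes)) {
      shape <- shape + amp[k] * exp(-0.5 * ((tt - spikes[k]) /
                                              cfg$spike_width_s)^2)
    }
  }
  inhead <- !away
  # normalize so mean CH4 excess / mean CO2 excess over in-head seconds
  # equals the latent ratio before noise
  ch4_excess <- latent * co2_excess * shape
  if (any(inhead)) {
    target <- latent * mean(co2_excess[inhead])
    ch4_excess <- ch4_excess * target / mean(ch4_excess[inhead])
  }

  trace <- data.frame(
    t = tt,
    ch4 = pmax(cfg$bg_ch4 + ch4_excess +
                 stats::rnorm(dur, 0, cfg$noise_sd_ch4), 0),
    co2 = pmax(cfg$bg_co2 + co2_excess +
                 stats::rnorm(dur, 0, cfg$noise_sd_co2), 0)
  )
  n_visible <- sum(vapply(spikes, function(s) {
    i <- round(s) + 1
    i >= 1 && i <= dur && inhead[i]
  }, logical(1)))
  list(
    trace = trace,
    truth = list(latent_ratio = latent, n_spikes = length(spikes),
                 n_spikes_visible = n_visible, spike_times = spikes,
                 head_away = away, time_after_eating = time_after_eating,
                 diet = diet)
  )
}

#' Generate a background (ambient-air) trace
#'
#' @param cfg A [trace_config()].
#' @param length_s Trace length, s.
#' @return Data frame t, ch4, co2 at background levels plus analyzer noise.
#' @export
gen_background_trace <- function(cfg = trace_config(), length_s = 300) {
  data.frame(
    t = seq_len(length_s) - 1,
    ch4 = pmax(stats::rnorm(length_s, cfg$bg_ch4, cfg$noise_sd_ch4), 0),
    co2 = pmax(stats::rnorm(length_s, cfg$bg_co2, cfg$noise_sd_co2), 0)
  )
}

#' Generate a synthetic head-box measurement from a known emission
#'
#' Builds a 900-s trace whose integrated flux equals \code{true_daily_ch4/96}
#' before noise: per-second concentration excess is the true emission rate
#' divided by the per-second airflow, so [compute_flux()] inverts the
#' construction exactly in the noise-free case.
#'
#' @param true_daily_ch4 True daily CH4 emission, L/day.
#' @param true_ratio True CH4/CO2 emission ratio (sets the CO2 channel).
#' @param flow_mean,flow_sd Box airflow, L/min (jittered per second).
#' @param bg_ch4,bg_co2 Background concentrations, ppm.
#' @param noise_sd_ch4,noise_sd_co2 Analyzer noise SDs, ppm.
#' @param duration_s Measurement length, s.
#' @param seed Seed (NULL = leave RNG state alone).
#' @return List: \code{trace} (t, ch4, co2, flow), \code{bg},
#'   \code{truth} (true_daily_ch4, true_daily_co2).
#' @export
gen_headbox_measurement <- function(true_daily_ch4, true_ratio = 0.088,
                                    flow_mean = 520, flow_sd = 5,
                                    bg_ch4 = 20, bg_co2 = 600,
                                    noise_sd_ch4 = 0, noise_sd_co2 = 0,
                                    duration_s = 900, seed = NULL) {
  if (true_daily_ch4 < 0) stop("true_daily_ch4 must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  flow <- pmax(stats::rnorm(duration_s, flow_mean, flow_sd), 1)
  ch4_rate <- true_daily_ch4 / 86400            # L/s of pure CH4
  co2_rate <- if (true_ratio > 0) ch4_rate / true_ratio else 0
  ch4 <- bg_ch4 + ch4_rate / (flow / 60) * 1e6 +
    stats::rnorm(duration_s, 0, noise_sd_ch4)
  co2 <- bg_co2 + co2_rate / (flow / 60) * 1e6 +
    stats::rnorm(duration_s, 0, noise_sd_co2)
  list(
    trace = data.frame(t = seq_len(duration_s) - 1, ch4 = ch4, co2 = co2,
                       flow = flow),
    bg = c(bg_ch4 = bg_ch4, bg_co2 = bg_co2),
    truth = list(true_daily_ch4 = true_daily_ch4,
                 true_daily_co2 = co2_rate * 86400)
  )
}

#' Generate a day's activity log in 10-min dominant-activity bins
#'
#' Eating bouts start at each planned feeding/milking event and run for a
#' randomized number of 10-min bins; remaining bins are filled with
#' rumination, lying or standing.
#'
#' @param feeding_times Event start times, seconds since midnight (feedings
#'   at 10:00, 13:00 and 17:00 plus milkings is the trial's plan).
#' @param bout_min Mean eating-bout length, minutes (rounded to 10-min bins;
#'   randomized +/- one bin).
#' @param day_s Day length, s.
#' @param bin_s Bin width, s.
#' @param seed Seed (NULL = leave RNG state alone).
#' @return Data frame: bin_start (s since midnight), activity.
#' @export
gen_activity_log <- function(feeding_times = c(10, 13, 17) * 3600,
                             bout_min = 40, day_s = 86400, bin_s = 600,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  starts <- seq(0, day_s - bin_s, by = bin_s)
  n <- length(starts)
  activity <- sample(c("ruminating", "lying", "standing"), n, replace = TRUE,
                     prob = c(0.45, 0.4, 0.15))
  for (ft in feeding_times) {
    first <- which(starts <= ft & ft < starts + bin_s)
    if (!length(first)) next
    n_bins <- max(1, round(bout_min / (bin_s / 60)) +
                    sample(c(-1L, 0L, 1L), 1))
    idx <- first:min(first + n_bins - 1, n)
    activity[idx] <- "eating"
  }
  data.frame(bin_start = starts, activity = activity,
             stringsAsFactors = FALSE)
}

#' Generate a synthetic visit-summary table for the time-after-eating model
#'
#' Simulates the feeding trial's repeated-measures structure directly at the
#' visit-summary level: Latin squares, cows within squares, each cow
#' measured under every diet, with latent ratio
#' \code{intercept + time_slope * t + diet offset (+ interaction * t)} plus
#' square, cow and residual Gaussian effects; t ~ Uniform(0, t_max) h.
#'
#' @param n_squares,cows_per_square,visits_per_cow_diet Design sizes.
#' @param diets Diet labels (reference first by convention of the defaults).
#' @param intercept Latent ratio at 0 h on the reference diet.
#' @param time_slope Ratio change per hour after eating.
#' @param diet_offsets,interaction Named offsets (per diet) on the intercept
#'   and on the time slope.
#' @param square_sd,cow_sd,resid_sd Gaussian SDs of the square and
#'   cow-within-square random intercepts and the residual.
#' @param t_max Maximum time after eating, h.
#' @param seed Seed (NULL = leave RNG state alone).
#' @return Data frame: square, cow_id, diet, time_after_eating, ratio, plus
#'   attribute \code{truth} with the generating coefficients.
#' @export
gen_visit_table <- function(n_squares = 2, cows_per_square = 3,
                            visits_per_cow_diet = 60,
                            diets = c("HF", "LF", "MF"),
                            intercept = 0.102, time_slope = -0.0034,
                            diet_offsets = c(HF = 0, LF = -0.026,
                                             MF = -0.016),
                            interaction = c(HF = 0, LF = 0, MF = 0),
                            square_sd = 0.002, cow_sd = 0.005,
                            resid_sd = 0.005, t_max = 8,
                            seed = 20210930) {
  if (!is.null(seed)) set.seed(seed)
  grid <- expand.grid(
    square = paste0("sq", seq_len(n_squares)),
    cow = seq_len(cows_per_square),
    diet = diets,
    visit = seq_len(visits_per_cow_diet),
    stringsAsFactors = FALSE
  )
  grid$cow_id <- paste0(grid$square, "_cow", grid$cow)
  sq_eff <- stats::rnorm(n_squares, 0, square_sd)
  names(sq_eff) <- paste0("sq", seq_len(n_squares))
  cows <- unique(grid$cow_id)
  cow_eff <- stats::rnorm(length(cows), 0, cow_sd)
  names(cow_eff) <- cows

  t <- stats::runif(nrow(grid), 0, t_max)
  ratio <- intercept +
    (time_slope + interaction[grid$diet]) * t +
    diet_offsets[grid$diet] +
    sq_eff[grid$square] + cow_eff[grid$cow_id] +
    stats::rnorm(nrow(grid), 0, resid_sd)

  out <- data.frame(
    square = grid$square, cow_id = grid$cow_id, diet = grid$diet,
    time_after_eating = t, ratio = unname(ratio),
    stringsAsFactors = FALSE
  )
  attr(out, "truth") <- list(
    intercept = intercept, time_slope = time_slope,
    diet_offsets = diet_offsets, interaction = interaction,
    square_sd = square_sd, cow_sd = cow_sd, resid_sd = resid_sd
  )
  out
}
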