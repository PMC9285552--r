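#' Background gas concentration around a milking visit
#'
#' Breath concentrations are corrected against ambient barn air measured for
#' 5 min immediately before or after milking. This returns the arithmetic
#' mean CH4 and CO2 over the chosen window.
#'
#' @param trace Data frame with columns \code{t} (s, 1-Hz), \code{ch4} and
#'   \code{co2} (ppm); a background trace recorded adjacent to the visit.
#' @param window \code{"pre"} or \code{"post"} (bookkeeping only; the caller
#'   supplies the matching trace).
#' @param length_s Nominal window length; the last/first \code{length_s}
#'   seconds of the trace are used for \code{"pre"}/\code{"post"}.
#' @return Named numeric vector \code{c(bg_ch4=, bg_co2=)} in ppm.
#' @export
estimate_background <- function(trace, window = c("pre", "post"),
                                length_s = 300) {
  window <- match.arg(window)
  n <- nrow(trace)
  if (is.null(n) || n < 60) {
    stop("invalid background: window shorter than 60 s")
  }
  idx <- if (n <= length_s) seq_len(n)
         else if (window == "pre") (n - length_s + 1):n
         else seq_len(length_s)
  c(bg_ch4 = mean(trace$ch4[idx]), bg_co2 = mean(trace$co2[idx]))
}

#' Background-correct and head-position-filter a breath trace
#'
#' Subtracts background from both gases and drops every second whose CO2
#' excess over background is below \code{co2_threshold} (the cow's head is
#' judged to be away from the sample inlet). Corrected CH4 is clipped at 0.
#'
#' @param trace 1-Hz gas trace (\code{t}, \code{ch4}, \code{co2} columns).
#' @param bg Background as returned by [estimate_background()].
#' @param co2_threshold Minimum CO2 excess, ppm; seconds below it are removed.
#' @return Data frame of retained seconds with columns \code{t},
#'   \code{ch4_corr}, \code{co2_corr} (ppm above background).
#' @export
correct_and_filter <- function(trace, bg, co2_threshold = 500) {
  if (any(!is.finite(bg))) stop("background must be finite")
  if (is.null(nrow(trace)) || nrow(trace) == 0) {
    return(data.frame(t = numeric(), ch4_corr = numeric(),
                      co2_corr = numeric()))
  }
  co2_corr <- trace$co2 - bg[["bg_co2"]]
  keep <- co2_corr >= co2_threshold
  data.frame(
    t = trace$t[keep],
    ch4_corr = pmax(trace$ch4[keep] - bg[["bg_ch4"]], 0),
    co2_corr = co2_corr[keep]
  )
}

#' Per-visit CH4/CO2 ratio
#'
#' Averages the corrected concentrations over the retained seconds of a visit
#' and takes their quotient: a ratio of means, not a mean of per-second
#' ratios (the per-second quotient is noisy when CO2 excess is small).
#' The mean-of-ratios alternative is available for sensitivity analysis.
#'
#' @param corrected Output of [correct_and_filter()].
#' @param min_retained Minimum number of retained seconds for a valid visit.
#' @param method \code{"ratio_of_means"} (default) or \code{"mean_of_ratios"}.
#' @return List: \code{mean_ch4_corr}, \code{mean_co2_corr}, \code{ratio},
#'   \code{n_retained}, \code{valid}. When invalid, means and ratio are NA.
#' @export
visit_ratio <- function(corrected, min_retained = 60,
                        method = c("ratio_of_means", "mean_of_ratios")) {
  method <- match.arg(method)
  n <- nrow(corrected)
  if (n < min_retained) {
    return(list(mean_ch4_corr = NA_real_, mean_co2_corr = NA_real_,
                ratio = NA_real_, n_retained = n, valid = FALSE))
  }
  m_ch4 <- mean(corrected$ch4_corr)
  m_co2 <- mean(corrected$co2_corr)
  ratio <- if (method == "ratio_of_means") m_ch4 / m_co2
           else mean(corrected$ch4_corr / corrected$co2_corr)
  list(mean_ch4_corr = m_ch4, mean_co2_corr = m_co2, ratio = ratio,
       n_retained = n, valid = TRUE)
}

# Topographic prominence of local maxima, scipy-style: for each candidate
# peak, walk out to the nearest higher point (or the series end) on each side,
# take the minimum on each walk, and subtract the higher of the two minima.
peak_prominence <- function(x, peaks) {
  vapply(peaks, function(i) {
    h <- x[i]
    lo <- i
    left_min <- h
    while (lo > 1 && x[lo - 1] <= h) {
      lo <- lo - 1
      if (x[lo] < left_min) left_min <- x[lo]
    }
    hi <- i
    right_min <- h
    while (hi < length(x) && x[hi + 1] <= h) {
      hi <- hi + 1
      if (x[hi] < right_min) right_min <- x[hi]
    }
    h - max(left_min, right_min)
  }, numeric(1))
}

#' Detect peaks in a 1-Hz series by prominence and spacing
#'
#' Local maxima are kept if their topographic prominence reaches
#' \code{min_prominence}; among surviving peaks closer together than
#' \code{min_distance} seconds, only the highest is retained (taller peaks
#' claim their neighborhood first).
#'
#' @param x Numeric series (1-Hz).
#' @param min_prominence Prominence threshold, series units.
#' @param min_distance Minimum spacing between reported peaks, samples (s).
#' @return Integer vector of peak indices, sorted.
#' @export
find_peaks <- function(x, min_prominence, min_distance = 10) {
  n <- length(x)
  if (n < 3) return(integer())
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  # drop plateau repeats: a candidate equal to its successor candidate value
  # at distance 1 is the same plateau
  if (!length(cand)) return(integer())
  prom <- peak_prominence(x, cand)
  cand <- cand[prom >= min_prominence]
  if (!length(cand)) return(integer())
  ord <- cand[order(x[cand], decreasing = TRUE)]
  kept <- integer()
  for (i in ord) {
    if (!length(kept) || all(abs(kept - i) >= min_distance)) {
      kept <- c(kept, i)
    }
  }
  sort(kept)
}

#' Eructation rate from the per-second CH4/CO2 ratio
#'
#' Eructations (belches of rumen gas) appear as sharp CH4 spikes, hence
#' spikes in the per-second CH4/CO2 ratio, at roughly one per minute. The
#' rate is the number of detected ratio peaks per minute of observation.
#' The prominence threshold adapts to the series: the larger of
#' \code{prominence_frac} times the median positive ratio and
#' \code{noise_mult} robust noise SDs (estimated from first differences).
#'
#' @param ratio_series Per-second CH4/CO2 ratio over the retained seconds of
#'   a visit (gaps bridged, not interpolated).
#' @param duration_s Observation time the rate refers to, seconds (>= 60).
#' @param min_distance Refractory spacing between peaks, s.
#' @param prominence_frac Fraction of the median positive ratio.
#' @param noise_mult Multiplier on the robust noise SD.
#' @return List: \code{rate} (peaks/min), \code{n_peaks}, \code{peaks}
#'   (indices into \code{ratio_series}).
#' @export
eructation_rate <- function(ratio_series, duration_s,
                            min_distance = 10, prominence_frac = 0.25,
                            noise_mult = 3) {
  if (duration_s < 60) stop("invalid eructation rate: duration below 60 s")
  pos <- ratio_series[ratio_series > 0]
  med <- if (length(pos)) stats::median(pos) else 0
  noise_sd <- if (length(ratio_series) > 2) {
    stats::mad(diff(ratio_series)) / sqrt(2)
  } else 0
  prom <- max(prominence_frac * med, noise_mult * noise_sd)
  peaks <- find_peaks(ratio_series, min_prominence = prom,
                      min_distance = min_distance)
  list(rate = length(peaks) * 60 / duration_s, n_peaks = length(peaks),
       peaks = peaks)
}

#' Time since the end of the last eating bout
#'
#' The breath CH4/CO2 ratio declines as rumen fermentation slows after a
#' meal, so the interval between the end of the last eating bout and the gas
#' measurement is a covariate of every visit. Activity is logged in 10-min
#' bins with a dominant-activity label.
#'
#' @param log Data frame with \code{bin_start} (POSIXct or numeric seconds)
#'   and \code{activity} (one of eating/ruminating/moving/standing/lying).
#' @param visit_start Visit start time, same representation as
#'   \code{bin_start}.
#' @param bin_s Bin width, seconds.
#' @return Hours since the last eating bin ended, or \code{NA_real_}
#'   (missing-covariate flag) when no eating bin precedes the visit.
#' @export
time_after_eating <- function(log, visit_start, bin_s = 600) {
  start <- as.numeric(log$bin_start)
  end <- start + bin_s
  eat_end <- end[log$activity == "eating" & end <= as.numeric(visit_start)]
  if (!length(eat_end)) return(NA_real_)
  (as.numeric(visit_start) - max(eat_end)) / 3600
}

#' Adjust a visit ratio to zero hours after eating
#'
#' Uses the fitted linear mixed model (see [fit_time_model()]) to remove the
#' time-after-eating decline from a measured CH4/CO2 ratio: the reported
#' value is the model's prediction at t = 0 h with every other term held at
#' its observed value, i.e. \code{ratio - (b_time + b_time_x_diet) * t}.
#'
#' @param ratio Measured per-visit ratio (L/L).
#' @param t Time after eating, h.
#' @param diet Diet label of the cow-period ("LF", "MF" or "HF").
#' @param fit A [fit_time_model()] result (or any list with a \code{fixed}
#'   table holding \code{time} and \code{time:diet<level>} rows).
#' @return Adjusted ratio at t = 0. Vectorized over \code{ratio}, \code{t},
#'   \code{diet}.
#' @export
adjust_ratio_to_zero <- function(ratio, t, diet, fit) {
  fixed <- fit$fixed
  slope_time <- fixed$coefficient[fixed$term == "time"]
  if (!length(slope_time)) stop("fit contains no time slope")
  diet <- as.character(diet)
  levels_known <- fit$diet_levels
  if (is.null(levels_known)) levels_known <- c("HF", "LF", "MF")
  if (any(!diet %in% levels_known)) {
    stop("unknown diet label: ",
         paste(unique(diet[!diet %in% levels_known]), collapse = ", "))
  }
  inter <- vapply(diet, function(d) {
    row <- fixed$coefficient[fixed$term == paste0("time:diet", d)]
    if (length(row)) row else 0   # reference level: structurally zero
  }, numeric(1))
  unname(ratio - (slope_time + inter) * t)
}

#' Summarize one AMS visit from its traces
#'
#' Full per-visit processing: background estimation, correction and 500-ppm
#' head-position filtering, ratio-of-means, eructation-peak detection on the
#' retained per-second ratio, and the time-after-eating covariate.
#'
#' @param visit_trace 1-Hz trace during the visit (\code{t}, \code{ch4},
#'   \code{co2}).
#' @param bg_trace Background trace adjacent to the visit, or a list of
#'   \code{pre}/\code{post} traces (averaged when both present), or a
#'   precomputed background vector.
#' @param activity_log Activity log for [time_after_eating()]; may be NULL.
#' @param visit_start Visit start time (for the activity covariate).
#' @param visit_id,cow_id Identifiers carried into the summary.
#' @param diet Diet label carried into the summary.
#' @param config List of processing options: \code{co2_threshold} (ppm, 500),
#'   \code{min_retained} (s, 60), \code{min_distance} (s, 10),
#'   \code{prominence_frac} (0.25), \code{noise_mult} (3),
#'   \code{ratio_method}.
#' @return One-row data frame: visit/cow ids, duration, backgrounds,
#'   corrected means, ratio, retained-second count, eructation rate,
#'   time after eating, validity flag.
#' @export
process_visit <- function(visit_trace, bg_trace, activity_log = NULL,
                          visit_start = NULL, visit_id = NA, cow_id = NA,
                          diet = NA_character_, config = list()) {
  cfg <- utils::modifyList(list(
    co2_threshold = 500, min_retained = 60, min_distance = 10,
    prominence_frac = 0.25, noise_mult = 3, ratio_method = "ratio_of_means"
  ), config)

  bg <- if (is.numeric(bg_trace)) {
    bg_trace
  } else if (is.data.frame(bg_trace)) {
    estimate_background(bg_trace, "pre")
  } else {
    # list with $pre and/or $post; average when both are available
    parts <- list()
    if (!is.null(bg_trace$pre)) {
      parts$pre <- estimate_background(bg_trace$pre, "pre")
    }
    if (!is.null(bg_trace$post)) {
      parts$post <- estimate_background(bg_trace$post, "post")
    }
    if (!length(parts)) stop("no background trace supplied")
    colMeans(do.call(rbind, parts))
  }

  corrected <- correct_and_filter(visit_trace, bg,
                                  co2_threshold = cfg$co2_threshold)
  vr <- visit_ratio(corrected, min_retained = cfg$min_retained,
                    method = cfg$ratio_method)

  duration <- nrow(visit_trace)
  er_rate <- NA_real_
  if (vr$valid && vr$n_retained >= 60) {
    ratio_series <- corrected$ch4_corr / corrected$co2_corr
    er <- eructation_rate(ratio_series, duration_s = vr$n_retained,
                          min_distance = cfg$min_distance,
                          prominence_frac = cfg$prominence_frac,
                          noise_mult = cfg$noise_mult)
    er_rate <- er$rate
  }

  tae <- if (!is.null(activity_log) && !is.null(visit_start)) {
    time_after_eating(activity_log, visit_start)
  } else NA_real_

  data.frame(
    visit_id = visit_id, cow_id = cow_id, diet = diet,
    start_time = if (is.null(visit_start)) NA else as.numeric(visit_start),
    duration = duration,
    bg_ch4 = bg[["bg_ch4"]], bg_co2 = bg[["bg_co2"]],
    mean_ch4_corr = vr$mean_ch4_corr, mean_co2_corr = vr$mean_co2_corr,
    ratio = vr$ratio, n_retained = vr$n_retained,
    eructation_rate = er_rate, time_after_eating = tae,
    valid = vr$valid,
    stringsAsFactors = FALSE
  )
}
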