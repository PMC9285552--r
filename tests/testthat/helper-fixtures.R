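# Small fixture builders shared across the suite.

# 1-Hz trace from raw concentration vectors.
make_trace <- function(co2, ch4 = rep(50, length(co2)), flow = NULL) {
  out <- data.frame(t = seq_along(co2) - 1, ch4 = ch4, co2 = co2)
  if (!is.null(flow)) out$flow <- rep_len(flow, length(co2))
  out
}

# Noise-free spike train: baseline plus triangular spikes of the given
# amplitude at the given centers (1-based indices).
make_spike_train <- function(n, centers, amplitude = 1, baseline = 0.08,
                             half_width = 2) {
  x <- rep(baseline, n)
  for (c0 in centers) {
    for (dt in -half_width:half_width) {
      i <- c0 + dt
      if (i >= 1 && i <= n) {
        x[i] <- x[i] + amplitude * (1 - abs(dt) / (half_width + 1))
      }
    }
  }
  x
}

# Plain OLS by normal equations: independent oracle for fit_equation.
ols_oracle <- function(X, y) {
  solve(t(X) %*% X, t(X) %*% y)[, 1]
}
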