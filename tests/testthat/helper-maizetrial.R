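# constant-temperature weather covering a window, for closed-form GDD checks
constant_weather <- function(start, n_days, tmean = 25, range = 10, year = 2020) {
  dates <- as.Date(start) + seq_len(n_days) - 1
  data.frame(year = year, date = dates,
             tmax_c = tmean + range / 2, tmin_c = tmean - range / 2)
}

# brute-force balanced two-way decomposition (cell/marginal means), the
# independent oracle for two_way_anova
anova_oracle <- function(value, year, hybrid) {
  year <- factor(year); hybrid <- factor(hybrid)
  grand <- mean(value)
  a <- nlevels(year); b <- nlevels(hybrid)
  n <- length(value) / (a * b)
  ym <- tapply(value, year, mean)
  hm <- tapply(value, hybrid, mean)
  cm <- tapply(value, list(year, hybrid), mean)
  ss_y <- b * n * sum((ym - grand)^2)
  ss_h <- a * n * sum((hm - grand)^2)
  ss_cells <- n * sum((cm - grand)^2)
  ss_int <- ss_cells - ss_y - ss_h
  ss_tot <- sum((value - grand)^2)
  ss_err <- ss_tot - ss_cells
  df <- c(a - 1, b - 1, (a - 1) * (b - 1), a * b * (n - 1))
  ss <- c(ss_y, ss_h, ss_int, ss_err)
  ms <- ss / df
  list(df = df, ss = ss, ms = ms, F = c(ms[1:3] / ms[4], NA))
}

# tiny noise-free LAI series from known Gaussian truth
gaussian_points <- function(A, B, C, days = seq(-30, 60, by = 10)) {
  data.frame(day = days, lai = A * exp(-(days - B)^2 / (2 * C^2)))
}

# exit status of a system2(stdout=TRUE) result (NULL attribute means 0)
status_of <- function(x) {
  s <- attr(x, "status")
  if (is.null(s)) 0L else as.integer(s)
}
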