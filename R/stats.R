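#' Balanced two-way fixed-effects ANOVA (Year x Hybrid)
#'
#' The standard trial-report decomposition: main effects of year and hybrid
#' and their interaction, all fixed, on a balanced design with replicate
#' plots as the error stratum. F statistics are each effect mean square over
#' the error mean square.
#'
#' @param value Response, one number per (year, hybrid, replicate).
#' @param year,hybrid Factor labels, recycled against `value`.
#' @return Data frame with rows Year, Hybrid, `Year:Hybrid`, Error and
#'   columns `df`, `ss`, `ms`, `F`, `p`. When the error SS is numerically
#'   zero (noise-free data) `F` and `p` are `NA` and the attribute
#'   `zero_error` is set.
#' @export
two_way_anova <- function(value, year, hybrid) {
  year <- factor(year); hybrid <- factor(hybrid)
  if (nlevels(year) < 2 || nlevels(hybrid) < 2)
    stop("need at least 2 levels of year and hybrid")
  n_cell <- table(year, hybrid)
  if (length(unique(as.vector(n_cell))) != 1L)
    stop("unbalanced design: unequal replicates per year x hybrid cell")
  if (n_cell[1] < 2) stop("single replicate per cell: no error term")
  fit <- stats::aov(value ~ year * hybrid)
  tab <- summary(fit)[[1]]
  out <- data.frame(
    effect = c("Year", "Hybrid", "Year:Hybrid", "Error"),
    df = tab$Df, ss = tab$`Sum Sq`, ms = tab$`Mean Sq`,
    F = c(tab$`F value`[1:3], NA), p = c(tab$`Pr(>F)`[1:3], NA),
    stringsAsFactors = FALSE
  )
  if (out$ss[4] < .Machine$double.eps * sum(out$ss)) {
    out$F[1:3] <- NA_real_; out$p[1:3] <- NA_real_
    attr(out, "zero_error") <- TRUE
  }
  out
}

#' LSD mean separation with letter display
#'
#' Least significant difference at level `alpha`:
#' `LSD = t(1 - alpha/2, df_error) * sqrt(2 * mse / n)`. Treatments whose
#' means differ by at most the LSD share a letter. Letters are assigned by
#' the usual greedy sweep over means sorted in descending order
#' (insert-and-absorb); ties broken by label order.
#'
#' @param means Named numeric vector of treatment means.
#' @param mse Error mean square from the pooled ANOVA.
#' @param df_error Error degrees of freedom, >= 1.
#' @param n Replicates per mean, >= 2.
#' @param alpha Significance level, default 0.05.
#' @return List with `lsd` (the threshold, same units as the means) and
#'   `letters` (named character vector, e.g. `"a"`, `"ab"`, `"b"`).
#' @export
lsd_letters <- function(means, mse, df_error, n, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (mse < 0 || df_error < 1 || n < 2) stop("invalid mse, df_error or n")
  lsd <- stats::qt(1 - alpha / 2, df_error) * sqrt(2 * mse / n)
  if (is.null(names(means))) names(means) <- seq_along(means)
  ord <- order(-means, names(means))
  m <- means[ord]
  k <- length(m)
  # each group is a maximal run [i, j] with m[i] - m[j] <= lsd
  groups <- list()
  for (i in seq_len(k)) {
    j <- max(which(m[i] - m <= lsd + 1e-12))
    groups[[length(groups) + 1L]] <- i:j
  }
  # absorb groups nested in an earlier one
  keep <- !vapply(seq_along(groups), function(g) {
    any(vapply(seq_along(groups)[-g], function(h) all(groups[[g]] %in% groups[[h]]),
               logical(1)))
  }, logical(1))
  groups <- groups[keep]
  lab <- rep("", k)
  for (g in seq_along(groups)) {
    lab[groups[[g]]] <- paste0(lab[groups[[g]]], letters[g])
  }
  out <- stats::setNames(lab[order(ord)], names(means))
  list(lsd = unname(lsd), letters = out)
}

#' Pearson correlation with two-sided p-value
#'
#' @param x,y Numeric vectors of equal length >= 3 with nonzero variance.
#' @return List with `r` and `p` (t transform on n - 2 df).
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 pairs")
  if (stats::var(x) == 0 || stats::var(y) == 0) stop("zero variance")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Simple linear regression y = a + b x
#'
#' @param x,y Numeric vectors as in [pearson()].
#' @return List with `a` (intercept), `b` (slope) and `r` (Pearson
#'   correlation).
#' @export
linear_regression <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 pairs")
  if (stats::var(x) == 0) stop("zero variance in x")
  fit <- stats::lm(y ~ x)
  list(a = unname(stats::coef(fit)[1]), b = unname(stats::coef(fit)[2]),
       r = if (stats::var(y) == 0) 0 else stats::cor(x, y))
}

#' Per-year percent difference between two hybrids, with range
#'
#' For a metric observed per year for a focal and a reference hybrid,
#' computes `100 (focal - reference)/reference` per year and its min/max
#' across years. Values are rounded half-up to 1 decimal only in the
#' returned `min`/`max` summaries (report parity); per-year values keep full
#' precision.
#'
#' @param focal,reference Numeric vectors, one value per year, same order.
#' @return List with `per_year` (%), `min`, `max`.
#' @export
pct_difference_range <- function(focal, reference) {
  if (length(focal) != length(reference)) stop("focal and reference must align by year")
  if (any(reference <= 0)) stop("reference values must be positive")
  pct <- 100 * (focal - reference) / reference
  list(per_year = pct, min = round_half_up(min(pct), 1), max = round_half_up(max(pct), 1))
}

#' Per-year paired difference between two hybrids, with range
#'
#' Like [pct_difference_range()] but in the metric's native units:
#' `focal - reference` per year, plus min/max (rounded half-up to 1 decimal).
#'
#' @param focal,reference Numeric vectors, one value per year, same order;
#'   `NA` on either side is a pairing error.
#' @return List with `per_year`, `min`, `max`.
#' @export
paired_difference_range <- function(focal, reference) {
  if (length(focal) != length(reference)) stop("focal and reference must align by year")
  if (anyNA(focal) || anyNA(reference)) stop("missing year on one side: cannot pair")
  d <- focal - reference
  list(per_year = d, min = round_half_up(min(d), 1), max = round_half_up(max(d), 1))
}

# round-half-up at `digits` decimals (base round() is banker's rounding)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
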