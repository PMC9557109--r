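#' Fit a Gaussian trajectory to post-silking leaf area index
#'
#' The post-silking course of LAI in maize follows a bell-shaped rise-and-fall
#' that is well described by the Gaussian model
#' \deqn{LAI(t) = A \exp(-(t - B)^2 / (2 C^2))}
#' on the days-after-silking axis, where `A` is the maximum LAI, `B` the day
#' it occurs (typically 3-8 d after silking) and `C` the curve width in days.
#' Parameters are initialized from a quadratic regression on `log(LAI)`
#' (exact for noiseless data) and refined by nonlinear least squares.
#'
#' @param day Days after silking (negative values are pre-silking
#'   observations). At least 4 points spanning the peak.
#' @param lai Leaf area index observations (m^2 leaf per m^2 ground), >= 0.
#' @param max_iter Maximum refinement iterations (default 200).
#' @param tol Relative convergence tolerance (default 1e-10).
#' @return An object of class `lai_gaussian`: a list with elements `A`, `B`,
#'   `C`, `R` (determination coefficient, 1 - SSres/SStot), `DLAI` (days for
#'   the fitted curve to fall from `A` to `A/2`, equal to `C * sqrt(2 ln 2)`),
#'   `fitted`, `residuals`, and the `data`.
#' @seealso [dlai()], [fit_pn_linear()]
#' @examples
#' d <- seq(-30, 60, by = 10)
#' fit <- fit_lai_gaussian(d, 5 * exp(-(d - 5)^2 / (2 * 45^2)))
#' coef(fit)
#' @export
fit_lai_gaussian <- function(day, lai, max_iter = 200, tol = 1e-10) {
  ok <- is.finite(day) & is.finite(lai)
  day <- day[ok]; lai <- lai[ok]
  if (length(day) < 4) stop("need at least 4 LAI observations")
  if (any(lai < 0)) stop("LAI must be non-negative")
  if (diff(range(lai)) < .Machine$double.eps^0.5) stop("degenerate fit: all LAI values equal")
  pos <- lai > 0
  if (sum(pos) < 4) stop("need at least 4 observations with LAI > 0")

  # log-domain quadratic: log LAI = log A - (t-B)^2/(2C^2) = c0 + c1 t + c2 t^2
  qf <- stats::lm(log(lai[pos]) ~ day[pos] + I(day[pos]^2))
  cc <- stats::coef(qf)
  if (!is.finite(cc[3]) || cc[3] >= 0) {
    # no interior maximum in the log-quadratic; fall back to moment guesses
    start <- list(A = max(lai), B = day[which.max(lai)],
                  C = max(diff(range(day)) / 4, 1))
  } else {
    C0 <- sqrt(-1 / (2 * cc[3]))
    B0 <- cc[2] * C0^2
    A0 <- exp(cc[1] + B0^2 / (2 * C0^2))
    start <- list(A = unname(A0), B = unname(B0), C = unname(C0))
  }

  fit <- try(stats::nls(lai ~ A * exp(-(day - B)^2 / (2 * C^2)),
                        start = start, algorithm = "port",
                        lower = c(A = 1e-8, B = -Inf, C = 1e-8),
                        control = stats::nls.control(maxiter = max_iter, tol = tol,
                                                     warnOnly = FALSE)),
             silent = TRUE)
  if (inherits(fit, "try-error")) {
    # noiseless or near-singular data: the log-quadratic start is the solution
    par <- unlist(start)
    fitted <- par["A"] * exp(-(day - par["B"])^2 / (2 * par["C"]^2))
    if (sum((lai - fitted)^2) > 1e-6 * sum((lai - mean(lai))^2)) {
      stop("Gaussian fit failed to converge; last iterate: A=", signif(par["A"], 6),
           " B=", signif(par["B"], 6), " C=", signif(par["C"], 6))
    }
  } else {
    par <- stats::coef(fit)
    fitted <- as.numeric(stats::fitted(fit))
  }
  par <- c(A = unname(par["A"]), B = unname(par["B"]), C = abs(unname(par["C"])))
  ss_res <- sum((lai - fitted)^2)
  ss_tot <- sum((lai - mean(lai))^2)
  out <- list(A = par[["A"]], B = par[["B"]], C = par[["C"]],
              R = max(0, min(1, 1 - ss_res / ss_tot)),
              DLAI = par[["C"]] * sqrt(2 * log(2)),
              fitted = fitted, residuals = lai - fitted,
              data = data.frame(day = day, lai = lai))
  class(out) <- "lai_gaussian"
  out
}

#' Duration of higher LAI from a Gaussian fit
#'
#' The number of days for the fitted Gaussian LAI curve to fall from its
#' maximum `A` to `A/2`: the closed form `C * sqrt(2 ln 2)` (about 1.1774 C).
#'
#' @param fit A `lai_gaussian` object, or directly the numeric width
#'   parameter `C` (days).
#' @return DLAI in days.
#' @examples
#' dlai(43.10)  # 50.75
#' @export
dlai <- function(fit) {
  C <- if (inherits(fit, "lai_gaussian")) fit$C else as.numeric(fit)
  if (any(C <= 0)) stop("Gaussian width C must be positive")
  C * sqrt(2 * log(2))
}

#' @export
print.lai_gaussian <- function(x, digits = 4, ...) {
  cat("Gaussian LAI trajectory: LAI(t) = A * exp(-(t - B)^2 / (2 C^2))\n")
  cat(sprintf("  A (LAImax)        %s m2 m-2\n", format(x$A, digits = digits)))
  cat(sprintf("  B (day of LAImax) %s d after silking\n", format(x$B, digits = digits)))
  cat(sprintf("  C (width)         %s d\n", format(x$C, digits = digits)))
  cat(sprintf("  R (determination) %s\n", format(x$R, digits = digits)))
  cat(sprintf("  DLAI              %s d (max to half-max)\n", format(x$DLAI, digits = digits)))
  invisible(x)
}

#' @export
coef.lai_gaussian <- function(object, ...) {
  c(A = object$A, B = object$B, C = object$C)
}

#' @export
predict.lai_gaussian <- function(object, newdata = NULL, ...) {
  day <- if (is.null(newdata)) object$data$day else {
    if (is.data.frame(newdata)) newdata$day else as.numeric(newdata)
  }
  object$A * exp(-(day - object$B)^2 / (2 * object$C^2))
}

#' @export
residuals.lai_gaussian <- function(object, ...) object$residuals

#' @export
plot.lai_gaussian <- function(x, ...) {
  rng <- range(x$data$day)
  tt <- seq(rng[1] - 5, rng[2] + 5, length.out = 200)
  plot(x$data$day, x$data$lai, xlab = "days after silking",
       ylab = expression(LAI ~ (m^2 ~ m^-2)), ...)
  graphics::lines(tt, predict(x, tt))
  graphics::abline(v = x$B, lty = 3)
  invisible(x)
}

#' Fit the linear post-silking decline of ear-leaf net photosynthesis
#'
#' Ordinary least squares of net photosynthetic rate Pn on days after
#' silking, reported in the decline form `y = a - b x` with `b > 0` for a
#' senescing canopy. `Pi`, the initial net photosynthetic rate, is the
#' observed Pn at the earliest post-silking time point (not the fitted
#' intercept), and APD — the active photosynthesis duration, days from `Pi`
#' to `Pi/2` under the fitted decline — is `Pi / (2 b)`.
#'
#' @param day Days after silking; at least 3 distinct values.
#' @param pn Net photosynthetic rate (umol CO2 m^-2 s^-1).
#' @return An object of class `pn_linear`: list with `a` (intercept), `b`
#'   (decline rate, positive when Pn declines), `r` (Pearson correlation
#'   magnitude), `Pi`, `APD`, `fitted`, `residuals`, `data`.
#' @seealso [apd()], [fit_lai_gaussian()]
#' @export
fit_pn_linear <- function(day, pn) {
  ok <- is.finite(day) & is.finite(pn)
  day <- day[ok]; pn <- pn[ok]
  if (length(day) < 3) stop("need at least 3 post-silking Pn observations")
  if (stats::var(day) == 0) stop("zero variance in observation times")
  fit <- stats::lm(pn ~ day)
  a <- unname(stats::coef(fit)[1]); slope <- unname(stats::coef(fit)[2])
  b <- -slope
  r <- if (stats::var(pn) == 0) 0 else abs(stats::cor(day, pn))
  Pi <- pn[which.min(day)]
  out <- list(a = a, b = b, r = r, Pi = Pi,
              APD = if (b > 0 && Pi > 0) Pi / (2 * b) else NA_real_,
              fitted = as.numeric(stats::fitted(fit)),
              residuals = as.numeric(stats::resid(fit)),
              data = data.frame(day = day, pn = pn))
  class(out) <- "pn_linear"
  out
}

#' Active photosynthesis duration from a linear decline fit
#'
#' Days for ear-leaf Pn to fall from its initial post-silking value `Pi` to
#' `Pi/2` under the fitted linear decline: `Pi / (2 b)`.
#'
#' @param fit A `pn_linear` object, or a list with numeric `Pi` and `b`.
#' @return APD in days.
#' @examples
#' apd(list(Pi = 46.07, b = 0.572))  # 40.27
#' @export
apd <- function(fit) {
  if (is.null(fit$b) || is.null(fit$Pi)) stop("fit must carry Pi and b")
  if (fit$b <= 0) stop("no decline (b <= 0): APD undefined")
  if (fit$Pi <= 0) stop("Pi must be positive")
  fit$Pi / (2 * fit$b)
}

#' @export
print.pn_linear <- function(x, digits = 4, ...) {
  cat(sprintf("Linear Pn decline: y = %s - %s x\n",
              format(x$a, digits = digits), format(x$b, digits = digits)))
  cat(sprintf("  r   %s\n", format(x$r, digits = digits)))
  cat(sprintf("  Pi  %s umol m-2 s-1 (earliest post-silking Pn)\n",
              format(x$Pi, digits = digits)))
  cat(sprintf("  APD %s d (Pi to Pi/2)\n", format(x$APD, digits = digits)))
  invisible(x)
}

#' @export
coef.pn_linear <- function(object, ...) c(a = object$a, b = object$b)

#' @export
predict.pn_linear <- function(object, newdata = NULL, ...) {
  day <- if (is.null(newdata)) object$data$day else {
    if (is.data.frame(newdata)) newdata$day else as.numeric(newdata)
  }
  object$a - object$b * day
}

#' @export
residuals.pn_linear <- function(object, ...) object$residuals

#' Canopy photosynthetic capacity
#'
#' Ground-area photosynthetic capacity as the product of leaf-level net
#' photosynthetic rate and leaf area index: `Pn x LAI`.
#'
#' @param pn Net photosynthetic rate (umol CO2 m^-2 leaf s^-1), >= 0.
#' @param lai Leaf area index (m^2 leaf m^-2 ground), >= 0.
#' @return Capacity in umol CO2 m^-2 ground s^-1 (vectorized).
#' @export
canopy_photosynthetic_capacity <- function(pn, lai) {
  if (any(pn < 0) || any(lai < 0)) stop("pn and lai must be non-negative")
  pn * lai
}

#' Percent change relative to a reference value
#'
#' Stage-wise percent comparison helper: `100 (value - reference)/reference`.
#' Used for the "increased by x%" statements of trial reports.
#'
#' @param value Numeric vector of focal values.
#' @param reference Positive reference value (scalar or vector).
#' @return Percent change per element.
#' @export
stage_decline_summary <- function(value, reference) {
  if (any(reference <= 0)) stop("reference must be positive")
  100 * (value - reference) / reference
}
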