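test_that("Gaussian LAI fit recovers noiseless truth exactly", {
  pts <- gaussian_points(5, 5, 45)
  fit <- fit_lai_gaussian(pts$day, pts$lai)
  expect_equal(unname(coef(fit)), c(5, 5, 45), tolerance = 1e-6)
  expect_equal(fit$R, 1, tolerance = 1e-9)
  expect_equal(fit$DLAI, 45 * sqrt(2 * log(2)), tolerance = 1e-6)
  expect_equal(predict(fit, pts$day), pts$lai, tolerance = 1e-6)
})

test_that("Gaussian fit equals the log-quadratic closed form on noiseless data", {
  set.seed(5)
  for (k in 1:10) {
    A <- runif(1, 4, 6); B <- runif(1, 2, 9); C <- runif(1, 38, 55)
    pts <- gaussian_points(A, B, C)
    # independent closed form: quadratic regression on log(LAI)
    q <- coef(lm(log(pts$lai) ~ pts$day + I(pts$day^2)))
    C0 <- sqrt(-1 / (2 * q[3])); B0 <- unname(q[2] * C0^2)
    A0 <- unname(exp(q[1] + B0^2 / (2 * C0^2)))
    fit <- fit_lai_gaussian(pts$day, pts$lai)
    expect_equal(unname(coef(fit)), c(A0, B0, unname(C0)), tolerance = 1e-6)
  }
})

test_that("Gaussian fit rejects degenerate input", {
  expect_error(fit_lai_gaussian(1:3, c(1, 2, 1)), "at least 4")
  expect_error(fit_lai_gaussian(seq(-30, 60, 10), rep(4, 10)), "all LAI values equal")
})

test_that("Gaussian fit is shift-invariant in time and scale-equivariant in LAI", {
  pts <- gaussian_points(4.8, 6, 43)
  base <- fit_lai_gaussian(pts$day, pts$lai)
  shifted <- fit_lai_gaussian(pts$day + 17, pts$lai)
  expect_equal(shifted$A, base$A, tolerance = 1e-6)
  expect_equal(shifted$B, base$B + 17, tolerance = 1e-5)
  expect_equal(shifted$C, base$C, tolerance = 1e-5)
  expect_equal(shifted$DLAI, base$DLAI, tolerance = 1e-5)
  scaled <- fit_lai_gaussian(pts$day, 3 * pts$lai)
  expect_equal(scaled$A, 3 * base$A, tolerance = 1e-6)
  expect_equal(scaled$B, base$B, tolerance = 1e-5)
  expect_equal(scaled$C, base$C, tolerance = 1e-5)
  # the fitted curve is at half maximum exactly DLAI days from its peak
  expect_equal(predict(base, base$B + base$DLAI), base$A / 2, tolerance = 1e-9)
  expect_equal(predict(base, base$B - base$DLAI), base$A / 2, tolerance = 1e-9)
})

test_that("Gaussian width is recovered without bias under observation noise", {
  set.seed(11)
  C_true <- 45
  est <- replicate(200, {
    pts <- gaussian_points(5, 5, C_true)
    fit_lai_gaussian(pts$day, pmax(0.01, pts$lai + rnorm(nrow(pts), 0, 0.05)))$C
  })
  expect_lt(abs(mean(est) - C_true) / C_true, 0.02)
})

test_that("DLAI closed form and its domain", {
  expect_equal(dlai(43.10), 50.75, tolerance = 2e-4)
  expect_equal(dlai(40.45), 40.45 * sqrt(2 * log(2)))
  expect_lt(dlai(1e-9), 1e-8)  # C -> 0+ limit
  expect_error(dlai(-1), "positive")
})

test_that("linear Pn decline fit: exact on collinear points, OLS otherwise", {
  # collinear series with slope -0.572
  fit <- fit_pn_linear(c(0, 30, 60), c(46.07, 28.91, 11.75))
  expect_equal(fit$a, 46.07, tolerance = 1e-9)
  expect_equal(fit$b, 0.572, tolerance = 1e-9)
  expect_equal(fit$r, 1, tolerance = 1e-9)
  expect_equal(fit$Pi, 46.07)   # earliest post-silking observation
  expect_equal(fit$APD, 46.07 / (2 * 0.572), tolerance = 1e-9)
  # noiseless recovery from arbitrary truth
  d <- c(0, 15, 45)
  fit2 <- fit_pn_linear(d, 48.3 - 0.43 * d)
  expect_equal(c(fit2$a, fit2$b), c(48.3, 0.43), tolerance = 1e-9)
  expect_equal(sum(residuals(fit2)^2), 0, tolerance = 1e-18)
  expect_error(fit_pn_linear(c(0, 15), c(40, 30)), "at least 3")
  expect_error(fit_pn_linear(c(5, 5, 5), c(40, 30, 20)), "zero variance")
})

test_that("Pn decline slope is recovered without bias under noise", {
  set.seed(12)
  d <- c(0, 15, 30, 45)
  est <- replicate(200, fit_pn_linear(d, 47 - 0.54 * d + rnorm(4, 0, 1.2))$b)
  expect_lt(abs(mean(est) - 0.54) / 0.54, 0.02)
})

test_that("APD is the half-life of the linear decline", {
  expect_equal(apd(list(Pi = 46.07, b = 0.572)), 40.27, tolerance = 1e-3)
  # printed-coefficient rounding limits agreement for the 2018 row
  expect_equal(apd(list(Pi = 46.33, b = 0.52)), 44.55, tolerance = 1e-3)
  expect_equal(apd(list(Pi = 10, b = 5)), 1)
  expect_error(apd(list(Pi = 40, b = -0.1)), "no decline")
  expect_error(apd(list(Pi = 0, b = 0.5)), "positive")
})

test_that("canopy photosynthetic capacity is the elementwise product", {
  expect_equal(canopy_photosynthetic_capacity(30, 5), 150)
  expect_equal(canopy_photosynthetic_capacity(0, 5), 0)
  pn <- c(40, 35, 12); lai <- c(4.8, 4.2, 1.5)
  expect_equal(canopy_photosynthetic_capacity(pn, lai),
               vapply(1:3, function(i) pn[i] * lai[i], numeric(1)))
  expect_error(canopy_photosynthetic_capacity(-1, 5), "non-negative")
})

test_that("percent-change helper against a reference stage", {
  expect_equal(stage_decline_summary(60, 50), 20)
  expect_equal(stage_decline_summary(50, 41), 21.95, tolerance = 1e-2)
  expect_equal(stage_decline_summary(c(41, 41), 41), c(0, 0))
  expect_error(stage_decline_summary(10, 0), "positive")
})
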