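test_that("two-way ANOVA matches the brute-force balanced decomposition", {
  set.seed(21)
  for (k in 1:5) {
    yr <- rep(2017:2021, each = 6)
    hy <- rep(rep(c("A", "B"), each = 3), 5)
    v <- rnorm(30, 10, 2) + rep(rnorm(5), each = 6) +
      ifelse(hy == "A", 0.5, -0.5)
    tab <- two_way_anova(v, yr, hy)
    or <- anova_oracle(v, yr, hy)
    expect_equal(tab$df, or$df)
    expect_equal(tab$ss, or$ss, tolerance = 1e-9)
    expect_equal(tab$F[1:3], or$F[1:3], tolerance = 1e-9)
    # decomposition conserves total SS
    expect_equal(sum(tab$ss), sum((v - mean(v))^2), tolerance = 1e-9)
    # permuting replicates within cells changes nothing
    idx <- unlist(lapply(split(seq_along(v), paste(yr, hy)), sample))
    tab2 <- two_way_anova(v[idx], yr[idx], hy[idx])
    expect_equal(tab2$ss, tab$ss, tolerance = 1e-9)
  }
})

test_that("two-way ANOVA null, degenerate and invalid designs", {
  yr <- rep(1:2, each = 4); hy <- rep(rep(c("A", "B"), each = 2), 2)
  # equal cell means, pure replicate noise: all effect SS and F are zero
  v <- rep(c(-1, 1), 4)
  tab <- two_way_anova(v, yr, hy)
  expect_equal(tab$ss[1:3], rep(0, 3), tolerance = 1e-12)
  expect_equal(tab$F[1:3], rep(0, 3), tolerance = 1e-12)
  # additive effects, zero noise: error SS 0 is flagged, F guarded as NA
  v2 <- rep(c(0, 1), each = 4) + ifelse(hy == "A", 0, 2)
  tab2 <- two_way_anova(v2, yr, hy)
  expect_true(isTRUE(attr(tab2, "zero_error")))
  expect_true(all(is.na(tab2$F[1:3])))
  expect_error(two_way_anova(1:6, c(1, 1, 1, 2, 2, 2), c("A", "B", "B", "A", "B", "B")),
               "unbalanced")
  expect_error(two_way_anova(1:4, c(1, 1, 2, 2), c("A", "B", "A", "B")),
               "single replicate")
})

test_that("LSD letters match exhaustive pairwise comparisons", {
  lt <- lsd_letters(c(a1 = 10, a2 = 5), mse = 1, df_error = 8, n = 3)$letters
  expect_equal(unname(lt), c("a", "b"))
  expect_equal(unname(lsd_letters(c(x = 5, y = 5), 1, 8, 3)$letters), c("a", "a"))
  set.seed(31)
  for (k in 1:20) {
    means <- sort(rnorm(4, 10, 1.5), decreasing = TRUE)
    names(means) <- paste0("t", 1:4)
    res <- lsd_letters(means, mse = 1.2, df_error = 8, n = 3)
    share <- function(i, j) {
      li <- strsplit(res$letters[i], "")[[1]]
      lj <- strsplit(res$letters[j], "")[[1]]
      length(intersect(li, lj)) > 0
    }
    for (i in 1:3) for (j in (i + 1):4) {
      # oracle: share a letter iff the pairwise t test is non-significant,
      # i.e. |difference| <= LSD
      expect_equal(share(i, j), unname(abs(means[i] - means[j]) <= res$lsd + 1e-12),
                   info = paste("pair", i, j, "seed-case", k))
    }
  }
  expect_error(lsd_letters(c(a = 1, b = 2), 1, 8, 3, alpha = 0), "alpha")
})

test_that("Pearson correlation with t-transform p-value", {
  x <- c(1, 2, 3, 5, 8)
  expect_equal(pearson(x, x)$r, 1)
  expect_equal(pearson(x, -2 * x + 3)$r, -1)
  set.seed(17)
  y <- x + rnorm(5)
  ct <- pearson(x, y)
  r <- ct$r; tt <- r * sqrt(3 / (1 - r^2))
  expect_equal(ct$p, 2 * pt(-abs(tt), 3), tolerance = 1e-12)
  # affine invariance (sign flips with negative scale)
  expect_equal(pearson(3 * x - 7, y)$r, ct$r, tolerance = 1e-12)
  expect_equal(pearson(-2 * x + 1, y)$r, -ct$r, tolerance = 1e-12)
  expect_error(pearson(rep(1, 5), y), "zero variance")
  expect_error(pearson(1:2, 1:2), "at least 3")
})

test_that("linear regression equals the normal-equation oracle", {
  f <- linear_regression(c(0, 1, 2), c(3, 5, 7))
  expect_equal(c(f$a, f$b, f$r), c(3, 2, 1))
  set.seed(23)
  x <- rnorm(12); y <- 2 - 0.7 * x + rnorm(12, 0, 0.3)
  f2 <- linear_regression(x, y)
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(c(f2$a, f2$b), as.vector(beta), tolerance = 1e-10)
  expect_error(linear_regression(rep(2, 5), rnorm(5)), "zero variance")
})

test_that("percent and paired difference ranges bracket the per-year values", {
  pr <- pct_difference_range(c(110, 120, 95), c(100, 100, 100))
  expect_equal(pr$per_year, c(10, 20, -5))
  expect_equal(c(pr$min, pr$max), c(-5, 20))
  expect_true(all(pr$per_year >= pr$min - 0.05 & pr$per_year <= pr$max + 0.05))
  expect_equal(pct_difference_range(c(5, 5), c(5, 5))$per_year, c(0, 0))
  one <- pct_difference_range(103.4, 100)
  expect_equal(one$min, one$max)
  expect_error(pct_difference_range(1, 0), "positive")
  pd <- paired_difference_range(c(846.1, 931.5), c(800, 900))
  expect_equal(pd$per_year, c(46.1, 31.5))
  expect_error(paired_difference_range(c(1, NA), c(1, 2)), "missing year")
})
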