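test_that("pre/post-silking split follows the printed formulas and sums to 100", {
  pp <- pre_post_silking(40, 100)
  expect_equal(pp$prsdmar, 40)
  expect_equal(pp$posdma, 60)
  expect_equal(pp$posdmar, 60)
  pp2 <- pre_post_silking(100, 100)
  expect_equal(c(pp2$prsdmar, pp2$posdma, pp2$posdmar), c(100, 0, 0))
  expect_warning(pre_post_silking(110, 100), "negative post-silking")
  set.seed(3)
  for (k in 1:20) {
    r1 <- runif(1, 50, 150); r6 <- r1 + runif(1, 0, 200)
    pp <- pre_post_silking(r1, r6)
    expect_equal(pp$prsdmar + pp$posdmar, 100, tolerance = 1e-9)
  }
})

test_that("crop growth rate is mass gain over days", {
  expect_equal(crop_growth_rate(0, 92, 46), 2)
  expect_equal(crop_growth_rate(92, 240, 60), 2.467, tolerance = 1e-3)
  expect_equal(crop_growth_rate(50, 50, 10), 0)
  expect_error(crop_growth_rate(0, 10, 0), "positive")
})

test_that("organ remobilization and efficiency, including organ gain", {
  d <- dmr_and_dmre(69.87, 52.06)
  expect_equal(d$dmr, 17.81, tolerance = 1e-9)
  expect_equal(d$dmre, 25.49, tolerance = 1e-2)
  expect_equal(unlist(dmr_and_dmre(50, 50)), c(dmr = 0, dmre = 0))
  d2 <- dmr_and_dmre(50, 60)   # gained mass: flagged by sign, not rejected
  expect_equal(c(d2$dmr, d2$dmre), c(-10, -20))
  expect_error(dmr_and_dmre(0, 10), "positive")
})

test_that("13C distribution: excess bookkeeping, flooring and normalization", {
  organ <- rep(c("grain", "other", "stalk", "leaf"), 2)
  labeled <- rep(c(TRUE, FALSE), each = 4)
  mass <- rep(c(140, 30, 60, 20), 2)
  atom <- c(1.30, 1.15, 1.12, 1.10, rep(1.08, 4))
  cd <- c13_distribution(organ, labeled, mass, atom)
  # frozen from the brute-force excess formula (lab-ref)/100 * mass
  expect_equal(cd$fraction[["grain"]], 0.86274510, tolerance = 1e-7)
  expect_equal(cd$fraction[["other"]], 0.05882353, tolerance = 1e-7)
  expect_equal(cd$fraction[["stalk"]], 0.06722689, tolerance = 1e-7)
  expect_equal(cd$fraction[["leaf"]], 0.011204482, tolerance = 1e-7)
  expect_equal(sum(cd$fraction), 1, tolerance = 1e-12)
  # permutation of sample order leaves fractions unchanged
  p <- sample(8)
  cd2 <- c13_distribution(organ[p], labeled[p], mass[p], atom[p])
  expect_equal(cd2$fraction[names(cd$fraction)], cd$fraction)
  # all excess in grain
  atom3 <- c(1.5, 1.08, 1.08, 1.08, rep(1.08, 4))
  expect_equal(c13_distribution(organ, labeled, mass, atom3)$fraction[["grain"]], 1)
  # labeling failure
  expect_error(c13_distribution(organ, labeled, mass, rep(1.08, 8)),
               "labeling failure")
  # negative excess floored before normalization
  atom4 <- c(1.3, 1.0, 1.08, 1.08, rep(1.08, 4))
  cd4 <- c13_distribution(organ, labeled, mass, atom4)
  expect_true(all(cd4$fraction >= 0))
  expect_equal(cd4$fraction[["other"]], 0)
})

test_that("remobilized mass to grain: tracer-weighted, floored at zero", {
  expect_equal(dmr_to_grain(5.26, 17.81, 0.6216), 14.34, tolerance = 5e-3)
  expect_equal(dmr_to_grain(7, 12, 0), 0)
  expect_equal(dmr_to_grain(10, 10, 1), 20)
  expect_equal(dmr_to_grain(-4, 10, 0.5), 5)  # organ gain contributes nothing
  expect_error(dmr_to_grain(5, 5, 1.2), "\\[0, 1\\]")
})

test_that("DMRC and its post-silking complement", {
  expect_equal(dmrc(14.34, 150.9), 9.50, tolerance = 1e-2)
  expect_equal(dmrc(0, 150), 0)
  expect_error(dmrc(10, 0), "positive")
  set.seed(8)
  for (k in 1:10) {
    v <- dmrc(runif(1, 5, 20), runif(1, 120, 180))
    expect_lte(v, 100)
    expect_equal(v + (100 - v), 100)
  }
})

test_that("harvest index is grain over total with invariant guard", {
  expect_equal(harvest_index(50, 100), 0.5)
  expect_equal(harvest_index(0.582 * 260, 260), 0.582)
  expect_error(harvest_index(110, 100), "exceeds")
  expect_error(harvest_index(0, 100), "positive")
})

test_that("sink capacity and grain/leaf ratio", {
  expect_equal(sink_capacity(6.91, 497, 0.355), 1219.2, tolerance = 1e-4)
  expect_equal(sink_capacity(1, 1, 1), 1)
  expect_equal(sink_capacity(2 * 6.91, 497, 0.355),
               2 * sink_capacity(6.91, 497, 0.355))
  expect_error(sink_capacity(0, 10, 1), "positive")
  expect_equal(round(grain_leaf_ratio(1219.2, 4.56), 3), 0.267)
  expect_equal(grain_leaf_ratio(1000, 4), 0.25)
  expect_equal(grain_leaf_ratio(1000, 1), 1)
  expect_error(grain_leaf_ratio(1000, 0), "positive")
  # homogeneous of degree 1 in ear density through the composition
  expect_equal(grain_leaf_ratio(sink_capacity(2 * 6.91, 497, 0.355), 4.56),
               2 * grain_leaf_ratio(sink_capacity(6.91, 497, 0.355), 4.56))
})

test_that("yield standardization to 14% moisture", {
  expect_equal(standardize_yield(10000, 0.14), 10000)
  expect_equal(standardize_yield(10000, 0.225), 10000 * 0.775 / 0.86)
  expect_equal(standardize_yield(10000, 0.225), 9011.6, tolerance = 1e-4)
  expect_equal(standardize_yield(0, 0.2), 0)
  expect_error(standardize_yield(10000, 0.45), "moisture")
})
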