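test_that("shift distances follow the definition and its symmetries", {
  b <- seq(-2, 2, length.out = 10)
  expect_equal(shift_distances(b, b, 0), rep(0, 10))
  toy <- make_toy(b, dif_item = 4, dif_size = 0.75)
  d <- shift_distances(toy$beta1, toy$beta2, 0)
  expect_equal(d, replace(rep(0, 10), 4, 0.75))
  set.seed(1)
  b2 <- rnorm(10)
  expect_equal(shift_distances(b, b2, 0.3), shift_distances(b2, b, -0.3))
  expect_error(shift_distances(b, b2[-1], 0), "same number")
})

test_that("Gini Index attains its bounds and is scale invariant", {
  expect_equal(gini_index(c(1, rep(0, 9))), 0.9)           # 1 - 1/10
  expect_equal(gini_index(c(7.3, rep(0, 9))), 0.9)         # magnitude-free
  expect_equal(gini_index(rep(2, 5)), 0)                   # perfect equality
  expect_equal(gini_index(c(1, 2, 3, 4)), 0.25)
  set.seed(12)
  for (i in 1:20) {
    d <- runif(sample(3:15, 1), 0, 5)
    g <- gini_index(d)
    expect_gte(g, 0)
    expect_lte(g, 1 - 1 / length(d))
    expect_equal(gini_index(3.7 * d), g, tolerance = 1e-12)
  }
  expect_message(expect_equal(gini_index(rep(0, 4)), 0), "perfect alignment")
  expect_error(gini_index(c(1, -0.1)), "nonnegative")
})

test_that("rank-based Gini equals the pairwise mean-absolute-difference form", {
  set.seed(99)
  for (i in 1:100) {
    d <- runif(sample(2:25, 1), 0, 10)
    if (i %% 5 == 0) d[sample(length(d), 2)] <- d[1]  # inject ties
    expect_equal(gini_index(d), gini_pairwise(d), tolerance = 1e-12)
  }
})

test_that("CLF criterion is the negated sum of (smoothed) distances", {
  expect_equal(clf_criterion(rep(0, 5)), 0)
  expect_equal(clf_criterion(c(1, 2, 3, 4)), -10)
  toy <- make_toy()
  expect_equal(clf_criterion(shift_distances(toy$beta1, toy$beta2, 0)), -0.75)
  expect_equal(clf_criterion(c(3, 4), epsilon = 0.5),
               -(sqrt(9.5) + sqrt(16.5)))
  expect_error(clf_criterion(c(1, 2), epsilon = -1), "nonnegative")
})

test_that("search interval spans the full interlocking range", {
  expect_equal(search_interval(c(-2, 2), c(-1, 3)), c(-5, 3))
  b <- c(-1.2, 0.4, 2)
  expect_equal(search_interval(b, b), c(min(b) - max(b), max(b) - min(b)))
  expect_equal(search_interval(1.5, 0.25), c(1.25, 1.25))
})

test_that("candidate shifts are the unique single-item differences", {
  toy <- make_toy()
  expect_equal(candidate_shifts(toy$beta1, toy$beta2), c(-0.75, 0))
  b <- rnorm(6)
  expect_equal(candidate_shifts(b, b), 0)
  expect_equal(candidate_shifts(c(1, 1 + 5e-13), c(0, 0)), 1)  # collapse
})

test_that("sparse candidate optima coincide with dense-grid optima", {
  set.seed(2024)
  for (i in 1:100) {
    m <- sample(4:9, 1)
    b1 <- runif(m, -1, 1)
    b2 <- b1 + runif(m, -0.5, 0.5)
    delta <- b1 - b2
    cand <- candidate_shifts(b1, b2)
    iv <- search_interval(b1, b2)
    grid <- seq(iv[1], iv[2], by = 1e-3)
    for (cr in c("gini", "clf")) {
      vg <- anchorpoint:::eval_criterion(delta, grid, cr)
      vc <- anchorpoint:::eval_criterion(delta, cand, cr)
      best_grid <- grid[which.max(vg)]
      # candidates dominate the dense grid ...
      expect_gte(max(vc), max(vg) - 1e-9)
      # ... and the grid argmax lies on (or within one step of) the span of
      # near-optimal candidates: exact plateaus (the CLF is flat on the
      # median interval for even m) let rounding noise place the grid argmax
      # anywhere between the tied candidates
      near <- cand[vc >= max(vc) - 1e-9]
      expect_gte(best_grid, min(near) - 1.0001e-3)
      expect_lte(best_grid, max(near) + 1.0001e-3)
    }
  }
})

test_that("CLF-optimal shift is a median of the candidate differences", {
  set.seed(5)
  for (i in 1:25) {
    m <- sample(3:12, 1)
    delta <- rnorm(m)
    sh <- suppressWarnings(anchorpoint:::anchor_shift(delta, rep(0, m), "clf"))
    med <- stats::median(delta)
    if (m %% 2 == 1) {
      expect_equal(sh, med, tolerance = 1e-12)
    } else {
      s <- sort(delta)
      expect_true(sh >= s[m / 2] - 1e-12 && sh <= s[m / 2 + 1] + 1e-12)
      expect_equal(-sum(abs(delta - sh)), -sum(abs(delta - med)),
                   tolerance = 1e-12)
    }
  }
})

test_that("toy example: global optimum at 0 for both criteria, Gini local peak at -0.75", {
  toy <- make_toy()
  cc <- criterion_curve(toy$beta1, toy$beta2)
  expect_equal(cc$global$gini$shift, 0)
  expect_equal(cc$global$clf$shift, 0)
  expect_equal(cc$global$gini$value, 0.9)
  lo <- local_optima(cc, "gini")
  expect_equal(lo$shift, -0.75)
  # the Gini at the optimum does not depend on the DIF magnitude
  toy2 <- make_toy(dif_size = 1.5)
  cc2 <- criterion_curve(toy2$beta1, toy2$beta2)
  expect_equal(cc2$global$gini$shift, 0)
  expect_equal(cc2$global$gini$value, 0.9)
})

test_that("local optima: none for a single candidate, majority cluster case", {
  b <- rnorm(5)
  cc <- criterion_curve(b, b + 0.2)   # all differences equal: one candidate
  expect_equal(nrow(local_optima(cc, "gini")), 0)
  # 6 of 10 items share DIF +1: both criteria align the majority at c = -1
  b1 <- seq(-2, 2, length.out = 10)
  b2 <- b1 + c(rep(1, 6), rep(0, 4))
  cc2 <- criterion_curve(b1, b2)
  expect_equal(cc2$global$gini$shift, -1)
  expect_equal(cc2$global$gini$value, 0.6)
  expect_equal(cc2$global$clf$shift, -1)
  expect_equal(anchorpoint:::eval_criterion(b1 - b2, 0, "gini"), 0.4)
  expect_equal(local_optima(cc2, "gini")$shift, 0)
})

test_that("criterion curve is invariant to the initial restriction up to the shift", {
  set.seed(8)
  b1 <- rnorm(8)
  b2 <- b1 + c(rep(0, 6), 0.8, 0.8)
  cc <- criterion_curve(b1, b2)
  k <- 1.37
  cck <- criterion_curve(b1, b2 + k)
  expect_equal(cck$global$gini$shift, cc$global$gini$shift - k)
  expect_equal(cck$global$gini$value, cc$global$gini$value)
  expect_equal(cck$global$clf$shift, cc$global$clf$shift - k)
  # aligned differences are unchanged
  expect_equal(b1 - (b2 + k) - cck$shift, b1 - b2 - cc$shift)
})

test_that("tied global optima resolve to the smaller |shift| with a warning", {
  b1 <- c(0, 0, 1, 1)
  b2 <- c(0.6, 0.6, 0, 0)   # candidates -0.6 and 1, each aligning two items
  w <- capture_warnings(cc <- criterion_curve(b1, b2))  # one warning per criterion
  expect_true(all(grepl("tied global optima", w)) && length(w) >= 1)
  expect_equal(cc$global$gini$shift, -0.6)
  expect_equal(sort(cc$global$gini$ties), c(-0.6, 1))
})

test_that("degenerate and invalid curve inputs are rejected", {
  expect_error(criterion_curve(1, 2), "at least 2 items")
  expect_error(criterion_curve(rnorm(4), rnorm(3)), "same number")
  expect_error(criterion_curve(rnorm(4), rnorm(4), resolution = 1), "resolution")
})
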