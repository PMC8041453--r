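# build a rasch_cml-shaped object from given estimates and covariance
fake_fit <- function(beta, vcov, restriction = "sum_zero") {
  structure(list(beta = stats::setNames(beta, paste0("Item", seq_along(beta))),
                 vcov = vcov, restriction = restriction, loglik = NA_real_,
                 n_used = NA_integer_, n_dropped = 0L),
            class = "rasch_cml")
}

test_that("identical fits give zero statistics and p-values of one", {
  X <- simulate_group(200, c(-1, 0, 1), seed = 2)
  f <- rasch_cml(X)
  tab <- wald_test(f, f, shift = 0)
  expect_equal(tab$statistic, rep(0, 3))
  expect_equal(tab$p_value, rep(1, 3))
  expect_false(any(tab$flag))
})

test_that("Wald statistics match the printed formula on hand-specified inputs", {
  b1 <- c(0.2, -0.1, -0.1); b2 <- c(-0.3, 0.25, 0.05)
  V1 <- diag(c(0.04, 0.05, 0.06)); V2 <- diag(c(0.03, 0.02, 0.07))
  tab <- wald_test(fake_fit(b1, V1), fake_fit(b2, V2), shift = 0.1)
  want_t <- (b1 - b2 - 0.1) / sqrt(diag(V1) + diag(V2))
  expect_equal(tab$statistic, want_t, tolerance = 1e-12)
  expect_equal(tab$p_value, 2 * pnorm(-abs(want_t)), tolerance = 1e-12)
  expect_equal(tab$flag, tab$p_value < 0.05)
  # the normal reference: |t| = 1.96 sits at p ~ 0.05
  se <- sqrt(V1[1, 1] + V2[1, 1])
  tab2 <- wald_test(fake_fit(c(1.96 * se, 0, -1.96 * se), V1),
                    fake_fit(c(0, 0, 0), V2), shift = 0)
  expect_equal(tab2$p_value[1], 0.05, tolerance = 1e-3)
})

test_that("anchor sets reduce to shifts; single-item anchors align themselves", {
  X1 <- simulate_group(300, seq(-1.5, 1.5, length.out = 6), seed = 3)
  X2 <- simulate_group(300, seq(-1.5, 1.5, length.out = 6), seed = 4)
  f1 <- rasch_cml(X1); f2 <- rasch_cml(X2)
  # all items: the equal-mean shift
  tab_all <- anchored_wald_test(f1, f2, anchor = 1:6)
  expect_equal(attr(tab_all, "shift"), mean(f1$beta) - mean(f2$beta))
  # single item k: candidate shift, t_k = 0
  tab_k <- anchored_wald_test(f1, f2, anchor = 3)
  expect_equal(attr(tab_k, "shift"), unname(f1$beta[3] - f2$beta[3]))
  expect_equal(tab_k$statistic[3], 0)
  expect_equal(tab_k$p_value[3], 1)
  # equivalence: anchor-point selection at candidate k = anchored test at {k}
  sh <- attr(tab_k, "shift")
  tab_c <- wald_test(f1, f2, shift = sh,
                     anchor = anchorpoint:::matching_anchor(f1$beta, f2$beta, sh))
  expect_equal(tab_c$statistic, tab_k$statistic, tolerance = 1e-12)
  expect_error(anchored_wald_test(f1, f2, anchor = integer(0)), "non-empty")
  expect_error(anchored_wald_test(f1, f2, anchor = 9), "indices")
})

test_that("statistics are invariant to the initial restriction of the fits", {
  X1 <- simulate_group(250, c(-1, -0.5, 0.5, 1), seed = 6)
  X2 <- simulate_group(250, c(-1, -0.5, 0.5, 1), theta_mean = -0.4, seed = 7)
  f1 <- rasch_cml(X1); f2 <- rasch_cml(X2)
  f1f <- convert_restriction(f1, "first_zero")
  f2f <- convert_restriction(f2, "first_zero")
  tab <- anchored_wald_test(f1, f2, anchor = c(1, 2))
  tabf <- anchored_wald_test(f1f, f2f, anchor = c(1, 2))
  expect_equal(tab$statistic, tabf$statistic, tolerance = 1e-9)
  expect_equal(tab$p_value, tabf$p_value, tolerance = 1e-9)
  # constant shift of one group's estimates is absorbed by the recomputed c
  f2k <- f2; f2k$beta <- f2$beta + 0.9; f2k$restriction <- "shifted"
  tabk <- anchored_wald_test(f1, f2k, anchor = c(1, 2))
  expect_equal(tabk$statistic, tab$statistic, tolerance = 1e-9)
})

test_that("a large-sample toy dataset flags the DIF item", {
  d <- sim_design(m = 10, n_ref = 1000, n_foc = 1000, dif_items = 4,
                  dif_size = 0.75, seed = 314, beta_range = c(-2, 2))
  dat <- generate_study1(d, 1)
  a <- anchorpoint(dat, method = "gini")
  expect_true(a$dif$flag[4])
  expect_lte(sum(a$dif$flag[-4]), 1)    # at most one false alarm among nine
  # with estimates, CLF may land on a neighbouring candidate (its median
  # plateau), but both criteria align the same DIF-free cluster
  expect_lt(abs(a$curve$global$clf$shift - a$curve$global$gini$shift), 0.15)
})

test_that("zero standard error on a non-anchor contrast is an error", {
  V <- diag(c(0, 0.02, 0.02))
  expect_error(wald_test(fake_fit(c(0.5, 0, -0.5), V),
                         fake_fit(c(0, 0, 0), V), shift = 0), "Item1")
})
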