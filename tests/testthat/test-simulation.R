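test_that("designs validate their inputs", {
  expect_s3_class(sim_design(), "sim_design")
  expect_error(sim_design(m = 1), "m")
  expect_error(sim_design(dif_items = c(3, 99)), "dif_items")
  expect_error(sim_design(dif_size = -1), "dif_size")
  expect_error(sim_design(study = 3), "study")
})

test_that("generation is deterministic and respects the null case", {
  d <- sim_design(m = 6, n_ref = 40, n_foc = 50, seed = 3)
  a <- generate_study1(d, 2)
  b <- generate_study1(d, 2)
  expect_identical(a$responses, b$responses)
  expect_false(identical(a$responses, generate_study1(d, 3)$responses))
  expect_equal(a$beta_ref, a$beta_foc)   # no DIF items
  expect_equal(levels(a$group), c("reference", "focal"))
  expect_equal(tabulate(a$group), c(40, 50))
})

test_that("injected DIF moves the focal group's success rates in the right direction", {
  d <- sim_design(m = 40, n_ref = 1000, n_foc = 1000,
                  dif_items = seq(1, 40, by = 5), dif_size = 1.5, seed = 8)
  dat <- generate_study1(d, 1)
  pr <- colMeans(dat$responses[dat$group == "reference", ])
  pf <- colMeans(dat$responses[dat$group == "focal", ])
  # harder items for the focal group: success drops on every DIF item
  expect_true(all((pr - pf)[d$dif_items] > 0))
  expect_lt(mean(abs((pr - pf)[-d$dif_items])), 0.05)
  # balanced DIF alternates direction
  db <- sim_design(m = 10, n_ref = 2000, n_foc = 2000, dif_items = c(2, 7),
                   dif_size = 1.5, direction = "balanced", seed = 9)
  datb <- generate_study1(db, 1)
  gap <- colMeans(datb$responses[datb$group == "reference", ]) -
    colMeans(datb$responses[datb$group == "focal", ])
  expect_gt(gap[2], 0)
  expect_lt(gap[7], 0)
})

test_that("study-2 generator reduces to the study-1 null stream without loadings", {
  d2 <- sim_design(m = 7, n_ref = 30, n_foc = 45, study = 2, seed = 21)
  d1 <- sim_design(m = 7, n_ref = 30, n_foc = 45, study = 1, seed = 21)
  expect_identical(generate_study2(d2, 4)$responses,
                   generate_study1(d1, 4)$responses)
  # with a secondary dimension, DIF items get harder for the focal group
  d2b <- sim_design(m = 10, n_ref = 2000, n_foc = 2000, dif_items = 1:2,
                    study = 2, seed = 22)
  dat <- generate_study2(d2b, 1)
  gap <- colMeans(dat$responses[dat$group == "reference", ]) -
    colMeans(dat$responses[dat$group == "focal", ])
  expect_true(all(gap[1:2] > 0.05))
  expect_lt(mean(abs(gap[-(1:2)])), 0.05)
  expect_error(generate_study2(d1, 1), "Study-2")
  expect_error(generate_study1(d2, 1), "Study-1")
})

test_that("scoring counts false alarms and hits, with label switching", {
  expect_equal(score_run(9L, truth = c(9L, 10L), m = 10),
               c(false_alarm_rate = 0, hit_rate = 0.5))
  expect_equal(score_run(integer(0), truth = c(1L, 2L), m = 10),
               c(false_alarm_rate = 0, hit_rate = 0))
  expect_equal(score_run(c(1L, 5L), truth = integer(0), m = 10),
               c(false_alarm_rate = 0.2, hit_rate = NA_real_))
  # 60% DIF scenario: flags are exactly the complement of truth
  truth <- 1:6
  flags <- 7:10
  plain <- score_run(flags, truth, 10, mode = "plain")
  expect_equal(unname(plain), c(1, 0))
  switched <- score_run(flags, truth, 10, mode = "label_switching")
  expect_equal(unname(switched), c(0, 1))
  expect_error(score_run(11L, truth = 1L, m = 10), "1..10")
})

test_that("the toy builder reproduces the single-DIF configuration", {
  toy <- make_toy()
  expect_equal(toy$beta2 - toy$beta1, replace(rep(0, 10), 4, 0.75))
  expect_equal(make_toy(dif_size = 0)$beta2, make_toy(dif_size = 0)$beta1)
  expect_equal(candidate_shifts(toy$beta1, toy$beta2), c(-0.75, 0))
})

test_that("run_simulation aggregates per-replication rates with MC errors", {
  d <- sim_design(m = 6, n_ref = 120, n_foc = 120, dif_items = 3,
                  dif_size = 1.2, seed = 66)
  res <- run_simulation(d, methods = c("gini", "equalmean"), reps = 5)
  expect_s3_class(res, "sim_result")
  expect_equal(res$method, c("gini", "equalmean"))
  expect_true(all(res$false_alarm_rate >= 0 & res$false_alarm_rate <= 1))
  expect_true(all(res$hit_rate >= 0 & res$hit_rate <= 1))
  expect_true(all(is.finite(res$far_se)))
  one <- run_simulation(d, methods = "gini", reps = 1)
  expect_true(is.na(one$far_se))
  expect_error(run_simulation(d, methods = "bogus"), "unknown method")
})

test_that("designs round-trip through JSON serialization", {
  d <- sim_design(m = 12, n_ref = 111, n_foc = 222, dif_items = c(2, 4),
                  dif_size = 0.45, direction = "balanced", impact = 0.3,
                  study = 2, secondary_loading = 0.8, secondary_gap = 1.2,
                  reps = 7, seed = 99, beta_range = c(-1.5, 2.5))
  f <- tempfile(fileext = ".json")
  write_sim_design(d, f)
  d2 <- read_sim_design(f)
  expect_equal(unclass(d2), unclass(d))
  # identical designs generate identical data
  expect_identical(generate_response(d2, 1)$responses,
                   generate_response(d, 1)$responses)
})
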