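make_series <- function(time, mean) {
  structure(data.frame(time_h = time, mean = mean, sd = 0,
                       n = 1L),
            class = c("normalized_series", "data.frame"))
}

test_that("normalize_timecourse divides by OD and masks low-OD points", {
  tc <- data.frame(time_h = c(0, 1, 2), fluorescence = c(100, 50, 80),
                   od600 = c(1, 0.5, 0.005), condition = "tagged",
                   genotype = "WT", replicate = 1)
  ns <- normalize_timecourse(tc)
  expect_equal(ns$mean, c(100, 100))       # 100/1, 50/0.5; third masked
  expect_identical(attr(ns, "masked"), 1L)

  # scale equivariance: same constant on fluorescence and OD
  # (away from the OD floor, where masking differs by construction)
  above <- tc[tc$od600 >= 0.01, ]
  tc2 <- above; tc2$fluorescence <- above$fluorescence * 7
  tc2$od600 <- above$od600 * 7
  expect_equal(normalize_timecourse(tc2)$mean,
               normalize_timecourse(above)$mean)

  # constant fluorescence with growing OD is strictly decreasing
  tc3 <- data.frame(time_h = 0:5, fluorescence = 100,
                    od600 = seq(0.2, 1.2, 0.2), condition = "x",
                    genotype = "WT", replicate = 1)
  expect_true(all(diff(normalize_timecourse(tc3)$mean) < 0))
})

test_that("replicates are averaged after normalization", {
  tc <- rbind(
    data.frame(time_h = 0:1, fluorescence = c(10, 20), od600 = 1,
               condition = "t", genotype = "WT", replicate = 1),
    data.frame(time_h = 0:1, fluorescence = c(40, 80), od600 = 2,
               condition = "t", genotype = "WT", replicate = 2))
  ns <- normalize_timecourse(tc)
  expect_equal(ns$mean, c(15, 30))  # (10/1 + 40/2)/2, (20/1 + 80/2)/2
  expect_identical(ns$n, c(2L, 2L))
})

test_that("percent_of_control and degradation_percent obey the identities", {
  s <- make_series(c(0, 10, 20, 30), c(100, 200, 300, 400))
  expect_equal(percent_of_control(s, s, 15), 100)
  tagged <- make_series(c(20, 30), c(8.6, 8.6))
  control <- make_series(c(20, 30), c(100, 100))
  expect_equal(percent_of_control(tagged, control, 30), 8.6)
  t25 <- make_series(c(0, 25), c(38, 38))
  c25 <- make_series(c(0, 25), c(100, 100))
  expect_equal(degradation_percent(t25, c25, 25), 62)
  expect_equal(degradation_percent(s, s, 10), 0)
  expect_error(percent_of_control(tagged, control, 40), "cover")

  # complement identity on random series
  set.seed(31)
  for (i in 1:10) {
    a <- make_series(0:5, runif(6, 10, 100))
    b <- make_series(0:5, runif(6, 10, 100))
    t <- runif(1, 0, 5)
    expect_equal(percent_of_control(a, b, t) +
                   degradation_percent(a, b, t), 100)
  }
})

test_that("percent_of_control interpolates linearly between samples", {
  tagged <- make_series(c(0, 10), c(0, 100))
  control <- make_series(c(0, 10), c(100, 100))
  expect_equal(percent_of_control(tagged, control, 5), 50)
})

test_that("recovery_index subtracts knockout from WT degradation", {
  c100 <- make_series(0:24, rep(100, 25))
  wt <- degradation_result(make_series(0:24, rep(10, 25)), c100, 24,
                           fit_rate = FALSE)     # 90% degraded
  ko <- degradation_result(make_series(0:24, rep(50, 25)), c100, 24,
                           fit_rate = FALSE)     # 50% degraded
  expect_equal(recovery_index(ko, wt), 40)
  expect_equal(recovery_index(wt, wt), 0)
  ko2 <- degradation_result(make_series(0:20, rep(50, 21)), c100, 20,
                            fit_rate = FALSE)
  expect_error(recovery_index(ko2, wt), "endpoint")
})

test_that("knockout simulated with halved decay shows positive recovery", {
  base <- timecourse_sim_config(noise_cv = 0.02, decay_rate = 0.3,
                                seed = 8)
  half <- timecourse_sim_config(noise_cv = 0.02, decay_rate = 0.15,
                                seed = 8)
  ctrl <- normalize_timecourse(simulate_timecourse(base, tagged = FALSE))
  wt <- degradation_result(
    normalize_timecourse(simulate_timecourse(base)), ctrl, 25)
  ko <- degradation_result(
    normalize_timecourse(simulate_timecourse(half, genotype = "dClpA")),
    ctrl, 25)
  expect_gt(recovery_index(ko, wt), 0)
})

test_that("fit_decay_rate recovers a noiseless closed-form decay exactly", {
  tc <- simulate_timecourse(decay_config(), tagged = TRUE)
  fit <- fit_decay_rate(normalize_timecourse(tc))
  expect_equal(fit$rate, 0.2, tolerance = 1e-6 / 0.2)
  expect_equal(fit$r_squared, 1)
  expect_false(fit$not_degrading)

  flat <- make_series(0:10, rep(5, 11))
  ffit <- fit_decay_rate(flat)
  expect_equal(ffit$rate, 0)
  expect_true(ffit$not_degrading)
  expect_error(fit_decay_rate(make_series(0:2, c(1, 3, 2))),
               "not estimable")
})

test_that("fold_change uses max/min with truncated display", {
  fc <- fold_change(90.9, 16.6)
  expect_equal(fc$display, 5.47)             # 5.4759... truncated
  expect_identical(fc$direction, "decrease")
  expect_equal(fold_change(14.9, 9.6)$display, 1.55)
  expect_equal(fold_change(49.1, 42.7)$display, 1.14)   # 1.1499 -> 1.14
  fc2 <- fold_change(3.1, 3.9)
  expect_identical(fc2$direction, "increase")
  expect_equal(fc2$display, 1.25)            # 1.258... truncated
  eq <- fold_change(10, 10)
  expect_equal(eq$display, 1.00)
  expect_identical(eq$direction, "none")
  expect_error(fold_change(0, 5), "positive")

  # antisymmetry: same fold, opposite direction
  set.seed(12)
  for (i in 1:10) {
    a <- runif(1, 1, 100); b <- runif(1, 1, 100)
    expect_equal(fold_change(a, b)$fold, fold_change(b, a)$fold)
  }
})

test_that("net_effect divides abundance gain by activity loss", {
  ne <- net_effect(2.65, 5.47)
  expect_equal(ne$predicted_fold, 2.65 / 5.47)
  expect_identical(ne$direction, "decrease")
  ne2 <- net_effect(3.3, 1.14)
  expect_equal(ne2$predicted_fold, 3.3 / 1.14)
  expect_identical(ne2$direction, "increase")
  expect_identical(net_effect(1, 1)$direction, "neutral")
  expect_error(net_effect(0.5, 2), ">= 1")
})

test_that("time-course validation catches format and vocabulary errors", {
  tc <- simulate_timecourse(timecourse_sim_config(seed = 2))
  expect_s3_class(as_time_course(tc), "time_course")
  bad <- tc; bad$od600 <- NULL
  expect_error(as_time_course(bad), "od600")
  bad2 <- as.data.frame(tc); bad2$genotype <- "dFtsH"
  expect_error(as_time_course(bad2), "unknown genotype")
})
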