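test_that("km_estimate reproduces hand and oracle product-limit values", {
  # one death among four at t = 1
  km <- km_estimate(c(1, 3, 4, 5), c(1, 0, 0, 0))
  expect_equal(km_at(km, 1), 0.75)
  expect_equal(km_at(km, 10), 0.75)

  # all censored: flat at 1
  km2 <- km_estimate(c(2, 4, 6), c(0, 0, 0))
  expect_true(all(km2$steps$surv == 1))

  # mixed censoring; expected values frozen from survival::survfit
  km3 <- km_estimate(c(1, 2, 3, 4, 5), c(1, 0, 1, 1, 0))
  expect_equal(km_at(km3, c(1, 3, 4)), c(0.8, 8 / 15, 4 / 15), tolerance = 1e-12)
  ref <- survival::survfit(survival::Surv(c(1, 2, 3, 4, 5),
                                          c(1, 0, 1, 1, 0)) ~ 1)
  sf <- summary(ref, times = km3$steps$time)
  expect_equal(km3$steps$surv[km3$steps$time %in% sf$time], sf$surv,
               tolerance = 1e-12)
  expect_equal(km3$steps$se[km3$steps$time %in% sf$time], sf$std.err,
               tolerance = 1e-12)

  expect_error(km_estimate(c(0, 0), c(0, 0)), class = "slaml_degenerate_error")
})

test_that("KM on uncensored data equals the empirical survival function", {
  set.seed(12)
  t <- round(rexp(200, 0.1), 1)
  km <- km_estimate(t, rep(1, 200))
  grid <- quantile(t, seq(0.05, 0.95, by = 0.1), type = 1)
  expect_equal(km_at(km, grid),
               vapply(grid, function(x) mean(t > x), numeric(1)),
               tolerance = 1e-12)
})

test_that("KM median recovers ln(2)/lambda on exponential data", {
  set.seed(77)
  lambda <- 0.04
  t <- rexp(5000, lambda)
  cens <- runif(5000, 0, 120)
  km <- km_estimate(pmin(t, cens), as.integer(t <= cens))
  expect_equal(km_median(km), log(2) / lambda, tolerance = 0.08)
})

test_that("logrank_test: identical groups, df, and power under HR = 3", {
  set.seed(2)
  t <- rexp(50, 0.1)
  expect_error(logrank_test(t, rep(1, 50), rep("a", 50)),
               class = "slaml_test_error")  # single group

  # exact copies of one group as two groups: statistic ~ 0
  lr0 <- logrank_test(rep(t[1:50], 2), rep(1, 100), rep(c("a", "b"), each = 50))
  expect_lt(lr0$statistic, 1e-9)
  expect_gt(lr0$p, 0.99)

  # six groups => df 5
  set.seed(3)
  lr6 <- logrank_test(rexp(120), rbinom(120, 1, 0.8),
                      rep(sla_levels(), each = 20))
  expect_equal(lr6$df, 5)

  # hazard ratio 3, n = 200/arm: p < 0.001 in >= 95% of seeds
  hits <- 0
  for (seed in 1:10) {
    set.seed(seed)
    tt <- c(rexp(200, 0.03), rexp(200, 0.09))
    cc <- runif(400, 0, 120)
    lr <- logrank_test(pmin(tt, cc), as.integer(tt <= cc),
                       rep(c("lo", "hi"), each = 200))
    hits <- hits + (lr$p < 0.001)
  }
  expect_gte(hits, 10 * 0.95 - 1e-9)
})

test_that("cumulative_incidence matches the hand Aalen-Johansen example", {
  ci <- cumulative_incidence(c(1, 2, 3, 4),
                             c("relapse", "death", "relapse", "censored"))
  expect_equal(cir_at(ci, 3, "relapse"), 0.25 + 0.5 * 0.5, tolerance = 1e-12)
  expect_equal(cir_at(ci, 3, "death"), 0.25, tolerance = 1e-12)
  expect_error(cumulative_incidence(1, "explode"), class = "slaml_argument_error")
})

test_that("single-cause reduction: CI_relapse = 1 - KM exactly", {
  set.seed(8)
  t <- round(rexp(150, 0.08), 1)
  ev <- sample(c("relapse", "censored"), 150, replace = TRUE, prob = c(0.7, 0.3))
  ci <- cumulative_incidence(t, ev)
  km <- km_estimate(t, as.integer(ev == "relapse"))
  grid <- sort(unique(t))
  expect_equal(cir_at(ci, grid), 1 - km_at(km, grid), tolerance = 1e-12)

  allc <- cumulative_incidence(t, rep("censored", 150))
  expect_true(all(allc$steps$ci_relapse == 0 & allc$steps$ci_death == 0))
})

test_that("Aalen-Johansen conservation identity holds on random outcome sets", {
  set.seed(99)
  for (i in 1:50) {
    n <- sample(5:60, 1)
    t <- round(rexp(n, 0.1), sample(0:1, 1))
    ev <- sample(c("relapse", "death", "censored"), n, replace = TRUE)
    ci <- cumulative_incidence(t, ev)
    expect_true(all(abs(ci$steps$ci_relapse + ci$steps$ci_death +
                          ci$steps$event_free - 1) < 1e-9))
  }
})

test_that("cumulative incidence agrees with the multi-state oracle", {
  set.seed(4)
  n <- 120
  t <- rexp(n, 0.1)
  ev <- sample(c("relapse", "death", "censored"), n, replace = TRUE,
               prob = c(0.5, 0.2, 0.3))
  ci <- cumulative_incidence(t, ev)
  st <- factor(ifelse(ev == "censored", "censor", ev),
               levels = c("censor", "relapse", "death"))
  fit <- survival::survfit(survival::Surv(t, st) ~ 1)
  ref <- fit$pstate[, match("relapse", fit$states)]
  expect_equal(cir_at(ci, fit$time), ref, tolerance = 1e-9)
})

test_that("compare_cir: null, power, and degenerate input", {
  # two identical copies of the same outcome set: p ~ 1
  set.seed(10)
  t <- rexp(150, 0.08)
  ev <- sample(c("relapse", "death", "censored"), 150, replace = TRUE)
  res0 <- compare_cir(rep(t, 2), rep(ev, 2), rep(c("a", "b"), each = 150))
  expect_gt(res0$p, 0.95)

  expect_error(compare_cir(t, ev, rep("a", 150)), class = "slaml_test_error")

  # relapse hazard ratio 3, equal death hazards, n = 300/arm
  hits <- 0
  for (seed in 1:10) {
    set.seed(seed)
    n <- 300
    tr <- c(rexp(n, 0.02), rexp(n, 0.06))
    td <- rexp(2 * n, 0.02)
    cc <- runif(2 * n, 0, 120)
    first <- pmin(tr, td, cc)
    type <- ifelse(tr <= first, "relapse", ifelse(td <= first, "death", "censored"))
    res <- compare_cir(first, type, rep(c("lo", "hi"), each = n))
    hits <- hits + (res$p < 0.01)
  }
  expect_gte(hits, 10 * 0.95 - 1e-9)
})

test_that("simulated cohorts respect the configured survival ordering", {
  # immature arrest configured worse: median OS order HSC/MPP < CMP < mature
  ok <- 0
  for (seed in 1:5) {
    co <- simulate_cohort(cohort_config(n_patients = 1266, seed = seed))
    d <- co$outcomes
    med <- vapply(split(d, d$true_sla), function(g) {
      km_median(km_estimate(g$os_months, g$os_event))
    }, numeric(1))
    imm <- mean(med[c("HSC-L", "MPP-L")], na.rm = TRUE)
    mature <- med[c("GMP-L", "GP-L", "MP-L")]
    ok <- ok + (imm < med[["CMP-L"]] && all(med[["CMP-L"]] < mature))
  }
  expect_gte(ok, 4)
})
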