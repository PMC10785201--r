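scored_toy <- function(df) {
  p <- as_panel(df)
  score_panel(p)
}

test_that("episodes follow the midpoint rule for state changes", {
  # nondisabled at 80, disabled at 83
  df <- toy_panel(n = 1, waves = 2, age0 = 80)
  df$badl_bathing[2] <- "partial"
  ep <- build_episodes(scored_toy(df))
  e01 <- ep[ep$transition == "01", ]
  e02 <- ep[ep$transition == "02", ]
  expect_equal(c(e01$entry, e01$exit, e01$event), c(80, 81.5, 1))
  expect_equal(c(e02$entry, e02$exit, e02$event), c(80, 81.5, 0))
  # after the midpoint the subject is at risk of 10 and 12
  expect_equal(ep$entry[ep$transition %in% c("10", "12")], c(81.5, 81.5))
  expect_equal(ep$exit[ep$transition %in% c("10", "12")], c(83, 83))

  # disabled at 85, nondisabled at 88: recovery at the midpoint
  df2 <- toy_panel(n = 1, waves = 2, age0 = 85)
  df2$walk_1km[1] <- "unable"
  ep2 <- build_episodes(scored_toy(df2))
  e10 <- ep2[ep2$transition == "10", ]
  expect_equal(c(e10$entry, e10$exit, e10$event), c(85, 86.5, 1))
})

test_that("death is dated exactly and attributed from the last observed state", {
  df <- toy_panel(n = 1, waves = 1, age0 = 80)
  df$vital_status <- "dead"
  df$death_date <- df$wave_date + round(2.4 * 365.25)
  ep <- build_episodes(scored_toy(df))
  e02 <- ep[ep$transition == "02", ]
  e01 <- ep[ep$transition == "01", ]
  expect_equal(e02$event, 1L)
  expect_equal(e02$exit, 82.4, tolerance = 0.01)
  expect_equal(e01$event, 0L)
  expect_equal(e01$exit, e02$exit)
})

test_that("risk sets share person-years pairwise (01/02 and 10/12)", {
  set.seed(20)
  sim <- simulate_cohort(sim_scenario(n_subjects = 400), seed = 20)
  sp <- score_panel(sim$panel, strict = FALSE)
  ep <- build_episodes(sp)
  py <- tapply(ep$exit - ep$entry, ep$transition, sum)
  expect_equal(py[["01"]], py[["02"]], tolerance = 1e-10)
  expect_equal(py[["10"]], py[["12"]], tolerance = 1e-10)
  expect_true(all(ep$exit > ep$entry))
  expect_true(all(ep$entry >= 65))
})

test_that("the Gompertz MLE recovers level and slope from episodes", {
  set.seed(21)
  ep <- gomp_episodes(20000, lambda = 0.02, gamma = 0.08)
  f <- fit_gompertz(ep$entry, ep$exit, ep$event)
  expect_lt(abs(f$lambda / 0.02 - 1), 0.10)
  expect_lt(abs(f$gamma - 0.08), 0.01)
})

test_that("the MLE agrees with an independent parametric survival fit", {
  skip_if_not_installed("flexsurv")
  set.seed(22)
  ep <- gomp_episodes(4000, lambda = 0.03, gamma = 0.07)
  f <- fit_gompertz(ep$entry, ep$exit, ep$event)
  fs <- flexsurv::flexsurvreg(
    survival::Surv(entry - 65, exit - 65, event) ~ 1,
    data = ep, dist = "gompertz")
  expect_equal(f$gamma, unname(fs$res["shape", "est"]), tolerance = 1e-3)
  expect_equal(f$lambda, unname(fs$res["rate", "est"]), tolerance = 1e-3)
})

test_that("with gamma fixed at zero the fit is the exponential rate events/py", {
  set.seed(23)
  ep <- gomp_episodes(3000, lambda = 0.05, gamma = 0)
  f <- fit_gompertz(ep$entry, ep$exit, ep$event, fix_gamma = TRUE)
  expect_equal(f$lambda, sum(ep$event) / sum(ep$exit - ep$entry),
               tolerance = 1e-6)
  expect_equal(f$gamma, 0)
})

test_that("a binary covariate hazard ratio of 0.7 is recovered", {
  set.seed(24)
  X <- matrix(rbinom(20000, 1, 0.5), ncol = 1,
              dimnames = list(NULL, "exposed"))
  ep <- gomp_episodes(20000, lambda = 0.04, gamma = 0.06, X = X,
                      beta = log(0.7))
  f <- fit_gompertz(ep$entry, ep$exit, ep$event, X = X)
  expect_gt(exp(f$beta), 0.6)
  expect_lt(exp(f$beta), 0.8)
})

test_that("zero-event fits error, except recovery which pins the rate at 0", {
  ep <- data.frame(entry = c(70, 75), exit = c(72, 78), event = c(0L, 0L))
  expect_error(fit_gompertz(ep$entry, ep$exit, ep$event), "no events")
})

test_that("group proportions are person-years shares", {
  ep <- data.frame(
    subject_id = c("a", "a", "b", "b"),
    transition = c("01", "02", "01", "02"),
    entry = c(70, 70, 80, 80), exit = c(73, 73, 87, 87),
    event = 0L)
  pr <- group_proportions(ep, c(a = "g1", b = "g2"))
  expect_equal(unname(pr["01", ]), c(0.3, 0.7))
  expect_equal(unname(rowSums(pr)), rep(1, 4)[1:nrow(pr)])
  expect_error(group_proportions(ep, c(a = "g1")), "unmapped")
  # single group and symmetric cases
  pr1 <- group_proportions(ep, c(a = "g1", b = "g1"))
  expect_equal(unname(pr1["01", ]), 1)
})

test_that("interval likelihood matches the episode fit when states are constant", {
  # with no state changes and exact death dates the two likelihood styles
  # should give similar mortality estimates
  set.seed(25)
  sc <- sim_scenario(n_subjects = 1500,
                     lambda = c(q01 = 0, q02 = 0.04, q10 = 0, q12 = 0.04),
                     gamma = c(0.09, 0.09, 0, 0.09))
  sim <- simulate_cohort(sc, seed = 25)
  sp <- score_panel(sim$panel, strict = FALSE)
  f_ep <- gompertz_msm(sp, method = "episode")
  f_iv <- gompertz_msm(sp, method = "interval")
  expect_equal(f_iv$transitions[["02"]]$lambda, f_ep$transitions[["02"]]$lambda,
               tolerance = 0.02)
  expect_equal(f_iv$transitions[["02"]]$gamma, f_ep$transitions[["02"]]$gamma,
               tolerance = 0.02)
})

test_that("sample size planning is monotone and simulation-calibrated", {
  n_hi <- plan_sample_size(0.3, 0.7, power = 0.9, allocation = 1.5)
  n_lo <- plan_sample_size(0.3, 0.7, power = 0.5, allocation = 1.5)
  expect_lt(n_lo[1], n_hi[1])
  expect_equal(unname(n_hi[2] / n_hi[1]), 1.5, tolerance = 0.01)
  # balanced allocation reduces to the symmetric formula
  nb <- plan_sample_size(0.3, 0.7, allocation = 1)
  expect_equal(unname(nb[1]), unname(nb[2]))
  expect_error(plan_sample_size(0.3, 1), "infinite")

  # independent power simulation at the returned sizes
  set.seed(26)
  odds_u <- (0.3 / 0.7) / 0.7
  p_u <- odds_u / (1 + odds_u)
  rej <- replicate(600, {
    x1 <- rbinom(1, n_hi[1], 0.3)
    x2 <- rbinom(1, n_hi[2], p_u)
    suppressWarnings(prop.test(c(x1, x2), c(n_hi[1], n_hi[2]),
                               correct = FALSE)$p.value) < 0.05
  })
  expect_gte(mean(rej), 0.875)   # 0.9 nominal minus 3 MC standard errors
})
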