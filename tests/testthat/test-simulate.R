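test_that("a fixed seed reproduces the cohort bit-identically", {
  sc <- sim_scenario(n_subjects = 150)
  a <- simulate_cohort(sc, seed = 7)
  b <- simulate_cohort(sc, seed = 7)
  expect_identical(a$panel, b$panel)
  expect_identical(a$truth$subjects, b$truth$subjects)
})

test_that("zero intensities leave everyone alive and nondisabled", {
  sc <- sim_scenario(n_subjects = 100,
                     lambda = c(q01 = 0, q02 = 0, q10 = 0, q12 = 0),
                     missing_rate = 0)
  sim <- simulate_cohort(sc, seed = 8)
  expect_true(all(sim$panel$vital_status == "alive"))
  sp <- score_panel(sim$panel)
  expect_false(any(sp$score_disabled))
  expect_equal(nrow(sim$panel), 100 * sc$n_waves)
})

test_that("death is absorbing and no waves are observed after it", {
  sim <- simulate_cohort(sim_scenario(n_subjects = 400), seed = 9)
  segs <- sim$truth$segments
  # state sequences never move after death (death is not a recorded segment;
  # check instead that all observed waves precede the death age)
  tr <- sim$truth$subjects
  last_wave_age <- tapply(sim$panel$age, sim$panel$subject_id, max)
  # panel ages are reported to 2 decimals, so allow that reporting precision
  expect_true(all(last_wave_age < tr$death_age[match(names(last_wave_age),
                                                     tr$subject_id)] + 0.006))
  # recorded death dates equal the true death ages
  dead <- sim$panel$vital_status == "dead"
  aD <- sim$panel$age[dead] +
    as.numeric(sim$panel$death_date[dead] - sim$panel$wave_date[dead]) / 365.25
  true_d <- tr$death_age[match(sim$panel$subject_id[dead], tr$subject_id)]
  expect_lt(max(abs(aD - true_d)), 0.02)
})

test_that("a pure constant mortality scenario yields exponential death ages", {
  skip_if_not_installed("survival")
  mu <- 0.1
  sc <- sim_scenario(n_subjects = 4000, entry_age = c(65, 65.01), n_waves = 4,
                     wave_spacing_mean = 10, wave_spacing_sd = 0.01,
                     lambda = c(q01 = 0, q02 = mu, q10 = 0, q12 = mu),
                     gamma = c(0, 0, 0, 0),
                     loghr_lifestyle = rep(0, 4), loghr_ses = rep(0, 4),
                     loghr_male = rep(0, 4), missing_rate = 0)
  sim <- simulate_cohort(sc, seed = 10)
  tr <- sim$truth$subjects
  time <- pmin(tr$death_age, 65 + 30) - 65
  status <- as.integer(tr$death_age <= 65 + 30)
  km <- survival::survfit(survival::Surv(time, status) ~ 1)
  med <- summary(km)$table["median"]
  expect_equal(unname(med), log(2) / mu, tolerance = 0.08)
})

test_that("scored lifestyle counts reproduce the class trajectories", {
  sim <- simulate_cohort(sim_scenario(n_subjects = 1500), seed = 11)
  sp <- score_panel(sim$panel, strict = FALSE)
  tr <- sim$truth$subjects
  cls <- tr$lifestyle_class[match(sp$subject_id, tr$subject_id)]
  m <- tapply(sp$score_n_healthy, cls, mean, na.rm = TRUE)
  expect_lt(abs(m[["favourable"]] - 4.29), 0.15)
  expect_lt(abs(m[["unfavourable"]] - 2.64), 0.15)
})

test_that("the microsimulation oracle matches closed forms", {
  # zero hazards: the full 50-year window in the nondisabled state
  z <- microsim_le(rep(0, 4), rep(0, 4), n = 500, seed = 12)
  expect_equal(as.numeric(z), c(50, 50))
  # constant mortality: LE = (1 - exp(-50 mu)) / mu
  mu <- 0.08
  m <- microsim_le(c(0, mu, 0, mu), rep(0, 4), n = 2e5, seed = 13)
  expect_equal(unname(m["total_le"]), (1 - exp(-50 * mu)) / mu,
               tolerance = 0.01)
})

test_that("truth_le marginalises over the scenario covariate mix", {
  sc <- sim_scenario()
  u <- truth_le(sc, "unfavourable", n = 5e4, seed = 14)
  f <- truth_le(sc, "favourable", n = 5e4, seed = 15)
  expect_gt(f["total_le"], u["total_le"])
  expect_gt(f["dfle"], u["dfle"])
  expect_true(all(u > 0))
})
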