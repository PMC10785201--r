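test_that("MMSE cut-offs follow the education bands", {
  expect_equal(mmse_cutoff(c(0, 0.5, 1, 6, 6.5, 7, 12)),
               c(18L, 18L, 20L, 20L, 24L, 24L, 24L))
  expect_error(mmse_cutoff(-1), "non-negative")
})

test_that("lifestyle factors are scored by the stated rules", {
  r <- healthy_wave_row()
  s <- score_lifestyle(r)
  expect_true(all(unlist(s[1, 1:6])))
  expect_equal(s$n_healthy, 6)

  # sleep of 6.5 h fails the duration rule regardless of quality
  r2 <- healthy_wave_row()
  r2$sleep_hours <- 6.5
  r2$sleep_quality <- "very good"
  expect_false(score_lifestyle(r2)$healthy_sleep)

  # only 6 weekly diet items fails the >= 7 rule
  r3 <- healthy_wave_row()
  r3[, healthspan:::.diet_items] <- 0
  r3[, healthspan:::.diet_items[1:6]] <- 1
  expect_false(score_lifestyle(r3)$healthy_diet)
  r3[, healthspan:::.diet_items[7]] <- 1
  expect_true(score_lifestyle(r3)$healthy_diet)

  # former use does not count as healthy
  r4 <- healthy_wave_row()
  r4$smoke_status <- "former"
  r4$drink_status <- "former"
  s4 <- score_lifestyle(r4)
  expect_false(s4$never_smoking)
  expect_false(s4$never_drinking)

  # missing items after imputation are a contract violation
  r5 <- healthy_wave_row()
  r5$sleep_hours <- NA
  expect_error(score_lifestyle(r5), "missing")
})

test_that("disability definitions follow the item rules", {
  r <- healthy_wave_row()
  expect_false(score_disability(r, "badl"))
  r$badl_bathing <- "partial"
  expect_true(score_disability(r, "badl"))

  r <- healthy_wave_row()
  expect_false(score_disability(r, "mobility"))
  r$walk_1km <- "a little difficult"
  expect_true(score_disability(r, "mobility"))

  r <- healthy_wave_row()
  r$vision_item <- 3
  expect_true(score_disability(r, "vision"))
  r$vision_item <- 2
  expect_false(score_disability(r, "vision"))
  r$hearing_item <- 4
  expect_true(score_disability(r, "hearing"))

  # MMSE 19 with no formal education is above the cut-off of 18
  r <- healthy_wave_row()
  r$education_years <- 0
  r$mmse_score <- 19
  expect_false(score_disability(r, "cognition"))
  r$mmse_score <- 17
  expect_true(score_disability(r, "cognition"))

  # any_of_five is the union
  r <- healthy_wave_row()
  expect_false(score_disability(r, "any_of_five"))
  r$hearing_item <- 3
  expect_true(score_disability(r, "any_of_five"))

  expect_error(score_disability(r, "frailty"), "unknown")
})

test_that("SEVI is a clipped weighted mean of component vulnerabilities", {
  # most advantaged on all six components -> 0
  r <- healthy_wave_row()
  r$education_years <- 10
  r$occupation <- "white collar"
  r$economic_status <- "very rich"
  expect_equal(score_sevi(r)$sevi, 0)

  # most vulnerable on all six -> 1
  r2 <- healthy_wave_row()
  r2$education_years <- 0
  r2$occupation <- "other"
  r2$economic_independence <- "others"
  r2$economic_status <- "very poor"
  r2$timely_healthcare <- "no"
  r2$residence <- "rural"
  expect_equal(score_sevi(r2)$sevi, 1)

  # three components at 1, three at 0, equal weights -> 0.5 (direct arithmetic)
  r3 <- healthy_wave_row()
  r3$education_years <- 0              # 1
  r3$occupation <- "other"             # 1
  r3$economic_independence <- "others" # 1
  r3$economic_status <- "very rich"    # 0
  r3$timely_healthcare <- "yes"        # 0
  r3$residence <- "urban"              # 0
  expect_equal(score_sevi(r3)$sevi, 0.5)

  # partial missingness renormalises; all-missing errors
  r4 <- r3
  r4$residence <- NA
  expect_equal(score_sevi(r4)$sevi, 3 / 5)
  r5 <- r3
  for (v in c("education_years", "occupation", "economic_independence",
              "economic_status", "timely_healthcare", "residence")) {
    r5[[v]] <- NA
  }
  expect_error(score_sevi(r5), "missing")
})

test_that("scoring is pure and n_healthy is monotone in factor flips", {
  set.seed(5)
  r <- healthy_wave_row()
  expect_identical(score_lifestyle(r), score_lifestyle(r))
  unhealthy_mods <- list(
    function(x) { x[, healthspan:::.diet_items] <- 0; x },
    function(x) { x$smoke_status <- "current"; x },
    function(x) { x$exercise_status <- "never"; x },
    function(x) { x$drink_status <- "former"; x },
    function(x) { x[, healthspan:::.cog_items] <- 0; x },
    function(x) { x$sleep_hours <- 5; x }
  )
  for (i in seq_along(unhealthy_mods)) {
    worse <- unhealthy_mods[[i]](r)
    expect_equal(score_lifestyle(worse)$n_healthy, 5)
    # flipping a second factor can only decrease further
    for (j in seq_along(unhealthy_mods)) {
      worse2 <- unhealthy_mods[[j]](worse)
      expect_lte(score_lifestyle(worse2)$n_healthy,
                 score_lifestyle(worse)$n_healthy)
    }
  }
})

test_that("cognition flag is monotone non-increasing in MMSE at fixed education", {
  for (edu in c(0, 3, 9)) {
    r <- healthy_wave_row(n = 31)
    r$education_years <- edu
    r$mmse_score <- 0:30
    flag <- score_disability(r, "cognition")
    expect_true(all(diff(as.integer(flag)) <= 0))
    expect_equal(sum(flag), mmse_cutoff(edu))
  }
})

test_that("score_panel appends prefixed columns and the working flag", {
  p <- as_panel(toy_panel(n = 3))
  sp <- score_panel(p, definition = "mobility")
  expect_true(all(c("score_n_healthy", "score_sevi", "score_dis_badl",
                    "score_dis_any_of_five", "score_disabled") %in% names(sp)))
  expect_identical(sp$score_disabled, sp$score_dis_mobility)
})
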