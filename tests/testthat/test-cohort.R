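test_that("a well-formed file reads into a complete, sorted panel", {
  f <- withr::local_tempfile(fileext = ".csv")
  df <- toy_panel(n = 3, waves = 2)
  write.csv(df, f, row.names = FALSE)
  p <- read_cohort(f)
  expect_s3_class(p, "cohort_panel")
  expect_equal(nrow(p), 6)
  expect_false(anyNA(p[, setdiff(names(p), "death_date")]))
  expect_true(all(diff(order(p$subject_id, p$wave_date)) == 1))
})

test_that("schema mapping renames file columns and flags absent ones", {
  f <- withr::local_tempfile(fileext = ".csv")
  df <- toy_panel()
  names(df)[names(df) == "subject_id"] <- "pid"
  write.csv(df, f, row.names = FALSE)
  expect_error(read_cohort(f), "mandatory")
  p <- read_cohort(f, schema = c(subject_id = "pid"))
  expect_equal(nrow(p), 6)
  expect_error(read_cohort(f, schema = c(subject_id = "nope")), "absent")
})

test_that("duplicate (subject, wave) rows are an integrity error and bad cells become NA", {
  f <- withr::local_tempfile(fileext = ".csv")
  df <- toy_panel()
  write.csv(rbind(df, df[1, ]), f, row.names = FALSE)
  expect_error(read_cohort(f), "integrity")

  df2 <- toy_panel()
  df2$bmi <- as.character(df2$bmi)
  df2$bmi[2] <- "not-a-number"
  write.csv(df2, f, row.names = FALSE)
  expect_message(p <- read_cohort(f), "unparseable")
  expect_true(is.na(p$bmi[order(p$subject_id, p$wave_date)][2]))
})

test_that("exclusion rules drop the right subjects and account exactly", {
  df <- toy_panel(n = 10, waves = 2)
  # two subjects with only one wave
  df <- df[!(df$subject_id %in% c("P001", "P002")) |
             df$wave_date == min(df$wave_date), ]
  p <- as_panel(df)
  res <- apply_exclusions(p)
  expect_equal(res$report$retained_n, 8)
  expect_equal(unname(res$report$counts["single_wave_state"]), 2L)
  expect_equal(res$report$retained_n + sum(res$report$counts), 10)

  # all valid -> all-zero report
  res2 <- apply_exclusions(as_panel(toy_panel(n = 4)))
  expect_true(all(res2$report$counts == 0))
  expect_equal(res2$report$retained_n, 4)
})

test_that("under-65 entries and dead-without-death-date subjects are excluded", {
  df <- toy_panel(n = 3, waves = 2)
  df$age[df$subject_id == "P001"] <- c(60, 63)
  p <- as_panel(df)
  res <- apply_exclusions(p)
  expect_equal(unname(res$report$counts["under_65"]), 1L)
  expect_false("P001" %in% res$panel$subject_id)

  # dead subject with a missing death date and a single other usable wave:
  # the death record is unusable, so only one observation remains
  df2 <- toy_panel(n = 3, waves = 2)
  df2 <- df2[!(df2$subject_id == "P002" & df2$wave_date == max(df2$wave_date)), ]
  df2$vital_status[df2$subject_id == "P002"] <- "dead"   # no death_date
  res2 <- apply_exclusions(as_panel(df2))
  expect_equal(unname(res2$report$counts["single_wave_death_date"]), 1L)
  expect_false("P002" %in% res2$panel$subject_id)

  # one wave plus a valid death date counts as two observations
  df3 <- toy_panel(n = 2, waves = 1)
  df3$vital_status <- "dead"
  df3$death_date <- df3$wave_date + 400
  res3 <- apply_exclusions(as_panel(df3))
  expect_equal(res3$report$retained_n, 2)
})

test_that("a user-supplied registration-error predicate is honoured", {
  p <- as_panel(toy_panel(n = 4))
  res <- apply_exclusions(p, registration_error = function(pp) "P003")
  expect_equal(unname(res$report$counts["registration_error"]), 1L)
  expect_false("P003" %in% res$panel$subject_id)
})

test_that("results are written at reporting precision and round-trip", {
  f <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(group = c("a", "b"), total_le = c(10.2431, 12.8284),
                   pct_dfle = c(56.7432, 59.5951))
  write_results(df, f)
  back <- read.csv(f, stringsAsFactors = FALSE)
  expect_equal(back$total_le, c(10.243, 12.828))
  expect_equal(back$pct_dfle, c(56.74, 59.60))
  # round-trip at written precision
  write_results(back, f)
  expect_equal(read.csv(f), back)
  # empty result -> header-only file
  write_results(df[0, ], f)
  expect_equal(nrow(read.csv(f)), 0)
  expect_equal(names(read.csv(f)), names(df))
})

test_that("half-away rounding matches the reporting convention", {
  expect_equal(round_half_away(2.5), 3)
  expect_equal(round_half_away(-2.5), -3)
  expect_equal(round_half_away(56.745, 2), 56.75)
  expect_equal(round_half_away(10.2435, 3), 10.244)
})

test_that("missingness report counts per-column gaps", {
  df <- toy_panel()
  df$bmi[1:2] <- NA
  rep <- missingness_report(df)
  expect_equal(rep$n_missing[rep$column == "bmi"], 2L)
})
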