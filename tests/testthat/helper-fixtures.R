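# In-code fixtures shared across the test files.

# one fully "healthy" wave row with all raw items present
healthy_wave_row <- function(n = 1) {
  diet <- as.data.frame(matrix(2, n, 13,
                               dimnames = list(NULL, healthspan:::.diet_items)))
  cogs <- as.data.frame(matrix(0, n, 6,
                               dimnames = list(NULL, healthspan:::.cog_items)))
  cogs[[1]] <- 3                       # daily writing
  badl <- as.data.frame(matrix("independent", n, 6,
                               dimnames = list(NULL, healthspan:::.badl_items)),
                        stringsAsFactors = FALSE)
  ill <- as.data.frame(matrix(0L, n, 5,
                              dimnames = list(NULL, healthspan:::.illness_items)))
  cbind(
    data.frame(
      subject_id = sprintf("P%03d", seq_len(n)),
      wave_date = as.Date("2008-06-01"),
      age = 70, vital_status = "alive", death_date = as.Date(NA),
      smoke_status = "never", drink_status = "never",
      exercise_status = "current",
      sleep_hours = 8, sleep_quality = "good",
      walk_1km = "no difficulty", vision_item = 1L, hearing_item = 1L,
      mmse_score = 28L, education_years = 4,
      occupation = "other", economic_independence = "own",
      economic_status = "general", timely_healthcare = "yes",
      residence = "urban",
      gender = "female", region = "east", marital = "married", bmi = 21,
      stringsAsFactors = FALSE),
    diet, cogs, badl, ill)
}

# a minimal well-formed panel: `n` subjects x `waves` waves
toy_panel <- function(n = 3, waves = 2, age0 = 70) {
  rows <- do.call(rbind, lapply(seq_len(waves), function(w) {
    r <- healthy_wave_row(n)
    r$wave_date <- as.Date("2008-06-01") + (w - 1) * 1096
    r$age <- age0 + (w - 1) * 3
    r
  }))
  rows <- rows[order(rows$subject_id, rows$wave_date), ]
  rownames(rows) <- NULL
  rows
}

as_panel <- function(df) as_cohort_panel(df)

# direct episode generation from a single Gompertz hazard (no panel pipeline):
# entry ages uniform, exact event times by inversion, administrative censoring
gomp_episodes <- function(n, lambda, gamma, entry = c(65, 90), cens = c(1, 8),
                          X = NULL, beta = NULL) {
  a0 <- runif(n, entry[1], entry[2])
  mult <- if (is.null(X)) rep(1, n) else exp(drop(X %*% beta))
  E <- rexp(n)
  u0 <- a0 - 65
  t <- if (abs(gamma) < 1e-9) E / (lambda * mult) else {
    arg <- 1 + gamma * E * exp(-gamma * u0) / (lambda * mult)
    ifelse(arg > 0, log(pmax(arg, 1e-300)) / gamma, Inf)
  }
  cc <- runif(n, cens[1], cens[2])
  data.frame(entry = a0, exit = a0 + pmin(t, cc), event = as.integer(t <= cc))
}
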