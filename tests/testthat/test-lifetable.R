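test_that("weighted rates satisfy the stated identities", {
  overall <- gompertz_rates(c(0.05, 0.02, 0.1, 0.06), c(0.07, 0.09, -0.04, 0.08))
  # HR = 1 -> both groups equal the overall rate
  hr1 <- matrix(1, 2, 4, dimnames = list(c("u", "f"), NULL))
  pi_ <- matrix(0.5, 4, 2)
  w1 <- weighted_rates(overall, hr1, pi_)
  expect_equal(w1$u, overall)
  expect_equal(w1$f, overall)

  # hand arithmetic: q = 0.10, HR = 0.5, pi = (0.5, 0.5)
  ov <- matrix(0.10, 1, 4)
  hr <- rbind(u = rep(1, 4), f = rep(0.5, 4))
  w <- weighted_rates(ov, hr, matrix(0.5, 4, 2))
  expect_equal(unname(w$u[1, 1]), 0.10 / 0.75)
  expect_equal(unname(w$f[1, 1]), 0.05 / 0.75)
  expect_equal(0.5 * w$u + 0.5 * w$f, ov, ignore_attr = TRUE)

  # degenerate mixture: pi = (1, 0) -> reference keeps the overall rate
  pw <- cbind(rep(1, 4), 0)
  expect_warning(w0 <- weighted_rates(ov, hr, pw), "single group")
  expect_equal(w0$u, ov, ignore_attr = TRUE)
  expect_lt(attr(w0, "mixture_error"), 1e-12)
})

test_that("one-band transition probabilities equal the matrix exponential", {
  skip_if_not_installed("Matrix")
  q <- c(0.1, 0.05, 0.02, 0.2)
  P <- age_step_probabilities(q[1], q[2], q[3], q[4])
  Q <- matrix(c(-(q[1] + q[2]), q[1], q[2],
                q[3], -(q[3] + q[4]), q[4],
                0, 0, 0), 3, byrow = TRUE)
  expect_equal(unname(P), as.matrix(Matrix::expm(Q)), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_lt(max(abs(rowSums(P) - 1)), 1e-12)
  expect_equal(P[3, ], c(nondisabled = 0, disabled = 0, dead = 1))

  # 10,000-substep Euler oracle
  n <- 10000
  E <- diag(3)
  step <- diag(3) + Q / n
  for (i in seq_len(n)) E <- E %*% step
  expect_equal(unname(P), unname(E), tolerance = 1e-4)

  # degenerate cases
  expect_equal(unname(age_step_probabilities(0, 0, 0, 0)), diag(3))
  expect_warning(Pbig <- age_step_probabilities(0, 100, 0, 100), "capped")
  expect_gt(Pbig[1, 3], 1 - 1e-12)
})

test_that("the life table reproduces closed forms", {
  # no mortality, no disability: everyone lives the whole 50-year window
  lt0 <- build_life_table(matrix(0, 50, 4))
  expect_equal(lt0$total_le, 50)
  expect_equal(lt0$dfle, 50)

  # constant total mortality, no disability: LE = (1 - exp(-50 mu)) / mu
  for (mu in c(0.02, 0.05, 0.1)) {
    rates <- cbind(q01 = 0, q02 = mu, q10 = 0, q12 = mu)[rep(1, 50), ]
    lt <- build_life_table(rates)
    expect_equal(lt$total_le, (1 - exp(-50 * mu)) / mu, tolerance = 1e-3)
    expect_equal(lt$dle, 0)
  }
  expect_error(build_life_table(matrix(0, 50, 4), init = c(2, -1)),
               "non-negative")
})

test_that("conservation and monotonicity hold across a scenario grid", {
  set.seed(30)
  for (rep in 1:5) {
    lam <- runif(4, 0.01, 0.2)
    gam <- runif(4, -0.05, 0.1)
    rates <- gompertz_rates(lam, gam)
    init <- c(0.9, 0.1)
    lt <- build_life_table(rates, init = init)
    # DFLE + DLE = total LE exactly
    expect_equal(lt$dfle + lt$dle, lt$total_le, tolerance = 1e-10)
    # occupancy rows sum to 1
    expect_lt(max(abs(rowSums(lt$occupancy) - 1)), 1e-12)
    expect_equal(unname(lt$occupancy[1, ]), c(init, 0))
    # more disability onset can never increase DFLE
    for (f in c(1.2, 1.5, 2)) {
      r2 <- rates
      r2[, 1] <- rates[, 1] * f
      expect_lte(build_life_table(r2, init = init)$dfle, lt$dfle + 1e-12)
    }
    # more mortality can never increase total LE
    for (f in c(1.2, 2)) {
      r3 <- rates
      r3[, 2] <- rates[, 2] * f
      r3[, 4] <- rates[, 4] * f
      expect_lte(build_life_table(r3, init = init)$total_le,
                 lt$total_le + 1e-12)
    }
  }
})

test_that("contrast tables reproduce reported-style arithmetic", {
  df <- data.frame(group = c("unfavourable", "favourable"),
                   total_le = c(12.828, 17.187),
                   dfle = c(7.279, 10.243))
  ct <- le_contrasts(df)
  expect_equal(round_half_away(ct$pct_dfle, 2), c(56.74, 59.60))
  expect_equal(ct$total_diff, c(0, 4.359))
  expect_equal(ct$dfle_diff, c(0, 2.964))

  # identical groups -> zero differences
  same <- data.frame(group = c("a", "b"), total_le = 10, dfle = 6)
  ct2 <- le_contrasts(same)
  expect_equal(ct2$total_diff, c(0, 0))
  expect_error(le_contrasts(df, reference = "nope"), "missing")
})

test_that("the analytic life table matches a small microsimulation", {
  lam <- c(0.08, 0.02, 0.10, 0.05)
  gam <- c(0.07, 0.09, -0.04, 0.08)
  lt <- build_life_table(gompertz_rates(lam, gam))
  ms <- microsim_le(lam, gam, n = 2e5, seed = 31)
  se <- attr(ms, "se")
  expect_lt(abs(lt$total_le - ms["total_le"]), 3 * se["total_le"] + 0.02)
  expect_lt(abs(lt$dfle - ms["dfle"]), 3 * se["dfle"] + 0.02)
})
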