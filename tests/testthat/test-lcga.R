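sim_two_class <- function(n = 400, means = c(4.5, 2.5), sd = 0.9,
                          waves = 4, p1 = 0.5) {
  cls <- 1L + (runif(n) > p1)
  d <- data.frame(
    id = rep(seq_len(n), each = waves),
    t = rep(seq(0, by = 3, length.out = waves), n)
  )
  d$y <- means[cls[d$id]] + rnorm(nrow(d), 0, sd)
  list(data = d, class = cls)
}

test_that("EM recovers two well-separated flat classes", {
  set.seed(10)
  sim <- sim_two_class(n = 400)
  fit <- lcga(y ~ t, sim$data, subject = "id", K = 2, degree = 1,
              n_starts = 5, seed = 1)
  mu <- sort(fit$class_mean, decreasing = TRUE)
  expect_lt(abs(mu[1] - 4.5), 0.1)
  expect_lt(abs(mu[2] - 2.5), 0.1)
  grp <- assign_groups(fit, labels = c("hi", "lo"))
  acc <- mean((grp[as.character(seq_len(400))] == "hi") == (sim$class == 1L))
  expect_gte(max(acc, 1 - acc), 0.9)
  # posterior rows sum to one
  expect_lt(max(abs(rowSums(fit$posterior) - 1)), 1e-10)
  # EM log-likelihood never decreases
  expect_true(all(diff(fit$loglik_trace) > -1e-8))
})

test_that("a one-class mixture equals the pooled polynomial regression", {
  set.seed(11)
  sim <- sim_two_class(n = 80, means = c(3, 3))
  fit <- lcga(y ~ t, sim$data, subject = "id", K = 1, degree = 1, n_starts = 1)
  lmfit <- lm(y ~ t, sim$data)
  s2 <- mean(residuals(lmfit)^2)
  ll <- sum(dnorm(sim$data$y, fitted(lmfit), sqrt(s2), log = TRUE))
  expect_equal(fit$loglik, ll, tolerance = 1e-6)
})

test_that("a richer class structure never fits worse on the same data", {
  set.seed(12)
  sim <- sim_two_class(n = 200)
  f2 <- lcga(y ~ t, sim$data, subject = "id", K = 2, n_starts = 5, seed = 2)
  f3 <- lcga(y ~ t, sim$data, subject = "id", K = 3, n_starts = 10, seed = 3)
  expect_gte(f3$loglik, f2$loglik - 1e-6)
})

test_that("BIC uses the subject count and the stated parameter count", {
  set.seed(13)
  sim <- sim_two_class(n = 120)
  fit <- lcga(y ~ t, sim$data, subject = "id", K = 2, degree = 1,
              n_starts = 3, seed = 4)
  n_par <- 2 * 2 + 2 + 1
  expect_equal(fit$n_params, n_par)
  expect_equal(fit$bic, -2 * fit$loglik + n_par * log(120))
})

test_that("model selection honours the classification criteria, then |BIC|, then K", {
  fake <- function(K, bic, avg = 0.9, share = 0.9, frac = 0.3) {
    structure(list(K = K, degree = 1, bic = bic,
                   posterior = NULL, pi = rep(1 / K, K)), class = "lcga")
  }
  # craft posteriors giving the wanted diagnostics
  mk <- function(K, bic, frac_min) {
    n <- 100
    cls <- rep(seq_len(K), times = c(round(n * frac_min),
                                     rep(round(n * (1 - frac_min) / (K - 1)),
                                         K - 1)))[1:n]
    post <- matrix(0.02, n, K)
    post[cbind(1:n, cls)] <- 1 - 0.02 * (K - 1)
    structure(list(K = K, degree = 1, bic = bic, posterior = post,
                   pi = tabulate(cls, K) / n, class_mean = seq_len(K)),
              class = "lcga")
  }
  m_ok_lowbic <- mk(2, 10350, 0.4)
  m_ok_highbic <- mk(2, 10400, 0.4)
  m_small_class <- mk(3, 10000, 0.02)   # a class below 5% membership
  sel <- select_lcga(list(m_ok_highbic, m_small_class, m_ok_lowbic))
  expect_equal(sel$bic, 10350)
  # the small-class candidate is rejected despite the best |BIC|
  expect_false(attr(sel, "selected_by_fallback"))
  # tie in BIC -> smaller K
  sel2 <- select_lcga(list(mk(3, 10350, 0.3), m_ok_lowbic))
  expect_equal(sel2$K, 2)
  # nothing passes -> fallback with warning
  expect_warning(sel3 <- select_lcga(list(m_small_class)), "no candidate")
  expect_true(attr(sel3, "selected_by_fallback"))
  expect_error(select_lcga(list()), "empty")
})

test_that("group labelling follows the trajectory means in either direction", {
  set.seed(14)
  sim <- sim_two_class(n = 200)
  fit <- lcga(y ~ t, sim$data, subject = "id", K = 2, n_starts = 5, seed = 5)
  fav <- assign_groups(fit, labels = c("favourable", "unfavourable"),
                       higher_first = TRUE)
  ses <- assign_groups(fit, labels = c("higher", "lower"),
                       higher_first = FALSE)
  # the class called favourable (higher count) must be called "lower" under
  # the SEVI-style ordering
  expect_true(all((fav == "favourable") == (ses == "lower")))
  hi_mean <- mean(sim$data$y[sim$data$id %in%
                               as.integer(names(fav)[fav == "favourable"])])
  lo_mean <- mean(sim$data$y[sim$data$id %in%
                               as.integer(names(fav)[fav == "unfavourable"])])
  expect_gt(hi_mean, lo_mean)
})
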