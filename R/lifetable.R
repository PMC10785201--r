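# Multi-state life tables over ages 65-115 for the illness-death model with
# recovery, plus group-specific weighted transition rates.

# Closed-form matrix exponential of the living-states block of the generator
#   Q_LL = [ -(q01+q02)  q01 ;  q10  -(q10+q12) ] * dt.
# For a real 2x2 matrix M with non-negative off-diagonals,
#   exp(M) = e^m [ cosh(d) I + sinh(d)/d (M - m I) ],
# m = tr(M)/2, d = sqrt(((a - dd)/2)^2 + b c) (real, since b c >= 0).
# Death probabilities follow from row deficits.  Fully vectorised.
.expm_living <- function(q01, q02, q10, q12, dt) {
  a <- -(q01 + q02) * dt
  d <- -(q10 + q12) * dt
  b <- q01 * dt
  cc <- q10 * dt
  m <- (a + d) / 2
  delta <- sqrt(((a - d) / 2)^2 + b * cc)
  shc <- ifelse(delta < 1e-8, 1 + delta^2 / 6, sinh(delta) / delta)
  ch <- cosh(delta)
  em <- exp(m)
  p00 <- em * (ch + (a - m) * shc)
  p01 <- em * b * shc
  p10 <- em * cc * shc
  p11 <- em * (ch + (d - m) * shc)
  list(p00 = p00, p01 = p01, p02 = pmax(1 - p00 - p01, 0),
       p10 = p10, p11 = p11, p12 = pmax(1 - p10 - p11, 0))
}

#' One-band transition probability matrix
#'
#' Exact matrix exponential `P = exp(Q dt)` of the three-state generator with
#' off-diagonal intensities `q01, q02, q10, q12` (per person-year), zero flow
#' out of death, rows summing to zero.  Intensities are capped at 50/year with
#' a warning to guard the exponential overflow region.
#'
#' @param q01,q02,q10,q12 non-negative intensities (per person-year).
#' @param dt band width in years.
#' @return row-stochastic 3x3 matrix over states
#'   (nondisabled, disabled, dead); the death row is `(0, 0, 1)`.
#' @export
age_step_probabilities <- function(q01, q02, q10, q12, dt = 1) {
  q <- c(q01, q02, q10, q12)
  stopifnot(all(is.finite(q)), all(q >= 0), dt > 0)
  if (any(q > 50)) {
    warning("intensity above 50/year capped at 50")
    q <- pmin(q, 50)
  }
  P <- .expm_living(q[1], q[2], q[3], q[4], dt)
  matrix(c(P$p00, P$p01, P$p02,
           P$p10, P$p11, P$p12,
           0, 0, 1),
         nrow = 3, byrow = TRUE,
         dimnames = rep(list(c("nondisabled", "disabled", "dead")), 2))
}

#' Gompertz rate schedule over the life-table age bands
#'
#' Evaluates `lambda_r * exp(gamma_r * (a - 65))` at the mid-band ages of each
#' one-year band between `age_min` and `age_max`.
#'
#' @param lambda,gamma numeric vectors of length 4 in transition order
#'   `01, 02, 10, 12`.
#' @param age_min,age_max life-table age window (defaults 65 and 115).
#' @return matrix of intensities, one row per band, columns `q01,q02,q10,q12`.
#' @export
gompertz_rates <- function(lambda, gamma, age_min = 65, age_max = 115) {
  ages <- seq(age_min, age_max - 1) + 0.5
  out <- vapply(1:4, function(r) lambda[r] * exp(gamma[r] * (ages - 65)),
                numeric(length(ages)))
  matrix(out, nrow = length(ages),
         dimnames = list(format(ages), paste0("q", .transitions)))
}

#' Group-specific weighted transition rates
#'
#' Distributes an overall rate schedule over groups so that the person-years
#' mixture reproduces it exactly: with group proportions `pi_rg` and hazard
#' ratios `HR_rg` (reference group 1), the reference rate is
#' `q_r / sum_g pi_rg HR_rg` and group g's rate is `HR_rg` times that, hence
#' `sum_g pi_rg q_rg = q_r` at every age by construction.
#'
#' @param overall rate matrix (ages x 4, columns `q01,q02,q10,q12`), e.g. from
#'   [gompertz_rates()] or [predict.gompertz_msm()].
#' @param hr hazard-ratio matrix, groups x 4 transitions; the reference
#'   group's row must be all 1.  A group absent from a transition's risk set
#'   (`pi = 0`) simply drops out of the mixture (with a warning when a whole
#'   transition degenerates to one group).
#' @param pi proportion matrix from [group_proportions()] (4 transitions x
#'   groups, rows summing to 1).
#' @return named list of per-group rate matrices, with attribute
#'   `mixture_error` (largest absolute violation of the mixture identity).
#' @export
weighted_rates <- function(overall, hr, pi) {
  hr <- as.matrix(hr)
  pi <- as.matrix(pi)
  G <- nrow(hr)
  stopifnot(ncol(hr) == 4, nrow(pi) == 4, ncol(pi) == G,
            all(hr > 0), all(pi >= 0))
  if (max(abs(rowSums(pi) - 1)) > 1e-8) .stopf("pi rows must sum to 1")
  if (any(abs(hr[1, ] - 1) > 1e-12)) .stopf("first hr row must be the reference (all 1)")
  if (any(apply(pi > 0, 1, sum) < 2) && G > 1) {
    warning("a transition's risk set is concentrated in a single group; weighted rates reduce to the overall rate there")
  }
  groups <- rownames(hr)
  if (is.null(groups)) groups <- paste0("group", seq_len(G))
  denom <- colSums(t(pi) * hr)        # length 4: sum_g pi_rg * hr_gr
  out <- lapply(seq_len(G), function(g) {
    sweep(overall, 2, hr[g, ] / denom, "*")
  })
  names(out) <- groups
  mix <- Reduce(`+`, lapply(seq_len(G), function(g)
    sweep(out[[g]], 2, pi[, g], "*")))
  attr(out, "mixture_error") <- max(abs(mix - overall))
  out
}

#' Build a multi-state life table
#'
#' Propagates a starting state distribution at 65 through one-year bands with
#' the exact per-band matrix exponential, accumulates person-years by the
#' trapezoid rule, and closes the table at 115 (remaining survivorship
#' contributes no further person-years).  Disability-free LE is the
#' person-years lived nondisabled; by construction `DFLE + DLE = total LE`.
#'
#' @param rates rate matrix (bands x 4, columns `q01,q02,q10,q12`).
#' @param init length-2 distribution over the living states at 65 (sums to 1).
#' @param age_min starting age of the table.
#' @return object of class `mslt`: occupancy `l(a, s)`, person-years,
#'   `total_le`, `dfle`, `dle`, `pct_dfle`.
#' @export
build_life_table <- function(rates, init = c(1, 0), age_min = 65) {
  stopifnot(ncol(rates) == 4, all(rates >= 0), length(init) == 2)
  if (any(init < 0)) .stopf("init must be non-negative")
  if (abs(sum(init) - 1) > 1e-8) .stopf("init must sum to 1 over living states")
  nb <- nrow(rates)
  ages <- age_min + 0:nb
  occ <- matrix(0, nb + 1, 3,
                dimnames = list(ages, c("nondisabled", "disabled", "dead")))
  occ[1, ] <- c(init, 0)
  q <- pmin(rates, 50)
  P <- .expm_living(q[, 1], q[, 2], q[, 3], q[, 4], 1)
  for (a in seq_len(nb)) {
    l <- occ[a, ]
    occ[a + 1, 1] <- l[1] * P$p00[a] + l[2] * P$p10[a]
    occ[a + 1, 2] <- l[1] * P$p01[a] + l[2] * P$p11[a]
    occ[a + 1, 3] <- 1 - occ[a + 1, 1] - occ[a + 1, 2]
  }
  Lx <- (occ[-(nb + 1), 1:2, drop = FALSE] + occ[-1, 1:2, drop = FALSE]) / 2
  dfle <- sum(Lx[, 1])
  dle <- sum(Lx[, 2])
  total <- dfle + dle
  structure(list(
    ages = ages, occupancy = occ, person_years = Lx,
    total_le = total, dfle = dfle, dle = dle,
    pct_dfle = 100 * dfle / total, init = init, rates = rates
  ), class = "mslt")
}

#' @export
print.mslt <- function(x, ...) {
  cat(sprintf("Multi-state life table (%d-%d)\n", x$ages[1], max(x$ages)))
  cat(sprintf("  total LE at %d: %.3f y | DFLE %.3f y | disabled %.3f y | %%DFLE %.2f\n",
              x$ages[1], x$total_le, x$dfle, x$dle, x$pct_dfle))
  invisible(x)
}

#' @export
summary.mslt <- function(object, ...) {
  data.frame(total_le = object$total_le, dfle = object$dfle,
             dle = object$dle, pct_dfle = object$pct_dfle)
}

#' @export
plot.mslt <- function(x, ...) {
  matplot(x$ages, x$occupancy, type = "l", lty = 1, lwd = 2,
          xlab = "age (years)", ylab = "occupancy l(a, s)", ...)
  legend("right", legend = colnames(x$occupancy), col = 1:3, lty = 1,
         lwd = 2, bty = "n")
  invisible(x)
}

#' Group contrasts of life-table summaries
#'
#' Differences in total LE and DFLE against a reference group and the
#' percentage of total LE lived disability-free.
#'
#' @param x named list of `mslt` objects (or a data.frame with columns
#'   `group`, `total_le`, `dfle`); the reference is the first entry unless
#'   named by `reference`.
#' @param reference name of the reference group.
#' @return data.frame of class `mslt_contrasts` with columns `group`,
#'   `total_le`, `total_diff`, `dfle`, `dfle_diff`, `dle`, `pct_dfle`.
#' @export
le_contrasts <- function(x, reference = NULL) {
  if (is.data.frame(x)) {
    df <- x
    stopifnot(all(c("group", "total_le", "dfle") %in% names(df)))
    if (!"dle" %in% names(df)) df$dle <- df$total_le - df$dfle
  } else {
    stopifnot(length(x) >= 1, all(vapply(x, inherits, TRUE, "mslt")))
    df <- do.call(rbind, lapply(names(x), function(g)
      cbind(group = g, summary(x[[g]]))))
  }
  if (is.null(reference)) reference <- df$group[1]
  if (!reference %in% df$group) .stopf("reference group '%s' missing", reference)
  ref <- df[df$group == reference, ]
  df <- rbind(ref, df[df$group != reference, , drop = FALSE])
  out <- data.frame(
    group = df$group,
    total_le = df$total_le,
    total_diff = df$total_le - ref$total_le,
    dfle = df$dfle,
    dfle_diff = df$dfle - ref$dfle,
    dle = df$dle,
    pct_dfle = 100 * df$dfle / df$total_le,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("mslt_contrasts", "data.frame")
  out
}
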