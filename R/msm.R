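# Transition episodes and Gompertz proportional-hazards estimation for the
# four transitions of the illness-death model with recovery:
#   01 nondisabled -> disabled      02 nondisabled -> dead
#   10 disabled -> nondisabled      12 disabled -> dead

#' Build transition episodes from a scored panel
#'
#' Converts consecutive wave pairs into left-truncated, right-censored
#' episodes on the age timescale.  While nondisabled a subject is at risk of
#' transitions 01 and 02; while disabled, of 10 and 12.  A state change
#' between waves is dated at the interval midpoint (the subject then enters
#' the new state's risk set from the midpoint to the next wave); death is
#' dated exactly at the death date, attributed from the last observed state.
#'
#' @param panel a scored `cohort_panel` (see [score_panel()]); subjects must be
#'   sorted by wave date, have `age`, and the state column must be logical.
#' @param state_col name of the logical disability-state column.
#' @param covariates character vector of panel columns copied onto each
#'   episode (taken from the wave opening the interval).
#' @return data.frame of episodes: `subject_id`, `transition`
#'   (`"01","02","10","12"`), `entry`, `exit` (ages in years), `event`,
#'   plus the requested covariates.
#' @export
build_episodes <- function(panel, state_col = "score_disabled",
                           covariates = character()) {
  stopifnot(state_col %in% names(panel))
  panel <- panel[order(panel$subject_id, panel$wave_date), , drop = FALSE]
  st <- as.integer(panel[[state_col]])
  if (anyNA(st)) .stopf("missing disability state in %d wave(s)", sum(is.na(st)))
  sub <- panel$subject_id
  n <- nrow(panel)
  same <- sub[-n] == sub[-1]
  i0 <- which(same)          # wave opening each within-subject interval
  i1 <- i0 + 1L
  a0 <- panel$age[i0]
  a1 <- panel$age[i1]
  if (any(a1 <= a0)) .stopf("non-increasing age within subject: data error")
  s0 <- st[i0]
  s1 <- st[i1]

  # death after the last wave of each dead subject
  last <- which(!duplicated(sub, fromLast = TRUE))
  dd <- if ("death_date" %in% names(panel)) panel$death_date[last] else
    rep(as.Date(NA), length(last))
  dead <- panel$vital_status[last] == "dead" & !is.na(dd)
  aD <- panel$age[last] + as.numeric(dd - panel$wave_date[last]) / 365.25
  if (any(dead & aD < panel$age[last])) {
    .stopf("death date before last wave: integrity error")
  }
  aD <- pmax(aD, panel$age[last] + 0.5 / 365.25)  # same-day guard
  dlast <- last[dead]

  ep <- function(rows, transition, entry, exit, event) {
    if (!length(rows)) return(NULL)
    cbind(data.frame(subject_id = sub[rows], transition = transition,
                     entry = entry, exit = exit, event = event,
                     stringsAsFactors = FALSE),
          panel[rows, covariates, drop = FALSE])
  }
  m <- (a0 + a1) / 2
  w00 <- which(s0 == 0 & s1 == 0); j <- i0[w00]
  w01 <- which(s0 == 0 & s1 == 1); j01 <- i0[w01]
  w11 <- which(s0 == 1 & s1 == 1); j11 <- i0[w11]
  w10 <- which(s0 == 1 & s1 == 0); j10 <- i0[w10]
  dead0 <- dlast[st[dlast] == 0]
  dead1 <- dlast[st[dlast] == 1]
  aD0 <- aD[dead][st[dlast] == 0]
  aD1 <- aD[dead][st[dlast] == 1]

  out <- rbind(
    ep(j, "01", a0[w00], a1[w00], 0L),
    ep(j, "02", a0[w00], a1[w00], 0L),
    ep(j01, "01", a0[w01], m[w01], 1L),
    ep(j01, "02", a0[w01], m[w01], 0L),
    ep(j01, "10", m[w01], a1[w01], 0L),
    ep(j01, "12", m[w01], a1[w01], 0L),
    ep(j11, "10", a0[w11], a1[w11], 0L),
    ep(j11, "12", a0[w11], a1[w11], 0L),
    ep(j10, "10", a0[w10], m[w10], 1L),
    ep(j10, "12", a0[w10], m[w10], 0L),
    ep(j10, "01", m[w10], a1[w10], 0L),
    ep(j10, "02", m[w10], a1[w10], 0L),
    ep(dead0, "02", panel$age[dead0], aD0, 1L),
    ep(dead0, "01", panel$age[dead0], aD0, 0L),
    ep(dead1, "12", panel$age[dead1], aD1, 1L),
    ep(dead1, "10", panel$age[dead1], aD1, 0L)
  )
  rownames(out) <- NULL
  out
}

#' Fit a Gompertz proportional-hazards model to one transition's episodes
#'
#' Maximum likelihood for the hazard `lambda * exp(gamma * (age - 65)) *
#' exp(beta' x)` under left truncation at the episode entry age and right
#' censoring, using the closed-form Gompertz cumulative hazard and an analytic
#' gradient.  Restarts from jittered initial values if the optimiser fails.
#'
#' @param entry,exit episode entry and exit ages (years).
#' @param event 0/1 episode event indicators.
#' @param X optional covariate matrix (one row per episode).
#' @param init optional starting values `(log lambda, gamma, beta...)`.
#' @param restarts number of jittered restarts on failure.
#' @param fix_gamma if `TRUE`, the age slope is fixed at 0, reducing the model
#'   to a constant (exponential) rate.
#' @param hessian if `TRUE` (default), invert the observed information for the
#'   covariance of the estimates; skipped inside bootstrap replicates.
#' @param rel_tol relative convergence tolerance of the optimiser.
#' @return object of class `gompertz_fit`: `lambda`, `gamma`, `beta`, `vcov`,
#'   `loglik`, `events`, `person_years`, `convergence`.
#' @export
fit_gompertz <- function(entry, exit, event, X = NULL, init = NULL,
                         restarts = 5, fix_gamma = FALSE, hessian = TRUE,
                         rel_tol = 1e-10) {
  stopifnot(length(entry) == length(exit), length(exit) == length(event),
            all(exit > entry))
  if (is.null(X)) X <- matrix(0, length(entry), 0)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  events <- sum(event)
  py <- sum(exit - entry)
  if (events == 0) .stopf("no events in episode set: cannot fit")
  u0 <- as.numeric(entry - 65)
  u1 <- as.numeric(exit - 65)
  ev <- as.integer(event)
  p <- ncol(X)
  # fn and gr share one evaluation per parameter value
  last_par <- NULL
  last_val <- NULL
  eval_at <- function(par) {
    if (is.null(last_par) || !identical(par, last_par)) {
      last_val <<- gomp_nll_cpp(par, u0, u1, ev, X)
      last_par <<- par
    }
    last_val
  }
  if (fix_gamma) {
    expand <- function(par) append(par, 0, after = 1)
    fn <- function(par) eval_at(expand(par))$value
    gr <- function(par) eval_at(expand(par))$gradient[-2]
    par0 <- if (is.null(init)) c(log(events / py), rep(0, p)) else init[-2]
  } else {
    fn <- function(par) eval_at(par)$value
    gr <- function(par) eval_at(par)$gradient
    par0 <- if (is.null(init)) c(log(events / py), 0.05, rep(0, p)) else init
  }
  # the objective is convex (Cauchy-Schwarz on the Gompertz cumulative
  # hazard), so a damped Newton iteration with the analytic Hessian is the
  # primary solver; quasi-Newton restarts are kept as a safety net
  idx <- if (fix_gamma) setdiff(seq_len(2 + p), 2L) else seq_len(2 + p)
  full0 <- if (fix_gamma) append(par0, 0, after = 1) else par0
  newton <- function(par_full) {
    val <- NULL
    for (it in seq_len(100L)) {
      ev2 <- gomp_nll_hess_cpp(par_full, u0, u1, ev, X)
      g <- ev2$gradient[idx]
      Hm <- ev2$hessian[idx, idx, drop = FALSE]
      if (!all(is.finite(c(ev2$value, g, Hm)))) return(NULL)
      val <- ev2$value
      if (max(abs(g)) < 1e-8 * max(1, abs(val))) break
      step <- tryCatch(solve(Hm + diag(1e-10, length(idx)), g),
                       error = function(e) NULL)
      if (is.null(step)) return(NULL)
      tt <- 1
      repeat {
        cand <- par_full
        cand[idx] <- par_full[idx] - tt * step
        v2 <- gomp_nll_cpp(cand, u0, u1, ev, X)$value
        if (is.finite(v2) && v2 <= val + 1e-12) break
        tt <- tt / 2
        if (tt < 1e-10) return(NULL)
      }
      improved <- val - v2
      par_full <- cand
      val <- v2
      if (improved < rel_tol * (abs(val) + 1e-3)) break
    }
    list(par = par_full[idx], value = val, convergence = 0L)
  }
  best <- newton(full0)
  if (is.null(best)) {
    for (r in seq_len(restarts + 1L)) {
      start <- if (r == 1L) par0 else
        par0 + rnorm(length(par0), sd = 0.3)
      opt <- tryCatch({
        nb <- nlminb(start, fn, gr,
                     control = list(rel.tol = rel_tol, iter.max = 500))
        list(par = nb$par, value = nb$objective,
             convergence = as.integer(nb$convergence != 0))
      }, error = function(e) NULL)
      if (is.null(opt) || !is.finite(opt$value)) {
        opt <- tryCatch(
          optim(start, fn, gr, method = "BFGS",
                control = list(maxit = 500, reltol = 1e-10)),
          error = function(e) NULL)
      }
      if (is.null(opt) || !is.finite(opt$value)) next
      if (is.null(best) || opt$value < best$value) best <- opt
      if (best$convergence == 0) break
    }
  }
  if (is.null(best)) .stopf("Gompertz fit failed after %d restart(s)", restarts)
  V <- NULL
  if (hessian) {
    full_best <- best$par
    if (fix_gamma) full_best <- append(full_best, 0, after = 1)
    H <- gomp_nll_hess_cpp(full_best, u0, u1, ev, X)$hessian[idx, idx,
                                                             drop = FALSE]
    V <- tryCatch(solve(H), error = function(e) NULL)
  }
  par_full <- if (fix_gamma) append(best$par, 0, after = 1) else best$par
  beta <- par_full[-(1:2)]
  names(beta) <- colnames(X)
  structure(list(
    lambda = exp(par_full[1]), gamma = par_full[2], beta = beta,
    par = par_full, vcov = V, loglik = -best$value,
    events = events, person_years = py, n = length(entry),
    convergence = best$convergence
  ), class = "gompertz_fit")
}

#' @export
print.gompertz_fit <- function(x, ...) {
  cat(sprintf(
    "Gompertz PH fit: lambda = %.5f /py at 65, gamma = %.4f /y (%d events, %.0f py)\n",
    x$lambda, x$gamma, x$events, x$person_years))
  if (length(x$beta)) {
    cat("  hazard ratios:\n")
    print(round(exp(x$beta), 4))
  }
  invisible(x)
}

# ---- exact interval (panel) likelihood -------------------------------------

# per-subject interval table for the panel likelihood
.panel_intervals <- function(panel, state_col, covariates) {
  panel <- panel[order(panel$subject_id, panel$wave_date), , drop = FALSE]
  st <- as.integer(panel[[state_col]])
  sub <- panel$subject_id
  n <- nrow(panel)
  same <- if (n > 1) sub[-n] == sub[-1] else logical(0)
  i0 <- which(same)
  i1 <- i0 + 1L
  last <- which(!duplicated(sub, fromLast = TRUE))
  dd <- if ("death_date" %in% names(panel)) panel$death_date[last] else
    rep(as.Date(NA), length(last))
  dead <- panel$vital_status[last] == "dead" & !is.na(dd)
  aD <- panel$age[last] + as.numeric(dd - panel$wave_date[last]) / 365.25
  aD <- pmax(aD, panel$age[last] + 0.5 / 365.25)
  rows <- c(i0, last[dead])
  iv <- data.frame(
    a0 = c(panel$age[i0], panel$age[last[dead]]),
    a1 = c(panel$age[i1], aD[dead]),
    s0 = c(st[i0], st[last[dead]]),
    s1 = c(st[i1], rep(NA_integer_, sum(dead))),
    death = c(rep(FALSE, length(i0)), rep(TRUE, sum(dead)))
  )
  X <- if (length(covariates)) {
    mm <- model.matrix(as.formula(paste("~", paste(covariates, collapse = "+"))),
                       panel[rows, covariates, drop = FALSE])
    mm[, -1, drop = FALSE]
  } else matrix(0, nrow(iv), 0)
  iv$u_mid <- (iv$a0 + iv$a1) / 2 - 65
  iv$u1 <- iv$a1 - 65
  iv$dt <- iv$a1 - iv$a0
  al <- !iv$death
  iv <- as.list(iv)
  iv$i00 <- which(al & iv$s0 == 0 & iv$s1 == 0)
  iv$i01 <- which(al & iv$s0 == 0 & iv$s1 == 1)
  iv$i10 <- which(al & iv$s0 == 1 & iv$s1 == 0)
  iv$i11 <- which(al & iv$s0 == 1 & iv$s1 == 1)
  iv$id0 <- which(iv$death & iv$s0 == 0)
  iv$id1 <- which(iv$death & iv$s0 == 1)
  list(iv = iv, X = X)
}

.interval_nll <- function(par, iv, X, subdivisions = 2L) {
  p <- ncol(X)
  th <- matrix(par, nrow = 2 + p, ncol = 4)  # columns: 01, 02, 10, 12
  xb <- if (p) lapply(1:4, function(r) drop(X %*% th[-(1:2), r, drop = FALSE]))
    else rep(list(0), 4)
  q <- function(r, u, rows = NULL) {
    if (is.null(rows)) exp(th[1, r] + th[2, r] * u + xb[[r]])
    else exp(th[1, r] + th[2, r] * u[rows] +
               (if (p) xb[[r]][rows] else 0))
  }
  # piecewise-constant intensities over equal sub-bands of each interval,
  # each evaluated at its own midpoint age
  dt_k <- iv$dt / subdivisions
  P <- NULL
  for (k in seq_len(subdivisions)) {
    u_k <- iv$u_mid + (k - 0.5 - subdivisions / 2) * dt_k
    Pk <- .expm_living(q(1, u_k), q(2, u_k), q(3, u_k), q(4, u_k), dt_k)
    P <- if (is.null(P)) Pk else list(
      p00 = P$p00 * Pk$p00 + P$p01 * Pk$p10,
      p01 = P$p00 * Pk$p01 + P$p01 * Pk$p11,
      p10 = P$p10 * Pk$p00 + P$p11 * Pk$p10,
      p11 = P$p10 * Pk$p01 + P$p11 * Pk$p11)
  }
  lik <- numeric(length(iv$u_mid))
  lik[iv$i00] <- P$p00[iv$i00]
  lik[iv$i01] <- P$p01[iv$i01]
  lik[iv$i10] <- P$p10[iv$i10]
  lik[iv$i11] <- P$p11[iv$i11]
  if (length(iv$id0) || length(iv$id1)) {
    if (length(iv$id0)) {
      lik[iv$id0] <- P$p00[iv$id0] * q(2, iv$u1, iv$id0) +
        P$p01[iv$id0] * q(4, iv$u1, iv$id0)
    }
    if (length(iv$id1)) {
      lik[iv$id1] <- P$p10[iv$id1] * q(2, iv$u1, iv$id1) +
        P$p11[iv$id1] * q(4, iv$u1, iv$id1)
    }
  }
  -sum(log(pmax(lik, 1e-300)))
}

#' Fit the four-transition Gompertz multi-state model
#'
#' Fits Gompertz proportional-hazards intensities for the four transitions of
#' the illness-death-with-recovery model from a scored wave panel.
#'
#' `method = "episode"` (default) splits the panel into midpoint-imputed
#' transition episodes with [build_episodes()] and maximises each transition's
#' left-truncated, right-censored likelihood separately — the fast sequential
#' design that also powers the bootstrap.  `method = "interval"` maximises the
#' exact interval likelihood of the observed state sequence (transition
#' probabilities between waves from the matrix exponential of the generator,
#' with intensities evaluated at the interval midpoint age, and an exact
#' density term at death dates); it is slower but free of the midpoint
#' approximation's attribution bias.
#'
#' @param panel scored `cohort_panel`.
#' @param covariates character vector of covariate columns (factors expand to
#'   dummies); hazard ratios `exp(beta)` are estimated per transition.
#' @param state_col logical disability-state column.
#' @param method `"episode"` or `"interval"`.
#' @param episodes optionally, pre-built episodes (episode method only).
#' @return object of class `gompertz_msm` with one `gompertz_fit` per
#'   transition (named `"01"`, `"02"`, `"10"`, `"12"`).
#' @export
gompertz_msm <- function(panel, covariates = character(),
                         state_col = "score_disabled",
                         method = c("episode", "interval"),
                         episodes = NULL) {
  method <- match.arg(method)
  cl <- match.call()
  if (method == "episode") {
    if (is.null(episodes)) {
      episodes <- build_episodes(panel, state_col, covariates)
    }
    fits <- .fit_episode_msm(episodes, covariates)
  } else {
    pi_ <- .panel_intervals(panel, state_col, covariates)
    init_fits <- .fit_episode_msm(build_episodes(panel, state_col, covariates),
                                  covariates)
    p <- ncol(pi_$X)
    par0 <- unlist(lapply(.transitions, function(tr) {
      f <- init_fits[[tr]]
      if (is.null(f$par)) c(log(1e-4), 0.05, rep(0, p)) else f$par
    }))
    fn <- function(par) .interval_nll(par, pi_$iv, pi_$X)
    nb <- nlminb(par0, fn,
                 control = list(rel.tol = 1e-10, iter.max = 500))
    opt <- list(par = nb$par, value = nb$objective,
                convergence = as.integer(nb$convergence != 0))
    th <- matrix(opt$par, nrow = 2 + p, ncol = 4)
    H <- tryCatch(optimHess(opt$par, fn), error = function(e) NULL)
    V <- if (!is.null(H)) tryCatch(solve(H), error = function(e) NULL)
      else NULL
    fits <- setNames(lapply(1:4, function(r) {
      idx <- (r - 1) * (2 + p) + seq_len(2 + p)
      beta <- th[-(1:2), r]
      names(beta) <- colnames(pi_$X)
      structure(list(
        lambda = exp(th[1, r]), gamma = th[2, r], beta = beta,
        par = th[, r],
        vcov = if (!is.null(V)) V[idx, idx, drop = FALSE] else NULL,
        loglik = -opt$value, events = init_fits[[r]]$events,
        person_years = init_fits[[r]]$person_years,
        convergence = opt$convergence
      ), class = "gompertz_fit")
    }), .transitions)
  }
  structure(list(
    call = cl, transitions = fits, method = method,
    covariates = covariates, state_col = state_col,
    loglik = sum(vapply(fits, function(f)
      if (is.null(f$loglik)) 0 else f$loglik, numeric(1)))
  ), class = "gompertz_msm")
}

.fit_episode_msm <- function(episodes, covariates) {
  X_all <- if (length(covariates)) {
    mm <- model.matrix(as.formula(paste("~", paste(covariates, collapse = "+"))),
                       episodes[, covariates, drop = FALSE])
    mm[, -1, drop = FALSE]
  } else NULL
  setNames(lapply(.transitions, function(tr) {
    sel <- episodes$transition == tr
    if (!any(sel)) return(.zero_rate_fit())
    ev <- episodes$event[sel]
    if (sum(ev) == 0) {
      warning(sprintf("transition %s has zero events; its rate is set to 0", tr))
      return(.zero_rate_fit(py = sum(episodes$exit[sel] - episodes$entry[sel])))
    }
    fit_gompertz(episodes$entry[sel], episodes$exit[sel], ev,
                 X = if (is.null(X_all)) NULL else X_all[sel, , drop = FALSE])
  }), .transitions)
}

.zero_rate_fit <- function(py = 0) {
  structure(list(lambda = 0, gamma = 0, beta = numeric(0), par = NULL,
                 vcov = NULL, loglik = 0, events = 0, person_years = py,
                 convergence = 0L),
            class = "gompertz_fit")
}

#' @export
print.gompertz_msm <- function(x, ...) {
  cat(sprintf("Four-transition Gompertz multi-state model (%s likelihood)\n",
              x$method))
  for (tr in .transitions) {
    f <- x$transitions[[tr]]
    cat(sprintf("  %s: lambda = %.5f, gamma = %+.4f (%d events, %.0f py)\n",
                tr, f$lambda, f$gamma, f$events, f$person_years))
  }
  if (length(x$covariates)) {
    cat("  covariates:", paste(x$covariates, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.gompertz_msm <- function(object, ...) {
  rows <- lapply(.transitions, function(tr) {
    f <- object$transitions[[tr]]
    se <- if (!is.null(f$vcov)) sqrt(pmax(diag(f$vcov), 0)) else
      rep(NA_real_, length(f$par))
    data.frame(
      transition = tr,
      parameter = c("log_lambda", "gamma", names(f$beta)),
      estimate = if (is.null(f$par)) c(-Inf, 0) else f$par,
      se = if (is.null(f$par)) c(NA, NA) else se,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$hr <- ifelse(out$parameter %in% c("log_lambda", "gamma"), NA,
                   exp(out$estimate))
  class(out) <- c("summary.gompertz_msm", "data.frame")
  out
}

#' @export
coef.gompertz_msm <- function(object, ...) {
  vapply(object$transitions, function(f) {
    c(lambda = f$lambda, gamma = f$gamma, f$beta)
  }, numeric(2 + length(object$transitions[[1]]$beta)))
}

#' @export
logLik.gompertz_msm <- function(object, ...) {
  structure(object$loglik, class = "logLik")
}

#' Predicted transition intensities by age
#'
#' @param object a `gompertz_msm` fit.
#' @param ages ages (years) at which to evaluate the hazards; defaults to the
#'   mid-band ages 65.5..114.5 used by the life table.
#' @param x covariate vector on the model-matrix scale (default: reference,
#'   all zero).
#' @param ... unused.
#' @return matrix of intensities, one row per age, columns `q01,q02,q10,q12`.
#' @export
predict.gompertz_msm <- function(object, ages = 65:114 + 0.5, x = NULL, ...) {
  out <- vapply(.transitions, function(tr) {
    f <- object$transitions[[tr]]
    eta <- if (!is.null(x) && length(f$beta)) sum(f$beta * x) else 0
    f$lambda * exp(f$gamma * (ages - 65) + eta)
  }, numeric(length(ages)))
  out <- matrix(out, nrow = length(ages),
                dimnames = list(format(ages), paste0("q", .transitions)))
  out
}

#' Martingale-type residuals of an episode-method fit
#'
#' `event - estimated cumulative hazard` per episode, concatenated over the
#' four transitions; sums to approximately zero per transition at the MLE.
#'
#' @param object a `gompertz_msm` fitted with `method = "episode"`.
#' @param episodes the episode set used for fitting.
#' @param ... unused.
#' @return data.frame `transition`, `residual`.
#' @export
residuals.gompertz_msm <- function(object, episodes, ...) {
  if (object$method != "episode") {
    .stopf("residuals are defined for the episode method")
  }
  X_all <- if (length(object$covariates)) {
    mm <- model.matrix(
      as.formula(paste("~", paste(object$covariates, collapse = "+"))),
      episodes[, object$covariates, drop = FALSE])
    mm[, -1, drop = FALSE]
  } else NULL
  out <- lapply(.transitions, function(tr) {
    sel <- episodes$transition == tr
    f <- object$transitions[[tr]]
    if (!any(sel) || f$lambda == 0) return(NULL)
    u0 <- episodes$entry[sel] - 65
    u1 <- episodes$exit[sel] - 65
    eta <- if (!is.null(X_all) && length(f$beta)) {
      drop(X_all[sel, , drop = FALSE] %*% f$beta)
    } else 0
    H <- if (abs(f$gamma) < 1e-9) {
      f$lambda * exp(eta) * (u1 - u0)
    } else {
      f$lambda * exp(eta) * (exp(f$gamma * u1) - exp(f$gamma * u0)) / f$gamma
    }
    data.frame(transition = tr, residual = episodes$event[sel] - H)
  })
  do.call(rbind, out)
}

#' Person-years share of each group in each transition's risk set
#'
#' @param episodes episode set from [build_episodes()].
#' @param groups named vector/factor mapping subject id to group, or the name
#'   of a column of `episodes`.
#' @return matrix of proportions, transitions in rows (each row sums to 1),
#'   groups in columns.
#' @export
group_proportions <- function(episodes, groups) {
  g <- if (is.character(groups) && length(groups) == 1 &&
           groups %in% names(episodes)) {
    episodes[[groups]]
  } else {
    if (is.null(names(groups))) .stopf("groups must be named by subject id")
    groups[as.character(episodes$subject_id)]
  }
  if (anyNA(g)) .stopf("unmapped subject(s) in group assignment")
  g <- factor(g)
  py <- episodes$exit - episodes$entry
  trs <- intersect(.transitions, unique(episodes$transition))
  tot <- tapply(py, list(factor(episodes$transition, trs), g), sum,
                default = 0)
  tot / rowSums(tot)
}

#' Two-group sample size for a disability/death outcome
#'
#' Smallest group sizes detecting an exposure odds ratio for a binary outcome
#' with a two-sided normal-approximation two-proportion test under unequal
#' allocation.  The unexposed proportion is derived from `p_exposed` on the
#' odds scale: `odds_unexposed = odds_exposed / odds_ratio`.
#'
#' @param p_exposed outcome proportion in the exposed group.
#' @param odds_ratio exposed:unexposed odds ratio (must differ from 1).
#' @param alpha two-sided type-I error.
#' @param power target power.
#' @param allocation ratio `n_unexposed / n_exposed`.
#' @return named integer vector `c(n_exposed, n_unexposed)`.
#' @export
plan_sample_size <- function(p_exposed, odds_ratio, alpha = 0.05,
                             power = 0.9, allocation = 1) {
  stopifnot(p_exposed > 0, p_exposed < 1, odds_ratio > 0, allocation > 0)
  if (abs(odds_ratio - 1) < 1e-12) {
    .stopf("odds_ratio = 1 implies an infinite sample size")
  }
  odds_u <- (p_exposed / (1 - p_exposed)) / odds_ratio
  p_u <- odds_u / (1 + odds_u)
  r <- allocation
  p_bar <- (p_exposed + r * p_u) / (1 + r)
  za <- qnorm(1 - alpha / 2)
  zb <- qnorm(power)
  num <- (za * sqrt((1 + 1 / r) * p_bar * (1 - p_bar)) +
            zb * sqrt(p_exposed * (1 - p_exposed) + p_u * (1 - p_u) / r))^2
  n_e <- ceiling(num / (p_exposed - p_u)^2)
  c(n_exposed = as.integer(n_e), n_unexposed = as.integer(ceiling(r * n_e)))
}
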