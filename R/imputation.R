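# Chained-equations multiple imputation: predictive mean matching for
# continuous targets, logistic-model draws for binary targets.

# k-nearest-donor predictive mean matching, vectorised through a sorted
# candidate window around each missing row's predicted mean
.pmm_match <- function(pred_obs, y_obs, pred_mis, k) {
  ord <- order(pred_obs)
  po <- pred_obs[ord]
  yo <- y_obs[ord]
  n_obs <- length(po)
  k <- min(k, n_obs)
  pos <- findInterval(pred_mis, po)
  off <- seq(-k, k - 1L)
  cand <- outer(pos, off, "+") + 1L            # candidate indices window
  cand[cand < 1L] <- 1L
  cand[cand > n_obs] <- n_obs
  dist <- abs(matrix(po[cand], nrow = length(pred_mis)) - pred_mis)
  pick <- integer(length(pred_mis))
  for (i in seq_along(pick)) {
    ci <- cand[i, ]
    di <- dist[i, ]
    keep <- !duplicated(ci)
    ci <- ci[keep]; di <- di[keep]
    nearest <- ci[order(di)[seq_len(min(k, length(ci)))]]
    pick[i] <- nearest[sample.int(length(nearest), 1L)]
  }
  yo[pick]
}

.impute_design <- function(panel, predictors) {
  X <- matrix(1, nrow(panel), 1)
  for (p in predictors) {
    v <- panel[[p]]
    if (is.numeric(v)) {
      X <- cbind(X, v)
    } else {
      lev <- sort(unique(v[!is.na(v)]))
      if (length(lev) > 1) {
        for (l in lev[-1]) X <- cbind(X, as.numeric(v == l))
      }
    }
  }
  X
}

#' Multiple imputation of missing covariates
#'
#' Fills missing values in the target columns by chained equations: continuous
#' targets by predictive mean matching (the imputed value is always an observed
#' donor value, drawn from the `k_donors` nearest predicted means) and binary
#' 0/1 targets by Bernoulli draws from a fitted logistic model.  Observed cells
#' are never altered.  Continuous targets are swept before binary ones in each
#' of `cycles` passes; a logistic fit that fails falls back to the observed
#' marginal frequency with a warning.
#'
#' @param panel a `cohort_panel` or data.frame.
#' @param targets character vector of columns to impute; by default every
#'   covariate column (`bmi`, `sleep_hours`, `education_years`, `mmse_score`,
#'   the illness flags) with at least one missing value.
#' @param predictors character vector of predictor columns (default: `age`,
#'   `gender` when present, plus the other targets).
#' @param m number of imputed datasets.
#' @param k_donors donor-pool size for predictive mean matching.
#' @param cycles chained-equations passes per dataset.
#' @param seed optional integer seed for reproducibility.
#' @return list of `m` completed panels (invisibly of class `cohort_panel`
#'   when the input was one), with an `imputation` attribute describing the
#'   targets.
#' @export
impute_panel <- function(panel, targets = NULL, predictors = NULL, m = 5,
                         k_donors = 5, cycles = 10, seed = NULL) {
  stopifnot(m >= 1, k_donors >= 1, cycles >= 1)
  if (!is.null(seed)) set.seed(seed)
  default_targets <- intersect(
    c("bmi", "sleep_hours", "education_years", "mmse_score", .illness_items),
    names(panel))
  if (is.null(targets)) {
    targets <- default_targets[vapply(panel[default_targets], anyNA, TRUE)]
  }
  if (!length(targets)) {
    out <- replicate(m, panel, simplify = FALSE)
    attr(out, "imputation") <- list(targets = character(0))
    return(out)
  }
  for (tg in targets) {
    if (!anyNA(panel[[tg]])) next
    if (all(is.na(panel[[tg]]))) .stopf("column '%s' has no observed values", tg)
  }
  binary <- vapply(targets, function(tg) {
    v <- panel[[tg]]
    is.numeric(v) && all(v[!is.na(v)] %in% c(0, 1))
  }, logical(1))
  sweep_order <- c(targets[!binary], targets[binary])
  if (is.null(predictors)) {
    predictors <- intersect(c("age", "gender"), names(panel))
  }

  out <- vector("list", m)
  fellback <- character(0)
  for (d in seq_len(m)) {
    imp <- panel
    # initial fill: random observed draws
    for (tg in targets) {
      mis <- is.na(imp[[tg]])
      obs <- imp[[tg]][!mis]
      imp[[tg]][mis] <- sample(obs, sum(mis), replace = TRUE)
    }
    for (cy in seq_len(cycles)) {
      for (tg in sweep_order) {
        mis <- is.na(panel[[tg]])
        if (!any(mis)) next
        preds <- setdiff(unique(c(predictors, targets)), tg)
        X <- .impute_design(imp, preds)
        y <- imp[[tg]]
        if (binary[[tg]]) {
          fit <- tryCatch(
            suppressWarnings(glm.fit(X[!mis, , drop = FALSE], panel[[tg]][!mis],
                                     family = binomial())),
            error = function(e) NULL)
          if (is.null(fit) || !fit$converged || anyNA(fit$coefficients)) {
            if (!tg %in% fellback) {
              warning(sprintf(
                "logistic imputation model for '%s' did not converge; using marginal frequency", tg))
              fellback <- c(fellback, tg)
            }
            p_hat <- rep(mean(panel[[tg]][!mis]), sum(mis))
          } else {
            eta <- drop(X[mis, , drop = FALSE] %*% fit$coefficients)
            p_hat <- 1 / (1 + exp(-eta))
          }
          imp[[tg]][mis] <- rbinom(sum(mis), 1, p_hat)
        } else {
          cf <- qr.coef(qr(X[!mis, , drop = FALSE]), panel[[tg]][!mis])
          cf[is.na(cf)] <- 0
          pred <- drop(X %*% cf)
          imp[[tg]][mis] <- .pmm_match(pred[!mis], panel[[tg]][!mis],
                                       pred[mis], k_donors)
        }
      }
    }
    out[[d]] <- imp
  }
  attr(out, "imputation") <- list(targets = targets, binary = binary,
                                  m = m, k_donors = k_donors, cycles = cycles)
  out
}
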