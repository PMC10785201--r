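# Shared estimation core: from a scored, grouped panel to group life tables.
# Used by the pipeline for point estimates and re-run per bootstrap replicate.

.dfle_prepare <- function(panel, group_col, state_col = "score_disabled",
                          covariates = character()) {
  stopifnot(group_col %in% names(panel))
  g <- panel[[group_col]]
  if (!is.factor(g)) g <- factor(g)
  panel[[group_col]] <- g
  episodes <- build_episodes(panel, state_col,
                             covariates = unique(c(group_col, covariates)))
  form <- as.formula(paste("~", paste(unique(c(group_col, covariates)),
                                      collapse = "+")))
  mm <- model.matrix(form, episodes)
  X_hr <- mm[, -1, drop = FALSE]
  grp_cols <- which(colnames(X_hr) %in%
                      paste0(group_col, levels(g)[-1]))
  first <- !duplicated(panel$subject_id)
  subjects <- data.frame(
    subject_id = panel$subject_id[first],
    group = panel[[group_col]][first],
    entry_age = panel$age[first],
    baseline_disabled = as.integer(panel[[state_col]][first]),
    stringsAsFactors = FALSE
  )
  list(
    episodes = episodes, X_hr = X_hr, grp_cols = grp_cols,
    group_levels = levels(g), group_col = group_col,
    rows_by_sub = split(seq_len(nrow(episodes)), episodes$subject_id),
    subjects = subjects,
    # plain vectors for the replicate-level hot path
    ep_entry = episodes$entry, ep_exit = episodes$exit,
    ep_event = episodes$event,
    ep_tr = factor(episodes$transition, .transitions),
    ep_group = as.integer(episodes[[group_col]]),
    ep_py = episodes$exit - episodes$entry
  )
}

# fit one transition on a row subset; transition 10 may legitimately have
# zero observed recoveries (rate pinned at 0)
.fit_transition <- function(prep, rows, tr, X = NULL, init = NULL,
                            hessian = TRUE) {
  sel <- rows[prep$ep_tr[rows] == tr]
  if (!length(sel) || sum(prep$ep_event[sel]) == 0) {
    if (tr == "10") {
      return(.zero_rate_fit(py = sum(prep$ep_py[sel])))
    }
    .stopf("transition %s has zero events", tr)
  }
  fit_gompertz(prep$ep_entry[sel], prep$ep_exit[sel], prep$ep_event[sel],
               X = if (is.null(X)) NULL else X[sel, , drop = FALSE],
               init = init, restarts = 2, hessian = hessian,
               rel_tol = if (hessian) 1e-10 else 1e-8)
}

# One full pass of the weighted-rate estimation chain on a subject subset.
# subj_sel: character ids (possibly with repetitions) or NULL for all.
.dfle_estimate <- function(prep, subj_sel = NULL, init = "prevalence",
                           warm = NULL) {
  rows <- if (is.null(subj_sel)) seq_len(nrow(prep$episodes)) else
    unlist(prep$rows_by_sub[subj_sel], use.names = FALSE)
  hess <- is.null(subj_sel)
  overall <- setNames(lapply(.transitions, function(tr)
    .fit_transition(prep, rows, tr, init = warm$overall[[tr]]$par,
                    hessian = hess)), .transitions)
  hrfit <- setNames(lapply(.transitions, function(tr)
    .fit_transition(prep, rows, tr, X = prep$X_hr,
                    init = warm$hrfit[[tr]]$par, hessian = hess)),
    .transitions)
  G <- length(prep$group_levels)
  hr <- matrix(1, G, 4, dimnames = list(prep$group_levels, .transitions))
  for (r in seq_along(.transitions)) {
    b <- hrfit[[r]]$beta
    if (length(b)) hr[-1, r] <- exp(b[prep$grp_cols])
  }
  code <- (prep$ep_group[rows] - 1L) * 4L + as.integer(prep$ep_tr[rows])
  py_gt <- rowsum(prep$ep_py[rows], code)
  pi_ <- matrix(0, 4, G, dimnames = list(.transitions, prep$group_levels))
  pi_[as.integer(rownames(py_gt))] <- py_gt[, 1]
  pi_ <- pi_ / rowSums(pi_)
  lam <- vapply(overall, `[[`, 0, "lambda")
  gam <- vapply(overall, `[[`, 0, "gamma")
  q_overall <- gompertz_rates(lam, gam)
  q_groups <- weighted_rates(q_overall, hr, pi_)

  subj <- prep$subjects
  if (!is.null(subj_sel)) subj <- subj[match(subj_sel, subj$subject_id), ]
  lts <- setNames(lapply(prep$group_levels, function(g) {
    i0 <- if (init == "healthy") c(1, 0) else {
      young <- subj$group == g & subj$entry_age < 70
      if (any(young)) {
        p1 <- mean(subj$baseline_disabled[young])
        c(1 - p1, p1)
      } else c(1, 0)
    }
    build_life_table(q_groups[[g]], init = i0)
  }), prep$group_levels)
  contrasts <- le_contrasts(lts, reference = prep$group_levels[1])
  list(contrasts = contrasts, life_tables = lts, overall = overall,
       hrfit = hrfit, hr = hr, pi = pi_, rates = q_groups,
       mixture_error = attr(q_groups, "mixture_error"))
}

# flatten the replicate quantities tracked by the bootstrap
.contrast_vector <- function(contrasts) {
  v <- unlist(lapply(seq_len(nrow(contrasts)), function(i) {
    g <- contrasts$group[i]
    setNames(as.numeric(contrasts[i, c("total_le", "dfle", "dle", "pct_dfle",
                                       "total_diff", "dfle_diff")]),
             paste0(c("total_le_", "dfle_", "dle_", "pct_dfle_",
                      "total_diff_", "dfle_diff_"), g))
  }))
  v
}

#' Percentile bootstrap confidence intervals for the life-table quantities
#'
#' Resamples subjects with replacement, reruns the whole estimation chain
#' (episode building, sequential Gompertz fits, hazard ratios, group
#' proportions, weighted rates, life tables) on each replicate, and returns
#' percentile 2.5/97.5 bounds around the original-sample point estimates.
#' Replicates in which a mandatory transition loses all its events are dropped
#' with a log note; more than 10% dropped triggers a warning.
#'
#' @param panel scored `cohort_panel` containing the group column.
#' @param group_col name of the factor group column (reference level first).
#' @param B number of bootstrap replicates.
#' @param seed optional integer seed.
#' @param state_col logical disability-state column.
#' @param covariates adjustment covariates for the hazard-ratio fits.
#' @param init life-table starting distribution rule: `"prevalence"` (observed
#'   baseline state among subjects entering below age 70, per group) or
#'   `"healthy"` (everyone nondisabled at 65).
#' @param conf confidence level.
#' @return object of class `dfle_boot`: `point` (the contrast table), `ci`
#'   (named matrix of lower/upper bounds), `replicates`, `B_effective`.
#' @export
bootstrap_dfle <- function(panel, group_col, B = 1000, seed = NULL,
                           state_col = "score_disabled",
                           covariates = character(), init = "prevalence",
                           conf = 0.95) {
  stopifnot(B >= 2)
  if (!is.null(seed)) set.seed(seed)
  prep <- .dfle_prepare(panel, group_col, state_col, covariates)
  point <- .dfle_estimate(prep, init = init)
  ids <- prep$subjects$subject_id
  reps <- vector("list", B)
  n_fail <- 0L
  for (b in seq_len(B)) {
    sel <- sample(ids, length(ids), replace = TRUE)
    est <- tryCatch(
      .dfle_estimate(prep, subj_sel = sel, init = init, warm = point),
      error = function(e) NULL)
    if (is.null(est)) {
      n_fail <- n_fail + 1L
      next
    }
    reps[[b]] <- .contrast_vector(est$contrasts)
  }
  reps <- do.call(rbind, reps[!vapply(reps, is.null, TRUE)])
  if (n_fail > 0) {
    message(sprintf("bootstrap: %d of %d replicate(s) dropped", n_fail, B))
    if (n_fail > 0.1 * B) warning("more than 10% of bootstrap replicates dropped")
  }
  alpha <- (1 - conf) / 2
  ci <- apply(reps, 2, quantile, probs = c(alpha, 1 - alpha), names = FALSE,
              type = 6)
  rownames(ci) <- c("lower", "upper")
  structure(list(point = point$contrasts,
                 point_vector = .contrast_vector(point$contrasts),
                 ci = ci, replicates = reps,
                 B = B, B_effective = nrow(reps), conf = conf),
            class = "dfle_boot")
}

#' @export
print.dfle_boot <- function(x, ...) {
  cat(sprintf("Bootstrap life-table intervals (%d/%d usable replicates, %.0f%% CI)\n",
              x$B_effective, x$B, 100 * x$conf))
  est <- x$point_vector
  for (nm in names(est)) {
    cat(sprintf("  %-28s %8.3f (%8.3f, %8.3f)\n", nm, est[[nm]],
                x$ci["lower", nm], x$ci["upper", nm]))
  }
  invisible(x)
}
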