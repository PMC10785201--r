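# End-to-end orchestration: simulate/read -> exclusions -> imputation ->
# scoring -> trajectory grouping -> transition fits -> life tables ->
# bootstrap.

#' Pipeline run configuration
#'
#' Single source of truth for a pipeline run.  All tunables of the estimation
#' chain live here; [read_run_config()] fills the same structure from a YAML
#' file.
#'
#' @param definition disability definition used for the working state
#'   (`"any_of_five"` or one of the five individual definitions).
#' @param grouping `"lifestyle"` (two trajectory groups) or
#'   `"ses_x_lifestyle"` (four joint groups, lower-SES unfavourable as
#'   reference).
#' @param strata `NULL` or `"gender"` for a stratified rerun (the stratum
#'   variable is removed from the adjustment set).
#' @param covariates adjustment covariates for the hazard-ratio fits, named by
#'   panel columns (`"ses_group"` and `"gender"` by default).
#' @param K_range,degree_range,n_starts latent-class search grid for the
#'   trajectory models.
#' @param B bootstrap replicates (0 = no bootstrap).
#' @param init life-table starting distribution rule (`"prevalence"` or
#'   `"healthy"`).
#' @param method transition-intensity estimator: `"episode"` (midpoint
#'   episodes, sequential fits) or `"interval"` (exact interval likelihood).
#' @param impute run multiple imputation on missing covariates.
#' @param m imputed datasets; `pool` is `"first"` (use the first completed
#'   dataset) or `"average"` (average the life-table outputs over all `m`).
#' @param seed integer seed controlling every random stage.
#' @param verbose emit per-stage log lines.
#' @return a `dfle_config` list.
#' @export
dfle_config <- function(definition = "any_of_five",
                        grouping = c("lifestyle", "ses_x_lifestyle"),
                        strata = NULL,
                        covariates = c("ses_group", "gender"),
                        K_range = 2:3, degree_range = 1, n_starts = 10,
                        B = 0, init = "prevalence",
                        method = c("episode", "interval"),
                        impute = TRUE, m = 5, pool = c("first", "average"),
                        seed = 1, verbose = FALSE) {
  cfg <- list(definition = definition, grouping = match.arg(grouping),
              strata = strata, covariates = covariates,
              K_range = K_range, degree_range = degree_range,
              n_starts = n_starts, B = B, init = init,
              method = match.arg(method), impute = impute, m = m,
              pool = match.arg(pool), seed = seed, verbose = verbose)
  class(cfg) <- "dfle_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file whose keys match the arguments of [dfle_config()].
#' @return a `dfle_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(dfle_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) .stopf("unknown config key(s): %s", paste(bad, collapse = ", "))
  if (!is.null(vals$K_range)) vals$K_range <- do.call(seq, as.list(range(vals$K_range)))
  do.call(dfle_config, vals)
}

# latent-class trajectory grouping of one longitudinal outcome
.trajectory_groups <- function(panel, outcome, cfg, labels, higher_first,
                               seed) {
  first_age <- ave(panel$age, panel$subject_id, FUN = min)
  d <- data.frame(id = panel$subject_id, t = panel$age - first_age,
                  y = panel[[outcome]])
  # the mixture is fitted on subjects observed at >= 2 waves; subjects with a
  # single usable wave are classified afterwards from their posterior
  nw <- ave(seq_along(d$id), d$id, FUN = length)
  grid <- expand.grid(K = cfg$K_range, degree = cfg$degree_range)
  fits <- lapply(seq_len(nrow(grid)), function(i) {
    lcga(y ~ t, d[nw >= 2, ], subject = "id", K = grid$K[i],
         degree = grid$degree[i], n_starts = cfg$n_starts, seed = seed + i)
  })
  best <- select_lcga(fits)
  best$posterior <- .lcga_posterior_for(best, d$y, d$t, d$id)
  if (best$K != 2) {
    warning(sprintf("selected %d-class trajectory model for '%s'; using the two extreme classes for labelling", best$K, outcome))
  }
  groups <- assign_groups(best, labels = if (best$K == 2) labels else
    paste0("class", seq_len(best$K)), higher_first = higher_first)
  list(model = best, groups = groups, candidates = fits)
}

#' Run the full disability-free life expectancy pipeline
#'
#' Orchestrates: cohort simulation (when no panel is given), exclusions,
#' covariate imputation, scoring, latent-class trajectory grouping of the
#' healthy-lifestyle count (and of SEVI for the SES grouping), the
#' four-transition Gompertz fits with adjusted hazard ratios, group
#' proportions, weighted rates, the 65-115 multi-state life tables, group
#' contrasts and (optionally) the percentile bootstrap.
#'
#' @param panel a `cohort_panel`, or `NULL` to simulate from `scenario`.
#' @param scenario a [sim_scenario()] used when `panel` is `NULL`.
#' @param config a [dfle_config()].
#' @return object of class `dfle_run` containing every stage's output and a
#'   manifest of seeds and row counts.
#' @export
dfle_pipeline <- function(panel = NULL, scenario = NULL,
                          config = dfle_config()) {
  cfg <- config
  t0 <- Sys.time()
  truth <- NULL
  set.seed(cfg$seed)
  if (is.null(panel)) {
    .log_stage("simulate", "generating synthetic cohort", verbose = cfg$verbose)
    sim <- simulate_cohort(if (is.null(scenario)) sim_scenario() else scenario,
                           seed = cfg$seed)
    panel <- sim$panel
    truth <- sim$truth
  }
  excl <- apply_exclusions(panel)
  panel <- excl$panel
  .log_stage("exclusions", sprintf("retained %d subjects", excl$report$retained_n),
             verbose = cfg$verbose)

  imputed <- NULL
  if (cfg$impute) {
    imputed <- impute_panel(panel, m = cfg$m, seed = cfg$seed + 1000L)
    panel <- imputed[[1]]
    .log_stage("impute", sprintf("%d dataset(s), targets: %s", cfg$m,
                                 paste(attr(imputed, "imputation")$targets,
                                       collapse = ", ")),
               verbose = cfg$verbose)
  }
  panel <- score_panel(panel, definition = cfg$definition)
  .log_stage("score", sprintf("%d subject-waves scored", nrow(panel)),
             verbose = cfg$verbose)

  ls_traj <- .trajectory_groups(panel, "score_n_healthy", cfg,
                                labels = c("favourable", "unfavourable"),
                                higher_first = TRUE, seed = cfg$seed + 1L)
  ses_traj <- .trajectory_groups(panel, "score_sevi", cfg,
                                 labels = c("higher", "lower"),
                                 higher_first = FALSE, seed = cfg$seed + 101L)
  sid <- as.character(panel$subject_id)
  panel$lifestyle_group <- factor(as.character(ls_traj$groups[sid]),
                                  levels = c("unfavourable", "favourable"))
  panel$ses_group <- factor(as.character(ses_traj$groups[sid]),
                            levels = c("lower", "higher"))
  .log_stage("trajectories",
             sprintf("favourable share %.3f, higher-SES share %.3f",
                     mean(panel$lifestyle_group[!duplicated(panel$subject_id)] ==
                            "favourable"),
                     mean(panel$ses_group[!duplicated(panel$subject_id)] ==
                            "higher")),
             verbose = cfg$verbose)

  if (cfg$grouping == "ses_x_lifestyle") {
    lv <- c("unfavourable.lower", "favourable.lower",
            "unfavourable.higher", "favourable.higher")
    panel$joint_group <- factor(
      paste(panel$lifestyle_group, panel$ses_group, sep = "."), levels = lv)
    group_col <- "joint_group"
    covars <- setdiff(cfg$covariates, "ses_group")
  } else {
    group_col <- "lifestyle_group"
    covars <- cfg$covariates
  }

  run_one <- function(pan, covars) {
    if (cfg$method == "interval") {
      overall_msm <- gompertz_msm(pan, covariates = character(),
                                  state_col = "score_disabled",
                                  method = "interval")
      hr_msm <- gompertz_msm(pan, covariates = unique(c(group_col, covars)),
                             state_col = "score_disabled",
                             method = "interval")
      prep <- .dfle_prepare(pan, group_col, "score_disabled", covars)
      est <- .dfle_estimate(prep, init = cfg$init)
      # replace the episode-method rates and HRs by the interval-likelihood fit
      lam <- vapply(overall_msm$transitions, `[[`, 0, "lambda")
      gam <- vapply(overall_msm$transitions, `[[`, 0, "gamma")
      G <- length(prep$group_levels)
      hr <- matrix(1, G, 4, dimnames = list(prep$group_levels, .transitions))
      for (r in seq_along(.transitions)) {
        b <- hr_msm$transitions[[r]]$beta
        if (length(b)) hr[-1, r] <- exp(b[prep$grp_cols])
      }
      q_groups <- weighted_rates(gompertz_rates(lam, gam), hr, est$pi)
      lts <- setNames(lapply(prep$group_levels, function(g)
        build_life_table(q_groups[[g]],
                         init = if (cfg$init == "healthy") c(1, 0) else
                           est$life_tables[[g]]$init)),
        prep$group_levels)
      est$contrasts <- le_contrasts(lts, reference = prep$group_levels[1])
      est$life_tables <- lts
      est$hr <- hr
      est$rates <- q_groups
      est$overall_msm <- overall_msm
      est$hr_msm <- hr_msm
      est
    } else {
      prep <- .dfle_prepare(pan, group_col, "score_disabled", covars)
      .dfle_estimate(prep, init = cfg$init)
    }
  }

  if (!is.null(cfg$strata) && identical(cfg$strata, "gender")) {
    strata_est <- lapply(split(panel, panel$gender), run_one,
                         covars = setdiff(covars, "gender"))
    est <- run_one(panel, covars)
  } else {
    strata_est <- NULL
    est <- run_one(panel, covars)
  }
  .log_stage("fit", sprintf("mixture identity error %.2e", est$mixture_error),
             verbose = cfg$verbose)

  boot <- NULL
  if (cfg$B > 0) {
    boot <- bootstrap_dfle(panel, group_col, B = cfg$B,
                           seed = cfg$seed + 2000L,
                           covariates = covars, init = cfg$init)
    .log_stage("bootstrap", sprintf("%d usable replicates", boot$B_effective),
               verbose = cfg$verbose)
  }

  manifest <- list(
    seed = cfg$seed, definition = cfg$definition, grouping = cfg$grouping,
    method = cfg$method,
    n_subjects = length(unique(panel$subject_id)),
    n_waves = nrow(panel),
    exclusions = as.list(excl$report$counts),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  structure(list(
    config = cfg, panel = panel, exclusions = excl$report,
    imputation = attr(imputed, "imputation"),
    lifestyle_trajectory = ls_traj$model, ses_trajectory = ses_traj$model,
    group_col = group_col, estimate = est, strata = strata_est,
    bootstrap = boot, truth = truth, manifest = manifest
  ), class = "dfle_run")
}

#' @export
print.dfle_run <- function(x, ...) {
  cat("Disability-free life expectancy pipeline run\n")
  cat(sprintf("  %d subjects, %d subject-waves | definition: %s | grouping: %s (%s fits)\n",
              x$manifest$n_subjects, x$manifest$n_waves,
              x$config$definition, x$config$grouping, x$config$method))
  cat("  life-table contrasts at 65:\n")
  ct <- x$estimate$contrasts
  for (i in seq_len(nrow(ct))) {
    cat(sprintf("    %-22s total LE %7.3f (diff %+6.3f) | DFLE %7.3f (diff %+6.3f) | %%DFLE %5.2f\n",
                ct$group[i], ct$total_le[i], ct$total_diff[i], ct$dfle[i],
                ct$dfle_diff[i], round_half_away(ct$pct_dfle[i], 2)))
  }
  if (!is.null(x$bootstrap)) {
    cat(sprintf("  bootstrap: %d usable replicates\n", x$bootstrap$B_effective))
  }
  invisible(x)
}

#' Write the outputs of a pipeline run to a directory
#'
#' Writes the contrast summary (at reporting precision), the per-group life
#' tables, the transition-model coefficients, the subject group assignments
#' and a YAML manifest with seeds and row counts.
#'
#' @param run a `dfle_run`.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
write_dfle_run <- function(run, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(0)
  f <- file.path(dir, "summary.csv")
  write_results(run$estimate$contrasts, f)
  files <- c(files, f)
  for (g in names(run$estimate$life_tables)) {
    lt <- run$estimate$life_tables[[g]]
    f <- file.path(dir, paste0("lifetable_", gsub("[^a-z0-9]+", "_", g), ".csv"))
    write.csv(data.frame(age = lt$ages, lt$occupancy, check.names = FALSE),
              f, row.names = FALSE)
    files <- c(files, f)
  }
  coefs <- do.call(rbind, lapply(.transitions, function(tr) {
    fit <- run$estimate$overall[[tr]]
    data.frame(transition = tr, lambda = fit$lambda, gamma = fit$gamma,
               events = fit$events, person_years = fit$person_years)
  }))
  f <- file.path(dir, "transition_rates.csv")
  write.csv(coefs, f, row.names = FALSE)
  files <- c(files, f)
  first <- !duplicated(run$panel$subject_id)
  f <- file.path(dir, "group_assignments.csv")
  write.csv(data.frame(subject_id = run$panel$subject_id[first],
                       group = run$panel[[run$group_col]][first]),
            f, row.names = FALSE)
  files <- c(files, f)
  f <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(run$manifest, f)
  files <- c(files, f)
  invisible(files)
}
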