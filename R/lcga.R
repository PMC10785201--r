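# Latent class growth analysis (LCGA): a finite mixture of class-specific
# polynomial trajectories with class-specific residual variance and no
# within-class random effects, fitted by EM.

.lcga_estep <- function(y, X, subj, K, beta, sigma2, pi_k) {
  n <- max(subj)
  lp <- matrix(0, n, K)
  for (k in seq_len(K)) {
    r <- y - drop(X %*% beta[, k])
    ld <- -0.5 * (log(2 * pi * sigma2[k]) + r^2 / sigma2[k])
    lp[, k] <- rowsum(ld, subj)[, 1] + log(pi_k[k])
  }
  lse <- .row_logsumexp(lp)
  list(post = exp(lp - lse), loglik = sum(lse))
}

.lcga_em <- function(y, X, subj, K, post, max_iter, tol, min_weight) {
  n <- max(subj)
  loglik <- -Inf
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    pi_k <- colMeans(post)
    if (any(pi_k < min_weight)) {
      return(list(collapsed = TRUE))
    }
    beta <- matrix(0, ncol(X), K)
    sigma2 <- numeric(K)
    for (k in seq_len(K)) {
      w <- post[subj, k]
      fit <- lm.wfit(X, y, w)
      beta[, k] <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
      sigma2[k] <- max(sum(w * fit$residuals^2) / sum(w), 1e-8)
    }
    es <- .lcga_estep(y, X, subj, K, beta, sigma2, pi_k)
    post <- es$post
    trace <- c(trace, es$loglik)
    if (is.finite(loglik) && es$loglik - loglik < tol &&
        es$loglik >= loglik - 1e-8) {
      loglik <- es$loglik
      return(list(collapsed = FALSE, beta = beta, sigma2 = sigma2,
                  pi = pi_k, post = post, loglik = loglik, iter = it,
                  converged = TRUE, trace = trace))
    }
    loglik <- es$loglik
  }
  list(collapsed = FALSE, beta = beta, sigma2 = sigma2, pi = pi_k,
       post = post, loglik = loglik, iter = max_iter, converged = FALSE,
       trace = trace)
}

#' Fit a latent class growth model
#'
#' Fits a `K`-class mixture of polynomial trajectories of degree `degree` in
#' the time variable by EM, with class-specific residual variances and mixing
#' weights, taking the best of `n_starts` initialisations by log-likelihood
#' (the first start is a k-means partition of subject means, the rest are
#' random partitions).  A start in which a class collapses below one subject's
#' weight is discarded and restarted.
#'
#' @param formula `outcome ~ time`; both sides must be columns of `data`.
#' @param data data.frame in long format, one row per subject-observation.
#' @param subject name of the subject-id column.
#' @param K number of latent classes (>= 1).
#' @param degree polynomial degree of the class trajectories (1-3 typical).
#' @param n_starts number of initialisations.
#' @param seed optional integer seed.
#' @param max_iter,tol EM iteration cap and log-likelihood convergence
#'   tolerance.
#' @return an object of class `lcga` with coefficients (one column per class),
#'   residual SDs, mixing weights, the subject-by-class posterior matrix,
#'   log-likelihood and BIC (`-2 logLik + n_par log(n_subjects)`).
#' @examples
#' d <- data.frame(id = rep(1:60, each = 3), t = rep(0:2, 60))
#' d$y <- ifelse(d$id <= 30, 4.5, 2.5) + rnorm(nrow(d), sd = 0.5)
#' fit <- lcga(y ~ t, d, subject = "id", K = 2, n_starts = 3, seed = 1)
#' fit
#' @export
lcga <- function(formula, data, subject, K = 2, degree = 1, n_starts = 20,
                 seed = NULL, max_iter = 500, tol = 1e-6) {
  stopifnot(K >= 1, degree >= 0)
  if (!is.null(seed)) set.seed(seed)
  vars <- all.vars(formula)
  if (length(vars) != 2) .stopf("formula must be of the form outcome ~ time")
  y <- data[[vars[1]]]
  tv <- data[[vars[2]]]
  ids <- data[[subject]]
  ok <- !is.na(y) & !is.na(tv) & !is.na(ids)
  y <- y[ok]; tv <- tv[ok]; ids <- ids[ok]
  subj <- as.integer(factor(ids, levels = unique(ids)))
  id_levels <- unique(ids)
  n <- length(id_levels)
  nobs_subj <- tabulate(subj)
  if (any(nobs_subj < 2)) {
    .stopf("every subject needs >= 2 observations (%d subject(s) have fewer)",
           sum(nobs_subj < 2))
  }
  X <- outer(tv, 0:degree, "^")
  min_weight <- 1 / n

  subj_mean <- rowsum(y, subj)[, 1] / nobs_subj
  best <- NULL
  n_collapsed <- 0L
  for (s in seq_len(max(n_starts, 1L))) {
    assign <- if (s == 1L && K > 1L) {
      km <- suppressWarnings(kmeans(subj_mean, centers = K, nstart = 3))
      km$cluster
    } else if (K == 1L) {
      rep(1L, n)
    } else {
      sample.int(K, n, replace = TRUE)
    }
    post0 <- matrix(0.05 / max(K - 1, 1), n, K)
    post0[cbind(seq_len(n), assign)] <- 0.95
    if (K == 1L) post0 <- matrix(1, n, 1)
    fit <- .lcga_em(y, X, subj, K, post0, max_iter, tol, min_weight)
    if (isTRUE(fit$collapsed)) {
      n_collapsed <- n_collapsed + 1L
      next
    }
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
    if (K == 1L) break
  }
  if (is.null(best)) {
    .stopf("degenerate fit: a class collapsed in all %d start(s)", n_collapsed)
  }
  n_par <- K * (degree + 1) + K + (K - 1)
  bic <- -2 * best$loglik + n_par * log(n)
  rownames(best$beta) <- paste0("t^", 0:degree)
  colnames(best$beta) <- paste0("class", seq_len(K))
  # class mean trajectory averaged over the observed time points
  class_mean <- colMeans(X %*% best$beta)
  structure(list(
    call = match.call(), K = K, degree = degree,
    coefficients = best$beta, sigma = sqrt(best$sigma2), pi = best$pi,
    posterior = `rownames<-`(best$post, as.character(id_levels)),
    loglik = best$loglik, n_params = n_par, bic = bic,
    n_subjects = n, n_obs = length(y), subjects = id_levels,
    class_mean = class_mean, converged = best$converged, iter = best$iter,
    loglik_trace = best$trace, time_range = range(tv)
  ), class = "lcga")
}

#' @export
print.lcga <- function(x, ...) {
  cat(sprintf("Latent class growth model: K = %d, degree = %d, n = %d subjects\n",
              x$K, x$degree, x$n_subjects))
  cat(sprintf("  logLik %.3f | BIC %.3f | %s after %d EM iterations\n",
              x$loglik, x$bic,
              if (x$converged) "converged" else "NOT converged", x$iter))
  cat("  mixing weights:", sprintf("%.3f", x$pi), "\n")
  cat("  class means over observed times:",
      sprintf("%.3f", x$class_mean), "\n")
  invisible(x)
}

#' @export
coef.lcga <- function(object, ...) object$coefficients

#' @export
logLik.lcga <- function(object, ...) {
  structure(object$loglik, df = object$n_params, nobs = object$n_subjects,
            class = "logLik")
}

#' Posterior-classification diagnostics of an LCGA fit
#'
#' @param object an `lcga` fit.
#' @param threshold posterior-probability threshold used for the share
#'   diagnostic.
#' @param ... unused.
#' @return list with the modal assignment, per-class average posterior among
#'   assigned subjects, share of subjects with maximum posterior above the
#'   threshold, and class membership fractions.
#' @export
summary.lcga <- function(object, threshold = 0.7, ...) {
  post <- object$posterior
  cls <- max.col(post, ties.method = "first")
  maxp <- post[cbind(seq_len(nrow(post)), cls)]
  avg_post <- vapply(seq_len(object$K),
                     function(k) mean(maxp[cls == k]), numeric(1))
  out <- list(
    model = object,
    assignment = cls,
    avg_posterior = avg_post,
    share_above = mean(maxp > threshold),
    class_fraction = tabulate(cls, object$K) / nrow(post)
  )
  class(out) <- "summary.lcga"
  out
}

#' @export
print.summary.lcga <- function(x, ...) {
  print(x$model)
  cat("  avg posterior (assigned):", sprintf("%.3f", x$avg_posterior), "\n")
  cat(sprintf("  share with max posterior > 0.7: %.3f\n", x$share_above))
  cat("  class fractions:", sprintf("%.3f", x$class_fraction), "\n")
  invisible(x)
}

#' @export
predict.lcga <- function(object, times = NULL, ...) {
  if (is.null(times)) {
    times <- seq(object$time_range[1], object$time_range[2], length.out = 25)
  }
  X <- outer(times, 0:object$degree, "^")
  out <- X %*% object$coefficients
  rownames(out) <- format(times)
  out
}

#' @export
plot.lcga <- function(x, ...) {
  times <- seq(x$time_range[1], x$time_range[2], length.out = 50)
  mu <- predict(x, times)
  matplot(times, mu, type = "l", lty = 1, lwd = 2,
          xlab = "time in study (years)", ylab = "class mean trajectory", ...)
  legend("topright", legend = sprintf("class %d (pi = %.2f)",
                                      seq_len(x$K), x$pi),
         col = seq_len(x$K), lty = 1, lwd = 2, bty = "n")
  invisible(x)
}

# posterior class probabilities for arbitrary subjects (possibly with a
# single observation) under an already-fitted model
.lcga_posterior_for <- function(model, y, tv, ids) {
  ok <- !is.na(y) & !is.na(tv) & !is.na(ids)
  y <- y[ok]; tv <- tv[ok]; ids <- ids[ok]
  subj <- as.integer(factor(ids, levels = unique(ids)))
  X <- outer(tv, 0:model$degree, "^")
  K <- model$K
  lp <- matrix(0, max(subj), K)
  for (k in seq_len(K)) {
    r <- y - drop(X %*% model$coefficients[, k])
    ld <- -0.5 * (log(2 * pi * model$sigma[k]^2) + r^2 / model$sigma[k]^2)
    lp[, k] <- rowsum(ld, subj)[, 1] + log(model$pi[k])
  }
  post <- exp(lp - .row_logsumexp(lp))
  rownames(post) <- as.character(unique(ids))
  post
}

#' Select the best LCGA model under posterior-classification criteria
#'
#' Among candidates that satisfy all three classification criteria — average
#' posterior probability of each class at least `min_avg_posterior`, share of
#' subjects with maximum posterior above 0.7 at least `min_share`, and every
#' class holding at least `min_class_fraction` of subjects — returns the model
#' with the minimum absolute BIC; ties go to the smaller `K`, then the smaller
#' degree.  If no candidate passes, the best-|BIC| model is returned with a
#' warning and attribute `selected_by_fallback = TRUE`.
#'
#' @param models list of `lcga` fits.
#' @param min_avg_posterior,min_share,min_class_fraction the three
#'   classification thresholds (defaults 0.7, 0.65, 0.05).
#' @return the selected `lcga` fit, with a `selection` attribute table.
#' @export
select_lcga <- function(models, min_avg_posterior = 0.7, min_share = 0.65,
                        min_class_fraction = 0.05) {
  if (!length(models)) .stopf("empty candidate list")
  if (inherits(models, "lcga")) models <- list(models)
  diag <- lapply(models, summary, threshold = 0.7)
  tab <- data.frame(
    K = vapply(models, function(m) as.numeric(m$K), 0),
    degree = vapply(models, function(m) as.numeric(m$degree), 0),
    bic = vapply(models, `[[`, 0, "bic"),
    min_avg_posterior = vapply(diag, function(d) min(d$avg_posterior), 0),
    share_above = vapply(diag, `[[`, 0, "share_above"),
    min_class_fraction = vapply(diag, function(d) min(d$class_fraction), 0)
  )
  tab$passes <- tab$min_avg_posterior >= min_avg_posterior &
    tab$share_above >= min_share &
    tab$min_class_fraction >= min_class_fraction
  pool <- if (any(tab$passes)) which(tab$passes) else seq_len(nrow(tab))
  if (!any(tab$passes)) {
    warning("no candidate passes the classification criteria; returning best |BIC| model")
  }
  o <- pool[order(abs(tab$bic[pool]), tab$K[pool], tab$degree[pool])]
  chosen <- models[[o[1]]]
  attr(chosen, "selection") <- tab
  attr(chosen, "selected_by_fallback") <- !any(tab$passes)
  chosen
}

#' Assign subjects to labelled trajectory groups
#'
#' Assigns each subject to its maximum-posterior class (posterior ties go to
#' the class with the larger mixing weight, with a message) and labels classes
#' by their mean fitted trajectory: with `higher_first = TRUE` the class with
#' the higher mean gets `labels[1]` (e.g. "favourable" for lifestyle counts);
#' with `higher_first = FALSE` the class with the lower mean gets `labels[1]`
#' (e.g. "higher SES" for SEVI, where lower scores mean higher status).
#'
#' @param model a fitted 2+class `lcga`.
#' @param labels character vector of group labels, length `K`.
#' @param higher_first whether `labels[1]` goes to the class with the highest
#'   mean trajectory.
#' @return named factor mapping subject id to group label.
#' @export
assign_groups <- function(model, labels = c("favourable", "unfavourable"),
                          higher_first = TRUE) {
  stopifnot(inherits(model, "lcga"), length(labels) == model$K)
  post <- model$posterior
  cls <- max.col(post, ties.method = "first")
  maxp <- post[cbind(seq_len(nrow(post)), cls)]
  ties <- rowSums(abs(post - maxp) < 1e-12) > 1
  if (any(ties)) {
    tie_cls <- which.max(model$pi)
    cls[ties] <- tie_cls
    message(sprintf("%d posterior tie(s) assigned to the largest class",
                    sum(ties)))
  }
  ord <- order(model$class_mean, decreasing = higher_first)
  lab_by_class <- character(model$K)
  lab_by_class[ord] <- labels
  out <- factor(lab_by_class[cls], levels = labels)
  names(out) <- rownames(post)
  out
}
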