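# Deterministic rule-based scoring of lifestyle factors, disability
# definitions and the socioeconomic vulnerability index (SEVI).

#' Education-specific MMSE cut-off for cognitive disability
#'
#' Cut-offs are 18 for no formal education (< 1 year), 20 for primary school
#' (1-6 years) and 24 for more than 6 years of schooling; an MMSE score
#' strictly below the cut-off defines cognitive disability.
#'
#' @param education_years non-negative years of schooling (vectorised).
#' @return integer vector of cut-offs.
#' @examples
#' mmse_cutoff(c(0, 6, 7))
#' @export
mmse_cutoff <- function(education_years) {
  if (any(education_years < 0, na.rm = TRUE)) {
    .stopf("education_years must be non-negative")
  }
  out <- ifelse(education_years < 1, 18L,
                ifelse(education_years <= 6, 20L, 24L))
  out[is.na(education_years)] <- NA_integer_
  out
}

.check_items <- function(panel, cols, strict, what) {
  miss <- setdiff(cols, names(panel))
  if (length(miss)) .stopf("%s scoring needs column(s): %s", what,
                           paste(miss, collapse = ", "))
  if (strict && anyNA(panel[, cols, drop = FALSE])) {
    .stopf("missing %s item(s) after imputation: %s", what,
           paste(cols[vapply(panel[, cols, drop = FALSE], anyNA, TRUE)],
                 collapse = ", "))
  }
  invisible(NULL)
}

#' Score the six healthy-lifestyle factors
#'
#' Applies the rules: healthy diet = at least 7 of the 13 food items consumed
#' at least once per week; never smoking / never drinking = status `"never"`
#' (former use does not qualify); regular exercise = current exerciser; active
#' cognitive activity = any of the six listed activities at least weekly;
#' healthy sleep = 7-9 hours with very good / good / fair quality.
#'
#' @param panel a `cohort_panel` (or data.frame of rows) with the raw items.
#' @param strict if `TRUE` (default) missing items are a hard error, since
#'   scoring is meant to run on complete (post-imputation, post-exclusion)
#'   rows.  With `strict = FALSE` missing inputs yield `NA` flags.
#' @return data.frame with the six logical flags and `n_healthy` (0-6).
#' @export
score_lifestyle <- function(panel, strict = TRUE) {
  .check_items(panel, .lifestyle_items, strict, "lifestyle")
  diet <- panel[, .diet_items, drop = FALSE]
  cogs <- panel[, .cog_items, drop = FALSE]
  out <- data.frame(
    healthy_diet = rowSums(diet >= 1) >= 7,
    never_smoking = panel$smoke_status == "never",
    regular_exercise = panel$exercise_status == "current",
    never_drinking = panel$drink_status == "never",
    active_cognitive = rowSums(cogs >= 1) >= 1,
    healthy_sleep = panel$sleep_hours >= 7 & panel$sleep_hours <= 9 &
      panel$sleep_quality %in% c("very good", "good", "fair") &
      !is.na(panel$sleep_quality)
  )
  out$healthy_sleep[is.na(panel$sleep_hours) | is.na(panel$sleep_quality)] <- NA
  out$n_healthy <- rowSums(out)
  out
}

#' Score a disability definition at each wave
#'
#' Definitions: `badl` = any of the six basic activities of daily living not
#' completely independent; `mobility` = any difficulty walking 1 km
#' continuously; `vision` / `hearing` = option 3 or 4 of the 4-level item
#' (cannot see the test circle or blind; hears only partly or not at all
#' despite an aid); `cognition` = MMSE strictly below the education-specific
#' cut-off of [mmse_cutoff()]; `any_of_five` = the union of the five.
#'
#' @param panel a `cohort_panel` or data.frame with the relevant items.
#' @param definition one of `"badl"`, `"mobility"`, `"vision"`, `"hearing"`,
#'   `"cognition"`, `"any_of_five"`.
#' @param strict treat missing items as an error (default) or return `NA`.
#' @return logical vector, `TRUE` = disabled under the definition.
#' @export
score_disability <- function(panel, definition = "any_of_five",
                             strict = TRUE) {
  defs <- c("badl", "mobility", "vision", "hearing", "cognition",
            "any_of_five")
  if (!definition %in% defs) {
    .stopf("unknown disability definition '%s' (use one of: %s)",
           definition, paste(defs, collapse = ", "))
  }
  switch(definition,
    badl = {
      .check_items(panel, .badl_items, strict, "BADL")
      rowSums(panel[, .badl_items, drop = FALSE] != "independent") > 0
    },
    mobility = {
      .check_items(panel, "walk_1km", strict, "mobility")
      out <- panel$walk_1km %in% c("a little difficult", "unable")
      out[is.na(panel$walk_1km)] <- NA
      out
    },
    vision = {
      .check_items(panel, "vision_item", strict, "vision")
      panel$vision_item >= 3
    },
    hearing = {
      .check_items(panel, "hearing_item", strict, "hearing")
      panel$hearing_item >= 3
    },
    cognition = {
      .check_items(panel, c("mmse_score", "education_years"), strict,
                   "cognition")
      panel$mmse_score < mmse_cutoff(panel$education_years)
    },
    any_of_five = {
      flags <- vapply(defs[1:5], function(d)
        score_disability(panel, d, strict = strict), logical(nrow(panel)))
      flags <- matrix(flags, nrow = nrow(panel))
      rowSums(flags) > 0
    }
  )
}

#' Default SEVI component vulnerability coding
#'
#' Each of the six components is mapped to a vulnerability score in `[0, 1]`
#' (higher = more vulnerable / lower socioeconomic status):
#' education years (<1 -> 1, 1-6 -> 0.5, >6 -> 0); occupation (white collar ->
#' 0, other -> 1); economic independence (own income -> 0, dependent on others
#' -> 1); family economic status (very rich .. very poor -> 0, 0.25, 0.5,
#' 0.75, 1); timely access to health care (yes -> 0, no -> 1); residence
#' (urban -> 0, town -> 0.5, rural -> 1).  Override any entry to change the
#' coding.
#'
#' @return named list of scoring functions, one per component.
#' @export
sevi_default_coding <- function() {
  list(
    education = function(p)
      ifelse(p$education_years < 1, 1, ifelse(p$education_years <= 6, 0.5, 0)),
    occupation = function(p) ifelse(p$occupation == "white collar", 0, 1),
    economic_independence = function(p)
      ifelse(p$economic_independence == "own", 0, 1),
    economic_status = function(p)
      c("very rich" = 0, "rich" = 0.25, "general" = 0.5, "poor" = 0.75,
        "very poor" = 1)[as.character(p$economic_status)],
    timely_healthcare = function(p) ifelse(p$timely_healthcare == "yes", 0, 1),
    residence = function(p)
      c("urban" = 0, "town" = 0.5, "rural" = 1)[as.character(p$residence)]
  )
}

#' Score the socioeconomic vulnerability index (SEVI)
#'
#' The SEVI is a weighted mean (default: equal weights) of six component
#' vulnerability scores, clipped to `[0, 1]`; higher values indicate lower
#' socioeconomic status.  Components missing in a row are dropped and the
#' remaining weights renormalised; a row with all six components missing is an
#' error.
#'
#' @param panel a `cohort_panel` or data.frame.
#' @param weights numeric vector of six non-negative component weights.
#' @param coding component coding, as produced by [sevi_default_coding()].
#' @return data.frame with `sevi` and the six `sevi_<component>` scores.
#' @export
score_sevi <- function(panel, weights = rep(1, 6),
                       coding = sevi_default_coding()) {
  stopifnot(length(weights) == 6, all(weights >= 0), sum(weights) > 0)
  comp <- vapply(.sevi_components, function(nm) {
    unname(as.numeric(coding[[nm]](panel)))
  }, numeric(nrow(panel)))
  comp <- matrix(comp, nrow = nrow(panel),
                 dimnames = list(NULL, .sevi_components))
  if (any(rowSums(!is.na(comp)) == 0)) {
    .stopf("row(s) with all six SEVI components missing")
  }
  w <- matrix(weights, nrow(panel), 6, byrow = TRUE)
  w[is.na(comp)] <- 0
  value <- rowSums(comp * w, na.rm = TRUE) / rowSums(w)
  value <- pmin(pmax(value, 0), 1)
  out <- data.frame(sevi = value)
  colnames(comp) <- paste0("sevi_", .sevi_components)
  cbind(out, as.data.frame(comp))
}

#' Append all scored columns to a panel
#'
#' Adds, with a `score_` prefix: the six lifestyle flags and `score_n_healthy`,
#' `score_sevi`, one flag per disability definition
#' (`score_dis_badl`, ..., `score_dis_any_of_five`) and `score_disabled`, the
#' flag for the selected working definition.
#'
#' @param panel a `cohort_panel`.
#' @param definition working disability definition for `score_disabled`.
#' @param strict passed to the scoring functions.
#' @param sevi_weights passed to [score_sevi()].
#' @return the panel with scored columns appended.
#' @export
score_panel <- function(panel, definition = "any_of_five", strict = TRUE,
                        sevi_weights = rep(1, 6)) {
  ls <- score_lifestyle(panel, strict = strict)
  names(ls) <- paste0("score_", names(ls))
  sv <- score_sevi(panel, weights = sevi_weights)
  names(sv)[1] <- "score_sevi"
  sv <- sv[, "score_sevi", drop = FALSE]
  defs <- c("badl", "mobility", "vision", "hearing", "cognition",
            "any_of_five")
  dis <- vapply(defs, function(d) score_disability(panel, d, strict = strict),
                logical(nrow(panel)))
  dis <- as.data.frame(matrix(dis, nrow = nrow(panel)))
  names(dis) <- paste0("score_dis_", defs)
  out <- cbind(panel, ls, sv, dis)
  out$score_disabled <- out[[paste0("score_dis_", definition)]]
  class(out) <- c("cohort_panel", "data.frame")
  out
}
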