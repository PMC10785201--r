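# Reading, validating and writing cohort panel data.

#' Canonical column dictionary for cohort panel files
#'
#' Returns the canonical column names a cohort panel may carry, with the
#' mandatory subset marked.  A panel is one row per subject-wave.  Dates are
#' ISO-8601 strings; ages are in years; item frequencies are times per week.
#'
#' @return data.frame with columns `column`, `required`, `type`.
#' @export
cohort_schema <- function() {
  core <- data.frame(
    column = c("subject_id", "wave_date", "age", "vital_status", "death_date"),
    required = c(TRUE, TRUE, TRUE, TRUE, FALSE),
    type = c("character", "date", "numeric", "category", "date"),
    stringsAsFactors = FALSE
  )
  opt <- function(cols, type) data.frame(column = cols, required = FALSE,
                                         type = type, stringsAsFactors = FALSE)
  rbind(
    core,
    opt(c("smoke_status", "drink_status", "exercise_status"), "category"),
    opt(.diet_items, "numeric"),
    opt(.cog_items, "numeric"),
    opt(c("sleep_hours"), "numeric"),
    opt(c("sleep_quality"), "category"),
    opt(.badl_items, "category"),
    opt(c("walk_1km"), "category"),
    opt(c("vision_item", "hearing_item", "mmse_score", "education_years"),
        "numeric"),
    opt(c("occupation", "economic_independence", "economic_status",
          "timely_healthcare", "residence"), "category"),
    opt(c("gender", "region", "marital"), "category"),
    opt(c("bmi"), "numeric"),
    opt(.illness_items, "numeric")
  )
}

#' Read a cohort panel from delimited text
#'
#' Reads a subject-wave CSV, optionally renaming file columns to the canonical
#' dictionary of [cohort_schema()], coerces types, turns unparseable cells into
#' explicit `NA` markers (never silent zeros), and checks basic integrity.
#'
#' @param path path to a CSV file.
#' @param schema optional named character vector mapping canonical column names
#'   to the file's column names, e.g. `c(subject_id = "id")`.  Columns not
#'   mentioned are taken by their canonical name when present.
#' @return a `cohort_panel` (a data.frame sorted by subject and wave date).
#' @export
read_cohort <- function(path, schema = NULL) {
  if (!file.exists(path)) .stopf("cohort file not found: %s", path)
  raw <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                  colClasses = "character")
  if (!is.null(schema)) {
    miss <- setdiff(schema, names(raw))
    if (length(miss)) .stopf("schema maps absent file columns: %s",
                             paste(miss, collapse = ", "))
    names(raw)[match(schema, names(raw))] <- names(schema)
  }
  as_cohort_panel(raw)
}

#' Coerce a data.frame to a validated cohort panel
#'
#' @param x data.frame with (a subset of) the canonical columns.
#' @return a `cohort_panel`.
#' @export
as_cohort_panel <- function(x) {
  dict <- cohort_schema()
  req <- dict$column[dict$required]
  miss <- setdiff(req, names(x))
  if (length(miss)) .stopf("missing mandatory column(s): %s",
                           paste(miss, collapse = ", "))
  x <- as.data.frame(x, stringsAsFactors = FALSE)

  n_bad <- 0L
  for (col in intersect(dict$column[dict$type == "numeric"], names(x))) {
    v <- x[[col]]
    if (!is.numeric(v)) {
      v_num <- suppressWarnings(as.numeric(v))
      n_bad <- n_bad + sum(is.na(v_num) & !is.na(v) & nzchar(trimws(v)))
      x[[col]] <- v_num
    }
  }
  for (col in intersect(c("wave_date", "death_date"), names(x))) {
    v <- as.character(x[[col]])
    v[!is.na(v) & !nzchar(trimws(v))] <- NA_character_
    bad <- !is.na(v) & !.is_date_string(v)
    n_bad <- n_bad + sum(bad)
    v[bad] <- NA_character_
    x[[col]] <- as.Date(v)
  }
  for (col in intersect(dict$column[dict$type == "category"], names(x))) {
    v <- as.character(x[[col]])
    v[!is.na(v) & !nzchar(trimws(v))] <- NA_character_
    x[[col]] <- v
  }
  if (n_bad > 0) message(sprintf("read_cohort: %d unparseable cell(s) set to missing", n_bad))

  if (anyNA(x$wave_date)) .stopf("missing or unparseable wave_date")
  key <- paste(x$subject_id, format(x$wave_date), sep = "\r")
  if (anyDuplicated(key)) .stopf("duplicate (subject_id, wave_date) row(s): integrity error")
  x <- x[order(x$subject_id, x$wave_date), , drop = FALSE]
  rownames(x) <- NULL
  class(x) <- c("cohort_panel", "data.frame")
  x
}

# per-subject observation count where a valid death date counts as one
# observation (the multi-state model needs two time points, and an exactly
# dated death is one of them)
.n_observations <- function(panel) {
  tab <- table(panel$subject_id)
  n <- as.integer(tab)
  names(n) <- names(tab)
  first <- !duplicated(panel$subject_id)
  dead <- panel$subject_id[first][
    panel$vital_status[first] == "dead" & {
      dd <- if ("death_date" %in% names(panel)) panel$death_date[first] else
        rep(as.Date(NA), sum(first))
      !is.na(dd)
    }]
  n[names(n) %in% dead] <- n[names(n) %in% dead] + 1L
  n
}

# a wave is state-scoreable / lifestyle-scoreable if not all items missing
.wave_usable <- function(panel) {
  has_state <- rep(TRUE, nrow(panel))
  sc <- intersect(.state_items, names(panel))
  if (length(sc)) has_state <- rowSums(!is.na(panel[, sc, drop = FALSE])) > 0
  has_ls <- rep(TRUE, nrow(panel))
  lc <- intersect(.lifestyle_items, names(panel))
  if (length(lc)) has_ls <- rowSums(!is.na(panel[, lc, drop = FALSE])) > 0
  has_state & has_ls
}

#' Apply the cohort exclusion rules
#'
#' Drops, in order: subjects younger than 65 at their first wave; subjects left
#' with a single observation once a recorded death without a valid death date is
#' discarded; subjects left with a single observation once waves with no
#' scoreable state or lifestyle items are discarded; and subjects flagged by a
#' user-supplied registration-error predicate (none by default).  A valid death
#' date counts as an observation.  Every dropped subject is accounted for in the
#' returned report.
#'
#' @param panel a `cohort_panel`.
#' @param registration_error optional function taking the panel and returning
#'   the subject ids to drop as systematic registration errors.
#' @return list with elements `panel` (the retained `cohort_panel`) and
#'   `report` (an `exclusion_report`).
#' @export
apply_exclusions <- function(panel, registration_error = NULL) {
  stopifnot(inherits(panel, "cohort_panel"))
  n_input <- length(unique(panel$subject_id))
  counts <- c(under_65 = 0L, single_wave_death_date = 0L,
              single_wave_state = 0L, registration_error = 0L)

  # rule 1: under 65 at first retained wave
  first <- !duplicated(panel$subject_id)
  young <- unique(panel$subject_id[first][panel$age[first] < 65])
  counts["under_65"] <- length(young)
  panel <- panel[!panel$subject_id %in% young, , drop = FALSE]

  # rule 2: dead without a death date -> death record unusable; subjects with a
  # single remaining wave are excluded
  if (nrow(panel)) {
    dd <- if ("death_date" %in% names(panel)) panel$death_date else
      rep(as.Date(NA), nrow(panel))
    bad_death <- panel$vital_status == "dead" & is.na(dd)
    bad_subj <- unique(panel$subject_id[bad_death])
    nw <- table(panel$subject_id)
    drop2 <- bad_subj[nw[bad_subj] < 2]
    counts["single_wave_death_date"] <- length(drop2)
    panel <- panel[!panel$subject_id %in% drop2, , drop = FALSE]
  }

  # rule 3: waves with no scoreable state/lifestyle dropped; then < 2 obs
  if (nrow(panel)) {
    usable <- .wave_usable(panel)
    panel <- panel[usable, , drop = FALSE]
    nobs <- .n_observations(panel)
    drop3 <- names(nobs)[nobs < 2]
    counts["single_wave_state"] <- length(drop3)
    panel <- panel[!panel$subject_id %in% drop3, , drop = FALSE]
  }

  # rule 4: user-supplied systematic registration error predicate
  if (!is.null(registration_error) && nrow(panel)) {
    drop4 <- intersect(unique(panel$subject_id), registration_error(panel))
    counts["registration_error"] <- length(drop4)
    panel <- panel[!panel$subject_id %in% drop4, , drop = FALSE]
  }

  retained <- length(unique(panel$subject_id))
  if (retained == 0L) .stopf("all subjects excluded: empty retained panel")
  stopifnot(retained + sum(counts) == n_input)
  rownames(panel) <- NULL
  class(panel) <- c("cohort_panel", "data.frame")
  report <- structure(list(counts = counts, retained_n = retained,
                           input_n = n_input),
                      class = "exclusion_report")
  list(panel = panel, report = report)
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat("Cohort exclusions\n")
  cat(sprintf("  input subjects:    %d\n", x$input_n))
  for (nm in names(x$counts)) {
    cat(sprintf("  excluded %-24s %d\n", paste0(nm, ":"), x$counts[[nm]]))
  }
  cat(sprintf("  retained subjects: %d\n", x$retained_n))
  invisible(x)
}

#' Write a result table as delimited text at reporting precision
#'
#' Writes a data.frame as CSV with a fixed column order and the package's
#' reporting precision: life-expectancy columns (names containing `le`, `dfle`,
#' `dle` or ending `_diff`) at 3 decimals and percentage columns (names
#' containing `pct`) at 2 decimals, rounded half away from zero.  An empty
#' result writes a header-only file.
#'
#' @param x data.frame (or `mslt_contrasts`) to write.
#' @param path output file path.
#' @param le_digits,pct_digits decimal places for LE-type and percentage
#'   columns.
#' @return invisibly, the formatted data.frame that was written.
#' @export
write_results <- function(x, path, le_digits = 3, pct_digits = 2) {
  x <- as.data.frame(x)
  is_pct <- grepl("pct", names(x), ignore.case = TRUE)
  is_le <- grepl("(^|_)(le|dfle|dle)($|_)|_diff$|^diff", names(x),
                 ignore.case = TRUE) & !is_pct
  for (j in seq_along(x)) {
    if (!is.numeric(x[[j]])) next
    if (is_pct[j]) {
      x[[j]] <- sprintf(paste0("%.", pct_digits, "f"),
                        round_half_away(x[[j]], pct_digits))
    } else if (is_le[j]) {
      x[[j]] <- sprintf(paste0("%.", le_digits, "f"),
                        round_half_away(x[[j]], le_digits))
    }
  }
  ok <- tryCatch({
    write.csv(x, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) .stopf("cannot write results to %s: %s", path,
                          conditionMessage(ok))
  invisible(x)
}

#' Per-column missingness report
#'
#' @param panel a data.frame.
#' @return data.frame with one row per column that has missing values.
#' @export
missingness_report <- function(panel) {
  n <- vapply(panel, function(v) sum(is.na(v)), integer(1))
  out <- data.frame(column = names(n), n_missing = as.integer(n),
                    pct_missing = 100 * as.integer(n) / nrow(panel),
                    stringsAsFactors = FALSE)
  out <- out[out$n_missing > 0, , drop = FALSE]
  rownames(out) <- NULL
  out
}
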