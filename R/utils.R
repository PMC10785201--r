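# Shared internal constants and helpers.

.badl_items <- paste0("badl_", c("bathing", "dressing", "toileting",
                                 "indoor", "continence", "eating"))
.diet_items <- paste0("diet_", c("fruit", "vegetable", "fish", "meat", "dairy",
                                 "oil", "egg", "grain", "legume", "nut", "tea",
                                 "garlic", "fungus"))
.cog_items <- paste0("cog_", c("writing", "reading", "cards", "mahjong",
                               "tv", "radio"))
.illness_items <- c("hypertension", "diabetes", "heart_disease",
                    "stroke", "dyslipidaemia")
.sevi_components <- c("education", "occupation", "economic_independence",
                      "economic_status", "timely_healthcare", "residence")
.transitions <- c("01", "02", "10", "12")
.state_items <- c(.badl_items, "walk_1km", "vision_item", "hearing_item",
                  "mmse_score")
.lifestyle_items <- c("smoke_status", "drink_status", "exercise_status",
                      .diet_items, .cog_items, "sleep_hours", "sleep_quality")

#' Round half away from zero
#'
#' Rounds to `digits` decimal places with halves carried away from zero
#' (so `round_half_away(2.5) == 3`), matching the convention used for the
#' package's reported life-table values, rather than R's round-half-to-even.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return numeric vector of the same length as `x`.
#' @examples
#' round_half_away(10.2435, 3)
#' round_half_away(56.745, 2)
#' @export
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# log(sum(exp(x))) by row, numerically stable
.row_logsumexp <- function(m) {
  mx <- do.call(pmax, as.data.frame(m))
  mx + log(rowSums(exp(m - mx)))
}

.is_date_string <- function(x) {
  grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.log_stage <- function(stage, ..., verbose = TRUE) {
  if (isTRUE(verbose)) {
    message(sprintf("[%s] %s", stage, paste0(..., collapse = "")))
  }
  invisible(NULL)
}
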