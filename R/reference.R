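# Published reference estimates used to validate the contrast arithmetic.

#' Published life-table reference estimates by lifestyle group
#'
#' Point estimates of total life expectancy and disability-free life
#' expectancy (years at age 65, free of the five major disabilities in
#' combination) for Chinese older adults of the CLHLS cohort (2008-2018), by
#' healthy-lifestyle trajectory group, overall and by gender, as published for
#' that cohort.  Used to check that [le_contrasts()] reproduces the reported
#' group differences and percent-DFLE values from the reported levels.
#'
#' @return data.frame with columns `stratum` (`all`, `male`, `female`),
#'   `group` (`unfavourable`, `favourable`), `total_le`, `dfle`.
#' @export
reference_le_estimates <- function() {
  data.frame(
    stratum = rep(c("all", "male", "female"), each = 2),
    group = rep(c("unfavourable", "favourable"), 3),
    total_le = c(12.828, 17.187, 11.866, 14.496, 13.818, 18.689),
    dfle = c(7.279, 10.243, 7.710, 9.914, 6.622, 10.301),
    stringsAsFactors = FALSE
  )
}
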