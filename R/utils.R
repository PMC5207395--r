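# Internal helpers shared across modules.

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Run code under a temporary RNG seed, restoring the caller's RNG state.
#' @noRd
with_seed <- function(seed, code) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' @noRd
stop_config <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...), class = c("normbrain_config_error", "error")))
}

#' @noRd
stop_schema <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...), class = c("normbrain_schema_error", "error")))
}

#' @noRd
stop_parse <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...), class = c("normbrain_parse_error", "error")))
}

# Names of the ROI (biomarker) columns of a cohort table, in order.
#' @noRd
roi_columns <- function(cohort) {
  grep("^roi_", names(cohort), value = TRUE)
}

# Coarse clinical class of a per-visit diagnosis or a longitudinal label.
#' @noRd
coarse_class <- function(x) {
  map <- c(NL = "HC", MCI = "MCI", Dementia = "AD",
           sHC = "HC", sMCI = "MCI", cMCI = "MCI", sAD = "AD", cAD = "AD")
  unname(map[as.character(x)])
}

# Five-year age stratum label ("60-64", ...) used in the advancement tables.
#' @noRd
age_stratum <- function(age) {
  lo <- 5L * (floor(age) %/% 5L)
  sprintf("%d-%d", lo, lo + 4L)
}
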