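# Shared internal helpers: seeded RNG scoping, half-away-from-zero
# rounding, and validation of mortality tables.

# Evaluate `code` under a locally seeded RNG without disturbing the
# caller's RNG state.  seed = NULL leaves the global stream in place.
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(as.integer(seed), code)
}

# One sub-seed per replicate, drawn up-front from the top-level stream, so
# each replicate is an independent, individually reproducible stream.
derive_seeds <- function(n) {
  sample.int(.Machine$integer.max - 1L, n, replace = FALSE)
}

#' Round half away from zero
#'
#' Rounds to `digits` decimal places with ties going away from zero
#' (2.5 -> 3, -2.5 -> -3), the convention used for all reported percent
#' effect sizes in this package.  Base [round()] rounds ties to even and
#' would print -22.0 as -22 but 77.25 as 77.2.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 0).
#' @return Numeric vector of the same length.
#' @examples
#' round_half_away(c(2.5, -2.5, 77.25), 0:0)
#' @export
round_half_away <- function(x, digits = 0) {
  scale <- 10^digits
  # nudge by machine epsilon so values that are exactly .5 after decimal
  # expansion (e.g. 35.45 stored as 35.449999...) still behave sanely
  sign(x) * floor(abs(x) * scale + 0.5 + sqrt(.Machine$double.eps)) / scale
}

# Validate a mortality tibble (one well observed once).  Returns the data
# with timepoint/n_alive/n_dead coerced to numeric, or raises a typed
# schema error naming the offending rows.
validate_mortality <- function(data, call = rlang::caller_env()) {
  required <- c("timepoint", "n_alive", "n_dead")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    stop_schema(paste0(
      "mortality data is missing column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  data <- tibble::as_tibble(data)
  bad <- which(
    !is.finite(data$timepoint) | data$timepoint < 0 |
      !is.finite(data$n_alive) | data$n_alive < 0 |
      !is.finite(data$n_dead) | data$n_dead < 0 |
      (data$n_alive + data$n_dead) < 1
  )
  if (length(bad) > 0) {
    stop_schema(paste0(
      "invalid mortality rows (need timepoint >= 0, counts >= 0, ",
      "n_alive + n_dead >= 1): rows ",
      paste(head(bad, 10), collapse = ", ")
    ))
  }
  data
}

# Validate a lifespan event tibble (columns day, censored).
validate_events <- function(data, arg = "events") {
  required <- c("day", "censored")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    stop_schema(paste0(
      arg, " is missing column(s): ", paste(missing_cols, collapse = ", ")
    ))
  }
  data <- tibble::as_tibble(data)
  if (nrow(data) == 0) stop_empty_input(paste0(arg, " has no rows"))
  if (any(!is.finite(data$day) | data$day < 0)) {
    stop_schema(paste0(arg, ": day must be finite and >= 0"))
  }
  data$censored <- as.logical(data$censored)
  if (anyNA(data$censored)) {
    stop_schema(paste0(arg, ": censored must be 0/1 or logical"))
  }
  if (!any(!data$censored)) {
    stop_empty_input(paste0(arg, " contains no uncensored (death) events"))
  }
  data
}
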