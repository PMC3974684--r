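#' Kaplan-Meier survival curve for traditional lifespan assays
#'
#' Product-limit estimate of the survivor function from per-animal death
#' days with right censoring, for longitudinally tracked cohorts (the
#' "traditional" counterpart of the replica-set design).  Computed via
#' [survival::survfit()].
#'
#' @param events Data frame with columns `day` (death or censor time,
#'   >= 0) and `censored` (logical or 0/1); optional `condition`,
#'   `animal_id`.
#' @return A `km_curve` object: a tibble with columns `time`, `n_risk`,
#'   `n_event`, `n_censor`, `survival` (one row per distinct event/censor
#'   time, survival starting at 1 and non-increasing), with attributes
#'   `median` (first time at which survival drops to <= 0.5, `NA` if the
#'   curve never does) and `n` (number of animals).
#' @section Errors: `replilife_empty_input_error` when there are no rows
#'   or no uncensored events.
#' @examples
#' ev <- tibble::tibble(day = 1:4, censored = FALSE)
#' kaplan_meier(ev)
#' @export
kaplan_meier <- function(events) {
  events <- validate_events(events)
  sf <- survival::survfit(
    survival::Surv(events$day, !events$censored) ~ 1
  )
  curve <- tibble::tibble(
    time = sf$time,
    n_risk = sf$n.risk,
    n_event = sf$n.event,
    n_censor = sf$n.censor,
    survival = sf$surv
  )
  drops <- curve$time[curve$survival <= 0.5 + 1e-12]
  structure(
    curve,
    median = if (length(drops) > 0) min(drops) else NA_real_,
    n = nrow(events),
    class = c("km_curve", class(curve))
  )
}

#' Median survival time of a Kaplan-Meier curve
#'
#' @param curve A [kaplan_meier()] object.
#' @return First time at which estimated survival is <= 0.5.
#' @export
km_median <- function(curve) {
  stopifnot(inherits(curve, "km_curve"))
  attr(curve, "median")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: %d animals, median survival %s\n",
              attr(x, "n"),
              format(attr(x, "median"))))
  NextMethod()
}

#' @export
glance.km_curve <- function(x, ...) {
  tibble::tibble(
    n = attr(x, "n"),
    n_events = sum(x$n_event),
    median = attr(x, "median")
  )
}

#' @export
autoplot.km_curve <- function(object, ...) {
  df <- tibble::tibble(
    time = c(0, object$time),
    survival = c(1, object$survival)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$survival)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time", y = "proportion surviving") +
    ggplot2::theme_minimal()
}

#' Mantel-Cox log-rank test between two lifespan event sets
#'
#' Unweighted Mantel-Cox log-rank statistic (1 degree of freedom, no
#' continuity correction) comparing the survival experience of two
#' groups, computed via [survival::survdiff()] with `rho = 0`.
#'
#' @param events_a,events_b Data frames of lifespan events (columns
#'   `day`, `censored`), one per group.
#' @return A `logrank_test` object (list with `statistic`, `p_value`,
#'   `n_a`, `n_b`) with [tidy()] and [glance()] methods.
#' @section Errors: `replilife_empty_input_error` when either group has
#'   no uncensored events.
#' @examples
#' a <- tibble::tibble(day = c(2, 3, 5, 7), censored = FALSE)
#' b <- tibble::tibble(day = c(9, 11, 12, 15), censored = FALSE)
#' logrank_test(a, b)
#' @export
logrank_test <- function(events_a, events_b) {
  events_a <- validate_events(events_a, "events_a")
  events_b <- validate_events(events_b, "events_b")
  df <- dplyr::bind_rows(
    dplyr::mutate(events_a[, c("day", "censored")], group = "A"),
    dplyr::mutate(events_b[, c("day", "censored")], group = "B")
  )
  sd <- survival::survdiff(
    survival::Surv(df$day, !df$censored) ~ df$group, rho = 0
  )
  structure(
    list(
      statistic = unname(sd$chisq),
      p_value = pchisq(unname(sd$chisq), df = 1, lower.tail = FALSE),
      n_a = nrow(events_a),
      n_b = nrow(events_b)
    ),
    class = "logrank_test"
  )
}

#' @export
print.logrank_test <- function(x, ...) {
  cat(sprintf(
    "Mantel-Cox log-rank test: chisq = %.4g (1 df), p = %.4g (n = %d vs %d)\n",
    x$statistic, x$p_value, x$n_a, x$n_b
  ))
  invisible(x)
}

#' @export
tidy.logrank_test <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df = 1, p.value = x$p_value)
}

#' @export
glance.logrank_test <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p.value = x$p_value,
                 n_a = x$n_a, n_b = x$n_b)
}
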