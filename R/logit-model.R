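#' Fit a two-parameter logit survival curve to replica-set mortality data
#'
#' Replica-set lifespan and stress-survival assays observe each well of
#' animals exactly once: at its assigned timepoint the well is scored for
#' alive and dead counts and discarded.  Pooling those independent
#' cross-sectional observations, survival is modelled as
#' \deqn{p(t) = \frac{1}{1 + e^{a t - b}}}
#' with alive counts binomial, i.e. a binomial generalized linear model in
#' time, maximised by iteratively reweighted least squares (Newton
#' scoring).  The slope `a` (> 0 for declining survival) and intercept `b`
#' determine the median survival time LD50 = b/a and the fitted-curve
#' maximum lifespan (see [ld50()], [max_life()]).
#'
#' Iteration starts from the timepoint where pooled observed survival
#' first crosses 0.5 (linear interpolation) with the slope seeded from the
#' empirical logits of the two pooled timepoints bracketing the crossing;
#' when pooled survival never crosses 0.5 the start falls back to a
#' least-squares line through the empirical logits.  Convergence is a
#' maximum absolute parameter change below `tol` within `maxit`
#' iterations; non-convergence sets `converged = FALSE` without raising,
#' so resampling replicates never abort a run.
#'
#' @param data Data frame with columns `timepoint`, `n_alive`, `n_dead`
#'   (one row per well; counts may be fractional for expected-count
#'   inputs).  Optional columns `condition` and `trial` are carried along.
#' @param time_unit Unit label carried as metadata, `"days"` or
#'   `"hours"`; never mixed within one dataset.
#' @param per_trial If `TRUE` and a `trial` column is present, fit each
#'   trial separately and return a tibble with a `fit` list-column;
#'   default pools all wells.
#' @param tol,maxit IRLS convergence tolerance (max absolute change in
#'   `(a, b)`) and iteration cap.
#' @return An object of class `logit_fit` with elements `a`, `b`,
#'   `loglik` (binomial kernel), `n_obs`, `n_animals`, `converged`,
#'   `iterations`, `time_unit` and the validated `data`.  A fitted slope
#'   `a <= 0` (survival not declining) is flagged with a warning.
#' @section Errors: raises a `replilife_separation_error` when deaths are
#'   perfectly separated in time (including the all-alive and all-dead
#'   degenerate cases, where the likelihood is unbounded), and a
#'   `replilife_insufficient_data_error` with fewer than two distinct
#'   timepoints.
#' @examples
#' wells <- simulate_replica_set(true_a = 0.4, true_b = 7.2,
#'                               n_wells = 24, seed = 1)
#' fit <- fit_logit(wells)
#' ld50(fit)
#' @seealso [ld50()], [max_life()], [predict_survival()],
#'   [bootstrap_ld50()]
#' @export
fit_logit <- function(data, time_unit = c("days", "hours"),
                      per_trial = FALSE, tol = 1e-8, maxit = 100L) {
  time_unit <- match.arg(time_unit)
  data <- validate_mortality(data)

  if (per_trial && "trial" %in% names(data)) {
    fits <- data |>
      dplyr::group_by(.data$trial) |>
      dplyr::group_map(~ fit_logit(.x, time_unit = time_unit,
                                   tol = tol, maxit = maxit))
    return(tibble::tibble(
      trial = sort(unique(data$trial)),
      fit = fits
    ))
  }

  core <- fit_logit_core(data$timepoint, data$n_alive, data$n_dead,
                         on_separation = "error", tol = tol, maxit = maxit)
  if (core$a <= 0) {
    rlang::warn(
      "fitted slope a <= 0: survival does not decline with time; LD50/max-life are not meaningful",
      class = "replilife_nonpositive_slope_warning"
    )
  }
  structure(
    list(
      a = core$a, b = core$b, loglik = core$loglik,
      n_obs = nrow(data), n_animals = sum(data$n_alive + data$n_dead),
      converged = core$converged, iterations = core$iterations,
      time_unit = time_unit, data = data
    ),
    class = "logit_fit"
  )
}

# Fast numeric-vector path shared with the resampling module.
# on_separation = "error" raises; "flag" returns a stand-in LD50 (the
# midpoint of the separating time interval) with separated = TRUE so
# bootstrap/permutation replicates stay countable.
fit_logit_core <- function(t, alive, dead,
                           on_separation = c("error", "flag"),
                           tol = 1e-8, maxit = 100L) {
  on_separation <- match.arg(on_separation)
  if (length(unique(t)) < 2) {
    stop_insufficient_data(
      "at least 2 distinct timepoints are required to fit the logit curve"
    )
  }

  sep <- detect_separation(t, alive, dead)
  if (!is.null(sep)) {
    if (on_separation == "error") stop_separation()
    return(list(
      a = NA_real_, b = NA_real_, loglik = NA_real_, converged = FALSE,
      iterations = 0L, separated = TRUE, ld50 = sep$midpoint
    ))
  }

  start <- irls_start(t, alive, dead)
  res <- logit_irls_cpp(as.numeric(t), as.numeric(alive), as.numeric(dead),
                        b0 = start[["b"]], s0 = -start[["a"]],
                        tol = tol, maxit = as.integer(maxit))
  list(
    a = res[[1]], b = res[[2]], loglik = res[[3]],
    converged = res[[4]] > 0, iterations = as.integer(res[[5]]),
    separated = FALSE, ld50 = if (res[[1]] != 0) res[[2]] / res[[1]] else NA_real_
  )
}

# (Quasi-)complete separation for the 1-D binomial logit.  Pooling by
# timepoint, the likelihood supremum sits at infinite slope exactly when
# the pooled survival fractions form a step pattern in time: a block of
# all-alive timepoints, at most ONE fractional timepoint, then a block
# of all-dead timepoints (or the reverse ordering, slope -> -Inf).  The
# limiting curve fits such data perfectly (p -> 1 before the threshold,
# any fixed value at it, p -> 0 after), so no finite (a, b) attains the
# supremum.  Two or more fractional timepoints, or any non-monotone
# pattern, pin the MLE at finite parameters.  Returns NULL when the MLE
# is finite, else the separating interval and the stand-in LD50 used
# when flagging (the interval midpoint; the fractional threshold time
# itself for quasi-separation; min/max observed time when one side is
# empty).
detect_separation <- function(t, alive, dead) {
  tt <- sort(unique(t))
  af <- vapply(tt, function(ti) sum(alive[t == ti]), numeric(1))
  df <- vapply(tt, function(ti) sum(dead[t == ti]), numeric(1))
  ones <- df == 0
  zeros <- af == 0
  frac <- !ones & !zeros
  if (sum(frac) > 1) return(NULL)

  code <- ifelse(ones, 0L, ifelse(frac, 1L, 2L))
  declining <- all(diff(code) >= 0)
  increasing <- all(diff(code) <= 0)
  if (!declining && !increasing) return(NULL)

  kind <- if (declining) "declining" else "increasing"
  if (sum(frac) == 1) {
    c0 <- tt[frac]
    return(list(lower = c0, upper = c0, midpoint = c0,
                kind = paste0("quasi_", kind)))
  }
  if (!any(zeros)) {
    m <- max(tt)
    return(list(lower = m, upper = m, midpoint = m, kind = "no_deaths"))
  }
  if (!any(ones)) {
    m <- min(tt)
    return(list(lower = m, upper = m, midpoint = m,
                kind = "no_survivors"))
  }
  lo <- if (declining) max(tt[ones]) else max(tt[zeros])
  hi <- if (declining) min(tt[zeros]) else min(tt[ones])
  list(lower = lo, upper = hi, midpoint = (lo + hi) / 2, kind = kind)
}

# Starting values: pooled survival by timepoint; LD50 seed where the
# pooled curve crosses 0.5 (linear interpolation), slope seed from the
# empirical logits of the bracketing timepoints.  Fallback: least squares
# through the empirical logits.
irls_start <- function(t, alive, dead) {
  tt <- sort(unique(t))
  surv <- vapply(tt, function(ti) {
    sum(alive[t == ti]) / sum(alive[t == ti] + dead[t == ti])
  }, numeric(1))
  n_t <- vapply(tt, function(ti) sum(alive[t == ti] + dead[t == ti]),
                numeric(1))
  # empirical logits, shrunk away from 0/1
  elog <- qlogis((surv * n_t + 0.5) / (n_t + 1))

  cross <- which(surv[-length(surv)] >= 0.5 & surv[-1] < 0.5)
  if (length(tt) >= 2 && length(cross) > 0) {
    i <- cross[[1]]
    f <- (surv[i] - 0.5) / max(surv[i] - surv[i + 1], 1e-12)
    ld50_seed <- tt[i] + f * (tt[i + 1] - tt[i])
    a_seed <- (elog[i] - elog[i + 1]) / (tt[i + 1] - tt[i])
    if (!is.finite(a_seed) || a_seed <= 0) a_seed <- 0.5
    return(c(a = a_seed, b = a_seed * ld50_seed))
  }
  # fallback: OLS of empirical logit on time (logit(p) = b - a t)
  sl <- stats::coef(stats::lm(elog ~ tt))
  a_seed <- -sl[[2]]
  if (!is.finite(a_seed) || a_seed == 0) a_seed <- 1e-3
  c(a = a_seed, b = sl[[1]])
}

coerce_fit <- function(fit) {
  if (inherits(fit, "logit_fit")) return(fit)
  if (is.list(fit) && all(c("a", "b") %in% names(fit))) return(fit)
  rlang::abort("`fit` must be a logit_fit object or a list with elements a and b")
}

#' Predicted survival from a fitted logit curve
#'
#' Evaluates \eqn{p(t) = 1 / (1 + e^{a t - b})} at the given times.
#'
#' @param fit A [fit_logit()] object (or any list with elements `a`, `b`).
#' @param t Numeric vector of times.
#' @return Numeric vector of survival fractions in (0, 1).
#' @export
predict_survival <- function(fit, t) {
  fit <- coerce_fit(fit)
  plogis(fit$b - fit$a * t)
}

#' Median survival time (LD50) of a fitted logit curve
#'
#' For the two-parameter logit survival curve the time at which predicted
#' survival equals one half is `b / a`, intercept over slope.
#'
#' @inheritParams predict_survival
#' @return The LD50, in the fit's time unit.
#' @section Errors: `replilife_zero_slope_error` when `a = 0`.
#' @export
ld50 <- function(fit) {
  fit <- coerce_fit(fit)
  if (fit$a == 0) stop_zero_slope()
  fit$b / fit$a
}

#' Maximum lifespan from the fitted curve (5% survival crossing)
#'
#' Maximum life is read off the fitted logit curve, not the raw data: the
#' time at which predicted survival drops to `threshold` (default 5%),
#' \deqn{t = \frac{b + \log((1 - \tau)/\tau)}{a}}
#' which for the 5% rule is `(b + log(19)) / a`.
#'
#' @inheritParams predict_survival
#' @param threshold Survival fraction defining "maximum life"
#'   (default 0.05).
#' @return Time at which the fitted curve crosses `threshold`.
#' @section Errors: `replilife_zero_slope_error` when `a = 0`.
#' @export
max_life <- function(fit, threshold = 0.05) {
  fit <- coerce_fit(fit)
  if (fit$a == 0) stop_zero_slope()
  stopifnot(threshold > 0, threshold < 1)
  (fit$b + log((1 - threshold) / threshold)) / fit$a
}

#' @export
print.logit_fit <- function(x, ...) {
  cat("Two-parameter logit survival fit\n")
  cat(sprintf("  a (slope)     = %.6g per %s\n", x$a, sub("s$", "", x$time_unit)))
  cat(sprintf("  b (intercept) = %.6g\n", x$b))
  if (x$a > 0) {
    cat(sprintf("  LD50          = %.4g %s\n", ld50(x), x$time_unit))
    cat(sprintf("  max life (5%%) = %.4g %s\n", max_life(x), x$time_unit))
  }
  cat(sprintf("  %d wells, %.0f animals, loglik %.3f, %s in %d iterations\n",
              x$n_obs, x$n_animals, x$loglik,
              if (x$converged) "converged" else "NOT converged",
              x$iterations))
  invisible(x)
}

# Observed Fisher information at the fitted (a, b); standard errors for
# tidy().  Parameterised as (b, s = -a); SE(a) = SE(s).
logit_fit_se <- function(fit) {
  t <- fit$data$timepoint
  m <- fit$data$n_alive + fit$data$n_dead
  p <- predict_survival(fit, t)
  w <- m * p * (1 - p)
  j00 <- sum(w); j01 <- sum(w * t); j11 <- sum(w * t^2)
  det <- j00 * j11 - j01^2
  c(a = sqrt(j00 / det), b = sqrt(j11 / det))
}

#' @export
tidy.logit_fit <- function(x, ...) {
  se <- logit_fit_se(x)
  tibble::tibble(
    term = c("a", "b"),
    estimate = c(x$a, x$b),
    std.error = unname(se[c("a", "b")])
  )
}

#' @export
glance.logit_fit <- function(x, ...) {
  tibble::tibble(
    a = x$a, b = x$b,
    ld50 = if (x$a != 0) x$b / x$a else NA_real_,
    max_life = if (x$a > 0) max_life(x) else NA_real_,
    logLik = x$loglik,
    n_obs = x$n_obs,
    n_animals = x$n_animals,
    converged = x$converged,
    time_unit = x$time_unit
  )
}

#' @export
autoplot.logit_fit <- function(object, ...) {
  obs <- object$data |>
    dplyr::mutate(
      n = .data$n_alive + .data$n_dead,
      frac_alive = .data$n_alive / .data$n
    )
  tmax <- max(obs$timepoint, if (object$a > 0) max_life(object) else 0)
  curve <- tibble::tibble(
    timepoint = seq(0, tmax * 1.05, length.out = 200),
    survival = predict_survival(object, seq(0, tmax * 1.05, length.out = 200))
  )
  ggplot2::ggplot(obs, ggplot2::aes(x = .data$timepoint)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$frac_alive, size = .data$n),
                        alpha = 0.6) +
    ggplot2::geom_line(data = curve, ggplot2::aes(y = .data$survival)) +
    ggplot2::scale_size_area(max_size = 4) +
    ggplot2::labs(
      x = paste0("time (", object$time_unit, ")"),
      y = "fraction alive",
      size = "animals/well",
      title = sprintf("Logit survival fit: LD50 = %.2f %s",
                      if (object$a != 0) object$b / object$a else NA,
                      object$time_unit)
    ) +
    ggplot2::theme_minimal()
}
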