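# Nonparametric uncertainty and hypothesis testing on LD50.  The
# resampling unit throughout is the WELL (one cross-sectional
# observation): wells are the independent unit of the replica-set design.
# Each top-level call seeds one RNG stream from `seed` and derives one
# sub-seed per replicate, so results are bit-reproducible and replicates
# are individually reconstructible.

# Refit a well-index resample; separation is flagged, not fatal, and the
# flagged replicate contributes the midpoint of its separating interval
# as a stand-in LD50 so replicates remain countable.
resample_ld50_once <- function(t, alive, dead, idx) {
  ti <- t[idx]
  if (length(unique(ti)) < 2) {
    # a resample can collapse onto one timepoint; treat like separation
    # flagging: contribute that timepoint as the stand-in LD50
    return(list(ld50 = ti[[1]], separated = TRUE, converged = FALSE))
  }
  core <- fit_logit_core(ti, alive[idx], dead[idx], on_separation = "flag")
  list(ld50 = core$ld50, separated = core$separated,
       converged = core$converged)
}

#' Bootstrap confidence interval for the LD50 of a replica-set dataset
#'
#' Resamples wells with replacement (`K` replicates, same number of wells
#' as observed), refits the two-parameter logit curve to each replicate
#' and reports percentile bounds of the resulting LD50 distribution.
#' Replicates with perfect separation contribute the midpoint of their
#' separating time interval as a stand-in LD50 and are counted (and
#' reported) as flagged; replicates whose refit fails to converge are
#' still counted with their final parameter values.
#'
#' @inheritParams fit_logit
#' @param K Number of bootstrap resamples (default 10000).
#' @param seed Integer seed; identical seed and data give bit-identical
#'   results.  `NULL` uses (and advances) the session RNG.
#' @param conf Confidence level for the percentile interval
#'   (default 0.95).
#' @return An `ld50_interval` object: list with `point` (LD50 of the fit
#'   to the full data), `lower`, `upper`, `conf`, `K`, `K_effective`
#'   (replicates yielding a finite LD50), `n_separated`, and the vector
#'   of `replicates`.
#' @examples
#' wells <- simulate_replica_set(true_a = 0.4, true_b = 7.2,
#'                               n_wells = 24, seed = 1)
#' bootstrap_ld50(wells, K = 200, seed = 42)
#' @export
bootstrap_ld50 <- function(data, K = 10000, seed = NULL, conf = 0.95) {
  stopifnot(K >= 1)
  data <- validate_mortality(data)
  fit <- fit_logit(data)
  point <- ld50(fit)
  t <- data$timepoint; alive <- data$n_alive; dead <- data$n_dead
  n <- length(t)

  with_local_seed(seed, {
    seeds <- derive_seeds(K)
    reps <- vapply(seq_len(K), function(k) {
      withr::with_seed(seeds[[k]], {
        idx <- sample.int(n, n, replace = TRUE)
        r <- resample_ld50_once(t, alive, dead, idx)
        c(r$ld50, r$separated)
      })
    }, numeric(2))
  })
  ld50s <- reps[1, ]
  separated <- reps[2, ] > 0
  ok <- is.finite(ld50s)
  alpha <- (1 - conf) / 2
  ci <- unname(quantile(ld50s[ok], c(alpha, 1 - alpha), names = FALSE))

  structure(
    list(
      point = point, lower = ci[[1]], upper = ci[[2]], conf = conf,
      K = K, K_effective = sum(ok), n_separated = sum(separated),
      replicates = ld50s
    ),
    class = "ld50_interval"
  )
}

#' @export
print.ld50_interval <- function(x, ...) {
  cat(sprintf(
    "LD50 = %.4g, %d%% bootstrap CI [%.4g, %.4g] (K = %d, effective %d, %d flagged separations)\n",
    x$point, round(100 * x$conf), x$lower, x$upper,
    x$K, x$K_effective, x$n_separated
  ))
  invisible(x)
}

#' @export
tidy.ld50_interval <- function(x, ...) {
  tibble::tibble(
    estimate = x$point, conf.low = x$lower, conf.high = x$upper,
    conf.level = x$conf
  )
}

#' @export
glance.ld50_interval <- function(x, ...) {
  tibble::tibble(
    estimate = x$point, conf.low = x$lower, conf.high = x$upper,
    K = x$K, K_effective = x$K_effective, n_separated = x$n_separated
  )
}

#' Label-swap permutation test for an LD50 difference
#'
#' Tests the null hypothesis that two replica-set conditions share one
#' survival curve: wells are pooled, condition labels are randomly
#' reassigned preserving group sizes, both groups are refit, and the
#' absolute resampled LD50 difference is compared with the observed one.
#' The two-sided p-value uses the add-one estimator
#' `(count + 1) / (K + 1)`, so it is never exactly zero.
#'
#' @param data_a,data_b Mortality data frames (columns `timepoint`,
#'   `n_alive`, `n_dead`), one per condition.
#' @inheritParams bootstrap_ld50
#' @param stratify_trial If `TRUE` and both datasets have a `trial`
#'   column, labels are swapped within trial only.
#' @return An `ld50_permtest` object: list with `observed_delta`
#'   (LD50_A - LD50_B), `p_value`, `K`, `n_separated`, and the vector of
#'   permuted differences `deltas`.
#' @examples
#' a <- simulate_replica_set(true_a = 0.4, true_b = 7.2,
#'                           n_wells = 24, seed = 1)
#' b <- simulate_replica_set(true_a = 0.4, true_b = 8.4,
#'                           n_wells = 24, seed = 2)
#' permutation_ld50_test(a, b, K = 200, seed = 7)
#' @export
permutation_ld50_test <- function(data_a, data_b, K = 10000, seed = NULL,
                                  stratify_trial = FALSE) {
  stopifnot(K >= 1)
  data_a <- validate_mortality(data_a)
  data_b <- validate_mortality(data_b)
  obs_delta <- ld50(fit_logit(data_a)) - ld50(fit_logit(data_b))

  t <- c(data_a$timepoint, data_b$timepoint)
  alive <- c(data_a$n_alive, data_b$n_alive)
  dead <- c(data_a$n_dead, data_b$n_dead)
  n_a <- nrow(data_a); n <- length(t)
  strata <- if (stratify_trial &&
                "trial" %in% names(data_a) && "trial" %in% names(data_b)) {
    c(data_a$trial, data_b$trial)
  } else {
    rep(1L, n)
  }
  is_a <- c(rep(TRUE, n_a), rep(FALSE, n - n_a))

  with_local_seed(seed, {
    seeds <- derive_seeds(K)
    reps <- vapply(seq_len(K), function(k) {
      withr::with_seed(seeds[[k]], {
        lab <- logical(n)
        for (ii in split(seq_len(n), strata)) lab[ii] <- sample(is_a[ii])
        ra <- resample_ld50_once(t, alive, dead, which(lab))
        rb <- resample_ld50_once(t, alive, dead, which(!lab))
        c(ra$ld50 - rb$ld50, ra$separated || rb$separated)
      })
    }, numeric(2))
  })
  deltas <- reps[1, ]
  count <- sum(abs(deltas) >= abs(obs_delta) - 1e-12, na.rm = TRUE)
  structure(
    list(
      observed_delta = obs_delta,
      p_value = (count + 1) / (K + 1),
      K = K,
      n_separated = sum(reps[2, ] > 0),
      deltas = deltas
    ),
    class = "ld50_permtest"
  )
}

#' @export
print.ld50_permtest <- function(x, ...) {
  cat(sprintf(
    "Label-swap permutation test: observed LD50 difference %.4g, p = %.4g (K = %d)\n",
    x$observed_delta, x$p_value, x$K
  ))
  invisible(x)
}

#' @export
tidy.ld50_permtest <- function(x, ...) {
  tibble::tibble(estimate = x$observed_delta, p.value = x$p_value, K = x$K)
}

#' @export
glance.ld50_permtest <- function(x, ...) {
  tibble::tibble(observed_delta = x$observed_delta, p.value = x$p_value,
                 K = x$K, n_separated = x$n_separated)
}

# Bootstrap LD50 replicates for one condition (internal to the ratio test).
boot_ld50_vector <- function(data, K, seeds) {
  t <- data$timepoint; alive <- data$n_alive; dead <- data$n_dead
  n <- length(t)
  vapply(seq_len(K), function(k) {
    withr::with_seed(seeds[[k]], {
      idx <- sample.int(n, n, replace = TRUE)
      resample_ld50_once(t, alive, dead, idx)$ld50
    })
  }, numeric(1))
}

#' Compare the ratio of treatment to control LD50 across two backgrounds
#'
#' Measures whether a perturbation has a larger proportional effect in
#' one genetic background than another: the statistic is
#' `(LD50_treat_A / LD50_ctrl_A) - (LD50_treat_B / LD50_ctrl_B)`.  Each
#' of the four conditions' wells is resampled with replacement `K` times
#' to estimate the distribution of each ratio and of their difference;
#' the two-sided p-value is the shifted-bootstrap form
#' `(#(|d* - d_obs| >= |d_obs|) + 1) / (K + 1)`, the resampled spread
#' around the observed difference standing in for the null spread
#' around zero.
#'
#' @param ctrl_a,treat_a Mortality data for control and treatment in
#'   background A.
#' @param ctrl_b,treat_b Same for background B.
#' @inheritParams bootstrap_ld50
#' @return An `ld50_ratio_test` object: list with `ratio_a`, `ratio_b`
#'   (observed ratios), `ratio_a_ci`, `ratio_b_ci` (95% percentile CIs),
#'   `observed_delta`, `p_value`, `K`, and the replicate `deltas`.
#' @export
ratio_ld50_test <- function(ctrl_a, treat_a, ctrl_b, treat_b,
                            K = 10000, seed = NULL, conf = 0.95) {
  stopifnot(K >= 1)
  sets <- lapply(list(ctrl_a = ctrl_a, treat_a = treat_a,
                      ctrl_b = ctrl_b, treat_b = treat_b),
                 validate_mortality)
  point <- vapply(sets, function(d) ld50(fit_logit(d)), numeric(1))
  ratio_a <- point[["treat_a"]] / point[["ctrl_a"]]
  ratio_b <- point[["treat_b"]] / point[["ctrl_b"]]
  obs_delta <- ratio_a - ratio_b

  with_local_seed(seed, {
    boots <- lapply(sets, function(d) {
      boot_ld50_vector(d, K, derive_seeds(K))
    })
  })
  ra <- boots$treat_a / boots$ctrl_a
  rb <- boots$treat_b / boots$ctrl_b
  deltas <- ra - rb
  ok <- is.finite(deltas)
  alpha <- (1 - conf) / 2
  # shifted-bootstrap two-sided p: the resampled spread around the
  # observed difference stands in for the null spread around zero
  p <- (sum(abs(deltas[ok] - obs_delta) >= abs(obs_delta) - 1e-12) + 1) /
    (sum(ok) + 1)

  structure(
    list(
      ratio_a = ratio_a, ratio_b = ratio_b,
      ratio_a_ci = unname(quantile(ra[is.finite(ra)],
                                   c(alpha, 1 - alpha), names = FALSE)),
      ratio_b_ci = unname(quantile(rb[is.finite(rb)],
                                   c(alpha, 1 - alpha), names = FALSE)),
      observed_delta = obs_delta,
      p_value = p,
      K = K,
      conf = conf,
      deltas = deltas
    ),
    class = "ld50_ratio_test"
  )
}

#' @export
print.ld50_ratio_test <- function(x, ...) {
  cat(sprintf(
    paste0("Ratio-of-LD50 comparison:\n",
           "  background A: %.4g [%.4g, %.4g]\n",
           "  background B: %.4g [%.4g, %.4g]\n",
           "  difference %.4g, two-sided p = %.4g (K = %d)\n"),
    x$ratio_a, x$ratio_a_ci[[1]], x$ratio_a_ci[[2]],
    x$ratio_b, x$ratio_b_ci[[1]], x$ratio_b_ci[[2]],
    x$observed_delta, x$p_value, x$K
  ))
  invisible(x)
}

#' @export
tidy.ld50_ratio_test <- function(x, ...) {
  tibble::tibble(
    background = c("A", "B"),
    ratio = c(x$ratio_a, x$ratio_b),
    conf.low = c(x$ratio_a_ci[[1]], x$ratio_b_ci[[1]]),
    conf.high = c(x$ratio_a_ci[[2]], x$ratio_b_ci[[2]])
  )
}

#' @export
glance.ld50_ratio_test <- function(x, ...) {
  tibble::tibble(
    ratio_a = x$ratio_a, ratio_b = x$ratio_b,
    observed_delta = x$observed_delta, p.value = x$p_value, K = x$K
  )
}
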