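# The two-parameter logit survival fit and its derived quantities.

noise_free_curve <- function(a, b, times = seq(2, 18, by = 2),
                             n_per_well = 20) {
  p <- plogis(b - a * times)
  tibble::tibble(
    timepoint = times,
    n_alive = n_per_well * p,
    n_dead = n_per_well * (1 - p)
  )
}

test_that("noise-free data on the curve recover (a, b) exactly", {
  data <- noise_free_curve(a = 1, b = 10)
  fit <- fit_logit(data)
  expect_true(fit$converged)
  expect_equal(fit$a, 1, tolerance = 1e-6)
  expect_equal(fit$b, 10, tolerance = 1e-6)
  expect_equal(ld50(fit), 10, tolerance = 1e-6)
})

test_that("fit equals the brute-force grid + polish MLE on simulated wells", {
  data <- simulate_replica_set(true_a = 0.5, true_b = 10, n_wells = 6,
                               animals_per_well = 20,
                               schedule = seq(5, 35, by = 6), seed = 6)
  fit <- fit_logit(data)
  ref <- oracle_grid_mle(data$timepoint, data$n_alive, data$n_dead,
                         a0 = 0.5, b0 = 10)
  expect_equal(fit$a, ref$a, tolerance = 1e-6)
  expect_equal(fit$b, ref$b, tolerance = 1e-6)
  expect_gte(fit$loglik, ref$loglik - 1e-6)
})

test_that("fit agrees with glm(binomial) as an independent IRLS cross-check", {
  data <- simulate_replica_set(true_a = 0.4, true_b = 7.2, seed = 21)
  fit <- fit_logit(data)
  g <- stats::glm(cbind(n_alive, n_dead) ~ timepoint, binomial(), data)
  expect_equal(fit$b, unname(coef(g)[1]), tolerance = 1e-6)
  expect_equal(fit$a, -unname(coef(g)[2]), tolerance = 1e-6)
})

test_that("degenerate and underdetermined inputs raise typed errors", {
  all_alive <- tibble::tibble(timepoint = c(2, 4, 6),
                              n_alive = c(20, 20, 20),
                              n_dead = c(0, 0, 0))
  expect_error(fit_logit(all_alive), class = "replilife_separation_error")

  all_dead <- tibble::tibble(timepoint = c(2, 4), n_alive = 0,
                             n_dead = 20)
  expect_error(fit_logit(all_dead), class = "replilife_separation_error")

  separated <- tibble::tibble(timepoint = c(2, 4, 10, 12),
                              n_alive = c(20, 20, 0, 0),
                              n_dead = c(0, 0, 20, 20))
  expect_error(fit_logit(separated), class = "replilife_separation_error")

  one_time <- tibble::tibble(timepoint = c(5, 5), n_alive = c(10, 12),
                             n_dead = c(10, 8))
  expect_error(fit_logit(one_time),
               class = "replilife_insufficient_data_error")

  empty_well <- tibble::tibble(timepoint = c(2, 4), n_alive = c(0, 5),
                               n_dead = c(0, 5))
  expect_error(fit_logit(empty_well), class = "replilife_schema_error")
})

test_that("quasi-complete separation is distinguished from finite-MLE patterns", {
  # one fractional timepoint flanked by all-alive then all-dead: the
  # likelihood supremum is at infinite slope
  quasi <- tibble::tibble(timepoint = c(2, 6, 10),
                          n_alive = c(20, 11, 0),
                          n_dead = c(0, 9, 20))
  expect_error(fit_logit(quasi), class = "replilife_separation_error")

  # two fractional timepoints pin the MLE at finite parameters
  finite <- tibble::tibble(timepoint = c(2, 6, 10, 14),
                           n_alive = c(20, 15, 5, 0),
                           n_dead = c(0, 5, 15, 20))
  fit <- fit_logit(finite)
  expect_true(is.finite(fit$loglik))
  expect_true(fit$converged)

  # non-monotone extremes also keep the likelihood bounded
  bumpy <- tibble::tibble(timepoint = c(2, 6, 10, 14),
                          n_alive = c(20, 0, 10, 0),
                          n_dead = c(0, 20, 10, 20))
  fit2 <- fit_logit(bumpy)
  expect_true(is.finite(fit2$loglik))

  # survival increasing in time fits with a < 0 and warns
  rising <- tibble::tibble(timepoint = c(2, 6, 10, 14),
                           n_alive = c(0, 5, 15, 20),
                           n_dead = c(20, 15, 5, 0))
  expect_warning(fit3 <- fit_logit(rising),
                 class = "replilife_nonpositive_slope_warning")
  expect_lt(fit3$a, 0)
})

test_that("ld50 and max_life follow their closed forms and are self-consistent", {
  expect_equal(ld50(list(a = 2, b = 20)), 10)
  expect_equal(ld50(list(a = 1, b = 0)), 0)
  expect_equal(max_life(list(a = 1, b = 0)), log(19))
  expect_equal(max_life(list(a = 1, b = 0), threshold = 0.5), 0)
  expect_error(ld50(list(a = 0, b = 3)),
               class = "replilife_zero_slope_error")
  expect_error(max_life(list(a = 0, b = 3)),
               class = "replilife_zero_slope_error")

  data <- simulate_replica_set(true_a = 0.5, true_b = 10, seed = 31)
  fit <- fit_logit(data)
  expect_equal(predict_survival(fit, ld50(fit)), 0.5, tolerance = 1e-10)
  expect_equal(predict_survival(fit, max_life(fit)), 0.05,
               tolerance = 1e-10)
})

test_that("predict_survival evaluates the logit curve pointwise", {
  fit <- list(a = 1, b = 10)
  expect_equal(predict_survival(fit, 10), 0.5)
  expect_equal(predict_survival(fit, 12), 1 / (1 + exp(2)))
  expect_lt(predict_survival(fit, 1e4), 1e-100)
  # strictly decreasing when a > 0
  ts <- seq(0, 30, by = 0.5)
  expect_true(all(diff(predict_survival(fit, ts)) < 0))
})

test_that("fit log-likelihood dominates a dense grid on random small instances", {
  for (seed in 1:5) {
    inst <- random_replica_instance(seed)
    fit <- tryCatch(fit_logit(inst$data),
                    replilife_separation_error = function(e) NULL)
    if (is.null(fit)) next
    as <- seq(inst$a * 0.5, inst$a * 1.5, length.out = 60)
    bs <- seq(inst$b * 0.5, inst$b * 1.5, length.out = 60)
    grid_best <- max(outer(as, bs, Vectorize(function(a, b) {
      oracle_loglik(a, b, inst$data$timepoint, inst$data$n_alive,
                    inst$data$n_dead)
    })))
    expect_gte(fit$loglik, grid_best - 1e-9)
  }
})

test_that("per-trial fitting returns one fit per trial", {
  d1 <- simulate_replica_set(seed = 41, trial = "t1")
  d2 <- simulate_replica_set(seed = 42, trial = "t2")
  fits <- fit_logit(dplyr::bind_rows(d1, d2), per_trial = TRUE)
  expect_equal(nrow(fits), 2)
  expect_s3_class(fits$fit[[1]], "logit_fit")
  expect_equal(fits$fit[[1]]$a, fit_logit(d1)$a)
})

test_that("tidy/glance expose estimates and autoplot builds", {
  fit <- fit_logit(simulate_replica_set(seed = 51))
  td <- tidy(fit)
  expect_equal(td$term, c("a", "b"))
  expect_true(all(td$std.error > 0))
  gl <- glance(fit)
  expect_equal(gl$ld50, fit$b / fit$a)
  expect_s3_class(autoplot(fit), "ggplot")
})
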