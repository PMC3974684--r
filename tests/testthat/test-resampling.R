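# Bootstrap, permutation, and ratio resampling on LD50.

test_that("bootstrap is deterministic given a seed and sensitive to it", {
  data <- simulate_replica_set(seed = 1)
  b1 <- bootstrap_ld50(data, K = 100, seed = 5)
  b2 <- bootstrap_ld50(data, K = 100, seed = 5)
  expect_identical(b1$replicates, b2$replicates)
  expect_identical(c(b1$lower, b1$upper), c(b2$lower, b2$upper))
  b3 <- bootstrap_ld50(data, K = 100, seed = 6)
  expect_false(identical(b1$replicates, b3$replicates))
})

test_that("noise-free wells give a zero-width interval at the point estimate", {
  # counts lie exactly on a logit curve, so every resample that keeps
  # two timepoints has the same unique MLE: the generating curve
  p <- plogis(10 - 1 * c(6, 10, 14))
  data <- tibble::tibble(
    timepoint = rep(c(6, 10, 14), each = 4),
    n_alive = rep(20 * p, each = 4),
    n_dead = rep(20 * (1 - p), each = 4)
  )
  b <- bootstrap_ld50(data, K = 200, seed = 3)
  expect_equal(b$point, 10, tolerance = 1e-6)
  expect_equal(b$lower, 10, tolerance = 1e-6)
  expect_equal(b$upper, 10, tolerance = 1e-6)
})

test_that("two seeds at K = 500 agree within the Monte-Carlo error of K = 5000", {
  data <- simulate_replica_set(seed = 7)
  small1 <- bootstrap_ld50(data, K = 500, seed = 11)
  small2 <- bootstrap_ld50(data, K = 500, seed = 22)
  big <- bootstrap_ld50(data, K = 5000, seed = 33)
  # Monte-Carlo scale of the percentile endpoints: spread of the
  # bootstrap distribution over sqrt(K), inflated for tail quantiles
  mc <- 6 * stats::sd(big$replicates) / sqrt(500)
  expect_lt(abs(small1$lower - small2$lower), mc)
  expect_lt(abs(small1$upper - small2$upper), mc)
})

test_that("bootstrap intervals narrow as wells accumulate", {
  widths <- function(n_wells) {
    vapply(1:12, function(i) {
      d <- simulate_replica_set(n_wells = n_wells, seed = 100 + i)
      b <- bootstrap_ld50(d, K = 200, seed = 200 + i)
      b$upper - b$lower
    }, numeric(1))
  }
  expect_lt(median(widths(48)), median(widths(12)))
})

test_that("permutation test returns p = 1 for identical datasets", {
  data <- simulate_replica_set(seed = 2)
  pt <- permutation_ld50_test(data, data, K = 99, seed = 1)
  expect_equal(pt$observed_delta, 0)
  expect_equal(pt$p_value, 1)
})

test_that("permutation p-value is deterministic, bounded below, and stratifiable", {
  a <- simulate_replica_set(true_b = 7.2, seed = 3)
  b <- simulate_replica_set(true_b = 8.0, seed = 4)
  p1 <- permutation_ld50_test(a, b, K = 200, seed = 9)
  p2 <- permutation_ld50_test(a, b, K = 200, seed = 9)
  expect_identical(p1$deltas, p2$deltas)
  expect_gte(p1$p_value, 1 / 201)
  ps <- permutation_ld50_test(a, b, K = 50, seed = 9,
                              stratify_trial = TRUE)
  expect_gte(ps$p_value, 1 / 51)
})

test_that("permutation test detects a strong LD50 shift", {
  a <- simulate_replica_set(true_a = 0.4, true_b = 7.2, seed = 5)  # LD50 18
  b <- simulate_replica_set(true_a = 0.4, true_b = 10.4, seed = 6) # LD50 26
  pt <- permutation_ld50_test(a, b, K = 200, seed = 10)
  expect_lt(pt$p_value, 0.05)
})

test_that("permutation p agrees with exhaustive label enumeration at tiny n", {
  # 4 wells per group: choose(8, 4) = 70 relabellings, enumerable
  a <- simulate_replica_set(true_a = 0.4, true_b = 7.2, n_wells = 4,
                            schedule = c(10, 14, 18, 22), seed = 15)
  b <- simulate_replica_set(true_a = 0.4, true_b = 8.4, n_wells = 4,
                            schedule = c(10, 14, 18, 22), seed = 16)
  t <- c(a$timepoint, b$timepoint)
  alive <- c(a$n_alive, b$n_alive)
  dead <- c(a$n_dead, b$n_dead)

  # independent refit (glm) plus the documented stand-in rules for
  # degenerate relabellings
  fit_ld50 <- function(idx) {
    ti <- t[idx]; al <- alive[idx]; de <- dead[idx]
    if (!any(al > 0 & de > 0)) {
      at <- ti[al > 0]; dt <- ti[de > 0]
      if (length(dt) == 0) return(max(ti))
      if (length(at) == 0) return(min(ti))
      if (max(at) < min(dt)) return((max(at) + min(dt)) / 2)
      if (max(dt) < min(at)) return((max(dt) + min(at)) / 2)
    }
    if (length(unique(ti)) < 2) return(ti[1])
    cf <- coef(stats::glm(cbind(al, de) ~ ti, binomial()))
    unname(cf[1] / -cf[2])
  }
  obs <- abs(fit_ld50(1:4) - fit_ld50(5:8))
  combos <- utils::combn(8, 4)
  deltas <- apply(combos, 2, function(ia) {
    abs(fit_ld50(ia) - fit_ld50(setdiff(1:8, ia)))
  })
  exact_p <- mean(deltas >= obs - 1e-9)

  pt <- permutation_ld50_test(a, b, K = 2000, seed = 17)
  # Monte-Carlo error of a proportion at K = 2000
  mc <- 3 * sqrt(exact_p * (1 - exact_p) / 2000) + 2 / 2000
  expect_lt(abs(pt$p_value - exact_p), mc + 0.02)
})

test_that("ratio test is null for identical conditions and deterministic", {
  d <- simulate_replica_set(seed = 8)
  rt <- ratio_ld50_test(d, d, d, d, K = 50, seed = 2)
  expect_equal(rt$ratio_a, 1)
  expect_equal(rt$ratio_b, 1)
  expect_equal(rt$observed_delta, 0)
  expect_equal(rt$p_value, 1)
  rt2 <- ratio_ld50_test(d, d, d, d, K = 50, seed = 2)
  expect_identical(rt$deltas, rt2$deltas)
})

test_that("ratio test separates clearly different treatment ratios", {
  ca <- simulate_replica_set(true_a = 0.25, true_b = 0.25 * 46, seed = 21)
  ta <- simulate_replica_set(true_a = 0.25, true_b = 0.25 * 46 * 0.5,
                             seed = 22)
  cb <- simulate_replica_set(true_a = 0.4, true_b = 0.4 * 18.4, seed = 23)
  tb <- simulate_replica_set(true_a = 0.4, true_b = 0.4 * 18.4 * 0.95,
                             seed = 24)
  rt <- ratio_ld50_test(ca, ta, cb, tb, K = 400, seed = 25)
  expect_lt(rt$p_value, 0.05)
  expect_lt(rt$ratio_a_ci[2], rt$ratio_b_ci[1])
})
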