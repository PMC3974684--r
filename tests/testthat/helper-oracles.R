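# Independent oracles used across the suite.  Each is a deliberately
# naive reference implementation (direct formula, enumeration, or brute
# force) that shares no code with the package internals it checks.

# Binomial log-likelihood kernel of the logit survival curve, written
# directly from the model definition.
oracle_loglik <- function(a, b, t, alive, dead) {
  p <- plogis(b - a * t)
  sum(alive * log(p) + dead * log(1 - p))
}

# Brute-force MLE: dense grid around (a0, b0) then Nelder-Mead polish
# from the best grid point.
oracle_grid_mle <- function(t, alive, dead, a0, b0, span = 0.5,
                            n_grid = 200) {
  as <- seq(a0 * (1 - span), a0 * (1 + span), length.out = n_grid)
  bs <- seq(b0 * (1 - span), b0 * (1 + span), length.out = n_grid)
  ll <- outer(as, bs, Vectorize(function(a, b) {
    oracle_loglik(a, b, t, alive, dead)
  }))
  best <- arrayInd(which.max(ll), dim(ll))
  polish <- optim(
    c(as[best[1]], bs[best[2]]),
    function(par) -oracle_loglik(par[1], par[2], t, alive, dead),
    method = "Nelder-Mead",
    control = list(reltol = 1e-14, maxit = 5000)
  )
  list(a = polish$par[1], b = polish$par[2], loglik = -polish$value,
       grid_best = max(ll))
}

# Product-limit estimator written from the hand formula
# S(t) = prod_{t_i <= t} (1 - d_i / n_i).
oracle_km <- function(day, censored) {
  times <- sort(unique(day[!censored]))
  n <- length(day)
  surv <- numeric(length(times))
  s <- 1
  for (i in seq_along(times)) {
    ti <- times[i]
    d <- sum(day == ti & !censored)
    at_risk <- sum(day >= ti)
    s <- s * (1 - d / at_risk)
    surv[i] <- s
  }
  list(times = times, surv = surv)
}

# Mantel-Cox log-rank by explicit per-event-time hypergeometric
# enumeration: chi2 = (sum(O - E))^2 / sum(V).
oracle_logrank <- function(day_a, cens_a, day_b, cens_b) {
  day <- c(day_a, day_b)
  cens <- c(cens_a, cens_b)
  grp <- c(rep(1L, length(day_a)), rep(2L, length(day_b)))
  times <- sort(unique(day[!cens]))
  o_minus_e <- 0
  v <- 0
  for (ti in times) {
    n1 <- sum(day >= ti & grp == 1L)
    n2 <- sum(day >= ti & grp == 2L)
    d1 <- sum(day == ti & !cens & grp == 1L)
    d2 <- sum(day == ti & !cens & grp == 2L)
    n <- n1 + n2
    d <- d1 + d2
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1) {
      v <- v + d * (n1 / n) * (n2 / n) * (n - d) / (n - 1)
    }
  }
  chi2 <- o_minus_e^2 / v
  list(statistic = chi2, p_value = pchisq(chi2, 1, lower.tail = FALSE))
}

# Bisection root of p(t) = threshold for the logit curve.
oracle_bisect_crossing <- function(a, b, threshold, lo = -1e6, hi = 1e6,
                                   tol = 1e-12) {
  f <- function(t) plogis(b - a * t) - threshold
  stopifnot(f(lo) > 0, f(hi) < 0)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Sliding-window E-box count straight from the consensus definition.
oracle_ebox_count <- function(s) {
  s <- toupper(s)
  n <- nchar(s)
  if (n < 6) return(0L)
  count <- 0L
  for (i in seq_len(n - 5)) {
    w <- substr(s, i, i + 5)
    if (substr(w, 1, 2) == "CA" && substr(w, 5, 6) == "TG" &&
        !grepl("N", substr(w, 3, 4), fixed = TRUE) &&
        !grepl("[^ACGT]", w)) {
      count <- count + 1L
    }
  }
  count
}

# All-pairs target assignment: double loop over (peak, gene).
oracle_assign_targets <- function(peaks, genes, window = c(-700, 100)) {
  out <- list()
  for (i in seq_len(nrow(peaks))) {
    mid <- floor((peaks$start[i] + peaks$end[i] - 1) / 2)
    for (j in seq_len(nrow(genes))) {
      if (peaks$chrom[i] != genes$chrom[j]) next
      raw <- mid - genes$tss[j]
      off <- if (genes$strand[j] == "-") -raw else raw
      if (off >= window[1] && off <= window[2]) {
        out[[length(out) + 1]] <- c(peaks$factor[i], genes$id[j])
      }
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(factor = character(0), gene_id = character(0)))
  }
  m <- do.call(rbind, out)
  dplyr::distinct(dplyr::arrange(
    tibble::tibble(factor = m[, 1], gene_id = m[, 2]),
    factor, gene_id
  ))
}

# Pearson chi-squared from the textbook sum((O - E)^2 / E) expansion.
oracle_chisq <- function(k_in, n_in, k_out, n_out) {
  obs <- matrix(c(k_in, n_in - k_in, k_out, n_out - k_out), nrow = 2)
  exp_ <- outer(rowSums(obs), colSums(obs)) / sum(obs)
  sum((obs - exp_)^2 / exp_)
}

# Random gene/peak instance for overlap property tests.
random_genome_instance <- function(seed, n_genes = 30, n_peaks = 120,
                                   chrom_length = 4e5) {
  withr::with_seed(seed, {
    chroms <- c("chrI", "chrII")
    genes <- tibble::tibble(
      id = sprintf("g%03d", seq_len(n_genes)),
      chrom = sample(chroms, n_genes, replace = TRUE),
      tss = sample.int(chrom_length, n_genes),
      strand = sample(c("+", "-"), n_genes, replace = TRUE)
    )
    start <- sample.int(chrom_length - 300, n_peaks)
    peaks <- tibble::tibble(
      chrom = sample(chroms, n_peaks, replace = TRUE),
      start = start,
      end = start + sample(50:300, n_peaks, replace = TRUE),
      factor = sample(c("MDL-1", "PHA-4", "DAF-16"), n_peaks,
                      replace = TRUE)
    )
  })
  list(genes = genes, peaks = peaks)
}

# Random mortality data for property tests.
random_replica_instance <- function(seed, n_timepoints = NULL) {
  withr::with_seed(seed, {
    a <- runif(1, 0.2, 1.5)
    ld <- runif(1, 8, 25)
    b <- a * ld
    n_t <- if (is.null(n_timepoints)) sample(3:8, 1) else n_timepoints
    # keep a timepoint near the LD50 so instances stay informative
    schedule <- sort(unique(c(sample(seq(2, 2 * ceiling(ld), by = 2), n_t),
                              2 * round(ld / 2))))
    wells_per_t <- sample(2:4, 1)
    animals <- sample(10:25, 1)
  })
  data <- simulate_replica_set(
    true_a = a, true_b = b,
    n_wells = n_t * wells_per_t, animals_per_well = animals,
    schedule = schedule, seed = seed + 1000L
  )
  list(data = data, a = a, b = b, ld50 = ld)
}
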