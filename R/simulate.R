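# Seeded generators for every input the pipeline consumes, with the
# statistical structure the analysis assumes.  RNG layout: each
# generator seeds one local stream from `seed` (the caller's RNG state
# is untouched) and draws in the documented order, so outputs are
# bit-reproducible per seed.

#' Simulate a replica-set mortality experiment
#'
#' Emulates the cross-sectional well design: wells of ~25 animals are
#' each observed once, at a timepoint assigned round-robin over the
#' schedule (so every timepoint is covered evenly), and deaths are drawn
#' binomially with death probability `1 - p(t)` under the logit survival
#' curve `p(t) = 1 / (1 + exp(true_a * t - true_b))`.  The true LD50 is
#' `true_b / true_a`.
#'
#' Draw order: one binomial draw per well, in well order.
#'
#' @param true_a,true_b Logit slope (> 0) and intercept of the
#'   generating curve.  Defaults give LD50 = 18 days on an adult
#'   lifespan scale typical of wild-type *C. elegans* at 20 degrees C.
#' @param n_wells Number of wells (>= 2; default 24, one culture plate).
#' @param animals_per_well Animals per well (default 25).
#' @param schedule Timepoints cycled over (default every 2 days from 2
#'   to twice the LD50, the every-other-day scoring cadence).
#' @param condition,trial Labels stamped on every row.
#' @param seed Integer seed (`NULL` = use session RNG).
#' @return A mortality tibble with columns `condition`, `trial`,
#'   `well_id`, `timepoint`, `n_alive`, `n_dead`.
#' @examples
#' simulate_replica_set(seed = 1)
#' @export
simulate_replica_set <- function(true_a = 0.4, true_b = 7.2,
                                 n_wells = 24, animals_per_well = 25,
                                 schedule = NULL,
                                 condition = "sim", trial = "t1",
                                 seed = NULL) {
  stopifnot(true_a > 0, n_wells >= 2, animals_per_well >= 1)
  if (is.null(schedule)) {
    ld <- true_b / true_a
    schedule <- seq(2, 2 * ceiling(ld), by = 2)
  }
  timepoint <- rep_len(schedule, n_wells)
  p_dead <- 1 - plogis(true_b - true_a * timepoint)
  n_dead <- as.numeric(with_local_seed(seed,
    rbinom(n_wells, size = animals_per_well, prob = p_dead)
  ))
  tibble::tibble(
    condition = condition,
    trial = trial,
    well_id = sprintf("w%03d", seq_len(n_wells)),
    timepoint = timepoint,
    n_alive = animals_per_well - n_dead,
    n_dead = n_dead
  )
}

#' Simulate a traditional (longitudinal) lifespan experiment
#'
#' Death days are drawn by inverse-CDF sampling from the logistic
#' survival curve `p(t) = 1 / (1 + exp(true_a * t - true_b))` (so the
#' median death day is `true_b / true_a`), truncated at 0; censoring is
#' independent Bernoulli per animal, with the censor day uniform on
#' (0, death day).
#'
#' Draw order: n survival uniforms, then n censoring indicators, then
#' the censor-time uniforms.
#'
#' @param n Number of animals.
#' @param true_a,true_b Generating logit parameters (`true_a` > 0).
#' @param censor_rate Probability an animal is right-censored
#'   (default 0).
#' @param condition Label stamped on every row.
#' @inheritParams simulate_replica_set
#' @return A lifespan-event tibble with columns `condition`,
#'   `animal_id`, `day`, `censored`.
#' @export
simulate_traditional_lifespan <- function(n, true_a = 0.4, true_b = 7.2,
                                          censor_rate = 0,
                                          condition = "sim",
                                          seed = NULL) {
  stopifnot(n >= 1, true_a > 0, censor_rate >= 0, censor_rate < 1)
  with_local_seed(seed, {
    u <- runif(n)
    day <- pmax(0, (true_b + qlogis(u)) / true_a)
    censored <- runif(n) < censor_rate
    day[censored] <- runif(sum(censored)) * day[censored]
  })
  tibble::tibble(
    condition = condition,
    animal_id = sprintf("a%05d", seq_len(n)),
    day = day,
    censored = censored
  )
}

# Mutate every CANNTG occurrence (the C becomes G) until a sequence is
# E-box free; uniform random sequences of a few hundred bp carry many
# background E-boxes, and a clean background is what makes planted
# fractions exactly recoverable.
scrub_ebox <- function(seqs) {
  vapply(seqs, function(s) {
    repeat {
      m <- regexpr("CA[ACGT]{2}TG", s)
      if (m < 0) return(s)
      substr(s, m, m) <- "G"
    }
  }, character(1), USE.NAMES = FALSE)
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
          collapse = "")
  }, character(1))
}

#' Simulate a genome scenario for the regulatory-overlap pipeline
#'
#' Generates a coherent set of genes, ChIP-seq-style peaks, peak
#' sequences and GO annotations with planted structure, so the full
#' target-assignment / E-box / enrichment pipeline can be exercised and
#' its recovery checked against ground truth:
#'
#' * genes get TSS positions on a spacing grid (windows of distinct
#'   genes never overlap) and random strands;
#' * a `planted_fraction` of genes receive one peak whose midpoint falls
#'   at a strand-aware offset drawn uniformly from `planted_window`
#'   (default the -700/+100 promoter band); remaining peaks are placed
#'   uniformly at random;
#' * peak sequences are i.i.d. uniform ACGT; with
#'   `ebox_background = "scrub"` (default) background E-boxes are
#'   removed and exactly `round(ebox_fraction * n_peaks)` sequences get
#'   one planted E-box, so the planted fraction is exactly recoverable
#'   ("natural" keeps the background occurrences);
#' * every gene draws each of `n_terms` GO terms at rate `go_base_rate`;
#'   term 1 is enriched among planted target genes by `go_fold`.
#'
#' @param n_chroms,chrom_length Chromosome count and length (bp).
#' @param n_genes Number of genes.
#' @param n_peaks Number of peaks for the (single) simulated factor.
#' @param factor Factor label stamped on the peaks.
#' @param planted_fraction Fraction of peaks planted into gene promoter
#'   windows (in \[0, 1\]).
#' @param planted_window Offset band for planted midpoints.
#' @param peak_width Width of every peak (bp).
#' @param ebox_fraction Fraction of peak sequences carrying a planted
#'   E-box.
#' @param ebox_background `"scrub"` (default) or `"natural"`, see
#'   Details.
#' @param n_terms,go_base_rate,go_fold GO vocabulary size, background
#'   annotation rate, and the enrichment fold of term 1 among planted
#'   targets.
#' @inheritParams simulate_replica_set
#' @return A list with tibbles `genes` (`id`, `chrom`, `tss`,
#'   `strand`), `peaks` (`chrom`, `start`, `end`, `factor`, `peak_id`),
#'   `annotations` (`gene_id`, `term_id`), a named character vector
#'   `sequences` keyed by `peak_id`, and `planted_genes` (the ground
#'   truth target set).
#' @section Errors: `replilife_capacity_error` when genes or peaks
#'   cannot be placed within the chromosome bounds.
#' @export
simulate_genome <- function(n_chroms = 2, chrom_length = 2e6,
                            n_genes = 500, n_peaks = 300,
                            factor = "MDL-1",
                            planted_fraction = 0.4,
                            planted_window = c(-700, 100),
                            peak_width = 200,
                            ebox_fraction = 0.5,
                            ebox_background = c("scrub", "natural"),
                            n_terms = 20, go_base_rate = 0.1,
                            go_fold = 3,
                            seed = NULL) {
  ebox_background <- match.arg(ebox_background)
  stopifnot(planted_fraction >= 0, planted_fraction <= 1,
            ebox_fraction >= 0, ebox_fraction <= 1,
            n_genes >= 1, n_peaks >= 1, peak_width >= 6)
  # gene spacing grid: windows plus a planted peak must fit without
  # crossing chromosome bounds or a neighbouring gene's window
  spacing <- 2 * (diff(planted_window) + peak_width) + 100
  margin <- 1000 + peak_width
  slots_per_chrom <- floor((chrom_length - 2 * margin) / spacing)
  if (slots_per_chrom * n_chroms < n_genes) {
    stop_capacity(
      "cannot place genes: increase chrom_length or n_chroms, or reduce n_genes"
    )
  }

  with_local_seed(seed, {
    chroms <- paste0("chr", as.roman(seq_len(n_chroms)))
    gene_chrom <- rep_len(chroms, n_genes)
    genes <- dplyr::bind_rows(lapply(chroms, function(ch) {
      ii <- which(gene_chrom == ch)
      if (length(ii) == 0) return(NULL)
      slots <- sort(sample.int(slots_per_chrom, length(ii)))
      tibble::tibble(
        id = sprintf("gene%04d", ii),
        chrom = ch,
        tss = margin + slots * spacing,
        strand = sample(c("+", "-"), length(ii), replace = TRUE)
      )
    }))
    genes <- dplyr::arrange(genes, .data$id)

    n_planted <- round(planted_fraction * n_peaks)
    planted_gene_idx <- if (n_planted > 0) {
      sample.int(n_genes, n_planted, replace = n_planted > n_genes)
    } else integer(0)

    peak_rows <- vector("list", n_peaks)
    for (j in seq_len(n_peaks)) {
      if (j <= n_planted) {
        g <- genes[planted_gene_idx[[j]], ]
        off <- runif(1, planted_window[[1]], planted_window[[2]])
        mid <- if (g$strand == "+") g$tss + off else g$tss - off
        start <- round(mid) - floor((peak_width - 1) / 2)
        peak_rows[[j]] <- tibble::tibble(chrom = g$chrom, start = start,
                                         end = start + peak_width)
      } else {
        chrom <- sample(chroms, 1)
        start <- floor(runif(1, 0, chrom_length - peak_width))
        peak_rows[[j]] <- tibble::tibble(chrom = chrom, start = start,
                                         end = start + peak_width)
      }
    }
    peaks <- dplyr::bind_rows(peak_rows)
    if (any(peaks$start < 0 | peaks$end > chrom_length)) {
      stop_capacity("peak placement exceeded chromosome bounds")
    }
    peaks$factor <- factor
    # canonical id scheme shared with read_bed_peaks(), so BED
    # round-trips keep the sequence keys
    peaks$peak_id <- paste0(peaks$factor, ":", peaks$chrom, ":",
                            peaks$start, "-", peaks$end)

    seqs <- random_dna(n_peaks, peak_width)
    if (ebox_background == "scrub") seqs <- scrub_ebox(seqs)
    n_ebox <- round(ebox_fraction * n_peaks)
    if (n_ebox > 0) {
      which_ebox <- sample.int(n_peaks, n_ebox)
      for (j in which_ebox) {
        pos <- sample.int(peak_width - 5, 1)
        motif <- paste0("CA", paste(sample(c("A", "C", "G", "T"), 2,
                                           replace = TRUE), collapse = ""),
                        "TG")
        substr(seqs[[j]], pos, pos + 5) <- motif
      }
    }
    sequences <- setNames(seqs, peaks$peak_id)

    planted_genes <- sort(unique(genes$id[planted_gene_idx]))
    is_planted <- genes$id %in% planted_genes
    terms <- sprintf("GO:%07d", seq_len(n_terms))
    ann <- dplyr::bind_rows(lapply(seq_len(n_terms), function(k) {
      rate <- rep(go_base_rate, n_genes)
      if (k == 1) rate[is_planted] <- pmin(1, go_fold * go_base_rate)
      hit <- runif(n_genes) < rate
      tibble::tibble(gene_id = genes$id[hit], term_id = terms[[k]])
    }))
  })

  list(
    genes = genes,
    peaks = peaks,
    sequences = sequences,
    annotations = ann,
    planted_genes = planted_genes,
    enriched_term = sprintf("GO:%07d", 1L)
  )
}
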