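# E-box scanning, three-set overlap counts, chi-squared enrichment.

test_that("E-box counts match hand counts on canonical cases", {
  expect_equal(scan_ebox("CACGTG"), 1L)
  expect_equal(scan_ebox("AAAAAA"), 0L)
  expect_equal(scan_ebox("CATATGCACGTG"), 2L)
  expect_equal(scan_ebox("cacgtg"), 1L)   # case-insensitive
  # an unknown base satisfies only the wildcard positions of the motif
  expect_equal(scan_ebox("CANNTG"), 1L)
  expect_equal(scan_ebox("NACGTG"), 0L)
  expect_equal(scan_ebox("ACGT"), 0L)     # shorter than the motif
})

test_that("E-box scan equals the sliding-window oracle on random sequences", {
  withr::with_seed(4, {
    seqs <- vapply(1:30, function(i) {
      paste(sample(c("A", "C", "G", "T"), 120, replace = TRUE),
            collapse = "")
    }, character(1))
  })
  expect_equal(scan_ebox(seqs),
               vapply(seqs, oracle_ebox_count, integer(1),
                      USE.NAMES = FALSE))
})

test_that("E-box count is invariant under reverse complement", {
  revcomp <- function(s) {
    chartr("ACGT", "TGCA",
           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }
  withr::with_seed(8, {
    seqs <- vapply(1:20, function(i) {
      paste(sample(c("A", "C", "G", "T"), 90, replace = TRUE),
            collapse = "")
    }, character(1))
  })
  expect_equal(scan_ebox(seqs),
               scan_ebox(vapply(seqs, revcomp, character(1),
                                USE.NAMES = FALSE)))
})

test_that("non-nucleotide characters raise an alphabet error", {
  expect_error(scan_ebox("CACGXG"), class = "replilife_alphabet_error")
})

test_that("ebox_fraction counts peaks with at least one motif and reports percent", {
  pk <- tibble::tibble(chrom = "c", start = c(0, 10, 20),
                       end = c(6, 16, 26),
                       peak_id = c("p1", "p2", "p3"))
  res <- ebox_fraction(pk, c(p1 = "CACGTG", p2 = "AAAAAA",
                             p3 = "CATTTG"))
  expect_equal(res$n_with_ebox, 2)
  expect_equal(res$fraction, 2 / 3)
  expect_equal(res$percent, 66.7)
  expect_error(ebox_fraction(pk, c(p1 = "CACGTG")),
               class = "replilife_missing_sequence_error")
  # 3555 of 4605 is the one-decimal percent convention's anchor case
  expect_equal(round_half_away(100 * 3555 / 4605, 1), 77.2)
})

test_that("venn3 partitions the universe exactly", {
  v <- venn3(c("a", "b"), c("b", "c"), "b", letters[1:5])
  expect_equal(unclass(v)[["ABC"]], 1)
  expect_equal(unclass(v)[["outside"]], 2)
  expect_equal(sum(unclass(v)), 5)

  same <- venn3(letters[1:4], letters[1:4], letters[1:4], letters[1:10])
  expect_equal(unclass(same)[["ABC"]], 4)
  expect_equal(sum(unclass(same)[setdiff(names(unclass(same)),
                                         c("ABC", "outside"))]), 0)

  disj <- venn3("a", "b", "c", letters[1:5])
  expect_equal(unname(unclass(disj)[c("A_only", "B_only", "C_only")]),
               c(1, 1, 1))
})

test_that("venn3 counts match per-element membership enumeration", {
  for (seed in 1:10) {
    withr::with_seed(seed, {
      universe <- sprintf("e%03d", 1:80)
      a <- sample(universe, sample(0:60, 1))
      b <- sample(universe, sample(0:60, 1))
      cc <- sample(universe, sample(0:60, 1))
    })
    v <- unclass(venn3(a, b, cc, universe))
    member <- cbind(universe %in% a, universe %in% b, universe %in% cc)
    key <- apply(member, 1, function(m) paste(as.integer(m),
                                              collapse = ""))
    ref <- c(A_only = sum(key == "100"), B_only = sum(key == "010"),
             C_only = sum(key == "001"), AB = sum(key == "110"),
             AC = sum(key == "101"), BC = sum(key == "011"),
             ABC = sum(key == "111"), outside = sum(key == "000"))
    expect_equal(v[names(ref)], ref)
    expect_equal(sum(v), 80)
  }
})

test_that("set elements outside the universe are rejected", {
  expect_error(venn3("z9", "a", "b", letters[1:5]),
               class = "replilife_not_in_universe_error")
})

test_that("chi-squared enrichment equals the hand-expanded formula", {
  ref <- oracle_chisq(20, 1000, 30, 2000)
  ann <- tibble::tibble(
    gene_id = c(sprintf("t%04d", 1:20), sprintf("u%04d", 1:30)),
    term_id = "GO:X"
  )
  res <- chisq_enrichment(sprintf("t%04d", 1:1000),
                          c(sprintf("t%04d", 1:1000),
                            sprintf("u%04d", 1:2000)), ann)
  expect_equal(res$chi2, ref, tolerance = 1e-9)
  expect_equal(res$p, pchisq(ref, 1, lower.tail = FALSE),
               tolerance = 1e-9)
  expect_equal(res$fold, (20 / 1000) / (50 / 3000))
})

test_that("equal in/out term frequency gives chi2 = 0, p = 1, fold = 1", {
  # 10% of targets and 10% of the rest carry the term
  ann <- tibble::tibble(
    gene_id = c(sprintf("t%03d", 1:10), sprintf("u%03d", 1:10)),
    term_id = "GO:E"
  )
  res <- chisq_enrichment(sprintf("t%03d", 1:100),
                          c(sprintf("t%03d", 1:100),
                            sprintf("u%03d", 1:100)), ann)
  expect_equal(res$chi2, 0, tolerance = 1e-12)
  expect_equal(res$p, 1, tolerance = 1e-12)
  expect_equal(res$fold, 1)
})

test_that("degenerate margins are flagged with p = 1, and BH is optional", {
  # every gene carries the term: zero 'without-term' margin
  genes <- sprintf("g%02d", 1:20)
  ann <- tibble::tibble(gene_id = genes, term_id = "GO:ALL")
  res <- chisq_enrichment(genes[1:5], genes, ann)
  expect_true(res$degenerate)
  expect_equal(res$p, 1)
  expect_equal(res$chi2, 0)

  ann2 <- dplyr::bind_rows(ann,
                           tibble::tibble(gene_id = genes[1:6],
                                          term_id = "GO:SOME"))
  res2 <- chisq_enrichment(genes[1:5], genes, ann2, adjust = TRUE)
  expect_true("p_adj" %in% names(res2))
  expect_true(all(res2$p_adj >= res2$p - 1e-12))
})

test_that("target genes outside the universe are rejected", {
  expect_error(
    chisq_enrichment("zz", c("a", "b"),
                     tibble::tibble(gene_id = "a", term_id = "GO:1")),
    class = "replilife_not_in_universe_error"
  )
})
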