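#' Chi-squared GO-term enrichment of a bound gene set against the genome
#'
#' For each annotation term, forms the 2x2 contingency table of (gene in
#' target set vs not) by (gene annotated with term vs not) over the gene
#' universe and applies the Pearson chi-squared test (1 df, no
#' continuity correction).  Fold enrichment is the term frequency among
#' target genes over its frequency in the whole universe,
#' `(k_in / n_in) / ((k_in + k_out) / (n_in + n_out))`.
#'
#' @param target_genes Character vector of bound (target) gene ids; must
#'   be a subset of `genes`.
#' @param genes Character vector: the gene universe.
#' @param annotations Data frame with columns `gene_id`, `term_id`
#'   (one row per gene-term assignment; genes outside the universe are
#'   ignored).
#' @param adjust If `TRUE`, append a Benjamini-Hochberg `p_adj` column
#'   (off by default; raw chi-squared p-values are the primary report).
#' @return A tibble sorted by p-value with one row per term: `term`,
#'   `k_in`, `n_in`, `k_out`, `n_out`, `chi2`, `p`, `fold`,
#'   `degenerate`.  Terms whose 2x2 table has a zero margin are flagged
#'   `degenerate` and reported with `chi2 = 0`, `p = 1`.
#' @examples
#' ann <- tibble::tibble(gene_id = c("g1", "g2", "g3"),
#'                       term_id = "GO:1")
#' chisq_enrichment(c("g1", "g2"), paste0("g", 1:10), ann)
#' @export
chisq_enrichment <- function(target_genes, genes, annotations,
                             adjust = FALSE) {
  genes <- unique(as.character(genes))
  target_genes <- unique(as.character(target_genes))
  stray <- setdiff(target_genes, genes)
  if (length(stray) > 0) {
    stop_not_in_universe(paste0(
      "target gene(s) not in universe: ",
      paste(head(stray, 5), collapse = ", ")
    ))
  }
  required <- c("gene_id", "term_id")
  if (!all(required %in% names(annotations))) {
    stop_schema("annotations must have columns gene_id and term_id")
  }
  ann <- tibble::as_tibble(annotations) |>
    dplyr::filter(.data$gene_id %in% genes) |>
    dplyr::distinct(.data$gene_id, .data$term_id)

  n_in <- length(target_genes)
  n_out <- length(genes) - n_in
  in_target <- ann$gene_id %in% target_genes

  rows <- ann |>
    dplyr::mutate(in_target = in_target) |>
    dplyr::group_by(term = .data$term_id) |>
    dplyr::summarise(
      k_in = sum(.data$in_target),
      k_out = dplyr::n() - sum(.data$in_target),
      .groups = "drop"
    ) |>
    dplyr::mutate(n_in = n_in, n_out = n_out) |>
    dplyr::select("term", "k_in", "n_in", "k_out", "n_out")

  stat <- purrr::pmap(rows[, -1], function(k_in, n_in, k_out, n_out) {
    tab <- matrix(c(k_in, n_in - k_in, k_out, n_out - k_out), nrow = 2)
    degenerate <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
    if (degenerate) {
      return(list(chi2 = 0, p = 1, degenerate = TRUE))
    }
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    list(chi2 = unname(ct$statistic), p = unname(ct$p.value),
         degenerate = FALSE)
  })
  total_rate <- (rows$k_in + rows$k_out) / (n_in + n_out)
  rows |>
    dplyr::mutate(
      chi2 = purrr::map_dbl(stat, "chi2"),
      p = purrr::map_dbl(stat, "p"),
      fold = (.data$k_in / .data$n_in) / total_rate,
      degenerate = purrr::map_lgl(stat, "degenerate")
    ) |>
    (\(d) if (adjust) {
      dplyr::mutate(d, p_adj = stats::p.adjust(.data$p, "BH"))
    } else d)() |>
    dplyr::arrange(.data$p, dplyr::desc(.data$chi2))
}
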