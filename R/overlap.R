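# Peak-to-promoter informatics: midpoints, strand-aware TSS offsets,
# window-based target assignment, and base-level peak overlap.  All
# coordinates are 0-based half-open (BED dialect); a TSS is a single
# 0-based coordinate.

validate_peaks <- function(peaks, arg = "peaks") {
  required <- c("chrom", "start", "end")
  missing_cols <- setdiff(required, names(peaks))
  if (length(missing_cols) > 0) {
    stop_schema(paste0(arg, " is missing column(s): ",
                       paste(missing_cols, collapse = ", ")))
  }
  peaks <- tibble::as_tibble(peaks)
  if (any(peaks$start < 0 | peaks$start >= peaks$end)) {
    stop_schema(paste0(arg, ": need 0 <= start < end (0-based half-open)"))
  }
  peaks
}

validate_genes <- function(genes) {
  required <- c("id", "chrom", "tss", "strand")
  missing_cols <- setdiff(required, names(genes))
  if (length(missing_cols) > 0) {
    stop_schema(paste0("genes is missing column(s): ",
                       paste(missing_cols, collapse = ", ")))
  }
  genes <- tibble::as_tibble(genes)
  if (!all(genes$strand %in% c("+", "-"))) {
    stop_schema("genes: strand must be '+' or '-'")
  }
  genes
}

#' Peak midpoints under the half-open convention
#'
#' The midpoint of a 0-based half-open interval `[start, end)` is
#' `floor((start + end - 1) / 2)`: the coordinate of the middle base,
#' left of centre for even-length peaks.  Always lies inside the peak.
#'
#' @param peaks Data frame with columns `chrom`, `start`, `end` (plus
#'   anything else, carried through).
#' @return The input with a `midpoint` column added.
#' @examples
#' peak_midpoint(tibble::tibble(chrom = "I", start = 100, end = 200))
#' @export
peak_midpoint <- function(peaks) {
  peaks <- validate_peaks(peaks)
  dplyr::mutate(peaks, midpoint = floor((.data$start + .data$end - 1) / 2))
}

#' Strand-aware offsets of peak midpoints to the nearest TSS
#'
#' For each peak, the signed distance from its midpoint to the nearest
#' transcription start site on the same chromosome; the sign is flipped
#' for minus-strand genes so that upstream is always negative.
#'
#' @param peaks Peak data frame (`chrom`, `start`, `end`, optional
#'   `factor`).
#' @param genes Gene data frame (`id`, `chrom`, `tss`, `strand`).
#' @return A tibble with one row per peak on a chromosome that has at
#'   least one gene: the peak columns plus `midpoint`, `gene_id`,
#'   `offset`.  Peaks on chromosomes without genes are dropped with a
#'   warning (`replilife_no_gene_on_chrom_warning`).
#' @export
tss_offsets <- function(peaks, genes) {
  peaks <- peak_midpoint(peaks)
  genes <- validate_genes(genes)
  orphan <- setdiff(unique(peaks$chrom), unique(genes$chrom))
  if (length(orphan) > 0) {
    rlang::warn(
      paste0("no genes on chromosome(s) ", paste(orphan, collapse = ", "),
             "; their peaks are skipped"),
      class = "replilife_no_gene_on_chrom_warning"
    )
    peaks <- peaks[!peaks$chrom %in% orphan, , drop = FALSE]
  }
  if (nrow(peaks) == 0) {
    return(dplyr::mutate(peaks, gene_id = character(0),
                         offset = numeric(0)))
  }
  peaks |>
    dplyr::group_by(.data$chrom) |>
    dplyr::group_modify(function(pk, key) {
      g <- genes[genes$chrom == key$chrom, , drop = FALSE]
      nearest <- vapply(pk$midpoint, function(m) {
        which.min(abs(g$tss - m))
      }, integer(1))
      pk$gene_id <- g$id[nearest]
      raw <- pk$midpoint - g$tss[nearest]
      pk$offset <- ifelse(g$strand[nearest] == "-", -raw, raw)
      pk
    }) |>
    dplyr::ungroup()
}

#' Histogram of peak-midpoint offsets around the TSS
#'
#' Bins the strand-aware nearest-TSS offsets of [tss_offsets()] into
#' `bin_width`-bp bins (bins are `[lower, upper)`, aligned to multiples
#' of `bin_width`).  Used to locate the promoter-proximal band of
#' enriched binding around the transcription start site.
#'
#' @inheritParams tss_offsets
#' @param bin_width Bin width in bp (default 50).
#' @return A `tss_profile` tibble with columns `bin_start`, `bin_end`,
#'   `bin_mid`, `count`; the per-peak offsets are kept in the
#'   `"offsets"` attribute.
#' @export
tss_offset_profile <- function(peaks, genes, bin_width = 50) {
  stopifnot(bin_width > 0)
  off <- tss_offsets(peaks, genes)
  bins <- floor(off$offset / bin_width)
  counts <- table(bins)
  out <- tibble::tibble(
    bin_start = as.numeric(names(counts)) * bin_width,
    bin_end = (as.numeric(names(counts)) + 1) * bin_width,
    count = as.integer(counts)
  ) |>
    dplyr::mutate(bin_mid = (.data$bin_start + .data$bin_end) / 2,
                  .after = "bin_end") |>
    dplyr::arrange(.data$bin_start)
  structure(out, offsets = off$offset, bin_width = bin_width,
            class = c("tss_profile", class(out)))
}

#' @export
autoplot.tss_profile <- function(object, window = c(-700, 100), ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$bin_mid, y = .data$count)) +
    ggplot2::geom_col(width = attr(object, "bin_width")) +
    ggplot2::geom_vline(xintercept = window, linetype = "dashed") +
    ggplot2::labs(x = "offset of peak midpoint from TSS (bp)",
                  y = "peaks") +
    ggplot2::theme_minimal()
}

#' Assign peaks to promoter target genes within a TSS window
#'
#' A gene is a target of a factor when at least one of that factor's
#' peak midpoints falls, strand-aware, within `window` of the gene's
#' TSS (default -700 bp upstream to +100 bp downstream, both ends
#' inclusive) -- the promoter-proximal band in which binding is most
#' enriched.  Assignment is by midpoint only; a peak may target several
#' genes and a gene may be hit by several peaks.
#'
#' @inheritParams tss_offsets
#' @param window Length-2 numeric, `c(upstream, downstream)` offsets
#'   defining the inclusive window (upstream negative).
#' @param mode `"all"` (default) assigns every gene whose window
#'   contains a midpoint; `"nearest"` restricts each peak to its nearest
#'   TSS before applying the window.
#' @return A tibble with columns `factor`, `gene_id` (distinct pairs).
#'   When `peaks` lacks a `factor` column all peaks form one factor
#'   `"peak"`.
#' @examples
#' genes <- tibble::tibble(id = "g1", chrom = "I", tss = 1000,
#'                         strand = "+")
#' peaks <- tibble::tibble(chrom = "I", start = 550, end = 651,
#'                         factor = "MDL-1")
#' assign_targets(peaks, genes)  # midpoint 600, offset -400: target
#' @export
assign_targets <- function(peaks, genes, window = c(-700, 100),
                           mode = c("all", "nearest")) {
  mode <- match.arg(mode)
  stopifnot(length(window) == 2, window[[1]] < window[[2]])
  peaks <- peak_midpoint(peaks)
  genes <- validate_genes(genes)
  if (!"factor" %in% names(peaks)) peaks$factor <- "peak"

  empty <- tibble::tibble(factor = character(0), gene_id = character(0))
  if (nrow(peaks) == 0 || nrow(genes) == 0) return(empty)

  if (mode == "nearest") {
    off <- suppressWarnings(tss_offsets(peaks, genes))
    hits <- off[off$offset >= window[[1]] & off$offset <= window[[2]], ,
                drop = FALSE]
    out <- tibble::tibble(factor = hits$factor, gene_id = hits$gene_id)
    return(dplyr::distinct(dplyr::arrange(out, .data$factor,
                                          .data$gene_id)))
  }

  # all-in-window mode via interval overlap: each gene contributes its
  # strand-oriented window as a genomic interval, each peak a width-1
  # midpoint interval
  win_start <- ifelse(genes$strand == "+",
                      genes$tss + window[[1]], genes$tss - window[[2]])
  win_end <- ifelse(genes$strand == "+",
                    genes$tss + window[[2]], genes$tss - window[[1]])
  gene_gr <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(start = win_start + 1, end = win_end + 1)
  )
  peak_gr <- GenomicRanges::GRanges(
    peaks$chrom, IRanges::IRanges(start = peaks$midpoint + 1, width = 1)
  )
  ov <- GenomicRanges::findOverlaps(peak_gr, gene_gr)
  out <- tibble::tibble(
    factor = peaks$factor[S4Vectors::queryHits(ov)],
    gene_id = genes$id[S4Vectors::subjectHits(ov)]
  )
  dplyr::distinct(dplyr::arrange(out, .data$factor, .data$gene_id))
}

#' Fraction of a peak covered by other peaks
#'
#' Base-level coverage: for each row of `peaks`, the fraction of its
#' bases covered by the union of `other_peaks` on the same chromosome.
#' Used to ask whether one factor's binding peak lies mostly inside the
#' binding regions of other factors (e.g. the ">= 75% overlapped" rule
#' for shared regulatory regions).
#'
#' @param peaks Peak data frame whose coverage is measured.
#' @param other_peaks Peak data frame forming the covering union.
#' @return `peaks` with an `overlap_frac` column in \[0, 1\].
#' @examples
#' p <- tibble::tibble(chrom = "I", start = 0, end = 100)
#' o <- tibble::tibble(chrom = c("I", "I"), start = c(0, 20),
#'                     end = c(30, 60))
#' peak_overlap_fraction(p, o)$overlap_frac  # 0.6
#' @export
peak_overlap_fraction <- function(peaks, other_peaks) {
  peaks <- validate_peaks(peaks)
  other_peaks <- validate_peaks(other_peaks, "other_peaks")
  if (nrow(other_peaks) == 0) {
    return(dplyr::mutate(peaks, overlap_frac = 0))
  }
  q <- GenomicRanges::GRanges(
    peaks$chrom,
    IRanges::IRanges(start = peaks$start + 1, end = peaks$end)
  )
  s <- GenomicRanges::reduce(GenomicRanges::GRanges(
    other_peaks$chrom,
    IRanges::IRanges(start = other_peaks$start + 1, end = other_peaks$end)
  ))
  ov <- GenomicRanges::findOverlaps(q, s)
  covered <- rep(0, nrow(peaks))
  if (length(ov) > 0) {
    inter_w <- GenomicRanges::width(GenomicRanges::pintersect(
      q[S4Vectors::queryHits(ov)], s[S4Vectors::subjectHits(ov)]
    ))
    agg <- tapply(inter_w, S4Vectors::queryHits(ov), sum)
    covered[as.integer(names(agg))] <- as.numeric(agg)
  }
  dplyr::mutate(peaks,
                overlap_frac = covered / (.data$end - .data$start))
}
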