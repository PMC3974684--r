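# File-format readers and writers.  TSVs are UTF-8 with '.' decimal and
# a required header; BED is 0-based half-open; FASTA goes through
# Biostrings.  Readers validate and report offending data line numbers
# in typed schema errors; writers round-trip losslessly through the
# corresponding reader.

read_tsv_strict <- function(path, col_types) {
  if (!file.exists(path)) stop_parse(paste0("file not found: ", path))
  out <- tryCatch(
    # suppress readr's parser/column mismatch warning; missing columns
    # are reported as a typed schema error by the caller
    suppressWarnings(
      readr::read_tsv(path, col_types = col_types, comment = "#",
                      progress = FALSE)
    ),
    error = function(e) stop_parse(paste0("cannot parse ", path, ": ",
                                          conditionMessage(e)))
  )
  probs <- readr::problems(out)
  if (nrow(probs) > 0) {
    stop_parse(paste0(
      "malformed rows in ", path, " (data line(s) ",
      paste(head(unique(probs$row), 10), collapse = ", "), "): ",
      probs$expected[[1]], " expected, got ", probs$actual[[1]]
    ))
  }
  out
}

check_columns <- function(data, required, path) {
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    stop_schema(paste0(path, " is missing column(s): ",
                       paste(missing_cols, collapse = ", ")))
  }
}

#' Read a replica-set mortality TSV
#'
#' Expected columns: `condition`, `trial`, `well_id`, `timepoint`,
#' `n_alive`, `n_dead` (tab-separated, header required, UTF-8, `.`
#' decimal separator; `#` comment lines tolerated).
#'
#' @param path File path.
#' @return A validated mortality tibble (one row per well observation).
#'   Invalid rows (negative counts, empty wells, negative timepoints)
#'   raise a `replilife_schema_error` naming the data line numbers.
#' @export
read_mortality_tsv <- function(path) {
  data <- read_tsv_strict(path, readr::cols(
    condition = readr::col_character(),
    trial = readr::col_character(),
    well_id = readr::col_character(),
    timepoint = readr::col_double(),
    n_alive = readr::col_double(),
    n_dead = readr::col_double()
  ))
  check_columns(data, c("condition", "trial", "well_id", "timepoint",
                        "n_alive", "n_dead"), path)
  bad <- which(
    !is.finite(data$timepoint) | data$timepoint < 0 |
      !is.finite(data$n_alive) | data$n_alive < 0 |
      !is.finite(data$n_dead) | data$n_dead < 0 |
      (data$n_alive + data$n_dead) < 1
  )
  if (length(bad) > 0) {
    stop_schema(paste0(
      path, ": invalid observation(s) at data line(s) ",
      paste(head(bad + 1, 10), collapse = ", "),
      " (need timepoint >= 0, counts >= 0, n_alive + n_dead >= 1)"
    ))
  }
  data
}

#' Write a replica-set mortality TSV
#' @param data Mortality tibble ([read_mortality_tsv()] layout).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mortality_tsv <- function(data, path) {
  data <- validate_mortality(data)
  if (!"condition" %in% names(data)) data$condition <- "unknown"
  if (!"trial" %in% names(data)) data$trial <- "t1"
  if (!"well_id" %in% names(data)) {
    data$well_id <- sprintf("w%03d", seq_len(nrow(data)))
  }
  readr::write_tsv(data[, c("condition", "trial", "well_id", "timepoint",
                            "n_alive", "n_dead")], path)
  invisible(path)
}

#' Read a traditional lifespan event TSV
#'
#' Expected columns: `condition`, `animal_id`, `day`, `censored` (0/1).
#'
#' @param path File path.
#' @return A lifespan-event tibble with logical `censored`.
#' @export
read_lifespan_tsv <- function(path) {
  data <- read_tsv_strict(path, readr::cols(
    condition = readr::col_character(),
    animal_id = readr::col_character(),
    day = readr::col_double(),
    censored = readr::col_double()
  ))
  check_columns(data, c("condition", "animal_id", "day", "censored"),
                path)
  bad <- which(!is.finite(data$day) | data$day < 0 |
                 !data$censored %in% c(0, 1))
  if (length(bad) > 0) {
    stop_schema(paste0(
      path, ": invalid event(s) at data line(s) ",
      paste(head(bad + 1, 10), collapse = ", "),
      " (need day >= 0 and censored in {0, 1})"
    ))
  }
  data$censored <- data$censored == 1
  data
}

#' Write a traditional lifespan event TSV
#' @param data Lifespan-event tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lifespan_tsv <- function(data, path) {
  data <- validate_events(data)
  if (!"condition" %in% names(data)) data$condition <- "unknown"
  if (!"animal_id" %in% names(data)) {
    data$animal_id <- sprintf("a%05d", seq_len(nrow(data)))
  }
  out <- data[, c("condition", "animal_id", "day", "censored")]
  out$censored <- as.integer(out$censored)
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read ChIP-seq peaks from a BED file
#'
#' BED dialect: 0-based half-open, tab-separated, no header; column 4
#' (if present) is the factor label.  Track/browser/comment lines are
#' skipped.
#'
#' @param path File path.
#' @return A peak tibble (`chrom`, `start`, `end`, `factor`, `peak_id`);
#'   `peak_id` is the canonical `factor:chrom:start-end` key used to
#'   attach sequences.
#' @export
read_bed_peaks <- function(path) {
  if (!file.exists(path)) stop_parse(paste0("file not found: ", path))
  lines <- readr::read_lines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) &
                   nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(tibble::tibble(chrom = character(0), start = numeric(0),
                          end = numeric(0), factor = character(0),
                          peak_id = character(0)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    stop_parse(paste0(path, ": BED line(s) ",
                      paste(head(which(nf < 3), 10), collapse = ", "),
                      " have fewer than 3 fields"))
  }
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3)))
  bad <- which(!is.finite(start) | !is.finite(end) | start < 0 |
                 start >= end)
  if (length(bad) > 0) {
    stop_schema(paste0(
      path, ": invalid coordinates at line(s) ",
      paste(head(bad, 10), collapse = ", "),
      " (need numeric 0 <= start < end, 0-based half-open)"
    ))
  }
  peaks <- tibble::tibble(
    chrom = vapply(fields, `[[`, "", 1),
    start = start,
    end = end,
    factor = ifelse(nf >= 4,
                    vapply(fields, function(f) {
                      if (length(f) >= 4) f[[4]] else "peak"
                    }, ""),
                    "peak")
  )
  peaks$peak_id <- paste0(peaks$factor, ":", peaks$chrom, ":",
                          peaks$start, "-", peaks$end)
  peaks
}

#' Write peaks to a BED file (BED3 + factor name column)
#' @param peaks Peak tibble (`chrom`, `start`, `end`, optional
#'   `factor`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed_peaks <- function(peaks, path) {
  peaks <- validate_peaks(peaks)
  if (!"factor" %in% names(peaks)) peaks$factor <- "peak"
  readr::write_tsv(peaks[, c("chrom", "start", "end", "factor")], path,
                   col_names = FALSE)
  invisible(path)
}

#' Read a gene table TSV
#'
#' Expected columns: `id`, `chrom`, `tss` (single 0-based coordinate),
#' `strand` (`+`/`-`).
#'
#' @param path File path.
#' @return A gene tibble.
#' @export
read_gene_table <- function(path) {
  data <- read_tsv_strict(path, readr::cols(
    id = readr::col_character(),
    chrom = readr::col_character(),
    tss = readr::col_double(),
    strand = readr::col_character()
  ))
  check_columns(data, c("id", "chrom", "tss", "strand"), path)
  bad <- which(!is.finite(data$tss) | data$tss < 0 |
                 !data$strand %in% c("+", "-"))
  if (length(bad) > 0) {
    stop_schema(paste0(
      path, ": invalid gene(s) at data line(s) ",
      paste(head(bad + 1, 10), collapse = ", "),
      " (need tss >= 0 and strand '+' or '-')"
    ))
  }
  data
}

#' Write a gene table TSV
#' @param genes Gene tibble (`id`, `chrom`, `tss`, `strand`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(genes, path) {
  genes <- validate_genes(genes)
  readr::write_tsv(genes[, c("id", "chrom", "tss", "strand")], path)
  invisible(path)
}

#' Read peak sequences from a FASTA file
#'
#' @param path File path.
#' @return Named character vector of uppercase sequences keyed by FASTA
#'   record name (the peak id).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_parse(paste0("file not found: ", path))
  set <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) stop_parse(paste0("cannot parse FASTA ", path,
                                          ": ", conditionMessage(e)))
  )
  setNames(toupper(as.character(set)), names(set))
}

#' Write peak sequences to a FASTA file
#' @param sequences Named character vector (names become record ids).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  if (is.null(names(sequences)) || any(!nzchar(names(sequences)))) {
    stop_schema("sequences must be a fully named vector")
  }
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(sequences), path
  )
  invisible(path)
}

#' Read a gene-to-GO-term annotation TSV
#'
#' Two columns, `gene_id` and `term_id`, one row per assignment.
#'
#' @param path File path.
#' @return An annotation tibble.
#' @export
read_go_tsv <- function(path) {
  data <- read_tsv_strict(path, readr::cols(
    gene_id = readr::col_character(),
    term_id = readr::col_character()
  ))
  check_columns(data, c("gene_id", "term_id"), path)
  data
}

#' Write a gene-to-GO-term annotation TSV
#' @param annotations Annotation tibble (`gene_id`, `term_id`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_go_tsv <- function(annotations, path) {
  if (!all(c("gene_id", "term_id") %in% names(annotations))) {
    stop_schema("annotations must have columns gene_id and term_id")
  }
  readr::write_tsv(annotations[, c("gene_id", "term_id")], path)
  invisible(path)
}

#' Write an analysis result to disk
#'
#' Serialises a result object (a tidy data frame or a named list, e.g.
#' the [glance()] of any fitted object) as JSON or TSV with stable field
#' ordering and an embedded schema version.
#'
#' @param results A data frame or named list.
#' @param path Output path.
#' @param fmt `"json"` (default) or `"tsv"` (data frames only).
#' @return `path`, invisibly.
#' @export
report <- function(results, path, fmt = c("json", "tsv")) {
  fmt <- match.arg(fmt)
  if (fmt == "tsv") {
    if (!is.data.frame(results)) {
      stop_schema("TSV reports require a data frame")
    }
    readr::write_tsv(results, path)
  } else {
    payload <- list(schema = "replilife/1", results = results)
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}
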