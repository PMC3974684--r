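# E-box (enhancer box) scanning.  Myc-family bHLHZip dimers bind the
# E-box consensus CANNTG (N = any base); the pattern class is closed
# under reverse complement, so a single-strand scan suffices.

EBOX <- "CANNTG"

#' Count E-box motif matches in DNA sequences
#'
#' Counts positions matching the Myc-family E-box consensus `CANNTG`
#' (`N` = any of A/C/G/T).  Matching uses [Biostrings] ambiguity codes
#' in the pattern only, so an `N` in the *input* sequence matches
#' nothing but the pattern's `N` positions.  Overlapping matches are
#' counted (the consensus cannot overlap itself in-frame, but a sliding
#' scan is used regardless).
#'
#' @param sequence Character vector of DNA sequences (alphabet
#'   A/C/G/T/N, case-insensitive) or a [Biostrings::DNAStringSet].
#' @return Integer vector of match counts, one per sequence.
#' @section Errors: `replilife_alphabet_error` on characters outside
#'   A/C/G/T/N.
#' @examples
#' scan_ebox(c("CACGTG", "AAAAAA", "CATATGCACGTG"))  # 1 0 2
#' @export
scan_ebox <- function(sequence) {
  if (inherits(sequence, "DNAStringSet")) {
    sequence <- as.character(sequence)
  }
  sequence <- toupper(sequence)
  bad <- grepl("[^ACGTN]", sequence)
  if (any(bad)) {
    stop_alphabet(paste0(
      "sequence(s) ", paste(head(which(bad), 5), collapse = ", "),
      " contain characters outside the A/C/G/T/N alphabet"
    ))
  }
  vapply(
    sequence,
    function(s) {
      if (nchar(s) < nchar(EBOX)) return(0L)
      Biostrings::countPattern(EBOX, Biostrings::DNAString(s),
                               fixed = "subject")
    },
    integer(1),
    USE.NAMES = FALSE
  )
}

#' Fraction of peaks containing at least one E-box
#'
#' @param peaks Peak data frame with a `peak_id` column (as produced by
#'   [simulate_genome()] or [read_bed_peaks()]).
#' @param sequences Named character vector or
#'   [Biostrings::DNAStringSet], one sequence per peak, keyed by
#'   `peak_id`.
#' @return A list with `n_peaks`, `n_with_ebox`, `fraction` (in
#'   \[0, 1\]) and `percent` (one-decimal percent, rounded half away
#'   from zero, the reporting convention for this quantity).
#' @section Errors: `replilife_missing_sequence_error` when a peak has
#'   no sequence.
#' @examples
#' pk <- tibble::tibble(chrom = "I", start = 0, end = 6,
#'                      peak_id = c("p1"))
#' ebox_fraction(pk, c(p1 = "CACGTG"))
#' @export
ebox_fraction <- function(peaks, sequences) {
  peaks <- validate_peaks(peaks)
  if (!"peak_id" %in% names(peaks)) {
    stop_schema("peaks must have a peak_id column to key sequences")
  }
  if (inherits(sequences, "DNAStringSet")) {
    sequences <- setNames(as.character(sequences), names(sequences))
  }
  missing_seq <- setdiff(peaks$peak_id, names(sequences))
  if (length(missing_seq) > 0) {
    stop_missing_sequence(paste0(
      "no sequence for peak(s): ",
      paste(head(missing_seq, 5), collapse = ", ")
    ))
  }
  counts <- scan_ebox(sequences[peaks$peak_id])
  n_with <- sum(counts >= 1)
  n <- nrow(peaks)
  list(
    n_peaks = n,
    n_with_ebox = n_with,
    fraction = n_with / n,
    percent = round_half_away(100 * n_with / n, 1)
  )
}
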