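#' Three-set overlap (Venn) counts over a fixed universe
#'
#' Partitions `universe` into the seven non-empty regions of three sets
#' plus the outside, by per-element membership.  Used to count gene
#' promoters bound by each combination of three transcription factors.
#'
#' @param set_a,set_b,set_c Character vectors (subsets of `universe`).
#' @param universe Character vector of all elements (e.g. all genes).
#' @param names Length-3 character, display names of the sets.
#' @return A `venn3` object: named integer vector of counts with
#'   elements `A_only`, `B_only`, `C_only`, `AB`, `AC`, `BC`, `ABC`,
#'   `outside` (regions are exclusive and partition the universe), with
#'   a [tidy()] method.
#' @section Errors: `replilife_not_in_universe_error` when a set
#'   contains elements outside the universe.
#' @examples
#' venn3(c("a", "b"), c("b", "c"), c("b"), letters[1:5])
#' @export
venn3 <- function(set_a, set_b, set_c, universe,
                  names = c("A", "B", "C")) {
  stopifnot(length(names) == 3)
  universe <- unique(as.character(universe))
  sets <- list(unique(as.character(set_a)), unique(as.character(set_b)),
               unique(as.character(set_c)))
  stray <- setdiff(unique(unlist(sets)), universe)
  if (length(stray) > 0) {
    stop_not_in_universe(paste0(
      "set element(s) not in universe: ",
      paste(head(stray, 5), collapse = ", ")
    ))
  }
  in_a <- universe %in% sets[[1]]
  in_b <- universe %in% sets[[2]]
  in_c <- universe %in% sets[[3]]
  counts <- c(
    A_only = sum(in_a & !in_b & !in_c),
    B_only = sum(!in_a & in_b & !in_c),
    C_only = sum(!in_a & !in_b & in_c),
    AB = sum(in_a & in_b & !in_c),
    AC = sum(in_a & !in_b & in_c),
    BC = sum(!in_a & in_b & in_c),
    ABC = sum(in_a & in_b & in_c),
    outside = sum(!in_a & !in_b & !in_c)
  )
  structure(counts, set_names = names, universe_size = length(universe),
            class = "venn3")
}

#' @export
print.venn3 <- function(x, ...) {
  nm <- attr(x, "set_names")
  cat(sprintf("Three-set overlap of %s, %s, %s (universe %d):\n",
              nm[1], nm[2], nm[3], attr(x, "universe_size")))
  print(unclass(x))
  invisible(x)
}

#' @export
tidy.venn3 <- function(x, ...) {
  tibble::tibble(region = names(unclass(x)),
                 count = as.integer(unclass(x)))
}
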