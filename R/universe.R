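#' Define the spot universe for HrSMLP1 profiling
#'
#' The self-marker protein HrSMLP1 resolves into a fixed series of 2D-DIGE
#' spots (by default twelve, labelled 1..12). Four of these ("core" spots
#' 3, 5, 7 and 9) are constitutively expressed in every individual examined;
#' the remaining spots vary between individuals. Spot calling additionally
#' relies on a small set of reference spots (three 49-kDa protein spots)
#' used for intensity normalization; these live in a separate namespace
#' from the target spots.
#'
#' @param spot_ids Integer vector of target spot labels (unique, 1-based).
#' @param core_ids Subset of `spot_ids` expected present in all individuals.
#' @param reference_ids Character labels of the normalization reference
#'   spots; must be disjoint from the target labels.
#'
#' @return An object of class `spot_universe`.
#' @examples
#' u <- spot_universe()
#' u$core_ids
#' @export
spot_universe <- function(spot_ids = 1:12,
                          core_ids = c(3L, 5L, 7L, 9L),
                          reference_ids = c("ref1", "ref2", "ref3")) {
  spot_ids <- as.integer(spot_ids)
  core_ids <- as.integer(core_ids)
  if (anyNA(spot_ids) || anyDuplicated(spot_ids))
    stop("spot_ids must be unique non-missing integers")
  if (!all(core_ids %in% spot_ids))
    stop("core_ids must be a subset of spot_ids")
  reference_ids <- as.character(reference_ids)
  if (anyDuplicated(reference_ids))
    stop("reference_ids must be unique")
  if (any(reference_ids %in% as.character(spot_ids)))
    stop("reference_ids must be disjoint from spot_ids")
  structure(
    list(spot_ids = sort(spot_ids),
         core_ids = sort(core_ids),
         reference_ids = reference_ids),
    class = "spot_universe"
  )
}

#' @export
print.spot_universe <- function(x, ...) {
  cat("Spot universe:", length(x$spot_ids), "target spots (",
      paste(x$spot_ids, collapse = ", "), ")\n")
  cat("  core spots:", paste(x$core_ids, collapse = ", "), "\n")
  cat("  reference spots:", paste(x$reference_ids, collapse = ", "), "\n")
  invisible(x)
}

variable_spots <- function(universe) {
  setdiff(universe$spot_ids, universe$core_ids)
}
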