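#' Assay configuration for CR calling
#'
#' Bundles the tunables of the contact-reaction (CR) call: the OD520
#' threshold separating CR-positive from CR-negative mixtures (0.13 on the
#' raw replicate aggregate), the replicate aggregation statistic, the
#' boundary convention at exactly the threshold, and the declared replicate
#' count.
#'
#' @param cr_threshold Non-negative OD520 threshold; default 0.13.
#' @param replicate_agg `"mean"` (default) or `"median"`.
#' @param boundary_rule `"ge"` (default; OD equal to the threshold calls
#'   CR-positive) or `"gt"`.
#' @param n_replicates Declared replicates per mixture; default 3.
#' @return A list of class `assay_config`.
#' @export
assay_config <- function(cr_threshold = 0.13,
                         replicate_agg = c("mean", "median"),
                         boundary_rule = c("ge", "gt"),
                         n_replicates = 3L) {
  replicate_agg <- match.arg(replicate_agg)
  boundary_rule <- match.arg(boundary_rule)
  if (!is.numeric(cr_threshold) || cr_threshold < 0)
    stop("cr_threshold must be >= 0")
  n_replicates <- as.integer(n_replicates)
  if (is.na(n_replicates) || n_replicates < 1)
    stop("n_replicates must be >= 1")
  structure(list(cr_threshold = cr_threshold, replicate_agg = replicate_agg,
                 boundary_rule = boundary_rule, n_replicates = n_replicates),
            class = "assay_config")
}

#' Construct a binary contact-reaction matrix
#'
#' A CR matrix records, for every unordered pair of individuals, whether
#' mixing their hemocytes induced a contact reaction (1) or not (0). It is
#' symmetric with a zero diagonal (CR is defined between distinct
#' individuals only).
#'
#' @param values Square 0/1 matrix (symmetric, hollow diagonal). `NA`
#'   marks a pair whose CR status was not assayed; such pairs are
#'   excluded from downstream consistency counts.
#' @param individuals Character IDs in row/column order; defaults to the
#'   dimnames of `values`.
#' @return A matrix of class `cr_matrix`.
#' @export
cr_matrix <- function(values, individuals = rownames(values)) {
  values <- as.matrix(values)
  if (is.null(individuals))
    stop("individual IDs are required (rownames or `individuals`)")
  individuals <- as.character(individuals)
  if (nrow(values) != ncol(values) || nrow(values) != length(individuals))
    stop("values must be square with one row per individual")
  if (anyDuplicated(individuals)) stop("duplicate individual IDs")
  storage.mode(values) <- "integer"
  if (!all(values %in% c(0L, 1L, NA))) stop("CR entries must be 0, 1 or NA")
  if (!identical(values, t(values))) stop("CR matrix must be symmetric")
  if (anyNA(diag(values)) || any(diag(values) != 0L))
    stop("CR matrix diagonal must be 0")
  dimnames(values) <- list(individuals, individuals)
  class(values) <- c("cr_matrix", "matrix")
  values
}

#' @export
print.cr_matrix <- function(x, ...) {
  n <- nrow(x)
  cat("CR matrix over", n, "individuals;",
      sum(x[upper.tri(x)]), "of", choose(n, 2), "pairs reactive\n")
  print(unclass(x))
  invisible(x)
}

#' Aggregate replicate PO readings per canonical pair
#'
#' @param table A [po_table()] of pairwise mixtures (mAb rows are dropped).
#' @param cfg An [assay_config()].
#' @param strict If `TRUE` (default), every pair must have exactly
#'   `cfg$n_replicates` readings; if `FALSE`, any positive count is
#'   accepted.
#' @return A data.frame with columns `subject_a`, `subject_b`, `od`
#'   (one aggregated OD per canonical pair).
#' @export
aggregate_replicates <- function(table, cfg = assay_config(),
                                 strict = TRUE) {
  stopifnot(inherits(table, "po_table"))
  tab <- table[table$subject_b != "mAb", , drop = FALSE]
  if (nrow(tab) == 0) stop("no pairwise readings in table")
  key <- paste(tab$subject_a, tab$subject_b, sep = "\r")
  counts <- table(key)
  if (strict && any(counts != cfg$n_replicates)) {
    off <- names(counts)[counts != cfg$n_replicates][1]
    stop("pair ", gsub("\r", "/", off), " has ", counts[[off]],
         " replicates; expected ", cfg$n_replicates,
         " (use strict = FALSE to allow)")
  }
  f <- switch(cfg$replicate_agg, mean = mean, median = stats::median)
  agg <- tapply(tab$od520, key, f)
  parts <- strsplit(names(agg), "\r", fixed = TRUE)
  out <- data.frame(subject_a = vapply(parts, `[`, "", 1),
                    subject_b = vapply(parts, `[`, "", 2),
                    od = as.numeric(agg), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Binarize aggregated PO readings into a CR matrix
#'
#' An off-diagonal entry is 1 iff the aggregated OD reaches the threshold
#' (`>=` under the default boundary rule). Self-mixes, if present in the
#' input, are ignored: the diagonal is 0 by definition.
#'
#' @param mean_od Data.frame from [aggregate_replicates()] (`subject_a`,
#'   `subject_b`, `od`).
#' @param cfg An [assay_config()].
#' @param individuals Character vector of all individuals to include;
#'   defaults to those present in `mean_od`.
#' @param strict If `TRUE` (default), every unordered pair must be present;
#'   if `FALSE`, missing pairs are filled with 0 with a warning.
#' @return A [cr_matrix()].
#' @export
binarize_cr <- function(mean_od, cfg = assay_config(), individuals = NULL,
                        strict = TRUE) {
  if (is.null(individuals))
    individuals <- sort(unique(c(mean_od$subject_a, mean_od$subject_b)))
  individuals <- as.character(individuals)
  unknown <- setdiff(unique(c(mean_od$subject_a, mean_od$subject_b)),
                     individuals)
  if (length(unknown))
    stop("unknown individual(s) in OD map: ", paste(unknown, collapse = ", "))
  n <- length(individuals)
  m <- matrix(0L, n, n, dimnames = list(individuals, individuals))
  seen <- matrix(FALSE, n, n, dimnames = list(individuals, individuals))
  cmp <- if (cfg$boundary_rule == "ge") `>=` else `>`
  for (r in seq_len(nrow(mean_od))) {
    a <- mean_od$subject_a[r]; b <- mean_od$subject_b[r]
    if (a == b) next  # self-mix: diagonal stays 0
    v <- as.integer(cmp(mean_od$od[r], cfg$cr_threshold))
    m[a, b] <- v; m[b, a] <- v
    seen[a, b] <- seen[b, a] <- TRUE
  }
  missing <- which(!seen & upper.tri(seen), arr.ind = TRUE)
  if (nrow(missing)) {
    msg <- paste(individuals[missing[, 1]], individuals[missing[, 2]],
                 sep = "/", collapse = ", ")
    if (strict)
      stop("missing OD for pair(s): ", msg)
    warning("missing OD for pair(s) ", msg, "; filled with 0", call. = FALSE)
  }
  cr_matrix(m, individuals)
}

#' Call a CR matrix straight from a PO table
#'
#' Convenience wrapper: [aggregate_replicates()] then [binarize_cr()].
#'
#' @inheritParams aggregate_replicates
#' @inheritParams binarize_cr
#' @return A [cr_matrix()].
#' @export
call_cr <- function(table, cfg = assay_config(), individuals = NULL,
                    strict = TRUE) {
  binarize_cr(aggregate_replicates(table, cfg, strict = strict),
              cfg, individuals, strict = strict)
}
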