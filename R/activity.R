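#' Configuration for activity grouping
#'
#' @param alpha Two-sided significance level used when deciding whether
#'   the next individual (in descending mean order) still belongs to the
#'   current activity group; default 0.01.
#' @param min_reps Minimum replicates required per individual; default 3.
#' @param pool If `TRUE` (default) the candidate is tested against the
#'   pooled replicates of the growing group; if `FALSE`, against the
#'   nearest member (the last one merged) only.
#' @return A list of class `grouping_config`.
#' @export
grouping_config <- function(alpha = 0.01, min_reps = 3L, pool = TRUE) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must be in (0, 1)")
  structure(list(alpha = alpha, min_reps = as.integer(min_reps),
                 pool = isTRUE(pool)),
            class = "grouping_config")
}

#' Welch's unequal-variance t test
#'
#' Two-sided Welch t test with Welch-Satterthwaite degrees of freedom.
#' When both samples are constant, the comparison degenerates: equal
#' constants give p = 1 by convention; different constants give p = 0
#' (the samples are separated with certainty at any level).
#'
#' @param a,b Numeric replicate vectors, each of length >= 2.
#' @return A list with `t` and `p`.
#' @export
welch_t_test <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2 || length(b) < 2)
    stop("each sample needs at least 2 replicates")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, p = 1))
    return(list(t = sign(mean(a) - mean(b)) * Inf, p = 0))
  }
  tt <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(tt$statistic), p = tt$p.value)
}

#' Group individuals into discrete activity classes
#'
#' Individuals are sorted by mean antibody-induced OD520 (descending) and
#' scanned greedily: the next individual joins the current group iff the
#' Welch test of its replicates against the group's replicates (pooled by
#' default) is not significant at `alpha`; otherwise a new group opens.
#' The procedure is deterministic and invariant to input row order.
#'
#' @param table A [po_table()]; rows with `subject_b == "mAb"` are used
#'   (a table with only pairwise rows is an error).
#' @param cfg A [grouping_config()].
#' @return A list of class `activity_grouping` with `groups` (list of
#'   member ID vectors, in descending-activity order), `means` (named
#'   per-individual means) and `cfg`.
#' @export
group_by_activity <- function(table, cfg = grouping_config()) {
  stopifnot(inherits(table, "po_table"))
  tab <- table[table$subject_b == "mAb", , drop = FALSE]
  if (nrow(tab) == 0) stop("no antibody-stimulation rows (subject_b == 'mAb')")
  reps <- split(tab$od520, tab$subject_a)
  short <- names(reps)[lengths(reps) < cfg$min_reps]
  if (length(short))
    stop("individual(s) with fewer than ", cfg$min_reps, " replicates: ",
         paste(short, collapse = ", "))
  means <- vapply(reps, mean, 0)
  # stable order: by descending mean, ties by ID
  ord <- order(-means, names(means))
  ids <- names(means)[ord]

  groups <- list()
  cur <- ids[1]
  for (id in ids[-1]) {
    ref <- if (cfg$pool) unlist(reps[cur], use.names = FALSE)
           else reps[[cur[length(cur)]]]
    p <- welch_t_test(reps[[id]], ref)$p
    if (p >= cfg$alpha) cur <- c(cur, id)
    else { groups <- c(groups, list(cur)); cur <- id }
  }
  groups <- c(groups, list(cur))
  structure(list(groups = groups, means = means[ids], cfg = cfg),
            class = "activity_grouping")
}

#' @export
print.activity_grouping <- function(x, ...) {
  cat("Activity grouping:", length(x$groups), "group(s)\n")
  for (i in seq_along(x$groups)) {
    g <- x$groups[[i]]
    cat(sprintf("  group %d (mean OD %.3f): %s\n", i,
                mean(x$means[g]), paste(g, collapse = ", ")))
  }
  invisible(x)
}

#' Concordance between activity groups and CR clusters
#'
#' Quantifies how closely the antibody-induced activity classes track the
#' partition obtained by clustering the CR matrix: Rand and adjusted Rand
#' indices plus the cross-tabulation.
#'
#' @param activity_groups An [group_by_activity()] result or a partition
#'   (list of ID vectors).
#' @param cr_clusters A partition (e.g. from [cut_dendrogram()]).
#' @return A list of class `concordance_report` with `rand_index`,
#'   `adjusted_rand` and `contingency`.
#' @export
concordance_report <- function(activity_groups, cr_clusters) {
  if (inherits(activity_groups, "activity_grouping"))
    activity_groups <- activity_groups$groups
  idx <- compare_partitions(activity_groups, cr_clusters)
  m1 <- partition_membership(activity_groups)
  m2 <- partition_membership(cr_clusters)
  ids <- sort(names(m1))
  tab <- table(activity = m1[ids], cr_cluster = m2[ids])
  structure(c(idx, list(contingency = tab)), class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf("Partition concordance: Rand %.4f, adjusted Rand %.4f\n",
              x$rand_index, x$adjusted_rand))
  print(x$contingency)
  invisible(x)
}
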