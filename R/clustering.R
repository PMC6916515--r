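#' Manhattan distances between individuals' CR rows
#'
#' Treats each individual's row of the binary CR matrix as a feature
#' vector and computes pairwise L1 (Manhattan) distances. By default the
#' full rows are used, including the self column and the two mutual
#' columns of each pair; `include_self_cols = FALSE` drops columns i and j
#' when computing d(i, j).
#'
#' @param cr A [cr_matrix()].
#' @param include_self_cols Use full rows (default) or exclude the pair's
#'   own columns.
#' @return A symmetric numeric distance matrix with zero diagonal.
#' @export
manhattan_matrix <- function(cr, include_self_cols = TRUE) {
  stopifnot(inherits(cr, "cr_matrix"))
  m <- unclass(cr)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = dimnames(m))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i >= j) next
    cols <- if (include_self_cols) seq_len(n) else setdiff(seq_len(n), c(i, j))
    d[i, j] <- d[j, i] <- sum(abs(m[i, cols] - m[j, cols]))
  }
  d
}

#' UPGMA (group-average) agglomerative clustering
#'
#' From-scratch unweighted pair-group average clustering. At each step the
#' two clusters at minimal average cross-pair distance are merged; the
#' merge height is half the merge distance (the standard cophenetic
#' convention). Ties — frequent with small binary matrices — are broken
#' deterministically by the lexicographically smallest pair
#' (min leaf ID of cluster a, min leaf ID of cluster b).
#'
#' @param dist Symmetric non-negative distance matrix with zero diagonal;
#'   dimnames supply leaf IDs (defaults to `"1"`, `"2"`, ... otherwise).
#' @return An object of class `upgma_tree`: a list with `leaves`
#'   (character IDs) and `merges` (list of merges; each has `members_a`,
#'   `members_b`, `height`, `dist`).
#' @examples
#' d <- matrix(c(0, 2, 4, 2, 0, 6, 4, 6, 0), 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' upgma(d)
#' @export
upgma <- function(dist) {
  dist <- as.matrix(dist)
  n <- nrow(dist)
  if (n < 2) stop("need at least 2 leaves")
  if (!isTRUE(all.equal(dist, t(dist))) || any(dist < 0) ||
      any(diag(dist) != 0))
    stop("dist must be symmetric, non-negative, with zero diagonal")
  leaves <- rownames(dist)
  if (is.null(leaves)) leaves <- as.character(seq_len(n))

  clusters <- as.list(leaves)        # character vectors of member leaves
  sizes <- rep(1L, n)
  d <- dist
  dimnames(d) <- NULL
  merges <- vector("list", n - 1L)

  for (step in seq_len(n - 1L)) {
    k <- length(clusters)
    # find minimal off-diagonal distance, lexicographic tie-break
    best <- NULL; best_key <- NULL; best_d <- Inf
    for (i in seq_len(k - 1L)) for (j in seq((i + 1L), k)) {
      dij <- d[i, j]
      if (dij > best_d + 1e-12) next
      mi <- min(clusters[[i]]); mj <- min(clusters[[j]])
      key <- if (mi <= mj) c(mi, mj) else c(mj, mi)
      take <- dij < best_d - 1e-12 ||
        (is.null(best_key) || key[1] < best_key[1] ||
         (key[1] == best_key[1] && key[2] < best_key[2]))
      if (take) { best <- c(i, j); best_key <- key; best_d <- dij }
    }
    i <- best[1]; j <- best[2]
    a <- clusters[[i]]; b <- clusters[[j]]
    if (min(b) < min(a)) { tmp <- a; a <- b; b <- tmp }
    merges[[step]] <- list(members_a = sort(a), members_b = sort(b),
                           height = best_d / 2, dist = best_d)
    # Lance–Williams average-linkage update
    ni <- sizes[i]; nj <- sizes[j]
    newrow <- (ni * d[i, ] + nj * d[j, ]) / (ni + nj)
    keep <- setdiff(seq_len(k), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], newrow[keep]),
               c(newrow[keep], 0))
    clusters <- c(clusters[keep], list(c(a, b)))
    sizes <- c(sizes[keep], ni + nj)
  }
  structure(list(leaves = leaves, merges = merges), class = "upgma_tree")
}

#' @export
print.upgma_tree <- function(x, ...) {
  cat("UPGMA dendrogram:", length(x$leaves), "leaves,",
      length(x$merges), "merges\n")
  for (m in x$merges)
    cat(sprintf("  {%s} + {%s} at height %.4g\n",
                paste(m$members_a, collapse = ","),
                paste(m$members_b, collapse = ","), m$height))
  invisible(x)
}

#' Cophenetic distance matrix of a UPGMA dendrogram
#'
#' The cophenetic distance between two leaves is twice the height of the
#' merge that first joins them (i.e. the merge distance).
#'
#' @param tree An [upgma()] result.
#' @return Symmetric numeric matrix over `tree$leaves`.
#' @export
cophenetic_matrix <- function(tree) {
  stopifnot(inherits(tree, "upgma_tree"))
  ids <- tree$leaves
  n <- length(ids)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  for (mg in tree$merges)
    m[mg$members_a, mg$members_b] <- m[mg$members_b, mg$members_a] <-
      2 * mg$height
  m
}

#' Cut a dendrogram into k clusters
#'
#' Removes the k-1 highest (last) merges and returns the resulting
#' partition, sorted by each cluster's smallest member ID.
#'
#' @param tree An [upgma()] result.
#' @param k Number of clusters, between 1 and the number of leaves.
#' @return A list of character vectors (the clusters).
#' @export
cut_dendrogram <- function(tree, k) {
  stopifnot(inherits(tree, "upgma_tree"))
  n <- length(tree$leaves)
  k <- as.integer(k)
  if (is.na(k) || k < 1 || k > n) stop("k must be in [1, ", n, "]")
  parent <- stats::setNames(tree$leaves, tree$leaves)
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  nkeep <- n - k
  for (mg in tree$merges[seq_len(nkeep)])
    parent[[find(mg$members_b[1])]] <- find(mg$members_a[1])
  roots <- vapply(tree$leaves, find, "")
  cl <- split(tree$leaves, roots)
  cl <- lapply(cl, sort)
  cl[order(vapply(cl, min, ""))] |> unname()
}

#' Rand and adjusted Rand indices between two partitions
#'
#' Pair-counting agreement between two partitions of the same leaf set:
#' the Rand index is the fraction of unordered pairs classified alike
#' (together in both or apart in both); the adjusted Rand index corrects
#' it for chance.
#'
#' @param p1,p2 Partitions: lists of character vectors over identical leaf
#'   sets.
#' @return A list with `rand_index` and `adjusted_rand`.
#' @export
compare_partitions <- function(p1, p2) {
  m1 <- partition_membership(p1)
  m2 <- partition_membership(p2)
  ids <- sort(names(m1))
  if (!identical(ids, sort(names(m2))))
    stop("partitions must cover identical leaf sets")
  m1 <- m1[ids]; m2 <- m2[ids]
  tab <- table(m1, m2)
  n <- length(ids)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  total <- choose(n, 2)
  # pairs together in both (a) and apart in both (d)
  a <- sum_ij
  d <- total - sum_a - sum_b + sum_ij
  rand <- (a + d) / total
  expected <- sum_a * sum_b / total
  denom <- (sum_a + sum_b) / 2 - expected
  ari <- if (denom == 0) 1 else (sum_ij - expected) / denom
  list(rand_index = rand, adjusted_rand = ari)
}

partition_membership <- function(p) {
  if (is.list(p)) {
    ids <- unlist(p, use.names = FALSE)
    if (anyDuplicated(ids)) stop("partition has overlapping clusters")
    stats::setNames(rep(seq_along(p), lengths(p)), ids)
  } else if (!is.null(names(p))) {
    stats::setNames(as.integer(factor(p)), names(p))
  } else stop("partition must be a list of ID vectors or a named vector")
}

#' Export a dendrogram in Newick format
#'
#' Branch lengths are height differences, so leaf-to-leaf path lengths
#' reproduce the cophenetic distances.
#'
#' @param tree An [upgma()] result.
#' @param path Optional file to write to.
#' @return The Newick string, invisibly if `path` is given.
#' @export
write_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "upgma_tree"))
  node_str <- stats::setNames(tree$leaves, tree$leaves)
  node_h <- stats::setNames(rep(0, length(tree$leaves)), tree$leaves)
  key <- function(members) paste(sort(members), collapse = "\r")
  for (mg in tree$merges) {
    ka <- key(mg$members_a); kb <- key(mg$members_b)
    s <- sprintf("(%s:%.10g,%s:%.10g)",
                 node_str[[ka]], mg$height - node_h[[ka]],
                 node_str[[kb]], mg$height - node_h[[kb]])
    kk <- key(c(mg$members_a, mg$members_b))
    node_str[[kk]] <- s
    node_h[[kk]] <- mg$height
  }
  out <- paste0(node_str[[key(tree$leaves)]], ";")
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}
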