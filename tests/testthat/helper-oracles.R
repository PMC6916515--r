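# Shared helpers: independent oracles and random-input generators.

# random symmetric hollow 0/1 matrix over n individuals
random_cr <- function(n, p = 0.5) {
  m <- matrix(0L, n, n)
  up <- upper.tri(m)
  m[up] <- stats::rbinom(sum(up), 1, p)
  m <- m + t(m)
  ids <- sprintf("i%02d", seq_len(n))
  cr_matrix(m, ids)
}

# brute-force Manhattan distances by explicit double loop
naive_manhattan <- function(m) {
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = dimnames(m))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    s <- 0
    for (k in seq_len(n)) s <- s + abs(m[i, k] - m[j, k])
    d[i, j] <- s
  }
  d
}

# naive UPGMA: at every step recompute every inter-cluster average from
# the original leaf-level matrix (no Lance-Williams update); same
# lexicographic tie rule as the implementation
naive_upgma <- function(dist) {
  ids <- rownames(dist)
  clusters <- as.list(ids)
  merges <- list()
  while (length(clusters) > 1) {
    k <- length(clusters)
    best <- NULL; best_d <- Inf; best_key <- NULL
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      dd <- mean(dist[clusters[[i]], clusters[[j]]])
      mi <- min(clusters[[i]]); mj <- min(clusters[[j]])
      key <- sort(c(mi, mj))
      if (dd < best_d - 1e-12 ||
          (dd < best_d + 1e-12 &&
           (is.null(best_key) || key[1] < best_key[1] ||
            (key[1] == best_key[1] && key[2] < best_key[2])))) {
        best <- c(i, j); best_d <- dd; best_key <- key
      }
    }
    a <- clusters[[best[1]]]; b <- clusters[[best[2]]]
    if (min(b) < min(a)) { tmp <- a; a <- b; b <- tmp }
    merges <- c(merges, list(list(members_a = sort(a), members_b = sort(b),
                                  height = best_d / 2, dist = best_d)))
    clusters <- c(clusters[-best], list(c(a, b)))
  }
  structure(list(leaves = ids, merges = merges), class = "upgma_tree")
}

# pair-enumeration Rand / ARI oracle
brute_rand <- function(p1, p2) {
  m1 <- allomark:::partition_membership(p1)
  m2 <- allomark:::partition_membership(p2)
  ids <- sort(names(m1))
  agree <- 0; tog1 <- 0; tog2 <- 0; both <- 0; tot <- 0
  for (i in seq_along(ids)) for (j in seq_along(ids)) {
    if (i >= j) next
    tot <- tot + 1
    s1 <- m1[[ids[i]]] == m1[[ids[j]]]
    s2 <- m2[[ids[i]]] == m2[[ids[j]]]
    if (s1 == s2) agree <- agree + 1
    tog1 <- tog1 + s1; tog2 <- tog2 + s2; both <- both + (s1 && s2)
  }
  exp_b <- tog1 * tog2 / tot
  denom <- (tog1 + tog2) / 2 - exp_b
  list(rand_index = agree / tot,
       adjusted_rand = if (denom == 0) 1 else (both - exp_b) / denom)
}

# random profile set over the default universe
random_profiles <- function(n, p = 0.4, universe = spot_universe()) {
  vs <- setdiff(universe$spot_ids, universe$core_ids)
  profs <- lapply(seq_len(n), function(i)
    sort(c(universe$core_ids, vs[stats::runif(length(vs)) < p])))
  names(profs) <- sprintf("r%03d", seq_len(n))
  spot_profile_set(profs, universe)
}

# intensity table realizing given profiles exactly (present = reference level)
intensities_from_profiles <- function(profiles, universe = attr(profiles, "universe"),
                                      ref_level = 100) {
  rows <- list()
  for (id in names(profiles)) {
    pres <- profiles[[id]]
    for (s in universe$spot_ids)
      rows[[length(rows) + 1]] <- data.frame(
        individual = id, spot = as.character(s),
        intensity = if (s %in% pres) ref_level else 0)
    for (r in universe$reference_ids)
      rows[[length(rows) + 1]] <- data.frame(
        individual = id, spot = r, intensity = ref_level)
  }
  spot_intensity_table(do.call(rbind, rows), universe)
}
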