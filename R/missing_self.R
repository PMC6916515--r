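#' A set of per-individual spot presence/absence profiles
#'
#' A `spot_profile_set` is a named list mapping each individual ID to the
#' sorted integer vector of spots it expresses, over a common
#' [spot_universe()].
#'
#' @param profiles Named list of integer vectors (present spots).
#' @param universe A [spot_universe()].
#' @return An object of class `spot_profile_set`.
#' @examples
#' spot_profile_set(list(`92` = c(1, 3, 5, 7, 9), `99` = c(3, 5, 7, 9, 12)))
#' @export
spot_profile_set <- function(profiles, universe = spot_universe()) {
  if (is.null(names(profiles)) || any(names(profiles) == ""))
    stop("profiles must be a fully named list (individual IDs)")
  if (anyDuplicated(names(profiles))) stop("duplicate individual IDs")
  profiles <- lapply(profiles, function(v) sort(unique(as.integer(v))))
  for (id in names(profiles)) {
    extra <- setdiff(profiles[[id]], universe$spot_ids)
    if (length(extra))
      stop("individual ", id, " has spot(s) outside the universe: ",
           paste(extra, collapse = ", "))
  }
  structure(profiles, universe = universe, class = "spot_profile_set")
}

#' @export
print.spot_profile_set <- function(x, ...) {
  cat("Spot profiles for", length(x), "individual(s):\n")
  for (id in names(x))
    cat(sprintf("  %s: {%s}\n", id, paste(x[[id]], collapse = ", ")))
  invisible(x)
}

#' @export
`[.spot_profile_set` <- function(x, i) {
  spot_profile_set(unclass(x)[i], attr(x, "universe"))
}

#' Call presence/absence spot profiles from DIGE intensities
#'
#' Each target-spot intensity is normalized by the mean intensity of the
#' individual's reference spots; a spot is called present when the
#' normalized intensity reaches the relative threshold `tau`.
#'
#' @param intensities A [spot_intensity_table()].
#' @param universe A [spot_universe()]; defaults to the table's own.
#' @param tau Relative presence threshold (> 0); default 0.1.
#' @return A [spot_profile_set()].
#' @export
call_spots <- function(intensities, universe = NULL, tau = 0.1) {
  stopifnot(inherits(intensities, "spot_intensity_table"))
  if (is.null(universe)) universe <- attr(intensities, "universe")
  if (!is.numeric(tau) || tau <= 0) stop("tau must be > 0")
  profs <- list()
  for (ind in unique(intensities$individual)) {
    sub <- intensities[intensities$individual == ind, ]
    refs <- sub$intensity[sub$spot %in% universe$reference_ids]
    refmean <- mean(refs)
    if (refmean == 0)
      stop("individual ", ind, ": mean reference intensity is 0")
    tgt <- sub[sub$spot %in% as.character(universe$spot_ids), ]
    norm <- tgt$intensity / refmean
    profs[[ind]] <- as.integer(tgt$spot[norm >= tau])
  }
  spot_profile_set(profs, universe)
}

#' Compare the spot profiles of a pair of individuals
#'
#' Partitions the spot universe into spots expressed by both individuals
#' (`shared_expressed`), expressed by neither (`shared_absent`), and
#' expressed by exactly one (`discordant`).
#'
#' @param a,b Integer vectors of present spots, or a single ID each if
#'   `profiles` is given.
#' @param universe A [spot_universe()].
#' @param profiles Optional [spot_profile_set()] to look `a` and `b` up in.
#' @return A list of class `pair_comparison` with the three spot sets and
#'   `cr_observed` / `cr_predicted` slots (initially `NA`).
#' @examples
#' compare_pair(c(1, 3, 5, 7, 9), c(3, 5, 7, 9, 12))
#' @export
compare_pair <- function(a, b, universe = spot_universe(), profiles = NULL) {
  ids <- c(NA_character_, NA_character_)
  if (!is.null(profiles)) {
    stopifnot(inherits(profiles, "spot_profile_set"))
    universe <- attr(profiles, "universe")
    ids <- c(as.character(a), as.character(b))
    a <- profiles[[ids[1]]]; b <- profiles[[ids[2]]]
    if (is.null(a) || is.null(b)) stop("unknown individual ID")
  }
  a <- sort(unique(as.integer(a))); b <- sort(unique(as.integer(b)))
  if (length(setdiff(c(a, b), universe$spot_ids)))
    stop("profiles contain spots outside the universe")
  structure(list(
    pair = ids,
    shared_expressed = intersect(a, b),
    shared_absent = setdiff(universe$spot_ids, union(a, b)),
    discordant = sort(c(setdiff(a, b), setdiff(b, a))),
    cr_observed = NA_integer_,
    cr_predicted = NA_integer_
  ), class = "pair_comparison")
}

#' @export
print.pair_comparison <- function(x, ...) {
  if (!anyNA(x$pair)) cat("Pair:", x$pair[1], "vs", x$pair[2], "\n")
  cat("  shared expressed:", paste(x$shared_expressed, collapse = ", "), "\n")
  cat("  shared absent:   ", paste(x$shared_absent, collapse = ", "), "\n")
  cat("  discordant:      ", paste(x$discordant, collapse = ", "), "\n")
  if (!is.na(x$cr_observed))
    cat("  CR observed:", x$cr_observed,
        " predicted:", x$cr_predicted, "\n")
  invisible(x)
}

#' Spots expressed by every individual
#'
#' @param profiles A [spot_profile_set()].
#' @return Sorted integer vector: the intersection of all present sets.
#' @export
core_spots <- function(profiles) {
  stopifnot(inherits(profiles, "spot_profile_set"), length(profiles) >= 1)
  sort(Reduce(intersect, unclass(profiles)))
}

#' Predict contact reaction under the missing-self rule
#'
#' Two individuals are predicted CR-reactive (1) iff their profiles,
#' restricted to `spot_set`, differ — identical restricted patterns
#' (including shared absences) predict no reaction (0). The prediction is
#' symmetric in its arguments and monotone in `spot_set`.
#'
#' @param a,b Integer vectors of present spots.
#' @param spot_set Subset of the universe to compare on; default all spots.
#' @param universe A [spot_universe()].
#' @return 0 or 1.
#' @export
predict_cr <- function(a, b, spot_set = universe$spot_ids,
                       universe = spot_universe()) {
  spot_set <- as.integer(spot_set)
  if (length(setdiff(spot_set, universe$spot_ids)))
    stop("spot_set must be a subset of the universe")
  ia <- sort(intersect(as.integer(a), spot_set))
  ib <- sort(intersect(as.integer(b), spot_set))
  as.integer(!identical(ia, ib))
}

#' Evaluate missing-self predictions against observed CR
#'
#' Applies [predict_cr()] on every unordered pair with known CR status
#' (NA entries in the CR matrix are treated as unknown and excluded) and
#' tabulates agreement: tp/tn are correctly predicted reactive /
#' non-reactive pairs, fp/fn the disagreements. Each disagreement is
#' returned as a [compare_pair()] record with its CR slots filled in.
#'
#' @param cr A [cr_matrix()] (NA allowed off-diagonal for unknown pairs).
#' @param profiles A [spot_profile_set()] covering all CR individuals.
#' @param spot_set Spot subset used for prediction; default all spots.
#' @return A list of class `consistency_report` with `spot_set_tested`,
#'   `tp`, `tn`, `fp`, `fn`, `n_pairs` and `violations`.
#' @export
consistency_report <- function(cr, profiles,
                               spot_set = attr(profiles, "universe")$spot_ids) {
  stopifnot(inherits(cr, "cr_matrix"), inherits(profiles, "spot_profile_set"))
  universe <- attr(profiles, "universe")
  ids <- rownames(cr)
  miss <- setdiff(ids, names(profiles))
  if (length(miss))
    stop("missing profile(s) for: ", paste(miss, collapse = ", "))
  tp <- tn <- fp <- fn <- 0L
  violations <- list()
  n <- length(ids)
  for (i in seq_len(n - 1L)) for (j in seq((i + 1L), n)) {
    obs <- cr[i, j]
    if (is.na(obs)) next
    pred <- predict_cr(profiles[[ids[i]]], profiles[[ids[j]]],
                       spot_set, universe)
    if (pred == 1L && obs == 1L) tp <- tp + 1L
    else if (pred == 0L && obs == 0L) tn <- tn + 1L
    else {
      if (pred == 1L) fp <- fp + 1L else fn <- fn + 1L
      v <- compare_pair(ids[i], ids[j], profiles = profiles)
      v$cr_observed <- as.integer(obs)
      v$cr_predicted <- pred
      violations <- c(violations, list(v))
    }
  }
  structure(list(spot_set_tested = sort(as.integer(spot_set)),
                 tp = tp, tn = tn, fp = fp, fn = fn,
                 n_pairs = tp + tn + fp + fn,
                 violations = violations),
            class = "consistency_report")
}

#' @export
print.consistency_report <- function(x, ...) {
  cat(sprintf(
    "Missing-self consistency on spot set {%s}: %d pair(s)\n",
    paste(x$spot_set_tested, collapse = ", "), x$n_pairs))
  cat(sprintf("  tp %d  tn %d  fp %d  fn %d  (%d violation(s))\n",
              x$tp, x$tn, x$fp, x$fn, length(x$violations)))
  invisible(x)
}

#' Exhaustive search for minimal discriminating spot sets
#'
#' Enumerates every subset of the spot universe up to `max_size` and
#' returns those under which the missing-self prediction reproduces the
#' observed CR matrix without error (zero false positives and false
#' negatives), filtered to inclusion-minimal sets and sorted by size,
#' then lexicographically.
#'
#' @param cr A [cr_matrix()] (NA = unknown pairs, excluded).
#' @param profiles A [spot_profile_set()].
#' @param max_size Largest subset size to consider; default the full
#'   universe.
#' @return A list of integer vectors (possibly empty).
#' @examples
#' fx <- fixture_trio3()
#' search_discriminating_sets(fixture_trio_cr(3), fx)
#' @export
search_discriminating_sets <- function(cr, profiles, max_size = NULL) {
  stopifnot(inherits(cr, "cr_matrix"), inherits(profiles, "spot_profile_set"))
  universe <- attr(profiles, "universe")
  spots <- universe$spot_ids
  ns <- length(spots)
  if (ns > 30) stop("exhaustive search supports at most 30 spots")
  if (is.null(max_size)) max_size <- ns
  if (max_size > ns) stop("max_size exceeds the number of spots")
  ids <- rownames(cr)
  miss <- setdiff(ids, names(profiles))
  if (length(miss))
    stop("missing profile(s) for: ", paste(miss, collapse = ", "))

  # bitmask of each pair's discordant spots, split by observed CR status
  bit <- stats::setNames(bitwShiftL(1L, seq_along(spots) - 1L), spots)
  mask <- function(v) sum(bit[as.character(v)])
  d_reactive <- integer(0); d_nonreactive <- integer(0)
  n <- length(ids)
  for (i in seq_len(n - 1L)) for (j in seq((i + 1L), n)) {
    obs <- cr[i, j]
    if (is.na(obs)) next
    a <- profiles[[ids[i]]]; b <- profiles[[ids[j]]]
    dm <- mask(c(setdiff(a, b), setdiff(b, a)))
    if (obs == 1L) d_reactive <- c(d_reactive, dm)
    else d_nonreactive <- c(d_nonreactive, dm)
  }

  valid <- list()
  for (s in 0:(2^ns - 1L)) {
    size <- sum(bitwAnd(s, bit) > 0)
    if (size > max_size) next
    if (length(d_nonreactive) && any(bitwAnd(s, d_nonreactive) != 0L)) next
    if (length(d_reactive) && any(bitwAnd(s, d_reactive) == 0L)) next
    valid <- c(valid, list(s))
  }
  valid <- unlist(valid)
  if (!length(valid)) return(list())

  to_set <- function(s) spots[bitwAnd(s, bit) > 0]
  sets <- lapply(valid, to_set)
  ord <- order(lengths(sets),
               vapply(sets, function(v) paste(sprintf("%04d", v),
                                              collapse = ","), ""))
  valid <- valid[ord]; sets <- sets[ord]
  keep <- rep(TRUE, length(valid))
  for (i in seq_along(valid)) {
    if (!keep[i]) next
    for (j in seq_along(valid)) {
      if (i == j || !keep[i]) next
      # drop i if a kept j is a proper subset of i
      if (keep[j] && valid[j] != valid[i] &&
          bitwAnd(valid[j], valid[i]) == valid[j]) keep[i] <- FALSE
    }
  }
  sets[keep]
}
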