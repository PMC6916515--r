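#' Generative model for a synthetic allorecognition population
#'
#' Describes a population in which every individual carries the core
#' spots and each variable spot independently with a per-spot frequency,
#' contact reactions follow the missing-self rule (reactive iff the two
#' profiles differ), and PO readings are graded with replicate noise.
#' When `variable_freqs` is omitted, a single shared frequency is
#' calibrated with [calibrate_spot_frequency()] so that the expected
#' fraction of reactive pairs equals `target_reactive_fraction`
#' (default 0.85, the reported population CR rate).
#'
#' @param universe A [spot_universe()].
#' @param variable_freqs Per-variable-spot presence probabilities in
#'   `[0, 1]`, recycled/named over the variable spots; `NULL` (default)
#'   calibrates a common value from the target.
#' @param target_reactive_fraction Desired fraction of reactive pairs in
#'   `[0, 1)`; default 0.85.
#' @param po_reactive_mean Mean OD520 contributed per discordant spot
#'   (linear, capped); default 0.08.
#' @param po_baseline_sd Gaussian replicate noise sd on OD520; default 0.02.
#' @param n_replicates Replicates per assay; default 3.
#' @param discordance_cap Discordant-spot count at which the PO signal
#'   saturates; default 4. With the defaults a single-spot difference
#'   yields mean OD 0.08, below the 0.13 call threshold — a deliberate,
#'   documented failure mode of threshold calling.
#' @param effector_spots Spots driving the antibody-induced PO signal;
#'   default c(1, 2, 4, 6, 11).
#' @param effector_weights OD520 contribution of each effector spot when
#'   present; default 0.1 each.
#' @param scenario `"independent"` (default) or `"variant_groups"`, in
#'   which the variant groups \{1, 11\} and \{2, 4, 6\} toggle as blocks
#'   (each block present with the frequency of its first member).
#' @param seed Optional default RNG seed used by the sampling functions.
#' @return A list of class `population_model`.
#' @export
population_model <- function(universe = spot_universe(),
                             variable_freqs = NULL,
                             target_reactive_fraction = 0.85,
                             po_reactive_mean = 0.08,
                             po_baseline_sd = 0.02,
                             n_replicates = 3L,
                             discordance_cap = 4L,
                             effector_spots = c(1L, 2L, 4L, 6L, 11L),
                             effector_weights = rep(0.1, 5),
                             scenario = c("independent", "variant_groups"),
                             seed = NULL) {
  scenario <- match.arg(scenario)
  vs <- variable_spots(universe)
  if (is.null(variable_freqs)) {
    p <- calibrate_spot_frequency(target_reactive_fraction, length(vs))
    variable_freqs <- stats::setNames(rep(p, length(vs)), vs)
  } else {
    variable_freqs <- rep_len(as.numeric(variable_freqs), length(vs))
    names(variable_freqs) <- vs
  }
  if (any(variable_freqs < 0 | variable_freqs > 1))
    stop("variable_freqs must lie in [0, 1]")
  if (!all(effector_spots %in% universe$spot_ids))
    stop("effector_spots must be in the universe")
  structure(list(
    universe = universe,
    variable_freqs = variable_freqs,
    target_reactive_fraction = target_reactive_fraction,
    po_reactive_mean = po_reactive_mean,
    po_baseline_sd = po_baseline_sd,
    n_replicates = as.integer(n_replicates),
    discordance_cap = as.integer(discordance_cap),
    effector_spots = as.integer(effector_spots),
    effector_weights = stats::setNames(rep_len(effector_weights,
                                               length(effector_spots)),
                                       effector_spots),
    scenario = scenario,
    seed = seed
  ), class = "population_model")
}

#' @export
print.population_model <- function(x, ...) {
  cat("Population model:", length(x$variable_freqs), "variable spots,",
      "scenario", x$scenario, "\n")
  cat(sprintf("  expected reactive fraction %.4f (target %.2f)\n",
              expected_reactive_fraction(x$variable_freqs),
              x$target_reactive_fraction))
  invisible(x)
}

#' Calibrate a common spot frequency to a target reactive-pair fraction
#'
#' Under independent variable spots with common presence probability p,
#' two random individuals share a given spot's state with probability
#' q = p^2 + (1-p)^2, so they are profile-identical with probability q^n.
#' Setting q^n = 1 - target and solving q = p^2 + (1-p)^2 for the root
#' at or below 1/2 gives p = (1 - sqrt(2q - 1)) / 2. The target is
#' feasible only when q >= 1/2, i.e. target <= 1 - (1/2)^n.
#'
#' @param target Desired reactive-pair fraction in `[0, 1)`.
#' @param n_variable Number of variable spots (>= 1).
#' @return The calibrated frequency p in `[0, 0.5]`.
#' @examples
#' calibrate_spot_frequency(0.85, 8)  # ~0.12
#' @export
calibrate_spot_frequency <- function(target, n_variable) {
  n_variable <- as.integer(n_variable)
  if (n_variable < 1) stop("n_variable must be >= 1")
  if (!is.numeric(target) || target < 0 || target >= 1)
    stop("target must lie in [0, 1)")
  q <- (1 - target)^(1 / n_variable)
  if (q < 0.5)
    stop(sprintf(
      "target %.4f infeasible for %d variable spots (max %.6f)",
      target, n_variable, 1 - 0.5^n_variable))
  (1 - sqrt(2 * q - 1)) / 2
}

#' Expected reactive-pair fraction under independent spots
#'
#' Closed form: 1 - prod_s (p_s^2 + (1 - p_s)^2).
#'
#' @param freqs Per-spot presence probabilities.
#' @return Expected fraction of pairs with non-identical profiles.
#' @export
expected_reactive_fraction <- function(freqs) {
  1 - prod(freqs^2 + (1 - freqs)^2)
}

#' Sample a population of spot profiles
#'
#' Each individual carries every core spot, plus each variable spot
#' independently with its modelled frequency (or by variant-group blocks
#' under the `"variant_groups"` scenario).
#'
#' @param model A [population_model()].
#' @param n Number of individuals (>= 2).
#' @param seed RNG seed; defaults to the model's.
#' @return A [spot_profile_set()] with IDs `"ind0001"`, ...
#' @export
sample_population <- function(model, n, seed = model$seed) {
  stopifnot(inherits(model, "population_model"))
  n <- as.integer(n)
  if (is.na(n) || n < 2) stop("n must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  u <- model$universe
  vs <- as.integer(names(model$variable_freqs))
  ids <- sprintf("ind%04d", seq_len(n))
  if (model$scenario == "variant_groups") {
    blocks <- list(intersect(c(1L, 11L), vs), intersect(c(2L, 4L, 6L), vs))
    blocks <- blocks[lengths(blocks) > 0]
    singles <- setdiff(vs, unlist(blocks))
    profs <- lapply(ids, function(id) {
      pres <- u$core_ids
      for (bl in blocks)
        if (stats::runif(1) < model$variable_freqs[[as.character(bl[1])]])
          pres <- c(pres, bl)
      on <- singles[stats::runif(length(singles)) <
                      model$variable_freqs[as.character(singles)]]
      sort(c(pres, on))
    })
  } else {
    profs <- lapply(ids, function(id) {
      on <- vs[stats::runif(length(vs)) < model$variable_freqs]
      sort(c(u$core_ids, on))
    })
  }
  names(profs) <- ids
  spot_profile_set(profs, u)
}

#' Fraction of unordered pairs with non-identical profiles
#'
#' @param profiles A [spot_profile_set()] with >= 2 profiles.
#' @return Real in `[0, 1]`.
#' @export
reactive_fraction <- function(profiles) {
  stopifnot(inherits(profiles, "spot_profile_set"), length(profiles) >= 2)
  keys <- vapply(unclass(profiles),
                 function(v) paste(v, collapse = ","), "")
  tab <- table(keys)
  n <- length(keys)
  1 - sum(choose(tab, 2)) / choose(n, 2)
}

#' Simulate pairwise and antibody PO assay tables
#'
#' Pairwise mixtures: each replicate OD520 is
#' `min(n_discordant, cap) * po_reactive_mean` plus Gaussian noise,
#' floored at 0; profile-identical pairs draw from baseline noise only.
#' Antibody stimulations: each individual's mean OD is the sum of the
#' weights of the effector spots it expresses, plus the same noise.
#'
#' @param profiles A [spot_profile_set()].
#' @param model A [population_model()].
#' @param seed RNG seed; defaults to the model's.
#' @return A list with `pairwise` and `antibody`, both [po_table()]s.
#' @export
simulate_po_tables <- function(profiles, model, seed = model$seed) {
  stopifnot(inherits(profiles, "spot_profile_set"),
            inherits(model, "population_model"))
  if (!is.null(seed)) set.seed(seed)
  ids <- names(profiles)
  n <- length(ids)
  nr <- model$n_replicates
  rows_a <- rows_b <- rows_r <- rows_od <- list()
  k <- 0L
  for (i in seq_len(n - 1L)) for (j in seq((i + 1L), n)) {
    a <- profiles[[i]]; b <- profiles[[j]]
    disc <- length(setdiff(a, b)) + length(setdiff(b, a))
    mu <- min(disc, model$discordance_cap) * model$po_reactive_mean
    od <- pmax(0, mu + stats::rnorm(nr, 0, model$po_baseline_sd))
    k <- k + 1L
    rows_a[[k]] <- rep(ids[i], nr); rows_b[[k]] <- rep(ids[j], nr)
    rows_r[[k]] <- seq_len(nr); rows_od[[k]] <- od
  }
  pairwise <- po_table(data.frame(
    subject_a = unlist(rows_a), subject_b = unlist(rows_b),
    replicate = unlist(rows_r), od520 = unlist(rows_od),
    stringsAsFactors = FALSE))

  w <- model$effector_weights
  ab <- do.call(rbind, lapply(ids, function(id) {
    mu <- sum(w[as.character(intersect(model$effector_spots,
                                       profiles[[id]]))])
    data.frame(subject_a = id, subject_b = "mAb",
               replicate = seq_len(nr),
               od520 = pmax(0, mu + stats::rnorm(nr, 0,
                                                 model$po_baseline_sd)),
               stringsAsFactors = FALSE)
  }))
  list(pairwise = pairwise, antibody = po_table(ab))
}
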