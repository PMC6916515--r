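#' Worked CR-trio fixtures
#'
#' Spot profiles for two of the published CR-trios, reconstructed by
#' constraint satisfaction from the pairwise shared/discordant spot
#' statements of the 2D-DIGE analysis:
#'
#' * Trio 2 (#59, #60, #61): #59 and #60 are CR-non-reactive, #61 reacts
#'   with both. #59 = \{1,3,5,7,9,11,12\}, #60 = \{1,3,5,7,9,11\},
#'   #61 = \{2,3,4,5,6,7,8,9,10,12\}. Spot 12 is ambiguous in the printed
#'   statements (two consistent assignments exist); the assignment here —
#'   present in #59 and #61, absent in #60 — is fixed. Under it the
#'   non-reactive pair #59/#60 differs at spot 12, a strict missing-self
#'   violation that [consistency_report()] duly reports rather than
#'   resolves.
#' * Trio 3 (#92, #93, #99): #92 and #93 are CR-non-reactive, #99 reacts
#'   with both. #92 = \{1,3,4,5,6,7,8,9,10,11\}, #93 = \{1,3,5,7,9\},
#'   #99 = \{3,5,7,9,12\}.
#'
#' Trio 1 is not shipped: its printed pairwise statements are mutually
#' inconsistent (no profile assignment satisfies them all), so no fixture
#' is guessed.
#'
#' @return `fixture_trio2()` / `fixture_trio3()`: a [spot_profile_set()].
#'   `fixture_trio_cr(trio)`: the corresponding observed [cr_matrix()].
#' @examples
#' compare_pair("59", "60", profiles = fixture_trio2())
#' @export
fixture_trio2 <- function() {
  spot_profile_set(list(
    `59` = c(1, 3, 5, 7, 9, 11, 12),
    `60` = c(1, 3, 5, 7, 9, 11),
    `61` = c(2, 3, 4, 5, 6, 7, 8, 9, 10, 12)
  ))
}

#' @rdname fixture_trio2
#' @export
fixture_trio3 <- function() {
  spot_profile_set(list(
    `92` = c(1, 3, 4, 5, 6, 7, 8, 9, 10, 11),
    `93` = c(1, 3, 5, 7, 9),
    `99` = c(3, 5, 7, 9, 12)
  ))
}

#' @rdname fixture_trio2
#' @param trio 2 or 3.
#' @export
fixture_trio_cr <- function(trio) {
  if (trio == 2) {
    ids <- c("59", "60", "61")
  } else if (trio == 3) {
    ids <- c("92", "93", "99")
  } else stop("only trios 2 and 3 have consistent fixtures")
  # in both trios: the first two individuals are non-reactive with each
  # other, the third reacts with both
  m <- matrix(c(0L, 0L, 1L,
                0L, 0L, 1L,
                1L, 1L, 0L), 3, 3)
  cr_matrix(m, ids)
}
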