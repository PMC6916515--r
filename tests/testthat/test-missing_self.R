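test_that("spot calling normalizes by the reference mean and thresholds", {
  u <- spot_universe()
  rows <- rbind(
    data.frame(individual = "x", spot = as.character(1:12),
               intensity = c(50, rep(0, 11))),
    data.frame(individual = "x", spot = u$reference_ids, intensity = 100))
  tab <- spot_intensity_table(rows, u)
  profs <- call_spots(tab, tau = 0.1)
  expect_equal(profs[["x"]], 1L)           # 50/100 = 0.5 >= 0.1
  expect_equal(call_spots(tab, tau = 0.6)[["x"]], integer(0))
  expect_error(call_spots(tab, tau = 0), "tau")

  zero_ref <- rows
  zero_ref$intensity[zero_ref$spot %in% u$reference_ids] <- 0
  expect_error(call_spots(spot_intensity_table(zero_ref, u)),
               "reference intensity is 0")
})

test_that("profiles survive the intensity round trip exactly", {
  set.seed(31)
  profs <- random_profiles(8, p = 0.5)
  tab <- intensities_from_profiles(profs)
  called <- call_spots(tab, tau = 0.1)
  expect_equal(unclass(called)[names(profs)], unclass(profs),
               ignore_attr = TRUE)
})

test_that("trio fixtures reproduce every printed pairwise spot count", {
  fx2 <- fixture_trio2()
  # non-reactive pair #59/#60: six spots expressed in both
  expect_equal(compare_pair("59", "60", profiles = fx2)$shared_expressed,
               c(1L, 3L, 5L, 7L, 9L, 11L))
  # reactive #59/#61: seven discordant spots
  expect_equal(compare_pair("59", "61", profiles = fx2)$discordant,
               c(1L, 2L, 4L, 6L, 8L, 10L, 11L))
  # reactive #60/#61: eight discordant spots
  expect_equal(compare_pair("60", "61", profiles = fx2)$discordant,
               c(1L, 2L, 4L, 6L, 8L, 10L, 11L, 12L))

  fx3 <- fixture_trio3()
  cmp9293 <- compare_pair("92", "93", profiles = fx3)
  # non-reactive #92/#93: five shared spots; 2 and 12 absent in both
  expect_equal(cmp9293$shared_expressed, c(1L, 3L, 5L, 7L, 9L))
  expect_true(all(c(2L, 12L) %in% cmp9293$shared_absent))
  expect_equal(compare_pair("92", "99", profiles = fx3)$discordant,
               c(1L, 4L, 6L, 8L, 10L, 11L, 12L))
  expect_equal(compare_pair("93", "99", profiles = fx3)$discordant,
               c(1L, 12L))
})

test_that("core spots across both fixture trios are 3, 5, 7, 9", {
  all6 <- spot_profile_set(c(unclass(fixture_trio2()),
                             unclass(fixture_trio3())))
  expect_equal(core_spots(all6), c(3L, 5L, 7L, 9L))
  one <- fixture_trio3()["93"]
  expect_equal(core_spots(one), c(1L, 3L, 5L, 7L, 9L))
  disjoint <- spot_profile_set(list(p = c(1, 2), q = c(4, 6)))
  expect_equal(core_spots(disjoint), integer(0))
})

test_that("pair comparison partitions the universe into three disjoint sets", {
  self <- compare_pair(c(1, 3, 5), c(1, 3, 5))
  expect_equal(self$discordant, integer(0))
  expect_equal(self$shared_expressed, c(1L, 3L, 5L))

  set.seed(17)
  u <- spot_universe()
  for (rep in 1:25) {
    a <- sort(sample(u$spot_ids, sample(0:12, 1)))
    b <- sort(sample(u$spot_ids, sample(0:12, 1)))
    pc <- compare_pair(a, b, u)
    parts <- c(pc$shared_expressed, pc$shared_absent, pc$discordant)
    expect_equal(sort(parts), u$spot_ids)   # cover, no overlap
  }
})

test_that("missing-self prediction is symmetric and monotone in the spot set", {
  fx3 <- fixture_trio3()
  # observed reactivity of #93/#99 is reproduced over the full universe
  expect_equal(predict_cr(fx3[["93"]], fx3[["99"]]), 1L)
  # restricted to {1, 12}, the non-reactive pair #92/#93 stays at 0
  expect_equal(predict_cr(fx3[["92"]], fx3[["93"]], spot_set = c(1, 12)), 0L)
  expect_equal(predict_cr(fx3[["92"]], fx3[["92"]]), 0L)

  set.seed(19)
  u <- spot_universe()
  for (rep in 1:25) {
    a <- sample(u$spot_ids, sample(0:12, 1))
    b <- sample(u$spot_ids, sample(0:12, 1))
    s <- sample(u$spot_ids, sample(0:12, 1))
    t <- union(s, sample(u$spot_ids, sample(0:12, 1)))
    expect_equal(predict_cr(a, b, s), predict_cr(b, a, s))
    if (predict_cr(a, b, s) == 1L) expect_equal(predict_cr(a, b, t), 1L)
  }
})

test_that("consistency report is clean on generative data and flags faults", {
  model <- population_model(seed = 23)
  profs <- sample_population(model, 14)
  # CR generated by the missing-self rule itself
  ids <- names(profs)
  m <- outer(ids, ids, Vectorize(function(i, j)
    if (i == j) 0L else predict_cr(profs[[i]], profs[[j]])))
  cr <- cr_matrix(m, ids)
  rep0 <- consistency_report(cr, profs)
  expect_equal(rep0$fp + rep0$fn, 0L)
  expect_equal(rep0$n_pairs, choose(14, 2))

  # flip one spot in one member of a non-reactive identical pair
  twin <- spot_profile_set(list(t1 = c(3, 5, 7, 9), t2 = c(3, 5, 7, 9)))
  cr2 <- cr_matrix(matrix(0L, 2, 2), c("t1", "t2"))
  broken <- spot_profile_set(list(t1 = c(1, 3, 5, 7, 9), t2 = c(3, 5, 7, 9)))
  rep1 <- consistency_report(cr2, broken)
  expect_equal(rep1$fp, 1L)
  expect_length(rep1$violations, 1)
  expect_equal(rep1$violations[[1]]$cr_observed, 0L)
  expect_equal(rep1$violations[[1]]$cr_predicted, 1L)

  # empty spot set: everything predicted non-reactive
  rep2 <- consistency_report(cr, profs, spot_set = integer(0))
  expect_equal(rep2$fp, 0L)
  expect_equal(rep2$fn, rep0$tp)

  # NA-status pairs are excluded from the counts
  m3 <- unclass(cr2); m3[1, 2] <- m3[2, 1] <- NA
  rep3 <- consistency_report(cr_matrix(m3, c("t1", "t2")), twin)
  expect_equal(rep3$n_pairs, 0L)
})

test_that("the spot-12 ambiguity in trio 2 surfaces as a reported violation", {
  # under the fixed fixture assignment, non-reactive #59/#60 differ at
  # spot 12 -- a strict missing-self violation the report must expose
  rep <- consistency_report(fixture_trio_cr(2), fixture_trio2())
  expect_equal(rep$fp, 1L)
  expect_equal(rep$fn, 0L)
  expect_equal(rep$violations[[1]]$pair, c("59", "60"))
  expect_equal(rep$violations[[1]]$discordant, 12L)
})

test_that("trio 3 yields the minimal discriminating sets {1} and {12}", {
  sets <- search_discriminating_sets(fixture_trio_cr(3), fixture_trio3())
  expect_equal(sets, list(1L, 12L))
})

test_that("a reactive pair with identical profiles admits no discriminating set", {
  profs <- spot_profile_set(list(a = c(3, 5), b = c(3, 5)))
  cr <- cr_matrix(matrix(c(0L, 1L, 1L, 0L), 2), c("a", "b"))
  expect_equal(search_discriminating_sets(cr, profs), list())
})

test_that("every returned set is zero-violation and inclusion-minimal", {
  set.seed(29)
  for (rep in 1:5) {
    profs <- random_profiles(8, p = 0.5)
    ids <- names(profs)
    m <- outer(ids, ids, Vectorize(function(i, j)
      if (i == j) 0L else predict_cr(profs[[i]], profs[[j]],
                                     spot_set = c(2L, 4L))))
    cr <- cr_matrix(m, ids)
    sets <- search_discriminating_sets(cr, profs, max_size = 4)
    for (s in sets) {
      r <- consistency_report(cr, profs, spot_set = s)
      expect_equal(r$fp + r$fn, 0L)
      if (length(s) > 1) for (drop in seq_along(s)) {
        sub <- s[-drop]
        rsub <- consistency_report(cr, profs, spot_set = sub)
        expect_gt(rsub$fp + rsub$fn, 0L)
      }
    }
  }
})
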