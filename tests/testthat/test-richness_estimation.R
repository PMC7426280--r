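test_that("chao1 follows the classic form with the no-doubleton fallback", {
  expect_equal(chao1(88, 19, 12), 88 + 19^2 / 24)
  expect_equal(round(chao1(88, 19, 12), 2), 103.04)
  expect_equal(chao1(10, 0, 5), 10)          # no singletons, no correction
  expect_equal(chao1(10, 4, 0), 10 + 4 * 3 / 2)  # F2 = 0 fallback
  expect_equal(chao1(10, 4, 2, corrected = TRUE), 10 + 4 * 3 / 6)
  # fractional order-averaged inputs are accepted unrounded
  expect_equal(chao1(50, 9.78, 3.37), 50 + 9.78^2 / (2 * 3.37))
})

test_that("jackknife1 scales uniques by (m-1)/m", {
  expect_equal(jackknife1(20, 0, 6), 20)
  expect_equal(jackknife1(20, 4, 6), 20 + 4 * 5 / 6)
  expect_equal(round(jackknife1(20, 4, 6), 3), 23.333)
  expect_equal(jackknife1(20, 4, 1), 20)  # single sample: factor vanishes
  expect_error(jackknife1(20, 4, 0), "m must be")
})

test_that("estimators never fall below observed richness", {
  set.seed(5)
  for (i in 1:200) {
    S <- sample(1:80, 1); F1 <- runif(1, 0, S); F2 <- runif(1, 0, S)
    expect_true(chao1(S, F1, F2) >= S)
    expect_true(jackknife1(S, F1, sample(1:10, 1)) >= S)
  }
  expect_equal(chao1(30, 0, 0), 30)
  expect_equal(jackknife1(30, 0, 7), 30)
})

test_that("final_slope is the last first-difference", {
  expect_equal(final_slope(c(20, 40, 50, 50)), 0)
  expect_equal(final_slope(c(90, 100, 103)), 3)
  expect_error(final_slope(42), "at least 2")
})

test_that("rarefy_individuals matches its boundary cases and monotonicity", {
  x <- c(12, 5, 3, 1)
  expect_equal(rarefy_individuals(x, sum(x)), length(x))
  expect_equal(rarefy_individuals(c(2, 1), 1), 1)
  expect_error(rarefy_individuals(x, sum(x) + 1), "between 0 and N")
  expect_equal(rarefy_individuals(x, 0), 0)
  vals <- vapply(1:sum(x), function(n) rarefy_individuals(x, n), 0)
  expect_true(all(diff(vals) > 0))
})

test_that("rarefy_individuals agrees with an independent implementation", {
  skip_if_not_installed("vegan")
  set.seed(17)
  for (i in 1:10) {
    x <- rpois(30, 6) + 1
    n <- sample(5:(sum(x) - 1), 1)
    expect_equal(rarefy_individuals(x, n),
                 unname(c(suppressWarnings(vegan::rarefy(x, n)))),
                 tolerance = 1e-10)
  }
})

test_that("accumulate handles degenerate sites and ends at observed values", {
  sm <- data.frame(species = c("a", "b"), status = "native",
                   trophic = "unknown", order_name = "Araneae",
                   stringsAsFactors = FALSE)
  # single sample: curve of length 1, mean_S = S for any R
  cnt <- data.frame(species = c("a", "b"), sample = "s1", stage = "adult",
                    count = c(3, 1), stringsAsFactors = FALSE)
  m1 <- community_matrix(cnt, sm, data.frame(sample = "s1", site = "X"))
  acc1 <- accumulate(m1, "X", R = 7, seed = 1)
  expect_equal(nrow(acc1), 1)
  expect_equal(acc1$mean_S, 2)
  expect_equal(acc1$mean_F1, 1)

  # two identical samples: ordering cannot matter
  cnt2 <- rbind(cnt, transform(cnt, sample = "s2"))
  m2 <- community_matrix(cnt2, sm,
                         data.frame(sample = c("s1", "s2"), site = "X"))
  acc2 <- accumulate(m2, "X", R = 13, seed = 2)
  expect_equal(acc2$mean_S, c(2, 2))
  expect_equal(acc2$mean_Q1, c(2, 0))

  expect_error(accumulate(m1, "X", R = 0), "R must be")
})

test_that("accumulate converges to the exhaustive order average", {
  m <- generate_community(small_spec(seed = 37))
  mat <- site_sample_matrix(m, "A")
  oracle <- exhaustive_accumulation(mat)     # all 4! = 24 orders
  acc <- accumulate(m, "A", R = 2000, seed = 8)

  expect_equal(acc$mean_S, oracle$mean_S, tolerance = 0.02)
  expect_equal(acc$mean_F1, oracle$mean_F1, tolerance = 0.03)
  expect_equal(acc$mean_F2, oracle$mean_F2, tolerance = 0.03)
  expect_equal(acc$mean_Q1, oracle$mean_Q1, tolerance = 0.03)

  # last level is exact (every ordering ends at the full pool)
  x <- pool(m, "A")
  expect_equal(acc$mean_S[4], length(x))
  expect_equal(acc$mean_F1[4], sum(x == 1))
  # mean_S is non-decreasing in level
  expect_true(all(diff(acc$mean_S) >= 0))

  # the exhaustive mean_S also matches the closed-form expectation
  expect_equal(oracle$mean_S, closed_form_mean_S(mat), tolerance = 1e-10)
})

test_that("order-averaged richness matches an independent exact curve", {
  skip_if_not_installed("vegan")
  m <- generate_community(small_spec(seed = 41))
  mat <- site_sample_matrix(m, "B")
  sp <- suppressWarnings(vegan::specaccum(t(mat), method = "exact"))
  expect_equal(closed_form_mean_S(mat), unname(sp$richness),
               tolerance = 1e-8)
})

test_that("richness_estimate assembles value, slope and completeness", {
  m <- generate_community(small_spec(seed = 23))
  est <- richness_estimate(m, "A", R = 200, seed = 3)
  x <- pool(m, "A")
  expect_equal(est$S_obs, length(x))
  expect_true(est$value >= est$S_obs)
  expect_true(est$completeness > 0 && est$completeness <= 1)
  expect_equal(est$completeness, est$S_obs / est$value)
  expect_equal(length(est$curve), 4)

  # jackknife route, with rarefaction to a reference abundance
  estj <- richness_estimate(m, "B", estimator = "jackknife1",
                            R = 100, seed = 4, rarefy_to = sum(x))
  expect_true(estj$value >= estj$S_obs)
  expect_equal(estj$rarefied_S, rarefy_individuals(pool(m, "B"), sum(x)))

  # saturated community: every species in every sample, flat estimator curve
  sm <- data.frame(species = c("a", "b", "c"), status = "native",
                   trophic = "unknown", order_name = "Araneae",
                   stringsAsFactors = FALSE)
  cnt <- expand.grid(species = c("a", "b", "c"),
                     sample = c("s1", "s2", "s3"),
                     stringsAsFactors = FALSE)
  cnt$stage <- "adult"; cnt$count <- 5
  msat <- community_matrix(cnt, sm,
                           data.frame(sample = c("s1", "s2", "s3"),
                                      site = "X"))
  esat <- richness_estimate(msat, "X", estimator = "jackknife1",
                            R = 10, seed = 1)
  expect_equal(esat$slope, 0)
  expect_equal(esat$value, 3)
  expect_equal(unname(esat$curve), c(3, 3, 3))
})
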