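test_that("aquaculture vector sums weight x farms inside the radius", {
  expect_equal(aquaculture_vector(NULL), 0)
  expect_equal(aquaculture_vector(data.frame(species = "a", status_weight = 1,
                                             n_farms = 1, distance_km = 5)), 1)
  expect_equal(aquaculture_vector(data.frame(species = "a", status_weight = 3,
                                             n_farms = 1, distance_km = 5)), 3)
  # farms outside the radius are ignored
  f <- data.frame(species = c("a", "b"), status_weight = c(2, 3),
                  n_farms = c(2, 4), distance_km = c(9, 11))
  expect_equal(aquaculture_vector(f, radius_km = 10), 4)
  expect_error(aquaculture_vector(data.frame(species = "a", status_weight = 4,
                                             n_farms = 1, distance_km = 1)),
               "status_weight")
})

test_that("aquaculture vector is additive and monotone in farm count", {
  set.seed(11)
  for (rep in 1:10) {
    n <- sample(2:6, 1)
    f <- data.frame(species = letters[1:n],
                    status_weight = sample(1:3, n, replace = TRUE),
                    n_farms = sample(1:4, n, replace = TRUE),
                    distance_km = runif(n, 0, 10))
    split_val <- aquaculture_vector(f[1, , drop = FALSE]) +
      aquaculture_vector(f[-1, , drop = FALSE])
    expect_equal(aquaculture_vector(f), split_val)
    f2 <- f; f2$n_farms[1] <- f2$n_farms[1] + 1
    expect_gt(aquaculture_vector(f2), aquaculture_vector(f))
  }
})

test_that("native vs exotic farm scores scale 1:2, matching the fixture ratio", {
  native <- aquaculture_vector(data.frame(species = "pearl_oyster",
                                          status_weight = 1, n_farms = 1,
                                          distance_km = 2))
  exotic <- aquaculture_vector(data.frame(species = "shrimp",
                                          status_weight = 2, n_farms = 1,
                                          distance_km = 2))
  expect_equal(exotic / native, 2)
  d <- packaged_table1()
  ratio_fixture <- d$aquaculture[d$site_id == "M-Op"] /
    d$aquaculture[d$site_id == "M-Ti"]
  expect_equal(exotic / native, ratio_fixture, tolerance = 1e-8)
})

test_that("likert rescaling maps linearly, keeps zeros and preserves rank", {
  expect_equal(likert_rescale(c(0, 31.5, 63)), c(0, 2.5, 5))
  expect_equal(likert_rescale(rep(0, 4)), rep(0, 4))
  expect_error(likert_rescale(rep(2, 4), anchor_zero = FALSE), "constant")
  # the max-anchored map reproduces the fixture's smallest nonzero cell:
  # one native farm against a dataset maximum raw score of 63
  expect_equal(likert_rescale(c(1, 2, 63))[1], 0.079365079, tolerance = 1e-8)
  expect_equal(likert_rescale(c(1, 2, 63))[2], 0.158730159, tolerance = 1e-8)
  set.seed(5)
  x <- rexp(20)
  expect_identical(order(likert_rescale(x)), order(x))
  z <- rnorm(20)
  y <- likert_rescale(z, lo = 1, hi = 5, anchor_zero = FALSE)
  expect_identical(order(y), order(z))
  expect_true(all(y >= 1 & y <= 5))
})

test_that("protection tiers map to the four-level score", {
  expect_equal(protection_level("mpa"), 5)
  expect_equal(protection_level("National Park"), 5)
  expect_equal(protection_level("ecological reserve"), 3)
  expect_equal(protection_level("regional park"), 2)
  expect_equal(protection_level("none"), 1)
  expect_error(protection_level("marine sanctuary"), "unknown")
})

test_that("weighted protection reproduces the worked 10-km example", {
  seg <- data.frame(level = c(5, 3, 2, 1), duration = 0,
                    length_km = c(1, 3, 2, 4))
  expect_identical(weighted_protection(seg, 10), 2.2)
  # unprotected baseline
  base <- data.frame(level = 1, duration = 0, length_km = 10)
  expect_equal(weighted_protection(base, 10), 1)
  # duration-weighted variant
  seg2 <- data.frame(level = c(5, 1), duration = c(3, 0), length_km = c(1, 1))
  expect_equal(weighted_protection(seg2, 2, include_duration = TRUE), 7.5)
  # coverage errors
  expect_error(weighted_protection(seg, 11), "cover")
  bad <- data.frame(level = 1, duration = 0, length_km = c(-1, 11))
  expect_error(weighted_protection(bad, 10), "positive")
})

test_that("weighted protection is split-invariant, bounded and monotone", {
  set.seed(7)
  for (rep in 1:10) {
    n <- sample(2:5, 1)
    len <- rexp(n) + 0.1
    seg <- data.frame(level = sample(c(1, 2, 3, 5), n, replace = TRUE),
                      duration = runif(n, 0, 4), length_km = len)
    w <- sum(len)
    ps <- weighted_protection(seg, w)
    # split the first segment in two
    half <- seg[c(1, 1:n), ]
    half$length_km[1:2] <- seg$length_km[1] / 2
    expect_equal(weighted_protection(half, w), ps)
    expect_equal(weighted_protection(half, w, include_duration = TRUE),
                 weighted_protection(seg, w, include_duration = TRUE))
    expect_gte(ps, 1); expect_lte(ps, 5)
    # raising any segment's level cannot lower the score
    i <- sample(n, 1)
    lv <- c(1, 2, 3, 5)
    if (seg$level[i] < 5) {
      seg2 <- seg
      seg2$level[i] <- lv[match(seg$level[i], lv) + 1]
      expect_gte(weighted_protection(seg2, w), ps)
    }
  }
})
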