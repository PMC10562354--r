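test_that("site-class generator hits configured shares to within one cell", {
  shares <- c(0.324, 0.511, 0.156, 0.009)
  g <- generate_site_classes(960, 960, 16, shares = shares, seed = 3)
  n <- length(g)
  expect_equal(n, 3600)
  achieved <- tabulate(g, 4) / n
  expect_true(all(abs(achieved - shares) <= 1 / n + 1e-12))

  # degenerate shares: everything one class
  g1 <- generate_site_classes(160, 160, 16, shares = c(1, 0, 0, 0), seed = 1)
  expect_true(all(g1 == 1L))
})

test_that("site-class generator is deterministic in the seed", {
  a <- generate_site_classes(320, 320, 16, seed = 11)
  b <- generate_site_classes(320, 320, 16, seed = 11)
  c <- generate_site_classes(320, 320, 16, seed = 12)
  expect_identical(unclass(a), unclass(b))
  expect_false(identical(unclass(a), unclass(c)))
  # different seeds still honour the shares
  expect_equal(attr(a, "shares"), attr(c, "shares"))
})

test_that("non-divisible extents are rejected with the offending dimension", {
  expect_error(generate_site_classes(170, 160, 16), "extent_x")
  expect_error(generate_site_classes(160, 170, 16), "extent_y")
})

test_that("rare class forms contiguous patches, not salt-and-pepper noise", {
  g <- generate_site_classes(960, 960, 16, seed = 5)
  idx <- which(unclass(g) == 4L, arr.ind = TRUE)
  # every f4 cell has at least one f4 cell within a 2-cell radius
  has_near <- vapply(seq_len(nrow(idx)), function(i) {
    d <- abs(idx[, 1] - idx[i, 1]) + abs(idx[, 2] - idx[i, 2])
    sum(d <= 2) > 1
  }, TRUE)
  expect_gt(mean(has_near), 0.9)
})

test_that("allometries follow their closed forms and reject bad input", {
  expect_equal(allometry_dbh(20, a = 1, b = 1), 20)
  # doubling height multiplies dbh by 2^b
  expect_equal(allometry_dbh(30, a = 1.3, b = 1.1) /
                 allometry_dbh(15, a = 1.3, b = 1.1), 2^1.1)
  p <- default_species_params()$spruce
  expect_equal(allometry_dbh(25, params = p), p$dbh_a * 25^p$dbh_b)
  expect_error(allometry_dbh(0), "positive")

  expect_equal(allometry_volume(30, 20, c_form = 0.5), 0.9)
  expect_lt(allometry_volume(1e-6, 20), 1e-9)  # vanishes with dbh
  expect_lt(allometry_volume(10, 15), allometry_volume(20, 15))
  expect_lt(allometry_volume(20, 10), allometry_volume(20, 15))
  expect_error(allometry_volume(-1, 10), "positive")
})

test_that("tree generator reproduces the configured composition", {
  counts <- t(sapply(1:5, function(s) {
    sg <- generate_site_classes(960, 960, 16, seed = s)
    tr <- generate_trees(sg, seed = s + 50)
    expect_true(all(tr$x >= 0 & tr$x < 960 & tr$y >= 0 & tr$y < 960))
    expect_true(all(tr$height_m > 0))
    c(table(tr$species), vol = as.vector(tapply(tr$vol_m3, tr$species, sum)))
  }))
  # aspen is rare: under a tenth of spruce stems, every seed
  expect_true(all(counts[, "aspen"] < 0.1 * counts[, "spruce"]))
  # seed-averaged volume shares near 40/35/17/5 (normalised)
  vshare <- colMeans(counts[, 5:8] / rowSums(counts[, 5:8]))
  target <- c(40, 35, 17, 5) / 97
  expect_true(all(abs(vshare - target) < 0.10))
})

test_that("tree generator handles empty and deterministic cases", {
  sg <- generate_site_classes(160, 160, 16, seed = 1)
  none <- generate_trees(sg, params = list(
    spruce = species_params(0, "clustered")), seed = 1)
  expect_equal(nrow(none), 0)
  a <- generate_trees(sg, seed = 9)
  b <- generate_trees(sg, seed = 9)
  expect_identical(a, b)
})

test_that("sporadic pattern is more dispersed than clustered at equal intensity", {
  nn_median <- function(pts) {
    d <- as.matrix(stats::dist(cbind(pts$x, pts$y)))
    diag(d) <- Inf
    stats::median(apply(d, 1, min))
  }
  res <- t(sapply(1:5, function(s) {
    sg <- generate_site_classes(320, 320, 16, seed = s)
    pc <- list(a = species_params(30, "clustered", cluster_size = 8,
                                  dispersion = 10))
    ps <- list(a = species_params(30, "sporadic"))
    c(clustered = nn_median(generate_trees(sg, pc, seed = s + 10)),
      sporadic = nn_median(generate_trees(sg, ps, seed = s + 10)))
  }))
  # sporadic nearest-neighbour distances stochastically larger
  expect_true(all(res[, "sporadic"] > res[, "clustered"]))
})

test_that("DDW records satisfy their geometric invariants", {
  sg <- generate_site_classes(960, 960, 16, seed = 2)
  ddw <- generate_ddw(sg, intensity = 12, seed = 4)
  expect_gt(nrow(ddw), 500)
  len <- sqrt((ddw$x2 - ddw$x1)^2 + (ddw$y2 - ddw$y1)^2)
  expect_equal(len, ddw$length_m, tolerance = 1e-9)
  expect_true(all(ddw$vol_m3 > 0))
  expect_true(all(ddw$x1 >= 0 & ddw$x2 <= 960 & ddw$y1 >= 0 & ddw$y2 <= 960))
  # empty landscape allowed
  expect_equal(nrow(generate_ddw(sg, intensity = 0, seed = 1)), 0)
  # determinism
  expect_identical(generate_ddw(sg, seed = 8), generate_ddw(sg, seed = 8))
})

test_that("mean DDW volume matches the cylinder closed form", {
  sg <- generate_site_classes(960, 960, 16, seed = 3)
  ddw <- generate_ddw(sg, intensity = 150, seed = 5,
                      length_meanlog = log(6), length_sdlog = 0.3,
                      diam_mean = 20, diam_sd = 0.01,
                      diam_min = 19, diam_max = 21)
  expect_gt(nrow(ddw), 1000)
  # with an (almost) fixed diameter, E[vol] = pi (d/200)^2 E[len],
  # E[len] = exp(meanlog + sdlog^2/2) for the lognormal
  expected <- pi * (20 / 200)^2 * exp(log(6) + 0.3^2 / 2)
  expect_equal(mean(ddw$vol_m3), expected, tolerance = 0.05)
})
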