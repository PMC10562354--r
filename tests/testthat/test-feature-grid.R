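test_that("single- and multi-tree cells produce the expected statistics", {
  tr <- data.frame(x = 5, y = 5, species = "spruce",
                   height_m = 20, dbh_cm = 25, vol_m3 = 0.55)
  st <- rasterize_trees(tr, 32, 32, 16)
  expect_equal(get_layer(st, "Hmax", "spruce")[1, 1], 20)
  expect_equal(get_layer(st, "Hmean", "spruce")[1, 1], 20)
  expect_equal(get_layer(st, "Vol", "spruce")[1, 1], 0.55)
  expect_equal(sum(get_layer(st, "Vol", "pine")), 0)

  two <- data.frame(x = c(3, 9), y = c(3, 9), species = "pine",
                    height_m = c(10, 20), dbh_cm = c(12, 25),
                    vol_m3 = c(0.1, 0.5))
  st2 <- rasterize_trees(two, 16, 16, 16)
  expect_equal(get_layer(st2, "Hmean", "pine")[1, 1], 15)
  expect_equal(get_layer(st2, "Hmax", "pine")[1, 1], 20)
  expect_equal(get_layer(st2, "Vol", "pine")[1, 1], 0.6)
})

test_that("tree rasterization agrees with a brute-force binning oracle", {
  set.seed(42)
  n <- 50
  tr <- data.frame(x = runif(n, 0, 64), y = runif(n, 0, 48),
                   species = sample(c("spruce", "pine", "birch", "aspen"),
                                    n, replace = TRUE),
                   height_m = runif(n, 5, 30))
  tr$dbh_cm <- allometry_dbh(tr$height_m)
  tr$vol_m3 <- allometry_volume(tr$dbh_cm, tr$height_m)
  st <- rasterize_trees(tr, 64, 48, 16)
  for (sp in c("spruce", "pine", "birch", "aspen")) {
    oracle <- naive_tree_cell_stats(tr, 64, 48, 16, sp)
    expect_equal(get_layer(st, "Hmax", sp), oracle$Hmax)
    expect_equal(get_layer(st, "Hmean", sp), oracle$Hmean)
    expect_equal(get_layer(st, "Vol", sp), oracle$Vol)
  }
})

test_that("edge conventions: far-edge clamping and out-of-extent errors", {
  tr <- data.frame(x = c(32, 16), y = c(32, 0), species = "birch",
                   height_m = c(10, 12), dbh_cm = c(10, 12),
                   vol_m3 = c(0.1, 0.2))
  st <- rasterize_trees(tr, 32, 32, 16)
  vol <- get_layer(st, "Vol", "birch")
  expect_equal(vol[2, 2], 0.1)  # far corner clamped into last cell
  expect_equal(vol[1, 2], 0.2)  # on a shared edge -> cell to the right
  bad <- data.frame(x = 40, y = 5, species = "pine", height_m = 10,
                    dbh_cm = 10, vol_m3 = 0.1)
  expect_error(rasterize_trees(bad, 32, 32, 16), "outside the extent")
})

test_that("DDW volume is split proportionally to within-cell length", {
  # 10 m trunk along x: 4 m in cell (1,1), 6 m in cell (1,2)
  ddw <- data.frame(x1 = 12, y1 = 8, x2 = 22, y2 = 8,
                    diameter_cm = 20, length_m = 10, vol_m3 = 0.10)
  st <- rasterize_ddw(ddw, 32, 16, 16)
  lay <- get_layer(st, "DDWVol", "none")
  expect_equal(lay[1, 1], 0.04)
  expect_equal(lay[1, 2], 0.06)

  # wholly inside one cell
  inside <- data.frame(x1 = 2, y1 = 2, x2 = 10, y2 = 9,
                       diameter_cm = 15, length_m = sqrt(8^2 + 7^2),
                       vol_m3 = 0.2)
  st2 <- rasterize_ddw(inside, 32, 16, 16)
  expect_equal(get_layer(st2, "DDWVol", "none")[1, 1], 0.2)

  # zero-length degenerate segment keeps its whole volume
  pt <- data.frame(x1 = 20, y1 = 5, x2 = 20, y2 = 5,
                   diameter_cm = 15, length_m = 0, vol_m3 = 0.3)
  st3 <- rasterize_ddw(pt, 32, 16, 16)
  expect_equal(get_layer(st3, "DDWVol", "none")[1, 2], 0.3)
})

test_that("DDW rasterization conserves total volume for random segments", {
  sg <- generate_site_classes(320, 320, 16, seed = 6)
  ddw <- generate_ddw(sg, intensity = 40, seed = 7)
  st <- rasterize_ddw(ddw, 320, 320, 16)
  expect_equal(sum(st$values), sum(ddw$vol_m3), tolerance = 1e-9)
  expect_true(all(st$values >= 0))
})

test_that("stratification partitions layers by site class", {
  ls <- small_landscape(seed = 13)
  st <- ls$stack
  expect_equal(dim(st$values)[3], 52)
  expect_equal(nrow(st$manifest), 52)

  # partition property: the four class layers of one (variable, species)
  # sum back to the unstratified layer
  ext <- attr(ls$site_grid, "extent")
  unstrat <- rasterize_trees(ls$trees, ext[["x"]], ext[["y"]], 16)
  for (sp in c("spruce", "aspen")) {
    strat_sum <- Reduce(`+`, lapply(1:4, function(cl)
      get_layer(st, "Vol", sp, cl)))
    expect_equal(strat_sum, get_layer(unstrat, "Vol", sp))
  }

  # at baseline, per cell at most one class layer of a feature is nonzero
  for (cl in 1:4) {
    lay <- get_layer(st, "Vol", "spruce", cl)
    expect_true(all(lay[unclass(ls$site_grid) != cl] == 0))
  }

  # total volume conservation through rasterization + stratification
  tree_tot <- sum(ls$trees$vol_m3)
  strat_tree_tot <- sum(vapply(1:4, function(cl) {
    sum(vapply(c("spruce", "pine", "birch", "aspen"), function(sp)
      sum(get_layer(st, "Vol", sp, cl)), 0))
  }, 0))
  expect_equal(strat_tree_tot, tree_tot, tolerance = 1e-9)

  # Hmax >= Hmean wherever both nonzero
  hx <- get_layer(unstrat, "Hmax", "pine")
  hm <- get_layer(unstrat, "Hmean", "pine")
  expect_true(all(hx[hm > 0] >= hm[hm > 0] - 1e-12))

  # all-class-1 grid zeroes classes 2-4
  g1 <- generate_site_classes(ext[["x"]], ext[["y"]], 16,
                              shares = c(1, 0, 0, 0), seed = 1)
  st1 <- stratify(unstrat, g1)
  for (cl in 2:4)
    expect_equal(sum(get_layer(st1, "Vol", "spruce", cl)), 0)

  # lattice mismatch rejected
  g_small <- generate_site_classes(160, 160, 16, seed = 1)
  expect_error(stratify(unstrat, g_small), "lattice")
})
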