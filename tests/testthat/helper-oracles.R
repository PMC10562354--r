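# Shared fixtures and independent oracles.  Oracles deliberately use the
# naive formulation (full recomputation, explicit loops) so they stay
# independent of the package's incremental code paths.

# build a feature_stack from a list of value matrices
make_stack <- function(mats, resolution = 16, variable = "Vol",
                       species = NULL, site_class = NULL) {
  k <- length(mats)
  if (is.null(species)) species <- paste0("sp", seq_len(k))
  if (is.null(site_class)) site_class <- rep(1L, k)
  d <- dim(mats[[1]])
  feature_stack(array(unlist(mats), c(d[1], d[2], k)),
                data.frame(variable = rep_len(variable, k),
                           species = species, site_class = site_class),
                resolution)
}

# small random stack: n cells (<= 12), f features (<= 4), sparse values
random_small_stack <- function(seed, max_cells = 12, max_features = 4) {
  set.seed(seed)
  repeat {
    nr <- sample(1:3, 1); nc <- sample(1:4, 1)
    if (nr * nc <= max_cells) break
  }
  f <- sample(1:max_features, 1)
  mats <- lapply(seq_len(f), function(j) {
    m <- matrix(stats::rexp(nr * nc), nr, nc)
    m[stats::runif(nr * nc) < 0.3] <- 0   # sparsity and exact ties
    m
  })
  # ensure at least one feature has positive total
  if (all(vapply(mats, sum, 0) == 0)) mats[[1]][1, 1] <- 1
  make_stack(mats)
}

# full-recomputation greedy ranking: before every removal, score every
# remaining cell by the drop in total benefit sum_j w_j * r_j^z computed
# from scratch; remove the first minimiser in row-major cell order.
greedy_oracle_order <- function(stack, z = 0.25, w = 1) {
  d <- dim(stack$values)
  n <- d[1] * d[2]
  V <- matrix(aperm(stack$values, c(2, 1, 3)), nrow = n)
  tot <- colSums(V)
  V <- V[, tot > 0, drop = FALSE]
  tot <- tot[tot > 0]
  f <- length(tot)
  w <- rep_len(w, f)
  Q <- sweep(V, 2, tot, "/")
  total_benefit <- function(alive) {
    b <- 0
    for (j in seq_len(f))
      b <- b + w[j] * sum(Q[alive, j])^z
    b
  }
  alive <- rep(TRUE, n)
  ord <- integer(n)
  for (k in seq_len(n)) {
    cur <- total_benefit(alive)
    losses <- rep(Inf, n)
    for (i in which(alive)) {
      trial <- alive; trial[i] <- FALSE
      losses[i] <- cur - total_benefit(trial)
    }
    pick <- which.min(losses)
    ord[k] <- pick
    alive[pick] <- FALSE
  }
  ord
}

# brute-force binning of tree records into per-cell statistics
naive_tree_cell_stats <- function(trees, extent_x, extent_y, cell_size,
                                  species) {
  nc <- extent_x / cell_size
  nr <- extent_y / cell_size
  hmax <- hmean <- vol <- matrix(0, nr, nc)
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    in_cell <- trees$species == species &
      trees$x >= (cc - 1) * cell_size &
      (trees$x < cc * cell_size | (cc == nc & trees$x == extent_x)) &
      trees$y >= (r - 1) * cell_size &
      (trees$y < r * cell_size | (r == nr & trees$y == extent_y))
    if (any(in_cell)) {
      hmax[r, cc] <- max(trees$height_m[in_cell])
      hmean[r, cc] <- mean(trees$height_m[in_cell])
      vol[r, cc] <- sum(trees$vol_m3[in_cell])
    }
  }
  list(Hmax = hmax, Hmean = hmean, Vol = vol)
}

# a small landscape + baseline stack used by several test files
small_landscape <- function(seed = 7, extent = 320) {
  sg <- generate_site_classes(extent, extent, 16, seed = seed)
  trees <- generate_trees(sg, seed = seed + 1)
  ddw <- generate_ddw(sg, seed = seed + 2)
  list(site_grid = sg, trees = trees, ddw = ddw,
       stack = build_baseline_stack(trees, ddw, sg))
}
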