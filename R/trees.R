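#' Per-species simulation parameters
#'
#' Bundles the point-process and size parameters of one tree species group.
#' Clustered species follow a Thomas process (Poisson parents, Poisson
#' offspring counts, isotropic Gaussian dispersal); sporadic species follow
#' a homogeneous Poisson process, matching a species that occurs scattered
#' through the landscape, often as single trees.  Stem density varies with
#' site-fertility class through the `site_affinity` multipliers (realised
#' density in a class-c cell is `intensity * site_affinity[c]`, and
#' `intensity` is the density a class with affinity 1 would carry).
#'
#' @param intensity stems per hectare at affinity 1.
#' @param mode `"clustered"` (Thomas process) or `"sporadic"`
#'   (homogeneous Poisson).
#' @param site_affinity 4 non-negative multipliers, one per site class f1-f4.
#' @param cluster_size mean offspring per cluster parent (clustered mode).
#' @param dispersion Gaussian offspring dispersal sd in metres
#'   (clustered mode).
#' @param height_mean,height_sd,height_min,height_max truncated-normal
#'   height distribution in metres.
#' @param dbh_a,dbh_b height-to-DBH power-law coefficients
#'   (see [allometry_dbh()]).
#' @param vol_c stem form factor (see [allometry_volume()]).
#' @return A list of class `species_params`.
#' @export
species_params <- function(intensity, mode = c("clustered", "sporadic"),
                           site_affinity = rep(1, 4),
                           cluster_size = 6, dispersion = 15,
                           height_mean = 17, height_sd = 5,
                           height_min = 2, height_max = 40,
                           dbh_a = 1.0, dbh_b = 1.1, vol_c = 0.45) {
  mode <- match.arg(mode)
  stopifnot(intensity >= 0, all(site_affinity >= 0), dispersion > 0,
            cluster_size > 0,
            height_min <= height_mean, height_mean <= height_max)
  structure(list(intensity = intensity, mode = mode,
                 site_affinity = site_affinity,
                 cluster_size = cluster_size, dispersion = dispersion,
                 height_mean = height_mean, height_sd = height_sd,
                 height_min = height_min, height_max = height_max,
                 dbh_a = dbh_a, dbh_b = dbh_b, vol_c = vol_c),
            class = "species_params")
}

#' Default species parameter set
#'
#' Four boreal species groups: Norway spruce and Scots pine (dominant,
#' clustered), birches (clustered), and European aspen (rare, sporadic,
#' single large stems).  Intensities and affinities are calibrated so that
#' under the default site-class composition the landscape volume shares
#' approximate 40/35/17/5 % (spruce/pine/birch/aspen) and aspen stems stay
#' below a tenth of spruce stems.
#'
#' @return Named list of [species_params()], names
#'   `c("spruce", "pine", "birch", "aspen")`.
#' @export
default_species_params <- function() {
  list(
    spruce = species_params(80, "clustered",
                            site_affinity = c(1.3, 1.0, 0.4, 0.1),
                            cluster_size = 8, dispersion = 15,
                            height_mean = 18, height_sd = 6,
                            dbh_a = 1.1, dbh_b = 1.1, vol_c = 0.45),
    pine = species_params(115, "clustered",
                          site_affinity = c(0.6, 1.0, 1.5, 1.2),
                          cluster_size = 6, dispersion = 15,
                          height_mean = 17, height_sd = 5,
                          dbh_a = 1.0, dbh_b = 1.1, vol_c = 0.45),
    birch = species_params(98, "clustered",
                           site_affinity = c(1.2, 1.0, 0.6, 0.2),
                           cluster_size = 5, dispersion = 15,
                           height_mean = 15, height_sd = 5,
                           dbh_a = 0.9, dbh_b = 1.1, vol_c = 0.42),
    aspen = species_params(6, "sporadic",
                           site_affinity = c(1.5, 1.0, 0.3, 0.1),
                           height_mean = 22, height_sd = 6,
                           dbh_a = 1.15, dbh_b = 1.1, vol_c = 0.42)
  )
}

#' Height-to-diameter allometry
#'
#' Power-law placeholder for species-specific DBH equations:
#' `dbh = a * height^b` (DBH in centimetres, height in metres).  The
#' coefficients live in [species_params()] so published equations can be
#' substituted.
#'
#' @param height tree height in metres, > 0 (vectorised).
#' @param a,b coefficients; either given directly or taken from `params`.
#' @param params optional [species_params()] supplying `dbh_a`, `dbh_b`.
#' @return DBH in centimetres; strictly increasing in height for b > 0.
#' @examples
#' allometry_dbh(20, a = 1, b = 1)  # 20
#' @export
allometry_dbh <- function(height, a = 1.0, b = 1.1, params = NULL) {
  if (!is.null(params)) { a <- params$dbh_a; b <- params$dbh_b }
  if (any(height <= 0)) stop("height must be positive")
  a * height^b
}

#' Stem-volume allometry
#'
#' Cylinder-with-form-factor placeholder for species-specific volume
#' equations: `vol = c * dbh^2 * height * 1e-4` (volume in cubic metres,
#' DBH in centimetres, height in metres).  Strictly increasing in both
#' arguments for c > 0.
#'
#' @param dbh diameter at breast height, cm, > 0 (vectorised).
#' @param height tree height, m, > 0.
#' @param c_form form factor; either given directly or from `params`.
#' @param params optional [species_params()] supplying `vol_c`.
#' @return stem volume in cubic metres.
#' @examples
#' allometry_volume(30, 20, c_form = 0.5)  # 0.9
#' @export
allometry_volume <- function(dbh, height, c_form = 0.45, params = NULL) {
  if (!is.null(params)) c_form <- params$vol_c
  if (any(dbh <= 0) || any(height <= 0))
    stop("dbh and height must be positive")
  c_form * dbh^2 * height * 1e-4
}

#' Simulate tree records over a site-class grid
#'
#' Clustered species are drawn from a Thomas process (parents simulated in
#' a buffered window to avoid edge deficits, offspring displaced by
#' isotropic Gaussian noise); sporadic species from a homogeneous Poisson
#' process.  Site-class density modulation is applied by location-dependent
#' thinning, which yields the exact inhomogeneous intensity
#' `intensity * site_affinity[class]`.  Heights are truncated-normal;
#' DBH and stem volume follow the configured allometries.
#'
#' @param site_grid a [generate_site_classes()] grid.
#' @param params named list of [species_params()] (default
#'   [default_species_params()]).
#' @param seed integer seed.
#' @return data.frame with columns `x`, `y` (m), `species` (factor),
#'   `height_m`, `dbh_cm`, `vol_m3`.
#' @export
generate_trees <- function(site_grid, params = default_species_params(),
                           seed = 1L) {
  stopifnot(inherits(site_grid, "site_class_grid"))
  ext <- attr(site_grid, "extent")
  set.seed(seed)
  out <- lapply(names(params), function(sp) {
    p <- params[[sp]]
    maxa <- max(p$site_affinity, 1e-12)
    lam0 <- p$intensity * maxa / 1e4       # dominating intensity per m^2
    pts <- if (p$mode == "clustered") {
      rthomas(lam0 / p$cluster_size, p$cluster_size,
              p$dispersion, ext[["x"]], ext[["y"]])
    } else {
      rpoispp(lam0, ext[["x"]], ext[["y"]])
    }
    if (nrow(pts) == 0L)
      return(empty_tree_df())
    # thin to the per-class intensity: realised density is
    # intensity * site_affinity[class]
    aff <- p$site_affinity / maxa
    keep <- stats::runif(nrow(pts)) < aff[site_class_at(site_grid, pts$x, pts$y)]
    pts <- pts[keep, , drop = FALSE]
    n <- nrow(pts)
    if (n == 0L) return(empty_tree_df())
    h <- rtruncnorm(n, p$height_mean, p$height_sd, p$height_min, p$height_max)
    d <- allometry_dbh(h, params = p)
    v <- allometry_volume(d, h, params = p)
    data.frame(x = pts$x, y = pts$y, species = sp,
               height_m = h, dbh_cm = d, vol_m3 = v)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out$species <- factor(out$species, levels = names(params))
  out
}

empty_tree_df <- function() {
  data.frame(x = numeric(0), y = numeric(0), species = character(0),
             height_m = numeric(0), dbh_cm = numeric(0), vol_m3 = numeric(0))
}

# Thomas process on [0,ex] x [0,ey]: parents at intensity kappa per m^2
# simulated in a window buffered by 4*sigma, Poisson(mu) offspring each,
# displaced N(0, sigma^2) per coordinate; offspring outside the window are
# dropped (the buffer makes the retained pattern stationary).
rthomas <- function(kappa, mu, sigma, ex, ey) {
  buf <- 4 * sigma
  area <- (ex + 2 * buf) * (ey + 2 * buf)
  np <- stats::rpois(1L, kappa * area)
  if (np == 0L) return(data.frame(x = numeric(0), y = numeric(0)))
  px <- stats::runif(np, -buf, ex + buf)
  py <- stats::runif(np, -buf, ey + buf)
  noff <- stats::rpois(np, mu)
  tot <- sum(noff)
  if (tot == 0L) return(data.frame(x = numeric(0), y = numeric(0)))
  x <- rep.int(px, noff) + stats::rnorm(tot, sd = sigma)
  y <- rep.int(py, noff) + stats::rnorm(tot, sd = sigma)
  inside <- x >= 0 & x < ex & y >= 0 & y < ey
  data.frame(x = x[inside], y = y[inside])
}

# homogeneous Poisson process, lambda per m^2
rpoispp <- function(lambda, ex, ey) {
  n <- stats::rpois(1L, lambda * ex * ey)
  data.frame(x = stats::runif(n, 0, ex), y = stats::runif(n, 0, ey))
}

# inverse-CDF truncated normal
rtruncnorm <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}
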