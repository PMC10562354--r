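#' Simulate downed-deadwood (DDW) segment records
#'
#' Fallen trunks are modelled as line segments: midpoints from a homogeneous
#' Poisson process over the extent, orientations uniform on [0, 2*pi),
#' lengths lognormal and diameters truncated-normal.  A segment whose
#' endpoints would fall outside the extent has its position and orientation
#' redrawn (size retained), so every record lies wholly inside the landscape
#' and rasterized volume is conserved exactly.  Volume is the cylinder
#' `pi * (diameter/200)^2 * length`.
#'
#' @param site_grid a [generate_site_classes()] grid (supplies the extent;
#'   DDW density is not modulated by site class).
#' @param intensity segments per hectare (default 12).
#' @param length_meanlog,length_sdlog lognormal trunk-length parameters
#'   (metres; defaults give a mean length of about 6 m).
#' @param diam_mean,diam_sd,diam_min,diam_max truncated-normal trunk
#'   diameter parameters in centimetres.
#' @param seed integer seed.
#' @return data.frame with columns `x1`, `y1`, `x2`, `y2` (m),
#'   `diameter_cm`, `length_m`, `vol_m3`.
#' @export
generate_ddw <- function(site_grid, intensity = 12,
                         length_meanlog = log(5.5), length_sdlog = 0.45,
                         diam_mean = 18, diam_sd = 5,
                         diam_min = 5, diam_max = 40, seed = 1L) {
  stopifnot(inherits(site_grid, "site_class_grid"), intensity >= 0)
  ext <- attr(site_grid, "extent")
  ex <- ext[["x"]]; ey <- ext[["y"]]
  set.seed(seed)
  n <- stats::rpois(1L, intensity / 1e4 * ex * ey)
  if (n == 0L)
    return(data.frame(x1 = numeric(0), y1 = numeric(0), x2 = numeric(0),
                      y2 = numeric(0), diameter_cm = numeric(0),
                      length_m = numeric(0), vol_m3 = numeric(0)))
  len <- stats::rlnorm(n, length_meanlog, length_sdlog)
  len <- pmin(len, 0.9 * min(ex, ey))  # a trunk cannot exceed the landscape
  diam <- rtruncnorm(n, diam_mean, diam_sd, diam_min, diam_max)
  x1 <- y1 <- x2 <- y2 <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      mx <- stats::runif(1, 0, ex); my <- stats::runif(1, 0, ey)
      th <- stats::runif(1, 0, 2 * pi)
      dx <- cos(th) * len[i] / 2; dy <- sin(th) * len[i] / 2
      if (mx - abs(dx) >= 0 && mx + abs(dx) <= ex &&
          my - abs(dy) >= 0 && my + abs(dy) <= ey) {
        x1[i] <- mx - dx; y1[i] <- my - dy
        x2[i] <- mx + dx; y2[i] <- my + dy
        break
      }
    }
  }
  data.frame(x1 = x1, y1 = y1, x2 = x2, y2 = y2,
             diameter_cm = diam, length_m = len,
             vol_m3 = pi * (diam / 200)^2 * len)
}
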