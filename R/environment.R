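#' Rectangular environment with a concentric region sequence
#'
#' Defines the 2-D arena the megamap represents. Coordinates are continuous,
#' in meters, with the origin at the lower-left corner. For incremental
#' learning the environment is partitioned into an ordered sequence of
#' concentric square frames growing outward from the center: region 1 is the
#' innermost square, region `k > 1` is the ring between consecutive squares.
#' Regions tile the environment without overlap.
#'
#' @param width,height Environment dimensions in meters; both must be positive.
#' @param margin Boundary margin in meters (default 0.15). Training and probe
#'   locations must lie at least this far from every boundary.
#' @param n_regions Number of concentric growth stages (default 1).
#' @param region_fracs Optional increasing fractions in (0, 1] giving the
#'   outer extent of each concentric frame relative to the environment
#'   (overrides the equal-increment default; the last must be 1).
#' @return An object of class `megamap_env`.
#' @examples
#' env <- env_rect(3, 3, n_regions = 3)
#' region_area(env)
#' @export
env_rect <- function(width, height, margin = 0.15, n_regions = 1L,
                     region_fracs = NULL) {
  stopifnot(is.numeric(width), is.numeric(height), width > 0, height > 0,
            margin >= 0, 2 * margin < min(width, height), n_regions >= 1)
  if (!is.null(region_fracs)) {
    stopifnot(all(diff(region_fracs) > 0), all(region_fracs > 0),
              abs(region_fracs[length(region_fracs)] - 1) < 1e-12)
    n_regions <- length(region_fracs)
    frac <- region_fracs
  } else {
    frac <- seq_len(n_regions) / n_regions
  }
  n_regions <- as.integer(n_regions)
  structure(
    list(width = width, height = height, margin = margin,
         n_regions = n_regions,
         center = c(width / 2, height / 2),
         half_w = frac * width / 2, half_h = frac * height / 2),
    class = "megamap_env")
}

#' @export
print.megamap_env <- function(x, ...) {
  cat(sprintf("<megamap_env> %.2f m x %.2f m (%.2f m^2), margin %.2f m, %d region(s)\n",
              x$width, x$height, x$width * x$height, x$margin, x$n_regions))
  invisible(x)
}

#' Cumulative and per-region areas of an environment
#'
#' @param env A [env_rect()] environment.
#' @return A tibble with one row per region: `region`, `area` (of the ring)
#'   and `cum_area` (of the environment learned up to that region), in m^2.
#' @export
region_area <- function(env) {
  stopifnot(inherits(env, "megamap_env"))
  cum <- 4 * env$half_w * env$half_h
  tibble::tibble(region = seq_len(env$n_regions),
                 area = c(cum[1], diff(cum)),
                 cum_area = cum)
}

#' Region index of points
#'
#' @param env Environment.
#' @param xy Numeric matrix (or 2-vector) of coordinates.
#' @return Integer vector: the region (concentric frame) each point falls in.
#' @export
region_of <- function(env, xy) {
  xy <- to_xy_matrix(xy)
  dx <- abs(xy[, 1] - env$center[1])
  dy <- abs(xy[, 2] - env$center[2])
  # smallest concentric square containing the point
  k <- pmax(findInterval(dx, env$half_w, left.open = TRUE),
            findInterval(dy, env$half_h, left.open = TRUE)) + 1L
  pmin(k, env$n_regions)
}

#' Check that points respect the boundary margin
#' @param env Environment.
#' @param xy Matrix or 2-vector of coordinates.
#' @return Logical vector.
#' @export
in_bounds <- function(env, xy) {
  xy <- to_xy_matrix(xy)
  m <- env$margin
  xy[, 1] >= m & xy[, 1] <= env$width - m &
    xy[, 2] >= m & xy[, 2] <= env$height - m
}

to_xy_matrix <- function(xy) {
  if (is.null(dim(xy))) {
    stopifnot(length(xy) == 2L)
    xy <- matrix(xy, ncol = 2L)
  }
  stopifnot(ncol(xy) == 2L)
  xy
}

#' Uniform grid of training locations
#'
#' Locations are spaced uniformly and kept at least the boundary margin away
#' from every wall; each carries its region index for incremental learning.
#'
#' @param env Environment.
#' @param spacing Grid spacing in meters (default 0.05).
#' @return Tibble with columns `x`, `y`, `region`.
#' @export
training_grid <- function(env, spacing = 0.05) {
  stopifnot(inherits(env, "megamap_env"), spacing > 0)
  gx <- seq(env$margin, env$width - env$margin, by = spacing)
  gy <- seq(env$margin, env$height - env$margin, by = spacing)
  g <- expand.grid(x = gx, y = gy, KEEP.OUT.ATTRS = FALSE)
  tibble::tibble(x = g$x, y = g$y,
                 region = region_of(env, cbind(g$x, g$y)))
}
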