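#' Place-field density matching a target silent fraction
#'
#' Field counts per cell are Poisson with mean `lambda * area`, so the
#' probability a cell is silent (zero fields) in an environment of the given
#' area is `exp(-lambda * area)`. Solving for the density gives
#' `lambda = -log(silent_fraction) / area`.
#'
#' @param silent_fraction Target fraction of silent cells, in (0, 1).
#'   The megamap's benchmark calibration uses 0.8 in a 1 m^2 environment.
#' @param area Environment area in m^2.
#' @return Field density `lambda` in fields per m^2 per cell.
#' @examples
#' calibrate_field_density(0.8, 1) # 0.2231
#' @export
calibrate_field_density <- function(silent_fraction, area = 1) {
  if (!is.numeric(silent_fraction) || silent_fraction <= 0 || silent_fraction >= 1)
    stop("`silent_fraction` must lie strictly between 0 and 1", call. = FALSE)
  stopifnot(area > 0)
  -log(silent_fraction) / area
}

#' Sample a Poisson place-field map
#'
#' Each of `n_cells` place cells receives `M_i ~ Poisson(lambda * area)` field
#' centers placed uniformly over the environment. Cells with zero fields
#' (silent cells) are retained so cell indices are stable.
#'
#' @param env A [env_rect()] environment.
#' @param n_cells Number of place cells.
#' @param lambda Field density (fields per m^2 per cell), e.g. from
#'   [calibrate_field_density()].
#' @param seed Integer seed; the map is reproducible given the seed.
#' @return An object of class `place_field_map` with elements `n_cells`,
#'   `counts` (fields per cell), `fields` (F x 2 matrix of centers), `cell`
#'   (cell index of each field row), `lambda`, `seed`, `env`.
#' @export
sample_place_fields <- function(env, n_cells, lambda, seed) {
  stopifnot(inherits(env, "megamap_env"), n_cells >= 1, lambda > 0)
  area <- env$width * env$height
  if (area <= 0) stop("environment has zero area", call. = FALSE)
  n_cells <- as.integer(n_cells)
  seed <- as.integer(seed)
  counts <- withr::with_seed(seed, stats::rpois(n_cells, lambda * area))
  total <- sum(counts)
  xy <- withr::with_seed(seed + 1L, cbind(stats::runif(total, 0, env$width),
                                          stats::runif(total, 0, env$height)))
  new_place_field_map(env, n_cells, counts, xy, lambda, seed)
}

new_place_field_map <- function(env, n_cells, counts, fields, lambda, seed) {
  structure(
    list(n_cells = as.integer(n_cells), counts = as.integer(counts),
         fields = fields, cell = rep.int(seq_len(n_cells), counts),
         lambda = lambda, seed = as.integer(seed), env = env),
    class = "place_field_map")
}

#' @export
print.place_field_map <- function(x, ...) {
  cat(sprintf("<place_field_map> %d cells, %d fields (lambda = %.4g /m^2), %.0f%% silent, seed %d\n",
              x$n_cells, nrow(x$fields), x$lambda,
              100 * mean(x$counts == 0), x$seed))
  invisible(x)
}

# squared distances from every field center to location x (length F)
field_dist2 <- function(pfm, x) {
  (pfm$fields[, 1] - x[1])^2 + (pfm$fields[, 2] - x[2])^2
}

#' Training input vector at a location
#'
#' The idealistic external drive into each cell at location `x`: a sum of
#' Gaussian bumps of amplitude `b_pk` over the cell's field centers,
#' `b_i(x) = b_pk * sum_m exp(-|x - c_im|^2 / (2 sigma^2))`.
#'
#' @param pfm A [sample_place_fields()] map.
#' @param x Location (2-vector, meters).
#' @param params A [megamap_params()] object (uses `b_pk`, `sigma`), or `NULL`
#'   if both scalars are given.
#' @param b_pk,sigma Optional scalar overrides.
#' @return Numeric vector of length `n_cells`, nonnegative.
#' @export
training_input <- function(pfm, x, params = NULL, b_pk = params$b_pk,
                           sigma = params$sigma) {
  stopifnot(inherits(pfm, "place_field_map"), length(x) == 2)
  if (!is.numeric(sigma) || is.na(sigma) || sigma <= 0)
    stop("`sigma` must be a positive number", call. = FALSE)
  stopifnot(is.numeric(b_pk), !is.na(b_pk))
  g <- exp(-field_dist2(pfm, x) / (2 * sigma^2))
  b_pk * cell_sum(pfm, g)
}

#' Desired (embedded) activity vector at a location
#'
#' The activity pattern embedded at `x`: each field contributes a thresholded
#' Gaussian bump of height `f_pk`,
#' `f_i(x) = sum_m f_pk * ((1 + u0) exp(-|x - c_im|^2 / (2 sigma^2)) - u0)_+`.
#' The contribution vanishes beyond the bump radius [bump_radius()]. When a
#' full parameter object with `normalize_net = TRUE` and a finite `f_net` is
#' supplied, the pattern is rescaled so its sum equals `f_net` exactly (the
#' embedded patterns are constructed to have a location-independent net
#' activity); scalar-argument calls return the raw sum of bumps.
#'
#' @inheritParams training_input
#' @param u0,f_pk Optional scalar overrides.
#' @return Numeric vector of length `n_cells`, in Hz.
#' @export
desired_activity <- function(pfm, x, params = NULL, sigma = params$sigma,
                             u0 = params$u0, f_pk = params$f_pk) {
  stopifnot(inherits(pfm, "place_field_map"), length(x) == 2)
  if (!is.numeric(u0) || is.na(u0) || u0 <= 0)
    stop("`u0` must be a positive number", call. = FALSE)
  stopifnot(sigma > 0, f_pk > 0)
  v <- (1 + u0) * exp(-field_dist2(pfm, x) / (2 * sigma^2)) - u0
  f <- f_pk * cell_sum(pfm, pmax(v, 0))
  if (!is.null(params) && isTRUE(params$normalize_net) &&
      is.finite(params$f_net) && sum(f) > 0)
    f <- f * (params$f_net / sum(f))
  f
}

# sum per-field values into per-cell values, keeping silent cells as 0
cell_sum <- function(pfm, values) {
  out <- numeric(pfm$n_cells)
  if (length(values)) {
    s <- rowsum(values, pfm$cell)
    out[as.integer(rownames(s))] <- s[, 1]
  }
  out
}

#' Embedded active set at a location
#'
#' The set of cells active in the embedded activity bump over `x`: cells with
#' at least one field center within the bump radius.
#'
#' @inheritParams desired_activity
#' @return Integer vector of cell indices.
#' @export
embedded_active_set <- function(pfm, x, params = NULL, sigma = params$sigma,
                                u0 = params$u0) {
  f <- desired_activity(pfm, x, sigma = sigma, u0 = u0, f_pk = 1)
  which(f > 0)
}

#' Net embedded activity over a training grid
#'
#' The embedded patterns are built so the summed activity is (approximately)
#' location-independent. This measures the mean and coefficient of variation
#' of `sum_i f_i(x)` over grid locations.
#'
#' @param pfm Place-field map.
#' @param grid A [training_grid()] tibble (columns `x`, `y`).
#' @param params,sigma,u0,f_pk As in [desired_activity()].
#' @return A list with `f_net` (mean, Hz), `cv` (coefficient of variation)
#'   and `per_location` (tibble of the net activity at each grid location).
#' @export
net_activity_constant <- function(pfm, grid, params = NULL,
                                  sigma = params$sigma, u0 = params$u0,
                                  f_pk = params$f_pk) {
  stopifnot(nrow(grid) >= 1)
  nets <- purrr::map_dbl(seq_len(nrow(grid)), function(j)
    sum(desired_activity(pfm, c(grid$x[j], grid$y[j]),
                         sigma = sigma, u0 = u0, f_pk = f_pk)))
  mu <- mean(nets)
  if (mu == 0) warning("net embedded activity is zero everywhere (empty map?)")
  list(f_net = mu,
       cv = if (mu > 0) stats::sd(nets) / mu else NA_real_,
       per_location = tibble::tibble(x = grid$x, y = grid$y, f_net = nets))
}

#' Training-input peak matching a target reduced input strength
#'
#' Scales the training-input amplitude `b_pk` so the reduced input
#' `b_hat = (f_pk / f_net) * sum_{i in S_k} b_i(x_k)`, averaged over probe
#' locations, equals a target reduced training strength (by default the value
#' fixed by the training-constraint identity `1 = w0 - w_I_hat (1 - theta) +
#' b_hat_pk` of the reduced model).
#'
#' @param pfm Place-field map.
#' @param locations Matrix of probe locations (rows are `x, y`).
#' @param params Parameters; `f_net` must be set.
#' @param b_hat_pk Target reduced training strength (default 0.33).
#' @return The calibrated scalar `b_pk`.
#' @export
calibrate_input_peak <- function(pfm, locations, params, b_hat_pk = 0.33) {
  locations <- to_xy_matrix(locations)
  stopifnot(is.finite(params$f_net), params$f_net > 0, b_hat_pk > 0)
  per_unit <- purrr::map_dbl(seq_len(nrow(locations)), function(k) {
    x <- locations[k, ]
    S <- embedded_active_set(pfm, x, params)
    b1 <- training_input(pfm, x, b_pk = 1, sigma = params$sigma)
    params$f_pk / params$f_net * sum(b1[S])
  })
  b_hat_pk / mean(per_unit)
}
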