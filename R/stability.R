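#' Active-set stability index
#'
#' The stability of a fixed point of the threshold-linear dynamics depends
#' only on which cells are active there. With `S` the active excitatory set
#' and the inhibitory unit active or not, the fixed point is stable if and
#' only if `r < 1`, where `r` is the largest real part over eigenvalues of
#' `f_pk * (W - chi * w_I * 11^T) * D(S)` and `D(S)` zeroes the columns of
#' inactive cells. Zeroed columns contribute only zero eigenvalues, so `r` is
#' computed on the `|S| x |S|` active submatrix. Neither the external input
#' nor the state magnitudes enter.
#'
#' @param W N x N recurrent weight matrix (or a `megamap_weights` object).
#' @param w_I Inhibitory weight.
#' @param f_pk Peak firing rate (slope of the activation function times its
#'   peak; use 1 for the reduced model's unit-peak activation).
#' @param active Integer vector of active cell indices (possibly empty).
#' @param inhibition_active Is the inhibitory unit active at the fixed point?
#'   (It always is at megamap equilibria; kept explicit for generality.)
#' @return Scalar `r`; 0 for an empty active set.
#' @export
stability_index <- function(W, w_I, f_pk, active, inhibition_active = TRUE) {
  if (inherits(W, "megamap_weights")) W <- W$W
  if (length(active) == 0) return(0)
  M <- W[active, active, drop = FALSE]
  if (inhibition_active) M <- M - w_I
  ev <- eigen(f_pk * M, only.values = TRUE)$values
  max(Re(ev))
}

#' A-priori operational-mode test
#'
#' Classifies a trained megamap as winner-take-all (WTA) or combinatorial for
#' a pair of well-separated probe locations: the system is combinatorial if
#' and only if the union of the two embedded active sets is stable with the
#' inhibitory unit active, i.e. `r(S1 U S2, {inh}) < 1`. Also reports the
#' single-bump indices `r(S_k, {inh})`, which are below 1 for any properly
#' embedded pattern.
#'
#' @param W Weight matrix or `megamap_weights`.
#' @param pfm Place-field map.
#' @param params [megamap_params()] (uses `w_I`, `f_pk`, `sigma`, `u0`).
#' @param x1,x2 Probe locations (2-vectors, meters), at least 0.5 m apart and
#'   at least the boundary margin from every wall.
#' @param marginal_tol Width of the band around `r = 1` reported as
#'   `"marginal"` rather than classified (default 1e-3).
#' @return An object of class `megamap_mode` (list with `r_union`, `r1`, `r2`,
#'   `mode`, the sets, and the probe locations). `tidy()` turns it into a
#'   tibble.
#' @export
classify_mode <- function(W, pfm, params, x1, x2, marginal_tol = 1e-3) {
  check_probe_pair(pfm$env, x1, x2)
  S1 <- embedded_active_set(pfm, x1, params)
  S2 <- embedded_active_set(pfm, x2, params)
  if (!length(S1) || !length(S2))
    stop("a probe location activates no cell; move it or densify the map",
         call. = FALSE)
  r1 <- stability_index(W, params$w_I, params$f_pk, S1)
  r2 <- stability_index(W, params$w_I, params$f_pk, S2)
  r_union <- stability_index(W, params$w_I, params$f_pk, union(S1, S2))
  mode <- if (abs(r_union - 1) < marginal_tol) "marginal"
          else if (r_union < 1) "combinatorial" else "WTA"
  structure(list(r_union = r_union, r1 = r1, r2 = r2, mode = mode,
                 S1 = S1, S2 = S2, x1 = x1, x2 = x2),
            class = "megamap_mode")
}

check_probe_pair <- function(env, x1, x2, min_sep = 0.5) {
  stopifnot(length(x1) == 2, length(x2) == 2)
  if (sqrt(sum((x1 - x2)^2)) < min_sep)
    stop(sprintf("probe locations must be at least %.2f m apart", min_sep),
         call. = FALSE)
  if (!in_bounds(env, x1) || !in_bounds(env, x2))
    stop(sprintf("probe locations must be at least %.2f m from every boundary",
                 env$margin), call. = FALSE)
  invisible(TRUE)
}

#' @export
print.megamap_mode <- function(x, ...) {
  cat(sprintf("<megamap_mode> %s  (r_union = %.4f; r1 = %.4f, r2 = %.4f; |S1| = %d, |S2| = %d)\n",
              x$mode, x$r_union, x$r1, x$r2, length(x$S1), length(x$S2)))
  invisible(x)
}

#' Local active set near a location
#'
#' The cells that are currently active and have a field within `delta` of
#' location `x`; the instantaneous membership of the activity bump over `x`.
#' `delta` must exceed the embedded bump radius and be small enough to exclude
#' cells belonging to the other bump.
#'
#' @param u State vector.
#' @param pfm Place-field map.
#' @param x Location (2-vector).
#' @param params Parameters (for the bump radius check).
#' @param delta Radius in meters (default 0.25).
#' @param max_delta Upper admissible bound (e.g. separation minus bump
#'   radius); `Inf` to skip the check.
#' @return Integer vector of cell indices.
#' @export
local_active_set <- function(u, pfm, x, params, delta = 0.25,
                             max_delta = Inf) {
  R <- bump_radius(params)
  if (delta <= R || delta >= max_delta)
    stop(sprintf("`delta` must lie in (%.3f, %.3f)", R, max_delta),
         call. = FALSE)
  d2 <- field_dist2(pfm, x)
  near <- unique(pfm$cell[d2 < delta^2])
  near[u[near] > 0]
}

#' Operational mode across a growing environment
#'
#' Applies the mode test to the cumulative weight matrices of an incremental
#' learning sequence with fixed probe locations (which must lie in the first
#' learned region so their patterns exist at every stage).
#'
#' @param weights_list List of `megamap_weights` from [incremental_learning()].
#' @param pfm,params,x1,x2 As in [classify_mode()].
#' @return A tibble of class `mode_sweep`: `region`, `cum_area`, `r_union`,
#'   `r1`, `r2`, `mode`, `method`.
#' @export
mode_vs_area_sweep <- function(weights_list, pfm, params, x1, x2) {
  areas <- region_area(pfm$env)
  rows <- purrr::map(seq_along(weights_list), function(k) {
    m <- classify_mode(weights_list[[k]], pfm, params, x1, x2)
    tibble::tibble(region = k, cum_area = areas$cum_area[k],
                   r_union = m$r_union, r1 = m$r1, r2 = m$r2, mode = m$mode,
                   method = weights_list[[k]]$method)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("mode_sweep", class(out))
  out
}
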