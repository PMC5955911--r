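#' Megamap model parameters
#'
#' Bundles the firing-rate network parameters with the parameters of the
#' embedded activity patterns. Units: `tau` in ms, `f_pk` in Hz, `sigma` in
#' meters; `u0`, `b_pk`, `w_I` and `theta` are dimensionless.
#'
#' @param tau Membrane time constant in ms (default 10).
#' @param f_pk Peak firing rate of an activity bump in Hz (default 15).
#' @param w_I Inhibitory weight (nonnegative scalar). Default `NA`: set it
#'   explicitly or via [calibrate_inhibition()].
#' @param theta Inhibitory threshold, a fraction in (0, 1) of the embedded net
#'   activity (default 0.9).
#' @param sigma Gaussian place-field width in meters (default 0.10).
#' @param u0 Depolarization shift at which a cell becomes active (default 0.3).
#'   The embedded activity bump has radius `sigma * sqrt(2 * log((1 + u0)/u0))`.
#' @param b_pk Peak amplitude of the training input (dimensionless). Default
#'   `NA`: set explicitly or via [calibrate_input_peak()].
#' @param f_net Net embedded activity (Hz), the location-independent sum of the
#'   desired activity over all cells. Default `NA`: measured from a map with
#'   [net_activity_constant()].
#' @param normalize_net If `TRUE` (default), embedded activity patterns are
#'   rescaled so their summed activity equals `f_net` exactly at every
#'   location (the patterns are constructed to make the net activity
#'   location-independent; the raw sum-of-bumps fluctuates with the Poisson
#'   field sample, strongly so in small maps). Takes effect only once `f_net`
#'   is set.
#' @return An object of class `megamap_params` (a named list).
#' @examples
#' p <- megamap_params(w_I = 1.6e-3, f_net = 300)
#' bump_radius(p)
#' @export
megamap_params <- function(tau = 10, f_pk = 15, w_I = NA_real_, theta = 0.9,
                           sigma = 0.10, u0 = 0.3, b_pk = NA_real_,
                           f_net = NA_real_, normalize_net = TRUE) {
  stopifnot(tau > 0, f_pk > 0, theta > 0, theta < 1, sigma > 0, u0 > 0,
            is.na(w_I) || w_I >= 0, is.na(b_pk) || b_pk > 0,
            is.na(f_net) || f_net > 0, is.logical(normalize_net))
  structure(list(tau = tau, f_pk = f_pk, w_I = w_I, theta = theta,
                 sigma = sigma, u0 = u0, b_pk = b_pk, f_net = f_net,
                 normalize_net = normalize_net),
            class = "megamap_params")
}

#' @export
print.megamap_params <- function(x, ...) {
  cat("<megamap_params>\n")
  cat(sprintf("  tau = %g ms, f_pk = %g Hz, theta = %g, w_I = %g\n",
              x$tau, x$f_pk, x$theta, x$w_I))
  cat(sprintf("  sigma = %g m, u0 = %g, b_pk = %g, f_net = %g Hz\n",
              x$sigma, x$u0, x$b_pk, x$f_net))
  invisible(x)
}

#' Radius of the embedded activity bump
#'
#' The desired activity of a field centered at `c` is
#' `f_pk * ((1 + u0) * exp(-d^2 / (2 sigma^2)) - u0)_+`, which crosses zero at
#' distance `R = sigma * sqrt(2 * log((1 + u0) / u0))`.
#'
#' @param params A [megamap_params()] object (or `sigma` directly).
#' @param u0 Shift parameter, used when `params` is numeric.
#' @return Radius in meters.
#' @export
bump_radius <- function(params, u0 = NULL) {
  if (inherits(params, "megamap_params")) {
    sigma <- params$sigma; u0 <- params$u0
  } else {
    sigma <- params
    stopifnot(!is.null(u0))
  }
  stopifnot(sigma > 0, u0 > 0)
  sigma * sqrt(2 * log((1 + u0) / u0))
}

#' Inhibitory weight matching a target reduced inhibitory weight
#'
#' The reduced inhibitory weight of the two-unit model is
#' `w_I_hat = f_pk * N_bar * w_I`, where `N_bar` is the mean number of active
#' cells in an embedded activity bump. This inverts that relation so a
#' scaled-down megamap reproduces a desired `w_I_hat`.
#'
#' @param w_I_hat Target reduced inhibitory weight (default 5.3).
#' @param f_pk Peak firing rate in Hz.
#' @param N_bar Mean embedded active-set size.
#' @return The megamap inhibitory weight `w_I`.
#' @export
calibrate_inhibition <- function(w_I_hat = 5.3, f_pk = 15, N_bar) {
  stopifnot(w_I_hat >= 0, f_pk > 0, N_bar > 0)
  w_I_hat / (f_pk * N_bar)
}
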