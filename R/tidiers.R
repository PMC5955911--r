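#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the reduced two-unit parameters
#'
#' @param x A [reduced_params()] object.
#' @param ... Unused.
#' @return One row per parameter: `term`, `estimate`.
#' @export
tidy.reduced_params <- function(x, ...) {
  tibble::tibble(
    term = c("w0", "q", "w_I_hat", "theta", "b_pk", "N_bar"),
    estimate = c(x$w0, x$q, x$w_I_hat, x$theta, x$b_pk, x$N_bar))
}

#' One-row summary of the reduced model
#'
#' @param x A [reduced_params()] object.
#' @param ... Unused.
#' @return A one-row tibble with the parameters, the attractor strength
#'   `w0 - q`, the implied operational mode, and (when the object came from
#'   [reduce_megamap()]) the reduction validity diagnostics.
#' @export
glance.reduced_params <- function(x, ...) {
  out <- tibble::tibble(
    w0 = x$w0, q = x$q, w_I_hat = x$w_I_hat, theta = x$theta,
    b_pk = x$b_pk, N_bar = x$N_bar, attractor_strength = x$w0 - x$q,
    mode = if (x$w0 - x$q > 1) "WTA" else "combinatorial")
  if (!is.null(x$diagnostics)) {
    out$overlap_frac <- x$diagnostics$overlap_frac
    out$q_asymmetry <- x$diagnostics$q_asymmetry
    out$valid <- x$diagnostics$valid
  }
  out
}

#' Tidy an operational-mode report
#'
#' @param x A [classify_mode()] result.
#' @param ... Unused.
#' @return A one-row tibble: `r_union`, `r1`, `r2`, `stable_union`, `mode`,
#'   set sizes.
#' @export
tidy.megamap_mode <- function(x, ...) {
  tibble::tibble(r_union = x$r_union, r1 = x$r1, r2 = x$r2,
                 stable_union = x$r_union < 1, mode = x$mode,
                 n_S1 = length(x$S1), n_S2 = length(x$S2))
}

#' Plot a bifurcation diagram
#'
#' Grid points colored by dynamics type with the analytic boundary curves
#' `q = (w0 - 1) + g(+/-|db|)` overlaid.
#'
#' @param object A [bifurcation_diagram()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.bifurcation_diagram <- function(object, ...) {
  ggplot2::ggplot(object$grid, ggplot2::aes(x = .data$db, y = .data$q)) +
    ggplot2::geom_point(ggplot2::aes(color = .data$type), size = 1) +
    ggplot2::geom_line(data = object$boundaries,
                       ggplot2::aes(y = .data$q_hysteresis), linewidth = 0.4) +
    ggplot2::geom_line(data = object$boundaries,
                       ggplot2::aes(y = .data$q_combinatorial), linewidth = 0.4) +
    ggplot2::labs(x = expression(Delta * hat(b)), y = "q",
                  color = "dynamics",
                  title = sprintf("w0 = %.2f, w_I_hat = %.2f, theta = %.2f",
                                  object$rp$w0, object$rp$w_I_hat,
                                  object$rp$theta)) +
    ggplot2::theme_minimal()
}

#' Plot an operational-mode area sweep
#'
#' The union-set stability index against the learned area, with the `r = 1`
#' mode boundary.
#'
#' @param object A [mode_vs_area_sweep()] tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mode_sweep <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$cum_area, y = .data$r_union,
                                       color = .data$method)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = expression("learned area (m"^2 * ")"),
                  y = "dominant eigenvalue r(S1 U S2, {inh})") +
    ggplot2::theme_minimal()
}

#' Plot a conflicting-input sweep
#'
#' Full-model activity ratios of the two bumps against the input split, with
#' the reduced model's equilibrium states for comparison.
#'
#' @param object A [run_conflict_sweep()] tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.conflict_sweep <- function(object, ...) {
  long <- dplyr::bind_rows(
    tibble::tibble(b_pk1 = object$b_pk1, value = object$act1,
                   series = "bump 1 (full)"),
    tibble::tibble(b_pk1 = object$b_pk1, value = object$act2,
                   series = "bump 2 (full)"),
    tibble::tibble(b_pk1 = object$b_pk1, value = pmax(object$u_hat1, 0),
                   series = "unit 1 (reduced)"),
    tibble::tibble(b_pk1 = object$b_pk1, value = pmax(object$u_hat2, 0),
                   series = "unit 2 (reduced)"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$b_pk1, y = .data$value,
                                     color = .data$series)) +
    ggplot2::geom_line(na.rm = TRUE) + ggplot2::geom_point(na.rm = TRUE) +
    ggplot2::labs(x = "input strength toward location 1",
                  y = "activity ratio / reduced state") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
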