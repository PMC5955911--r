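#' Parameters of the reduced two-unit model
#'
#' The two-unit model collapses the megamap driven by two conflicting inputs
#' onto two collective threshold-linear units with self-excitation `w0`,
#' cross-excitation `q`, shared inhibition of weight `w_I_hat` thresholded at
#' `theta`, and training-input strength `b_pk`. When `b_pk` is omitted it is
#' fixed by the training constraint `1 = w0 - w_I_hat * (1 - theta) + b_pk`.
#'
#' @param w0 Self-excitation (must exceed 1 for single bumps to be attractors
#'   without input).
#' @param q Cross-excitation, in `[0, w_I_hat * (1 - theta))`.
#' @param w_I_hat Reduced inhibitory weight.
#' @param theta Inhibitory threshold in (0, 1).
#' @param b_pk Reduced training-input strength; default from the constraint.
#' @param tau Time constant in ms (default 10).
#' @param N_bar Mean embedded active-set size (diagnostic; optional).
#' @return An object of class `reduced_params`.
#' @examples
#' rp <- reduced_params(w0 = 1.2, q = 0.3, w_I_hat = 5.3, theta = 0.9)
#' rp$b_pk  # 0.33
#' @export
reduced_params <- function(w0, q, w_I_hat, theta, b_pk = NULL, tau = 10,
                           N_bar = NA_real_) {
  stopifnot(is.numeric(w0), is.numeric(q), w_I_hat >= 0, theta > 0, theta < 1,
            tau > 0)
  if (is.null(b_pk)) b_pk <- 1 - w0 + w_I_hat * (1 - theta)
  structure(list(w0 = w0, q = q, w_I_hat = w_I_hat, theta = theta,
                 b_pk = b_pk, tau = tau, N_bar = N_bar,
                 diagnostics = NULL),
            class = "reduced_params")
}

#' @export
print.reduced_params <- function(x, ...) {
  cat(sprintf("<reduced_params> w0 = %.4g, q = %.4g, w_I_hat = %.4g, theta = %.3g, b_pk = %.4g\n",
              x$w0, x$q, x$w_I_hat, x$theta, x$b_pk))
  cat(sprintf("  w0 - q = %.4g  (%s mode)\n", x$w0 - x$q,
              if (x$w0 - x$q > 1) "WTA" else "combinatorial"))
  invisible(x)
}

#' Reduced inhibitory weight
#'
#' `w_I_hat = f_pk * N_bar * w_I`: the reduced model's inhibitory weight is
#' the megamap's scaled by the peak rate and the mean active-set size.
#'
#' @param w_I Megamap inhibitory weight.
#' @param f_pk Peak firing rate (Hz).
#' @param N_bar Mean embedded active-set size.
#' @return Scalar `w_I_hat`.
#' @export
reduce_inhibition <- function(w_I, f_pk, N_bar) {
  stopifnot(w_I >= 0, f_pk > 0, N_bar > 0)
  f_pk * N_bar * w_I
}

#' Reduced input for one unit
#'
#' `b_hat_k = (f_pk / f_net) * sum_{i in S_k} b_i`: the collective external
#' input into the cells of unit `k`.
#'
#' @param b Input vector over all cells (nonnegative).
#' @param S_k Indices of the cells in unit `k`.
#' @param f_pk,f_net Peak rate and net embedded activity.
#' @return Scalar `b_hat_k >= 0`.
#' @export
reduce_input <- function(b, S_k, f_pk, f_net) {
  stopifnot(all(b >= 0), f_net > 0)
  f_pk / f_net * sum(b[S_k])
}

#' Reduced state for one unit
#'
#' `u_hat_k = (f_pk / f_net) * sum_{i in S_k} u_i`. For an activity bump
#' proportional to the embedded pattern with peak `u_pk`, this is
#' approximately `u_pk`.
#'
#' @param u State vector.
#' @inheritParams reduce_input
#' @return Scalar `u_hat_k`.
#' @export
reduce_state <- function(u, S_k, f_pk, f_net) {
  stopifnot(f_net > 0)
  f_pk / f_net * sum(u[S_k])
}

#' Reduce a megamap to two-unit parameters
#'
#' Maps a trained megamap and two well-separated probe locations onto the
#' reduced model's parameters:
#' `w0 = (f_pk / f_net) * sum_{i,j in S1} w_ij * f_bar_j(x1)` (computed at
#' both locations; the mean is reported),
#' `q = (f_pk / N_bar) * sum_{i in S1, j in S2} w_ij` (symmetrized over the
#' two directions), and `w_I_hat = f_pk * N_bar * w_I` with `N_bar` the mean
#' of the two set sizes. Cells in both embedded sets are assigned to the
#' nearer location so the partial sums stay disjoint.
#'
#' Validity diagnostics follow the approximations behind the reduction:
#' the overlap fraction `|S1 n S2| / N_bar` must be below 5% and the relative
#' asymmetry of the two directed cross-sums below 10% for `valid = TRUE`.
#'
#' @param W Weight matrix or `megamap_weights`.
#' @param pfm Place-field map.
#' @param params [megamap_params()] with `w_I`, `f_net` set.
#' @param x1,x2 Probe locations.
#' @return A `reduced_params` object whose `diagnostics` element records
#'   `w0_1`, `w0_2`, `q_12`, `q_21`, `overlap_frac`, `q_asymmetry`, `valid`,
#'   and `b_pk_measured` (the reduced training input actually delivered at
#'   `x1`, for comparison with the constraint value).
#' @export
reduce_megamap <- function(W, pfm, params, x1, x2) {
  if (inherits(W, "megamap_weights")) W <- W$W
  check_probe_pair(pfm$env, x1, x2)
  stopifnot(is.finite(params$f_net), params$f_net > 0)
  S1 <- embedded_active_set(pfm, x1, params)
  S2 <- embedded_active_set(pfm, x2, params)
  if (!length(S1) || !length(S2))
    stop("empty embedded active set at a probe location", call. = FALSE)
  overlap <- intersect(S1, S2)
  if (length(overlap)) {
    d1 <- purrr::map_dbl(overlap, function(i) {
      idx <- pfm$cell == i
      min((pfm$fields[idx, 1] - x1[1])^2 + (pfm$fields[idx, 2] - x1[2])^2)
    })
    d2 <- purrr::map_dbl(overlap, function(i) {
      idx <- pfm$cell == i
      min((pfm$fields[idx, 1] - x2[1])^2 + (pfm$fields[idx, 2] - x2[2])^2)
    })
    S1 <- setdiff(S1, overlap[d1 >= d2])
    S2 <- setdiff(S2, overlap[d1 < d2])
  }
  N_bar <- mean(c(length(S1), length(S2)))
  f1 <- desired_activity(pfm, x1, params)
  f2 <- desired_activity(pfm, x2, params)
  scale_f <- params$f_pk / params$f_net
  w0_1 <- scale_f * sum(colSums(W[S1, S1, drop = FALSE]) * f1[S1])
  w0_2 <- scale_f * sum(colSums(W[S2, S2, drop = FALSE]) * f2[S2])
  q_12 <- params$f_pk / N_bar * sum(W[S1, S2])   # drive from unit 2 into unit 1
  q_21 <- params$f_pk / N_bar * sum(W[S2, S1])
  q <- (q_12 + q_21) / 2
  b1 <- training_input(pfm, x1, params)
  rp <- reduced_params(w0 = mean(c(w0_1, w0_2)), q = q,
                       w_I_hat = reduce_inhibition(params$w_I, params$f_pk, N_bar),
                       theta = params$theta, b_pk = NULL, tau = params$tau,
                       N_bar = N_bar)
  overlap_frac <- length(overlap) / N_bar
  # asymmetry relative to the effective coupling scale; floored at 10% of w0
  # so vanishing cross-coupling (where the difference cannot alter the mode)
  # is not flagged as asymmetric
  q_asym <- abs(q_12 - q_21) / max(abs(q), 0.1 * abs(rp$w0))
  rp$diagnostics <- list(
    w0_1 = w0_1, w0_2 = w0_2, q_12 = q_12, q_21 = q_21,
    overlap_frac = overlap_frac, q_asymmetry = q_asym,
    valid = overlap_frac < 0.05 && q_asym < 0.10,
    b_pk_measured = reduce_input(b1, S1, params$f_pk, params$f_net),
    S1 = S1, S2 = S2, x1 = x1, x2 = x2)
  rp
}

#' Check the constraints of the reduced model
#'
#' The four admissibility constraints plus the training-constraint residual:
#' (1) `0 < theta < 1`; (2) `0 < b_pk << 1` (warn level 0.2); (3) `w0 > 1`;
#' (4) `q < w_I_hat * (1 - theta)`; and `1 - (w0 - w_I_hat (1 - theta) + b_pk)`
#' must vanish.
#'
#' @param rp A [reduced_params()] object.
#' @return A tibble with columns `constraint`, `pass`, `margin`; attribute
#'   `all_pass`.
#' @export
check_constraints <- function(rp) {
  eq9 <- 1 - (rp$w0 - rp$w_I_hat * (1 - rp$theta) + rp$b_pk)
  out <- tibble::tibble(
    constraint = c("0 < theta < 1",
                   "0 < b_pk << 1",
                   "w0 > 1",
                   "q < w_I_hat * (1 - theta)",
                   "training constraint residual = 0"),
    pass = c(rp$theta > 0 && rp$theta < 1,
             rp$b_pk > 0 && rp$b_pk < 1,
             rp$w0 > 1,
             rp$q < rp$w_I_hat * (1 - rp$theta),
             abs(eq9) < 1e-8),
    margin = c(min(rp$theta, 1 - rp$theta),
               min(rp$b_pk, 1 - rp$b_pk),
               rp$w0 - 1,
               rp$w_I_hat * (1 - rp$theta) - rp$q,
               -abs(eq9)))
  if (rp$b_pk > 0.2 && rp$b_pk < 1)
    warning(sprintf("b_pk = %.3g is large; the training input is meant to be weak (<< 1)",
                    rp$b_pk), call. = FALSE)
  attr(out, "all_pass") <- all(out$pass)
  out
}

assert_valid_params <- function(rp) {
  cc <- withCallingHandlers(check_constraints(rp),
                            warning = function(w) invokeRestart("muffleWarning"))
  if (!attr(cc, "all_pass"))
    stop(paste0("reduced parameters violate: ",
                paste(cc$constraint[!cc$pass], collapse = "; ")),
         call. = FALSE)
  invisible(rp)
}
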