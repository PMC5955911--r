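#' Conflicting external input encoding two locations
#'
#' The weighted mixture `b = (1 / b_pk) * (b_pk1 * b_bar(x1) + b_pk2 *
#' b_bar(x2))` of the two training inputs, or the split variant in which a
#' seeded random 50% of the cells receive (only) location 1's input and the
#' rest location 2's.
#'
#' @param net A [megamap_network()] (or supply `pfm` and `params` fields
#'   through it).
#' @param x1,x2 Probe locations, at least 0.5 m apart and inside the margin.
#' @param b_pk1,b_pk2 Peak strengths of the two components (same units as the
#'   training amplitude `b_pk`).
#' @param split Use the random-assignment variant instead of the weighted sum.
#' @param seed Seed for the 50/50 assignment (dedicated stream, independent of
#'   the field-map seed).
#' @return Input vector of length `n_cells`.
#' @export
build_conflicting_input <- function(net, x1, x2, b_pk1, b_pk2,
                                    split = FALSE, seed = 1L) {
  pfm <- net$pfm; params <- net$params
  check_probe_pair(pfm$env, x1, x2)
  stopifnot(b_pk1 >= 0, b_pk2 >= 0, is.finite(params$b_pk))
  b1 <- training_input(pfm, x1, params)
  b2 <- training_input(pfm, x2, params)
  if (!split) return((b_pk1 * b1 + b_pk2 * b2) / params$b_pk)
  pick1 <- withr::with_seed(as.integer(seed),
                            sample(c(TRUE, FALSE), pfm$n_cells, replace = TRUE))
  ifelse(pick1, b_pk1 * b1, b_pk2 * b2) / params$b_pk
}

#' Activity ratio of a bump relative to its isolated response
#'
#' `act(u, s_k) = sum_{i in S_k} f(u_i) / sum_{i in S_k} f(s_i)`: the summed
#' activity of the cells of unit `k` at the equilibrium under the conflicting
#' input, relative to the equilibrium under location `k`'s isolated input.
#' Returns `NA` (an omitted data point, not an error) when the isolated
#' response carries no bump.
#'
#' @param u Equilibrium state under the conflicting input.
#' @param s_k Equilibrium state under the isolated input for location `k`.
#' @param S_k Embedded active set of location `k`.
#' @param f_pk Peak firing rate.
#' @return Scalar ratio, or `NA_real_`.
#' @export
activity_ratio <- function(u, s_k, S_k, f_pk = 15) {
  denom <- sum(activation(s_k[S_k], f_pk))
  if (denom <= 0) return(NA_real_)
  sum(activation(u[S_k], f_pk)) / denom
}

bump_present <- function(u, pfm, params, x, S, frac = 0.25) {
  f_bar <- desired_activity(pfm, x, params)
  sum(activation(u[S], params$f_pk)) > frac * sum(f_bar[S])
}

#' Sweep the relative strength of two conflicting inputs
#'
#' Reproduces the conflicting-input protocol: the net input strength is held
#' constant (`b_pk1 + b_pk2 = b_pk`) while the split between the two locations
#' varies. For each condition the full network is integrated from the
#' embedded pattern at `x2`, the activity ratio of each bump is measured
#' against its isolated response, and the reduced model's prediction
#' (two-unit equilibrium and dynamics type) is reported side by side.
#'
#' @param net A trained [megamap_network()].
#' @param x1,x2 Probe locations.
#' @param n_steps Number of conditions across `b_pk1 in [0, b_pk]`.
#' @param rp Reduced parameters; default [reduce_megamap()] of the network.
#' @param t_max,tol Passed to [find_equilibrium()].
#' @return A tibble of class `conflict_sweep`: `b_pk1`, `b_pk2`, `act1`,
#'   `act2`, `u_hat1`, `u_hat2`, `type_reduced`, `converged`.
#' @export
run_conflict_sweep <- function(net, x1, x2, n_steps = 9, rp = NULL,
                               t_max = 1500, tol = 1e-6) {
  pfm <- net$pfm; params <- net$params; W <- net$weights$W
  if (is.null(rp)) rp <- reduce_megamap(W, pfm, params, x1, x2)
  S1 <- embedded_active_set(pfm, x1, params)
  S2 <- embedded_active_set(pfm, x2, params)
  u_init <- desired_activity(pfm, x2, params) / params$f_pk
  b_grid <- seq(0, params$b_pk, length.out = n_steps)
  rows <- purrr::map(b_grid, function(bp1) {
    bp2 <- params$b_pk - bp1
    b <- build_conflicting_input(net, x1, x2, bp1, bp2)
    eq <- find_equilibrium(u_init, W, params, b, tol = tol, t_max = t_max)
    s1 <- find_equilibrium(desired_activity(pfm, x1, params) / params$f_pk,
                           W, params,
                           (bp1 / params$b_pk) * training_input(pfm, x1, params),
                           tol = tol, t_max = t_max)
    s2 <- find_equilibrium(desired_activity(pfm, x2, params) / params$f_pk,
                           W, params,
                           (bp2 / params$b_pk) * training_input(pfm, x2, params),
                           tol = tol, t_max = t_max)
    ok1 <- bump_present(s1$u, pfm, params, x1, S1)
    ok2 <- bump_present(s2$u, pfm, params, x2, S2)
    db_hat <- rp$b_pk * (bp1 - bp2) / params$b_pk
    rs <- simulate_two_unit(c(0, 1), rp,
                            rp$b_pk / 2 + c(db_hat, -db_hat) / 2)
    tibble::tibble(
      b_pk1 = bp1, b_pk2 = bp2,
      act1 = if (ok1) activity_ratio(eq$u, s1$u, S1, params$f_pk) else NA_real_,
      act2 = if (ok2) activity_ratio(eq$u, s2$u, S2, params$f_pk) else NA_real_,
      u_hat1 = rs$u[1], u_hat2 = rs$u[2],
      type_reduced = classify_dynamics(rp, db_hat),
      converged = eq$converged)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("conflict_sweep", class(out))
  attr(out, "rp") <- rp
  out
}

#' Hysteresis probe with random initial states
#'
#' Equal-strength conflicting inputs (`b_pk1 = b_pk2 = b_pk / 2`) and random
#' initial bump mixtures `u0 = (c1 f_bar(x1) + c2 f_bar(x2)) / f_pk`,
#' `c_k ~ U(0, 1)`. In the WTA regime the equilibrium reached depends on the
#' initial state (two distinct outcomes); in the combinatorial regime it does
#' not (one outcome).
#'
#' @param net Trained network.
#' @param x1,x2 Probe locations.
#' @param n_init Number of random initial states.
#' @param seed Seed for the initial-state stream.
#' @param t_max,tol Passed to [find_equilibrium()].
#' @return A list with `outcomes` (tibble: `c1`, `c2`, `bump1`, `bump2`,
#'   `label`) and `n_distinct` (number of distinct equilibrium
#'   configurations).
#' @export
run_hysteresis_probe <- function(net, x1, x2, n_init = 8, seed = 1L,
                                 t_max = 1500, tol = 1e-6) {
  pfm <- net$pfm; params <- net$params; W <- net$weights$W
  S1 <- embedded_active_set(pfm, x1, params)
  S2 <- embedded_active_set(pfm, x2, params)
  f1 <- desired_activity(pfm, x1, params)
  f2 <- desired_activity(pfm, x2, params)
  b <- build_conflicting_input(net, x1, x2, params$b_pk / 2, params$b_pk / 2)
  cs <- withr::with_seed(as.integer(seed),
                         matrix(stats::runif(2 * n_init), ncol = 2))
  rows <- purrr::map(seq_len(n_init), function(i) {
    u0 <- (cs[i, 1] * f1 + cs[i, 2] * f2) / params$f_pk
    eq <- find_equilibrium(u0, W, params, b, tol = tol, t_max = t_max)
    b1p <- bump_present(eq$u, pfm, params, x1, S1)
    b2p <- bump_present(eq$u, pfm, params, x2, S2)
    tibble::tibble(c1 = cs[i, 1], c2 = cs[i, 2], bump1 = b1p, bump2 = b2p,
                   label = paste0(as.integer(b1p), as.integer(b2p)),
                   converged = eq$converged)
  })
  outcomes <- dplyr::bind_rows(rows)
  list(outcomes = outcomes, n_distinct = dplyr::n_distinct(outcomes$label))
}
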