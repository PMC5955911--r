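#' Right-hand side of the two-unit reduced model
#'
#' `tau u1' = -u1 + w0 [u1]_+ + q [u2]_+ - w_I_hat [[u1]_+ + [u2]_+ - theta]_+ + b1`
#' and symmetrically for unit 2. The activation has unit slope and unit peak
#' (the megamap's `f_pk` is absorbed by the reduction).
#'
#' @param u Length-2 state vector.
#' @param rp A [reduced_params()] object.
#' @param b Length-2 nonnegative input vector.
#' @return Length-2 derivative, per ms.
#' @export
two_unit_rhs <- function(u, rp, b = c(0, 0)) {
  stopifnot(length(u) == 2, length(b) == 2)
  f <- pmax(u, 0)
  inh <- rp$w_I_hat * max(sum(f) - rp$theta, 0)
  (-u + c(rp$w0 * f[1] + rp$q * f[2], rp$q * f[1] + rp$w0 * f[2]) - inh + b) / rp$tau
}

#' M-unit generalization of the reduced model
#'
#' `tau u_k' = -u_k + (w0 - q) [u_k]_+ + q sum_j [u_j]_+ -
#' w_I_hat [sum_j [u_j]_+ - theta]_+ + b_k`, for `M >= 2` well-separated
#' conflicting inputs; identical to [two_unit_rhs()] at `M = 2`.
#'
#' @param u Length-M state vector (`M >= 2`).
#' @param rp A [reduced_params()] object.
#' @param b Length-M nonnegative input vector.
#' @return Length-M derivative, per ms.
#' @export
m_unit_rhs <- function(u, rp, b = numeric(length(u))) {
  if (length(u) < 2) stop("the reduced model needs at least 2 units", call. = FALSE)
  stopifnot(length(b) == length(u))
  f <- pmax(u, 0)
  inh <- rp$w_I_hat * max(sum(f) - rp$theta, 0)
  (-u + (rp$w0 - rp$q) * f + rp$q * sum(f) - inh + b) / rp$tau
}

#' Integrate the two-unit (or M-unit) reduced model
#'
#' Fixed-step explicit Euler, stopping once `max(abs(du/dt))` drops below
#' `tol`.
#'
#' @param u Initial state (length >= 2).
#' @param rp A [reduced_params()] object.
#' @param b Input vector.
#' @param dt Step in ms (default `tau / 20`).
#' @param t_max Horizon in ms.
#' @param tol Equilibrium tolerance per ms.
#' @return List with `u`, `t`, `converged`.
#' @export
simulate_two_unit <- function(u, rp, b = numeric(length(u)),
                              dt = rp$tau / 20, t_max = 2000, tol = 1e-6) {
  rhs <- if (length(u) == 2) function(u) two_unit_rhs(u, rp, b)
         else function(u) m_unit_rhs(u, rp, b)
  t <- 0; converged <- FALSE
  for (s in seq_len(ceiling(t_max / dt))) {
    du <- rhs(u)
    u <- u + dt * du
    t <- t + dt
    if (max(abs(du)) < tol) { converged <- TRUE; break }
  }
  list(u = u, t = t, converged = converged)
}

# the 8 on/off configurations of (unit1, unit2, inhibition)
two_unit_configs <- function() {
  expand.grid(a1 = c(TRUE, FALSE), a2 = c(TRUE, FALSE),
              inh = c(TRUE, FALSE), KEEP.OUT.ATTRS = FALSE)
}

#' Enumerate all fixed points of the two-unit model
#'
#' Linear case analysis over the eight sign configurations (each unit active
#' or silent, inhibition on or off): for each configuration the dynamics are
#' linear, so the candidate fixed point is solved exactly and kept only if its
#' signs are consistent with the configuration. Stability follows from the
#' configuration's Jacobian via the active-submatrix eigenvalue index
#' ([stability_index()] with unit slope): stable iff `r < 1`. An all-silent
#' candidate is marked unstable whenever `w0 > 1` (a supra-threshold
#' perturbation of either unit then grows).
#'
#' @param rp A [reduced_params()] object satisfying [check_constraints()].
#' @param b1,b2 Nonnegative inputs.
#' @param tol Sign-consistency tolerance (default 1e-10).
#' @return Tibble with columns `u1`, `u2`, `unit1_active`, `unit2_active`,
#'   `inh_active`, `r`, `stable`, `residual` (of the full RHS, for
#'   verification).
#' @export
enumerate_fixed_points <- function(rp, b1, b2, tol = 1e-10) {
  assert_valid_params(rp)
  stopifnot(b1 >= 0, b2 >= 0)
  W2 <- matrix(c(rp$w0, rp$q, rp$q, rp$w0), 2, 2)
  b <- c(b1, b2)
  cfgs <- two_unit_configs()
  rows <- list()
  for (i in seq_len(nrow(cfgs))) {
    a <- c(cfgs$a1[i], cfgs$a2[i]); inh <- cfgs$inh[i]
    A <- which(a)
    # solve the linear system of this configuration
    if (length(A)) {
      M <- W2[A, A, drop = FALSE]
      if (inh) M <- M - rp$w_I_hat
      rhs_A <- (if (inh) rp$w_I_hat * rp$theta else 0) + b[A]
      sol <- tryCatch(solve(diag(length(A)) - M, rhs_A), error = function(e) NULL)
      if (is.null(sol)) next
      uA <- drop(sol)
      s <- sum(uA)
      u <- numeric(2)
      u[A] <- uA
      inact <- setdiff(1:2, A)
      if (length(inact))
        u[inact] <- drop(W2[inact, A, drop = FALSE] %*% uA) -
          (if (inh) rp$w_I_hat * (s - rp$theta) else 0) + b[inact]
    } else {
      s <- 0
      u <- b + (if (inh) -rp$w_I_hat * (0 - rp$theta) else 0)
      if (inh) next  # inhibition on requires s > theta, impossible with no active unit
    }
    ok <- all(u[a] > tol) && all(u[!a] < tol) &&
      (if (inh) s - rp$theta > tol else s - rp$theta < tol)
    if (!ok) next
    r <- stability_index(W2, rp$w_I_hat, 1, A, inhibition_active = inh)
    stable <- if (!length(A)) rp$w0 < 1 else r < 1
    rows[[length(rows) + 1L]] <- tibble::tibble(
      u1 = u[1], u2 = u[2], unit1_active = a[1], unit2_active = a[2],
      inh_active = inh, r = r, stable = stable,
      residual = max(abs(rp$tau * two_unit_rhs(u, rp, b))))
  }
  if (!length(rows))
    return(tibble::tibble(u1 = numeric(), u2 = numeric(),
                          unit1_active = logical(), unit2_active = logical(),
                          inh_active = logical(), r = numeric(),
                          stable = logical(), residual = numeric()))
  dplyr::distinct(dplyr::bind_rows(rows),
                  .data$unit1_active, .data$unit2_active, .data$inh_active,
                  .keep_all = TRUE)
}

#' Stability of the both-active configuration
#'
#' A fixed point in which both units are active is stable if and only if
#' `w0 - q < 1`; the configuration's Jacobian eigenvalues are
#' `(w0 - q - 1) / tau` and `(w0 + q - 2 w_I_hat - 1) / tau`, and the second
#' is negative under the model constraints.
#'
#' @param rp A [reduced_params()] object.
#' @param marginal_tol Band around `w0 - q = 1` flagged as marginal.
#' @return `TRUE`, `FALSE`, or `NA` (marginal).
#' @export
both_active_stable <- function(rp, marginal_tol = 0) {
  d <- rp$w0 - rp$q
  if (marginal_tol > 0 && abs(d - 1) < marginal_tol) return(NA)
  d < 1
}

#' Input-difference amplification at the both-active fixed point
#'
#' In the combinatorial regime the equilibrium amplifies the input difference
#' linearly: `u1 - u2 = (b1 - b2) / (q - (w0 - 1))`.
#'
#' @param rp A [reduced_params()] object with `q > w0 - 1`.
#' @param b1,b2 Inputs.
#' @return Scalar `u1 - u2`.
#' @export
amplification <- function(rp, b1, b2) {
  if (rp$q <= rp$w0 - 1)
    stop("amplification formula requires the combinatorial regime (q > w0 - 1)",
         call. = FALSE)
  (b1 - b2) / (rp$q - (rp$w0 - 1))
}

#' Bifurcation function g
#'
#' All bifurcation boundaries of the reduced model under a constant net input
#' `b1 + b2 = b_pk` are expressed through
#' `g(x) = 2 x (w_I_hat - (w0 - 1)) / (w_I_hat (1 + theta) - (w0 - 1) + x)`,
#' which is strictly increasing on `[-b_pk, b_pk]` with `g(0) = 0`.
#'
#' @param x Evaluation points in `[-b_pk, b_pk]`.
#' @param rp A [reduced_params()] object.
#' @return `g(x)`.
#' @export
g_function <- function(x, rp) {
  if (any(abs(x) > rp$b_pk + 1e-12))
    stop("`x` must lie in [-b_pk, b_pk]", call. = FALSE)
  denom <- rp$w_I_hat * (1 + rp$theta) - (rp$w0 - 1) + x
  if (any(denom <= 0))
    stop("nonpositive denominator in g; parameters violate the model constraints",
         call. = FALSE)
  2 * x * (rp$w_I_hat - (rp$w0 - 1)) / denom
}

#' Classify the qualitative dynamics (Types I-IV)
#'
#' Under a constant net input `b1 + b2 = b_pk` and input difference
#' `db = b1 - b2`, the dynamics are Type III (hysteresis, two co-stable
#' single-unit equilibria) iff `q < (w0 - 1) + g(-|db|)`, Type IV (unique
#' both-active equilibrium) iff `q > (w0 - 1) + g(|db|)`, and otherwise
#' Type I (`db > 0`, unit 1 wins) or Type II (`db < 0`).
#'
#' @param rp A [reduced_params()] object.
#' @param db Input difference in `[-b_pk, b_pk]`.
#' @param marginal_tol Distance to a boundary below which the point is
#'   reported `"marginal"` (default 1e-6).
#' @return One of `"I"`, `"II"`, `"III"`, `"IV"`, `"marginal"`.
#' @export
classify_dynamics <- function(rp, db, marginal_tol = 1e-6) {
  if (abs(db) > rp$b_pk + 1e-12)
    stop("`db` must lie in [-b_pk, b_pk]", call. = FALSE)
  lower <- (rp$w0 - 1) + g_function(-abs(db), rp)
  upper <- (rp$w0 - 1) + g_function(abs(db), rp)
  if (min(abs(rp$q - lower), abs(rp$q - upper)) < marginal_tol) return("marginal")
  if (rp$q < lower) return("III")
  if (rp$q > upper) return("IV")
  if (db > 0) "I" else if (db < 0) "II" else "marginal"
}

#' Detect hysteresis by simulation
#'
#' Integrates the reduced model from the two single-unit desired patterns
#' `(1, 0)` and `(0, 1)` under the same input and reports whether the reached
#' equilibria differ in their active configuration.
#'
#' @param rp A [reduced_params()] object.
#' @param b1,b2 Inputs.
#' @param ... Passed to [simulate_two_unit()].
#' @return List with `hysteresis` (logical), the two equilibria, and their
#'   active configurations.
#' @export
detect_hysteresis <- function(rp, b1, b2, ...) {
  s1 <- simulate_two_unit(c(1, 0), rp, c(b1, b2), ...)
  s2 <- simulate_two_unit(c(0, 1), rp, c(b1, b2), ...)
  cfg <- function(u) u > 1e-6
  list(hysteresis = !identical(cfg(s1$u), cfg(s2$u)),
       from_unit1 = s1, from_unit2 = s2,
       config_from_unit1 = cfg(s1$u), config_from_unit2 = cfg(s2$u),
       converged = s1$converged && s2$converged)
}

# Fig.4-style simulation classification: start from the desired pattern of
# the unit driven by the weaker input
simulate_dynamics_type <- function(rp, db, ...) {
  b1 <- (rp$b_pk + db) / 2
  b2 <- (rp$b_pk - db) / 2
  u0 <- if (b1 >= b2) c(0, 1) else c(1, 0)
  s <- simulate_two_unit(u0, rp, c(b1, b2), ...)
  act <- s$u > 1e-6
  if (all(act)) return("IV")
  if (!any(act)) return("none")
  winner <- which(act)
  stronger <- if (db > 0) 1L else if (db < 0) 2L else NA_integer_
  weaker_init <- which(u0 > 0)
  if (winner == weaker_init &&
      (is.na(stronger) || winner != stronger)) return("III")
  if (!is.na(stronger) && winner == stronger) return(if (db > 0) "I" else "II")
  # weaker unit won from its own basin with db != 0: hysteresis branch
  "III"
}

#' Bifurcation diagram over (input difference, cross-excitation)
#'
#' Classifies a grid over `db = b1 - b2` in `[-b_pk, b_pk]` and `q` in
#' `[0, w_I_hat (1 - theta))` analytically, draws the boundary curves
#' `q = (w0 - 1) + g(+/-|db|)`, and (optionally) verifies a subsample by
#' direct simulation with the protocol: start from the desired pattern of the
#' weaker-input unit, then classify by which units are active at equilibrium.
#'
#' @param rp A [reduced_params()] object (its `q` element is ignored; the grid
#'   supplies `q`).
#' @param q_steps,db_steps Grid resolution (default 25 each).
#' @param simulate Simulate every `simulate`-th grid point for verification
#'   (1 = all, 0 = none; default 1).
#' @return An object of class `bifurcation_diagram`: `grid` tibble
#'   (`q`, `db`, `type`, `type_sim`), `boundaries` tibble, `agreement`
#'   (fraction of off-boundary simulated points agreeing with the analytic
#'   classification), and `rp`.
#' @export
bifurcation_diagram <- function(rp, q_steps = 25, db_steps = 25, simulate = 1) {
  stopifnot(q_steps >= 2, db_steps >= 2)
  q_max <- rp$w_I_hat * (1 - rp$theta)
  qs <- seq(0, q_max * (1 - 1e-9), length.out = q_steps)
  dbs <- seq(-rp$b_pk, rp$b_pk, length.out = db_steps)
  grid <- qdb_grid(qs, dbs)
  grid$type <- purrr::map_chr(seq_len(nrow(grid)), function(i) {
    rpi <- rp; rpi$q <- grid$q[i]
    classify_dynamics(rpi, grid$db[i])
  })
  grid$type_sim <- NA_character_
  if (simulate >= 1) {
    idx <- seq(1, nrow(grid), by = simulate)
    grid$type_sim[idx] <- purrr::map_chr(idx, function(i) {
      rpi <- rp; rpi$q <- grid$q[i]
      simulate_dynamics_type(rpi, grid$db[i])
    })
  }
  db_curve <- seq(-rp$b_pk, rp$b_pk, length.out = 201)
  boundaries <- tibble::tibble(
    db = db_curve,
    q_hysteresis = (rp$w0 - 1) + g_function(-abs(db_curve), rp),
    q_combinatorial = (rp$w0 - 1) + g_function(abs(db_curve), rp))
  comp <- grid[!is.na(grid$type_sim) & grid$type != "marginal", ]
  agreement <- if (nrow(comp)) mean(comp$type == comp$type_sim) else NA_real_
  structure(list(grid = grid, boundaries = boundaries,
                 agreement = agreement, rp = rp),
            class = "bifurcation_diagram")
}

# expand.grid returning a tibble with stable column order (q, db)
qdb_grid <- function(qs, dbs) {
  g <- expand.grid(db = dbs, q = qs, KEEP.OUT.ATTRS = FALSE)
  tibble::tibble(q = g$q, db = g$db)
}

#' @export
print.bifurcation_diagram <- function(x, ...) {
  tab <- table(x$grid$type)
  cat(sprintf("<bifurcation_diagram> %d points; types: %s\n",
              nrow(x$grid),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  if (!is.na(x$agreement))
    cat(sprintf("  simulation agreement (off-boundary): %.1f%%\n",
                100 * x$agreement))
  invisible(x)
}

#' Locate the critical cross-excitation by bisection
#'
#' Bisects over `q` on the predicate "a stable fixed point with both units
#' active exists" (linear case analysis plus Jacobian), at fixed inputs.
#' Under equal inputs the boundary sits at `q = w0 - 1`, i.e. at the critical
#' attractor strength `w0 - q = 1`.
#'
#' @param rp A [reduced_params()] object; its `q` is ignored.
#' @param db Input difference (default 0, equal inputs).
#' @param tol Bisection tolerance on `q` (default 1e-8).
#' @return The critical `q`.
#' @export
critical_q <- function(rp, db = 0, tol = 1e-8) {
  b1 <- (rp$b_pk + db) / 2
  b2 <- (rp$b_pk - db) / 2
  has_stable_both <- function(q) {
    rpi <- rp; rpi$q <- q
    fp <- enumerate_fixed_points(rpi, b1, b2)
    any(fp$unit1_active & fp$unit2_active & fp$stable)
  }
  lo <- 0
  hi <- rp$w_I_hat * (1 - rp$theta) * (1 - 1e-9)
  if (has_stable_both(lo) || !has_stable_both(hi))
    stop("predicate does not bracket a transition on [0, w_I_hat(1-theta))",
         call. = FALSE)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (has_stable_both(mid)) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}
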