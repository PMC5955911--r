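test_that("the two-unit right-hand side is symmetric and vanishes at rest", {
  rp <- fig4a_params(q = 0.3)
  expect_equal(two_unit_rhs(c(0, 0), rp, c(0, 0)), c(0, 0))
  u <- c(0.4, -0.1); b <- c(0.2, 0.05)
  expect_equal(two_unit_rhs(rev(u), rp, rev(b)), rev(two_unit_rhs(u, rp, b)))
})

test_that("fixed points match the published training-input and symmetric cases", {
  rp <- fig4a_params(q = 0.1)
  fp <- enumerate_fixed_points(rp, 0.33, 0)
  one <- fp[fp$unit1_active & !fp$unit2_active, ]
  expect_equal(nrow(one), 1)
  expect_equal(one$u1, 1, tolerance = 1e-12)
  expect_equal(one$u2, 0.1 - 5.3 * 0.1, tolerance = 1e-12)   # q - w_I_hat(1-theta)
  expect_true(one$stable)
  expect_lt(one$residual, 1e-10)

  rp4 <- fig4a_params(q = 0.3)
  fp4 <- enumerate_fixed_points(rp4, 0.165, 0.165)
  both <- fp4[fp4$unit1_active & fp4$unit2_active, ]
  expect_equal(nrow(both), 1)
  # linear-solve oracle: u (1 - w0 - q + 2 w_I_hat) = w_I_hat theta + b
  u_oracle <- (5.3 * 0.9 + 0.165) / (1 - 1.2 - 0.3 + 2 * 5.3)
  expect_equal(both$u1, u_oracle, tolerance = 1e-12)
  expect_equal(both$u2, u_oracle, tolerance = 1e-12)
  expect_true(both$stable)
  # and simulation lands on it
  sim <- simulate_two_unit(c(0.9, 0.1), rp4, c(0.165, 0.165), tol = 1e-9)
  expect_equal(sim$u, c(u_oracle, u_oracle), tolerance = 1e-5)

  # q = 0.1 with equal inputs: two stable single-unit points, no stable both-active
  fp3 <- enumerate_fixed_points(rp, 0.165, 0.165)
  singles <- fp3[xor(fp3$unit1_active, fp3$unit2_active) & fp3$stable, ]
  expect_equal(nrow(singles), 2)
  expect_false(any(fp3$unit1_active & fp3$unit2_active & fp3$stable))
})

test_that("existence predicates reproduce the linear case analysis on a dense grid", {
  rp <- fig4a_params()
  w0 <- rp$w0; wI <- rp$w_I_hat; th <- rp$theta; bpk <- rp$b_pk
  qs <- seq(0, wI * (1 - th) * 0.999, length.out = 50)
  dbs <- seq(0, bpk, length.out = 50)   # derived under b1 >= b2
  for (q in qs) {
    rpq <- fig4a_params(q = q)
    for (db in dbs) {
      b1 <- (bpk + db) / 2; b2 <- (bpk - db) / 2
      fp <- enumerate_fixed_points(rpq, b1, b2)
      pred1 <- q < (w0 - 1) + db * (wI - (w0 - 1)) / (wI * th + b1)
      pred2 <- q < (w0 - 1) - db * (wI - (w0 - 1)) / (wI * th + b2)
      got1 <- any(fp$unit1_active & !fp$unit2_active)
      got2 <- any(!fp$unit1_active & fp$unit2_active)
      expect_identical(got1, pred1)
      expect_identical(got2, pred2)
      if (w0 - q < 1) {
        pred12 <- q > (w0 - 1) + db * (wI - (w0 - 1)) / (wI * th + b1)
        both <- fp[fp$unit1_active & fp$unit2_active, ]
        expect_identical(nrow(both) > 0, pred12)
        if (nrow(both)) expect_equal(nrow(both), 1)   # uniqueness
      }
    }
  }
})

test_that("stability claims: single-unit points always stable, both-active iff w0 - q < 1", {
  set.seed(5)
  for (rp in random_valid_params(12, seed = 5)) {
    b1 <- runif(1, 0, rp$b_pk); b2 <- runif(1, 0, b1)
    fp <- enumerate_fixed_points(rp, b1, b2)
    singles <- fp[xor(fp$unit1_active, fp$unit2_active), ]
    expect_true(all(singles$stable))
    both <- fp[fp$unit1_active & fp$unit2_active, ]
    if (nrow(both)) expect_identical(both$stable, rp$w0 - rp$q < 1)
    # no stable all-silent state under w0 > 1
    silent <- fp[!fp$unit1_active & !fp$unit2_active, ]
    if (nrow(silent)) expect_false(any(silent$stable))
    expect_true(all(fp$residual < 1e-9))
  }
  # cross-check the closed-form test and its Jacobian eigenvalues
  rp <- fig4a_params(q = 0.3)
  expect_true(both_active_stable(rp))
  expect_false(both_active_stable(fig4a_params(q = 0.1)))
  expect_true(is.na(both_active_stable(fig4a_params(q = 0.2),
                                       marginal_tol = 1e-6)))
  W2 <- matrix(c(rp$w0, rp$q, rp$q, rp$w0), 2) - rp$w_I_hat
  ev <- sort(Re(eigen((-diag(2) + W2) / rp$tau, only.values = TRUE)$values))
  expect_equal(ev, sort(c(rp$w0 - rp$q - 1,
                          rp$w0 + rp$q - 2 * rp$w_I_hat - 1)) / rp$tau)
})

test_that("amplification follows the closed form and the enumerated equilibrium", {
  rp <- fig4a_params(q = 0.3)
  expect_equal(amplification(rp, 0.165, 0.165), 0)
  expect_equal(amplification(rp, 0.19, 0.14), 0.05 / 0.1)
  fp <- enumerate_fixed_points(rp, 0.19, 0.14)
  both <- fp[fp$unit1_active & fp$unit2_active, ]
  expect_equal(both$u1 - both$u2, amplification(rp, 0.19, 0.14),
               tolerance = 1e-8)
  expect_error(amplification(fig4a_params(q = 0.1), 0.2, 0.1), "combinatorial")
})

test_that("the bifurcation function is zero at zero, increasing, with the stated theta limit", {
  rp <- fig4a_params()
  expect_identical(g_function(0, rp), 0)
  for (rpi in random_valid_params(10, seed = 2)) {
    expect_identical(g_function(0, rpi), 0)
    xs <- seq(-rpi$b_pk, rpi$b_pk, length.out = 21)
    expect_true(all(diff(g_function(xs, rpi)) > 0))
  }
  expect_equal(g_function(-0.33, rp), -0.3528302, tolerance = 1e-7)
  expect_error(g_function(2 * rp$b_pk, rp), "b_pk")
  # slope near zero approaches (wI - (w0-1)) / (wI - (w0-1)/2) as theta -> 1
  rp_hi <- reduced_params(w0 = 1.002, q = 0.001, w_I_hat = 5.3, theta = 0.999)
  slope <- (g_function(1e-6, rp_hi) - g_function(-1e-6, rp_hi)) / 2e-6
  expect_equal(slope, (5.3 - 0.002) / (5.3 - 0.001), tolerance = 1e-2)
})

test_that("dynamics types classify as the boundary curves dictate", {
  expect_identical(classify_dynamics(fig4a_params(q = 0.1), 0), "III")
  expect_identical(classify_dynamics(fig4a_params(q = 0.3), 0), "IV")
  expect_identical(classify_dynamics(fig4a_params(q = 0.1), 0.33), "I")
  expect_identical(classify_dynamics(fig4a_params(q = 0.1), -0.33), "II")
  expect_identical(classify_dynamics(fig4a_params(q = 0.2), 0), "marginal")
  expect_error(classify_dynamics(fig4a_params(q = 0.1), 0.5), "b_pk")
})

test_that("hysteresis appears exactly when two single-unit attractors coexist", {
  rp3 <- fig4a_params(q = 0.1)     # Type III at equal inputs
  h3 <- detect_hysteresis(rp3, 0.165, 0.165)
  expect_true(h3$hysteresis)
  rp4 <- fig4a_params(q = 0.3)     # Type IV
  expect_false(detect_hysteresis(rp4, 0.165, 0.165)$hysteresis)
  expect_false(detect_hysteresis(rp3, 0.33, 0)$hysteresis)   # Type I
  # agreement with enumeration
  fp <- enumerate_fixed_points(rp3, 0.165, 0.165)
  n_single_stable <- sum(xor(fp$unit1_active, fp$unit2_active) & fp$stable)
  expect_identical(h3$hysteresis, n_single_stable == 2L)
})

test_that("winner-take-all versus combinatorial is decided by w0 - q alone", {
  for (rp in random_valid_params(20, seed = 9)) {
    if (abs(rp$w0 - rp$q - 1) < 0.05) next
    b <- rp$b_pk / 2
    eq <- simulate_two_unit(c(1, 0), rp, c(b, b), t_max = 4000)$u
    both_on <- all(eq > 1e-6)
    expect_identical(both_on, rp$w0 - rp$q < 1)
  }
})

test_that("the bifurcation diagram is contiguous and matches simulation off-boundary", {
  rp <- fig4a_params()
  bd <- bifurcation_diagram(rp, q_steps = 13, db_steps = 13, simulate = 1)
  expect_gte(bd$agreement, 0.99)
  g <- bd$grid
  # region layout as in the phase diagram: III below, IV above, I right, II left
  expect_true(all(g$type[g$q < 0.05 & abs(g$db) < 0.05] == "III"))
  expect_true(all(g$type[g$q > 0.4 & abs(g$db) < 0.05] == "IV"))
  expect_true(all(g$type[g$db > 0.3 & g$q > 0.1 & g$q < 0.15] == "I"))
  # no Type IV below the analytic bound at extreme input difference
  bound <- (rp$w0 - 1) + g_function(rp$b_pk, rp)
  expect_false(any(g$type == "IV" & abs(g$db) > rp$b_pk - 1e-9 &
                     g$q < bound - 1e-9))
  # smaller theta bends the boundaries: compare slopes of the upper curve
  rp_lo <- reduced_params(w0 = 1.2, q = 0.1, w_I_hat = 5.3, theta = 0.5)
  b_lo <- bifurcation_diagram(rp_lo, q_steps = 3, db_steps = 3, simulate = 0)
  curv <- function(b) {
    cur <- b$boundaries
    d1 <- diff(cur$q_combinatorial) / diff(cur$db)
    max(abs(diff(d1)))
  }
  expect_gt(curv(b_lo), curv(bd))
  expect_s3_class(autoplot(bd), "ggplot")
})

test_that("the M-unit generalization collapses to the two-unit model at M = 2", {
  rp <- fig4a_params(q = 0.3)
  u <- c(0.4, -0.2); b <- c(0.1, 0.2)
  expect_equal(m_unit_rhs(u, rp, b), two_unit_rhs(u, rp, b), tolerance = 1e-12)
  expect_error(m_unit_rhs(0.5, rp, 0.1), "at least 2")
  # permutation equivariance at M = 3
  u3 <- c(0.5, 0.1, -0.3); b3 <- c(0.1, 0.2, 0.05)
  perm <- c(3, 1, 2)
  expect_equal(m_unit_rhs(u3, rp, b3)[perm], m_unit_rhs(u3[perm], rp, b3[perm]))
  # symmetric combinatorial-regime equilibrium is symmetric across units
  eq <- simulate_two_unit(c(1, 0, 0.5), rp, rep(rp$b_pk / 3, 3),
                          t_max = 8000, tol = 1e-9)
  expect_lt(diff(range(eq$u)), 1e-4)
})

test_that("bisection locates the critical cross-excitation", {
  rp <- fig4a_params()
  expect_equal(critical_q(rp), rp$w0 - 1, tolerance = 1e-6)
  for (rpi in random_valid_params(3, seed = 4)) {
    expect_equal(critical_q(rpi), rpi$w0 - 1, tolerance = 1e-6)
  }
})
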