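test_that("one cell, one location: the delta rule recovers the closed-form weight", {
  # a single active cell with no inhibition: the fixed point requires
  # u = W * f + b with u = f_bar/f_pk, so W = (u - b) / f_bar
  m <- manual_map(1, rbind(c(0.5, 0.5)), cell = 1, n_cells = 1)
  params <- megamap_params(w_I = 0, b_pk = 0.1, f_net = 15,
                           normalize_net = FALSE)
  grid <- tibble::tibble(x = 0.5, y = 0.5)
  cfg <- learning_config(max_epochs = 50, embed_tol = 1e-10, zero_diag = FALSE)
  wts <- learn_optimal_weights(m, params, cfg, grid = grid)
  expect_true(wts$report$converged)
  W_expected <- (1 - 0.1) / 15
  expect_equal(wts$W[1, 1], W_expected, tolerance = 1e-8)
})

test_that("embedded patterns are fixed points of the trained network", {
  net <- wta_fixture()
  pfm <- net$pfm; params <- net$params
  for (x in list(net$meta$x1, net$meta$x2)) {
    f_bar <- desired_activity(pfm, x, params)
    u_bar <- f_bar / params$f_pk
    u_bar[f_bar == 0] <- -0.1    # sub-threshold values are unconstrained
    du <- megamap_rhs(u_bar, net$weights$W, params,
                      training_input(pfm, x, params))
    active <- f_bar > 0
    expect_lt(max(abs(du[active])) * params$tau, 10 * 1.5e-3)
  }
})

test_that("perturbed embedded bumps relax back onto the pattern", {
  net <- wta_fixture()
  pfm <- net$pfm; params <- net$params; x <- net$meta$x1
  f_bar <- desired_activity(pfm, x, params)
  u0 <- f_bar / params$f_pk
  noise <- withr::with_seed(9, 1 + 0.05 * runif(length(u0), -1, 1))
  eq <- find_equilibrium(u0 * noise, net$weights$W, params,
                         training_input(pfm, x, params), t_max = 2000)
  f_eq <- activation(eq$u, params$f_pk)
  cosine <- sum(f_eq * f_bar) / sqrt(sum(f_eq^2) * sum(f_bar^2))
  expect_gt(cosine, 0.95)
})

test_that("summed squared residual is non-increasing across epochs", {
  pfm <- tiny_map()
  env <- pfm$env
  grid <- training_grid(env, 0.15)
  params <- megamap_params(f_net = NA)
  params$f_net <- net_activity_constant(pfm, grid, params)$f_net
  params$w_I <- calibrate_inhibition(5.3, 15, 8)
  params$b_pk <- 0.05
  for (eta in c(1, 0.1)) {
    W <- NULL
    losses <- sapply(1:4, function(k) {
      cfg <- learning_config(eta = eta, max_epochs = 1, embed_tol = 1e-12,
                             spacing = 0.15, shuffle_seed = k)
      wts <- learn_optimal_weights(pfm, params, cfg, grid = grid, W_init = W)
      W <<- wts$W
      embedding_loss(W, pfm, params, grid)
    })
    expect_true(all(diff(losses) <= 1e-8))
  }
})

test_that("the learned tuning curve peaks at zero distance and decays", {
  tun <- shared_tuning()
  prof <- tun$profile
  expect_lt(prof$r[which.max(prof$w)], 0.05)
  R <- bump_radius(0.1, u0 = 0.3)
  tail_max <- max(abs(prof$w[prof$r > 2 * R]), 0)
  expect_lt(tail_max, 0.05 * max(prof$w))
  # evaluation: interpolation inside support, zero beyond
  expect_equal(tuning_value(tun, prof$r[3]), prof$w[3])
  expect_equal(tuning_value(tun, tun$r_max + 0.1), 0)
})

test_that("Hebbian weights sum clamped tuning values over field pairs", {
  tun <- shared_tuning()
  w0 <- tuning_value(tun, 0, clamp = TRUE)
  # two single-field cells with coincident fields
  m <- manual_map(1, rbind(c(0.5, 0.5), c(0.5, 0.5)), cell = c(1, 2),
                  n_cells = 2)
  hw <- hebbian_weights(m, tun)
  expect_equal(hw$W[1, 2], w0)
  expect_identical(hw$W, t(hw$W))
  # far-apart cells are unconnected
  m2 <- manual_map(2, rbind(c(0.3, 0.3), c(1.7, 1.7)), cell = c(1, 2),
                   n_cells = 2)
  expect_equal(hebbian_weights(m2, tun)$W[1, 2], 0)
  expect_true(all(hebbian_weights(m2, tun)$W >= 0))
})

test_that("on single-field maps the Hebbian kernel matches the optimal profile", {
  sf <- single_field_fixture()
  tun <- shared_tuning()
  hw <- hebbian_weights(sf$pfm, tun)
  od <- row(hw$W) != col(hw$W)
  # radial averages of both constructions agree closely
  d <- as.matrix(dist(sf$pfm$fields))
  bins <- round(d / 0.02) * 0.02
  sel <- od & d < 2 * bump_radius(sf$params)
  prof_o <- tapply(sf$weights$W[sel], bins[sel], mean)
  prof_h <- tapply(hw$W[sel], bins[sel], mean)
  expect_gt(cor(prof_o, prof_h), 0.95)
  # entrywise agreement is positive but noisier: the exact delta-rule
  # solution carries non-radial structure that radial averaging removes
  expect_gt(cor(hw$W[od], sf$weights$W[od]), 0.4)
})

test_that("incremental learning: one region reduces to the plain learner; Hebbian grows", {
  pfm <- tiny_map()
  params <- megamap_params()
  grid <- training_grid(pfm$env, 0.15)
  params$f_net <- net_activity_constant(pfm, grid, params)$f_net
  params$w_I <- calibrate_inhibition(5.3, 15, 8)
  params$b_pk <- 0.05
  cfg <- learning_config(spacing = 0.15, max_epochs = 60, embed_tol = 2e-3)
  inc <- incremental_learning(pfm, params, cfg, method = "optimal")
  expect_length(inc, 1)
  plain <- learn_optimal_weights(pfm, params, cfg, grid = grid)
  expect_equal(inc[[1]]$W, plain$W)
  # Hebbian: weights never decrease as regions accumulate
  cb <- comb_fixture()
  tun <- shared_tuning()
  h1 <- hebbian_weights(cb$pfm, tun, max_region = 1)$W
  h2 <- hebbian_weights(cb$pfm, tun, max_region = 2)$W
  h3 <- hebbian_weights(cb$pfm, tun, max_region = 3)$W
  expect_true(all(h2 - h1 >= -1e-12))
  expect_true(all(h3 - h2 >= -1e-12))
})
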