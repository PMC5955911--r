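test_that("field-density calibration inverts the Poisson zero class", {
  expect_equal(calibrate_field_density(0.8, 1), -log(0.8))
  expect_equal(calibrate_field_density(exp(-1), 1), 1)
  expect_equal(calibrate_field_density(0.8, 4), -log(0.8) / 4)
  expect_error(calibrate_field_density(0), "silent_fraction")
  expect_error(calibrate_field_density(1.2), "silent_fraction")
})

test_that("sampled maps hit the calibrated silent fraction and are reproducible", {
  env <- env_rect(1, 1, margin = 0.15)
  lam <- calibrate_field_density(0.8, 1)
  pfm <- sample_place_fields(env, 10000, lam, seed = 11)
  n_silent <- sum(pfm$counts == 0)
  ci <- qbinom(c(0.005, 0.995), 10000, 0.8)   # exact 99% binomial band
  expect_gte(n_silent, ci[1])
  expect_lte(n_silent, ci[2])
  # determinism
  pfm2 <- sample_place_fields(env, 10000, lam, seed = 11)
  expect_identical(pfm$fields, pfm2$fields)
  expect_identical(pfm$counts, pfm2$counts)
  # vanishing density silences everyone
  expect_true(all(sample_place_fields(env, 200, 1e-9, 1)$counts == 0))
})

test_that("training input follows the sum-of-Gaussians form", {
  x <- c(0.5, 0.5); sigma <- 0.1; b_pk <- 0.2
  m1 <- manual_map(1, rbind(x), cell = 1, n_cells = 3)
  b <- training_input(m1, x, b_pk = b_pk, sigma = sigma)
  expect_equal(b, c(b_pk, 0, 0))
  # two fields at distances sigma and 2 sigma
  m2 <- manual_map(1, rbind(x + c(sigma, 0), x + c(0, 2 * sigma)),
                   cell = c(1, 1), n_cells = 1)
  expect_equal(training_input(m2, x, b_pk = b_pk, sigma = sigma),
               b_pk * (exp(-0.5) + exp(-2)))
  expect_error(training_input(m1, x, b_pk = b_pk, sigma = -1), "sigma")
})

test_that("desired activity is a thresholded bump vanishing at the bump radius", {
  x <- c(0.5, 0.5); sigma <- 0.1; u0 <- 0.3; f_pk <- 15
  R <- bump_radius(sigma, u0 = u0)
  m <- manual_map(1.4, rbind(x, x + c(R + 1e-9, 0), x + c(R + 0.01, 0)),
                  cell = c(1, 2, 3), n_cells = 3)
  f <- desired_activity(m, x, sigma = sigma, u0 = u0, f_pk = f_pk)
  expect_equal(f[1], f_pk)
  expect_equal(f[2], 0)
  expect_equal(f[3], 0)
  # at exactly the radius the contribution crosses zero
  m_at <- manual_map(1.4, rbind(x + c(R, 0)), cell = 1, n_cells = 1)
  expect_equal(desired_activity(m_at, x, sigma = sigma, u0 = u0,
                                f_pk = f_pk)[1], 0, tolerance = 1e-12)
  expect_error(desired_activity(m, x, sigma = sigma, u0 = -1, f_pk = f_pk),
               "u0")
  # active set = cells with a field within R
  expect_equal(embedded_active_set(m, x, sigma = sigma, u0 = u0), 1L)
})

test_that("inputs and activity are radially symmetric about the probe", {
  x <- c(0.7, 0.7)
  pfm <- tiny_map()
  rot <- function(theta) matrix(c(cos(theta), sin(theta),
                                  -sin(theta), cos(theta)), 2)
  rotated <- sweep(pfm$fields, 2, x) %*% rot(1.1)
  pfm_rot <- megamapr:::new_place_field_map(pfm$env, pfm$n_cells, pfm$counts,
                                            sweep(rotated, 2, x, `+`),
                                            pfm$lambda, pfm$seed)
  expect_equal(training_input(pfm, x, b_pk = 1, sigma = 0.1),
               training_input(pfm_rot, x, b_pk = 1, sigma = 0.1))
  expect_equal(desired_activity(pfm, x, sigma = 0.1, u0 = 0.3, f_pk = 15),
               desired_activity(pfm_rot, x, sigma = 0.1, u0 = 0.3, f_pk = 15))
})

test_that("active cells receive supra-threshold input from their nearest field", {
  pfm <- tiny_map()
  x <- c(0.5, 0.5); sigma <- 0.1; u0 <- 0.3; b_pk <- 0.4
  f <- desired_activity(pfm, x, sigma = sigma, u0 = u0, f_pk = 15)
  b <- training_input(pfm, x, b_pk = b_pk, sigma = sigma)
  expect_true(all(b[f > 0] > u0 * b_pk / (1 + u0)))
})

test_that("net embedded activity is constant under normalization, near-constant raw", {
  env <- env_rect(2, 2, margin = 0.4)   # generous margin: no boundary truncation
  pfm <- sample_place_fields(env, 3000, 1, seed = 5)
  grid <- training_grid(env, 0.12)
  params <- megamap_params()
  nac <- net_activity_constant(pfm, grid, params)
  expect_lt(nac$cv, 0.1)
  params$f_net <- nac$f_net
  f <- desired_activity(pfm, c(1, 1), params)
  expect_equal(sum(f), params$f_net)
  # single cell, single field, probed at its center
  m1 <- manual_map(1, rbind(c(0.5, 0.5)), cell = 1, n_cells = 1)
  one <- net_activity_constant(m1, tibble::tibble(x = 0.5, y = 0.5),
                               sigma = 0.1, u0 = 0.3, f_pk = 15)
  expect_equal(one$f_net, 15)
  expect_warning(
    net_activity_constant(m1, tibble::tibble(x = 0.2, y = 0.2),
                          sigma = 0.01, u0 = 0.3, f_pk = 15), "zero")
})

test_that("place-field maps round-trip through JSON", {
  pfm <- tiny_map()
  path <- withr::local_tempfile(fileext = ".json")
  write_place_field_map(pfm, path)
  back <- read_place_field_map(path)
  expect_equal(back$fields, pfm$fields)
  expect_identical(back$counts, pfm$counts)
  expect_identical(back$seed, pfm$seed)
})
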