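# shared, lazily built objects: fixture training is the expensive step, so
# each named object is built once per test session
.cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .cache)) assign(key, builder(), envir = .cache)
  get(key, envir = .cache)
}

wta_fixture <- function() cached("wta_small", function() make_fixture("wta_small", seed = 1))
comb_fixture <- function() cached("comb_small", function() make_fixture("comb_small", seed = 1))
single_field_fixture <- function() cached("single_field", function() make_fixture("single_field", seed = 1))

shared_tuning <- function() cached("tuning", function()
  compute_tuning_curve(cfg = learning_config(spacing = 0.12, max_epochs = 300,
                                             embed_tol = 1.5e-3),
                       n_cells = 220, width = 1.2, seed = 2))

# small deterministic map for cheap unit tests
tiny_map <- function() cached("tiny_map", function() {
  env <- env_rect(1, 1, margin = 0.15)
  sample_place_fields(env, 60, 2, seed = 7)
})

# hand-built map: given field centers, one row per field
manual_map <- function(width, centers, cell = seq_len(nrow(centers)),
                       n_cells = max(cell), margin = 0.15) {
  env <- env_rect(width, width, margin = margin)
  ord <- order(cell)
  megamapr:::new_place_field_map(env, n_cells, tabulate(cell, nbins = n_cells),
                                 centers[ord, , drop = FALSE],
                                 lambda = NA_real_, seed = 0L)
}

fig4a_params <- function(q = 0.1) reduced_params(w0 = 1.2, q = q,
                                                 w_I_hat = 5.3, theta = 0.9)

# random parameter draws satisfying the reduced-model constraints
random_valid_params <- function(n, seed = 1) {
  withr::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      repeat {
        theta <- runif(1, 0.55, 0.95)
        w_I_hat <- runif(1, 1, 8)
        b_pk <- runif(1, 0.05, min(0.45, w_I_hat * (1 - theta) * 0.9))
        w0 <- 1 + w_I_hat * (1 - theta) - b_pk
        if (w0 <= 1) next
        q <- runif(1, 0, w_I_hat * (1 - theta) * 0.95)
        return(reduced_params(w0, q, w_I_hat, theta))
      }
    })
  })
}
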