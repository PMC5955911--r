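#' Deterministic small megamap fixtures
#'
#' Builds scaled-down trained megamaps that sit, verifiably, in a named
#' operational regime. The regime depends only on the attractor strength
#' `w0 - q`, so a desk-scale network reproduces it without full-size
#' geometry:
#'
#' * `"wta_small"`: a 1.6 m x 1.6 m map with sparse Poisson fields (little
#'   cross-excitation), trained in one pass; probe locations are chosen among
#'   grid points whose embedded bumps are pinned (single-bump `r < 1`) so the
#'   winner-take-all competition is exercised from stable bumps.
#' * `"comb_small"`: a 2.6 m x 2.6 m map with three concentric regions whose
#'   outer rings carry shared remote fields for pairs of cells from the two
#'   units ([add_shared_fields()]), learned incrementally; the later rings
#'   raise the cross-excitation `q` without reinforcing the inner region,
#'   driving the network into the combinatorial regime.
#' * `"single_field"`: every cell has exactly one field (the construction on
#'   which the optimal and Hebbian rules coincide); winner-take-all.
#'
#' Each fixture is verified against [classify_mode()] before being returned;
#' a verification failure is an error, never a silently shipped fixture.
#'
#' @param name Fixture name.
#' @param seed Integer seed controlling field placement.
#' @param cfg A [learning_config()]; the default trains on a 0.12 m grid.
#' @return A [megamap_network()] whose `meta` records the fixture name, seed,
#'   probe locations `x1`, `x2`, the verified `mode`, the stability indices,
#'   the reduced parameters, and (for `"comb_small"`) the per-region history
#'   `r_sequence` and the weight matrices `weights_by_region`.
#' @export
make_fixture <- function(name = c("wta_small", "comb_small", "single_field"),
                         seed = 1L,
                         cfg = learning_config(spacing = 0.12,
                                               max_epochs = 300,
                                               embed_tol = 1.5e-3)) {
  name <- match.arg(name)
  seed <- as.integer(seed)
  switch(name,
         wta_small = fixture_single_pass(seed, cfg, n_cells = 900,
                                         lambda = 0.5, name = name),
         single_field = fixture_single_pass(seed, cfg, n_cells = 320,
                                            lambda = NA, name = name),
         comb_small = fixture_incremental(seed, cfg))
}

# one-pass trained fixture on a 1.6 m square; WTA regime
fixture_single_pass <- function(seed, cfg, n_cells, lambda, name) {
  env <- env_rect(1.6, 1.6, margin = 0.15)
  if (name == "single_field") {
    xy <- withr::with_seed(seed, cbind(stats::runif(n_cells, 0, env$width),
                                       stats::runif(n_cells, 0, env$height)))
    pfm <- new_place_field_map(env, n_cells, rep(1L, n_cells), xy,
                               lambda = n_cells / (env$width * env$height),
                               seed = seed)
  } else {
    pfm <- sample_place_fields(env, n_cells, lambda, seed)
  }
  grid <- training_grid(env, cfg$spacing)
  params <- calibrate_fixture_params(pfm, grid)
  wts <- learn_optimal_weights(pfm, params, cfg, grid = grid)
  if (!wts$report$converged)
    warning(sprintf("fixture '%s': embedding not fully converged (worst residual %.3g)",
                    name, wts$report$worst_residual), call. = FALSE)
  pr <- select_probe_pair(wts$W, pfm, params, grid, prefer = "wta")
  mode <- classify_mode(wts, pfm, params, pr$x1, pr$x2)
  if (mode$mode != "WTA")
    stop(sprintf("fixture '%s' verification failed: expected WTA, got %s (r_union = %.3f)",
                 name, mode$mode, mode$r_union), call. = FALSE)
  rp <- reduce_megamap(wts, pfm, params, pr$x1, pr$x2)
  megamap_network(pfm, wts, params,
                  meta = fixture_meta(name, seed, pr, mode, rp))
}

# incremental shared-field fixture; combinatorial regime
fixture_incremental <- function(seed, cfg) {
  env <- env_rect(2.6, 2.6, margin = 0.15, region_fracs = c(0.45, 0.73, 1))
  x1 <- c(1.0, 1.3); x2 <- c(1.6, 1.3)
  pfm <- sample_place_fields(env, 900, 0.45, seed)
  p0 <- megamap_params()
  S1 <- embedded_active_set(pfm, x1, p0)
  S2 <- embedded_active_set(pfm, x2, p0)
  pfm <- add_shared_fields(pfm, setdiff(S1, S2), setdiff(S2, S1), 130,
                           region = 2, seed = seed + 20L)
  pfm <- add_shared_fields(pfm, setdiff(S1, S2), setdiff(S2, S1), 130,
                           region = 3, seed = seed + 21L)
  grid <- training_grid(env, cfg$spacing)
  params <- calibrate_fixture_params(pfm, grid, probes = rbind(x1, x2))
  wseq <- incremental_learning(pfm, params, cfg, method = "optimal")
  wts <- wseq[[length(wseq)]]
  sweep <- mode_vs_area_sweep(wseq, pfm, params, x1, x2)
  mode <- classify_mode(wts, pfm, params, x1, x2)
  if (mode$mode != "combinatorial")
    stop(sprintf("fixture 'comb_small' verification failed: expected combinatorial, got %s (r_union = %.3f)",
                 mode$mode, mode$r_union), call. = FALSE)
  rp <- reduce_megamap(wts, pfm, params, x1, x2)
  meta <- fixture_meta("comb_small", seed, list(x1 = x1, x2 = x2), mode, rp)
  meta$r_sequence <- sweep
  meta$weights_by_region <- wseq
  megamap_network(pfm, wts, params, meta = meta)
}

# shared calibration: f_net from the grid, inhibition from the mean
# active-set size, input peak from central probes (reduced strength 0.33)
calibrate_fixture_params <- function(pfm, grid, probes = NULL) {
  params <- megamap_params()
  params$f_net <- net_activity_constant(pfm, grid, params)$f_net
  idx <- seq(1, nrow(grid), by = 3)
  N_bar <- mean(purrr::map_int(idx, function(j)
    length(embedded_active_set(pfm, c(grid$x[j], grid$y[j]), params))))
  params$w_I <- calibrate_inhibition(5.3, params$f_pk, N_bar)
  if (is.null(probes)) {
    env <- pfm$env
    cen <- grid[abs(grid$x - env$center[1]) <= env$width / 4 &
                  abs(grid$y - env$center[2]) <= env$height / 4, ]
    probes <- cbind(cen$x, cen$y)[seq(1, nrow(cen), by = 5), , drop = FALSE]
  }
  params$b_pk <- calibrate_input_peak(pfm, probes, params, b_hat_pk = 0.33)
  params
}

# deterministic probe-pair choice among pinned (r < 1) interior grid bumps
select_probe_pair <- function(W, pfm, params, grid, prefer = c("wta", "comb"),
                              min_sep = 0.55) {
  prefer <- match.arg(prefer)
  env <- pfm$env
  interior <- grid$x >= env$margin + 0.3 & grid$x <= env$width - env$margin - 0.3 &
    grid$y >= env$margin + 0.3 & grid$y <= env$height - env$margin - 0.3
  cand <- which(interior)
  sets <- lapply(cand, function(j)
    embedded_active_set(pfm, c(grid$x[j], grid$y[j]), params))
  rs <- purrr::map_dbl(sets, ~ stability_index(W, params$w_I, params$f_pk, .x))
  keep <- which(rs < 0.97)
  if (length(keep) < 2)
    stop("fixture generation failed: fewer than two pinned bump locations",
         call. = FALSE)
  best <- NULL; best_val <- -Inf
  for (i in keep) for (j in keep) {
    if (j <= i) next
    d <- sqrt((grid$x[cand[i]] - grid$x[cand[j]])^2 +
                (grid$y[cand[i]] - grid$y[cand[j]])^2)
    if (d < min_sep) next
    if (length(intersect(sets[[i]], sets[[j]])) > 0.05 * length(sets[[i]])) next
    ru <- stability_index(W, params$w_I, params$f_pk,
                          union(sets[[i]], sets[[j]]))
    val <- if (prefer == "wta") ru else -ru
    if (val > best_val) { best_val <- val; best <- c(i, j) }
  }
  if (is.null(best))
    stop("fixture generation failed: no admissible probe pair", call. = FALSE)
  list(x1 = c(grid$x[cand[best[1]]], grid$y[cand[best[1]]]),
       x2 = c(grid$x[cand[best[2]]], grid$y[cand[best[2]]]))
}

fixture_meta <- function(name, seed, pr, mode, rp) {
  list(name = name, seed = seed, x1 = pr$x1, x2 = pr$x2,
       mode = mode$mode, r_union = mode$r_union, r1 = mode$r1, r2 = mode$r2,
       reduced = rp[c("w0", "q", "w_I_hat", "theta", "b_pk", "N_bar")])
}

#' Add shared remote fields to a place-field map
#'
#' Gives pairs of cells -- one from each of two cell sets -- a common field at
#' a random remote location. Cells with fields near two represented locations
#' and a shared field elsewhere are the substrate of cross-excitation between
#' embedded activity bumps: once the remote location is learned, the pair
#' becomes mutually excitatory, raising the reduced cross-weight `q` without
#' touching the within-unit structure. This emulates, in a small map, the
#' field multiplicity that large environments produce under Poisson sampling.
#'
#' @param pfm Base map.
#' @param S1,S2 Disjoint cell index sets (typically two embedded active sets).
#' @param n_pairs Number of shared-field pairs to add.
#' @param region Region index (or indices) of `pfm$env` in which the shared
#'   locations are placed.
#' @param seed Seed for pair sampling and placement.
#' @param buffer Keep shared locations at least this far (meters) outside the
#'   previous region's outer frame, so they are not touched before their
#'   region is learned (activity bumps straddle region boundaries).
#' @return A new `place_field_map` with `2 * n_pairs` extra fields.
#' @export
add_shared_fields <- function(pfm, S1, S2, n_pairs, region, seed = 1L,
                              buffer = 0.12) {
  env <- pfm$env
  stopifnot(length(intersect(S1, S2)) == 0, n_pairs >= 1,
            all(region >= 1), all(region <= env$n_regions))
  inner_ok <- function(z, k) {
    if (k == 1) return(TRUE)
    dx <- abs(z[1] - env$center[1]) - env$half_w[k - 1]
    dy <- abs(z[2] - env$center[2]) - env$half_h[k - 1]
    max(dx, dy) >= buffer
  }
  withr::with_seed(as.integer(seed), {
    a <- sample(S1, n_pairs, replace = TRUE)
    b <- sample(S2, n_pairs, replace = TRUE)
    zs <- matrix(NA_real_, n_pairs, 2)
    i <- 0; tries <- 0
    while (i < n_pairs) {
      tries <- tries + 1
      if (tries > 200000)
        stop("no admissible shared-field locations: the target region is too thin for the requested buffer and margin", call. = FALSE)
      z <- c(stats::runif(1, env$margin, env$width - env$margin),
             stats::runif(1, env$margin, env$height - env$margin))
      k <- region_of(env, z)
      if (k %in% region && inner_ok(z, k)) { i <- i + 1; zs[i, ] <- z }
    }
  })
  extra_cells <- as.vector(rbind(a, b))
  fields <- rbind(pfm$fields, zs[rep(seq_len(n_pairs), each = 2), , drop = FALSE])
  cell <- c(pfm$cell, extra_cells)
  ord <- order(cell)
  new_place_field_map(env, pfm$n_cells, tabulate(cell, nbins = pfm$n_cells),
                      fields[ord, , drop = FALSE], pfm$lambda, pfm$seed)
}
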