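#' Configuration for weight learning
#'
#' @param eta Normalized delta-rule step size in (0, 1]; the update applied for
#'   a pattern is scaled by `eta / ||f_bar||^2`, so `eta` is the fraction of a
#'   pattern's residual removed per visit.
#' @param max_epochs Maximum passes over the training grid.
#' @param embed_tol Convergence tolerance on the worst fixed-point residual
#'   (dimensionless, on the scale of `u`).
#' @param spacing Training-grid spacing in meters.
#' @param shuffle_seed Seed for the per-epoch shuffle of training locations.
#' @param zero_diag Constrain self-connections to zero (`TRUE`, the default):
#'   the delta rule is projected onto the no-autapse subspace. Without the
#'   constraint every pattern a cell joins deposits self-weight, which at
#'   small network sizes inflates the within-unit excitation and erodes the
#'   stability of previously embedded bumps during incremental learning.
#' @return An object of class `learning_config`.
#' @export
learning_config <- function(eta = 1, max_epochs = 500, embed_tol = 1e-3,
                            spacing = 0.05, shuffle_seed = 1L,
                            zero_diag = TRUE) {
  stopifnot(eta > 0, eta <= 1, max_epochs >= 1, embed_tol > 0, spacing > 0)
  structure(list(eta = eta, max_epochs = as.integer(max_epochs),
                 embed_tol = embed_tol, spacing = spacing,
                 shuffle_seed = as.integer(shuffle_seed),
                 zero_diag = isTRUE(zero_diag)),
            class = "learning_config")
}

new_megamap_weights <- function(W, method, report = list()) {
  asym <- norm(W - t(W), "F") / max(norm(W, "F"), .Machine$double.eps)
  structure(list(W = W, method = method, report = report, asymmetry = asym),
            class = "megamap_weights")
}

#' @export
print.megamap_weights <- function(x, ...) {
  cat(sprintf("<megamap_weights> %d x %d, method = %s, relative asymmetry %.2e\n",
              nrow(x$W), ncol(x$W), x$method, x$asymmetry))
  if (!is.null(x$report$converged))
    cat(sprintf("  training: %s after %d epoch(s), worst residual %.3g\n",
                if (x$report$converged) "converged" else "NOT converged",
                x$report$epochs, x$report$worst_residual))
  invisible(x)
}

# precompute the per-location training data used by the delta rule
pattern_set <- function(pfm, params, grid) {
  purrr::map(seq_len(nrow(grid)), function(j) {
    x <- c(grid$x[j], grid$y[j])
    f_bar <- desired_activity(pfm, x, params)
    S <- which(f_bar > 0)
    list(x = x, S = S, fS = f_bar[S],
         target_u = f_bar[S] / params$f_pk,
         b = training_input(pfm, x, params),
         inh = params$w_I *
           max(sum(f_bar) - params$theta * params$f_net, 0),
         norm2 = sum(f_bar[S]^2))
  })
}

# one delta-rule residual evaluation for a pattern (no update)
pattern_residual <- function(W, p) {
  drive <- drop(W[, p$S, drop = FALSE] %*% p$fS) - p$inh + p$b
  err <- -pmax(drive, 0)          # silent cells: push positive drive to <= 0
  err[p$S] <- p$target_u - drive[p$S]
  err
}

#' Learn optimal recurrent weights by delta-rule embedding
#'
#' Embeds the desired activity pattern at every training-grid location as a
#' fixed point of the dynamics under its training input. For cells active in a
#' pattern the fixed point pins `u_i = f_bar_i / f_pk`; for silent cells only
#' the inequality "net drive <= 0" is enforced, with perceptron-style updates
#' applied only on violation (sub-threshold values are otherwise free).
#'
#' @param pfm A [sample_place_fields()] map.
#' @param params [megamap_params()] with `w_I`, `b_pk` and `f_net` set.
#' @param cfg A [learning_config()].
#' @param grid Training locations (tibble with `x`, `y`); default
#'   `training_grid(pfm$env, cfg$spacing)`.
#' @param W_init Starting weight matrix (default zero); used for incremental
#'   learning.
#' @return A `megamap_weights` object with a convergence report (`converged`,
#'   `epochs`, `worst_residual`, and a per-epoch `history` tibble).
#' @export
learn_optimal_weights <- function(pfm, params, cfg = learning_config(),
                                  grid = NULL, W_init = NULL) {
  stopifnot(inherits(pfm, "place_field_map"))
  for (nm in c("w_I", "b_pk", "f_net"))
    if (!is.finite(params[[nm]]))
      stop(sprintf("`params$%s` must be set before learning", nm), call. = FALSE)
  if (is.null(grid)) grid <- training_grid(pfm$env, cfg$spacing)
  pats <- pattern_set(pfm, params, grid)
  pats <- pats[purrr::map_int(pats, ~ length(.x$S)) > 0]
  if (!length(pats))
    stop("no training location activates any cell; increase lambda or n_cells",
         call. = FALSE)
  N <- pfm$n_cells
  W <- if (is.null(W_init)) matrix(0, N, N) else W_init
  stopifnot(nrow(W) == N, ncol(W) == N)
  history <- numeric(0)
  worst <- Inf
  epochs <- 0L
  eta <- cfg$eta
  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- withr::with_seed(cfg$shuffle_seed + epoch, sample(length(pats)))
    worst <- 0
    for (j in ord) {
      p <- pats[[j]]
      # inlined residual: a function call on W would force a copy per update
      drive <- drop(W[, p$S, drop = FALSE] %*% p$fS) - p$inh + p$b
      err <- -pmax(drive, 0)
      err[p$S] <- p$target_u - drive[p$S]
      worst <- max(worst, max(abs(err)))
      rows <- which(err != 0)
      if (length(rows)) {
        W[rows, p$S] <- W[rows, p$S, drop = FALSE] +
          (eta / p$norm2) * tcrossprod(err[rows], p$fS)
        if (cfg$zero_diag) {
          both <- intersect(rows, p$S)
          if (length(both)) W[cbind(both, both)] <- 0
        }
      }
    }
    history <- c(history, worst)
    epochs <- epoch
    if (worst < cfg$embed_tol) break
  }
  new_megamap_weights(W, "optimal", list(
    converged = worst < cfg$embed_tol, epochs = epochs,
    worst_residual = worst, n_patterns = length(pats),
    history = tibble::tibble(epoch = seq_along(history), worst_residual = history)))
}

#' Summed squared embedding residual over a pattern set
#'
#' Diagnostic used to check delta-rule monotonicity: the sum over training
#' locations of the squared fixed-point residuals (equality residuals for
#' active cells, positive-drive violations for silent cells).
#'
#' @param W Weight matrix.
#' @param pfm,params,grid As in [learn_optimal_weights()].
#' @return Scalar.
#' @export
embedding_loss <- function(W, pfm, params, grid) {
  pats <- pattern_set(pfm, params, grid)
  sum(purrr::map_dbl(pats, function(p) {
    if (!length(p$S)) return(0)
    sum(pattern_residual(W, p)^2)
  }))
}

#' Radial weight tuning curve from single-field training
#'
#' Trains a synthetic network in which every cell has exactly one place field,
#' then radially averages the learned weights as a function of the distance
#' between field centers. The resulting profile is approximately Gaussian and
#' is the kernel used by [hebbian_weights()].
#'
#' @param params [megamap_params()]; `f_net` is measured internally on the
#'   synthetic map, and `w_I` / `b_pk`, if unset, are calibrated there (to a
#'   reduced inhibitory weight of 5.3 and a reduced training strength of
#'   0.33).
#' @param cfg A [learning_config()].
#' @param n_cells Number of single-field cells (default 250).
#' @param width Side of the square training environment in meters (default 1.2).
#' @param seed Seed for the synthetic field placement.
#' @param bin Radial bin width in meters (default 0.01).
#' @return An object of class `tuning_curve`: tibble `profile` (`r`, `w`,
#'   `n_pairs`), the support radius `r_max` (profile truncated where
#'   `|w| < 1e-4 * peak`), and the training report.
#' @export
compute_tuning_curve <- function(params = megamap_params(),
                                 cfg = learning_config(),
                                 n_cells = 250, width = 1.2, seed = 1L,
                                 bin = 0.01) {
  env <- env_rect(width, width, margin = params$sigma)
  xy <- withr::with_seed(seed, cbind(stats::runif(n_cells, 0, width),
                                     stats::runif(n_cells, 0, width)))
  pfm <- new_place_field_map(env, n_cells, rep(1L, n_cells), xy,
                             lambda = n_cells / width^2, seed = seed)
  grid <- training_grid(env, cfg$spacing)
  nac <- net_activity_constant(pfm, grid, params)
  params$f_net <- nac$f_net
  if (!is.finite(params$w_I)) {
    N_bar <- mean(purrr::map_int(seq(1, nrow(grid), by = 3), function(j)
      length(embedded_active_set(pfm, c(grid$x[j], grid$y[j]), params))))
    params$w_I <- calibrate_inhibition(5.3, params$f_pk, N_bar)
  }
  if (!is.finite(params$b_pk)) {
    cen <- grid[abs(grid$x - width / 2) <= width / 4 &
                  abs(grid$y - width / 2) <= width / 4, ]
    params$b_pk <- calibrate_input_peak(
      pfm, cbind(cen$x, cen$y)[seq(1, nrow(cen), by = 5), , drop = FALSE],
      params, b_hat_pk = 0.33)
  }
  wts <- learn_optimal_weights(pfm, params, cfg, grid = grid)
  d <- as.matrix(stats::dist(xy))
  rb <- round(d / bin) * bin
  offdiag <- row(d) != col(d)   # self-connections are constrained, not learned
  prof <- tibble::tibble(r = rb[offdiag], w = wts$W[offdiag]) |>
    dplyr::group_by(.data$r) |>
    dplyr::summarise(n_pairs = dplyr::n(), w = mean(.data$w)) |>
    dplyr::arrange(.data$r)
  peak <- max(abs(prof$w))
  keep <- which(abs(prof$w) >= 1e-4 * peak)
  r_max <- prof$r[max(keep)]
  structure(list(profile = prof[prof$r <= r_max, c("r", "w", "n_pairs")],
                 r_max = r_max, bin = bin, report = wts$report,
                 f_net = nac$f_net),
            class = "tuning_curve")
}

#' Evaluate a tuning curve at given distances
#'
#' Linear interpolation of the tabulated radial profile; zero beyond its
#' support.
#'
#' @param tuning A [compute_tuning_curve()] object.
#' @param d Distances in meters.
#' @param clamp If `TRUE` (the Hebbian convention), negative interpolated
#'   values are clamped to zero.
#' @return Numeric vector of weights.
#' @export
tuning_value <- function(tuning, d, clamp = FALSE) {
  stopifnot(inherits(tuning, "tuning_curve"))
  w <- stats::approx(tuning$profile$r, tuning$profile$w, xout = d,
                     yleft = tuning$profile$w[1], yright = 0, rule = 2)$y
  w[d > tuning$r_max] <- 0
  if (clamp) w <- pmax(w, 0)
  w
}

#' @export
print.tuning_curve <- function(x, ...) {
  cat(sprintf("<tuning_curve> peak %.3g at r = 0, support %.2f m (%d bins)\n",
              max(x$profile$w), x$r_max, nrow(x$profile)))
  invisible(x)
}

#' Hebbian weight matrix from summed tuning curves
#'
#' `W[j, k] = sum_m sum_n w_tune(|c_jm - c_kn|)` over all field pairs of cells
#' `j` and `k`. Exactly symmetric; diagonal entries include cross-field self
#' terms. The tuning curve is clamped at zero (its positive, approximately
#' Gaussian lobe), so weights are nonnegative and grow additively as fields
#' are added.
#'
#' @param pfm Place-field map.
#' @param tuning A [compute_tuning_curve()] object.
#' @param max_region If given, only field pairs whose later-learned member is
#'   in a region `<= max_region` contribute (incremental learning).
#' @return A `megamap_weights` object with method `"hebbian"`.
#' @export
hebbian_weights <- function(pfm, tuning, max_region = NULL) {
  N <- pfm$n_cells
  Fn <- nrow(pfm$fields)
  if (Fn == 0) return(new_megamap_weights(matrix(0, N, N), "hebbian"))
  V <- tuning_value(tuning, as.matrix(stats::dist(pfm$fields)), clamp = TRUE)
  V <- matrix(V, Fn, Fn)
  if (!is.null(max_region)) {
    reg <- region_of(pfm$env, pfm$fields)
    keep <- reg <= max_region
    V[!keep, ] <- 0
    V[, !keep] <- 0
  }
  A <- matrix(0, N, Fn)
  A[cbind(pfm$cell, seq_len(Fn))] <- 1
  W <- A %*% V %*% t(A)
  W <- (W + t(W)) / 2   # numerically exact symmetry
  new_megamap_weights(W, "hebbian")
}

#' Incremental region-by-region learning
#'
#' Mimics an animal learning a growing environment: at iteration `k` only
#' training locations in region `k` are used. For optimal weights the delta
#' rule continues from the previous matrix without revisiting earlier regions;
#' for Hebbian weights the tuning-curve terms of newly learned field pairs are
#' added.
#'
#' @param pfm Place-field map whose environment has `n_regions > 1`.
#' @param params,cfg As in [learn_optimal_weights()].
#' @param method `"optimal"` or `"hebbian"`.
#' @param tuning Tuning curve (required for `"hebbian"`).
#' @return A list of `megamap_weights`, one per region (cumulative).
#' @export
incremental_learning <- function(pfm, params, cfg = learning_config(),
                                 method = c("optimal", "hebbian"),
                                 tuning = NULL) {
  method <- match.arg(method)
  env <- pfm$env
  stopifnot(env$n_regions >= 1)
  grid <- training_grid(env, cfg$spacing)
  out <- vector("list", env$n_regions)
  if (method == "optimal") {
    W <- NULL
    for (k in seq_len(env$n_regions)) {
      gk <- grid[grid$region == k, ]
      wts <- learn_optimal_weights(pfm, params, cfg, grid = gk, W_init = W)
      wts$report$region <- k
      W <- wts$W
      out[[k]] <- wts
    }
  } else {
    if (is.null(tuning)) stop("`tuning` is required for Hebbian learning",
                              call. = FALSE)
    for (k in seq_len(env$n_regions)) {
      wts <- hebbian_weights(pfm, tuning, max_region = k)
      wts$report$region <- k
      out[[k]] <- wts
    }
  }
  out
}
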