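#' Bundle a megamap network
#'
#' A trained network: place-field map, recurrent weights, parameters, and
#' free-form metadata (provenance, expected operational mode, seeds).
#'
#' @param pfm A [sample_place_fields()] map.
#' @param weights A `megamap_weights` object (or bare matrix).
#' @param params A [megamap_params()] object.
#' @param meta Named list of metadata.
#' @return An object of class `megamap_network`.
#' @export
megamap_network <- function(pfm, weights, params, meta = list()) {
  if (is.matrix(weights)) weights <- new_megamap_weights(weights, "unknown")
  stopifnot(inherits(pfm, "place_field_map"),
            inherits(weights, "megamap_weights"),
            inherits(params, "megamap_params"),
            nrow(weights$W) == pfm$n_cells)
  structure(list(pfm = pfm, weights = weights, params = params, meta = meta),
            class = "megamap_network")
}

#' @export
print.megamap_network <- function(x, ...) {
  cat(sprintf("<megamap_network> %d cells, %s weights", x$pfm$n_cells,
              x$weights$method))
  if (!is.null(x$meta$mode)) cat(sprintf(", %s regime", x$meta$mode))
  cat("\n")
  invisible(x)
}

serialization_version <- "megamapr/1"

#' Write / read a place-field map as JSON
#'
#' Portable plain-text serialization with a version tag and the sampling seed
#' recorded.
#'
#' @param pfm Map to write.
#' @param path File path.
#' @return `write_place_field_map()` returns `path` invisibly;
#'   `read_place_field_map()` returns the map.
#' @export
write_place_field_map <- function(pfm, path) {
  obj <- list(version = serialization_version, type = "place_field_map",
              n_cells = pfm$n_cells, counts = pfm$counts,
              fields = pfm$fields, lambda = pfm$lambda, seed = pfm$seed,
              env = list(width = pfm$env$width, height = pfm$env$height,
                         margin = pfm$env$margin,
                         n_regions = pfm$env$n_regions))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_place_field_map
#' @export
read_place_field_map <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  stopifnot(identical(obj$type, "place_field_map"))
  env <- env_rect(obj$env$width, obj$env$height, obj$env$margin,
                  obj$env$n_regions)
  fields <- matrix(as.numeric(obj$fields), ncol = 2)
  new_place_field_map(env, obj$n_cells, obj$counts, fields, obj$lambda,
                      obj$seed)
}

#' Write / read a full network bundle as JSON
#'
#' One structured text file holding the field map, weight matrix (with its
#' provenance tag), parameters and metadata.
#'
#' @param net A [megamap_network()].
#' @param path File path.
#' @return `write_megamap_network()` returns `path` invisibly;
#'   `read_megamap_network()` returns the network.
#' @export
write_megamap_network <- function(net, path) {
  p <- net$params
  obj <- list(version = serialization_version, type = "megamap_network",
              pfm = list(n_cells = net$pfm$n_cells, counts = net$pfm$counts,
                         fields = net$pfm$fields, lambda = net$pfm$lambda,
                         seed = net$pfm$seed,
                         env = list(width = net$pfm$env$width,
                                    height = net$pfm$env$height,
                                    margin = net$pfm$env$margin,
                                    n_regions = net$pfm$env$n_regions)),
              W = net$weights$W, method = net$weights$method,
              params = list(tau = p$tau, f_pk = p$f_pk, w_I = p$w_I,
                            theta = p$theta, sigma = p$sigma, u0 = p$u0,
                            b_pk = p$b_pk, f_net = p$f_net,
                            normalize_net = p$normalize_net),
              meta = net$meta)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_megamap_network
#' @export
read_megamap_network <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  stopifnot(identical(obj$type, "megamap_network"))
  env <- env_rect(obj$pfm$env$width, obj$pfm$env$height, obj$pfm$env$margin,
                  obj$pfm$env$n_regions)
  pfm <- new_place_field_map(env, obj$pfm$n_cells, obj$pfm$counts,
                             matrix(as.numeric(obj$pfm$fields), ncol = 2),
                             obj$pfm$lambda, obj$pfm$seed)
  p <- obj$params
  params <- megamap_params(tau = p$tau, f_pk = p$f_pk, w_I = p$w_I,
                           theta = p$theta, sigma = p$sigma, u0 = p$u0,
                           b_pk = p$b_pk, f_net = p$f_net,
                           normalize_net = isTRUE(p$normalize_net))
  W <- matrix(as.numeric(obj$W), nrow = obj$pfm$n_cells)
  megamap_network(pfm, new_megamap_weights(W, obj$method),
                  params, as.list(obj$meta))
}
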