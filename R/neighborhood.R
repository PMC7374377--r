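#' Neighbourhood system on the pixel grid
#'
#' Describes the square sliding window used by all spatial operators: side
#' length `window`, the `window^2` offsets of the block centred on each pixel
#' (centre included, so `n_i = 25` for the default 5x5 window) and replicate
#' padding at the image border, which gives every pixel a full window.
#'
#' @param window odd window side length (3, 5 or 7).
#' @return list of class `nbr_system` with `window`, `offsets` (n_i x 2 matrix
#'   of (dr, dc)), and `n_i`.
#' @export
nbr_system <- function(window = 5L) {
  window <- as.integer(window)
  stopifnot(window %in% c(3L, 5L, 7L))
  r <- (window - 1L) %/% 2L
  offsets <- as.matrix(expand.grid(dr = -r:r, dc = -r:r))
  structure(
    list(window = window, offsets = offsets, n_i = window^2L),
    class = "nbr_system"
  )
}

#' Windowed sum with replicate padding
#'
#' Sum of the w x w window centred on each pixel (centre included).  Border
#' pixels see the nearest-edge values replicated outward, so every window has
#' exactly `w^2` terms.  This is the single primitive behind the neighbourhood
#' weights, the smoothing factor and the window-mean feature.
#'
#' @param m numeric matrix.
#' @param window odd window side length.
#' @return matrix of the same shape as `m`.
#' @export
box_filter_sum <- function(m, window) {
  stopifnot(is.matrix(m), window %% 2L == 1L, window >= 1L)
  r <- (window - 1L) %/% 2L
  if (r == 0L) return(m)
  H <- nrow(m); W <- ncol(m)
  ri <- c(rep(1L, r), seq_len(H), rep(H, r))
  ci <- c(rep(1L, r), seq_len(W), rep(W, r))
  pad <- m[ri, ci, drop = FALSE]
  out <- matrix(0, H, W)
  for (dr in 0:(2L * r)) {
    for (dc in 0:(2L * r)) {
      out <- out + pad[(1L + dr):(H + dr), (1L + dc):(W + dc), drop = FALSE]
    }
  }
  out
}

#' Neighbourhood class-likelihood weights
#'
#' For every pixel i, class j and feature l, the window sum of the class-j
#' Gaussian likelihood of the neighbouring feature values, raised to the
#' exponent `alpha`:
#' `h_ijl = ( sum_{t in N_i} Phi(x_tl | mu_jl, sigma_jl^2) )^alpha`.
#' Implemented as a replicate-padded box filter over the per-pixel likelihood
#' image; the result is floored at `1e-300` so downstream normalisations stay
#' finite even where every class underflows.
#'
#' @param features a [pixel_features()] object.
#' @param params `cluster_params` list (see [fcm_initialize()]).
#' @param sys a [nbr_system()].
#' @param alpha positive exponent on the windowed likelihood sum.
#' @return N x C x D array of positive weights.
#' @export
neighbor_class_weights <- function(features, params, sys, alpha = 2) {
  v <- features$values
  gs <- features$grid_shape
  C <- nrow(params$mu); D <- ncol(params$mu)
  h <- array(0, dim = c(nrow(v), C, D))
  for (j in seq_len(C)) {
    for (l in seq_len(D)) {
      lik <- exp(gaussian_log_pdf(v[, l], params$mu[j, l], params$sigma2[j, l]))
      lik_img <- matrix(lik, gs[1], gs[2])
      h[, j, l] <- pmax(as.vector(box_filter_sum(lik_img, sys$window))^alpha,
                        1e-300)
    }
  }
  h
}

#' Markov spatial prior from neighbourhood weights
#'
#' Feature-summed, class-normalised neighbourhood weights:
#' `pi_ij = sum_l h_ijl / sum_k sum_l h_ikl`.  Rows sum to one; positivity of
#' `h` guarantees a valid normaliser.
#'
#' @param h N x C x D array from [neighbor_class_weights()].
#' @return N x C matrix of per-pixel class priors.
#' @export
markov_prior <- function(h) {
  stopifnot(is.array(h), length(dim(h)) == 3L)
  if (dim(h)[3] == 1L) {
    hm <- h[, , 1, drop = TRUE]
  } else {
    hm <- rowSums(h, dims = 2)
  }
  hm <- matrix(hm, nrow = dim(h)[1], ncol = dim(h)[2])
  hm / rowSums(hm)
}

#' Noise smoothing factor
#'
#' `G_ij = exp( beta / (2 n_i) * sum_{t in N_i} (z_tj + h_tj) )`, where `h`
#' is the class-normalised neighbourhood weight ([markov_prior()] output).
#' Each bracketed term lies in `[0, 2]`, so `G` is bounded in
#' `[1, exp(beta)]`.  The factor inflates the prior of classes that dominate
#' the local window, which is what suppresses isolated noise pixels.
#'
#' @param z N x C membership matrix.
#' @param h_norm N x C class-normalised neighbourhood weights.
#' @param sys a [nbr_system()].
#' @param beta positive smoothing weight.
#' @param grid_shape `c(H, W)` pixel grid geometry.
#' @return N x C matrix with entries in `[1, exp(beta)]`.
#' @export
smoothing_factor <- function(z, h_norm, sys, beta, grid_shape) {
  stopifnot(all(dim(z) == dim(h_norm)))
  G <- matrix(0, nrow(z), ncol(z))
  for (j in seq_len(ncol(z))) {
    fld <- matrix(z[, j] + h_norm[, j], grid_shape[1], grid_shape[2])
    G[, j] <- exp(beta / (2 * sys$n_i) * as.vector(box_filter_sum(fld, sys$window)))
  }
  G
}

#' Combined prior from memberships and smoothing factors
#'
#' `pi_ij = (z_ij + G_ij) / sum_k (z_ik + G_ik)`; the prior used by the
#' membership update of the improved algorithm.  Rows sum to one.
#'
#' @param z N x C membership matrix.
#' @param G N x C smoothing factors (each at least 1).
#' @return N x C prior matrix.
#' @export
combined_prior <- function(z, G) {
  stopifnot(all(dim(z) == dim(G)))
  w <- z + G
  w / rowSums(w)
}
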