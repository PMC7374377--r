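#' Fuzzy C-means initialisation
#'
#' Runs standard fuzzy C-means (via [e1071::cmeans()]) on the feature matrix
#' and converts the result into the model's starting state: memberships `z`
#' from FCM, class means and variances as `z`-weighted moments, background
#' Gaussians from the global per-feature moments, saliency priors
#' `rho_l = 1/D` (clipped), saliency memberships `s = 1/2` and a uniform
#' prior `pi = 1/C`.  Cluster centres are initialised from `config$seed` by
#' sampling C distinct feature rows.
#'
#' @param features a [pixel_features()] object with at least C pixels.
#' @param config a [seg_config()].
#' @return list with elements `params` (a `cluster_params` list: `mu`,
#'   `sigma2` C x D; `eps`, `nu2`, `rho` length D) and `state` (a
#'   `membership_state` list: `z`, `pi`, `G` N x C; `s` N x C x D).
#' @export
fcm_initialize <- function(features, config) {
  v <- features$values
  N <- nrow(v); D <- ncol(v); C <- config$C
  stopifnot(N >= C)
  rng <- apply(v, 2, function(col) diff(range(col)))
  if (any(rng == 0)) {
    stop(sprintf("degenerate input: feature %d ('%s') is constant across all pixels",
                 which(rng == 0)[1],
                 colnames(v)[which(rng == 0)[1]]), call. = FALSE)
  }
  uv <- unique(v)
  if (nrow(uv) < C) {
    stop(sprintf("only %d distinct feature vectors for C = %d clusters",
                 nrow(uv), C), call. = FALSE)
  }

  if (C == 1L) {
    z <- matrix(1, N, 1L)
  } else {
    set.seed(config$seed)
    centers <- uv[sample.int(nrow(uv), C), , drop = FALSE]
    fit <- e1071::cmeans(v, centers = centers, iter.max = 100L,
                         method = "cmeans", m = config$fcm_fuzzifier)
    z <- fit$membership
  }

  mu <- matrix(0, C, D); sigma2 <- matrix(0, C, D)
  for (j in seq_len(C)) {
    w <- z[, j]; M <- sum(w)
    for (l in seq_len(D)) {
      mu[j, l] <- sum(w * v[, l]) / M
      sigma2[j, l] <- max(sum(w * (v[, l] - mu[j, l])^2) / M,
                          config$variance_floor)
    }
  }
  eps <- colMeans(v)
  nu2 <- pmax(colMeans(sweep(v, 2, eps)^2), config$variance_floor)
  rho <- pmin(pmax(rep(1 / D, D), config$rho_floor), 1 - config$rho_floor)

  params <- list(mu = mu, sigma2 = sigma2, eps = eps, nu2 = nu2, rho = rho)
  state <- list(
    z = z,
    s = array(0.5, dim = c(N, C, D)),
    pi = matrix(1 / C, N, C),
    G = matrix(1, N, C)
  )
  list(params = params, state = state)
}

#' Plain fuzzy C-means segmentation (baseline)
#'
#' Segments an image with standard fuzzy C-means on the same features the
#' main model uses, with no spatial information.  Serves as the reference
#' method in noise-robustness comparisons and shares the centre
#' initialisation of [fcm_initialize()].
#'
#' @param image numeric H x W matrix of grey levels in `[0, 255]`.
#' @param C number of clusters.
#' @param seed integer seed for centre initialisation.
#' @param fuzzifier FCM fuzzifier `m > 1`.
#' @return list with `labels` (H x W integer matrix, values `0..C-1`,
#'   per-pixel membership argmax with ties to the lowest class), `centers`
#'   (C x D matrix) and `membership` (N x C).
#' @export
fcm_segment <- function(image, C, seed = 1L, fuzzifier = 2) {
  config <- seg_config(C = C, seed = seed, fcm_fuzzifier = fuzzifier)
  features <- pixel_features(image)
  init <- fcm_initialize(features, config)
  lab <- max.col(init$state$z, ties.method = "first") - 1L
  list(
    labels = matrix(lab, features$grid_shape[1], features$grid_shape[2]),
    centers = init$params$mu,
    membership = init$state$z
  )
}
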