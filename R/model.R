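#' Log density of the univariate normal
#'
#' All per-class and background densities in the model go through this one
#' routine and are handled in log space; densities are only exponentiated
#' where a linear-scale quantity (e.g. a windowed likelihood sum) is needed.
#'
#' @param x numeric vector of feature values; must be finite.
#' @param mean scalar mean.
#' @param var scalar variance, at least the variance floor of the caller.
#' @return numeric vector of log densities.
#' @export
#' @examples
#' gaussian_log_pdf(0, 0, 1 / (2 * pi)) # exactly 0: density 1
gaussian_log_pdf <- function(x, mean, var) {
  if (any(!is.finite(x)) || !is.finite(mean) || !is.finite(var)) {
    stop("non-finite input to gaussian_log_pdf: corrupt feature values",
         call. = FALSE)
  }
  stopifnot(var > 0)
  -0.5 * log(2 * pi * var) - (x - mean)^2 / (2 * var)
}

# N x C x D array of class log densities and N x D matrix of background log
# densities for a feature matrix; small C and D keep the loops cheap.
log_density_arrays <- function(features, params) {
  v <- features$values
  C <- nrow(params$mu); D <- ncol(params$mu); N <- nrow(v)
  lc <- array(0, dim = c(N, C, D))
  lb <- matrix(0, N, D)
  for (l in seq_len(D)) {
    for (j in seq_len(C)) {
      lc[, j, l] <- gaussian_log_pdf(v[, l], params$mu[j, l], params$sigma2[j, l])
    }
    lb[, l] <- gaussian_log_pdf(v[, l], params$eps[l], params$nu2[l])
  }
  list(class = lc, background = lb)
}

#' Saliency membership update
#'
#' Posterior probability that feature l is informative (salient) for pixel i
#' under class j, with both the class and the background likelihood tempered
#' by the exponent `1/gamma`:
#' `s_ijl = rho_l Phi_jl^(1/gamma) /
#'          (rho_l Phi_jl^(1/gamma) + (1 - rho_l) Phi_l^(1/gamma))`.
#' Computed in log space and clipped to `[1e-10, 1 - 1e-10]`.
#'
#' @param features a [pixel_features()] object.
#' @param params `cluster_params` list.
#' @param config a [seg_config()].
#' @return N x C x D array of saliency memberships in (0, 1).
#' @export
update_saliency <- function(features, params, config) {
  ld <- log_density_arrays(features, params)
  C <- nrow(params$mu); D <- ncol(params$mu); N <- nrow(features$values)
  s <- array(0, dim = c(N, C, D))
  for (l in seq_len(D)) {
    b <- log1p(-params$rho[l]) + ld$background[, l] / config$gamma
    for (j in seq_len(C)) {
      a <- log(params$rho[l]) + ld$class[, j, l] / config$gamma
      s[, j, l] <- stats::plogis(a - b)
    }
  }
  pmin(pmax(s, 1e-10), 1 - 1e-10)
}

#' Saliency-weighted dissimilarity
#'
#' The per-pixel, per-class cost
#' `d_ij = sum_l ( -s_ijl log Phi(x_il | mu_jl, sigma_jl^2)
#'                 - (1 - s_ijl) log Phi(x_il | eps_l, nu_l^2) )`,
#' i.e. the negative log likelihood with each feature's contribution split
#' between its class-specific and background Gaussian according to the
#' saliency membership.
#'
#' @inheritParams update_saliency
#' @param s N x C x D saliency membership array.
#' @return N x C matrix of dissimilarities.
#' @export
dissimilarity <- function(features, params, s) {
  ld <- log_density_arrays(features, params)
  C <- nrow(params$mu); D <- ncol(params$mu)
  d <- matrix(0, nrow(features$values), C)
  for (l in seq_len(D)) {
    for (j in seq_len(C)) {
      d[, j] <- d[, j] -
        s[, j, l] * ld$class[, j, l] -
        (1 - s[, j, l]) * ld$background[, l]
    }
  }
  d
}

#' Saliency KL penalty
#'
#' `K_ij = sum_l ( s_ijl log(s_ijl / rho_l)
#'                 + (1 - s_ijl) log((1 - s_ijl) / (1 - rho_l)) )`,
#' the Bernoulli KL divergence of the saliency memberships from their prior,
#' summed over features.  Enters the membership update and the objective with
#' weight `gamma`.
#'
#' @param s N x C x D saliency membership array.
#' @param rho length-D saliency prior vector.
#' @return N x C matrix.
#' @export
saliency_kl <- function(s, rho) {
  C <- dim(s)[2]; D <- dim(s)[3]
  K <- matrix(0, dim(s)[1], C)
  for (l in seq_len(D)) {
    for (j in seq_len(C)) {
      sl <- s[, j, l]
      K[, j] <- K[, j] + sl * log(sl / rho[l]) +
        (1 - sl) * log((1 - sl) / (1 - rho[l]))
    }
  }
  K
}

#' Classification membership update
#'
#' Stationarity solution of the KL-regularised objective with the prior and
#' smoothing factor held fixed (ICM-style block treatment of `G`):
#' `z_ij` proportional to `pi_ij * exp(-(d_ij + gamma K_ij) / lambda)`,
#' normalised over classes per pixel.  Computed with a per-pixel log-sum-exp
#' shift so that even pixels whose every class weight underflows keep a valid
#' membership row.
#'
#' @param d N x C dissimilarity matrix.
#' @param K N x C saliency KL penalty.
#' @param pi N x C prior matrix with unit row sums.
#' @param config a [seg_config()].
#' @return N x C membership matrix with unit row sums.
#' @export
update_membership <- function(d, K, pi, config) {
  logw <- log(pmax(pi, 1e-300)) - (d + config$gamma * K) / config$lam
  logw <- logw - apply(logw, 1, max)
  w <- exp(logw)
  w / rowSums(w)
}

#' Class mean and variance update
#'
#' Weighted moments with weights `z_ij * s_ijl`:
#' `mu_jl = sum_i z_ij s_ijl x_il / M_jl`,
#' `sigma_jl^2 = sum_i z_ij s_ijl (x_il - mu_jl)^2 / M_jl`,
#' `M_jl = sum_i z_ij s_ijl`.  Variances are floored at
#' `config$variance_floor`.  A class-feature pair whose weight mass `M_jl`
#' falls below `1e-12` keeps its previous parameters and a warning is raised
#' (empty-cluster guard).
#'
#' @inheritParams update_saliency
#' @param z N x C membership matrix.
#' @param s N x C x D saliency array.
#' @return list with updated `mu` and `sigma2` (both C x D).
#' @export
update_class_params <- function(features, z, s, params, config) {
  v <- features$values
  C <- nrow(params$mu); D <- ncol(params$mu)
  mu <- params$mu; sigma2 <- params$sigma2
  for (j in seq_len(C)) {
    for (l in seq_len(D)) {
      w <- z[, j] * s[, j, l]
      M <- sum(w)
      if (M < 1e-12) {
        warning(sprintf("empty cluster guard: class %d, feature %d keeps its parameters", j, l),
                call. = FALSE)
        next
      }
      mu[j, l] <- sum(w * v[, l]) / M
      sigma2[j, l] <- max(sum(w * (v[, l] - mu[j, l])^2) / M,
                          config$variance_floor)
    }
  }
  list(mu = mu, sigma2 = sigma2)
}

#' Background (non-salient) parameter update
#'
#' Weighted global moments with weights `z_ij (1 - s_ijl)` summed over
#' classes:
#' `eps_l = sum_ij z_ij (1 - s_ijl) x_il / F_l`,
#' `nu_l^2 = sum_ij z_ij (1 - s_ijl) (x_il - eps_l)^2 / F_l`,
#' `F_l = sum_ij z_ij (1 - s_ijl)`.  Variances floored; a feature whose
#' weight mass vanishes keeps its previous values with a warning.
#'
#' @inheritParams update_class_params
#' @return list with updated `eps` and `nu2` (both length D).
#' @export
update_background_params <- function(features, z, s, params, config) {
  v <- features$values
  C <- nrow(params$mu); D <- ncol(params$mu)
  eps <- params$eps; nu2 <- params$nu2
  for (l in seq_len(D)) {
    w <- rowSums(z * (1 - s[, , l, drop = TRUE]))
    if (ncol(z) == 1L) w <- z[, 1] * (1 - s[, 1, l])
    F_l <- sum(w)
    if (F_l < 1e-12) {
      warning(sprintf("empty background guard: feature %d keeps its parameters", l),
              call. = FALSE)
      next
    }
    eps[l] <- sum(w * v[, l]) / F_l
    nu2[l] <- max(sum(w * (v[, l] - eps[l])^2) / F_l, config$variance_floor)
  }
  list(eps = eps, nu2 = nu2)
}

#' Saliency prior update
#'
#' `rho_l = (1/N) sum_ij z_ij s_ijl`, clipped to
#' `[rho_floor, 1 - rho_floor]`.  Because membership rows sum to one this is
#' the mean saliency of feature l across pixels.
#'
#' @param z N x C membership matrix with unit row sums.
#' @param s N x C x D saliency array.
#' @param rho_floor clipping bound.
#' @return length-D vector of saliency priors.
#' @export
update_saliency_prior <- function(z, s, rho_floor = 1e-3) {
  D <- dim(s)[3]
  rho <- numeric(D)
  for (l in seq_len(D)) {
    zs <- z * matrix(s[, , l], nrow(z), ncol(z))
    rho[l] <- sum(zs) / nrow(z)
  }
  pmin(pmax(rho, rho_floor), 1 - rho_floor)
}

#' Objective function of the regularised model
#'
#' `J = sum_ij z_ij d_ij
#'      + lambda sum_ij ( z_ij log(z_ij / pi_ij) + G_ij log(G_ij / pi_ij) )
#'      + gamma sum_ij z_ij K_ij`
#' with the conventions `0 log 0 = 0` and log arguments clipped at `1e-300`.
#'
#' @inheritParams update_saliency
#' @param state list with elements `z`, `s`, `pi`, `G` (a `membership_state`).
#' @return scalar objective value.
#' @export
objective <- function(features, params, state, config) {
  d <- dissimilarity(features, params, state$s)
  K <- saliency_kl(state$s, params$rho)
  zt <- state$z * log(pmax(state$z, 1e-300) / pmax(state$pi, 1e-300))
  zt[state$z == 0] <- 0
  Gt <- state$G * log(pmax(state$G, 1e-300) / pmax(state$pi, 1e-300))
  sum(state$z * d) + config$lam * sum(zt + Gt) + config$gamma * sum(state$z * K)
}
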