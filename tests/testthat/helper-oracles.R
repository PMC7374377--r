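# Independent oracles and small fixture builders shared across the suite.
# Oracles are deliberately naive (explicit loops, grid search) so that they
# stay independent of the vectorised implementation paths they check.

# Replicate-padded windowed sum by explicit nested loops.
naive_box_sum <- function(m, window) {
  r <- (window - 1L) %/% 2L
  H <- nrow(m); W <- ncol(m)
  out <- matrix(0, H, W)
  for (i in seq_len(H)) {
    for (j in seq_len(W)) {
      acc <- 0
      for (dr in -r:r) {
        for (dc in -r:r) {
          acc <- acc + m[min(max(i + dr, 1L), H), min(max(j + dc, 1L), W)]
        }
      }
      out[i, j] <- acc
    }
  }
  out
}

# Feature object over a small image given as a numeric matrix.
feat_of <- function(img) pixel_features(img, type = "intensity")

# Random but reproducible model fixtures on n pixels, C classes, D features.
rand_instance <- function(n, C, D = 1L, seed = 42L) {
  set.seed(seed)
  side <- ceiling(sqrt(n))
  vals <- matrix(runif(side * side, 0, 255), side, side)
  features <- list(
    values = matrix(runif(n * D, 0, 255), n, D),
    grid_shape = c(n, 1L)
  )
  class(features) <- "pixel_features"
  z <- matrix(rexp(n * C), n, C)
  z <- z / rowSums(z)
  s <- array(runif(n * C * D, 0.05, 0.95), dim = c(n, C, D))
  params <- list(
    mu = matrix(runif(C * D, 20, 230), C, D),
    sigma2 = matrix(runif(C * D, 50, 400), C, D),
    eps = runif(D, 50, 200),
    nu2 = runif(D, 500, 5000),
    rho = runif(D, 0.2, 0.8)
  )
  list(features = features, z = z, s = s, params = params)
}

# Objective restricted to a single saliency coordinate s_ijl (everything
# else frozen); used for grid-search minimisation.
objective_in_s <- function(s_val, x, z_ij, mu, sig2, eps, nu2, rho, gamma) {
  lc <- dnorm(x, mu, sqrt(sig2), log = TRUE)
  lb <- dnorm(x, eps, sqrt(nu2), log = TRUE)
  z_ij * (-s_val * lc - (1 - s_val) * lb) +
    gamma * z_ij * (s_val * log(s_val / rho) +
                      (1 - s_val) * log((1 - s_val) / (1 - rho)))
}

# Objective restricted to a single pixel's membership pair (z, 1 - z), C = 2.
objective_in_z <- function(z1, d, K, pi_row, lam, gamma) {
  z <- c(z1, 1 - z1)
  sum(z * d) + lam * sum(z * log(z / pi_row)) + gamma * sum(z * K)
}

# Weighted class moments by explicit loops (oracle for update_class_params).
naive_class_moments <- function(v, z, s) {
  C <- ncol(z); D <- ncol(v)
  mu <- matrix(0, C, D); sig2 <- matrix(0, C, D)
  for (j in seq_len(C)) {
    for (l in seq_len(D)) {
      num <- 0; den <- 0
      for (i in seq_len(nrow(v))) {
        num <- num + z[i, j] * s[i, j, l] * v[i, l]
        den <- den + z[i, j] * s[i, j, l]
      }
      mu[j, l] <- num / den
      acc <- 0
      for (i in seq_len(nrow(v))) {
        acc <- acc + z[i, j] * s[i, j, l] * (v[i, l] - mu[j, l])^2
      }
      sig2[j, l] <- acc / den
    }
  }
  list(mu = mu, sigma2 = sig2)
}

# Background moments by explicit loops (oracle for update_background_params).
naive_background_moments <- function(v, z, s) {
  D <- ncol(v)
  eps <- numeric(D); nu2 <- numeric(D)
  for (l in seq_len(D)) {
    num <- 0; den <- 0
    for (i in seq_len(nrow(v))) {
      for (j in seq_len(ncol(z))) {
        w <- z[i, j] * (1 - s[i, j, l])
        num <- num + w * v[i, l]
        den <- den + w
      }
    }
    eps[l] <- num / den
    acc <- 0
    for (i in seq_len(nrow(v))) {
      for (j in seq_len(ncol(z))) {
        acc <- acc + z[i, j] * (1 - s[i, j, l]) * (v[i, l] - eps[l])^2
      }
    }
    nu2[l] <- acc / den
  }
  list(eps = eps, nu2 = nu2)
}
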