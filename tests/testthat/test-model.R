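test_that("gaussian log density matches its closed form and an independent evaluation", {
  # normalising constant cancels the exponent: density exactly 1
  expect_equal(gaussian_log_pdf(0, 0, 1 / (2 * pi)), 0)
  # zero exponent at the mean
  for (v in c(0.5, 4, 123)) {
    expect_equal(gaussian_log_pdf(7, 7, v), -0.5 * log(2 * pi * v))
  }
  # independent evaluation through stats::dnorm
  expect_equal(gaussian_log_pdf(2, 0, 4), dnorm(2, 0, 2, log = TRUE),
               tolerance = 1e-12)
  xs <- c(-3.2, 0, 17, 254.9)
  expect_equal(gaussian_log_pdf(xs, 100, 230),
               dnorm(xs, 100, sqrt(230), log = TRUE), tolerance = 1e-12)
  expect_error(gaussian_log_pdf(NaN, 0, 1), "non-finite")
  expect_error(gaussian_log_pdf(Inf, 0, 1), "non-finite")
})

test_that("FCM initialisation recovers well-separated blobs and guards degenerate input", {
  set.seed(11)
  vals <- c(rnorm(500, 60, 5), rnorm(500, 180, 5))
  vals <- pmin(pmax(vals, 0), 255)
  img <- matrix(vals, 25, 40)
  config <- seg_config(C = 2, seed = 7)
  init <- fcm_initialize(pixel_features(img), config)
  km <- kmeans(as.vector(img), centers = 2, nstart = 5)
  expect_equal(sort(init$params$mu[, 1]), sort(as.vector(km$centers)),
               tolerance = 3, ignore_attr = TRUE)
  expect_true(all(abs(sort(init$params$mu[, 1]) - c(60, 180)) < 3))
  expect_equal(rowSums(init$state$z), rep(1, 1000), tolerance = 1e-8)
  expect_true(all(init$state$s == 0.5))
  expect_true(all(init$state$pi == 0.5))

  # C = 1: single centre is the sample mean
  init1 <- fcm_initialize(pixel_features(img), seg_config(C = 1))
  expect_equal(init1$params$mu[1, 1], mean(img))

  expect_error(fcm_initialize(pixel_features(matrix(128, 32, 32)),
                              seg_config(C = 2)),
               "feature 1 .* constant")
})

test_that("dissimilarity is the saliency-weighted negative log likelihood", {
  inst <- rand_instance(n = 12, C = 3, seed = 5)
  # s = 1: background term vanishes
  s1 <- array(1 - 1e-12, dim = dim(inst$s))
  d1 <- dissimilarity(inst$features, inst$params, s1)
  for (j in 1:3) {
    expect_equal(d1[, j],
                 -dnorm(inst$features$values[, 1], inst$params$mu[j, 1],
                        sqrt(inst$params$sigma2[j, 1]), log = TRUE),
                 tolerance = 1e-6)
  }
  # s = 0: all classes share the background cost
  s0 <- array(1e-12, dim = dim(inst$s))
  d0 <- dissimilarity(inst$features, inst$params, s0)
  expect_equal(d0[, 1], d0[, 2], tolerance = 1e-9)
  expect_equal(d0[, 2], d0[, 3], tolerance = 1e-9)

  # scalar hand evaluation on a 1-pixel, 1-feature, 2-class instance
  x <- 120; s <- c(0.7, 0.2)
  f <- structure(list(values = matrix(x, 1, 1), grid_shape = c(1L, 1L)),
                 class = "pixel_features")
  p <- list(mu = matrix(c(100, 200), 2, 1), sigma2 = matrix(c(100, 400), 2, 1),
            eps = 150, nu2 = 2000, rho = 0.5)
  d <- dissimilarity(f, p, array(s, dim = c(1, 2, 1)))
  for (j in 1:2) {
    expect_equal(d[1, j],
                 -s[j] * dnorm(x, p$mu[j, 1], sqrt(p$sigma2[j, 1]), log = TRUE) -
                   (1 - s[j]) * dnorm(x, p$eps, sqrt(p$nu2), log = TRUE),
                 tolerance = 1e-12)
  }
})

test_that("saliency update has symmetric odds, flattens to rho, and minimises the objective", {
  # identical class and background density with rho = 1/2 gives s = 1/2
  f <- structure(list(values = matrix(130, 1, 1), grid_shape = c(1L, 1L)),
                 class = "pixel_features")
  p <- list(mu = matrix(130, 1, 1), sigma2 = matrix(500, 1, 1),
            eps = 130, nu2 = 500, rho = 0.5)
  s <- update_saliency(f, p, seg_config(C = 2))
  expect_equal(s[1, 1, 1], 0.5, tolerance = 1e-12)

  # very large gamma tempers both likelihoods away: s -> rho
  inst <- rand_instance(n = 8, C = 2, seed = 9)
  inst$params$rho <- 0.31
  cfg <- seg_config(C = 2, gamma = 1e9)
  s_flat <- update_saliency(inst$features, inst$params, cfg)
  expect_equal(as.vector(s_flat), rep(0.31, length(s_flat)), tolerance = 1e-4)

  # grid-search minimiser of the single-coordinate objective
  cfg <- seg_config(C = 2, gamma = 15)
  s_hat <- update_saliency(inst$features, inst$params, cfg)
  grid <- seq(1e-4, 1 - 1e-4, by = 1e-4)
  for (i in c(1, 4)) {
    for (j in 1:2) {
      vals <- objective_in_s(grid, inst$features$values[i, 1], inst$z[i, j],
                             inst$params$mu[j, 1], inst$params$sigma2[j, 1],
                             inst$params$eps, inst$params$nu2,
                             inst$params$rho, cfg$gamma)
      expect_lt(abs(s_hat[i, j, 1] - grid[which.min(vals)]), 1.01e-4)
    }
  }
})

test_that("membership update is the softmax stationarity solution", {
  cfg <- seg_config(C = 3)
  # symmetric inputs give uniform memberships
  d <- matrix(5, 4, 3); K <- matrix(0.2, 4, 3); pi <- matrix(1 / 3, 4, 3)
  expect_equal(update_membership(d, K, pi, cfg), matrix(1 / 3, 4, 3))

  # enormous lambda: the KL term dominates and z -> pi
  set.seed(2)
  pi <- matrix(rexp(12), 4, 3); pi <- pi / rowSums(pi)
  d <- matrix(runif(12, 0, 50), 4, 3)
  cfg_inf <- seg_config(C = 3, lam = 1e12)
  expect_equal(update_membership(d, K, pi, cfg_inf), pi, tolerance = 1e-9)

  # grid-search minimiser for one pixel, C = 2
  cfg2 <- seg_config(C = 2, lam = 150, gamma = 15)
  d1 <- c(12, 40); K1 <- c(0.4, 0.9); pi1 <- c(0.6, 0.4)
  z_hat <- update_membership(matrix(d1, 1), matrix(K1, 1), matrix(pi1, 1), cfg2)
  grid <- seq(1e-4, 1 - 1e-4, by = 1e-4)
  vals <- vapply(grid, objective_in_z, numeric(1),
                 d = d1, K = K1, pi_row = pi1, lam = 150, gamma = 15)
  expect_lt(abs(z_hat[1, 1] - grid[which.min(vals)]), 1.01e-4)
  expect_equal(rowSums(z_hat), 1, tolerance = 1e-12)

  # extreme dissimilarities underflow gracefully through the log-sum-exp shift
  d_huge <- matrix(c(1e8, 2e8), 1)
  z_u <- update_membership(d_huge, matrix(0, 1, 2), matrix(0.5, 1, 2), cfg2)
  expect_true(all(is.finite(z_u)))
  expect_equal(sum(z_u), 1)
})

test_that("class parameter updates match brute-force weighted moments", {
  cfg <- seg_config(C = 2, variance_floor = 1e-4)
  # hard z and s = 1 reduce to per-class sample moments
  v <- matrix(c(10, 12, 14, 200, 210, 220), 6, 1)
  f <- structure(list(values = v, grid_shape = c(6L, 1L)),
                 class = "pixel_features")
  z <- cbind(rep(c(1, 0), c(3, 3)), rep(c(0, 1), c(3, 3)))
  s <- array(1, dim = c(6, 2, 1))
  p0 <- list(mu = matrix(0, 2, 1), sigma2 = matrix(1, 2, 1),
             eps = 0, nu2 = 1, rho = 0.5)
  up <- update_class_params(f, z, s, p0, cfg)
  expect_equal(up$mu[, 1], c(12, 210))
  expect_equal(up$sigma2[, 1], c(var(c(10, 12, 14)), var(c(200, 210, 220))) * 2 / 3)

  # a single supporting pixel gives a floored variance
  f1 <- structure(list(values = matrix(77, 1, 1), grid_shape = c(1L, 1L)),
                  class = "pixel_features")
  up1 <- update_class_params(f1, matrix(1, 1, 1), array(1, c(1, 1, 1)),
                             list(mu = matrix(0, 1, 1), sigma2 = matrix(1, 1, 1),
                                  eps = 0, nu2 = 1, rho = 0.5), cfg)
  expect_equal(up1$mu[1, 1], 77)
  expect_equal(up1$sigma2[1, 1], cfg$variance_floor)

  # random instance against the loop oracle
  inst <- rand_instance(n = 20, C = 3, D = 2, seed = 31)
  cfg3 <- seg_config(C = 3, variance_floor = 1e-8)
  up <- update_class_params(inst$features, inst$z, inst$s, inst$params, cfg3)
  oracle <- naive_class_moments(inst$features$values, inst$z, inst$s)
  expect_equal(up$mu, oracle$mu, tolerance = 1e-10)
  expect_equal(up$sigma2, oracle$sigma2, tolerance = 1e-10)

  # empty-cluster guard: zero weight mass keeps previous parameters and warns
  z0 <- cbind(rep(1, 6), rep(0, 6))
  pprev <- list(mu = matrix(c(1, 99), 2, 1), sigma2 = matrix(c(2, 98), 2, 1),
                eps = 0, nu2 = 1, rho = 0.5)
  expect_warning(upg <- update_class_params(f, z0, s, pprev, cfg),
                 "empty cluster")
  expect_equal(upg$mu[2, 1], 99)
  expect_equal(upg$sigma2[2, 1], 98)
})

test_that("background parameter updates match brute-force moments and guard empty masses", {
  cfg <- seg_config(C = 2, variance_floor = 1e-8)
  inst <- rand_instance(n = 20, C = 2, D = 2, seed = 13)

  # s = 0 collapses the weights to one per pixel: global moments
  s0 <- array(0, dim = dim(inst$s))
  up0 <- update_background_params(inst$features, inst$z, s0, inst$params, cfg)
  expect_equal(up0$eps, colMeans(inst$features$values), tolerance = 1e-10)

  # s = 1: empty background, guard path keeps previous values
  s1 <- array(1, dim = dim(inst$s))
  expect_warning(expect_warning(  # one guard warning per feature, D = 2
    up1 <- update_background_params(inst$features, inst$z, s1, inst$params, cfg),
    "empty background"), "empty background")
  expect_equal(up1$eps, inst$params$eps)
  expect_equal(up1$nu2, inst$params$nu2)

  # random instance against the loop oracle
  up <- update_background_params(inst$features, inst$z, inst$s, inst$params, cfg)
  oracle <- naive_background_moments(inst$features$values, inst$z, inst$s)
  expect_equal(up$eps, oracle$eps, tolerance = 1e-10)
  expect_equal(up$nu2, oracle$nu2, tolerance = 1e-10)
})

test_that("saliency prior update is the mean saliency, clipped", {
  inst <- rand_instance(n = 15, C = 2, D = 2, seed = 3)
  # all-salient saturates at the clipping bound
  expect_equal(update_saliency_prior(inst$z, array(1, dim = dim(inst$s))),
               rep(1 - 1e-3, 2))
  expect_equal(update_saliency_prior(inst$z, array(0.5, dim = dim(inst$s))),
               rep(0.5, 2))
  # loop oracle
  rho <- update_saliency_prior(inst$z, inst$s)
  for (l in 1:2) {
    acc <- 0
    for (i in 1:15) for (j in 1:2) acc <- acc + inst$z[i, j] * inst$s[i, j, l]
    expect_equal(rho[l], acc / 15, tolerance = 1e-12)
  }
})

test_that("parameter updates zero the analytic partial derivatives of the objective", {
  inst <- rand_instance(n = 20, C = 2, D = 1, seed = 21)
  cfg <- seg_config(C = 2, variance_floor = 1e-8, rho_floor = 1e-6)
  v <- inst$features$values
  up <- update_class_params(inst$features, inst$z, inst$s, inst$params, cfg)
  bg <- update_background_params(inst$features, inst$z, inst$s, inst$params, cfg)
  rho <- update_saliency_prior(inst$z, inst$s, cfg$rho_floor)
  for (j in 1:2) {
    # d/dmu: sum_i z s (mu - x) / sigma^2
    g_mu <- sum(inst$z[, j] * inst$s[, j, 1] * (up$mu[j, 1] - v[, 1])) /
      up$sigma2[j, 1]
    expect_lt(abs(g_mu), 1e-6 * sum(inst$z[, j] * inst$s[, j, 1]))
    # d/dsigma2: 0.5 sum_i z s (1/sigma^2 - (x - mu)^2 / sigma^4)
    g_s2 <- 0.5 * sum(inst$z[, j] * inst$s[, j, 1] *
                        (1 / up$sigma2[j, 1] -
                           (v[, 1] - up$mu[j, 1])^2 / up$sigma2[j, 1]^2))
    expect_lt(abs(g_s2), 1e-6)
  }
  g_eps <- sum(inst$z * (1 - inst$s[, , 1]) * (bg$eps[1] - v[, 1])) / bg$nu2[1]
  expect_lt(abs(g_eps), 1e-6)
  g_nu2 <- 0.5 * sum(inst$z * (1 - inst$s[, , 1]) *
                       (1 / bg$nu2[1] - (v[, 1] - bg$eps[1])^2 / bg$nu2[1]^2))
  expect_lt(abs(g_nu2), 1e-6)
  g_rho <- sum(inst$z * (-inst$s[, , 1] / rho[1] +
                           (1 - inst$s[, , 1]) / (1 - rho[1])))
  expect_lt(abs(g_rho), 1e-4 * nrow(v))
})

test_that("objective evaluates its closed form and vanishing KL terms", {
  inst <- rand_instance(n = 10, C = 2, seed = 17)
  cfg <- seg_config(C = 2)
  # z = pi and G = pi rowwise: the lambda-term is exactly zero
  state <- list(z = inst$z, s = inst$s, pi = inst$z, G = inst$z)
  d <- dissimilarity(inst$features, inst$params, inst$s)
  K <- saliency_kl(inst$s, inst$params$rho)
  expect_equal(objective(inst$features, inst$params, state, cfg),
               sum(inst$z * d) + cfg$gamma * sum(inst$z * K),
               tolerance = 1e-10)

  # term-by-term scalar evaluation on a single pixel
  f <- structure(list(values = matrix(90, 1, 1), grid_shape = c(1L, 1L)),
                 class = "pixel_features")
  p <- list(mu = matrix(c(80, 190), 2, 1), sigma2 = matrix(c(120, 90), 2, 1),
            eps = 130, nu2 = 3000, rho = 0.4)
  st <- list(z = matrix(c(0.8, 0.2), 1), s = array(c(0.6, 0.3), c(1, 2, 1)),
             pi = matrix(c(0.55, 0.45), 1), G = matrix(c(1.2, 1.1), 1))
  expected <- 0
  for (j in 1:2) {
    sj <- st$s[1, j, 1]
    dj <- -sj * dnorm(90, p$mu[j, 1], sqrt(p$sigma2[j, 1]), log = TRUE) -
      (1 - sj) * dnorm(90, p$eps, sqrt(p$nu2), log = TRUE)
    Kj <- sj * log(sj / p$rho) + (1 - sj) * log((1 - sj) / (1 - p$rho))
    expected <- expected + st$z[1, j] * dj +
      cfg$lam * (st$z[1, j] * log(st$z[1, j] / st$pi[1, j]) +
                   st$G[1, j] * log(st$G[1, j] / st$pi[1, j])) +
      cfg$gamma * st$z[1, j] * Kj
  }
  expect_equal(objective(f, p, st, cfg), expected, tolerance = 1e-10)
})

test_that("a block-coordinate sweep with frozen prior and smoothing factor never increases the objective", {
  set.seed(8)
  img <- matrix(pmin(pmax(round(c(rnorm(300, 70, 15), rnorm(324, 190, 15))), 0), 255),
                24, 26)
  cfg <- seg_config(C = 2, seed = 4)
  features <- pixel_features(img)
  init <- fcm_initialize(features, cfg)
  params <- init$params
  state <- init$state
  sys <- nbr_system(cfg$window)
  h_norm <- markov_prior(neighbor_class_weights(features, params, sys, cfg$alpha))
  state$G <- smoothing_factor(state$z, h_norm, sys, cfg$beta, features$grid_shape)
  state$pi <- combined_prior(state$z, state$G)

  obj <- objective(features, params, state, cfg)
  for (sweep in 1:4) {
    state$s <- update_saliency(features, params, cfg)
    o1 <- objective(features, params, state, cfg)
    expect_lte(o1, obj + 1e-6 * abs(obj))
    d <- dissimilarity(features, params, state$s)
    K <- saliency_kl(state$s, params$rho)
    state$z <- update_membership(d, K, state$pi, cfg)
    o2 <- objective(features, params, state, cfg)
    expect_lte(o2, o1 + 1e-6 * abs(o1))
    cp <- update_class_params(features, state$z, state$s, params, cfg)
    params$mu <- cp$mu; params$sigma2 <- cp$sigma2
    bp <- update_background_params(features, state$z, state$s, params, cfg)
    params$eps <- bp$eps; params$nu2 <- bp$nu2
    params$rho <- update_saliency_prior(state$z, state$s, cfg$rho_floor)
    obj <- objective(features, params, state, cfg)
    expect_lte(obj, o2 + 1e-6 * abs(o2))
  }
})
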