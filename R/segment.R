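#' Segment a greyscale image
#'
#' The full iterative solver.  After fuzzy C-means initialisation, each outer
#' iteration performs the block-coordinate sweep
#' (1) recompute the neighbourhood likelihood weights and their
#'     class-normalised form,
#' (2) update the noise smoothing factor `G`,
#' (3) update the combined prior `pi` from `z` and `G`,
#' (4) update the saliency memberships `s`,
#' (5) update the classification memberships `z`,
#' (6) update the class, background and saliency-prior parameters,
#' then records the objective.  Iteration stops when the absolute change of
#' the objective falls below `config$delta` or after `config$t_max` sweeps.
#'
#' @param image numeric H x W matrix of grey levels in `[0, 255]`, or a file
#'   path readable by [read_grey_image()].
#' @param config a [seg_config()]; `config$C` classes are fitted.
#' @param init optional initial state, a list with elements `params` and
#'   `state` as returned by [fcm_initialize()]; used e.g. to study
#'   equivariance under class relabelling.  When supplied the FCM
#'   initialisation is skipped.
#' @return object of class `saliseg_result`: `labels` (H x W integer matrix,
#'   values `0..C-1`, per-pixel argmax of `z` with ties to the lowest class
#'   index), `state`, `params`, `objective_trace`, `iterations`, `converged`
#'   and the `config` used.
#' @export
#' @examples
#' ph <- make_phantom("two_region", 32 * 2, 32 * 2, levels = c(60, 180))
#' res <- run_segmentation(ph$clean, seg_config(C = 2, t_max = 30))
#' table(res$labels, ph$truth)
run_segmentation <- function(image, config, init = NULL) {
  if (is.character(image)) image <- read_grey_image(image)
  image <- as_grey_matrix(image)
  if (config$C < 2L) stop("segmentation needs C >= 2 clusters", call. = FALSE)
  if (length(unique(as.vector(image))) < config$C) {
    stop(sprintf("C = %d exceeds the %d distinct grey levels in the image",
                 config$C, length(unique(as.vector(image)))), call. = FALSE)
  }

  features <- pixel_features(image, type = config$features,
                             window = config$window)
  sys <- nbr_system(config$window)
  gs <- features$grid_shape

  if (is.null(init)) init <- fcm_initialize(features, config)
  params <- init$params
  state <- init$state

  trace <- numeric(0)
  converged <- FALSE
  t <- 0L
  while (t < config$t_max) {
    t <- t + 1L
    h <- neighbor_class_weights(features, params, sys, config$alpha)
    h_norm <- markov_prior(h)
    state$G <- smoothing_factor(state$z, h_norm, sys, config$beta, gs)
    state$pi <- combined_prior(state$z, state$G)
    state$s <- update_saliency(features, params, config)
    d <- dissimilarity(features, params, state$s)
    K <- saliency_kl(state$s, params$rho)
    state$z <- update_membership(d, K, state$pi, config)
    cp <- update_class_params(features, state$z, state$s, params, config)
    params$mu <- cp$mu; params$sigma2 <- cp$sigma2
    bp <- update_background_params(features, state$z, state$s, params, config)
    params$eps <- bp$eps; params$nu2 <- bp$nu2
    params$rho <- update_saliency_prior(state$z, state$s, config$rho_floor)

    trace[t] <- objective(features, params, state, config)
    if (t >= 2L && abs(trace[t] - trace[t - 1L]) < config$delta) {
      converged <- TRUE
      break
    }
  }

  lab <- max.col(state$z, ties.method = "first") - 1L
  structure(
    list(
      labels = matrix(lab, gs[1], gs[2]),
      state = state,
      params = params,
      objective_trace = trace,
      iterations = t,
      converged = converged,
      config = config
    ),
    class = "saliseg_result"
  )
}

#' @export
print.saliseg_result <- function(x, ...) {
  cat(sprintf(
    "saliseg segmentation: %d x %d image, C = %d, %d iteration(s), %s\n",
    nrow(x$labels), ncol(x$labels), x$config$C, x$iterations,
    if (x$converged) "converged" else "stopped at t_max"
  ))
  cat("class means (feature 1):",
      paste(sprintf("%.2f", x$params$mu[, 1]), collapse = ", "), "\n")
  invisible(x)
}

#' Class-mean reconstruction of a segmentation
#'
#' Replaces every pixel by the fitted intensity mean of its class, producing
#' the grey image used as the PSNR operand.  For a label map without fitted
#' parameters, pass the per-class levels explicitly.
#'
#' @param labels H x W integer label matrix (values `0..C-1`), or a
#'   `saliseg_result`.
#' @param levels per-class grey levels; taken from the fitted class means
#'   when a `saliseg_result` is given.
#' @return numeric H x W matrix of grey levels, rounded and clipped to
#'   `[0, 255]`.
#' @export
reconstruct <- function(labels, levels = NULL) {
  if (inherits(labels, "saliseg_result")) {
    levels <- labels$params$mu[, 1]
    labels <- labels$labels
  }
  stopifnot(!is.null(levels), max(labels) < length(levels))
  out <- matrix(levels[as.vector(labels) + 1L], nrow(labels), ncol(labels))
  pmin(pmax(round(out), 0), 255)
}
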