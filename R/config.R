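#' Algorithm configuration
#'
#' Collects every tunable of the segmenter in one validated list.  Defaults
#' follow the settings used throughout the experiments in this package:
#' `lam = 150` (KL regularisation weight), `gamma = 15` (feature-saliency
#' tempering), `delta = 1e-4` (absolute objective-change convergence
#' threshold), `t_max = 400` outer iterations and a 5x5 neighbourhood window.
#'
#' @param C integer number of clusters, at least 2 (1 is allowed only for the
#'   degenerate single-class fit used in testing).
#' @param window odd neighbourhood side length; one of 3, 5, 7.  3x3 suits low
#'   noise, 5x5 is the default trade-off between smoothing power and detail.
#' @param lam positive weight `lambda` of the KL divergence penalty tying the
#'   memberships to the spatial prior.
#' @param gamma positive feature parameter tempering the saliency posterior;
#'   larger values flatten the per-feature evidence.
#' @param beta positive weight of the noise smoothing factor
#'   `G_ij = exp(beta / (2 N_i) * sum_t (z_tj + h_tj))`.  It bounds
#'   `G` in `[1, exp(beta)]` and therefore controls how strongly the local
#'   class vote can dominate the combined prior.
#' @param alpha positive exponent applied to the windowed likelihood sum in
#'   the neighbourhood weight function.
#' @param delta positive convergence threshold on the absolute change of the
#'   objective between outer iterations.
#' @param t_max maximum number of outer iterations.
#' @param seed integer seed driving fuzzy C-means centre initialisation (the
#'   only stochastic step of the solver).
#' @param variance_floor lower bound for all fitted variances, in squared
#'   grey-level units; keeps log densities finite on noise-free regions.
#' @param rho_floor saliency priors `rho_l` are clipped to
#'   `[rho_floor, 1 - rho_floor]`.
#' @param fcm_fuzzifier fuzzifier `m > 1` of the fuzzy C-means initialiser.
#' @param features feature construction: `"intensity"` (D = 1, raw grey
#'   level) or `"intensity_mean"` (D = 2, grey level plus window mean; an
#'   extension beyond the plain greyscale model).
#'
#' @return a list of class `seg_config`.
#' @export
#' @examples
#' seg_config(C = 2)
seg_config <- function(C,
                       window = 5L,
                       lam = 150,
                       gamma = 15,
                       beta = 12,
                       alpha = 2,
                       delta = 1e-4,
                       t_max = 400L,
                       seed = 1L,
                       variance_floor = 1e-4,
                       rho_floor = 1e-3,
                       fcm_fuzzifier = 2,
                       features = c("intensity", "intensity_mean")) {
  features <- match.arg(features)
  C <- as.integer(C)
  stopifnot(
    length(C) == 1L, C >= 1L,
    window %in% c(3L, 5L, 7L),
    lam > 0, gamma > 0, beta > 0, alpha > 0, delta > 0,
    t_max >= 1L, variance_floor > 0,
    rho_floor > 0, rho_floor < 0.5,
    fcm_fuzzifier > 1
  )
  structure(
    list(
      C = C, window = as.integer(window), lam = lam, gamma = gamma,
      beta = beta, alpha = alpha, delta = delta, t_max = as.integer(t_max),
      seed = as.integer(seed), variance_floor = variance_floor,
      rho_floor = rho_floor, fcm_fuzzifier = fcm_fuzzifier,
      features = features
    ),
    class = "seg_config"
  )
}

#' @export
print.seg_config <- function(x, ...) {
  cat("Segmentation configuration\n")
  cat(sprintf("  clusters C        : %d\n", x$C))
  cat(sprintf("  window            : %dx%d\n", x$window, x$window))
  cat(sprintf(
    "  lambda / gamma    : %g / %g\n  beta / alpha      : %g / %g\n",
    x$lam, x$gamma, x$beta, x$alpha
  ))
  cat(sprintf(
    "  delta / t_max     : %g / %d\n  seed              : %d\n",
    x$delta, x$t_max, x$seed
  ))
  cat(sprintf("  features          : %s\n", x$features))
  invisible(x)
}

#' Per-pixel feature matrix
#'
#' Converts an H x W greyscale image (values 0-255) into the N x D feature
#' matrix the clustering model operates on.  Pixels are indexed in R's
#' column-major order; `grid_shape` retains the geometry so spatial operators
#' can reshape vectors back into images.
#'
#' @param image numeric H x W matrix with finite entries in `[0, 255]`.
#' @param type `"intensity"` for D = 1 raw grey levels, `"intensity_mean"`
#'   to append the replicate-padded window mean as a second feature.
#' @param window window side used for the `"intensity_mean"` feature.
#' @return list of class `pixel_features` with elements `values` (N x D
#'   matrix) and `grid_shape` (`c(H, W)`).
#' @export
pixel_features <- function(image, type = c("intensity", "intensity_mean"),
                           window = 5L) {
  type <- match.arg(type)
  image <- as_grey_matrix(image)
  values <- matrix(as.vector(image), ncol = 1L)
  if (type == "intensity_mean") {
    wm <- box_filter_sum(image, window) / (window^2)
    values <- cbind(values, as.vector(wm))
  }
  colnames(values) <- c("intensity", "window_mean")[seq_len(ncol(values))]
  structure(
    list(values = values, grid_shape = dim(image)),
    class = "pixel_features"
  )
}

# Validate an image argument: numeric matrix, finite, within [0, 255].
as_grey_matrix <- function(image) {
  if (!is.matrix(image) || !is.numeric(image)) {
    stop("`image` must be a numeric H x W matrix of grey levels", call. = FALSE)
  }
  if (any(!is.finite(image))) {
    stop("`image` contains non-finite grey levels", call. = FALSE)
  }
  if (min(image) < 0 || max(image) > 255) {
    stop("grey levels must lie in [0, 255] (8-bit scale)", call. = FALSE)
  }
  image
}
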