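#' Piecewise-constant phantom images
#'
#' Deterministic geometric phantoms with known ground-truth labels, the test
#' material for the noise-robustness experiments:
#' \describe{
#'   \item{two_region}{a centred disk (class 1) on a background (class 0);
#'     disk radius `min(H, W) / 4`.}
#'   \item{four_region}{quadrant blocks, one class each, with a centred inset
#'     rectangle of the "next" class inside every quadrant - a stand-in for
#'     composite scenes of man-made objects.}
#'   \item{stripes}{equal-width vertical bands, one per level.}
#' }
#'
#' @param kind phantom layout, one of `"two_region"`, `"four_region"`,
#'   `"stripes"`.
#' @param H,W image size, both at least 32.
#' @param levels distinct per-class grey levels in `[0, 255]`; exactly 2 for
#'   `two_region`, exactly 4 for `four_region`, 2-4 for `stripes`.
#' @param seed integer, accepted for interface uniformity with the noise
#'   generators; the layouts themselves are deterministic.
#' @return object of class `phantom`: `clean` (H x W grey image), `truth`
#'   (H x W integer labels `0..C-1`), `levels`.
#' @export
#' @examples
#' ph <- make_phantom("two_region", 64, 64, levels = c(60, 180))
#' table(ph$truth)
make_phantom <- function(kind = c("two_region", "four_region", "stripes"),
                         H, W, levels, seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(H >= 32, W >= 32, length(levels) >= 2, length(levels) <= 4,
            all(levels >= 0), all(levels <= 255))
  if (anyDuplicated(levels)) {
    stop("phantom grey levels must be distinct", call. = FALSE)
  }
  truth <- matrix(0L, H, W)
  rows <- matrix(seq_len(H), H, W)
  cols <- matrix(seq_len(W), H, W, byrow = TRUE)

  if (kind == "two_region") {
    if (length(levels) != 2) stop("two_region needs exactly 2 levels", call. = FALSE)
    cr <- (H + 1) / 2; cc <- (W + 1) / 2
    r <- min(H, W) / 4
    truth[(rows - cr)^2 + (cols - cc)^2 <= r^2] <- 1L
  } else if (kind == "four_region") {
    if (length(levels) != 4) stop("four_region needs exactly 4 levels", call. = FALSE)
    top <- rows <= H %/% 2
    left <- cols <= W %/% 2
    truth[top & !left] <- 1L
    truth[!top & left] <- 2L
    truth[!top & !left] <- 3L
    # centred inset rectangle (half the quadrant) of the cyclically next class
    inset <- function(r0, r1, c0, c1, cls) {
      rh <- (r1 - r0 + 1) %/% 4; cw <- (c1 - c0 + 1) %/% 4
      truth[(r0 + rh):(r1 - rh), (c0 + cw):(c1 - cw)] <<- cls
    }
    hh <- H %/% 2; wh <- W %/% 2
    inset(1, hh, 1, wh, 1L)
    inset(1, hh, wh + 1, W, 2L)
    inset(hh + 1, H, 1, wh, 3L)
    inset(hh + 1, H, wh + 1, W, 0L)
  } else {
    k <- length(levels)
    truth <- matrix(pmin(as.integer(floor((cols - 1) * k / W)), k - 1L), H, W)
  }

  clean <- matrix(as.numeric(levels[truth + 1L]), H, W)
  structure(list(clean = clean, truth = truth, levels = as.numeric(levels)),
            class = "phantom")
}

#' Noise process specification
#'
#' Declarative description of a corruption process on the 0-255 grey scale.
#' Noise "levels" quoted for Gaussian and multiplicative noise are standard
#' deviations on that scale; for multiplicative (speckle) noise the model is
#' `I + I * n` with `n ~ Normal(0, (std/255)^2)`, mapping the 0-255 level
#' onto the conventional unit-scale multiplicative form.
#'
#' @param kind one of `"gaussian"`, `"salt_pepper"`, `"multiplicative"`,
#'   `"mixed"` (Gaussian followed by salt-and-pepper).
#' @param gaussian_mean mean of the additive Gaussian component.
#' @param gaussian_std standard deviation of the Gaussian / speckle
#'   component, on the 0-255 scale.
#' @param sp_fraction expected fraction of pixels hit by impulse noise, at
#'   most 0.9; each corrupted pixel is set to 0 or 255 with equal
#'   probability.
#' @param seed integer seed; corruption is a pure function of
#'   `(image, spec)`.
#' @return list of class `noise_spec`.
#' @export
noise_spec <- function(kind = c("gaussian", "salt_pepper", "multiplicative", "mixed"),
                       gaussian_mean = 0, gaussian_std = NULL,
                       sp_fraction = NULL, seed = 1L) {
  kind <- match.arg(kind)
  if (kind %in% c("gaussian", "multiplicative", "mixed") &&
      (is.null(gaussian_std) || gaussian_std < 0)) {
    stop(sprintf("'%s' noise requires a non-negative gaussian_std", kind),
         call. = FALSE)
  }
  if (kind %in% c("salt_pepper", "mixed")) {
    if (is.null(sp_fraction) || sp_fraction < 0 || sp_fraction > 0.9) {
      stop(sprintf("'%s' noise requires sp_fraction in [0, 0.9]", kind),
           call. = FALSE)
    }
  }
  structure(
    list(kind = kind, gaussian_mean = gaussian_mean,
         gaussian_std = if (is.null(gaussian_std)) 0 else gaussian_std,
         sp_fraction = if (is.null(sp_fraction)) 0 else sp_fraction,
         seed = as.integer(seed)),
    class = "noise_spec"
  )
}

#' Corrupt an image with a specified noise process
#'
#' Applies the process described by a [noise_spec()] and returns an 8-bit
#' image: the result is clipped to `[0, 255]` and rounded to integers, with
#' the input's shape preserved.  Salt-and-pepper corruption selects each
#' pixel independently with probability `sp_fraction` and leaves all other
#' pixels untouched.  `"mixed"` applies the Gaussian stage and the impulse
#' stage with independent substreams derived from the same seed.
#'
#' @param image numeric H x W matrix of grey levels in `[0, 255]`.
#' @param spec a [noise_spec()].
#' @return numeric H x W matrix with integer values in `[0, 255]`.
#' @export
corrupt <- function(image, spec) {
  stopifnot(inherits(spec, "noise_spec"))
  image <- as_grey_matrix(image)
  n <- length(image)
  dims <- dim(image)

  add_gaussian <- function(img, seed) {
    set.seed(seed)
    img + stats::rnorm(n, spec$gaussian_mean, spec$gaussian_std)
  }
  add_sp <- function(img, seed) {
    set.seed(seed)
    hit <- stats::runif(n) < spec$sp_fraction
    val <- ifelse(stats::runif(n) < 0.5, 0, 255)
    img[hit] <- val[hit]
    img
  }

  out <- switch(spec$kind,
    gaussian = add_gaussian(image, spec$seed),
    salt_pepper = add_sp(image, spec$seed),
    multiplicative = {
      set.seed(spec$seed)
      image + image * stats::rnorm(n, 0, spec$gaussian_std / 255)
    },
    mixed = add_sp(add_gaussian(image, spec$seed), spec$seed + 1L),
    stop(sprintf("unknown noise kind '%s'", spec$kind), call. = FALSE)
  )
  matrix(pmin(pmax(round(out), 0), 255), dims[1], dims[2])
}
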