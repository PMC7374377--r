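#' Read a single-channel 8-bit greyscale image
#'
#' Accepts PNG and TIFF.  Multi-channel images and bit depths other than 8
#' are rejected with an informative error; the PNG bit depth is taken from
#' the IHDR header, the TIFF bit depth from the file's `bits.per.sample`
#' field.
#'
#' @param path path to a `.png`, `.tif` or `.tiff` file.
#' @return numeric H x W matrix with integer grey levels in `[0, 255]`.
#' @export
read_grey_image <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("image file not found: '%s'", path), call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    hdr <- readBin(path, "raw", n = 26L)
    bit_depth <- as.integer(hdr[25])
    color_type <- as.integer(hdr[26])
    if (bit_depth != 8L) {
      stop(sprintf("'%s' has bit depth %d; only 8-bit images are supported",
                   path, bit_depth), call. = FALSE)
    }
    if (color_type != 0L) {
      stop(sprintf("'%s' is not single-channel greyscale (PNG colour type %d)",
                   path, color_type), call. = FALSE)
    }
    img <- png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path, info = TRUE, as.is = TRUE)
    bits <- attr(img, "bits.per.sample")
    if (!is.null(bits) && bits != 8L) {
      stop(sprintf("'%s' has bit depth %d; only 8-bit images are supported",
                   path, bits), call. = FALSE)
    }
    if (length(dim(img)) == 3L) {
      stop(sprintf("'%s' has %d channels; expected single-channel greyscale",
                   path, dim(img)[3]), call. = FALSE)
    }
    attributes(img) <- list(dim = dim(img))
    return(matrix(as.numeric(img), nrow(img), ncol(img)))
  } else {
    stop(sprintf("unsupported image format '.%s' (use PNG or TIFF)", ext),
         call. = FALSE)
  }
  if (length(dim(img)) == 3L) {
    stop(sprintf("'%s' has %d channels; expected single-channel greyscale",
                 path, dim(img)[3]), call. = FALSE)
  }
  round(img * 255)
}

#' Write a grey image (values 0-255) as 8-bit PNG
#'
#' @param image numeric H x W matrix with values in `[0, 255]`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_grey_png <- function(image, path) {
  stopifnot(is.matrix(image), min(image) >= 0, max(image) <= 255)
  png::writePNG(image / 255, path)
  invisible(path)
}

#' Write segmentation outputs and return a run manifest
#'
#' Writes three files into `dir`: `labels.png` (label map stored losslessly
#' as grey values `0..C-1`), `reconstruction.png` (class-mean reconstruction
#' used for PSNR) and `result.json` (objective trace, converged parameters,
#' iteration count and configuration snapshot).
#'
#' @param result a `saliseg_result` from [run_segmentation()].
#' @param dir output directory, created if missing.
#' @return list of class `run_manifest` listing the files written, the seed,
#'   iteration count and convergence flag; every listed file exists on
#'   return.
#' @export
write_outputs <- function(result, dir) {
  stopifnot(inherits(result, "saliseg_result"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  label_path <- file.path(dir, "labels.png")
  recon_path <- file.path(dir, "reconstruction.png")
  json_path <- file.path(dir, "result.json")

  write_grey_png(result$labels, label_path)
  write_grey_png(reconstruct(result), recon_path)
  sidecar <- list(
    config = unclass(result$config),
    iterations = result$iterations,
    converged = result$converged,
    objective_trace = result$objective_trace,
    parameters = list(
      mu = result$params$mu, sigma2 = result$params$sigma2,
      eps = result$params$eps, nu2 = result$params$nu2,
      rho = result$params$rho
    )
  )
  jsonlite::write_json(sidecar, json_path, auto_unbox = TRUE, digits = NA)

  manifest <- structure(
    list(
      files = c(labels = label_path, reconstruction = recon_path,
                sidecar = json_path),
      seed = result$config$seed,
      iterations = result$iterations,
      converged = result$converged
    ),
    class = "run_manifest"
  )
  stopifnot(all(file.exists(manifest$files)))
  manifest
}

#' Read a label map written by [write_outputs()]
#'
#' @param path path to a `labels.png` file.
#' @return integer H x W matrix of class labels.
#' @export
read_labels_png <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) stop("label PNG must be single-channel", call. = FALSE)
  matrix(as.integer(round(m * 255)), nrow(m), ncol(m))
}
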