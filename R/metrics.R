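#' Peak signal-to-noise ratio between two grey images
#'
#' `MSE = mean((I1 - I2)^2)` over all pixels and
#' `PSNR = 10 log10(max_level^2 / MSE)` in dB.  In segmentation evaluation
#' `I1` is the class-mean reconstruction of the segmentation of the noisy
#' image and `I2` the reconstruction of the ideal noise-free segmentation
#' (see [reconstruct()]).  Identical images give `mse = 0` and an infinite
#' PSNR.
#'
#' @param result_image,reference_image numeric matrices of the same shape.
#' @param max_level peak grey level, 255 for 8-bit images.
#' @return list with `mse` and `psnr_db`.
#' @export
#' @examples
#' psnr(matrix(10, 4, 4), matrix(15, 4, 4)) # mse 25
psnr <- function(result_image, reference_image, max_level = 255) {
  if (!all(dim(result_image) == dim(reference_image))) {
    stop("psnr: image shapes differ", call. = FALSE)
  }
  mse <- mean((result_image - reference_image)^2)
  list(mse = mse,
       psnr_db = if (mse == 0) Inf else 10 * log10(max_level^2 / mse))
}

# All permutations of 1..n as an n! x n matrix (n small; used for label
# alignment and as its own brute-force check).
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Misclassification rate with optimal label alignment
#'
#' Builds the confusion matrix between predicted and true label maps, finds
#' the class-index permutation maximising the number of matched pixels
#' (cluster labels are arbitrary, so alignment is required for the rate to
#' be meaningful) and returns `100 * (1 - matched / total)` percent.
#'
#' @param pred_labels,true_labels integer matrices (or vectors) of the same
#'   shape; at most 6 distinct classes between them.
#' @return list with `mcr_percent`, `mapping` (named integer vector sending
#'   each predicted class to the true class it was matched with) and
#'   `confusion` (classes x classes contingency table, rows = predicted).
#' @export
#' @examples
#' mcr(c(0, 1, 1, 1), c(0, 0, 1, 1))$mcr_percent # 25
mcr <- function(pred_labels, true_labels) {
  if (length(pred_labels) == 0) stop("mcr: empty input", call. = FALSE)
  if (!all(dim(pred_labels) == dim(true_labels)) ||
      length(pred_labels) != length(true_labels)) {
    stop("mcr: label map shapes differ", call. = FALSE)
  }
  classes <- sort(union(unique(as.vector(pred_labels)),
                        unique(as.vector(true_labels))))
  K <- length(classes)
  if (K > 6) stop("mcr: more than 6 classes is not supported", call. = FALSE)
  conf <- table(factor(as.vector(pred_labels), levels = classes),
                factor(as.vector(true_labels), levels = classes))
  perms <- all_permutations(K)
  matched <- apply(perms, 1, function(p) sum(conf[cbind(p, seq_len(K))]))
  best <- perms[which.max(matched), ]
  # predicted class classes[best[k]] is aligned with true class classes[k]
  map <- stats::setNames(classes, classes[best])
  map <- map[as.character(classes)]
  list(
    mcr_percent = 100 * (1 - max(matched) / length(pred_labels)),
    mapping = map,
    confusion = conf
  )
}
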