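#' Spot-detection filter configuration
#'
#' Parameters of the polar-cluster detection pipeline: the Laplacian-of-
#' Gaussian (LoG) kernel (size `kernel_size` = 9 px, width `sigma` = 1.75
#' px), the detection threshold (3 standard deviations above the mean of
#' the in-cell reference pixels), the minimal contiguous spot size (3 px),
#' the polar search disc radius (10 px) and its anchor on the 5th centerline
#' segment from the pole.
#'
#' @param sigma LoG width parameter (px).
#' @param kernel_size Kernel side length L (odd, >= 3).
#' @param threshold_sds Threshold in standard deviations above the reference
#'   mean.
#' @param min_spot_pixels Minimum contiguous pixels for a spot call.
#' @param search_radius Polar search disc radius (px).
#' @param anchor_segment Centerline segment (counted from the pole, 1 px
#'   spacing) on which each search disc is centred.
#' @param threshold_on Whether the threshold statistics are computed on the
#'   `"filtered"` (default) or `"raw"` background-subtracted image.
#' @param min_spot_intensity Optional minimum integrated spot intensity;
#'   spots below it are discarded (0 disables the filter). A stand-in for
#'   manual curation of false positives in noisy conditions.
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(sigma = 1.75, kernel_size = 9L, threshold_sds = 3,
                          min_spot_pixels = 3L, search_radius = 10,
                          anchor_segment = 5L,
                          threshold_on = c("filtered", "raw"),
                          min_spot_intensity = 0) {
  threshold_on <- match.arg(threshold_on)
  if (kernel_size < 3 || kernel_size %% 2 != 1)
    abort("kernel_size must be odd and >= 3")
  if (sigma <= 0) abort("sigma must be positive")
  if (min_spot_pixels < 1) abort("min_spot_pixels must be >= 1")
  structure(list(sigma = sigma, kernel_size = as.integer(kernel_size),
                 threshold_sds = threshold_sds,
                 min_spot_pixels = as.integer(min_spot_pixels),
                 search_radius = search_radius,
                 anchor_segment = as.integer(anchor_segment),
                 threshold_on = threshold_on,
                 min_spot_intensity = min_spot_intensity),
            class = "filter_config")
}

#' Negative Laplacian-of-Gaussian kernel
#'
#' Returns the L x L kernel with entry at offset `(i, j)` from the centre
#' equal to
#' \deqn{K(i,j) = \frac{2\sigma^2 - (i^2+j^2)}{2\pi\sigma^6}
#'       \exp\!\left(-\frac{i^2+j^2}{2\sigma^2}\right),}
#' which enhances spot-like features while compressing non-spot intensity
#' variation. The centre value is `1 / (pi sigma^4)`.
#'
#' @param config A [filter_config()], or `NULL` to use `sigma`/`kernel_size`
#'   directly.
#' @param sigma,kernel_size Used when `config` is `NULL`.
#' @return A `kernel_size` x `kernel_size` numeric matrix.
#' @export
#' @examples
#' K <- log_kernel()
#' K[5, 5] * pi * 1.75^4  # = 1
log_kernel <- function(config = NULL, sigma = 1.75, kernel_size = 9L) {
  if (!is.null(config)) {
    sigma <- config$sigma
    kernel_size <- config$kernel_size
  }
  half <- (kernel_size - 1) / 2
  off <- -half:half
  r2 <- outer(off^2, off^2, "+")
  (2 * sigma^2 - r2) / (2 * pi * sigma^6) * exp(-r2 / (2 * sigma^2))
}

#' Filter a cell image with the LoG kernel
#'
#' Sets pixels inside other cells' masks to zero (avoiding double counting
#' of nearby polar spots), then convolves with the LoG kernel using zero
#' padding at the borders.
#'
#' @param image_bgsub Background-subtracted image matrix.
#' @param labels Integer label mask (0 = background).
#' @param cell_id Label of the cell being processed; every pixel with a
#'   different non-zero label is zeroed. Use `NULL` to skip zeroing.
#' @param config A [filter_config()].
#' @return Filtered image matrix of the same size.
#' @export
filter_cell_image <- function(image_bgsub, labels = NULL, cell_id = NULL,
                              config = filter_config()) {
  img <- image_bgsub
  if (!is.null(labels) && !is.null(cell_id))
    img[labels != 0 & labels != cell_id] <- 0
  conv2_same(img, log_kernel(config))
}

# 2-D convolution with zero padding, "same" output size.
conv2_same <- function(img, kernel) {
  k <- kernel[rev(seq_len(nrow(kernel))), rev(seq_len(ncol(kernel))),
              drop = FALSE]
  hr <- (nrow(k) - 1) / 2
  hc <- (ncol(k) - 1) / 2
  H <- nrow(img); W <- ncol(img)
  pad <- matrix(0, H + 2 * hr, W + 2 * hc)
  pad[hr + seq_len(H), hc + seq_len(W)] <- img
  out <- matrix(0, H, W)
  for (i in seq_len(nrow(k))) {
    for (j in seq_len(ncol(k))) {
      if (k[i, j] == 0) next
      out <- out + k[i, j] * pad[(i - 1) + seq_len(H), (j - 1) + seq_len(W)]
    }
  }
  out
}
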