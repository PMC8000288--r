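#' Full-reference image quality metrics
#'
#' Mean squared error, peak signal-to-noise ratio and the structural
#' similarity index, computed between a reference and a test image of equal
#' dimensions.
#'
#' @name quality
NULL

check_same_dim <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("images must have identical dimensions")
}

#' Mean squared error between two images
#'
#' @param a,b numeric matrices of identical dimensions.
#' @return mean over pixels of the squared intensity difference.
#' @export
mse <- function(a, b) {
  check_same_dim(a, b)
  mean((a - b)^2)
}

#' Peak signal-to-noise ratio in decibels
#'
#' `10 * log10(max_value^2 / MSE)`. Identical images (MSE = 0) return `Inf`.
#'
#' @param a,b numeric matrices of identical dimensions.
#' @param max_value peak intensity of the dynamic range (255 for 8-bit).
#' @return PSNR in dB.
#' @export
psnr <- function(a, b, max_value = 255) {
  m <- mse(a, b)
  if (m == 0) return(Inf)
  10 * log10(max_value^2 / m)
}

# valid-mode 2-D filtering with a separable window (outer(g, g))
filter_valid <- function(img, g) {
  k <- length(g)
  h <- nrow(img) - k + 1L; w <- ncol(img) - k + 1L
  # separable: filter columns then rows
  tmp <- matrix(0, h, ncol(img))
  for (j in seq_len(k)) tmp <- tmp + g[j] * img[j:(j + h - 1L), , drop = FALSE]
  out <- matrix(0, h, w)
  for (j in seq_len(k)) out <- out + g[j] * tmp[, j:(j + w - 1L), drop = FALSE]
  out
}

#' Structural similarity index (SSIM)
#'
#' Mean SSIM over all positions where the full Gaussian window fits
#' (valid-mode windows, the original SSIM convention). Local statistics are
#' Gaussian-weighted means, variances and covariance; the stabilizers are
#' `C1 = (k1 * L)^2` and `C2 = (k2 * L)^2` with dynamic range `L`.
#'
#' @param a,b numeric matrices of identical dimensions, at least as large as
#'   the window.
#' @param window_size odd Gaussian window width (default 11).
#' @param sigma Gaussian window standard deviation in pixels (default 1.5).
#' @param k1,k2 stabilizer constants (defaults 0.01, 0.03).
#' @param dynamic_range intensity range L (255 for 8-bit).
#' @return mean SSIM index in \[-1, 1\].
#' @export
ssim <- function(a, b, window_size = 11L, sigma = 1.5, k1 = 0.01, k2 = 0.03,
                 dynamic_range = 255) {
  check_same_dim(a, b)
  if (nrow(a) < window_size || ncol(a) < window_size)
    stop("images smaller than the SSIM window")
  r <- (window_size - 1) / 2
  g <- exp(-((-r):r)^2 / (2 * sigma^2))
  g <- g / sum(g)
  C1 <- (k1 * dynamic_range)^2
  C2 <- (k2 * dynamic_range)^2
  mu_a <- filter_valid(a, g)
  mu_b <- filter_valid(b, g)
  var_a <- filter_valid(a * a, g) - mu_a^2
  var_b <- filter_valid(b * b, g) - mu_b^2
  cov_ab <- filter_valid(a * b, g) - mu_a * mu_b
  s <- ((2 * mu_a * mu_b + C1) * (2 * cov_ab + C2)) /
       ((mu_a^2 + mu_b^2 + C1) * (var_a + var_b + C2))
  mean(s)
}

#' Downscale-upscale image quality protocol
#'
#' For each candidate upscaling method, every image is downscaled to the low
#' resolution with a neutral box-average filter, upscaled back to its
#' original size with the method under test, and compared against the
#' original with MSE, PSNR and SSIM. Results are aggregated as mean and
#' sample standard deviation over images and sorted by mean MSE ascending.
#'
#' With a single image the standard deviations are reported as `NA`
#' (sample sd is undefined for n = 1).
#'
#' @param images list of numeric matrices, all the same size.
#' @param methods character vector of upscaling methods: any kernel kind
#'   accepted by [resize_image()] and/or `"srcnn"` (requires `srcnn`).
#' @param low_height,low_width the intermediate low resolution (defaults
#'   128 x 128, paired with 720 x 720 sources).
#' @param srcnn optional trained [srcnn_model()] used when `"srcnn"` is
#'   among `methods`.
#' @param quantize quantize the reconstruction to 8-bit before measuring.
#' @return a data frame of class `iqm_report` with columns `method`,
#'   `mse_mean`, `mse_sd`, `psnr_mean`, `psnr_sd`, `ssim_mean`, `ssim_sd`,
#'   plus a `per_image` attribute with the per-image metric table.
#' @export
downup_protocol <- function(images, methods = c("nearest", "bilinear",
                                                "bicubic", "lanczos"),
                            low_height = 128L, low_width = 128L,
                            srcnn = NULL, quantize = TRUE) {
  if (length(images) == 0) stop("empty image list")
  dims <- vapply(images, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all images must share the same dimensions")
  per <- do.call(rbind, lapply(methods, function(meth) {
    do.call(rbind, lapply(seq_along(images), function(i) {
      orig <- images[[i]]
      low <- resize_image(orig, low_height, low_width, "area")
      rec <- if (meth == "srcnn") {
        if (is.null(srcnn)) stop("method 'srcnn' requires a trained model")
        srcnn_apply(srcnn, low, out_height = nrow(orig), out_width = ncol(orig))
      } else {
        resize_image(low, nrow(orig), ncol(orig), meth)
      }
      if (quantize) rec <- quantize_image(rec)
      data.frame(method = meth, image = i, mse = mse(orig, rec),
                 psnr = psnr(orig, rec), ssim = ssim(orig, rec))
    }))
  }))
  agg <- do.call(rbind, lapply(split(per, per$method), function(d) {
    sdv <- function(x) if (nrow(d) > 1) stats::sd(x) else NA_real_
    data.frame(method = d$method[1],
               mse_mean = mean(d$mse), mse_sd = sdv(d$mse),
               psnr_mean = mean(d$psnr), psnr_sd = sdv(d$psnr),
               ssim_mean = mean(d$ssim), ssim_sd = sdv(d$ssim))
  }))
  agg <- agg[order(agg$mse_mean), , drop = FALSE]
  rownames(agg) <- NULL
  attr(agg, "per_image") <- per
  class(agg) <- c("iqm_report", class(agg))
  agg
}
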