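#' Interpolation kernel weights
#'
#' Analytic 1-D kernel value at signed offset `t` for the four classical
#' interpolation families:
#' \describe{
#'   \item{nearest}{box of half-width 0.5 (pixel replication).}
#'   \item{triangle}{tent of support 1 — bilinear interpolation when used
#'     separably.}
#'   \item{keys_cubic}{Keys' cubic convolution kernel with a = -0.5
#'     (the standard "bicubic"), support 2.}
#'   \item{lanczos}{Lanczos-windowed sinc with a = 3:
#'     sinc(t) sinc(t/3) on |t| < 3, support 3.}
#' }
#' All kernels satisfy `weight(0) == 1` and vanish at and beyond their
#' support radius.
#'
#' @param kind one of `"nearest"`, `"triangle"`, `"keys_cubic"`, `"lanczos"`.
#'   `"bilinear"` and `"bicubic"` are accepted as aliases.
#' @param t numeric vector of signed offsets (destination minus source
#'   position, in source-pixel units).
#' @return numeric vector of kernel values.
#' @export
#' @examples
#' kernel_weight("keys_cubic", 0.5)   # 0.5625
#' kernel_weight("triangle", c(0, 0.5, 1))
kernel_weight <- function(kind, t) {
  kind <- normalize_kernel_kind(kind)
  a <- abs(t)
  switch(kind,
    nearest = as.numeric(a < 0.5),
    triangle = pmax(0, 1 - a),
    keys_cubic = {
      w <- numeric(length(a))
      i1 <- a < 1
      i2 <- !i1 & a < 2
      # Keys (1981) with a = -0.5
      w[i1] <- (1.5 * a[i1] - 2.5) * a[i1]^2 + 1
      w[i2] <- ((-0.5 * a[i2] + 2.5) * a[i2] - 4) * a[i2] + 2
      w
    },
    lanczos = {
      w <- numeric(length(a))
      i <- a < 3 & a > 0
      w[a == 0] <- 1
      w[i] <- sin(pi * a[i]) / (pi * a[i]) * sin(pi * a[i] / 3) / (pi * a[i] / 3)
      w
    },
    stop("unknown kernel kind: ", kind)
  )
}

kernel_support <- c(nearest = 0.5, triangle = 1, keys_cubic = 2, lanczos = 3)

normalize_kernel_kind <- function(kind) {
  kind <- match.arg(kind, c("nearest", "triangle", "keys_cubic", "lanczos",
                            "bilinear", "bicubic", "area"))
  switch(kind, bilinear = "triangle", bicubic = "keys_cubic", kind)
}

# 1-D resampling weight matrix (n_out x n_in) under the half-pixel-center
# mapping src = (dst + 0.5) * (n_in / n_out) - 0.5 with clamp-to-edge
# boundary and per-output-pixel weight normalization. "area" rows are the
# fractional overlap of each destination pixel footprint with the source
# pixels (exact box average, used as the neutral downscaler).
resample_weights <- function(n_in, n_out, kind) {
  W <- matrix(0, n_out, n_in)
  scale <- n_in / n_out
  if (kind == "area") {
    for (d in seq_len(n_out)) {
      lo <- (d - 1) * scale
      hi <- d * scale
      i0 <- floor(lo)
      i1 <- ceiling(hi) - 1
      idx <- i0:i1
      ov <- pmin(hi, idx + 1) - pmax(lo, idx)
      keep <- ov > 1e-12
      idx <- pmin(pmax(idx[keep], 0), n_in - 1)
      W[d, ] <- 0
      for (k in seq_along(idx)) W[d, idx[k] + 1] <- W[d, idx[k] + 1] + ov[keep][k]
      W[d, ] <- W[d, ] / sum(W[d, ])
    }
    return(W)
  }
  kind <- normalize_kernel_kind(kind)
  for (d in seq_len(n_out)) {
    src <- (d - 1 + 0.5) * scale - 0.5
    if (kind == "nearest") {
      # round-half-up of the source position; reproduces exact pixel
      # replication at integer magnification factors
      i <- min(max(floor(src + 0.5), 0), n_in - 1)
      W[d, i + 1] <- 1
      next
    }
    r <- kernel_support[[kind]]
    taps <- (floor(src) - ceiling(r) + 1):(floor(src) + ceiling(r))
    w <- kernel_weight(kind, src - taps)
    keep <- w != 0
    taps <- taps[keep]; w <- w[keep]
    taps <- pmin(pmax(taps, 0), n_in - 1)  # clamp-to-edge
    for (k in seq_along(taps)) W[d, taps[k] + 1] <- W[d, taps[k] + 1] + w[k]
    W[d, ] <- W[d, ] / sum(W[d, ])
  }
  W
}

#' Resize an image by separable kernel resampling
#'
#' Rows and columns are resampled independently under the half-pixel-center
#' coordinate mapping `src = (dst + 0.5) * (in / out) - 0.5`, with
#' clamp-to-edge boundary handling and per-output-pixel normalization of the
#' kernel weights (so constant images are reproduced exactly by every
#' kernel). `"area"` computes the exact box average of each destination
#' pixel's source footprint and is the recommended neutral downscaler.
#'
#' @param img numeric matrix.
#' @param out_height,out_width output dimensions in pixels (>= 1).
#' @param kind kernel kind (see [kernel_weight()]) or `"area"`.
#' @param quantize if `TRUE`, quantize the result to 8-bit (see
#'   [quantize_image()]); by default real-valued output is returned.
#' @return numeric matrix of size `out_height` x `out_width`.
#' @export
#' @examples
#' img <- matrix(0:3 * 80, 2, 2)
#' resize_image(img, 4, 4, "triangle")
resize_image <- function(img, out_height, out_width, kind = "keys_cubic",
                         quantize = FALSE) {
  stopifnot(is.matrix(img), is.numeric(img))
  out_height <- as.integer(out_height); out_width <- as.integer(out_width)
  if (out_height < 1L || out_width < 1L) stop("output dimensions must be >= 1")
  Wr <- resample_weights(nrow(img), out_height, kind)
  Wc <- resample_weights(ncol(img), out_width, kind)
  out <- Wr %*% img %*% t(Wc)
  if (quantize) out <- quantize_image(out)
  out
}
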