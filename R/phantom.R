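#' Specification of a radiograph-like phantom
#'
#' Describes a stylized periapical-like test image: a row of bright convex
#' tooth crowns over a darker interproximal background, a bright alveolar
#' crest band between the teeth, and optionally a radiolucent (darkened)
#' bone-loss defect at one interproximal crest site. Geometry is stylized,
#' not anatomically fitted — the phantoms exist to exercise the downstream
#' resampling, quality-metric and rating machinery with controllable,
#' reproducible structure.
#'
#' @param height,width image dimensions in pixels (>= 32).
#' @param n_teeth number of tooth regions (>= 1).
#' @param lesion defect type: `"none"`, `"horizontal"` (uniform loss of
#'   crest height across the interproximal space), `"vertical"` (a narrow
#'   angular defect along one tooth face), or `"crater"` (a trough-like
#'   depression between the two teeth).
#' @param lesion_depth defect depth as a fraction of the crest height, in
#'   \[0, 1\].
#' @param noise_sd standard deviation of the additive Gaussian intensity
#'   noise (applied last), in intensity units.
#' @param blur_sigma Gaussian blur standard deviation in pixels (applied
#'   before the noise).
#' @param seed integer seed; identical spec + seed gives a bit-identical
#'   image.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(height = 256L, width = 256L, n_teeth = 3L,
                         lesion = c("none", "horizontal", "vertical", "crater"),
                         lesion_depth = 0.5, noise_sd = 4, blur_sigma = 1,
                         seed = 1L) {
  lesion <- match.arg(lesion)
  if (height < 32 || width < 32) stop("height and width must be >= 32")
  if (n_teeth < 1) stop("n_teeth must be >= 1")
  if (lesion_depth < 0 || lesion_depth > 1) stop("lesion_depth must be in [0, 1]")
  if (noise_sd < 0 || blur_sigma < 0) stop("noise_sd and blur_sigma must be >= 0")
  structure(list(height = as.integer(height), width = as.integer(width),
                 n_teeth = as.integer(n_teeth), lesion = lesion,
                 lesion_depth = lesion_depth, noise_sd = noise_sd,
                 blur_sigma = blur_sigma, seed = as.integer(seed)),
            class = "phantom_spec")
}

# fixed intensity levels of the piecewise-constant construction
phantom_levels <- c(background = 90, tooth = 200, gap = 50,
                    crest = 140, lesion = 55)

#' Generate a radiograph-like phantom image
#'
#' The image is built piecewise-constant from the declared intensity levels
#' (background, tooth, interproximal gap, crest band, lesion), then Gaussian
#' blur and additive Gaussian noise are applied and intensities clipped to
#' \[0, 255\]. With `blur_sigma = 0` and `noise_sd = 0` every pixel equals
#' one of the declared levels exactly.
#'
#' The returned matrix carries attributes `lesion_bbox` (rows/cols bounding
#' the lesion edit, `NULL` when `lesion = "none"`) and `levels` (the
#' intensity levels used).
#'
#' @param spec a [phantom_spec()].
#' @return numeric matrix `height` x `width` with values in \[0, 255\].
#' @export
#' @examples
#' img <- generate_phantom(phantom_spec(64, 64, lesion = "crater", seed = 3))
#' range(img)
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  h <- spec$height; w <- spec$width; nt <- spec$n_teeth
  lv <- phantom_levels
  img <- matrix(lv[["background"]], h, w)
  ys <- matrix(seq_len(h), h, w)
  xs <- matrix(seq_len(w), h, w, byrow = TRUE)

  # interproximal gap corridor between crowns (darker than background)
  gap_top <- round(0.10 * h); gap_bot <- round(0.95 * h)
  img[ys >= gap_top & ys <= gap_bot] <- lv[["gap"]]

  # teeth: vertical ellipses, evenly spaced crowns
  pitch <- w / nt
  centers <- (seq_len(nt) - 0.5) * pitch
  a <- 0.30 * pitch            # tooth half-width
  cy <- 0.50 * h; b <- 0.45 * h
  for (cx in centers) {
    inside <- ((xs - cx) / a)^2 + ((ys - cy) / b)^2 <= 1
    img[inside] <- lv[["tooth"]]
  }

  # alveolar crest band across the interproximal spaces
  crest_top <- round(0.55 * h); crest_bot <- round(0.68 * h)
  in_crest <- ys >= crest_top & ys <= crest_bot & img != lv[["tooth"]]
  img[in_crest] <- lv[["crest"]]

  bbox <- NULL
  if (spec$lesion != "none" && spec$lesion_depth > 0) {
    # lesion site: interproximal space right of the middle tooth (or right
    # of the single tooth)
    i <- max(1L, nt %/% 2L)
    gx0 <- centers[i] + a
    gx1 <- if (i < nt) centers[i + 1] - a else min(w, centers[i] + pitch - a)
    gw <- gx1 - gx0
    depth_px <- spec$lesion_depth * (crest_bot - crest_top + 1)
    lmask <- switch(spec$lesion,
      horizontal = {
        # uniform loss of crest height across the whole interproximal span
        ys >= crest_top & ys <= crest_top + depth_px - 1 & xs >= gx0 & xs <= gx1
      },
      vertical = {
        # narrow angular defect along the mesial tooth face: width shrinks
        # with depth
        frac <- (ys - crest_top) / max(depth_px, 1)
        ys >= crest_top & frac <= 1 & xs >= gx0 & xs <= gx0 + 0.35 * gw * (1 - frac)
      },
      crater = {
        # two-walled trough centred between the teeth: a semi-elliptic
        # depression
        cx0 <- (gx0 + gx1) / 2
        ((xs - cx0) / (0.45 * gw))^2 + ((ys - crest_top) / depth_px)^2 <= 1 &
          ys >= crest_top
      })
    lmask <- lmask & img != lv[["tooth"]]   # defect erodes bone, not enamel
    if (any(lmask)) {
      img[lmask] <- lv[["lesion"]]
      rr <- range(ys[lmask]); cc <- range(xs[lmask])
      bbox <- c(row_min = rr[1], row_max = rr[2],
                col_min = cc[1], col_max = cc[2])
    }
  }

  if (spec$blur_sigma > 0) img <- gaussian_blur(img, spec$blur_sigma)
  if (spec$noise_sd > 0)
    img <- img + with_seed(spec$seed,
                           matrix(stats::rnorm(h * w, sd = spec$noise_sd), h, w))
  img <- pmin(pmax(img, 0), 255)
  attr(img, "lesion_bbox") <- bbox
  attr(img, "levels") <- lv
  img
}

# separable Gaussian blur with clamp-to-edge boundary
gaussian_blur <- function(img, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  g <- exp(-((-r):r)^2 / (2 * sigma^2))
  g <- g / sum(g)
  idx <- function(i, n) pmin(pmax(i, 1L), n)
  h <- nrow(img); w <- ncol(img)
  tmp <- matrix(0, h, w)
  for (j in seq_along(g)) tmp <- tmp + g[j] * img[idx(seq_len(h) + j - r - 1L, h), , drop = FALSE]
  out <- matrix(0, h, w)
  for (j in seq_along(g)) out <- out + g[j] * tmp[, idx(seq_len(w) + j - r - 1L, w), drop = FALSE]
  out
}

#' Downscale an image by a magnification factor
#'
#' Output dimensions are `round(dim / factor)`. The default method is the
#' neutral box-average filter, deliberately distinct from the upscaling
#' kernels under evaluation.
#'
#' @param img numeric matrix.
#' @param factor downscale factor (> 1).
#' @param method resampling method passed to [resize_image()].
#' @return the downscaled image.
#' @export
degrade <- function(img, factor, method = "area") {
  if (factor <= 1) stop("factor must be > 1")
  oh <- round(nrow(img) / factor); ow <- round(ncol(img) / factor)
  if (oh < 1 || ow < 1) stop("output dimensions would be < 1")
  resize_image(img, oh, ow, method)
}
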