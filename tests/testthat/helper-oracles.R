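# Independent oracles and shared fixtures for the test suite.

# Brute-force non-separable resampling: direct evaluation of the half-pixel
# mapping and 2-D kernel product at every output pixel, independent of the
# separable row/column implementation.
brute_resize <- function(img, oh, ow, kind) {
  support <- c(triangle = 1, keys_cubic = 2, lanczos = 3)[[kind]]
  sy <- nrow(img) / oh; sx <- ncol(img) / ow
  out <- matrix(0, oh, ow)
  for (dy in seq_len(oh)) {
    src_y <- (dy - 0.5) * sy - 0.5
    ty <- (floor(src_y) - support + 1):(floor(src_y) + support)
    wy <- kernel_weight(kind, src_y - ty)
    for (dx in seq_len(ow)) {
      src_x <- (dx - 0.5) * sx - 0.5
      tx <- (floor(src_x) - support + 1):(floor(src_x) + support)
      wx <- kernel_weight(kind, src_x - tx)
      acc <- 0; wsum <- 0
      for (a in seq_along(ty)) for (b in seq_along(tx)) {
        yy <- min(max(ty[a], 0), nrow(img) - 1)
        xx <- min(max(tx[b], 0), ncol(img) - 1)
        w <- wy[a] * wx[b]
        acc <- acc + w * img[yy + 1, xx + 1]
        wsum <- wsum + w
      }
      out[dy, dx] <- acc / wsum
    }
  }
  out
}

# Exhaustive one-sided signed-rank p-value: every sign assignment of the
# non-zero differences, mid-ranks of |d|, P(V* >= V_observed).
brute_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  total <- 0
  for (mask in 0:(2^n - 1)) {
    v <- sum(r[bitwAnd(bitwShiftR(mask, 0:(n - 1)), 1L) == 1L])
    if (v >= V - 1e-9) total <- total + 1
  }
  total / 2^n
}

# O(n^2) rank-comparison ROC AUC: P(score_pos > score_neg) + 0.5 P(equal).
brute_roc_auc <- function(labels, scores) {
  sp <- scores[labels == "PBL"]
  sn <- scores[labels == "healthy"]
  tot <- 0
  for (p in sp) for (q in sn) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(sp) * length(sn))
}

# Fine-grid numeric integration of the piecewise-linear VGC curve via
# stats::approx interpolation on a dense grid that includes the knots.
# Exact (to rounding) when the x-coordinates are strictly increasing.
grid_auc <- function(pts, n_grid = 2000) {
  xs <- sort(unique(c(seq(0, 1, length.out = n_grid), pts[, 1])))
  ys <- stats::approx(pts[, 1], pts[, 2], xout = xs)$y
  sum(diff(xs) * (utils::head(ys, -1) + utils::tail(ys, -1)) / 2)
}

# deterministic phantom training/eval patches for the SRCNN checks
phantom_patches <- function(n, seed0, size = 32L) {
  lapply(seq_len(n), function(i) {
    ph <- generate_phantom(phantom_spec(64, 64, n_teeth = 2 + (i %% 3),
      lesion = c("none", "horizontal", "vertical", "crater")[1 + (i %% 4)],
      noise_sd = 2, blur_sigma = 1, seed = seed0 + i))
    r0 <- 1 + ((i * 7) %% (64 - size)); c0 <- 1 + ((i * 13) %% (64 - size))
    high <- ph[r0:(r0 + size - 1), c0:(c0 + size - 1)]
    list(low = degrade(high, 2), high = high)
  })
}

# published MOS count blocks (scores 1..4) used to build expected values
table1_counts <- list(
  experts = list(nearest = c(9, 6, 8, 2), bilinear = c(11, 6, 6, 2),
                 bicubic = c(7, 12, 4, 2), lanczos = c(2, 13, 7, 3),
                 srcnn = c(2, 10, 9, 4), srgan = c(1, 4, 11, 9)),
  lay = list(nearest = c(41, 30, 11, 3), bilinear = c(16, 45, 20, 4),
             bicubic = c(8, 39, 32, 6), lanczos = c(5, 27, 46, 7),
             srcnn = c(2, 23, 49, 11), srgan = c(2, 24, 36, 23)))

# random small score-count table (scores 1..4), at least one rating
random_counts <- function() {
  repeat {
    k <- rpois(4, 2)
    if (sum(k) > 0) return(k)
  }
}

fixture_ratings <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) tab <<- read_rating_table(periosr_example("table1_ratings.csv"))
    tab
  }
})
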