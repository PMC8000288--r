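#' Three-stage super-resolution CNN
#'
#' A small convolutional network in the classical three-stage layout —
#' patch extraction and representation, nonlinear mapping, reconstruction —
#' applied to an image that has first been upscaled to the target size with
#' the Keys bicubic kernel. Stages 1 and 2 are followed by elementwise
#' rectification; stage 3 is linear. All convolutions use same-padding
#' (zero-padded), so each stage preserves spatial dimensions.
#'
#' Weights are stored stage-wise as `(filter^2 * channels_in) x channels_out`
#' matrices matching the internal im2col layout; intensities are scaled to
#' \[0, 1\] inside the network and rescaled on output.
#'
#' @name srcnn
NULL

#' Construct an untrained SRCNN model
#'
#' Filters default to the compact 9/1/5 layout with 16/8/1 channels, a
#' desk-scale variant of the canonical 64/32/1 design. Initialization is
#' near-identity: one channel per rectified stage carries a center-tap
#' pass-through (so the untrained network starts at the bicubic-upscale
#' baseline) and the remaining weights are small Gaussian perturbations.
#' Training then learns a residual correction on top of the baseline.
#'
#' @param filters integer vector of 3 odd filter sizes.
#' @param channels integer vector of 3 channel counts; the last must be 1.
#' @param init_sd standard deviation of the random weight perturbations.
#'   Kept small enough that the untrained network stays close to its
#'   bicubic baseline.
#' @param seed integer seed for the weight initialization.
#' @return an object of class `srcnn_model`.
#' @export
srcnn_model <- function(filters = c(9L, 1L, 5L), channels = c(16L, 8L, 1L),
                        init_sd = 0.001, seed = 1L) {
  stopifnot(length(filters) == 3, length(channels) == 3,
            all(filters %% 2 == 1), channels[3] == 1L)
  cin <- c(1L, channels[1], channels[2])
  with_seed(seed, {
    stages <- lapply(1:3, function(s) {
      k2 <- filters[s]^2
      W <- matrix(stats::rnorm(k2 * cin[s] * channels[s], sd = init_sd),
                  k2 * cin[s], channels[s])
      # center-tap identity on the first input channel -> first output channel
      center <- (filters[s]^2 + 1) %/% 2
      W[center, 1] <- W[center, 1] + 1
      list(W = W, b = numeric(channels[s]), filter = filters[s],
           cin = cin[s], cout = channels[s])
    })
    structure(list(stages = stages, filters = filters, channels = channels,
                   pre_upscale = "keys_cubic"),
              class = "srcnn_model")
  })
}

# im2col gather indices for a k x k same-padded window on an h x w image.
# Returns an (h*w) x k^2 matrix of linear indices into the column-major
# image vector, with index h*w + 1 denoting a padding (zero) tap.
im2col_index <- function(h, w, k) {
  r <- (k - 1L) %/% 2L
  off <- expand.grid(dy = -r:r, dx = -r:r)
  ys <- rep(seq_len(h), times = w)
  xs <- rep(seq_len(w), each = h)
  idx <- matrix(0L, h * w, k * k)
  for (j in seq_len(nrow(off))) {
    y <- ys + off$dy[j]; x <- xs + off$dx[j]
    ok <- y >= 1 & y <= h & x >= 1 & x <= w
    idx[, j] <- ifelse(ok, (x - 1L) * h + y, h * w + 1L)
  }
  idx
}

# Gather an (n x cin) activation matrix into (n x k^2*cin) patch rows.
# Column order: all k^2 taps of channel 1, then channel 2, ... matching the
# row layout of the stage weight matrices.
im2col_gather <- function(A, idx) {
  n <- nrow(A); k2 <- ncol(idx); cin <- ncol(A)
  Aaug <- rbind(A, 0)
  out <- matrix(0, n, k2 * cin)
  for (c in seq_len(cin))
    out[, (c - 1L) * k2 + seq_len(k2)] <- Aaug[idx, c]
  out
}

# forward pass on a normalized (h*w x 1) image vector; returns activations
srcnn_forward <- function(model, x, idx1, idx3) {
  s <- model$stages
  P1 <- im2col_gather(x, idx1)
  Z1 <- sweep(P1 %*% s[[1]]$W, 2, s[[1]]$b, "+")
  A1 <- pmax(Z1, 0)
  Z2 <- sweep(A1 %*% s[[2]]$W, 2, s[[2]]$b, "+")   # 1x1 stage: gather is identity
  A2 <- pmax(Z2, 0)
  P3 <- im2col_gather(A2, idx3)
  Z3 <- sweep(P3 %*% s[[3]]$W, 2, s[[3]]$b, "+")
  list(P1 = P1, Z1 = Z1, A1 = A1, Z2 = Z2, A2 = A2, P3 = P3, Z3 = Z3)
}

#' Apply an SRCNN model to an image
#'
#' The image is first upscaled to the target size with the Keys bicubic
#' kernel, then passed through the three convolution stages. Output has the
#' pre-upscaled dimensions and is real-valued (quantize explicitly if 8-bit
#' output is needed).
#'
#' @param model an `srcnn_model`.
#' @param img numeric matrix with intensities in \[0, 255\].
#' @param factor magnification factor (> 1), or use `out_height`/`out_width`.
#' @param out_height,out_width explicit output size (overrides `factor`).
#' @return numeric matrix of the target size.
#' @export
srcnn_apply <- function(model, img, factor = NULL, out_height = NULL,
                        out_width = NULL) {
  stopifnot(inherits(model, "srcnn_model"))
  if (is.null(out_height)) {
    if (is.null(factor) || factor <= 1) stop("factor must be > 1")
    out_height <- round(nrow(img) * factor)
    out_width <- round(ncol(img) * factor)
  }
  up <- resize_image(img, out_height, out_width, "keys_cubic")
  h <- nrow(up); w <- ncol(up)
  idx1 <- im2col_index(h, w, model$filters[1])
  idx3 <- im2col_index(h, w, model$filters[3])
  x <- matrix(as.vector(up) / 255, ncol = 1)
  fw <- srcnn_forward(model, x, idx1, idx3)
  matrix(fw$Z3 * 255, h, w)
}

#' Train an SRCNN model by full-batch gradient descent
#'
#' Minimizes the mean squared reconstruction error between the network
#' output (on the bicubic-upscaled low-resolution inputs) and the
#' high-resolution targets, over all pixels of all training pairs.
#' Full-batch gradient descent with multiplicative step adaptation: a step
#' that increases the loss is reverted and the step size halved, otherwise
#' the step size grows by 5% — so the recorded loss sequence is
#' non-increasing. The returned model carries the weights with the lowest
#' recorded training loss. Deterministic given the seed.
#'
#' @param pairs list of `list(low = matrix, high = matrix)` training pairs;
#'   all pairs must share the same magnification factor (i.e. identical
#'   low and high dimensions across pairs).
#' @param filters,channels architecture passed to [srcnn_model()].
#' @param learning_rate positive step size.
#' @param iterations number of gradient steps.
#' @param seed integer seed for weight initialization.
#' @return a trained `srcnn_model` with attributes `loss_trace` (numeric
#'   vector of per-iteration losses, element 1 = loss at initialization) and
#'   `best_loss`.
#' @export
srcnn_train <- function(pairs, filters = c(9L, 1L, 5L), channels = c(16L, 8L, 1L),
                        learning_rate = 0.1, iterations = 200L, seed = 1L) {
  if (length(pairs) < 1) stop("need at least one training pair")
  if (learning_rate <= 0) stop("learning rate must be positive")
  dims <- vapply(pairs, function(p) c(dim(p$low), dim(p$high)), numeric(4))
  if (any(apply(dims, 1, function(r) length(unique(r)) != 1)))
    stop("all pairs must share the same low/high dimensions")
  h <- nrow(pairs[[1]]$high); w <- ncol(pairs[[1]]$high)
  model <- srcnn_model(filters, channels, seed = seed)
  n_img <- length(pairs)
  npix <- h * w
  N <- n_img * npix
  # Stack every pair into one tall system: the same-padded im2col indices
  # of a single image are replicated per block, padding taps mapped to the
  # shared zero row N + 1.
  stack_index <- function(k) {
    idx <- im2col_index(h, w, k)
    pad <- idx == npix + 1L
    do.call(rbind, lapply(seq_len(n_img), function(m) {
      b <- idx + (m - 1L) * npix
      b[pad] <- N + 1L
      b
    }))
  }
  idx1 <- stack_index(filters[1])
  idx3 <- stack_index(filters[3])
  x <- matrix(unlist(lapply(pairs, function(p)
    as.vector(resize_image(p$low, h, w, "keys_cubic")) / 255)), ncol = 1)
  y <- matrix(unlist(lapply(pairs, function(p)
    as.vector(p$high) / 255)), ncol = 1)
  P1 <- im2col_gather(x, idx1)   # stage-1 patches are fixed by the input
  eval_loss <- function(s) {
    Z1 <- sweep(P1 %*% s[[1]]$W, 2, s[[1]]$b, "+"); A1 <- pmax(Z1, 0)
    Z2 <- sweep(A1 %*% s[[2]]$W, 2, s[[2]]$b, "+"); A2 <- pmax(Z2, 0)
    P3 <- im2col_gather(A2, idx3)
    Z3 <- sweep(P3 %*% s[[3]]$W, 2, s[[3]]$b, "+")
    list(loss = mean((Z3 - y)^2), Z1 = Z1, A1 = A1, Z2 = Z2, A2 = A2,
         P3 = P3, Z3 = Z3)
  }
  s <- model$stages
  fw <- eval_loss(s)
  loss <- fw$loss
  loss_trace <- numeric(iterations + 1L)
  loss_trace[1L] <- loss
  best <- list(loss = loss, stages = s)
  lr <- learning_rate
  for (it in seq_len(iterations)) {
    resid <- fw$Z3 - y
    d3 <- 2 * resid / N
    g3W <- crossprod(fw$P3, d3); g3b <- colSums(d3)
    dA2 <- scatter_add(d3 %*% t(s[[3]]$W), idx3, ncol(fw$A2))
    d2 <- dA2 * (fw$Z2 > 0)
    g2W <- crossprod(fw$A1, d2); g2b <- colSums(d2)
    d1 <- (d2 %*% t(s[[2]]$W)) * (fw$Z1 > 0)
    g1W <- crossprod(P1, d1); g1b <- colSums(d1)
    cand <- s
    cand[[1]]$W <- s[[1]]$W - lr * g1W; cand[[1]]$b <- s[[1]]$b - lr * g1b
    cand[[2]]$W <- s[[2]]$W - lr * g2W; cand[[2]]$b <- s[[2]]$b - lr * g2b
    cand[[3]]$W <- s[[3]]$W - lr * g3W; cand[[3]]$b <- s[[3]]$b - lr * g3b
    fw_cand <- eval_loss(cand)
    if (fw_cand$loss <= loss) {
      s <- cand; fw <- fw_cand; loss <- fw_cand$loss
      lr <- lr * 1.05
    } else {
      lr <- lr / 2   # reject the step, retry smaller from the same point
    }
    loss_trace[it + 1L] <- loss
    if (loss < best$loss) best <- list(loss = loss, stages = s)
  }
  model$stages <- best$stages
  attr(model, "loss_trace") <- loss_trace
  attr(model, "best_loss") <- best$loss
  model
}

# scatter-add of patch-row gradients back onto the activation grid
# (adjoint of im2col_gather); padding taps are discarded.
scatter_add <- function(G, idx, cin) {
  n <- nrow(idx); k2 <- ncol(idx)
  dA <- matrix(0, n + 1L, cin)
  for (j in seq_len(k2)) {
    tgt <- idx[, j]
    for (c in seq_len(cin)) {
      col <- G[, (c - 1L) * k2 + j]
      dA[, c] <- dA[, c] + rowsum_fixed(col, tgt, n + 1L)
    }
  }
  dA[seq_len(n), , drop = FALSE]
}

# rowsum over a fixed index range 1..m, returning a dense length-m vector
rowsum_fixed <- function(x, idx, m) {
  out <- numeric(m)
  rs <- rowsum(x, idx)
  out[as.integer(rownames(rs))] <- rs[, 1]
  out
}

#' Serialize an SRCNN model to JSON
#'
#' Stage shapes, weights and biases are written to a single JSON file and
#' can be restored with [srcnn_load()].
#'
#' @param model an `srcnn_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
srcnn_save <- function(model, path) {
  obj <- list(filters = model$filters, channels = model$channels,
              pre_upscale = model$pre_upscale,
              stages = lapply(model$stages, function(s)
                list(W = as.vector(s$W),   # column-major flat weights
                     b = s$b, filter = s$filter,
                     cin = s$cin, cout = s$cout)))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname srcnn_save
#' @export
srcnn_load <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  field <- function(f, i) {
    v <- if (is.data.frame(obj$stages)) obj$stages[[f]] else
      lapply(obj$stages, `[[`, f)
    if (is.list(v)) v[[i]] else v[i]
  }
  stages <- lapply(seq_len(3), function(i) {
    list(W = matrix(as.numeric(field("W", i)),
                    nrow = field("filter", i)^2 * field("cin", i),
                    ncol = field("cout", i)),
         b = as.numeric(field("b", i)), filter = as.integer(field("filter", i)),
         cin = as.integer(field("cin", i)), cout = as.integer(field("cout", i)))
  })
  structure(list(stages = stages, filters = as.integer(obj$filters),
                 channels = as.integer(obj$channels),
                 pre_upscale = obj$pre_upscale),
            class = "srcnn_model")
}
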