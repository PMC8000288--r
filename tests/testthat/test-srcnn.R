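tiny_cfg <- list(filters = c(3L, 1L, 3L), channels = c(2L, 2L, 1L))

test_that("an all-zero network maps everything to zero", {
  m <- srcnn_model(tiny_cfg$filters, tiny_cfg$channels, seed = 1)
  for (k in 1:3) { m$stages[[k]]$W[] <- 0; m$stages[[k]]$b[] <- 0 }
  out <- srcnn_apply(m, matrix(100, 8, 8), factor = 2)
  expect_equal(dim(out), c(16L, 16L))
  expect_equal(max(abs(out)), 0)
})

test_that("a pass-through network reproduces the bicubic pre-upscale", {
  m <- srcnn_model(tiny_cfg$filters, tiny_cfg$channels, init_sd = 0, seed = 1)
  # init_sd = 0 leaves exactly the center-tap identity path
  img <- 100 + 50 * outer(sin(seq(0, pi, length.out = 8)),
                          cos(seq(0, pi / 2, length.out = 8)))
  out <- srcnn_apply(m, img, factor = 2)
  expect_equal(out, resize_image(img, 16, 16, "keys_cubic"), tolerance = 1e-10)
})

test_that("backpropagation matches numeric gradients on a tiny model", {
  set.seed(4)
  h <- 6L; w <- 6L
  m <- srcnn_model(c(3L, 1L, 3L), c(2L, 2L, 1L), init_sd = 0.1, seed = 3)
  # bias the net away from exact ReLU kinks so two-sided differences are valid
  for (k in 1:2) m$stages[[k]]$b[] <- 0.05
  x <- matrix(runif(h * w), ncol = 1)
  y <- matrix(runif(h * w), ncol = 1)
  idx1 <- periosr:::im2col_index(h, w, 3L)
  idx3 <- periosr:::im2col_index(h, w, 3L)
  fw <- periosr:::srcnn_forward(m, x, idx1, idx3)
  N <- h * w
  d3 <- 2 * (fw$Z3 - y) / N
  g3W <- crossprod(fw$P3, d3)
  dA2 <- periosr:::scatter_add(d3 %*% t(m$stages[[3]]$W), idx3, 2)
  d2 <- dA2 * (fw$Z2 > 0)
  g2W <- crossprod(fw$A1, d2)
  d1 <- (d2 %*% t(m$stages[[2]]$W)) * (fw$Z1 > 0)
  g1W <- crossprod(fw$P1, d1)
  loss_fn <- function(model) {
    f <- periosr:::srcnn_forward(model, x, idx1, idx3)
    mean((f$Z3 - y)^2)
  }
  numeric_grad <- function(stage, i, j) {
    eps <- 1e-6
    mp <- m; mp$stages[[stage]]$W[i, j] <- mp$stages[[stage]]$W[i, j] + eps
    mm <- m; mm$stages[[stage]]$W[i, j] <- mm$stages[[stage]]$W[i, j] - eps
    (loss_fn(mp) - loss_fn(mm)) / (2 * eps)
  }
  for (probe in list(c(1, 4, 2), c(1, 9, 1), c(2, 1, 2), c(3, 5, 1), c(3, 14, 1))) {
    g <- list(g1W, g2W, g3W)[[probe[1]]]
    expect_equal(g[probe[2], probe[3]],
                 numeric_grad(probe[1], probe[2], probe[3]), tolerance = 1e-5)
  }
})

test_that("training reduces the loss and is deterministic given the seed", {
  pairs <- phantom_patches(6, 400, size = 16L)
  m1 <- srcnn_train(pairs, tiny_cfg$filters, tiny_cfg$channels,
                    learning_rate = 0.1, iterations = 40L, seed = 9L)
  m2 <- srcnn_train(pairs, tiny_cfg$filters, tiny_cfg$channels,
                    learning_rate = 0.1, iterations = 40L, seed = 9L)
  tr <- attr(m1, "loss_trace")
  expect_lt(attr(m1, "best_loss"), tr[1])
  expect_true(all(diff(tr) <= 1e-15))  # adaptive steps never increase loss
  expect_equal(m1$stages, m2$stages)
})

test_that("the zero-residual task converges to near-zero loss", {
  # target equals the bicubic upscale of the input, so the identity
  # initialization is already near the optimum and descent stays there
  pairs <- lapply(phantom_patches(4, 700, size = 16L), function(p)
    list(low = p$low, high = resize_image(p$low, 16, 16, "keys_cubic")))
  m <- srcnn_train(pairs, tiny_cfg$filters, tiny_cfg$channels,
                   learning_rate = 0.1, iterations = 40L, seed = 2L)
  expect_lt(attr(m, "best_loss"), 1e-5)
})

test_that("models survive a JSON round trip", {
  m <- srcnn_train(phantom_patches(3, 50, size = 16L), tiny_cfg$filters,
                   tiny_cfg$channels, iterations = 5L, seed = 1L)
  path <- tempfile(fileext = ".json")
  srcnn_save(m, path)
  m2 <- srcnn_load(path)
  img <- phantom_patches(1, 999, size = 16L)[[1]]$low
  expect_equal(srcnn_apply(m2, img, factor = 2), srcnn_apply(m, img, factor = 2))
})

test_that("invalid training inputs are rejected", {
  expect_error(srcnn_train(list()), "at least one")
  p <- phantom_patches(2, 1, size = 16L)
  expect_error(srcnn_train(p, learning_rate = 0), "positive")
  p[[2]]$high <- p[[2]]$high[1:8, 1:8]
  expect_error(srcnn_train(p), "same low/high dimensions")
})
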