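#' Latent-quality observer rating model
#'
#' A cumulative-threshold (ordered-categorical) model for mean-opinion-score
#' ratings on the 4-level scale (1 = poor ... 4 = very high). Each rating of
#' an image treated with a given method arises from a latent quality value
#'
#' `latent = method_quality[method] + observer_bias[observer] + noise`
#'
#' with Gaussian noise, cut by three increasing thresholds into the four
#' score levels: `score = 1 + #\{thresholds below latent\}`. Raising a
#' method's latent quality shifts its whole score distribution stochastically
#' upward, which is exactly the ordering the VGC analysis measures.
#'
#' @param method_quality named numeric vector: latent quality per method
#'   (arbitrary scale).
#' @param observer_bias named numeric vector: additive offset per observer.
#' @param observer_noise_sd positive noise standard deviation.
#' @param thresholds three strictly increasing cutpoints.
#' @param seed integer seed.
#' @return an object of class `observer_model`.
#' @export
observer_model <- function(method_quality, observer_bias,
                           observer_noise_sd = 1,
                           thresholds = c(-0.5, 0.5, 1.5), seed = 1L) {
  if (length(method_quality) < 1 || is.null(names(method_quality)))
    stop("method_quality must be a non-empty named vector")
  if (length(observer_bias) < 1 || is.null(names(observer_bias)))
    stop("observer_bias must be a non-empty named vector")
  if (observer_noise_sd <= 0) stop("observer_noise_sd must be > 0")
  if (length(thresholds) != 3 || any(diff(thresholds) <= 0))
    stop("thresholds must be 3 strictly increasing values")
  structure(list(method_quality = method_quality,
                 observer_bias = observer_bias,
                 observer_noise_sd = observer_noise_sd,
                 thresholds = thresholds, seed = as.integer(seed)),
            class = "observer_model")
}

#' Default latent qualities for the six resolution-improvement methods
#'
#' Evenly spaced latent qualities encoding the expected ordering
#' nearest < bilinear < bicubic < lanczos < srcnn < srgan.
#'
#' @param gap latent-quality spacing between consecutive methods.
#' @return named numeric vector over the six methods.
#' @export
default_method_quality <- function(gap = 0.4) {
  q <- seq(0, by = gap, length.out = 6)
  names(q) <- c("nearest", "bilinear", "bicubic", "lanczos", "srcnn", "srgan")
  q
}

#' Simulate an observer rating table
#'
#' Draws one MOS score per (observer, image, method) triple from the latent
#' ordinal model, producing a complete rating table.
#'
#' @param model an [observer_model()].
#' @param image_ids character or integer vector of image identifiers.
#' @param observers data frame with columns `observer_id` and `group`
#'   (values `"expert"` or `"lay"`); every `observer_id` must appear in the
#'   model's `observer_bias`.
#' @return a `rating_table` data frame with columns `observer_id`, `group`,
#'   `image_id`, `method`, `score`.
#' @export
simulate_ratings <- function(model, image_ids, observers) {
  stopifnot(inherits(model, "observer_model"))
  if (length(image_ids) < 1) stop("empty image list")
  if (nrow(observers) < 1) stop("empty observer list")
  if (!all(c("observer_id", "group") %in% names(observers)))
    stop("observers needs columns observer_id and group")
  missing_obs <- setdiff(observers$observer_id, names(model$observer_bias))
  if (length(missing_obs)) stop("no bias for observer(s): ",
                                paste(missing_obs, collapse = ", "))
  methods <- names(model$method_quality)
  grid <- expand.grid(observer_id = observers$observer_id,
                      image_id = image_ids, method = methods,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$group <- observers$group[match(grid$observer_id, observers$observer_id)]
  latent <- model$method_quality[grid$method] +
    model$observer_bias[grid$observer_id] +
    with_seed(model$seed, stats::rnorm(nrow(grid), sd = model$observer_noise_sd))
  grid$score <- 1L + findInterval(latent, model$thresholds)
  out <- grid[, c("observer_id", "group", "image_id", "method", "score")]
  rating_table(out)
}

#' Specification of a simulated binary classifier
#'
#' Scores for the two classes are drawn from unit-variance Gaussians whose
#' means differ by `separation_d`, then squashed to \[0, 1\] with the
#' logistic function (a strictly monotone map, so rank-based measures such
#' as ROC AUC are unchanged). The expected ROC AUC is the binormal closed
#' form `pnorm(separation_d / sqrt(2))`.
#'
#' @param n_pos,n_neg class sample counts (>= 1); positives are labelled
#'   `"PBL"`, negatives `"healthy"`.
#' @param separation_d difference of class score means in units of the
#'   common spread (>= 0).
#' @param seed integer seed.
#' @return an object of class `classifier_sim_spec`.
#' @export
classifier_sim_spec <- function(n_pos, n_neg, separation_d = 1, seed = 1L) {
  if (n_pos < 1 || n_neg < 1) stop("n_pos and n_neg must be >= 1")
  if (separation_d < 0) stop("separation_d must be >= 0")
  structure(list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 separation_d = separation_d, seed = as.integer(seed)),
            class = "classifier_sim_spec")
}

#' Simulate scored binary predictions
#'
#' @param spec a [classifier_sim_spec()].
#' @return a `prediction_set` data frame with columns `sample_id`, `label`
#'   (`"healthy"`/`"PBL"`) and `score` in \[0, 1\].
#' @export
simulate_classifier_scores <- function(spec) {
  stopifnot(inherits(spec, "classifier_sim_spec"))
  n <- spec$n_pos + spec$n_neg
  latent <- with_seed(spec$seed, {
    c(stats::rnorm(spec$n_neg, mean = 0),
      stats::rnorm(spec$n_pos, mean = spec$separation_d))
  })
  out <- data.frame(
    sample_id = sprintf("s%05d", seq_len(n)),
    label = c(rep("healthy", spec$n_neg), rep("PBL", spec$n_pos)),
    score = stats::plogis(latent),
    stringsAsFactors = FALSE)
  class(out) <- c("prediction_set", class(out))
  out
}
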