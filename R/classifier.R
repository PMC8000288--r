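#' Global histogram equalization
#'
#' Maps each 8-bit intensity level v to `round(255 * cdf(v))` where `cdf`
#' is the normalized cumulative histogram of the image. Constant images are
#' returned unchanged (their histogram is degenerate and the mapping would
#' only relabel the single level).
#'
#' @param img numeric matrix with integer-valued intensities in \[0, 255\]
#'   (real-valued input is quantized first).
#' @return equalized matrix with integer values in \[0, 255\].
#' @export
equalize_histogram <- function(img) {
  img <- quantize_image(img)
  if (length(unique(as.vector(img))) == 1L) return(img)
  counts <- tabulate(as.vector(img) + 1L, nbins = 256L)
  cdf <- cumsum(counts) / length(img)
  lut <- floor(255 * cdf + 0.5)    # round half up; values are nonnegative
  matrix(lut[img + 1L], nrow(img), ncol(img))
}

#' Dataset split specification
#'
#' Controls how a labeled image set is prepared for classifier training:
#' how many untouched originals per class form the test set, the
#' train-validation ratio, and the flip-augmentation operations per class.
#'
#' @param test_per_class originals held out per class for testing
#'   (default 52, i.e. a 104-region test set).
#' @param train_fraction fraction of the remaining originals assigned to
#'   training (default 0.8, an 80:20 train-validation ratio).
#' @param augment_ops named list of flip operations per class label; the
#'   defaults double the PBL class (horizontal flip) and triple the healthy
#'   class (horizontal + vertical flips).
#' @param seed integer seed controlling the shuffle.
#' @return an object of class `split_spec`.
#' @export
split_spec <- function(test_per_class = 52L, train_fraction = 0.8,
                       augment_ops = list(PBL = "horizontal",
                                          healthy = c("horizontal", "vertical")),
                       seed = 1L) {
  stopifnot(test_per_class >= 0, train_fraction > 0, train_fraction < 1)
  structure(list(test_per_class = as.integer(test_per_class),
                 train_fraction = train_fraction, augment_ops = augment_ops,
                 seed = as.integer(seed)),
            class = "split_spec")
}

#' Flip-augment a labeled image set
#'
#' Each image yields its original plus the class-specific flips declared in
#' the spec; provenance (`source_id`, `op`) is recorded per output row.
#'
#' @param set data frame with columns `id`, `label` and a list-column
#'   `image` of numeric matrices.
#' @param spec a [split_spec()].
#' @return augmented data frame with columns `id`, `label`, `source_id`,
#'   `op`, `image`.
#' @export
augment_set <- function(set, spec = split_spec()) {
  stopifnot(all(c("id", "label", "image") %in% names(set)))
  unknown <- setdiff(unique(set$label), names(spec$augment_ops))
  if (length(unknown)) stop("no augmentation ops declared for label(s): ",
                            paste(unknown, collapse = ", "))
  rows <- lapply(seq_len(nrow(set)), function(i) {
    ops <- spec$augment_ops[[set$label[i]]]
    ids <- c(set$id[i], paste0(set$id[i], "_", substr(ops, 1, 1), "flip"))
    imgs <- c(list(set$image[[i]]),
              lapply(ops, function(o) flip_image(set$image[[i]], o)))
    data.frame(id = ids, label = set$label[i], source_id = set$id[i],
               op = c("orig", ops), stringsAsFactors = FALSE,
               image = I(imgs))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Split a labeled image set into train / validation / test partitions
#'
#' `test_per_class` originals per class are set aside untouched (never
#' augmented). The remaining originals are flip-augmented and then split
#' into training and validation at the original-image level: every
#' augmented copy follows its source image, so no image (or flipped version
#' of it) can appear on both sides of the boundary. Deterministic given the
#' spec seed.
#'
#' @param set data frame with columns `id`, `label`, list-column `image`.
#' @param spec a [split_spec()].
#' @return list of data frames `train`, `val`, `test` (test rows are
#'   originals only).
#' @export
split_set <- function(set, spec = split_spec()) {
  stopifnot(all(c("id", "label", "image") %in% names(set)))
  labels <- unique(set$label)
  test_idx <- integer(0)
  train_src <- character(0)
  with_seed(spec$seed, {
    for (lb in labels) {
      idx <- which(set$label == lb)
      if (length(idx) <= spec$test_per_class)
        stop("not enough '", lb, "' originals for the test quota")
      idx <- sample(idx)  # shuffle within class
      test_idx <- c(test_idx, idx[seq_len(spec$test_per_class)])
      rest <- idx[-seq_len(spec$test_per_class)]
      n_train <- round(spec$train_fraction * length(rest))
      train_src <- c(train_src, set$id[rest[seq_len(n_train)]])
    }
  })
  test <- set[test_idx, , drop = FALSE]
  remain <- set[-test_idx, , drop = FALSE]
  aug <- augment_set(remain, spec)
  in_train <- aug$source_id %in% train_src
  list(train = aug[in_train, , drop = FALSE],
       val = aug[!in_train, , drop = FALSE],
       test = test)
}

#' 2x2 confusion matrix
#'
#' Positive class is PBL (periodontal bone loss), negative class healthy.
#'
#' @param tn,fp,fn,tp nonnegative integer counts: healthy correctly
#'   classified, healthy called PBL, PBL called healthy, PBL correctly
#'   classified.
#' @return an object of class `confusion_matrix`.
#' @export
confusion_matrix <- function(tn, fp, fn, tp) {
  counts <- c(tn = tn, fp = fp, fn = fn, tp = tp)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  if (sum(counts) < 1) stop("confusion matrix must contain at least one count")
  structure(as.list(counts), class = "confusion_matrix")
}

#' Diagnostic metrics from a confusion matrix
#'
#' Sensitivity (recall) `tp/(fn+tp)`, specificity `tn/(fp+tn)`, precision
#' (PPV) `tp/(fp+tp)`, negative predictive value `tn/(fn+tn)` and accuracy
#' `(tp+tn)/n`. A metric whose denominator is zero is reported as `NA` and
#' listed in `undefined` — never silently as 0.
#'
#' @param cm a [confusion_matrix()].
#' @return object of class `metric_report`: list with the five metrics,
#'   `fractions` (numerator/denominator strings of the exact rationals) and
#'   `undefined` (names of metrics with zero denominator).
#' @export
confusion_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  num <- c(sensitivity = cm$tp, specificity = cm$tn, ppv = cm$tp,
           npv = cm$tn, accuracy = cm$tp + cm$tn)
  den <- c(sensitivity = cm$fn + cm$tp, specificity = cm$fp + cm$tn,
           ppv = cm$fp + cm$tp, npv = cm$fn + cm$tn,
           accuracy = cm$tn + cm$fp + cm$fn + cm$tp)
  vals <- ifelse(den > 0, num / den, NA_real_)
  structure(list(sensitivity = vals[["sensitivity"]],
                 specificity = vals[["specificity"]],
                 ppv = vals[["ppv"]], npv = vals[["npv"]],
                 accuracy = vals[["accuracy"]],
                 fractions = paste0(num, "/", den),
                 undefined = names(den)[den == 0]),
            class = "metric_report")
}

#' ROC and precision-recall curves with AUCs
#'
#' Thresholds sweep the distinct scores in descending order with tied
#' scores grouped, so the ROC curve moves diagonally through ties; its
#' trapezoidal AUC equals the rank statistic
#' `P(score_pos > score_neg) + 0.5 P(equal)`. The PR AUC uses the step
#' convention: precision at each threshold weighted by the recall
#' increment (as in average precision).
#'
#' @param preds a `prediction_set` data frame (columns `sample_id`, `label`
#'   in `{"healthy", "PBL"}`, `score` in \[0, 1\]); both classes must be
#'   present.
#' @return list with `roc` (data frame `threshold`, `fpr`, `tpr`), `pr`
#'   (data frame `threshold`, `recall`, `precision`), `roc_auc`, `pr_auc`.
#' @export
roc_pr_curves <- function(preds) {
  stopifnot(all(c("label", "score") %in% names(preds)))
  pos <- preds$label == "PBL"
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present")
  thr <- sort(unique(preds$score), decreasing = TRUE)
  tp <- cumsum(vapply(thr, function(t) sum(pos & preds$score == t), numeric(1)))
  fp <- cumsum(vapply(thr, function(t) sum(!pos & preds$score == t), numeric(1)))
  tpr <- c(0, tp / n_pos); fpr <- c(0, fp / n_neg)
  roc <- data.frame(threshold = c(Inf, thr), fpr = fpr, tpr = tpr)
  roc_auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  recall <- tp / n_pos
  precision <- tp / (tp + fp)
  pr <- data.frame(threshold = thr, recall = recall, precision = precision)
  pr_auc <- sum(diff(c(0, recall)) * precision)
  list(roc = roc, pr = pr, roc_auc = roc_auc, pr_auc = pr_auc)
}

#' Read a confusion-matrix CSV
#'
#' Schema: `model,tn,fp,fn,tp` (extra annotation columns are preserved).
#' Each row is checked against `expected_n`; rows whose cells do not sum to
#' it are flagged `consistent = FALSE` but kept.
#'
#' @param path file path.
#' @param expected_n expected total count per matrix (`NA` to skip the
#'   check).
#' @return data frame with an added logical `consistent` column.
#' @export
read_confusion_csv <- function(path, expected_n = NA) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("model", "tn", "fp", "fn", "tp")
  if (!all(need %in% names(df)))
    stop("confusion CSV needs columns: ", paste(need, collapse = ", "))
  n <- df$tn + df$fp + df$fn + df$tp
  df$consistent <- if (is.na(expected_n)) TRUE else n == expected_n
  df
}

#' Read a prediction CSV
#'
#' Schema: `sample_id,label,score` with labels in `{"healthy", "PBL"}` and
#' scores in \[0, 1\].
#'
#' @param path file path.
#' @return a `prediction_set` data frame.
#' @export
read_prediction_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "label", "score")
  if (!all(need %in% names(df)))
    stop("prediction CSV needs columns: ", paste(need, collapse = ", "))
  if (!all(df$label %in% c("healthy", "PBL")))
    stop("labels must be 'healthy' or 'PBL'")
  if (any(df$score < 0 | df$score > 1)) stop("scores must lie in [0, 1]")
  class(df) <- c("prediction_set", class(df))
  df
}
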