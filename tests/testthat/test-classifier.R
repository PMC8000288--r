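test_that("histogram equalization maps levels through the cumulative histogram", {
  img <- matrix(10, 20, 20)
  img[1:5, ] <- 10          # 25% at level 10, 75% at level 200
  img[6:20, ] <- 200
  eq <- equalize_histogram(img)
  expect_setequal(unique(as.vector(eq)), c(64, 255))  # round(255 * cdf)
  expect_equal(eq[img == 10][1], 64)

  const <- matrix(77, 8, 8)
  expect_equal(equalize_histogram(const), const)

  ramp <- matrix(rep(0:255, each = 4), 32, 32)  # already uniform histogram
  expect_lte(max(abs(equalize_histogram(ramp) - ramp)), 1)
})

make_labeled_set <- function(n_pbl, n_healthy, size = 8) {
  n <- n_pbl + n_healthy
  set.seed(99)
  data.frame(id = sprintf("r%03d", seq_len(n)),
             label = c(rep("PBL", n_pbl), rep("healthy", n_healthy)),
             stringsAsFactors = FALSE,
             image = I(lapply(seq_len(n), function(i)
               matrix(runif(size^2, 0, 255), size, size))))
}

test_that("augmentation applies the declared per-class flip operations", {
  set <- make_labeled_set(10, 10)
  aug <- augment_set(set, split_spec())
  expect_equal(sum(aug$label == "PBL"), 20)       # original + horizontal flip
  expect_equal(sum(aug$label == "healthy"), 30)   # original + two flips
  expect_true(all(aug$source_id %in% set$id))
  # flips are involutions
  img <- set$image[[1]]
  expect_equal(flip_image(flip_image(img, "horizontal"), "horizontal"), img)
  expect_equal(flip_image(flip_image(img, "vertical"), "vertical"), img)
  hf <- aug$image[[which(aug$op == "horizontal")[1]]]
  src <- aug$source_id[which(aug$op == "horizontal")[1]]
  expect_equal(flip_image(hf, "horizontal"), set$image[[which(set$id == src)]])
  bad <- set; bad$label[1] <- "unknown"
  expect_error(augment_set(bad), "unknown")
})

test_that("splitting honors the test quota, avoids leakage, and is deterministic", {
  set <- make_labeled_set(60, 60)
  spec <- split_spec(test_per_class = 10, seed = 5)
  sp <- split_set(set, spec)
  expect_equal(nrow(sp$test), 20)
  expect_true(all(table(sp$test$label) == 10))
  expect_false("op" %in% names(sp$test) && any(sp$test$op != "orig"))
  # no source image straddles partitions
  src_of <- function(d) unique(if ("source_id" %in% names(d)) d$source_id else d$id)
  expect_length(intersect(src_of(sp$train), src_of(sp$val)), 0)
  expect_length(intersect(src_of(sp$train), src_of(sp$test)), 0)
  expect_length(intersect(src_of(sp$val), src_of(sp$test)), 0)
  # 80:20 at the original level
  expect_equal(length(src_of(sp$train)) / (length(src_of(sp$train)) +
                                           length(src_of(sp$val))), 0.8)
  sp2 <- split_set(set, spec)
  expect_identical(sp$test$id, sp2$test$id)
  expect_identical(sp$train$id, sp2$train$id)
  expect_error(split_set(make_labeled_set(5, 60), spec), "quota")
})

test_that("confusion metrics reproduce the published model rows", {
  mr <- confusion_metrics(confusion_matrix(19, 33, 3, 49))
  expect_equal(round(mr$sensitivity, 3), 0.942)
  expect_equal(round(mr$specificity, 3), 0.365)
  expect_equal(round(mr$ppv, 3), 0.598)
  expect_equal(round(mr$npv, 3), 0.864)
  expect_equal(round(mr$accuracy, 3), 0.654)
  mr2 <- confusion_metrics(confusion_matrix(25, 27, 1, 51))
  expect_equal(round(mr2$npv, 3), 0.962)
  expect_equal(round(mr2$accuracy, 3), 0.731)
  perfect <- confusion_metrics(confusion_matrix(50, 0, 0, 50))
  expect_equal(unlist(perfect[c("sensitivity", "specificity", "ppv", "npv",
                                "accuracy")], use.names = FALSE), rep(1, 5))
})

test_that("zero denominators yield explicit undefined metrics, never zero", {
  mr <- confusion_metrics(confusion_matrix(0, 0, 3, 49))  # no healthy samples
  expect_true(is.na(mr$specificity))
  expect_true("specificity" %in% mr$undefined)
  expect_equal(mr$sensitivity, 49 / 52)
  expect_error(confusion_matrix(0, 0, 0, 0), "at least one")
  expect_error(confusion_matrix(-1, 0, 0, 2), "nonnegative")
})

test_that("metrics depend only on their own margins", {
  base <- confusion_metrics(confusion_matrix(19, 33, 3, 49))
  moved <- confusion_metrics(confusion_matrix(5, 47, 3, 49))  # healthy row changed
  expect_equal(moved$sensitivity, base$sensitivity)
  expect_equal(moved$npv == base$npv, FALSE)  # npv uses tn
  moved2 <- confusion_metrics(confusion_matrix(19, 33, 10, 42))  # PBL row changed
  expect_equal(moved2$specificity, base$specificity)
})

test_that("ROC and PR curves agree with rank statistics and tie conventions", {
  sep <- data.frame(sample_id = 1:6,
                    label = rep(c("healthy", "PBL"), each = 3),
                    score = c(0.1, 0.2, 0.3, 0.7, 0.8, 0.9))
  cr <- roc_pr_curves(sep)
  expect_equal(cr$roc_auc, 1)
  expect_equal(cr$pr_auc, 1)

  tied <- data.frame(sample_id = 1:8,
                     label = rep(c("healthy", "PBL"), 4), score = 0.5)
  expect_equal(roc_pr_curves(tied)$roc_auc, 0.5)

  set.seed(12)
  preds <- data.frame(sample_id = 1:30,
                      label = sample(c("healthy", "PBL"), 30, replace = TRUE,
                                     prob = c(0.5, 0.5)),
                      score = round(runif(30), 1))   # rounded: forces ties
  if (length(unique(preds$label)) == 2) {
    cr2 <- roc_pr_curves(preds)
    expect_equal(cr2$roc_auc, brute_roc_auc(preds$label, preds$score))
    # invariance under strictly monotone score transforms
    preds2 <- preds; preds2$score <- plogis(5 * preds$score - 2)
    expect_equal(roc_pr_curves(preds2)$roc_auc, cr2$roc_auc)
  }
  expect_error(roc_pr_curves(data.frame(sample_id = 1, label = "PBL",
                                        score = 0.5)), "both classes")
})

test_that("prediction and confusion CSV readers validate their schemas", {
  path <- tempfile(fileext = ".csv")
  write.csv(data.frame(sample_id = 1:4, label = c("PBL", "healthy", "PBL", "healthy"),
                       score = c(0.9, 0.1, 0.6, 0.4)), path, row.names = FALSE)
  preds <- read_prediction_csv(path)
  expect_s3_class(preds, "prediction_set")
  write.csv(data.frame(sample_id = 1, label = "PBL", score = 2), path,
            row.names = FALSE)
  expect_error(read_prediction_csv(path), "0, 1")
  cm <- read_confusion_csv(periosr_example("confusion_matrices.csv"),
                           expected_n = 104)
  expect_equal(nrow(cm), 12)
  expect_equal(cm$model[!cm$consistent], "Inception_Bilinear")
})
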