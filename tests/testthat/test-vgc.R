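test_that("score distributions reproduce the worked observer example", {
  rt <- fixture_ratings()
  d <- score_distribution(rt, "bicubic", "expert1")
  expect_equal(d$prob, c(0.6, 0.4, 0, 0))
  expect_equal(unname(cumulative_top_down(d)), c(0, 0, 0.4, 1.0))
  d2 <- score_distribution(rt, "nearest", "experts-all")
  expect_equal(d2$counts, c(9, 6, 8, 2))
  expect_equal(d2$prob, c(0.36, 0.24, 0.32, 0.08))
  expect_error(score_distribution(rt, "srgan2000"), "no ratings")
})

test_that("top-down cumulatives are monotone and end at one", {
  u <- periosr:::score_distribution_from_counts(c(1, 1, 1, 1))
  expect_equal(unname(cumulative_top_down(u)), c(0.25, 0.5, 0.75, 1))
  set.seed(2)
  for (i in 1:25) {
    cm <- cumulative_top_down(periosr:::score_distribution_from_counts(random_counts()))
    expect_true(all(diff(cm) >= 0))       # C(4) <= C(3) <= C(2) <= C(1)
    expect_equal(unname(cm[4]), 1)
  }
})

test_that("VGC curves carry the anchored cumulative points", {
  rt <- fixture_ratings()
  cv <- vgc_curve(score_distribution(rt, "nearest", "experts-all"),
                  score_distribution(rt, "bilinear", "experts-all"))
  expect_equal(unname(cv$points[, 1]), c(0, 0.08, 0.40, 0.64, 1))
  expect_equal(unname(cv$points[, 2]), c(0, 0.08, 0.32, 0.56, 1))
  expect_equal(cv$auc, 0.4536, tolerance = 1e-12)
})

test_that("self-comparison sits on the diagonal with AUC one half", {
  set.seed(3)
  for (i in 1:25) {
    d <- periosr:::score_distribution_from_counts(random_counts())
    cv <- vgc_curve(d, d)
    expect_equal(cv$points[, 1], cv$points[, 2])
    expect_equal(cv$auc, 0.5)
  }
})

test_that("stochastic dominance lifts the curve and never lowers the AUC", {
  a <- periosr:::score_distribution_from_counts(c(6, 2, 1, 1))
  b <- periosr:::score_distribution_from_counts(c(1, 1, 2, 6))  # dominates a
  cv <- vgc_curve(a, b)
  expect_true(all(cv$points[, 2] >= cv$points[, 1] - 1e-12))  # curve above diagonal
  expect_gt(cv$auc, 0.5)
  # moving mass of b from score 1 to score 4 cannot decrease AUC(a, b)
  set.seed(4)
  for (i in 1:20) {
    k <- random_counts(); k[1] <- k[1] + 2
    b1 <- periosr:::score_distribution_from_counts(k)
    k2 <- k; k2[1] <- k2[1] - 2; k2[4] <- k2[4] + 2
    b2 <- periosr:::score_distribution_from_counts(k2)
    a1 <- periosr:::score_distribution_from_counts(random_counts())
    expect_gte(vgc_curve(a1, b2)$auc, vgc_curve(a1, b1)$auc - 1e-12)
  }
})

test_that("the AUC matrix covers all pairs and populations with complement symmetry", {
  rt <- fixture_ratings()
  m <- vgc_matrix(rt, "all", c("experts-all", "lay-all"))
  expect_equal(nrow(m), 15)
  swapped <- vgc_matrix(rt, list(c("bilinear", "nearest")), "experts-all")
  expect_equal(swapped[["experts-all"]] + m[["experts-all"]][1], 1)
  same <- vgc_matrix(rt, list(c("srgan", "srgan")), "all")
  expect_equal(same[["all"]], 0.5)
  expect_error(vgc_matrix(rt, list(c("nearest", "srgan2"))), "missing")
  # per-observer populations work too
  m1 <- vgc_matrix(rt, list(c("nearest", "srgan")), "expert2")
  expect_gt(m1[["expert2"]], 0.5)
})

test_that("one-sided Wilcoxon matches exact enumeration and flags degenerate input", {
  tab3 <- rating_table(data.frame(
    observer_id = "o1", group = "expert",
    image_id = rep(paste0("i", 1:3), 2),
    method = rep(c("A", "B"), each = 3), score = c(1, 1, 1, 2, 2, 2)))
  w <- wilcoxon_one_sided(tab3, "A", "B")
  expect_equal(w$p_value, 1 / 8)    # all three differences positive
  expect_equal(w$method, "exact")

  same <- rating_table(data.frame(
    observer_id = "o1", group = "expert", image_id = rep(paste0("i", 1:3), 2),
    method = rep(c("A", "B"), each = 3), score = rep(2, 6)))
  expect_true(wilcoxon_one_sided(same, "A", "B")$indeterminate)

  # 7 gains and 1 loss of one scale step, against exhaustive enumeration
  tab8 <- rating_table(data.frame(
    observer_id = "o1", group = "expert", image_id = rep(paste0("i", 1:8), 2),
    method = rep(c("A", "B"), each = 8),
    score = c(rep(2, 8), rep(3, 7), 1)))
  w8 <- wilcoxon_one_sided(tab8, "A", "B")
  expect_equal(w8$p_value, brute_signed_rank_p(c(rep(1, 7), -1)))

  set.seed(6)
  for (i in 1:10) {
    n <- sample(4:10, 1)
    sa <- sample(1:4, n, replace = TRUE)
    sb <- pmin(4, pmax(1, sa + sample(-1:2, n, replace = TRUE)))
    tab <- rating_table(data.frame(
      observer_id = "o1", group = "expert", image_id = rep(paste0("i", 1:n), 2),
      method = rep(c("A", "B"), each = n), score = c(sa, sb)))
    if (all(sb == sa)) next
    expect_equal(wilcoxon_one_sided(tab, "A", "B")$p_value,
                 brute_signed_rank_p(sb - sa))
  }
})

test_that("the normal approximation tracks the exact tail for moderate n", {
  set.seed(8)
  n <- 12
  sa <- sample(1:3, n, replace = TRUE)
  sb <- pmin(4, sa + sample(0:2, n, replace = TRUE))
  tab <- rating_table(data.frame(
    observer_id = "o1", group = "expert", image_id = rep(paste0("i", 1:n), 2),
    method = rep(c("A", "B"), each = n), score = c(sa, sb)))
  exact <- wilcoxon_one_sided(tab, "A", "B")$p_value
  approx <- wilcoxon_one_sided(tab, "A", "B", exact_limit = 0L)$p_value
  expect_equal(approx, exact, tolerance = 0.25)  # loose: asymptotic regime
})

test_that("rating-table validation catches malformed inputs", {
  df <- data.frame(observer_id = "o", group = "expert", image_id = "i",
                   method = "m", score = 5)
  expect_error(rating_table(df), "1..4")
  df$score <- 2
  dup <- rbind(df, df)
  expect_error(rating_table(dup), "one rating")
  df$group <- "dentist"
  expect_error(rating_table(df), "group")
})
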