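#' Ordinal observer rating tables
#'
#' A rating table holds one mean-opinion-score (MOS) rating per
#' (observer, image, method) triple on the 4-level scale 1 = poor,
#' 2 = reasonable, 3 = good, 4 = very high. Observers belong to one of two
#' groups, `"expert"` or `"lay"`.
#'
#' @param df data frame with columns `observer_id`, `group`, `image_id`,
#'   `method`, `score`.
#' @return a validated `rating_table` data frame.
#' @export
rating_table <- function(df) {
  need <- c("observer_id", "group", "image_id", "method", "score")
  if (!all(need %in% names(df))) {
    stop("rating table needs columns: ", paste(need, collapse = ", "))
  }
  df <- as.data.frame(df)[, need]
  for (col in c("observer_id", "group", "image_id", "method"))
    df[[col]] <- as.character(df[[col]])
  if (!all(df$score %in% 1:4)) stop("scores must lie in 1..4")
  if (!all(df$group %in% c("expert", "lay")))
    stop("group must be 'expert' or 'lay'")
  key <- paste(df$observer_id, df$image_id, df$method, sep = "\r")
  if (anyDuplicated(key))
    stop("at most one rating per (observer, image, method)")
  df$score <- as.integer(df$score)
  class(df) <- c("rating_table", "data.frame")
  df
}

#' Read / write a rating table CSV
#'
#' CSV schema: `observer_id,group,image_id,method,score`.
#'
#' @param path file path.
#' @return a `rating_table` (for the reader).
#' @export
read_rating_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("empty ratings file: ", path)
  bad <- which(!(suppressWarnings(as.numeric(df$score)) %in% 1:4))
  if (length(bad))
    stop("malformed score at data line(s): ", paste(bad, collapse = ", "))
  rating_table(df)
}

#' @rdname read_rating_table
#' @param table a `rating_table`.
#' @export
write_rating_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# select rows of a rating table for a method and a population
# population: an observer_id, or "experts-all", "lay-all", "all"
filter_population <- function(table, population) {
  switch(population,
    "all" = table,
    "experts-all" = table[table$group == "expert", , drop = FALSE],
    "lay-all" = table[table$group == "lay", , drop = FALSE],
    table[table$observer_id == population, , drop = FALSE])
}

#' Score distribution of a method for a population
#'
#' Counts and probabilities of the four MOS levels over all ratings of a
#' method within a population: a single observer (pass the observer id), all
#' experts (`"experts-all"`), all lay participants (`"lay-all"`), or every
#' observer pooled (`"all"`). Group distributions pool all member ratings
#' into one count table.
#'
#' @param table a `rating_table`.
#' @param method method name.
#' @param population population selector (see Details).
#' @return an object of class `score_distribution` with fields `method`,
#'   `population`, `counts` (length 4, scores 1..4) and `prob`.
#' @export
score_distribution <- function(table, method, population = "all") {
  rows <- filter_population(table, population)
  rows <- rows[rows$method == method, , drop = FALSE]
  if (nrow(rows) == 0)
    stop("no ratings for method '", method, "' in population '", population, "'")
  counts <- tabulate(rows$score, nbins = 4)
  structure(list(method = method, population = population,
                 counts = counts, prob = counts / sum(counts)),
            class = "score_distribution")
}

# build a score_distribution directly from counts over scores 1..4
score_distribution_from_counts <- function(counts, method = "M",
                                           population = "all") {
  stopifnot(length(counts) == 4, all(counts >= 0), sum(counts) > 0)
  structure(list(method = method, population = population,
                 counts = counts, prob = counts / sum(counts)),
            class = "score_distribution")
}

#' Top-down cumulative score distribution
#'
#' `C(x) = P(score >= x)` for x = 4, 3, 2, 1. By construction
#' `C(4) <= C(3) <= C(2) <= C(1) = 1`.
#'
#' @param dist a [score_distribution()].
#' @return named numeric vector `c("4", "3", "2", "1")` of cumulative
#'   probabilities in top-down order.
#' @export
cumulative_top_down <- function(dist) {
  stopifnot(inherits(dist, "score_distribution"))
  cum <- rev(cumsum(rev(dist$prob)))  # cum[x] = P(score >= x), x = 1..4
  stats::setNames(cum[4:1], c("4", "3", "2", "1"))
}

#' Visual grading characteristics (VGC) curve
#'
#' Compares two methods' rating distributions the way an ROC curve compares
#' score distributions: the curve consists of the anchor point (0, 0)
#' followed by the points `(C_A(x), C_B(x))` for x = 4, 3, 2, 1, where `C`
#' is the top-down cumulative distribution. The last point is always (1, 1).
#' Area above 0.5 means method B's ratings stochastically dominate method
#' A's — B is rated better.
#'
#' @param dist_a,dist_b [score_distribution()] objects for the x-axis
#'   (method A) and y-axis (method B).
#' @return object of class `vgc_curve`: list with `points` (5 x 2 matrix),
#'   `auc`, `method_a`, `method_b`.
#' @export
vgc_curve <- function(dist_a, dist_b) {
  stopifnot(inherits(dist_a, "score_distribution"),
            inherits(dist_b, "score_distribution"))
  ca <- cumulative_top_down(dist_a)
  cb <- cumulative_top_down(dist_b)
  pts <- cbind(i = c(0, unname(ca)), j = c(0, unname(cb)))
  rownames(pts) <- c("anchor", "4", "3", "2", "1")
  curve <- structure(list(points = pts, auc = NA_real_,
                          method_a = dist_a$method, method_b = dist_b$method),
                     class = "vgc_curve")
  curve$auc <- vgc_auc(curve)
  curve
}

#' Trapezoidal area under a VGC curve
#'
#' @param curve a [vgc_curve()], or a 2-column matrix of curve points
#'   ordered along the x-axis.
#' @return area in \[0, 1\].
#' @export
vgc_auc <- function(curve) {
  pts <- if (inherits(curve, "vgc_curve")) curve$points else curve
  i <- pts[, 1]; j <- pts[, 2]
  if (any(diff(i) < -1e-12) || any(diff(j) < -1e-12))
    stop("curve points must be nondecreasing in both coordinates")
  sum(diff(i) * (utils::head(j, -1) + utils::tail(j, -1)) / 2)
}

#' @export
plot.vgc_curve <- function(x, ...) {
  plot(x$points, type = "o", pch = 19, xlim = c(0, 1), ylim = c(0, 1),
       xlab = paste0("C(", x$method_a, ")"),
       ylab = paste0("C(", x$method_b, ")"),
       main = sprintf("VGC %s vs %s (AUC = %.3f)", x$method_a, x$method_b,
                      x$auc), ...)
  graphics::abline(0, 1, lty = 2, col = "grey50")
  invisible(x)
}

#' All method pairs present in a rating table, in method order
#' @noRd
default_pairs <- function(methods) {
  if (length(methods) < 2) stop("need at least two methods")
  pairs <- utils::combn(methods, 2)
  lapply(seq_len(ncol(pairs)), function(k) pairs[, k])
}

#' VGC AUC matrix over method pairs and populations
#'
#' Computes the VGC AUC for every requested (method pair, population)
#' combination. Group populations pool their members' ratings into one count
#' table.
#'
#' @param table a `rating_table`.
#' @param pairs list of 2-element character vectors `(method_a, method_b)`,
#'   or `"all"` for every ordered pair in first-appearance method order.
#' @param populations character vector of population selectors (see
#'   [score_distribution()]).
#' @return data frame with columns `method_a`, `method_b`, one AUC column
#'   per population, and attribute `curves` (nested list of `vgc_curve`s).
#' @export
vgc_matrix <- function(table, pairs = "all",
                       populations = c("experts-all", "lay-all", "all")) {
  methods <- unique(table$method)
  if (identical(pairs, "all")) pairs <- default_pairs(methods)
  for (p in pairs) {
    if (!all(p %in% methods)) {
      stop("method(s) missing from table: ",
           paste(setdiff(p, methods), collapse = ", "))
    }
  }
  curves <- list()
  out <- do.call(rbind, lapply(pairs, function(p) {
    row <- data.frame(method_a = p[1], method_b = p[2],
                      stringsAsFactors = FALSE)
    for (pop in populations) {
      cv <- vgc_curve(score_distribution(table, p[1], pop),
                      score_distribution(table, p[2], pop))
      curves[[paste(p[1], p[2], pop, sep = "|")]] <<- cv
      row[[pop]] <- cv$auc
    }
    row
  }))
  attr(out, "curves") <- curves
  out
}

#' One-sided paired Wilcoxon signed-rank test on MOS scores
#'
#' Tests the alternative "method B's MOS scores are higher than method A's"
#' over paired (observer, image) rating units. Zero differences are dropped;
#' tied absolute differences receive mid-ranks. For up to `exact_limit`
#' non-zero differences the p-value is computed by exact enumeration of all
#' sign assignments (conditional on the observed mid-ranks); beyond that a
#' tie-corrected normal approximation with continuity correction is used.
#'
#' @param table a `rating_table` containing both methods.
#' @param method_a,method_b method names; the alternative is B > A.
#' @param exact_limit maximum number of non-zero differences for exact
#'   enumeration (default 12).
#' @return list with `p_value`, `statistic` (positive-rank sum `V`),
#'   `n_pairs` (paired units), `n_nonzero`, `method` (`"exact"` or
#'   `"normal"`), and `indeterminate` (`TRUE` when all differences are
#'   zero, in which case `p_value` is `NA`).
#' @export
wilcoxon_one_sided <- function(table, method_a, method_b, exact_limit = 12L) {
  a <- table[table$method == method_a, , drop = FALSE]
  b <- table[table$method == method_b, , drop = FALSE]
  key_a <- paste(a$observer_id, a$image_id, sep = "\r")
  key_b <- paste(b$observer_id, b$image_id, sep = "\r")
  common <- intersect(key_a, key_b)
  if (length(common) < 1) stop("no (observer, image) pairs scored under both methods")
  d <- b$score[match(common, key_b)] - a$score[match(common, key_a)]
  d_nz <- d[d != 0]
  n <- length(d_nz)
  if (n == 0) {
    return(list(p_value = NA_real_, statistic = NA_real_,
                n_pairs = length(d), n_nonzero = 0L, method = "none",
                indeterminate = TRUE))
  }
  r <- rank(abs(d_nz))
  V <- sum(r[d_nz > 0])
  if (n <= exact_limit) {
    # enumerate all 2^n sign assignments of the observed mid-ranks
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    stats_all <- as.vector(signs %*% r)
    p <- mean(stats_all >= V - 1e-9)
    meth <- "exact"
  } else {
    mu <- sum(r) / 2
    sigma <- sqrt(sum(r^2) / 4)   # conditional variance given mid-ranks
    z <- (V - mu - 0.5) / sigma   # continuity-corrected
    p <- stats::pnorm(z, lower.tail = FALSE)
    meth <- "normal"
  }
  list(p_value = p, statistic = V, n_pairs = length(d), n_nonzero = n,
       method = meth, indeterminate = FALSE)
}
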