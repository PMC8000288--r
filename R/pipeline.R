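#' Bundled example data
#'
#' Paths to the plain-text fixtures shipped with the package: the observer
#' MOS rating table of the five-radiograph observer study (expanded to one
#' row per rating; per-image assignment within each observer x method cell
#' is synthetic, which leaves every count, distribution and VGC quantity
#' unchanged) and the twelve published confusion matrices of the two
#' classifier architectures.
#'
#' @param file file name under the package's `extdata/` (empty to list).
#' @return full file path.
#' @export
#' @examples
#' periosr_example()
#' head(read_rating_table(periosr_example("table1_ratings.csv")))
periosr_example <- function(file = "") {
  if (file == "") return(list.files(system.file("extdata", package = "periosr")))
  path <- system.file("extdata", file, package = "periosr")
  if (path == "") stop("no such example file: ", file)
  path
}

write_manifest <- function(out_dir, study, config, seed) {
  manifest <- list(study = study, config = config, seed = seed,
                   package = "periosr",
                   version = as.character(utils::packageVersion("periosr")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest
}

#' Run the observer-study analysis (study 1)
#'
#' From a rating table — read from CSV, passed directly, or simulated from
#' a latent observer model — computes Table-style score-count blocks per
#' population, the VGC AUC matrix over all method pairs, and one-sided
#' paired Wilcoxon tests (alternative: the later method is rated higher)
#' over all observers pooled.
#'
#' @param ratings path to a ratings CSV, or a `rating_table`; `NULL` to
#'   simulate.
#' @param simulate list for the synthetic branch: `n_experts`, `n_lay`,
#'   `n_images`, optional `method_quality`, `bias_sd`, `noise_sd`.
#' @param pairs method pairs for [vgc_matrix()] (default `"all"`).
#' @param populations population selectors for the AUC matrix.
#' @param seed integer seed (used by the synthetic branch).
#' @param out_dir optional directory; when given, writes `counts_<pop>.csv`,
#'   `vgc_auc.csv`, `wilcoxon.csv`, per-pair curve point files and
#'   `manifest.json`.
#' @return list with `table`, `counts`, `auc`, `wilcoxon`, `manifest`.
#' @export
run_study1 <- function(ratings = NULL, simulate = NULL, pairs = "all",
                       populations = c("experts-all", "lay-all", "all"),
                       seed = 1L, out_dir = NULL) {
  if (is.null(ratings) && is.null(simulate))
    stop("provide a ratings table or a simulation spec")
  if (is.null(ratings)) {
    sim <- simulate
    quality <- sim$method_quality %||% default_method_quality()
    n_obs <- sim$n_experts + sim$n_lay
    obs <- data.frame(
      observer_id = sprintf("obs%03d", seq_len(n_obs)),
      group = c(rep("expert", sim$n_experts), rep("lay", sim$n_lay)),
      stringsAsFactors = FALSE)
    bias <- with_seed(derive_seed(seed, "observer_bias"),
                      stats::rnorm(n_obs, sd = sim$bias_sd %||% 0.3))
    names(bias) <- obs$observer_id
    model <- observer_model(quality, bias,
                            observer_noise_sd = sim$noise_sd %||% 1,
                            seed = derive_seed(seed, "ratings"))
    ratings <- simulate_ratings(model, sprintf("img%03d", seq_len(sim$n_images)), obs)
  } else if (is.character(ratings)) {
    ratings <- read_rating_table(ratings)
  } else {
    ratings <- rating_table(ratings)
  }
  methods <- unique(ratings$method)
  counts <- lapply(stats::setNames(populations, populations), function(pop) {
    sapply(methods, function(m) score_distribution(ratings, m, pop)$counts)
  })
  auc <- vgc_matrix(ratings, pairs, populations)
  wil <- do.call(rbind, lapply(
    if (identical(pairs, "all")) default_pairs(methods) else pairs,
    function(p) {
      wt <- wilcoxon_one_sided(ratings, p[1], p[2])
      data.frame(method_a = p[1], method_b = p[2], p_value = wt$p_value,
                 statistic = wt$statistic, n_nonzero = wt$n_nonzero,
                 test = wt$method, stringsAsFactors = FALSE)
    }))
  manifest <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (pop in populations) {
      cdf <- data.frame(score = 1:4, counts[[pop]], check.names = FALSE)
      utils::write.csv(cdf, file.path(out_dir, paste0("counts_", pop, ".csv")),
                       row.names = FALSE, quote = FALSE)
    }
    utils::write.csv(format_auc(auc),
                     file.path(out_dir, "vgc_auc.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(wil, file.path(out_dir, "wilcoxon.csv"),
                     row.names = FALSE, quote = FALSE)
    curves <- attr(auc, "curves")
    for (nm in names(curves)) {
      fn <- paste0("curve_", gsub("\\|", "_", nm), ".csv")
      utils::write.csv(as.data.frame(curves[[nm]]$points),
                       file.path(out_dir, fn), row.names = FALSE, quote = FALSE)
    }
    manifest <- write_manifest(out_dir, "study1",
                               list(pairs = "all", populations = populations),
                               seed)
  }
  list(table = ratings, counts = counts, auc = auc, wilcoxon = wil,
       manifest = manifest)
}

# report AUCs at 3 decimals (full precision is kept in the returned objects)
format_auc <- function(auc) {
  out <- auc
  for (col in names(out)[-(1:2)]) out[[col]] <- sprintf("%.3f", out[[col]])
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the classifier evaluation (study 2)
#'
#' Consumes published confusion matrices, scored predictions, or a
#' simulated-classifier spec, and produces the diagnostic metric table
#' (sensitivity, specificity, PPV, NPV, accuracy) plus ROC/PR curves where
#' scores are available. Confusion matrices whose cells do not sum to the
#' declared test-set size are flagged inconsistent; their metrics are still
#' reported but marked.
#'
#' @param confusions path to a confusion CSV (`model,tn,fp,fn,tp`) or a
#'   data frame.
#' @param predictions path to a prediction CSV, a `prediction_set`, or a
#'   [classifier_sim_spec()].
#' @param expected_n declared test-set size per model (104 regions by
#'   default; `NA` to skip the consistency check).
#' @param out_dir optional output directory (`metrics.csv`, `roc.csv`,
#'   `pr.csv`, `manifest.json`).
#' @param seed integer seed (simulated predictions only).
#' @return list with `metrics` (one row per model, with `consistent` flag),
#'   `curves` (list with roc/pr data and AUCs, or `NULL`), `manifest`.
#' @export
run_study2 <- function(confusions = NULL, predictions = NULL,
                       expected_n = 104L, out_dir = NULL, seed = 1L) {
  if (is.null(confusions) && is.null(predictions))
    stop("provide confusion matrices, predictions, or a simulation spec")
  metrics <- NULL
  if (!is.null(confusions)) {
    df <- if (is.character(confusions)) read_confusion_csv(confusions, expected_n)
          else {
            confusions$consistent <-
              if (is.na(expected_n)) TRUE
              else confusions$tn + confusions$fp + confusions$fn + confusions$tp == expected_n
            confusions
          }
    metrics <- do.call(rbind, lapply(seq_len(nrow(df)), function(i) {
      mr <- confusion_metrics(confusion_matrix(df$tn[i], df$fp[i],
                                               df$fn[i], df$tp[i]))
      data.frame(model = df$model[i], tn = df$tn[i], fp = df$fp[i],
                 fn = df$fn[i], tp = df$tp[i],
                 sensitivity = mr$sensitivity, specificity = mr$specificity,
                 ppv = mr$ppv, npv = mr$npv, accuracy = mr$accuracy,
                 consistent = df$consistent[i], stringsAsFactors = FALSE)
    }))
  }
  curves <- NULL
  if (!is.null(predictions)) {
    preds <- if (inherits(predictions, "classifier_sim_spec")) {
      spec <- predictions
      spec$seed <- derive_seed(seed, "classifier_scores")
      simulate_classifier_scores(spec)
    } else if (is.character(predictions)) {
      read_prediction_csv(predictions)
    } else predictions
    curves <- roc_pr_curves(preds)
  }
  manifest <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(metrics))
      utils::write.csv(metrics, file.path(out_dir, "metrics.csv"),
                       row.names = FALSE, quote = FALSE)
    if (!is.null(curves)) {
      utils::write.csv(curves$roc, file.path(out_dir, "roc.csv"),
                       row.names = FALSE, quote = FALSE)
      utils::write.csv(curves$pr, file.path(out_dir, "pr.csv"),
                       row.names = FALSE, quote = FALSE)
    }
    manifest <- write_manifest(out_dir, "study2",
                               list(expected_n = expected_n), seed)
  }
  list(metrics = metrics, curves = curves, manifest = manifest)
}

#' Run the downscale-upscale quality protocol
#'
#' Applies [downup_protocol()] to a set of images — either supplied or
#' generated as phantoms — and reports the per-method MSE / PSNR / SSIM
#' table.
#'
#' @param images list of numeric matrices, or `NULL` to generate
#'   `n_phantoms` phantoms.
#' @param n_phantoms number of phantoms when `images` is `NULL`.
#' @param size phantom height = width in pixels.
#' @param low_size intermediate low resolution.
#' @param methods upscaling methods under test.
#' @param seed integer seed for phantom generation.
#' @param out_dir optional output directory (`iqm_report.csv`,
#'   `manifest.json`).
#' @return list with `report` (see [downup_protocol()]) and `manifest`.
#' @export
run_protocol <- function(images = NULL, n_phantoms = 5L, size = 720L,
                         low_size = 128L,
                         methods = c("nearest", "bilinear", "bicubic", "lanczos"),
                         seed = 1L, out_dir = NULL) {
  if (is.null(images)) {
    lesions <- c("none", "horizontal", "vertical", "crater")
    images <- lapply(seq_len(n_phantoms), function(i)
      generate_phantom(phantom_spec(size, size,
                                    n_teeth = 2L + (i %% 3L),
                                    lesion = lesions[1L + (i %% 4L)],
                                    seed = derive_seed(seed, paste0("phantom", i)))))
  }
  report <- downup_protocol(images, methods, low_size, low_size)
  manifest <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(as.data.frame(report),
                     file.path(out_dir, "iqm_report.csv"),
                     row.names = FALSE, quote = FALSE)
    manifest <- write_manifest(out_dir, "protocol",
                               list(n_images = length(images),
                                    low_size = low_size, methods = methods),
                               seed)
  }
  list(report = report, manifest = manifest)
}
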