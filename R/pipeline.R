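#' Full pipeline configuration
#'
#' Bundles every tunable of the screening pipeline: which scalar color
#' feature to use, whether to apply the Kalman smoothing, which regressor
#' fits the feature-versus-Hb curve, the RES settings, and the
#' cross-validation layout. Defaults are the published protocol: mean red
#' feature, Kalman filter on, order-4 penalized fit, threshold 11 g/dL
#' with ETR from the training Hb standard deviation, 10 folds, and
#' 500 x 500 resize.
#'
#' @param feature_name one of `"mean_red"`, `"erythema"`, `"hue"`.
#' @param use_kf apply the simplified Kalman filter to the training series.
#' @param regressor `"penalty_poly"` (order-n penalized gradient-descent
#'   fit) or `"linear"` (closed-form least-squares baseline).
#' @param kalman a [kalman_params()].
#' @param penalty a [penalty_config()].
#' @param res a [res_config()].
#' @param n_folds number of cross-validation folds (>= 2).
#' @param cv_seed seed for the fold permutation.
#' @param resize_side resize target in pixels.
#' @param stratified stratify folds by anemia label (off by default; the
#'   protocol uses simple random folds).
#' @param grid_points grid resolution for curve inversion.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(feature_name = c("mean_red", "erythema", "hue"),
                            use_kf = TRUE,
                            regressor = c("penalty_poly", "linear"),
                            kalman = kalman_params(),
                            penalty = penalty_config(),
                            res = res_config(),
                            n_folds = 10,
                            cv_seed = 1L,
                            resize_side = 500,
                            stratified = FALSE,
                            grid_points = 10000) {
  feature_name <- match.arg(feature_name)
  regressor <- match.arg(regressor)
  if (n_folds < 2) stop_validation("n_folds must be >= 2")
  structure(
    list(feature_name = feature_name, use_kf = isTRUE(use_kf),
         regressor = regressor, kalman = kalman, penalty = penalty,
         res = res, n_folds = as.integer(n_folds),
         cv_seed = as.integer(cv_seed), resize_side = resize_side,
         stratified = isTRUE(stratified), grid_points = grid_points),
    class = "pipeline_config"
  )
}

#' Human-readable variant name ("KF + R + nonlinear penalty regression")
#'
#' @param cfg a [pipeline_config()].
#' @return A character scalar.
#' @export
variant_label <- function(cfg) {
  feat <- switch(cfg$feature_name,
                 mean_red = "R", erythema = "erythema index", hue = "hue")
  reg <- switch(cfg$regressor,
                penalty_poly = "nonlinear penalty regression",
                linear = "linear regression")
  paste0(if (cfg$use_kf) "KF + " else "", feat, " + ", reg)
}

#' k-fold cross-validation split
#'
#' A seeded permutation of `1..n` partitioned into `k` near-equal test
#' folds (sizes differing by at most one); the training set is the
#' complement of each test fold. With `stratify` supplied, the permutation
#' is drawn within each stratum and folds are filled round-robin so label
#' proportions stay balanced.
#'
#' @param n number of samples.
#' @param k number of folds (`2 <= k <= n`).
#' @param seed integer seed.
#' @param stratify optional vector of length `n` of stratum labels.
#' @return A list of `k` elements, each `list(train = ..., test = ...)`.
#' @export
kfold_split <- function(n, k, seed = 1L, stratify = NULL) {
  if (k < 2) stop_validation("k must be >= 2")
  if (n < k) stop_validation("need at least as many samples as folds")
  fold_of <- integer(n)
  with_rng_seed(seed, {
    if (is.null(stratify)) {
      perm <- sample.int(n)
      fold_of[perm] <- rep(seq_len(k), length.out = n)
    } else {
      stopifnot(length(stratify) == n)
      for (s in unique(stratify)) {
        idx <- which(stratify == s)
        perm <- idx[sample.int(length(idx))]
        fold_of[perm] <- rep(seq_len(k), length.out = length(idx))
      }
    }
  })
  lapply(seq_len(k), function(f) {
    list(train = which(fold_of != f), test = which(fold_of == f))
  })
}

# A dataset here is a feature table: subject_id, hb_g_dl, and one column
# per extracted feature (from extract_features() or
# generate_feature_table(), whose single column is renamed by
# as_feature_dataset()).
check_dataset <- function(dataset, cfg) {
  for (col in c("subject_id", "hb_g_dl", cfg$feature_name)) {
    if (!col %in% names(dataset)) {
      stop_validation(sprintf("dataset is missing column '%s'", col))
    }
  }
  invisible(dataset)
}

#' Coerce a single-feature table to a pipeline dataset
#'
#' [generate_feature_table()] emits a generic `feature` column; this
#' renames it to the configured feature so the table can feed the
#' pipeline directly.
#'
#' @param tab a `data.frame` with a `feature` column.
#' @param feature_name target feature column name.
#' @return The renamed `data.frame`.
#' @export
as_feature_dataset <- function(tab, feature_name = "mean_red") {
  names(tab)[names(tab) == "feature"] <- feature_name
  tab
}

#' Run one train/test fold of the screening pipeline
#'
#' Prepares the Hb-ordered series from the training rows, optionally
#' applies the Kalman filter, fits the configured regressor, computes the
#' ETR from the training Hb values, then inverts the fitted curve over the
#' training Hb range for every test feature (estimates are clamped to
#' that range) and classifies each estimate with the RES.
#'
#' @param train,test `data.frame`s with columns `subject_id`, `hb_g_dl`
#'   and the configured feature column.
#' @param cfg a [pipeline_config()].
#' @param fold_id identifier attached to the outcome rows.
#' @return Per-sample outcome `data.frame` (`subject_id`, `hb_g_dl`,
#'   `label`, `est_hb`, `level`, `suspect`, `fold`) with attributes `etr`,
#'   `fit_report`, `variance_report` and `n_matching_warnings`.
#' @export
run_fold <- function(train, test, cfg, fold_id = 1L) {
  check_dataset(train, cfg)
  check_dataset(test, cfg)
  if (nrow(train) == 0) stop_validation("empty training set")
  series <- prepare_series(train$hb_g_dl, train[[cfg$feature_name]])
  vrep <- NULL
  if (cfg$use_kf) {
    series <- kalman_filter(series, cfg$kalman)
    vrep <- variance_report(series)
  }
  model <- switch(cfg$regressor,
                  penalty_poly = fit_penalty_regression(series, cfg$penalty),
                  linear = fit_linear_regression(series))
  etr <- compute_etr(train$hb_g_dl, cfg$res)
  h_range <- range(train$hb_g_dl)
  n_match <- 0L
  est <- vapply(test[[cfg$feature_name]], function(f) {
    withCallingHandlers(
      invert_model(model, f, h_range, grid_points = cfg$grid_points),
      warning = function(w) {
        if (grepl("matching issue", conditionMessage(w))) {
          n_match <<- n_match + 1L
          invokeRestart("muffleWarning")
        }
      })
  }, numeric(1))
  cls <- classify_sample(est, threshold = cfg$res$threshold, etr = etr)
  out <- data.frame(
    subject_id = test$subject_id,
    hb_g_dl = test$hb_g_dl,
    label = ifelse(test$hb_g_dl < cfg$res$threshold, "anemic", "nonanemic"),
    est_hb = est,
    level = cls$level,
    suspect = cls$suspect,
    fold = fold_id,
    stringsAsFactors = FALSE
  )
  attr(out, "etr") <- etr
  attr(out, "fit_report") <- model$fit_report
  attr(out, "variance_report") <- vrep
  attr(out, "n_matching_warnings") <- n_match
  out
}

#' Cross-validated evaluation of one pipeline variant
#'
#' Runs [run_fold()] over a seeded k-fold split, pools the per-sample
#' outcomes (every sample is tested exactly once, so the pooled set covers
#' the whole dataset), and computes the RES indices and nonsuspect
#' sensitivity/specificity on the pooled outcomes.
#'
#' @param dataset feature table with `subject_id`, `hb_g_dl` and the
#'   configured feature column.
#' @param cfg a [pipeline_config()].
#' @return A list of class `cv_report`: pooled `outcomes`, the [res_report()]
#'   `res`, per-fold ETRs, the Spearman correlation between pooled
#'   estimates and true Hb, the variant label, and the config.
#' @export
run_cv <- function(dataset, cfg = pipeline_config()) {
  check_dataset(dataset, cfg)
  n <- nrow(dataset)
  folds <- kfold_split(
    n, cfg$n_folds, seed = cfg$cv_seed,
    stratify = if (cfg$stratified) {
      ifelse(dataset$hb_g_dl < cfg$res$threshold, "anemic", "nonanemic")
    } else NULL)
  outcomes <- vector("list", length(folds))
  etrs <- numeric(length(folds))
  for (f in seq_along(folds)) {
    out <- tryCatch(
      run_fold(dataset[folds[[f]]$train, , drop = FALSE],
               dataset[folds[[f]]$test, , drop = FALSE],
               cfg, fold_id = f),
      error = function(e) {
        stop(errorCondition(
          sprintf("fold %d: %s", f, conditionMessage(e)),
          class = class(e)))
      })
    etrs[f] <- attr(out, "etr")
    outcomes[[f]] <- out
  }
  pooled <- do.call(rbind, outcomes)
  rep <- res_report(pooled, etr = mean(etrs))
  structure(
    list(variant = variant_label(cfg),
         outcomes = pooled,
         res = rep,
         fold_etr = etrs,
         spearman = cor(pooled$est_hb, pooled$hb_g_dl, method = "spearman"),
         config = cfg),
    class = "cv_report"
  )
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("Cross-validated screening evaluation: %s\n", x$variant))
  cat(sprintf("  %d samples, %d folds, Spearman(est, true Hb) = %.3f\n",
              nrow(x$outcomes), length(x$fold_etr), x$spearman))
  print(x$res)
  invisible(x)
}

#' Compare pipeline variants side by side
#'
#' Runs [run_cv()] for each variant and assembles a comparison table (one
#' row per variant) plus, for every feature/regressor pair present both
#' with and without the Kalman filter, the relative changes the filter
#' brings: `(KF on - KF off) / KF off`, in percent, for sensitivity,
#' specificity and the suspect count.
#'
#' @param dataset feature table (must contain every configured feature
#'   column).
#' @param variants list of [pipeline_config()]s.
#' @return A list of class `comparison_report` with `table` (per-variant
#'   metrics), `deltas` (KF on/off changes) and the individual `reports`.
#' @export
run_comparison <- function(dataset, variants) {
  if (length(variants) < 1) stop_validation("need at least one variant")
  reports <- lapply(variants, function(cfg) run_cv(dataset, cfg))
  tab <- do.call(rbind, lapply(reports, function(r) {
    data.frame(
      variant = r$variant,
      feature = r$config$feature_name,
      regressor = r$config$regressor,
      use_kf = r$config$use_kf,
      sensitivity = r$res$sensitivity,
      specificity = r$res$specificity,
      n_suspect = r$res$n_suspect,
      high_risk_index = r$res$high_risk_index,
      low_risk_index = r$res$low_risk_index,
      doubtful_index = r$res$doubtful_index,
      spearman = r$spearman,
      stringsAsFactors = FALSE
    )
  }))
  rel_change <- function(after, before) {
    if (!is.finite(before) || before == 0) return(NaN)
    100 * (after - before) / before
  }
  deltas <- NULL
  pairs <- unique(tab[, c("feature", "regressor")])
  for (i in seq_len(nrow(pairs))) {
    on <- tab[tab$feature == pairs$feature[i] &
                tab$regressor == pairs$regressor[i] & tab$use_kf, ]
    off <- tab[tab$feature == pairs$feature[i] &
                 tab$regressor == pairs$regressor[i] & !tab$use_kf, ]
    if (nrow(on) == 1 && nrow(off) == 1) {
      deltas <- rbind(deltas, data.frame(
        feature = pairs$feature[i],
        regressor = pairs$regressor[i],
        sensitivity_change_pct = rel_change(on$sensitivity, off$sensitivity),
        specificity_change_pct = rel_change(on$specificity, off$specificity),
        n_suspect_change_pct = rel_change(on$n_suspect, off$n_suspect),
        stringsAsFactors = FALSE
      ))
    }
  }
  structure(list(table = tab, deltas = deltas, reports = reports),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("Method comparison (pooled cross-validated RES metrics)\n\n")
  tab <- x$table
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], function(v) signif(v, 4))
  print(tab[, c("variant", "sensitivity", "specificity", "n_suspect",
                "high_risk_index", "low_risk_index", "doubtful_index")],
        row.names = FALSE)
  if (!is.null(x$deltas)) {
    cat("\nEffect of the Kalman filter (relative change, %)\n\n")
    d <- x$deltas
    d[-(1:2)] <- lapply(d[-(1:2)], function(v) signif(v, 4))
    print(d, row.names = FALSE)
  }
  invisible(x)
}

#' Write a comparison report as CSV
#'
#' @param comparison a `comparison_report`.
#' @param table_path,deltas_path output CSV paths (`NULL` skips).
#' @export
write_comparison_csv <- function(comparison, table_path,
                                 deltas_path = NULL) {
  write.csv(comparison$table, table_path, row.names = FALSE)
  if (!is.null(deltas_path) && !is.null(comparison$deltas)) {
    write.csv(comparison$deltas, deltas_path, row.names = FALSE)
  }
  invisible(NULL)
}
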