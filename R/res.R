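#' Configuration of the risk evaluation scheme (RES)
#'
#' The RES replaces the hard anemic/nonanemic cut with three levels. Every
#' estimate carries an error tolerance range (ETR, a half-width in g/dL),
#' and so does the threshold: the interval `[T - ETR, T + ETR]` around the
#' threshold `T` is the doubtful zone. A sample whose own interval touches
#' the doubtful zone — equivalently `|est - T| <= 2 ETR` — is a suspect
#' sample needing a confirmatory blood test; the rest are confidently
#' high-risk (low Hb estimate) or low-risk (high Hb estimate).
#'
#' @param threshold anemia threshold, g/dL (default 11; subjects with Hb
#'   below it are anemic).
#' @param etr either the string `"train_sd"` (use the sample standard
#'   deviation of the training Hb values, the protocol choice) or a fixed
#'   nonnegative half-width in g/dL.
#' @return An object of class `res_config`.
#' @export
res_config <- function(threshold = 11, etr = "train_sd") {
  if (!is.finite(threshold) || threshold <= 0) {
    stop_validation("threshold must be a positive Hb level")
  }
  if (is.character(etr)) {
    if (!identical(etr, "train_sd")) {
      stop_validation("etr must be \"train_sd\" or a nonnegative number")
    }
  } else if (!is.finite(etr) || etr < 0) {
    stop_validation("fixed etr must be a nonnegative number")
  }
  structure(list(threshold = threshold, etr = etr), class = "res_config")
}

#' Error tolerance range from training data
#'
#' @param train_hb training Hb values, g/dL.
#' @param cfg a [res_config()]; with `etr = "train_sd"` the ETR is the
#'   sample standard deviation (denominator N - 1) of `train_hb`,
#'   otherwise the configured fixed value is returned unchanged.
#' @return ETR in g/dL.
#' @export
compute_etr <- function(train_hb, cfg = res_config()) {
  stopifnot(inherits(cfg, "res_config"))
  if (is.numeric(cfg$etr)) return(cfg$etr)
  if (length(train_hb) < 2) {
    stop_validation("need at least 2 training Hb values for etr = \"train_sd\"")
  }
  sd(train_hb)
}

#' Classify estimated Hb levels into risk levels
#'
#' Interval touching is a closed comparison: boundary contact counts as
#' suspect (the conservative screening choice).
#'
#' @param est_hb estimated Hb levels, g/dL (vectorized).
#' @param threshold anemia threshold, g/dL.
#' @param etr error tolerance range, g/dL.
#' @return A `data.frame` with columns `est_hb`, `level` (one of
#'   `"high_risk"`, `"doubtful"`, `"low_risk"`) and `suspect` (`TRUE` iff
#'   doubtful).
#' @export
classify_sample <- function(est_hb, threshold = 11, etr = 1) {
  if (etr < 0) stop_validation("etr must be nonnegative")
  d <- est_hb - threshold
  level <- ifelse(abs(d) <= 2 * etr, "doubtful",
                  ifelse(d < 0, "high_risk", "low_risk"))
  data.frame(est_hb = est_hb, level = level, suspect = level == "doubtful",
             stringsAsFactors = FALSE)
}

check_outcomes <- function(outcomes) {
  if (is.null(outcomes) || nrow(outcomes) == 0) {
    stop_validation("empty outcome table")
  }
  for (col in c("level", "suspect", "label")) {
    if (!col %in% names(outcomes)) {
      stop_validation(sprintf("outcome table is missing column '%s'", col))
    }
  }
  invisible(outcomes)
}

#' Aggregate RES indices
#'
#' * high-risk index: fraction of samples placed in the high-risk level
#'   whose true label is anemic;
#' * low-risk index: fraction of samples placed in the low-risk level
#'   whose true label is nonanemic;
#' * doubtful index: fraction of all samples that are nonsuspect (higher
#'   means better screening capability).
#'
#' Empty denominators are reported as `NaN` with the corresponding
#' `undefined_*` flag set — e.g. when every sample is suspect, the
#' high-risk and low-risk indices are undefined and the doubtful index
#' is 0.
#'
#' @param outcomes `data.frame` with columns `level`, `suspect`, `label`
#'   (`"anemic"` / `"nonanemic"`).
#' @return A list with the three indices, `n_suspect`, `n`, and undefined
#'   flags.
#' @export
compute_indices <- function(outcomes) {
  check_outcomes(outcomes)
  n <- nrow(outcomes)
  high <- outcomes$level == "high_risk"
  low <- outcomes$level == "low_risk"
  n_suspect <- sum(outcomes$suspect)
  hr <- sum(high & outcomes$label == "anemic") / sum(high)
  lr <- sum(low & outcomes$label == "nonanemic") / sum(low)
  list(
    high_risk_index = hr,
    low_risk_index = lr,
    doubtful_index = (n - n_suspect) / n,
    n_suspect = n_suspect,
    n = n,
    undefined_high = sum(high) == 0,
    undefined_low = sum(low) == 0
  )
}

#' Sensitivity and specificity on nonsuspect samples
#'
#' Follows the usual definitions restricted to nonsuspect samples:
#' predicted anemic iff placed in the high-risk level, true anemic from
#' the label. Empty denominators give `NaN` with a flag.
#'
#' @inheritParams compute_indices
#' @return A list with `sensitivity`, `specificity`, counts, and
#'   undefined flags.
#' @export
nonsuspect_confusion <- function(outcomes) {
  check_outcomes(outcomes)
  ns <- outcomes[!outcomes$suspect, , drop = FALSE]
  anemic <- ns$label == "anemic"
  pred_anemic <- ns$level == "high_risk"
  tp <- sum(anemic & pred_anemic)
  fn <- sum(anemic & !pred_anemic)
  tn <- sum(!anemic & !pred_anemic)
  fp <- sum(!anemic & pred_anemic)
  list(
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    tp = tp, fn = fn, tn = tn, fp = fp,
    n_nonsuspect = nrow(ns),
    undefined_sensitivity = (tp + fn) == 0,
    undefined_specificity = (tn + fp) == 0
  )
}

#' Full RES report for an outcome table
#'
#' @inheritParams compute_indices
#' @param etr the ETR used, echoed into the report.
#' @return A list of class `res_report` combining [compute_indices()] and
#'   [nonsuspect_confusion()].
#' @export
res_report <- function(outcomes, etr = NA_real_) {
  rep <- c(compute_indices(outcomes), nonsuspect_confusion(outcomes))
  rep$etr <- etr
  class(rep) <- "res_report"
  rep
}

#' @export
print.res_report <- function(x, ...) {
  fmt <- function(v) if (is.nan(v)) "NaN (undefined)" else sprintf("%.4f", v)
  cat("Risk evaluation scheme report\n")
  cat(sprintf("  samples: %d, suspect: %d, ETR: %s g/dL\n",
              x$n, x$n_suspect,
              if (is.na(x$etr)) "?" else signif(x$etr, 4)))
  cat(sprintf("  high-risk index: %s\n", fmt(x$high_risk_index)))
  cat(sprintf("  low-risk index:  %s\n", fmt(x$low_risk_index)))
  cat(sprintf("  doubtful index:  %s\n", fmt(x$doubtful_index)))
  cat(sprintf("  nonsuspect sensitivity: %s, specificity: %s\n",
              fmt(x$sensitivity), fmt(x$specificity)))
  invisible(x)
}

#' Write RES outputs
#'
#' Writes the per-sample outcome CSV and an aggregate JSON report.
#'
#' @param outcomes per-sample outcome `data.frame`.
#' @param report a [res_report()].
#' @param csv_path,json_path output paths (either may be `NULL` to skip).
#' @export
write_res_outputs <- function(outcomes, report, csv_path = NULL,
                              json_path = NULL) {
  if (!is.null(csv_path)) {
    write.csv(outcomes, csv_path, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(unclass(report), json_path, auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(NULL)
}
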