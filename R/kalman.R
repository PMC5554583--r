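#' Prepare an Hb-ordered feature series
#'
#' The filtering stage treats the Hb level as the independent variable
#' (the role time plays in a conventional tracking filter). Measurements
#' are therefore sorted by Hb in ascending order, and subjects sharing an
#' identical Hb value are collapsed to a single row whose feature is their
#' arithmetic mean, turning a possibly one-to-many map into a one-to-one
#' series.
#'
#' Duplicate detection compares the Hb values exactly as given; no rounding
#' or binning is applied by default. Pass `round_digits` to collapse values
#' that agree after rounding (off by default).
#'
#' @param hb numeric vector of Hb levels, g/dL, all positive.
#' @param feature numeric vector of feature values, same length.
#' @param round_digits optional number of decimals to round Hb to before
#'   duplicate collapsing; `NULL` (default) compares values as given.
#' @return A `feature_series`: a `data.frame` with strictly increasing `hb`
#'   and the collapsed feature column `z`.
#' @export
prepare_series <- function(hb, feature, round_digits = NULL) {
  if (length(hb) != length(feature)) {
    stop_validation("hb and feature must have the same length")
  }
  if (length(hb) == 0) {
    stop_validation("empty input: need at least one (hb, feature) pair")
  }
  if (any(!is.finite(hb)) || any(hb <= 0)) {
    stop_validation("all Hb values must be finite and positive")
  }
  if (!is.null(round_digits)) hb <- round(hb, round_digits)
  o <- order(hb)
  hb <- hb[o]; feature <- feature[o]
  grp <- factor(hb, levels = unique(hb))
  series <- data.frame(
    hb = unique(hb),
    z = as.vector(tapply(feature, grp, mean))
  )
  class(series) <- c("feature_series", "data.frame")
  series
}

#' Parameters of the simplified scalar Kalman filter
#'
#' The filter collapses the full state-space machinery to scalars: state
#' transition and observation maps fixed at 1, no control input, and
#' constant process / measurement noise scalars `Q` and `R`. The defaults
#' take both at 1e-2, the top of the working range 1e-3..1e-2; values
#' outside `sanity_range` trigger a warning (they are legal but usually a
#' sign of a units mistake).
#'
#' @param Q process-noise constant, > 0.
#' @param R measurement-noise constant, > 0.
#' @param P1 initial error covariance; 0 by default (the first measurement
#'   is trusted exactly).
#' @param sanity_range length-2 numeric; warn when Q or R fall outside it.
#' @return An object of class `kalman_params`.
#' @export
kalman_params <- function(Q = 1e-2, R = 1e-2, P1 = 0,
                          sanity_range = c(1e-4, 1e-1)) {
  if (!is.finite(Q) || Q <= 0 || !is.finite(R) || R <= 0) {
    stop_validation("Q and R must be positive finite scalars")
  }
  if (P1 < 0) stop_validation("P1 must be nonnegative")
  if (Q < sanity_range[1] || Q > sanity_range[2] ||
      R < sanity_range[1] || R > sanity_range[2]) {
    warning(sprintf(
      "Q = %g or R = %g outside the usual range [%g, %g]",
      Q, R, sanity_range[1], sanity_range[2]))
  }
  structure(list(Q = Q, R = R, P1 = P1), class = "kalman_params")
}

#' Apply the simplified scalar Kalman filter to a feature series
#'
#' Runs the scalar recursion over the Hb-ascending series `z`:
#' \deqn{K(k) = \frac{P(k-1) + Q}{P(k-1) + Q + R}}
#' \deqn{x(k) = K(k) z(k) + (1 - K(k)) x(k-1)}
#' \deqn{P(k) = (1 - K(k)) P(k-1) - 2 Q K(k) + 2 Q}
#' initialised with `x(1) = z(1)` and `P(1) = P1` (default 0). Since
#' `0 < K <= 1` whenever `P >= 0`, each update is a convex combination of
#' the current measurement and the running estimate, so the filter shrinks
#' measurement scatter without leaving the data's range. The covariance
#' update equals `(1 - K)(P + 2Q)`, which is nonnegative for positive `R`;
#' a clamp at 0 (with a warning) is kept as a numerical guard.
#'
#' The recursion is causal in ascending-Hb order; filtering the reversed
#' series generally gives a different (also valid) smoothing.
#'
#' @param series a `feature_series` from [prepare_series()].
#' @param params a [kalman_params()].
#' @return The series with columns `x` (filtered feature), `K` (gain;
#'   reported as 1 at k = 1 by convention) and `P` (error covariance).
#' @export
kalman_filter <- function(series, params = kalman_params()) {
  stopifnot(inherits(series, "feature_series"))
  if (!inherits(params, "kalman_params")) {
    stop_validation("params must be a kalman_params object")
  }
  M <- nrow(series)
  if (M == 0) stop_validation("empty series")
  z <- series$z
  x <- numeric(M); K <- numeric(M); P <- numeric(M)
  x[1] <- z[1]
  P[1] <- params$P1
  K[1] <- 1
  clamped <- FALSE
  if (M > 1) {
    for (k in 2:M) {
      K[k] <- (P[k - 1] + params$Q) / (P[k - 1] + params$Q + params$R)
      x[k] <- K[k] * z[k] + (1 - K[k]) * x[k - 1]
      P[k] <- (1 - K[k]) * P[k - 1] - 2 * params$Q * K[k] + 2 * params$Q
      if (P[k] < 0) {
        P[k] <- 0
        clamped <- TRUE
      }
    }
  }
  if (clamped) {
    warning("error covariance went negative and was clamped to 0")
  }
  series$x <- x
  series$K <- K
  series$P <- P
  series
}

#' Scatter reduction achieved by the filter
#'
#' @param series a filtered `feature_series` (column `x` present).
#' @return A list with `sd_z`, `sd_x` (sample standard deviations of the
#'   raw and filtered features; 0 when fewer than two rows) and their
#'   `ratio` `sd_x / sd_z` (1 when `sd_z` is 0).
#' @export
variance_report <- function(series) {
  stopifnot(inherits(series, "feature_series"))
  if (is.null(series$x)) {
    stop_validation("series has not been filtered (no x column)")
  }
  if (nrow(series) < 2) {
    return(list(sd_z = 0, sd_x = 0, ratio = 1))
  }
  sd_z <- sd(series$z)
  sd_x <- sd(series$x)
  list(sd_z = sd_z, sd_x = sd_x,
       ratio = if (sd_z > 0) sd_x / sd_z else 1)
}

#' Write a filtered feature series as CSV
#'
#' @param series a `feature_series`.
#' @param path output CSV path (columns `hb_g_dl, z` plus `x, K, P` when
#'   filtered).
#' @export
write_series_csv <- function(series, path) {
  out <- as.data.frame(series)
  names(out)[names(out) == "hb"] <- "hb_g_dl"
  write.csv(out, path, row.names = FALSE)
  invisible(out)
}
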