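#' Configuration of the penalized polynomial fit
#'
#' The feature-versus-Hb curve is an order-`n` polynomial
#' `f(h) = sum_{i=0}^{n} a_i h^i` fitted by gradient descent on the cost
#' `E = alpha * sum_k (f(h_k) - x_k)^2 + lambda * sum_{i>=1} c_i a_i^2`.
#' The ridge-type penalty leaves the intercept unpenalized and, with
#' increasing coefficients `c_i`, bears down hardest on the high-order
#' terms, which is what controls overfitting wiggle in the fitted curve.
#'
#' Defaults follow the screening protocol: order 4, `c = (1, 10, 20, 30)`,
#' `alpha = 1e-11`, `lambda = 1e-12`, stop when successive costs differ by
#' less than 1e-6. The tiny `alpha` is both the weight of the data term
#' and the gradient-descent step size, sized for raw 8-bit feature scales;
#' rescaled problems should use a proportionally larger `alpha`.
#'
#' @param order polynomial order `n >= 1`.
#' @param c penalty coefficients `c_1..c_n` (nonnegative; a decreasing
#'   sequence triggers a warning since higher orders are meant to be
#'   penalized harder).
#' @param lambda penalty parameter, >= 0.
#' @param alpha learning rate / data-term weight, > 0.
#' @param tol convergence threshold on the change in cost between
#'   successive iterations.
#' @param tol_type `"relative"` (default) stops when
#'   `|E_t - E_(t-1)| <= tol * E_t`; `"absolute"` compares the raw change.
#'   The cost carries the factor `alpha`, so an absolute threshold is tied
#'   to `alpha` times the squared data scale and fires almost immediately
#'   on 8-bit feature data; the relative reading lets the descent actually
#'   converge, which is the behaviour the protocol's published curves
#'   show.
#' @param max_iter iteration cap.
#' @param init_seed seed for the random initialisation of `a_1..a_n`
#'   (uniform on `[0, 1]`); `a_0` starts at the first feature value.
#' @param standardize center/scale `h` and the feature before fitting
#'   (coefficients are always reported in raw units). Off by default to
#'   honour the raw-scale protocol.
#' @param adapt_step backtrack (halve) the step when it would increase the
#'   cost, growing back afterwards; `FALSE` gives the raw update, which
#'   diverges when the step is too large for the problem's curvature.
#' @return An object of class `penalty_config`.
#' @export
penalty_config <- function(order = 4,
                           c = base::c(1, 10, 20, 30),
                           lambda = 1e-12,
                           alpha = 1e-11,
                           tol = 1e-6,
                           tol_type = c("relative", "absolute"),
                           max_iter = 5e6,
                           init_seed = 1L,
                           standardize = FALSE,
                           adapt_step = TRUE) {
  if (order < 1) stop_validation("order must be >= 1")
  if (length(c) < order) {
    stop_validation(sprintf("need at least %d penalty coefficients c_i", order))
  }
  c <- c[seq_len(order)]
  if (any(c < 0)) stop_validation("penalty coefficients c_i must be >= 0")
  if (any(diff(c) < 0)) {
    warning("penalty coefficients c_i are not nondecreasing; higher-order terms are usually penalized harder")
  }
  if (lambda < 0) stop_validation("lambda must be >= 0")
  if (alpha <= 0) stop_validation("alpha must be > 0")
  if (tol <= 0) stop_validation("tol must be > 0")
  tol_type <- match.arg(tol_type)
  structure(
    list(order = as.integer(order), c = c, lambda = lambda, alpha = alpha,
         tol = tol, tol_type = tol_type,
         max_iter = max_iter, init_seed = as.integer(init_seed),
         standardize = isTRUE(standardize), adapt_step = isTRUE(adapt_step)),
    class = "penalty_config"
  )
}

#' Polynomial feature-versus-Hb model
#'
#' @param coeffs numeric vector `a_0..a_n` (feature units per (g/dL)^i).
#' @param fit_report optional list describing how the fit was obtained.
#' @return An object of class `poly_model`.
#' @export
poly_model <- function(coeffs, fit_report = NULL) {
  if (length(coeffs) < 2 || any(!is.finite(coeffs))) {
    stop_validation("coeffs must be >= 2 finite values (a_0..a_n, n >= 1)")
  }
  structure(list(order = length(coeffs) - 1L, coeffs = as.numeric(coeffs),
                 fit_report = fit_report),
            class = "poly_model")
}

#' @export
print.poly_model <- function(x, ...) {
  cat(sprintf("Polynomial model, order %d\n", x$order))
  cat("  coefficients a_0..a_n:",
      paste(signif(x$coeffs, 6), collapse = ", "), "\n")
  if (!is.null(x$fit_report)) {
    fr <- x$fit_report
    cat(sprintf("  fit: %s, %g iterations, final cost %.6g, converged: %s\n",
                fr$method %||% "gradient descent", fr$iterations %||% NA,
                fr$final_cost %||% NA,
                as.character(fr$converged %||% NA)))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate the fitted polynomial at Hb levels
#'
#' @param model a [poly_model()].
#' @param h Hb levels, g/dL (vectorized).
#' @return Predicted feature values, computed in Horner form.
#' @export
predict_feature <- function(model, h) {
  stopifnot(inherits(model, "poly_model"))
  a <- model$coeffs
  out <- rep(a[length(a)], length(h))
  for (i in rev(seq_len(length(a) - 1))) {
    out <- out * h + a[i]
  }
  out
}

# Response column for fitting: the filtered feature when present, else the
# raw collapsed measurement.
series_response <- function(series) {
  if (!is.null(series$x)) series$x else series$z
}

#' Penalized cost of a model on a series
#'
#' `E = alpha * sum_k (f(h_k) - x_k)^2 + lambda * sum_{i>=1} c_i a_i^2`,
#' using the filtered feature `x` when the series has been filtered. An
#' empty or `NULL` series contributes only the penalty term.
#'
#' @param model a [poly_model()].
#' @param series a `feature_series` (or `NULL`).
#' @param cfg a [penalty_config()].
#' @return The scalar cost.
#' @export
cost <- function(model, series, cfg) {
  stopifnot(inherits(model, "poly_model"), inherits(cfg, "penalty_config"))
  sse <- 0
  if (!is.null(series) && nrow(series) > 0) {
    resp <- series_response(series)
    sse <- sum((predict_feature(model, series$hb) - resp)^2)
  }
  a <- model$coeffs[-1]
  n <- length(a)
  cvec <- cfg$c[seq_len(min(n, length(cfg$c)))]
  if (n > length(cvec)) cvec <- c(cvec, rep(0, n - length(cvec)))
  cfg$alpha * sse + cfg$lambda * sum(cvec * a^2)
}

#' Analytic gradient of the penalized cost
#'
#' Components `g_0 = 2 alpha sum_k (f - x)` and, for `i >= 1`,
#' `g_i = 2 alpha sum_k (f - x) h^i + 2 lambda c_i a_i`. This is the update
#' applied verbatim by the gradient-descent fit.
#'
#' @inheritParams cost
#' @return Numeric vector of length `order + 1`.
#' @export
cost_gradient <- function(model, series, cfg) {
  stopifnot(inherits(model, "poly_model"), inherits(cfg, "penalty_config"))
  a <- model$coeffs
  n <- length(a) - 1
  g <- numeric(n + 1)
  if (!is.null(series) && nrow(series) > 0) {
    resp <- series_response(series)
    resid <- predict_feature(model, series$hb) - resp
    for (i in 0:n) {
      g[i + 1] <- 2 * cfg$alpha * sum(resid * series$hb^i)
    }
  }
  cvec <- cfg$c[seq_len(min(n, length(cfg$c)))]
  if (n > length(cvec)) cvec <- c(cvec, rep(0, n - length(cvec)))
  g[-1] <- g[-1] + 2 * cfg$lambda * cvec * a[-1]
  g
}

#' Fit the penalized polynomial by gradient descent
#'
#' Iterates `a_i <- a_i - g_i` (see [cost_gradient()]) from the protocol
#' initialisation — `a_0` at the first feature value of the (filtered)
#' series, `a_1..a_n` uniform on `[0, 1]` under `init_seed` — until
#' successive costs differ by less than `tol` or `max_iter` is reached.
#' With `adapt_step = TRUE` (default) a backtracking damping factor
#' guarantees the cost never increases across accepted iterations; with
#' `adapt_step = FALSE` a step too large for the problem diverges and
#' raises an error suggesting a smaller `alpha`.
#'
#' @param series a `feature_series` (filtered or raw).
#' @param cfg a [penalty_config()].
#' @param trace record the cost trace in the fit report.
#' @return A [poly_model()] whose `fit_report` records iterations, final
#'   cost, convergence flag, the step damping in effect, and the seed used.
#' @export
fit_penalty_regression <- function(series, cfg = penalty_config(),
                                   trace = FALSE) {
  stopifnot(inherits(series, "feature_series"), inherits(cfg, "penalty_config"))
  M <- nrow(series)
  n <- cfg$order
  if (M < n + 1) {
    warning(sprintf(
      "only %d distinct Hb values for an order-%d fit; coefficients are underdetermined",
      M, n))
  }
  h <- series$hb
  resp <- series_response(series)
  ctr <- list(mh = 0, sh = 1, mx = 0, sx = 1)
  if (cfg$standardize) {
    ctr$mh <- mean(h); ctr$sh <- if (sd(h) > 0) sd(h) else 1
    ctr$mx <- mean(resp); ctr$sx <- if (sd(resp) > 0) sd(resp) else 1
    h <- (h - ctr$mh) / ctr$sh
    resp <- (resp - ctr$mx) / ctr$sx
  }
  a_init <- with_rng_seed(cfg$init_seed, c(resp[1], runif(n)))
  res <- gd_fit_cpp(h, resp, a_init, cfg$c, cfg$alpha, cfg$lambda,
                    cfg$tol, cfg$tol_type == "relative",
                    cfg$max_iter, cfg$adapt_step, trace)
  if (isTRUE(res$diverged)) {
    stop_numerical(
      "gradient descent diverged (cost grew beyond 1e12 or became non-finite); reduce alpha")
  }
  coeffs <- res$coeffs
  if (cfg$standardize) {
    coeffs <- destandardize_coeffs(coeffs, ctr)
  }
  report <- list(
    method = "penalized gradient descent",
    iterations = res$iterations,
    final_cost = res$final_cost,
    converged = res$converged,
    step_scale = res$step_scale,
    init_seed = cfg$init_seed,
    standardized = cfg$standardize
  )
  if (trace) report$cost_trace <- res$cost_trace
  poly_model(coeffs, fit_report = report)
}

# Convert coefficients fitted on standardized axes back to raw units:
# f_raw(h) = mx + sx * sum_i b_i ((h - mh)/sh)^i, expanded binomially.
destandardize_coeffs <- function(b, ctr) {
  n <- length(b) - 1
  a <- numeric(n + 1)
  for (i in 0:n) {
    # ((h - mh)/sh)^i = sh^-i * sum_j choose(i, j) h^j (-mh)^(i-j)
    for (j in 0:i) {
      a[j + 1] <- a[j + 1] +
        b[i + 1] * choose(i, j) * (-ctr$mh)^(i - j) / ctr$sh^i
    }
  }
  a <- ctr$sx * a
  a[1] <- a[1] + ctr$mx
  a
}

#' Closed-form linear baseline fit
#'
#' Ordinary least-squares line (feature on Hb), the baseline regressor the
#' nonlinear penalized fit is compared against. Uses the filtered feature
#' when the series has been filtered.
#'
#' @param series a `feature_series` with at least two distinct Hb values.
#' @return A [poly_model()] of order 1.
#' @export
fit_linear_regression <- function(series) {
  stopifnot(inherits(series, "feature_series"))
  if (nrow(series) < 2 || length(unique(series$hb)) < 2) {
    stop_validation("need at least two distinct Hb values for a linear fit")
  }
  resp <- series_response(series)
  fit <- lm(resp ~ hb, data = data.frame(hb = series$hb, resp = resp))
  poly_model(as.numeric(coef(fit)),
             fit_report = list(method = "ordinary least squares",
                               iterations = 0, converged = TRUE,
                               final_cost = sum(fit$residuals^2)))
}

#' Invert the fitted curve: estimate Hb from a feature value
#'
#' Returns the Hb level in `h_range` whose predicted feature is closest to
#' the observed one: a dense-grid argmin of `|f(h) - feature|` followed by
#' local refinement. When the curve is non-monotone one feature value can
#' match several Hb levels (a "matching issue"); ties within `tie_tol` are
#' resolved to the lowest Hb — the conservative choice for anemia
#' screening — with a warning. Features outside the curve's range on
#' `h_range` land on the boundary argmin, i.e. estimates are clamped to
#' the training Hb range.
#'
#' @param model a [poly_model()].
#' @param feature observed feature value.
#' @param h_range length-2 numeric, the training Hb range `[h_lo, h_hi]`.
#' @param grid_points number of grid points (default 10000).
#' @param tie_tol absolute tolerance within which competing minima count
#'   as tied.
#' @return Estimated Hb, g/dL.
#' @export
invert_model <- function(model, feature, h_range,
                         grid_points = 10000, tie_tol = 1e-9) {
  stopifnot(inherits(model, "poly_model"))
  if (length(h_range) != 2 || !all(is.finite(h_range)) ||
      h_range[1] >= h_range[2]) {
    stop_validation("h_range must be a finite increasing pair [h_lo, h_hi]")
  }
  grid <- seq(h_range[1], h_range[2], length.out = grid_points)
  d <- abs(predict_feature(model, grid) - feature)
  objective <- function(h) abs(predict_feature(model, h) - feature)
  # Local minima of the discretized objective (including endpoints), each
  # refined on its bracketing interval.
  n <- length(d)
  is_min <- d <= c(Inf, d[-n]) & d <= c(d[-1], Inf)
  cand_idx <- which(is_min)
  cands <- lapply(cand_idx, function(i) {
    lo <- grid[max(i - 1, 1)]
    hi <- grid[min(i + 1, n)]
    if (lo == hi) return(list(h = grid[i], v = d[i]))
    opt <- optimize(objective, lower = lo, upper = hi,
                    tol = .Machine$double.eps^0.5)
    # Keep the grid point if refinement did not improve (flat objective).
    if (opt$objective <= d[i]) list(h = opt$minimum, v = opt$objective)
    else list(h = grid[i], v = d[i])
  })
  # Endpoints are legitimate argmins (clamping); include them explicitly.
  cands <- c(cands,
             list(list(h = h_range[1], v = d[1]),
                  list(h = h_range[2], v = d[n])))
  hs <- vapply(cands, `[[`, numeric(1), "h")
  vs <- vapply(cands, `[[`, numeric(1), "v")
  vmin <- min(vs)
  tied <- hs[vs - vmin <= tie_tol]
  # Distinct tied locations further apart than one grid step signal a
  # genuine multi-valued inversion.
  tied <- sort(tied)
  step <- (h_range[2] - h_range[1]) / (grid_points - 1)
  if (length(tied) > 1 && any(diff(tied) > 2 * step)) {
    warning(sprintf(
      "matching issue: feature %.6g matches multiple Hb levels (%s); returning the lowest",
      feature, paste(signif(tied, 6), collapse = ", ")))
  }
  tied[1]
}

#' Serialize a polynomial model to JSON
#'
#' @param model a [poly_model()].
#' @param path output path.
#' @param cfg optional [penalty_config()] echoed alongside the model.
#' @export
write_model_json <- function(model, path, cfg = NULL) {
  payload <- list(order = model$order, coeffs = model$coeffs,
                  fit_report = model$fit_report[
                    setdiff(names(model$fit_report), "cost_trace")])
  if (!is.null(cfg)) payload$config <- unclass(cfg)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(payload)
}
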