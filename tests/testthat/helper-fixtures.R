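# Shared fixture builders: tiny images and feature series constructed in
# code, no files needed.

uniform_image <- function(r, g = r * 0.5, b = r * 0.4, h = 4, w = 4) {
  px <- array(0, dim = c(h, w, 3))
  px[, , 1] <- r; px[, , 2] <- g; px[, , 3] <- b
  image_record(px)
}

# A feature series on an exact line feature = intercept + slope * hb.
line_series <- function(hb, slope = 8, intercept = 60) {
  prepare_series(hb, intercept + slope * hb)
}

# Noisy polynomial series with a fixed seed.
noisy_series <- function(n, coeffs, noise_sd, seed, hb_range = c(6, 16)) {
  withr::with_seed(seed, {
    hb <- sort(runif(n, hb_range[1], hb_range[2]))
    f <- outer(hb, seq_along(coeffs) - 1, `^`) %*% coeffs
    prepare_series(hb, as.vector(f) + rnorm(n, 0, noise_sd))
  })
}

# Quiet penalty config for rescaled toy problems.
toy_penalty_config <- function(order, lambda = 0, alpha = 1e-3,
                               c = rep(1, order), tol = 1e-15,
                               tol_type = "absolute", max_iter = 5e5,
                               init_seed = 1, standardize = TRUE) {
  penalty_config(order = order, c = c, lambda = lambda, alpha = alpha,
                 tol = tol, tol_type = tol_type, max_iter = max_iter,
                 init_seed = init_seed, standardize = standardize)
}

# Outcome table builder for RES tests.
outcome_table <- function(level, label) {
  data.frame(level = level, suspect = level == "doubtful", label = label,
             stringsAsFactors = FALSE)
}
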