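#' Specification for a synthetic conjunctiva-like dataset
#'
#' Describes the generative model used to emulate a clinical
#' conjunctiva-photograph study: hemoglobin (Hb) levels drawn uniformly on
#' `[hb_min, hb_max]` g/dL, a mean red intensity that increases linearly
#' with Hb, per-subject physiological scatter, per-pixel sensor noise, and
#' optional saturated specular highlights. Image sides are sampled
#' independently (images are generally not square) and kept below 150 px,
#' matching the small cropped conjunctiva patches the method expects.
#'
#' @param n_subjects number of subjects (one image each).
#' @param hb_min,hb_max range of Hb levels, g/dL.
#' @param anemia_threshold Hb cutoff in g/dL; subjects strictly below it are
#'   labelled anemic.
#' @param slope,intercept linear map from Hb to the generating mean red
#'   intensity (8-bit units): `mean_R = intercept + slope * Hb`.
#' @param pixel_noise_sd per-pixel Gaussian noise sd, 8-bit units.
#' @param subject_noise_sd per-subject Gaussian scatter of the generating
#'   mean red value, 8-bit units.
#' @param spot_probability probability that an image receives one circular
#'   saturated bright spot (specular reflection).
#' @param spot_intensity 8-bit intensity of the bright spot (near 255).
#' @param img_min_side,img_max_side range of image side lengths in pixels;
#'   must stay below 150.
#' @param seed integer seed; all generation is reproducible given the spec.
#'
#' @return An object of class `synthetic_spec`.
#' @seealso [generate_dataset()], [generate_feature_table()]
#' @export
synthetic_spec <- function(n_subjects = 100,
                           hb_min = 6, hb_max = 16,
                           anemia_threshold = 11,
                           slope = 8, intercept = 60,
                           pixel_noise_sd = 5,
                           subject_noise_sd = 4,
                           spot_probability = 0.1,
                           spot_intensity = 250,
                           img_min_side = 80, img_max_side = 149,
                           seed = 1L) {
  spec <- list(
    n_subjects = as.integer(n_subjects),
    hb_min = hb_min, hb_max = hb_max,
    anemia_threshold = anemia_threshold,
    slope = slope, intercept = intercept,
    pixel_noise_sd = pixel_noise_sd,
    subject_noise_sd = subject_noise_sd,
    spot_probability = spot_probability,
    spot_intensity = spot_intensity,
    img_min_side = as.integer(img_min_side),
    img_max_side = as.integer(img_max_side),
    seed = as.integer(seed)
  )
  class(spec) <- "synthetic_spec"
  validate_synthetic_spec(spec)
  spec
}

validate_synthetic_spec <- function(spec) {
  if (spec$n_subjects < 0) {
    stop_validation("n_subjects must be >= 0")
  }
  if (!(spec$hb_min < spec$hb_max)) {
    stop_validation("hb_min must be strictly less than hb_max")
  }
  if (!(spec$hb_min < spec$anemia_threshold &&
        spec$anemia_threshold < spec$hb_max)) {
    stop_validation("anemia_threshold must lie strictly inside [hb_min, hb_max]")
  }
  if (spec$slope <= 0) {
    stop_validation("slope must be positive (mean red increases with Hb)")
  }
  if (spec$pixel_noise_sd < 0 || spec$subject_noise_sd < 0) {
    stop_validation("noise standard deviations must be nonnegative")
  }
  if (spec$spot_probability < 0 || spec$spot_probability > 1) {
    stop_validation("spot_probability must be in [0, 1]")
  }
  if (spec$img_min_side < 1 || spec$img_max_side < spec$img_min_side) {
    stop_validation("image side range invalid (need 1 <= img_min_side <= img_max_side)")
  }
  if (spec$img_max_side >= 150) {
    stop_validation("img_max_side must be below 150 pixels")
  }
  invisible(spec)
}

# Draw the per-subject quantities shared by the image and feature-table
# generators: Hb levels, generating mean-R values, labels.
draw_subjects <- function(spec) {
  n <- spec$n_subjects
  hb <- runif(n, spec$hb_min, spec$hb_max)
  feature <- spec$intercept + spec$slope * hb +
    rnorm(n, 0, spec$subject_noise_sd)
  data.frame(
    subject_id = sprintf("subj%03d", seq_len(n)),
    hb_g_dl = hb,
    feature = feature,
    label = ifelse(hb < spec$anemia_threshold, "anemic", "nonanemic"),
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic conjunctiva image dataset on disk
#'
#' Writes one 8-bit RGB PNG per subject plus a manifest CSV
#' (`filename, hb_g_dl, label`) and a YAML echo of the generating spec.
#' The red channel of each image is the subject's generating mean-R value
#' plus per-pixel Gaussian noise; green and blue sit at fixed lower
#' baselines (0.5x and 0.4x of the red mean) so the images are red-dominant
#' like real conjunctiva crops. With probability `spot_probability` a
#' saturated disk (radius 10% of the shorter side) is stamped on all three
#' channels, emulating a specular reflection from the tear film.
#'
#' @param spec a [synthetic_spec()].
#' @param dir output directory; created if missing.
#' @return Invisibly, the manifest `data.frame` with an extra
#'   `generating_mean_r` column (the noise-free mean red value per subject).
#' @export
generate_dataset <- function(spec, dir) {
  validate_synthetic_spec(spec)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  manifest <- with_rng_seed(spec$seed, {
    subjects <- draw_subjects(spec)
    filenames <- character(nrow(subjects))
    for (i in seq_len(nrow(subjects))) {
      h <- sample(spec$img_min_side:spec$img_max_side, 1)
      w <- sample(spec$img_min_side:spec$img_max_side, 1)
      mean_r <- subjects$feature[i]
      px <- array(0, dim = c(h, w, 3))
      base <- c(1, 0.5, 0.4) * mean_r
      for (ch in 1:3) {
        px[, , ch] <- base[ch] + rnorm(h * w, 0, spec$pixel_noise_sd)
      }
      if (runif(1) < spec$spot_probability) {
        px <- stamp_spot(px, spec$spot_intensity)
      }
      px <- pmin(pmax(round(px), 0), 255)
      filenames[i] <- sprintf("%s.png", subjects$subject_id[i])
      png::writePNG(px / 255, file.path(dir, filenames[i]))
    }
    data.frame(
      filename = filenames,
      hb_g_dl = subjects$hb_g_dl,
      label = subjects$label,
      generating_mean_r = subjects$feature,
      stringsAsFactors = FALSE
    )
  })
  write.csv(manifest[, c("filename", "hb_g_dl", "label")],
            file.path(dir, "manifest.csv"), row.names = FALSE)
  yaml::write_yaml(unclass(spec), file.path(dir, "spec.yaml"))
  invisible(manifest)
}

# Saturated disk at a random centre, radius 10% of the shorter side.
stamp_spot <- function(px, intensity) {
  h <- dim(px)[1]; w <- dim(px)[2]
  r <- 0.1 * min(h, w)
  cy <- runif(1, 1, h); cx <- runif(1, 1, w)
  yy <- matrix(seq_len(h), h, w)
  xx <- matrix(seq_len(w), h, w, byrow = TRUE)
  mask <- (yy - cy)^2 + (xx - cx)^2 <= r^2
  for (ch in 1:3) {
    plane <- px[, , ch]
    plane[mask] <- intensity
    px[, , ch] <- plane
  }
  px
}

#' Generate a synthetic feature table (no images)
#'
#' Applies the same generative model as [generate_dataset()] at the feature
#' level only: `feature = intercept + slope * Hb + subject_noise`. Useful
#' for fast tests of the filtering and regression stages. Duplicate Hb
#' values, if drawn, are kept as-is; collapsing them is the series
#' preparation step's job.
#'
#' @param spec a [synthetic_spec()].
#' @param path optional CSV path; when given, the table is also written out.
#' @return A `data.frame` with columns `subject_id`, `hb_g_dl`, `feature`,
#'   `label`. Zero subjects yields an empty table.
#' @export
generate_feature_table <- function(spec, path = NULL) {
  validate_synthetic_spec(spec)
  tab <- with_rng_seed(spec$seed, draw_subjects(spec))
  tab <- tab[, c("subject_id", "hb_g_dl", "feature", "label")]
  if (!is.null(path)) write.csv(tab, path, row.names = FALSE)
  tab
}
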