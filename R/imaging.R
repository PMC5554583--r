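#' Image records
#'
#' An image record couples an RGB pixel array (H x W x 3, intensities on
#' the 0-255 scale; real-valued after resampling) with a subject id and,
#' when known, the subject's Hb level in g/dL.
#'
#' @param pixels numeric array H x W x 3 (channels R, G, B in that order).
#' @param subject_id character scalar.
#' @param hb_g_dl optional Hb level, g/dL.
#' @return An object of class `image_record`.
#' @export
image_record <- function(pixels, subject_id = "unknown", hb_g_dl = NA_real_) {
  d <- dim(pixels)
  if (length(d) != 3 || d[3] != 3) {
    stop_validation("pixels must be an H x W x 3 array (R, G, B channels)")
  }
  if (d[1] < 1 || d[2] < 1) {
    stop_validation("image must have at least one pixel")
  }
  structure(
    list(pixels = pixels, subject_id = as.character(subject_id),
         hb_g_dl = hb_g_dl),
    class = "image_record"
  )
}

#' Read an 8-bit RGB PNG as an image record
#'
#' @param path PNG file path.
#' @inheritParams image_record
#' @return An `image_record` with intensities on the 0-255 scale. An alpha
#'   channel, if present, is dropped.
#' @export
read_image <- function(path, subject_id = sub("\\.png$", "", basename(path)),
                       hb_g_dl = NA_real_) {
  if (!file.exists(path)) {
    stop_validation(sprintf("image file not found: %s", path))
  }
  px <- png::readPNG(path)
  if (length(dim(px)) == 2) {
    stop_validation(sprintf("grayscale image not supported (need RGB): %s", path))
  }
  if (dim(px)[3] == 4) px <- px[, , 1:3, drop = FALSE]
  image_record(px * 255, subject_id = subject_id, hb_g_dl = hb_g_dl)
}

# Keys bicubic kernel, a = -0.5 (the conventional photographic choice).
cubic_kernel <- function(t, a = -0.5) {
  t <- abs(t)
  w <- numeric(length(t))
  i1 <- t <= 1
  i2 <- t > 1 & t < 2
  w[i1] <- (a + 2) * t[i1]^3 - (a + 3) * t[i1]^2 + 1
  w[i2] <- a * t[i2]^3 - 5 * a * t[i2]^2 + 8 * a * t[i2] - 4 * a
  w
}

# Interpolation matrix mapping n_in samples to n_out samples along one
# axis. Pixel centres live at integer coordinates; edges are replicated;
# each output row is normalised to sum exactly to 1 so constants are
# preserved bit-for-bit.
bicubic_matrix <- function(n_in, n_out) {
  scale <- n_in / n_out
  x <- (seq_len(n_out) - 0.5) * scale + 0.5
  W <- matrix(0, n_out, n_in)
  base <- floor(x)
  for (j in -1:2) {
    idx <- base + j
    w <- cubic_kernel(x - idx)
    idx <- pmin(pmax(idx, 1), n_in)
    W[cbind(seq_len(n_out), idx)] <- W[cbind(seq_len(n_out), idx)] + w
  }
  W / rowSums(W)
}

#' Resize an image to a fixed square size by bicubic resampling
#'
#' Cropped conjunctiva patches arrive at varying small sizes; the protocol
#' enlarges every image to a common `side` x `side` (default 500 x 500)
#' before feature extraction. Resampling is separable bicubic (Keys kernel,
#' a = -0.5) with replicated edges; output intensities are clipped to
#' `[0, 255]` (bicubic overshoot can leave the 8-bit range).
#'
#' @param img an [image_record()].
#' @param side target side length in pixels.
#' @return An `image_record` of size `side` x `side` x 3 with real-valued
#'   intensities.
#' @export
resize_image <- function(img, side = 500) {
  stopifnot(inherits(img, "image_record"))
  d <- dim(img$pixels)
  if (side < 1) stop_validation("side must be >= 1")
  Wr <- bicubic_matrix(d[1], side)
  Wc <- bicubic_matrix(d[2], side)
  out <- array(0, dim = c(side, side, 3))
  for (ch in 1:3) {
    out[, , ch] <- pmin(pmax(Wr %*% img$pixels[, , ch] %*% t(Wc), 0), 255)
  }
  image_record(out, subject_id = img$subject_id, hb_g_dl = img$hb_g_dl)
}

#' Scalar color features of a conjunctiva image
#'
#' Three single-number recognition features are supported:
#' * `mean_red` — arithmetic mean of the red channel (pallor decreases it);
#' * `erythema` — erythema index, `log10` of the mean red intensity;
#' * `hue` — circular mean of the per-pixel HSI hue in degrees, gray
#'   pixels (R = G = B) excluded.
#'
#' @param img an [image_record()].
#' @return A single numeric value.
#' @export
extract_mean_red <- function(img) {
  stopifnot(inherits(img, "image_record"))
  mean(img$pixels[, , 1])
}

#' @rdname extract_mean_red
#' @export
extract_erythema <- function(img) {
  m <- extract_mean_red(img)
  if (m <= 0) {
    stop_validation("erythema index undefined: mean red intensity is 0")
  }
  log10(m)
}

#' @rdname extract_mean_red
#' @export
extract_hue <- function(img) {
  stopifnot(inherits(img, "image_record"))
  R <- as.vector(img$pixels[, , 1])
  G <- as.vector(img$pixels[, , 2])
  B <- as.vector(img$pixels[, , 3])
  gray <- R == G & G == B
  R <- R[!gray]; G <- G[!gray]; B <- B[!gray]
  if (length(R) == 0) return(0)
  # Standard HSI hue: theta = acos(((R-G)+(R-B)) / (2 sqrt((R-G)^2+(R-B)(G-B))));
  # hue = theta when B <= G, else 360 - theta. Denominator is 0 only for
  # gray pixels, which were removed above.
  num <- 0.5 * ((R - G) + (R - B))
  den <- sqrt((R - G)^2 + (R - B) * (G - B))
  theta <- acos(pmin(pmax(num / den, -1), 1)) * 180 / pi
  hue <- ifelse(B > G, 360 - theta, theta)
  # Circular mean via unit vectors; an arithmetic mean of angles would be
  # biased near the 0/360 wrap where red hues live.
  rad <- hue * pi / 180
  ang <- atan2(mean(sin(rad)), mean(cos(rad))) * 180 / pi
  (ang + 360) %% 360
}

#' @param feature_name one of `"mean_red"`, `"erythema"`, `"hue"`.
#' @rdname extract_mean_red
#' @export
extract_feature <- function(img, feature_name = c("mean_red", "erythema", "hue")) {
  feature_name <- match.arg(feature_name)
  switch(feature_name,
         mean_red = extract_mean_red(img),
         erythema = extract_erythema(img),
         hue = extract_hue(img))
}

#' Read and validate an image manifest
#'
#' The manifest is a CSV with columns `filename` and `hb_g_dl` (a `label`
#' column is optional and recomputed downstream from the threshold).
#'
#' @param path manifest CSV path.
#' @param dir directory holding the images; defaults to the manifest's own
#'   directory.
#' @param require_images when `TRUE` (default) every referenced file must
#'   exist.
#' @return A `data.frame` with columns `subject_id`, `path`, `hb_g_dl` and,
#'   if present in the input, `label`.
#' @export
read_manifest <- function(path, dir = dirname(path), require_images = TRUE) {
  if (!file.exists(path)) {
    stop_validation(sprintf("manifest not found: %s", path))
  }
  man <- read.csv(path, stringsAsFactors = FALSE)
  for (col in c("filename", "hb_g_dl")) {
    if (!col %in% names(man)) {
      stop_validation(sprintf("manifest is missing required column '%s'", col))
    }
  }
  bad <- which(!is.finite(man$hb_g_dl) | man$hb_g_dl <= 0)
  if (length(bad) > 0) {
    stop_validation(sprintf(
      "manifest row %d has nonpositive or missing hb_g_dl (%s)",
      bad[1], man$filename[bad[1]]))
  }
  full <- file.path(dir, man$filename)
  if (require_images) {
    missing <- which(!file.exists(full))
    if (length(missing) > 0) {
      stop_validation(sprintf("manifest references missing image file: %s",
                              man$filename[missing[1]]))
    }
  }
  out <- data.frame(
    subject_id = sub("\\.[A-Za-z]+$", "", man$filename),
    path = full,
    hb_g_dl = man$hb_g_dl,
    stringsAsFactors = FALSE
  )
  if ("label" %in% names(man)) out$label <- man$label
  out
}

#' Extract features for every image in a manifest
#'
#' Reads each image, resizes it to `side` x `side`, and computes the
#' requested scalar features.
#'
#' @param manifest a `data.frame` from [read_manifest()].
#' @param side resize target (pixels); the protocol default is 500.
#' @param features character vector of feature names to extract.
#' @return A `data.frame` with `subject_id`, `hb_g_dl`, optional `label`,
#'   and one column per feature.
#' @export
extract_features <- function(manifest, side = 500,
                             features = c("mean_red", "erythema", "hue")) {
  features <- match.arg(features, c("mean_red", "erythema", "hue"),
                        several.ok = TRUE)
  vals <- matrix(NA_real_, nrow(manifest), length(features),
                 dimnames = list(NULL, features))
  for (i in seq_len(nrow(manifest))) {
    img <- read_image(manifest$path[i], subject_id = manifest$subject_id[i],
                      hb_g_dl = manifest$hb_g_dl[i])
    img <- resize_image(img, side = side)
    for (f in features) vals[i, f] <- extract_feature(img, f)
  }
  out <- data.frame(subject_id = manifest$subject_id,
                    hb_g_dl = manifest$hb_g_dl,
                    stringsAsFactors = FALSE)
  if ("label" %in% names(manifest)) out$label <- manifest$label
  cbind(out, as.data.frame(vals))
}

#' Write a feature table in long format
#'
#' @param features wide feature table from [extract_features()].
#' @param path output CSV path.
#' @return Invisibly, the long-format `data.frame`
#'   (`subject_id, hb_g_dl, feature_name, value`).
#' @export
write_feature_csv <- function(features, path) {
  feat_cols <- intersect(c("mean_red", "erythema", "hue"), names(features))
  long <- do.call(rbind, lapply(feat_cols, function(f) {
    data.frame(subject_id = features$subject_id,
               hb_g_dl = features$hb_g_dl,
               feature_name = f,
               value = features[[f]],
               stringsAsFactors = FALSE)
  }))
  write.csv(long, path, row.names = FALSE)
  invisible(long)
}
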