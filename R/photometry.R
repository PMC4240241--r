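#' Grayscale image patch
#'
#' A numeric matrix of gray levels with a bit depth and a physical pixel
#' size. Gray levels must lie in `[0, 2^bit_depth - 1]`; they need not be
#' integers in memory (quantization happens only on file output).
#'
#' @param pixels numeric matrix (rows = y, columns = x).
#' @param bit_depth 8 or 16.
#' @param pixel_size physical pixel size, micrometres per pixel.
#' @return object of class `"image_patch"` (a matrix with `bit_depth` and
#'   `pixel_size` attributes).
#' @export
image_patch <- function(pixels, bit_depth = 8, pixel_size = 1) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("pixels must be a numeric matrix", call. = FALSE)
  }
  if (!bit_depth %in% c(8, 16)) stop("bit_depth must be 8 or 16", call. = FALSE)
  maxval <- 2^bit_depth - 1
  if (any(is.na(pixels)) || any(pixels < 0) || any(pixels > maxval)) {
    stop(sprintf("gray levels must be in [0, %d]", maxval), call. = FALSE)
  }
  structure(pixels, bit_depth = bit_depth, pixel_size = pixel_size,
            class = c("image_patch", class(pixels)))
}

#' @export
print.image_patch <- function(x, ...) {
  cat(sprintf("Image patch: %d x %d px, %d-bit, %.3g um/px, gray levels [%.4g, %.4g]\n",
              ncol(x), nrow(x), attr(x, "bit_depth"), attr(x, "pixel_size"),
              min(x), max(x)))
  invisible(x)
}

#' Read/write an image patch (grayscale PNG or TIFF)
#'
#' Files store intensity on `[0, 1]`; gray levels are scaled by
#' `2^bit_depth - 1`. Multi-channel images are averaged to grayscale on
#' read.
#'
#' @param path file path ending in `.png`, `.tif` or `.tiff`.
#' @param bit_depth bit depth to interpret/write the file at.
#' @param pixel_size micrometres per pixel to attach on read.
#' @return `read_image_patch()`: an [image_patch()]; `write_image_patch()`:
#'   `path`, invisibly.
#' @export
read_image_patch <- function(path, bit_depth = 8, pixel_size = 1) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = tiff::readTIFF(path),
    stop(sprintf("unsupported image format: .%s", ext), call. = FALSE))
  if (length(dim(img)) == 3L) img <- apply(img, c(1, 2), mean)
  image_patch(img * (2^bit_depth - 1), bit_depth = bit_depth,
              pixel_size = pixel_size)
}

#' @rdname read_image_patch
#' @param image an [image_patch()].
#' @export
write_image_patch <- function(image, path) {
  stopifnot(inherits(image, "image_patch"))
  bit_depth <- attr(image, "bit_depth")
  norm <- unclass(image) / (2^bit_depth - 1)
  attributes(norm) <- list(dim = dim(image))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(norm, path),
    tif = , tiff = tiff::writeTIFF(norm, path,
                                   bits.per.sample = if (bit_depth == 16) 16L else 8L),
    stop(sprintf("unsupported image format: .%s", ext), call. = FALSE))
  invisible(path)
}

#' Rectangular site region of interest
#'
#' Coordinates are 0-based from the top-left pixel with half-open extents:
#' the ROI covers columns `x .. x+width-1` and rows `y .. y+height-1`.
#'
#' @param x,y top-left corner (0-based).
#' @param width,height extent in pixels.
#' @param site_id optional identifier.
#' @return object of class `"site_roi"`.
#' @export
site_roi <- function(x, y, width, height, site_id = NA_character_) {
  v <- c(x = x, y = y, width = width, height = height)
  if (any(is.na(v)) || any(v != round(v)) || x < 0 || y < 0 || width < 1 || height < 1) {
    stop("x, y must be non-negative integers; width, height positive integers",
         call. = FALSE)
  }
  structure(list(site_id = as.character(site_id), x = as.integer(x),
                 y = as.integer(y), width = as.integer(width),
                 height = as.integer(height)),
            class = "site_roi")
}

#' Read site ROI definitions from CSV
#'
#' Expects columns `site_id, x, y, width, height` (0-based, top-left
#' origin).
#'
#' @param path CSV file path.
#' @return list of [site_roi()] objects.
#' @export
read_roi_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("site_id", "x", "y", "width", "height")
  if (!all(need %in% names(df))) {
    stop(sprintf("ROI CSV must have columns: %s", paste(need, collapse = ", ")),
         call. = FALSE)
  }
  lapply(seq_len(nrow(df)), function(i) {
    site_roi(df$x[i], df$y[i], df$width[i], df$height[i], site_id = df$site_id[i])
  })
}

#' Write site ROI definitions to CSV
#' @param rois list of [site_roi()] objects.
#' @param path output CSV path.
#' @export
write_roi_table <- function(rois, path) {
  df <- do.call(rbind, lapply(rois, function(r) {
    data.frame(site_id = r$site_id, x = r$x, y = r$y,
               width = r$width, height = r$height, stringsAsFactors = FALSE)
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

roi_pixels <- function(image, roi) {
  stopifnot(inherits(image, "image_patch"), inherits(roi, "site_roi"))
  if (roi$x + roi$width > ncol(image) || roi$y + roi$height > nrow(image)) {
    stop(sprintf("ROI %s extends outside the image", roi$site_id), call. = FALSE)
  }
  unclass(image)[(roi$y + 1):(roi$y + roi$height),
                 (roi$x + 1):(roi$x + roi$width), drop = FALSE]
}

#' Mean gray level of a site ROI
#'
#' @param image an [image_patch()].
#' @param roi a [site_roi()] fully inside the image.
#' @return arithmetic mean of the ROI's gray levels.
#' @export
site_intensity <- function(image, roi) mean(roi_pixels(image, roi))

#' Histogram extreme of an image
#'
#' The reference intensity for the optical indices: the maximum gray level
#' for radiopacity, the minimum for translucency.
#'
#' @param image an [image_patch()].
#' @param kind `"radiopacity"` or `"translucency"`.
#' @return a gray level.
#' @export
histogram_extreme <- function(image, kind = c("radiopacity", "translucency")) {
  stopifnot(inherits(image, "image_patch"))
  kind <- match.arg(kind)
  if (kind == "radiopacity") max(image) else min(image)
}

#' Optical index of a site
#'
#' `(I_ext - delta_I) / I_ext` with `delta_I = |I_site - I_ext|`, where
#' `I_ext` is the image-histogram extreme (maximum for radiopacity, minimum
#' for translucency). For radiopacity this reduces algebraically to
#' `I_site / I_max`. The index can be negative (when `I_site > 2 * I_min`
#' for translucency); negative values are preserved and flagged, not
#' clipped.
#'
#' @param I_site site gray level(s).
#' @param I_ext histogram extreme; must be positive.
#' @param kind `"radiopacity"` or `"translucency"`.
#' @return data frame with columns `kind`, `I_site`, `I_ext`, `delta_I`,
#'   `value`, `negative`.
#' @export
optical_index <- function(I_site, I_ext, kind = c("radiopacity", "translucency")) {
  kind <- match.arg(kind)
  if (is.na(I_ext) || I_ext <= 0) {
    stop("I_ext must be positive: index undefined", call. = FALSE)
  }
  delta_I <- abs(I_site - I_ext)
  value <- (I_ext - delta_I) / I_ext
  data.frame(kind = kind, I_site = I_site, I_ext = I_ext, delta_I = delta_I,
             value = value, negative = value < 0, stringsAsFactors = FALSE)
}

#' Saturation quality control
#'
#' An image passes when its maximum gray level is strictly below `fraction`
#' of the representable maximum, guarding against clipped highlights.
#'
#' @param image an [image_patch()].
#' @param fraction saturation threshold as a fraction of `2^bit_depth - 1`.
#' @return object of class `"saturation_qc"`: `pass`, `max_level`,
#'   `threshold`.
#' @export
check_saturation <- function(image, fraction = 0.8) {
  stopifnot(inherits(image, "image_patch"))
  threshold <- fraction * (2^attr(image, "bit_depth") - 1)
  max_level <- max(image)
  structure(list(pass = max_level < threshold, max_level = max_level,
                 threshold = threshold, fraction = fraction),
            class = "saturation_qc")
}

#' @export
print.saturation_qc <- function(x, ...) {
  cat(sprintf("Saturation QC: %s (max gray level %.4g, threshold %.4g)\n",
              if (x$pass) "pass" else "FAIL", x$max_level, x$threshold))
  invisible(x)
}

#' Min-max normalization of optical indices
#'
#' `(v - min) / (max - min)`: order-preserving, invariant under affine
#' transforms of the input, maps the observed range onto `[0, 1]`.
#'
#' @param values numeric vector with at least two distinct finite values;
#'   `NA`s are preserved.
#' @return normalized vector in `[0, 1]`.
#' @export
normalize_indices <- function(values) {
  v <- values[!is.na(values)]
  if (length(unique(v)) < 2L) {
    stop("need at least two distinct values to normalize", call. = FALSE)
  }
  (values - min(v)) / (max(v) - min(v))
}

#' Pearson correlation with adjusted R-squared
#'
#' Pearson product-moment correlation plus the least-squares line and the
#' adjusted coefficient of determination
#' `1 - (1 - r^2) * (n - 1) / (n - 2)`, which (unlike plain `r^2`) can be
#' negative for uncorrelated data — at `r = 0`, `n = 80` it equals
#' `1 - 79/78 = -0.0128`.
#'
#' @param x,y equal-length numeric vectors, `n >= 3`, each with nonzero
#'   variance.
#' @return object of class `"photometric_correlation"`: `r`,
#'   `r_squared_plain`, `r_squared_adjusted`, `slope`, `intercept`, `n`.
#' @export
correlate <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L || length(y) != n) stop("need >= 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance: correlation undefined", call. = FALSE)
  }
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  slope <- r * stats::sd(y) / stats::sd(x)
  structure(list(r = r, r_squared_plain = r^2,
                 r_squared_adjusted = 1 - (1 - r^2) * (n - 1) / (n - 2),
                 slope = slope, intercept = mean(y) - slope * mean(x), n = n),
            class = "photometric_correlation")
}

#' @export
print.photometric_correlation <- function(x, ...) {
  cat(sprintf("Pearson r = %.4f (n = %d); adjusted R^2 = %.4f; fit y = %.4g + %.4g x\n",
              x$r, x$n, x$r_squared_adjusted, x$intercept, x$slope))
  invisible(x)
}

#' Optical indices for every site ROI of an image
#'
#' Convenience wrapper: measures each ROI's mean gray level, the image's
#' histogram extreme for the requested index kind, and the per-site optical
#' index.
#'
#' @param image an [image_patch()].
#' @param rois list of [site_roi()] objects.
#' @inheritParams optical_index
#' @return data frame, one row per site: `site_id`, `kind`, `I_site`,
#'   `I_ext`, `delta_I`, `value`, `negative`.
#' @export
measure_sites <- function(image, rois, kind = c("radiopacity", "translucency")) {
  kind <- match.arg(kind)
  I_ext <- histogram_extreme(image, kind)
  out <- do.call(rbind, lapply(rois, function(roi) {
    idx <- optical_index(site_intensity(image, roi), I_ext, kind)
    cbind(data.frame(site_id = roi$site_id, stringsAsFactors = FALSE), idx)
  }))
  rownames(out) <- NULL
  out
}
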