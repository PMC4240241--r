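#' Fit an illumination-heterogeneity model to an image
#'
#' Characterizes vignetting (radial brightness fall-off) of a micrograph.
#' The image is normalized by its maximum gray level; two 1-D profiles are
#' formed by averaging over rows (the x profile) and over columns (the y
#' profile); each profile is fitted by least squares to either
#' `baseline + height * exp(-(t - mu)^2 / (2 * sigma^2))` (`"gaussian"`) or
#' `baseline + slope * t` (`"linear"`). The reported `height` is the mean
#' fitted amplitude over the two axes (for the linear model, the amplitude
#' is `|slope|` times the profile span, the total rise across the field);
#' `r_squared` is the adjusted R-squared of the pooled two-axis fit and can
#' be negative when the model explains nothing.
#'
#' Regions holding specimen structure rather than illumination (the
#' measured site ROIs) can be excluded: every image row intersecting an
#' excluded region is dropped from the x profile and every such column
#' from the y profile, so each profile averages the same background pixels
#' at every position and keeps its shape.
#'
#' @param image an [image_patch()], at least 16 x 16 pixels.
#' @param model `"gaussian"` or `"linear"`.
#' @param exclude optional list of [site_roi()] regions to drop from the
#'   profiles.
#' @return object of class `"illumination_fit"`: `model`, `height`,
#'   `r_squared`, per-axis `params`, `profiles`, `fitted`, `converged`.
#'   Supports `print()`, `summary()`, `coef()`, `fitted()`, `residuals()`,
#'   `predict()` and `plot()`.
#' @examples
#' img <- generate_micrograph(image_scenario(n_sites = 0,
#'   vignette_model = "gaussian", vignette_height = 0.13, noise_sd = 0))$mr
#' fit_illumination(img, "gaussian")
#' @export
fit_illumination <- function(image, model = c("gaussian", "linear"),
                             exclude = NULL) {
  stopifnot(inherits(image, "image_patch"))
  model <- match.arg(model)
  if (nrow(image) < 16 || ncol(image) < 16) {
    stop("image must be at least 16 x 16 pixels", call. = FALSE)
  }
  I <- unclass(image)
  keep_rows <- rep(TRUE, nrow(I))
  keep_cols <- rep(TRUE, ncol(I))
  for (roi in exclude) {
    keep_rows[(roi$y + 1):(roi$y + roi$height)] <- FALSE
    keep_cols[(roi$x + 1):(roi$x + roi$width)] <- FALSE
  }
  if (sum(keep_rows) < 2 || sum(keep_cols) < 2) {
    stop("excluded regions leave too little background to profile", call. = FALSE)
  }
  mx <- max(I[keep_rows, keep_cols])
  if (mx <= 0) stop("blank image: cannot normalize", call. = FALSE)
  I <- I / mx
  profiles <- list(x = colMeans(I[keep_rows, , drop = FALSE]),
                   y = rowMeans(I[, keep_cols, drop = FALSE]))

  axis_fits <- lapply(profiles, fit_profile, model = model)
  sse <- sum(vapply(axis_fits, function(f) sum(f$residuals^2), numeric(1)))
  sst <- sum(vapply(profiles, function(p) sum((p - mean(p))^2), numeric(1)))
  r2 <- if (sst <= .Machine$double.eps) 0 else 1 - sse / sst
  n <- sum(lengths(profiles))
  k <- sum(vapply(axis_fits, function(f) f$n_params, numeric(1)))
  r2_adj <- 1 - (1 - r2) * (n - 1) / (n - k)

  structure(list(model = model,
                 height = mean(vapply(axis_fits, function(f) f$height, numeric(1))),
                 r_squared = r2_adj, r_squared_plain = r2,
                 params = lapply(axis_fits, function(f) f$params),
                 profiles = profiles,
                 fitted = lapply(axis_fits, function(f) f$fitted),
                 converged = all(vapply(axis_fits, function(f) f$converged, logical(1))),
                 notes = unlist(lapply(axis_fits, function(f) f$note))),
            class = "illumination_fit")
}

## least-squares fit of one averaged 1-D profile; t is the 0-based pixel index
fit_profile <- function(p, model) {
  t <- seq_along(p) - 1
  if (stats::sd(p) < 1e-12) {
    # degenerate flat profile: nothing to fit
    fitted <- rep(mean(p), length(p))
    params <- if (model == "gaussian") {
      c(baseline = mean(p), height = 0, mu = mean(t), sigma = length(p) / 4)
    } else {
      c(baseline = mean(p), slope = 0)
    }
    return(list(params = params, height = 0, fitted = fitted,
                residuals = p - fitted, converged = TRUE,
                n_params = if (model == "gaussian") 4 else 2,
                note = "degenerate flat profile"))
  }
  if (model == "linear") {
    fit <- stats::lm(p ~ t)
    slope <- unname(stats::coef(fit)[2])
    return(list(params = c(baseline = unname(stats::coef(fit)[1]), slope = slope),
                height = abs(slope) * (length(p) - 1),
                fitted = as.numeric(stats::fitted(fit)),
                residuals = as.numeric(stats::residuals(fit)),
                converged = TRUE, n_params = 2, note = NULL))
  }
  # coarse grid over (mu, sigma) with baseline/amplitude solved linearly,
  # then Levenberg-Marquardt polish; the grid solution is the fallback when
  # the polish fails (a shallow gaussian is weakly identified and an
  # unbounded fit trades amplitude against baseline)
  n_p <- length(p)
  best <- NULL
  for (mu0 in stats::quantile(t, c(0.25, 0.5, 0.75), names = FALSE)) {
    for (s0 in n_p * c(1/6, 1/3, 0.45, 0.6)) {
      g <- exp(-(t - mu0)^2 / (2 * s0^2))
      cf <- stats::coef(stats::lm(p ~ g))
      h0 <- max(unname(cf[2]), 0)
      b0 <- if (h0 > 0) unname(cf[1]) else mean(p)
      res <- p - (b0 + h0 * g)
      cand <- list(b = b0, h = h0, mu = mu0, s = s0, sse = sum(res^2))
      if (is.null(best) || cand$sse < best$sse) best <- cand
    }
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(p ~ b + h * exp(-(t - mu)^2 / (2 * s^2)),
                      start = best[c("b", "h", "mu", "s")],
                      lower = c(b = -1, h = 0, mu = min(t), s = 2),
                      upper = c(b = 1, h = 1, mu = max(t), s = 0.6 * n_p),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    fitted <- best$b + best$h * exp(-(t - best$mu)^2 / (2 * best$s^2))
    return(list(params = c(baseline = best$b, height = best$h,
                           mu = best$mu, sigma = best$s),
                height = best$h, fitted = fitted, residuals = p - fitted,
                converged = FALSE, n_params = 4,
                note = paste("grid start only; LM polish failed:",
                             conditionMessage(fit))))
  }
  cf <- stats::coef(fit)
  list(params = c(baseline = unname(cf["b"]), height = unname(cf["h"]),
                  mu = unname(cf["mu"]), sigma = unname(cf["s"])),
       height = unname(cf["h"]), fitted = as.numeric(stats::fitted(fit)),
       residuals = as.numeric(stats::residuals(fit)), converged = TRUE,
       n_params = 4, note = NULL)
}

#' @export
print.illumination_fit <- function(x, ...) {
  cat(sprintf("Illumination fit (%s): height = %.4f, adjusted R^2 = %.4f%s\n",
              x$model, x$height, x$r_squared,
              if (x$converged) "" else "  [DID NOT CONVERGE]"))
  invisible(x)
}

#' @export
summary.illumination_fit <- function(object, ...) {
  print(object)
  for (ax in names(object$params)) {
    cat(sprintf("  %s axis: %s\n", ax,
                paste(sprintf("%s=%.4g", names(object$params[[ax]]),
                              object$params[[ax]]), collapse = ", ")))
  }
  if (length(object$notes)) cat("  notes:", paste(object$notes, collapse = "; "), "\n")
  invisible(object)
}

#' @export
coef.illumination_fit <- function(object, ...) {
  c(height = object$height,
    baseline = mean(vapply(object$params, function(p) p[["baseline"]], numeric(1))))
}

#' @export
fitted.illumination_fit <- function(object, ...) object$fitted

#' @export
residuals.illumination_fit <- function(object, ...) {
  Map(function(p, f) p - f, object$profiles, object$fitted)
}

#' Predict illumination profiles at pixel positions
#'
#' @param object an `"illumination_fit"`.
#' @param newdata optional list with numeric elements `x` and/or `y` of
#'   0-based pixel positions; defaults to the fitted positions.
#' @param ... unused.
#' @return list of predicted normalized-intensity profiles per axis.
#' @export
predict.illumination_fit <- function(object, newdata = NULL, ...) {
  eval_axis <- function(params, t) {
    if (object$model == "gaussian") {
      params[["baseline"]] + params[["height"]] *
        exp(-(t - params[["mu"]])^2 / (2 * params[["sigma"]]^2))
    } else {
      params[["baseline"]] + params[["slope"]] * t
    }
  }
  axes <- if (is.null(newdata)) {
    lapply(object$profiles, function(p) seq_along(p) - 1)
  } else {
    newdata[intersect(names(newdata), c("x", "y"))]
  }
  Map(function(ax, t) eval_axis(object$params[[ax]], t), names(axes), axes)
}

#' @export
plot.illumination_fit <- function(x, ...) {
  old <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(old))
  for (ax in names(x$profiles)) {
    t <- seq_along(x$profiles[[ax]]) - 1
    graphics::plot(t, x$profiles[[ax]], type = "p", pch = 16, cex = 0.4,
                   xlab = sprintf("%s (px)", ax), ylab = "normalized intensity",
                   main = sprintf("%s profile (%s fit)", ax, x$model), ...)
    graphics::lines(t, x$fitted[[ax]], col = "red", lwd = 2)
  }
  invisible(x)
}
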