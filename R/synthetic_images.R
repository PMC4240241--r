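#' Specify a synthetic micrograph scenario
#'
#' Describes one pair of grayscale patches — an SM-like image (bright dentin
#' sites on a dark background, translucency measured against the histogram
#' minimum) and an MR-like image (radiopacity measured against the
#' histogram maximum) — with a shared multiplicative vignette, additive
#' Gaussian noise, and per-site ground-truth optical indices drawn from a
#' Gaussian copula with correlation `rho`. Defaults describe the
#' flat-illumination digital-microradiography setup used for the
#' translucency-vs-radiopacity experiment: mild sensor noise, 16 sites per
#' patch and uncorrelated true indices; with `vignette_model = "gaussian"`
#' the default height 0.028 gives the almost-flat field that setup
#' measured (under `"flat"` the height is forced to 0).
#'
#' @param width,height patch size in pixels.
#' @param pixel_size micrometres per pixel; the default ROI edge is
#'   `round(150 / pixel_size)` pixels (a 150 um x 150 um site).
#' @param bit_depth 8 or 16.
#' @param vignette_model `"flat"`, `"gaussian"` or `"linear"`.
#' @param vignette_height vignette amplitude on normalized intensity, in
#'   `[0, 1)`: the centre-to-edge modulation of the separable profile
#'   `(1 - h) + h * g(t)` applied along both axes.
#' @param noise_sd additive Gaussian noise, gray levels.
#' @param n_sites number of site ROIs (may be 0 for a site-free field).
#' @param rho correlation of the Gaussian copula joining the true
#'   translucency and radiopacity of a site, in `[-1, 1]`.
#' @param index_range range the true optical indices are drawn over.
#' @param seed integer RNG seed.
#' @return object of class `"image_scenario"`.
#' @export
image_scenario <- function(width = 256, height = 256, pixel_size = 6.25,
                           bit_depth = 8, vignette_model = c("flat", "gaussian", "linear"),
                           vignette_height = 0.028, noise_sd = 2, n_sites = 16,
                           rho = 0, index_range = c(0.2, 0.9), seed = 1) {
  vignette_model <- match.arg(vignette_model)
  if (vignette_height < 0 || vignette_height >= 1) {
    stop("vignette_height must be in [0, 1)", call. = FALSE)
  }
  if (abs(rho) > 1) stop("rho must be in [-1, 1]", call. = FALSE)
  if (!bit_depth %in% c(8, 16)) stop("bit_depth must be 8 or 16", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  stopifnot(length(index_range) == 2, index_range[1] < index_range[2],
            index_range[1] >= 0, index_range[2] <= 1)
  if (vignette_model == "flat") vignette_height <- 0
  structure(list(width = as.integer(width), height = as.integer(height),
                 pixel_size = pixel_size, bit_depth = as.integer(bit_depth),
                 vignette_model = vignette_model, vignette_height = vignette_height,
                 noise_sd = noise_sd, n_sites = as.integer(n_sites), rho = rho,
                 index_range = index_range, seed = as.integer(seed)),
            class = "image_scenario")
}

## separable vignette surface: outer product of per-axis profiles
## (1 - h) + h * g(t); gaussian g peaks at the field centre with
## sigma = 0.45 x axis length (identifiable within the field),
## linear g ramps 0 -> 1
vignette_surface <- function(scenario) {
  prof <- function(n) {
    t <- seq_len(n) - 1
    h <- scenario$vignette_height
    g <- switch(scenario$vignette_model,
      flat = rep(1, n),
      gaussian = exp(-(t - (n - 1) / 2)^2 / (2 * (0.45 * n)^2)),
      linear = t / (n - 1))
    (1 - h) + h * g
  }
  outer(prof(scenario$height), prof(scenario$width))
}

## deterministic grid placement of square ROIs with a 4 px gap;
## error when the grid cannot hold n_sites
place_rois <- function(scenario, roi_px, margin) {
  step <- roi_px + 4L
  xs <- seq(margin, scenario$width - roi_px, by = step)
  ys <- seq(margin, scenario$height - roi_px, by = step)
  if (length(xs) < 1 || length(ys) < 1 || length(xs) * length(ys) < scenario$n_sites) {
    stop(sprintf("cannot place %d non-overlapping %dpx ROIs in a %dx%d patch",
                 scenario$n_sites, roi_px, scenario$width, scenario$height),
         call. = FALSE)
  }
  grid <- expand.grid(x = xs, y = ys)[seq_len(scenario$n_sites), , drop = FALSE]
  lapply(seq_len(nrow(grid)), function(i) {
    site_roi(grid$x[i], grid$y[i], roi_px, roi_px, site_id = sprintf("site%03d", i))
  })
}

#' Generate a synthetic SM/MR micrograph pair with ground truth
#'
#' Builds two patches from a shared scenario. Each image is a background
#' field (the SM-like patch a dark background at gray level `0.2 * maxval`,
#' its histogram minimum; the MR-like patch a bright field at
#' `0.75 * maxval`, its histogram maximum, below the 80% saturation gate)
#' multiplied by the vignette surface, with each site ROI painted at the
#' constant gray level for which the optical-index formula recovers the
#' site's assigned true index exactly in the noise-free flat-field limit
#' (`I_site = radiopacity * I_max` on MR; `I_site = (2 - translucency) *
#' I_min` on SM). Under a non-flat vignette the background extremes shift
#' with the field, so recovery acquires the same flat-field error a real
#' acquisition would have. Gaussian noise is added last and clamped to the
#' representable range.
#'
#' @param scenario an [image_scenario()].
#' @return list of class `"micrograph_bundle"`: `sm` and `mr`
#'   ([image_patch()]es), `rois` (list of [site_roi()]), `truth` (data
#'   frame `site_id`, `translucency_true`, `radiopacity_true`) and
#'   `scenario`.
#' @examples
#' b <- generate_micrograph(image_scenario(n_sites = 4, noise_sd = 0,
#'                                         vignette_model = "flat"))
#' measure_sites(b$mr, b$rois, "radiopacity")$value  # == b$truth$radiopacity_true
#' @export
generate_micrograph <- function(scenario) {
  stopifnot(inherits(scenario, "image_scenario"))
  with_local_seed(scenario$seed, {
    maxval <- 2^scenario$bit_depth - 1
    n <- scenario$n_sites
    lo <- scenario$index_range[1]; hi <- scenario$index_range[2]

    # bivariate-normal copula over the true site indices
    z1 <- stats::rnorm(n)
    z2 <- scenario$rho * z1 + sqrt(1 - scenario$rho^2) * stats::rnorm(n)
    truth <- data.frame(site_id = sprintf("site%03d", seq_len(n)),
                        translucency_true = lo + (hi - lo) * stats::pnorm(z1),
                        radiopacity_true = lo + (hi - lo) * stats::pnorm(z2),
                        stringsAsFactors = FALSE)
    if (n == 0L) truth <- truth[0, , drop = FALSE]

    # the background field itself carries the histogram extreme: the SM
    # patch has a dark background (its minimum) with brighter dentin sites,
    # the MR patch a bright field (its maximum) with radiolucent sites
    V <- vignette_surface(scenario)
    I_min_ref <- 0.20 * maxval   # SM dark-background level
    I_max_ref <- 0.75 * maxval   # MR field level (below the 80% saturation gate)
    sm <- I_min_ref * V
    mr <- I_max_ref * V

    roi_px <- max(1L, as.integer(round(150 / scenario$pixel_size)))
    rois <- if (n > 0L) place_rois(scenario, roi_px, margin = 8L) else list()
    for (i in seq_along(rois)) {
      r <- rois[[i]]
      rows <- (r$y + 1):(r$y + r$height); cols <- (r$x + 1):(r$x + r$width)
      sm[rows, cols] <- (2 - truth$translucency_true[i]) * I_min_ref
      mr[rows, cols] <- truth$radiopacity_true[i] * I_max_ref
    }
    if (scenario$noise_sd > 0) {
      sm <- sm + stats::rnorm(length(sm), sd = scenario$noise_sd)
      mr <- mr + stats::rnorm(length(mr), sd = scenario$noise_sd)
    }
    clamp <- function(x) pmin(pmax(x, 0), maxval)
    structure(list(sm = image_patch(clamp(sm), scenario$bit_depth, scenario$pixel_size),
                   mr = image_patch(clamp(mr), scenario$bit_depth, scenario$pixel_size),
                   rois = rois, truth = truth, scenario = scenario),
              class = "micrograph_bundle")
  })
}

#' @export
print.micrograph_bundle <- function(x, ...) {
  cat(sprintf("Micrograph bundle: %d site(s), %s vignette (height %.3g), noise sd %.3g\n",
              length(x$rois), x$scenario$vignette_model,
              x$scenario$vignette_height, x$scenario$noise_sd))
  invisible(x)
}

#' Write a reproducible desk-scale fixture bundle
#'
#' Emulates the deposited study materials at desk scale: one 168-site score
#' table (the study's sample size) and five SM/MR patch pairs with 16 sites
#' each (80 sites total, as in the translucency-vs-radiopacity
#' experiment), all derived deterministically from one seed.
#'
#' @param seed integer master seed.
#' @param dir output directory (created if needed).
#' @return invisibly, a list with the written `paths` and the in-memory
#'   `scores` and `bundles` objects.
#' @export
study_fixtures <- function(seed, dir = tempfile("fixtures")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(seed)
  scores <- generate_score_table(agreement_spec(seed = seed))
  score_path <- file.path(dir, "score_table.csv")
  write_score_table(scores$table, score_path)

  paths <- score_path
  bundles <- vector("list", 5)
  truth_all <- NULL
  for (i in 1:5) {
    b <- generate_micrograph(image_scenario(vignette_model = "gaussian",
                                            seed = seed + i))
    bundles[[i]] <- b
    sm_path <- file.path(dir, sprintf("sm_%02d.png", i))
    mr_path <- file.path(dir, sprintf("mr_%02d.png", i))
    roi_path <- file.path(dir, sprintf("rois_%02d.csv", i))
    write_image_patch(b$sm, sm_path)
    write_image_patch(b$mr, mr_path)
    write_roi_table(b$rois, roi_path)
    truth_all <- rbind(truth_all,
                       cbind(data.frame(patch = i), b$truth))
    paths <- c(paths, sm_path, mr_path, roi_path)
  }
  truth_path <- file.path(dir, "truth_synthetic.csv")
  utils::write.csv(truth_all, truth_path, row.names = FALSE, quote = FALSE)
  paths <- c(paths, truth_path)
  invisible(list(paths = paths, scores = scores, bundles = bundles, dir = dir))
}
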