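#' Configuration for the synthetic scene generator
#'
#' Describes a field of elliptical "nuclei" rendered into an instance mask
#' with known ground truth, emulating the statistical structure of
#' segmentation output from lymphoma tiles: 1024 x 1024 pixels at 0.25
#' micrometre per pixel, per-class equivalent-diameter bands equal to the
#' classification bands times the dog reference (4.14), mild ellipticity,
#' and an optional fraction of under-segmentation artifacts ("merged pairs":
#' two nuclei joined by a thin bridge, rendered as a single label).
#'
#' @param image_size_px `c(height, width)` in pixels.
#' @param um_per_pixel Pixel resolution (micrometre per pixel).
#' @param n_objects Number of labels to place.
#' @param class_mix Proportions over small/intermediate/large; must sum to 1.
#' @param diameter_bands_um Named list of `c(min, max)` equivalent-diameter
#'   ranges in micrometre for small, intermediate, large.
#' @param eccentricity_range Axis-ratio (major/minor) bounds.
#' @param merged_pair_fraction Fraction of labels rendered as merged pairs.
#' @param seed RNG seed making the scene fully reproducible.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(image_size_px = c(1024L, 1024L),
                             um_per_pixel = 0.25,
                             n_objects = 100L,
                             class_mix = c(small = 1/3, intermediate = 1/3,
                                           large = 1/3),
                             diameter_bands_um = default_diameter_bands(),
                             eccentricity_range = c(1, 1.6),
                             merged_pair_fraction = 0,
                             seed = 1L) {
  stopifnot(length(image_size_px) == 2L, all(image_size_px >= 1),
            um_per_pixel > 0, n_objects >= 1,
            abs(sum(class_mix) - 1) < 1e-8,
            merged_pair_fraction >= 0, merged_pair_fraction <= 1,
            eccentricity_range[1] >= 1,
            eccentricity_range[2] >= eccentricity_range[1])
  names(class_mix) <- size_class_levels
  structure(list(image_size_px = as.integer(image_size_px),
                 um_per_pixel = um_per_pixel,
                 n_objects = as.integer(n_objects),
                 class_mix = class_mix,
                 diameter_bands_um = diameter_bands_um,
                 eccentricity_range = eccentricity_range,
                 merged_pair_fraction = merged_pair_fraction,
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Default per-class equivalent-diameter bands in micrometre
#'
#' The classification bands (1-1.21, 1.21-1.5, 1.5-2.24 times the reference)
#' multiplied by the dog reference diameter of 4.14 micrometre.
#'
#' @param reference_um Reference diameter the multiplier bands are scaled by.
#' @return Named list of `c(min, max)` per class.
#' @export
default_diameter_bands <- function(reference_um = 4.14) {
  lapply(default_multiplier_bands(), function(b) b * reference_um)
}

default_multiplier_bands <- function() {
  list(small = c(1, 1.21), intermediate = c(1.21, 1.5),
       large = c(1.5, 2.24))
}

# Run code under a temporary RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  code
}

# Pixel-center rasterization of an ellipse: integer pixels whose centers
# satisfy the ellipse inequality. Returns a 2-column matrix (row, col),
# clipped to the image.
rasterize_ellipse <- function(cr, cc, a, b, theta, nr, nc) {
  r0 <- max(1L, floor(cr - a)); r1 <- min(nr, ceiling(cr + a))
  c0 <- max(1L, floor(cc - a)); c1 <- min(nc, ceiling(cc + a))
  if (r0 > r1 || c0 > c1) return(cbind(row = integer(0), col = integer(0)))
  rows <- r0:r1; cols <- c0:c1
  dy <- matrix(rows - cr, length(rows), length(cols))
  dx <- matrix(rep(cols - cc, each = length(rows)), length(rows))
  u <- (dx * cos(theta) + dy * sin(theta)) / a
  v <- (-dx * sin(theta) + dy * cos(theta)) / b
  inside <- u^2 + v^2 <= 1
  idx <- which(inside, arr.ind = TRUE)
  cbind(row = rows[idx[, 1]], col = cols[idx[, 2]])
}

# Pixels within `halfwidth` of the segment (r1,c1)-(r2,c2).
rasterize_bridge <- function(r1, c1, r2, c2, halfwidth, nr, nc) {
  rr0 <- max(1L, floor(min(r1, r2) - halfwidth))
  rr1 <- min(nr, ceiling(max(r1, r2) + halfwidth))
  cc0 <- max(1L, floor(min(c1, c2) - halfwidth))
  cc1 <- min(nc, ceiling(max(c1, c2) + halfwidth))
  rows <- rr0:rr1; cols <- cc0:cc1
  py <- matrix(rows, length(rows), length(cols))
  px <- matrix(rep(cols, each = length(rows)), length(rows))
  vx <- c2 - c1; vy <- r2 - r1
  len2 <- vx^2 + vy^2
  t <- pmin(1, pmax(0, ((px - c1) * vx + (py - r1) * vy) / len2))
  d2 <- (px - (c1 + t * vx))^2 + (py - (r1 + t * vy))^2
  idx <- which(d2 <= halfwidth^2, arr.ind = TRUE)
  cbind(row = rows[idx[, 1]], col = cols[idx[, 2]])
}

#' Generate a synthetic instance mask with known ground truth
#'
#' Places `n_objects` labels into the image: single elliptical nuclei with
#' equivalent diameters drawn uniformly within their class band, plus the
#' configured fraction of merged pairs (two nuclei of the same class joined
#' by a 2-pixel-wide bridge, the morphology of under-segmentation artifacts
#' that the circularity filter is designed to remove). Single objects are
#' kept at least 2 pixels away from everything else. The rasterized area of
#' each single object is required to be within 5% of the area implied by the
#' drawn diameter (placement is resampled otherwise), so generator truth and
#' morphometry agree closely.
#'
#' @param config A [generator_config()].
#' @return A list of class `synthetic_scene` with `mask` (integer instance
#'   mask), `truth` (data frame: label, intended_class,
#'   true_equivalent_diameter_um, is_merged_pair, n_pixels, centroid_row,
#'   centroid_col — centroids 0-based), and `intended_image_class`.
#' @export
generate_scene <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  with_seed(config$seed, generate_scene_impl(config))
}

generate_scene_impl <- function(config) {
  nr <- config$image_size_px[1]; nc <- config$image_size_px[2]
  s <- config$um_per_pixel
  n <- config$n_objects
  n_merged <- round(config$merged_pair_fraction * n)
  classes <- sample(size_class_levels, n, replace = TRUE,
                    prob = config$class_mix)
  diam <- vapply(classes, function(cl) {
    b <- config$diameter_bands_um[[cl]]
    stats::runif(1, b[1], b[2])
  }, numeric(1))
  is_merged <- c(rep(TRUE, n_merged), rep(FALSE, n - n_merged))
  # feasibility: implied foreground below 40% of the image
  implied_px <- pi * (diam / (2 * s))^2 * ifelse(is_merged, 2, 1)
  if (sum(implied_px) >= 0.4 * nr * nc) {
    stop("infeasible packing: requested objects would cover >= 40% of the image")
  }
  mask <- matrix(0L, nr, nc)
  blocked <- matrix(FALSE, nr, nc)
  truth <- vector("list", n)
  for (k in seq_len(n)) {
    placed <- FALSE
    d_px <- diam[k] / s                 # equivalent diameter in pixels
    for (try in seq_len(300L)) {
      q <- stats::runif(1, config$eccentricity_range[1],
                        config$eccentricity_range[2])
      b_ax <- d_px / (2 * sqrt(q)); a_ax <- q * b_ax
      theta <- stats::runif(1, 0, pi)
      if (is_merged[k]) {
        d2_um <- stats::runif(1, config$diameter_bands_um[[classes[k]]][1],
                              config$diameter_bands_um[[classes[k]]][2])
        d2_px <- d2_um / s
        sep <- 1.9 * (d_px / 2 + d2_px / 2)
        margin <- a_ax + d2_px + sep
        if (margin * 2 > min(nr, nc)) next
        cr <- stats::runif(1, margin, nr - margin)
        cc <- stats::runif(1, margin, nc - margin)
        phi <- stats::runif(1, 0, 2 * pi)
        cr2 <- cr + sep * sin(phi); cc2 <- cc + sep * cos(phi)
        q2 <- stats::runif(1, config$eccentricity_range[1],
                           config$eccentricity_range[2])
        b2 <- d2_px / (2 * sqrt(q2)); a2 <- q2 * b2
        th2 <- stats::runif(1, 0, pi)
        px <- rbind(rasterize_ellipse(cr, cc, a_ax, b_ax, theta, nr, nc),
                    rasterize_ellipse(cr2, cc2, a2, b2, th2, nr, nc),
                    rasterize_bridge(cr, cc, cr2, cc2, 1.2, nr, nc))
        px <- unique(px)
      } else {
        margin <- a_ax + 1
        if (margin * 2 > min(nr, nc)) next
        cr <- stats::runif(1, margin, nr - margin)
        cc <- stats::runif(1, margin, nc - margin)
        px <- rasterize_ellipse(cr, cc, a_ax, b_ax, theta, nr, nc)
        implied <- pi * (d_px / 2)^2
        if (abs(nrow(px) - implied) > 0.05 * implied) next
      }
      lin <- (px[, "col"] - 1L) * nr + px[, "row"]
      if (any(blocked[lin])) next
      mask[lin] <- k
      # block the object plus a 2-pixel separation margin (Chebyshev)
      for (dr in -2:2) for (dc in -2:2) {
        rr <- px[, "row"] + dr; cc2b <- px[, "col"] + dc
        ok <- rr >= 1L & rr <= nr & cc2b >= 1L & cc2b <= nc
        blocked[(cc2b[ok] - 1L) * nr + rr[ok]] <- TRUE
      }
      truth[[k]] <- data.frame(
        label = k,
        intended_class = classes[k],
        true_equivalent_diameter_um = if (is_merged[k]) {
          2 * sqrt(nrow(px) / pi) * s
        } else diam[k],
        is_merged_pair = is_merged[k],
        n_pixels = nrow(px),
        centroid_row = if (is_merged[k]) mean(px[, "row"]) - 1 else cr - 1,
        centroid_col = if (is_merged[k]) mean(px[, "col"]) - 1 else cc - 1)
      placed <- TRUE
      break
    }
    if (!placed) {
      stop("packing failure: could not place object ", k,
           " after bounded retries")
    }
  }
  truth <- do.call(rbind, truth)
  # image class intended by the generator: majority of intended classes,
  # ties toward the larger class (same rule as the classifier)
  counts <- vapply(size_class_levels,
                   function(cl) sum(truth$intended_class == cl), integer(1))
  intended <- size_class_levels[max(which(counts == max(counts)))]
  structure(list(mask = mask, truth = truth, intended_image_class = intended,
                 config = config),
            class = "synthetic_scene")
}

#' Generate a labeled measurement set for threshold optimization
#'
#' Emulates the optimization dataset: each image carries one consensus size
#' label and 20-60 per-nucleus diameter measurements. Two kinds of images are
#' produced. *Generic* images draw all diameters uniformly from the interior
#' of their class band. *Boundary-informative* images (seven types, cycled
#' first) concentrate a strict majority of their measurements just inside one
#' band edge, with the minority mass placed so that shifting that edge by one
#' grid step flips the image's majority class. Real optimization sets contain
#' such near-boundary cases; without them the image-level majority vote
#' cannot identify the thresholds to grid precision (the F1 landscape is
#' flat around the truth). With `noise_sd_um = 0` the band edges are then
#' exactly recoverable.
#'
#' Gaussian noise of standard deviation `noise_sd_um` (micrometre) is added
#' to every diameter.
#'
#' @param n_images Number of images (at least 1).
#' @param bands Named list of per-class `c(min, max)` bands as multipliers of
#'   the reference diameter.
#' @param noise_sd_um Gaussian measurement noise in micrometre.
#' @param seed RNG seed.
#' @param reference A [reference_size()].
#' @param n_per_image Range `c(min, max)` of measurements per image.
#' @param pin_halfwidth Width (in multiplier units) of the edge-hugging
#'   component of boundary-informative images; must stay below half the
#'   optimization grid step.
#' @return A [measurement_set()].
#' @export
generate_measurement_set <- function(n_images = 30L,
                                     bands = default_multiplier_bands(),
                                     noise_sd_um = 0,
                                     seed = 1L,
                                     reference = reference_size("dog"),
                                     n_per_image = c(20L, 60L),
                                     pin_halfwidth = 0.004) {
  stopifnot(n_images >= 1, noise_sd_um >= 0, pin_halfwidth > 0)
  with_seed(seed, generate_measurement_set_impl(
    n_images, bands, noise_sd_um, reference, n_per_image, pin_halfwidth))
}

generate_measurement_set_impl <- function(n_images, bands, noise_sd_um,
                                          reference, n_per_image, pw) {
  a <- bands$small[1]; b <- bands$small[2]
  cc <- bands$intermediate[2]; d <- bands$large[2]
  stopifnot(abs(bands$intermediate[1] - b) < 1e-9,
            abs(bands$large[1] - cc) < 1e-9)
  mid <- function(lo, hi) c(lo + 0.25 * (hi - lo), hi - 0.25 * (hi - lo))
  mid_small <- mid(a, b); mid_inter <- mid(b, cc); mid_large <- mid(cc, d)
  eps <- pw / 8
  roles <- c("a_low", "a_pin", "b_low", "b_high", "c_low", "c_high",
             "d_low", "d_high")
  rows <- vector("list", n_images)
  labels <- character(n_images)
  generic_cycle <- size_class_levels
  for (i in seq_len(n_images)) {
    n <- sample(seq(n_per_image[1], n_per_image[2]), 1L)
    if (i <= 2L * length(roles) && i <= floor(n_images / 2) * 2) {
      role <- roles[((i - 1L) %% length(roles)) + 1L]
    } else {
      role <- "generic"
    }
    draw <- function(k, lo, hi) stats::runif(k, lo, hi)
    maj <- max(round(0.6 * n), floor(n / 2) + 1L)
    if (role == "a_low") {
      # sub-reference debris just below the small limit: lowering the limit
      # lets it vote and flips the image to small
      u <- c(draw(maj, a - pw, a - eps), draw(n - maj, mid_inter[1], mid_inter[2]))
      lab <- "intermediate"
    } else if (role == "a_pin") {
      # pins small_lower from above: raising it excludes the majority mass
      k2 <- n - maj
      u <- c(draw(maj, a + eps, a + pw), draw(k2, mid_inter[1], mid_inter[2]))
      lab <- "small"
    } else if (role == "b_low") {
      u <- c(draw(maj, b - pw, b - eps), draw(n - maj, mid_small[1], mid_small[2]))
      lab <- "small"
    } else if (role == "b_high") {
      u <- c(draw(maj, b + eps, b + pw), draw(n - maj, mid_inter[1], mid_inter[2]))
      lab <- "intermediate"
    } else if (role == "c_low") {
      u <- c(draw(maj, cc - pw, cc - eps), draw(n - maj, mid_inter[1], mid_inter[2]))
      lab <- "intermediate"
    } else if (role == "c_high") {
      u <- c(draw(maj, cc + eps, cc + pw), draw(n - maj, mid_large[1], mid_large[2]))
      lab <- "large"
    } else if (role == "d_low") {
      # lowering large_upper excludes the edge mass; the intermediate
      # contamination then outvotes the remaining large nuclei
      k1 <- max(round(0.5 * n), floor(n / 2) + 1L)
      k2 <- round(0.2 * n); k3 <- n - k1 - k2
      u <- c(draw(k1, d - pw, d - eps), draw(k2, mid_large[1], mid_large[2]),
             draw(k3, mid_inter[1], mid_inter[2]))
      lab <- "large"
    } else if (role == "d_high") {
      # oversized artifacts just above the large limit: raising the limit
      # lets them vote and flips the image to large
      u <- c(draw(maj, d + eps, d + pw), draw(n - maj, mid_inter[1], mid_inter[2]))
      lab <- "intermediate"
    } else {
      lab <- generic_cycle[((i - 1L) %% 3L) + 1L]
      bb <- bands[[lab]]
      w <- 0.02 * (bb[2] - bb[1]) + 0.01
      u <- draw(n, bb[1] + w, bb[2] - w)
    }
    diam <- u * reference$reference_diameter_um
    if (noise_sd_um > 0) diam <- diam + stats::rnorm(n, 0, noise_sd_um)
    diam <- pmax(diam, 1e-6)
    rows[[i]] <- data.frame(image_id = sprintf("img%03d", i),
                            diameter_um = diam)
    labels[i] <- lab
  }
  measurement_set(do.call(rbind, rows),
                  data.frame(image_id = sprintf("img%03d", seq_len(n_images)),
                             consensus_label = labels),
                  reference)
}
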