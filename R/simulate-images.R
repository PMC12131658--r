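## synthetic_data: image generators with serialized ground truth.

## separable Gaussian blur (zero-padded borders)
.gauss_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  conv1 <- function(x) {
    out <- matrix(0, nrow(x), ncol(x))
    for (i in -r:r) out <- out + k[i + r + 1L] * .shift_mat(x, i, 0)
    out
  }
  t(conv1(t(conv1(m))))
}

.disk_mask <- function(size, cx, cy, radius) {
  x <- matrix(rep(seq_len(size), each = size), size, size)
  y <- matrix(rep(seq_len(size), times = size), size, size)
  (x - cx)^2 + (y - cy)^2 <= radius^2
}

#' Generate a synthetic TGN image of a given morphology archetype
#'
#' Renders an intact annulus (`normal`), a dimmer annulus plus detached
#' satellite blobs (`scattered`), or blobs only (`fragmented`), then
#' applies Gaussian blur and Poisson photon noise.
#'
#' @param state `"normal"`, `"scattered"` or `"fragmented"`.
#' @param size Image side length in pixels (default 128).
#' @param pixel_size_um Pixel size (default 0.1 um, a typical 63x
#'   confocal sampling).
#' @param diameter_um Outer ring diameter (default 3.4 um, the scale of
#'   a healthy perinuclear TGN; enlarged TGNs run to ~6-7 um).
#' @param ring_width_um Radial ring thickness (default 0.5 um).
#' @param satellite_frac Fraction of foreground area carried by
#'   satellites in the scattered state (default 0.2).
#' @param n_satellites Number of satellite/fragment blobs.
#' @param intensity Expected foreground photon count per pixel.
#' @param blur_sigma_px Gaussian blur sigma (default 1 px).
#' @param noise Apply Poisson noise (default TRUE).
#' @param seed Integer seed.
#' @return List with `image` ([image2d()]) and `truth` (state, planted
#'   diameter, satellite fraction, seed).
#' @export
generate_tgn_image <- function(state = c("normal", "scattered", "fragmented"),
                               size = 128L, pixel_size_um = 0.1,
                               diameter_um = 3.4, ring_width_um = 0.5,
                               satellite_frac = 0.2, n_satellites = 4L,
                               intensity = 100, blur_sigma_px = 1,
                               noise = TRUE, seed) {
  state <- match.arg(state)
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  set.seed(seed)
  c0 <- (size + 1) / 2
  r_out <- diameter_um / 2 / pixel_size_um
  r_in <- max(1, r_out - ring_width_um / pixel_size_um)
  stopifnot(r_out < size / 2 - 8)
  annulus <- .disk_mask(size, c0, c0, r_out) & !.disk_mask(size, c0, c0, r_in)
  img <- matrix(0, size, size)
  add_blobs <- function(img, n, total_area, r_lo, r_hi, level) {
    blob_r <- sqrt(total_area / n / pi)
    angles <- stats::runif(n, 0, 2 * pi)
    radii <- stats::runif(n, r_lo, r_hi)
    for (i in seq_len(n)) {
      img[.disk_mask(size, c0 + radii[i] * cos(angles[i]),
                     c0 + radii[i] * sin(angles[i]), blob_r)] <- level
    }
    img
  }
  if (state == "normal") {
    img[annulus] <- intensity
  } else if (state == "scattered") {
    img[annulus] <- 0.7 * intensity
    sat_area <- satellite_frac / (1 - satellite_frac) * sum(annulus)
    img <- add_blobs(img, n_satellites, sat_area,
                     r_out + 6, min(size / 2 - 4, r_out + 16), intensity)
  } else {
    frag_area <- sum(annulus)
    img <- add_blobs(img, max(4L, n_satellites), frag_area,
                     r_in * 0.5, r_out + 10, intensity)
  }
  img <- .gauss_blur(img, blur_sigma_px)
  if (noise) img <- matrix(stats::rpois(length(img), img), size, size)
  list(image = image2d(img, pixel_size_um),
       truth = list(state = state,
                    diameter_um = if (state == "fragmented") NA_real_
                                  else diameter_um,
                    satellite_frac = if (state == "scattered")
                      satellite_frac else 0,
                    seed = seed))
}

#' Generate a channel pair with a planted Manders M1t overlap
#'
#' Channel B is a compartment disk; channel A's intensity mass is split
#' between a disk inside B and a disjoint disk far outside it so that
#' the planted above-background mass fraction inside B equals
#' `target_m1` before blur and noise. The truth records the exact
#' rasterized pre-noise fraction (the nominal target is met within
#' discretization of the disk areas).
#'
#' @param target_m1 Planted M1t in `[0, 1]`.
#' @param size Image side (default 128 px).
#' @param pixel_size_um Pixel size (default 0.1 um).
#' @param a_area_px Total above-background area of channel A.
#' @param intensity Foreground level.
#' @param noise_sd Additive Gaussian noise SD (0 disables).
#' @param seed Integer seed.
#' @return List with `imgA`, `imgB` ([image2d()]s) and `truth`
#'   (`target_m1`, `planted_m1` = exact rasterized fraction).
#' @export
generate_coloc_pair <- function(target_m1, size = 128L, pixel_size_um = 0.1,
                                a_area_px = 600, intensity = 100,
                                noise_sd = 2, seed) {
  stopifnot(target_m1 >= 0, target_m1 <= 1)
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  set.seed(seed)
  bx <- size * 0.32; by <- size / 2
  ax_out <- size * 0.78
  b_mask <- .disk_mask(size, bx, by, size * 0.17)
  a_in <- if (target_m1 > 0) {
    .disk_mask(size, bx, by, sqrt(target_m1 * a_area_px / pi))
  } else matrix(FALSE, size, size)
  a_out <- if (target_m1 < 1) {
    .disk_mask(size, ax_out, by, sqrt((1 - target_m1) * a_area_px / pi))
  } else matrix(FALSE, size, size)
  imgA <- matrix(0, size, size)
  imgA[a_in | a_out] <- intensity
  imgB <- matrix(0, size, size)
  imgB[b_mask] <- intensity
  planted <- if (!any(a_in | a_out)) NA_real_ else
    sum(imgA[b_mask]) / sum(imgA)
  if (noise_sd > 0) {
    imgA <- pmax(imgA + matrix(stats::rnorm(size^2, 0, noise_sd), size, size), 0)
    imgB <- pmax(imgB + matrix(stats::rnorm(size^2, 0, noise_sd), size, size), 0)
  }
  list(imgA = image2d(imgA, pixel_size_um),
       imgB = image2d(imgB, pixel_size_um),
       truth = list(target_m1 = target_m1, planted_m1 = planted,
                    seed = seed))
}

## rasterize a polyline (n x 2 matrix of (x, y) pixel coords) onto a mask
.raster_polyline <- function(mask, pts, half_width) {
  for (i in seq_len(nrow(pts) - 1L)) {
    p0 <- pts[i, ]; p1 <- pts[i + 1L, ]
    len <- sqrt(sum((p1 - p0)^2))
    tt <- seq(0, 1, length.out = max(2L, ceiling(len * 4)))
    xs <- round(p0[1] + tt * (p1[1] - p0[1]))
    ys <- round(p0[2] + tt * (p1[2] - p0[2]))
    ok <- xs >= 1 & xs <= ncol(mask) & ys >= 1 & ys <= nrow(mask)
    mask[unique(cbind(ys[ok], xs[ok]))] <- TRUE
  }
  if (half_width > 0) {
    for (i in seq_len(half_width)) {
      mask <- mask | .shift_mat(mask, 1, 0) > 0 | .shift_mat(mask, -1, 0) > 0 |
        .shift_mat(mask, 0, 1) > 0 | .shift_mat(mask, 0, -1) > 0
    }
  }
  mask
}

.polyline_length <- function(pts) {
  sum(sqrt(rowSums((pts[-1L, , drop = FALSE] -
                      pts[-nrow(pts), , drop = FALSE])^2)))
}

## extend the free ends of a polyline outward, clamped to the canvas.
## Thinning erodes the flat end of an axis-aligned line by roughly the
## half-width plus two pixels but leaves a diagonal tip (already one
## pixel wide) intact; the cap interpolates between those extremes so
## the planted skeleton length stays equal to the geometric polyline
## length.
.cap_polyline <- function(pts, ext, size) {
  cap_one <- function(p, d) {
    d <- d / sqrt(sum(d^2))
    frac <- (sqrt(2) - (abs(d[1]) + abs(d[2]))) / (sqrt(2) - 1)
    pmin(pmax(p + ext * max(0, min(1, frac)) * d, 1), size)
  }
  pts[1L, ] <- cap_one(pts[1L, ], pts[1L, ] - pts[2L, ])
  n <- nrow(pts)
  pts[n, ] <- cap_one(pts[n, ], pts[n, ] - pts[n - 1L, ])
  pts
}

#' Generate a synthetic neurite-network image with known skeleton truth
#'
#' Rasterizes the supplied polylines (dilated to `width_px`) and
#' optionally plants `crossings` isolated X-shaped four-way crossings on
#' a reserved grid; supplied polylines should stay clear of that grid
#' when both are used. Truth records the summed polyline length and the
#' planted quadruple-point count.
#'
#' @param segments List of `n x 2` matrices of `(x, y)` pixel
#'   coordinates (may be empty).
#' @param crossings Number of planted X crossings.
#' @param size Image side (default 256 px).
#' @param pixel_size_um Pixel size (default 1 um, a 10x overview scale).
#' @param width_px Odd line width in pixels (default 3).
#' @param intensity Foreground level; Gaussian noise of SD
#'   `noise_sd` is added.
#' @param noise_sd Additive noise SD.
#' @param seed Integer seed.
#' @return List with `image` ([image2d()]) and `truth`
#'   (`total_length_um`, `n_quadruple_points`).
#' @export
generate_neurite_image <- function(segments = list(), crossings = 0L,
                                   size = 256L, pixel_size_um = 1,
                                   width_px = 3L, intensity = 100,
                                   noise_sd = 4, seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  set.seed(seed)
  stopifnot(width_px %% 2 == 1)
  mask <- matrix(FALSE, size, size)
  total_len <- 0
  cap <- (width_px - 1L) / 2 + 2
  for (pts in segments) {
    stopifnot(is.matrix(pts), ncol(pts) == 2,
              all(pts >= 1), all(pts <= size))
    mask <- .raster_polyline(mask, .cap_polyline(pts, cap, size),
                             (width_px - 1L) / 2)
    total_len <- total_len + .polyline_length(pts)
  }
  if (crossings > 0) {
    arm <- 14
    spacing <- 2 * arm + 22
    per_row <- floor((size - spacing) / spacing)
    stopifnot(crossings <= per_row^2)
    for (i in seq_len(crossings)) {
      cx <- spacing * (((i - 1) %% per_row) + 1)
      cy <- spacing * (((i - 1) %/% per_row) + 1)
      d1 <- rbind(c(cx - arm, cy - arm), c(cx + arm, cy + arm))
      d2 <- rbind(c(cx - arm, cy + arm), c(cx + arm, cy - arm))
      mask <- .raster_polyline(mask, .cap_polyline(d1, cap, size),
                               (width_px - 1L) / 2)
      mask <- .raster_polyline(mask, .cap_polyline(d2, cap, size),
                               (width_px - 1L) / 2)
      total_len <- total_len + .polyline_length(d1) + .polyline_length(d2)
    }
  }
  img <- matrix(0, size, size)
  img[mask] <- intensity
  ## noise models acquisition noise on a specimen; a blank canvas stays
  ## blank so the empty case is well defined for any auto-threshold
  if (noise_sd > 0 && any(mask)) {
    img <- pmax(img + matrix(stats::rnorm(size^2, 0, noise_sd), size, size), 0)
  }
  list(image = image2d(img, pixel_size_um),
       truth = list(total_length_um = total_len * pixel_size_um,
                    n_quadruple_points = as.integer(crossings),
                    seed = seed))
}

#' Generate labeled nuclei and a matching signal image
#'
#' Simple disk nuclei on a grid with a per-nucleus mean signal level —
#' enough structure to exercise nuclear-region intensity quantification.
#'
#' @param n_nuclei Number of nuclei.
#' @param mean_signal Expected signal level inside each nucleus (scalar
#'   or per-nucleus vector).
#' @param size Image side.
#' @param radius Nucleus radius in pixels.
#' @param noise_sd Additive Gaussian noise SD on the signal channel.
#' @param seed Integer seed.
#' @return List with `labels` (integer matrix), `signal` ([image2d()]),
#'   and `truth` (per-nucleus planted means).
#' @export
generate_nuclei_signal <- function(n_nuclei, mean_signal, size = 192L,
                                   radius = 9, noise_sd = 1, seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  set.seed(seed)
  mean_signal <- rep_len(mean_signal, n_nuclei)
  per_row <- floor(size / (3 * radius))
  stopifnot(n_nuclei <= per_row^2)
  labels <- matrix(0L, size, size)
  signal <- matrix(0, size, size)
  for (i in seq_len(n_nuclei)) {
    cx <- 3 * radius * (((i - 1) %% per_row) + 0.7)
    cy <- 3 * radius * (((i - 1) %/% per_row) + 0.7)
    d <- .disk_mask(size, cx, cy, radius)
    labels[d] <- i
    signal[d] <- mean_signal[i]
  }
  if (noise_sd > 0) {
    signal <- pmax(signal +
                     matrix(stats::rnorm(size^2, 0, noise_sd), size, size), 0)
  }
  list(labels = labels, signal = image2d(signal, 1),
       truth = list(mean_signal = mean_signal, seed = seed))
}
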