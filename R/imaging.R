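## imaging_metrics: colocalization, line profiles, AUC partitioning.
## Images are plain numeric matrices (row = y, column = x) carrying a
## physical pixel size; see image2d().

#' Single-channel 2-D image with physical pixel size
#'
#' @param pixels Numeric matrix of nonnegative, finite intensities.
#' @param pixel_size_um Physical edge length of one pixel in micrometers.
#' @return An `image2d`: the matrix with a `pixel_size_um` attribute.
#' @export
image2d <- function(pixels, pixel_size_um = 1) {
  stopifnot(is.matrix(pixels), all(is.finite(pixels)), all(pixels >= 0),
            is.numeric(pixel_size_um), pixel_size_um > 0)
  structure(pixels, pixel_size_um = pixel_size_um, class = c("image2d", "matrix"))
}

#' @export
print.image2d <- function(x, ...) {
  cat(sprintf("<image2d> %d x %d px, %.4g um/px, range [%.4g, %.4g]\n",
              nrow(x), ncol(x), attr(x, "pixel_size_um"),
              min(x), max(x)))
  invisible(x)
}

pixel_size <- function(img) {
  ps <- attr(img, "pixel_size_um")
  if (is.null(ps)) 1 else ps
}

.px <- function(img) {
  m <- unclass(img)
  attr(m, "pixel_size_um") <- NULL
  m
}

#' Read / write a single-channel TIFF as an `image2d`
#'
#' @param path TIFF path.
#' @param pixel_size_um Pixel size to attach on read (TIFF resolution
#'   tags are not relied upon).
#' @param img An [image2d()] (written as 16-bit grayscale after scaling
#'   to the image maximum, or as 32-bit float when `float = TRUE`).
#' @param float Write float samples without rescaling.
#' @return `read_image_tiff()` an `image2d`; `write_image_tiff()` the
#'   path, invisibly.
#' @export
read_image_tiff <- function(path, pixel_size_um = 1) {
  px <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(px)) == 3L) px <- px[, , 1L]
  image2d(px, pixel_size_um)
}

#' @rdname read_image_tiff
#' @export
write_image_tiff <- function(img, path, float = FALSE) {
  px <- .px(img)
  if (float) {
    tiff::writeTIFF(px, path, bits.per.sample = 32L, reduce = FALSE)
  } else {
    mx <- max(px)
    scaled <- if (mx > 0) px / mx else px
    tiff::writeTIFF(scaled, path, bits.per.sample = 16L)
  }
  invisible(path)
}

#' Otsu threshold of an image histogram
#'
#' Maximizes the between-class variance over a 256-bin histogram
#' spanning the image's value range. The returned threshold is the upper
#' edge of the chosen bin, so that foreground is `pixels > threshold`.
#'
#' @param img An [image2d()] or numeric matrix with >= 2 distinct values.
#' @param n_bins Number of histogram bins (default 256).
#' @return Threshold on the image's intensity scale.
#' @export
otsu_threshold <- function(img, n_bins = 256L) {
  v <- as.vector(.px(img))
  lo <- min(v); hi <- max(v)
  if (lo == hi) stop("degenerate image: all pixels equal", call. = FALSE)
  breaks <- seq(lo, hi, length.out = n_bins + 1L)
  counts <- tabulate(pmin(findInterval(v, breaks, rightmost.closed = TRUE),
                          n_bins), nbins = n_bins)
  mids <- (breaks[-1L] + breaks[-(n_bins + 1L)]) / 2
  w <- cumsum(counts)
  m <- cumsum(counts * mids)
  total_w <- w[n_bins]
  total_m <- m[n_bins]
  ## between-class variance for split after bin i
  valid <- w > 0 & w < total_w
  between <- rep(-Inf, n_bins)
  between[valid] <- (total_m * w[valid] - m[valid] * total_w)^2 /
    (w[valid] * (total_w - w[valid]))
  breaks[which.max(between) + 1L]
}

#' Thresholded Manders overlap coefficients
#'
#' With Otsu thresholds `tA`, `tB` set independently per channel,
#' `M1t` is the fraction of channel-A intensity above `tA` that lies in
#' pixels where channel B is above `tB`; `M2t` is the symmetric
#' fraction for channel B. Channel A is the tracked species (e.g. the
#' alpha-synuclein channel), channel B the compartment marker.
#'
#' @param imgA,imgB [image2d()]s of identical dimensions.
#' @return List with `M1t`, `M2t` (fractions, `NA` with an `undefined`
#'   flag when a channel has no above-threshold signal), `tA`, `tB`.
#' @export
manders_m1t <- function(imgA, imgB) {
  a <- .px(imgA); b <- .px(imgB)
  stopifnot(all(dim(a) == dim(b)))
  tA <- otsu_threshold(a)
  tB <- otsu_threshold(b)
  maskA <- a > tA
  maskB <- b > tB
  m1 <- if (!any(maskA)) NA_real_ else sum(a[maskA & maskB]) / sum(a[maskA])
  m2 <- if (!any(maskB)) NA_real_ else sum(b[maskA & maskB]) / sum(b[maskB])
  list(M1t = m1, M2t = m2, tA = tA, tB = tB,
       undefined = !any(maskA) || !any(maskB))
}

.bilinear <- function(px, x, y) {
  ## x = column coordinate, y = row coordinate, both 1-based continuous
  x0 <- pmin(pmax(floor(x), 1L), ncol(px) - 1L)
  y0 <- pmin(pmax(floor(y), 1L), nrow(px) - 1L)
  fx <- x - x0
  fy <- y - y0
  idx <- function(r, c) px[cbind(r, c)]
  idx(y0, x0) * (1 - fx) * (1 - fy) + idx(y0, x0 + 1L) * fx * (1 - fy) +
    idx(y0 + 1L, x0) * (1 - fx) * fy + idx(y0 + 1L, x0 + 1L) * fx * fy
}

#' Intensity profile along a line ROI
#'
#' Samples the image by bilinear interpolation at unit-pixel steps along
#' the segment from `p0` to `p1`, averaging over `width_px` parallel
#' lines perpendicular to it.
#'
#' @param img An [image2d()].
#' @param p0,p1 Endpoints as `(x, y)` pixel coordinates (1-based).
#' @param width_px Odd integer ROI width in pixels (default 1).
#' @return data.frame `distance_um`, `intensity`.
#' @export
line_profile <- function(img, p0, p1, width_px = 1L) {
  px <- .px(img)
  stopifnot(length(p0) == 2, length(p1) == 2, width_px >= 1,
            width_px %% 2 == 1)
  for (p in list(p0, p1)) {
    if (p[1] < 1 || p[1] > ncol(px) || p[2] < 1 || p[2] > nrow(px)) {
      stop("ROI endpoint outside image bounds", call. = FALSE)
    }
  }
  d <- sqrt(sum((p1 - p0)^2))
  if (d == 0) stop("ROI endpoints coincide", call. = FALSE)
  n <- floor(d) + 1L
  tt <- seq(0, d, length.out = n)
  ux <- (p1[1] - p0[1]) / d
  uy <- (p1[2] - p0[2]) / d
  offs <- seq_len(width_px) - (width_px + 1L) / 2
  intensity <- rowMeans(vapply(offs, function(o) {
    .bilinear(px, p0[1] + tt * ux - o * uy, p0[2] + tt * uy + o * ux)
  }, numeric(n)))
  data.frame(distance_um = tt * pixel_size(img), intensity = intensity)
}

#' Fraction of profile signal inside an interval (AUC in / AUC total)
#'
#' The profile minimum is subtracted as background (disable with
#' `subtract_background = FALSE`), then trapezoidal areas under the
#' curve are computed inside `[d_lo, d_hi]` and over the remainder; the
#' returned value is `AUC_in / (AUC_in + AUC_out)`. Per-cell analyses
#' conventionally average four such ROI lines per cell, and condition
#' summaries should pool at least 50 cells.
#'
#' @param profile data.frame from [line_profile()].
#' @param inside Length-2 numeric, the `[d_lo, d_hi]` interval in um.
#' @param subtract_background Subtract the profile minimum first.
#' @return Fraction in `[0, 1]`, or `NA` when the background-subtracted
#'   profile carries no mass (degenerate, flagged by attribute
#'   `"undefined"`).
#' @export
inside_fraction <- function(profile, inside, subtract_background = TRUE) {
  stopifnot(is.data.frame(profile), length(inside) == 2, inside[1] < inside[2])
  d <- profile$distance_um
  y <- profile$intensity
  if (inside[1] < min(d) || inside[2] > max(d)) {
    stop("inside interval exceeds profile extent", call. = FALSE)
  }
  if (subtract_background) y <- y - min(y)
  if (any(y < 0)) stop("profile must be nonnegative after background subtraction",
                       call. = FALSE)
  ## integrate on a grid refined with the interval endpoints so the
  ## in/out split is exact
  dd <- sort(unique(c(d, inside)))
  yy <- stats::approx(d, y, xout = dd)$y
  seg <- diff(dd) * (head(yy, -1) + yy[-1]) / 2
  mid <- (head(dd, -1) + dd[-1]) / 2
  auc_in <- sum(seg[mid >= inside[1] & mid <= inside[2]])
  auc_total <- sum(seg)
  if (auc_total == 0) {
    return(structure(NA_real_, undefined = TRUE))
  }
  auc_in / auc_total
}
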