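## Trans-Golgi network (TGN) morphology. The TGN of a healthy cell
## stains as an intact perinuclear ring; under alpha-synuclein stress it
## scatters (ring plus detached fragments) or fragments entirely (no
## ring). The classifier formalizes that reading: a ring is a connected
## component enclosing a topological hole of sufficient area, and the
## satellite fraction separates normal from scattered.

#' Classify TGN morphology from a single-cell crop
#'
#' The image is segmented with [otsu_threshold()] and labeled with
#' 8-connectivity. The principal component (nearest `nucleus_center`
#' when given, else the largest) passes the ring test when it encloses a
#' background hole of at least `min_hole_px` pixels. With a ring,
#' morphology is `normal` when all remaining (satellite) components
#' carry less than `sat_frac` of the total foreground area, `scattered`
#' otherwise; with no ring it is `fragmented`. The diameter (maximum
#' Feret diameter of the union of foreground components, in um) is
#' reported for normal and scattered states only.
#'
#' `min_hole_px` and `sat_frac` are free tuning constants of this
#' package (the published description of the three states is visual).
#'
#' @param img An [image2d()] single-cell crop of the TGN channel.
#' @param nucleus_center Optional `(x, y)` pixel coordinates used to
#'   pick the perinuclear principal component.
#' @param min_hole_px Minimum enclosed-hole area in pixels (default 20).
#' @param sat_frac Satellite area fraction separating normal from
#'   scattered (default 0.10).
#' @return List with `state` (`"normal"`, `"scattered"`, `"fragmented"`
#'   or `"unclassifiable"`), `diameter_um` (`NA` for fragmented or
#'   unclassifiable), `hole_px`, `satellite_frac`, `n_components`.
#' @export
classify_tgn <- function(img, nucleus_center = NULL, min_hole_px = 20,
                         sat_frac = 0.10) {
  px <- .px(img)
  ps <- pixel_size(img)
  if (min(px) == max(px)) {
    return(list(state = "unclassifiable", diameter_um = NA_real_,
                hole_px = 0L, satellite_frac = NA_real_, n_components = 0L))
  }
  mask <- px > otsu_threshold(px)
  if (!any(mask)) {
    return(list(state = "unclassifiable", diameter_um = NA_real_,
                hole_px = 0L, satellite_frac = NA_real_, n_components = 0L))
  }
  lab <- label_components(mask, connectivity = 8)
  n_comp <- max(lab)
  principal <- if (!is.null(nucleus_center)) {
    ## component whose centroid is nearest the nucleus center
    cent <- vapply(seq_len(n_comp), function(i) {
      w <- which(lab == i, arr.ind = TRUE)
      c(mean(w[, 2]), mean(w[, 1]))            # (x, y)
    }, numeric(2))
    which.min((cent[1, ] - nucleus_center[1])^2 +
                (cent[2, ] - nucleus_center[2])^2)
  } else 1L                                    # labels sorted by size
  ## hole test: background components (4-connectivity) that touch the
  ## principal component but not the image border
  comp <- lab == principal
  bg <- label_components(!mask, connectivity = 4)
  border_ids <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  touching <- unique(bg[.neighbor_count(comp) > 0L & bg > 0L])
  hole_ids <- setdiff(touching, border_ids)
  hole_px <- sum(bg %in% hole_ids)
  ring <- hole_px >= min_hole_px
  satellite_frac <- 1 - sum(comp) / sum(mask)
  state <- if (!ring) "fragmented"
           else if (satellite_frac >= sat_frac) "scattered"
           else "normal"
  diameter <- NA_real_
  if (ring) {
    diameter <- feret_diameter(mask) * ps
  }
  list(state = state, diameter_um = diameter, hole_px = hole_px,
       satellite_frac = satellite_frac, n_components = n_comp)
}

#' Maximum Feret diameter of a pixel mask (in pixels)
#'
#' Largest pairwise distance between foreground pixel centers, computed
#' on the convex hull.
#'
#' @param mask Logical matrix.
#' @return Diameter in pixel units (0 for empty or single-pixel masks).
#' @export
feret_diameter <- function(mask) {
  pts <- which(mask != 0, arr.ind = TRUE)
  if (nrow(pts) < 2L) return(0)
  hull <- pts[grDevices::chull(pts[, 2], pts[, 1]), , drop = FALSE]
  max(stats::dist(hull))
}
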