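## Neurite network metrics: total branch length (network density) and
## quadruple points (network complexity) from the tubulin channel.

#' Neurite skeleton metrics: total branch length and quadruple points
#'
#' Binarizes the image (Otsu), thins the mask to a 1-pixel skeleton
#' ([skeletonize()]) and measures (i) total branch length as the sum
#' over adjacent skeleton-pixel pairs — `pixel_size` for orthogonal,
#' `sqrt(2) * pixel_size` for diagonal steps, reported in mm — and (ii)
#' the number of quadruple points: clusters of junction pixels (skeleton
#' pixels with >= 3 skeleton neighbors) from which exactly four distinct
#' branches emanate. Junction clusters with five or more branches are
#' counted separately, not as quadruple points.
#'
#' Binarized masks are despeckled first: foreground components smaller
#' than `min_object_px` are noise at any realistic neurite scale and
#' are dropped, so a signal-free image yields `(0, 0)`.
#'
#' @param img An [image2d()] of the neurite (tubulin) channel, or a
#'   logical matrix already binarized.
#' @param min_object_px Minimum component area kept after
#'   binarization (default 16).
#' @return List with `total_branch_length_mm`, `n_quadruple_points`,
#'   `n_junctions`, `skeleton_px`, and `branch_counts` (table of
#'   branches per junction cluster).
#' @export
neurite_metrics <- function(img, min_object_px = 16L) {
  ps <- pixel_size(img)
  px <- .px(img)
  mask <- if (is.logical(px)) px else {
    if (min(px) == max(px)) matrix(FALSE, nrow(px), ncol(px))
    else px > otsu_threshold(px)
  }
  if (any(mask) && min_object_px > 1) {
    lab <- label_components(mask, connectivity = 8)
    sizes <- tabulate(lab[lab > 0L])
    keep <- lab > 0L
    keep[keep] <- sizes[lab[keep]] >= min_object_px
    mask <- keep
  }
  if (!any(mask)) {
    return(list(total_branch_length_mm = 0, n_quadruple_points = 0L,
                n_junctions = 0L, skeleton_px = 0L,
                branch_counts = integer()))
  }
  sk <- skeletonize(mask)
  if (!any(sk)) {
    return(list(total_branch_length_mm = 0, n_quadruple_points = 0L,
                n_junctions = 0L, skeleton_px = sum(sk),
                branch_counts = integer()))
  }
  s <- sk * 1L
  n_orth <- sum(s[, -1L] & s[, -ncol(s)]) + sum(s[-1L, ] & s[-nrow(s), ])
  ## diagonal steps; a diagonal pair bridged by an orthogonal skeleton
  ## pixel is not counted (the path runs through the bridge — counting
  ## both would double the triangle)
  se <- .shift_mat(s, -1L, -1L); e <- .shift_mat(s, 0L, -1L)
  so <- .shift_mat(s, -1L, 0L)
  n_diag <- sum(s & se & !(e | so))
  sw <- .shift_mat(s, -1L, 1L); w <- .shift_mat(s, 0L, 1L)
  n_diag <- n_diag + sum(s & sw & !(w | so))
  length_um <- (n_orth + sqrt(2) * n_diag) * ps
  ## junction pixels and their clusters
  nb <- .neighbor_count(sk)
  junction <- sk & nb >= 3L
  branch_counts <- integer()
  if (any(junction)) {
    jlab <- label_components(junction, connectivity = 8)
    branch_counts <- vapply(seq_len(max(jlab)), function(i) {
      cl <- jlab == i
      ## skeleton pixels adjacent to (but outside) the cluster
      touch <- sk & !cl & .neighbor_count(cl) > 0L
      if (!any(touch)) return(0L)
      max(label_components(touch, connectivity = 8))
    }, 1L)
  }
  list(total_branch_length_mm = length_um / 1000,
       n_quadruple_points = sum(branch_counts == 4L),
       n_junctions = length(branch_counts),
       skeleton_px = sum(sk),
       branch_counts = branch_counts)
}
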