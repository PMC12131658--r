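## Morphological primitives shared by the TGN classifier and the
## neurite metrics: connected-component labeling by iterative label
## propagation, and Zhang-Suen thinning. Both operate on logical
## matrices and are fully vectorized over matrix shifts.

.shift_mat <- function(m, dr, dc, fill = 0) {
  out <- matrix(fill, nrow(m), ncol(m))
  rs <- seq_len(nrow(m)) - dr
  cs <- seq_len(ncol(m)) - dc
  ok_r <- rs >= 1 & rs <= nrow(m)
  ok_c <- cs >= 1 & cs <= ncol(m)
  out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
  out
}

.neigh_offsets <- function(connectivity) {
  if (connectivity == 4) {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  } else {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
         c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  }
}

#' Label connected components of a binary mask
#'
#' Iterative minimum-label propagation; deterministic labels, renumbered
#' 1..n by decreasing component size.
#'
#' @param mask Logical matrix.
#' @param connectivity 8 (default) or 4.
#' @return Integer matrix; 0 is background.
#' @export
label_components <- function(mask, connectivity = 8) {
  stopifnot(is.matrix(mask), connectivity %in% c(4, 8))
  mask <- mask != 0
  lab <- matrix(0L, nrow(mask), ncol(mask))
  lab[mask] <- seq_len(sum(mask))
  lab_full <- matrix(0L, nrow(mask), ncol(mask))
  lab_full[mask] <- lab[mask]
  offs <- .neigh_offsets(connectivity)
  inf <- sum(mask) + 1L
  cur <- ifelse(mask, lab_full, inf)
  repeat {
    nxt <- cur
    for (o in offs) {
      nxt <- pmin(nxt, .shift_mat(cur, o[1], o[2], fill = inf))
    }
    nxt[!mask] <- inf
    if (all(nxt == cur)) break
    cur <- nxt
  }
  cur[cur == inf] <- 0L
  ids <- sort(unique(cur[cur > 0L]))
  sizes <- tabulate(match(cur[cur > 0L], ids))
  remap <- integer(max(ids))
  remap[ids[order(-sizes)]] <- seq_along(ids)
  out <- matrix(0L, nrow(mask), ncol(mask))
  out[cur > 0L] <- remap[cur[cur > 0L]]
  out
}

## counts of 8-neighbors that are TRUE
.neighbor_count <- function(mask) {
  b <- mask * 1L
  Reduce(`+`, lapply(.neigh_offsets(8), function(o)
    .shift_mat(b, o[1], o[2])))
}

#' Skeletonize a binary mask to 1-pixel width (Zhang-Suen thinning)
#'
#' @param mask Logical matrix (foreground = TRUE).
#' @return Logical matrix of the same size.
#' @export
skeletonize <- function(mask) {
  stopifnot(is.matrix(mask))
  b <- (mask != 0) * 1L
  ## neighbors in the circular order p2..p9: N, NE, E, SE, S, SW, W, NW
  ord <- list(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
              c(1, 0), c(1, -1), c(0, -1), c(-1, -1))
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      p <- lapply(ord, function(o) .shift_mat(b, o[1], o[2]))
      bsum <- Reduce(`+`, p)
      ## A(p): number of 0->1 transitions around the circle
      a <- Reduce(`+`, lapply(1:8, function(i) {
        (p[[i]] == 0L) & (p[[if (i == 8) 1 else i + 1]] == 1L)
      }))
      if (step == 1) {
        cond <- p[[1]] * p[[3]] * p[[5]] == 0L & p[[3]] * p[[5]] * p[[7]] == 0L
      } else {
        cond <- p[[1]] * p[[3]] * p[[7]] == 0L & p[[1]] * p[[5]] * p[[7]] == 0L
      }
      del <- b == 1L & bsum >= 2L & bsum <= 6L & a == 1L & cond
      if (any(del)) {
        b[del] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  b == 1L
}
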