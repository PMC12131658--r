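## qc_normalize: survival fractions, library-referenced Z-statistics, and
## control performance accounting.

#' Survival fraction of a well
#'
#' Cell death is read out as the fraction of Hoechst-positive nuclei that
#' incorporated propidium iodide (PI enters only membrane-compromised
#' cells); survival is the complement.
#'
#' @param n_nuclei Total nuclei count(s), >= 1.
#' @param n_pi_pos PI-positive count(s), `0 <= n_pi_pos <= n_nuclei`.
#' @return Numeric vector of survival fractions in `[0, 1]`.
#' @examples
#' survival_fraction(100, 50)  # 0.5, the baseline under aSyn overexpression
#' @export
survival_fraction <- function(n_nuclei, n_pi_pos) {
  if (any(n_nuclei == 0)) {
    stop("undefined well: n_nuclei = 0 (no objects counted)", call. = FALSE)
  }
  stopifnot(all(n_nuclei >= 1), all(n_pi_pos >= 0), all(n_pi_pos <= n_nuclei))
  (n_nuclei - n_pi_pos) / n_nuclei
}

#' Library-referenced survival Z-scores
#'
#' Each well's survival is standardized against the mean and standard
#' deviation (n-1 denominator) of the *library* wells of its normalization
#' scope: control wells are scored against the same library distribution,
#' never against themselves. Wells with `n_nuclei = 0` are excluded (they
#' carry no measurement); library Z-scores within a scope therefore have
#' mean 0 and SD 1 by construction.
#'
#' @param ds A [screen_dataset()].
#' @param scope Normalization scope: `"per_run"` pools library wells over
#'   all plates of one screening run (default; guards against run-to-run
#'   drift), `"per_plate"` and `"global"` are available alternatives. The
#'   choice cannot be disambiguated from published control rates alone.
#' @return A `z_table` data.frame: `treatment`, `klass`, `run_id`,
#'   `plate_id`, `row`, `col`, `survival`, `z`.
#' @export
compute_zscores <- function(ds, scope = c("per_run", "per_plate", "global")) {
  scope <- match.arg(scope)
  stopifnot(inherits(ds, "screen_dataset"))
  w <- ds$wells[ds$wells$n_nuclei > 0L, , drop = FALSE]
  if (!nrow(w)) stop("no usable wells (all have n_nuclei = 0)", call. = FALSE)
  surv <- survival_fraction(w$n_nuclei, w$n_pi_pos)
  scope_id <- switch(scope,
    per_run   = w$run_id,
    per_plate = paste(w$run_id, w$plate_id, sep = "/"),
    global    = rep("all", nrow(w))
  )
  z <- numeric(nrow(w))
  for (s in unique(scope_id)) {
    in_scope <- scope_id == s
    lib <- in_scope & w$klass == "library"
    if (sum(lib) < 2L) {
      stop("scope '", s, "' has fewer than 2 library wells", call. = FALSE)
    }
    m <- mean(surv[lib])
    sdev <- stats::sd(surv[lib])
    if (sdev == 0) {
      stop("degenerate scope '", s, "': library survival SD is 0",
           call. = FALSE)
    }
    z[in_scope] <- (surv[in_scope] - m) / sdev
  }
  out <- data.frame(
    treatment = w$treatment, klass = w$klass, run_id = w$run_id,
    plate_id = w$plate_id, row = w$row, col = w$col,
    survival = surv, z = z, stringsAsFactors = FALSE
  )
  class(out) <- c("z_table", "data.frame")
  out
}

## round half away from zero, the convention behind the published
## integer percentages (78.86 -> 79, 89.96 -> 90)
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Control performance at a Z threshold
#'
#' Tabulates, per treatment class, how many wells fall strictly above and
#' strictly below the hit threshold. For the positive control the
#' above-threshold rate is the screen's true-positive rate; for the
#' negative controls (F-Luc, mock) the below-threshold rate is the
#' true-negative rate. Comparisons are strict in both directions, so a
#' well exactly at the threshold is a non-hit and counts toward the
#' below-threshold tally.
#'
#' @param zt A `z_table` from [compute_zscores()] (any data.frame with
#'   `klass` and `z` columns works).
#' @param threshold Survival Z-score hit threshold (default 2.4).
#' @return A `qc_report` data.frame, one row per class present: `klass`,
#'   `n_wells`, `n_above`, `n_below`, `rate_above`, `rate_below`
#'   (percent, 2 decimals), `rate_above_pct`/`rate_below_pct` (integer
#'   percent, half-away-from-zero — the publication comparison view),
#'   `mean_z`, `sd_z`, `threshold`.
#' @export
control_performance <- function(zt, threshold = 2.4) {
  stopifnot(nrow(zt) > 0, all(c("klass", "z") %in% names(zt)))
  absent <- setdiff(setdiff(klass_levels(), "untreated"), unique(zt$klass))
  if (length(absent)) {
    message("control_performance: class(es) absent from Z-table, omitted: ",
            paste(absent, collapse = ", "))
  }
  rows <- lapply(intersect(klass_levels(), unique(zt$klass)), function(k) {
    z <- zt$z[zt$klass == k]
    n_above <- sum(z > threshold)
    n_below <- sum(z <= threshold)  # at-threshold wells are non-hits
    data.frame(
      klass = k, n_wells = length(z), n_above = n_above, n_below = n_below,
      rate_above = round(100 * n_above / length(z), 2),
      rate_below = round(100 * n_below / length(z), 2),
      rate_above_pct = round_half_away(100 * n_above / length(z)),
      rate_below_pct = round_half_away(100 * n_below / length(z)),
      mean_z = mean(z), sd_z = if (length(z) > 1) stats::sd(z) else NA_real_,
      threshold = threshold, stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("qc_report", "data.frame")
  out
}
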