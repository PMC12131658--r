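## Nuclear-region signal quantification (caspase-3/7 activity readout)
## and LDH-release kinetics.

#' Per-nucleus mean signal intensity
#'
#' Measures the mean of the signal channel inside every labeled nucleus
#' mask — the readout used for fluorogenic caspase-3/7 substrates, whose
#' product accumulates in the nuclear region of apoptotic cells.
#'
#' @param signal_img An [image2d()] of the signal channel.
#' @param nuclei_labels Integer matrix of the same dimensions: 0 =
#'   background, `1..n` = nucleus ids (e.g. from an upstream
#'   segmentation or the synthetic generator).
#' @return data.frame `nucleus`, `n_px`, `mean_intensity`; nuclei whose
#'   mask is empty are skipped with a message.
#' @export
nuclear_signal <- function(signal_img, nuclei_labels) {
  px <- .px(signal_img)
  stopifnot(all(dim(px) == dim(nuclei_labels)))
  ids <- seq_len(max(0L, max(nuclei_labels)))
  if (!length(ids)) stop("no nuclei in label image", call. = FALSE)
  n_px <- tabulate(nuclei_labels[nuclei_labels > 0L], nbins = length(ids))
  empty <- which(n_px == 0L)
  if (length(empty)) {
    message("nuclear_signal: skipping empty nucleus mask(s): ",
            paste(empty, collapse = ", "))
  }
  keep <- n_px > 0L
  sums <- vapply(ids[keep], function(i) sum(px[nuclei_labels == i]), 1.0)
  data.frame(nucleus = ids[keep], n_px = n_px[keep],
             mean_intensity = sums / n_px[keep])
}

#' Normalize a condition's mean signal to a reference condition
#'
#' @param values Per-nucleus (or per-image) intensities of the condition.
#' @param reference Intensities of the reference condition (set to 100%).
#' @return Percent of the reference mean.
#' @export
signal_vs_reference <- function(values, reference) {
  stopifnot(length(reference) >= 1, mean(reference) != 0)
  100 * mean(values) / mean(reference)
}

#' LDH kinetic rate from an absorbance time series
#'
#' Lactate dehydrogenase released into the medium consumes NADH, whose
#' absorbance at 340 nm declines over the ~4-minute read; the
#' cytotoxicity readout is the ordinary-least-squares decline rate.
#'
#' @param times_min Strictly increasing time points (minutes), >= 3.
#' @param absorbance Absorbance values at 340 nm, same length.
#' @return NADH consumption rate in absorbance units per minute
#'   (positive for declining absorbance).
#' @export
ldh_rate <- function(times_min, absorbance) {
  stopifnot(length(times_min) == length(absorbance))
  if (length(times_min) < 3) {
    stop("LDH rate needs at least 3 time points", call. = FALSE)
  }
  if (any(diff(times_min) <= 0)) {
    stop("time points must be strictly increasing", call. = FALSE)
  }
  fit <- stats::lm(absorbance ~ times_min)
  -unname(stats::coef(fit)[2])
}

#' Relative LDH cytotoxicity versus a reference condition
#'
#' @param rate Condition's NADH consumption rate ([ldh_rate()]).
#' @param rate_reference Reference condition's rate (set to 100%).
#' @return Percent cytotoxicity relative to the reference.
#' @export
ldh_cytotoxicity <- function(rate, rate_reference) {
  stopifnot(rate_reference != 0)
  100 * rate / rate_reference
}
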