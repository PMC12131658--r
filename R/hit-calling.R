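## hit_calling: the three-tier cascade — primary Z-rule, annotation
## filter, Dunnett confirmation vs the F-Luc control, and the
## alpha-synuclein-vs-GFP specificity tier.

#' Primary hit calling by the run-replicated Z rule
#'
#' A library gene is a primary hit when its survival Z-score exceeds the
#' threshold (strictly) in at least `min_runs` screening runs. When a
#' gene occupies several wells within one run, the run's Z is their
#' mean. Genes with fewer usable runs than `min_runs` are reported
#' `uncallable` and never called.
#'
#' @param zt A `z_table` from [compute_zscores()].
#' @param threshold Z threshold (default 2.4; strict `>`, a run exactly
#'   at the threshold does not count).
#' @param min_runs Minimum number of runs above threshold (default 2).
#' @return data.frame with one row per library gene: `symbol`, `n_runs`,
#'   `n_runs_above`, `max_z`, `called`, `uncallable`.
#' @export
call_primary <- function(zt, threshold = 2.4, min_runs = 2) {
  lib <- zt[zt$klass == "library", , drop = FALSE]
  if (!nrow(lib)) {
    return(data.frame(symbol = character(), n_runs = integer(),
                      n_runs_above = integer(), max_z = numeric(),
                      called = logical(), uncallable = logical(),
                      stringsAsFactors = FALSE))
  }
  per_run <- stats::aggregate(z ~ treatment + run_id, data = lib, FUN = mean)
  spl <- split(per_run$z, per_run$treatment)
  out <- data.frame(
    symbol = names(spl),
    n_runs = vapply(spl, length, 1L),
    n_runs_above = vapply(spl, function(z) sum(z > threshold), 1L),
    max_z = vapply(spl, max, 1.0),
    stringsAsFactors = FALSE
  )
  out$uncallable <- out$n_runs < min_runs
  out$called <- !out$uncallable & out$n_runs_above >= min_runs
  rownames(out) <- NULL
  out
}

#' Filter primary hits by gene annotation
#'
#' Retains only hits annotated `protein_coding`; hits matched to a
#' pseudogene or non-coding RNA, or absent from the annotation table,
#' are excluded with the reason recorded.
#'
#' @param hits data.frame of primary hits ([call_primary()] output); if a
#'   `called` column is present only called rows are considered.
#' @param ann Annotation data.frame with `symbol` and `biotype` columns
#'   (see [read_annotations()]).
#' @return List with `kept` (data.frame of retained hits) and `excluded`
#'   (data.frame with an additional `reason` column).
#' @export
filter_annotations <- function(hits, ann) {
  if ("called" %in% names(hits)) hits <- hits[hits$called, , drop = FALSE]
  biotype <- ann$biotype[match(hits$symbol, ann$symbol)]
  reason <- ifelse(is.na(biotype), "unmatched", biotype)
  keep <- !is.na(biotype) & biotype == "protein_coding"
  excluded <- hits[!keep, , drop = FALSE]
  excluded$reason <- reason[!keep]
  rownames(excluded) <- NULL
  kept <- hits[keep, , drop = FALSE]
  rownames(kept) <- NULL
  list(kept = kept, excluded = excluded)
}

.survival_by_treatment <- function(ds, symbols) {
  w <- ds$wells[ds$wells$n_nuclei > 0L & ds$wells$klass == "library", ,
                drop = FALSE]
  surv <- survival_fraction(w$n_nuclei, w$n_pi_pos)
  by_sym <- split(surv, w$treatment)
  out <- by_sym[symbols]
  out[vapply(out, is.null, TRUE)] <- list(numeric())
  names(out) <- symbols
  out
}

#' Secondary hit confirmation by ANOVA-gated Dunnett comparisons
#'
#' Candidate survivals (all replicate wells across runs) are compared
#' many-to-one against the F-Luc negative-control wells: a one-way ANOVA
#' across candidates plus control gates the family, then each candidate
#' receives a two-sided Dunnett-adjusted p-value. A candidate is called
#' when its adjusted p is below `alpha`, its mean survival exceeds the
#' control mean (direction filter), and — when `anova_gate` is on — the
#' ANOVA itself is significant at `alpha`.
#'
#' @param ds A `screen_dataset` of the confirmation screen (3 runs).
#' @param candidates Character vector of candidate gene symbols.
#' @param alpha Significance level (default 0.05).
#' @param anova_gate Require the gate ANOVA to pass (default TRUE).
#' @param tol Quadrature tolerance forwarded to [dunnett_adjusted()].
#' @return data.frame (one row per candidate): Dunnett columns plus
#'   `mean_survival`, `called`. The gate ANOVA is attached as attribute
#'   `"anova"`.
#' @export
call_secondary <- function(ds, candidates, alpha = 0.05, anova_gate = TRUE,
                           tol = 1e-6) {
  stopifnot(inherits(ds, "screen_dataset"), length(candidates) >= 1)
  w <- ds$wells[ds$wells$n_nuclei > 0L, , drop = FALSE]
  ctrl_rows <- w$klass == "neg_ctrl_fluc"
  if (!any(ctrl_rows)) {
    stop("configuration error: no F-Luc control wells in dataset",
         call. = FALSE)
  }
  runs <- unique(w$run_id)
  ctrl_runs <- unique(w$run_id[ctrl_rows])
  if (!all(runs %in% ctrl_runs)) {
    stop("configuration error: F-Luc control wells missing in run(s): ",
         paste(setdiff(runs, ctrl_runs), collapse = ", "), call. = FALSE)
  }
  control <- survival_fraction(w$n_nuclei[ctrl_rows], w$n_pi_pos[ctrl_rows])
  groups <- .survival_by_treatment(ds, candidates)
  short <- vapply(groups, length, 1L) < 2L
  if (any(short)) {
    stop("candidate(s) with fewer than 2 replicate wells: ",
         paste(names(groups)[short], collapse = ", "), call. = FALSE)
  }
  gate <- one_way_anova(c(groups, list(.control = control)))
  res <- dunnett_adjusted(groups, control, tol = tol)
  res$mean_survival <- vapply(groups, mean, 1.0)
  res$called <- res$p_adj < alpha & res$estimate > 0 &
    (!anova_gate | gate$p < alpha)
  attr(res, "anova") <- gate
  res
}

#' Tertiary specificity calls: alpha-synuclein versus GFP arms
#'
#' For each condition, candidate well survivals are expressed relative to
#' the mean survival of that condition's F-Luc negative-control wells
#' (in percent). Per candidate, the relative survivals of the two arms
#' are compared with a Welch t-test; the raw p-values are adjusted
#' across candidates (step-down Sidak by default). A final hit must be
#' both significant after adjustment and *more* protected in the
#' alpha-synuclein arm (`diff > 0`), i.e. specific.
#'
#' @param asyn `screen_dataset` of the alpha-synuclein-overexpression arm.
#' @param gfp `screen_dataset` of the GFP control arm.
#' @param candidates Character vector of candidate symbols.
#' @param alpha Significance level (default 0.05).
#' @param correction `"holm_sidak"` (default) or `"bonferroni_holm"`.
#' @param relative Normalize to the condition's negative-control mean
#'   (default); `FALSE` compares raw survival fractions (scaled to %).
#' @return List with `records` (per candidate: `symbol`,
#'   `mean_rel_survival_asyn`, `mean_rel_survival_gfp`, `diff`, `t`,
#'   `df`, `p_raw`, `p_adj`, `final_hit`) and `volcano` (`symbol`,
#'   `diff`, `neg_log10_p_raw`, `p_adj`, `final_hit`).
#' @export
call_tertiary <- function(asyn, gfp, candidates, alpha = 0.05,
                          correction = c("holm_sidak", "bonferroni_holm"),
                          relative = TRUE) {
  correction <- match.arg(correction)
  stopifnot(length(candidates) >= 1)
  rel_values <- function(ds) {
    w <- ds$wells[ds$wells$n_nuclei > 0L, , drop = FALSE]
    ctrl <- w$klass == "neg_ctrl_fluc"
    if (relative && !any(ctrl)) {
      stop("configuration error: no negative-control wells in '",
           ds$condition, "' dataset", call. = FALSE)
    }
    ref <- if (relative) {
      mean(survival_fraction(w$n_nuclei[ctrl], w$n_pi_pos[ctrl]))
    } else 1
    vals <- .survival_by_treatment(ds, candidates)
    lapply(vals, function(v) 100 * v / ref)
  }
  va <- rel_values(asyn)
  vg <- rel_values(gfp)
  short <- vapply(va, length, 1L) < 2L | vapply(vg, length, 1L) < 2L
  if (any(short)) {
    stop("candidate(s) need >= 2 replicates per condition: ",
         paste(candidates[short], collapse = ", "), call. = FALSE)
  }
  tests <- lapply(candidates, function(s) welch_t(va[[s]], vg[[s]]))
  rec <- data.frame(
    symbol = candidates,
    mean_rel_survival_asyn = vapply(va, mean, 1.0)[candidates],
    mean_rel_survival_gfp = vapply(vg, mean, 1.0)[candidates],
    t = vapply(tests, `[[`, 1.0, "t"),
    df = vapply(tests, `[[`, 1.0, "df"),
    p_raw = vapply(tests, `[[`, 1.0, "p"),
    stringsAsFactors = FALSE
  )
  rec$diff <- rec$mean_rel_survival_asyn - rec$mean_rel_survival_gfp
  rec$p_adj <- switch(correction,
                      holm_sidak = holm_sidak(rec$p_raw),
                      bonferroni_holm = bonferroni_holm(rec$p_raw))
  rec$final_hit <- rec$p_adj < alpha & rec$diff > 0
  rownames(rec) <- NULL
  volcano <- data.frame(
    symbol = rec$symbol, diff = rec$diff,
    neg_log10_p_raw = -log10(rec$p_raw),
    p_adj = rec$p_adj, final_hit = rec$final_hit,
    stringsAsFactors = FALSE
  )
  list(records = rec[c("symbol", "mean_rel_survival_asyn",
                       "mean_rel_survival_gfp", "diff", "t", "df",
                       "p_raw", "p_adj", "final_hit")],
       volcano = volcano)
}
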