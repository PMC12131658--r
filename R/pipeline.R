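## cli_report: configuration, end-to-end cascade, report bundle.

#' Pipeline configuration
#'
#' Collects every knob of the screening cascade. `paths` names the input
#' files: `primary`, `secondary`, `tertiary_asyn`, `tertiary_gfp` (well
#' tables), `layout` (CSV grid, optional — bundled default otherwise)
#' and `annotations` (TSV). Configs round-trip losslessly through YAML
#' ([read_pipeline_config()] / [write_pipeline_config()]).
#'
#' @param paths Named list of input paths (see above).
#' @param threshold Primary Z threshold (default 2.4).
#' @param min_runs Primary run-replication requirement (default 2).
#' @param alpha Significance level for the confirmation tiers (0.05).
#' @param correction Tertiary correction, `"holm_sidak"` (default) or
#'   `"bonferroni_holm"`.
#' @param scope Z-normalization scope (see [compute_zscores()]).
#' @param seed Integer seed recorded in the run log (the cascade itself
#'   is deterministic).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(paths, threshold = 2.4, min_runs = 2,
                            alpha = 0.05,
                            correction = c("holm_sidak", "bonferroni_holm"),
                            scope = c("per_run", "per_plate", "global"),
                            seed = 1L) {
  correction <- match.arg(correction)
  scope <- match.arg(scope)
  needed <- c("primary", "secondary", "tertiary_asyn", "tertiary_gfp",
              "annotations")
  missing <- setdiff(needed, names(paths))
  if (length(missing)) {
    stop("pipeline config lacks path(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  structure(list(paths = paths, threshold = threshold,
                 min_runs = as.integer(min_runs), alpha = alpha,
                 correction = correction, scope = scope,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file path.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  pipeline_config(paths = y$paths, threshold = y$threshold %||% 2.4,
                  min_runs = y$min_runs %||% 2, alpha = y$alpha %||% 0.05,
                  correction = y$correction %||% "holm_sidak",
                  scope = y$scope %||% "per_run", seed = y$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname pipeline_config
#' @param cfg A `pipeline_config`.
#' @export
write_pipeline_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full screening cascade and write a report bundle
#'
#' Executes QC (Z-scores and control performance), primary Z-rule
#' calling, annotation filtering, secondary Dunnett confirmation and the
#' tertiary specificity tier, writing every stage's table plus a
#' cascade summary, the fully resolved config, a MANIFEST and a run
#' log. Candidates for each confirmation tier are the upstream tier's
#' calls restricted to genes present in that tier's dataset. On a stage
#' error the partial outputs are retained, the MANIFEST marks the
#' bundle incomplete, and the error names the stage.
#'
#' @param cfg A [pipeline_config()] or path to its YAML file.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the stage results (`qc`, `primary`,
#'   `filtered`, `secondary`, `tertiary`, `summary`).
#' @export
run_pipeline <- function(cfg, out_dir) {
  if (is.character(cfg)) cfg <- read_pipeline_config(cfg)
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- file.path(out_dir, "MANIFEST")
  writeLines(c("status: INCOMPLETE"), manifest)
  cfg_bytes <- utf8ToInt(paste(unlist(cfg), collapse = "|"))
  log_lines <- c(
    sprintf("screencall %s", as.character(utils::packageVersion("screencall"))),
    sprintf("seed: %d", cfg$seed),
    sprintf("config_hash: %08x",
            sum(cfg_bytes * seq_along(cfg_bytes)) %% .Machine$integer.max))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(c("status: INCOMPLETE", sprintf("failed_stage: %s", name)),
                 manifest)
      stop(sprintf("pipeline stage %s failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  layout <- if (!is.null(cfg$paths$layout)) {
    stage("screen_model.read_layout", read_layout(cfg$paths$layout))
  } else default_layout()
  ann <- stage("hit_calling.filter_annotations",
               read_annotations(cfg$paths$annotations))
  ds1 <- stage("screen_model.read_well_table",
               read_well_table(cfg$paths$primary, layout = layout))

  qc <- stage("qc_normalize", {
    zt <- compute_zscores(ds1, scope = cfg$scope)
    perf <- control_performance(zt, threshold = cfg$threshold)
    .write_tsv(zt, file.path(out_dir, "qc_zscores.tsv"))
    .write_tsv(perf, file.path(out_dir, "qc_report.tsv"))
    jsonlite::write_json(perf, file.path(out_dir, "qc_report.json"),
                         dataframe = "rows", digits = NA, pretty = TRUE)
    list(z = zt, performance = perf)
  })

  primary <- stage("hit_calling.call_primary", {
    ph <- call_primary(qc$z, threshold = cfg$threshold,
                       min_runs = cfg$min_runs)
    .write_tsv(ph, file.path(out_dir, "primary_hits.tsv"))
    ph
  })

  filtered <- stage("hit_calling.filter_annotations", {
    fa <- filter_annotations(primary, ann)
    .write_tsv(fa$excluded, file.path(out_dir, "annotation_excluded.tsv"))
    .write_tsv(fa$kept, file.path(out_dir, "annotation_kept.tsv"))
    fa
  })

  secondary <- stage("hit_calling.call_secondary", {
    ds2 <- read_well_table(cfg$paths$secondary, layout = layout)
    cand <- intersect(filtered$kept$symbol, unique(ds2$wells$treatment))
    res <- if (length(cand)) {
      call_secondary(ds2, cand, alpha = cfg$alpha)
    } else {
      dunnett_adjusted(list(), numeric())
    }
    .write_tsv(res, file.path(out_dir, "secondary_results.tsv"))
    res
  })

  tertiary <- stage("hit_calling.call_tertiary", {
    sec_hits <- secondary$label[secondary$called]
    ds3a <- read_well_table(cfg$paths$tertiary_asyn, layout = layout)
    ds3g <- read_well_table(cfg$paths$tertiary_gfp, layout = layout,
                            condition = "gfp")
    cand <- intersect(sec_hits,
                      intersect(unique(ds3a$wells$treatment),
                                unique(ds3g$wells$treatment)))
    if (length(cand)) {
      res <- call_tertiary(ds3a, ds3g, cand, alpha = cfg$alpha,
                           correction = cfg$correction)
    } else {
      empty <- data.frame(symbol = character(), diff = numeric(),
                          p_raw = numeric(), p_adj = numeric(),
                          final_hit = logical())
      res <- list(records = empty, volcano = empty)
    }
    .write_tsv(res$records, file.path(out_dir, "tertiary_records.tsv"))
    .write_tsv(res$volcano, file.path(out_dir, "volcano.tsv"))
    res
  })

  summary <- list(
    n_library_genes = length(unique(qc$z$treatment[qc$z$klass == "library"])),
    n_primary_hits = sum(primary$called),
    n_excluded_by_annotation = nrow(filtered$excluded),
    n_after_annotation = nrow(filtered$kept),
    n_secondary_hits = sum(secondary$called),
    n_tertiary_raw = sum(tertiary$records$p_raw < cfg$alpha &
                           tertiary$records$diff > 0),
    n_final_hits = sum(tertiary$records$final_hit),
    threshold = cfg$threshold, min_runs = cfg$min_runs, alpha = cfg$alpha
  )
  jsonlite::write_json(summary, file.path(out_dir, "cascade_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_pipeline_config(cfg, file.path(out_dir, "resolved_config.yaml"))
  writeLines(log_lines, file.path(out_dir, "run.log"))
  writeLines(c("status: COMPLETE",
               paste("files:", paste(sort(setdiff(list.files(out_dir),
                                                  "MANIFEST")),
                                     collapse = " "))), manifest)
  invisible(list(qc = qc, primary = primary, filtered = filtered,
                 secondary = secondary, tertiary = tertiary,
                 summary = summary))
}

#' Write a layout back to its CSV grid form
#' @param layout A [plate_layout()].
#' @param path Output CSV path.
#' @export
write_layout <- function(layout, path) {
  inv <- stats::setNames(names(.klass_codes), .klass_codes)
  codes <- matrix(inv[as.vector(unclass(layout))], nrow(layout), ncol(layout))
  writeLines(apply(codes, 1, paste, collapse = ","), path)
  invisible(path)
}

#' Simulate a screening campaign to disk
#'
#' Generates the primary screen, runs the primary caller to decide
#' which genes the confirmation tiers would have screened (as the
#' original campaign did), and writes all four well tables, the layout,
#' the annotation table and a ground-truth JSON into `dir`.
#'
#' @param dir Output directory.
#' @param seed Integer seed.
#' @param n_genes,n_planted_hits Primary scale.
#' @param ... Forwarded to [simulate_campaign()].
#' @return Invisibly, a [pipeline_config()] pointing at the files.
#' @export
write_campaign <- function(dir, seed, n_genes = 1000L,
                           n_planted_hits = 20L, ...) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  camp <- simulate_campaign(seed, n_genes = n_genes,
                            n_planted_hits = n_planted_hits, ...)
  zt <- compute_zscores(camp$primary$dataset)
  ph <- call_primary(zt)
  fa <- filter_annotations(ph, camp$annotations)
  cand <- fa$kept$symbol
  if (!length(cand)) cand <- camp$truth$planted$symbol
  sec <- camp$make_secondary(cand)
  ter <- camp$make_tertiary(cand)
  p <- function(f) file.path(dir, f)
  write_well_table(camp$primary$dataset, p("primary_wells.csv"))
  write_well_table(sec$dataset, p("secondary_wells.csv"))
  write_well_table(ter$asyn$dataset, p("tertiary_asyn_wells.csv"))
  write_well_table(ter$gfp$dataset, p("tertiary_gfp_wells.csv"))
  write_layout(camp$primary$dataset$layout, p("layout.csv"))
  .write_tsv(camp$annotations, p("annotations.tsv"))
  jsonlite::write_json(
    list(planted = camp$truth$planted, seed = seed,
         candidates_screened = cand),
    p("truth.json"), dataframe = "rows", digits = NA, pretty = TRUE)
  cfg <- pipeline_config(
    paths = list(primary = p("primary_wells.csv"),
                 secondary = p("secondary_wells.csv"),
                 tertiary_asyn = p("tertiary_asyn_wells.csv"),
                 tertiary_gfp = p("tertiary_gfp_wells.csv"),
                 layout = p("layout.csv"),
                 annotations = p("annotations.tsv")),
    seed = seed)
  write_pipeline_config(cfg, p("config.yaml"))
  invisible(cfg)
}
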