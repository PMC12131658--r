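test_that("the primary Z rule is strict and run-replicated", {
  zt <- make_ztable(
    treatment = rep(c("G1", "G2", "G3", "G4"), each = 2),
    klass = "library",
    run_id = rep(c("R1", "R2"), 4),
    z = c(2.5, 2.6,   # called
          2.5, 2.3,   # one run only
          2.4, 2.4,   # exactly at threshold: strict >
          3.5, 3.5))  # called
  hits <- call_primary(zt)
  expect_equal(hits$called[match(c("G1", "G2", "G3", "G4"), hits$symbol)],
               c(TRUE, FALSE, FALSE, TRUE))
  # a gene with fewer usable runs than min_runs is uncallable, never called
  zt1 <- make_ztable("G9", "library", "R1", 5.0)
  h1 <- call_primary(zt1)
  expect_true(h1$uncallable)
  expect_false(h1$called)
  expect_equal(nrow(call_primary(make_ztable(character(), character(),
                                             character(), numeric()))), 0L)
})

test_that("raising threshold or min_runs never enlarges the hit set", {
  set.seed(21)
  zt <- make_ztable(
    treatment = rep(sprintf("G%03d", 1:200), each = 3),
    klass = "library",
    run_id = rep(c("R1", "R2", "R3"), 200),
    z = rnorm(600, 1.5, 1.2))
  base <- call_primary(zt, threshold = 2.4, min_runs = 2)
  for (t in c(2.6, 3.0, 3.5)) {
    higher <- call_primary(zt, threshold = t, min_runs = 2)
    expect_true(all(higher$symbol[higher$called] %in%
                      base$symbol[base$called]))
  }
  stricter <- call_primary(zt, threshold = 2.4, min_runs = 3)
  expect_true(all(stricter$symbol[stricter$called] %in%
                    base$symbol[base$called]))
})

test_that("annotation filtering keeps protein-coding hits only", {
  hits <- data.frame(symbol = sprintf("H%02d", 1:80), called = TRUE)
  ann <- data.frame(symbol = sprintf("H%02d", 1:76),
                    biotype = c(rep("protein_coding", 69),
                                rep("pseudogene", 4), rep("non_coding", 3)))
  # 4 pseudogenes + 3 non-coding + 4 unmatched = 11 excluded, 69 kept
  fa <- filter_annotations(hits, ann)
  expect_equal(nrow(fa$kept), 69L)
  expect_equal(nrow(fa$excluded), 11L)
  expect_equal(sum(fa$excluded$reason == "pseudogene"), 4L)
  expect_equal(sum(fa$excluded$reason == "non_coding"), 3L)
  expect_equal(sum(fa$excluded$reason == "unmatched"), 4L)
})

test_that("secondary confirmation separates real shifts from the control", {
  surv <- c(rep(c(0.49, 0.51, 0.50, 0.52), 3),  # null, = control distribution
            rep(c(0.74, 0.76, 0.75, 0.77), 3),  # strongly shifted
            rep(c(0.49, 0.51, 0.50, 0.52), 3))  # F-Luc control wells
  ds <- make_dataset(
    treatment = c(rep("NULL1", 12), rep("PROT1", 12), rep("FLUC", 12)),
    klass = c(rep("library", 24), rep("neg_ctrl_fluc", 12)),
    survival = surv,
    run_id = rep(rep(c("R1", "R2", "R3"), each = 4), 3))
  res <- call_secondary(ds, c("NULL1", "PROT1"))
  expect_false(res$called[res$label == "NULL1"])
  expect_gt(res$p_adj[res$label == "NULL1"], 0.5)
  expect_true(res$called[res$label == "PROT1"])
  expect_true(all(res$p_adj >= res$p_raw))
  expect_type(attr(res, "anova"), "list")
  expect_lt(attr(res, "anova")$p, 0.05)
  # missing control is a configuration error
  ds2 <- make_dataset("G1", "library", 0.5)
  expect_error(call_secondary(ds2, "G1"), "configuration error")
})

test_that("tertiary calls require alpha-synuclein-specific protection", {
  mk <- function(vals_by_sym, condition) {
    syms <- names(vals_by_sym)
    n <- lengths(vals_by_sym)
    make_wells(rep(syms, n), "library", unlist(vals_by_sym) / 200,
               run_id = "R1") |>
      screen_dataset(condition = condition, validate = FALSE)
  }
  # equal protection in both arms is non-specific; asyn-only is a hit
  asyn <- mk(list(BOTH = c(139, 140, 141), SPEC = c(139, 140, 141)), "asyn")
  gfp <- mk(list(BOTH = c(139, 140, 141), SPEC = c(99, 100, 101)), "gfp")
  res <- call_tertiary(asyn, gfp, c("BOTH", "SPEC"), relative = FALSE)
  expect_false(res$records$final_hit[res$records$symbol == "BOTH"])
  expect_equal(res$records$diff[res$records$symbol == "BOTH"], 0)
  expect_true(res$records$final_hit[res$records$symbol == "SPEC"])
  expect_equal(res$volcano$symbol, res$records$symbol)

  # calibrated 28-candidate fixture: 12 nominally protective, 4 survive
  # the step-down Sidak adjustment
  fx <- make_tertiary_fixture()
  res28 <- call_tertiary(mk(fx$asyn, "asyn"), mk(fx$gfp, "gfp"),
                         fx$symbols, relative = FALSE)
  rec <- res28$records
  expect_equal(sum(rec$p_raw < 0.05 & rec$diff > 0), 12L)
  expect_equal(sum(rec$final_hit), 4L)
  expect_true(all(rec$p_adj >= rec$p_raw))
})

test_that("the cascade nests and recovers planted protectors", {
  camp <- simulate_campaign(1)
  zt <- compute_zscores(camp$primary$dataset)
  primary <- call_primary(zt)
  fa <- filter_annotations(primary, camp$annotations)
  sec_ds <- camp$make_secondary(fa$kept$symbol)
  sec <- call_secondary(sec_ds$dataset, fa$kept$symbol, tol = 1e-5)
  sec_hits <- sec$label[sec$called]
  ter_ds <- camp$make_tertiary(sec_hits)
  ter <- call_tertiary(ter_ds$asyn$dataset, ter_ds$gfp$dataset, sec_hits)
  final <- ter$records$symbol[ter$records$final_hit]
  # monotone nesting: final within secondary within filtered primary
  expect_true(all(sec_hits %in% fa$kept$symbol))
  expect_true(all(final %in% sec_hits))
  expect_true(all(fa$kept$symbol %in% primary$symbol[primary$called]))
  # planted protectors dominate the final list
  planted <- camp$truth$planted$symbol
  expect_gte(sum(planted %in% final), 1)
  expect_true(all(final %in% planted))
})
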