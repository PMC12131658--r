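test_that("well tables parse, validate and round-trip", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("plate_id,run_id,row,col,treatment,klass,n_nuclei,n_pi_pos",
               "p1,r1,0,0,SNX5,library,100,50"), f)
  ds <- read_well_table(f)
  expect_s3_class(ds, "screen_dataset")
  expect_equal(nrow(ds$wells), 1L)
  expect_equal(survival_fraction(ds$wells$n_nuclei, ds$wells$n_pi_pos), 0.5)

  # A1-style well column accepted
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("plate_id,run_id,well,treatment,klass,n_nuclei,n_pi_pos",
               "p1,r1,B3,SNX5,library,100,50"), f2)
  ds2 <- read_well_table(f2)
  expect_equal(ds2$wells$row, 1L)
  expect_equal(ds2$wells$col, 2L)

  # missing column names the column; invariant violation names the well
  f3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("plate_id,run_id,row,col,treatment,klass,n_nuclei",
               "p1,r1,0,0,SNX5,library,100"), f3)
  expect_error(read_well_table(f3), "n_pi_pos")
  f4 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("plate_id,run_id,row,col,treatment,klass,n_nuclei,n_pi_pos",
               "p1,r1,3,7,SNX5,library,100,120"), f4)
  expect_error(read_well_table(f4), "D8")

  # full synthetic round trip, canonical and A1 styles
  sim <- generate_screen(screen_sim_config(n_genes = 320L, n_runs = 2L,
                                           seed = 11))
  expect_gte(nrow(sim$dataset$wells), 320 * 2)
  fo <- withr::local_tempfile(fileext = ".csv")
  write_well_table(sim$dataset, fo)
  back <- read_well_table(fo)
  expect_identical(back$wells, sim$dataset$wells)
  fa1 <- withr::local_tempfile(fileext = ".tsv")
  write_well_table(sim$dataset, fa1, style = "a1")
  back2 <- read_well_table(fa1)
  expect_identical(back2$wells, sim$dataset$wells)
  # byte-stable rewrite
  fo2 <- withr::local_tempfile(fileext = ".csv")
  write_well_table(back, fo2)
  expect_identical(readLines(fo), readLines(fo2))
})

test_that("A1 labels map to 0-based coordinates and back", {
  expect_equal(well_a1(0, 0), "A1")
  expect_equal(well_a1(15, 23), "P24")
  expect_equal(parse_a1(c("A1", "P24")),
               data.frame(row = c(0L, 15L), col = c(0L, 23L)))
  expect_error(parse_a1("Q1"), "not A1-style")
})

test_that("layout grids read, count and reject ragged input", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(rep(paste(rep(".", 24), collapse = ","), 16), f)
  lay <- read_layout(f)
  expect_equal(dim(lay), c(16L, 24L))
  expect_equal(unname(layout_counts(lay)["library"]), 384L)

  f2 <- withr::local_tempfile(fileext = ".csv")
  grid <- matrix(".", 16, 24)
  grid[1:8, c(1, 24)] <- "L"
  writeLines(apply(grid, 1, paste, collapse = ","), f2)
  expect_equal(unname(layout_counts(read_layout(f2))["neg_ctrl_fluc"]), 16L)

  # bundled default: documented control-block counts
  counts <- layout_counts(default_layout())
  expect_equal(counts[c("library", "pos_ctrl_asyn", "neg_ctrl_fluc", "mock")],
               c(library = 352L, pos_ctrl_asyn = 8L, neg_ctrl_fluc = 16L,
                 mock = 8L))

  f3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(".,.,.", ".,."), f3)
  expect_error(read_layout(f3), "ragged")

  # write/read round trip
  f4 <- withr::local_tempfile(fileext = ".csv")
  write_layout(default_layout(), f4)
  expect_identical(read_layout(f4), default_layout())
})

test_that("validate_dataset finds exactly the planted violations", {
  clean <- generate_screen(screen_sim_config(n_genes = 100L, seed = 3))$dataset
  expect_equal(nrow(validate_dataset(clean)), 0L)

  set.seed(42)
  for (rep in 1:5) {
    w <- clean$wells
    n_dup <- sample(0:2, 1)
    n_empty <- sample(0:2, 1)
    n_pi <- sample(0:2, 1)
    if (n_dup) {
      w <- rbind(w, w[sample(nrow(w), n_dup), ])
    }
    idx <- sample(nrow(clean$wells), n_empty + n_pi)
    if (n_empty) {
      w$n_nuclei[idx[seq_len(n_empty)]] <- 0L
      w$n_pi_pos[idx[seq_len(n_empty)]] <- 0L
    }
    if (n_pi) {
      j <- idx[n_empty + seq_len(n_pi)]
      w$n_pi_pos[j] <- w$n_nuclei[j] + 5L
    }
    v <- validate_dataset(screen_dataset(w, validate = FALSE))
    expect_equal(sum(v$rule == "duplicate well"), 2 * n_dup)
    expect_equal(sum(v$rule == "empty well"), n_empty)
    expect_equal(sum(v$rule == "pi_exceeds_nuclei"), n_pi)
  }
})
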