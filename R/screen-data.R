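#' @importFrom stats sd var qlogis plogis rnorm rpois rbinom runif pnorm pt
#'   qchisq pchisq pbeta lm coef qt rchisq setNames aggregate
#' @importFrom utils read.csv read.delim write.table head
NULL

## treatment classes ---------------------------------------------------------

#' Treatment classes of a screening well
#'
#' Every well carries one of five treatment classes: `library` reagents (one
#' esiRNA pool per gene), the positive control (`pos_ctrl_asyn`, esiRNA
#' against alpha-synuclein itself, best possible survival), the negative
#' transfection control (`neg_ctrl_fluc`, esiRNA against firefly luciferase,
#' a sequence absent from the cells), `mock` transfection, and `untreated`
#' (used only in follow-up validation tables, never on screening plates).
#'
#' @return Character vector of the valid class names, in canonical order.
#' @export
klass_levels <- function() {
  c("library", "pos_ctrl_asyn", "neg_ctrl_fluc", "mock", "untreated")
}

## single-letter codes used in layout grids
.klass_codes <- c(
  "." = "library", A = "pos_ctrl_asyn", L = "neg_ctrl_fluc",
  M = "mock", U = "untreated"
)

.assert_klass <- function(klass) {
  bad <- setdiff(unique(klass), klass_levels())
  if (length(bad)) {
    stop("unknown treatment class(es): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  invisible(klass)
}

## well coordinates ----------------------------------------------------------

#' Convert between 0-based (row, col) indices and A1-style well labels
#'
#' Rows map to letters (`A` = row 0), columns to 1-based numbers, so `A1`
#' is row 0, column 0 and `P24` is row 15, column 23 on a 384-well plate.
#'
#' @param row,col Integer vectors of 0-based coordinates.
#' @param labels Character vector of A1-style labels.
#' @return `well_a1()` returns a character vector of labels; `parse_a1()`
#'   a data.frame with 0-based `row` and `col` columns.
#' @examples
#' well_a1(0, 0)        # "A1"
#' parse_a1("P24")      # row 15, col 23
#' @export
well_a1 <- function(row, col) {
  stopifnot(all(row >= 0), all(row < 26), all(col >= 0))
  paste0(LETTERS[row + 1L], col + 1L)
}

#' @rdname well_a1
#' @export
parse_a1 <- function(labels) {
  m <- regmatches(labels, regexec("^([A-Pa-p])([0-9]{1,2})$", labels))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) {
    stop("not A1-style well label(s): ", paste(labels[bad], collapse = ", "),
         call. = FALSE)
  }
  data.frame(
    row = match(toupper(vapply(m, `[`, "", 2L)), LETTERS) - 1L,
    col = as.integer(vapply(m, `[`, "", 3L)) - 1L
  )
}

## plate layouts -------------------------------------------------------------

#' Construct a plate layout from a matrix of treatment classes
#'
#' @param assignment Character matrix (rows x columns of the plate) whose
#'   entries are treatment class names (see [klass_levels()]).
#' @return A `plate_layout`: the character matrix with class attribute.
#' @seealso [read_layout()], [default_layout()]
#' @export
plate_layout <- function(assignment) {
  stopifnot(is.matrix(assignment), is.character(assignment))
  .assert_klass(as.vector(assignment))
  structure(assignment, class = "plate_layout")
}

#' @export
print.plate_layout <- function(x, ...) {
  cat(sprintf("<plate_layout> %d x %d wells\n", nrow(x), ncol(x)))
  print(layout_counts(x))
  invisible(x)
}

#' Count wells per treatment class in a layout
#' @param layout A [plate_layout()].
#' @return Named integer vector over [klass_levels()].
#' @export
layout_counts <- function(layout) {
  tab <- table(factor(as.vector(unclass(layout)), levels = klass_levels()))
  stats::setNames(as.integer(tab), names(tab))
}

#' Read a plate layout from a CSV grid of class codes
#'
#' The file is a headerless CSV whose cells are single-letter codes:
#' `.` library, `L` F-Luc negative control, `M` mock, `A` alpha-synuclein
#' positive control, `U` untreated.
#'
#' @param path Path to the CSV grid.
#' @return A [plate_layout()].
#' @export
read_layout <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  cells <- strsplit(lines, ",", fixed = TRUE)
  ncols <- unique(vapply(cells, length, 1L))
  if (length(ncols) != 1L) {
    stop("ragged layout grid in '", path, "': rows have ",
         paste(sort(ncols), collapse = "/"), " cells", call. = FALSE)
  }
  codes <- trimws(do.call(rbind, cells))
  unknown <- setdiff(unique(as.vector(codes)), names(.klass_codes))
  if (length(unknown)) {
    stop("unknown layout code(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  plate_layout(matrix(.klass_codes[as.vector(codes)], nrow(codes), ncol(codes)))
}

#' Default 384-well screening layout
#'
#' A 16 x 24 layout with contiguous control blocks in the first and last
#' columns (per plate: 16 F-Luc, 8 mock, 8 positive-control wells, 352
#' library wells). The real screen's exact control-block coordinates are
#' not published; this bundled layout is a documented stand-in that keeps
#' the screen-wide control ratios (F-Luc : positive : mock roughly 2:1:1).
#'
#' @return A [plate_layout()].
#' @export
default_layout <- function() {
  read_layout(system.file("extdata", "layout_384.csv", package = "screencall",
                          mustWork = TRUE))
}

## screen datasets -----------------------------------------------------------

.well_columns <- c("plate_id", "run_id", "row", "col", "treatment", "klass",
                   "n_nuclei", "n_pi_pos")

#' Construct a screen dataset from a well table
#'
#' @param wells data.frame with columns `plate_id`, `run_id`, `row`, `col`
#'   (0-based integers), `treatment` (gene symbol or control label),
#'   `klass` (see [klass_levels()]), `n_nuclei`, `n_pi_pos`.
#' @param layout A [plate_layout()] giving plate dimensions.
#' @param condition `"asyn"` for alpha-synuclein-overexpressing cells,
#'   `"gfp"` for the GFP-transduced viability control arm.
#' @param validate Stop on invariant violations (default) or defer to
#'   [validate_dataset()].
#' @return A `screen_dataset` (list with elements `wells`, `layout`,
#'   `condition`).
#' @export
screen_dataset <- function(wells, layout = default_layout(),
                           condition = c("asyn", "gfp"), validate = TRUE) {
  condition <- match.arg(condition)
  missing <- setdiff(.well_columns, names(wells))
  if (length(missing)) {
    stop("well table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  wells <- wells[.well_columns]
  wells$row <- as.integer(wells$row)
  wells$col <- as.integer(wells$col)
  wells$n_nuclei <- as.integer(wells$n_nuclei)
  wells$n_pi_pos <- as.integer(wells$n_pi_pos)
  .assert_klass(wells$klass)
  ds <- structure(list(wells = wells, layout = layout, condition = condition),
                  class = "screen_dataset")
  if (validate) {
    bad <- wells$n_pi_pos > wells$n_nuclei
    if (any(bad)) {
      w <- wells[which(bad)[1L], ]
      stop(sprintf(
        "n_pi_pos > n_nuclei at plate %s run %s well %s (%d > %d)",
        w$plate_id, w$run_id, well_a1(w$row, w$col), w$n_pi_pos, w$n_nuclei),
        call. = FALSE)
    }
  }
  ds
}

#' @export
print.screen_dataset <- function(x, ...) {
  cat(sprintf(
    "<screen_dataset> %d wells, %d plates, %d runs, condition '%s'\n",
    nrow(x$wells), length(unique(x$wells$plate_id)),
    length(unique(x$wells$run_id)), x$condition))
  invisible(x)
}

#' Read a well-level screen table from CSV/TSV
#'
#' The file must have a header with columns `plate_id`, `run_id`, `row`,
#' `col`, `treatment`, `klass`, `n_nuclei`, `n_pi_pos`. Alternatively a
#' single `well` column with A1-style labels may replace `row`/`col`.
#' The delimiter is taken from the file extension (`.tsv`/`.txt` = tab,
#' otherwise comma).
#'
#' @inheritParams screen_dataset
#' @param path Path to the table.
#' @return A `screen_dataset`.
#' @export
read_well_table <- function(path, layout = default_layout(),
                            condition = c("asyn", "gfp")) {
  reader <- if (grepl("\\.(tsv|txt)$", path)) read.delim else read.csv
  tab <- reader(path, stringsAsFactors = FALSE)
  if ("well" %in% names(tab) && !all(c("row", "col") %in% names(tab))) {
    rc <- parse_a1(tab$well)
    tab$row <- rc$row
    tab$col <- rc$col
    tab$well <- NULL
  }
  screen_dataset(tab, layout = layout, condition = condition)
}

#' Write a well table to CSV or TSV
#'
#' @param ds A `screen_dataset` (or bare well data.frame).
#' @param path Output path; `.tsv` extension selects tab delimiting.
#' @param style `"index"` writes 0-based `row`/`col` columns (canonical
#'   round-trip form); `"a1"` writes a single A1-style `well` column.
#' @return `path`, invisibly.
#' @export
write_well_table <- function(ds, path, style = c("index", "a1")) {
  style <- match.arg(style)
  wells <- if (inherits(ds, "screen_dataset")) ds$wells else ds[.well_columns]
  if (style == "a1") {
    wells <- cbind(wells[c("plate_id", "run_id")],
                   well = well_a1(wells$row, wells$col),
                   wells[c("treatment", "klass", "n_nuclei", "n_pi_pos")])
  }
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  write.table(wells, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-annotation table (TSV: symbol, biotype)
#'
#' @param path Path to a tab-separated file with header columns `symbol`
#'   and `biotype` (one of `protein_coding`, `pseudogene`, `non_coding`,
#'   `unmatched`).
#' @return data.frame with one row per symbol.
#' @export
read_annotations <- function(path) {
  ann <- read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("symbol", "biotype"), names(ann))
  if (length(missing)) {
    stop("annotation table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(ann$symbol)) {
    stop("annotation table has duplicated symbol(s): ",
         paste(unique(ann$symbol[duplicated(ann$symbol)]), collapse = ", "),
         call. = FALSE)
  }
  ann
}

#' Check a screen dataset against its type invariants
#'
#' Violations are returned as data, not raised: real screens contain
#' failed wells and the pipeline excludes rather than rejects them.
#'
#' @param ds A `screen_dataset`.
#' @return data.frame with columns `plate_id`, `run_id`, `well`, `rule`,
#'   `detail`; zero rows iff the dataset is clean.
#' @export
validate_dataset <- function(ds) {
  stopifnot(inherits(ds, "screen_dataset"))
  w <- ds$wells
  out <- list()
  note <- function(idx, rule, detail) {
    if (!length(idx)) return(NULL)
    data.frame(plate_id = w$plate_id[idx], run_id = w$run_id[idx],
               well = well_a1(w$row[idx], w$col[idx]),
               rule = rule, detail = detail, stringsAsFactors = FALSE)
  }
  key <- paste(w$plate_id, w$run_id, w$row, w$col, sep = "\r")
  out$dup <- note(which(duplicated(key) | duplicated(key, fromLast = TRUE)),
                  "duplicate well", "same (plate, run, row, col) appears twice")
  out$pi <- note(which(w$n_pi_pos > w$n_nuclei), "pi_exceeds_nuclei",
                 "n_pi_pos > n_nuclei")
  out$empty <- note(which(w$n_nuclei == 0L), "empty well", "n_nuclei = 0")
  out$neg <- note(which(w$n_nuclei < 0L | w$n_pi_pos < 0L),
                  "negative count", "counts must be nonnegative")
  out$oob <- note(which(w$row < 0L | w$row >= nrow(ds$layout) |
                          w$col < 0L | w$col >= ncol(ds$layout)),
                  "outside layout", "coordinates exceed plate dimensions")
  res <- do.call(rbind, Filter(Negate(is.null), unname(out)))
  if (is.null(res)) {
    res <- data.frame(plate_id = character(), run_id = character(),
                      well = character(), rule = character(),
                      detail = character(), stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  res
}
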