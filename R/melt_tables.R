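# Domain containers and I/O for CETSA melting tables.
#
# A melting panel is one cell line's matrix of relative soluble abundances:
# one row per protein, one column per temperature of the heating series
# (by default 37-64 degrees C in 3-degree steps, columns T37 ... T64).

DEFAULT_TEMPERATURES <- c(37, 40, 43, 46, 49, 52, 55, 58, 61, 64)

#' Temperature grid of a CETSA heating series
#'
#' @param temperatures Numeric vector of temperatures in degrees Celsius,
#'   strictly increasing, length at least 2. Defaults to the canonical
#'   ten-point series 37, 40, ..., 64.
#' @return A `cetsa_grid` object (numeric vector with `T<temp>` labels).
#' @export
#' @examples
#' temperature_grid()
temperature_grid <- function(temperatures = DEFAULT_TEMPERATURES) {
  if (!is.numeric(temperatures) || length(temperatures) < 2L ||
      anyNA(temperatures)) {
    abort_cycletsa("`temperatures` must be a numeric vector of length >= 2.",
                   "cycletsa_argument_error")
  }
  if (any(diff(temperatures) <= 0)) {
    abort_cycletsa("Temperatures must be strictly increasing.",
                   "cycletsa_argument_error")
  }
  temperatures <- as.numeric(temperatures)
  names(temperatures) <- paste0("T", format(temperatures, trim = TRUE,
                                            drop0trailing = TRUE))
  structure(temperatures, class = "cetsa_grid")
}

grid_labels <- function(grid) names(unclass(grid))

#' @export
print.cetsa_grid <- function(x, ...) {
  cat(sprintf("<cetsa_grid> %d temperatures: %s (degrees C)\n", length(x),
              paste(unclass(x), collapse = ", ")))
  invisible(x)
}

same_grid <- function(a, b) {
  length(a) == length(b) && all(unclass(a) == unclass(b))
}

#' Single cell line melting panel
#'
#' Bundles one cell line's melting profiles into a validated container.
#'
#' @param cell_line Name of the cell line.
#' @param values Numeric matrix, one row per protein and one column per
#'   temperature; rownames are protein accessions.
#' @param grid A [temperature_grid()] matching `ncol(values)`.
#' @param nonnegative Require all abundances to be >= 0 (the invariant for
#'   experimental relative abundances). Model-predicted panels may switch
#'   this off because the decoder output layer is unbounded.
#' @return A `cetsa_panel` object.
#' @export
cell_line_panel <- function(cell_line, values, grid = temperature_grid(),
                            nonnegative = TRUE) {
  if (!is.character(cell_line) || length(cell_line) != 1L || !nzchar(cell_line)) {
    abort_cycletsa("`cell_line` must be a non-empty string.",
                   "cycletsa_argument_error")
  }
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (ncol(values) != length(grid)) {
    abort_cycletsa(
      sprintf("Panel has %d value columns but the grid has %d temperatures.",
              ncol(values), length(grid)),
      "cycletsa_grid_error")
  }
  acc <- rownames(values)
  if (nrow(values) > 0L && (is.null(acc) || any(!nzchar(acc)))) {
    abort_cycletsa("Every profile row must carry an accession rowname.",
                   "cycletsa_integrity_error")
  }
  if (anyDuplicated(acc)) {
    dup <- unique(acc[duplicated(acc)])
    abort_cycletsa(
      sprintf("Duplicate accession(s): %s.", paste(dup, collapse = ", ")),
      "cycletsa_integrity_error")
  }
  if (nrow(values) > 0L && any(!is.finite(values))) {
    abort_cycletsa("All abundances must be finite.", "cycletsa_integrity_error")
  }
  if (nonnegative && nrow(values) > 0L && any(values < 0)) {
    abort_cycletsa("All relative abundances must be >= 0.",
                   "cycletsa_integrity_error")
  }
  colnames(values) <- grid_labels(grid)
  structure(list(cell_line = cell_line, grid = grid, values = values),
            class = "cetsa_panel")
}

#' @export
print.cetsa_panel <- function(x, ...) {
  cat(sprintf("<cetsa_panel> %s: %d proteins x %d temperatures (%s)\n",
              x$cell_line, nrow(x$values), length(x$grid),
              paste(range(unclass(x$grid)), collapse = "-")))
  invisible(x)
}

#' Accessions of a panel
#' @param panel A `cetsa_panel`.
#' @return Character vector of protein accessions.
#' @export
panel_accessions <- function(panel) rownames(panel$values) %||% character()

detect_delim <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0L) return(",")
  if (grepl("\t", first, fixed = TRUE)) "\t" else ","
}

#' Read a wide CETSA melting table
#'
#' Reads a delimited table with an accession column and one numeric column per
#' temperature (default `T37` ... `T64`) into a [cell_line_panel()]. Rows with
#' missing abundance cells are dropped with a warning; non-numeric cells and
#' duplicate accessions are errors.
#'
#' @param path Path to a CSV or TSV file.
#' @param cell_line Cell-line name to attach to the panel.
#' @param temperature_columns Names of the abundance columns, in grid order.
#' @param accession_col Name of the accession column (default `"Accession"`).
#' @param delim Field delimiter; `NULL` auto-detects comma vs. tab.
#' @param nonnegative Require abundances to be >= 0 (the invariant for
#'   experimental tables); set to `FALSE` when reading model-predicted
#'   panels, whose values are unbounded.
#' @return A `cetsa_panel`.
#' @export
read_cetsa_table <- function(path, cell_line,
                             temperature_columns = grid_labels(temperature_grid()),
                             accession_col = "Accession",
                             delim = NULL, nonnegative = TRUE) {
  if (!file.exists(path)) {
    abort_cycletsa(sprintf("File not found: %s", path), "cycletsa_io_error")
  }
  delim <- delim %||% detect_delim(path)
  tab <- readr::read_delim(path, delim = delim,
                           col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE)
  missing_cols <- setdiff(c(accession_col, temperature_columns), names(tab))
  if (length(missing_cols) > 0L) {
    abort_cycletsa(
      sprintf("Missing column(s): %s.", paste(missing_cols, collapse = ", ")),
      "cycletsa_format_error")
  }
  acc <- as.character(tab[[accession_col]])
  raw <- as.matrix(tab[temperature_columns])
  num <- matrix(suppressWarnings(as.numeric(raw)), nrow = nrow(raw),
                ncol = ncol(raw), dimnames = dimnames(raw))
  bad <- which(is.na(num) & !is.na(raw) & nzchar(trimws(raw)), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    abort_cycletsa(
      sprintf("Non-numeric value '%s' at row %d, column %s.",
              raw[bad[1, 1], bad[1, 2]], bad[1, 1],
              temperature_columns[bad[1, 2]]),
      "cycletsa_parse_error")
  }
  if (anyDuplicated(acc)) {
    dup <- unique(acc[duplicated(acc)])
    abort_cycletsa(
      sprintf("Duplicate accession(s) in %s: %s.", path,
              paste(dup, collapse = ", ")),
      "cycletsa_integrity_error")
  }
  incomplete <- rowSums(is.na(num)) > 0L
  if (any(incomplete)) {
    rlang::warn(sprintf(
      "Dropped %d row(s) with missing abundance cells: %s.",
      sum(incomplete), paste(utils::head(acc[incomplete], 5L), collapse = ", ")))
    num <- num[!incomplete, , drop = FALSE]
    acc <- acc[!incomplete]
  }
  rownames(num) <- acc
  grid <- temperature_grid(as.numeric(sub("^T", "", temperature_columns)))
  cell_line_panel(cell_line, num, grid, nonnegative = nonnegative)
}

#' Write a melting panel to a delimited file
#'
#' Values are written with 6 significant digits by default;
#' `full_precision = TRUE` writes shortest round-trippable doubles so that
#' [read_cetsa_table()] reproduces the panel bit-for-bit.
#'
#' @param panel A `cetsa_panel`.
#' @param path Output path.
#' @param delim Field delimiter (`","` or `"\t"`).
#' @param digits Significant digits when not in full-precision mode.
#' @param full_precision Write full double precision.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path, delim = ",", digits = 6,
                        full_precision = FALSE) {
  stopifnot(inherits(panel, "cetsa_panel"))
  vals <- panel$values
  if (!full_precision) vals <- signif(vals, digits)
  df <- data.frame(Accession = panel_accessions(panel), vals,
                   check.names = FALSE, row.names = NULL)
  res <- tryCatch(
    readr::write_delim(df, path, delim = delim, progress = FALSE),
    error = function(e) {
      abort_cycletsa(sprintf("Cannot write panel to %s: %s", path,
                             conditionMessage(e)), "cycletsa_io_error")
    })
  invisible(path)
}

#' Aligned multi-cell-line panel collection
#'
#' Keeps a list of per-cell-line panels together with the lexicographically
#' sorted intersection of their protein accessions, which is the index over
#' which cross-cell-line training and evaluation operate.
#'
#' @param panels List of `cetsa_panel` objects with identical grids and
#'   distinct cell-line names.
#' @param split Optional named character vector assigning every common
#'   accession to `"train"` or `"test"`.
#' @param allow_empty Permit an empty common index (used when per-panel
#'   dropout legitimately empties the intersection).
#' @return A `cetsa_multipanel` object.
#' @export
multi_panel <- function(panels, split = NULL, allow_empty = FALSE) {
  if (!is.list(panels) || length(panels) < 1L ||
      !all(vapply(panels, inherits, logical(1), "cetsa_panel"))) {
    abort_cycletsa("`panels` must be a list of cetsa_panel objects.",
                   "cycletsa_argument_error")
  }
  nms <- vapply(panels, function(p) p$cell_line, character(1))
  if (anyDuplicated(nms)) {
    abort_cycletsa("Cell-line names must be distinct.",
                   "cycletsa_argument_error")
  }
  grid <- panels[[1L]]$grid
  for (p in panels[-1L]) {
    if (!same_grid(grid, p$grid)) {
      abort_cycletsa("All panels must share one temperature grid.",
                     "cycletsa_grid_error")
    }
  }
  common <- Reduce(intersect, lapply(panels, panel_accessions))
  if (length(common) == 0L && !allow_empty) {
    abort_cycletsa("The intersection of panel accessions is empty.",
                   "cycletsa_empty_common_error")
  }
  common <- sort_accessions(common)
  if (!is.null(split)) {
    if (!setequal(names(split), common) || length(split) != length(common) ||
        !all(split %in% c("train", "test"))) {
      abort_cycletsa(
        "`split` must assign exactly the common accessions to train/test.",
        "cycletsa_argument_error")
    }
    split <- split[common]
  }
  names(panels) <- nms
  structure(list(panels = panels, cell_lines = nms, grid = grid,
                 common_index = common, split = split),
            class = "cetsa_multipanel")
}

#' Intersect cell-line panels into an aligned collection
#'
#' @param panels List of at least two `cetsa_panel` objects on one grid.
#' @return A `cetsa_multipanel` whose `common_index` is the sorted
#'   intersection of all panels' accessions.
#' @export
intersect_panels <- function(panels) {
  if (!is.list(panels) || length(panels) < 2L) {
    abort_cycletsa("Need at least two panels to intersect.",
                   "cycletsa_argument_error")
  }
  multi_panel(panels)
}

#' @export
print.cetsa_multipanel <- function(x, ...) {
  cat(sprintf("<cetsa_multipanel> %d cell lines (%s), %d common proteins\n",
              length(x$panels), paste(x$cell_lines, collapse = ", "),
              length(x$common_index)))
  if (!is.null(x$split)) {
    cat(sprintf("  split: %d train / %d test\n",
                sum(x$split == "train"), sum(x$split == "test")))
  }
  invisible(x)
}

#' Randomly split the common proteins into train and test sets
#'
#' The train set size is `round(train_fraction * n)` with half-up rounding;
#' the assignment is a deterministic function of `seed`.
#'
#' @param multipanel A `cetsa_multipanel`.
#' @param train_fraction Proportion of common proteins assigned to training,
#'   strictly between 0 and 1 (default 0.7).
#' @param seed Integer seed.
#' @return The multipanel with its `split` field populated.
#' @export
split_dataset <- function(multipanel, train_fraction = 0.7, seed = 1L) {
  stopifnot(inherits(multipanel, "cetsa_multipanel"))
  if (!is_number(train_fraction) || train_fraction <= 0 || train_fraction >= 1) {
    abort_cycletsa("`train_fraction` must lie strictly between 0 and 1.",
                   "cycletsa_argument_error")
  }
  seed <- check_seed(seed)
  common <- multipanel$common_index
  n_train <- floor(train_fraction * length(common) + 0.5)
  train_acc <- withr::with_seed(seed, sample(common, n_train))
  split <- stats::setNames(rep("test", length(common)), common)
  split[train_acc] <- "train"
  multipanel$split <- split
  multipanel
}

#' Accessions belonging to one part of the split
#' @param multipanel A split `cetsa_multipanel`.
#' @param part `"train"` or `"test"`.
#' @return Character vector of accessions, in common-index order.
#' @export
split_accessions <- function(multipanel, part = c("train", "test")) {
  part <- match.arg(part)
  if (is.null(multipanel$split)) {
    abort_cycletsa("Multipanel has no split; call split_dataset() first.",
                   "cycletsa_data_error")
  }
  multipanel$common_index[multipanel$split == part]
}

# Aligned value matrix of one cell line over the given accessions.
panel_matrix <- function(multipanel, cell_line, accessions = NULL) {
  accessions <- accessions %||% multipanel$common_index
  multipanel$panels[[cell_line]]$values[accessions, , drop = FALSE]
}
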