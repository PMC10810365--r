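test_that("temperature grid validates its invariants", {
  g <- temperature_grid()
  expect_length(g, 10L)
  expect_equal(unclass(g)[[1]], 37)
  expect_error(temperature_grid(c(37, 37, 40)), class = "cycletsa_argument_error")
  expect_error(temperature_grid(50), class = "cycletsa_argument_error")
})

test_that("a written table reads back identically", {
  p <- tiny_panel()
  path <- withr::local_tempfile(fileext = ".csv")
  write_panel(p, path, full_precision = TRUE)
  q <- read_cetsa_table(path, "A")
  expect_equal(q$values, p$values)
  expect_equal(panel_accessions(q), panel_accessions(p))

  # irrational-ish value survives the full-precision round trip exactly
  p$values[1, 1] <- 0.123456789
  p$values[2, 2] <- 1 / 3
  write_panel(p, path, full_precision = TRUE)
  expect_identical(read_cetsa_table(path, "A")$values, p$values)

  # tab-delimited dialect is auto-detected
  write_panel(p, path, delim = "\t", full_precision = TRUE)
  expect_equal(read_cetsa_table(path, "A")$values, p$values)

  # an empty panel writes a header-only file that reads back as empty
  empty <- cell_line_panel("A", matrix(numeric(0), 0, 10))
  write_panel(empty, path)
  expect_equal(length(readLines(path)), 1L)
  expect_equal(nrow(read_cetsa_table(path, "A")$values), 0L)
})

test_that("malformed tables are rejected with informative errors", {
  p <- tiny_panel()
  path <- withr::local_tempfile(fileext = ".csv")
  write_panel(p, path)

  # missing temperature column
  tab <- readr::read_csv(path, show_col_types = FALSE)
  readr::write_csv(tab[setdiff(names(tab), "T55")], path)
  err <- expect_error(read_cetsa_table(path, "A"),
                      class = "cycletsa_format_error")
  expect_match(conditionMessage(err), "T55")

  # non-numeric cell names row and column
  write_panel(p, path)
  tab <- readr::read_csv(path, col_types = readr::cols(.default = "c"))
  tab$T40[2] <- "oops"
  readr::write_csv(tab, path)
  err <- expect_error(read_cetsa_table(path, "A"),
                      class = "cycletsa_parse_error")
  expect_match(conditionMessage(err), "row 2")
  expect_match(conditionMessage(err), "T40")

  # duplicate accession
  write_panel(p, path)
  tab <- readr::read_csv(path, show_col_types = FALSE)
  tab$Accession[2] <- "P1"
  readr::write_csv(tab, path)
  expect_error(read_cetsa_table(path, "A"),
               class = "cycletsa_integrity_error")

  # missing cells drop the row with a warning rather than imputing
  write_panel(p, path)
  tab <- readr::read_csv(path, col_types = readr::cols(.default = "c"))
  tab$T43[3] <- ""
  readr::write_csv(tab, path, na = "")
  expect_warning(q <- read_cetsa_table(path, "A"), "Dropped 1")
  expect_equal(panel_accessions(q), c("P1", "P2"))
})

test_that("panel intersection matches brute-force set intersection", {
  pa <- panel_with("A", c("P1", "P2", "P3"))
  pb <- panel_with("B", c("P2", "P3", "P4"))
  mp <- intersect_panels(list(pa, pb))
  expect_equal(mp$common_index, c("P2", "P3"))

  # identical accession sets: intersection is the full (sorted) set
  mp2 <- intersect_panels(list(pa, panel_with("B", c("P3", "P1", "P2"))))
  expect_equal(mp2$common_index, c("P1", "P2", "P3"))

  # three panels
  mp3 <- intersect_panels(list(panel_with("A", c("a", "b")),
                               panel_with("B", c("b", "c")),
                               panel_with("C", "b")))
  expect_equal(mp3$common_index, "b")

  # property: equals brute-force intersection on random accession sets
  withr::with_seed(42, {
    pool <- sprintf("Q%02d", 1:20)
    for (rep in 1:20) {
      sets <- lapply(1:3, function(i) sample(pool, sample(5:15, 1)))
      expected <- sort(Reduce(intersect, sets), method = "radix")
      if (length(expected) == 0) {
        expect_error(
          intersect_panels(lapply(seq_along(sets), function(i) {
            panel_with(LETTERS[i], sets[[i]])
          })),
          class = "cycletsa_empty_common_error")
      } else {
        mp <- intersect_panels(lapply(seq_along(sets), function(i) {
          panel_with(LETTERS[i], sets[[i]])
        }))
        expect_equal(mp$common_index, expected)
      }
    }
  })

  expect_error(intersect_panels(list(pa)), class = "cycletsa_argument_error")
  expect_error(
    intersect_panels(list(pa, cell_line_panel("B",
      matrix(0.5, 1, 9, dimnames = list("P2", NULL)),
      temperature_grid(seq(37, 61, by = 3))))),
    class = "cycletsa_grid_error")
})

test_that("train/test split is a seeded partition with half-up rounding", {
  mp <- intersect_panels(list(panel_with("A", sprintf("P%02d", 1:10)),
                              panel_with("B", sprintf("P%02d", 1:10))))
  sp <- split_dataset(mp, 0.7, seed = 5)
  expect_equal(sum(sp$split == "train"), 7)
  expect_equal(sum(sp$split == "test"), 3)
  expect_setequal(c(split_accessions(sp, "train"), split_accessions(sp, "test")),
                  mp$common_index)

  # determinism
  sp2 <- split_dataset(mp, 0.7, seed = 5)
  expect_identical(sp$split, sp2$split)
  sp3 <- split_dataset(mp, 0.7, seed = 6)
  expect_false(identical(sp$split, sp3$split))

  # the published panel size: 4860 common proteins at 70% -> 3402 / 1458
  expect_equal(floor(0.7 * 4860 + 0.5), 3402)
  big <- intersect_panels(list(panel_with("A", sprintf("P%04d", 1:4860)),
                               panel_with("B", sprintf("P%04d", 1:4860))))
  bs <- split_dataset(big, 0.7, seed = 1)
  expect_equal(sum(bs$split == "train"), 3402)
  expect_equal(sum(bs$split == "test"), 1458)

  expect_error(split_dataset(mp, 1.2), class = "cycletsa_argument_error")
  expect_error(split_dataset(mp, 0), class = "cycletsa_argument_error")
})

test_that("panel constructor enforces profile invariants", {
  vals <- matrix(0.5, 2, 10, dimnames = list(c("P1", "P2"), NULL))
  expect_s3_class(cell_line_panel("A", vals), "cetsa_panel")
  bad <- vals; bad[1, 1] <- -0.1
  expect_error(cell_line_panel("A", bad), class = "cycletsa_integrity_error")
  expect_silent(cell_line_panel("A", bad, nonnegative = FALSE))
  bad2 <- vals; bad2[1, 1] <- NaN
  expect_error(cell_line_panel("A", bad2), class = "cycletsa_integrity_error")
  expect_error(cell_line_panel("A", vals[, 1:9]), class = "cycletsa_grid_error")
  dup <- vals; rownames(dup) <- c("P1", "P1")
  expect_error(cell_line_panel("A", dup), class = "cycletsa_integrity_error")
})
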