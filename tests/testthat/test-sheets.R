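test_that("a workbook holds the eleven section worksheets", {
  dir <- withr::local_tempdir()
  write_sheets(generate_dataset("field_network", seed = 1), dir)
  files <- list.files(dir)
  expect_setequal(files, paste0(miappe_sections(), ".tsv"))
  expect_length(files, 11)
})

test_that("one row per record, headers from the field registry", {
  inv <- minimal_investigation()
  inv$studies[[1]]$observation_units <- list(
    miappe_observation_unit(id = "OU1", level = "plot",
                            biological_material_id = "BM1"),
    miappe_observation_unit(id = "OU2", level = "plot"),
    miappe_observation_unit(id = "OU3", level = "study"))
  dir <- withr::local_tempdir()
  write_sheets(build_dataset(inv), dir)
  ou <- readLines(file.path(dir, "Observation unit.tsv"))
  expect_length(ou, 1 + 3)
  expect_identical(strsplit(ou[1], "\t")[[1]],
                   c(miappe_field_registry()$header[
                     miappe_field_registry()$section == "Observation unit"],
                     "Study id"))
})

test_that("workbooks round-trip every scenario", {
  for (sc in synth_scenarios()) {
    d <- generate_dataset(sc, seed = 17)
    dir <- withr::local_tempdir()
    write_sheets(d, dir)
    expect_dataset_equal(d, read_sheets(dir))
  }
})

test_that("row order inside a sheet does not matter", {
  d <- generate_dataset("glasshouse_factorial", seed = 2)
  dir <- withr::local_tempdir()
  write_sheets(d, dir)
  f <- file.path(dir, "Observation unit.tsv")
  lines <- readLines(f)
  writeLines(c(lines[1], rev(lines[-1])), f)
  expect_dataset_equal(d, read_sheets(dir))
})

test_that("missing mandatory sheets and header mismatches are errors", {
  d <- generate_dataset("time_series", seed = 3)
  dir <- withr::local_tempdir()
  write_sheets(d, dir)
  file.remove(file.path(dir, "Study.tsv"))
  expect_error(read_sheets(dir), "missing mandatory sheet 'Study'")
  dir2 <- withr::local_tempdir()
  write_sheets(d, dir2)
  f <- file.path(dir2, "Sample.tsv")
  lines <- readLines(f)
  lines[1] <- sub("Sample ID", "Sample identifier", lines[1])
  writeLines(lines, f)
  expect_error(read_sheets(dir2), "header mismatch at column 'Sample ID'")
})

test_that("unknown sheets are ignored and extra columns preserved", {
  d <- generate_dataset("sensor_only", seed = 4)
  dir <- withr::local_tempdir()
  write_sheets(d, dir)
  writeLines("a\tb", file.path(dir, "Scratchpad.tsv"))
  f <- file.path(dir, "Person.tsv")
  lines <- readLines(f)
  writeLines(paste0(lines, "\t", c("Favourite colour", "green", "blue")), f)
  expect_message(d2 <- read_sheets(dir), "Scratchpad")
  expect_dataset_equal(d, d2)
  expect_identical(d2$provenance$extras$Person, "Favourite colour")
})

test_that("a hand-authored two-row workbook parses to the expected dataset", {
  dir <- withr::local_tempdir()
  headers_of <- function(section) {
    c(miappe_field_registry()$header[
      miappe_field_registry()$section == section],
      if (section != "Investigation") "Study id")
  }
  row_of <- function(section, values) {
    h <- headers_of(section)
    cells <- stats::setNames(rep("", length(h)), h)
    cells[names(values)] <- values
    paste(cells, collapse = "\t")
  }
  sheet <- function(section, ...) {
    writeLines(c(paste(headers_of(section), collapse = "\t"),
                 vapply(list(...), function(v) row_of(section, v),
                        character(1))),
               file.path(dir, paste0(section, ".tsv")))
  }
  sheet("Investigation",
        c("Investigation unique ID" = "inv-w",
          "Investigation title" = "Workbook investigation",
          "MIAPPE version" = "1.1"))
  sheet("Study",
        c("Study unique ID" = "stw", "Study title" = "Workbook study",
          "Geographic location (country)" = "Spain",
          "Observation unit level hierarchy" = "study; plot"))
  sheet("Biological material",
        c("Biological material ID" = "BMW1", "Organism" = "Vitis vinifera",
          "Organism accession" = "NCBITaxon:29760", "Study id" = "stw"))
  sheet("Observation unit",
        c("Observation unit ID" = "OUW1", "Observation unit level" = "plot",
          "Biological material ID" = "BMW1", "Study id" = "stw"),
        c("Observation unit ID" = "OUW2", "Observation unit level" = "study",
          "Study id" = "stw"))
  d <- read_sheets(dir)
  expected <- build_dataset(miappe_investigation(
    id = "inv-w", title = "Workbook investigation", miappe_version = "1.1",
    studies = list(miappe_study(
      id = "stw", title = "Workbook study",
      location = list(country = "Spain"),
      observation_unit_level_hierarchy = c("study", "plot"),
      biological_materials = list(miappe_biological_material(
        id = "BMW1",
        organism = ontology_ref("Vitis vinifera", "NCBITaxon:29760"))),
      observation_units = list(
        miappe_observation_unit(id = "OUW1", level = "plot",
                                biological_material_id = "BMW1"),
        miappe_observation_unit(id = "OUW2", level = "study"))))))
  expect_dataset_equal(d, expected)
})

test_that("values containing the list separator are rejected on write", {
  inv <- minimal_investigation()
  inv$studies[[1]]$description <- "before; after"
  expect_error(write_sheets(build_dataset(inv), withr::local_tempdir()),
               "reserved separator")
})

test_that("no registry field is absent from its written sheet header", {
  dir <- withr::local_tempdir()
  write_sheets(minimal_dataset(), dir)
  reg <- miappe_field_registry()
  for (section in miappe_sections()) {
    written <- strsplit(readLines(
      file.path(dir, paste0(section, ".tsv")))[1], "\t")[[1]]
    expect_true(all(reg$header[reg$section == section] %in% written),
                label = section)
  }
})
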