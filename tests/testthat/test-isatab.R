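read_lines_of <- function(dir, file) readLines(file.path(dir, file))

test_that("the growth protocol carries environment parameters", {
  d <- generate_dataset("glasshouse_factorial", seed = 1)  # 2 env parameters
  dir <- withr::local_tempdir()
  write_isatab(d, dir)
  ilines <- read_lines_of(dir, "i_investigation.txt")
  params_row <- grep("^Study Protocol Parameters Name\t", ilines, value = TRUE)
  growth_params <- strsplit(params_row, "\t")[[1]][2]
  expect_length(strsplit(growth_params, "; ", fixed = TRUE)[[1]], 2)
  names_row <- grep("^Study Protocol Name\t", ilines, value = TRUE)
  expect_match(names_row, "\tGrowth\t")
  expect_match(names_row, "\tPhenotyping\t")
})

test_that("each data file becomes exactly one assay file", {
  d <- generate_dataset("field_network", params = list(locations = 3), seed = 2)
  dir <- withr::local_tempdir()
  arch <- write_isatab(d, dir)
  n_dfs <- sum(vapply(d$investigation$studies,
                      function(s) length(s$data_files), integer(1)))
  expect_length(arch$assay_files, n_dfs)
  for (a in arch$assay_files) {
    tab <- read_lines_of(dir, a)
    header <- strsplit(tab[1], "\t")[[1]]
    j <- match("Raw Data File", header)
    links <- unique(vapply(strsplit(tab[-1], "\t"), `[[`, character(1), j))
    expect_length(links, 1)
  }
})

test_that("event types become protocols and occurrences events-file rows", {
  d <- generate_dataset("field_network", seed = 3)
  # 2 event types, one of them repeated: 3 occurrences total per study
  dir <- withr::local_tempdir()
  write_isatab(d, dir)
  ilines <- read_lines_of(dir, "i_investigation.txt")
  names_rows <- grep("^Study Protocol Name\t", ilines, value = TRUE)
  first <- strsplit(names_rows[1], "\t")[[1]]
  expect_length(grep("^Event: ", first), 2)
  ev_file <- sprintf("ev_%s.txt",
                     gsub("[^A-Za-z0-9]+", "_",
                          d$investigation$studies[[1]]$id))
  ev <- read_lines_of(dir, ev_file)
  expect_length(ev, 1 + 3)  # header + one row per occurrence
})

test_that("studies without samples link units straight to the data file", {
  d <- generate_dataset("forest_geo", seed = 4)  # no samples
  dir <- withr::local_tempdir()
  arch <- write_isatab(d, dir)
  header <- strsplit(read_lines_of(dir, arch$assay_files[[1]])[1], "\t")[[1]]
  expect_false("Extract Name" %in% header)
  expect_true(all(c("Sample Name", "Raw Data File") %in% header))
})

test_that("write/read round-trips every scenario", {
  for (sc in synth_scenarios()) {
    d <- generate_dataset(sc, seed = 8)
    dir <- withr::local_tempdir()
    write_isatab(d, dir)
    expect_dataset_equal(d, read_isatab(dir))
  }
})

test_that("writing refuses datasets with validation errors", {
  m <- mutate_dataset(mutation_base(), "REQ-DF-VERSION")
  expect_error(write_isatab(m, withr::local_tempdir()), "validation error")
})

test_that("a referenced but absent file is an error naming it", {
  d <- generate_dataset("time_series", seed = 5)
  dir <- withr::local_tempdir()
  write_isatab(d, dir)
  ev <- list.files(dir, pattern = "^ev_")
  file.remove(file.path(dir, ev))
  expect_error(read_isatab(dir), ev, fixed = TRUE)
  expect_error(read_isatab(withr::local_tempdir()), "i_investigation.txt")
})

test_that("cells with tabs or newlines are rejected rather than quoted", {
  inv <- minimal_investigation()
  inv$studies[[1]]$description <- "two\tcolumns"
  expect_error(write_isatab(build_dataset(inv), withr::local_tempdir()),
               "tab/newline")
})

test_that("a hand-written minimal archive parses to the expected dataset", {
  dir <- withr::local_tempdir()
  writeLines(c(
    "ONTOLOGY SOURCE REFERENCE",
    "Term Source Name\tMIAPPE",
    "INVESTIGATION",
    "Investigation Identifier\tinv-hand",
    "Investigation Title\tHand-authored archive",
    "Comment[MIAPPE: MIAPPE version]\t1.1",
    "INVESTIGATION PUBLICATIONS",
    "Investigation Publication DOI",
    "INVESTIGATION CONTACTS",
    "STUDY",
    "Study Identifier\tsh1",
    "Study Title\tHand study",
    "Study File Name\ts_sh1.txt",
    "Comment[MIAPPE: Trait definition file]\ttdf_sh1.txt",
    "Comment[MIAPPE: Geographic location (country)]\tPortugal",
    "Comment[MIAPPE: Observation unit level hierarchy]\tstudy; plot",
    "STUDY DESIGN DESCRIPTORS",
    "STUDY FACTORS",
    "STUDY ASSAYS",
    "Study Assay File Name\ta_sh1_1.txt",
    "Comment[MIAPPE: Data file link]\tobs.tsv",
    "Comment[MIAPPE: Data file description]\tObservations",
    "Comment[MIAPPE: Data file version]\t1.0",
    "STUDY PROTOCOLS",
    "Study Protocol Name\tGrowth\tPhenotyping",
    "STUDY CONTACTS"), file.path(dir, "i_investigation.txt"))
  writeLines(c(
    paste("Source Name", "Characteristics[Organism]", "Protocol REF",
          "Sample Name", "Comment[MIAPPE: Observation unit level]",
          sep = "\t"),
    paste("BMH1", "Quercus suber", "Growth", "OUH1", "plot", sep = "\t")),
    file.path(dir, "s_sh1.txt"))
  writeLines(paste(c("Variable ID", "Variable name", "Trait",
                     "Trait accession", "Method", "Method accession",
                     "Method description", "Method reference", "Scale",
                     "Scale accession", "Time scale"), collapse = "\t"),
             file.path(dir, "tdf_sh1.txt"))
  writeLines(c("Sample Name\tProtocol REF\tRaw Data File",
               "OUH1\tPhenotyping\tobs.tsv"),
             file.path(dir, "a_sh1_1.txt"))
  d <- read_isatab(dir)
  expected <- build_dataset(miappe_investigation(
    id = "inv-hand", title = "Hand-authored archive", miappe_version = "1.1",
    studies = list(miappe_study(
      id = "sh1", title = "Hand study",
      location = list(country = "Portugal"),
      observation_unit_level_hierarchy = c("study", "plot"),
      data_files = list(miappe_data_file("obs.tsv", "Observations", "1.0")),
      biological_materials = list(miappe_biological_material(
        id = "BMH1", organism = ontology_ref("Quercus suber"))),
      observation_units = list(miappe_observation_unit(
        id = "OUH1", level = "plot", biological_material_id = "BMH1"))))))
  expect_dataset_equal(d, expected)
})

test_that("every checklist field has exactly one place in the column map", {
  map <- isatab_column_map()
  reg <- miappe_field_registry()
  expect_identical(nrow(map), nrow(reg))
  expect_false(anyDuplicated(paste(map$section, map$header)) > 0)
  expect_true(all(nzchar(map$isatab)))
})
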