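test_that("a minimal valid dataset passes with no issues", {
  r <- miappe_validate(minimal_dataset())
  expect_identical(r$verdict, "PASS")
  expect_identical(r$error_count, 0L)
  expect_identical(r$warning_count, 0L)
})

test_that("an investigation without studies fails the study cardinality", {
  inv <- miappe_investigation(id = "inv0", title = "Empty", studies = list())
  r <- miappe_validate(build_dataset(inv))
  expect_identical(r$verdict, "FAIL")
  expect_true("CARD-INV-STUDY" %in% r$issues$rule_id)
  expect_identical(r$error_count, 1L)
})

test_that("a study without observation units warns but passes", {
  inv <- minimal_investigation()
  inv$studies[[1]]$observation_units <- list()
  inv$studies[[1]]$samples <- list()
  r <- miappe_validate(build_dataset(inv))
  expect_identical(r$verdict, "PASS")
  expect_true("CARD-STU-OU" %in% r$issues$rule_id)
  expect_identical(
    r$issues$severity[r$issues$rule_id == "CARD-STU-OU"], "WARNING")
})

test_that("required-field rules fire as errors", {
  inv <- minimal_investigation()
  inv$studies[[1]]$samples[[1]]$observation_unit_id <- NULL
  inv$studies[[1]]$biological_materials[[1]]$organism <- NULL
  inv$studies[[1]]$data_files <- list(miappe_data_file(
    link = "data.tsv", description = "obs"))  # no version
  r <- miappe_validate(build_dataset(inv))
  expect_identical(r$verdict, "FAIL")
  expect_true(all(c("CARD-SAM-OU", "REQ-BM-ORGANISM", "REQ-DF-VERSION")
                  %in% r$issues$rule_id))
})

test_that("value format checks catch bad dates, coordinates and terms", {
  inv <- minimal_investigation()
  inv$studies[[1]]$samples[[1]]$collection_date <- "2017-06-31"
  inv$studies[[1]]$locations[[1]]$geo <- list(latitude = 91, longitude = 3)
  inv$studies[[1]]$biological_materials[[1]]$organism$accession <-
    "not a curie"
  issues <- check_value_formats(build_dataset(inv))
  expect_true(all(c("FMT-DATE", "FMT-GEO", "FMT-CURIE") %in% issues$rule_id))
})

test_that("undeclared factor values on observation units are flagged", {
  inv <- minimal_investigation()
  inv$studies[[1]]$factors <- list(miappe_factor(
    type = "drought", values = c("rainfed", "irrigated")))
  inv$studies[[1]]$observation_units[[1]]$factor_values <-
    list(drought = "flooded")
  issues <- check_value_formats(build_dataset(inv))
  expect_true("FMT-FACTORVALUE" %in% issues$rule_id)
  # a declared value passes
  inv$studies[[1]]$observation_units[[1]]$factor_values <-
    list(drought = "rainfed")
  expect_false("FMT-FACTORVALUE" %in%
                 check_value_formats(build_dataset(inv))$rule_id)
})

test_that("ISO 8601 reduced precision is accepted, impossible dates are not", {
  inv <- minimal_investigation()
  inv$studies[[1]]$start_date <- "2016"
  inv$studies[[1]]$end_date <- "2017-11"
  inv$studies[[1]]$samples[[1]]$collection_date <- "2016-06-20T10:30:00Z"
  r <- miappe_validate(build_dataset(inv))
  expect_identical(r$error_count, 0L)
  expect_identical(r$warning_count, 0L)
  inv$studies[[1]]$end_date <- "2015-02-29"  # not a leap year
  r2 <- miappe_validate(build_dataset(inv))
  expect_true("FMT-DATE" %in% r2$issues$rule_id)
})

test_that("collection dates outside the study range only warn", {
  inv <- minimal_investigation()
  inv$studies[[1]]$start_date <- "2021-01-01"
  inv$studies[[1]]$end_date <- "2021-12-31"
  inv$studies[[1]]$samples[[1]]$collection_date <- "2022-03-01"
  r <- miappe_validate(build_dataset(inv))
  expect_identical(r$verdict, "PASS")
  expect_true("WARN-SAM-DATE" %in% r$issues$rule_id)
})

test_that("rule registry ids are unique and severities are ERROR/WARNING", {
  reg <- rule_registry()
  expect_false(anyDuplicated(reg$rule_id) > 0)
  expect_true(all(reg$severity %in% c("ERROR", "WARNING")))
  expect_identical(reg$severity[reg$rule_id == "CARD-INV-STUDY"], "ERROR")
  expect_identical(reg$severity[reg$rule_id == "CARD-STU-OU"], "WARNING")
})

test_that("reports are deterministic and serializable", {
  d <- build_dataset(miappe_investigation(id = "i", title = "t",
                                          studies = list()))
  r1 <- miappe_validate(d)
  r2 <- miappe_validate(d)
  expect_identical(report_to_tsv(r1), report_to_tsv(r2))
  expect_identical(as.character(report_to_json(r1)),
                   as.character(report_to_json(r2)))
  j <- jsonlite::fromJSON(report_to_json(r1))
  expect_identical(j$verdict, "FAIL")
  expect_identical(j$error_count, r1$error_count)
  # ordering key is (section, record_id, rule_id)
  iss <- miappe_validate(mutation_base())$issues
  key <- paste(iss$section, iss$record_id, iss$rule_id)
  expect_identical(key, sort(key, method = "radix"))
})

test_that("every issue a mutated dataset raises uses a registered rule", {
  base <- mutation_base()
  for (rid in c("REQ-PER-ROLE", "FMT-GEO", "UNIQ-ENV-PARAMETER")) {
    r <- miappe_validate(mutate_dataset(base, rid))
    expect_true(all(r$issues$rule_id %in% rule_registry()$rule_id))
  }
})
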