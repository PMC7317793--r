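test_that("direct field carries follow the section-to-object mapping", {
  inv <- minimal_investigation()
  inv$title <- "Drought network"
  docs <- to_brapi(build_dataset(inv))$documents
  expect_identical(docs$trials[[1]]$trialName, "Drought network")
  expect_identical(docs$trials[[1]]$trialDbId, "inv1")
  expect_length(docs$germplasm, 1)
  expect_identical(docs$germplasm[[1]]$germplasmDbId, "BM1")
  expect_identical(docs$samples[[1]]$observationUnitDbId, "OU1")
  expect_identical(docs$variables[[1]]$observationVariableDbId, "var1")
  expect_identical(docs$variables[[1]]$trait$traitName, "Plant height")
})

test_that("sections absent from BrAPI 1.3 ride under additionalInfo", {
  d <- generate_dataset("glasshouse_factorial", seed = 1)
  docs <- to_brapi(d)$documents
  ai <- docs$studies[[1]]$additionalInfo
  expect_length(ai[["miappe:environment"]], 2)
  expect_named(ai[["miappe:environment"]][[1]], c("parameter", "value"))
  expect_length(ai[["miappe:event"]],
                length(d$investigation$studies[[1]]$events))
})

test_that("each declared factor value becomes a treatment entry", {
  inv <- minimal_investigation()
  inv$studies[[1]]$factors <- list(miappe_factor(
    type = "nitrogen input level",
    values = c("high nitrogen input", "low nitrogen input",
               "no nitrogen inputs")))
  docs <- to_brapi(build_dataset(inv))$documents
  tr <- docs$studies[[1]]$treatments
  expect_length(tr, 3)
  expect_identical(vapply(tr, `[[`, character(1), "factor"),
                   rep("nitrogen input level", 3))
})

test_that("document sets round-trip through memory and disk", {
  for (sc in synth_scenarios()) {
    d <- generate_dataset(sc, seed = 21)
    expect_dataset_equal(d, from_brapi(to_brapi(d)))
  }
  d <- generate_dataset("field_network", seed = 22)
  dir <- withr::local_tempdir()
  write_brapi(to_brapi(d), dir)
  expect_true(file.exists(file.path(dir, "trials.json")))
  expect_dataset_equal(d, from_brapi(read_brapi(dir)))
})

test_that("dangling DbId references are an error naming the id", {
  d <- generate_dataset("time_series", seed = 2)
  docs <- to_brapi(d)
  docs$documents$samples <- list(list(sampleDbId = "sx",
                                      observationUnitDbId = "OU-GONE",
                                      studyDbId = "maize-time-series"))
  expect_error(from_brapi(docs), "OU-GONE")
  docs2 <- to_brapi(d)
  docs2$documents$observationunits[[1]]$germplasmDbId <- "BM-GONE"
  expect_error(from_brapi(docs2), "BM-GONE")
})

test_that("a canned BrAPI payload parses to the expected dataset", {
  docs <- structure(list(documents = list(
    trials = list(list(trialDbId = "trial-x", trialName = "Canned trial",
                       additionalInfo = list("miappe:MIAPPE version" = "1.1"))),
    studies = list(list(studyDbId = "study-x", studyName = "Canned study",
                        trialDbId = "trial-x",
                        location = list(countryName = "Poland"),
                        additionalInfo = list(
                          "miappe:Observation unit level hierarchy" =
                            "study; plot"))),
    contacts = list(),
    germplasm = list(list(germplasmDbId = "G-1", genus = "Hordeum",
                          studyDbIds = list("study-x"),
                          additionalInfo = list(
                            "miappe:Organism" = "Hordeum vulgare"))),
    observationunits = list(list(observationUnitDbId = "OU-1",
                                 observationLevel = "plot",
                                 germplasmDbId = "G-1",
                                 studyDbId = "study-x")),
    samples = list(), variables = list(), datalinks = list())),
    class = "brapi_document_set")
  expected <- build_dataset(miappe_investigation(
    id = "trial-x", title = "Canned trial", miappe_version = "1.1",
    studies = list(miappe_study(
      id = "study-x", title = "Canned study",
      location = list(country = "Poland"),
      observation_unit_level_hierarchy = c("study", "plot"),
      biological_materials = list(miappe_biological_material(
        id = "G-1", organism = ontology_ref("Hordeum vulgare"),
        genus = "Hordeum")),
      observation_units = list(miappe_observation_unit(
        id = "OU-1", level = "plot", biological_material_id = "G-1"))))))
  expect_dataset_equal(from_brapi(docs), expected)
})

test_that("the field map partitions the registry with miappe: fallbacks", {
  map <- brapi_field_map()
  reg <- miappe_field_registry()
  expect_identical(nrow(map), nrow(reg))
  expect_true(all(nzchar(map$brapi_key)))
  # every unnamed field is carried under a miappe:-prefixed additionalInfo key
  fallback <- grepl("additionalInfo\\.miappe:", map$brapi_key) |
    grepl("miappe:(environment|experimentalFactors|event)", map$brapi_key)
  named <- map$brapi_key[!fallback]
  expect_false(any(grepl("miappe:", named)))
  expect_true(all(c("trialDbId", "germplasmDbId", "observationUnitDbId",
                    "sampleDbId", "observationVariableDbId") %in% named))
})

test_that("export refuses datasets with validation errors", {
  m <- mutate_dataset(mutation_base(), "REQ-BM-ORGANISM")
  expect_error(to_brapi(m), "validation error")
})
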