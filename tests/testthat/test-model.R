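test_that("value types normalise and prune empty fields", {
  expect_null(ontology_ref("", ""))
  r <- ontology_ref("Zea mays", "NCBITaxon:4577")
  expect_identical(r$label, "Zea mays")
  expect_identical(r$accession, "NCBITaxon:4577")
  g <- geo_point(latitude = "45.5", longitude = 3)
  expect_identical(g$latitude, 45.5)
  expect_null(g$altitude)
  # empty string and absent are the same thing
  expect_identical(miappe_person(name = "A", email = "", role = "lead"),
                   miappe_person(name = "A", role = "lead"))
})

test_that("build_dataset indexes a minimal well-formed graph", {
  d <- minimal_dataset()
  n <- sum(vapply(d$index, length, integer(1)))
  # study + biological material + observation unit + sample + variable
  expect_identical(n, 5L)
  expect_identical(nrow(resolve_references(d)), 0L)
  expect_s3_class(d, "miappe_dataset")
})

test_that("duplicate differing identifiers are a construction error", {
  inv <- minimal_investigation()
  inv$studies[[1]]$observation_units <- c(
    inv$studies[[1]]$observation_units,
    list(miappe_observation_unit(id = "OU1", level = "study")))
  expect_error(build_dataset(inv), "duplicate observation unit id 'OU1'")
})

test_that("identical records may share an id across studies (shared lists)", {
  inv <- minimal_investigation()
  st2 <- inv$studies[[1]]
  st2$id <- "st2"
  st2$observation_units <- list()
  st2$samples <- list()
  inv$studies <- c(inv$studies, list(st2))
  d <- build_dataset(inv)
  expect_identical(length(d$index[["Biological material"]]), 1L)
  expect_setequal(d$owners[["Biological material"]][["BM1"]], c("st1", "st2"))
})

test_that("build_dataset does not mutate its input and is idempotent", {
  inv <- minimal_investigation()
  snapshot <- inv
  d1 <- build_dataset(inv)
  expect_identical(inv, snapshot)
  d2 <- build_dataset(inv)
  expect_identical(canonical_dataset(d1), canonical_dataset(d2))
})

test_that("resolve_references reports each dangling edge", {
  inv <- minimal_investigation()
  inv$studies[[1]]$samples[[1]]$observation_unit_id <- "OU9"
  refs <- resolve_references(build_dataset(inv))
  expect_identical(nrow(refs), 1L)
  expect_identical(refs$section, "Sample")
  expect_identical(refs$record_id, "SA1")
  expect_identical(refs$field, "observation_unit_id")
  expect_identical(refs$missing_id, "OU9")
})

test_that("reference graphs of generated datasets are closed across seeds", {
  for (sc in synth_scenarios()) {
    for (seed in c(1, 19, 404)) {
      d <- generate_dataset(sc, seed = seed)
      expect_identical(nrow(resolve_references(d)), 0L)
    }
  }
})

test_that("observation unit ancestry follows the declared level hierarchy", {
  inv <- miappe_investigation(
    id = "inv-h", title = "Hierarchy", studies = list(miappe_study(
      id = "sth", location = list(country = "France"),
      observation_unit_level_hierarchy = c("study", "genotype", "plot"),
      observation_units = list(
        miappe_observation_unit(id = "p1", level = "plot"),
        miappe_observation_unit(id = "top", level = "study"),
        miappe_observation_unit(id = "weird", level = "pot")))))
  d <- build_dataset(inv)
  expect_identical(observation_unit_ancestry(d, "p1"),
                   c("study", "genotype", "plot"))
  expect_identical(observation_unit_ancestry(d, "top"), "study")
  expect_error(observation_unit_ancestry(d, "weird"), "absent from hierarchy")
  expect_error(observation_unit_ancestry(d, "nope"), "unknown observation unit")
})

test_that("canonical form is invariant under record reordering", {
  inv <- minimal_investigation()
  inv2 <- inv
  inv2$studies[[1]]$observation_units <-
    rev(inv2$studies[[1]]$observation_units)
  inv2$studies[[1]]$biological_materials <- c(
    inv2$studies[[1]]$biological_materials,
    list(miappe_biological_material(id = "BM0",
                                    organism = ontology_ref("Zea mays"))))
  inv$studies[[1]]$biological_materials <- c(
    list(miappe_biological_material(id = "BM0",
                                    organism = ontology_ref("Zea mays"))),
    inv$studies[[1]]$biological_materials)
  expect_dataset_equal(build_dataset(inv), build_dataset(inv2))
})
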