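test_that("field networks have one study per location with shared lists", {
  d <- generate_dataset("field_network", params = list(locations = 3, years = 2),
                        seed = 42)
  inv <- d$investigation
  expect_length(inv$studies, 3)
  # shared biological material and variable lists across the network
  bm_ids <- lapply(inv$studies, function(s)
    vapply(s$biological_materials, `[[`, character(1), "id"))
  expect_true(all(vapply(bm_ids, identical, logical(1), bm_ids[[1]])))
  for (id in names(d$owners[["Biological material"]])) {
    expect_length(d$owners[["Biological material"]][[id]], 3)
  }
  # hierarchy and a study-level weather-station unit per study
  for (st in inv$studies) {
    expect_identical(st$observation_unit_level_hierarchy,
                     c("study", "genotype", "plot"))
    levels <- vapply(st$observation_units, `[[`, character(1), "level")
    expect_true("study" %in% levels)
    expect_true("plot" %in% levels)
  }
  # studies span several years
  st <- inv$studies[[1]]
  expect_true(substr(st$end_date, 1, 4) > substr(st$start_date, 1, 4))
})

test_that("forest trees are identified by coordinates alone", {
  d <- generate_dataset("forest_geo", params = list(trees = 10), seed = 1)
  bms <- d$investigation$studies[[1]]$biological_materials
  expect_length(bms, 10)
  for (bm in bms) {
    expect_false(is.null(bm$geo$latitude))
    expect_false(is.null(bm$geo$longitude))
    expect_null(bm$material_source$id)
    expect_null(bm$material_source$doi)
  }
  expect_identical(miappe_validate(d)$error_count, 0L)
})

test_that("factorial glasshouse units carry crossed declared factor values", {
  d <- generate_dataset("glasshouse_factorial", seed = 2)
  st <- d$investigation$studies[[1]]
  expect_gte(length(st$factors), 1)
  expect_true(all(vapply(st$factors, function(f) length(f$values) >= 2,
                         logical(1))))
  combos <- unique(vapply(st$observation_units, function(o)
    paste(unlist(o$factor_values), collapse = "|"), character(1)))
  expect_identical(length(combos),
                   as.integer(prod(vapply(st$factors,
                                          function(f) length(f$values),
                                          numeric(1)))))
})

test_that("time series use a thermal time scale and repeated events", {
  d <- generate_dataset("time_series", seed = 3)
  st <- d$investigation$studies[[1]]
  scales <- vapply(st$observed_variables, function(v)
    if (is.null(v$time_scale)) "" else v$time_scale, character(1))
  expect_true("growing degree days" %in% scales)
  keys <- vapply(st$events, function(e)
    paste(e$type$label, e$description), character(1))
  dates <- vapply(st$events, `[[`, character(1), "date")
  expect_identical(length(unique(keys)), 1L)
  expect_gte(length(unique(dates)), 3)
})

test_that("a sensor observation unit with no plant is still valid", {
  d <- generate_dataset("sensor_only", seed = 4)
  st <- d$investigation$studies[[1]]
  plantless <- Filter(function(o) is.null(o$biological_material_id),
                      st$observation_units)
  expect_length(plantless, 1)
  expect_identical(miappe_validate(d)$error_count, 0L)
})

test_that("crossing populations trace progeny to one parental cross", {
  d <- generate_dataset("crossing_population", params = list(progeny = 8),
                        seed = 5)
  bms <- d$investigation$studies[[1]]$biological_materials
  expect_length(bms, 8)
  expect_identical(length(unique(vapply(bms, `[[`, character(1), "id"))), 8L)
  sources <- unique(vapply(bms, function(b) b$material_source$id, character(1)))
  expect_length(sources, 1)
})

test_that("generation is a pure function of (scenario, params, seed)", {
  a <- generate_dataset("field_network", seed = 99)
  b <- generate_dataset("field_network", seed = 99)
  ja <- jsonlite::toJSON(canonical_dataset(a), auto_unbox = TRUE, digits = NA)
  jb <- jsonlite::toJSON(canonical_dataset(b), auto_unbox = TRUE, digits = NA)
  expect_identical(as.character(ja), as.character(jb))
  expect_identical(a$payloads, b$payloads)
  c <- generate_dataset("field_network", seed = 100)
  expect_false(identical(
    as.character(ja),
    as.character(jsonlite::toJSON(canonical_dataset(c), auto_unbox = TRUE,
                                  digits = NA))))
  expect_error(generate_dataset("space_station", seed = 1),
               "unknown scenario")
})

test_that("generation leaves the global RNG stream untouched", {
  set.seed(123)
  before <- .Random.seed
  invisible(generate_dataset("glasshouse_factorial", seed = 77))
  expect_identical(.Random.seed, before)
})

test_that("mutate introduces the targeted defect and nothing else", {
  base <- mutation_base()
  for (rid in rule_registry()$rule_id) {
    m <- mutate_dataset(base, rid)
    r <- miappe_validate(m)
    expect_true(rid %in% r$issues$rule_id, label = rid)
    other_errors <- setdiff(r$issues$rule_id[r$issues$severity == "ERROR"], rid)
    expect_identical(other_errors, character(0), label = rid)
  }
  expect_error(mutate_dataset(base, "NOT-A-RULE"), "unknown rule")
})

test_that("mutate refuses rules whose target section is absent", {
  lean <- generate_dataset("forest_geo", seed = 1)  # no samples, no events
  expect_error(mutate_dataset(lean, "CARD-SAM-OU"), "not mutable")
  expect_error(mutate_dataset(lean, "REQ-EV-DATE"), "not mutable")
})
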