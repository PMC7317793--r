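test_that("object properties connect instances per the data model", {
  d <- minimal_dataset()
  tr <- to_rdf(d, "https://example.org/m/")$triples
  ns <- "https://w3id.org/ppeo/terms#"
  expect_true(any(
    tr$subject == "https://example.org/m/observation_unit/OU1" &
      tr$predicate == paste0(ns, "hasBiologicalMaterial") &
      tr$object == "https://example.org/m/biological_material/BM1"))
  # exactly one hasStudy triple from the investigation
  expect_identical(sum(tr$predicate == paste0(ns, "hasStudy")), 1L)
  # sample collection date is a typed date literal
  cd <- tr[tr$predicate == paste0(ns, "hasSampleCollectionDate"), ]
  expect_identical(cd$object, "2021-06-01")
  expect_identical(cd$datatype, "http://www.w3.org/2001/XMLSchema#date")
  # every subject carries exactly one class
  types <- tr[grepl("type$", tr$predicate), ]
  expect_identical(anyDuplicated(types$subject), 0L)
  expect_setequal(unique(tr$subject), types$subject)
})

test_that("timestamped literals are typed as dateTime", {
  d <- generate_dataset("glasshouse_factorial", seed = 1)
  tr <- to_rdf(d)$triples
  cd <- tr[grepl("hasSampleCollectionDate$", tr$predicate), ]
  expect_true(all(cd$datatype == "http://www.w3.org/2001/XMLSchema#dateTime"))
  lat <- tr[grepl("hasGeographicLocationLatitude$", tr$predicate), ]
  expect_true(all(lat$datatype == "http://www.w3.org/2001/XMLSchema#decimal"))
})

test_that("a minimal dataset emits the independently counted triples", {
  # brute-force enumeration for the minimal fixture:
  # investigation: type + {id,title,version} literals + hasStudy        =  5
  # study: type + {id,title,hierarchy} + links to location, OU, BM,
  #        sample and variable                                          =  9
  # location node: type + country                                       =  2
  # biological material: type + id + organism label                     =  3
  # observation unit: type + id + level + hasBiologicalMaterial         =  4
  # sample: type + id + collection date + hasObservationUnit            =  4
  # variable: type + id + name + 3 component links                      =  6
  # trait/method/scale nodes: type + name each                          =  6
  expect_identical(nrow(to_rdf(minimal_dataset())$triples), 39L)
})

test_that("cardinality restrictions are re-checkable on the graph", {
  base <- generate_dataset("glasshouse_factorial", seed = 5)
  expect_identical(nrow(check_rdf_constraints(to_rdf(base))), 0L)
  for (rid in c("CARD-INV-STUDY", "CARD-SAM-OU", "CARD-STU-LOC")) {
    g <- check_rdf_constraints(to_rdf(mutate_dataset(base, rid)))
    expect_identical(nrow(g), 1L, label = rid)
  }
  # hand-mutated graph: a sample linking two observation units
  tr <- to_rdf(base)
  sample_subj <- tr$triples$subject[
    grepl("hasObservationUnit$", tr$triples$predicate) &
      grepl("/sample/", tr$triples$subject)][1]
  tr$triples <- rbind(tr$triples, data.frame(
    subject = sample_subj,
    predicate = "https://w3id.org/ppeo/terms#hasObservationUnit",
    object = "https://example.org/miappe/observation_unit/ghost",
    obj_type = "iri", datatype = "", stringsAsFactors = FALSE))
  v <- check_rdf_constraints(tr)
  expect_identical(v$restriction, "sample-exactly-1-observation-unit")
})

test_that("serialization is deterministic and formats are equivalent", {
  tr <- to_rdf(generate_dataset("field_network", seed = 13))
  t1 <- withr::local_tempfile(fileext = ".ttl")
  t2 <- withr::local_tempfile(fileext = ".ttl")
  j1 <- withr::local_tempfile(fileext = ".jsonld")
  write_rdf(tr, t1, "turtle")
  write_rdf(tr, t2, "turtle")
  expect_identical(readBin(t1, "raw", file.size(t1) + 10),
                   readBin(t2, "raw", file.size(t2) + 10))
  write_rdf(tr, j1, "jsonld")
  expect_identical(read_rdf(t1, "turtle")$triples,
                   read_rdf(j1, "jsonld")$triples)
  # parsing recovers the exact triple set
  expect_identical(read_rdf(t1, "turtle")$triples, tr$triples)
  expect_error(write_rdf(tr, t1, "n-quads"), "unknown RDF format")
})

test_that("literals with quotes, tabs and backslashes survive Turtle", {
  inv <- minimal_investigation()
  inv$description <- "a \"quoted\" value with back\\slash"
  tr <- to_rdf(build_dataset(inv))
  p <- withr::local_tempfile(fileext = ".ttl")
  write_rdf(tr, p, "turtle")
  expect_identical(read_rdf(p)$triples, tr$triples)
})

test_that("datasets rebuild from RDF in both formats", {
  for (sc in synth_scenarios()) {
    d <- generate_dataset(sc, seed = 31)
    expect_dataset_equal(d, from_rdf(to_rdf(d)))
  }
  d <- generate_dataset("sensor_only", seed = 32)
  p <- withr::local_tempfile(fileext = ".jsonld")
  write_rdf(to_rdf(d), p, "jsonld")
  expect_dataset_equal(d, from_rdf(read_rdf(p)))
})

test_that("a relative base IRI is rejected", {
  expect_error(to_rdf(minimal_dataset(), "not-an-iri"), "absolute IRI")
})

test_that("graph-level and checklist-level cardinality verdicts agree", {
  base <- mutation_base(seed = 41)
  card_rules <- c("CARD-INV-STUDY", "CARD-SAM-OU", "CARD-STU-LOC")
  for (rid in c(card_rules, "REQ-DF-VERSION", "WARN-SAM-DATE")) {
    m <- mutate_dataset(base, rid)
    rep <- miappe_validate(m)
    has_card_error <- any(rep$issues$rule_id %in% card_rules &
                            rep$issues$severity == "ERROR")
    graph_flags <- nrow(check_rdf_constraints(to_rdf(m))) > 0
    expect_identical(graph_flags, has_card_error, label = rid)
  }
})
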