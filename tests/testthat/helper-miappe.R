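# Shared fixtures, built in code.

# The smallest checklist-valid dataset: one study, one biological material,
# one observation unit, one sample, one observed variable.
minimal_investigation <- function() {
  miappe_investigation(
    id = "inv1", title = "Minimal maize investigation",
    miappe_version = "1.1",
    studies = list(miappe_study(
      id = "st1", title = "Minimal study",
      location = list(country = "France"),
      observation_unit_level_hierarchy = c("study", "plot"),
      biological_materials = list(miappe_biological_material(
        id = "BM1", organism = ontology_ref("Zea mays"))),
      observation_units = list(miappe_observation_unit(
        id = "OU1", level = "plot", biological_material_id = "BM1")),
      samples = list(miappe_sample(
        id = "SA1", observation_unit_id = "OU1",
        collection_date = "2021-06-01")),
      observed_variables = list(miappe_observed_variable(
        id = "var1", name = "PH_M_cm", trait = "Plant height",
        method = "Tape measure", scale = "cm")))))
}

minimal_dataset <- function() build_dataset(minimal_investigation())

expect_dataset_equal <- function(a, b) {
  expect_true(dataset_equal(a, b))
}

# rules whose defect requires a record the base dataset must carry; the
# field_network scenario exercises every section
mutation_base <- function(seed = 11) generate_dataset("field_network", seed = seed)
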