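# miappe

An R implementation of **MIAPPE 1.1** (Minimum Information About a Plant
Phenotyping Experiment), the community metadata standard for plant phenotyping
experiments. The package is aimed at data managers and phenotyping-platform
engineers who need to validate, exchange and convert experiment metadata, and
at tool developers who need a reference implementation of the standard's data
model to test against.

## What it provides

Plant phenotyping metadata is hard to standardise: experiments range from
multi-local, multi-year field networks over automated glasshouses to natural
forest stands where trees are identified only by their coordinates. MIAPPE 1.1
addresses this with an explicit data model of eleven sections — investigation,
study, person, data file, biological material, environment, experimental
factor, event, observation unit, sample and observed variable — connected by
typed references and governed by cardinality rules (an investigation **must**
have at least one study; a sample **must** derive from exactly one observation
unit; a study has exactly one location and **should** have observation units).
Observed variables follow the Crop Ontology decomposition into a *trait* (what
is measured), a *method* (how) and a *scale* (in which unit). Plant material
has two identification levels: the *biological material* used in the
experiment and its pre-experiment *material source*, each of which can carry
geographic coordinates — which is how forest trees without gene-bank
accessions are identified.

The package implements:

* **Model** — typed record constructors, a dataset container with a global
  identifier index, reference resolution and observation-unit level ancestry.
* **Validation** — a deterministic checklist validator with a stable rule
  registry (`rule_registry()`); MUST-level rules produce errors, SHOULD-level
  rules warnings. Reports serialize as TSV and JSON.
* **Four serializations**, all lossless and interconvertible:
  ISA-Tab archives (`write_isatab()` / `read_isatab()`), BrAPI v1.3-shaped
  JSON document sets (`to_brapi()` / `from_brapi()`), spreadsheet workbooks
  with one worksheet per section (`write_sheets()` / `read_sheets()`), and
  RDF instantiating the Plant Phenotyping Experiment Ontology
  (`to_rdf()` / `from_rdf()` with Turtle and JSON-LD on disk and a
  closed-world cardinality checker, `check_rdf_constraints()`).
* **A synthetic-data generator** (`generate_dataset()`) covering six hard
  archetypes: `field_network`, `forest_geo`, `glasshouse_factorial`,
  `time_series`, `sensor_only` and `crossing_population`, plus a mutation
  harness (`mutate_dataset()`) that injects exactly one checklist defect at a
  time.
* **A command line** (`miappe_cli()`, wrapped by `inst/cli/miappe.R`) with
  `validate`, `convert`, `generate` and `rules` subcommands.

## Worked example

```r
library(miappe)

# a multi-local, multi-year wheat field network with shared germplasm
d <- generate_dataset("field_network", params = list(locations = 3), seed = 42)
d
#> <miappe_dataset> doi:10.5072/miappe.field_network.42
#>   European wheat nitrogen field network
#>   Study                3
#>   Biological material  5
#>   Observation unit     33
#>   Sample               6
#>   Observed variable    4
#>   Data file            3

miappe_validate(d)
#> <miappe_report> PASS: 0 error(s), 0 warning(s)

# a plot-level unit sits below study and genotype in the level hierarchy
observation_unit_ancestry(d, d$investigation$studies[[1]]$observation_units[[2]]$id)
#> [1] "study"    "genotype" "plot"

# break one rule and watch the validator name it
m <- mutate_dataset(d, "REQ-DF-VERSION")
miappe_validate(m)
#> <miappe_report> FAIL: 1 error(s), 0 warning(s)
#>  severity        rule_id   section                               record_id
#>     ERROR REQ-DF-VERSION Data file data_wheat_network_clermont_ferrand.tsv
#>                   message
#>  data file has no version

# serialize, convert, round-trip
write_isatab(d, "archive/")                      # i_/s_/a_/tdf_/ev_ files
docs <- to_brapi(d)                              # BrAPI document set
dataset_equal(d, from_brapi(docs))
#> [1] TRUE
```

The counts above mean: three studies (one per location) share one list of
five wheat genotypes and four observed variables; each study has ten plot
units, a study-level weather-station unit, one data file and two flag-leaf
samples.

From a shell:

```sh
Rscript inst/cli/miappe.R generate field_network out/ --seed 42
Rscript inst/cli/miappe.R validate out/ --report report.json   # exit 0 = PASS
Rscript inst/cli/miappe.R convert out/ brapi/ --from isatab --to brapi --strict
Rscript inst/cli/miappe.R rules | head -4
```

## Package layout

* `R/` — model, validate, isatab, brapi, rdf, sheets, synth and cli modules;
  the field registry in `R/registry.R` is the single source of truth from
  which worksheet headers, ISA-Tab `Comment[MIAPPE: ...]` keys, BrAPI
  `additionalInfo` keys and PPEO predicates are derived.
* `vignettes/miappe-methods.Rmd` — the methods vignette: data model,
  validation semantics, serialization dialects, generator design and
  limitations.
* `tests/testthat/` — unit, property and acceptance suites.
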