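---
title: "MIAPPE 1.1 in R: data model, validation and serializations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MIAPPE 1.1 in R: data model, validation and serializations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(miappe)
```

## The problem

A plant phenotyping experiment is described by structurally heterogeneous
metadata: where and when it ran, which plant material it used and where that
material came from, which conditions were held constant, which were varied on
purpose, what happened during the experiment, what was observed on what, and
how. MIAPPE 1.1 organises this into eleven sections with explicit
cardinalities, and this package implements that data model as a typed object
graph, a checklist validator, and four interconvertible serializations. The
package does not touch observation data themselves: data files are opaque
payloads referenced by link, with the standard constraining only their
metadata (description, version) and their connection to observation units and
variables.

## The data model

The root object is the *investigation*, which owns one or more *studies* (a
MUST in the standard: the validator treats an investigation without studies
as an error). A study is one experiment at one location — the single-location
rule is part of the model — with a duration, design, growth-facility
description and optional cultural practices. Below the study sit the record
lists: data files, biological materials, environment parameters (constant per
study), experimental factors (deliberately varied, with a declared value
list), events (dated occurrences affecting the study or named units),
observation units, samples and observed variables.

Three modelling points deserve emphasis:

* **Observation units are hierarchical.** Each unit carries a level drawn
  from the study's declared level hierarchy (e.g. `study > genotype > plot`),
  and `observation_unit_ancestry()` returns a unit's path from the root. A
  unit need not contain a plant: a field sensor is a valid observation unit
  with no biological material, which is why the reference from unit to
  material is optional.
* **Plant material has two identification levels.** The *biological
  material* identifies material within the experiment; the *material source*
  identifies it before the experiment (gene bank accession, parental cross,
  wild stand). Both carry four geolocation fields (latitude, longitude,
  altitude, coordinate uncertainty), and identification by coordinates alone
  — the forest-tree case — is fully valid: no rule requires a material source
  when coordinates are present.
* **Observed variables decompose into trait, method and scale**, following
  the Crop Ontology model; all three component names are required, and each
  may carry an ontology accession. The optional time scale (e.g. "growing
  degree days") declares the time axis of repeated observations.

Identifiers are unique per section type across the whole dataset. Field
networks share one biological-material list and one variable list across
studies; the package represents this by allowing the *same* record (compared
field by field) to be listed by several studies, while two *different*
records under one identifier remain a construction error. This choice makes
cross-format conversion unambiguous: each identifier denotes exactly one
record everywhere.

Dates are ISO 8601 with reduced precision (`YYYY`, `YYYY-MM`, `YYYY-MM-DD`,
or a full timestamp with optional zone), because field trials frequently
record year-only dates. Coordinates are WGS84 decimal degrees with sign
encoding the hemisphere; out-of-range values are an error, never clamped.
Empty strings and absent fields are equivalent everywhere.

## Validation semantics

`miappe_validate()` evaluates the checklist and returns a deterministic
report: issues sorted by (section, record id, rule id, field), so the same
dataset always yields a byte-identical report. The severity mapping is
strict: MUST-level rules become errors, SHOULD-level rules become warnings,
and fields the standard leaves unqualified get no rule at all — the validator
never invents requirements. Two consequences of that policy: an experimental
factor needs a type and values but its description is optional, and a
sample collection date outside the study date range is only a warning
(storage and processing lags are plausible).

Ontology-term checks are syntactic only: an accession must look like a CURIE
(`PREFIX:ID`) or an absolute IRI. Resolving terms against ontology services
would make validation non-deterministic and network-dependent, and whether a
term really denotes a trait is out of scope.

The rule registry (`rule_registry()`) is part of the public contract: every
issue uses a registered rule id, and the synthetic-data module ships a
mutation harness (`mutate_dataset()`) that, for *each* registered rule,
injects exactly one defect violating it. Mutators suppress knock-on defects —
blanking a biological-material identifier also clears the now-dangling
optional references to it — so a mutated dataset's report contains the
targeted rule and no unrelated errors. This gives the validator a complete,
self-contained conformance suite.

## Serializations

All four formats are driven by one field registry
(`miappe_field_registry()`): one row per checklist field with its
human-readable name, its path in the model and its codec (text, number,
"; "-joined list, or "key: value" pairs). Because worksheet headers, ISA-Tab
comment keys, BrAPI `additionalInfo` keys and PPEO predicates are all derived
from this table, a field cannot be silently dropped from any format; the test
suite walks the registry against each format's map to enforce the partition.

**ISA-Tab.** The archive follows the Investigation/Study/Assay convention:
`i_investigation.txt`, one `s_<study>.txt` sample table per study, one assay
file per data file, a trait definition file per study and an events file for
studies with events. ISA Sources are biological materials, ISA Samples are
observation units and ISA Extracts are MIAPPE samples; where a study has no
samples, assay rows link units directly to the data file with no Extract
column. A protocol named "Growth" carries the cultural practices and declares
the environment parameters; one protocol per event type points to the
occurrences in the events file. MIAPPE-specific fields use
`Comment[MIAPPE: <checklist field name>]` keys so the reverse mapping is
mechanical. Cells may not contain tabs or newlines — the writer raises an
error rather than quoting, because quoting dialects for ISA-Tab are
inconsistent in the wild — and "; " is reserved as the in-cell list
separator, so leaf values may not contain ";". File names are slugs of study
identifiers, chosen for determinism and human readability.

**BrAPI.** The document set targets the v1.3 shape, the released version at
the time the mapping was drawn up, exchanged as one JSON array per collection
on disk (no HTTP layer, no pagination). Sections with a direct BrAPI object
map onto named keys; sections absent from BrAPI 1.3 — environment and event —
travel under `additionalInfo` as `miappe:environment` and `miappe:event`
lists, and every otherwise unmapped field is carried under an
`additionalInfo` key prefixed `miappe:`. DbIds equal MIAPPE identifiers
verbatim, which is what makes the mapping reversible. Declared factor values
additionally surface as `treatments` entries for BrAPI-side consumers; the
reader treats these as derived and reconstructs factors from the
`additionalInfo` record.

**Spreadsheet workbook.** One worksheet per section, headed by the checklist
field names — this is the biologist-facing format, so headers are
human-readable names, not slugs. The canonical on-disk form is a directory of
TSV files (one per worksheet, same headers); `.xlsx` workbooks are read
through readxl when installed. Parent-child links use a `Study id` column on
the child sheet; records shared across studies carry a "; "-joined id list.

**PPEO RDF.** Each section is a class and each field a data property; linked
field groups — trait, method, scale, material source and the study location —
are classes of their own grouped under the parent instance. Modelling the
location as a node (rather than literals on the study) is what makes the
exactly-one-location restriction expressible on the graph. Predicates are
camel-cased from the checklist field names under a single package namespace;
the published ontology IRIs are not hard-coded because they can be remapped
by prefix later without touching instance data. Instance IRIs are minted as
`<base>/<section-slug>/<percent-encoded id>`, with owner-scoped, zero-padded
indices for identifier-less records, so serialization is deterministic.
`check_rdf_constraints()` re-evaluates the cardinality restrictions
closed-world directly on the graph — open-world OWL reasoning cannot flag a
*missing* study, a closed-world count can — and agrees with the checklist
validator's cardinality verdicts by construction (a property the acceptance
suite verifies on valid and mutated graphs). Turtle output is one sorted
full-IRI triple per line; JSON-LD output is a sorted node array under the
shipped context. Both parse back to the exact triple set. Literal typing is
by rule: numbers are `xsd:decimal`; values of date-named fields are typed
`xsd:date` or `xsd:dateTime` by shape; everything else is a plain string, so
reduced-precision dates (a bare year) are never mis-typed.

## The synthetic-data generator

`generate_dataset(scenario, params, seed)` is a pure function: the same
triple always returns the identical dataset, and the global RNG stream is
left untouched. Six scenarios cover the modelling situations that stress the
standard:

| scenario | what it emulates | defaults |
|---|---|---|
| `field_network` | multi-local multi-year trial network; shared germplasm and variable lists; `study > genotype > plot` hierarchy; a study-level weather-station unit; nitrogen factor; repeated fertiliser events; leaf samples | 3 locations, 2 years, 5 genotypes, 2 plots each |
| `forest_geo` | natural stand; trees identified by coordinates only, no material source | 10 trees |
| `glasshouse_factorial` | automated glasshouse; drought x nitrogen crossed over pot units; environment setpoints | 4 genotypes, 2 replicates |
| `time_series` | one variable on a growing-degree-days time scale; one event type repeated at several timestamps | 4 plots, 3 repeats |
| `sensor_only` | an observation unit holding no plant | 1 sensor, 2 plots |
| `crossing_population` | progeny materials with unique ids tracing to one parental cross via the material source | 8 progeny |

The scenario defaults were chosen once as representative of small instances
of each design — a three-site network, a 32-pot factorial — and are the sizes
the test and acceptance suites run at; parameters scale the structure, not
the guarantees. Content (names, coordinates, dates) comes from fixed
vocabularies with seeded jitter inside plausible European agricultural
bounds; realism of the *values* is cosmetic, since the guarantee that matters
is structural: every generated dataset validates with zero errors, its
reference graph is closed, and it round-trips every serialization. Small TSV
observation tables ride along so ISA-Tab data-file references resolve; their
values are uniform noise, deliberately so — the package makes no claims about
phenotype distributions, and passing tests say nothing about statistical
properties of real data. Equally, generated metadata is cleaner than real
submissions: free-text fields are short and separator-free, identifiers are
well-formed, and vocabularies are consistent, so round-trip results here do
not prove robustness to the messiness of hand-authored archives (the test
suite covers hand-authored fixtures separately).

## Numerical and procedural choices

* Dataset equality is defined on a canonical form (`canonical_dataset()`):
  record lists sorted by identifier or by a stable natural key, event
  affected-unit sets sorted, empty fields pruned, provenance dropped.
  Numeric comparison uses a 1e-9 relative tolerance; coordinates are written
  with up to 15 significant digits, so round-trips are exact in practice.
* Validation report ordering is total: (section, record id, rule id, field),
  radix-sorted, so reports are byte-stable across platforms and locales.
* The ISA-Tab reader requires that duplicated sample definitions across assay
  files be identical, and errors otherwise; the first Growth protocol wins
  when reading environment parameters.
* Degenerate inputs: a study with zero observation units is valid (with a
  warning) and still round-trips, which is why environment parameter values
  are stored in the investigation file rather than as per-row parameter
  values in the study table; unreferenced biological materials are written as
  declaration-only rows (a Source with no Sample) for the same reason.
* The CLI maps outcomes to exit codes (0 pass, 1 validation errors, 2
  unreadable input or usage error) and prints human-readable text to stderr;
  only the exit codes are stable API.

## Known limitations

* The checklist's normative field-by-field requirement levels beyond those
  stated in the standard's text are treated as optional; the registry is this
  package's own complete field enumeration, not a copy of any external
  configuration.
* BrAPI coverage is the v1.3 shape; v2.x object names are not emitted. The
  key-level mapping for a few fields without an obvious v1.3 key (e.g. the
  material source DOI) deliberately sits under `additionalInfo`.
* The RDF dialect is self-contained: the parsers read what the writers
  produce (plus any graph using the same namespace discipline), not arbitrary
  Turtle or JSON-LD.
* Writing `.xlsx` is not supported; the TSV worksheet directory is the
  writable workbook form, and `.xlsx` is read-only via readxl.
* Samples may derive from any observation unit, including plant-free ones;
  the standard does not forbid it and neither does the validator.

## Problem sizes used by the shipped suites

The test suite and `scripts/acceptance.R` exercise: the full 37-rule mutation
harness on a field-network dataset; generator soundness over all six
scenarios at 10-12 seeds; round-trip identity over all scenarios times 20
seeds (tests) or 5 seeds (acceptance script) across the four serializations;
and cross-path conversion agreement per scenario. These sizes keep each suite
in the minutes range on one CPU while sweeping every scenario and every rule.
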