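# MIAPPE 1.1 object graph: one record type per checklist section plus the
# shared value types (ontology reference, geographic point). Records are plain
# nested lists in canonical (pruned) form; constructors normalise structure but
# deliberately do NOT enforce checklist rules -- that is the validator's job,
# so that defective datasets can be represented, validated and reported on.

#' Ontology term reference
#'
#' A controlled-vocabulary annotation: a human-readable label plus an optional
#' term accession, either a CURIE (`PREFIX:ID`) or an absolute IRI.
#'
#' @param label Free-text label.
#' @param accession Optional term reference string.
#' @return A list with elements `label` and `accession`, or `NULL` if both are
#'   empty.
#' @export
ontology_ref <- function(label = NULL, accession = NULL) {
  prune_record(list(label = norm_chr(label), accession = norm_chr(accession)))
}

#' Geographic point
#'
#' WGS84 decimal-degree coordinates with optional altitude (metres) and
#' coordinate uncertainty (metres). Out-of-range values are preserved and
#' flagged by [miappe_validate()], never clamped.
#'
#' @param latitude,longitude Decimal degrees.
#' @param altitude Metres above sea level.
#' @param coordinates_uncertainty Uncertainty radius in metres.
#' @return A list of the non-empty coordinate fields, or `NULL`.
#' @export
geo_point <- function(latitude = NULL, longitude = NULL, altitude = NULL,
                      coordinates_uncertainty = NULL) {
  prune_record(list(
    latitude = norm_num(latitude), longitude = norm_num(longitude),
    altitude = norm_num(altitude),
    coordinates_uncertainty = norm_num(coordinates_uncertainty)
  ))
}

#' @rdname miappe_record
#' @export
miappe_person <- function(name = NULL, email = NULL, orcid_or_id = NULL,
                          affiliation = NULL, role = NULL) {
  prune_record(list(name = norm_chr(name), email = norm_chr(email),
                    orcid_or_id = norm_chr(orcid_or_id),
                    affiliation = norm_chr(affiliation), role = norm_chr(role)))
}

#' @rdname miappe_record
#' @export
miappe_data_file <- function(link = NULL, description = NULL, version = NULL) {
  prune_record(list(link = norm_chr(link), description = norm_chr(description),
                    version = norm_chr(version)))
}

#' @rdname miappe_record
#' @export
miappe_biological_material <- function(id = NULL, organism = NULL, genus = NULL,
                                       species = NULL, infraspecific_name = NULL,
                                       geo = NULL, preprocessing = NULL,
                                       material_source = NULL) {
  prune_record(list(
    id = norm_chr(id), organism = organism, genus = norm_chr(genus),
    species = norm_chr(species),
    infraspecific_name = norm_chr(infraspecific_name), geo = geo,
    preprocessing = norm_chr(preprocessing), material_source = material_source
  ))
}

#' @rdname miappe_record
#' @export
material_source <- function(id = NULL, doi = NULL, geo = NULL,
                            description = NULL) {
  prune_record(list(id = norm_chr(id), doi = norm_chr(doi), geo = geo,
                    description = norm_chr(description)))
}

#' @rdname miappe_record
#' @export
miappe_environment <- function(parameter = NULL, value = NULL) {
  prune_record(list(parameter = norm_chr(parameter), value = norm_chr(value)))
}

#' @rdname miappe_record
#' @export
miappe_factor <- function(type = NULL, description = NULL, values = NULL) {
  if (is.character(type)) type <- ontology_ref(label = type)
  prune_record(list(type = type, description = norm_chr(description),
                    values = if (is_blank(values)) NULL else as.character(values)))
}

#' @rdname miappe_record
#' @export
miappe_event <- function(type = NULL, description = NULL, date = NULL,
                         affected_units = NULL) {
  if (is.character(type)) type <- ontology_ref(label = type)
  prune_record(list(type = type, description = norm_chr(description),
                    date = norm_chr(date),
                    affected_units = if (is_blank(affected_units)) NULL else
                      as.character(affected_units)))
}

#' @rdname miappe_record
#' @export
miappe_observation_unit <- function(id = NULL, level = NULL,
                                    biological_material_id = NULL,
                                    external_ref = NULL,
                                    spatial_distribution = NULL,
                                    factor_values = NULL) {
  prune_record(list(
    id = norm_chr(id), level = norm_chr(level),
    biological_material_id = norm_chr(biological_material_id),
    external_ref = norm_chr(external_ref),
    spatial_distribution = spatial_distribution,
    factor_values = factor_values
  ))
}

#' @rdname miappe_record
#' @export
miappe_sample <- function(id = NULL, observation_unit_id = NULL,
                          description = NULL, plant_anatomical_entity = NULL,
                          plant_structure_development_stage = NULL,
                          collection_date = NULL, external_id = NULL) {
  prune_record(list(
    id = norm_chr(id), observation_unit_id = norm_chr(observation_unit_id),
    description = norm_chr(description),
    plant_anatomical_entity = plant_anatomical_entity,
    plant_structure_development_stage = plant_structure_development_stage,
    collection_date = norm_chr(collection_date),
    external_id = norm_chr(external_id)
  ))
}

#' @rdname miappe_record
#' @export
miappe_observed_variable <- function(id = NULL, name = NULL, trait = NULL,
                                     method = NULL, scale = NULL,
                                     time_scale = NULL) {
  as_part <- function(x) {
    if (is.character(x)) list(name = x) else x
  }
  prune_record(list(id = norm_chr(id), name = norm_chr(name),
                    trait = as_part(trait), method = as_part(method),
                    scale = as_part(scale), time_scale = norm_chr(time_scale)))
}

#' MIAPPE record constructors
#'
#' Build the per-section records of the MIAPPE 1.1 data model. Constructors
#' normalise empty strings to absent fields and prune empty sub-structures;
#' they do not enforce checklist rules.
#'
#' @param id,name,email,orcid_or_id,affiliation,role,link,description,version
#'   Text fields; see the checklist section documentation.
#' @param organism,type,plant_anatomical_entity,plant_structure_development_stage
#'   [ontology_ref()] values (a bare string is taken as a label).
#' @param geo A [geo_point()].
#' @param genus,species,infraspecific_name,preprocessing,parameter,value,date,
#'   level,biological_material_id,external_ref,observation_unit_id,
#'   collection_date,external_id,time_scale,doi Text fields.
#' @param material_source A [material_source()] block.
#' @param values,affected_units Character vectors.
#' @param spatial_distribution,factor_values Named lists of key-value text
#'   pairs.
#' @param trait,method,scale Named lists (`name`, `accession`, ...); a bare
#'   string is taken as the component name.
#' @name miappe_record
NULL

#' @rdname miappe_record
#' @param location A study location block: named list with optional `country`,
#'   `site_name` and `geo` ([geo_point()]) entries. Exactly one location is
#'   required per study by the checklist.
#' @param title,start_date,end_date,contact_institution,cultural_practices Text.
#' @param experimental_design Named list `description`/`type`/`map`.
#' @param growth_facility Named list `description`/`type`.
#' @param observation_unit_level_hierarchy Ordered character vector of level
#'   names, root first (e.g. `c("study", "genotype", "plot")`).
#' @param data_files,biological_materials,environments,factors,events,
#'   observation_units,samples,observed_variables,persons Lists of records.
#' @export
miappe_study <- function(id = NULL, title = NULL, description = NULL,
                         start_date = NULL, end_date = NULL,
                         contact_institution = NULL, location = NULL,
                         experimental_design = NULL, growth_facility = NULL,
                         cultural_practices = NULL,
                         observation_unit_level_hierarchy = NULL,
                         data_files = list(), biological_materials = list(),
                         environments = list(), factors = list(),
                         events = list(), observation_units = list(),
                         samples = list(), observed_variables = list(),
                         persons = list()) {
  st <- list(
    id = norm_chr(id), title = norm_chr(title),
    description = norm_chr(description), start_date = norm_chr(start_date),
    end_date = norm_chr(end_date),
    contact_institution = norm_chr(contact_institution),
    locations = if (is.null(location)) list() else list(prune_record(location) %||% list()),
    experimental_design = prune_record(experimental_design),
    growth_facility = prune_record(growth_facility),
    cultural_practices = norm_chr(cultural_practices),
    observation_unit_level_hierarchy =
      if (is_blank(observation_unit_level_hierarchy)) NULL else
        as.character(observation_unit_level_hierarchy),
    data_files = data_files, biological_materials = biological_materials,
    environments = environments, factors = factors, events = events,
    observation_units = observation_units, samples = samples,
    observed_variables = observed_variables, persons = persons
  )
  st[!vapply(st, is.null, logical(1))]
}

#' @rdname miappe_record
#' @param submission_date,public_release_date ISO 8601 dates.
#' @param license Licence text.
#' @param miappe_version MIAPPE version literal, `"1.1"`.
#' @param publications Character vector of DOIs or citations.
#' @param studies List of [miappe_study()] records.
#' @export
miappe_investigation <- function(id = NULL, title = NULL, description = NULL,
                                 submission_date = NULL,
                                 public_release_date = NULL, license = NULL,
                                 miappe_version = "1.1", publications = NULL,
                                 persons = list(), studies = list()) {
  inv <- list(
    id = norm_chr(id), title = norm_chr(title),
    description = norm_chr(description),
    submission_date = norm_chr(submission_date),
    public_release_date = norm_chr(public_release_date),
    license = norm_chr(license), miappe_version = norm_chr(miappe_version),
    publications = if (is_blank(publications)) NULL else
      as.character(publications),
    persons = persons, studies = studies
  )
  inv[!vapply(inv, is.null, logical(1))]
}

# -- dataset ------------------------------------------------------------------

# sections carrying dataset-global unique identifiers, with the id field used
id_sections <- function() {
  c("Study" = "id", "Biological material" = "id", "Observation unit" = "id",
    "Sample" = "id", "Observed variable" = "id", "Data file" = "link")
}

study_records <- function(study, section) {
  slot <- c("Data file" = "data_files",
            "Biological material" = "biological_materials",
            "Environment" = "environments",
            "Experimental factor" = "factors", "Event" = "events",
            "Observation unit" = "observation_units", "Sample" = "samples",
            "Observed variable" = "observed_variables", "Person" = "persons")
  study[[slot[[section]]]] %||% list()
}

#' Build an indexed MIAPPE dataset
#'
#' Wraps an investigation into a dataset with an id-to-record index for every
#' identifier-bearing section type. Identifiers must be unique per section
#' type across the dataset; the same identifier may recur in several studies
#' only when the records are identical, which is how shared biological-material
#' and observed-variable lists of multi-study field networks are represented.
#' Checklist rules are not checked here (see [miappe_validate()]).
#'
#' @param investigation A [miappe_investigation()].
#' @param provenance Optional source-format tag and file manifest.
#' @return An object of class `miappe_dataset`.
#' @export
build_dataset <- function(investigation, provenance = NULL) {
  stopifnot(is.list(investigation))
  index <- list()
  owners <- list()
  for (section in names(id_sections())) {
    index[[section]] <- list()
    owners[[section]] <- list()
  }
  add <- function(section, rec, owner) {
    key <- rec[[id_sections()[[section]]]]
    if (is_blank(key)) return(invisible())  # missing ids are a validator issue
    key <- key[[1]]
    prev <- index[[section]][[key]]
    if (!is.null(prev) && !identical(prune_record(prev), prune_record(rec))) {
      stop(sprintf(
        "duplicate %s id '%s': two differing records share this identifier",
        tolower(section), key), call. = FALSE)
    }
    index[[section]][[key]] <<- rec
    owners[[section]][[key]] <<- unique(c(owners[[section]][[key]], owner))
    invisible()
  }
  for (st in investigation$studies %||% list()) {
    add("Study", st, investigation$id %||% "-")
    sid <- st$id %||% "-"
    for (section in setdiff(names(id_sections()), "Study")) {
      for (rec in study_records(st, section)) add(section, rec, sid)
    }
  }
  structure(list(investigation = investigation, index = index,
                 owners = owners, provenance = provenance),
            class = "miappe_dataset")
}

#' @export
print.miappe_dataset <- function(x, ...) {
  inv <- x$investigation
  cat("<miappe_dataset>", inv$id %||% "(no id)", "\n")
  cat("  ", inv$title %||% "", "\n", sep = "")
  counts <- vapply(names(id_sections()),
                   function(s) length(x$index[[s]]), integer(1))
  for (s in names(counts)) cat(sprintf("  %-20s %d\n", s, counts[[s]]))
  invisible(x)
}

dataset_studies <- function(dataset) dataset$investigation$studies %||% list()

#' Report unresolved cross-references
#'
#' Walks every reference edge of the object graph (sample to observation unit,
#' observation unit to biological material, event to affected observation
#' units) and reports each dangling reference. An empty result means the graph
#' is closed.
#'
#' @param dataset A [build_dataset()] result.
#' @return A data.frame with columns `section`, `record_id`, `field`,
#'   `missing_id`, one row per dangling reference.
#' @export
resolve_references <- function(dataset) {
  out <- list()
  note <- function(section, rid, field, missing) {
    out[[length(out) + 1]] <<- data.frame(
      section = section, record_id = rid, field = field, missing_id = missing,
      stringsAsFactors = FALSE)
  }
  ou_ids <- names(dataset$index[["Observation unit"]])
  bm_ids <- names(dataset$index[["Biological material"]])
  for (st in dataset_studies(dataset)) {
    for (ou in study_records(st, "Observation unit")) {
      ref <- ou$biological_material_id
      if (!is_blank(ref) && !(ref %in% bm_ids)) {
        note("Observation unit", ou$id %||% "-", "biological_material_id", ref)
      }
    }
    for (sm in study_records(st, "Sample")) {
      for (ref in sm$observation_unit_id %||% character(0)) {
        if (!is_blank(ref) && !(ref %in% ou_ids)) {
          note("Sample", sm$id %||% "-", "observation_unit_id", ref)
        }
      }
    }
    for (i in seq_along(study_records(st, "Event"))) {
      ev <- study_records(st, "Event")[[i]]
      for (ref in ev$affected_units %||% character(0)) {
        if (!is_blank(ref) && !(ref %in% ou_ids)) {
          note("Event", sprintf("%s#%d", st$id %||% "-", i),
               "affected_units", ref)
        }
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(section = character(0), record_id = character(0),
                      field = character(0), missing_id = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Observation-unit level ancestry
#'
#' Observation-unit levels are hierarchical, from the whole study down to the
#' single plant. Returns the path of the unit's level within its study's
#' declared hierarchy, root first.
#'
#' @param dataset A `miappe_dataset`.
#' @param ou_id Observation-unit identifier.
#' @return Character vector of level names from the hierarchy root down to the
#'   unit's level.
#' @export
observation_unit_ancestry <- function(dataset, ou_id) {
  ou <- dataset$index[["Observation unit"]][[ou_id]]
  if (is.null(ou)) stop(sprintf("unknown observation unit '%s'", ou_id),
                        call. = FALSE)
  sid <- dataset$owners[["Observation unit"]][[ou_id]][[1]]
  st <- dataset$index[["Study"]][[sid]]
  hier <- st$observation_unit_level_hierarchy
  if (is_blank(hier)) {
    stop(sprintf("study '%s' declares no observation unit level hierarchy",
                 sid), call. = FALSE)
  }
  pos <- match(ou$level, hier)
  if (is.na(pos)) {
    stop(sprintf(
      "observation unit '%s' has level '%s' absent from hierarchy [%s]",
      ou_id, ou$level %||% "", paste(hier, collapse = " > ")), call. = FALSE)
  }
  hier[seq_len(pos)]
}

# -- canonical form and equality ---------------------------------------------

sort_records <- function(recs, keyf) {
  if (length(recs) == 0) return(list())
  keys <- vapply(recs, keyf, character(1))
  recs[order(keys, method = "radix")]
}

canonical_study <- function(st) {
  st <- prune_record(st) %||% list()
  st$data_files <- sort_records(st$data_files %||% list(),
                                function(r) r$link %||% "")
  st$biological_materials <- sort_records(st$biological_materials %||% list(),
                                          function(r) r$id %||% "")
  st$environments <- sort_records(st$environments %||% list(),
                                  function(r) r$parameter %||% "")
  st$factors <- sort_records(st$factors %||% list(),
                             function(r) r$type$label %||% "")
  st$events <- lapply(st$events %||% list(), function(e) {
    # affected units form a set; order them for comparison
    if (!is.null(e$affected_units)) {
      e$affected_units <- sort(e$affected_units, method = "radix")
    }
    e
  })
  st$events <- sort_records(st$events, function(r)
    paste(r$type$label %||% "", r$date %||% ""))
  st$observation_units <- sort_records(st$observation_units %||% list(),
                                       function(r) r$id %||% "")
  st$samples <- sort_records(st$samples %||% list(), function(r) r$id %||% "")
  st$observed_variables <- sort_records(st$observed_variables %||% list(),
                                        function(r) r$id %||% "")
  st$persons <- sort_records(st$persons %||% list(), function(r)
    paste(r$name %||% "", r$role %||% ""))
  # canonical slot order, empty lists dropped
  slots <- c("id", "title", "description", "start_date", "end_date",
             "contact_institution", "locations", "experimental_design",
             "growth_facility", "cultural_practices",
             "observation_unit_level_hierarchy", "data_files",
             "biological_materials", "environments", "factors", "events",
             "observation_units", "samples", "observed_variables", "persons")
  st <- st[intersect(slots, names(st))]
  st[!vapply(st, function(v) is.list(v) && length(v) == 0, logical(1))]
}

#' Canonical form of a dataset
#'
#' Returns the dataset's object graph as a plain nested list in canonical
#' order: record lists sorted by identifier (or by a stable natural key for
#' identifier-less sections), empty fields pruned, provenance dropped. Two
#' datasets are considered equal modulo ordering iff their canonical forms are
#' equal; all round-trip guarantees of the format modules are stated in these
#' terms.
#'
#' @param dataset A `miappe_dataset`.
#' @return A nested list.
#' @export
canonical_dataset <- function(dataset) {
  inv <- prune_record(dataset$investigation) %||% list()
  studies <- lapply(inv$studies %||% list(), canonical_study)
  inv$studies <- sort_records(studies, function(s) s$id %||% "")
  inv$persons <- sort_records(inv$persons %||% list(), function(r)
    paste(r$name %||% "", r$role %||% ""))
  slots <- c("id", "title", "description", "submission_date",
             "public_release_date", "license", "miappe_version",
             "publications", "persons", "studies")
  inv <- inv[intersect(slots, names(inv))]
  inv[!vapply(inv, function(v) is.list(v) && length(v) == 0, logical(1))]
}

#' Test dataset equality modulo ordering
#'
#' @param a,b `miappe_dataset` objects.
#' @return `TRUE` or `FALSE`.
#' @export
dataset_equal <- function(a, b) {
  isTRUE(all.equal(canonical_dataset(a), canonical_dataset(b),
                   tolerance = 1e-9))
}
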