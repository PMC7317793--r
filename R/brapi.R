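# BrAPI v1.3-shaped JSON document sets. Sections with a direct BrAPI object
# (trial, study, contact, germplasm, observation unit, sample, variable,
# data link) map onto named keys; sections absent from BrAPI 1.3
# (environment, event) and MIAPPE-only fields ride under additionalInfo with
# keys prefixed "miappe:", so the mapping is a lossless partition of the
# field registry. DbIds equal MIAPPE identifiers verbatim for reversibility.
# Documents are exchanged as one JSON array per collection on disk; there is
# no HTTP layer.

brapi_collections <- function() {
  c("trials", "studies", "contacts", "germplasm", "observationunits",
    "samples", "variables", "datalinks")
}

# header -> named BrAPI key (dot path inside the document); unlisted headers
# are carried as additionalInfo["miappe:<header>"] flat strings
brapi_named_keys <- function(section) {
  switch(section,
    "Investigation" = c("Investigation unique ID" = "trialDbId",
                        "Investigation title" = "trialName"),
    "Study" = c("Study unique ID" = "studyDbId",
                "Study title" = "studyName",
                "Study description" = "studyDescription",
                "Start date of study" = "startDate",
                "End date of study" = "endDate",
                "Geographic location (country)" = "location.countryName",
                "Experimental site name" = "location.locationName",
                "Geographic location (latitude)" = "location.latitude",
                "Geographic location (longitude)" = "location.longitude",
                "Geographic location (altitude)" = "location.altitude"),
    "Person" = c("Person name" = "name", "Person email" = "email",
                 "Person affiliation" = "instituteName",
                 "Person role" = "type"),
    "Data file" = c("Data file link" = "url",
                    "Data file description" = "description",
                    "Data file version" = "version"),
    "Biological material" = c(
      "Biological material ID" = "germplasmDbId", "Genus" = "genus",
      "Species" = "species", "Infraspecific name" = "subtaxa",
      "Biological material latitude" = "germplasmOrigin.latitude",
      "Biological material longitude" = "germplasmOrigin.longitude",
      "Biological material altitude" = "germplasmOrigin.altitude",
      "Biological material coordinates uncertainty" =
        "germplasmOrigin.coordinateUncertainty"),
    "Observation unit" = c("Observation unit ID" = "observationUnitDbId",
                           "Observation unit level" = "observationLevel",
                           "Biological material ID" = "germplasmDbId"),
    "Sample" = c("Sample ID" = "sampleDbId",
                 "Observation unit ID" = "observationUnitDbId",
                 "Sample collection date" = "sampleTimestamp",
                 "Plant anatomical entity" = "plantAnatomicalEntity",
                 "Plant structure development stage" =
                   "plantStructureDevelopmentStage",
                 "Sample description" = "notes"),
    "Observed variable" = c("Variable ID" = "observationVariableDbId",
                            "Variable name" = "observationVariableName",
                            "Trait" = "trait.traitName",
                            "Trait accession" = "trait.traitDbId",
                            "Method" = "method.methodName",
                            "Method accession" = "method.methodDbId",
                            "Method description" = "method.description",
                            "Method reference" = "method.reference",
                            "Scale" = "scale.scaleName",
                            "Scale accession" = "scale.scaleDbId"),
    c())
}

#' BrAPI field map
#'
#' The shipped configuration table mapping every MIAPPE checklist field to its
#' place in the BrAPI document set: a named BrAPI key, or an
#' `additionalInfo` key prefixed `miappe:` for fields (and whole sections,
#' e.g. environment and event) absent from BrAPI v1.3. Together with
#' [miappe_field_registry()] this is a complete partition: no field is
#' dropped.
#'
#' @return A data.frame with columns `section`, `header`, `brapi_key`.
#' @export
brapi_field_map <- function() {
  reg <- miappe_field_registry()
  key <- character(nrow(reg))
  for (i in seq_len(nrow(reg))) {
    named <- brapi_named_keys(reg$section[i])
    key[i] <- if (reg$section[i] == "Environment") {
      "studies[].additionalInfo.miappe:environment[]"
    } else if (reg$section[i] == "Experimental factor") {
      "studies[].additionalInfo.miappe:experimentalFactors[]"
    } else if (reg$section[i] == "Event") {
      "studies[].additionalInfo.miappe:event[]"
    } else if (reg$header[i] %in% names(named)) {
      named[[reg$header[i]]]
    } else {
      sprintf("additionalInfo.miappe:%s", reg$header[i])
    }
  }
  data.frame(section = reg$section, header = reg$header, brapi_key = key,
             stringsAsFactors = FALSE)
}

# flatten a record into a BrAPI document: named keys (numbers kept numeric)
# plus additionalInfo for the rest
brapi_doc <- function(record, section, skip = character(0)) {
  reg <- registry_for(section)
  named <- brapi_named_keys(section)
  flat <- record_flatten(record, section)
  doc <- list()
  for (i in seq_len(nrow(reg))) {
    h <- reg$header[i]
    if (h %in% skip || flat[[h]] == "") next
    if (h %in% names(named)) {
      v <- if (reg$kind[i] == "num") as.numeric(flat[[h]]) else flat[[h]]
      doc <- path_set(doc, named[[h]], v)
    } else {
      doc[["additionalInfo"]][[sprintf("miappe:%s", h)]] <- flat[[h]]
    }
  }
  doc
}

# inverse: BrAPI document -> model record via the registry
brapi_row <- function(doc, section) {
  reg <- registry_for(section)
  named <- brapi_named_keys(section)
  row <- list()
  for (i in seq_len(nrow(reg))) {
    h <- reg$header[i]
    v <- if (h %in% names(named)) {
      path_get(doc, named[[h]])
    } else {
      doc[["additionalInfo"]][[sprintf("miappe:%s", h)]]
    }
    if (!is_blank(v)) row[[h]] <- v
  }
  record_unflatten(row, section)
}

treatments_of <- function(factor_values) {
  out <- list()
  for (k in names(factor_values %||% list())) {
    out[[length(out) + 1]] <- list(factor = k,
                                   modality = factor_values[[k]])
  }
  out
}

#' Convert a dataset to a BrAPI document set
#'
#' Maps the investigation to a trial, studies to studies, persons to
#' contacts, data files to data links, biological materials to germplasm,
#' observation units, samples and observed variables to their namesake BrAPI
#' objects. Experimental factors additionally surface as `treatments` entries
#' (one per declared value on the study, one per applied value on each
#' observation unit); environment parameters and events, absent from BrAPI
#' v1.3, travel under `additionalInfo` as `miappe:environment` and
#' `miappe:event` lists. Germplasm and variables shared by several studies
#' carry a `studyDbIds` array.
#'
#' @param dataset A `miappe_dataset` passing validation with zero errors.
#' @return A `brapi_document_set`.
#' @export
to_brapi <- function(dataset) {
  rep <- miappe_validate(dataset)
  if (rep$error_count > 0) {
    stop(sprintf("refusing BrAPI export: dataset has %d validation error(s)",
                 rep$error_count), call. = FALSE)
  }
  inv <- dataset$investigation
  docs <- stats::setNames(vector("list", length(brapi_collections())),
                          brapi_collections())
  trial <- brapi_doc(inv, "Investigation")
  trial$studies <- lapply(dataset_studies(dataset), function(st) {
    list(studyDbId = st$id %||% "", studyName = st$title %||% "")
  })
  docs$trials <- list(trial)
  contact_n <- 0
  add_contact <- function(p, trial_id, study_id) {
    contact_n <<- contact_n + 1
    doc <- brapi_doc(p, "Person")
    doc$contactDbId <- sprintf("contact%03d", contact_n)
    if (!is.null(trial_id)) doc$trialDbId <- trial_id
    if (!is.null(study_id)) doc$studyDbId <- study_id
    docs$contacts[[length(docs$contacts) + 1]] <<- doc
  }
  for (p in inv$persons %||% list()) add_contact(p, inv$id %||% "", NULL)
  bm_owner <- dataset$owners[["Biological material"]]
  var_owner <- dataset$owners[["Observed variable"]]
  for (st in dataset_studies(dataset)) {
    sid <- st$id %||% ""
    sdoc <- brapi_doc(st, "Study")
    sdoc$trialDbId <- inv$id %||% ""
    envs <- lapply(st$environments %||% list(), function(e) {
      list(parameter = e$parameter %||% "", value = e$value %||% "")
    })
    if (length(envs)) sdoc$additionalInfo[["miappe:environment"]] <- envs
    facs <- lapply(st$factors %||% list(), function(f) {
      as.list(Filter(nzchar, record_flatten(f, "Experimental factor")))
    })
    if (length(facs)) {
      sdoc$additionalInfo[["miappe:experimentalFactors"]] <- facs
      tr <- list()
      for (f in st$factors) {
        for (v in f$values %||% character(0)) {
          tr[[length(tr) + 1]] <- list(factor = f$type$label %||% "",
                                       modality = v)
        }
      }
      sdoc$treatments <- tr
    }
    evs <- lapply(st$events %||% list(), function(e) {
      as.list(Filter(nzchar, record_flatten(e, "Event")))
    })
    if (length(evs)) sdoc$additionalInfo[["miappe:event"]] <- evs
    docs$studies[[length(docs$studies) + 1]] <- sdoc
    for (p in st$persons %||% list()) add_contact(p, NULL, sid)
    for (df in st$data_files %||% list()) {
      doc <- brapi_doc(df, "Data file")
      doc$studyDbId <- sid
      docs$datalinks[[length(docs$datalinks) + 1]] <- doc
    }
    for (ou in st$observation_units %||% list()) {
      doc <- brapi_doc(ou, "Observation unit")
      doc$studyDbId <- sid
      sp <- ou$spatial_distribution %||% list()
      if (!is.null(sp$X)) doc$positionCoordinateX <- sp$X
      if (!is.null(sp$Y)) doc$positionCoordinateY <- sp$Y
      tr <- treatments_of(ou$factor_values)
      if (length(tr)) doc$treatments <- tr
      docs$observationunits[[length(docs$observationunits) + 1]] <- doc
    }
    for (sm in st$samples %||% list()) {
      doc <- brapi_doc(sm, "Sample")
      doc$studyDbId <- sid
      docs$samples[[length(docs$samples) + 1]] <- doc
    }
  }
  for (id in names(dataset$index[["Biological material"]])) {
    doc <- brapi_doc(dataset$index[["Biological material"]][[id]],
                     "Biological material")
    doc$studyDbIds <- I(sort(bm_owner[[id]]))
    docs$germplasm[[length(docs$germplasm) + 1]] <- doc
  }
  for (id in names(dataset$index[["Observed variable"]])) {
    doc <- brapi_doc(dataset$index[["Observed variable"]][[id]],
                     "Observed variable")
    doc$studyDbIds <- I(sort(var_owner[[id]]))
    docs$variables[[length(docs$variables) + 1]] <- doc
  }
  for (coll in brapi_collections()) docs[[coll]] <- docs[[coll]] %||% list()
  structure(list(documents = docs), class = "brapi_document_set")
}

#' Rebuild a dataset from a BrAPI document set
#'
#' Inverts [to_brapi()], recovering environment and event sections from
#' `additionalInfo`. Cross-document identifiers must resolve within the set;
#' a dangling DbId reference is an error naming the missing identifier.
#'
#' @param docs A `brapi_document_set`.
#' @return A `miappe_dataset`.
#' @export
from_brapi <- function(docs) {
  d <- docs$documents
  sval <- function(x) if (is_blank(x)) NULL else as.character(x)[[1]]
  trial <- d$trials[[1]] %||% list()
  ou_ids <- vapply(d$observationunits %||% list(),
                   function(x) sval(x$observationUnitDbId) %||% "", character(1))
  germ_ids <- vapply(d$germplasm %||% list(),
                     function(x) sval(x$germplasmDbId) %||% "", character(1))
  study_ids <- vapply(d$studies %||% list(),
                      function(x) sval(x$studyDbId) %||% "", character(1))
  for (sm in d$samples %||% list()) {
    ref <- sval(sm$observationUnitDbId)
    if (!is.null(ref) && !(ref %in% ou_ids)) {
      stop(sprintf("dangling observationUnitDbId '%s' in sample '%s'",
                   ref, sval(sm$sampleDbId) %||% "?"), call. = FALSE)
    }
  }
  for (ou in d$observationunits %||% list()) {
    ref <- sval(ou$germplasmDbId)
    if (!is.null(ref) && !(ref %in% germ_ids)) {
      stop(sprintf("dangling germplasmDbId '%s' in observation unit '%s'",
                   ref, sval(ou$observationUnitDbId) %||% "?"), call. = FALSE)
    }
  }
  persons_for <- function(study_id) {
    out <- list()
    for (ct in d$contacts %||% list()) {
      owner <- sval(ct$studyDbId)
      if (identical(owner, study_id) ||
          (is.null(owner) && is.null(study_id))) {
        out[[length(out) + 1]] <- brapi_row(ct, "Person")
      }
    }
    out
  }
  owned <- function(coll, study_id) {
    Filter(function(x) identical(sval(x$studyDbId), study_id),
           d[[coll]] %||% list())
  }
  shared <- function(coll, study_id) {
    Filter(function(x) {
      study_id %in% as.character(unlist(x$studyDbIds %||% list()))
    }, d[[coll]] %||% list())
  }
  studies <- lapply(d$studies %||% list(), function(sdoc) {
    sid <- sval(sdoc$studyDbId)
    st <- brapi_row(sdoc, "Study")
    ai <- sdoc$additionalInfo %||% list()
    environments <- lapply(ai[["miappe:environment"]] %||% list(), function(e) {
      miappe_environment(sval(e$parameter), sval(e$value))
    })
    factors <- lapply(ai[["miappe:experimentalFactors"]] %||% list(),
                      function(f) record_unflatten(f, "Experimental factor"))
    events <- lapply(ai[["miappe:event"]] %||% list(),
                     function(e) record_unflatten(e, "Event"))
    dfs <- lapply(owned("datalinks", sid),
                  function(x) brapi_row(x, "Data file"))
    ous <- lapply(owned("observationunits", sid),
                  function(x) brapi_row(x, "Observation unit"))
    sms <- lapply(owned("samples", sid), function(x) brapi_row(x, "Sample"))
    bms <- lapply(shared("germplasm", sid),
                  function(x) brapi_row(x, "Biological material"))
    vars <- lapply(shared("variables", sid),
                   function(x) brapi_row(x, "Observed variable"))
    miappe_study(
      id = st$id, title = st$title, description = st$description,
      start_date = st$start_date, end_date = st$end_date,
      contact_institution = st$contact_institution,
      location = if (length(st$locations %||% list()) >= 1)
        st$locations[[1]] else NULL,
      experimental_design = st$experimental_design,
      growth_facility = st$growth_facility,
      cultural_practices = st$cultural_practices,
      observation_unit_level_hierarchy = st$observation_unit_level_hierarchy,
      data_files = dfs, biological_materials = bms,
      environments = environments, factors = factors, events = events,
      observation_units = ous, samples = sms, observed_variables = vars,
      persons = persons_for(sid))
  })
  inv_row <- brapi_row(trial, "Investigation")
  inv <- miappe_investigation(
    id = inv_row$id, title = inv_row$title, description = inv_row$description,
    submission_date = inv_row$submission_date,
    public_release_date = inv_row$public_release_date,
    license = inv_row$license, miappe_version = inv_row$miappe_version,
    publications = inv_row$publications,
    persons = persons_for(NULL), studies = studies)
  build_dataset(inv, provenance = list(format = "brapi"))
}

#' Write/read a BrAPI document set on disk
#'
#' One UTF-8 JSON array per collection (`trials.json`, `studies.json`, ...),
#' with deterministic key order.
#'
#' @param docs A `brapi_document_set`.
#' @param dir Target directory.
#' @return `write_brapi` the directory (invisibly); `read_brapi` a
#'   `brapi_document_set`.
#' @export
write_brapi <- function(docs, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (coll in brapi_collections()) {
    jsonlite::write_json(docs$documents[[coll]] %||% list(),
                         file.path(dir, paste0(coll, ".json")),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         null = "null")
  }
  invisible(dir)
}

#' @rdname write_brapi
#' @export
read_brapi <- function(dir) {
  if (!file.exists(file.path(dir, "trials.json"))) {
    stop(sprintf("no trials.json in %s: not a BrAPI document set", dir),
         call. = FALSE)
  }
  docs <- list()
  for (coll in brapi_collections()) {
    p <- file.path(dir, paste0(coll, ".json"))
    docs[[coll]] <- if (file.exists(p)) {
      jsonlite::fromJSON(p, simplifyVector = FALSE)
    } else list()
  }
  structure(list(documents = docs), class = "brapi_document_set")
}
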