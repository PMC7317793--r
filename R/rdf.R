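# RDF instantiation of the data model under PPEO-style class and property
# names. Each checklist section is a class; linked field groups (trait,
# method, scale, material source, location) are classes of their own, grouped
# under their parent instance. Predicate names are camel-cased from the
# checklist field names under a single package namespace; a prefix remap is
# possible later since the published ontology IRIs are not hard-coded.
# Serialization is a deterministic dialect: sorted full-IRI triples in Turtle,
# a sorted node array in JSON-LD with a shipped context. Constraint checking
# is closed-world at the instance level (open-world reasoning cannot flag a
# missing study; a closed-world count can).

PPEO_NS <- "https://w3id.org/ppeo/terms#"
RDF_TYPE <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#type"
XSD_NS <- "http://www.w3.org/2001/XMLSchema#"

ppeo_class_of <- function(section) {
  c("Investigation" = "Investigation", "Study" = "Study", "Person" = "Person",
    "Data file" = "DataFile", "Biological material" = "BiologicalMaterial",
    "Environment" = "Environment",
    "Experimental factor" = "ExperimentalFactor", "Event" = "Event",
    "Observation unit" = "ObservationUnit", "Sample" = "Sample",
    "Observed variable" = "ObservedVariable")[[section]]
}

ppeo_section_slug <- function(section) {
  gsub(" ", "_", tolower(section))
}

iri_encode <- function(id) utils::URLencode(id, reserved = TRUE)

iri_decode_local <- function(iri) utils::URLdecode(basename(iri))

# registry rows routed to a sub-node of the owning record
rdf_node_of <- function(section, path) {
  if (section == "Biological material" && startsWith(path, "material_source."))
    return("material_source")
  if (section == "Study" && startsWith(path, "locations.1."))
    return("location")
  if (section == "Observed variable") {
    if (startsWith(path, "trait.")) return("trait")
    if (startsWith(path, "method.")) return("method")
    if (startsWith(path, "scale.")) return("scale")
  }
  "self"
}

# fields serialized as object links rather than literals
rdf_linked_headers <- function() {
  data.frame(
    section = c("Observation unit", "Sample", "Event"),
    header = c("Biological material ID", "Observation unit ID",
               "Affected observation units"),
    stringsAsFactors = FALSE)
}

rdf_predicate_of <- function(header) {
  special <- c("Trait" = "hasTraitName", "Method" = "hasMethodName",
               "Scale" = "hasScaleName")
  if (header %in% names(special)) return(paste0(PPEO_NS, special[[header]]))
  paste0(PPEO_NS, predicate_for_header(header))
}

#' PPEO property map
#'
#' One row per checklist field: the PPEO class hosting it (either the section
#' class itself or a grouped sub-class such as Trait or MaterialSource), the
#' predicate IRI, and the registry path it round-trips to. Link fields
#' (observation unit to biological material, sample to observation unit,
#' event to affected units) are object properties and excluded here.
#'
#' @return A data.frame with columns `section`, `header`, `path`, `kind`,
#'   `node`, `predicate`.
#' @export
ppeo_property_map <- function() {
  memo_table("ppeo_property_map", build_ppeo_property_map())
}

build_ppeo_property_map <- function() {
  reg <- miappe_field_registry()
  linked <- rdf_linked_headers()
  keep <- !mapply(function(s, h) any(linked$section == s & linked$header == h),
                  reg$section, reg$header)
  reg <- reg[keep, , drop = FALSE]
  reg$node <- mapply(rdf_node_of, reg$section, reg$path)
  reg$predicate <- vapply(reg$header, rdf_predicate_of, character(1))
  rownames(reg) <- NULL
  reg
}

rdf_literal_datatype <- function(header, kind, value) {
  if (kind == "num") return(paste0(XSD_NS, "decimal"))
  if (grepl("date", tolower(header), fixed = TRUE)) {
    if (grepl("^\\d{4}-\\d{2}-\\d{2}T", value)) return(paste0(XSD_NS, "dateTime"))
    if (grepl("^\\d{4}-\\d{2}-\\d{2}$", value)) return(paste0(XSD_NS, "date"))
  }
  ""
}

new_triple_frame <- function() {
  data.frame(subject = character(0), predicate = character(0),
             object = character(0), obj_type = character(0),
             datatype = character(0), stringsAsFactors = FALSE)
}

triple_rows_to_frame <- function(rows) {
  if (length(rows) == 0) return(new_triple_frame())
  m <- do.call(rbind, rows)
  data.frame(subject = m[, 1], predicate = m[, 2], object = m[, 3],
             obj_type = m[, 4], datatype = m[, 5], stringsAsFactors = FALSE)
}

sort_triples <- function(tr) {
  tr <- unique(tr)
  tr <- tr[order(tr$subject, tr$predicate, tr$object, method = "radix"), ,
           drop = FALSE]
  rownames(tr) <- NULL
  tr
}

#' Serialize a dataset as PPEO RDF
#'
#' Mints one instance IRI per record (`<base>/<section-slug>/<encoded id>`;
#' identifier-less records get an owner-scoped index), types every instance
#' with exactly one PPEO class, carries field values as datatyped literals and
#' connects instances with object properties (e.g. an observation unit to its
#' biological material via `hasBiologicalMaterial`). Trait, method and scale
#' are instances of their own classes grouped under the observed variable.
#'
#' @param dataset A `miappe_dataset`.
#' @param base_iri Absolute base IRI for minted instances.
#' @return A `ppeo_triples` object (triple data.frame plus base IRI).
#' @export
to_rdf <- function(dataset, base_iri = "https://example.org/miappe/") {
  if (!grepl("^[a-z][a-z0-9+.-]*://", base_iri)) {
    stop(sprintf("base_iri must be an absolute IRI, got '%s'", base_iri),
         call. = FALSE)
  }
  if (!grepl("[/#]$", base_iri)) base_iri <- paste0(base_iri, "/")
  rows <- list()
  emit <- function(s, p, o, obj_type = "iri", datatype = "") {
    rows[[length(rows) + 1]] <<- c(s, p, o, obj_type, datatype)
  }
  mint <- function(section_slug, id) {
    paste0(base_iri, section_slug, "/", iri_encode(id))
  }
  cls <- function(subject, class_name) {
    emit(subject, RDF_TYPE, paste0(PPEO_NS, class_name))
  }
  prop_map <- ppeo_property_map()
  emit_literals <- function(subject, record, section, node) {
    pm <- prop_map[prop_map$section == section & prop_map$node == node, ,
                   drop = FALSE]
    flat <- record_flatten(record, section)
    for (i in seq_len(nrow(pm))) {
      v <- flat[[pm$header[i]]]
      if (v == "") next
      emit(subject, pm$predicate[i], v, "literal",
           rdf_literal_datatype(pm$header[i], pm$kind[i], v))
    }
  }
  op <- function(name) paste0(PPEO_NS, name)
  inv <- dataset$investigation
  inv_iri <- mint("investigation", inv$id %||% "investigation")
  cls(inv_iri, "Investigation")
  emit_literals(inv_iri, inv, "Investigation", "self")
  add_persons <- function(owner_iri, owner_id, persons) {
    for (i in seq_along(persons)) {
      p_iri <- mint("person", sprintf("%s/%03d", owner_id, i))
      cls(p_iri, "Person")
      emit_literals(p_iri, persons[[i]], "Person", "self")
      emit(owner_iri, op("hasPerson"), p_iri)
    }
  }
  add_persons(inv_iri, inv$id %||% "investigation", inv$persons %||% list())
  for (st in dataset_studies(dataset)) {
    sid <- st$id %||% "study"
    st_iri <- mint("study", sid)
    cls(st_iri, "Study")
    emit(inv_iri, op("hasStudy"), st_iri)
    emit_literals(st_iri, st, "Study", "self")
    for (i in seq_along(st$locations %||% list())) {
      loc_iri <- mint("location", sprintf("%s/%03d", sid, i))
      cls(loc_iri, "Location")
      emit(st_iri, op("hasLocation"), loc_iri)
      # location properties are registered against the first block's paths
      block_as_study <- list(locations = list(st$locations[[i]]))
      emit_literals(loc_iri, block_as_study, "Study", "location")
    }
    add_persons(st_iri, sid, st$persons %||% list())
    for (df in st$data_files %||% list()) {
      df_iri <- mint("data_file", df$link %||% "file")
      cls(df_iri, "DataFile")
      emit(st_iri, op("hasDataFile"), df_iri)
      emit_literals(df_iri, df, "Data file", "self")
    }
    for (bm in st$biological_materials %||% list()) {
      bm_iri <- mint("biological_material", bm$id %||% "material")
      cls(bm_iri, "BiologicalMaterial")
      emit(st_iri, op("hasBiologicalMaterial"), bm_iri)
      emit_literals(bm_iri, bm, "Biological material", "self")
      if (!is.null(bm$material_source)) {
        ms_iri <- mint("material_source", bm$id %||% "material")
        cls(ms_iri, "MaterialSource")
        emit(bm_iri, op("hasMaterialSource"), ms_iri)
        emit_literals(ms_iri, bm, "Biological material", "material_source")
      }
    }
    for (i in seq_along(st$environments %||% list())) {
      en_iri <- mint("environment", sprintf("%s/%03d", sid, i))
      cls(en_iri, "Environment")
      emit(st_iri, op("hasEnvironment"), en_iri)
      emit_literals(en_iri, st$environments[[i]], "Environment", "self")
    }
    for (i in seq_along(st$factors %||% list())) {
      fa_iri <- mint("experimental_factor", sprintf("%s/%03d", sid, i))
      cls(fa_iri, "ExperimentalFactor")
      emit(st_iri, op("hasExperimentalFactor"), fa_iri)
      emit_literals(fa_iri, st$factors[[i]], "Experimental factor", "self")
    }
    for (i in seq_along(st$events %||% list())) {
      ev <- st$events[[i]]
      ev_iri <- mint("event", sprintf("%s/%03d", sid, i))
      cls(ev_iri, "Event")
      emit(st_iri, op("hasEvent"), ev_iri)
      emit_literals(ev_iri, ev, "Event", "self")
      for (ou_id in ev$affected_units %||% character(0)) {
        emit(ev_iri, op("affectsObservationUnit"),
             mint("observation_unit", ou_id))
      }
    }
    for (ou in st$observation_units %||% list()) {
      ou_iri <- mint("observation_unit", ou$id %||% "unit")
      cls(ou_iri, "ObservationUnit")
      emit(st_iri, op("hasObservationUnit"), ou_iri)
      emit_literals(ou_iri, ou, "Observation unit", "self")
      if (!is_blank(ou$biological_material_id)) {
        emit(ou_iri, op("hasBiologicalMaterial"),
             mint("biological_material", ou$biological_material_id))
      }
    }
    for (sm in st$samples %||% list()) {
      sm_iri <- mint("sample", sm$id %||% "sample")
      cls(sm_iri, "Sample")
      emit(st_iri, op("hasSample"), sm_iri)
      emit_literals(sm_iri, sm, "Sample", "self")
      for (ou_id in sm$observation_unit_id %||% character(0)) {
        emit(sm_iri, op("hasObservationUnit"), mint("observation_unit", ou_id))
      }
    }
    for (ov in st$observed_variables %||% list()) {
      ov_iri <- mint("observed_variable", ov$id %||% "variable")
      cls(ov_iri, "ObservedVariable")
      emit(st_iri, op("hasObservedVariable"), ov_iri)
      emit_literals(ov_iri, ov, "Observed variable", "self")
      for (part in c("trait", "method", "scale")) {
        if (is.null(ov[[part]])) next
        part_iri <- mint(part, ov$id %||% "variable")
        cls(part_iri, paste0(toupper(substring(part, 1, 1)),
                             substring(part, 2)))
        emit(ov_iri, op(paste0("has", toupper(substring(part, 1, 1)),
                               substring(part, 2))), part_iri)
        emit_literals(part_iri, ov, "Observed variable", part)
      }
    }
  }
  tr <- if (length(rows) == 0) new_triple_frame() else {
    m <- do.call(rbind, rows)
    data.frame(subject = m[, 1], predicate = m[, 2], object = m[, 3],
               obj_type = m[, 4], datatype = m[, 5], stringsAsFactors = FALSE)
  }
  structure(list(triples = sort_triples(tr), base_iri = base_iri),
            class = "ppeo_triples")
}

#' @export
print.ppeo_triples <- function(x, ...) {
  cat(sprintf("<ppeo_triples> %d triples, base <%s>\n", nrow(x$triples),
              x$base_iri))
  invisible(x)
}

triples_with_type <- function(tr, class_name) {
  unique(tr$subject[tr$predicate == RDF_TYPE &
                      tr$object == paste0(PPEO_NS, class_name)])
}

#' Check PPEO cardinality restrictions on an instance graph
#'
#' Re-evaluates the data model's cardinality restrictions directly on the
#' triples, closed-world: an investigation must have at least one study, a
#' sample exactly one observation unit, a study exactly one location. Returns
#' one violation per (instance, restriction).
#'
#' @param triples A `ppeo_triples` object.
#' @return A data.frame with columns `instance`, `restriction`, `message`.
#' @export
check_rdf_constraints <- function(triples) {
  tr <- triples$triples
  out <- list()
  note <- function(instance, restriction, message) {
    out[[length(out) + 1]] <<- data.frame(
      instance = instance, restriction = restriction, message = message,
      stringsAsFactors = FALSE)
  }
  count_links <- function(subject, predicate) {
    sum(tr$subject == subject & tr$predicate == paste0(PPEO_NS, predicate))
  }
  for (s in triples_with_type(tr, "Investigation")) {
    n <- count_links(s, "hasStudy")
    if (n < 1) note(s, "investigation-min-1-study",
                    "investigation has no study")
  }
  for (s in triples_with_type(tr, "Sample")) {
    n <- count_links(s, "hasObservationUnit")
    if (n != 1) note(s, "sample-exactly-1-observation-unit",
                     sprintf("sample links %d observation units", n))
  }
  for (s in triples_with_type(tr, "Study")) {
    n <- count_links(s, "hasLocation")
    if (n != 1) note(s, "study-exactly-1-location",
                     sprintf("study links %d locations", n))
  }
  if (length(out) == 0) {
    return(data.frame(instance = character(0), restriction = character(0),
                      message = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

# -- dataset reconstruction ---------------------------------------------------

#' Rebuild a dataset from PPEO triples
#'
#' Inverse of [to_rdf()] for graphs produced by this package's dialect:
#' literals are routed back to their registry paths via [ppeo_property_map()],
#' object properties rebuild the record lists, and grouped nodes (trait,
#' method, scale, material source, location) fold back into their parent
#' records.
#'
#' @param triples A `ppeo_triples` object.
#' @return A `miappe_dataset`.
#' @export
from_rdf <- function(triples) {
  tr <- triples$triples
  prop_map <- ppeo_property_map()
  lits_of <- function(subject) {
    tr[tr$subject == subject & tr$obj_type == "literal", , drop = FALSE]
  }
  links_of <- function(subject, predicate) {
    sort(tr$object[tr$subject == subject &
                     tr$predicate == paste0(PPEO_NS, predicate) &
                     tr$obj_type == "iri"])
  }
  # rebuild one record of `section` from its own node plus grouped sub-nodes
  rebuild <- function(subject, section, nodes = list()) {
    row <- list()
    absorb <- function(subj, node) {
      pm <- prop_map[prop_map$section == section & prop_map$node == node, ,
                     drop = FALSE]
      lits <- lits_of(subj)
      for (i in seq_len(nrow(lits))) {
        j <- match(lits$predicate[i], pm$predicate)
        if (!is.na(j)) row[[pm$header[j]]] <<- lits$object[i]
      }
    }
    absorb(subject, "self")
    for (node in names(nodes)) {
      for (subj in nodes[[node]]) absorb(subj, node)
    }
    record_unflatten(row, section)
  }
  build_person_list <- function(owner_iri) {
    subjects <- links_of(owner_iri, "hasPerson")
    lapply(subjects, function(s) rebuild(s, "Person"))
  }
  inv_subjects <- triples_with_type(tr, "Investigation")
  if (length(inv_subjects) == 0) {
    stop("graph contains no Investigation instance", call. = FALSE)
  }
  inv_iri <- sort(inv_subjects)[[1]]
  studies <- lapply(links_of(inv_iri, "hasStudy"), function(st_iri) {
    st <- rebuild(st_iri, "Study",
                  nodes = list(location = links_of(st_iri, "hasLocation")))
    dfs <- lapply(links_of(st_iri, "hasDataFile"),
                  function(s) rebuild(s, "Data file"))
    bms <- lapply(links_of(st_iri, "hasBiologicalMaterial"), function(s) {
      rebuild(s, "Biological material",
              nodes = list(material_source = links_of(s, "hasMaterialSource")))
    })
    envs <- lapply(links_of(st_iri, "hasEnvironment"),
                   function(s) rebuild(s, "Environment"))
    facs <- lapply(links_of(st_iri, "hasExperimentalFactor"),
                   function(s) rebuild(s, "Experimental factor"))
    decode_ids <- function(iris) {
      if (length(iris) == 0) return(NULL)
      sort(vapply(iris, iri_decode_local, character(1), USE.NAMES = FALSE),
           method = "radix")
    }
    evs <- lapply(links_of(st_iri, "hasEvent"), function(s) {
      ev <- rebuild(s, "Event")
      miappe_event(type = ev$type, description = ev$description,
                   date = ev$date,
                   affected_units = decode_ids(
                     links_of(s, "affectsObservationUnit")))
    })
    ous <- lapply(links_of(st_iri, "hasObservationUnit"), function(s) {
      ou <- rebuild(s, "Observation unit")
      bm_links <- links_of(s, "hasBiologicalMaterial")
      miappe_observation_unit(
        id = ou$id, level = ou$level,
        biological_material_id = if (length(bm_links))
          iri_decode_local(bm_links[[1]]) else NULL,
        external_ref = ou$external_ref,
        spatial_distribution = ou$spatial_distribution,
        factor_values = ou$factor_values)
    })
    sms <- lapply(links_of(st_iri, "hasSample"), function(s) {
      sm <- rebuild(s, "Sample")
      miappe_sample(
        id = sm$id,
        observation_unit_id = decode_ids(links_of(s, "hasObservationUnit")),
        description = sm$description,
        plant_anatomical_entity = sm$plant_anatomical_entity,
        plant_structure_development_stage =
          sm$plant_structure_development_stage,
        collection_date = sm$collection_date, external_id = sm$external_id)
    })
    ovs <- lapply(links_of(st_iri, "hasObservedVariable"), function(s) {
      rebuild(s, "Observed variable",
              nodes = list(trait = links_of(s, "hasTrait"),
                           method = links_of(s, "hasMethod"),
                           scale = links_of(s, "hasScale")))
    })
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
      data_files = dfs, biological_materials = bms, environments = envs,
      factors = facs, events = evs, observation_units = ous, samples = sms,
      observed_variables = ovs, persons = build_person_list(st_iri))
  })
  inv_row <- rebuild(inv_iri, "Investigation")
  inv <- miappe_investigation(
    id = inv_row$id, title = inv_row$title, description = inv_row$description,
    submission_date = inv_row$submission_date,
    public_release_date = inv_row$public_release_date,
    license = inv_row$license, miappe_version = inv_row$miappe_version,
    publications = inv_row$publications,
    persons = build_person_list(inv_iri), studies = studies)
  build_dataset(inv, provenance = list(format = "rdf",
                                       base_iri = triples$base_iri))
}

# -- serialization ------------------------------------------------------------

escape_ttl <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x <- gsub("\r", "\\r", x, fixed = TRUE)
  gsub("\t", "\\t", x, fixed = TRUE)
}

unescape_ttl <- function(x) {
  out <- character(length(x))
  for (k in seq_along(x)) {
    s <- x[[k]]
    res <- ""
    i <- 1
    while (i <= nchar(s)) {
      ch <- substr(s, i, i)
      if (ch == "\\" && i < nchar(s)) {
        nxt <- substr(s, i + 1, i + 1)
        res <- paste0(res, switch(nxt, "n" = "\n", "r" = "\r", "t" = "\t",
                                  "\\" = "\\", "\"" = "\"", nxt))
        i <- i + 2
      } else {
        res <- paste0(res, ch)
        i <- i + 1
      }
    }
    out[[k]] <- res
  }
  out
}

compact_term <- function(iri) {
  if (startsWith(iri, PPEO_NS)) {
    return(paste0("ppeo:", substring(iri, nchar(PPEO_NS) + 1)))
  }
  if (startsWith(iri, XSD_NS)) {
    return(paste0("xsd:", substring(iri, nchar(XSD_NS) + 1)))
  }
  NULL
}

expand_term <- function(term) {
  if (startsWith(term, "ppeo:")) return(paste0(PPEO_NS, substring(term, 6)))
  if (startsWith(term, "xsd:")) return(paste0(XSD_NS, substring(term, 5)))
  term
}

ttl_object <- function(object, obj_type, datatype) {
  if (obj_type == "iri") {
    ct <- compact_term(object)
    return(ct %||% sprintf("<%s>", object))
  }
  lit <- sprintf("\"%s\"", escape_ttl(object))
  if (datatype != "") lit <- paste0(lit, "^^", compact_term(datatype))
  lit
}

#' Write RDF to disk
#'
#' Deterministic serialization: triples sorted by subject, predicate and
#' object; canonical `ppeo:`/`rdf:`/`xsd:` prefixes; JSON-LD uses the shipped
#' context document. The same triple set always produces byte-identical
#' output.
#'
#' @param triples A `ppeo_triples` object.
#' @param path Output file path.
#' @param format `"turtle"` or `"jsonld"` (default guessed from the file
#'   extension, falling back to turtle).
#' @return The path, invisibly.
#' @export
write_rdf <- function(triples, path, format = NULL) {
  format <- format %||%
    switch(tools::file_ext(path), jsonld = "jsonld", json = "jsonld", "turtle")
  if (!format %in% c("turtle", "jsonld")) {
    stop(sprintf("unknown RDF format '%s' (use turtle or jsonld)", format),
         call. = FALSE)
  }
  tr <- sort_triples(triples$triples)
  if (format == "turtle") {
    lines <- c(
      sprintf("@prefix ppeo: <%s> .", PPEO_NS),
      sprintf("@prefix rdf: <%s> .",
              "http://www.w3.org/1999/02/22-rdf-syntax-ns#"),
      sprintf("@prefix xsd: <%s> .", XSD_NS),
      sprintf("# base: %s", triples$base_iri),
      "")
    body <- vapply(seq_len(nrow(tr)), function(i) {
      pred <- if (tr$predicate[i] == RDF_TYPE) "a" else
        compact_term(tr$predicate[i]) %||% sprintf("<%s>", tr$predicate[i])
      sprintf("<%s> %s %s .", tr$subject[i], pred,
              ttl_object(tr$object[i], tr$obj_type[i], tr$datatype[i]))
    }, character(1))
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(c(lines, body), con, sep = "\n", useBytes = TRUE)
    return(invisible(path))
  }
  # JSON-LD: one node object per subject, keys and subjects sorted
  nodes <- list()
  for (s in sort(unique(tr$subject))) {
    rows <- tr[tr$subject == s, , drop = FALSE]
    node <- list("@id" = s)
    types <- rows$object[rows$predicate == RDF_TYPE]
    if (length(types)) node[["@type"]] <- compact_term(sort(types)[[1]])
    rest <- rows[rows$predicate != RDF_TYPE, , drop = FALSE]
    for (p in sort(unique(rest$predicate))) {
      pr <- rest[rest$predicate == p, , drop = FALSE]
      vals <- lapply(seq_len(nrow(pr)), function(i) {
        if (pr$obj_type[i] == "iri") {
          list("@id" = pr$object[i])
        } else if (pr$datatype[i] != "") {
          list("@value" = pr$object[i],
               "@type" = compact_term(pr$datatype[i]))
        } else {
          pr$object[i]
        }
      })
      key <- compact_term(p) %||% p
      node[[key]] <- if (length(vals) == 1) vals[[1]] else vals
    }
    nodes[[length(nodes) + 1]] <- node
  }
  doc <- list("@context" = ppeo_jsonld_context(),
              "@graph" = nodes)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' JSON-LD context for the PPEO dialect
#'
#' @return Named list mapping the `ppeo`, `rdf` and `xsd` prefixes; also
#'   shipped at `inst/extdata/ppeo_context.json`.
#' @export
ppeo_jsonld_context <- function() {
  list(ppeo = PPEO_NS,
       rdf = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
       xsd = XSD_NS)
}

#' Read RDF from disk
#'
#' Parses the package's deterministic Turtle or JSON-LD dialect back into the
#' exact triple set that produced it.
#'
#' @param path File path.
#' @param format `"turtle"` or `"jsonld"`; guessed from the extension when
#'   `NULL`.
#' @return A `ppeo_triples` object.
#' @export
read_rdf <- function(path, format = NULL) {
  format <- format %||%
    switch(tools::file_ext(path), jsonld = "jsonld", json = "jsonld", "turtle")
  if (format == "turtle") {
    lines <- readLines(path, encoding = "UTF-8")
    base_iri <- NA_character_
    rows <- list()
    for (i in seq_along(lines)) {
      line <- lines[[i]]
      if (line == "" || startsWith(line, "@prefix")) next
      if (startsWith(line, "# base: ")) {
        base_iri <- substring(line, 9)
        next
      }
      m <- regmatches(line,
                      regexec("^<([^>]+)> (a|[A-Za-z0-9:]+|<[^>]+>) (.*) \\.$",
                              line))[[1]]
      if (length(m) != 4) {
        stop(sprintf("malformed Turtle at %s line %d", basename(path), i),
             call. = FALSE)
      }
      subject <- m[2]
      predicate <- if (m[3] == "a") RDF_TYPE else if (startsWith(m[3], "<")) {
        substr(m[3], 2, nchar(m[3]) - 1)
      } else expand_term(m[3])
      obj <- m[4]
      if (startsWith(obj, "<")) {
        rows[[length(rows) + 1]] <- c(subject, predicate,
                                      substr(obj, 2, nchar(obj) - 1),
                                      "iri", "")
      } else if (grepl("^(ppeo|xsd|rdf):", obj)) {
        rows[[length(rows) + 1]] <- c(subject, predicate, expand_term(obj),
                                      "iri", "")
      } else {
        lm <- regmatches(obj,
                         regexec("^\"((?:[^\"\\\\]|\\\\.)*)\"(?:\\^\\^([A-Za-z]+:[A-Za-z0-9]+))?$",
                                 obj))[[1]]
        if (length(lm) < 2) {
          stop(sprintf("malformed literal at %s line %d", basename(path), i),
               call. = FALSE)
        }
        rows[[length(rows) + 1]] <- c(
          subject, predicate, unescape_ttl(lm[2]), "literal",
          if (length(lm) >= 3 && lm[3] != "") expand_term(lm[3]) else "")
      }
    }
    tr <- triple_rows_to_frame(rows)
    return(structure(list(triples = sort_triples(tr), base_iri = base_iri),
                     class = "ppeo_triples"))
  }
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  rows <- list()
  for (node in doc[["@graph"]] %||% list()) {
    s <- node[["@id"]]
    if (!is.null(node[["@type"]])) {
      rows[[length(rows) + 1]] <- c(s, RDF_TYPE,
                                    expand_term(node[["@type"]]), "iri", "")
    }
    for (key in setdiff(names(node), c("@id", "@type"))) {
      pred <- expand_term(key)
      vals <- node[[key]]
      if (!is.null(names(vals)) || !is.list(vals)) vals <- list(vals)
      for (v in vals) {
        rows[[length(rows) + 1]] <- if (is.list(v) && !is.null(v[["@id"]])) {
          c(s, pred, v[["@id"]], "iri", "")
        } else if (is.list(v) && !is.null(v[["@value"]])) {
          c(s, pred, v[["@value"]], "literal",
            if (is.null(v[["@type"]])) "" else expand_term(v[["@type"]]))
        } else {
          c(s, pred, as.character(v), "literal", "")
        }
      }
    }
  }
  tr <- triple_rows_to_frame(rows)
  base <- doc[["@context"]][["@base"]] %||% NA_character_
  structure(list(triples = sort_triples(tr), base_iri = base),
            class = "ppeo_triples")
}
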