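# Field registry: the single source of truth for MIAPPE 1.1 checklist fields.
# Every serialization (worksheet headers, ISA-Tab Comment keys, BrAPI
# additionalInfo keys, PPEO data-property names) is derived from this table,
# which keeps the four formats lossless and mutually consistent.

`%||%` <- function(a, b) if (is.null(a)) b else a

is_blank <- function(x) {
  is.null(x) || length(x) == 0 || all(is.na(x)) ||
    (is.character(x) && all(trimws(x) == ""))
}

norm_chr <- function(x) {
  if (is_blank(x)) return(NULL)
  as.character(x)
}

norm_num <- function(x) {
  if (is_blank(x)) return(NULL)
  as.numeric(x)
}

# list separator used in all tabular cells; values may not contain it
LIST_SEP <- "; "

assert_no_sep <- function(x, what) {
  if (any(grepl(";", x, fixed = TRUE))) {
    stop(sprintf("value in %s contains the reserved list separator ';': %s",
                 what, paste(grep(";", x, fixed = TRUE, value = TRUE),
                             collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

join_list <- function(x) {
  if (is_blank(x)) return("")
  paste(as.character(x), collapse = LIST_SEP)
}

split_list <- function(s) {
  if (is_blank(s)) return(NULL)
  strsplit(s, LIST_SEP, fixed = TRUE)[[1]]
}

join_kv <- function(x) {
  if (is_blank(x) || length(x) == 0) return("")
  paste(sprintf("%s: %s", names(x), as.character(unlist(x))),
        collapse = LIST_SEP)
}

split_kv <- function(s) {
  if (is_blank(s)) return(NULL)
  parts <- strsplit(s, LIST_SEP, fixed = TRUE)[[1]]
  keys <- sub(": .*$", "", parts)
  vals <- sub("^[^:]*: ", "", parts)
  stats::setNames(as.list(vals), keys)
}

fmt_num <- function(x) {
  if (is_blank(x)) return("")
  format(x, scientific = FALSE, trim = TRUE, digits = 15)
}

#' MIAPPE section names
#'
#' The eleven checklist sections of MIAPPE 1.1, in canonical order.
#' @return Character vector of section names.
#' @export
miappe_sections <- function() {
  c("Investigation", "Study", "Person", "Data file", "Biological material",
    "Environment", "Experimental factor", "Event", "Observation unit",
    "Sample", "Observed variable")
}

#' MIAPPE 1.1 field registry
#'
#' One row per checklist field: the section it belongs to, the human-readable
#' header used on worksheets and in `Comment[MIAPPE: ...]` keys, the dotted
#' path of the field inside the corresponding model record, and its codec kind
#' (`chr` plain text, `num` decimal number, `list` "; "-joined list,
#' `kv` "; "-joined "key: value" pairs).
#'
#' @return A data.frame with columns `section`, `header`, `path`, `kind`.
#' @export
miappe_field_registry <- function() {
  memo_table("field_registry", build_field_registry())
}

# registry and derived lookup tables are built once per session
.miappe_cache <- new.env(parent = emptyenv())

memo_table <- function(key, expr) {
  if (is.null(.miappe_cache[[key]])) .miappe_cache[[key]] <- force(expr)
  .miappe_cache[[key]]
}

build_field_registry <- function() {
  reg <- function(section, header, path, kind = "chr") {
    data.frame(section = section, header = header, path = path, kind = kind,
               stringsAsFactors = FALSE)
  }
  do.call(rbind, list(
    reg("Investigation", "Investigation unique ID", "id"),
    reg("Investigation", "Investigation title", "title"),
    reg("Investigation", "Investigation description", "description"),
    reg("Investigation", "Submission date", "submission_date"),
    reg("Investigation", "Public release date", "public_release_date"),
    reg("Investigation", "License", "license"),
    reg("Investigation", "MIAPPE version", "miappe_version"),
    reg("Investigation", "Associated publication", "publications", "list"),

    reg("Study", "Study unique ID", "id"),
    reg("Study", "Study title", "title"),
    reg("Study", "Study description", "description"),
    reg("Study", "Start date of study", "start_date"),
    reg("Study", "End date of study", "end_date"),
    reg("Study", "Contact institution", "contact_institution"),
    reg("Study", "Geographic location (country)", "locations.1.country"),
    reg("Study", "Experimental site name", "locations.1.site_name"),
    reg("Study", "Geographic location (latitude)", "locations.1.geo.latitude", "num"),
    reg("Study", "Geographic location (longitude)", "locations.1.geo.longitude", "num"),
    reg("Study", "Geographic location (altitude)", "locations.1.geo.altitude", "num"),
    reg("Study", "Description of the experimental design", "experimental_design.description"),
    reg("Study", "Type of experimental design", "experimental_design.type.label"),
    reg("Study", "Type of experimental design accession", "experimental_design.type.accession"),
    reg("Study", "Map of experimental design", "experimental_design.map"),
    reg("Study", "Description of growth facility", "growth_facility.description"),
    reg("Study", "Type of growth facility", "growth_facility.type.label"),
    reg("Study", "Type of growth facility accession", "growth_facility.type.accession"),
    reg("Study", "Cultural practices", "cultural_practices"),
    reg("Study", "Observation unit level hierarchy", "observation_unit_level_hierarchy", "list"),

    reg("Person", "Person name", "name"),
    reg("Person", "Person email", "email"),
    reg("Person", "Person ID", "orcid_or_id"),
    reg("Person", "Person affiliation", "affiliation"),
    reg("Person", "Person role", "role"),

    reg("Data file", "Data file link", "link"),
    reg("Data file", "Data file description", "description"),
    reg("Data file", "Data file version", "version"),

    reg("Biological material", "Biological material ID", "id"),
    reg("Biological material", "Organism", "organism.label"),
    reg("Biological material", "Organism accession", "organism.accession"),
    reg("Biological material", "Genus", "genus"),
    reg("Biological material", "Species", "species"),
    reg("Biological material", "Infraspecific name", "infraspecific_name"),
    reg("Biological material", "Biological material latitude", "geo.latitude", "num"),
    reg("Biological material", "Biological material longitude", "geo.longitude", "num"),
    reg("Biological material", "Biological material altitude", "geo.altitude", "num"),
    reg("Biological material", "Biological material coordinates uncertainty", "geo.coordinates_uncertainty", "num"),
    reg("Biological material", "Biological material preprocessing", "preprocessing"),
    reg("Biological material", "Material source ID", "material_source.id"),
    reg("Biological material", "Material source DOI", "material_source.doi"),
    reg("Biological material", "Material source latitude", "material_source.geo.latitude", "num"),
    reg("Biological material", "Material source longitude", "material_source.geo.longitude", "num"),
    reg("Biological material", "Material source altitude", "material_source.geo.altitude", "num"),
    reg("Biological material", "Material source coordinates uncertainty", "material_source.geo.coordinates_uncertainty", "num"),
    reg("Biological material", "Material source description", "material_source.description"),

    reg("Environment", "Environment parameter", "parameter"),
    reg("Environment", "Environment parameter value", "value"),

    reg("Experimental factor", "Experimental factor type", "type.label"),
    reg("Experimental factor", "Experimental factor type accession", "type.accession"),
    reg("Experimental factor", "Experimental factor description", "description"),
    reg("Experimental factor", "Experimental factor values", "values", "list"),

    reg("Event", "Event type", "type.label"),
    reg("Event", "Event type accession", "type.accession"),
    reg("Event", "Event description", "description"),
    reg("Event", "Event date", "date"),
    reg("Event", "Affected observation units", "affected_units", "list"),

    reg("Observation unit", "Observation unit ID", "id"),
    reg("Observation unit", "Observation unit level", "level"),
    reg("Observation unit", "Biological material ID", "biological_material_id"),
    reg("Observation unit", "External ID", "external_ref"),
    reg("Observation unit", "Spatial distribution", "spatial_distribution", "kv"),
    reg("Observation unit", "Observation unit factor values", "factor_values", "kv"),

    reg("Sample", "Sample ID", "id"),
    reg("Sample", "Observation unit ID", "observation_unit_id"),
    reg("Sample", "Sample description", "description"),
    reg("Sample", "Plant anatomical entity", "plant_anatomical_entity.label"),
    reg("Sample", "Plant anatomical entity accession", "plant_anatomical_entity.accession"),
    reg("Sample", "Plant structure development stage", "plant_structure_development_stage.label"),
    reg("Sample", "Plant structure development stage accession", "plant_structure_development_stage.accession"),
    reg("Sample", "Sample collection date", "collection_date"),
    reg("Sample", "External sample ID", "external_id"),

    reg("Observed variable", "Variable ID", "id"),
    reg("Observed variable", "Variable name", "name"),
    reg("Observed variable", "Trait", "trait.name"),
    reg("Observed variable", "Trait accession", "trait.accession"),
    reg("Observed variable", "Method", "method.name"),
    reg("Observed variable", "Method accession", "method.accession"),
    reg("Observed variable", "Method description", "method.description"),
    reg("Observed variable", "Method reference", "method.reference"),
    reg("Observed variable", "Scale", "scale.name"),
    reg("Observed variable", "Scale accession", "scale.accession"),
    reg("Observed variable", "Time scale", "time_scale")
  ))
}

registry_for <- function(section) {
  memo_table(paste0("registry_", section), {
    reg <- miappe_field_registry()
    reg[reg$section == section, , drop = FALSE]
  })
}

# -- dotted-path access -------------------------------------------------------

path_get <- function(record, path) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  cur <- record
  for (p in parts) {
    if (is.null(cur)) return(NULL)
    cur <- if (grepl("^[0-9]+$", p)) {
      i <- as.integer(p)
      if (i > length(cur)) NULL else cur[[i]]
    } else {
      cur[[p]]
    }
  }
  cur
}

path_set <- function(record, path, value) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  set_rec <- function(node, parts, value) {
    if (is.null(node)) node <- list()
    key <- parts[[1]]
    if (grepl("^[0-9]+$", key)) key <- as.integer(key)
    if (length(parts) == 1) {
      node[key] <- list(value)  # allows assigning NULL without dropping
      if (is.null(value)) node[[key]] <- NULL
    } else {
      sub <- if (is.numeric(key) && key > length(node)) NULL else
        tryCatch(node[[key]], error = function(e) NULL)
      node[[key]] <- set_rec(sub, parts[-1], value)
    }
    node
  }
  set_rec(record, parts, value)
}

# flatten one record to a named character vector keyed by registry header
record_flatten <- function(record, section) {
  reg <- registry_for(section)
  vals <- vapply(seq_len(nrow(reg)), function(i) {
    v <- path_get(record, reg$path[i])
    switch(reg$kind[i],
      chr  = if (is_blank(v)) "" else paste(as.character(v), collapse = LIST_SEP),
      num  = fmt_num(v),
      list = join_list(v),
      kv   = join_kv(v)
    )
  }, character(1))
  stats::setNames(vals, reg$header)
}

# inverse of record_flatten: named character vector -> nested record list
record_unflatten <- function(row, section) {
  reg <- registry_for(section)
  rec <- list()
  for (i in seq_len(nrow(reg))) {
    raw <- row[[reg$header[i]]]
    if (is_blank(raw)) next
    v <- switch(reg$kind[i],
      chr  = {
        s <- as.character(raw)
        if (grepl(LIST_SEP, s, fixed = TRUE)) split_list(s) else s
      },
      num  = as.numeric(raw),
      list = split_list(as.character(raw)),
      kv   = split_kv(as.character(raw))
    )
    rec <- path_set(rec, reg$path[i], v)
  }
  rec
}

# prune NULLs, empty strings and empty lists recursively; canonical record form
prune_record <- function(x) {
  if (!is.list(x)) {
    if (is_blank(x)) return(NULL)
    return(x)
  }
  out <- lapply(x, prune_record)
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0) return(NULL)
  out
}

slugify <- function(x) {
  s <- gsub("[^A-Za-z0-9]+", "_", x)
  gsub("^_+|_+$", "", s)
}

camel_term <- function(header) {
  s <- gsub("[()]", "", header)
  parts <- strsplit(tolower(s), "[^a-z0-9]+")[[1]]
  parts <- parts[nzchar(parts)]
  paste0(parts[1], paste0(toupper(substring(parts[-1], 1, 1)),
                          substring(parts[-1], 2), collapse = ""))
}

# "Sample collection date" -> "hasSampleCollectionDate"
predicate_for_header <- function(header) {
  t <- camel_term(header)
  paste0("has", toupper(substring(t, 1, 1)), substring(t, 2))
}
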