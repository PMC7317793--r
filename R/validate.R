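# Checklist validation. Requirement levels map exactly as MUST -> ERROR,
# SHOULD -> WARNING; fields the standard leaves unqualified get no rule.
# Ontology-term checks are syntactic only (CURIE/IRI shape), so validation is
# deterministic and needs no network access.

#' Validation rule registry
#'
#' The full table of checklist rules the validator can emit. Rule identifiers
#' are stable strings grouped by prefix: `CARD-` cardinality, `REQ-` required
#' field, `UNIQ-` uniqueness, `REF-` reference resolution, `FMT-` value
#' format, `WARN-` advisory. Every issue emitted by [miappe_validate()] uses a
#' rule from this table, and every rule has a matching defect generator in
#' [mutate_dataset()].
#'
#' @return A data.frame with columns `rule_id`, `severity`, `section`,
#'   `description`.
#' @export
rule_registry <- function() {
  memo_table("rule_registry", build_rule_registry())
}

build_rule_registry <- function() {
  r <- function(rule_id, severity, section, description) {
    data.frame(rule_id = rule_id, severity = severity, section = section,
               description = description, stringsAsFactors = FALSE)
  }
  do.call(rbind, list(
    r("CARD-INV-STUDY", "ERROR", "Investigation",
      "an investigation must have one or more studies"),
    r("CARD-STU-LOC", "ERROR", "Study",
      "a study must have exactly one location"),
    r("CARD-SAM-OU", "ERROR", "Sample",
      "a sample must be derived from exactly one observation unit"),
    r("CARD-STU-OU", "WARNING", "Study",
      "a study should have one or more observation units"),
    r("REQ-INV-ID", "ERROR", "Investigation",
      "investigation unique identifier must be provided"),
    r("FMT-MIAPPE-VERSION", "ERROR", "Investigation",
      "MIAPPE version must equal '1.1'"),
    r("REQ-STU-ID", "ERROR", "Study",
      "study unique identifier must be provided"),
    r("REQ-PER-NAME", "ERROR", "Person", "person name must be provided"),
    r("REQ-PER-ROLE", "ERROR", "Person", "person role must be provided"),
    r("REQ-DF-LINK", "ERROR", "Data file", "data file link must be provided"),
    r("REQ-DF-DESCRIPTION", "ERROR", "Data file",
      "a description must be provided for each data file"),
    r("REQ-DF-VERSION", "ERROR", "Data file",
      "a version must be provided for each data file"),
    r("REQ-BM-ID", "ERROR", "Biological material",
      "biological material ID must be provided"),
    r("REQ-BM-ORGANISM", "ERROR", "Biological material",
      "biological material must be identified through the organism field"),
    r("REQ-ENV-PARAMETER", "ERROR", "Environment",
      "environment parameter name must be provided"),
    r("REQ-ENV-VALUE", "ERROR", "Environment",
      "environment parameter value must be provided"),
    r("UNIQ-ENV-PARAMETER", "ERROR", "Environment",
      "environment parameter names must be unique within a study"),
    r("REQ-FAC-TYPE", "ERROR", "Experimental factor",
      "experimental factor type must be provided"),
    r("REQ-FAC-VALUES", "ERROR", "Experimental factor",
      "experimental factor must declare at least one value"),
    r("UNIQ-FAC-VALUES", "ERROR", "Experimental factor",
      "experimental factor values must be pairwise distinct"),
    r("REQ-EV-TYPE", "ERROR", "Event", "event type must be provided"),
    r("REQ-EV-DATE", "ERROR", "Event", "event date must be provided"),
    r("REQ-OU-LEVEL", "ERROR", "Observation unit",
      "observation unit level must be one of the study's declared hierarchy"),
    r("REQ-VAR-ID", "ERROR", "Observed variable",
      "observed variable ID must be provided"),
    r("REQ-VAR-NAME", "ERROR", "Observed variable",
      "observed variable name must be provided"),
    r("REQ-VAR-TRAIT", "ERROR", "Observed variable",
      "observed variable must name its trait component"),
    r("REQ-VAR-METHOD", "ERROR", "Observed variable",
      "observed variable must name its method component"),
    r("REQ-VAR-SCALE", "ERROR", "Observed variable",
      "observed variable must name its scale component"),
    r("REF-SAM-OU", "ERROR", "Sample",
      "sample observation unit reference must resolve within the dataset"),
    r("REF-OU-BM", "ERROR", "Observation unit",
      "observation unit biological material reference must resolve"),
    r("REF-EV-OU", "ERROR", "Event",
      "event affected observation unit references must resolve"),
    r("FMT-DATE", "ERROR", "-",
      "dates must be valid ISO 8601 (reduced precision allowed)"),
    r("FMT-DATERANGE", "ERROR", "Study",
      "study end date must not precede its start date"),
    r("FMT-GEO", "ERROR", "-",
      "coordinates must be valid WGS84 decimal degrees"),
    r("FMT-CURIE", "ERROR", "-",
      "term accessions must be CURIEs or absolute IRIs"),
    r("FMT-FACTORVALUE", "ERROR", "Observation unit",
      "factor values must match a declared factor and one of its values"),
    r("WARN-SAM-DATE", "WARNING", "Sample",
      "sample collection date should fall within the study date range")
  ))
}

# ISO 8601 with reduced precision: YYYY | YYYY-MM | YYYY-MM-DD | full
# timestamp with optional seconds/fraction and optional zone.
is_iso8601 <- function(x) {
  if (is_blank(x)) return(TRUE)
  pat <- paste0(
    "^\\d{4}(-\\d{2}(-\\d{2}",
    "(T\\d{2}:\\d{2}(:\\d{2}(\\.\\d+)?)?(Z|[+-]\\d{2}:\\d{2})?)?",
    ")?)?$")
  if (!grepl(pat, x)) return(FALSE)
  y <- as.integer(substr(x, 1, 4))
  if (nchar(x) >= 7) {
    m <- as.integer(substr(x, 6, 7))
    if (m < 1 || m > 12) return(FALSE)
  }
  if (nchar(x) >= 10) {
    d <- as.integer(substr(x, 9, 10))
    dim <- c(31, if (y %% 4 == 0 && (y %% 100 != 0 || y %% 400 == 0)) 29 else 28,
             31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
    if (d < 1 || d > dim[m]) return(FALSE)
  }
  if (nchar(x) >= 16) {
    hh <- as.integer(substr(x, 12, 13)); mm <- as.integer(substr(x, 15, 16))
    if (hh > 23 || mm > 59) return(FALSE)
  }
  TRUE
}

date_key <- function(x) substr(paste0(x, "-01-01"), 1, 10)

is_curie_or_iri <- function(x) {
  if (is_blank(x)) return(TRUE)
  grepl("^[A-Za-z_][A-Za-z0-9_.]*:[A-Za-z0-9_.-]+$", x) ||
    grepl("^[a-z][a-z0-9+.-]*://\\S+$", x)
}

check_geo <- function(geo) {
  msgs <- character(0)
  if (is.null(geo)) return(msgs)
  lat <- geo$latitude; lon <- geo$longitude
  if (!is_blank(lat) && (lat < -90 || lat > 90)) {
    msgs <- c(msgs, sprintf("latitude %s outside [-90, 90]", fmt_num(lat)))
  }
  if (!is_blank(lon) && (lon < -180 || lon > 180)) {
    msgs <- c(msgs, sprintf("longitude %s outside [-180, 180]", fmt_num(lon)))
  }
  unc <- geo$coordinates_uncertainty
  if (!is_blank(unc)) {
    if (unc < 0) msgs <- c(msgs, "coordinates uncertainty is negative")
    if (is_blank(lat) || is_blank(lon)) {
      msgs <- c(msgs, "coordinates uncertainty given without latitude/longitude")
    }
  }
  msgs
}

new_issue_frame <- function() {
  data.frame(severity = character(0), rule_id = character(0),
             section = character(0), record_id = character(0),
             field = character(0), message = character(0),
             stringsAsFactors = FALSE)
}

issue_collector <- function() {
  issues <- list()
  registry <- rule_registry()
  add <- function(rule_id, section, record_id, field, message) {
    sev <- registry$severity[registry$rule_id == rule_id]
    stopifnot(length(sev) == 1)
    issues[[length(issues) + 1]] <<- data.frame(
      severity = sev, rule_id = rule_id, section = section,
      record_id = record_id %||% "-", field = field %||% "-",
      message = message, stringsAsFactors = FALSE)
  }
  frame <- function() {
    if (length(issues) == 0) return(new_issue_frame())
    f <- do.call(rbind, issues)
    f <- unique(f)
    f[order(f$section, f$record_id, f$rule_id, f$field, method = "radix"), ,
      drop = FALSE]
  }
  list(add = add, frame = frame)
}

#' Check value formats across a dataset
#'
#' Flags non-ISO-8601 dates, out-of-range coordinates, malformed term
#' accessions (neither CURIE nor absolute IRI), a MIAPPE version other than
#' "1.1", and observation-unit factor values that do not match a declared
#' experimental factor and one of its declared values.
#'
#' @param dataset A `miappe_dataset`.
#' @return A data.frame of issues (same columns as a validation report).
#' @export
check_value_formats <- function(dataset) {
  col <- issue_collector()
  inv <- dataset$investigation
  if (!is_blank(inv$miappe_version) && !identical(inv$miappe_version, "1.1")) {
    col$add("FMT-MIAPPE-VERSION", "Investigation", inv$id, "miappe_version",
            sprintf("MIAPPE version is '%s', expected '1.1'",
                    inv$miappe_version))
  }
  chk_date <- function(x, section, rid, field) {
    if (!is_blank(x) && !is_iso8601(x)) {
      col$add("FMT-DATE", section, rid, field,
              sprintf("'%s' is not a valid ISO 8601 date", x))
    }
  }
  chk_geo <- function(geo, section, rid, field) {
    for (m in check_geo(geo)) col$add("FMT-GEO", section, rid, field, m)
  }
  chk_curie <- function(x, section, rid, field) {
    if (!is_blank(x) && !is_curie_or_iri(x)) {
      col$add("FMT-CURIE", section, rid, field,
              sprintf("'%s' is neither a CURIE nor an absolute IRI", x))
    }
  }
  chk_date(inv$submission_date, "Investigation", inv$id, "submission_date")
  chk_date(inv$public_release_date, "Investigation", inv$id,
           "public_release_date")
  for (st in dataset_studies(dataset)) {
    sid <- st$id %||% "-"
    chk_date(st$start_date, "Study", sid, "start_date")
    chk_date(st$end_date, "Study", sid, "end_date")
    if (!is_blank(st$start_date) && !is_blank(st$end_date) &&
        is_iso8601(st$start_date) && is_iso8601(st$end_date) &&
        substr(paste0(st$end_date, "-12-31"), 1, 10) < date_key(st$start_date)) {
      col$add("FMT-DATERANGE", "Study", sid, "end_date",
              sprintf("end date %s precedes start date %s",
                      st$end_date, st$start_date))
    }
    for (loc in st$locations %||% list()) {
      chk_geo(loc$geo, "Study", sid, "location.geo")
    }
    chk_curie(st$experimental_design$type$accession, "Study", sid,
              "experimental_design.type")
    chk_curie(st$growth_facility$type$accession, "Study", sid,
              "growth_facility.type")
    declared <- list()
    for (fa in study_records(st, "Experimental factor")) {
      if (!is_blank(fa$type$label)) declared[[fa$type$label]] <- fa$values
      chk_curie(fa$type$accession, "Experimental factor",
                sprintf("%s:%s", sid, fa$type$label %||% "-"), "type.accession")
    }
    for (bm in study_records(st, "Biological material")) {
      rid <- bm$id %||% "-"
      chk_geo(bm$geo, "Biological material", rid, "geo")
      chk_geo(bm$material_source$geo, "Biological material", rid,
              "material_source.geo")
      chk_curie(bm$organism$accession, "Biological material", rid,
                "organism.accession")
    }
    for (i in seq_along(study_records(st, "Event"))) {
      ev <- study_records(st, "Event")[[i]]
      rid <- sprintf("%s#%d", sid, i)
      chk_date(ev$date, "Event", rid, "date")
      chk_curie(ev$type$accession, "Event", rid, "type.accession")
    }
    for (ou in study_records(st, "Observation unit")) {
      rid <- ou$id %||% "-"
      for (ft in names(ou$factor_values %||% list())) {
        val <- ou$factor_values[[ft]]
        if (!(ft %in% names(declared))) {
          col$add("FMT-FACTORVALUE", "Observation unit", rid, "factor_values",
                  sprintf("factor '%s' is not declared in study '%s'", ft, sid))
        } else if (!(val %in% declared[[ft]])) {
          col$add("FMT-FACTORVALUE", "Observation unit", rid, "factor_values",
                  sprintf("value '%s' is not among declared values of factor '%s'",
                          val, ft))
        }
      }
    }
    for (sm in study_records(st, "Sample")) {
      rid <- sm$id %||% "-"
      chk_date(sm$collection_date, "Sample", rid, "collection_date")
      chk_curie(sm$plant_anatomical_entity$accession, "Sample", rid,
                "plant_anatomical_entity.accession")
      chk_curie(sm$plant_structure_development_stage$accession, "Sample", rid,
                "plant_structure_development_stage.accession")
      if (!is_blank(sm$collection_date) && is_iso8601(sm$collection_date)) {
        cd <- date_key(sm$collection_date)
        lo <- if (!is_blank(st$start_date) && is_iso8601(st$start_date))
          date_key(st$start_date) else NULL
        hi <- if (!is_blank(st$end_date) && is_iso8601(st$end_date))
          substr(paste0(st$end_date, "-12-31"), 1, 10) else NULL
        if ((!is.null(lo) && cd < lo) || (!is.null(hi) && cd > hi)) {
          col$add("WARN-SAM-DATE", "Sample", rid, "collection_date",
                  sprintf("collection date %s outside study range [%s, %s]",
                          sm$collection_date, st$start_date %||% "",
                          st$end_date %||% ""))
        }
      }
    }
    for (ov in study_records(st, "Observed variable")) {
      rid <- ov$id %||% "-"
      chk_curie(ov$trait$accession, "Observed variable", rid, "trait.accession")
      chk_curie(ov$method$accession, "Observed variable", rid,
                "method.accession")
      chk_curie(ov$scale$accession, "Observed variable", rid,
                "scale.accession")
    }
  }
  col$frame()
}

#' Validate a dataset against the MIAPPE 1.1 checklist
#'
#' Evaluates cardinality, required-field, uniqueness, reference-resolution and
#' value-format rules and returns a deterministic report: issues are sorted by
#' (section, record id, rule id, field), so the same dataset always yields a
#' byte-identical report. MUST-level rules produce errors, SHOULD-level rules
#' produce warnings; the verdict is PASS iff there are no errors.
#'
#' @param dataset A `miappe_dataset` (see [build_dataset()]).
#' @return An object of class `miappe_report` with elements `issues`
#'   (data.frame), `error_count`, `warning_count` and `verdict`.
#' @export
miappe_validate <- function(dataset) {
  stopifnot(inherits(dataset, "miappe_dataset"))
  col <- issue_collector()
  inv <- dataset$investigation
  if (is_blank(inv$id)) {
    col$add("REQ-INV-ID", "Investigation", "-", "id",
            "investigation has no unique identifier")
  }
  if (length(inv$studies %||% list()) == 0) {
    col$add("CARD-INV-STUDY", "Investigation", inv$id, "studies",
            "investigation has no studies")
  }
  chk_person <- function(p, rid) {
    if (is_blank(p$name)) col$add("REQ-PER-NAME", "Person", rid, "name",
                                  "person has no name")
    if (is_blank(p$role)) col$add("REQ-PER-ROLE", "Person", rid, "role",
                                  "person has no role")
  }
  for (i in seq_along(inv$persons %||% list())) {
    chk_person(inv$persons[[i]], sprintf("investigation#%d", i))
  }
  for (st in dataset_studies(dataset)) {
    sid <- st$id %||% "-"
    if (is_blank(st$id)) {
      col$add("REQ-STU-ID", "Study", "-", "id", "study has no unique identifier")
    }
    nloc <- length(st$locations %||% list())
    if (nloc != 1) {
      col$add("CARD-STU-LOC", "Study", sid, "location",
              sprintf("study has %d location blocks, exactly 1 required", nloc))
    }
    if (length(study_records(st, "Observation unit")) == 0) {
      col$add("CARD-STU-OU", "Study", sid, "observation_units",
              "study has no observation units")
    }
    for (i in seq_along(study_records(st, "Person"))) {
      chk_person(study_records(st, "Person")[[i]], sprintf("%s#%d", sid, i))
    }
    for (i in seq_along(study_records(st, "Data file"))) {
      df <- study_records(st, "Data file")[[i]]
      rid <- df$link %||% sprintf("%s#%d", sid, i)
      if (is_blank(df$link)) col$add("REQ-DF-LINK", "Data file", rid, "link",
                                     "data file has no link")
      if (is_blank(df$description)) {
        col$add("REQ-DF-DESCRIPTION", "Data file", rid, "description",
                "data file has no description")
      }
      if (is_blank(df$version)) {
        col$add("REQ-DF-VERSION", "Data file", rid, "version",
                "data file has no version")
      }
    }
    for (i in seq_along(study_records(st, "Biological material"))) {
      bm <- study_records(st, "Biological material")[[i]]
      rid <- bm$id %||% sprintf("%s#%d", sid, i)
      if (is_blank(bm$id)) col$add("REQ-BM-ID", "Biological material", rid,
                                   "id", "biological material has no ID")
      if (is.null(bm$organism) || is_blank(bm$organism$label) &&
          is_blank(bm$organism$accession)) {
        col$add("REQ-BM-ORGANISM", "Biological material", rid, "organism",
                "biological material has no organism")
      }
    }
    envs <- study_records(st, "Environment")
    seen <- character(0)
    for (i in seq_along(envs)) {
      en <- envs[[i]]
      rid <- sprintf("%s#%d", sid, i)
      if (is_blank(en$parameter)) {
        col$add("REQ-ENV-PARAMETER", "Environment", rid, "parameter",
                "environment parameter has no name")
      } else if (en$parameter %in% seen) {
        col$add("UNIQ-ENV-PARAMETER", "Environment", rid, "parameter",
                sprintf("environment parameter '%s' declared more than once",
                        en$parameter))
      } else {
        seen <- c(seen, en$parameter)
      }
      if (is_blank(en$value)) {
        col$add("REQ-ENV-VALUE", "Environment", rid, "value",
                "environment parameter has no value")
      }
    }
    for (i in seq_along(study_records(st, "Experimental factor"))) {
      fa <- study_records(st, "Experimental factor")[[i]]
      rid <- sprintf("%s:%s", sid, fa$type$label %||% sprintf("#%d", i))
      if (is_blank(fa$type$label) && is_blank(fa$type$accession)) {
        col$add("REQ-FAC-TYPE", "Experimental factor", rid, "type",
                "experimental factor has no type")
      }
      if (length(fa$values %||% character(0)) == 0) {
        col$add("REQ-FAC-VALUES", "Experimental factor", rid, "values",
                "experimental factor declares no values")
      } else if (anyDuplicated(fa$values)) {
        col$add("UNIQ-FAC-VALUES", "Experimental factor", rid, "values",
                "experimental factor values are not pairwise distinct")
      }
    }
    for (i in seq_along(study_records(st, "Event"))) {
      ev <- study_records(st, "Event")[[i]]
      rid <- sprintf("%s#%d", sid, i)
      if (is.null(ev$type) || (is_blank(ev$type$label) &&
                               is_blank(ev$type$accession))) {
        col$add("REQ-EV-TYPE", "Event", rid, "type", "event has no type")
      }
      if (is_blank(ev$date)) {
        col$add("REQ-EV-DATE", "Event", rid, "date", "event has no date")
      }
    }
    hier <- st$observation_unit_level_hierarchy %||% character(0)
    for (ou in study_records(st, "Observation unit")) {
      rid <- ou$id %||% "-"
      if (is_blank(ou$level) || (length(hier) > 0 && !(ou$level %in% hier))) {
        col$add("REQ-OU-LEVEL", "Observation unit", rid, "level",
                sprintf("level '%s' is not in the declared hierarchy [%s]",
                        ou$level %||% "", paste(hier, collapse = " > ")))
      }
    }
    for (i in seq_along(study_records(st, "Sample"))) {
      sm <- study_records(st, "Sample")[[i]]
      rid <- sm$id %||% sprintf("%s#%d", sid, i)
      n_ou <- length(sm$observation_unit_id %||% character(0))
      if (n_ou != 1) {
        col$add("CARD-SAM-OU", "Sample", rid, "observation_unit_id",
                sprintf("sample references %d observation units, exactly 1 required",
                        n_ou))
      }
    }
    for (i in seq_along(study_records(st, "Observed variable"))) {
      ov <- study_records(st, "Observed variable")[[i]]
      rid <- ov$id %||% sprintf("%s#%d", sid, i)
      if (is_blank(ov$id)) col$add("REQ-VAR-ID", "Observed variable", rid,
                                   "id", "observed variable has no ID")
      if (is_blank(ov$name)) col$add("REQ-VAR-NAME", "Observed variable", rid,
                                     "name", "observed variable has no name")
      if (is_blank(ov$trait$name)) {
        col$add("REQ-VAR-TRAIT", "Observed variable", rid, "trait",
                "observed variable has no trait name")
      }
      if (is_blank(ov$method$name)) {
        col$add("REQ-VAR-METHOD", "Observed variable", rid, "method",
                "observed variable has no method name")
      }
      if (is_blank(ov$scale$name)) {
        col$add("REQ-VAR-SCALE", "Observed variable", rid, "scale",
                "observed variable has no scale name")
      }
    }
  }
  refs <- resolve_references(dataset)
  rule_for_field <- c(observation_unit_id = "REF-SAM-OU",
                      biological_material_id = "REF-OU-BM",
                      affected_units = "REF-EV-OU")
  for (i in seq_len(nrow(refs))) {
    col$add(rule_for_field[[refs$field[i]]], refs$section[i],
            refs$record_id[i], refs$field[i],
            sprintf("reference to missing id '%s'", refs$missing_id[i]))
  }
  issues <- rbind(col$frame(), check_value_formats(dataset))
  issues <- unique(issues)
  issues <- issues[order(issues$section, issues$record_id, issues$rule_id,
                         issues$field, method = "radix"), , drop = FALSE]
  rownames(issues) <- NULL
  structure(list(
    issues = issues,
    error_count = sum(issues$severity == "ERROR"),
    warning_count = sum(issues$severity == "WARNING"),
    verdict = if (any(issues$severity == "ERROR")) "FAIL" else "PASS"
  ), class = "miappe_report")
}

#' @export
print.miappe_report <- function(x, ...) {
  cat(sprintf("<miappe_report> %s: %d error(s), %d warning(s)\n",
              x$verdict, x$error_count, x$warning_count))
  if (nrow(x$issues) > 0) {
    print(x$issues[, c("severity", "rule_id", "section", "record_id",
                       "message")], row.names = FALSE)
  }
  invisible(x)
}

#' Serialize a validation report
#'
#' `report_to_tsv()` renders the issue table as tab-delimited text;
#' `report_to_json()` renders the full report as a JSON document with stable
#' key order. Both are byte-identical across runs on the same dataset.
#'
#' @param report A `miappe_report`.
#' @param path Optional file path; when `NULL` the text is returned.
#' @return The serialized text, invisibly when written to `path`.
#' @export
report_to_tsv <- function(report, path = NULL) {
  f <- report$issues
  lines <- c(paste(names(f), collapse = "\t"),
             vapply(seq_len(nrow(f)), function(i)
               paste(unlist(f[i, ]), collapse = "\t"), character(1)))
  txt <- paste0(paste(lines, collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(txt, path, sep = "")
    return(invisible(txt))
  }
  txt
}

#' @rdname report_to_tsv
#' @export
report_to_json <- function(report, path = NULL) {
  obj <- list(verdict = report$verdict, error_count = report$error_count,
              warning_count = report$warning_count, issues = report$issues)
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}
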