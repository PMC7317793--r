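# ISA-Tab serialization. The archive layout follows the Investigation/Study/
# Assay convention: investigation, per-study sample tables, one assay file per
# data file, a trait definition file listing the observed variables, and an
# events file for dated occurrences. MIAPPE-specific fields are carried as
# `Comment[MIAPPE: <checklist field name>]` keys so the reverse mapping is
# unambiguous. Cells may not contain tabs or newlines (error on write, not
# quoted), and "; " is reserved as the in-cell list separator.

I_FILE <- "i_investigation.txt"

isa_blocks <- function() {
  c("ONTOLOGY SOURCE REFERENCE", "INVESTIGATION",
    "INVESTIGATION PUBLICATIONS", "INVESTIGATION CONTACTS", "STUDY",
    "STUDY DESIGN DESCRIPTORS", "STUDY FACTORS", "STUDY ASSAYS",
    "STUDY PROTOCOLS", "STUDY CONTACTS")
}

mcomment <- function(header) sprintf("Comment[MIAPPE: %s]", header)

check_cells <- function(x, where) {
  bad <- grepl("[\t\n\r]", x)
  if (any(bad)) {
    stop(sprintf("cell value with tab/newline not representable in %s: %s",
                 where, paste(utils::head(x[bad], 3), collapse = " | ")),
         call. = FALSE)
  }
  invisible(x)
}

write_cells <- function(lines, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

# render a list of rows (character vectors) padded to equal length
render_rows <- function(rows) {
  n <- max(c(1L, vapply(rows, length, integer(1))))
  vapply(rows, function(r) {
    r <- c(r, rep("", n - length(r)))
    check_cells(r, "investigation file")
    paste(r, collapse = "\t")
  }, character(1))
}

study_slug <- function(study) slugify(study$id %||% "study")

person_rows <- function(persons, prefix) {
  get <- function(f) vapply(persons, function(p) p[[f]] %||% "", character(1))
  list(c(sprintf("%s Person Name", prefix), get("name")),
       c(sprintf("%s Person Email", prefix), get("email")),
       c(sprintf("%s Person Affiliation", prefix), get("affiliation")),
       c(sprintf("%s Person Roles", prefix), get("role")),
       c(mcomment("Person ID"), get("orcid_or_id")))
}

#' Write a MIAPPE ISA-Tab archive
#'
#' Serializes a dataset to a directory of tab-delimited files: an
#' investigation file, one sample-table file per study (`s_<study>.txt`), one
#' assay file per data file (`a_<study>_<n>.txt`), one trait definition file
#' per study (`tdf_<study>.txt`) and, for studies with events, an events file
#' (`ev_<study>.txt`). The dataset must validate with zero errors. Synthetic
#' data-file payloads attached to the dataset are materialized so assay
#' references resolve.
#'
#' @param dataset A `miappe_dataset` passing [miappe_validate()] without
#'   errors.
#' @param root_dir Target directory (created if needed).
#' @return An `isatab_archive` manifest, invisibly.
#' @export
write_isatab <- function(dataset, root_dir) {
  rep <- miappe_validate(dataset)
  if (rep$error_count > 0) {
    stop(sprintf("refusing to write ISA-Tab: dataset has %d validation error(s)",
                 rep$error_count), call. = FALSE)
  }
  dir.create(root_dir, recursive = TRUE, showWarnings = FALSE)
  inv <- dataset$investigation
  rows <- list("ONTOLOGY SOURCE REFERENCE",
               c("Term Source Name", "MIAPPE"),
               "INVESTIGATION",
               c("Investigation Identifier", inv$id %||% ""),
               c("Investigation Title", inv$title %||% ""),
               c("Investigation Description", inv$description %||% ""),
               c("Investigation Submission Date", inv$submission_date %||% ""),
               c("Investigation Public Release Date",
                 inv$public_release_date %||% ""),
               c(mcomment("License"), inv$license %||% ""),
               c(mcomment("MIAPPE version"), inv$miappe_version %||% ""),
               "INVESTIGATION PUBLICATIONS",
               c("Investigation Publication DOI", inv$publications %||% character(0)),
               "INVESTIGATION CONTACTS")
  rows <- c(rows, person_rows(inv$persons %||% list(), "Investigation"))
  manifest <- list(root_dir = root_dir, investigation_file = I_FILE,
                   study_files = character(0), assay_files = character(0),
                   trait_definition_files = character(0),
                   events_files = character(0))
  for (st in dataset_studies(dataset)) {
    slug <- study_slug(st)
    s_file <- sprintf("s_%s.txt", slug)
    tdf_file <- sprintf("tdf_%s.txt", slug)
    ev_file <- sprintf("ev_%s.txt", slug)
    has_events <- length(st$events %||% list()) > 0
    flat <- record_flatten(st, "Study")
    study_comment_headers <- setdiff(
      registry_for("Study")$header,
      c("Study unique ID", "Study title", "Study description",
        "Description of the experimental design",
        "Type of experimental design", "Type of experimental design accession",
        "Cultural practices"))
    rows <- c(rows, list(
      "STUDY",
      c("Study Identifier", st$id %||% ""),
      c("Study Title", st$title %||% ""),
      c("Study Description", st$description %||% ""),
      c("Study File Name", s_file),
      c(mcomment("Trait definition file"), tdf_file),
      c(mcomment("Events file"), if (has_events) ev_file else "")))
    for (h in study_comment_headers) {
      rows <- c(rows, list(c(mcomment(h), flat[[h]])))
    }
    rows <- c(rows, list(
      "STUDY DESIGN DESCRIPTORS",
      c("Study Design Type", flat[["Type of experimental design"]]),
      c("Study Design Type Term Accession Number",
        flat[["Type of experimental design accession"]]),
      c(mcomment("Description of the experimental design"),
        flat[["Description of the experimental design"]])))
    factors <- st$factors %||% list()
    fget <- function(f) vapply(factors, f, character(1))
    rows <- c(rows, list(
      "STUDY FACTORS",
      c("Study Factor Name", fget(function(x) x$type$label %||% "")),
      c("Study Factor Type", fget(function(x) x$type$label %||% "")),
      c("Study Factor Type Term Accession Number",
        fget(function(x) x$type$accession %||% "")),
      c(mcomment("Experimental factor description"),
        fget(function(x) x$description %||% "")),
      c(mcomment("Experimental factor values"),
        fget(function(x) join_list(x$values)))))
    dfs <- st$data_files %||% list()
    assay_names <- if (length(dfs) > 0) {
      sprintf("a_%s_%d.txt", slug, seq_along(dfs))
    } else character(0)
    dget <- function(f) vapply(dfs, function(x) x[[f]] %||% "", character(1))
    rows <- c(rows, list(
      "STUDY ASSAYS",
      c("Study Assay File Name", assay_names),
      c("Study Assay Measurement Type", rep("phenotyping", length(dfs))),
      c(mcomment("Data file link"), dget("link")),
      c(mcomment("Data file description"), dget("description")),
      c(mcomment("Data file version"), dget("version"))))
    envs <- st$environments %||% list()
    env_names <- vapply(envs, function(e) e$parameter %||% "", character(1))
    env_vals <- vapply(envs, function(e) e$value %||% "", character(1))
    has_samples <- length(st$samples %||% list()) > 0
    ev_types <- unique(vapply(st$events %||% list(),
                              function(e) e$type$label %||% "", character(1)))
    ev_accs <- vapply(ev_types, function(tl) {
      for (e in st$events) if (identical(e$type$label %||% "", tl)) {
        return(e$type$accession %||% "")
      }
      ""
    }, character(1))
    pn <- c("Growth", "Phenotyping", if (has_samples) "Sampling",
            if (length(ev_types)) paste0("Event: ", ev_types))
    pt <- c("Growth", "Phenotyping", if (has_samples) "Sampling",
            rep("Event", length(ev_types)))
    pa <- c("", "", if (has_samples) "", unname(ev_accs))
    pd <- c(st$cultural_practices %||% "", "", if (has_samples) "",
            rep("", length(ev_types)))
    pp <- c(join_list(env_names), "", if (has_samples) "",
            rep("", length(ev_types)))
    pv <- c(join_list(env_vals), "", if (has_samples) "",
            rep("", length(ev_types)))
    rows <- c(rows, list(
      "STUDY PROTOCOLS",
      c("Study Protocol Name", pn),
      c("Study Protocol Type", pt),
      c("Study Protocol Type Term Accession Number", pa),
      c("Study Protocol Description", pd),
      c("Study Protocol Parameters Name", pp),
      c(mcomment("Environment parameter values"), pv),
      "STUDY CONTACTS"))
    rows <- c(rows, person_rows(st$persons %||% list(), "Study"))

    # -- study sample table --
    bm_headers <- setdiff(registry_for("Biological material")$header,
                          "Biological material ID")
    factor_labels <- vapply(factors, function(x) x$type$label %||% "",
                            character(1))
    s_header <- c("Source Name",
                  sprintf("Characteristics[%s]", bm_headers),
                  "Protocol REF", "Sample Name",
                  mcomment("Observation unit level"),
                  mcomment("External ID"),
                  mcomment("Spatial distribution"),
                  if (length(factor_labels))
                    sprintf("Factor Value[%s]", factor_labels))
    bm_by_id <- list()
    for (bm in st$biological_materials %||% list()) {
      bm_by_id[[bm$id %||% "-"]] <- bm
    }
    bm_cells <- function(bm) {
      if (is.null(bm)) return(rep("", length(bm_headers)))
      flat <- record_flatten(bm, "Biological material")
      unname(flat[bm_headers])
    }
    s_rows <- list()
    referenced <- character(0)
    for (ou in st$observation_units %||% list()) {
      bm <- if (!is_blank(ou$biological_material_id))
        bm_by_id[[ou$biological_material_id]] else NULL
      referenced <- c(referenced, ou$biological_material_id %||% character(0))
      fv <- vapply(factor_labels, function(fl)
        as.character(ou$factor_values[[fl]] %||% ""), character(1))
      s_rows[[length(s_rows) + 1]] <- c(
        ou$biological_material_id %||% "", bm_cells(bm), "Growth",
        ou$id %||% "", ou$level %||% "", ou$external_ref %||% "",
        join_kv(ou$spatial_distribution), unname(fv))
    }
    for (bm in st$biological_materials %||% list()) {
      if (!(bm$id %||% "") %in% referenced) {
        s_rows[[length(s_rows) + 1]] <- c(
          bm$id %||% "", bm_cells(bm), "Growth", "", "", "", "",
          rep("", length(factor_labels)))
      }
    }
    tab_lines <- vapply(c(list(s_header), s_rows), function(r) {
      check_cells(r, s_file)
      paste(r, collapse = "\t")
    }, character(1))
    write_cells(tab_lines, file.path(root_dir, s_file))
    manifest$study_files <- c(manifest$study_files, s_file)

    # -- trait definition file --
    tdf_header <- registry_for("Observed variable")$header
    tdf_rows <- lapply(st$observed_variables %||% list(), function(ov) {
      unname(record_flatten(ov, "Observed variable"))
    })
    write_cells(vapply(c(list(tdf_header), tdf_rows), function(r) {
      check_cells(r, tdf_file)
      paste(r, collapse = "\t")
    }, character(1)), file.path(root_dir, tdf_file))
    manifest$trait_definition_files <- c(manifest$trait_definition_files,
                                         tdf_file)

    # -- events file --
    if (has_events) {
      ev_header <- c("Event type", "Event type accession", "Event description",
                     "Event date", "Affected observation units")
      ev_rows <- lapply(st$events, function(e) {
        c(e$type$label %||% "", e$type$accession %||% "",
          e$description %||% "", e$date %||% "", join_list(e$affected_units))
      })
      write_cells(vapply(c(list(ev_header), ev_rows), function(r) {
        check_cells(r, ev_file)
        paste(r, collapse = "\t")
      }, character(1)), file.path(root_dir, ev_file))
      manifest$events_files <- c(manifest$events_files, ev_file)
    }

    # -- assay files: one per data file --
    sample_comment_headers <- c("Sample description", "Plant anatomical entity",
                                "Plant anatomical entity accession",
                                "Plant structure development stage",
                                "Plant structure development stage accession",
                                "Sample collection date", "External sample ID")
    for (ai in seq_along(dfs)) {
      a_file <- assay_names[[ai]]
      link <- dfs[[ai]]$link %||% ""
      if (has_samples) {
        a_header <- c("Sample Name", "Protocol REF", "Extract Name",
                      vapply(sample_comment_headers, mcomment, character(1)),
                      "Raw Data File")
        a_rows <- lapply(st$samples, function(sm) {
          flat <- record_flatten(sm, "Sample")
          c(paste(sm$observation_unit_id %||% "", collapse = LIST_SEP),
            "Sampling", sm$id %||% "",
            unname(flat[sample_comment_headers]), link)
        })
      } else {
        a_header <- c("Sample Name", "Protocol REF", "Raw Data File")
        a_rows <- lapply(st$observation_units %||% list(), function(ou) {
          c(ou$id %||% "", "Phenotyping", link)
        })
      }
      write_cells(vapply(c(list(a_header), a_rows), function(r) {
        check_cells(r, a_file)
        paste(r, collapse = "\t")
      }, character(1)), file.path(root_dir, a_file))
      manifest$assay_files <- c(manifest$assay_files, a_file)
    }
  }
  write_cells(render_rows(rows), file.path(root_dir, I_FILE))
  for (nm in names(dataset$payloads %||% list())) {
    write_cells(dataset$payloads[[nm]], file.path(root_dir, nm))
  }
  invisible(structure(manifest, class = "isatab_archive"))
}

# -- reader -------------------------------------------------------------------

split_line <- function(line) {
  cells <- strsplit(line, "\t", fixed = TRUE)[[1]]
  if (length(cells) == 0) cells <- ""
  cells
}

read_table_file <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("referenced ISA-Tab file is missing: %s", basename(path)),
         call. = FALSE)
  }
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) == 0) {
    stop(sprintf("empty ISA-Tab table: %s (line 1)", basename(path)),
         call. = FALSE)
  }
  header <- split_line(lines[1])
  rows <- lapply(seq_along(lines)[-1], function(i) {
    cells <- split_line(lines[i])
    if (length(cells) > length(header)) {
      stop(sprintf("malformed row in %s (line %d): %d cells for %d columns",
                   basename(path), i, length(cells), length(header)),
           call. = FALSE)
    }
    c(cells, rep("", length(header) - length(cells)))
  })
  list(header = header, rows = rows)
}

cell_of <- function(tab, row, column) {
  j <- match(column, tab$header)
  if (is.na(j)) "" else row[[j]]
}

parse_investigation_file <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  top <- list(); studies <- list()
  block <- NULL; cur <- NULL
  flush_study <- function() {
    if (!is.null(cur)) studies[[length(studies) + 1]] <<- cur
  }
  for (i in seq_along(lines)) {
    cells <- split_line(lines[i])
    key <- cells[1]
    if (key %in% isa_blocks() && all(cells[-1] == "")) {
      if (key == "STUDY") {
        flush_study()
        cur <- list()
      }
      block <- key
      next
    }
    vals <- if (length(cells) > 1) cells[-1] else character(0)
    entry <- stats::setNames(list(vals), key)
    if (is.null(cur)) top[[block]] <- c(top[[block]], entry)
    else cur[[block]] <- c(cur[[block]], entry)
  }
  flush_study()
  list(top = top, studies = studies)
}

persons_from_block <- function(block, prefix) {
  g <- function(key) block[[sprintf("%s Person %s", prefix, key)]] %||%
    character(0)
  names_ <- g("Name"); emails <- g("Email"); affs <- g("Affiliation")
  roles <- g("Roles"); ids <- block[[mcomment("Person ID")]] %||% character(0)
  n <- max(length(names_), length(emails), length(affs), length(roles),
           length(ids), 0)
  at <- function(v, i) if (i <= length(v)) v[[i]] else ""
  out <- list()
  for (i in seq_len(n)) {
    p <- miappe_person(name = at(names_, i), email = at(emails, i),
                       orcid_or_id = at(ids, i), affiliation = at(affs, i),
                       role = at(roles, i))
    if (!is.null(p)) out[[length(out) + 1]] <- p
  }
  out
}

#' Read a MIAPPE ISA-Tab archive
#'
#' Inverts [write_isatab()]: ISA Sources become biological materials, ISA
#' Samples observation units, ISA Extracts samples; Growth-protocol parameters
#' become environment parameters, study factors experimental factors, events
#' file rows events and trait definition rows observed variables. Unknown
#' `Comment[...]` keys are preserved in the provenance side-map.
#'
#' @param root_dir Directory containing `i_investigation.txt`.
#' @return A `miappe_dataset`.
#' @export
read_isatab <- function(root_dir) {
  ipath <- file.path(root_dir, I_FILE)
  if (!file.exists(ipath)) {
    stop(sprintf("no investigation file (%s) in %s", I_FILE, root_dir),
         call. = FALSE)
  }
  parsed <- parse_investigation_file(ipath)
  top <- parsed$top
  ib <- top[["INVESTIGATION"]] %||% list()
  one <- function(block, key) {
    v <- block[[key]]
    if (is.null(v) || length(v) == 0) NULL else v[[1]]
  }
  pubs <- top[["INVESTIGATION PUBLICATIONS"]][["Investigation Publication DOI"]]
  pubs <- pubs[!is.na(pubs) & pubs != ""]
  extras <- list()
  studies <- list()
  for (sb in parsed$studies) {
    stb <- sb[["STUDY"]] %||% list()
    # study scalar fields via the registry headers embedded in Comment keys
    row <- list(
      "Study unique ID" = one(stb, "Study Identifier"),
      "Study title" = one(stb, "Study Title"),
      "Study description" = one(stb, "Study Description"))
    known <- registry_for("Study")$header
    for (key in names(stb)) {
      m <- regmatches(key, regexec("^Comment\\[MIAPPE: (.*)\\]$", key))[[1]]
      if (length(m) == 2) {
        if (m[2] %in% known) row[[m[2]]] <- one(stb, key)
        else if (!m[2] %in% c("Trait definition file", "Events file")) {
          extras[[key]] <- one(stb, key)
        }
      }
    }
    des <- sb[["STUDY DESIGN DESCRIPTORS"]] %||% list()
    row[["Type of experimental design"]] <- one(des, "Study Design Type")
    row[["Type of experimental design accession"]] <-
      one(des, "Study Design Type Term Accession Number")
    row[["Description of the experimental design"]] <-
      one(des, mcomment("Description of the experimental design"))
    st_rec <- record_unflatten(row, "Study")
    # factors
    fb <- sb[["STUDY FACTORS"]] %||% list()
    fnames <- fb[["Study Factor Name"]] %||% character(0)
    faccs <- fb[["Study Factor Type Term Accession Number"]] %||% character(0)
    fdescs <- fb[[mcomment("Experimental factor description")]] %||% character(0)
    fvals <- fb[[mcomment("Experimental factor values")]] %||% character(0)
    at <- function(v, i) if (i <= length(v)) v[[i]] else ""
    factors <- list()
    for (i in seq_along(fnames)) {
      if (fnames[[i]] == "" && at(faccs, i) == "") next
      factors[[length(factors) + 1]] <- miappe_factor(
        type = ontology_ref(fnames[[i]], at(faccs, i)),
        description = at(fdescs, i), values = split_list(at(fvals, i)))
    }
    # assays / data files
    ab <- sb[["STUDY ASSAYS"]] %||% list()
    a_files <- ab[["Study Assay File Name"]] %||% character(0)
    links <- ab[[mcomment("Data file link")]] %||% character(0)
    descs <- ab[[mcomment("Data file description")]] %||% character(0)
    vers <- ab[[mcomment("Data file version")]] %||% character(0)
    data_files <- list()
    for (i in seq_along(a_files)) {
      if (a_files[[i]] == "") next
      data_files[[length(data_files) + 1]] <- miappe_data_file(
        link = at(links, i), description = at(descs, i), version = at(vers, i))
    }
    # protocols: Growth carries cultural practices + environment parameters
    pb <- sb[["STUDY PROTOCOLS"]] %||% list()
    pnames <- pb[["Study Protocol Name"]] %||% character(0)
    pdescs <- pb[["Study Protocol Description"]] %||% character(0)
    pparams <- pb[["Study Protocol Parameters Name"]] %||% character(0)
    pvals <- pb[[mcomment("Environment parameter values")]] %||% character(0)
    environments <- list()
    gi <- match("Growth", pnames)
    if (!is.na(gi)) {
      if (at(pdescs, gi) != "") st_rec$cultural_practices <- at(pdescs, gi)
      en <- split_list(at(pparams, gi)) %||% character(0)
      ev <- split_list(at(pvals, gi)) %||% character(0)
      for (i in seq_along(en)) {
        environments[[length(environments) + 1]] <-
          miappe_environment(en[[i]], at(ev, i))
      }
    }
    # referenced per-study tables
    s_file <- one(stb, "Study File Name")
    stab <- read_table_file(file.path(root_dir, s_file))
    bm_headers <- setdiff(registry_for("Biological material")$header,
                          "Biological material ID")
    bms <- list(); bm_seen <- character(0)
    ous <- list()
    fv_cols <- grep("^Factor Value\\[", stab$header, value = TRUE)
    for (r in stab$rows) {
      src <- cell_of(stab, r, "Source Name")
      if (src != "" && !(src %in% bm_seen)) {
        brow <- list("Biological material ID" = src)
        for (h in bm_headers) {
          brow[[h]] <- cell_of(stab, r, sprintf("Characteristics[%s]", h))
        }
        bms[[length(bms) + 1]] <- record_unflatten(brow, "Biological material")
        bm_seen <- c(bm_seen, src)
      }
      sample_name <- cell_of(stab, r, "Sample Name")
      if (sample_name == "") next
      fv <- list()
      for (col in fv_cols) {
        v <- cell_of(stab, r, col)
        if (v != "") fv[[sub("^Factor Value\\[(.*)\\]$", "\\1", col)]] <- v
      }
      ous[[length(ous) + 1]] <- miappe_observation_unit(
        id = sample_name,
        level = cell_of(stab, r, mcomment("Observation unit level")),
        biological_material_id = if (src != "") src else NULL,
        external_ref = cell_of(stab, r, mcomment("External ID")),
        spatial_distribution =
          split_kv(cell_of(stab, r, mcomment("Spatial distribution"))),
        factor_values = if (length(fv)) fv else NULL)
    }
    # trait definition file
    tdf_file <- one(stb, mcomment("Trait definition file"))
    variables <- list()
    if (!is.null(tdf_file) && tdf_file != "") {
      ttab <- read_table_file(file.path(root_dir, tdf_file))
      for (r in ttab$rows) {
        vrow <- stats::setNames(as.list(r), ttab$header)
        variables[[length(variables) + 1]] <-
          record_unflatten(vrow, "Observed variable")
      }
    }
    # events file
    ev_file <- one(stb, mcomment("Events file"))
    events <- list()
    if (!is.null(ev_file) && ev_file != "") {
      etab <- read_table_file(file.path(root_dir, ev_file))
      for (r in etab$rows) {
        events[[length(events) + 1]] <- miappe_event(
          type = ontology_ref(cell_of(etab, r, "Event type"),
                              cell_of(etab, r, "Event type accession")),
          description = cell_of(etab, r, "Event description"),
          date = cell_of(etab, r, "Event date"),
          affected_units =
            split_list(cell_of(etab, r, "Affected observation units")))
      }
    }
    # samples from assay files
    samples <- list(); sample_seen <- list()
    for (a_file in a_files) {
      if (a_file == "") next
      atab <- read_table_file(file.path(root_dir, a_file))
      if (!"Extract Name" %in% atab$header) next
      for (r in atab$rows) {
        ext <- cell_of(atab, r, "Extract Name")
        if (ext == "") next
        rec <- miappe_sample(
          id = ext,
          observation_unit_id = split_list(cell_of(atab, r, "Sample Name")),
          description = cell_of(atab, r, mcomment("Sample description")),
          plant_anatomical_entity = ontology_ref(
            cell_of(atab, r, mcomment("Plant anatomical entity")),
            cell_of(atab, r, mcomment("Plant anatomical entity accession"))),
          plant_structure_development_stage = ontology_ref(
            cell_of(atab, r, mcomment("Plant structure development stage")),
            cell_of(atab, r,
                    mcomment("Plant structure development stage accession"))),
          collection_date = cell_of(atab, r, mcomment("Sample collection date")),
          external_id = cell_of(atab, r, mcomment("External sample ID")))
        if (!is.null(sample_seen[[ext]])) {
          if (!identical(sample_seen[[ext]], rec)) {
            stop(sprintf("sample '%s' has conflicting definitions across assays",
                         ext), call. = FALSE)
          }
          next
        }
        sample_seen[[ext]] <- rec
        samples[[length(samples) + 1]] <- rec
      }
    }
    st_rec$factors <- factors
    st_rec$data_files <- data_files
    st_rec$environments <- environments
    st_rec$biological_materials <- bms
    st_rec$observation_units <- ous
    st_rec$observed_variables <- variables
    st_rec$events <- events
    st_rec$samples <- samples
    st_rec$persons <- persons_from_block(sb[["STUDY CONTACTS"]] %||% list(),
                                         "Study")
    # normalise through the constructor pathway
    studies[[length(studies) + 1]] <- do.call(miappe_study, list(
      id = st_rec$id, title = st_rec$title, description = st_rec$description,
      start_date = st_rec$start_date, end_date = st_rec$end_date,
      contact_institution = st_rec$contact_institution,
      location = if (length(st_rec$locations %||% list()) >= 1)
        st_rec$locations[[1]] else NULL,
      experimental_design = st_rec$experimental_design,
      growth_facility = st_rec$growth_facility,
      cultural_practices = st_rec$cultural_practices,
      observation_unit_level_hierarchy = st_rec$observation_unit_level_hierarchy,
      data_files = data_files, biological_materials = bms,
      environments = environments, factors = factors, events = events,
      observation_units = ous, samples = samples,
      observed_variables = variables, persons = st_rec$persons))
  }
  inv <- miappe_investigation(
    id = one(ib, "Investigation Identifier"),
    title = one(ib, "Investigation Title"),
    description = one(ib, "Investigation Description"),
    submission_date = one(ib, "Investigation Submission Date"),
    public_release_date = one(ib, "Investigation Public Release Date"),
    license = one(ib, mcomment("License")),
    miappe_version = one(ib, mcomment("MIAPPE version")),
    publications = pubs,
    persons = persons_from_block(top[["INVESTIGATION CONTACTS"]] %||% list(),
                                 "Investigation"),
    studies = studies)
  build_dataset(inv, provenance = list(format = "isatab", dir = root_dir,
                                       extras = extras))
}

#' ISA-Tab column map
#'
#' Enumerates where every MIAPPE checklist field lands in the ISA-Tab writer:
#' a completeness walk over [miappe_field_registry()] guaranteeing no field is
#' silently dropped.
#'
#' @return A data.frame with columns `section`, `header`, `isatab`.
#' @export
isatab_column_map <- function() {
  reg <- miappe_field_registry()
  place <- character(nrow(reg))
  for (i in seq_len(nrow(reg))) {
    s <- reg$section[i]; h <- reg$header[i]
    place[i] <- if (s == "Investigation") {
      switch(h,
        "Investigation unique ID" = "Investigation Identifier",
        "Investigation title" = "Investigation Title",
        "Investigation description" = "Investigation Description",
        "Submission date" = "Investigation Submission Date",
        "Public release date" = "Investigation Public Release Date",
        "Associated publication" = "Investigation Publication DOI",
        mcomment(h))
    } else if (s == "Study") {
      switch(h,
        "Study unique ID" = "Study Identifier",
        "Study title" = "Study Title",
        "Study description" = "Study Description",
        "Type of experimental design" = "Study Design Type",
        "Type of experimental design accession" =
          "Study Design Type Term Accession Number",
        "Description of the experimental design" = mcomment(h),
        "Cultural practices" = "Study Protocol Description (Growth)",
        mcomment(h))
    } else if (s == "Person") {
      switch(h, "Person ID" = mcomment(h), paste("Investigation/Study", h))
    } else if (s == "Data file") {
      mcomment(h)
    } else if (s == "Biological material") {
      if (h == "Biological material ID") "Source Name"
      else sprintf("Characteristics[%s]", h)
    } else if (s == "Environment") {
      if (h == "Environment parameter")
        "Study Protocol Parameters Name (Growth)"
      else mcomment("Environment parameter values")
    } else if (s == "Experimental factor") {
      switch(h,
        "Experimental factor type" = "Study Factor Name",
        "Experimental factor type accession" =
          "Study Factor Type Term Accession Number",
        mcomment(h))
    } else if (s == "Event") {
      paste("Events file:", h)
    } else if (s == "Observation unit") {
      switch(h,
        "Observation unit ID" = "Sample Name",
        "Biological material ID" = "Source Name (reference)",
        "Observation unit factor values" = "Factor Value[<factor>]",
        mcomment(h))
    } else if (s == "Sample") {
      switch(h,
        "Sample ID" = "Extract Name",
        "Observation unit ID" = "Sample Name (assay)",
        mcomment(h))
    } else {
      paste("Trait definition file:", h)
    }
  }
  data.frame(section = reg$section, header = reg$header, isatab = place,
             stringsAsFactors = FALSE)
}
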