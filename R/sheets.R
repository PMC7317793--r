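# Spreadsheet workbook serialization: one worksheet per checklist section,
# header row of checklist field names, cross-sheet references through id
# columns. The biologist-facing format. The canonical on-disk form is a
# directory of TSV files (one per worksheet, same headers); .xlsx workbooks
# are read through readxl when available. "; " is the in-cell list separator,
# so leaf values may not contain ";" (rejected on write).

sheet_link_header <- "Study id"

sheet_file_of <- function(section) paste0(section, ".tsv")

assert_record_sep_free <- function(record, where) {
  leaves <- unlist(record, use.names = FALSE)
  leaves <- leaves[is.character(leaves)]
  # kv pairs additionally reserve ": " between key and value
  keys <- names(unlist(record))
  if (any(grepl(";", leaves, fixed = TRUE))) {
    stop(sprintf("value containing reserved separator ';' cannot be written (%s)",
                 where), call. = FALSE)
  }
  invisible(record)
}

sheet_headers_of <- function(section) {
  h <- registry_for(section)$header
  if (section != "Investigation") h <- c(h, sheet_link_header)
  h
}

#' Write a dataset as a spreadsheet workbook (TSV directory)
#'
#' One file per checklist section, named after the section with a header row
#' of checklist field names. One row per record; one-to-many links are
#' encoded by a `Study id` column on the child sheet (blank for
#' investigation-level persons; a "; "-joined list for biological materials
#' and observed variables shared across studies). List-valued fields are
#' joined with "; ".
#'
#' @param dataset A `miappe_dataset`.
#' @param path Target directory (created if needed).
#' @return The path, invisibly.
#' @export
write_sheets <- function(dataset, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  inv <- dataset$investigation
  tables <- stats::setNames(
    lapply(miappe_sections(), function(s) list()), miappe_sections())
  add_row <- function(section, record, owner) {
    assert_record_sep_free(record, section)
    row <- record_flatten(record, section)
    if (section != "Investigation") {
      row <- c(row, stats::setNames(owner, sheet_link_header))
    }
    tables[[section]][[length(tables[[section]]) + 1]] <<- row
  }
  add_row("Investigation", inv, NULL)
  for (p in inv$persons %||% list()) add_row("Person", p, "")
  shared_owner <- function(section, id) {
    paste(sort(dataset$owners[[section]][[id]] %||% character(0)),
          collapse = LIST_SEP)
  }
  seen_shared <- list()
  for (st in dataset_studies(dataset)) {
    sid <- st$id %||% ""
    add_row("Study", st, "")
    for (p in st$persons %||% list()) add_row("Person", p, sid)
    for (df in st$data_files %||% list()) add_row("Data file", df, sid)
    for (en in st$environments %||% list()) add_row("Environment", en, sid)
    for (fa in st$factors %||% list()) add_row("Experimental factor", fa, sid)
    for (ev in st$events %||% list()) add_row("Event", ev, sid)
    for (ou in st$observation_units %||% list()) {
      add_row("Observation unit", ou, sid)
    }
    for (sm in st$samples %||% list()) add_row("Sample", sm, sid)
    for (bm in st$biological_materials %||% list()) {
      key <- paste("Biological material", bm$id %||% "")
      if (is.null(seen_shared[[key]])) {
        seen_shared[[key]] <- TRUE
        add_row("Biological material", bm,
                shared_owner("Biological material", bm$id %||% ""))
      }
    }
    for (ov in st$observed_variables %||% list()) {
      key <- paste("Observed variable", ov$id %||% "")
      if (is.null(seen_shared[[key]])) {
        seen_shared[[key]] <- TRUE
        add_row("Observed variable", ov,
                shared_owner("Observed variable", ov$id %||% ""))
      }
    }
  }
  for (section in miappe_sections()) {
    headers <- sheet_headers_of(section)
    lines <- paste(headers, collapse = "\t")
    for (row in tables[[section]]) {
      cells <- vapply(headers, function(h) {
        v <- row[[h]] %||% ""
        if (is.na(v)) "" else v
      }, character(1))
      check_cells(cells, sheet_file_of(section))
      lines <- c(lines, paste(cells, collapse = "\t"))
    }
    write_cells(lines, file.path(path, sheet_file_of(section)))
  }
  invisible(path)
}

# read one sheet into list(header=..., rows=list of named character lists)
read_sheet_table <- function(path) {
  tab <- read_table_file(path)
  rows <- lapply(tab$rows, function(r) stats::setNames(as.list(r), tab$header))
  list(header = tab$header, rows = rows)
}

read_xlsx_tables <- function(path) {
  if (!requireNamespace("readxl", quietly = TRUE)) {
    stop("reading .xlsx workbooks requires the readxl package", call. = FALSE)
  }
  out <- list()
  for (sheet in readxl::excel_sheets(path)) {
    df <- readxl::read_excel(path, sheet = sheet, col_types = "text")
    header <- colnames(df)
    rows <- lapply(seq_len(nrow(df)), function(i) {
      vals <- as.character(unlist(df[i, ], use.names = FALSE))
      vals[is.na(vals)] <- ""
      stats::setNames(as.list(vals), header)
    })
    out[[sheet]] <- list(header = header, rows = rows)
  }
  out
}

#' Read a spreadsheet workbook
#'
#' Accepts either a directory of per-section TSV files (the form
#' [write_sheets()] produces) or an `.xlsx` workbook with one worksheet per
#' section. The `Investigation` and `Study` sheets are mandatory; each
#' sheet's header row must start with the shipped field-name headers for that
#' section (error naming sheet and column otherwise); unknown extra columns
#' are preserved in the provenance side-map and unknown sheets are ignored
#' with a notice.
#'
#' @param path Directory or `.xlsx` file.
#' @return A `miappe_dataset`.
#' @export
read_sheets <- function(path) {
  tables <- if (dir.exists(path)) {
    found <- list()
    for (f in list.files(path, pattern = "\\.tsv$")) {
      found[[sub("\\.tsv$", "", f)]] <- read_sheet_table(file.path(path, f))
    }
    found
  } else if (grepl("\\.xlsx$", path, ignore.case = TRUE)) {
    read_xlsx_tables(path)
  } else {
    stop(sprintf("not a workbook: %s (need a directory of TSV sheets or .xlsx)",
                 path), call. = FALSE)
  }
  for (mandatory in c("Investigation", "Study")) {
    if (is.null(tables[[mandatory]])) {
      stop(sprintf("missing mandatory sheet '%s'", mandatory), call. = FALSE)
    }
  }
  unknown_sheets <- setdiff(names(tables), miappe_sections())
  if (length(unknown_sheets)) {
    message("ignoring unknown sheet(s): ", paste(unknown_sheets, collapse = ", "))
    tables <- tables[intersect(names(tables), miappe_sections())]
  }
  extras <- list()
  for (section in names(tables)) {
    expected <- sheet_headers_of(section)
    got <- tables[[section]]$header
    n <- length(expected)
    if (length(got) < n || !identical(got[seq_len(n)], expected)) {
      bad <- if (length(got) < n) expected[length(got) + 1] else
        expected[which(got[seq_len(n)] != expected)[1]]
      stop(sprintf("sheet '%s': header mismatch at column '%s'", section, bad),
           call. = FALSE)
    }
    if (length(got) > n) extras[[section]] <- got[(n + 1):length(got)]
  }
  owner_of <- function(row) row[[sheet_link_header]] %||% ""
  inv_rows <- tables[["Investigation"]]$rows
  if (length(inv_rows) == 0) stop("Investigation sheet has no rows",
                                  call. = FALSE)
  inv_rec <- record_unflatten(inv_rows[[1]], "Investigation")
  # group child rows per study id
  children <- function(section) {
    if (is.null(tables[[section]])) return(list())
    tables[[section]]$rows
  }
  study_rows <- tables[["Study"]]$rows
  studies <- lapply(study_rows, function(srow) {
    st <- record_unflatten(srow, "Study")
    sid <- st$id %||% ""
    for_study <- function(section, multi = FALSE) {
      Filter(function(row) {
        owner <- owner_of(row)
        if (multi) sid %in% (split_list(owner) %||% "") else
          identical(owner, sid)
      }, children(section))
    }
    recs <- function(section, multi = FALSE) {
      lapply(for_study(section, multi),
             function(row) record_unflatten(row, section))
    }
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
      data_files = recs("Data file"),
      biological_materials = recs("Biological material", multi = TRUE),
      environments = recs("Environment"),
      factors = recs("Experimental factor"),
      events = recs("Event"),
      observation_units = recs("Observation unit"),
      samples = recs("Sample"),
      observed_variables = recs("Observed variable", multi = TRUE),
      persons = recs("Person"))
  })
  inv_persons <- lapply(
    Filter(function(row) identical(owner_of(row), ""), children("Person")),
    function(row) record_unflatten(row, "Person"))
  inv <- miappe_investigation(
    id = inv_rec$id, title = inv_rec$title, description = inv_rec$description,
    submission_date = inv_rec$submission_date,
    public_release_date = inv_rec$public_release_date,
    license = inv_rec$license, miappe_version = inv_rec$miappe_version,
    publications = inv_rec$publications,
    persons = inv_persons, studies = studies)
  build_dataset(inv, provenance = list(format = "sheets", path = path,
                                       extras = extras))
}
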