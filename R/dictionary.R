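#' Data dictionaries with uniform variable-group tagging
#'
#' A data dictionary records, for every variable in every contributing study:
#' its name as it appears in the study master file, a short label, a detailed
#' description, the unit of measurement, the format (continuous, categorical,
#' free text or date), the declared category labels for categorical variables,
#' the wave of assessment, the respondent, and a *variable group* — a
#' construct-level tag applied uniformly across studies so that every variable
#' measuring the same characteristic (e.g. `"School_travel"`) can be located
#' with one query.
#'
#' A `study_dictionary` is a tibble with columns
#' `study_id, variable_id, name, label, description, unit, format, categories,
#' variable_group, wave, respondent`, where `categories` is a list-column of
#' ordered character vectors.
#'
#' @name study_dictionary
NULL

DICTIONARY_COLUMNS <- c("study_id", "variable_id", "name", "label",
                        "description", "unit", "format", "categories",
                        "variable_group", "wave", "respondent")
DICTIONARY_FORMATS <- c("continuous", "categorical", "free_text", "date")
RESPONDENTS <- c("child", "parent", "teacher", "objective", "unknown")

#' Construct a validated data dictionary
#'
#' @param entries Tibble (or data frame) with the canonical dictionary columns.
#'   `categories` may be a list-column of character vectors or a character
#'   column of `";"`-delimited labels.
#' @return A `study_dictionary` object.
#' @export
new_dictionary <- function(entries) {
  entries <- as_tibble(entries)
  missing_cols <- setdiff(DICTIONARY_COLUMNS, names(entries))
  if (length(missing_cols)) {
    abort(paste0("dictionary is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "harmonisr_format_error")
  }
  extra <- setdiff(names(entries), DICTIONARY_COLUMNS)
  if (length(extra)) {
    abort(paste0("dictionary has unknown column(s): ",
                 paste(extra, collapse = ", ")),
          class = "harmonisr_format_error")
  }
  entries <- entries[DICTIONARY_COLUMNS]
  entries$study_id <- as.character(entries$study_id)
  entries$variable_id <- as.integer(entries$variable_id)
  entries$wave <- as.integer(entries$wave)
  if (!is.list(entries$categories)) {
    entries$categories <- split_categories(entries$categories)
  }
  for (col in c("name", "label", "description", "unit", "format",
                "variable_group", "respondent")) {
    entries[[col]] <- as.character(entries[[col]])
  }
  entries$respondent[is.na(entries$respondent) | entries$respondent == ""] <-
    "unknown"
  dict <- structure(entries, class = c("study_dictionary", class(entries)))
  validate_dictionary(dict)
  dict
}

split_categories <- function(x) {
  lapply(as.character(x), function(s) {
    if (is.na(s) || !nzchar(s)) character(0) else trimws(strsplit(s, ";", fixed = TRUE)[[1]])
  })
}

join_categories <- function(x) {
  vapply(x, function(cats) {
    if (length(cats) == 0) "" else paste(cats, collapse = ";")
  }, character(1))
}

#' Validate a data dictionary
#'
#' Checks the dictionary invariants: unique `(study_id, variable_id)` and
#' `(study_id, name)` keys, valid `format` and `respondent` values, non-empty
#' variable groups, declared category labels for every categorical entry, and
#' agreement between the `wave` field and any wave prefix in the name. A
#' linter warning is raised when two variable groups differ only by case,
#' which would silently fragment a construct.
#'
#' @param dict A `study_dictionary`.
#' @return `dict`, invisibly, if valid; otherwise an error is signalled.
#' @export
validate_dictionary <- function(dict) {
  dup_id <- duplicated(dict[c("study_id", "variable_id")]) |
    duplicated(dict[c("study_id", "variable_id")], fromLast = TRUE)
  if (any(dup_id)) {
    offenders <- dict[dup_id, c("study_id", "variable_id", "name")]
    abort(paste0("duplicate (study_id, variable_id): ",
                 paste(sprintf("%s:%d (%s)", offenders$study_id,
                               offenders$variable_id, offenders$name),
                       collapse = ", ")),
          class = "harmonisr_integrity_error")
  }
  dup_name <- duplicated(dict[c("study_id", "name")]) |
    duplicated(dict[c("study_id", "name")], fromLast = TRUE)
  if (any(dup_name)) {
    offenders <- dict[dup_name, ]
    abort(paste0("duplicate (study_id, name): ",
                 paste(sprintf("%s/%s has variable_ids %s", offenders$study_id,
                               offenders$name, offenders$variable_id),
                       collapse = "; ")),
          class = "harmonisr_integrity_error")
  }
  bad_format <- !dict$format %in% DICTIONARY_FORMATS
  if (any(bad_format)) {
    abort(paste0("invalid format value(s): ",
                 paste(unique(dict$format[bad_format]), collapse = ", "),
                 " (must be one of ",
                 paste(DICTIONARY_FORMATS, collapse = ", "), ")"),
          class = "harmonisr_format_error")
  }
  bad_resp <- !dict$respondent %in% RESPONDENTS
  if (any(bad_resp)) {
    abort(paste0("invalid respondent value(s): ",
                 paste(unique(dict$respondent[bad_resp]), collapse = ", ")),
          class = "harmonisr_format_error")
  }
  no_group <- is.na(dict$variable_group) | !nzchar(trimws(dict$variable_group))
  if (any(no_group)) {
    abort(paste0("entries without a variable_group: ",
                 paste(sprintf("%s/%s", dict$study_id[no_group],
                               dict$name[no_group]), collapse = ", ")),
          class = "harmonisr_integrity_error")
  }
  cat_missing <- dict$format == "categorical" &
    vapply(dict$categories, length, integer(1)) == 0L
  if (any(cat_missing)) {
    abort(paste0("categorical entries must declare their category labels: ",
                 paste(sprintf("%s/%s", dict$study_id[cat_missing],
                               dict$name[cat_missing]), collapse = ", ")),
          class = "harmonisr_integrity_error")
  }
  prefix_wave <- parse_wave_prefix(dict$name)
  conflict <- !is.na(prefix_wave) & !is.na(dict$wave) & prefix_wave != dict$wave
  if (any(conflict)) {
    abort(paste0("wave field conflicts with name prefix: ",
                 paste(sprintf("%s/%s (wave %d, prefix %d)",
                               dict$study_id[conflict], dict$name[conflict],
                               dict$wave[conflict], prefix_wave[conflict]),
                       collapse = ", ")),
          class = "harmonisr_integrity_error")
  }
  groups <- unique(dict$variable_group)
  folded <- tolower(groups)
  if (anyDuplicated(folded)) {
    clash <- groups[folded %in% folded[duplicated(folded)]]
    warn(paste0("variable groups differing only by case (possible construct ",
                "fragmentation): ", paste(sort(clash), collapse = ", ")),
         class = "harmonisr_group_case_warning")
  }
  invisible(dict)
}

#' Read a data dictionary from CSV
#'
#' The CSV carries the canonical header
#' `study_id,variable_id,name,label,description,unit,format,categories,variable_group,wave,respondent`
#' in UTF-8; empty fields are null and `categories` is a `";"`-delimited
#' ordered list of labels (labels must not contain `";"`).
#'
#' @param path Path to the dictionary CSV.
#' @return A validated `study_dictionary`.
#' @export
read_dictionary <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("dictionary file not found: ", path),
          class = "harmonisr_format_error")
  }
  header <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE,
                                  name_repair = "minimal"))
  if (anyDuplicated(header)) {
    abort(paste0("duplicate dictionary column(s): ",
                 paste(unique(header[duplicated(header)]), collapse = ", ")),
          class = "harmonisr_format_error")
  }
  if (!setequal(header, DICTIONARY_COLUMNS) ||
      length(header) != length(DICTIONARY_COLUMNS)) {
    missing_cols <- setdiff(DICTIONARY_COLUMNS, header)
    extra <- setdiff(header, DICTIONARY_COLUMNS)
    abort(paste0("dictionary header mismatch",
                 if (length(missing_cols)) paste0("; missing: ",
                   paste(missing_cols, collapse = ", ")) else "",
                 if (length(extra)) paste0("; unexpected: ",
                   paste(extra, collapse = ", ")) else ""),
          class = "harmonisr_format_error")
  }
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      study_id = readr::col_character(),
      variable_id = readr::col_integer(),
      name = readr::col_character(),
      label = readr::col_character(),
      description = readr::col_character(),
      unit = readr::col_character(),
      format = readr::col_character(),
      categories = readr::col_character(),
      variable_group = readr::col_character(),
      wave = readr::col_integer(),
      respondent = readr::col_character()
    ),
    na = "", show_col_types = FALSE
  )
  new_dictionary(raw)
}

#' Write a data dictionary to canonical CSV
#'
#' Writes the canonical column order with minimal quoting and empty fields for
#' nulls, so that `write_dictionary(read_dictionary(f))` is byte-identical to
#' the canonicalised form of `f`.
#'
#' @param dict A `study_dictionary`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dictionary <- function(dict, path) {
  out <- as_tibble(dict)
  out$categories <- join_categories(out$categories)
  out$categories[out$categories == ""] <- NA_character_
  atomic_write(function(tmp) {
    readr::write_csv(out, tmp, na = "", quote = "needed", eol = "\n")
  }, path)
}

#' Query a dictionary by variable group
#'
#' Variable groups are shared vocabulary across studies: querying a group
#' returns every entry tagged with it in any study, ordered by
#' `(study_id, wave, variable_id)`. Matching is exact and case-sensitive; an
#' unknown group returns an empty result.
#'
#' @param dict A `study_dictionary`.
#' @param group Variable-group tag, e.g. `"School_travel"`.
#' @return A tibble of matching dictionary entries.
#' @export
query_by_group <- function(dict, group) {
  stopifnot(is.character(group), length(group) == 1L)
  hits <- as_tibble(dict)[dict$variable_group == group, ]
  hits[order(hits$study_id, hits$wave, hits$variable_id,
             na.last = FALSE, method = "radix"), ]
}

#' Build a dictionary from a study table and column annotations
#'
#' Catalogues a study master file: one dictionary entry per annotated column,
#' with the wave parsed from the `W<digits>_` name prefix (unprefixed columns
#' are time-invariant unless the annotation supplies a wave). Variable ids are
#' assigned sequentially in annotation order.
#'
#' @param study_id Study identifier.
#' @param table Wide study table (first column the participant id), or `NULL`
#'   to catalogue from annotations alone.
#' @param metadata Tibble of per-column annotations with columns `name`,
#'   `label`, `description`, `unit`, `format`, `categories` (";"-delimited or
#'   list), `variable_group`, `respondent`, and optionally `wave`.
#' @return A validated `study_dictionary` for the study.
#' @export
catalogue_study <- function(study_id, table = NULL, metadata) {
  metadata <- as_tibble(metadata)
  if (!is.null(table)) {
    data_cols <- setdiff(names(table), names(table)[1])
    uncovered <- setdiff(data_cols, metadata$name)
    if (length(uncovered)) {
      abort(paste0("metadata does not cover column(s): ",
                   paste(uncovered, collapse = ", ")),
            class = "harmonisr_format_error")
    }
  }
  prefix_wave <- parse_wave_prefix(metadata$name)
  wave <- if ("wave" %in% names(metadata)) as.integer(metadata$wave) else
    rep(NA_integer_, nrow(metadata))
  conflict <- !is.na(wave) & !is.na(prefix_wave) & wave != prefix_wave
  if (any(conflict)) {
    abort(paste0("annotated wave conflicts with name prefix: ",
                 paste(metadata$name[conflict], collapse = ", ")),
          class = "harmonisr_integrity_error")
  }
  wave <- ifelse(is.na(wave), prefix_wave, wave)
  n <- nrow(metadata)
  grab <- function(col, default = NA_character_) {
    if (col %in% names(metadata)) metadata[[col]] else rep(default, n)
  }
  new_dictionary(tibble(
    study_id = study_id,
    variable_id = seq_len(n),
    name = metadata$name,
    label = grab("label"),
    description = grab("description"),
    unit = grab("unit"),
    format = grab("format"),
    categories = grab("categories"),
    variable_group = grab("variable_group"),
    wave = wave,
    respondent = grab("respondent", "unknown")
  ))
}

#' Combine per-study dictionaries into one
#'
#' @param ... `study_dictionary` objects.
#' @return A single validated `study_dictionary` covering all studies.
#' @export
bind_dictionaries <- function(...) {
  parts <- lapply(list(...), as_tibble)
  new_dictionary(dplyr::bind_rows(parts))
}

#' @export
print.study_dictionary <- function(x, ...) {
  cat(sprintf("<study_dictionary> %d entries, %d studies, %d variable groups\n",
              nrow(x), length(unique(x$study_id)),
              length(unique(x$variable_group))))
  NextMethod()
}

# Dictionary lookup for a single (study, name); errors if absent.
dict_entry <- function(dict, study_id, name) {
  hit <- dict$study_id == study_id & dict$name == name
  if (!any(hit)) {
    abort(sprintf("variable '%s' is not in the dictionary for study '%s'",
                  name, study_id),
          class = "harmonisr_spec_error")
  }
  as_tibble(dict)[hit, ][1, ]
}
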