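#' Harmonisation engine
#'
#' Applies harmonisation specs to per-study wide tables, resolves competing
#' sources, pools study-wave fragments into one long dataset, and tabulates
#' category counts. Every transformation is deterministic: identical inputs
#' and spec yield identical output after the canonical
#' `(study_id, wave, participant_id, variable)` sort.
#'
#' @name engine
NULL

#' Read a study master table from CSV
#'
#' Study tables are wide (one row per participant), UTF-8, first column the
#' participant id, remaining columns named as in the study dictionary with
#' `W<digits>_` wave prefixes where applicable. The canonical missing sentinel
#' is the empty field; study-specific numeric missing codes (e.g. `9`, `-99`)
#' are declared per variable via `missing_codes` and translated to missing on
#' load.
#'
#' @param path CSV path.
#' @param study_id Study identifier attached to the table.
#' @param missing_codes Optional named list: variable name -> vector of native
#'   missing codes to translate to the missing sentinel.
#' @return A tibble with attributes `study_id` and `missing_code_log`.
#' @export
read_study_table <- function(path, study_id, missing_codes = NULL) {
  tab <- readr::read_csv(path, na = "", show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_guess()))
  as_study_table(tab, study_id, missing_codes = missing_codes)
}

#' Mark a wide tibble as a study table
#'
#' @param table Wide tibble, first column the participant id.
#' @param study_id Study identifier.
#' @inheritParams read_study_table
#' @return The table with study metadata attached; participant ids must be
#'   unique within the study.
#' @export
as_study_table <- function(table, study_id, missing_codes = NULL) {
  table <- as_tibble(table)
  ids <- table[[1]]
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate participant ids in study '%s': %s", study_id,
                  paste(utils::head(unique(ids[duplicated(ids)]), 5),
                        collapse = ", ")),
          class = "harmonisr_integrity_error")
  }
  log <- list()
  for (var in names(missing_codes)) {
    if (!var %in% names(table)) next
    hit <- table[[var]] %in% missing_codes[[var]]
    if (any(hit)) {
      table[[var]][hit] <- NA
      log[[var]] <- sum(hit)
    }
  }
  attr(table, "study_id") <- study_id
  attr(table, "missing_code_log") <- log
  table
}

#' Write a study table to CSV
#'
#' @param table Study table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_study_table <- function(table, path) {
  atomic_write(function(tmp) {
    readr::write_csv(as_tibble(table), tmp, na = "", quote = "needed",
                     eol = "\n")
  }, path)
}

#' Apply a category map to a column
#'
#' Each non-missing value is matched (after NFC normalisation and whitespace
#' trimming) against the rule's mapping; the missing sentinel becomes
#' `"Missing"`. Unmapped values raise an error naming the value and context
#' under `unmapped_policy = "error"`, or become `"Missing"` under
#' `"missing"`.
#'
#' @param x Character (or coercible) vector of source categories.
#' @param rule A [category_map_rule()].
#' @param targets Declared target categories (used for sanity checks).
#' @param context Optional string (study/wave) used in error messages.
#' @return Character vector of assigned target categories.
#' @export
apply_category_map <- function(x, rule, targets = NULL, context = NULL) {
  xn <- norm_label(x)
  out <- unname(rule$mapping[xn])
  out[is.na(xn)] <- MISSING_LABEL
  unmapped <- !is.na(xn) & is.na(out)
  if (any(unmapped)) {
    if (rule$unmapped_policy == "error") {
      abort(sprintf("unmapped source value(s)%s: %s",
                    if (is.null(context)) "" else paste0(" in ", context),
                    paste(unique(xn[unmapped]), collapse = ", ")),
            class = "harmonisr_unmapped_error")
    }
    out[unmapped] <- MISSING_LABEL
  }
  if (!is.null(targets)) stopifnot(all(out %in% c(targets, MISSING_LABEL)))
  out
}

#' Assign continuous values to threshold bins
#'
#' Bin *i* accepts values in `(upper[i-1], upper[i]]` (first bin unbounded
#' below, last unbounded above), so every non-negative value lands in exactly
#' one bin. Missing values become `"Missing"`; negative values are a
#' validation error (they indicate upstream data corruption, not missingness).
#'
#' @param x Numeric vector (e.g. journey duration in minutes).
#' @param rule A [threshold_bin_rule()].
#' @param context Optional string for error messages.
#' @return Character vector of bin labels.
#' @export
apply_threshold_bins <- function(x, rule, context = NULL) {
  x <- as.numeric(x)
  neg <- which(!is.na(x) & x < 0)
  if (length(neg)) {
    abort(sprintf("negative duration value(s)%s at row(s) %s",
                  if (is.null(context)) "" else paste0(" in ", context),
                  paste(utils::head(neg, 5), collapse = ", ")),
          class = "harmonisr_validation_error")
  }
  uppers <- vapply(rule$bins, `[[`, numeric(1), "upper")
  labels <- vapply(rule$bins, `[[`, character(1), "label")
  out <- rep(MISSING_LABEL, length(x))
  ok <- !is.na(x)
  # index of the first bin whose inclusive upper bound is >= x: one more than
  # the number of strictly smaller bounds
  idx <- findInterval(x[ok], uppers, left.open = TRUE) + 1L
  out[ok] <- labels[idx]
  out
}

#' Resolve multiple candidate sources to one value per participant
#'
#' Candidates are given in preference order; the first non-missing value is
#' selected. Rows where two or more non-missing candidates disagree are
#' counted as conflicts and, under `conflict_policy = "missing_if_conflict"`,
#' set to missing.
#'
#' @param candidates Data frame / tibble whose columns are the candidate
#'   sources, ordered most- to least-preferred.
#' @param conflict_policy `"prefer_first"` or `"missing_if_conflict"`.
#' @return `list(value = <vector>, conflict = <logical>, n_conflicts = <int>)`.
#' @export
resolve_sources <- function(candidates,
                            conflict_policy = c("prefer_first",
                                                "missing_if_conflict")) {
  conflict_policy <- match.arg(conflict_policy)
  candidates <- as_tibble(candidates)
  mat <- as.data.frame(candidates)
  value <- mat[[1]]
  for (j in seq_along(mat)[-1]) {
    take <- is.na(value) & !is.na(mat[[j]])
    value[take] <- mat[[j]][take]
  }
  conflict <- apply(mat, 1L, function(row) {
    vals <- unique(row[!is.na(row)])
    length(vals) > 1L
  })
  if (conflict_policy == "missing_if_conflict") value[conflict] <- NA
  list(value = value, conflict = conflict, n_conflicts = sum(conflict))
}

#' Reassign residual missing values by logical inference
#'
#' When an instrument only asked about a subset of categories (e.g. walking
#' and cycling only), a participant answering negatively to every indicator
#' has logically determined their category even though no source category was
#' recorded. Rows whose base assignment is `"Missing"` and whose indicators
#' are all negative are reassigned to the rule's inferred category; all other
#' rows are unchanged.
#'
#' @param indicators Data frame of indicator responses (one column per
#'   indicator named in the rule).
#' @param rule An [inference_rule()].
#' @param base Character vector of base assignments.
#' @return `list(value = <character>, n_inferred = <int>)`.
#' @export
apply_inference <- function(indicators, rule, base) {
  indicators <- as_tibble(indicators)[, rule$indicators, drop = FALSE]
  negative <- vapply(indicators, function(col) {
    coln <- norm_label(col)
    neg <- coln %in% rule$negative_values
    if (rule$treat_missing_as_negative) neg | is.na(coln) else neg
  }, logical(nrow(indicators)))
  if (is.null(dim(negative))) negative <- matrix(negative, nrow = 1L)
  trigger <- rowSums(negative) == ncol(indicators)
  reassign <- base == MISSING_LABEL & trigger
  base[reassign] <- rule$inferred_category
  list(value = base, n_inferred = sum(reassign))
}

# Resolve a source_preference's selectors to concrete column names, using the
# dictionary for respondent-only selectors.
resolve_selector_columns <- function(sources, table, study_id, wave, dict,
                                     variable_group = NULL) {
  vapply(sources$selectors, function(s) {
    if (!is.null(s$variable)) {
      if (!s$variable %in% names(table)) {
        abort(sprintf("source '%s' not present in table for study '%s'",
                      s$variable, study_id),
              class = "harmonisr_spec_error")
      }
      return(s$variable)
    }
    if (is.null(dict)) {
      abort("respondent-only selectors need a dictionary to resolve",
            class = "harmonisr_spec_error")
    }
    pool <- as_tibble(dict)
    hit <- pool$study_id == study_id & pool$respondent == s$respondent &
      (is.na(pool$wave) | pool$wave == wave)
    if (!is.null(variable_group)) {
      hit <- hit & pool$variable_group == variable_group
    }
    hit <- hit & pool$name %in% names(table)
    if (sum(hit) != 1L) {
      abort(sprintf("respondent selector '%s' resolves to %d columns for %s wave %s",
                    s$respondent, sum(hit), study_id, wave),
            class = "harmonisr_spec_error")
    }
    pool$name[hit]
  }, character(1))
}

marginal_counts <- function(x, categories) {
  xn <- norm_label(x)
  categories <- setdiff(categories, MISSING_LABEL)
  counts <- table(factor(xn, levels = categories))
  tibble(category = c(categories, MISSING_LABEL),
         n = c(as.integer(counts),
               sum(is.na(xn) | xn == MISSING_LABEL, na.rm = TRUE)))
}

continuous_summary <- function(x) {
  x <- as.numeric(x)
  ok <- !is.na(x)
  tibble(
    statistic = c("mean", "median", "p25", "p75", "min", "max", "missing_n"),
    value = c(round(mean(x[ok]), 1), stats::median(x[ok]),
              unname(stats::quantile(x[ok], 0.25, type = 2)),
              unname(stats::quantile(x[ok], 0.75, type = 2)),
              min(x[ok]), max(x[ok]), sum(!ok))
  )
}

rule_text <- function(entry) {
  rule <- entry$rule
  if (rule$kind == "exclusion") {
    return(paste0("Excluded: ", rule$reason))
  }
  if (rule$kind == "category_map") {
    by_target <- split(names(rule$mapping), unname(rule$mapping))
    lines <- vapply(names(by_target), function(tgt) {
      sprintf("If [%s] = %s -> %s", rule$source_variable %||% "<resolved source>",
              paste(by_target[[tgt]], collapse = " OR "), tgt)
    }, character(1))
    return(paste(lines, collapse = "; "))
  }
  uppers <- vapply(rule$bins, `[[`, numeric(1), "upper")
  labels <- vapply(rule$bins, `[[`, character(1), "label")
  src <- rule$source_variable %||%
    paste0("duration item selected by [", rule$mode_gate$variable, "]")
  lo <- c(-Inf, uppers[-length(uppers)])
  lines <- sprintf("If [%s] %s -> %s", src,
                   ifelse(is.infinite(lo) & is.finite(uppers),
                          paste0("<= ", uppers),
                          ifelse(is.infinite(uppers),
                                 paste0("> ", lo),
                                 paste0("in (", lo, ", ", uppers, "]"))),
                   labels)
  paste(lines, collapse = "; ")
}

#' Harmonise one study-wave
#'
#' Applies the spec's rule for `(study_id, wave)` to the study table. An
#' excluded wave yields an empty fragment plus an exclusion record; otherwise
#' every participant receives exactly one assigned category. The returned
#' recode record carries the source marginals (or continuous summary), a
#' transcription of the rule applied, the output marginals, and counts of
#' source conflicts and inference reassignments, ready for the provenance
#' report.
#'
#' @param table Study table (see [as_study_table()]).
#' @param spec A `harmonisation_spec`.
#' @param wave Wave to harmonise.
#' @param dict Optional dictionary (needed for respondent-only selectors and
#'   source respondent lookup in the recode record).
#' @return `list(fragment = <tibble>, recode = <list>)`.
#' @export
harmonise_study_wave <- function(table, spec, wave, dict = NULL) {
  study_id <- attr(table, "study_id")
  if (is.null(study_id)) {
    abort("table has no study_id; use as_study_table()",
          class = "harmonisr_spec_error")
  }
  entry <- spec_rule_for(spec, study_id, wave)
  if (is.null(entry)) {
    abort(sprintf("spec '%s' has no rule or exclusion for %s wave %s",
                  spec$name, study_id, wave),
          class = "harmonisr_spec_error")
  }
  context <- sprintf("%s wave %s (%s)", study_id, wave, spec$name)
  empty_fragment <- tibble(study_id = character(), wave = integer(),
                           participant_id = character(),
                           variable = character(), category = character())
  base_recode <- list(study_id = study_id, wave = wave, variable = spec$name,
                      rule_text = rule_text(entry),
                      missing_code_log = attr(table, "missing_code_log") %||%
                        list())
  if (entry$rule$kind == "exclusion") {
    recode <- c(base_recode, list(excluded = TRUE,
                                  exclusion_reason = entry$rule$reason))
    return(list(fragment = empty_fragment, recode = recode))
  }
  ids <- as.character(table[[1]])
  rule <- entry$rule
  n_conflicts <- 0L
  n_inferred <- 0L
  source_vars <- character(0)
  source_summaries <- list()

  fetch <- function(var) {
    if (!var %in% names(table)) {
      abort(sprintf("source variable '%s' missing from table in %s", var,
                    context),
            class = "harmonisr_spec_error")
    }
    table[[var]]
  }

  if (rule$kind == "category_map") {
    if (!is.null(entry$sources)) {
      cols <- resolve_selector_columns(entry$sources, table, study_id, wave,
                                       dict, spec$variable_group)
      resolved <- resolve_sources(table[cols], entry$sources$conflict_policy)
      src <- resolved$value
      n_conflicts <- resolved$n_conflicts
      source_vars <- cols
    } else {
      src <- fetch(rule$source_variable)
      source_vars <- rule$source_variable
    }
    for (var in source_vars) {
      source_summaries[[var]] <- marginal_counts(
        fetch(var), setdiff(names(rule$mapping), MISSING_LABEL))
    }
    assigned <- apply_category_map(src, rule, spec$target_categories, context)
  } else { # threshold_bin
    if (!is.null(rule$mode_gate)) {
      gate <- norm_label(fetch(rule$mode_gate$variable))
      sel_cols <- rule$mode_gate$select
      src <- rep(NA_real_, nrow(table))
      for (mode in names(sel_cols)) {
        rows <- !is.na(gate) & gate == mode
        src[rows] <- as.numeric(fetch(sel_cols[[mode]])[rows])
      }
      source_vars <- c(rule$mode_gate$variable, unname(sel_cols))
      for (var in unname(sel_cols)) {
        source_summaries[[var]] <- continuous_summary(fetch(var))
      }
    } else if (!is.null(entry$sources)) {
      cols <- resolve_selector_columns(entry$sources, table, study_id, wave,
                                       dict, spec$variable_group)
      resolved <- resolve_sources(table[cols], entry$sources$conflict_policy)
      src <- as.numeric(resolved$value)
      n_conflicts <- resolved$n_conflicts
      source_vars <- cols
      for (var in cols) source_summaries[[var]] <- continuous_summary(fetch(var))
    } else {
      src <- as.numeric(fetch(rule$source_variable))
      source_vars <- rule$source_variable
      source_summaries[[rule$source_variable]] <- continuous_summary(src)
    }
    assigned <- apply_threshold_bins(src, rule, context)
  }

  if (!is.null(entry$inference)) {
    inferred <- apply_inference(table[entry$inference$indicators],
                                entry$inference, assigned)
    assigned <- inferred$value
    n_inferred <- inferred$n_inferred
    source_vars <- union(source_vars, entry$inference$indicators)
  }

  fragment <- tibble(study_id = study_id, wave = as.integer(wave),
                     participant_id = ids, variable = spec$name,
                     category = assigned)
  fragment <- fragment[order(fragment$participant_id, method = "radix"), ]
  respondent <- if (!is.null(dict)) {
    hits <- as_tibble(dict)
    hits <- hits[hits$study_id == study_id & hits$name %in% source_vars, ]
    paste(unique(hits$respondent), collapse = ", ")
  } else ""
  recode <- c(base_recode, list(
    excluded = FALSE,
    source_variables = source_vars,
    respondent = respondent,
    source_summaries = source_summaries,
    output_marginals = marginal_counts(
      assigned, setdiff(spec$target_categories, MISSING_LABEL)),
    n = nrow(table),
    n_conflicts = n_conflicts,
    n_inferred = n_inferred
  ))
  list(fragment = fragment, recode = recode)
}

#' Pool harmonised fragments into one long dataset
#'
#' Fragments are appended and canonically sorted; per-study-wave tabulations
#' of the pooled set are unchanged from the fragments. Excluded waves are
#' entirely absent from the pooled set (not present-as-missing). A duplicate
#' `(study_id, wave, participant_id, variable)` key is an integrity error.
#'
#' @param fragments List of fragment tibbles from [harmonise_study_wave()].
#' @param spec The `harmonisation_spec` the fragments were produced under.
#' @return A `harmonised_dataset` tibble with columns
#'   `study_id, wave, participant_id, variable, category`.
#' @export
pool <- function(fragments, spec = NULL) {
  ds <- dplyr::bind_rows(fragments)
  if (nrow(ds)) {
    key <- paste(ds$study_id, ds$wave, ds$participant_id, ds$variable,
                 sep = "\r")
    if (anyDuplicated(key)) {
      dups <- ds[duplicated(key), c("study_id", "wave", "participant_id",
                                    "variable")]
      abort(paste0("duplicate harmonised records: ",
                   paste(utils::head(sprintf("%s/%s/%s/%s", dups$study_id,
                                             dups$wave, dups$participant_id,
                                             dups$variable), 5),
                         collapse = "; ")),
            class = "harmonisr_integrity_error")
    }
    if (!is.null(spec)) {
      bad <- !ds$category %in% spec$target_categories
      if (any(bad)) {
        abort(paste0("categories outside the spec's target set: ",
                     paste(unique(ds$category[bad]), collapse = ", ")),
              class = "harmonisr_integrity_error")
      }
    }
    ds <- ds[order(ds$study_id, ds$wave, ds$participant_id, ds$variable,
                   method = "radix"), ]
  }
  structure(ds, class = c("harmonised_dataset", class(ds)),
            spec_name = if (!is.null(spec)) spec$name,
            target_categories = if (!is.null(spec)) spec$target_categories)
}

#' Tabulate a harmonised variable
#'
#' Counts per target category (in the spec's declared order, `Missing` last)
#' for each study-wave and overall. Conservation holds by construction: per
#' study-wave the category counts sum to the number of harmonised
#' participants.
#'
#' @param ds A `harmonised_dataset`.
#' @param variable Harmonised variable name; defaults to the dataset's single
#'   variable.
#' @param categories Category order; defaults to the dataset's target
#'   categories.
#' @return `list(by_wave = <tibble>, overall = <tibble>, variable, n_total)`
#'   of class `category_tabulation`.
#' @export
tabulate_harmonised <- function(ds, variable = NULL, categories = NULL) {
  vars <- unique(ds$variable)
  if (is.null(variable)) {
    if (length(vars) > 1L) {
      abort("dataset holds several variables; name one",
            class = "harmonisr_spec_error")
    }
    variable <- if (length(vars)) vars else attr(ds, "spec_name")
  } else if (nrow(ds) && !variable %in% vars) {
    abort(paste0("unknown harmonised variable: ", variable),
          class = "harmonisr_spec_error")
  }
  categories <- categories %||% attr(ds, "target_categories")
  sub <- as_tibble(ds)[ds$variable %in% variable, ]
  if (is.null(categories)) {
    categories <- c(setdiff(sort(unique(sub$category)), MISSING_LABEL),
                    MISSING_LABEL)
  }
  if (!MISSING_LABEL %in% categories) categories <- c(categories, MISSING_LABEL)
  sub$category <- factor(sub$category, levels = categories)
  by_wave <- sub |>
    dplyr::count(.data$study_id, .data$wave, .data$category,
                 .drop = FALSE, name = "n") |>
    dplyr::filter(!is.na(.data$category))
  overall <- sub |>
    dplyr::count(.data$category, .drop = FALSE, name = "n") |>
    dplyr::filter(!is.na(.data$category))
  per_wave_n <- by_wave |>
    dplyr::group_by(.data$study_id, .data$wave) |>
    dplyr::summarise(n = sum(.data$n), .groups = "drop")
  stopifnot(sum(overall$n) == nrow(sub))
  structure(list(by_wave = as_tibble(by_wave), overall = as_tibble(overall),
                 per_wave_n = per_wave_n, variable = variable,
                 categories = categories, n_total = nrow(sub)),
            class = "category_tabulation")
}

#' @export
print.category_tabulation <- function(x, ...) {
  cat(sprintf("<category_tabulation> %s (n = %d)\n", x$variable, x$n_total))
  print(tidyr::pivot_wider(x$by_wave, names_from = "category",
                           values_from = "n"))
  invisible(x)
}

#' Summarise coverage of harmonised variables
#'
#' For each harmonised variable: the number of distinct included studies, the
#' distribution of studies by number of contributing waves, and the total
#' study-wave count.
#'
#' @param inclusions Tibble `(variable, study_id, wave)` of included
#'   study-waves, e.g. from [spec_inclusions()] or an encoded inclusion
#'   registry.
#' @return Tibble with columns `variable`, `n_studies`, `wave_histogram`
#'   (list-column: named vector, `k` waves -> number of studies) and
#'   `n_waves`.
#' @export
coverage_summary <- function(inclusions) {
  inclusions <- as_tibble(inclusions)
  if (!nrow(inclusions)) {
    return(tibble(variable = character(), n_studies = integer(),
                  wave_histogram = list(), n_waves = integer()))
  }
  per_study <- inclusions |>
    dplyr::distinct(.data$variable, .data$study_id, .data$wave) |>
    dplyr::count(.data$variable, .data$study_id, name = "k")
  per_study |>
    dplyr::group_by(.data$variable) |>
    dplyr::summarise(
      n_studies = dplyr::n(),
      wave_histogram = list(table(.data$k)),
      n_waves = sum(.data$k),
      .groups = "drop"
    )
}

#' Write a harmonised dataset to CSV
#'
#' Long format with header `study_id,wave,participant_id,variable,category`;
#' optionally also a wide export with one column per harmonised variable per
#' wave (`W<wave>_<variable>`).
#'
#' @param ds A `harmonised_dataset`.
#' @param path Output CSV path.
#' @param wide Also write a wide export next to `path` (suffix `_wide.csv`)?
#' @return `path`, invisibly.
#' @export
write_harmonised <- function(ds, path, wide = FALSE) {
  atomic_write(function(tmp) {
    readr::write_csv(as_tibble(ds), tmp, na = "", quote = "needed", eol = "\n")
  }, path)
  if (wide && nrow(ds)) {
    wtab <- as_tibble(ds) |>
      dplyr::mutate(col = sprintf("W%d_%s", .data$wave, .data$variable)) |>
      dplyr::select("study_id", "participant_id", "col", "category") |>
      tidyr::pivot_wider(names_from = "col", values_from = "category")
    wide_path <- sub("\\.csv$", "_wide.csv", path)
    atomic_write(function(tmp) {
      readr::write_csv(wtab, tmp, na = "", quote = "needed", eol = "\n")
    }, wide_path)
  }
  invisible(path)
}
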