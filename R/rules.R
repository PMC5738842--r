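#' The harmonisation rule language
#'
#' A harmonised variable is derived from heterogeneous study variables by one
#' deterministic rule per study-wave (or a reasoned exclusion of that
#' study-wave). The rule kinds cover every algorithmic transformation used in
#' practice for categorical questionnaire data:
#'
#' * **category map** — collapse or relabel source categories onto the target
#'   categories (e.g. `Bicycle`/`On foot` -> `Active mode of travel`);
#' * **threshold bins** — cut a continuous variable (e.g. journey duration in
#'   minutes) into ordered target categories at fixed thresholds, with
#'   right-closed intervals `(-Inf, u1], (u1, u2], ..., (uk, Inf)`;
#' * **source preference** — when a study collected the same construct from
#'   several sources (parent- and child-report, to- and from-school journeys),
#'   an ordered preference list picks one value per participant;
#' * **inference rule** — reassign residual `Missing` values when the pattern
#'   of indicator responses logically determines the category (e.g. answering
#'   "no" to both walking and cycling on a walk/cycle-only instrument implies
#'   a non-active mode);
#' * **wave exclusion** — a study-wave left out of the harmonised variable,
#'   always with a mandatory written justification.
#'
#' @name rules
NULL

#' @rdname rules
#' @param source_variable Name of the source column in the study table.
#' @param mapping Named character vector: names are source category labels,
#'   values are target category labels.
#' @param unmapped_policy What to do with a non-missing source value that has
#'   no mapping: `"error"` (default — silent missingness hides recode gaps) or
#'   `"missing"`.
#' @export
category_map_rule <- function(source_variable, mapping,
                              unmapped_policy = c("error", "missing")) {
  unmapped_policy <- match.arg(unmapped_policy)
  mapping <- vapply(mapping, as.character, character(1))
  keys <- norm_label(names(mapping))
  if (anyDuplicated(keys)) {
    abort(paste0("duplicate mapping keys: ",
                 paste(unique(keys[duplicated(keys)]), collapse = ", ")),
          class = "harmonisr_spec_error")
  }
  names(mapping) <- keys
  structure(list(kind = "category_map", source_variable = source_variable,
                 mapping = mapping, unmapped_policy = unmapped_policy),
            class = "harmonisation_rule")
}

#' @rdname rules
#' @param bins Ordered list of bins, each `list(upper =, label =)`; `upper` is
#'   the inclusive upper bound of the bin, `NULL`/`Inf` for the last
#'   (unbounded) bin. Bin *i* accepts values in `(upper[i-1], upper[i]]`, the
#'   first bin accepting everything up to its bound, so the bins partition
#'   `[0, Inf)`.
#' @param mode_gate Optional `list(variable =, select =)`: the duration source
#'   is chosen per participant by a categorical gating variable — `select` maps
#'   gate categories to source column names; participants whose gate value has
#'   no entry (or is missing) get `Missing`. Used when an instrument collected
#'   durations only for specific travel modes.
#' @export
threshold_bin_rule <- function(source_variable = NULL, bins,
                               mode_gate = NULL) {
  bins <- lapply(bins, function(b) {
    upper <- b$upper %||% Inf
    if (is.character(upper)) upper <- as.numeric(upper)
    list(upper = as.numeric(upper), label = as.character(b$label))
  })
  uppers <- vapply(bins, `[[`, numeric(1), "upper")
  if (any(is.na(uppers))) {
    abort("bin upper bounds must be numeric (null/Inf for the last bin)",
          class = "harmonisr_spec_error")
  }
  if (any(diff(uppers) <= 0)) {
    abort(paste0("bin bounds must be strictly increasing; got ",
                 paste(uppers, collapse = ", ")),
          class = "harmonisr_spec_error")
  }
  if (!is.infinite(uppers[length(uppers)])) {
    abort("the last bin must be unbounded (upper = null) so bins cover [0, Inf)",
          class = "harmonisr_spec_error")
  }
  if (is.null(source_variable) && is.null(mode_gate)) {
    abort("threshold_bin needs a source_variable or a mode_gate",
          class = "harmonisr_spec_error")
  }
  if (!is.null(mode_gate)) {
    sel <- vapply(mode_gate$select, as.character, character(1))
    names(sel) <- norm_label(names(mode_gate$select))
    mode_gate <- list(variable = as.character(mode_gate$variable), select = sel)
  }
  structure(list(kind = "threshold_bin", source_variable = source_variable,
                 bins = bins, mode_gate = mode_gate),
            class = "harmonisation_rule")
}

#' @rdname rules
#' @param selectors List of source selectors in preference order; each is a
#'   `list(variable =)` and/or `list(respondent =)` (a respondent-only
#'   selector is resolved through the dictionary at application time).
#' @param conflict_policy `"prefer_first"` (default) keeps the first-preference
#'   value when simultaneous sources disagree; `"missing_if_conflict"` sets
#'   disagreeing rows to `Missing`. Conflicts are counted either way and
#'   surfaced in the provenance report.
#' @export
source_preference <- function(selectors,
                              conflict_policy = c("prefer_first",
                                                  "missing_if_conflict")) {
  conflict_policy <- match.arg(conflict_policy)
  if (length(selectors) < 1L) {
    abort("source_preference needs at least one selector",
          class = "harmonisr_spec_error")
  }
  key <- vapply(selectors, function(s)
    paste(s$variable %||% "", s$respondent %||% "", sep = "|"), character(1))
  if (anyDuplicated(key)) {
    abort("source_preference selectors must be distinct",
          class = "harmonisr_spec_error")
  }
  structure(list(selectors = selectors, conflict_policy = conflict_policy),
            class = "source_preference")
}

#' @rdname rules
#' @param indicators Character vector of indicator column names whose joint
#'   response pattern triggers the inference.
#' @param negative_values Values (after label normalisation) counting as a
#'   negative response, default `c("0", "No", "no", "Never")`.
#' @param inferred_category Target category assigned when every indicator is
#'   negative and the base assignment is `Missing`.
#' @param treat_missing_as_negative Whether a missing indicator counts as a
#'   negative response (default `FALSE`: a non-response is not a "no").
#' @export
inference_rule <- function(indicators,
                           inferred_category,
                           negative_values = c("0", "No", "no", "Never"),
                           treat_missing_as_negative = FALSE) {
  if (length(indicators) < 1L) {
    abort("inference_rule needs at least one indicator",
          class = "harmonisr_spec_error")
  }
  structure(list(indicators = as.character(indicators),
                 negative_values = norm_label(negative_values),
                 inferred_category = as.character(inferred_category),
                 treat_missing_as_negative = isTRUE(treat_missing_as_negative)),
            class = "inference_rule")
}

#' @rdname rules
#' @param reason Mandatory written justification for leaving the study-wave
#'   out of the harmonised variable.
#' @export
wave_exclusion <- function(reason) {
  reason <- as.character(reason)
  if (length(reason) != 1L || is.na(reason) || !nzchar(trimws(reason))) {
    abort("a wave exclusion requires a non-empty reason",
          class = "harmonisr_spec_error")
  }
  structure(list(kind = "exclusion", reason = reason),
            class = "harmonisation_rule")
}

#' Construct a harmonisation spec
#'
#' A harmonisation spec is the complete, declarative recipe for one harmonised
#' variable: its target categories (always including the reserved `Missing`)
#' and, for every contributing study-wave, exactly one rule or one reasoned
#' exclusion.
#'
#' @param name Harmonised variable name, e.g. `"ICAD_SchoolTravel2"`.
#' @param description Free-text description of the construct.
#' @param target_categories Ordered character vector of target categories;
#'   `"Missing"` is appended if absent.
#' @param rules List of entries, each
#'   `list(study_id =, wave =, rule =, sources = NULL, inference = NULL)`
#'   where `rule` is a [category_map_rule()], [threshold_bin_rule()] or
#'   [wave_exclusion()], `sources` an optional [source_preference()], and
#'   `inference` an optional [inference_rule()].
#' @param variable_group Optional construct tag linking the spec to the
#'   dictionary's variable group (needed for coverage validation).
#' @return A `harmonisation_spec` object.
#' @export
harmonisation_spec <- function(name, description = "", target_categories,
                               rules, variable_group = NULL) {
  target_categories <- as.character(target_categories)
  if (!MISSING_LABEL %in% target_categories) {
    target_categories <- c(target_categories, MISSING_LABEL)
  }
  keys <- vapply(rules, function(r) paste(r$study_id, r$wave, sep = ":"),
                 character(1))
  if (anyDuplicated(keys)) {
    abort(paste0("study-wave referenced more than once: ",
                 paste(unique(keys[duplicated(keys)]), collapse = ", ")),
          class = "harmonisr_spec_error")
  }
  spec <- structure(list(name = name, description = description,
                         target_categories = target_categories,
                         rules = rules, variable_group = variable_group),
                    class = "harmonisation_spec")
  validate_spec(spec)
  spec
}

#' @export
print.harmonisation_spec <- function(x, ...) {
  n_excl <- sum(vapply(x$rules, function(r) r$rule$kind == "exclusion",
                       logical(1)))
  cat(sprintf("<harmonisation_spec> %s\n  categories: %s\n  rules: %d study-waves (%d excluded)\n",
              x$name, paste(x$target_categories, collapse = ", "),
              length(x$rules), n_excl))
  invisible(x)
}

#' Validate a harmonisation spec, optionally against a dictionary
#'
#' Structural validation always runs: target categories include `Missing`,
#' every mapped/inferred category is a declared target, bins are strictly
#' increasing and jointly cover the non-negative line, exclusions carry a
#' reason. When `dict` is supplied, source variables must exist in the
#' dictionary with a compatible format (categorical for maps and gates,
#' continuous for bins) and every mapping key must be among the variable's
#' declared categories.
#'
#' @param spec A `harmonisation_spec`.
#' @param dict Optional `study_dictionary`.
#' @return `spec`, invisibly.
#' @export
validate_spec <- function(spec, dict = NULL) {
  targets <- spec$target_categories
  for (entry in spec$rules) {
    where <- sprintf("%s wave %s", entry$study_id, entry$wave)
    rule <- entry$rule
    if (rule$kind == "category_map") {
      bad <- setdiff(unique(rule$mapping), targets)
      if (length(bad)) {
        abort(sprintf("%s: mapping targets not declared in target_categories: %s",
                      where, paste(bad, collapse = ", ")),
              class = "harmonisr_spec_error")
      }
    } else if (rule$kind == "threshold_bin") {
      labels <- vapply(rule$bins, `[[`, character(1), "label")
      bad <- setdiff(labels, targets)
      if (length(bad)) {
        abort(sprintf("%s: bin labels not declared in target_categories: %s",
                      where, paste(bad, collapse = ", ")),
              class = "harmonisr_spec_error")
      }
    }
    if (!is.null(entry$inference)) {
      if (!entry$inference$inferred_category %in% targets) {
        abort(sprintf("%s: inferred category '%s' not a declared target",
                      where, entry$inference$inferred_category),
              class = "harmonisr_spec_error")
      }
      if (rule$kind == "exclusion") {
        abort(sprintf("%s: an excluded wave cannot carry an inference rule",
                      where), class = "harmonisr_spec_error")
      }
    }
    if (!is.null(dict)) validate_entry_against_dictionary(entry, dict, where)
  }
  invisible(spec)
}

validate_entry_against_dictionary <- function(entry, dict, where) {
  rule <- entry$rule
  if (rule$kind == "exclusion") return(invisible(NULL))
  check_categorical_source <- function(var, keys) {
    de <- dict_entry(dict, entry$study_id, var)
    if (de$format != "categorical") {
      abort(sprintf("%s: source '%s' must be categorical, dictionary says %s",
                    where, var, de$format),
            class = "harmonisr_spec_error")
    }
    declared <- norm_label(de$categories[[1]])
    bad <- setdiff(keys, declared)
    if (length(bad)) {
      abort(sprintf("%s: source categories unknown for '%s': %s (declared: %s)",
                    where, var, paste(bad, collapse = ", "),
                    paste(declared, collapse = ", ")),
            class = "harmonisr_spec_error")
    }
  }
  check_continuous_source <- function(var) {
    de <- dict_entry(dict, entry$study_id, var)
    if (de$format != "continuous") {
      abort(sprintf("%s: source '%s' must be continuous, dictionary says %s",
                    where, var, de$format),
            class = "harmonisr_spec_error")
    }
  }
  if (rule$kind == "category_map") {
    if (is.null(entry$sources)) {
      check_categorical_source(rule$source_variable, names(rule$mapping))
    } else {
      for (s in entry$sources$selectors) {
        if (!is.null(s$variable)) {
          check_categorical_source(s$variable, names(rule$mapping))
        }
      }
    }
  } else if (rule$kind == "threshold_bin") {
    if (!is.null(rule$mode_gate)) {
      check_categorical_source(rule$mode_gate$variable,
                               names(rule$mode_gate$select))
      for (var in unname(rule$mode_gate$select)) check_continuous_source(var)
    } else if (is.null(entry$sources)) {
      check_continuous_source(rule$source_variable)
    } else {
      for (s in entry$sources$selectors) {
        if (!is.null(s$variable)) check_continuous_source(s$variable)
      }
    }
  }
  if (!is.null(entry$inference)) {
    for (var in entry$inference$indicators) {
      dict_entry(dict, entry$study_id, var)
    }
  }
  invisible(NULL)
}

#' Read a harmonisation spec from YAML or JSON
#'
#' The file carries top-level keys `name`, `description`, `target_categories`,
#' `variable_group` (optional) and `rules` — a list keyed by `study_id` and
#' `wave`, each entry with `kind` in `category_map`, `threshold_bin`,
#' `exclusion` plus the kind-specific payload, and optional `sources`
#' (preference list) and `inference` blocks.
#'
#' @param path Spec file (`.yaml`/`.yml` or `.json`).
#' @param dict Optional `study_dictionary` to validate source variables and
#'   categories against.
#' @return A validated `harmonisation_spec`.
#' @export
read_spec <- function(path, dict = NULL) {
  if (!file.exists(path)) {
    abort(paste0("spec file not found: ", path),
          class = "harmonisr_format_error")
  }
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  spec <- spec_from_list(raw)
  if (!is.null(dict)) validate_spec(spec, dict)
  spec
}

spec_from_list <- function(raw) {
  for (key in c("name", "target_categories", "rules")) {
    if (is.null(raw[[key]])) {
      abort(paste0("spec is missing required key: ", key),
            class = "harmonisr_format_error")
    }
  }
  rules <- lapply(raw$rules, function(r) {
    for (key in c("study_id", "wave", "kind")) {
      if (is.null(r[[key]])) {
        abort(paste0("rule entry is missing required key: ", key),
              class = "harmonisr_format_error")
      }
    }
    rule <- switch(
      r$kind,
      category_map = category_map_rule(
        source_variable = r$source_variable,
        mapping = unlist(r$mapping),
        unmapped_policy = r$unmapped_policy %||% "error"
      ),
      threshold_bin = threshold_bin_rule(
        source_variable = r$source_variable,
        bins = r$bins,
        mode_gate = r$mode_gate
      ),
      exclusion = wave_exclusion(r$reason %||% ""),
      abort(paste0("unknown rule kind: ", r$kind),
            class = "harmonisr_format_error")
    )
    sources <- if (!is.null(r$sources)) {
      source_preference(r$sources$selectors,
                        r$sources$conflict_policy %||% "prefer_first")
    }
    inference <- if (!is.null(r$inference)) {
      inference_rule(
        indicators = unlist(r$inference$indicators),
        inferred_category = r$inference$inferred_category,
        negative_values = unlist(r$inference$negative_values) %||%
          c("0", "No", "no", "Never"),
        treat_missing_as_negative =
          isTRUE(r$inference$treat_missing_as_negative)
      )
    }
    list(study_id = as.character(r$study_id), wave = as.integer(r$wave),
         rule = rule, sources = sources, inference = inference)
  })
  harmonisation_spec(
    name = raw$name,
    description = raw$description %||% "",
    target_categories = unlist(raw$target_categories),
    rules = rules,
    variable_group = raw$variable_group
  )
}

spec_to_list <- function(spec) {
  rules <- lapply(spec$rules, function(entry) {
    rule <- entry$rule
    out <- list(study_id = entry$study_id, wave = entry$wave, kind = rule$kind)
    if (rule$kind == "category_map") {
      out$source_variable <- rule$source_variable
      out$mapping <- as.list(rule$mapping)
      out$unmapped_policy <- rule$unmapped_policy
    } else if (rule$kind == "threshold_bin") {
      if (!is.null(rule$source_variable)) {
        out$source_variable <- rule$source_variable
      }
      out$bins <- lapply(rule$bins, function(b) {
        list(upper = if (is.infinite(b$upper)) NULL else b$upper,
             label = b$label)
      })
      if (!is.null(rule$mode_gate)) {
        out$mode_gate <- list(variable = rule$mode_gate$variable,
                              select = as.list(rule$mode_gate$select))
      }
    } else {
      out$reason <- rule$reason
    }
    if (!is.null(entry$sources)) {
      out$sources <- list(selectors = entry$sources$selectors,
                          conflict_policy = entry$sources$conflict_policy)
    }
    if (!is.null(entry$inference)) {
      inf <- entry$inference
      out$inference <- list(
        indicators = as.list(inf$indicators),
        inferred_category = inf$inferred_category,
        negative_values = as.list(inf$negative_values),
        treat_missing_as_negative = inf$treat_missing_as_negative
      )
    }
    out
  })
  out <- list(name = spec$name, description = spec$description,
              target_categories = as.list(spec$target_categories),
              rules = rules)
  if (!is.null(spec$variable_group)) out$variable_group <- spec$variable_group
  out
}

#' Write a harmonisation spec to YAML or JSON
#'
#' Serialisation round-trips: `read_spec(write_spec(spec, f))` is structurally
#' equal to `spec`. Unbounded bin uppers are written as nulls so the same spec
#' is representable in both YAML and JSON.
#'
#' @param spec A `harmonisation_spec`.
#' @param path Output path; format chosen by extension (`.json` for JSON,
#'   YAML otherwise).
#' @return `path`, invisibly.
#' @export
write_spec <- function(spec, path) {
  lst <- spec_to_list(spec)
  atomic_write(function(tmp) {
    if (grepl("\\.json$", path, ignore.case = TRUE)) {
      jsonlite::write_json(lst, tmp, auto_unbox = TRUE, null = "null",
                           pretty = TRUE)
    } else {
      yaml::write_yaml(lst, tmp)
    }
  }, path)
}

#' Check that a spec covers the dictionary's study-waves
#'
#' Returns findings (never errors): (a) study-waves present in the
#' dictionary's variable group that have neither a rule nor an exclusion;
#' (b) declared source categories with no mapping under
#' `unmapped_policy = "error"`; (c) rules referencing study-waves that are
#' also excluded. A complete spec yields a zero-row tibble.
#'
#' @param spec A `harmonisation_spec` (its `variable_group` is used to locate
#'   the construct's study-waves; without one, type-(a) findings are skipped).
#' @param dict A `study_dictionary`.
#' @return Tibble with columns `type`, `study_id`, `wave`, `detail`.
#' @export
validate_coverage <- function(spec, dict) {
  findings <- list()
  rule_df <- tibble(
    study_id = vapply(spec$rules, `[[`, character(1), "study_id"),
    wave = vapply(spec$rules, `[[`, integer(1), "wave"),
    kind = vapply(spec$rules, function(r) r$rule$kind, character(1))
  )
  if (!is.null(spec$variable_group)) {
    in_group <- query_by_group(dict, spec$variable_group)
    group_waves <- unique(in_group[!is.na(in_group$wave),
                                   c("study_id", "wave")])
    covered <- paste(rule_df$study_id, rule_df$wave)
    uncovered <- group_waves[!paste(group_waves$study_id, group_waves$wave)
                             %in% covered, ]
    if (nrow(uncovered)) {
      findings$uncovered <- tibble(
        type = "uncovered_study_wave",
        study_id = uncovered$study_id, wave = uncovered$wave,
        detail = sprintf("study-wave in group '%s' has neither a rule nor an exclusion",
                         spec$variable_group))
    }
  }
  unmapped <- purrr::map_dfr(spec$rules, function(entry) {
    rule <- entry$rule
    if (rule$kind != "category_map" || rule$unmapped_policy != "error") {
      return(tibble())
    }
    vars <- if (is.null(entry$sources)) rule$source_variable else
      unlist(lapply(entry$sources$selectors, `[[`, "variable"))
    purrr::map_dfr(vars, function(var) {
      hit <- dict$study_id == entry$study_id & dict$name == var
      if (!any(hit)) return(tibble())
      declared <- norm_label(as_tibble(dict)$categories[hit][[1]])
      gap <- setdiff(declared, names(rule$mapping))
      if (!length(gap)) return(tibble())
      tibble(type = "unmapped_source_category",
             study_id = entry$study_id, wave = entry$wave,
             detail = sprintf("'%s' categories with no mapping: %s", var,
                              paste(gap, collapse = ", ")))
    })
  })
  if (nrow(unmapped)) findings$unmapped <- unmapped
  excluded <- rule_df[rule_df$kind == "exclusion", ]
  active <- rule_df[rule_df$kind != "exclusion", ]
  clash <- dplyr::inner_join(active, excluded, by = c("study_id", "wave"),
                             suffix = c("", ".x"))
  if (nrow(clash)) {
    findings$clash <- tibble(
      type = "rule_on_excluded_wave",
      study_id = clash$study_id, wave = clash$wave,
      detail = "study-wave carries both a transformation rule and an exclusion")
  }
  out <- dplyr::bind_rows(findings)
  if (!nrow(out)) {
    out <- tibble(type = character(), study_id = character(),
                  wave = integer(), detail = character())
  }
  out
}

# Rules for one study-wave, or NULL.
spec_rule_for <- function(spec, study_id, wave) {
  for (entry in spec$rules) {
    if (entry$study_id == study_id && entry$wave == wave) return(entry)
  }
  NULL
}

#' Included study-waves of one or more specs
#'
#' @param ... `harmonisation_spec` objects.
#' @return Tibble `(variable, study_id, wave)` of study-waves carrying a
#'   transformation rule (exclusions are absent, not present-as-missing).
#' @export
spec_inclusions <- function(...) {
  purrr::map_dfr(list(...), function(spec) {
    purrr::map_dfr(spec$rules, function(entry) {
      if (entry$rule$kind == "exclusion") return(tibble())
      tibble(variable = spec$name, study_id = entry$study_id,
             wave = entry$wave)
    })
  })
}
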