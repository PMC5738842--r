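#' Provenance reports
#'
#' Harmonisation is only trustworthy if it is auditable: which study-waves
#' went in, under what rule, with what source and output marginals, and why
#' any study-wave was left out. A `harmonisation_report` captures exactly
#' that, per harmonised variable, together with a machine-readable decision
#' ledger (source-conflict counts, inference reassignment counts, missing-code
#' translations) and a content hash of the specs it documents, so a report
#' provably corresponds to a spec version. Reports render deterministically:
#' re-rendering an unchanged report is byte-identical apart from the single
#' timestamp header line.
#'
#' @name provenance
NULL

spec_content_hash <- function(spec) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  write_spec(spec, tmp)
  unname(tools::md5sum(tmp))
}

#' Assemble a harmonisation report
#'
#' Validates the provenance invariants while assembling: every excluded
#' study-wave must carry a non-empty reason, every included study-wave must
#' have both source and output marginals, and per study-wave the output
#' marginals must sum to the number of input participants (conservation).
#'
#' @param specs Named list of `harmonisation_spec` objects.
#' @param results Per-spec engine results as returned by
#'   [harmonise_studies()].
#' @param coverage Optional coverage table (from [coverage_summary()]); when
#'   the harmonised variables are documented for a wider consortium than the
#'   studies processed here, pass the consortium-level inclusion registry's
#'   summary. Defaults to the coverage attribute of `results`.
#' @param notes Named list of free-text study-specific notes.
#' @return A `harmonisation_report` object.
#' @export
build_report <- function(specs, results, coverage = NULL, notes = list()) {
  if (is.null(names(specs))) {
    names(specs) <- vapply(specs, `[[`, character(1), "name")
  }
  variables <- lapply(names(specs), function(nm) {
    spec <- specs[[nm]]
    res <- results[[nm]]
    if (is.null(res)) {
      abort(paste0("no engine results for spec: ", nm),
            class = "harmonisr_integrity_error")
    }
    for (rec in res$recodes) {
      where <- sprintf("%s %s wave %s", nm, rec$study_id, rec$wave)
      if (isTRUE(rec$excluded)) {
        if (is.null(rec$exclusion_reason) ||
            !nzchar(trimws(rec$exclusion_reason))) {
          abort(paste0("excluded study-wave without a reason: ", where),
                class = "harmonisr_integrity_error")
        }
      } else {
        if (is.null(rec$output_marginals) || !length(rec$source_summaries)) {
          abort(paste0("included study-wave missing marginals: ", where),
                class = "harmonisr_integrity_error")
        }
        if (sum(rec$output_marginals$n) != rec$n) {
          abort(sprintf("conservation violated at %s: marginals sum to %d, n = %d",
                        where, sum(rec$output_marginals$n), rec$n),
                class = "harmonisr_integrity_error")
        }
      }
    }
    list(name = nm, description = spec$description,
         target_categories = spec$target_categories,
         recodes = res$recodes, tabulation = res$tabulation,
         findings = res$findings)
  })
  names(variables) <- names(specs)
  ledger <- list(
    conflicts = purrr::map_dfr(variables, function(v)
      purrr::map_dfr(v$recodes, function(rec) {
        if (isTRUE(rec$excluded)) return(tibble())
        tibble(variable = v$name, study_id = rec$study_id, wave = rec$wave,
               n_conflicts = rec$n_conflicts, n_inferred = rec$n_inferred)
      })),
    missing_code_translations = purrr::map_dfr(variables, function(v)
      purrr::map_dfr(v$recodes, function(rec) {
        if (!length(rec$missing_code_log)) return(tibble())
        tibble(variable = v$name, study_id = rec$study_id, wave = rec$wave,
               source_variable = names(rec$missing_code_log),
               n_translated = unlist(rec$missing_code_log))
      }))
  )
  coverage <- coverage %||% attr(results, "coverage")
  structure(list(
    spec_hashes = vapply(specs, spec_content_hash, character(1)),
    coverage = coverage,
    variables = variables,
    notes = notes,
    ledger = ledger
  ), class = "harmonisation_report")
}

#' @export
print.harmonisation_report <- function(x, ...) {
  cat(sprintf("<harmonisation_report> %d variable(s): %s\n",
              length(x$variables),
              paste(names(x$variables), collapse = ", ")))
  invisible(x)
}

md_table <- function(df) {
  df[] <- lapply(df, function(col) {
    out <- as.character(col)
    out[is.na(out)] <- ""
    out
  })
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  rows <- apply(df, 1L, function(r) paste0("| ", paste(r, collapse = " | "),
                                           " |"))
  c(header, sep, rows)
}

coverage_frame <- function(report) {
  cov <- report$coverage
  if (is.null(cov) || !nrow(cov)) {
    return(tibble(variable = character(), n_studies = integer(),
                  n_waves = integer()))
  }
  ks <- sort(unique(unlist(lapply(cov$wave_histogram,
                                  function(h) as.integer(names(h))))))
  hist_cols <- lapply(ks, function(k) {
    vapply(cov$wave_histogram, function(h) {
      v <- h[as.character(k)]
      if (is.na(v)) 0L else as.integer(v)
    }, integer(1))
  })
  names(hist_cols) <- sprintf("waves_%d", ks)
  desc <- vapply(cov$variable, function(v) {
    if (v %in% names(report$variables)) report$variables[[v]]$description
    else ""
  }, character(1))
  cats <- vapply(cov$variable, function(v) {
    if (v %in% names(report$variables))
      paste(report$variables[[v]]$target_categories, collapse = ", ")
    else ""
  }, character(1))
  dplyr::bind_cols(
    tibble(variable = cov$variable, description = desc,
           response_categories = cats, n_studies = cov$n_studies),
    as_tibble(hist_cols),
    tibble(n_waves = cov$n_waves)
  )
}

render_markdown <- function(report) {
  lines <- c(
    "# Harmonisation report",
    "",
    paste0("Generated: ", format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")),
    "",
    "Spec content hashes (md5 of canonical serialisation):",
    sprintf("* %s: `%s`", names(report$spec_hashes), report$spec_hashes),
    "",
    "## Coverage",
    ""
  )
  lines <- c(lines, md_table(coverage_frame(report)), "")
  for (v in report$variables) {
    lines <- c(lines, paste0("## ", v$name), "", v$description, "",
               paste0("Response categories: ",
                      paste(v$target_categories, collapse = ", ")), "")
    for (rec in v$recodes) {
      lines <- c(lines, sprintf("### %s — wave %s", rec$study_id, rec$wave),
                 "")
      if (isTRUE(rec$excluded)) {
        lines <- c(lines, paste0("**Excluded.** ", rec$exclusion_reason), "")
        next
      }
      lines <- c(lines,
                 paste0("Source variable(s): ",
                        paste(rec$source_variables, collapse = ", "),
                        if (nzchar(rec$respondent))
                          paste0(" (", rec$respondent, "-reported)") else ""),
                 "",
                 paste0("Rule: ", rec$rule_text), "")
      for (src in names(rec$source_summaries)) {
        lines <- c(lines, paste0("Source summary — `", src, "`:"), "",
                   md_table(rec$source_summaries[[src]]), "")
      }
      lines <- c(lines, "Output marginals:", "",
                 md_table(rec$output_marginals), "")
    }
    if (nrow(v$findings)) {
      lines <- c(lines, "### Coverage findings", "", md_table(v$findings), "")
    }
  }
  if (length(report$notes)) {
    lines <- c(lines, "## Study-specific notes", "")
    for (study in names(report$notes)) {
      lines <- c(lines, paste0("* **", study, "**: ", report$notes[[study]]))
    }
    lines <- c(lines, "")
  }
  lines <- c(lines, "## Decision ledger", "")
  if (nrow(report$ledger$conflicts)) {
    lines <- c(lines, "Source conflicts and inference reassignments:", "",
               md_table(report$ledger$conflicts), "")
  }
  if (nrow(report$ledger$missing_code_translations)) {
    lines <- c(lines, "Missing-code translations applied on load:", "",
               md_table(report$ledger$missing_code_translations), "")
  }
  lines
}

#' Render a harmonisation report
#'
#' `"markdown"` writes a single document with per-variable sections (coverage
#' table, per-study-wave source summaries, rule transcriptions, output
#' marginals, exclusions, notes, decision ledger). `"csv_bundle"` writes
#' `coverage.csv`, `recodes_<variable>.csv` and `tabulation_<variable>.csv`
#' plus the decision ledger as `ledger.json` into a directory. All numbers
#' are copied verbatim from the engine outputs held in the report — the
#' renderer never recomputes them.
#'
#' @param report A `harmonisation_report`.
#' @param format `"markdown"` or `"csv_bundle"`.
#' @param path Output file (markdown) or directory (csv bundle).
#' @return Character vector of files written, invisibly.
#' @export
render_report <- function(report, format = c("markdown", "csv_bundle"),
                          path) {
  format <- match.arg(format)
  if (format == "markdown") {
    lines <- render_markdown(report)
    atomic_write(function(tmp) writeLines(lines, tmp, useBytes = FALSE), path)
    return(invisible(path))
  }
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  cov_path <- file.path(path, "coverage.csv")
  atomic_write(function(tmp) {
    readr::write_csv(coverage_frame(report), tmp, na = "", eol = "\n")
  }, cov_path)
  written <- c(written, cov_path)
  for (v in report$variables) {
    recode_df <- purrr::map_dfr(v$recodes, function(rec) {
      if (isTRUE(rec$excluded)) {
        return(tibble(study_id = rec$study_id, wave = rec$wave,
                      status = "excluded", rule = rec$rule_text,
                      category = NA_character_, n = NA_integer_))
      }
      dplyr::bind_cols(
        tibble(study_id = rec$study_id, wave = rec$wave,
               status = "included", rule = rec$rule_text),
        rec$output_marginals
      )
    })
    rp <- file.path(path, paste0("recodes_", v$name, ".csv"))
    atomic_write(function(tmp) readr::write_csv(recode_df, tmp, na = "",
                                                eol = "\n"), rp)
    tab <- v$tabulation
    tab_df <- dplyr::bind_rows(
      dplyr::mutate(tab$by_wave, study_id = as.character(.data$study_id)),
      dplyr::mutate(tab$overall, study_id = "ALL", wave = NA_integer_)
    )
    tab_df$category <- as.character(tab_df$category)
    tp <- file.path(path, paste0("tabulation_", v$name, ".csv"))
    atomic_write(function(tmp) readr::write_csv(
      tab_df[c("study_id", "wave", "category", "n")], tmp, na = "",
      eol = "\n"), tp)
    written <- c(written, rp, tp)
  }
  lp <- file.path(path, "ledger.json")
  atomic_write(function(tmp) {
    jsonlite::write_json(
      list(spec_hashes = as.list(report$spec_hashes),
           conflicts = report$ledger$conflicts,
           missing_code_translations =
             report$ledger$missing_code_translations),
      tmp, auto_unbox = TRUE, pretty = TRUE, na = "null")
  }, lp)
  invisible(c(written, lp))
}
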