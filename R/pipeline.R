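#' Run the full harmonisation workflow over a set of studies
#'
#' For every spec, applies each study-wave rule to the matching study table,
#' pools the fragments, tabulates the pooled variable, and collects recode
#' records, exclusions and coverage findings — the inputs [build_report()]
#' needs.
#'
#' @param tables Named list of study tables (names are study ids).
#' @param specs Named list of `harmonisation_spec` objects.
#' @param dict A `study_dictionary`.
#' @return A list with one element per spec:
#'   `list(dataset, tabulation, recodes, findings)`, plus attribute
#'   `coverage` (from [coverage_summary()] over the specs' inclusions).
#' @export
harmonise_studies <- function(tables, specs, dict) {
  if (is.null(names(specs))) {
    names(specs) <- vapply(specs, `[[`, character(1), "name")
  }
  results <- lapply(specs, function(spec) {
    validate_spec(spec, dict)
    fragments <- list()
    recodes <- list()
    for (entry in spec$rules) {
      tab <- tables[[entry$study_id]]
      if (is.null(tab)) next
      out <- harmonise_study_wave(tab, spec, entry$wave, dict)
      fragments[[length(fragments) + 1L]] <- out$fragment
      recodes[[length(recodes) + 1L]] <- out$recode
    }
    ds <- pool(fragments, spec)
    list(dataset = ds,
         tabulation = tabulate_harmonised(ds, spec$name,
                                          spec$target_categories),
         recodes = recodes,
         findings = validate_coverage(spec, dict))
  })
  attr(results, "coverage") <-
    coverage_summary(do.call(spec_inclusions, unname(specs)))
  results
}
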