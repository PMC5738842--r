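spec_dir <- system.file("extdata/school_travel", package = "harmonisr")
fixture_dict <- read_dictionary(file.path(spec_dir, "dictionary.csv"))

test_that("the packaged binary mode spec parses and validates", {
  spec <- read_spec(file.path(spec_dir, "ICAD_SchoolTravel2.yaml"),
                    fixture_dict)
  expect_s3_class(spec, "harmonisation_spec")
  expect_equal(spec$target_categories,
               c("Active mode of travel", "Other mode of travel", "Missing"))
  expect_setequal(vapply(spec$rules, `[[`, character(1), "study_id"),
                  c("SPEEDY", "KISS", "Ballabeina"))
})

test_that("Missing is always among the target categories", {
  spec <- harmonisation_spec("X", "", c("A", "B"), rules = list())
  expect_true("Missing" %in% spec$target_categories)
})

test_that("bins must increase strictly and end unbounded", {
  expect_error(
    threshold_bin_rule("d", list(list(upper = 5, label = "a"),
                                 list(upper = 15, label = "b"),
                                 list(upper = 15, label = "c"))),
    class = "harmonisr_spec_error")
  expect_error(
    threshold_bin_rule("d", list(list(upper = 5, label = "a"),
                                 list(upper = 15, label = "b"))),
    class = "harmonisr_spec_error")
})

test_that("unknown mapping keys are named together with the candidates", {
  rule <- category_map_rule("a_schulweg_hin_sommer",
                            c("Walkk" = "Active mode of travel"))
  spec <- harmonisation_spec(
    "X", "", c("Active mode of travel", "Missing"),
    rules = list(list(study_id = "KISS", wave = 1L, rule = rule)))
  err <- expect_error(validate_spec(spec, fixture_dict),
                      class = "harmonisr_spec_error")
  expect_match(conditionMessage(err), "Walkk")
  expect_match(conditionMessage(err), "Cycle/scooter", fixed = TRUE)
})

test_that("source variables must exist with a compatible format", {
  spec <- harmonisation_spec(
    "X", "", c("A", "Missing"),
    rules = list(list(study_id = "KISS", wave = 1L,
                      rule = category_map_rule("no_such_var", c("Walk" = "A")))))
  expect_error(validate_spec(spec, fixture_dict),
               class = "harmonisr_spec_error")
  # continuous variable under a category map
  spec2 <- harmonisation_spec(
    "X", "", c("A", "Missing"),
    rules = list(list(study_id = "KISS", wave = 1L,
                      rule = category_map_rule("a_schulweg_hin_sommer_time",
                                               c("Walk" = "A")))))
  expect_error(validate_spec(spec2, fixture_dict),
               class = "harmonisr_spec_error")
})

test_that("exclusions demand a reason and study-waves are unique", {
  expect_error(wave_exclusion("  "), class = "harmonisr_spec_error")
  r <- list(study_id = "KISS", wave = 1L,
            rule = wave_exclusion("incompatible"))
  expect_error(harmonisation_spec("X", "", c("A"), rules = list(r, r)),
               class = "harmonisr_spec_error")
})

test_that("mapping to an undeclared target category is rejected", {
  expect_error(harmonisation_spec(
    "X", "", c("A", "Missing"),
    rules = list(list(study_id = "KISS", wave = 1L,
                      rule = category_map_rule("a_schulweg_hin_sommer",
                                               c("Walk" = "B"))))),
    class = "harmonisr_spec_error")
})

test_that("coverage validation flags uncovered study-waves", {
  spec3 <- school_travel_specs()$ICAD_SchoolTravel3
  # drop the Ballabeina exclusion entirely
  spec3$rules <- Filter(function(e) e$study_id != "Ballabeina", spec3$rules)
  findings <- validate_coverage(spec3, fixture_dict)
  expect_true(any(findings$type == "uncovered_study_wave" &
                    findings$study_id == "Ballabeina" & findings$wave == 1L))
})

test_that("complete packaged specs yield zero findings", {
  for (spec in school_travel_specs()) {
    expect_equal(nrow(validate_coverage(spec, fixture_dict)), 0L,
                 info = spec$name)
  }
})

test_that("coverage findings equal a brute-force cross-join check", {
  withr::with_seed(11L, {
    for (trial in 1:5) {
      dict <- random_dictionary(n_entries = 60L, n_studies = 4L,
                                n_groups = 3L, seed = trial)
      group <- sample(unique(dict$variable_group), 1)
      in_group <- query_by_group(dict, group)
      sw <- unique(in_group[!is.na(in_group$wave), c("study_id", "wave")])
      if (!nrow(sw)) next
      keep <- stats::runif(nrow(sw)) < 0.6
      rules <- lapply(which(keep), function(i) {
        list(study_id = sw$study_id[i], wave = sw$wave[i],
             rule = wave_exclusion("synthetic exclusion"))
      })
      spec <- harmonisation_spec("RND", "", c("A"), rules = rules,
                                 variable_group = group)
      findings <- validate_coverage(spec, dict)
      uncovered <- findings[findings$type == "uncovered_study_wave", ]
      # oracle: exhaustive loop over every dictionary study-wave in the group
      expected <- list()
      for (i in seq_len(nrow(sw))) {
        hit <- FALSE
        for (r in rules) {
          if (r$study_id == sw$study_id[i] && r$wave == sw$wave[i]) hit <- TRUE
        }
        if (!hit) expected[[length(expected) + 1L]] <-
            paste(sw$study_id[i], sw$wave[i])
      }
      expect_setequal(paste(uncovered$study_id, uncovered$wave),
                      unlist(expected) %||% character(0))
    }
  })
})

test_that("unmapped declared categories surface under policy = error", {
  rule <- category_map_rule("a_schulweg_hin_sommer",
                            c("Walk" = "A"), unmapped_policy = "error")
  spec <- harmonisation_spec(
    "X", "", c("A", "Missing"), variable_group = "School_travel",
    rules = list(list(study_id = "KISS", wave = 1L, rule = rule)))
  findings <- validate_coverage(spec, fixture_dict)
  gap <- findings[findings$type == "unmapped_source_category", ]
  expect_equal(nrow(gap), 1L)
  expect_match(gap$detail, "Cycle/scooter", fixed = TRUE)
})

test_that("spec serialisation round-trips through YAML and JSON", {
  specs <- school_travel_specs()
  rich <- harmonisation_spec(
    "RICH", "composite rule exercise", c("Active", "Other", "Missing"),
    variable_group = "School_travel",
    rules = list(
      list(study_id = "S1", wave = 2L,
           rule = category_map_rule("W2_mode", c("Walk" = "Active",
                                                 "Car" = "Other"),
                                    unmapped_policy = "missing"),
           sources = source_preference(
             list(list(variable = "W2_mode_parent"),
                  list(variable = "W2_mode_child")),
             "missing_if_conflict"),
           inference = inference_rule(c("W2_walk", "W2_cycle"), "Other")),
      list(study_id = "S2", wave = 1L,
           rule = wave_exclusion("instrument incompatible"))))
  for (spec in c(specs, list(rich))) {
    for (ext in c(".yaml", ".json")) {
      path <- withr::local_tempfile(fileext = ext)
      write_spec(spec, path)
      back <- read_spec(path)
      expect_equal(harmonisr:::spec_to_list(back),
                   harmonisr:::spec_to_list(spec), info = paste(spec$name, ext))
    }
  }
})

test_that("every non-negative value with <=3 decimals lands in exactly one bin", {
  rule <- threshold_bin_rule("d", list(
    list(upper = 5, label = "low"), list(upper = 15, label = "mid"),
    list(upper = NULL, label = "high")))
  uppers <- c(5, 15, Inf)
  sweep <- withr::with_seed(5L, round(stats::runif(500, 0, 40), 3))
  sweep <- c(sweep, 0, 5, 5.001, 15, 15.001, 4.999)
  for (v in sweep) {
    lo <- c(-Inf, uppers[-3])
    accepts <- sum(v > lo & v <= uppers)
    expect_equal(accepts, 1L)
  }
  # and the engine assignment agrees with direct membership
  got <- apply_threshold_bins(sweep, rule)
  expect_equal(got, oracle_bin(sweep, uppers, c("low", "mid", "high")))
})

test_that("a spec stays valid against a superset dictionary", {
  spec <- school_travel_specs()$ICAD_SchoolTravel2
  extra <- tibble::as_tibble(fixture_dict)[0, ]
  superset <- new_dictionary(rbind(
    tibble::as_tibble(fixture_dict),
    tibble::tibble(study_id = "NEW", variable_id = 1L, name = "W1_extra",
                   label = "x", description = "x", unit = NA_character_,
                   format = "continuous", categories = list(character(0)),
                   variable_group = "School_travel", wave = 1L,
                   respondent = "child")))
  expect_silent(validate_spec(spec, superset))
})
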