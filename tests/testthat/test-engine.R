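ACTIVE <- "Active mode of travel"
OTHER <- "Other mode of travel"

st2_map_speedy <- category_map_rule(
  "W1_school_travel",
  c("Bicycle" = ACTIVE, "On foot" = ACTIVE, "Car" = OTHER,
    "Bus/train" = OTHER))

test_that("category collapse reproduces the published study marginals", {
  # SPEEDY wave 1
  x <- c(rep("Car", 923), rep("Bus/train", 127), rep("Bicycle", 189),
         rep("On foot", 814), rep(NA, 11))
  got <- apply_category_map(x, st2_map_speedy, c(ACTIVE, OTHER, "Missing"))
  expect_equal(unname(table(got)[c(ACTIVE, OTHER, "Missing")]),
               c(1003L, 1050L, 11L), ignore_attr = TRUE)
  # Ballabeina wave 1
  x <- c(rep("Walk", 546), rep("Cycle/scooter", 1), rep("Bus/tram", 4),
         rep("Car", 32), rep("Other", 24), rep(NA, 62))
  rule <- category_map_rule("W1_a_schulweg",
                            c("Walk" = ACTIVE, "Cycle/scooter" = ACTIVE,
                              "Bus/tram" = OTHER, "Car" = OTHER,
                              "Other" = OTHER))
  got <- apply_category_map(x, rule)
  expect_equal(unname(table(got)[c(ACTIVE, OTHER, "Missing")]),
               c(547L, 60L, 62L), ignore_attr = TRUE)
})

test_that("an identity map leaves counts unchanged", {
  cats <- c("A", "B", "C")
  x <- random_categorical_column(200, cats, 0.15, seed = 3L)
  rule <- category_map_rule("v", stats::setNames(cats, cats))
  got <- apply_category_map(x, rule)
  expect_equal(unname(table(got)[cats]), unname(table(x)[cats]),
               ignore_attr = TRUE)
  expect_equal(sum(got == "Missing"), sum(is.na(x)))
})

test_that("category mapping agrees with a linear recount oracle", {
  cats <- c("a", "b", "c", "d", "e")
  x <- random_categorical_column(300, cats, 0.2, seed = 8L)
  mapping <- stats::setNames(sample(c("X", "Y"), 5, replace = TRUE), cats)
  rule <- category_map_rule("v", mapping)
  got <- apply_category_map(x, rule)
  oracle <- vapply(x, function(v) {
    if (is.na(v)) "Missing" else unname(mapping[v])
  }, character(1))
  expect_equal(got, unname(oracle))
})

test_that("unmapped values error (naming context) or become Missing by policy", {
  rule_err <- category_map_rule("v", c("A" = "X"))
  err <- expect_error(
    apply_category_map(c("A", "B"), rule_err, context = "KISS wave 1"),
    class = "harmonisr_unmapped_error")
  expect_match(conditionMessage(err), "KISS wave 1")
  expect_match(conditionMessage(err), "B")
  rule_miss <- category_map_rule("v", c("A" = "X"),
                                 unmapped_policy = "missing")
  expect_equal(apply_category_map(c("A", "B", NA), rule_miss),
               c("X", "Missing", "Missing"))
})

test_that("labels match after NFC normalisation and trimming, never fuzzily", {
  rule <- category_map_rule("v", c("zu Fuß" = "Active"))
  composed <- "zu Fuß"
  decomposed <- stringi::stri_trans_nfd(composed)
  expect_equal(apply_category_map(c(paste0("  ", composed, " "), decomposed),
                                  rule), c("Active", "Active"))
  expect_error(apply_category_map("zu Fuss", rule),
               class = "harmonisr_unmapped_error")
})

duration_rule <- threshold_bin_rule("d", list(
  list(upper = 5, label = "Less than or equal to 5 min"),
  list(upper = 15, label = "6–15 min"),
  list(upper = NULL, label = "More than 15 min")))

test_that("threshold binning honours the published boundary semantics", {
  expect_equal(apply_threshold_bins(c(5, 6, 15, 16), duration_rule),
               c("Less than or equal to 5 min", "6–15 min",
                 "6–15 min", "More than 15 min"))
  expect_equal(apply_threshold_bins(c(NA, NA), duration_rule),
               c("Missing", "Missing"))
  err <- expect_error(apply_threshold_bins(c(3, -1), duration_rule,
                                           context = "KISS wave 1"),
                      class = "harmonisr_validation_error")
  expect_match(conditionMessage(err), "2")
})

test_that("binning agrees with an if-chain oracle on uniform values", {
  x <- withr::with_seed(21L, round(stats::runif(1000, 0, 60), 1))
  x[withr::with_seed(22L, sample.int(1000, 50))] <- NA
  got <- apply_threshold_bins(x, duration_rule)
  expect_equal(got, oracle_bin(x, c(5, 15, Inf),
                               c("Less than or equal to 5 min",
                                 "6–15 min", "More than 15 min")))
})

test_that("source resolution prefers the first non-missing source", {
  r <- resolve_sources(tibble::tibble(parent = "Walk", child = "Car"))
  expect_equal(r$value, "Walk")
  expect_true(r$conflict)
  r <- resolve_sources(tibble::tibble(parent = NA_character_, child = "Car"))
  expect_equal(r$value, "Car")
  expect_false(r$conflict)
  r <- resolve_sources(tibble::tibble(parent = NA_character_,
                                      child = NA_character_))
  expect_true(is.na(r$value))
  r <- resolve_sources(tibble::tibble(parent = "Walk", child = "Car"),
                       "missing_if_conflict")
  expect_true(is.na(r$value))
  expect_equal(r$n_conflicts, 1L)
})

test_that("source resolution agrees with a per-row oracle", {
  df <- tibble::tibble(
    a = random_categorical_column(200, c("x", "y", "z"), 0.3, seed = 31L),
    b = random_categorical_column(200, c("x", "y", "z"), 0.3, seed = 32L))
  r <- resolve_sources(df)
  expect_equal(r$value, unname(oracle_resolve(df)))
  oracle_conf <- sum(!is.na(df$a) & !is.na(df$b) & df$a != df$b)
  expect_equal(r$n_conflicts, oracle_conf)
})

test_that("inference reassigns only triggered Missing rows", {
  rule <- inference_rule(c("walk", "cycle"), "Other mode of travel",
                         negative_values = c("0", "No"))
  ind <- tibble::tibble(walk = c("0", "0", "1", NA),
                        cycle = c("0", "0", "0", "0"))
  base <- c("Missing", "Active mode of travel", "Missing", "Missing")
  got <- apply_inference(ind, rule, base)
  expect_equal(got$value, c("Other mode of travel", "Active mode of travel",
                            "Missing", "Missing"))
  expect_equal(got$n_inferred, 1L)
  # missing indicators can be declared negative explicitly
  rule2 <- inference_rule(c("walk", "cycle"), "Other mode of travel",
                          negative_values = c("0", "No"),
                          treat_missing_as_negative = TRUE)
  expect_equal(apply_inference(ind, rule2, base)$value[4],
               "Other mode of travel")
})

test_that("inference matches a predicate-filter oracle on random rows", {
  withr::with_seed(41L, {
    n <- 500L
    ind <- tibble::tibble(
      walk = sample(c("0", "1", NA), n, replace = TRUE),
      cycle = sample(c("0", "1", NA), n, replace = TRUE))
    base <- sample(c("Missing", "Active"), n, replace = TRUE)
  })
  rule <- inference_rule(c("walk", "cycle"), "Other")
  got <- apply_inference(ind, rule, base)
  oracle <- base
  for (i in seq_len(n <- 500L)) {
    if (base[i] == "Missing" && isTRUE(ind$walk[i] == "0") &&
        isTRUE(ind$cycle[i] == "0")) {
      oracle[i] <- "Other"
    }
  }
  expect_equal(got$value, oracle)
  expect_equal(got$n_inferred, sum(oracle != base))
})

test_that("harmonising one study-wave returns fragment plus recode record", {
  ex <- school_travel_example()
  out <- harmonise_study_wave(ex$tables$KISS, ex$specs$ICAD_SchoolTravel2, 1L,
                              ex$dictionary)
  expect_equal(nrow(out$fragment), 540L)
  counts <- table(out$fragment$category)
  expect_equal(unname(counts[c(ACTIVE, OTHER, "Missing")]), c(443L, 10L, 87L),
               ignore_attr = TRUE)
  expect_false(out$recode$excluded)
  expect_equal(out$recode$respondent, "parent")
  expect_equal(sum(out$recode$output_marginals$n), out$recode$n)
  expect_match(out$recode$rule_text, "Walk OR Cycle/scooter", fixed = TRUE)
})

test_that("an excluded wave yields an empty fragment and a reasoned record", {
  ex <- school_travel_example()
  out <- harmonise_study_wave(ex$tables$Ballabeina,
                              ex$specs$ICAD_SchoolTravel3, 1L, ex$dictionary)
  expect_equal(nrow(out$fragment), 0L)
  expect_true(out$recode$excluded)
  expect_match(out$recode$exclusion_reason, "could not be suitably collapsed")
})

test_that("an empty table harmonises to an empty fragment with zero marginals", {
  ex <- school_travel_example()
  empty <- as_study_table(ex$tables$KISS[0, ], "KISS")
  out <- harmonise_study_wave(empty, ex$specs$ICAD_SchoolTravel2, 1L,
                              ex$dictionary)
  expect_equal(nrow(out$fragment), 0L)
  expect_true(all(out$recode$output_marginals$n == 0L))
})

test_that("pooling appends fragments and preserves per-wave tabulations", {
  ex <- school_travel_example()
  spec <- ex$specs$ICAD_SchoolTravel2
  frags <- lapply(ex$tables, function(tab)
    harmonise_study_wave(tab, spec, 1L, ex$dictionary)$fragment)
  ds <- pool(frags, spec)
  expect_equal(nrow(ds), 2064L + 540L + 669L)
  tab <- tabulate_harmonised(ds)
  expect_counts(tab, "SPEEDY",
                c("Active mode of travel" = 1003L,
                  "Other mode of travel" = 1050L, Missing = 11L))
  expect_counts(tab, "KISS",
                c("Active mode of travel" = 443L,
                  "Other mode of travel" = 10L, Missing = 87L))
  expect_counts(tab, "Ballabeina",
                c("Active mode of travel" = 547L,
                  "Other mode of travel" = 60L, Missing = 62L))
  # single fragment pools to itself
  single <- pool(frags[1], spec)
  expect_equal(as.data.frame(single), as.data.frame(frags[[1]]),
               ignore_attr = TRUE)
  # duplicates are integrity errors
  expect_error(pool(list(frags[[1]], frags[[1]]), spec),
               class = "harmonisr_integrity_error")
})

test_that("pooled n is the sum of fragment sizes on random fragments", {
  withr::with_seed(55L, {
    frags <- lapply(1:6, function(i) {
      n <- sample(0:40, 1)
      tibble::tibble(study_id = paste0("S", i), wave = 1L,
                     participant_id = sprintf("P%03d", seq_len(n)),
                     variable = "V", category = sample(c("A", "B", "Missing"),
                                                       n, replace = TRUE))
    })
  })
  expect_equal(nrow(pool(frags)), sum(vapply(frags, nrow, integer(1))))
})

test_that("tabulation equals a group-and-count oracle and conserves totals", {
  withr::with_seed(66L, {
    ds <- tibble::tibble(
      study_id = sample(c("S1", "S2"), 400, replace = TRUE),
      wave = sample(1:2, 400, replace = TRUE),
      participant_id = sprintf("P%03d", 1:400),
      variable = "V",
      category = sample(c("A", "B", "Missing"), 400, replace = TRUE))
  })
  tab <- tabulate_harmonised(pool(list(ds)), "V", c("A", "B", "Missing"))
  for (k in seq_len(nrow(tab$by_wave))) {
    row <- tab$by_wave[k, ]
    oracle <- sum(ds$study_id == row$study_id & ds$wave == row$wave &
                    ds$category == as.character(row$category))
    expect_equal(row$n, oracle)
  }
  sums <- tab$per_wave_n
  for (k in seq_len(nrow(sums))) {
    expect_equal(sums$n[k], sum(ds$study_id == sums$study_id[k] &
                                  ds$wave == sums$wave[k]))
  }
  expect_equal(sum(tab$overall$n), 400L)
  # empty dataset tabulates to zero counts
  empty <- tabulate_harmonised(pool(list(ds[0, ])), "V", c("A", "B"))
  expect_equal(sum(empty$overall$n), 0L)
})

test_that("row order does not affect harmonised output", {
  ex <- school_travel_example()
  spec <- ex$specs$ICAD_SchoolTravel3
  tab <- ex$tables$SPEEDY
  shuffled <- as_study_table(tab[withr::with_seed(9L, sample.int(nrow(tab))), ],
                             "SPEEDY")
  a <- harmonise_study_wave(tab, spec, 1L, ex$dictionary)$fragment
  b <- harmonise_study_wave(shuffled, spec, 1L, ex$dictionary)$fragment
  expect_identical(a, b)
})

test_that("coverage summary reproduces the encoded registry totals", {
  cov <- coverage_summary(school_travel_registry())
  got <- stats::setNames(
    lapply(cov$variable, function(v) cov[cov$variable == v, ]), cov$variable)
  expect_equal(got$ICAD_SchoolTravel1$n_studies, 11L)
  expect_equal(got$ICAD_SchoolTravel1$n_waves, 21L)
  expect_equal(got$ICAD_SchoolTravel2$n_studies, 14L)
  expect_equal(got$ICAD_SchoolTravel2$n_waves, 25L)
  expect_equal(got$ICAD_SchoolTravel3$n_studies, 8L)
  expect_equal(got$ICAD_SchoolTravel3$n_waves, 13L)
  expect_equal(unname(unlist(got$ICAD_SchoolTravel2$wave_histogram)),
               c(7L, 3L, 4L))
  empty <- coverage_summary(tibble::tibble(variable = character(),
                                           study_id = character(),
                                           wave = integer()))
  expect_equal(nrow(empty), 0L)
})

test_that("native missing codes are translated on load and logged", {
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(participant_id = c("P1", "P2", "P3"),
                                  W1_dur = c(10, -99, 5)), path, na = "")
  tab <- read_study_table(path, "DEMO",
                          missing_codes = list(W1_dur = -99))
  expect_true(is.na(tab$W1_dur[2]))
  expect_equal(attr(tab, "missing_code_log"), list(W1_dur = 1L))
})

test_that("mode-gated duration selection mirrors the instrument restriction", {
  ex <- school_travel_example()
  out <- harmonise_study_wave(ex$tables$SPEEDY, ex$specs$ICAD_SchoolTravel3,
                              1L, ex$dictionary)
  counts <- table(out$fragment$category)
  # bus/car participants have no separately-estimated duration -> Missing
  expect_equal(unname(counts["Missing"]), 1083L, ignore_attr = TRUE)
  expect_equal(unname(counts[c("Less than or equal to 5 min", "6–15 min",
                               "More than 15 min")]),
               c(356L, 432L, 193L), ignore_attr = TRUE)
})

test_that("conservation holds on random study-waves", {
  cats <- c("A", "B", "C", "D")
  rule <- category_map_rule("W1_v", stats::setNames(
    c("X", "X", "Y", "Y"), cats))
  spec <- harmonisation_spec(
    "RND", "", c("X", "Y", "Missing"),
    rules = list(list(study_id = "S", wave = 1L, rule = rule)))
  for (i in 1:20) {
    n <- withr::with_seed(100L + i, sample(0:300, 1))
    tab <- as_study_table(tibble::tibble(
      participant_id = sprintf("P%04d", seq_len(n)),
      W1_v = random_categorical_column(n, cats, 0.25, seed = 200L + i)), "S")
    out <- harmonise_study_wave(tab, spec, 1L)
    expect_equal(sum(out$recode$output_marginals$n), n)
    expect_equal(nrow(out$fragment), n)
  }
})
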