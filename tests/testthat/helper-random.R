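# Seeded random instances for property-style tests.

`%||%` <- function(x, y) if (is.null(x)) y else x

random_dictionary <- function(n_entries = 500L, n_studies = 5L,
                              n_groups = 10L, seed = 1L) {
  withr::with_seed(seed, {
    study <- sample(sprintf("study%02d", seq_len(n_studies)), n_entries,
                    replace = TRUE)
    idx <- stats::ave(seq_len(n_entries), study, FUN = seq_along)
    wave <- sample(c(NA, 1:3), n_entries, replace = TRUE)
    name <- ifelse(is.na(wave), sprintf("var%03d", idx),
                   sprintf("W%d_var%03d", wave, idx))
    fmt <- sample(c("categorical", "continuous"), n_entries, replace = TRUE)
    new_dictionary(tibble::tibble(
      study_id = study,
      variable_id = idx,
      name = name,
      label = paste("Label", idx),
      description = "synthetic entry",
      unit = ifelse(fmt == "continuous", "minutes", NA),
      format = fmt,
      categories = ifelse(fmt == "categorical", "A;B;C", NA),
      variable_group = sample(sprintf("Group_%02d", seq_len(n_groups)),
                              n_entries, replace = TRUE),
      wave = wave,
      respondent = sample(c("child", "parent", "unknown"), n_entries,
                          replace = TRUE)
    ))
  })
}

random_categorical_column <- function(n, categories, missing_rate = 0.1,
                                      seed = 1L) {
  withr::with_seed(seed, {
    x <- sample(categories, n, replace = TRUE)
    x[stats::runif(n) < missing_rate] <- NA
    x
  })
}

# Brute-force per-row oracle for threshold bins (explicit if-chain).
oracle_bin <- function(x, uppers, labels) {
  vapply(x, function(v) {
    if (is.na(v)) return("Missing")
    for (i in seq_along(uppers)) {
      if (v <= uppers[i]) return(labels[i])
    }
    stop("unreachable")
  }, character(1))
}

# Brute-force per-row oracle for first-non-missing source resolution.
oracle_resolve <- function(df) {
  apply(df, 1L, function(row) {
    nn <- row[!is.na(row)]
    if (length(nn)) nn[[1]] else NA_character_
  })
}

expect_counts <- function(tabulation, study, expected) {
  by_wave <- tabulation$by_wave
  sub <- by_wave[by_wave$study_id == study, ]
  got <- stats::setNames(sub$n, as.character(sub$category))
  expect_equal(got[names(expected)], expected, ignore_attr = TRUE)
}
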