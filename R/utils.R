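#' @importFrom rlang abort warn .data :=
#' @importFrom tibble tibble as_tibble
NULL

# Canonical missing category label, reserved in every harmonised variable.
MISSING_LABEL <- "Missing"

# Wave prefix convention: W<digits>_ at the start of a variable name marks the
# wave of assessment; unprefixed names are time-invariant.
WAVE_PREFIX_RE <- "^W([0-9]+)_"

#' Parse the wave prefix of a variable name
#'
#' Variable names carry their wave of assessment as a `W<digits>_` prefix
#' (`W1_height` is height at wave 1). Names without the prefix denote
#' time-invariant variables and return `NA`.
#'
#' @param name Character vector of variable names.
#' @return Integer vector of waves, `NA` where no prefix is present.
#' @examples
#' parse_wave_prefix(c("W1_school_travel", "W12_height", "sex"))
#' @export
parse_wave_prefix <- function(name) {
  m <- regmatches(name, regexec(WAVE_PREFIX_RE, name))
  vapply(m, function(x) if (length(x) == 2L) as.integer(x[2L]) else NA_integer_,
         integer(1))
}

# Exact label matching after Unicode NFC normalisation and whitespace trim.
# Translated instruments are matched on their verbatim labels, never fuzzily.
norm_label <- function(x) {
  out <- stringi::stri_trans_nfc(trimws(as.character(x)))
  out[is.na(x)] <- NA_character_
  out
}

# Atomic file write: write to a sibling temp file, then rename into place.
atomic_write <- function(writer, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) {
    file.copy(tmp, path, overwrite = TRUE)
    unlink(tmp)
  }
  invisible(path)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Stable per-purpose seed derived from a base seed; keeps streams independent
# across studies/variables while remaining a pure function of the base seed.
derive_seed <- function(seed, ...) {
  tokens <- paste(c(seed, ...), collapse = "/")
  h <- utils::head(utf8ToInt(tokens), 64)
  s <- sum(h * (seq_along(h) * 131L)) + seed * 7919
  as.integer(s %% 2147483647L)
}
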