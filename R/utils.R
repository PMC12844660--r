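# Controlled vocabularies for ICSR fields. EudraVigilance line listings code
# demographics into fixed strata; "NS" = not specified.

icsr_age_levels <- c("NS", "0-1 Month", "2 Months-2 Years", "3-11 Years",
                     "12-17 Years", "18-64 Years", "65-85 Years", ">85 Years")
icsr_sex_levels <- c("Female", "Male", "NS")
icsr_origin_levels <- c("EEA", "Non-EEA", "NS")
icsr_reporter_levels <- c("HP", "Non-HP", "NS")

# Outcomes ordered worst-first; worst_outcome() relies on this ordering.
icsr_outcome_levels <- c("Fatal", "NotRecovered", "RecoveredWithSequelae",
                         "Recovering", "Recovered", "Unknown")

icsr_columns <- c("report_id", "drug", "age_group", "sex", "origin",
                  "reporter", "pt", "soc", "outcome")

#' Round half-up
#'
#' Rounds to `digits` decimals with ties going away from zero, the convention
#' used when printing percentages and odds ratios in regulatory tables
#' (base [round()] rounds half to even).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @examples
#' round_half_up(0.125, 2)  # 0.13, not 0.12
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Normalize a term for matching: case-fold and collapse whitespace. PT
# matching is exact on the normalized form; no substring or fuzzy matching.
normalize_term <- function(x) {
  tolower(gsub("\\s+", " ", trimws(x)))
}

# Map free-text field values onto a controlled vocabulary, case-insensitively
# and with optional synonyms (named character vector: synonym -> level).
# Unmappable values fall back to `default` and are counted, not dropped.
map_enum <- function(x, levels, default, synonyms = NULL) {
  key <- normalize_term(x)
  lut <- stats::setNames(levels, normalize_term(levels))
  if (!is.null(synonyms)) {
    lut <- c(lut, stats::setNames(as.character(synonyms), normalize_term(names(synonyms))))
  }
  out <- unname(lut[key])
  n_bad <- sum(is.na(out) & !is.na(x) & nzchar(trimws(x)))
  out[is.na(out)] <- default
  list(values = out, n_unmapped = n_bad)
}

# Run an expression with a private RNG stream, restoring the caller's state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}
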