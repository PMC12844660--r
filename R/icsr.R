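#' ICSR line listings
#'
#' An ICSR (Individual Case Safety Report) set is stored as a data frame in
#' canonical long form: one row per reported reaction, with the report-level
#' fields (`report_id`, `drug`, `age_group`, `sex`, `origin`, `reporter`)
#' repeated across the rows of a report and the reaction-level fields (`pt`,
#' `soc`, `outcome`) varying. A report therefore always carries at least one
#' reaction. `as_icsr()` validates a data frame against this schema and the
#' controlled vocabularies and stamps it with class `icsr_set`.
#'
#' Validation enforces:
#' * all nine canonical columns present;
#' * `age_group`, `sex`, `origin`, `reporter`, `outcome` drawn from their
#'   controlled vocabularies;
#' * report-level fields constant within each `report_id` (rows of one report
#'   must agree on drug and demographics);
#' * non-empty `pt` on every row.
#'
#' @param x data frame with the canonical columns.
#' @return `x` with class `c("icsr_set", "data.frame")`.
#' @seealso [read_line_listing()], [write_line_listing()], [simulate_dataset()]
#' @export
as_icsr <- function(x) {
  stopifnot(is.data.frame(x))
  missing_cols <- setdiff(icsr_columns, names(x))
  if (length(missing_cols)) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  x <- as.data.frame(x)[icsr_columns]
  for (col in icsr_columns) x[[col]] <- as.character(x[[col]])

  checks <- list(age_group = icsr_age_levels, sex = icsr_sex_levels,
                 origin = icsr_origin_levels, reporter = icsr_reporter_levels,
                 outcome = icsr_outcome_levels)
  for (col in names(checks)) {
    bad <- setdiff(unique(x[[col]]), checks[[col]])
    if (length(bad)) {
      stop(sprintf("invalid %s value(s): %s", col, paste(bad, collapse = ", ")),
           call. = FALSE)
    }
  }
  if (any(!nzchar(trimws(x$pt)))) {
    stop("every reaction row must carry a non-empty preferred term", call. = FALSE)
  }

  # report-level fields must not conflict within a report_id
  demo <- unique(x[c("report_id", "drug", "age_group", "sex", "origin", "reporter")])
  dup <- unique(demo$report_id[duplicated(demo$report_id)])
  if (length(dup)) {
    stop("conflicting report-level fields for report_id(s): ",
         paste(utils::head(dup, 10L), collapse = ", "), call. = FALSE)
  }
  class(x) <- c("icsr_set", "data.frame")
  rownames(x) <- NULL
  x
}

#' Number of reports (cases) in an ICSR set
#'
#' @param x an `icsr_set`.
#' @param by_drug if `TRUE`, return a named vector of per-drug report counts.
#' @return integer count, or named integer vector.
#' @export
n_reports <- function(x, by_drug = FALSE) {
  stopifnot(inherits(x, "icsr_set"))
  ids <- unique(x[c("report_id", "drug")])
  if (by_drug) {
    tab <- table(ids$drug)
    stats::setNames(as.integer(tab), names(tab))
  } else {
    nrow(ids)
  }
}

#' @export
print.icsr_set <- function(x, ...) {
  cat(sprintf("ICSR line listing: %d reports, %d reaction rows, %d drug(s)\n",
              n_reports(x), nrow(x), length(unique(x$drug))))
  tab <- n_reports(x, by_drug = TRUE)
  for (d in names(tab)) cat(sprintf("  %-28s %5d reports\n", d, tab[[d]]))
  invisible(x)
}

#' Default line-listing dialect
#'
#' A dialect maps a foreign CSV layout onto the canonical schema: `col_map`
#' renames source columns (named character vector, canonical name ->
#' source name), and `synonyms` supplies extra case-insensitive aliases per
#' enum field (e.g. `"M"` for `"Male"`). Matching against the vocabularies is
#' always case-insensitive even without synonyms.
#'
#' @param col_map named character vector, canonical -> source column name.
#' @param synonyms named list of named character vectors, one per enum field.
#' @return a list of class `icsr_dialect`.
#' @export
icsr_dialect <- function(col_map = NULL, synonyms = NULL) {
  base_syn <- list(
    sex = c(m = "Male", f = "Female", "not specified" = "NS", na = "NS"),
    age_group = c("not specified" = "NS"),
    origin = c("european economic area" = "EEA", "not specified" = "NS"),
    reporter = c("healthcare professional" = "HP",
                 "non healthcare professional" = "Non-HP",
                 "non-healthcare professional" = "Non-HP",
                 "not specified" = "NS"),
    outcome = c("fatal" = "Fatal",
                "not recovered/not resolved" = "NotRecovered",
                "recovered/resolved with sequelae" = "RecoveredWithSequelae",
                "recovered/resolved" = "Recovered",
                "recovering/resolving" = "Recovering",
                "unknown" = "Unknown")
  )
  if (!is.null(synonyms)) {
    for (f in names(synonyms)) base_syn[[f]] <- c(base_syn[[f]], synonyms[[f]])
  }
  structure(list(col_map = col_map, synonyms = base_syn), class = "icsr_dialect")
}

#' Read an ICSR line listing from CSV
#'
#' Reads a canonical (or dialect-mapped) comma-separated line listing, maps
#' the enum fields case-insensitively onto their controlled vocabularies, and
#' validates the result. Values that cannot be mapped become `NS` (for
#' demographics) or `Unknown` (for outcomes); a single warning reports how
#' many values were coerced. Rows sharing a `report_id` form one report with
#' several reactions; conflicting report-level fields within an id are an
#' error.
#'
#' @param path CSV file path.
#' @param dialect an [icsr_dialect()]; the default handles canonical files
#'   and common EudraVigilance-style spellings.
#' @return an [as_icsr()]-validated `icsr_set`.
#' @export
read_line_listing <- function(path, dialect = icsr_dialect()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         fileEncoding = "UTF-8")
  if (!is.null(dialect$col_map)) {
    for (canon in names(dialect$col_map)) {
      src <- dialect$col_map[[canon]]
      if (src %in% names(raw)) names(raw)[names(raw) == src] <- canon
    }
  }
  missing_cols <- setdiff(icsr_columns, names(raw))
  if (length(missing_cols)) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  raw <- raw[icsr_columns]
  if (nrow(raw) == 0L) return(as_icsr(raw))

  specs <- list(age_group = list(icsr_age_levels, "NS"),
                sex = list(icsr_sex_levels, "NS"),
                origin = list(icsr_origin_levels, "NS"),
                reporter = list(icsr_reporter_levels, "NS"),
                outcome = list(icsr_outcome_levels, "Unknown"))
  n_coerced <- 0L
  for (col in names(specs)) {
    m <- map_enum(raw[[col]], specs[[col]][[1]], specs[[col]][[2]],
                  dialect$synonyms[[col]])
    raw[[col]] <- m$values
    n_coerced <- n_coerced + m$n_unmapped
  }
  if (n_coerced > 0L) {
    warning(sprintf("%d unmappable field value(s) coerced to NS/Unknown", n_coerced),
            call. = FALSE)
  }
  as_icsr(raw)
}

#' Write an ICSR line listing to canonical CSV
#'
#' Writes UTF-8, comma-separated, fully quoted CSV with the canonical header.
#' `read_line_listing(write_line_listing(x, p))` reproduces `x` exactly, and
#' writing an already-canonical file again is byte-identical.
#'
#' @param x an `icsr_set` (validated on the way out).
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_line_listing <- function(x, path) {
  x <- as_icsr(x)
  utils::write.csv(x, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8", eol = "\n")
  invisible(path)
}
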