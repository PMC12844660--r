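#' Preferred Term catalogs
#'
#' A PT catalog names the adverse-event categories of interest and lists, for
#' each, the MedDRA Preferred Terms whose presence puts a report in that
#' category. Matching is exact on the case-folded, whitespace-collapsed term:
#' MedDRA PTs are a controlled vocabulary, so substring or fuzzy matching
#' would invent cases. A PT may belong to at most one category.
#'
#' @param categories named list of non-empty character vectors
#'   (category name -> PTs).
#' @return a named list with class `pt_catalog`.
#' @seealso [default_pt_catalog()], [read_pt_catalog()], [classify_report()]
#' @export
pt_catalog <- function(categories) {
  stopifnot(is.list(categories), length(categories) > 0)
  nm <- names(categories)
  if (is.null(nm) || any(!nzchar(nm)) || anyDuplicated(nm)) {
    stop("categories must have unique non-empty names", call. = FALSE)
  }
  categories <- lapply(categories, as.character)
  if (any(vapply(categories, length, 1L) == 0L)) {
    stop("every category must list at least one preferred term", call. = FALSE)
  }
  norm <- lapply(categories, normalize_term)
  all_terms <- unlist(norm, use.names = FALSE)
  if (anyDuplicated(all_terms)) {
    stop("a preferred term may appear in at most one category: ",
         paste(unique(all_terms[duplicated(all_terms)]), collapse = ", "),
         call. = FALSE)
  }
  structure(categories, class = "pt_catalog")
}

#' Default PT catalog: resistance, ineffectiveness, off-label use
#'
#' The built-in catalog carries three categories with 3, 11 and 8 Preferred
#' Terms respectively — the category sizes used in EudraVigilance screens of
#' Reserve-group antibiotics. The exact regulatory term lists are
#' MedDRA-licensed and vary by MedDRA version, so the defaults are standard
#' current terms ("Drug resistance", "Drug ineffective", "Off label use",
#' ...) and any study-specific list should be supplied via [pt_catalog()] or
#' [read_pt_catalog()].
#'
#' @return a `pt_catalog` with categories `resistance` (3 PTs),
#'   `ineffectiveness` (11 PTs) and `off_label` (8 PTs).
#' @export
default_pt_catalog <- function() {
  pt_catalog(list(
    resistance = c(
      "Drug resistance",
      "Pathogen resistance",
      "Multiple drug resistance"
    ),
    ineffectiveness = c(
      "Drug ineffective",
      "Drug ineffective for unapproved indication",
      "Therapeutic product ineffective",
      "Therapeutic response decreased",
      "Therapeutic response unexpected",
      "Therapy non-responder",
      "Therapy partial responder",
      "Treatment failure",
      "Drug effect decreased",
      "Drug effect incomplete",
      "Therapeutic product effect decreased"
    ),
    off_label = c(
      "Off label use",
      "Product use in unapproved indication",
      "Intentional product use issue",
      "Product use issue",
      "Drug use for unknown indication",
      "Intentional product misuse",
      "Unintentional use for unapproved indication",
      "Inappropriate schedule of product administration"
    )
  ))
}

#' Read or write a PT catalog (YAML or JSON)
#'
#' The on-disk form is a flat mapping `category: [PT, ...]`. Format is chosen
#' by file extension (`.yml`/`.yaml` vs `.json`).
#'
#' @param path file path.
#' @return `read_pt_catalog()`: a validated `pt_catalog`;
#'   `write_pt_catalog()`: `path`, invisibly.
#' @export
read_pt_catalog <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  obj <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  pt_catalog(obj)
}

#' @rdname read_pt_catalog
#' @param catalog a `pt_catalog`.
#' @export
write_pt_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "pt_catalog"))
  obj <- unclass(catalog)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(obj, path)
  } else {
    jsonlite::write_json(obj, path, pretty = TRUE)
  }
  invisible(path)
}

#' @export
print.pt_catalog <- function(x, ...) {
  cat(sprintf("PT catalog: %d categories\n", length(x)))
  for (nm in names(x)) {
    cat(sprintf("  %-16s %2d PTs (e.g. %s)\n", nm, length(x[[nm]]), x[[nm]][1]))
  }
  invisible(x)
}

#' Classify a report's reactions into catalog categories
#'
#' A report belongs to category `c` iff at least one of its reaction PTs is
#' (case-insensitively, after whitespace collapse) in the catalog's list for
#' `c`. A report can carry several categories, or none. The result does not
#' depend on reaction order and the operation is idempotent.
#'
#' @param pts character vector of the report's reaction Preferred Terms.
#' @param catalog a [pt_catalog()].
#' @return character vector of matching category names (possibly empty),
#'   in catalog order.
#' @export
classify_report <- function(pts, catalog) {
  stopifnot(inherits(catalog, "pt_catalog"))
  key <- normalize_term(pts)
  hit <- vapply(catalog, function(terms) any(key %in% normalize_term(terms)),
                logical(1))
  names(catalog)[hit]
}

# Report x category membership for a whole icsr_set: logical matrix with one
# row per unique (report_id, drug) pair, in first-appearance order.
classify_reports <- function(x, catalog) {
  stopifnot(inherits(x, "icsr_set"), inherits(catalog, "pt_catalog"))
  key <- normalize_term(x$pt)
  ids <- unique(x[c("report_id", "drug")])
  idx <- match(x$report_id, ids$report_id)
  m <- matrix(FALSE, nrow = nrow(ids), ncol = length(catalog),
              dimnames = list(ids$report_id, names(catalog)))
  for (j in seq_along(catalog)) {
    in_cat <- key %in% normalize_term(catalog[[j]])
    if (any(in_cat)) m[unique(idx[in_cat]), j] <- TRUE
  }
  attr(m, "drug") <- ids$drug
  m
}

#' Per-drug report counts by category
#'
#' Counts at report (case) level: a report contributes at most 1 to a
#' category however many qualifying PTs it lists. This is the counting unit
#' under which per-drug totals and category counts combine into the 2x2
#' tables of [build_table()].
#'
#' @param x an `icsr_set` (non-empty).
#' @param catalog a [pt_catalog()].
#' @return data frame of class `category_counts`: one row per drug, columns
#'   `drug`, `n_total`, then one count column per catalog category.
#' @export
count_by_category <- function(x, catalog = default_pt_catalog()) {
  stopifnot(inherits(x, "icsr_set"))
  if (nrow(x) == 0L) stop("empty ICSR set", call. = FALSE)
  m <- classify_reports(x, catalog)
  drug <- attr(m, "drug")
  drugs <- unique(drug)
  out <- data.frame(drug = drugs,
                    n_total = as.integer(table(factor(drug, levels = drugs))),
                    stringsAsFactors = FALSE)
  for (cat_name in colnames(m)) {
    out[[cat_name]] <- vapply(drugs, function(d) sum(m[drug == d, cat_name]),
                              integer(1))
  }
  class(out) <- c("category_counts", "data.frame")
  rownames(out) <- NULL
  out
}

#' Construct category counts directly from known totals
#'
#' Builds the same `category_counts` container as [count_by_category()] from
#' pre-aggregated numbers (e.g. counts transcribed from a published table),
#' validating `0 <= count <= n_total`.
#'
#' @param drug character vector of drug names.
#' @param n_total integer vector of per-drug report totals.
#' @param ... one named integer vector per category.
#' @return a `category_counts` data frame.
#' @export
category_counts <- function(drug, n_total, ...) {
  cats <- list(...)
  out <- data.frame(drug = as.character(drug), n_total = as.integer(n_total),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$drug)) stop("duplicate drug names", call. = FALSE)
  for (nm in names(cats)) {
    v <- as.integer(cats[[nm]])
    if (length(v) != nrow(out)) stop("length mismatch for category ", nm, call. = FALSE)
    if (any(v < 0L | v > out$n_total)) {
      stop(sprintf("category '%s' count outside [0, n_total]", nm), call. = FALSE)
    }
    out[[nm]] <- v
  }
  class(out) <- c("category_counts", "data.frame")
  out
}

category_names <- function(counts) {
  setdiff(names(counts), c("drug", "n_total"))
}
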