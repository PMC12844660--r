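#' Pipeline run configuration
#'
#' Bundles everything an end-to-end run needs: the input (a line-listing CSV
#' path, or the built-in reference fixture), the PT catalog, the drug groups
#' to screen, and the estimator settings.
#'
#' @param input path to a canonical line-listing CSV, or `NULL` with
#'   `fixture = TRUE`.
#' @param fixture use [reserve_fixture()] simulated at `seed` as input.
#' @param out_dir output directory (created if missing).
#' @param catalog a [pt_catalog()], a path to a YAML/JSON catalog, or `NULL`
#'   for [default_pt_catalog()].
#' @param categories categories to screen (default: all in the catalog).
#' @param index,comparator drug-group name vectors (default: all drugs).
#'   Overlapping groups are allowed when `allow_overlap` (self-pairs are
#'   always skipped); set it to `FALSE` to insist on disjoint groups.
#' @param alpha,correction estimator settings, see [ror_estimate()].
#' @param seed integer seed (fixture simulation).
#' @param allow_overlap permit index/comparator groups to intersect.
#' @return a list of class `run_config`.
#' @export
run_config <- function(input = NULL, fixture = is.null(input), out_dir = "rorscreen-out",
                       catalog = NULL, categories = NULL, index = NULL,
                       comparator = NULL, alpha = 0.05,
                       correction = c("none", "haldane"), seed = 1L,
                       allow_overlap = TRUE) {
  correction <- match.arg(correction)
  if (is.null(input) && !fixture) {
    stop("either an input path or fixture = TRUE is required", call. = FALSE)
  }
  if (!is.null(input) && fixture) {
    stop("give either an input path or fixture = TRUE, not both", call. = FALSE)
  }
  if (is.character(catalog)) catalog <- read_pt_catalog(catalog)
  if (is.null(catalog)) catalog <- default_pt_catalog()
  stopifnot(inherits(catalog, "pt_catalog"))
  if (!allow_overlap && length(intersect(index, comparator))) {
    stop("index and comparator groups overlap", call. = FALSE)
  }
  structure(list(input = input, fixture = fixture, out_dir = out_dir,
                 catalog = catalog, categories = categories, index = index,
                 comparator = comparator, alpha = alpha,
                 correction = correction, seed = as.integer(seed)),
            class = "run_config")
}

write_table_csv <- function(df, path) {
  utils::write.csv(as.data.frame(df), path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8", eol = "\n")
  path
}

#' Run the full screening pipeline
#'
#' Loads or simulates the input, classifies reports, and writes the full
#' report bundle to `config$out_dir`: the line listing (when simulated), the
#' descriptive tables (demographics, SOC frequencies, report distribution,
#' category rates and distributions, unfavourable-outcome breakdown), the
#' long-format disproportionality screen, and a JSON manifest recording the
#' input, seed, package version and row counts. Inputs are validated before
#' any output is written, so a failing run leaves no partial bundle.
#'
#' @param config a [run_config()].
#' @param quiet suppress progress messages (logged via [message()]).
#' @return invisibly, a list with the computed objects (`reports`, `counts`,
#'   `screen`, tables) and `paths` of the files written.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message(sprintf(...))

  if (config$fixture) {
    say("stage load: simulating reference fixture (seed %d)", config$seed)
    reports <- simulate_dataset(reserve_fixture(seed = config$seed))
  } else {
    if (!file.exists(config$input)) {
      stop("stage load: input file not found: ", config$input, call. = FALSE)
    }
    say("stage load: reading %s", config$input)
    reports <- read_line_listing(config$input)
  }
  say("stage classify: %d reports, %d reaction rows", n_reports(reports),
      nrow(reports))
  counts <- count_by_category(reports, config$catalog)
  demo <- demographics_table(reports)
  soc <- soc_frequency(reports)
  rates <- category_rates(counts)
  dist <- category_distribution(counts)
  rep_dist <- report_distribution(counts)
  outcomes <- outcome_breakdown(reports, config$catalog)
  say("stage disprop: screening %d drug(s)", nrow(counts))
  screen <- ror_screen(counts, index = config$index,
                       comparator = config$comparator,
                       categories = config$categories,
                       alpha = config$alpha, correction = config$correction)

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  if (config$fixture) {
    paths$line_listing <- write_line_listing(
      reports, file.path(config$out_dir, "line_listing.csv"))
  }
  tables <- list(category_counts = counts, demographics = demo,
                 soc_frequency = soc, category_rates = rates,
                 category_distribution = dist, report_distribution = rep_dist,
                 outcome_breakdown = outcomes, ror_screen = as.data.frame(screen))
  for (nm in names(tables)) {
    paths[[nm]] <- write_table_csv(tables[[nm]],
                                   file.path(config$out_dir, paste0(nm, ".csv")))
  }
  manifest <- list(
    input = if (config$fixture) "reserve_fixture" else config$input,
    seed = config$seed,
    package = "rorscreen",
    version = as.character(utils::packageVersion("rorscreen")),
    generated = format(Sys.time(), tz = "UTC", usetz = TRUE),
    n_reports = n_reports(reports),
    n_reaction_rows = nrow(reports),
    n_drugs = nrow(counts),
    categories = category_names(counts),
    alpha = config$alpha,
    correction = config$correction,
    files = stats::setNames(as.list(basename(unlist(paths))), names(paths))
  )
  paths$manifest <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE, pretty = TRUE)
  say("wrote %d file(s) to %s", length(paths), config$out_dir)
  invisible(c(list(reports = reports, screen = screen, paths = paths), tables))
}
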