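# Built-in filler reactions for reports that fall in no screened category.
# Their SOCs deliberately avoid the two SOCs that host the screened PTs
# ("General disorders..." and "Injury, poisoning...") so category counts and
# SOC shares stay decoupled.
filler_reactions <- function() {
  data.frame(
    pt = c("Nausea", "Diarrhoea", "Vomiting",
           "Headache", "Dizziness",
           "Rash", "Pruritus",
           "Alanine aminotransferase increased", "Blood creatinine increased",
           "Hypotension", "Phlebitis"),
    soc = c(rep("Gastrointestinal disorders", 3),
            rep("Nervous system disorders", 2),
            rep("Skin and subcutaneous tissue disorders", 2),
            rep("Investigations", 2),
            rep("Vascular disorders", 2)),
    stringsAsFactors = FALSE
  )
}

# Representative PTs used when a config pins an exact per-SOC report count.
soc_pt_pool <- function(soc) {
  pool <- list(
    "Blood and lymphatic system disorders" = c("Anaemia", "Thrombocytopenia", "Neutropenia"),
    "Hepatobiliary disorders" = c("Hepatitis", "Hyperbilirubinaemia", "Hepatocellular injury"),
    "Nervous system disorders" = c("Headache", "Seizure", "Encephalopathy"),
    "Renal and urinary disorders" = c("Acute kidney injury", "Renal impairment"),
    "Skin and subcutaneous tissue disorders" = c("Rash", "Pruritus", "Drug eruption"),
    "Infections and infestations" = c("Clostridioides difficile colitis", "Superinfection"),
    "Gastrointestinal disorders" = c("Nausea", "Diarrhoea"),
    "Cardiac disorders" = c("Tachycardia", "Atrial fibrillation")
  )
  if (soc %in% names(pool)) pool[[soc]] else soc
}

default_category_soc <- function() {
  c(resistance = "General disorders and administration site conditions",
    ineffectiveness = "General disorders and administration site conditions",
    off_label = "Injury, poisoning and procedural complications")
}

#' Per-drug simulation specification
#'
#' Describes one drug's block of a synthetic ICSR dataset. Category counts
#' and outcome counts are *allocated exactly* (not sampled), so aggregate
#' counts recomputed from the simulated dataset equal the configured values
#' for every seed; demographics may be pinned exactly (integer counts summing
#' to `n_total`) or sampled (probability vectors summing to 1).
#'
#' @param n_total number of reports for the drug.
#' @param categories named integer vector or list: reports carrying each
#'   category. By default categories occupy disjoint report subsets; `overlap`
#'   entries (each `list(categories = c(...), n = k)`) pin `k` reports to
#'   carry all the listed categories jointly, subtracted from the marginals.
#' @param demographics named list with any of `age_group`, `sex`, `origin`,
#'   `reporter`; each a named vector of exact level counts (integers summing
#'   to `n_total`) or level probabilities (summing to 1). Unlisted levels get
#'   0; omitted characteristics default to all-`NS`.
#' @param outcomes named list, one entry per category: named vector of exact
#'   outcome counts (summing to at most the category count; the remainder is
#'   `Unknown`) or outcome probabilities.
#' @param soc_counts named integer vector: exact number of reports carrying
#'   at least one reaction in each named System Organ Class. Pinned SOCs must
#'   not collide with the SOCs hosting category PTs.
#' @param overlap list of joint-category blocks, see `categories`.
#' @return a list of class `drug_sim`.
#' @seealso [sim_config()], [simulate_dataset()]
#' @export
drug_sim <- function(n_total, categories = NULL, demographics = NULL,
                     outcomes = NULL, soc_counts = NULL, overlap = NULL) {
  stopifnot(is.numeric(n_total), length(n_total) == 1L, n_total >= 0)
  structure(list(n_total = as.integer(n_total),
                 categories = categories, demographics = demographics,
                 outcomes = outcomes, soc_counts = soc_counts,
                 overlap = overlap),
            class = "drug_sim")
}

#' Simulation configuration for a synthetic ICSR dataset
#'
#' @param drugs named list of [drug_sim()] specifications (name = drug name).
#' @param seed integer seed; identical seed and config give a byte-identical
#'   line listing.
#' @param catalog [pt_catalog()] supplying the PTs drawn (uniformly, seeded)
#'   for each category a report carries.
#' @param category_soc named character vector mapping category name to the
#'   SOC recorded on its reactions; defaults place resistance and
#'   ineffectiveness PTs in "General disorders and administration site
#'   conditions" and off-label PTs in "Injury, poisoning and procedural
#'   complications", mirroring MedDRA.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(drugs, seed = 1L, catalog = default_pt_catalog(),
                       category_soc = default_category_soc()) {
  stopifnot(is.list(drugs), length(drugs) > 0)
  if (is.null(names(drugs)) || any(!nzchar(names(drugs)))) {
    stop("drugs must be a named list", call. = FALSE)
  }
  cfg <- structure(list(drugs = drugs, seed = as.integer(seed),
                        catalog = catalog, category_soc = category_soc),
                   class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

# split a named numeric vector into exact counts (integers summing to total)
# or probabilities (summing to 1); returns list(mode=, values=)
parse_marginal <- function(v, total, what, allow_partial = FALSE) {
  v <- unlist(v)
  if (is.null(names(v)) || any(!nzchar(names(v)))) {
    stop(what, ": marginal must be a named vector", call. = FALSE)
  }
  if (any(v < 0)) stop(what, ": negative value", call. = FALSE)
  integral <- all(abs(v - round(v)) < 1e-9)
  count_ok <- if (allow_partial) sum(v) <= total + 1e-9 else abs(sum(v) - total) < 1e-9
  if (integral && count_ok) {
    # integer-valued vectors that fit are exact counts; anything else must be
    # a probability vector
    list(mode = "counts", values = stats::setNames(as.integer(round(v)), names(v)))
  } else {
    if (abs(sum(v) - 1) > 1e-9) {
      stop(sprintf("%s: expected %s counts summing to %s%d, or probabilities summing to 1",
                   what, if (integral) "" else "integer ",
                   if (allow_partial) "at most " else "", total),
           call. = FALSE)
    }
    list(mode = "probs", values = v)
  }
}

validate_sim_config <- function(cfg) {
  cat_names <- names(cfg$catalog)
  demo_levels <- list(age_group = icsr_age_levels, sex = icsr_sex_levels,
                      origin = icsr_origin_levels, reporter = icsr_reporter_levels)
  for (drug in names(cfg$drugs)) {
    spec <- cfg$drugs[[drug]]
    stopifnot(inherits(spec, "drug_sim"))
    n <- spec$n_total
    cats <- unlist(spec$categories)
    if (length(cats)) {
      bad <- setdiff(names(cats), cat_names)
      if (length(bad)) {
        stop(sprintf("%s: unknown category '%s'", drug, bad[1]), call. = FALSE)
      }
      if (any(cats < 0) || any(cats > n)) {
        stop(sprintf("%s: category count outside [0, n_total]", drug), call. = FALSE)
      }
      joint <- 0L
      excl <- cats
      for (ov in spec$overlap) {
        if (!all(ov$categories %in% names(cats))) {
          stop(drug, ": overlap names a category without a marginal count", call. = FALSE)
        }
        joint <- joint + ov$n
        excl[ov$categories] <- excl[ov$categories] - ov$n
      }
      if (any(excl < 0)) {
        stop(drug, ": overlap exceeds a category's marginal count", call. = FALSE)
      }
      if (sum(excl) + joint > n) {
        stop(sprintf("%s: categories need %d reports but n_total is %d",
                     drug, sum(excl) + joint, n), call. = FALSE)
      }
    }
    for (f in names(spec$demographics)) {
      if (!f %in% names(demo_levels)) stop(drug, ": unknown characteristic ", f, call. = FALSE)
      m <- parse_marginal(spec$demographics[[f]], n, paste(drug, f))
      bad <- setdiff(names(m$values), demo_levels[[f]])
      if (length(bad)) {
        stop(sprintf("%s %s: unknown level '%s'", drug, f, bad[1]), call. = FALSE)
      }
    }
    for (cat_name in names(spec$outcomes)) {
      if (!cat_name %in% names(cats)) {
        stop(sprintf("%s: outcomes given for category '%s' with no count",
                     drug, cat_name), call. = FALSE)
      }
      m <- parse_marginal(spec$outcomes[[cat_name]], cats[[cat_name]],
                          paste(drug, cat_name, "outcomes"), allow_partial = TRUE)
      bad <- setdiff(names(m$values), icsr_outcome_levels)
      if (length(bad)) {
        stop(sprintf("%s %s: unknown outcome '%s'", drug, cat_name, bad[1]),
             call. = FALSE)
      }
    }
    if (!is.null(spec$soc_counts)) {
      sc <- unlist(spec$soc_counts)
      if (any(sc < 0) || any(sc > n)) {
        stop(drug, ": SOC count outside [0, n_total]", call. = FALSE)
      }
      clash <- intersect(names(sc), unname(cfg$category_soc))
      if (length(clash)) {
        stop(drug, ": pinned SOC collides with a category SOC: ", clash[1],
             call. = FALSE)
      }
    }
  }
  invisible(cfg)
}

# expand one characteristic for n reports: exact counts are laid out then
# shuffled; probabilities are sampled.
draw_marginal <- function(marg, n, levels, default) {
  if (is.null(marg)) return(rep(default, n))
  m <- parse_marginal(marg, n, "marginal")
  if (m$mode == "counts") {
    sample(rep(names(m$values), m$values), n)
  } else {
    sample(names(m$values), n, replace = TRUE, prob = m$values)
  }
}

# per-category outcome vector for k category reports
draw_outcomes <- function(out_spec, k) {
  if (is.null(out_spec) || k == 0L) return(rep("Unknown", k))
  m <- parse_marginal(out_spec, k, "outcomes", allow_partial = TRUE)
  if (m$mode == "counts") {
    v <- c(rep(names(m$values), m$values), rep("Unknown", k - sum(m$values)))
    sample(v, k)
  } else {
    sample(names(m$values), k, replace = TRUE, prob = m$values)
  }
}

#' Simulate a synthetic ICSR line listing
#'
#' Generates one report block per configured drug. Category membership and
#' (exact-count) outcomes are allocated deterministically to report slots and
#' then shuffled with the seeded RNG, so the per-drug totals, per-category
#' report counts, pinned demographics, outcome counts and pinned SOC counts
#' recomputed from the output equal the configured values exactly — only the
#' arrangement across report ids, the PT drawn within a category, and
#' probability-specified marginals vary with the seed.
#'
#' Reports in a category get one reaction per carried category (PT uniform
#' over the catalog's list, SOC from `category_soc`, outcome as allocated);
#' reports in no category get one filler reaction (outcome `Unknown`) drawn
#' from a built-in common-PT pool, excluding any SOC whose report count the
#' config pins.
#'
#' @param config a [sim_config()].
#' @param seed overrides `config$seed` when given.
#' @return an `icsr_set`.
#' @export
simulate_dataset <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  if (is.null(seed)) seed <- config$seed
  with_seed(as.integer(seed), {
    blocks <- lapply(names(config$drugs), function(drug) {
      simulate_drug_block(drug, config$drugs[[drug]], config)
    })
    as_icsr(do.call(rbind, blocks))
  })
}

simulate_drug_block <- function(drug, spec, config) {
  n <- spec$n_total
  slug <- toupper(gsub("[^A-Za-z0-9]+", "", drug))
  ids <- sprintf("%s-%05d", slug, seq_len(n))
  empty <- data.frame(report_id = character(0), drug = character(0),
                      age_group = character(0), sex = character(0),
                      origin = character(0), reporter = character(0),
                      pt = character(0), soc = character(0),
                      outcome = character(0), stringsAsFactors = FALSE)
  if (n == 0L) return(empty)

  # --- category membership: overlap blocks first, then exclusive singles ---
  cats <- unlist(spec$categories)
  member <- matrix(FALSE, nrow = n, ncol = length(cats),
                   dimnames = list(NULL, names(cats)))
  if (length(cats)) {
    excl <- cats
    cursor <- 0L
    for (ov in spec$overlap) {
      if (ov$n > 0L) {
        member[cursor + seq_len(ov$n), ov$categories] <- TRUE
        cursor <- cursor + ov$n
        excl[ov$categories] <- excl[ov$categories] - ov$n
      }
    }
    for (cat_name in names(excl)) {
      if (excl[[cat_name]] > 0L) {
        member[cursor + seq_len(excl[[cat_name]]), cat_name] <- TRUE
        cursor <- cursor + excl[[cat_name]]
      }
    }
    member <- member[sample.int(n), , drop = FALSE]
  }

  demo <- list(
    age_group = draw_marginal(spec$demographics$age_group, n, icsr_age_levels, "NS"),
    sex = draw_marginal(spec$demographics$sex, n, icsr_sex_levels, "NS"),
    origin = draw_marginal(spec$demographics$origin, n, icsr_origin_levels, "NS"),
    reporter = draw_marginal(spec$demographics$reporter, n, icsr_reporter_levels, "NS")
  )

  rows <- list()
  # category reactions with allocated outcomes
  for (cat_name in colnames(member)) {
    in_cat <- which(member[, cat_name])
    k <- length(in_cat)
    if (k == 0L) next
    pts <- sample(config$catalog[[cat_name]], k, replace = TRUE)
    soc <- config$category_soc[[cat_name]]
    if (is.null(soc) || is.na(soc)) soc <- "General disorders and administration site conditions"
    rows[[length(rows) + 1L]] <- data.frame(
      slot = in_cat, pt = pts, soc = soc,
      outcome = draw_outcomes(spec$outcomes[[cat_name]], k),
      stringsAsFactors = FALSE)
  }
  # filler reaction for reports carrying no category
  none <- if (length(cats)) which(!apply(member, 1, any)) else seq_len(n)
  if (length(none)) {
    pool <- filler_reactions()
    pinned <- names(unlist(spec$soc_counts))
    pool <- pool[!pool$soc %in% pinned, , drop = FALSE]
    pick <- sample.int(nrow(pool), length(none), replace = TRUE)
    rows[[length(rows) + 1L]] <- data.frame(
      slot = none, pt = pool$pt[pick], soc = pool$soc[pick],
      outcome = "Unknown", stringsAsFactors = FALSE)
  }
  # pinned-SOC extra reactions on distinct reports
  for (soc in names(spec$soc_counts)) {
    k <- spec$soc_counts[[soc]]
    if (k == 0L) next
    slots <- sample.int(n, k)
    rows[[length(rows) + 1L]] <- data.frame(
      slot = slots, pt = sample(soc_pt_pool(soc), k, replace = TRUE),
      soc = soc, outcome = "Unknown", stringsAsFactors = FALSE)
  }

  rx <- do.call(rbind, rows)
  rx <- rx[order(rx$slot), , drop = FALSE]
  data.frame(report_id = ids[rx$slot], drug = drug,
             age_group = demo$age_group[rx$slot], sex = demo$sex[rx$slot],
             origin = demo$origin[rx$slot], reporter = demo$reporter[rx$slot],
             pt = rx$pt, soc = rx$soc, outcome = rx$outcome,
             stringsAsFactors = FALSE)
}

#' Read or write a simulation configuration (YAML)
#'
#' The on-disk form mirrors [sim_config()]: a `seed` and a `drugs` mapping of
#' per-drug blocks (`n_total`, `categories`, `demographics`, `outcomes`,
#' `soc_counts`, `overlap`). The PT catalog is not serialized — supply it via
#' the `catalog` argument (default: [default_pt_catalog()]). A copy of the
#' reference preset ships at
#' `system.file("extdata", "reserve_cephalosporins.yaml", package = "rorscreen")`.
#'
#' @param path YAML file path.
#' @param catalog,category_soc passed to [sim_config()].
#' @return `read_sim_config()`: a validated `sim_config`;
#'   `write_sim_config()`: `path`, invisibly.
#' @export
read_sim_config <- function(path, catalog = default_pt_catalog(),
                            category_soc = default_category_soc()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  obj <- yaml::read_yaml(path)
  if (is.null(obj$drugs)) stop("config has no 'drugs' block", call. = FALSE)
  drugs <- lapply(obj$drugs, function(d) {
    drug_sim(n_total = d$n_total, categories = d$categories,
             demographics = d$demographics, outcomes = d$outcomes,
             soc_counts = d$soc_counts, overlap = d$overlap)
  })
  sim_config(drugs, seed = if (is.null(obj$seed)) 1L else obj$seed,
             catalog = catalog, category_soc = category_soc)
}

#' @rdname read_sim_config
#' @param config a `sim_config`.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  drugs <- lapply(config$drugs, function(d) {
    d <- unclass(d)
    d <- d[!vapply(d, is.null, logical(1))]
    d[names(d) %in% c("categories", "soc_counts")] <-
      lapply(d[names(d) %in% c("categories", "soc_counts")], as.list)
    d$demographics <- lapply(d$demographics, as.list)
    d$outcomes <- lapply(d$outcomes, as.list)
    d
  })
  yaml::write_yaml(list(seed = config$seed, drugs = drugs), path)
  invisible(path)
}
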