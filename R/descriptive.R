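new_freq_table <- function(df, what) {
  class(df) <- c("freq_table", "data.frame")
  attr(df, "what") <- what
  rownames(df) <- NULL
  df
}

#' @export
print.freq_table <- function(x, ...) {
  cat(attr(x, "what"), "\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

# one report-level row per report with its demographics
report_level <- function(x) {
  unique(as.data.frame(x)[c("report_id", "drug", "age_group", "sex",
                            "origin", "reporter")])
}

pct <- function(n, denom) {
  denom <- rep_len(denom, length(n))
  out <- round_half_up(100 * n / denom, 1)
  out[denom <= 0] <- NA_real_
  out
}

#' Demographics frequency table
#'
#' Report-level counts and percentages per drug for the four reporting
#' characteristics (age stratum, sex, origin, reporter type). Denominators
#' are the per-drug report totals; percentages are rounded half-up to one
#' decimal, so a drug's block sums to 100 within rounding.
#'
#' @param x a non-empty `icsr_set`.
#' @return a tidy `freq_table` data frame with columns `characteristic`,
#'   `level`, `drug`, `n`, `pct`.
#' @export
demographics_table <- function(x) {
  stopifnot(inherits(x, "icsr_set"))
  rep_df <- report_level(x)
  if (nrow(rep_df) == 0L) stop("empty ICSR set", call. = FALSE)
  drugs <- unique(rep_df$drug)
  totals <- table(factor(rep_df$drug, levels = drugs))
  specs <- list(age_group = icsr_age_levels, sex = icsr_sex_levels,
                origin = icsr_origin_levels, reporter = icsr_reporter_levels)
  out <- do.call(rbind, lapply(names(specs), function(ch) {
    tab <- table(factor(rep_df[[ch]], levels = specs[[ch]]),
                 factor(rep_df$drug, levels = drugs))
    df <- as.data.frame(tab, stringsAsFactors = FALSE)
    names(df) <- c("level", "drug", "n")
    df$characteristic <- ch
    df$pct <- pct(df$n, as.integer(totals[df$drug]))
    df[c("characteristic", "level", "drug", "n", "pct")]
  }))
  new_freq_table(out, "Demographics (report-level counts, % of drug total)")
}

#' System Organ Class frequency table
#'
#' For each drug, the share of reports containing at least one reaction in
#' each SOC (report-level counting: several reactions of one report in the
#' same SOC count once). Denominator is the drug's report total.
#'
#' @param x a non-empty `icsr_set` whose reactions carry SOC labels.
#' @return a `freq_table` with columns `soc`, `drug`, `n`, `pct`.
#' @export
soc_frequency <- function(x) {
  stopifnot(inherits(x, "icsr_set"))
  df <- unique(as.data.frame(x)[c("report_id", "drug", "soc")])
  df <- df[nzchar(trimws(df$soc)), , drop = FALSE]
  if (nrow(df) == 0L) stop("no SOC labels present", call. = FALSE)
  drugs <- unique(x$drug)
  totals <- n_reports(x, by_drug = TRUE)
  tab <- as.data.frame(table(soc = df$soc, drug = factor(df$drug, levels = drugs)),
                       stringsAsFactors = FALSE)
  names(tab) <- c("soc", "drug", "n")
  tab$pct <- pct(tab$n, as.integer(totals[tab$drug]))
  tab <- tab[order(tab$soc, tab$drug), ]
  new_freq_table(tab, "SOC frequency (reports with >=1 reaction in SOC, % of drug total)")
}

#' Category rates: share of a drug's reports falling in each category
#'
#' `rate = n_by_category / n_total` per drug, as a percentage rounded half-up
#' to one decimal. A drug with no reports gets `NA`.
#'
#' @param counts a `category_counts` table (see [count_by_category()]).
#' @return a `freq_table` with columns `drug`, `category`, `n`, `pct`.
#' @export
category_rates <- function(counts) {
  stopifnot(inherits(counts, "category_counts"))
  cats <- category_names(counts)
  out <- do.call(rbind, lapply(cats, function(cat_name) {
    data.frame(drug = counts$drug, category = cat_name,
               n = counts[[cat_name]],
               pct = pct(counts[[cat_name]], counts$n_total),
               stringsAsFactors = FALSE)
  }))
  new_freq_table(out, "Category rates (% of the drug's reports)")
}

#' Category distribution: how a category's reports split across drugs
#'
#' `share = drug count / category total across drugs`, as a percentage
#' rounded half-up to one decimal; shares of a category sum to 100 within
#' rounding. If a category has no reports at all its shares are `NA`.
#'
#' @param counts a `category_counts` table.
#' @return a `freq_table` with columns `category`, `drug`, `n`, `pct`.
#' @export
category_distribution <- function(counts) {
  stopifnot(inherits(counts, "category_counts"))
  cats <- category_names(counts)
  out <- do.call(rbind, lapply(cats, function(cat_name) {
    total <- sum(counts[[cat_name]])
    data.frame(category = cat_name, drug = counts$drug,
               n = counts[[cat_name]],
               pct = pct(counts[[cat_name]], total),
               stringsAsFactors = FALSE)
  }))
  new_freq_table(out, "Category distribution (% of the category total across drugs)")
}

#' Share of all reports accounted for by each drug
#'
#' @param counts a `category_counts` table.
#' @return a `freq_table` with columns `drug`, `n`, `pct` (percent of the
#'   dataset's reports, half-up to one decimal).
#' @export
report_distribution <- function(counts) {
  stopifnot(inherits(counts, "category_counts"))
  out <- data.frame(drug = counts$drug, n = counts$n_total,
                    pct = pct(counts$n_total, sum(counts$n_total)),
                    stringsAsFactors = FALSE)
  new_freq_table(out, "Distribution of reports across drugs")
}

#' Report-level worst outcome
#'
#' Collapses a report's reaction outcomes to a single case outcome, taking
#' the worst under a severity ordering (default: Fatal > NotRecovered >
#' RecoveredWithSequelae > Recovering > Recovered > Unknown).
#'
#' @param outcomes character vector of reaction outcomes.
#' @param ordering severity ordering, worst first.
#' @return the worst outcome present.
#' @export
worst_outcome <- function(outcomes, ordering = icsr_outcome_levels) {
  ordering[min(match(outcomes, ordering))]
}

#' Unfavourable-outcome breakdown per category
#'
#' For each catalog category and drug, counts reports (cases) in the
#' category whose *worst* reaction outcome is unfavourable. By default the
#' unfavourable set is Fatal, Not recovered, and Recovered with sequelae —
#' each reported as its own subcategory; drop `"RecoveredWithSequelae"` from
#' `unfavourable` to treat sequelae cases as favourable instead. Per-outcome
#' totals across drugs are appended as drug `"Total"`.
#'
#' @param x an `icsr_set`.
#' @param catalog a [pt_catalog()].
#' @param unfavourable outcome levels counted, worst first.
#' @param ordering severity ordering passed to [worst_outcome()].
#' @return a `freq_table` with columns `category`, `drug`, `outcome`, `n`.
#' @export
outcome_breakdown <- function(x, catalog = default_pt_catalog(),
                              unfavourable = c("Fatal", "NotRecovered",
                                               "RecoveredWithSequelae"),
                              ordering = icsr_outcome_levels) {
  stopifnot(inherits(x, "icsr_set"), all(unfavourable %in% ordering))
  m <- classify_reports(x, catalog)
  drug <- attr(x = m, which = "drug")
  ids <- rownames(m)
  worst <- vapply(split(x$outcome, factor(x$report_id, levels = ids)),
                  worst_outcome, character(1), ordering = ordering)
  drugs <- unique(drug)
  out <- do.call(rbind, lapply(colnames(m), function(cat_name) {
    do.call(rbind, lapply(c(drugs, "Total"), function(d) {
      sel <- m[, cat_name] & (if (d == "Total") TRUE else drug == d)
      tab <- table(factor(worst[sel], levels = unfavourable))
      data.frame(category = cat_name, drug = d, outcome = unfavourable,
                 n = as.integer(tab), stringsAsFactors = FALSE)
    }))
  }))
  new_freq_table(out, "Unfavourable outcomes per category (report-level worst outcome)")
}
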