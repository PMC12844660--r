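#' Build the 2x2 contingency table for one drug pair and one category
#'
#' Cells follow the standard disproportionality layout: `a` = index-drug
#' reports with the event category, `b` = index-drug reports without it,
#' `c`/`d` likewise for the comparator. Rows of the same `category_counts`
#' table are directly comparable because both use report-level counting.
#'
#' @param counts_a,counts_b single-row `category_counts` slices (index and
#'   comparator drug respectively), e.g. `counts[counts$drug == "x", ]`.
#' @param category category (column) name.
#' @return a list of class `contingency_2x2` with fields `drug_a`, `drug_b`,
#'   `category`, `a`, `b`, `c`, `d`.
#' @seealso [ror_estimate()], [ror_screen()]
#' @export
build_table <- function(counts_a, counts_b, category) {
  for (cc in list(counts_a, counts_b)) {
    stopifnot(inherits(cc, "category_counts"), nrow(cc) == 1L)
    if (!category %in% category_names(cc)) {
      stop("unknown category: ", category, call. = FALSE)
    }
  }
  a <- counts_a[[category]][1]
  c_ <- counts_b[[category]][1]
  structure(list(drug_a = counts_a$drug[1], drug_b = counts_b$drug[1],
                 category = category,
                 a = a, b = counts_a$n_total[1] - a,
                 c = c_, d = counts_b$n_total[1] - c_),
            class = "contingency_2x2")
}

#' Construct a 2x2 table from raw cells
#'
#' @param a,b,c,d non-negative cell counts (`a` = index with event, `b` =
#'   index without, `c` = comparator with, `d` = comparator without).
#' @param drug_a,drug_b,category optional labels.
#' @return a `contingency_2x2`.
#' @export
contingency_2x2 <- function(a, b, c, d, drug_a = "index", drug_b = "comparator",
                            category = "event") {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0)) stop("cells must be non-negative", call. = FALSE)
  structure(c(list(drug_a = drug_a, drug_b = drug_b, category = category),
              as.list(cells)),
            class = "contingency_2x2")
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  cat(sprintf("2x2 table, %s: %s vs %s\n", x$category, x$drug_a, x$drug_b))
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2,
              dimnames = list(c(x$drug_a, x$drug_b), c("event", "no event")))
  print(m)
  invisible(x)
}

#' Reporting odds ratio with Woolf confidence interval and signal verdict
#'
#' The reporting odds ratio is `ROR = (a/b) / (c/d)`: the odds that an
#' index-drug report mentions the event category, relative to the same odds
#' for the comparator. The confidence interval is the Woolf (log-normal)
#' interval, `exp(log ROR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))` with
#' `z = qnorm(1 - alpha/2)`.
#'
#' The verdict applies the EMA disproportionality convention:
#' * `NotEvaluable` — fewer than 5 event cases for either drug
#'   (`min(a, c) < 5`), or any zero cell when no continuity correction is
#'   requested. Applying the minimum-case rule to both event cells means a
#'   verdict never hinges on a comparator too rare to assess: a drug with 2
#'   reported cases cannot be established as disproportionate *or* serve to
#'   establish another drug's signal;
#' * `Disproportionate` — evaluable and CI lower bound above 1;
#' * `NotDisproportionate` — otherwise.
#'
#' With `correction = "haldane"`, 0.5 is added to every cell of a table
#' containing a zero before estimation (Haldane–Anscombe), so only the
#' minimum-case rule can render a table not evaluable. The case count
#' `n_cases` is always the uncorrected `a`. Estimates are kept at full
#' precision; rendering rounds half-up to 2 decimals.
#'
#' @param table a `contingency_2x2`.
#' @param alpha two-sided significance level (default 0.05, i.e. 95% CI).
#' @param correction `"none"` (default) or `"haldane"`.
#' @return a list of class `signal_result`: `table`, `ror`, `ci_low`,
#'   `ci_high`, `n_cases`, `verdict`, `alpha`, `correction`. `ror` and the
#'   bounds are `NA` when a zero cell makes them undefined.
#' @examples
#' tab <- contingency_2x2(118, 786, 118, 441)
#' ror_estimate(tab)
#' @export
ror_estimate <- function(table, alpha = 0.05, correction = c("none", "haldane")) {
  stopifnot(inherits(table, "contingency_2x2"), alpha > 0, alpha < 1)
  correction <- match.arg(correction)
  cells <- c(table$a, table$b, table$c, table$d)
  any_zero <- any(cells == 0)
  n_cases <- table$a

  est <- cells
  if (any_zero && correction == "haldane") est <- est + 0.5
  if (all(est > 0)) {
    log_ror <- log(est[1]) - log(est[2]) - log(est[3]) + log(est[4])
    se <- sqrt(sum(1 / est))
    z <- stats::qnorm(1 - alpha / 2)
    ror <- exp(log_ror)
    ci_low <- exp(log_ror - z * se)
    ci_high <- exp(log_ror + z * se)
  } else {
    ror <- ci_low <- ci_high <- NA_real_
  }

  evaluable <- min(table$a, table$c) >= 5 && (correction == "haldane" || !any_zero)
  verdict <- if (!evaluable) {
    "NotEvaluable"
  } else if (ci_low > 1) {
    "Disproportionate"
  } else {
    "NotDisproportionate"
  }
  structure(list(table = table, ror = ror, ci_low = ci_low, ci_high = ci_high,
                 n_cases = n_cases, verdict = verdict, alpha = alpha,
                 correction = correction),
            class = "signal_result")
}

fmt2 <- function(x) {
  ifelse(is.na(x), "NA", formatC(round_half_up(x, 2), format = "f", digits = 2))
}

#' @export
print.signal_result <- function(x, ...) {
  cat(sprintf("%s: %s vs %s\n", x$table$category, x$table$drug_a, x$table$drug_b))
  cat(sprintf("  ROR %s, %d%% CI %s-%s (n = %d cases) -> %s\n",
              fmt2(x$ror), round(100 * (1 - x$alpha)), fmt2(x$ci_low),
              fmt2(x$ci_high), x$n_cases, x$verdict))
  invisible(x)
}

#' Pairwise disproportionality screen
#'
#' The package's central fitting function: computes a [ror_estimate()] for
#' every ordered (index, comparator) drug pair and every requested category,
#' from either an ICSR line listing (classified with `catalog`) or a
#' pre-aggregated `category_counts` table. Drug-vs-drug comparison (rather
#' than drug-vs-all-others) is the design used for within-group screens of
#' small drug classes.
#'
#' @param data an `icsr_set` or a `category_counts` table.
#' @param catalog [pt_catalog()] used when `data` is a line listing.
#' @param index,comparator drug name vectors; default: all drugs in `data`.
#'   Self-pairs are skipped.
#' @param categories category names to screen; default: all in the counts.
#' @param alpha two-sided significance level for the Woolf CI.
#' @param correction zero-cell handling, see [ror_estimate()].
#' @return an object of class `ror_screen` with `print()`, `summary()`
#'   (= [signal_summary()]), `coef()`, `confint()`, `as.data.frame()` and
#'   `plot()` methods. The long-format results have one row per (index,
#'   comparator, category) with cells, estimates and verdict.
#' @examples
#' counts <- count_by_category(simulate_dataset(reserve_fixture()))
#' screen <- ror_screen(counts, categories = "off_label")
#' summary(screen)
#' @export
ror_screen <- function(data, catalog = default_pt_catalog(), index = NULL,
                       comparator = NULL, categories = NULL, alpha = 0.05,
                       correction = c("none", "haldane")) {
  correction <- match.arg(correction)
  counts <- if (inherits(data, "category_counts")) data else {
    count_by_category(data, catalog)
  }
  if (is.null(index)) index <- counts$drug
  if (is.null(comparator)) comparator <- counts$drug
  missing_drugs <- setdiff(c(index, comparator), counts$drug)
  if (length(missing_drugs)) {
    stop("drug(s) not in the data: ", paste(missing_drugs, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(categories)) categories <- category_names(counts)

  rows <- list()
  for (cat_name in categories) {
    for (i in index) {
      for (j in comparator) {
        if (i == j) next
        est <- ror_estimate(build_table(counts[counts$drug == i, ],
                                        counts[counts$drug == j, ], cat_name),
                            alpha = alpha, correction = correction)
        rows[[length(rows) + 1L]] <- data.frame(
          index_drug = i, comparator_drug = j, category = cat_name,
          a = est$table$a, b = est$table$b, c = est$table$c, d = est$table$d,
          ror = est$ror, ci_low = est$ci_low, ci_high = est$ci_high,
          n_cases = est$n_cases, verdict = est$verdict,
          stringsAsFactors = FALSE)
      }
    }
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  structure(list(results = results, counts = counts, alpha = alpha,
                 correction = correction, call = match.call()),
            class = "ror_screen")
}

screen_labels <- function(r) {
  sprintf("%s vs %s [%s]", r$index_drug, r$comparator_drug, r$category)
}

#' @export
print.ror_screen <- function(x, ...) {
  r <- x$results
  cat(sprintf("ROR disproportionality screen: %d pair(s), %d categor%s, %d%% CI, correction = %s\n",
              nrow(unique(r[c("index_drug", "comparator_drug")])),
              length(unique(r$category)),
              if (length(unique(r$category)) == 1) "y" else "ies",
              round(100 * (1 - x$alpha)), x$correction))
  disp <- data.frame(category = r$category,
                     pair = paste(r$index_drug, "vs", r$comparator_drug),
                     `ROR [CI]` = sprintf("%s [%s-%s]", fmt2(r$ror),
                                          fmt2(r$ci_low), fmt2(r$ci_high)),
                     n = r$n_cases, verdict = r$verdict,
                     check.names = FALSE, stringsAsFactors = FALSE)
  print.data.frame(disp, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.ror_screen <- function(x, ...) x$results

#' @export
coef.ror_screen <- function(object, ...) {
  stats::setNames(object$results$ror, screen_labels(object$results))
}

#' @export
confint.ror_screen <- function(object, parm, level = 0.95, ...) {
  r <- object$results
  if (abs((1 - level) - object$alpha) > 1e-12) {
    # recompute bounds at the requested level from the stored cells
    refit <- ror_screen(object$counts, categories = unique(r$category),
                        index = unique(r$index_drug),
                        comparator = unique(r$comparator_drug),
                        alpha = 1 - level, correction = object$correction)
    r <- refit$results
  }
  out <- cbind(lwr = r$ci_low, upr = r$ci_high)
  rownames(out) <- screen_labels(r)
  if (!missing(parm)) out <- out[parm, , drop = FALSE]
  out
}

#' Summarize a disproportionality screen per index drug
#'
#' Counts, for each index drug and category, how many comparators were
#' flagged `Disproportionate`, `NotDisproportionate` or `NotEvaluable`, and
#' lists the disproportionate pairs ordered by decreasing ROR (the strongest
#' signals first).
#'
#' @param screen a [ror_screen()] result.
#' @return an object of class `summary.ror_screen`: list with `by_index`
#'   (verdict counts) and `signals` (disproportionate pairs, strongest
#'   first).
#' @export
signal_summary <- function(screen) {
  stopifnot(inherits(screen, "ror_screen"))
  r <- screen$results
  key <- interaction(r$index_drug, r$category, drop = FALSE)
  by_index <- do.call(rbind, lapply(split(r, key), function(g) {
    data.frame(index_drug = g$index_drug[1], category = g$category[1],
               disproportionate = sum(g$verdict == "Disproportionate"),
               not_disproportionate = sum(g$verdict == "NotDisproportionate"),
               not_evaluable = sum(g$verdict == "NotEvaluable"),
               stringsAsFactors = FALSE)
  }))
  rownames(by_index) <- NULL
  signals <- r[r$verdict == "Disproportionate", , drop = FALSE]
  signals <- signals[order(-signals$ror), , drop = FALSE]
  rownames(signals) <- NULL
  structure(list(by_index = by_index, signals = signals,
                 alpha = screen$alpha), class = "summary.ror_screen")
}

#' @export
summary.ror_screen <- function(object, ...) signal_summary(object)

#' @export
print.summary.ror_screen <- function(x, ...) {
  cat("Verdict counts per index drug:\n")
  print.data.frame(x$by_index, row.names = FALSE)
  if (nrow(x$signals)) {
    cat("\nDisproportionate signals (strongest first):\n")
    s <- x$signals
    print.data.frame(data.frame(category = s$category,
                                pair = paste(s$index_drug, "vs", s$comparator_drug),
                                `ROR [CI]` = sprintf("%s [%s-%s]", fmt2(s$ror),
                                                     fmt2(s$ci_low), fmt2(s$ci_high)),
                                n = s$n_cases, check.names = FALSE),
                     row.names = FALSE)
  } else {
    cat("\nNo disproportionate signal.\n")
  }
  invisible(x)
}

#' Forest plot of a disproportionality screen
#'
#' Draws the evaluable ROR point estimates and CIs of one category on a log
#' axis, one row per drug pair, with the null line at 1.
#'
#' @param x a `ror_screen`.
#' @param category category to plot (default: first in the results).
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.ror_screen <- function(x, category = NULL, ...) {
  r <- x$results
  if (is.null(category)) category <- r$category[1]
  r <- r[r$category == category & !is.na(r$ror), , drop = FALSE]
  if (!nrow(r)) stop("nothing to plot for category ", category, call. = FALSE)
  r <- r[order(r$ror), , drop = FALSE]
  y <- seq_len(nrow(r))
  xlim <- range(c(r$ci_low, r$ci_high, 1), na.rm = TRUE)
  op <- graphics::par(mar = c(4, 14, 3, 1))
  on.exit(graphics::par(op))
  graphics::plot(r$ror, y, log = "x", xlim = xlim, yaxt = "n",
                 xlab = "ROR (log scale)", ylab = "",
                 main = sprintf("Disproportionality: %s", category),
                 pch = 19, ...)
  graphics::segments(r$ci_low, y, r$ci_high, y)
  graphics::abline(v = 1, lty = 2, col = "grey40")
  graphics::axis(2, at = y, las = 1, cex.axis = 0.7,
                 labels = paste(r$index_drug, "vs", r$comparator_drug))
  invisible(x)
}
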