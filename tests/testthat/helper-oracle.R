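# Independent textbook computation of the sample odds ratio and its Woolf
# (log-normal) confidence interval, kept deliberately separate from the
# package's estimator: odds are formed by explicit division, the variance by
# summing reciprocal cells.
oracle_woolf <- function(a, b, c, d, alpha = 0.05) {
  odds_index <- a / b
  odds_comparator <- c / d
  or <- odds_index / odds_comparator
  se_log <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  z <- qnorm(1 - alpha / 2)
  list(or = or,
       lo = exp(log(or) - z * se_log),
       hi = exp(log(or) + z * se_log))
}

# Minimal one-reaction-per-row report builder for hand-made datasets.
make_reports <- function(report_id, pt, drug = "drugA",
                         outcome = "Unknown", soc = "",
                         age_group = "18-64 Years", sex = "Male",
                         origin = "EEA", reporter = "HP") {
  as_icsr(data.frame(report_id = report_id, drug = drug,
                     age_group = age_group, sex = sex, origin = origin,
                     reporter = reporter, pt = pt, soc = soc,
                     outcome = outcome, stringsAsFactors = FALSE))
}

# The reference-extract aggregates used across tests (drug order as in the
# fixture); resistance for ceftaroline / ceftolozane-tazobactam uses the
# default 24/24 split of the 48 unpublished cases.
fixture_counts_expected <- function() {
  category_counts(
    drug = c("ceftazidime/avibactam", "ceftaroline", "ceftolozane/tazobactam",
             "cefiderocol", "ceftobiprole"),
    n_total = c(904, 559, 560, 176, 146),
    resistance = c(93, 24, 24, 52, 0),
    ineffectiveness = c(85, 63, 60, 25, 2),
    off_label = c(118, 118, 154, 16, 30)
  )
}
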