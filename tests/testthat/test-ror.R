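test_that("build_table lays out the 2x2 from report-level counts", {
  counts <- fixture_counts_expected()
  tab <- build_table(counts[counts$drug == "ceftazidime/avibactam", ],
                     counts[counts$drug == "ceftaroline", ], "off_label")
  expect_equal(c(tab$a, tab$b, tab$c, tab$d), c(118, 786, 118, 441))
  expect_error(build_table(counts[1, ], counts[2, ], "nonsense"), "nonsense")
})

test_that("estimates agree with an independently computed reference", {
  # frozen from statsmodels.stats.Table2x2 (oddsratio, oddsratio_confint)
  ref <- list(
    list(cells = c(118, 786, 118, 441),
         or = 0.561068702290, lo = 0.423813961037, hi = 0.742774230277),
    list(cells = c(118, 786, 154, 406),
         or = 0.395789960675, lo = 0.302729070447, hi = 0.517458375373),
    list(cells = c(118, 786, 30, 116),
         or = 0.580491942324, lo = 0.371750436597, hi = 0.906443844930),
    list(cells = c(7, 13, 5, 29),
         or = 3.123076923077, lo = 0.833452903269, hi = 11.702652218496),
    list(cells = c(52, 124, 93, 811),
         or = 3.656954561221, lo = 2.479797325200, hi = 5.392907124680)
  )
  for (r in ref) {
    est <- ror_estimate(do.call(contingency_2x2, as.list(r$cells)))
    expect_equal(est$ror, r$or, tolerance = 1e-10)
    expect_equal(est$ci_low, r$lo, tolerance = 1e-10)
    expect_equal(est$ci_high, r$hi, tolerance = 1e-10)
  }
})

test_that("estimator matches the textbook oracle on 1000 random small tables", {
  set.seed(42)
  for (i in 1:1000) {
    cells <- sample(1:50, 4, replace = TRUE)
    est <- ror_estimate(contingency_2x2(cells[1], cells[2], cells[3], cells[4]))
    orc <- oracle_woolf(cells[1], cells[2], cells[3], cells[4])
    expect_equal(est$ror, orc$or, tolerance = 1e-12)
    expect_equal(est$ci_low, orc$lo, tolerance = 1e-12)
    expect_equal(est$ci_high, orc$hi, tolerance = 1e-12)
    expect_true(est$ci_low <= est$ror && est$ror <= est$ci_high)
  }
})

test_that("swapping index and comparator inverts the estimate and its CI", {
  set.seed(7)
  for (i in 1:200) {
    cells <- sample(1:60, 4, replace = TRUE)
    ab <- ror_estimate(contingency_2x2(cells[1], cells[2], cells[3], cells[4]))
    ba <- ror_estimate(contingency_2x2(cells[3], cells[4], cells[1], cells[2]))
    expect_equal(ab$ror * ba$ror, 1, tolerance = 1e-12)
    expect_equal(ab$ci_low, 1 / ba$ci_high, tolerance = 1e-12)
    expect_equal(ab$ci_high, 1 / ba$ci_low, tolerance = 1e-12)
  }
})

test_that("ROR is strictly increasing in cell a", {
  rors <- vapply(5:30, function(a)
    ror_estimate(contingency_2x2(a, 100, 20, 80))$ror, numeric(1))
  expect_true(all(diff(rors) > 0))
})

test_that("identical drugs give ROR 1", {
  counts <- fixture_counts_expected()
  tab <- build_table(counts[1, ], counts[1, ], "off_label")
  expect_equal(ror_estimate(tab)$ror, 1)
})

test_that("the signal rule: <5 cases or zero cells are never evaluable", {
  # fewer than 5 cases, huge effect: still NotEvaluable
  e1 <- ror_estimate(contingency_2x2(4, 10, 1, 1000))
  expect_equal(e1$verdict, "NotEvaluable")
  expect_equal(e1$n_cases, 4)
  # zero cell without correction: undefined estimate, NotEvaluable
  e2 <- ror_estimate(contingency_2x2(12, 0, 7, 50))
  expect_equal(e2$verdict, "NotEvaluable")
  expect_true(is.na(e2$ror))
  # same table with Haldane correction becomes evaluable
  e3 <- ror_estimate(contingency_2x2(12, 0, 7, 50), correction = "haldane")
  expect_false(is.na(e3$ror))
  expect_equal(e3$ror, (12.5 / 0.5) / (7.5 / 50.5))
  expect_true(e3$verdict %in% c("Disproportionate", "NotDisproportionate"))
  # haldane corrects zero cells but never rescues the minimum-case rule,
  # which applies to both event cells
  e4 <- ror_estimate(contingency_2x2(3, 100, 7, 50), correction = "haldane")
  expect_equal(e4$verdict, "NotEvaluable")
  e4b <- ror_estimate(contingency_2x2(12, 100, 0, 50), correction = "haldane")
  expect_equal(e4b$verdict, "NotEvaluable")
  expect_false(is.na(e4b$ror))
  # disproportionate requires ci_low > 1
  e5 <- ror_estimate(contingency_2x2(52, 124, 93, 811))
  expect_equal(e5$verdict, "Disproportionate")
})

test_that("no random table with fewer than 5 cases is ever flagged", {
  set.seed(11)
  for (i in 1:200) {
    a <- sample(0:4, 1)
    cells <- c(a, sample(0:40, 3, replace = TRUE))
    for (corr in c("none", "haldane")) {
      est <- ror_estimate(contingency_2x2(cells[1], cells[2], cells[3], cells[4]),
                          correction = corr)
      expect_equal(est$verdict, "NotEvaluable")
    }
  }
})

test_that("a pairwise screen enumerates ordered pairs and is reciprocal", {
  counts <- fixture_counts_expected()
  screen <- ror_screen(counts, categories = "off_label")
  r <- as.data.frame(screen)
  expect_equal(nrow(r), 20L)  # 5 x 4 ordered pairs
  for (i in seq_len(nrow(r))) {
    back <- r[r$index_drug == r$comparator_drug[i] &
                r$comparator_drug == r$index_drug[i], ]
    if (!is.na(r$ror[i]) && !is.na(back$ror)) {
      expect_equal(r$ror[i] * back$ror, 1, tolerance = 1e-12)
    }
  }
})

test_that("screens built from the line listing equal screens from its counts", {
  x <- simulate_dataset(reserve_fixture(seed = 2))
  s1 <- ror_screen(x)
  s2 <- ror_screen(count_by_category(x))
  expect_equal(as.data.frame(s1), as.data.frame(s2))
})

test_that("signal summary tallies verdicts and ranks signals by ROR", {
  counts <- fixture_counts_expected()
  screen <- ror_screen(counts)
  s <- signal_summary(screen)
  expect_equal(sum(s$by_index$disproportionate) +
                 sum(s$by_index$not_disproportionate) +
                 sum(s$by_index$not_evaluable),
               nrow(as.data.frame(screen)))
  if (nrow(s$signals) > 1) {
    expect_true(all(diff(s$signals$ror) <= 0))
  }
  # all-NotEvaluable matrix gives zero counts everywhere
  tiny <- category_counts(c("a", "b"), c(10, 10), ev = c(0, 0))
  s0 <- signal_summary(ror_screen(tiny))
  expect_true(all(s0$by_index$disproportionate == 0))
  expect_true(all(s0$by_index$not_evaluable == 1))
  expect_equal(nrow(s0$signals), 0L)
})

test_that("confint and coef expose the estimates at the fitted level", {
  counts <- fixture_counts_expected()
  screen <- ror_screen(counts, index = "ceftazidime/avibactam",
                       categories = "off_label")
  expect_equal(unname(coef(screen)), as.data.frame(screen)$ror)
  ci <- confint(screen)
  expect_equal(unname(ci[, "lwr"]), as.data.frame(screen)$ci_low)
  ci90 <- confint(screen, level = 0.90)
  expect_true(all(ci90[, "lwr"] >= ci[, "lwr"], na.rm = TRUE))
})
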