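test_that("the same seed gives a byte-identical line listing; a different seed does not", {
  cfg <- reserve_fixture(seed = 5)
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_line_listing(simulate_dataset(cfg), p1)
  write_line_listing(simulate_dataset(cfg), p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  other <- simulate_dataset(cfg, seed = 6)
  expect_false(identical(as.data.frame(simulate_dataset(cfg)), as.data.frame(other)))
})

test_that("allocated counts are exact for every seed", {
  cfg <- sim_config(list(
    drugA = drug_sim(50, categories = c(resistance = 9, ineffectiveness = 4,
                                        off_label = 12)),
    drugB = drug_sim(30, categories = c(resistance = 0, off_label = 30))
  ), seed = 1)
  for (seed in 1:6) {
    counts <- count_by_category(simulate_dataset(cfg, seed = seed))
    expect_equal(counts$n_total, c(50L, 30L))
    expect_equal(counts$resistance, c(9L, 0L))
    expect_equal(counts$ineffectiveness, c(4L, 0L))
    expect_equal(counts$off_label, c(12L, 30L))
  }
})

test_that("overlap blocks assign joint categories and adjust marginals", {
  cfg <- sim_config(list(
    drugA = drug_sim(20, categories = c(resistance = 6, off_label = 5),
                     overlap = list(list(categories = c("resistance", "off_label"),
                                         n = 3)))
  ), seed = 2)
  x <- simulate_dataset(cfg)
  counts <- count_by_category(x)
  expect_equal(counts$resistance, 6L)
  expect_equal(counts$off_label, 5L)
  # 3 reports carry both categories
  both <- sum(vapply(split(x$pt, x$report_id), function(p)
    all(c("resistance", "off_label") %in% classify_report(p, default_pt_catalog())),
    logical(1)))
  expect_equal(both, 3L)
})

test_that("infeasible configurations are rejected up front", {
  expect_error(sim_config(list(d = drug_sim(5, categories = c(resistance = 6)))),
               "outside")
  expect_error(sim_config(list(d = drug_sim(10, categories = c(resistance = 6,
                                                               off_label = 6)))),
               "n_total")
  expect_error(sim_config(list(d = drug_sim(10, categories = c(nonsense = 1)))),
               "unknown category")
  expect_error(sim_config(list(d = drug_sim(10,
    categories = c(resistance = 4),
    outcomes = list(resistance = c(Fatal = 5))))), "at most")
  expect_error(sim_config(list(d = drug_sim(10,
    demographics = list(sex = c(Male = 0.6, Female = 0.3))))), "sum")
})

test_that("sampled demographic marginals converge to their probabilities", {
  n <- 10000
  probs <- c(Female = 0.35, Male = 0.6, NS = 0.05)
  cfg <- sim_config(list(d = drug_sim(n, demographics = list(sex = probs))),
                    seed = 31)
  x <- simulate_dataset(cfg)
  rep_sex <- unique(as.data.frame(x)[c("report_id", "sex")])$sex
  for (lvl in names(probs)) {
    p <- probs[[lvl]]
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(mean(rep_sex == lvl) - p), 3 * se)
  }
})

test_that("the reference fixture reproduces every published aggregate", {
  x <- simulate_dataset(reserve_fixture(seed = 3))
  expect_equal(n_reports(x), 2345L)
  counts <- count_by_category(x)
  expect_identical(as.data.frame(counts), as.data.frame(fixture_counts_expected()))
  # no resistance reports at all for ceftobiprole
  cfb <- x[x$drug == "ceftobiprole", ]
  expect_length(intersect(classify_report(cfb$pt, default_pt_catalog()),
                          "resistance"), 0)
})

test_that("the fixture's share arithmetic matches the printed percentages", {
  counts <- count_by_category(simulate_dataset(reserve_fixture(seed = 4)))
  shares <- report_distribution(counts)
  expect_equal(shares$pct[shares$drug == "ceftazidime/avibactam"], 38.6)
  expect_equal(shares$pct[shares$drug == "cefiderocol"], 7.5)
  expect_equal(shares$pct[shares$drug == "ceftobiprole"], 6.2)
  rates <- category_rates(counts)
  pick <- function(d, cat) rates$pct[rates$drug == d & rates$category == cat]
  expect_equal(pick("cefiderocol", "resistance"), 29.5)
  expect_equal(pick("cefiderocol", "ineffectiveness"), 14.2)
  expect_equal(pick("ceftolozane/tazobactam", "off_label"), 27.5)
  expect_equal(pick("ceftobiprole", "off_label"), 20.5)
  expect_equal(pick("ceftaroline", "off_label"), 21.1)
  expect_equal(pick("ceftazidime/avibactam", "resistance"), 10.3)
  dist <- category_distribution(counts)
  pickd <- function(d, cat) dist$pct[dist$drug == d & dist$category == cat]
  expect_equal(pickd("ceftazidime/avibactam", "resistance"), 48.2)
  expect_equal(pickd("cefiderocol", "resistance"), 26.9)
  expect_equal(pickd("ceftazidime/avibactam", "ineffectiveness"), 36.2)
  expect_equal(pickd("ceftolozane/tazobactam", "off_label"), 35.3)
})

test_that("the unpublished resistance split is configurable but constrained", {
  cfg <- reserve_fixture(seed = 1, resistance_split = c(30, 18))
  counts <- count_by_category(simulate_dataset(cfg))
  expect_equal(counts$resistance[counts$drug == "ceftaroline"], 30L)
  expect_equal(counts$resistance[counts$drug == "ceftolozane/tazobactam"], 18L)
  expect_error(reserve_fixture(resistance_split = c(10, 10)), "48")
})

test_that("a sim config round-trips through YAML, including the packaged preset", {
  path <- withr::local_tempfile(fileext = ".yaml")
  cfg <- sim_config(list(
    drugA = drug_sim(25, categories = c(resistance = 4, off_label = 3),
                     demographics = list(sex = c(Female = 10, Male = 15)),
                     outcomes = list(resistance = c(Fatal = 2)),
                     overlap = list(list(categories = c("resistance", "off_label"),
                                         n = 2)))
  ), seed = 17)
  write_sim_config(cfg, path)
  back <- read_sim_config(path)
  expect_identical(as.data.frame(simulate_dataset(back)),
                   as.data.frame(simulate_dataset(cfg)))

  shipped <- system.file("extdata", "reserve_cephalosporins.yaml",
                         package = "rorscreen")
  expect_identical(as.data.frame(simulate_dataset(read_sim_config(shipped))),
                   as.data.frame(simulate_dataset(reserve_fixture(seed = 1))))
})
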