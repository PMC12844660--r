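#' Reference simulation preset: Reserve-group cephalosporins in EudraVigilance
#'
#' Returns a [sim_config()] whose exact-count marginals emulate an aggregated
#' EudraVigilance extract for the five WHO AWaRe Reserve-group cephalosporins
#' (ceftazidime/avibactam, ceftaroline, ceftolozane/tazobactam, cefiderocol,
#' ceftobiprole): per-drug report totals (904 / 559 / 560 / 176 / 146, 2345
#' in all), report counts for the resistance, ineffectiveness and off-label
#' categories, full demographic marginals (age stratum, sex, origin,
#' reporter), unfavourable-outcome counts per category (15 fatal resistance
#' cases, 50 fatal ineffectiveness cases, 5 fatal off-label cases, plus the
#' not-recovered and recovered-with-sequelae cases), and the per-drug System
#' Organ Class report shares known for this extract.
#'
#' Two quantities are not available as published counts and are encoded as
#' derived values: cefiderocol ineffectiveness (25 = round(0.142 x 176)) and
#' ceftobiprole off-label use (30 = round(0.205 x 146)), each cross-checked
#' against the category distribution shares and the off-label ROR/CI they
#' imply. The split of the 48 resistance cases between ceftaroline and
#' ceftolozane/tazobactam is likewise unpublished; it is exposed as
#' `resistance_split` (default an even 24/24) and no headline quantity
#' depends on it.
#'
#' @param seed integer seed stored in the config.
#' @param resistance_split length-2 integer vector summing to 48: resistance
#'   report counts for ceftaroline and ceftolozane/tazobactam, in that order.
#' @return a `sim_config` for [simulate_dataset()].
#' @examples
#' reports <- simulate_dataset(reserve_fixture(seed = 42))
#' count_by_category(reports)
#' @export
reserve_fixture <- function(seed = 1L, resistance_split = c(24L, 24L)) {
  resistance_split <- as.integer(resistance_split)
  if (length(resistance_split) != 2L || any(resistance_split < 0L) ||
      sum(resistance_split) != 48L) {
    stop("resistance_split must be two non-negative integers summing to 48",
         call. = FALSE)
  }
  # resistance outcome allocation needs >= 3 ceftaroline and >= 5
  # ceftolozane/tazobactam resistance reports
  drugs <- list(
    "ceftazidime/avibactam" = drug_sim(
      n_total = 904,
      categories = c(resistance = 93, ineffectiveness = 85, off_label = 118),
      demographics = list(
        age_group = c("NS" = 155, "0-1 Month" = 2, "2 Months-2 Years" = 15,
                      "3-11 Years" = 13, "12-17 Years" = 15, "18-64 Years" = 348,
                      "65-85 Years" = 279, ">85 Years" = 77),
        sex = c(Female = 295, Male = 539, NS = 70),
        origin = c(EEA = 399, "Non-EEA" = 505, NS = 0),
        reporter = c(HP = 793, "Non-HP" = 111, NS = 0)
      ),
      outcomes = list(
        resistance = c(Fatal = 9, NotRecovered = 1),
        ineffectiveness = c(Fatal = 21, NotRecovered = 5, RecoveredWithSequelae = 1),
        off_label = c(Fatal = 4, NotRecovered = 1)
      ),
      soc_counts = c("Hepatobiliary disorders" = 73)
    ),
    "ceftaroline" = drug_sim(
      n_total = 559,
      categories = c(resistance = resistance_split[1], ineffectiveness = 63,
                     off_label = 118),
      demographics = list(
        age_group = c("NS" = 107, "0-1 Month" = 1, "2 Months-2 Years" = 4,
                      "3-11 Years" = 5, "12-17 Years" = 18, "18-64 Years" = 233,
                      "65-85 Years" = 163, ">85 Years" = 28),
        sex = c(Female = 215, Male = 308, NS = 36),
        origin = c(EEA = 213, "Non-EEA" = 346, NS = 0),
        reporter = c(HP = 548, "Non-HP" = 11, NS = 0)
      ),
      outcomes = list(
        resistance = c(Fatal = 2, NotRecovered = 1),
        ineffectiveness = c(Fatal = 14, NotRecovered = 1),
        off_label = c(Fatal = 1, NotRecovered = 3)
      ),
      soc_counts = c("Blood and lymphatic system disorders" = 214,
                     "Hepatobiliary disorders" = 14,
                     "Nervous system disorders" = 40,
                     "Renal and urinary disorders" = 43,
                     "Skin and subcutaneous tissue disorders" = 108)
    ),
    "ceftolozane/tazobactam" = drug_sim(
      n_total = 560,
      categories = c(resistance = resistance_split[2], ineffectiveness = 60,
                     off_label = 154),
      demographics = list(
        age_group = c("NS" = 169, "0-1 Month" = 0, "2 Months-2 Years" = 3,
                      "3-11 Years" = 6, "12-17 Years" = 10, "18-64 Years" = 183,
                      "65-85 Years" = 164, ">85 Years" = 25),
        sex = c(Female = 194, Male = 308, NS = 58),
        origin = c(EEA = 312, "Non-EEA" = 248, NS = 0),
        reporter = c(HP = 552, "Non-HP" = 8, NS = 0)
      ),
      outcomes = list(
        resistance = c(Fatal = 3, NotRecovered = 2),
        ineffectiveness = c(Fatal = 7)
      ),
      soc_counts = c("Hepatobiliary disorders" = 21,
                     "Nervous system disorders" = 48)
    ),
    "cefiderocol" = drug_sim(
      n_total = 176,
      categories = c(resistance = 52, ineffectiveness = 25, off_label = 16),
      demographics = list(
        age_group = c("NS" = 21, "0-1 Month" = 0, "2 Months-2 Years" = 0,
                      "3-11 Years" = 1, "12-17 Years" = 6, "18-64 Years" = 86,
                      "65-85 Years" = 58, ">85 Years" = 4),
        sex = c(Female = 71, Male = 101, NS = 4),
        origin = c(EEA = 143, "Non-EEA" = 33, NS = 0),
        reporter = c(HP = 175, "Non-HP" = 1, NS = 0)
      ),
      outcomes = list(
        resistance = c(Fatal = 1, NotRecovered = 2),
        ineffectiveness = c(Fatal = 7, NotRecovered = 2)
      ),
      soc_counts = c("Hepatobiliary disorders" = 18)
    ),
    "ceftobiprole" = drug_sim(
      n_total = 146,
      categories = c(resistance = 0, ineffectiveness = 2, off_label = 30),
      demographics = list(
        age_group = c("NS" = 13, "0-1 Month" = 0, "2 Months-2 Years" = 0,
                      "3-11 Years" = 0, "12-17 Years" = 0, "18-64 Years" = 48,
                      "65-85 Years" = 71, ">85 Years" = 14),
        sex = c(Female = 62, Male = 79, NS = 5),
        origin = c(EEA = 118, "Non-EEA" = 28, NS = 0),
        reporter = c(HP = 146, "Non-HP" = 0, NS = 0)
      ),
      outcomes = list(
        ineffectiveness = c(Fatal = 1),
        off_label = c(NotRecovered = 2)
      ),
      soc_counts = c("Hepatobiliary disorders" = 5,
                     "Nervous system disorders" = 54,
                     "Renal and urinary disorders" = 7,
                     "Skin and subcutaneous tissue disorders" = 38,
                     "Infections and infestations" = 8)
    )
  )
  sim_config(drugs, seed = seed)
}

#' Drug groups of the reference extract
#'
#' Convenience name vectors: the five Reserve-group cephalosporins of the
#' reference extract, and the fourteen Watch-group cephalosporins used as the
#' between-group comparator set.
#'
#' @return character vector of drug names.
#' @export
reserve_drugs <- function() {
  c("ceftazidime/avibactam", "ceftaroline", "ceftolozane/tazobactam",
    "cefiderocol", "ceftobiprole")
}

#' @rdname reserve_drugs
#' @export
watch_drugs <- function() {
  c("cefepime", "cefpirome", "cefcapene pivoxil", "cefdinir",
    "cefditoren pivoxil", "cefixime", "cefodizime", "cefoperazone",
    "cefotaxime", "cefpodoxime proxetil", "ceftazidime", "ceftibuten",
    "ceftizoxime", "ceftriaxone")
}
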