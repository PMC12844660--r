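---
title: "Methods: ROR disproportionality screening of ICSR line listings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ROR disproportionality screening of ICSR line listings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rorscreen)
```

## The problem

Spontaneous-report pharmacovigilance databases (EudraVigilance, FAERS)
accumulate Individual Case Safety Reports: one case per report, a suspected
drug, and one or more reactions coded as MedDRA Preferred Terms. For
last-resort antibiotics — here the five WHO AWaRe *Reserve*-group
cephalosporins — three classes of coded events are of stewardship interest:
antimicrobial **resistance**, drug **ineffectiveness**, and **off-label
use**. `rorscreen` implements the standard screen for such questions: count
how often each drug's reports mention a category, and compare drugs pairwise
with the reporting odds ratio (ROR).

## Classification model

A report belongs to a category if at least one of its reaction PTs is in the
category's PT list. Matching is exact after case-folding and whitespace
collapse. MedDRA PTs are a controlled vocabulary, so substring or fuzzy
matching would manufacture cases; a misspelled PT is treated as absent, not
guessed. Counting is at **report (case) level**: a report listing three
resistance PTs contributes one resistance case. This is the counting unit
under which per-drug totals and per-category counts combine coherently into
2×2 tables, and it is what makes published per-drug totals and category
counts arithmetically consistent with published RORs.

The default catalog (`default_pt_catalog()`) has three categories sized 3
(resistance), 11 (ineffectiveness) and 8 (off-label use). Regulatory
screens define their exact lists against a licensed MedDRA version, which a
package cannot ship; the defaults are standard current terms, and any
study's list drops in via `pt_catalog()` or a YAML/JSON file
(`read_pt_catalog()`). A PT may appear in at most one category — overlap
between lists would silently double-count cases.

## The estimator

For index drug *i* and comparator *j*, with *a* = reports of *i* in the
category, *b* = its remaining reports, and *c*, *d* likewise for *j*:

$$\mathrm{ROR} = \frac{a/b}{c/d}, \qquad
\mathrm{CI}_{1-\alpha} = \exp\!\left(\ln \mathrm{ROR} \pm z_{1-\alpha/2}
\sqrt{\tfrac1a + \tfrac1b + \tfrac1c + \tfrac1d}\right)$$

The interval is the Woolf (log-normal) interval; `alpha` defaults to 0.05,
so $z = 1.959964$. Exact (conditional) intervals are deliberately out of
scope: the Woolf interval is the method whose bounds agree with the
reference results this package reproduces, and the published analyses in
this area do not state a CI method — log-normal agreement is the evidence.
Estimates are kept in full precision; only rendering rounds, half-up, to 2
decimals (percentages to 1 decimal), matching regulatory table conventions.
R's own `round()` rounds half to even, which would print 0.375 as 0.37 where
such tables print 0.38; `round_half_up()` is exported for this reason.

### Signal rule

A pair's verdict follows the EMA disproportionality convention: flag
**Disproportionate** only if the pair is evaluable and the CI lower bound
exceeds 1. A pair is **NotEvaluable** when either drug has fewer than 5
event cases, or when the table contains a zero cell (without correction).
Two points deserve emphasis:

* The 5-case minimum is applied to *both* event cells, `min(a, c) >= 5`. A
  drug with 2 reported cases can neither be established as disproportionate
  itself nor serve as the comparator establishing another drug's signal —
  the information in a 2-case column is the same whichever margin it sits
  in. Applying the rule to the index cell only would let a rare comparator
  manufacture strong "signals" for every common drug, which is exactly the
  artefact the minimum-case rule exists to prevent.
* Zero cells make the estimate undefined; the default verdict is
  NotEvaluable with `NA` estimates. `correction = "haldane"` adds 0.5 to
  every cell of a zero-containing table (Haldane–Anscombe) before
  estimation, which defines the estimate but never overrides the
  minimum-case rule.

No multiplicity adjustment is applied across the pairwise matrix. This
mirrors practice in signal *detection* (signals are hypotheses to
investigate, not confirmed associations) and is a documented limitation: at
$\alpha = 0.05$, a 20-pair screen under the null is expected to flag one
pair by chance.

### Degenerate inputs

Self-pairs are skipped in `ror_screen()`; a table of a drug against itself
gives ROR 1 exactly. Categories absent from a drug give `a = 0` (handled by
the zero-cell rule). An empty category across all drugs yields `NA` shares
in `category_distribution()` rather than an error, since a screen over many
catalogs should not abort on an unused category.

## The synthetic generator

`simulate_dataset()` exists because aggregated EudraVigilance extracts are
viewable but not redistributable: analyses must be reproducible from code
alone. The generator **allocates** counts exactly instead of sampling them —
category flags, exact-count demographics, per-category outcome counts and
pinned SOC counts are laid out deterministically over report slots and then
shuffled with the seeded RNG. Recomputing any configured aggregate from the
simulated line listing returns the configured value for *every* seed; the
seed controls only arrangement, the PT drawn within a category, and
marginals given as probabilities. Bernoulli sampling would reproduce
published counts only in expectation, and the downstream ROR display values
would wobble at the printed precision.

Design choices where the published record is silent:

* **Category overlap.** Nothing quantifies how often one report carries two
  categories, so the default assigns categories to disjoint report subsets;
  joint blocks are configurable (`overlap`).
* **Within-category PT choice** is uniform over the category's list —
  report-level counting makes the choice immaterial to every statistic the
  package computes.
* **Outcomes.** Reactions get the allocated outcome; everything unallocated
  is `Unknown`. Case outcome is the worst reaction outcome under
  Fatal > NotRecovered > RecoveredWithSequelae > Recovering > Recovered >
  Unknown (configurable). "Recovered with sequelae" is shown as its own
  unfavourable subcategory by default and can be excluded from the
  unfavourable set.
* **SOC shares.** Pinned per-SOC report counts attach one extra reaction to
  that many distinct reports; filler reactions for uncategorized reports
  avoid pinned SOCs so the pinned counts stay exact.

### The reference preset

`reserve_fixture()` encodes the aggregated extract for the five
Reserve-group cephalosporins: per-drug totals 904 / 559 / 560 / 176 / 146
(2345 reports), the per-category case counts, full demographic marginals,
unfavourable-outcome counts and known SOC shares. Three quantities are not
published as counts and are handled explicitly:

* cefiderocol ineffectiveness = 25, recovered from its published rate
  (14.2% of 176) and cross-checked against the category's distribution
  shares (85/235 = 36.2%);
* ceftobiprole off-label = 30, recovered from 20.5% of 146 and
  cross-checked by the off-label ROR/CI it implies (0.58, 0.37–0.91 — no
  neighbouring integer reproduces that interval);
* the split of the remaining 48 resistance cases between ceftaroline and
  ceftolozane/tazobactam is unpublished; it is a fixture parameter
  (`resistance_split`, default an even 24/24) and no headline quantity
  depends on it.

One published attribution is internally inconsistent: the fatal
ineffectiveness breakdown assigns 7 fatal cases to a drug recorded with only
2 ineffectiveness cases in total. The fixture keeps the published total of
50 fatal ineffectiveness cases and reassigns within the feasible bounds
(ceftolozane/tazobactam 7, cefiderocol 7, ceftobiprole 1).

### What passing tests do and do not show

The generator reproduces *marginals*: totals, category counts, demographics,
outcome and SOC counts. It does not model reporting delays, duplicate
reports, missing-data mechanisms, drug–drug interaction structure, or
correlation between demographics and categories (characteristics are
allocated independently of category flags). Tests passing on this fixture
show the pipeline's arithmetic is faithful to the configured study
conditions — not that real EudraVigilance extracts are free of the biases
(underreporting, no exposure denominator, reporting stimulation) inherent to
spontaneous data.

## Verification

The estimator is checked three ways: against reference values computed
independently with `statsmodels` (frozen into the tests at $10^{-10}$);
against a textbook oracle written separately in the test helper, over 1,000
random small tables at $10^{-12}$ relative tolerance; and by properties —
reciprocity (ROR(A,B)·ROR(B,A) = 1 with swap-and-invert CIs), strict
monotonicity in cell *a*, and CI coverage. Coverage uses a null simulation
with true odds ratio 1 (two binomial arms of 200 reports, event probability
0.3, 10⁴ replicates, fixed seed) and requires the 95% interval to cover 1
in 95% ± 1% of replicates — a problem size that keeps the whole suite under
a minute on one CPU while leaving the binomial standard error of the
coverage estimate (~0.2 points) well inside the band.

## Limitations

* Each ICSR carries exactly one suspected drug; multi-drug reports are out
  of scope of the counting model.
* Drug-vs-drug comparison only; drug-vs-all-others and shrinkage estimators
  (PRR, EBGM, IC) are not implemented.
* The ROR quantifies reporting behaviour. Without an exposure denominator
  it is not a risk ratio, and no causal reading is valid.
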