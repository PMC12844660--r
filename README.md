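# rorscreen

Disproportionality screening of spontaneous adverse-event reports, built for
pharmacovigilance questions like: *among the WHO AWaRe Reserve-group
cephalosporins, which drugs attract disproportionately many reports of
antimicrobial resistance, therapeutic ineffectiveness, or off-label use?*

Spontaneous-report databases such as EudraVigilance collect Individual Case
Safety Reports (ICSRs): one report per patient case, each listing a suspected
drug and one or more reactions coded as MedDRA Preferred Terms (PTs).
`rorscreen` takes such line listings (or pre-aggregated count tables) and

* classifies reports into named event categories via configurable PT
  catalogs (exact, case-insensitive PT matching — no fuzzy matching);
* produces the standard descriptive surfaces: demographics tables, System
  Organ Class frequencies, category rates and distributions, and
  unfavourable-outcome breakdowns (report-level worst outcome);
* screens drug pairs for disproportionate reporting with the reporting odds
  ratio and the EMA signal rule;
* simulates seeded synthetic ICSR datasets with *exact* count allocation,
  including a built-in preset emulating an aggregated EudraVigilance extract
  for the five Reserve-group cephalosporins, so the whole pipeline is
  testable offline.

## The statistic

For an index drug and a comparator, count reports at case level:

|            | event category | no event |
|------------|---------------|----------|
| index drug | a             | b        |
| comparator | c             | d        |

The reporting odds ratio is

```
ROR = (a/b) / (c/d)
```

with the Woolf (log-normal) confidence interval

```
exp( ln ROR ± z_{1-α/2} · sqrt(1/a + 1/b + 1/c + 1/d) )
```

A pair is flagged **Disproportionate** under the EMA convention when it is
evaluable (at least 5 event cases for each drug, no empty cell unless the
Haldane–Anscombe +0.5 correction is requested) and the CI lower bound
exceeds 1. The ROR is a reporting signal, not a risk estimate: it has no
exposure denominator and cannot support causal claims.

## Worked example

```r
library(rorscreen)

reports <- simulate_dataset(reserve_fixture(seed = 42))  # 2345 ICSRs
counts  <- count_by_category(reports)
counts
#>                     drug n_total resistance ineffectiveness off_label
#> 1  ceftazidime/avibactam     904         93              85       118
#> 2            ceftaroline     559         24              63       118
#> 3 ceftolozane/tazobactam     560         24              60       154
#> 4            cefiderocol     176         52              25        16
#> 5           ceftobiprole     146          0               2        30

ror_screen(counts, index = "ceftazidime/avibactam", categories = "off_label")
#>   category                                            pair         ROR [CI]   n             verdict
#>  off_label            ceftazidime/avibactam vs ceftaroline 0.56 [0.42-0.74] 118 NotDisproportionate
#>  off_label ceftazidime/avibactam vs ceftolozane/tazobactam 0.40 [0.30-0.52] 118 NotDisproportionate
#>  off_label            ceftazidime/avibactam vs cefiderocol 1.50 [0.87-2.60] 118 NotDisproportionate
#>  off_label           ceftazidime/avibactam vs ceftobiprole 0.58 [0.37-0.91] 118 NotDisproportionate
```

Ceftazidime/avibactam's off-label reporting odds are significantly *below*
those of ceftaroline (ROR 0.56), ceftolozane/tazobactam (0.40) and
ceftobiprole (0.58): all three CIs sit entirely below 1, so off-label use is
reported relatively less often for ceftazidime/avibactam, and no pair is a
positive disproportionality signal. Screening ineffectiveness across all
five drugs, `summary(ror_screen(counts, categories = "ineffectiveness"))`
reports zero disproportionate pairs — ceftobiprole's rows are
`NotEvaluable`, because its 2 ineffectiveness cases fall below the 5-case
minimum.

The fitted `ror_screen` object supports `print()`, `summary()`, `coef()`,
`confint()`, `as.data.frame()` (long-format results) and `plot()` (a forest
plot). `run_pipeline(run_config(fixture = TRUE, out_dir = "out"))` writes
the full CSV report bundle plus a JSON manifest; `inst/cli/rorscreen.R` is a
thin command-line front end with `simulate`, `describe`, `disprop` and
`report` subcommands.

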