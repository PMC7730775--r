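# coinca — Coincidence Analysis for configurational causal inference

`coinca` implements coincidence analysis (CNA), a configurational comparative
method for researchers — implementation scientists, health-services and policy
analysts, social scientists — who ask *which combinations of discrete
conditions are minimally necessary or sufficient for an outcome* across a set
of cases, rather than what the average effect of a variable is. It is built
for small-to-moderate *n* cross-case data (counties, clinics, organisations)
with crisp binary or multi-value factors, and it deliberately surfaces model
ambiguity instead of resolving it silently.

## The method

Cases are rows of a configuration table; factors take small integer levels
(`MC=1`, `SCHOOLS=2`). A **condition** is a disjunctive normal form over
factor-value literals, written `SCHOOLS=2 + SCHOOLS=1*MC=1` (`*` = AND,
`+` = OR). Its fit for an outcome literal `Y=1` is measured by

- **consistency** — the fraction of condition-instantiating cases that show
  the outcome (sufficiency fit), and
- **coverage** — the fraction of outcome cases the condition instantiates
  (necessity / empirical importance),

both computed as exact rationals so that thresholds of exactly 1.0 behave
correctly. The search is bottom-up: single factor values are tested for
sufficiency first, then conjunctions of two, three, … — every conjunction kept
is a **minimal sufficient condition** (msc: meets the consistency threshold
while no proper sub-conjunction does). Disjunctions of msc are then tested for
necessity the same way, yielding **atomic solution formulas**

    SCHOOLS=2 + SCHOOLS=1*MC=1*CCY=0  <->  HI_UPTAKE=1

(`<->` = sufficiency and necessity). With several outcomes, atomic models are
combined into complex solution formulas representing causal chains or
common-cause structures, after filtering cyclic and structurally redundant
combinations. Everything returned is redundancy-free by construction, and
*all* models passing the thresholds are reported.

## Worked example

The package ships a synthetic, constraint-equivalent reconstruction of a
published 21-county Swedish analysis of HPV catch-up vaccination uptake
(school delivery `SCHOOLS` in {0,1,2}, four binary information channels
`SBI`, `MC`, `SM`, `CCY`, and the dichotomized outcome `HI_UPTAKE`,
1 = uptake ≥ 65%). See `?hpv_fixture` for what is and is not constrained by
the source narrative.

```r
library(coinca)
ct <- hpv_fixture()

consistency("SCHOOLS=2 + SCHOOLS=1*MC=1", "HI_UPTAKE=1", ct)
#> 7/8 (0.88)

fit <- cna(ct, "HI_UPTAKE=1", con = 1, cov = 1)
fit
#> Coincidence analysis
#>   thresholds: con >= 1, cov >= 1; maxstep = (3, 4, 10)
#>   outcome HI_UPTAKE=1: 3 msc, 1 asf
#>     SCHOOLS=2 + CCY=0*MC=1*SCHOOLS=1 <-> HI_UPTAKE=1  [con 1/1 (1.00), cov 1/1 (1.00)]
```

Reading the output: high uptake occurs if, and only if, a county offered the
vaccine in all schools (`SCHOOLS=2`), **or** offered it in some schools
combined with media coverage and *without* the cinema/YouTube channel
(`SCHOOLS=1*MC=1*CCY=0`) — the condition `SCHOOLS=2 + SCHOOLS=1*MC=1` alone is
only 7/8 consistent because one county (Skåne) instantiates it without high
uptake. The same analysis for the absent outcome (`cna(ct, "HI_UPTAKE=0")`)
yields three models that all contain `SCHOOLS=0 + SCHOOLS=1*MC=0` (coverage
13/14, printed 0.93) as a submodel.

The full study pipeline — variation screening, diversity index, the six
analytic samples obtained by pairing the four channels into a meta-factor,
positive and negated analyses, pooled models, common cores, backfire
tabulation (8 counties used `CCY`; 7 of them had low uptake; the exception is
Jönköping), robustness scan, and an eight-item reporting checklist — runs as:

```r
rep <- run_hpv_study(ct)
rep                      # text report
render_report(rep, "json")
```

A thin command-line front end is installed under `exec/`:

```sh
cna solve --data inst/extdata/hpv_fixture_synthetic.csv --outcome HI_UPTAKE=1 --con 1 --cov 1
cna simulate --truth "A=1+B=1*C=1 <-> Y=1" --n 50 --seed 7
```

Method validation uses the built-in ground-truth simulator
(`ground_truth()` + `simulate()`): noise-free, full-diversity data generated
from random Boolean structures are always recovered, and the test suite
checks the search output against an independent brute-force application of
the minimality definitions on hundreds of random tables.

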