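---
title: "Coincidence analysis with coinca: model, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coincidence analysis with coinca}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coinca)
```

## The model

Coincidence analysis belongs to the configurational comparative family of
methods grounded in a regularity theory of causation: a factor value is
causally relevant for an outcome when it is a non-redundant part of a
condition that is sufficient, but itself unnecessary, for that outcome (an
INUS condition). The data model is a case-by-factor table of crisp levels;
the hypothesis space is disjunctive normal forms over factor-value literals,
linked biconditionally to one outcome literal:

$$\mathrm{SCHOOLS{=}2} \;+\; \mathrm{SCHOOLS{=}1}*\mathrm{MC{=}1}*\mathrm{CCY{=}0} \;\leftrightarrow\; \mathrm{HI\_UPTAKE{=}1}$$

Such a model expresses three structural features at once: *conjunctivity*
(several conditions jointly required within a disjunct), *equifinality*
(alternative disjuncts as separate paths to the outcome), and — when models
for several outcomes are chained — *sequentiality*.

Fit is measured by two exact rationals. For condition $X$ and outcome $Y{=}y$
over cases $C$:

- consistency $= |C_X \cap C_{Y=y}| \,/\, |C_X|$ (sufficiency fit),
- coverage $= |C_X \cap C_{Y=y}| \,/\, |C_{Y=y}|$ (necessity / importance).

A condition instantiated by no case, or an outcome with no case, yields a
*designated undefined* score: it is neither 0 nor 1, and searches exclude it.
Coercing either way would manufacture spurious models (a never-instantiated
conjunction would look perfectly sufficient, or perfectly useless, by fiat).

## The search and its contracts

The search is bottom-up and exhaustive within a complexity bound
`maxstep = (max conjuncts, max disjuncts, max total literals)`:

1. **Minimal sufficient conditions (msc).** All conjunctions of size
   1, 2, … are tested in order; a conjunction is kept iff its consistency
   meets the threshold while no proper sub-conjunction does. Because a
   minimal witness always exists below any sufficient sub-conjunction, it is
   enough to discard candidates containing an already-accepted msc — this
   short-circuit provably returns exactly the definition's extension, which
   the test suite re-checks against a literal brute-force enumeration on
   hundreds of random tables.
2. **Atomic solution formulas (asf).** Disjunctions of msc are tested by
   increasing size; one is kept iff consistency *and* coverage meet their
   thresholds while no proper sub-disjunction meets both (minimal necessity).
   Distinct msc can never subsume one another, so every asf condition is
   automatically in canonical antichain form.
3. **Complex solution formulas (csf).** With several outcomes, one asf per
   outcome is combined; combinations whose factor graph is cyclic are
   dropped (and counted in the diagnostics), and a basic structural
   redundancy filter removes combinations in which deleting a whole atom
   leaves the satisfying set of configurations over the involved factors
   unchanged. More aggressive structural-redundancy elimination for
   multi-outcome models is known in the literature but out of scope; output
   is therefore labelled as filtered by the basic deletion test only.

No randomness enters the search; ties are broken everywhere by canonical
text ordering (literals sorted by factor, disjuncts by size then text), so
identical inputs give byte-identical serialized solution sets.

All models surviving the thresholds are reported. Ambiguity — several models
fitting equally well — is a finding about the data, not a nuisance; the
determinate part of an ambiguous solution is its **common core**, the largest
condition that is a submodel (injective disjunct-wise containment) of every
model. One subtlety follows from minimal necessity and is asserted in the
tests: when thresholds are *loosened*, a previously listed model can be
superseded by one of its own sub-disjunctions that now passes both
thresholds itself; the model's content persists, but as a smaller model.

## Tunable parameters

| parameter | meaning | default | why |
|---|---|---|---|
| `con` | minimum consistency, in (0,1] | 1 | strict Boolean dependence; lower only if noise is assumed |
| `cov` | minimum coverage, in (0,1] | 1 | same |
| `maxstep` | (conjuncts, disjuncts, total literals) | (3, 4, 10) | the conventional search depth in the configurational literature; the factor spaces in scope are tiny, so completeness within the bound is cheap |
| `min_minority_count` | variation screen margin (cases) | 2 | a factor whose minority level occurs once cannot show a cross-case regularity; the screen only reports, the user decides |

Thresholds are accepted as exact strings (`"13/14"`, `"0.95"`) and compared
in integer arithmetic. Perfect thresholds risk overfitting whenever noise is
present; the `robustness_scan()` refits over a threshold grid and scores each
model by the fraction of grid cells containing it or a supermodel of it —
models recurring across the grid are robust to the exact cut-offs.

## Numerical and representational choices

- **Exact rational fit scores.** Fit measures are ratios of case counts; a
  tiny numerator/denominator class keeps them exact end-to-end. Floating
  arithmetic would silently drop valid models at a threshold of exactly 1.0,
  and would misrepresent quantities like 13/14. Rounding (half-up, two
  decimals) happens only at presentation, and serialized output always
  carries numerator and denominator alongside the decimal.
- **Notation.** ASCII `<->` is emitted; the Unicode biconditional arrow is
  accepted on input. Factor names are normalised to upper case; reserved
  characters (`= * + < > -` and whitespace) are rejected in names. Parsing a
  printed model reproduces the parsed structure exactly (round-trip law).
- **Negated outcomes** need no special machinery: analysing the absence of a
  binary outcome is simply choosing the literal `HI_UPTAKE=0`.
- **Degenerate inputs.** Contradictory case pairs (same configuration,
  different outcome) make perfect thresholds unattainable; the search then
  returns empty model lists and pipelines still emit complete reports with
  diagnostics. A table with a single observed level in a binary column is
  treated as a constant binary factor (domain {0, 1}); domains can always be
  declared explicitly.

## The worked study reproduction

`run_hpv_study()` reproduces a published county-level configurational
analysis of HPV catch-up vaccination in Sweden: calibration of raw measures
into crisp factors (uptake dichotomized at 65%, inclusive — a county at
exactly 65% counts as high uptake; school delivery recoded into an ordinal
trivalent factor where all-schools delivery dominates; channel pairs
aggregated by OR into meta-factors named `A_or_B`), screening of constant or
nearly constant factors, diversity indices (observed distinct configurations
over the logically possible space — 11 binary plus one trivalent factor span
$2^{11}\times 3 = 6144$ configurations, the five selected analysis factors
span 48), the six analytic samples induced by pairing four channels, positive
and negated-outcome searches under identical settings, pooling of distinct
models (canonical-text identity, matching how model counts are convention-
ally reported), common cores, a tabulation of channels that appear negated
in models (candidate "backfiring" strategies), and an eight-item reporting
checklist. Items whose content is substantive reasoning (why this method,
why these factors, why this final model) are user-supplied text; the tool
enforces their presence, not their content, and it never auto-selects "the
most plausible" completion among ambiguous models — that selection is an
argument, not a computation.

## The packaged fixture

The shipped 21-county table is a *synthetic, constraint-equivalent
reconstruction*, not the study's published analytic dataset. Every constraint
it satisfies — case and outcome counts, the Jönköping and Skåne
configurations, the cinema/YouTube cross-tabulation, the exact fit scores
(7/8, 1, 1, 13/14) of the three reported expressions, the five distinct
high-uptake configurations, and the solve-level requirement that the
preferred model emerges from the search while the negated core is a submodel
of every negated-outcome model — is recorded in a machine-readable manifest
(`hpv_fixture_constraints()`) and re-verified by the test suite. Cells not
pinned by any constraint follow a deterministic fill rule documented in the
manifest: zero unless a solve-level constraint requires presence, with the
minimal deviations listed there (for instance, a low-uptake county with
some-schools delivery and nothing else forces every negated-outcome model to
carry `SCHOOLS=1*MC=0`). Two consequences are worth stating plainly:

- analyses that depend only on the documented constraints reproduce the
  published quantities exactly;
- analyses that depend on unconstrained cells (for example the *number* of
  pooled models across the six analytic samples — published as 5 positive and
  7 negative) need the real table, which users can supply to the opt-in check
  in the test suite; on the reconstruction the pipeline yields 3 pooled
  positive models whose common core is exactly the published one.

## The simulator, and what passing tests do and do not show

`ground_truth()` + `simulate()` generate validation data: exogenous
configurations drawn uniformly over their space, optionally *fragmented*
(a share of distinct configurations removed first, emulating limited
diversity), outcomes set by evaluating the truth's atoms in causal order,
then flipped independently with a *noise* probability. Defaults are
noise 0 and fragmentation 0 — the idealised regime in which the method's
correctness contract is exact recovery; the test suite verifies 100%
recovery over 100 random ground truths at full diversity, oracle equality of
the search against brute force on 200 random tables (up to 5 binary factors
and 16 cases, sizes at which exhaustive enumeration is feasible in seconds),
redundancy-freeness of every returned model, and byte-level determinism.
The simulator draws configurations uniformly and flips outcomes
symmetrically; real observational data are skewed, autocorrelated, and
fragmented non-uniformly, so passing these tests certifies the *algorithm*,
not the inferential step from real data to causal structure. Confounding by
unmeasured factors, case heterogeneity, and measurement error outside the
outcome column remain the analyst's burden, as in any configurational study.

## Known limitations

- Only crisp multi-value factors; fuzzy-set membership calibration is out of
  scope, as is automatic threshold selection (sensitivity analyses are
  re-runs, by design).
- The csf redundancy filter is the basic deletion test; chains with subtler
  structural redundancies may pass it.
- Exhaustive search is exponential in `maxstep`; the package targets the
  small factor spaces configurational methods are designed for, not
  high-dimensional screening.
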