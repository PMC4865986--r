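---
title: "Measuring the number of drugs from refill claims: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the number of drugs from refill claims}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drugtally)
```

## The measurement problem

A pharmacy refill database records dispensings, not use. Turning a fill
history into "the number of drugs this patient uses on day *t*" therefore
requires a chain of operational decisions, and each decision moves the
count. drugtally organises those decisions into three components —
scope, uniqueness, timeframe — and evaluates any such specification as a
deterministic function of a patient's fills, the product dictionary, the
hospitalization episodes and the index date.

The underlying assumptions are the usual ones for refill-claims work: the
days-supply field is a faithful estimate of how long a dispensing lasts;
drugs not captured by the payer (samples, out-of-pocket purchases, most OTC
products) are invisible; and a dispensed drug is consumed at one day of
supply per calendar day from its fill date.

## The cross-sectional decision rule

For each candidate drug the engine finds the **anchor**: the last fill
strictly before the index date (a fill on the index date is post-index — on
admission day the patient is already in hospital). Split fills of the same
drug on one date are pooled into a single anchor whose days supply is their
sum. The drug counts when

> observed index gap < allowable index gap,

with the observed gap an exact calendar-day difference and the comparison a
strict real-number inequality — a supply that runs out exactly on the index
date does *not* count. The allowable gap is either flexible
(multiplier × anchor days supply; the default multiplier is 1.0, so the
1.2-multiplier variant is the same rule with a different constant) or fixed
(90 or 180 days in the presets). Flexible gaps may be non-integral (1.2 ×
28 = 33.6) and are never rounded: rounding would silently shift the
threshold for every fourth days-supply value.

Three optional extensions widen the allowable gap or rescue a failed drug:

- **Cabinet supply** (preset v11): leftover days accumulated from fills in
  the 180 days *before the anchor fill* (the look-back is anchored at the
  last prior fill, not at the index date). The carry recurrence
  `c ← max(0, c + days_supply − gap_to_next_fill)` walks the windowed fills
  chronologically and ends at the anchor; it is algebraically identical to
  a day-by-day consumption simulation with the stock floored at zero, which
  the test suite uses as an independent oracle. The carry is deliberately
  uncapped: a patient refilling early for months genuinely accumulates
  stock, and any cap would be an additional untestable parameter.
- **Hospitalization adjustment** (v12): inpatient days strictly inside the
  open interval (anchor, index) are added to the allowable gap, because the
  home supply is not consumed in hospital. A stay occupies
  `[admit, discharge)` — the admission day is inpatient, the discharge day
  is not, matching standard inpatient-day accounting — and overlapping
  stays are unioned before counting. Because claims sources differ in this
  convention, it is exposed as `hospital_day_convention`
  (`"admit_only"` default, `"admit_discharge"` alternative) rather than
  hard-coded.
- **Post-index rescue** (v10): a drug that fails the index-gap test counts
  if the gap from its anchor to its *first* post-index fill is below the
  allowable pre-post gap (2 × days supply in the preset). A drug with no
  pre-index fill has no anchor and can never be rescued — the pre-post gap
  is defined from the last pre-index fill, so a drug newly started after
  index (lisinopril in the packaged fixture) stays out of a cross-sectional
  count at index.

**Per-drug overrides** (v13, v14) attach an alternative index-gap rule to an
attribute predicate (as-needed drugs, metered-dose inhalers). A matching
drug counts if it satisfies *either* the base rule *or* the override — the
override widens, never narrows. When cabinet or hospitalization additions
are enabled alongside an override, they extend both allowable gaps: the
additions model supply physically on hand, which does not depend on which
rule is being tested. (No preset combines them, so this choice affects no
packaged measure.)

## Uniqueness and key generation

Keys are canonical strings built from lower-cased ingredient names plus
route / form / strength detail as the level demands; combination-product
ingredient lists are sorted, so the key is order-independent. Under the
product basis fills are grouped by key and the anchor is the last fill of
the key. Under the ingredient basis, eligibility is evaluated per product
first and an ingredient counts when *any* product containing it satisfies
the timeframe rule; the evidence row for an ingredient reports the product
that admitted it (preferring counted products, then the latest anchor, with
product id as the final deterministic tie-break). The two groupings can
disagree only when distinct products share a key, in which case
"any product passes" is the epidemiologically sensible reading — the
patient demonstrably has current access to the ingredient.

## Longitudinal orientation

Included for completeness of the framework although no preset uses it: the
count is the number of distinct keys among in-scope fills with a fill date
inside the window (inclusive ends, offsets relative to the index date).
This is the "drugs dispensed in the last *N* months" measure common in the
literature.

## Cohort analytics

`percentile_summary` uses nearest-rank percentiles
(`sorted[ceiling(p * n)]`), so integer counts yield integer percentiles;
the interpolating convention is available via `convention = "linear"` but
changes nothing that matters for count data. `change_distribution` bins the
absolute per-patient difference from a reference measure into 0 / 1 / ≥2
drugs; it depends only on |Δ|, and its three percentages always sum
to 100. In the plain-text report rendering, percentages strictly between 0
and 1 print as `<1`; the CSV always carries exact values.

## The synthetic cohort generator

`generate_cohort()` emulates the structural features the measures are
sensitive to, for an elderly claims population observed one year before an
index hospitalization. Defaults (all overridable in
`simulation_config()`):

| parameter | default | rationale |
|---|---|---|
| chronic drugs / patient | Poisson, mean 5 | elderly cardiovascular-population regimen size |
| days-supply mix | 30 d (60 %), 90 d (25 %), 28 d (15 %) | common retail and mail-order supplies |
| refill delay | discretized Exp, mean 4 d | modest average non-adherence beyond exhaustion |
| discontinuation | 20 % of chronic drugs, stopped ≥ 2 × supply + 30 d before index | "drugs taken in the past but no longer in use" |
| PRN use | 40 % of patients, inter-fill gaps 60–250 d | sparse irregular as-needed fills |
| combinations / OTC | 15 % / 10 % of products | enough to exercise uniqueness and scope variants |
| hospital stays | 0.5 / patient-year, LOS 1 + Poisson(3) d | exercises the hospitalization adjustment |

The generator is deterministic given its seed (it saves and restores the
caller's RNG state) and `cmd_simulate` writes byte-identical files across
runs — its provenance JSON records config, seed and version but no
timestamp, precisely so the output is reproducible bit-for-bit.

What it does **not** emulate: dose changes and strength switches within an
ingredient, therapeutic substitutions, seasonal drugs, payer gaps
(coverage interruptions), and any calibration to a real cohort's
demographics or comorbidity mix. Passing tests on generated cohorts
therefore demonstrate the engine's correctness and ordering properties, not
that any particular measure is unbiased on real claims.

One boundary case is worth knowing: under perfect adherence a refill chain
is exactly periodic, and a chain whose next refill lands exactly on the
index date leaves its last *prior* fill exactly one days-supply back — the
strict inequality then excludes the drug, correctly, since its supply ran
out the day before admission. Counts under perfect adherence thus equal the
number of chronic drugs except for this alignment and for distinct products
that collide on one key.

## Problem sizes used by the test suite

The packaged checks run the fifteen presets on the single-patient fixture
(14 fills, well under a second), compare the cabinet-supply recurrence with
the day-by-day oracle on 1,000 randomized fill sets, and verify the
component-wise count orderings (wider scope ≥ narrower, longer gap ≥
shorter, each optional extension ≥ off) on 100 simulated cohorts of 50
patients under all relevant preset pairs. These sizes give every ordering
thousands of patient-level chances to fail while keeping the whole suite in
a few minutes.

## Known limitations

- Strength strings are compared as normalised text at the
  ingredient–route–form–strength level; no unit parsing is attempted
  ("10 mg" ≠ "10mg" unless the dictionary is consistent).
- The dictionary is flat: no therapeutic classification, so scope cannot
  express "exclude antineoplastics" except through the generic drug-type /
  predicate mechanisms.
- Eligibility/enrollment gaps are not modelled; a patient unobserved for
  part of the look-back window will simply appear to have fewer fills.
- The post-index search horizon is bounded only by the data supplied; with
  a very long post-index extract and a fixed pre-post rule, late refills
  could be rescued that a bounded extract would miss.
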