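# drugtally

Counting the number of drugs a patient uses from a pharmacy refill database
sounds trivial and is anything but: the count depends on which products are
considered drugs, how combination products and duplicate ingredients are
merged, and how far back from the index date a fill may reach and still
represent current use. Published studies vary in all three choices, often
without saying so, which makes drug counts hard to compare across studies —
whether the count serves as a polypharmacy endpoint, a comorbidity proxy, or
a covariate.

drugtally makes those choices explicit and computable. A measure is a
three-component specification:

- **Scope** — filters on product attributes: prescription vs OTC status,
  drug type (standard, vitamin, herbal, ...), route of administration,
  dosage form, and regular vs as-needed common use.
- **Uniqueness** — product-based (a combination product counts once) or
  ingredient-based (it is dissected into ingredients), de-duplicated at one
  of four key levels: ingredient, ingredient–route, ingredient–route–form,
  or ingredient–route–form–strength.
- **Timeframe** — cross-sectional at an index date or longitudinal over a
  window. Cross-sectionally, a drug with last pre-index fill at gap
  *g* = index − fill date counts when *g* < allowable gap, where the
  allowable gap is either flexible (*m* × days supply, default *m* = 1) or
  fixed (e.g. 90 or 180 days), optionally extended by leftover
  "cabinet" supply carried over from earlier fills, by inpatient days
  falling inside the gap, rescued by an early post-index refill
  (pre-post fill gap < allowed), or overridden per drug class
  (e.g. a 180-day gap for as-needed drugs).

Fifteen preset measures (`default`, `v1`–`v14`) each vary a single
component, so running them together is a sensitivity analysis of the count
methodology itself. The package is aimed at pharmacoepidemiologists working
with refill claims (e.g. Medicare Part D prescription drug events linked to
a product dictionary); it deliberately knows nothing about any specific
claims format — inputs are four plain CSV tables (fills, product
dictionary, hospitalizations, index events).

## Worked example

A packaged single-patient fixture holds a 14-fill history: three chronic
drugs refilled monthly (an estradiol patch, metoprolol succinate, an
ezetimibe/simvastatin combination tablet), one sublingual nitroglycerin fill
73 days before the index admission, and a lisinopril fill at hospital
discharge.

```r
library(drugtally)
fix <- table3_fixture()
count_drugs(fix$history, preset("default"), fix$dictionary)
#> <count_result> hp01 | measure default | count 3
#>                                key counted rule_fired observed_index_gap
#>        estradiol|transdermal|patch    TRUE   base_gap                 13
#>  ezetimibe/simvastatin|oral|tablet    TRUE   base_gap                 13
#>             lisinopril|oral|tablet   FALSE       none                 NA
#>   metoprolol succinate|oral|tablet    TRUE   base_gap                 13
#>    nitroglycerin|sublingual|tablet   FALSE       none                 73
#>  allowable_index_gap
#>                   28
#>                   30
#>                   NA
#>                   30
#>                    9
```

The three chronic drugs count because each was refilled 13 days before
index, within its days supply. Nitroglycerin fails (73 ≥ 9) and lisinopril
has no pre-index fill. Changing one component moves the count: restricting
scope to oral routes drops the patch (count 2); ingredient-based uniqueness
splits the combination (count 4); a fixed 90-day gap or a 180-day as-needed
override recovers nitroglycerin (count 4):

```r
measures <- lapply(c("default", "v2", "v5", "v8", "v13"), preset)
comparison_report(list(fix$history), measures, "default", fix$dictionary)
#>   measure_id n_patients p25 p50 p75 p95 pct_no_change pct_change_1 pct_change_ge2
#> 1    default          1   3   3   3   3           100            0              0
#> 2         v2          1   2   2   2   2             0          100              0
#> 3         v5          1   4   4   4   4             0          100              0
#> 4         v8          1   4   4   4   4             0          100              0
#> 5        v13          1   4   4   4   4             0          100              0
```

At cohort scale the same report gives nearest-rank count percentiles per
measure and the share of patients whose count changes by 0 / 1 / ≥2 drugs
relative to the reference measure. A seedable generator produces synthetic
claims with the features these measures are sensitive to (refill delays,
discontinuations, PRN drugs, combination and OTC products, hospital stays):

```r
co <- generate_cohort(simulation_config(n_patients = 200, seed = 1))
h  <- assemble_histories(co$fills, co$hospitalizations, co$index_events)
comparison_report(h, lapply(preset_names(), preset), "default", co$dictionary)
```

## Command line

```sh
exec/drugtally simulate --out-dir cohort --seed 1
exec/drugtally count   --fills cohort/fills.csv --dictionary cohort/dictionary.csv \
                       --index cohort/index.csv --measure v9 --out counts.csv
exec/drugtally compare --fills cohort/fills.csv --dictionary cohort/dictionary.csv \
                       --index cohort/index.csv --hospitalizations cohort/hospitalizations.csv \
                       --out-prefix report
```

`--measure` accepts a preset name or a JSON measure file; see
`vignettes/drug-count-framework.Rmd` for the configuration schema and the
methodological details.

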