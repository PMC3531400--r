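---
title: "Costing the scale-up of adolescent-friendly health services"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Costing the scale-up of adolescent-friendly health services}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(afhscost)
```

`afhscost` estimates the additional financial resources required to scale
up a package of adolescent health services to universal coverage in 74
low- and middle-income countries over 2011–2015, from the provider
perspective, in constant US$ (2008). This vignette documents the model,
the defaults that required a modelling decision, the synthetic-data
generator that stands in for non-public price databases, and the limits of
what the test suite can show.

## Model structure

The pipeline has four stages, mirrored by the package's modules:

1. **Registry** (`load_country_table()`, `load_intervention_table()`,
   `load_characteristics_table()`): validated configuration tables — the
   74 countries with their WHO region, adolescent population, HIV
   prevalence and sexual-activity rates; the 19 costable service rows in 8
   reporting groups with their population-in-need bases and ranges,
   current-coverage ranges, targets and delivery-point shares; the 20
   AFHS characteristics across the five quality dimensions that define the
   programme activities.
2. **Need** (`population_in_need()`): the 2010 adolescent population is
   projected geometrically, split into sex × age-band slices, filtered and
   weighted per the intervention's basis, and multiplied by the country's
   need share.
3. **Coverage** (`coverage_trajectory()`, `incremental_coverage()`):
   linear scale-up from the observed 2010 baseline to the target (95%;
   50% for opioid substitution therapy) by 2015, clamped at zero when the
   baseline already exceeds the target.
4. **Costing and reporting** (`cost_per_case()`, `intervention_cost()`,
   `programme_cost()`, `run_scenario()`, `aggregate_costs()`,
   `per_head_metrics()`, `current_spending()`): ingredients-based cost per
   case, incremental cases × cost per case, programme-activity costs, and
   aggregation of the resulting cost cube.

Epidemiology is deliberately static: scaling up services does not feed
back into prevalence or incidence within the 5-year window, so need
changes only through population growth.

## Key parameters and defaults

| Parameter | Default | Unit | Rationale |
|---|---|---|---|
| Coverage target | 0.95 (0.50 for OST) | fraction | universal-access convention; OST per treatment guidelines |
| Costed window | 2011–2015 | years | the scale-up period of the exercise |
| Trajectory anchor | 2010 | year | see below |
| Sex / age-band splits | 0.5 each | fraction | registry carries only 10–19 totals |
| Currency | US$ 2008, undiscounted | — | constant-dollar flows, no discount rate |
| Annualization of current spending | total / 5 | — | the 5 costed years |
| IEC scaling unit | per 1,000 adolescents | — | keeps IEC exactly linear in population |

**Trajectory anchor.** Coverage equals the baseline at the anchor year and
the target at 2015. With the default 2010 anchor the first costed year
(2011) already carries one fifth of the gap, and the five costed years sum
to 3/5 of the full-gap volume: `sum(k/5 for k in 1..5) = 3`. Whether the
first year should instead be costed at baseline is not decidable from the
exercise's description, so the anchor is a configuration switch
(`afhs_options(anchor_year = 2011)` gives the zero-increment-in-2011
variant); the 2010 anchor is the default because it makes every costed
year contribute and keeps the closed forms used in the tests simple.

**Clamping.** Services whose observed coverage exceeds the target (care
during childbirth is catalogued at 98.8%) contribute zero incremental
volume rather than negative volume: dis-investment is out of scope.

**Exclusions.** Six countries (Botswana, DPR Korea, Sao Tome and
Principe, Solomon Islands, Turkmenistan, Uzbekistan) are excluded from the
maternity model and receive no maternity-care records; Somalia is excluded
from programme-activity costing. Abortion and harm-reduction services
produce zero need where the corresponding legality flag is off; the
packaged registry ships all flags as `TRUE` because no authoritative
country list is bundled, and scenarios toggle them per country.

**Need bases.** The HIV testing and counseling row is conditioned on the
sexually active population (its need range is consistent with the
sexual-activity rates); the two HIV care rows weight by sex-specific HIV
prevalence before applying the need share; maternity rows are a direct
share of female adolescents (no fertility sub-model); STI rows carry the
condition share directly. The catalogue row for HIV care, support and
treatment of opportunistic infections has no printed delivery-point
shares; it uses 85/15/0 like its group sibling, ART provision.

## Numerical choices

- Fractional persons flow through the pipeline as reals; rounding is a
  formatting concern only, so conservation identities hold to machine
  precision.
- `split_population()` reconciles sex × band slices to the exact input
  total with the largest-remainder method. Ties in the fractional
  remainders, and the fractional residue of non-integer totals, go to the
  earlier cell in (male 10–14, male 15–19, female 10–14, female 15–19)
  order; the rule is deterministic and documented so an independent
  implementation can reproduce cells exactly.
- Delivery shares must sum to 1 within 1e-9 at load; aggregation views are
  checked to partition the grand total within 1e-6 relative; trajectory
  endpoints are exact within 1e-12.
- Any validation failure aborts the scenario before output is produced;
  there are no partial cubes.

## The synthetic-data generator

The ingredient quantities and unit prices of the original exercise live in
a non-public technical report and in the WHO-CHOICE and MSH price
databases. The generator (`synth_config()`, `generate_config()`) therefore
emulates them:

- service-delivery unit costs are log-normally dispersed (configurable
  coefficient of variation, default 0.3, mean preserved) around
  illustrative level anchors — hospital $12, primary facility $3,
  community $1.20 per contact — ordered hospital > primary > community;
- commodity prices are dispersed the same way around the packaged
  illustrative ingredient table (order-of-magnitude plausible; no claim of
  matching any price database);
- baselines and need shares are drawn uniformly within each
  intervention's admissible range (`range_uniform`) or pinned at the
  midpoint (`range_midpoint`); the draw mode applies to both tables so a
  midpoint configuration is hand-checkable end to end;
- population growth rates are drawn within `growth_rate_range` (default
  0.5–3% per year);
- district and facility counts assume districts of roughly 500,000 people
  and one primary facility per 10,000 people, with the same log-normal
  noise;
- programme-activity components are fixed at field-plausible magnitudes,
  e.g. IEC at $790 per 1,000 adolescents per year across its three
  component lines.

Everything is drawn inside `withr::with_seed()`, so a seed fixes the whole
configuration; structural inputs (registry, catalogue shares and ranges)
are never randomized. What the generator does **not** emulate: real
cross-country price correlations, within-country heterogeneity of delivery
platforms, commodity price trends, exchange-rate effects, or any
relationship between coverage baselines and income. Passing tests
therefore demonstrate the engine's arithmetic and invariants — not the
empirical accuracy of any dollar figure. Absolute totals produced from
synthetic prices are indicative of magnitude only.

The registry itself carries two documented placeholders, since total
population and growth are not part of the transcribed country table: total
population is adolescent population / 0.21, and region-typical growth
rates are included for completeness (scenario runs normally overwrite them
from the generator). The low/middle income split (35/39) is a
configuration column used only as an aggregation key.

## The worked example

`make_toy_worked_example()` returns a 2-country, 2-intervention
configuration with zero population growth and its expected cost cube,
computed in that function directly from the closed forms (population ×
need share × incremental coverage × cost per case; programme components ×
scaling driver) rather than by the engine. It serves as the end-to-end
regression fixture: the engine must reproduce all 60 cells within 1e-9.

## Problem sizes used in the tests

The unit and property tests run on the toy configuration and on synthetic
registries of 3–8 countries; the naive-summation cross-check runs at 5
countries × 3 interventions × 5 years; the sampling check of the
generator pools about 1,000 baseline draws per intervention; the
acceptance script runs the full 74-country × 19-intervention × 5-year
model twice (incremental and from-zero). These sizes make every invariant
checkable in seconds while exercising the same code paths as a full run.

## Known limitations

- Prices and ingredient lists are illustrative; absolute dollar outputs
  are not comparable to any published total without replacing them with
  real price tables (`read_config()` accepts externally prepared
  directories).
- Sex and age-band splits default to 50/50; real age structures are
  country-specific.
- No uncertainty propagation: the model is deterministic given a
  configuration; scenario analysis proceeds by varying configurations.
- No discounting, no inflation, no demand-side or patient time costs
  (provider perspective), no health-sector capacity constraints, and no
  epidemiological feedback of scale-up on disease rates.
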