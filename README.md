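# afhscost

Bottom-up, ingredients-based costing of scaling up adolescent-friendly
health services (AFHS) in 74 low- and middle-income countries, 2011–2015.

Health planners and health economists estimating "global price tags" need a
reproducible pipeline from demographic and epidemiological inputs to an
aggregated cost of reaching universal coverage. `afhscost` implements that
pipeline for a standard set of adolescent health services — contraception,
maternity care, HIV testing and counseling, STI management, safe abortion,
harm reduction, HIV care and treatment, care of injuries due to intimate
partner violence — plus the programme activities (management, training,
supervision, IEC, infrastructure) that make services adolescent-friendly.

## The model

For every country *c*, intervention *i* and year *y* ∈ {2011, …, 2015}:

- **Population in need**:
  PIN(c, i, y) = E(c, i, y) · s(c, i), where the eligible population
  E applies the intervention's sex filter and need basis (all adolescents,
  female adolescents, sexually active — band- and sex-specific rates — or
  HIV-positive), and the need share s lies within the catalogue's
  admissible range. Populations grow geometrically,
  P(y) = P(2010) · (1 + g)<sup>y − 2010</sup>; epidemiological rates are
  held constant.
- **Coverage**: linear scale-up from the 2010 baseline b(c, i) to the
  target T(i) (95%, or 50% for opioid substitution therapy) by 2015. The
  incremental coverage costed in year 2010 + k is
  Δ(k) = max(0, k/5 · (T − b)); a from-zero run forces b = 0.
- **Cost per case** (ingredients approach): cost = Σ quantity × price.
  Commodity lines (drugs, lab tests, supplies) use global prices;
  visit/bed-day quantities are priced with country-specific unit costs per
  delivery level, weighted by the intervention's hospital/primary/community
  shares.
- **Cost cube**: cell(c, i, y, category) = PIN · Δ · cost-per-case, plus
  programme-activity cells costed per country-year, per district, per
  facility, or — IEC only — per 1,000 adolescents.
- **Current spending**: cell-wise (from-zero run − incremental run),
  annualized over the 5 costed years.

All amounts are constant US$ (2008). The detailed ingredient quantities and
price databases behind the original exercise are not public, so the package
ships an illustrative ingredient set and a seeded synthetic-configuration
generator; every structural number (74 countries, the intervention
catalogue with its printed ranges, delivery shares and targets, the 20 AFHS
characteristics, the 6 maternity-model exclusions, Somalia's programme
exclusion) is packaged as data.

## Worked example

The packaged toy configuration (2 countries, 2 interventions, zero
population growth) is small enough to cost by hand:

```r
library(afhscost)

toy <- make_toy_worked_example()
scenario <- run_scenario(toy$config, mode = "incremental")
scenario
#> <afhs_scenario> mode = incremental
#>   cells: 60
#>   total: US$ 1,801,100

aggregate_costs(scenario$cube, by = "cost_category")
#>   cost_category     total share_pct
#> 1 commodities      281700      15.6
#> 2 programme        650000      36.1
#> 3 service_delivery 869400      48.3

per_head_metrics(scenario$cube, population_denominators(toy$config))
#>    year  total per_adolescent per_capita
#> 1  2011 206740          0.689      0.138
#> ...
#> 5  2015 513700          1.71       0.342
```

The US$ 1,801,100 total is exactly the sum of the hand-computed cube in
`toy$expected_cube`: for instance country "alpha"'s universal preventive
service has 50,000 adolescents in need, a coverage gap of 0.75 closed
linearly over five years, and a cost per case of $1 commodities + $2
service delivery, giving 50,000 · (k/5) · 0.75 · 3 dollars in year
2010 + k. Per-head metrics divide each year's total by that year's
(constant, here) adolescent and total populations. The from-zero
counterpart of the same configuration costs the full volume; subtracting
the incremental run recovers what is already being spent
(`current_spending()`, US$ 138,000 per year on the toy).

A full-scale run uses the 74-country registry with synthetic prices:

```r
config <- generate_config(synth_config(seed = 1))
scenario <- run_scenario(config, mode = "incremental")
aggregate_costs(scenario$cube, by = "intervention_group")
```

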