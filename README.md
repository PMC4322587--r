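# lemurlife

Derivation of per-taxon life-history summary tables from captive
strepsirrhine colony records (lemurs, lorises, galagos), for comparative
biologists and colony data managers who need species-level values —
counts, reproduction, longevity, body mass — computed from raw studbook
files with explicit, reproducible rules.

The package reads the two record schemas used by the Duke Lemur Center
colony archive (an animal list, one row per individual with 32 columns,
and a weight file, one row per weighing event with 33 columns) and builds
a 91-variable life-history table per taxon:

* **S** — sample sizes and counts (historic, captive/wild-born, current
  residents, captive births, weighed and survival n's);
* **R** — reproduction: conception dates back-calculated as
  `DOB − expected gestation`, litter events keyed by (dam, exact birth
  date), litter-size statistics, male:female birth ratio, parental age
  extremes at conception (minima from exact dates of birth only), and
  seasonal breeding/birth peaks: the modal month of litter events,
  extended to adjacent months holding ≥ 1/3 of the peak month's events or
  ≥ 20% of all events;
* **L** — longevity: product-limit (Kaplan–Meier) survivorship after
  excluding deaths < 30 d and censoring living/unverifiable animals, a
  distance-weighted median longevity
  `((U − U·dU) + (L + L·dL)) / 2` interpolating the 50% crossing,
  maximum ages, and infant mortality (deaths < 30 d among captive
  births, stillbirths included);
* **M** — body mass: neonate (day 0/1), young-adult and adult summaries
  after excluding weights within 60 d of death, during pregnancy, and
  from wild-caught juveniles, averaging per calendar month then per
  individual, and removing individuals > 2 SD above the group mean as
  obese;
* **O** — activity pattern and biosample counts (registry pass-through).

A synthetic-colony simulator (`simulate_colony()`) generates schema-exact
input files from known parameters — seasonal conception distributions,
gestation, litter-size distributions, infant and adult mortality,
censoring, wild-caught founders with estimated birth dates, growth to an
adult plateau with seasonal oscillation, pregnancy gain, terminal
decline, injected obesity — so every derivation rule is verified by
parameter recovery.

## Worked example

```r
library(lemurlife)

params <- colony_params(taxon = "CMED", n_founders = 12,
                        years_simulated = 30, gestation_d = 60,
                        peak_concep_month = 11, adult_mass_g = 250)
sim <- simulate_colony(params, seed = 42)
tab <- build_life_history_table(sim$animals, sim$weights)
truth_report(sim$truth, tab)
#>   taxon          parameter     truth recovered  abs_error   rel_error
#> 1  CMED  peak_concep_month  11.00000     11.00 0.00000000 0.000000000
#> 2  CMED median_longevity_y  13.86294     13.77 0.09294361 0.006704464
#> 3  CMED   infant_mortality   0.25000      0.25 0.00000000 0.000000000
#> 4  CMED  adult_mean_mass_g 250.00000    249.98 0.02000000 0.000080000
```

The simulated colony (12 founders, 30 years) produced 390 individuals and
236 captive litters. The pipeline recovers the simulator's peak
conception month exactly (November, the mode of the conception pmf),
infant mortality to the table's two decimals (0.25), the adult mass
plateau within 0.1% (249.98 g vs 250 g — the obesity screen removes the
injected ×2 individuals), and median longevity within 0.1 y of the
closed-form exponential median ln 2 / 0.05 ≈ 13.86 y. A slice of the
built table for this run:

```
S_N_All_Historic               390
S_N_All_DLCBorn_Litter         236
R_Peak_Breeding_Month          11
R_Peak_Breeding_Season         10.11.12
L_Median_All_Longevity_gt30d_y 13.77
L_Pct_All_InfMort_lt30d        0.25
M_Mean_All_AdultWeight_g       249.98
```

Both published layouts are written by `serialize_reference()` (91 rows ×
one character column per taxon, missing as `"."`) and
`serialize_analysis()` (one row per taxon, typed columns). A command-line
wrapper with `simulate`, `validate`, `build-table` and `compare`
subcommands ships in `inst/cli/lemurlife.R`.

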