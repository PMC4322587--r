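---
title: "Deriving life-history tables from captive colony records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving life-history tables from captive colony records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lemurlife)
```

## The problem

Captive strepsirrhine colonies (lemurs, lorises, galagos) accumulate
decades of studbook records: one row per individual with pedigree, dates
and status, plus a longitudinal file of weighing events. Those records are
individually verifiable but not directly usable as species-level biology:
ages are censored in three different ways, wild-caught animals carry
estimated birth dates, weighing frequency varies by orders of magnitude
between research projects and routine husbandry, and management decides
who breeds and when. `lemurlife` turns a pair of record files in the
standard archive schemas (a 32-column animal list, a 33-column weight
file) into a 91-variable per-taxon life-history table — counts,
reproduction, longevity and body mass — applying a fixed, documented
cascade of inclusion and exclusion rules.

Because real colony files cannot ship with the package, a
synthetic-colony simulator generates schema-exact input files from known
demographic parameters. Every derivation rule is then testable as
parameter recovery: simulate with a known peak conception month, hazard
rate, infant mortality and adult mass, rebuild the table, compare.

## Record conventions

Ages are calendar-day differences divided by 365 exactly, with no leap
correction — this matches the published column definitions and keeps every
derived age reproducible from dates alone. Each individual carries exactly
one of three terminal ages: age at death (verified date of death), age if
living (against the file date), or age last verified (animals that left
the colony and were last confirmed alive elsewhere). The latter two are
right-censored observations for survivorship.

Dates are ISO-8601 on write; readers also accept `M/D/YYYY`. Missing
values are empty on write; `""`, `"."` and `"NA"` are accepted on read.
Calculated columns are recomputed on read and compared against the stored
values (tolerance `1e-6` for floating-point columns); disagreements are
reported, not silently overwritten, because a stored value may encode
information absent from the two files (for instance pregnancy flags set
from observed matings). A `recompute = TRUE` flag switches to
recompute-and-replace.

## Reproduction

Conception dates are back-calculated by subtracting the species' expected
gestation (a curated registry constant, not a fitted value) from the exact
birth date. Because premature births would produce spuriously early
conception estimates, infants that did not survive at least one day are
excluded from every conception-based statistic.

The unit for litter-size and seasonality statistics is the **litter
event**: all infants born to one dam on one exact date. Since captive
birth dates are exact, no fuzzy date matching is used; births to the same
dam on different days are different litters.

Seasonality works on months, not days, because the conception date is an
estimate. The peak month is the month with the most litter events; the
peak season extends outward month by month while a month holds at least a
third as many events as the peak month or at least 20% of all events, and
stops at the first failing month in each direction. The thresholds
deliberately trim single-event tails. Two subtleties are worth stating:

* **Tie-breaking** between equally full peak months is by the larger sum
  of the two circular neighbours, then the smaller month number. Any
  deterministic rule would do; this one favours the centre of the mass.
* The expansion rule is **not monotone**: adding events to the peak month
  raises the one-third threshold and can drop an edge month from the
  season (e.g. counts Mar 9 / Apr 4 / May 3 include May; raising Mar to 12
  excludes it). This is a property of the published rule itself. For the
  same reason a strictly contiguous season cannot reproduce every
  historically printed season string; one published taxon shows a
  non-contiguous season that the stated rule cannot generate.

Minimum parental ages at conception use only exact dates of birth, for
both the offspring and the parent — an estimated age can be artificially
young, which would corrupt a minimum, but not artificially old, so maxima
include estimated ages. Offspring with multiple candidate sires count for
no candidate, in the offspring tally and in sire age statistics alike.

## Longevity

Survivorship is estimated by the product-limit (Kaplan–Meier) method over
death ages, after excluding deaths before 30 days of age entirely and
censoring living and unverifiable animals at their last known age. The
"proportional hazards model" of the source workflow reduces to exactly
this estimator when there are no covariates; product-limit is the only
estimator consistent with the censoring scheme and the 50%-crossing
procedure below. Deaths are processed before censorings at tied ages.

The **weighted median longevity** interpolates the 50% crossing: with `U`
the first death age at which survivorship S falls to 0.5 or below, `L`
the last death age with S above 0.5, and `dU`, `dL` the distances of the
adjacent survivorship values from the 0.5 midpoint,

    median = ((U - U*dU) + (L + L*dL)) / 2 .

When the curve starts at or below 0.5, `L = U`; when it never reaches
0.5, the median is undefined and reported as missing (this occurs in real
colonies with few uncensored deaths). The bracketing of the source
formula is ambiguous as printed (one unmatched parenthesis); this reading
is fixed by its degenerate limit: with `dU = dL = 0` it returns the exact
crossing age. Distances are taken as magnitudes on the survivorship
scale, so both weights are nonnegative.

Two cautions. First, the estimator inherits the sampling noise of a
sample median: for exponential lifetimes with median 10 y at n = 300 the
asymptotic standard error is about 0.8 y, so recovery is assessed on the
mean across replicate cohorts, not per cohort. Second, adding censored
observations — even beyond the bracket — enlarges earlier risk sets and
can legitimately shift the bracket; the bracket is a function of the
whole curve, not of the deaths alone.

Infant mortality is the proportion of captive-born individuals (including
stillbirths) dying before 30 days; the 30-day cut is strict (`< 30 d`
excluded from survivorship, exactly 30 d retained).

## Body mass

Neonate values use weights on day 0 or day 1 (averaged when both exist),
for individuals surviving at least one day. Adult and young-adult values
apply a fixed cascade:

1. drop weights taken fewer than 60 days before death (terminal decline),
2. drop weights of pregnant females (a dam is pregnant at a weighing iff
   the date falls in `[conception, birth)` of one of her litters),
3. drop weights of wild-born animals at estimated ages younger than the
   species' minimum dam age at conception,
4. classify each remaining weight by age: infant/juvenile below the
   minimum dam age at conception `m`, young adult in `[m, 2m)`, adult at
   `>= 2m` (an individual can contribute to both adult classes, each
   weighing to exactly one),
5. average within calendar year-month, then across months, giving one
   value per individual regardless of weighing frequency,
6. flag individuals more than two sample standard deviations (n − 1)
   above the pooled-sex group mean as obese, in a single pass, and drop
   them,
7. report mean/min/max of the remaining individual values, by sex where
   indicated; `n` counts individuals, not weighings.

The sample-SD convention and the single-pass screen are choices the
source does not pin down; both are documented here because the published
obesity tallies are sensitive to them. A month-subset option supports
season-specific summaries (several small-bodied taxa show pronounced
summer/winter mass cycles).

## The synthetic colony

The simulator emulates the statistical structure the derivations assume:
founders arriving as adults (a configurable fraction wild-born, whose
emitted dates of birth pass through the estimation rule — first day of
the origin-breeding mid-month for seasonal taxa, acquisition month/day
with the estimated year otherwise); managed breeding as random pairing of
eligible females within a dam age window under a carrying capacity;
conception months drawn from a 12-month pmf; litters placed exactly one
gestation after conception; infant deaths before 30 days with a
configurable probability (undetermined sex more likely for infant
deaths); adult lifetimes exponential with a configurable hazard;
censoring split between living residents and animals last verified
elsewhere; and a mass model of saturating growth to a plateau times a
sinusoidal seasonal oscillation, with pregnancy gain, terminal pre-death
decline, injected obesity (a multiplier applied from adulthood) and 2%
log-normal measurement noise.

Default study conditions: 12 founders, 30 simulated years, carrying
capacity 150, conception probability 0.6 within a 2–15 y dam window,
infant mortality 0.25, adult hazard 0.05 y⁻¹ (median ≈ 13.9 y), litter
pmf (0.55, 0.35, 0.08, 0.02) over sizes 1–4, sex ratio 0.5, 20% of
survivors censored, 80% of founders wild-born, obesity at 5% with a ×2
multiplier, seasonal amplitude 5%, pregnancy gain 15% at term, terminal
decline 20%, weighing every 60 days. These are one realistic operating
point for a mid-sized breeding colony — large enough that a 30-year run
yields 300+ captive births (the scale at which the recovery tolerances
are assessed) while a full simulate → build → recover cycle stays under
ten seconds.

What the simulator does **not** emulate: pedigree genetics, transfers
between institutions, management-driven non-random mate choice,
cohort-varying husbandry, or secular trends in weighing practice. Passing
recovery tests therefore demonstrates that the derivation rules are
implemented as specified, not that real colony data satisfy the
generative assumptions.

```{r recovery}
params <- colony_params(taxon = "CMED", n_founders = 12,
                        years_simulated = 30, gestation_d = 60,
                        peak_concep_month = 11, adult_mass_g = 250)
sim <- simulate_colony(params, seed = 42)
tab <- build_life_history_table(sim$animals, sim$weights)
truth_report(sim$truth, tab)
```

## Numerical and formatting choices

* Rounding follows the published table: counts integer, the sex ratio to
  3 decimals, years, proportions and masses to 2 decimals.
* The reference layout prints missing values **and zero counts** as `"."`
  (the published table does the same); the analysis layout keeps numeric
  zeros and writes missing as `"."` only as a read-back-aware sentinel.
* The registry's origin-breeding mid-month (used only for wild-born date
  estimation) is the captive peak breeding month shifted by six months,
  since captive Northern-hemisphere seasons are opposite to those in the
  Southern-hemisphere countries of origin.
* Degenerate inputs: an all-zero month histogram is an error (non-seasonal
  taxa bypass seasonality and print `"0"`); an empty risk set makes the
  longevity block missing; a single individual disables the obesity
  screen; an empty taxon yields a row of missing values with registry
  pass-through fields populated.

## Limitations

The derived table is captive biology: longevity without predation,
reproduction under management, mass without resource scarcity. Species
values are suitable as relative indicators across taxa, not as wild
population estimates, and individual-level reproductive timing (ages at
reproduction per individual, inter-birth intervals, offspring counts as
fitness) must not be interpreted biologically — breeding is scheduled by
people. The package deliberately offers no such analyses.
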