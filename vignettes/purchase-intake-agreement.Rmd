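---
title: "Estimating dietary intake from grocery transactions and quantifying agreement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating dietary intake from grocery transactions and quantifying agreement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(basketdiet)
```

## The problem

Supermarket loyalty-card transaction records capture, automatically and at
scale, what a household buys. If purchased nutrients were a usable proxy
for what an individual eats, electronic point-of-sale data could support
population dietary monitoring without the cost and self-report biases of
surveys and questionnaires. `basketdiet` implements the full measurement
pipeline needed to test that proposition:

1. **Nutrient estimation** — link each transaction line to a product
   nutrient database (back-of-pack values per 100 g/ml), impute generic
   category-level values where product labels are missing, and convert a
   comparison period's purchases into mean daily household nutrients.
2. **Household-to-individual allocation** — attribute a share of household
   purchases to the study participant in proportion to age- and
   gender-specific recommended daily energy intakes.
3. **Energy adjustment** — express macronutrients as percentages of total
   energy (protein 4 kcal/g, fat and saturated fat 9 kcal/g, sugars
   3.9 kcal/g) and sodium as mg/kcal.
4. **Agreement analysis** — compare purchase estimates with
   food-frequency-questionnaire (FFQ) intake using Bland–Altman methods,
   in particular the regression approach to bias and limits of agreement
   (LoA) on the log scale.
5. **A synthetic-cohort generator** — commercial transaction data are
   confidential, so a generator with a known ground-truth agreement
   structure stands in for them, making every downstream stage testable.

The six analytes carried throughout are energy (kcal), total sugars (g),
protein (g), total fat (g), saturated fat (g) and sodium (mg), per day.

## Nutrient estimation

Each line's total grams are `quantity x pack_amount` for packs sold by
weight or volume (1 ml is treated as 1 g: no specific-gravity table is
used) and `quantity x unit_net_weight_g` for per-unit packs; loose-weight
items are modelled through `pack_amount` so one formula covers every
line. Line nutrients are the per-100 profile times grams/100.

Products with an absent — or blank, i.e. all-zero — per-100 profile fall
back to a generic food-composition entry for their category, and the
resolution records provenance (`retailer` vs `generic`). Imputation here
is deliberately coarser than a manual closest-product match: one generic
profile per category, chosen because it is reproducible and because the
agreement analysis depends only on totals. `match_rate()` reports the
fraction of distinct purchased products resolved from retailer labels
(about 72% in the emulated world) and the post-imputation rate, which is
1 whenever the generic table covers all 15 categories.

Daily household estimates divide in-period totals by the day count of the
primary comparison period, a **closed** interval (both endpoints count):
day counting must be fixed exactly for reproducible estimates. A period
with no purchases yields a flagged zero vector, which the exclusion rules
then remove.

## Allocation

A participant's share of household nutrients is their recommended daily
energy intake divided by the household sum. The participant's own gender
is known; other household members' genders are not collected, so they use
the mean of the female and male recommendations. The default table
reproduces three verifiable anchors exactly — a 30-year-old woman at
1928 kcal, the female/male average at age 30 at 2230 kcal, and the
average at age 3 at 1197.5 kcal — so the canonical worked example holds:

```{r}
allocation_share(30, "female", c(30, 3))   # 36% of household purchases
```

The rest of the default table is populated with plausible UK reference
values; because only those three anchors are externally verifiable, the
table is a documented CSV input (`load_energy_table()`;
a copy of the default ships in `inst/extdata/energy_recommendations.csv`)
and users validating against official recommendations should supply the
exact published values. Ages are taken as given in the participant
record; shares are computed once per participant per comparison period.

Because one share multiplies all six analytes, allocation conserves the
household vector exactly and leaves every energy-adjusted measure
unchanged — which is why relative purchase estimates are reported as a
single column rather than household/individual pairs.

## Energy-adjusted (relative) measures

`relative_profile()` returns sugars/protein/fat/saturated-fat as
percentages of total energy and sodium density in mg/kcal. Percentages
are *not* renormalised to 100: unmodelled energy sources (non-sugar
carbohydrate, fibre, alcohol) make up the remainder, and the denominator
is always the reported energy field, never re-derived from macronutrient
grams. A zero-energy vector has no defined composition and raises an
error rather than returning 0. The sugars factor is 3.9 kcal/g — not the
conventional 4 — following the convention of the validation study this
package operationalises.

## Agreement statistics

`classic_ba()` gives the textbook analysis: mean difference (always
purchase minus intake), sample SD, LoA at bias ± 1.96 SD.

Purchase–intake differences are strongly heteroskedastic — spread and
even direction depend on the magnitude of the mean — so the headline
analysis is `log_ba_regression()`: with d = ln P − ln I and
m = (ln P + ln I)/2, fit d = β₀ + β₁ m by ordinary least squares; the
bias line is β₀ + β₁ m and the LoA run parallel at ±1.96 s, where s is
the residual standard error on the n − 2 denominator (the source text
does not state a denominator; the regression convention is used).
Residual spread is modelled as constant in m; a magnitude-dependent
residual SD is out of scope. The multiplier is literally 1.96, not a
t-quantile. Pairs with a non-positive value on either side have no
logarithm; they are excluded and counted (`excluded_nonpositive`) — the
study's own exclusions guarantee positive energy but not positive values
of every nutrient.

`predict_ratio()` reports agreement at a chosen magnitude A: ln A times
the slope plus the intercept, back-transformed, gives the
purchase:intake ratio, with LoA ratios exp(d̂ ∓ 1.96 s). Note the recipe
plugs ln A into a regression whose x-axis is the *mean of logs* (the log
of the geometric mean), not the log of the arithmetic mean; the package
follows that reporting recipe exactly, as published, and this vignette is
where the conflation is documented. `a_star()` gives the ratio-unity
point A* = exp(−β₀/β₁), the magnitude at which purchases and intake
agree on average; it is undefined (NA) when β₁ = 0.

`agreement_by_measure()` runs the 17 standard fits — six absolute
analytes at household and individual level, five relative measures —
pooled or by subgroup (household size 1/2/3+; loyalty low-medium 0–60%,
high 61–80%, very high 81–100%). Energy is reported at A = 2000 kcal by
default; every other measure is reported at its own A*, where the fitted
ratio is 1 and the LoA columns show pure spread. Regressions are
unweighted with no trimming of influential points.

## The synthetic world

The generator emits everything the pipeline reads: a catalogue with
~28% of products lacking per-100 profiles, a 15-category generic table,
686 participants (72% female, ages ~56 ± 13, household sizes 1–5
averaging 2.2, five loyalty bands with 82% above 40%), five recruitment
waves each with a baseline year, a study year and a ~91-day primary
comparison period, two years of Poisson shopping trips, and FFQ records
emitted directly as daily nutrient vectors.

Its core is a known agreement structure. For each participant the energy
magnitude m (the mean of logs) is drawn first, then the log difference

d = b₀ + b₁ m + ε,  ε ~ N(0, σ²),

and the observable pair is reconstructed as ln P = m + d/2,
ln I = m − d/2. Drawing m first matters: solving for P given an
exogenously drawn intake would make the regressor correlated with the
noise, biasing any OLS fit of d on m — with the construction used here,
the pipeline's own regression is unbiased for (b₀, b₁, σ) and parameter
recovery is a meaningful end-to-end test. One magnitude regressor — the
*energy* m — drives the difference for all six analytes, because the
dominant cause of disagreement (how much of a household's food comes
from this one retailer) acts on the whole basket at once; each analyte
gets its own noise draw, correlated 0.93 within participant. Two
guards keep targets physically realizable, both counted in the ground
truth: saturated fat is clamped to total fat, and macro grams are scaled
back in the rare draws where macro energy would exceed 97% of total
energy.

Defaults state the published world rather than a convenient one:
σ = ln(3.43/0.86)/1.96 ≈ 0.71 and b₀ = ln(0.86) − 7.6 b₁ reproduce the
reported individual-level energy agreement (ratio 0.86 at 2000 kcal, LoA
22–343%); b₁ = 0.6 expresses the reported shape (purchases
under-estimate at low magnitudes and over-estimate several-fold at high
ones; no slope value is published); the noise correlation 0.93 is
derived from the published relative-sugar LoA (0.59–1.67). Food waste
and FFQ under-reporting both default to 10%; they relate *true* intake
to the observables in the ground-truth record (FFQ = true × 0.9) but do
not shift the observable purchase:FFQ ratio again — b₀ is the net
intercept between the two quantities the pipeline actually compares.

The individual-level target is inverted through the allocation share to
a household target, and transactions are constructed to hit it exactly:
random in-period basket lines are scaled by a per-household factor α
chosen so the remaining target is non-negative in every component (and
in residual non-macro energy), and the remainder is decomposed exactly
onto six staple products — sugar, protein powder, vegetable oil, coconut
oil, table salt and a spirit (energy without macronutrients, much like
the alcohol that real product databases must impute). In-period totals
therefore reproduce the target to machine precision, which is what makes
the identity configuration (σ = 0, b₀ = b₁ = 0) come back with ratios of
exactly 1 through the entire pipeline.

What the generator does **not** emulate — and hence what a green test
does not establish:

* imputation error: products with missing labels truly have their
  category-generic composition, so the 28% missingness affects
  provenance accounting only (real generic imputation is approximate);
* basket realism: trip frequency and basket sizes are simple Poisson
  placeholders (the source material gives no basket model, and only
  period totals matter downstream), and the staple correction gives
  staples an unrealistically systematic role;
* subgroup heterogeneity: one (b₀, b₁, σ) governs everyone, so
  household-size and loyalty subgroup machinery is exercised but true
  subgroup differences in agreement are absent;
* seasonality beyond wave timing, prices/promotions, store geography,
  and the 150-item FFQ instrument itself (intakes are emitted directly
  as daily nutrient vectors).

## Filters and reporting

Exclusions follow the recruitment funnel order — no completed FFQ, no
in-period purchase, then FFQ energy ≥ 8000 kcal/d (four times an adult
woman's recommended intake; the boundary is excluded) — with a ledger
that must conserve n. The sensitivity analysis drops participants whose
purchased energy is *strictly below* 500 kcal/d (a quarter of an adult
woman's recommendation; exactly 500 is retained). The published wording
does not say whether that threshold applies to household- or
individual-level purchased energy; the default is household-level with a
switch (`sensitivity_filter(level =)`). The recruitment eligibility
screen (≥7 of 15 categories on ≥10 occasions in a calendar year, annual
spend within Q3 + 1.5 IQR of a reference distribution with an
equal-proportion lower-tail cut) takes the reference bounds as
configuration, since they come from an external survey; it defaults to
off in synthetic runs.

`run_pipeline()` strings everything together from a single
`run_config()` (self-contained generator or CSV inputs), pools waves by
default, and emits the descriptive tables, the pooled and subgroup
coefficient tables, the sensitivity tables and a provenance block;
identical configuration and seed give byte-identical CSV outputs. A thin
command-line wrapper with `simulate` / `estimate` / `analyze` / `run-all`
subcommands ships in `inst/scripts/run-pipeline.R`.

```{r}
cfg <- run_config(generator = generator_config(seed = 42, n_participants = 120,
                                               catalogue_size = 60))
report <- run_pipeline(cfg)
report
subset(report$agreement, level == "relative",
       select = c(measure, n, beta0, beta1, resid_sd, A, loa_lo_ratio, loa_hi_ratio))
```

## Numerical choices and limitations

* Comparison periods and date filters are closed intervals; ISO-8601
  dates throughout.
* `ml -> g` is exactly 1:1; no density table.
* Blank (all-zero) label profiles are treated as missing and imputed.
* Degenerate inputs raise classed errors (`basketdiet_error_config`,
  `_data`, `_lookup`, `_domain`, `_insufficient_data`, `_singular`)
  rather than returning silent zeros; zero-energy composition is an
  error, not 0.
* The log-scale analyses require at least 3 positive pairs and a
  non-singular design (not all m identical).
* One RNG stream per generated family (catalogue, cohort, observations),
  so changing the cohort size does not perturb the catalogue.
* Confidence intervals for the LoA themselves, repeated-measures
  designs and mixed-effects agreement models are out of scope.
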