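---
title: "From household food records to fortification scenarios: models and assumptions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From household food records to fortification scenarios: models and assumptions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hcesfort)
```

`hcesfort` estimates apparent micronutrient intakes and the contribution of
large-scale food fortification (LSFF) from household consumption and
expenditure survey (HCES) food records. This vignette documents the models,
the assumptions behind every default, and what the synthetic survey does
and does not establish about real data.

## Apparent intake model

HCES record what the household acquired or consumed over a 7-day recall,
not what individuals ate. The pipeline therefore estimates *apparent*
intakes under an energy-proportional sharing assumption: nutrients are
distributed within the household in proportion to members' energy
requirements. The household's nutrient supply per day is

$$S_{h,n} = \sum_{f} \frac{q_{hf}}{7}\,(1-r_f)\,\frac{d_{fn}}{100},$$

where \(q_{hf}\) is the reported quantity converted to grams (kg ×1000;
volumes × density in g/mL; pieces × portion mass), \(r_f\) the refuse
(non-edible) fraction and \(d_{fn}\) the per-100 g edible-portion
composition. Apparent intake per adult female equivalent is
\(S_{h,n}/\mathrm{AFE}_h\). Households reporting no food consumption in
the recall period cannot be standardised and are excluded from analysis.

### Adult female equivalents

\(\mathrm{AFE}_h=\sum_i \mathrm{EER}_i / \mathrm{EER}_{\text{ref}}\), the
household's total energy requirement in units of the requirement of a
non-pregnant, non-lactating woman aged 18–29.9 years. The default
requirement table (`default_eer_table()`) computes EER as Schofield basal
metabolic rate — an affine function of body weight per age-sex band — times
a physical activity level of 1.85 ("active or moderately active"). Every
element is a configurable parameter, so any alternative requirement basis
can be substituted without touching code.

* **Children below 24 months** contribute the energy needed from
  complementary (non-breastmilk) foods directly: 0, 76, 269, 451 and
  746 kcal/d for 0–2, 3–5, 6–8, 9–11 and 12–23 months. A 1-month-old
  therefore contributes nothing to the household's food-sharing key, which
  is the intended behaviour for breastfed infants.
* **Lactation** adds 500 kcal/d. Surveys of this type carry no lactation
  status, so a woman is assumed lactating if she is linked as the
  biological mother of a household member under 24 months.
* **Pregnancy** is not modelled: the source data carry no pregnancy
  status, and no adjustment is attempted.
* **Body weights**: measured anthropometry is used where collected (women
  ≤50, boys ≤15 in the emulated survey). Adult men fall back to a
  global-database weight (61 kg); males 16 and 17 interpolate at the two
  midpoints between the 15-year-old survey mean and the adult value; women
  above 50 use the survey mean of measured women 19–49. The reference EER
  is evaluated at that same female mean, which makes "one reference woman
  = 1 AFE" hold by construction, and — because Schofield is affine in
  weight — sums of reference women scale exactly.

## Quantity cleaning

Reported quantities are right-skewed, so outlier screening happens on the
log scale: within each food item, values whose log deviates from the
median of logs by more than 3 standard deviations (of the logs) are
replaced by the untransformed median among consumers, as are missing
quantities. Three scale decisions matter and are deliberate:

* **After unit conversion**: quantities are compared in grams/day, the
  only scale on which consumers of the same item are comparable across
  reporting units.
* **Per AFE**: the rule runs on quantities divided by the household's
  AFE. Household size spans an order of magnitude; on the raw scale a
  single-person household's perfectly ordinary consumption sits several
  log-SD below the group median and would be "cleaned". Standardising
  first removes size from the outlyingness definition; replacements are
  mapped back to the household scale.
* **Per stratum** (when a stratum column is present): staple consumption
  differs so strongly between strata — maize flour medians differ by a
  factor of five between the lightest- and heaviest-consuming strata —
  that pooling nationally would flag the legitimate lower tail of
  low-consumption strata. Detection within (item, stratum) compares like
  with like.

A caveat worth stating: an extreme value inflates the very standard
deviation it is tested against. With a handful of consumers even a
six-orders-of-magnitude error can fail to cross 3 SD (masking). The rule
is kept as stated for fidelity; the tests verify detection at group sizes
where the rule genuinely works, and the generator (below) is conditioned
so that detection is exact.

## Fortification scenarios

Per vehicle (cooking oil, wheat flour, maize flour) and nutrient, the
added content in mg/kg is

* no fortification: 0,
* status quo: \(A \cdot B \cdot (1-C)\),
* full fortification: \(A \cdot (1-C)\),
* full fortification without maize: as full, but 0 through maize flour,

with \(A\) the legislated mean content (oil 25 mg/kg vitamin A RAE as
retinyl palmitate; flours: iron 33, zinc 44, vitamin B12 0.013, folic acid
2 mg/kg), \(B\) the market compliance (0.28 oil, 0.47 wheat, 0 maize —
essentially no maize flour is industrially milled), and \(C\) the fraction
of the nutrient lost between production and consumption. \(C\) is a
vitamin phenomenon; minerals carry \(C=0\). The default losses — 0.30 for
retinyl palmitate in open-market oil, 0.30 for folic acid through baking
and cooking, 0.10 for B12 — are typical storage/processing values chosen
once when the generator's operating point was calibrated (they reproduce
the published pattern of a ~11-point status-quo reduction in vitamin A
inadequacy and zero folic-acid excess in all scenarios); all are
per-(vehicle, nutrient) configurable.

Fortifiability is consumption-based: everything reported as consumed is
potentially fortifiable, which bounds the programme's effect from above.
A purchased-only variant (`purchased_only = TRUE`) restricts vehicle
equivalents to purchased records. Vehicle equivalents include flour and
oil embedded in bread, buns/cakes/biscuits and sweets via recipe mass
fractions; macaroni/spaghetti is excluded because its flour cannot be
attributed to domestic fortifiable milling. Added vitamin A accrues to
both total RAE (adequacy) and preformed retinol (excess); folic acid
accrues ×1.7 to dietary folate equivalents for adequacy and as folic-acid
mass for excess.

## Adequacy, excess and gaps

The fixed cut-point approach scores a household inadequate when its
per-AFE intake falls below the harmonised average requirement (zinc
10.2 mg, vitamin A 490 µg RAE, folate 250 µg DFE, B12 2 µg). Iron instead
uses the full probability approach for menstruating women at 5%
bioavailability: the prevalence is the weighted mean over households of
the probability that a requirement draw exceeds the household's intake. No
published table pins the requirement distribution, so the default curve
(`default_iron_risk_curve()`) models the absorbed requirement as lognormal
with median 1.46 mg/d and a 95th percentile at twice the median, divided
by the bioavailability; it ships as an interpolation table and is fully
overridable, and absolute iron prevalences should be read as conditional
on this curve. A degenerate step curve reduces the estimator exactly to
the cut-point form, which the tests exploit as an oracle.

Excess risk uses harmonised upper limits for iron (45 mg), zinc (25 mg
EFSA and 40 mg IOM, both reported), preformed retinol (3000 µg) and folic
acid (1000 µg); folate and B12 are excluded on toxicity grounds and
requesting them is an explicit error. The micronutrient gap is the
25th-percentile intake minus the requirement; the safety gap is the upper
limit minus the 75th percentile (positive = safe). Because the two zinc
limits differ by 15 mg, the two safety gaps differ by exactly 15 mg on any
data — a useful invariant.

All summaries are survey-weighted. The weighted quantile generalises the
interpolated type-7 sample quantile: the quantile is read at position
\(h = 1+(W-1)q\) along the cumulative-weight axis, so unit weights give
exactly the classical quantile and integer weights exactly the quantile of
the weight-replicated sample. Design-based variance estimation (replicate
weights, cluster-robust CIs) is out of scope; the full-probability iron
estimator in particular yields no CI.

## The synthetic survey and its ground truth

`generate_survey()` emulates the structure of a national panel survey:
four analytical strata ("Dar es Salaam", "Mainland other urban", "Mainland
rural", "Zanzibar"), clusters of 8 households (default 3288 households in
the strata proportions of the emulated survey round), inverse-sampling-
fraction weights with ±20% noise, rosters drawn from a young-population
age pyramid (household size 1 + Poisson(3.7), capped at 12), measured
anthropometry where the emulated survey collected it, and mother links
that drive the lactation rule.

Consumption follows a per-(stratum, item) model: a coverage probability
and a lognormal quantity whose median (in g/day per AFE) is taken from the
published stratified consumption pattern for the three vehicles and their
recipe products, and set to plausible values for the remaining items.
Quantities scale with the household's AFE, so per-AFE distributions are
size-invariant — the same energy-proportional sharing the pipeline
assumes. Nutrient densities of the synthetic composition table were scaled
once so that the national per-AFE intake distributions sit at the study's
reported operating point (median energy ≈2500 kcal; vitamin A inadequacy
≈92% without fortification, ≈81% under status quo; iron ≈75%, zinc ≈42%,
B12 ≈48%, folate ≈15%); the frozen values are exposed as
`generator_operating_point()` and recovery within Monte-Carlo error is an
acceptance test.

Two generator choices exist purely to make the cleaning rule exactly
testable, and are worth knowing when interpreting what passing tests
prove:

* log-quantities are drawn from a normal truncated at ±1.5 SD — still
  right-skewed on the natural scale, but with bounded spread, so the >3 SD
  rule can never fire on clean data;
* coverage is floored at 0.10 per stratum and corruption is injected only
  into (item, stratum) groups with ≥30 consumers, at most two inflated
  outliers per group, each multiplied by \(e^{9\sigma}\) — guaranteeing
  detection even after the injection inflates the group's SD.

Ground truth — per-household per-AFE intakes under every scenario, vehicle
flows and weighted prevalences — is computed from the uncorrupted
quantities by a deliberately independent straight-line implementation
(inline constants, no calls into the pipeline), so recovery tests compare
two implementations rather than one with itself.

What the synthetic survey does **not** emulate: real unit-conversion
ambiguity and food-matching error, correlated consumption across items,
cluster-level intra-class correlation, seasonal recall effects, heaped
reporting, and genuinely unbounded quantity errors. Passing the suite
shows the pipeline computes its estimands correctly and recovers known
parameters under the stated conditions — not that those conditions capture
all the messiness of real survey data.

## Numerical choices and problem sizes

Determinism: all randomness flows through a single integer seed
(`withr::with_seed`), so identical seeds give byte-identical surveys and
pipeline outputs. Degenerate inputs are handled explicitly: items with
fewer than two non-missing consumers pass through the outlier rule;
all-missing items are dropped with a warning; households whose members all
contribute zero energy requirement are excluded with a warning; empty
analysis domains are omitted from summaries. Risk curves are interpolated
linearly (step curves left-constant) and clamped at their endpoints.

The test suite exercises the full default scale where it matters —
parameter recovery runs ten seeds of the 3288-household survey, the
cleaning bookkeeping one, and the ordering suite ten seeds at 1000
households — and small algebraic fixtures everywhere else; the whole suite
runs in a few minutes on one CPU.

## Known limitations

Apparent intakes are a household-level proxy: intra-household inequity,
food eaten away from home, and within-person day-to-day variance are
invisible, so prevalence estimates are of *apparent* inadequacy, not usual
intake inadequacy. Single composition values per item ignore geographic
variation. The iron prevalence is conditional on an assumed requirement
distribution. Zinc excess under the EFSA limit should be read cautiously —
the two harmonised limits disagree by 15 mg/d, which the paired safety
gaps make explicit.
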