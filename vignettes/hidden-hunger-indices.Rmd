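---
title: "Constructing global hidden hunger indices: methods and assumptions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constructing global hidden hunger indices: methods and assumptions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hhindex)
```

## The problem

"Hidden hunger" is chronic deficiency of essential vitamins and minerals —
above all iron, zinc, vitamin A and iodine — that affects some two billion
people without producing the visible signs of caloric hunger. Deficiencies
of different micronutrients share causes (poor-quality diets, frequent
infection) and therefore co-occur in the same populations, but surveillance
data are collected one nutrient at a time. A composite, country-level index
lets analysts and advocates compare the joint burden across countries, rank
them, and target programs.

`hhindex` builds two complementary families of such indices from delimited
country tables:

* a **prevalence-based score** (`hhi_pd`) for preschool-age children, the
  unweighted mean of three prevalences (percent):

  $$\mathrm{HHI}_{PD} = \tfrac{1}{3}\left(\,p_{\text{stunting}} +
  p_{\text{IDA}} + p_{\text{VAD}}\,\right)$$

  where stunting (height-for-age z-score below −2) proxies zinc deficiency,
  iron deficiency anemia (IDA) is derived from total anemia, and vitamin A
  deficiency (VAD) is the prevalence of serum retinol below 0.70 µmol/L;

* two **burden-based indices** from disability-adjusted life years (DALYs)
  attributed to iron, zinc and vitamin A deficiency: the population-adjusted
  rate `hhi_dba` (DALYs per 100,000), and the absolute country burden
  `hhi_dbu` = rate × population / 100,000.

Iodine deficiency (urinary iodine below 100 µg/L in school-age children) is
carried through the pipeline and reported alongside, but deliberately enters
no index: it correlates only weakly with the other three deficiencies — its
drivers (soil iodine, salt-iodization policy) are different — so averaging it
in would blur rather than sharpen the composite.

## Harmonization rules

Raw country tables rarely carry exactly the quantities the index needs.
`harmonize_countries()` applies, in order:

1. **Vitamin A assumption** (`assume_vad_free()`): a country with 2005 GDP
   per capita at or above US$ 15,000 and *no* retinol data is assigned a VAD
   prevalence of 0 with provenance `assumed_zero`. The threshold is closed
   (exactly 15,000 qualifies) and measured values are never overwritten.
2. **Regional stunting imputation** (`impute_stunting()`): a missing
   stunting prevalence receives the mean of the observed values in the same
   WHO region, weighted by 2009 population. Imputation is single-pass —
   only observed values donate — so the result is order-independent and an
   imputed value can never seed another imputation. A region with no donor
   leaves its values missing, with a warning.
3. **Exclusions** (`apply_exclusions()`): countries whose development index
   (2007 HDI, or the Life Expectancy Index as substitute when the HDI is
   missing) is **at or above 0.9** are excluded, as are countries with
   neither anemia nor VAD data. Inclusion is the strict rule (score < 0.9):
   a country at exactly 0.9 is excluded. Every exclusion carries a
   machine-readable reason; a country with no development score at all is
   excluded with a warning rather than an error.
4. **Anemia → IDA** (`convert_anemia_to_ida()`): total anemia is multiplied
   by 0.60 where malaria is not endemic and by 0.50 where it is, reflecting
   the larger share of non-iron causes of anemia (hemoglobinopathies,
   infection, inflammation) in malaria-endemic settings. Malaria endemicity
   is an input column: the judgment of which countries are endemic is data,
   not code. `ida_adjust = FALSE` feeds raw anemia through instead, as a
   sensitivity analysis: the published index narrative uses the adjusted
   value, so that is the default.

All prevalences travel on the 0–100 percent scale end to end; proportions
appear only inside `hhi_policy()`, which also makes every constant above a
tunable parameter. Every prevalence carries exactly one provenance tag
(`national_survey`, `who_regression`, `regional_imputation`, `assumed_zero`,
`missing`), so sensitivity analyses can condition on data quality.

One upstream rule is documented but not enforced: anemia estimates should
exclude children below 0.5 years (no anemia cut-off is defined there). That
is survey processing on the supplier's side; the reader accepts whatever
national estimate is provided.

## Severity scale and rankings

Scores are banded as mild [0, 20), moderate [20, 35), severe [35, 45),
alarmingly high [45, 100]. The half-open bands reflect that the customary
"0–19.9 / 20–34.9 / 35–44.9 / 45–100" phrasing is one-decimal reporting,
not a binning rule: scores are categorized at full precision, and the
smallest alarmingly-high score is exactly 45. Rankings (`rank_countries()`)
are descending with ties broken by ISO3 code ascending, so they are
deterministic; countries missing the key are dropped and reported.

`select_high_burden()` implements the high-stunting-burden group: countries
with stunting ≥ 20%, ordered by estimated stunted children
(prevalence × under-five population), cut at the smallest prefix holding
90% of the global stunted-child total. The achieved coverage is returned
rather than forcing a fixed group size; on the synthetic panel below the
rule yields 38 countries at 90.3% coverage.

## Association analyses

`spearman_rho()` wraps the rank correlation with pairwise-complete deletion
and always reports the number of pairs actually used, because country panels
are missing-data-ridden and an *r* without its *n* is uninterpretable. No
p-values are attached: these are descriptive, whole-population summaries of
a country panel, not samples from a superpopulation. `top_k_overlap()`
counts the intersection of two top-k lists, the natural "do the two indices
point at the same hotspots?" statistic.

## The synthetic generator

No raw data ship with the package. `generate_cohort()` draws country panels
with the statistical structure the analysis assumes, so every pipeline stage
and every association property is testable offline:

* a **Gaussian copula** over four latent deficiency variables — default
  correlation 0.6 among stunting, anemia and VAD and 0.05 between iodine
  and the rest — mapped to per-region prevalence marginals by a clamped
  linear transform. Clamped linear maps were chosen over beta marginals for
  transparency: the rank-correlation target of the copula,
  $(6/\pi)\arcsin(r/2)$ (`copula_rank_target()`), survives any monotone
  map, and clamping events are counted and stay below 1% of cells at the
  default marginals (the default means and standard deviations were chosen
  jointly to respect that budget);
* a **DALY link**: the rate is a linear function of the mean deficiency
  burden (default 60 DALYs per 100,000 per percentage point) plus Gaussian
  noise, truncated at zero — this is what makes prevalence- and
  burden-based indices strongly rank-correlated (≥ 0.8 at n = 2,000), the
  regime observed in real panels; iodine-attributed DALYs are generated
  independently;
* an **inverse development-index link** (default 1.00 − 0.009 × burden,
  noise SD 0.04, clamped to [0.25, 0.98]) so that a realistic fraction of
  low-burden countries crosses the 0.9 exclusion threshold;
* log-normal populations, region-dependent malaria endemicity (exercising
  both IDA factors), and per-field completely-at-random missingness.

What the generator does **not** emulate: real missingness is structural
(data availability tracks poverty and conflict), subnational heterogeneity
is absent, and there are no time trends. Passing tests on synthetic cohorts
therefore demonstrate the *algebra and algorithms* of the pipeline, not the
epidemiology of any real year. Two further notes on test design: the
correlation-recovery property is checked with region-uniform marginals,
because region-varying means add between-region correlation on top of the
copula and would make the ±0.05 recovery bound meaningless; and test
problem sizes are n = 2,000 cohorts for distributional properties and a few
hundred for pipeline closure, sizes at which sampling error is comfortably
inside the asserted tolerances while the whole suite runs in seconds.

### The synthetic study panel

`synthetic_appendix()` builds a deterministic, RNG-free stand-in for a
published per-country panel: 190 prevalence-table countries of which 149
are scoreable and 41 are excluded at the 0.9 threshold (some via the
life-expectancy-index substitute, one exactly at the boundary), and a
136-country DALY table sharing 133 countries with the included set. Its
structure — the extremes of both indices, 18 sub-Saharan African countries
in each top-20 list, a top-20 overlap of 13, and a Spearman correlation of
0.89 between the two indices — is *designed in*, which is what makes it a
useful end-to-end oracle: the pipeline must recompute each of those
quantities from the raw tables. The 0.89 is realised constructively: for
n = 133, a Spearman correlation of ρ corresponds to a summed squared rank
displacement of $(1-\rho)\,n(n^2-1)/6 \approx 43{,}129$, which the
constructor assembles from designed head-of-list moves plus mid-list pair
swaps (a swap at rank distance g contributes 2g²), stopping within 2 units
of the target — a precision of about 5 × 10⁻⁶ on ρ. All values in the panel
are synthetic; only the structure mirrors published headline figures.

## Rendering

`render_choropleth()` draws categorical (or continuous-ramp) world maps
from user-supplied GeoJSON with an `iso3` property; no boundary geometry is
bundled, avoiding border-versioning and licensing questions, and a
six-polygon toy world ships for tests. The renderer is a small
jsonlite-based GeoJSON polygon reader plus base graphics. Excluded
countries get their own visual class, distinct from "no data" — on an
advocacy map, "we chose not to score this country" and "nobody measured
this country" are different statements. `render_letter_scatter()` draws
each country as the first letter of its name with glyph **area**
proportional to population (size ∝ √population), a seven-group regional
color scheme, and the Spearman ρ of the plotted points in the margin.
Rendering never alters data: the per-class polygon counts on a map equal
the per-class counts in the results table, and that reconciliation is
tested. Rendered rasters are not asserted byte-identical across graphics
library builds; the fixture *tables* are byte-identical under a fixed seed.

## Numerical choices and edge cases

* Scores are means of values in [0, 100]; no rounding anywhere before
  categorization or ranking.
* A missing component poisons the score (the country is dropped from the
  index and reported) — no partial averaging, which would silently change
  the estimand per country.
* The missing malaria flag is treated as non-endemic, i.e. the larger 0.60
  attribution; the flag is an input, so suppliers can be explicit.
* Correlations use pairwise-complete deletion and report n; with fewer than
  3 pairs the result is flagged undefined rather than returned.
* `compute_hhi_dbu()` treats a non-positive population as missing.

## Limitations

The package computes indices from whatever harmonized inputs it is given;
it does not re-estimate regression-based prevalences for survey-less
countries, derive DALYs from attributable fractions, or compute growth
z-scores from anthropometry — those are upstream of its contract. The
prevalence and burden indices share input data (anemia, stunting, retinol
feed both sides), so their high correlation partly reflects construction,
not only epidemiology; the same caveat applies to the published panels the
synthetic stand-in mirrors.
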