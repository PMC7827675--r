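---
title: "Methods: framework, adapters, valuation and synthetic data in safascore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: framework, adapters, valuation and synthetic data in safascore}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(safascore)
```

`safascore` implements a SAFA-style multicriteria sustainability
assessment for cattle farms: a fixed indicator hierarchy, converters from
field measurements to indicator percents, mean-based aggregation to theme
ratings, and a valuation-and-ranking summary on top. This vignette
documents the model, every tunable parameter, the numerical conventions,
and what the synthetic-data generator does and does not emulate.

## The hierarchical framework

The bundled framework (`load_framework()`) has 4 dimensions (Good
Governance, Environmental Integrity, Economic Resilience, Social
Well-Being), 21 themes, 58 subthemes and 116 indicators, with 19/52/26/19
indicators per dimension. Only the theme set and the subthemes and
indicators that play a computational role (animal welfare, biodiversity,
soil quality, and the five excludable subthemes) are bundled by name; the
remaining slots are structural placeholders (`placeholder: true`) evenly
distributed so the per-dimension counts hold. We deliberately do not
reproduce the full FAO SAFA guideline catalogue: the placeholders make
the aggregation arithmetic faithful without copying guideline content.

The config is YAML with a `format_version` header; ids are slugified
names and lookups are case-sensitive, so a framework document round-trips
exactly (`serialize_framework()` then `load_framework()` is the
identity). Validation on load checks referential integrity and the
declared per-dimension indicator counts, and fails naming the offending
id.

**Rating scale.** Percents map to five ratings. The band edges are shared
by adjacent ratings when written as ranges (60–80 / 80–100), so a
boundary convention is required: bands are lower-inclusive and
upper-exclusive, with the top band closed at 100. Thus 60 → good and
80 → best. This gives each percent exactly one rating and is consistent
with every published band pair.

**Exclusions.** `apply_exclusions()` flags subthemes that cannot be
measured; each needs a non-empty written justification.
`default_exclusions()` carries the five typical smallholder exclusions
(Stability of Production, Air Quality, Water Quality, Material Use,
Product Information), leaving 53 active subthemes. Excluded subthemes are
omitted from both the score aggregation and the accuracy totals; tests
verify they are fully inert.

## Indicator adapters

Adapters convert raw measurements into indicator percents. All outputs
are clamped to [0, 100].

**Welfare Quality (`wq_to_indicator_scores()`).** Principle scores
already lie on 0–100 and pass through unchanged: Good Feeding → Animal
Health Practices, Good Health → Animal Health, Appropriate Behavior →
Appropriate Animal Husbandry, the overall farm score → Freedom of Stress.
Humane Animal Handling Practices is defined as a combination of
criterion-level measures without a stated combiner; we use the unweighted
mean of whatever criterion scores are supplied, falling back to the
overall score when none are. The mean is the only symmetric choice that
invents no weights.

**Shannon–Wiener diversity (`shannon_index()`,
`genetic_diversity_rating()`).** H′ = −Σ pᵢ ln pᵢ over species relative
abundances, natural log. The base is not prescribed by convention
everywhere; we use ln, and since the indicator is the ratio to the cohort
maximum, the base cancels anyway. Per taxon group (birds, bats, rodents)
the maximum H′ across the farms of one assessment run is set to 100 % and
the farm's indicator percent is the unweighted mean of its group
percentages. Pooling across groups by the mean is a package decision —
whether the original groups were averaged, summed or rated separately is
not recoverable — and is isolated so other poolings can be added. The
normalisation cohort is the set of farms in the run, so the indicator is
cohort-relative by construction.

**Endemic species count (`endemic_count_to_rating()`).** 5 spp → best,
4 → good, 3 → moderate, 2 → limited, 1 → unacceptable; counts of 0 and
counts above 5 clamp to the nearest defined rating so the function is
total. Because this adapter natively produces a *rating*, not a percent,
it enters the percent aggregation as the midpoint of the rating's band
(unacceptable → 10, …, best → 90). The midpoint is the least-committal
percent consistent with the rating.

**Key species (`key_species_score()`).** The original per-species
calculation is described only in an unpublished thesis, so the score is
made explicit and configurable: each species scores
`w_endemic·endemic + w_at_risk·at_risk − w_introduced·introduced`,
floored at 0, and the farm percent is the total over `n_species · w_max`.
Defaults (`key_species_weights()`): all weights 1, `w_max = 2`. With the
defaults, a two-species table with one endemic-only and one
introduced-only species scores 25 %.

**Soil quality (`soil_indicator_percent()`).** Four indicators map to
soil properties: physical structure ← texture score and organic-matter
percentage; chemical quality ← nitrate:ammonium ratio and total organic
P; biological quality ← nitrate:ammonium ratio and total organic C;
organic matter ← total organic C. Each property is divided by its
undisturbed-reference value from the same area; since references are
stated as maxima, ratios are capped at 1 before the per-indicator mean.
(The property written "NO3–NO4 relation" in the source material is named
`no3_nh4_ratio` here — nitrate:ammonium — as the former appears to be a
typo; no chemistry depends on the name.)

## Aggregation and data quality

The combiner at every level is the unweighted arithmetic mean with
not-evaluated children omitted from numerator and denominator: indicator
percents → subtheme percent → theme percent. The upstream tooling that
performed this step originally does not document its weighting, so the
symmetric mean is the only defensible default; it is isolated behind
`subtheme_score()` / `theme_score()` so alternative combiners can be
slotted in. Ratings are derived from aggregated *percents* (never by
aggregating ordinal ratings), which preserves information and keeps
band boundaries meaningful at every level. Aggregates are bounded by
their children's range and monotone in every child; both properties are
tested against an independent recursive-mean oracle on 1000 random
hierarchies.

Each indicator score carries an accuracy tuple — timeframe
(current/outdated), data type (primary/secondary/estimate), methodology
(guideline-conform or not). A tuple earns one point per satisfied
criterion (0–3); the theme label is 1 (high) for a mean ≥ 2.5, 2 (medium)
for ≥ 1.5, else 3 (low) — thirds of the point range, since only the 1/2/3
output semantics are fixed. Adapter-computed indicators are labelled
current/primary/other (they are direct measurements but use their own
protocols rather than the assessment guidelines).

`assess_farm()` requires every theme to retain at least one evaluated
subtheme and errors otherwise, because the valuation step divides by the
full theme count (21).

## Valuation, bands and ranking

Per farm: count themes per rating; best+good counts are *positive*,
limited+unacceptable *negative*, moderate is dropped as uninformative.
Each side becomes `round(100·k/21)` — counts are summed first and the
percentage rounded once (per-class rounding would contradict several of
the published values). The rounding rule is floor for fractional parts
≤ 0.5 and ceiling above; the stated rule is silent on parts in (0.5, 0.6),
and rounding them up is the unique choice consistent with the published
value −10 % (2 of 21 themes → 9.52) and all eight published band cut
points.

Bands: the cohort's maximum valuation M on each side is divided by five;
cut points are `round_percent(k·M/5)` for k = 1…5, yielding five
contiguous integer intervals covering 0…M. For positive valuations labels
ascend toward best, for negative toward unacceptable. For M = 67 this
reproduces 0–13/14–27/28–40/41–54/55–67 and for M = 38
0–8/9–15/16–23/24–30/31–38. At very small M adjacent cut points can
coincide, leaving empty intervals; `categorize()` still assigns every
value a unique label. Bands are cohort-relative by definition
(`rank_farms(..., bands_from = "cohort")`); `bands_from = "fixed"`
substitutes a 0–100 scale for cross-study comparison.

Ranking sorts by descending positive valuation, ties broken by ascending
negative valuation; farms tied on both keep input order (stable radix
sort). No further tie-break is invented — a fully tied pair is genuinely
unordered by the procedure.

## The synthetic-data generator

`simulate_study()` generates the four raw inputs for three archetypes —
Native Silvopastoral (NS), Intensive Silvopastoral (IS), Monoculture
(MS) — with the default 3+3+3 layout mirroring a nine-farm study. All
randomness flows from one root seed with counter-based per-farm seeds, so
studies are byte-reproducible and individual farms regenerate stably.

Defaults (`archetype_profile()`), chosen once as synthetic calibration —
they are not measured values:

- *Generic indicator percents*: truncated normal on [0, 100] around a
  per-theme mean, sd 8. The theme-mean table encodes the qualitative
  archetype contrasts: NS strong on Participation (85), Land (78),
  Biodiversity (70) and Cultural Diversity (70); IS strongest on Holistic
  Management (72); every archetype weak on Atmosphere (28/22/12) and
  Water (30); MS lowest overall. An sd of 8 keeps a theme's mean over ~5
  indicators within a few points of its target, like a consistently
  filled questionnaire.
- *Captures*: per taxon group, richness ~ Poisson (NS 8, IS 6, MS 3),
  total abundance ~ Poisson (45/35/15), counts multinomial-uniform over
  species; endemic/at-risk/introduced flags Bernoulli (NS .40/.15/.05,
  IS .30/.10/.10, MS .12/.05/.25).
- *Soil*: measured = reference × Beta ratio with mean 0.85/0.70/0.45 and
  concentration 25 (moderate farm-to-farm variation); references are
  fixed per property (texture index 10, organic matter 8 %, NO3:NH4 12,
  organic P 650 mg/kg, organic C 45 g/kg).
- *Welfare Quality*: principles truncated normal, means 80/78/70, sd 6 —
  all archetypes rate good-or-best on animal welfare.

With these defaults a typical study ranks NS farms above IS above MS with
positive valuations near +57/+43/+24, inside the published per-system
ranges; across repeated seeds the NS mean positive valuation exceeds the
MS mean by ~30 points (checked as a sample-mean comparison with a wide
margin, not a significance test).

What the generator does *not* emulate: respondent-level questionnaire
microdata, capture effort and detectability (no rarefaction), spatial or
temporal structure in soil and diversity, and any correlation between
themes beyond the shared archetype mean. Passing tests therefore show the
pipeline's arithmetic and its qualitative archetype ordering are correct;
they do not validate the archetype parameters against real farms.

## Reporting

`render_polygon()` writes a deterministic SVG radar: one spoke per theme
(framework order, grouped by dimension), marker radius proportional to
rating ordinal + 1 on a 1–5 scale, rating-colored markers (best dark
green, good light green, moderate yellow, limited orange, unacceptable
red), dimension arcs (governance blue, environment green, economy yellow,
social grey), and each theme label annotated with its 1–3 data-quality
number. No timestamps are embedded, so identical assessments give
identical bytes. `export_report()` writes the ranking (CSV/JSON), the
band definitions used, and a combined per-farm theme table.

## Problem sizes and runtime

The test suite uses the full 116-indicator framework throughout; the
aggregation oracle runs 1000 random hierarchies; the archetype-recovery
check runs 200 nine-farm studies; the acceptance script averages 40
studies. A single simulate → assess → rank → plot round on nine farms
takes well under a second.

## Known limitations

- The aggregation weighting of the original SAFA Tool is undocumented;
  results here assume the unweighted mean, and indicator types
  (performance/practice/target) carry no weight.
- Key-species weighting defaults are explicit stand-ins for an
  unpublished formula; treat absolute values of that indicator as
  configuration-dependent.
- Cohort-relative normalisation (diversity, valuation bands) means a
  farm's category can change when the cohort changes; use
  `bands_from = "fixed"` when comparing across studies.
- A fully tied pair of farms has no defined order beyond input order.
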