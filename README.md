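# safascore

Multicriteria sustainability assessment of cattle farming systems with a
SAFA-style hierarchical indicator framework.

`safascore` is aimed at researchers and practitioners who assess farm
sustainability with the FAO SAFA approach (Sustainability Assessment of
Food and Agriculture systems) and want a reproducible, scriptable pipeline
instead of a spreadsheet tool: load a framework of **4 dimensions → 21
themes → 58 subthemes → 116 indicators**, score indicators on the
five-level percent scale, aggregate upward, and summarise and rank farms.
It was built around comparative studies of Native Silvopastoral (NS),
Intensive Silvopastoral (IS) and Monoculture (MS) cattle systems, and
ships a seeded synthetic-data generator for those three archetypes so the
whole pipeline runs without any field data.

## What it computes

**Rating scale.** Indicator, subtheme and theme scores are percents in
[0, 100], banded into five ratings: unacceptable [0, 20), limited
[20, 40), moderate [40, 60), good [60, 80), best [80, 100].

**Indicator adapters.** Field measurements are converted to indicator
percents:

- *Animal welfare*: Welfare Quality® principle scores (0–100) are assigned
  directly to the five animal-welfare indicators (Good Feeding → Animal
  Health Practices, Good Health → Animal Health, Appropriate Behavior →
  Appropriate Animal Husbandry, overall score → Freedom of Stress; Humane
  Animal Handling Practices takes the mean of criterion scores when
  available).
- *Wild-species diversity*: the Shannon–Wiener index
  H′ = −Σ pᵢ ln pᵢ per taxon group (birds, bats, rodents), normalised so
  the cohort maximum per group equals 100 %.
- *Endemic species*: counts map to ratings (≥5 spp best, 4 good, 3
  moderate, 2 limited, ≤1 unacceptable).
- *Key species*: a configurable weighted score over endemic / at-risk /
  introduced flags, clamped to [0, 100].
- *Soil quality*: measurements divided by undisturbed-reference maxima,
  capped at 1 and averaged per indicator.

**Aggregation.** Unweighted means at each level, with excluded subthemes
(and their accuracy contributions) omitted; each theme also carries a 1–3
data-quality label derived from timeframe / data-type / methodology
accuracy points.

**Valuation and ranking.** Per farm, themes rated best or good are
*positive*, limited or unacceptable *negative* (moderate dropped); each
side is a rounded percentage of the 21 themes. Farms are ranked by
descending positive valuation, ties broken by ascending negative
valuation. The cohort maximum M of each side defines five rating bands
with cut points `round(k·M/5)`, k = 1…5 (fractional parts > 0.5 round
up), against which the valuations are categorized.

## Worked example

```r
library(safascore)

fw     <- apply_exclusions(load_framework(), default_exclusions())
study  <- simulate_study(seed = 1, framework = fw)   # 3 NS + 3 IS + 3 MS farms
assess <- assess_study(study, fw)
rank_farms(assess)
#> # A tibble: 9 × 6
#>    rank farm_id positive_pct negative_pct positive_category negative_category
#>   <int> <chr>          <int>        <int> <ord>             <ord>
#> 1     1 NS3               62           14 best              limited
#> 2     2 NS1               57           14 best              limited
#> 3     3 NS2               57           14 best              limited
#> 4     4 IS1               43           14 good              limited
#> 5     5 IS2               43           14 good              limited
#> 6     6 IS3               38           14 good              limited
#> 7     7 M2                29           14 moderate          limited
#> 8     8 M1                24           19 limited           unacceptable
#> 9     9 M3                24           19 limited           unacceptable
```

Each row is one synthetic farm: `positive_pct` is the share of its 21
themes rated good-or-better (e.g. NS3's 62 % ≈ 13 of 21 themes),
`negative_pct` the share rated limited-or-worse, and the categories place
those shares inside the cohort-relative bands (here built from the maxima
62 and 19). The native silvopastoral farms head the list and the
monocultures trail it — the archetype contrast the generator encodes.
`render_polygon(assess$NS1, "NS1.svg", fw)` draws the 21-spoke
sustainability polygon for a farm, and `export_report(assess, dir = "out")`
writes the ranking, band definitions and per-farm theme tables.

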