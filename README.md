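# domiscore

Housing quality affects respiratory disease, injury risk, mental health and
well-being, yet "is this dwelling bad for its occupants?" is usually answered
ad hoc. The **Domiscore** is a multi-criteria instrument, modeled on the
Nutriscore food label, that rates a dwelling's impact on occupant health from
46 ordinal variables (ventilation, mold, lead, noise, natural light, pests,
fall protection, access to services, ...) grouped into 16 thematic
categories, filled in from on-site observation, mandatory diagnostics, open
public data and the occupants' reported experience. This package implements
the full scoring engine plus everything needed to exercise it at scale:
versioned grid definitions, occupant-vulnerability penalties, risk-alert
detection, a reproducible synthetic-assessment generator, and
territory-level housing-stock summaries. It is aimed at public-health and
housing practitioners, and at method developers who need a transparent
reference implementation.

## The score

Each variable *v* receives an ordinal score *s(v)* ∈ {0, 1, 2, 3}
(0 = most favorable, 3 = most unfavorable) or is left unscored with a
reason. Scoring proceeds in four steps:

1. **Vulnerability penalties.** For occupant vulnerabilities
   (young children < 4, elderly > 70, physical / visual / hearing
   disability) a rule table adds one point to specific variables whose
   pre-penalty score reaches the rule's trigger level, e.g. ventilation
   rated 3 with young children present becomes 4. Adjusted scores are not
   capped at 3.
2. **Thematic scores** (aspiration-level aggregation). Each thematic
   category *c* takes its worst scored variable:
   *T(c) = max{ s(v) : v ∈ c, v scored }*; a category with no scored
   variable is blank. Colors: 0 = green, 1 = yellow, 2 = orange, ≥ 3 = red,
   white when blank.
3. **Global score.** *G = Σ T(c)* over completed categories. If any
   category is blank, a penalty *P = Σ T(c) / #completed* (the mean
   completed thematic score) is added — missing information is presumed to
   hide a poor situation — and *G + P* is rounded half away from zero.
4. **Equivalence class.** With *n* themes the range is segmented at
   (⌊n/2⌋+1)·k for k = 1, 2, 3; for 15 themes: 0–7 green, 8–15 yellow,
   16–23 orange, ≥ 24 red (red is open-ended because penalties can exceed
   3n). Variables carrying an alert threshold additionally flag risk
   situations that must be reported to the authorities.

Assessments are anonymous by design: fields naming a person or an address
are rejected at the schema level.

## Worked example

```r
library(domiscore)
grid   <- load_grid(domiscore_grid_file("2020-11"))
matrix <- load_matrix(domiscore_matrix_file())

a <- generate_assessment(grid, quality_profile("mixed"), seed = 42)
domiscore(a, grid, matrix)
#> Domiscore (grid 2020-11, 16 themes)
#>   global score: 29  class: red
#>   completion rate: 83%
#>   profile: red red red red yellow yellow red yellow orange red yellow orange orange green green yellow
#>   ALERTS (report to authorities): mold=2, asbestos=2, lead_paint=2, drinking_water=3, gas_installation=3, fall_protection=3
```

The dwelling's 16-color profile shows *which* themes drive the risk; the
global score 29 falls at or above the red lower bound 27 = (⌊16/2⌋+1)·3, so
the dwelling is classed as exposing occupants to a high health risk, and six
variables sit at or above their reporting thresholds.

A territory is summarized by aggregating many assessments:

```r
stock   <- generate_stock(grid, stock_spec(28,
             list(quality_profile("favorable"), quality_profile("degraded")),
             seed = 1))
results <- lapply(stock, domiscore, grid = grid, matrix = matrix)
summarize_stock(results)
#> Housing-stock summary: 28 dwellings (grid 2020-11, penalty mode single_mean)
#>   classes: green=0, yellow=9, orange=2, red=17
#>   global score: mean 31.00 (SD 14.57), range 9-49
#>   completion rate: mean 91.5% (SD 4.3%)
#>   alerts flagged: 133
#>   ...per-theme color frequency table...
```

Class counts, score statistics, completion-rate statistics and the
per-theme color-frequency table together give the "picture of the quality
of housing" for the simulated territory; `render_report()` writes the same
summary as text or a static HTML page.

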