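---
title: "Scoring dwellings for health impact: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring dwellings for health impact: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(domiscore)
```

## The instrument

The Domiscore characterizes a dwelling's impact on occupant health and
well-being through a fixed grid of ordinal variables (46 in the 2020-11
version) grouped into thematic categories (16). Each variable is rated
0 (most favorable) to 3 (most unfavorable) from four information sources —
in-situ observation, legally mandated diagnostics, open public data, and
the occupants' reported experience — or left unscored with a reason when
the information cannot be obtained. Variables were chosen to depend on the
dwelling, not the occupants' behavior, and assessments carry no name or
address by construction; this package enforces that prohibition at the
schema level.

Scoring is a two-level multi-criteria aggregation:

* **Sectoral (thematic) aggregation** uses *aspiration levels*: a
  category's score is the maximum over its scored variables. The worst
  deficiency defines the theme — a single severe mold problem is not
  diluted by six unremarkable co-variables. The assumption is deliberate
  pessimism at the theme level: health risk is driven by the worst exposure,
  not the average.
* **Global aggregation** is the unweighted arithmetic sum of thematic
  scores. No weighting is applied because no defensible evidence ranks the
  themes against one another; the score therefore ranges over 0 to 3·n
  (45 for 15 themes, 48 for 16) before penalties.

Two penalty mechanisms shift scores upward:

* **Occupant vulnerability.** A rule table maps (vulnerability, variable,
  trigger level) to a one-point penalty, applied when the *pre-penalty*
  score reaches the trigger. Rules are a static table, not an iterative
  process: a rule never re-triggers off another rule's penalty, and
  distinct vulnerabilities stack independently on the same variable.
  Adjusted scores are deliberately **not capped at 3** — a variable rated 3
  with a firing rule becomes 4, a theme can exceed 3, and the red class is
  open-ended above. This is the only reading under which "downgraded by one
  point when rated 3" has any effect on the global score.
* **Missing data.** If at least one category is blank (none of its
  variables scored), the mean of the completed thematic scores is added to
  the sum. The engine's default, `penalty_mode = "single_mean"`, adds that
  mean exactly once however many categories are blank — the literal
  formula. The alternative `"mean_per_blank"` adds it once per blank
  category, which is mean-imputation of the blanks and arguably the
  intended behavior for multiply-incomplete assessments; it is exposed as
  an option and reported in all outputs, never silently applied.

The penalized sum is rounded to the nearest whole number. The rounding rule
is silent on ties; this implementation rounds **half away from zero**
(18 + 18/12 = 19.5 → 20), consistent with the penalty's own pessimism.
Ties are resolved in exact integer arithmetic (the penalty is carried as an
unreduced rational, e.g. `"18/12"`), so floating point can never flip a
boundary case.

### Classification

With *n* themes, the four classes are cut at lower bounds
(⌊n/2⌋+1)·k, k = 1, 2, 3 — "half plus one of all themes at level k". For
n = 15 this gives 8 / 16 / 24 and the published ranges 0–7 green, 8–15
yellow, 16–23 orange, ≥24 red. For the final 16-theme grid no boundaries
were ever published; this package generalizes the stated rule to 9 / 18 / 27
and flags that as an extrapolation, not a published value. The penalized,
rounded score is compared against the same boundaries — missingness changes
the score, not the cuts.

### Order of operations

Whether the missing-data penalty should see vulnerability-adjusted or raw
scores is unstated in the instrument's description. The engine applies
vulnerability adjustment first, because the penalty is defined over
thematic scores and thematic scores are defined over (adjusted) variables.
The alternative ordering would make the penalty blind to vulnerabilities
that the rest of the score accounts for. This is a documented engine
choice, not a claim about regulatory intent.

### Degenerate inputs

An assessment in which *every* category is blank is an error
("unscorable"), not a 0: an unobservable dwelling has no Domiscore, and
returning the most favorable score for it would invert the instrument's own
missing-data pessimism. Ties for a category's maximum are attributed to the
first variable in grid order (stable, reproducible provenance for the
"contributing variable" display). Scores are validated to 0–3 *before*
penalties; values outside that range in input files are rejected, never
clamped.

## The packaged grids are reconstructions

The two shipped grid fixtures reproduce every published structural fact —
47 variables / 15 categories pre-testing; 46 / 16 post-testing; nine alert
variables; "access to basic services" as variable 39 replacing "public
transportation"; pesticides split into its own variable; "ease of cleaning"
and "adequate kitchen space" removed; the urgent themes moved to the front
— but the per-variable wording is placeholder text written for this
package, and the choice of which theme was split to form the 16th category
(outdoor air pollution vs soil & hazards here) is the reconstruction's own.
The same holds for the vulnerability matrix: two rules are documented
worked examples (ventilation / young children at trigger 3; surface area /
visual disability at trigger 1) and are shipped verbatim; the remaining
rules are marked `placeholder: true` and merely make the matrix span 14
variables as described. Nothing in the engine depends on fixture content:
any grid passing the published schema loads and scores.

## The synthetic generator

No visit-level dataset exists (assessments are anonymous and unpublished),
so the generator is the package's instrument for exercising every other
module. A `quality_profile` holds: level weights over {0,1,2,3} (presets
`favorable` = .70/.20/.08/.02, `mixed` = .40/.30/.20/.10, `degraded` =
.10/.20/.30/.40 — chosen so the three presets produce clearly ordered
global-score distributions while keeping all levels reachable), a
missingness probability (default 0.09, matching the ~91% completion
observed in the instrument's 28-visit test phase, with reasons weighted
toward data unavailability as reported there), vulnerability prevalences,
and a metadata mixture whose defaults echo the test-phase sample (71%
urban, 68% collective, 32% overseas, tenure 46/32/22).

Variables are drawn independently by default. Real deficiencies cluster by
theme (a damp dwelling is likely to score poorly on mold *and* humidity),
so an optional `category_correlation` knob draws a shared latent severity
per category and tilts its variables' level weights together; it is a
modeling convenience, not an estimate of any real correlation structure.
Consequences for interpretation: under independence the thematic maximum is
stochastically larger than any single variable, so synthetic stocks skew
red faster than correlated real stocks of the same marginal quality would.
Passing tests on synthetic stocks demonstrates the engine's arithmetic,
ordering and reproducibility properties — not calibration to the French
housing stock, which the generator does not attempt.

Determinism: dwelling *i* of a stock uses the seed
`(seed · 48271 + i · 16807) mod (2^31 − 1)` — a stated, platform-stable
multiplicative hash in exact double arithmetic — so a stock of 1000 extends
a stock of 10 without reshuffling, and all draws go through R's own RNG
under a locally set (and restored) seed.

## Stock summaries and repeat-visit agreement

Territory summaries report class counts, global-score and completion-rate
statistics, the per-theme color-frequency table, and the alert total.
Standard deviations use the sample (n−1) convention — the published
descriptives name no convention, so the choice is stated in the output
(`sd_convention`) — and are `NA` for a single dwelling rather than 0.
Summaries are per *assessment* (visit): deduplicating repeat visits of one
dwelling is the caller's responsibility, since assessments are anonymous by
design and carry no dwelling key.

For repeat visits, reproducibility is reported as the exact-agreement
fraction over commonly scored variables plus signed thematic and global
deltas. No chance-corrected coefficient (e.g. weighted kappa) is computed:
any choice of disagreement weights on a 4-level ordinal scale would be
invented here, and the raw agreement plus deltas lose no information at
this sample size.

## Verification strategy and problem sizes

The engine is verified against an independent brute-force oracle (explicit
max/sum/penalty/threshold loops sharing no code with the engine) on 1,000
randomly generated small grids (2–6 categories × 1–4 variables) with random
assessments, matrices and both penalty modes; plus property suites for
monotonicity (raising any variable, or adding any vulnerability, never
lowers the global score), the penalty identity (penalty = mean of completed
thematic scores iff blanks exist), conservation (no blanks, no penalties ⇒
global = sum of maxima), and the full printed 15-theme classification table
over 0–60. Stochastic-ordering and missingness-rate checks use stocks of
500 and 1,000 dwellings under fixed seeds — sizes at which the expected
orderings separate by far more than simulation noise while the whole suite
stays fast on one core.

## Known limitations

* The fixtures are reconstructions; scores computed on them are
  structurally faithful but not legally meaningful for any real dwelling.
* The 16-theme class boundaries are an extrapolation of the published rule.
* The generator's independence default overstates thematic severity
  relative to correlated real data (see above).
* The engine flags alert situations but does not transmit reports, judge
  legal insalubrity, or model occupant behavior — all explicitly outside
  the instrument's scope.
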