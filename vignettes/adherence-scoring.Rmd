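---
title: "Scoring adherence to a psychosocial assessment schedule"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring adherence to a psychosocial assessment schedule}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carematrix)
```

## The measurement problem

Psychosocial standards of care for pediatric oncology call for *routine,
systematic* assessment of every child's psychosocial needs across the whole
cancer trajectory — not only when a crisis surfaces. Whether an institution
actually delivers that schedule is a question about longitudinal event data:
for each patient, which assessments happened, and did they fall inside the
time windows the schedule prescribes?

`carematrix` operationalizes a five-level adherence matrix over two
instruments — the social work assessment (SWA) and the provider
biopsychosocial assessment (PBA) — where level 1 means no assessment was
delivered and level 5 means the complete schedule was followed, from an
initial contact shortly after diagnosis through quarterly contacts during
treatment, an end-of-treatment contact, and annual follow-up thereafter.
Each patient receives three scores: an SWA-track level, a PBA-track level,
and a combined level that joins the two instruments' clauses.

## Records and censoring

A patient record consists of three anchor dates and an event history:

* `dx_date` — diagnosis; all windows are anchored directly or indirectly here;
* `eot_date` — end of oncologic treatment, optional (treatment may be
  ongoing); every follow-up window is anchored here;
* `censor_date` — the last date the chart was observable.

A requirement window is **assessable** when its end falls on or before the
censor date; only assessable windows impose requirements. Two refinements
keep the scores well behaved:

* *Early credit.* A window whose end postdates the censor date imposes
  nothing, but if an assessment already lies in its observed part the
  requirement counts as met. Without this, adding an event could lower a
  score.
* *No vacuous grants.* A level all of whose incremental requirements (beyond
  the level below) are non-assessable is unattainable. A patient censored six
  weeks after diagnosis can reach level 3, but not levels whose follow-up
  windows never closed.

Events before diagnosis or after censoring cannot satisfy any window and are
dropped (with a warning) at table-attach time; same-day duplicates of one
instrument collapse to a single event. The "initial" assessment of an
instrument is its earliest retained event.

## Window conventions

All windows are inclusive of both endpoints, computed on calendar dates with
no time component. Month offsets use calendar-month arithmetic with
day-of-month clamping (Jan 31 + 1 month = Feb 28/29). The defaults, shipped
as a versioned YAML rubric (`inst/extdata/rubric_uisfch_1a.yaml`) and
substitutable in every scoring function:

| window | definition | default |
|---|---|---|
| SWA initial | "within 1 month" of diagnosis | `[dx, dx + 30d]` |
| PBA initial | "within 4 weeks" of diagnosis | `[dx, dx + 28d]` |
| treatment bins | "every 3 months throughout treatment" | consecutive 3-calendar-month bins from `dx`; every complete bin needs ≥ 1 PBA; a trailing partial bin imposes nothing |
| EOT window | "± 2 months of treatment completion" | `[eot − 2m, eot + 2m]` |
| post-treatment year | "at least twice within the year following treatment (± 3 months)" | ≥ 2 PBAs in `(eot, eot + 15m]` |
| annual window *k* | "annually (12 ± 3 months)" | `[eot + 12k − 3m, eot + 12k + 3m]`, enumerated while the end is observable |

The 30-day and 28-day initial windows are deliberately distinct: the rubric
uses both phrasings, and quality-measure practice keeps "one month" and
"four weeks" apart. "Every 3 months" is interpreted as *bin coverage* rather
than a maximum-gap rule; bin coverage is order-independent and directly
auditable, while a max-gap reading is equally defensible but harder to
attribute to a specific missed contact. "Continuing for a lifetime" is
operationalized as *every assessable annual window up to the censor date*;
death or loss to follow-up is represented by the censor date.

## The ladders

Ladders are cumulative: the reported level is the highest whose full
(assessable) requirement set is met.

**SWA**: 1 no SWA; 2 any SWA after diagnosis; 3 initial SWA within one
month; 4 = 3 + an SWA in the first post-treatment-year window; 5 = 3 +
every assessable annual window covered. Level 5 additionally requires at
least *two* assessable annual windows — with only one, its requirement set
would not exceed level 4's, and "annually, for a lifetime" would be granted
vacuously.

**PBA**: 1 no PBA; 2 exactly one PBA; 3 at least two (initial plus
follow-up, any timing); 4 = 3 + the initial PBA during active treatment
(`[dx, eot]`, or the initial-contact month when no EOT is recorded); 5 = the
full schedule (initial within 4 weeks, all treatment bins, EOT window,
twice in the post-treatment year, every assessable annual window, at least
one being assessable). The published matrix defines the two ends of this
ladder precisely and describes the middle narratively; the decomposition
adopted here matches that narrative — one assessment scores near 2, initial
plus follow-up near 4, and timing failures block 5 — and is recorded as an
interpretation, since no authoritative per-instrument ladder exists.

**Combined**: the joint ladder pairs the SWA clause set of each level with
the PBA count/schedule clause of the same level: level 3 needs the one-month
SWA *and* any PBA, level 4 the level-4 SWA clauses *and* a PBA pair, level 5
both tracks at 5. Two consequences hold by construction: a combined score
above 2 is impossible without the timely initial SWA (the "gate"), and the
combined level never exceeds the better single track. Level 1 means *no
assessment of either instrument*; any retained event lifts a record to
level 2, so a patient with PBAs but no SWA scores 2, not 1.

Earlier censoring interacts with the ladders in one deliberate way: levels
1–3 are functions of the retained events alone, while levels 4–5 depend on
which follow-up windows were observable. A record followed for fewer years
is scored against fewer annual windows — that is the intended semantics of
an adherence audit under censoring, not an artifact.

## The synthetic generator

Real chart-review data of this kind are not publicly deposited, so the
package ships a generator that *inverts* the rubric: given a target track
and level, it places assessments at requirement-window midpoints (jittered
up to ±7 days, never across a window boundary) so the record scores exactly
the target, and deliberately violates one criterion of the next level,
chosen uniformly among the violations the record's shape allows. Inversion,
rather than rejection sampling, keeps rare levels cheap and makes the
round-trip property — `score(generate(track, k)) = k` — testable at scale.

Default study conditions: two cohorts of 68 (diagnosed 2017–2018) and 82
(2022–2023) patients; treatment duration uniform on 180–900 days (spanning
short solid-tumor protocols through multi-year leukemia maintenance);
censoring 30 months after treatment ends, which keeps two annual windows
assessable so every level through 5 is attainable; demographics sampled from
the published per-cohort proportions; combined-level mixtures with
expectations 2.0 and 3.0, echoing the reported cohort means (a
demonstration, not a validation claim). All randomness flows from one
integer seed, with a per-patient derived seed, so generated tables are
byte-deterministic and patients independent.

What the generator does *not* emulate: relapse and second anchors, death as
distinct from censoring, correlation between demographics and adherence,
staffing-driven clustering of missed visits, or content of the assessments.
Passing tests therefore demonstrate that the scoring engine implements the
rubric exactly and that the statistics reproduce their closed forms — not
that any real institution's adherence looks like the simulation.

## Numerical and design notes

* Dates are ISO-8601 at day resolution; ties ("initial" assessment) break to
  the earliest event; impossible calendar dates are rejected at parse time.
* The cohort comparison is the pooled (Student) two-sample t-test,
  `df = n1 + n2 − 2` — the design the published degrees of freedom imply —
  with the statistic oriented as (second cohort − first cohort)/SE and a
  one-tailed p in the requested direction. Identical cohorts give exactly
  `p = 0.5`; zero pooled variance with unequal means is flagged degenerate.
  Three tests at α = 0.05 are run without multiplicity correction,
  matching the published analysis; this is documented rather than "fixed".
* The 95% CI of a mean uses the t quantile with n − 1 df, also when
  recomputed from a printed `(mean, SD, n)` triple.
* Percentages are integers in per-cohort tables and two decimals in pooled
  summaries, following the two printing conventions; rounding happens only
  at the presentation layer.
* Ages bin by completed years (floor) into eight closed ranges; ages above
  25 fall into the top bin with a warning.

## Verification sizes

The test suite checks the engine against an independently written
literal-clause evaluator (its own month arithmetic via `lubridate`) on an
exhaustive lattice of ~11,600 small records (0–3 events per instrument at
canonical offsets, two diagnosis dates including a month-end, with and
without EOT, three censor horizons); generator round-trips run 200 seeds per
(track, level); monotonicity — no level decreases when an event is added —
runs over 10^4 random record/event pairs. These sizes were chosen so the
full suite completes in a few minutes on one CPU while covering every
clause interaction the rubric admits.

## Known limitations

* The per-instrument (SWA-only, PBA-only) ladders are one consistent reading
  of a matrix whose middle levels are defined jointly; scores on those
  tracks are interpretable relative to this package's stated ladder, not as
  a published standard.
* Only receipt and timing are scored; the content domains an assessment
  should cover are out of scope.
* Caregiver assessments and the other fourteen standards are out of scope.
* A single end-of-treatment anchor is assumed; relapse restarts of the
  schedule are not modeled.
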