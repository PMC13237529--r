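---
title: "Methods: rule-based symptom triage, episode grouping and service analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rule-based symptom triage, episode grouping and service analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oncotriage)
```

## The problem

Patients on systemic anticancer therapy (SACT) can deteriorate quickly
between scheduled contacts. Acute oncology services increasingly supplement
reactive helplines with daily electronic symptom check-ins that are triaged
automatically into red/amber/green acuity tiers, in the style of the UK
Oncology Nursing Society (UKONS) triage framework. Raw alert streams are
noisy, however: one clinical problem (say, three days of worsening
diarrhea) produces several alerts. `oncotriage` implements the computational
layer of such a service: per-check-in tiering, consolidation of amber/red
alerts into episode-level review events, the descriptive service analytics
used to evaluate such a deployment, and structured safety case-finding. A
seeded synthetic cohort generator makes the whole pipeline testable without
patient data.

## Triage model

Each daily check-in scores 11 symptoms (`symptom_names()`) on a 0–3 ordinal
scale. A `triage_policy()` holds a total map from (symptom, score) to tier.
The default map is `0,1 → GREEN`, `2 → AMBER`, `3 → RED` for every symptom.
Published deployments describe their tiering only as "UKONS-informed" and do
not print the cutpoints, so the default is a declared design choice, made
once, on two grounds: (i) a `1 → AMBER` map could not plausibly produce the
green-dominant alert mixes such services report (roughly three quarters
green), whereas `2 → AMBER` can; (ii) it keeps the map identical across
symptoms, which is the least-informed defensible choice. The map is fully
configurable per symptom and per score (monotonicity in score is enforced).

The alert tier is the maximum per-symptom tier, with one escalation rule: by
default, two or more individually-amber symptoms upgrade the alert to RED
(`multi_amber_upgrade`, threshold 2), mirroring the multi-symptom escalation
convention of the UKONS triage toolkit; it can be switched off. Guidance is
a function of tier (reassurance / monitor while awaiting review / urgent
contact), and each alert is classified against the staffed monitoring
schedule — by default Monday–Friday, 09:00–17:00, Europe/London, treated as
a half-open interval `[09:00, 17:00)` so that an alert at exactly 17:00 is
deterministically out of hours.

Tier monotonicity — raising any single score never lowers the alert tier —
is a property of the max-plus-upgrade construction and is tested by random
perturbation.

## Episode grouping

Review workload is better measured in episodes than alerts. `build_episodes()`
ignores green alerts and processes each patient's amber/red alerts in
chronological order (ties broken lexicographically by check-in id). An alert
joins an open episode when both hold:

* **window** — it falls within `episode_window_hours` (default 48, inclusive
  at the boundary) of that episode's *most recent* alert, i.e. a rolling
  window, not one anchored at the episode start;
* **continuity** — it shares at least one symptom domain (9 domains,
  `symptom_domain_names()`) with the episode's *cumulative* domain set.

Otherwise it starts a new episode, so one patient can hold concurrent open
episodes with distinct symptom patterns. Three choices here were genuinely
open and are resolved as follows:

* Continuity is evaluated against the cumulative union of member domains
  rather than only the latest alert's domains: an episode represents an
  evolving but connected symptom pattern, and the cumulative rule keeps a
  gastro episode that picks up pain connected to later pain-only alerts.
* When an alert is eligible for more than one open episode it joins the one
  with the most recent last alert (ties: larger domain intersection, then
  earlier episode start). Episodes are never merged. This makes the
  partition deterministic and auditable; operational deployments resolve
  such cases by periodic human review, which a library cannot assume.
* The window comparison is inclusive: a gap of exactly 48.0 hours joins.

The resulting partition is invariant to input row order, and on
single-domain streams it reduces exactly to classic 48-hour-gap chain
clustering, which is the brute-force oracle used in the tests.

`episode_stats()` reports the consolidation factor (alerts in / episodes
out), the per-episode size distribution and per-patient episode counts;
`attach_outcomes()` joins a review log and keeps each episode's
highest-severity action under
`none < telephone_advice < OHAU_assessment < ED_referral < admission`.

## Service analytics

All analytics are descriptive (counts, proportions, medians, ranges), with
every percentage carried alongside its numerator and denominator:

* **engagement** — distinct completed patient-days over expected
  patient-days; enrollment windows are inclusive of both endpoints and make
  no carve-out for inpatient days. Multiple same-day submissions count once
  toward engagement though each is triaged.
* **alert distribution** — per-tier counts over all triaged check-ins.
* **red burden** — per-patient red-alert counts over the full roster, with
  the zero-red and ≥10-red fractions as the skew summaries.
* **timeliness** — restricted to red alerts raised in staffed hours; first
  response per alert; same-day percentages use the service timezone's
  calendar day, never UTC; out-of-hours reds are excluded from delay
  statistics but reported as a count and proportion of all reds; unanswered
  in-hours reds stay in the same-day denominator and are reported as
  unreviewed.
* **run chart** — daily check-in counts, zero-filled across the observed
  span, with the median of daily counts as the centre line
  (`plot_run_chart()`); probability-based run-chart rules are out of scope.

Rendered percentages and medians are rounded half-up to one decimal
(`round_half_up()`), the convention of service-evaluation reporting; R's
default round-half-to-even would render 11/32 as 34.4 only by accident of
floating point and 2.25 as 2.2.

## Safety case-finding

`case_find()` screens every acute-care encounter (OHAU attendance, ED
presentation, unplanned admission) against the preceding 48 hours
(inclusive at the far edge, matching the episode window convention) of
check-ins, alerts and responses, and raises *candidates* in four predefined
categories: missed deterioration (green check-in on the encounter day, no
amber/red alert in the lookback), delayed escalation (an in-hours red whose
first response exceeded 2 hours — the configurable default; an unanswered
in-hours red is treated as the limiting case and also flagged),
inappropriate reassurance (a green-tiered check-in whose scores reach the
amber cutpoint of a reference audit policy — a constructed proxy that can
only fire when the operating policy is laxer than the reference), and
technical failure (a check-in with no alert record). Adjudication is
explicitly human: the tool never classifies harm, and an encounter with no
flags still appears in the output.

## Synthetic cohort generator

`simulate_cohort()` exists so that every operation above is testable at
realistic scale without patient data. Its defaults describe one fixed study
condition: 32 patients over 70 days, enrolled on staggered start dates over
the first 3 weeks (so expected patient-days fall short of 32×70, as in
rolling recruitment), daily adherence 0.917, a cohort alert mix of
74.9/15.8/9.3 green/amber/red, toxicity peaking at day 8 of a 21-day cycle,
a log-normal per-patient frailty (sdlog 1.2, mean fixed at 1) driving a
right-skewed red-alert burden, and first-response delays log-normal around
a 47-minute median truncated to the 12 min–6 h range (truncation shifts the
realised median by about one minute, well inside sampling noise at any
cohort size used here).

Tier emission is a two-stage construction. Stage one draws each adhered
patient-day's tier from the configured mix tilted multiplicatively by
frailty × cycle-phase weight and then *renormalised so the cohort-level
expected mix equals the configured mix exactly* (a short capped fixed-point
rescaling keeps probabilities in range without biasing the mean). Stage two
draws a score pattern consistent with the drawn tier under the default
policy: ambers get one score-2 symptom, reds get either one score-3 symptom
or two score-2 symptoms (exercising the multi-amber rule), and background
symptoms never exceed score 1. A latent-severity construction (baseline +
frailty + cycle bump, thresholded to 0–3) was considered and rejected: its
marginal tier mix moves with every variance parameter, whereas the
two-stage construction keeps the mix calibrated by construction while
preserving the frailty-driven skew and mid-cycle clustering. Severe days
reuse a per-patient dominant symptom 70% of the time, giving episodes
domain continuity.

Check-in clock times are Gaussian (mean 10:30, sd 2.5 h, truncated to
06:00–23:00), chosen so that about half of red alerts fall inside weekday
staffed hours, as observed in such services. Downstream artifacts are
generated by running the real pipeline: alerts come from `triage_checkins()`,
episodes from `build_episodes()`, the review log from per-episode
actionability probabilities (0.25 amber / 0.55 red, action mix 50/37.5/8.3/4.2
telephone/OHAU/ED/admission), escalation encounters follow escalating
reviews, and a small intraday event rate (0.0015 per green day) creates
encounters with no preceding amber/red alert so the safety rules have
something to find.

What the generator does *not* emulate: serial within-patient autocorrelation
of severe days beyond the cycle bump. Real toxicity episodes span
consecutive days, which is what drives the strong alert-to-episode
consolidation (five-to-six-fold) reported by deployed services; with
independent-given-frailty days, synthetic consolidation factors sit near
1.5–2. Passing tests on synthetic data therefore validate the engine's
correctness (partition, window, continuity, determinism), not the workload
economics of a real service — those are checked separately by feeding the
published aggregate counts through the analytics operations. Equally, the
generator is a test harness calibrated to aggregate proportions, not a
pharmacotoxicity model.

## Numerical and degenerate-input conventions

* Timestamps must carry explicit UTC offsets; everything is converted to the
  service timezone at load. Offset-less timestamps are rejected, not guessed.
* Equal-timestamp ties within a patient are broken by check-in id.
* `episode_stats()` on zero episodes and run charts on zero check-ins raise
  explicit errors rather than returning NaN.
* Zero expected patient-days and an empty roster are explicit errors.
* Seed determinism is byte-level: the same configuration writes identical
  fixture files.

## Problem sizes used in the test suite

Unit tests run on cohorts of 5–32 patients; the episode-engine oracle check
uses 1000 random single-domain streams of up to 20 alerts; parameter
recovery uses one 500-patient × 70-day cohort (≈30,000 patient-days, a few
seconds to generate), with agreement required within 3 standard errors of
the configured adherence, tier mix and delay median.

## Limitations

Beyond the generator's independence assumption above: the triage cutpoints
and the multi-amber rule are configurable defaults, not a validated clinical
algorithm; episode grouping is rule-based and deliberately conservative
(never merging); the inappropriate-reassurance screen is a policy-comparison
proxy, not a case-note review; and all analytics are descriptive — no
inferential statistics are provided by design.
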