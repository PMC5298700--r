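---
title: "Fuzzy situation inference: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fuzzy situation inference: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(situfuzz)
```

## The inference model

`situfuzz` recognises user-defined daily-routine situations from four
context channels: position, day of week, time of day and activity-class
probabilities. Each situation is a fuzzy rule whose antecedent conjoins
one condition per channel; conditions may hold several linguistic terms,
combined by fuzzy OR (maximum). The rule's degree of activation is the
*product* of the four condition truths (max-product composition). The
product was preferred over the more common minimum because it lets every
channel influence the result: a rule that is perfectly placed but whose
activity evidence is weak scores lower than one strong on all four.

Rules are evaluated *individually*, not as a shared Mamdani rule base:
each rule carries its own anchor point and activity subset, so two rules
built from identical fuzzy sets generally receive different inputs
(different distances, different probability sums). There is no rule
chaining and no defuzzification — the engine's output *is* the vector of
activations, and the "current situation" is simply the argmax set.

```{r}
plot_membership(domain = "time_of_day")
plot_membership(domain = "distance_m")
```

## Membership functions and their anchoring

The two clock-like sets that straddle a domain boundary are defined by
explicit piecewise formulas, reproduced exactly:

* **night** on x ∈ [0, 24): 0 on (3, 19], ramp (x−19)/2 on (19, 21],
  plateau 1 on (21, 24] ∪ [0, 1], ramp (3−x)/2 on (1, 3];
* **weekend** on x ∈ [0, 7) (Sunday = 0): 0 on (1.3, 5.7], ramp
  (x−5.7)/0.6 up to 6.3, plateau 1 on (6.3, 7) ∪ [0, 0.7], ramp
  (1.3−x)/0.6 down to 1.3.

Internally each is a single cyclic piecewise-linear function; evaluating
it is equivalent to taking the max of the two wrapped halves, which is how
a rule using "night" is expanded ("night1 OR night2"). The remaining
shapes are fixed by these choices:

* **weekday** is defined as 1 − weekend(x). Its full-membership plateau is
  then exactly the 1.3–5.7 interval, matching the region on which a
  weekday rule attains maximal activation.
* **dawn / morning / afternoon** are trapezoids with 2-hour ramps —
  morning ramps up over 4–6, holds 1 on [6, 12], and ramps down over
  12–14; afternoon ramps 12–14 up, holds on [14, 17], ramps 17–19 down;
  dawn ramps 1–3 up, holds on [3, 4], ramps 4–6 down. The 2-h ramps mirror
  night's printed ramps, and adjacent terms cross at 0.5, the standard
  partition-of-unity layout for linguistic scales.
* **location**: *same place* is 1 on [0, 100] m with a continuous linear
  ramp from (100, 1) to (300, 0). The published description has the ramp
  start at 101 m; we keep the function continuous at 100 m since the 1-m
  difference is far below GPS precision. *near* is 1 on [0, 800] and 0
  from 1200 m; *different* is its exact mirror. *Same place* ⊆ *near*
  pointwise, deliberately modelling "at the same place implies nearby" —
  and deliberately creating the *case of doubt* described below.
* **on activity** is the identity μ(a) = a on [0, 1]. The crisp input is
  the sum of the selected classes' normalised probabilities truncated at
  one; the identity is the simplest monotone map consistent with "a larger
  probability means the detection is more credible". Probabilities arrive
  on a 0–100 scale and are divided by 100, with no renormalisation across
  classes — the classes are not mutually exclusive (on foot generalises
  walking and running), so the raw sum may exceed 1, hence the cap.

Timestamps are reduced to minute resolution by truncation (not rounding):
seconds are treated as redundant information and removing them keeps the
time coordinates exactly on the minute grid. Altitude is likewise dropped.

## Location staleness

GPS/network fixes can be minutes old. The engine multiplies the location
condition truth by a confidence max(0, 1 − age/horizon). The linear form
and the 27-minute default horizon are package choices: the decay functional
form is otherwise unconstrained, and tying its exhaustion point to the
27-minute unavailability cutoff means a fix old enough to have zero
confidence coincides with the engine declaring inference stopped. Only
location is decayed; activity data are used as delivered, since staleness
is a location-specific failure mode (satellite visibility, network
coverage).

## The scheduler and the availability contract

Inference ticks every 3, 6 or 9 minutes and sensors are warmed 35, 45 or
60 s before retrieval, by battery tier. The tier boundaries are package
choices (battery > 0.5 high; 0.2–0.5 mid; below 0.2 low); the interval and
warm-up value sets themselves are fixed. After 27 minutes — three times
the largest interval — of continuously missing location or activity data,
the loop emits an `unavailable` event so the EMA client can switch to
fixed-time prompting; the first successful inference afterwards emits
`available`. The cutoff is a constant, not three times the *current*
interval. The loop runs on a simulated clock, sampling the latest
observation at or before each tick (context is collected once per tick,
immediately before inference); this makes every run deterministic and
testable. The client side of the contract is represented by
`ema_client_modes()`, a logging stub that tracks which prompting mode the
client would be in.

Missing context never silently evaluates to zero: `evaluate_rules()`
declines with a classed `situfuzz_suspended` condition, and the scheduler
translates persistent suspension into the availability events.

## Ties, doubt and notification status

`current_situation()` returns the full argmax set rather than an arbitrary
single rule: equal activations are a designed possibility (two rules
identical but for *same place* vs *near* tie whenever the user is within
100 m of the anchor). Defining such a twin raises a `situfuzz_doubt`
error at definition time, with an override to keep it; anchors are
compared with a 1 m tolerance to absorb float round-trips through JSON.
The doubt check is limited to the same_place/near pair — a near/different
pair cannot tie on the *near* plateau and is accepted silently.
`check_status()` resolves ties conservatively: a notification type is
allowed only if *every* tied situation allows it, minimising intrusive
prompts; when inference is suspended or no rule fires, every type reports
`unavailable`. Numeric argmax ties are detected with a 1e-9 tolerance on
the degree, well above accumulated float error in a product of four
memberships and well below any meaningful activation difference.

## The synthetic routine generator

No public context-trace corpus with situation ground truth exists, so the
package generates its own: an agent with a weekly schedule over named
places, one observation per minute. The stock `default_scenario()` spans
seven days — the duration of the field evaluation the accuracy arithmetic
mirrors — with four situations (night rest at home, weekday office work,
park exercise, a Saturday errand) whose anchors are pairwise ≥ 2 km apart.
Positions are the scheduled place plus isotropic Gaussian GPS noise
(default σ = 10 m per axis, a typical open-sky smartphone fix, giving a
Rayleigh-distributed displacement with mean σ√(π/2)); during schedule gaps
the agent moves linearly between places, emulating commutes. Activity
probabilities concentrate 0.95 of mass on the episode's classes with
Gaussian noise of 0.03; the battery discharges linearly at 4%/h from a
full overnight charge, enough to traverse all three scheduler tiers every
day. Labels derive from the schedule alone, never from the noise.

What the generator does *not* emulate: multipath/urban-canyon GPS error
(heavy-tailed, autocorrelated), activity-recogniser confusion structure
(e.g. on-foot vs walking correlation), irregular human schedules, missing
data unless injected explicitly, and any feedback of prompts on behaviour.
Passing the recovery tests therefore shows the inference pipeline is
correct and noise-robust under idealised conditions, not that field
accuracy would reach the same level.

## Accuracy scoring

A tick counts as *correct* when a situation fires and the ground-truth
label is in the argmax set, *incorrect* when a situation fires and the
label is not (including fires during unlabelled minutes — false
positives), and the headline percentage is 100·correct/(correct +
incorrect). Silent ticks are excluded from the percentage — tallied as
`correct_negative` (no label) or `missed` (labelled but silent) — because
the field protocol it mirrors could only collect confirmations of
*displayed* situations; false negatives are invisible to it. The same
ratio arithmetic drives `analyze_confirmations()`, which pools counts for
the overall figure (a weighted, not arithmetic, mean of per-participant
percentages). Displayed degrees are rounded to whole percents
(`degree_percent()`), matching how a confirmation prompt presents them.

```{r}
glance(analyze_confirmations(example_confirmation_counts()))
```

## Problem sizes and numerical choices

The self-checks evaluate membership grids at 0.01 resolution against
branch-by-branch oracles (agreement within 1e-12; piecewise-linear
interpolation between identical breakpoints is exact up to rounding), run
the noise-robustness sweep at σ ∈ {10, 200, 600, 1500} m × 20 seeds × one
simulated week each (the low-noise arm is required to recover ≥ 95% of
fired ticks and the medians must degrade monotonically), and cross-check
the vectorised engine against a naive loop-expanded evaluator on 1000
random snapshots. A full week at one observation per minute is 10,080
ticks; one simulate-plus-evaluate cycle takes on the order of a second, so
the whole sweep stays comfortably interactive. Degenerate inputs are
rejected rather than coerced: NaN coordinates, negative distances or ages,
probabilities outside their scale, overlapping episodes, unsorted traces.

## Known limitations

* The daytime trapezoids and the activity identity map are anchored to the
  published full-membership intervals but their ramp shapes are package
  choices; an engine with differently sloped ramps would differ in the
  partial-membership regions only.
* Day-of-week semantics assume the Sunday-first convention with all
  timestamps in one timezone (UTC in all examples); DST shifts and
  timezone changes are out of scope.
* The great-circle (haversine) distance stands in for planar Euclidean
  distance; at the sub-kilometre scales of the geofences the two agree to
  within centimetres.
* The transition history lives in memory with JSONL persistence; it is an
  inspectable log, not a concurrent database.
* Accuracy percentages are blind to false negatives by construction, as
  discussed above.
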