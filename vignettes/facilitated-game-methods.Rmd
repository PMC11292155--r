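---
title: "Methods: the facilitated diabetes-management game, its glucose model, and the trial statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the facilitated diabetes-management game}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(facilisim)
```

`facilisim` is a headless re-implementation of a rehearsal-based serious game
for diabetes management education, together with the gameplay analytics and
the two-arm trial statistics used to evaluate facilitation of that game.
This vignette is the package's account of the science inside it: the
simulation model and its assumptions, the parameters that matter, the design
decisions taken where the underlying game is described only behaviourally,
and what the package's tests do and do not establish.

## The game being simulated

A single player manages a community of nonplayer characters (NPCs), each
living with type 1 (T1D), type 2 (T2D), or gestational (GD) diabetes.  NPCs
work, eat, and recreate on their own schedules; the player can only
administer insulin boluses, snacks, and oral metformin.  The objective is to
keep each NPC's blood glucose within its ideal range — 5–9 mmol/L for T1D
and T2D, 5–7 mmol/L for GD, with both boundaries counting as in range.  A
game lasts 12 ticks, each tick representing one in-game hour (one real-time
minute of play in the original game).  The default population is 10 NPCs —
7 T2D, 2 T1D, 1 GD — reflecting phenotype incidence.

NPCs faint and are evacuated to hospital on severe (instantaneous) or
extended (sustained) hypo- or hyperglycemia.  In facilitated games a
facilitator checks in on tick 3 and every 2 ticks after, adjusts difficulty
by adding, removing, freezing, or unfreezing NPCs, and explains each
evacuation.  The original game is graphical and mouse-driven; this package
deliberately reimplements only the headless simulation core, with scripted
players standing in for humans, so the facilitation experiment can be run at
scale and every reported number recomputed from logs.

## The glucose–insulin model

The source game specifies its glucose behaviour only qualitatively (glucose
responds to activity intensity, meals, insulin, oral medication, and
phenotype characteristics such as insulin resistance).  The package
therefore adopts and documents its own minimal-model-style discrete system.
Per NPC, the state is plasma glucose $G$ (mmol/L), gut carbohydrate $Q$
(g), remote insulin action $X$ (dimensionless), and metformin effect
$M \in [0,1]$.  With sub-step $\Delta t$ (in-game hours):

$$
G \leftarrow G + \Delta t \Big[
  k_G G_b (1 - m\,M) - k_G G
  - \tfrac{S_I}{IR}\big(X + \sigma\, s(G)\big) G
  - a\, \text{intensity} + c_g k_{abs} Q \Big]
$$
$$
Q \leftarrow Q e^{-k_{abs}\Delta t} + \text{carbs}_{in}, \qquad
X \leftarrow X e^{-k_x \Delta t} + u_x\,\text{bolus}
$$

where $s(G) = s_{max}(G-G_b)/(K_s + G - G_b)$ for $G > G_b$ and 0 otherwise
is a saturating endogenous-secretion response, $\sigma$ the phenotype's
endogenous secretion capacity (exactly 0 for T1D), $IR \ge 1$ insulin
resistance, and $G_b$ basal glucose.  Writing endogenous production as
$k_G G_b$ against a linear clearance $k_G G$ makes $G = G_b$ an equilibrium
under zero stimuli *by construction*, and gives monotone decay of small
perturbations — both are tested properties.  Metformin suppresses
production multiplicatively ($m = 0.35$), switches on one sub-step after
dosing, and lasts 8 in-game hours.  Metformin given to a renally impaired
NPC is recorded as a contraindication error, never blocked: the game
records mistakes, it does not prevent them.

Key structural consequences, each enforced by property tests:

* **Monotone dose response.** A larger bolus never yields higher glucose at
  any later time; a larger meal never yields lower glucose.
* **Carbohydrate conservation.** $Q$ decays exponentially to below 1 % of a
  meal within $\ln(100)/k_{abs}$ hours and is never negative.
* **Discretization.** The default sub-step is 5 in-game minutes
  (12 sub-steps per tick); halving it moves end-of-game glucose by less
  than 0.1 mmol/L on a fixed action script.  The continuous counterpart of
  the system, integrated with `deSolve` at fine resolution, serves as an
  independent oracle in the tests; it never backs the implementation.

This is a game engine, not a medical-grade simulator: there is no
pharmacokinetic realism beyond first-order compartments, no delayed
exercise-induced hypoglycemia, and no circadian insulin sensitivity.

### Default physiology and why

Per-phenotype physiology is sampled per NPC.  Basal glucose is drawn at
uncontrolled-diabetes levels (T2D: normal(10.5, 1.3) truncated to 8–14
mmol/L; T1D: normal(11, 1.5) truncated to 7–16; GD: normal(6.8, 0.8)
truncated to 5–9), so an unmanaged T1D/T2D NPC sits above its ideal range
and drifts toward the sustained-hyperglycemia faint threshold — the game's
central pressure.  Insulin sensitivity ($S_I$ 0.06–0.15 per unit-hour),
insulin resistance (up to 3 for T2D), carbohydrate absorption
($k_{abs} \approx 1\,h^{-1}$), insulin action decay
($k_x \approx 0.5\,h^{-1}$), and glucose effectiveness
($k_G = 0.15\,h^{-1}$) are set so that one insulin unit lowers glucose by
roughly 1 mmol/L and a 60 g uncovered meal produces a multi-hour excursion
of 5–7 mmol/L.  Renal impairment affects 30 % of generated NPCs, making
contraindicated metformin a live hazard with 7 T2D NPCs in play.  All
constants live in one documented table (`generate_npc(..., dynamics =)`)
and are configurable; the defaults were fixed once, before the acceptance
experiments were run, and define the package's study conditions.

### Safety thresholds

The game states only that "extended or severe" excursions cause fainting.
The package uses clinically conventional defaults: severe bounds 3.0 and
20.0 mmol/L acting on the latest sample, extended bounds 3.9 and 13.9
mmol/L sustained for 3 consecutive hours.  Each post-initial trace sample
represents one sub-step interval, so a trailing run of $k$ out-of-bound
samples spans $k\Delta t$ hours; the faint fires exactly when that reaches
3 h, which makes "3 h constant excursion faints, 3 h minus one sub-step
does not" sharp, and matches the interval convention used by the
time-in-range analytics.

## Scheduling, ordering, and determinism

Each NPC draws a random schedule with meals at ticks 1, 5, 9 (about 60 g
each), an optional snack, and work/recreation/rest with intensities in
[0, 1] elsewhere.  Within a tick the order is fixed: facilitator requests,
then player actions, then dynamics sub-steps with safety evaluated after
each — so facilitator relief is never pre-empted by a faint in the same
tick.  Actions targeting evacuated NPCs are rejected with a logged warning;
the same policy is applied to frozen NPCs, since a frozen trace "need not
be managed" and silently accumulating state behind a flat trace would be
invisible to the player.  Evacuation is permanent; facilitator removal is a
distinct, non-evacuation exit.

All randomness fans out from one base seed through derived per-purpose
seeds (NPC generation, policy noise, moderation draws).  Two consequences
are tested: identical seeds give byte-identical event logs, and a log's
recorded actions replayed against the same seed reproduce the identical
final world without re-running the stochastic policies (log sufficiency).

## Scripted players and the facilitator

Human players are replaced by a heuristic threshold policy with a skill
parameter in [0, 1].  Skill lowers the dosing-error probability
($0.4(1-\text{skill})$, errors multiply or divide a dose by 2.5) and raises
the attention budget ($2 + \text{round}(4\,\text{skill})$ NPCs per tick).
The policy treats the NPCs furthest outside their range first: corrective
boluses above range, snacks below; T2D NPCs above range may get metformin,
and with probability equal to skill the player first checks the clinical
history and withholds it from renally impaired NPCs.  The policy is
deliberately not optimal control — its purpose is to exercise the
simulator, not to model students.  Across 200 seeds per level, mean
evacuations are non-increasing in skill (an acceptance property with a
one-sided tolerance of 0.05 evacuations).

Check-in feedback is synthesised deterministically: overwhelmed when more
NPCs are out of range than the attention budget, under-challenged when all
are in range and the population has shrunk, comfortable otherwise.  The
moderation rule table maps overwhelmed to freezing the worst-off active
NPC (freezing is preferred to removal), comfortable to no action, and
under-challenged to unfreezing the longest-frozen NPC or adding one with a
7:2:1 phenotype draw.  Evacuation explanations attribute hypoglycemic
faints to the largest bolus in a 3 h lookback window (the window is one
hour wider than the motivating "2 hours ago" example, to cover it with
margin), hyperglycemic faints to the largest uncovered meal, ties broken
toward recency, with "unmanaged" as the fallback.  The facilitator's other
verbal behaviours (answering control questions, withholding knowledge
unless asked) have no game-state consequences and are out of scope.

## Analytics

Three per-game outcomes mirror the trial's gameplay measures: mean hours
in ideal range (per-NPC time in range averaged over *every NPC ever
active*, with evacuated and removed NPCs contributing hours accrued before
exit and frozen intervals counting iff the frozen value is in range),
distinct NPCs given contraindicated metformin (per-NPC, not per-dose), and
evacuations (faint events; removals never count).  The event log carries
per-tick trace segments, so all three are recomputable from the serialized
log alone; equality of log-recomputed and in-memory metrics is a tested
invariant.

## Trial statistics

The statistics layer reproduces the trial's complete quantitative analysis
plan.  The Flow Short Scale (FSS) has 13 items on a 1–7 scale; overall flow
is the mean of items 1–10, which split 6/4 into fluency and absorption,
with items 11–13 measuring perceived importance.  The instrument's
item-to-subscale mapping is licensed content and not printed with the
trial; the default mapping (`fss_mapping()`) assigns the first six of
items 1–10 to fluency and is configurable.  The 6/4 split is corroborated
by the weighted-mean identity
$\text{flow} = (6\,\text{fluency} + 4\,\text{absorption})/10$, which
recovers the trial's printed overall-flow group means (4.4 control, 4.95
intervention) exactly from its printed subscale means.

`t_from_summary()` implements the pooled and Welch two-sample t tests
directly from (n, mean, SD) triples — sample SDs throughout, statistics
signed as control minus intervention — and `reproduce_trial_table()` applies it
to the built-in printed summaries (n = 26 and 22, df = 46).  Six of the
seven recomputed t statistics and all four Cohen's d values round to the
printed values; the overall-flow row computes −2.177, one final-digit unit
from the printed −2.17, because the printed means and SDs are themselves
rounded.  The acceptance tests therefore assert agreement within one unit
in the last printed digit, and `reproduce_trial_table()` reports |t| alongside
the signed statistic to absorb a sign inconsistency in the source table's
hours row.  `t_from_raw()` wraps `stats::t.test()` and is held to agree
with the summary route to 1e−12 relative — a genuine dual-route check.

The Mann-Whitney U test (the plan's fallback for non-normal data) is
implemented with exact enumeration over all $\binom{n+m}{n}$ labelings for
combined samples up to 12 — exact in the presence of ties, which
`stats::wilcox.test()` does not offer — and a tie-corrected normal
approximation beyond that.  Normality screening uses Shapiro-Wilk at
$\alpha = 0.05$ and the variance-equality gate an F test, both standard
choices the trial's plan names only generically.  Under a null simulation
at the trial's group sizes (20,000 replicates), the pooled t test's
empirical type-I error must land in [0.04, 0.06].

The power calculation (`sample_size_two_means()`) uses the planning inputs
$\alpha = 0.05$, power 0.90, means 4 vs 5.05, SD 1.  The closed-form
normal approximation gives 20 per group and the noncentral-t iteration
(via `stats::power.t.test()`) gives 21.  The trial reports an estimate of
22 per group from an external calculator; that figure is not reproducible
from the stated inputs (the calculator's internal adjustment is unstated),
so the operation reports the computed values and does not treat 22 as a
target.

## What the simulation does and does not show

The scripted-player experiment reproduces the *mechanics* of the trial —
check-in schedule, moderation, evacuation attribution, outcome analytics,
and the full statistical pipeline — and directional gameplay effects
(lower skill and absent facilitation both increase evacuations at matched
skill).  It does not and cannot reproduce the trial's human outcome, the
facilitated arm's higher flow: flow is a human self-report, and no model
of FSS responses from gameplay is attempted.  The synthetic FSS generator
(`simulate_fss_responses()`) exists to exercise the raw-data analysis
path, not to emulate psychometrics: it has a single latent factor,
independent item noise, and no reverse-scored or differentially
discriminating items.  Simulated arm-mean comparisons at small
`games_per_arm` are correspondingly noisy.

## Problem sizes

The shipped test-and-acceptance configuration uses full 12-tick games with
12 sub-steps per tick and 10 NPCs; 200 seeds per skill level for the
skill-monotonicity property; 20,000 replicates for the type-I error band;
exhaustive enumeration up to combined n = 10 for the Mann-Whitney oracle;
and 40 games per arm in the demonstration experiment.  These sizes give
stable stochastic bands while keeping a full run to a few minutes on one
core.

## Worked example

```{r example, eval = FALSE}
res <- run_game(game_config(), player_policy(skill = 0.6),
                facilitated = TRUE, seed = 42)
res$metrics
trial_tab <- reproduce_trial_table()
round(trial_tab$t, 2)
```

## Known limitations

* Glucose dynamics are first-order and phenomenological; parameter values
  are game-balance choices in physiologically plausible ranges, not fitted
  to patient data.
* The scripted player is reactive and threshold-based; it never
  anticipates meals or stacks corrections the way humans (mis)do.
* Facilitator behaviour is reduced to its game-state-changing actions; all
  dialogue except evacuation explanations is out of scope.
* One facilitator request per check-in; the cap on added NPCs
  (`max_npcs = 15`) has no empirical anchor and is configurable.
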