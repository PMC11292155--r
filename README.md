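# facilisim

Serious games are increasingly used to let health-professions students
rehearse clinical decision-making, and *facilitation* — a human moderator
who tunes difficulty in real time — is hypothesised to keep players in
flow, the absorbed state where learning games work best.  `facilisim` is a
headless R implementation of one such game and its evaluation trial: an
agent-based community of nonplayer characters (NPCs) living with type 1,
type 2, or gestational diabetes, managed by a (scripted) player under an
embedded facilitator protocol, together with the gameplay analytics and
the two-arm trial statistics.  It is aimed at researchers in simulation-
based medical education who want to run facilitated-vs-unfacilitated
experiments in silico, and at anyone auditing the arithmetic of the
associated trial.

## What is inside

**Simulation.** Each NPC carries sampled physiology and follows the
discrete glucose–insulin system

> G ← G + Δt·[ k_G·G_b·(1 − m·M) − k_G·G − (S_I/IR)·(X + σ·s(G))·G −
> a·intensity + c_g·k_abs·Q ],  Q ← Q·e^(−k_abs·Δt) + carbs,
> X ← X·e^(−k_x·Δt) + u_x·bolus

with glucose G (mmol/L), gut carbohydrate Q (g), insulin action X, and
metformin effect M; type 1 NPCs have zero endogenous secretion (σ = 0).
Games run 12 ticks (1 tick = 1 in-game hour, 12 five-minute sub-steps)
with 10 NPCs (7 T2D, 2 T1D, 1 GD) by default.  NPCs faint and are
evacuated on severe (< 3.0 or > 20.0 mmol/L) or sustained (beyond
3.9–13.9 mmol/L for 3 h) excursions.  Facilitated games check in at ticks
3, 5, 7, 9, 11 and moderate difficulty by adding, removing, freezing, or
unfreezing NPCs, and explain every evacuation, e.g.:

```
npc9 fainted from hypoglycemia after too much bolus insulin (15 units)
2.2 hours earlier and was evacuated.
```

**Analytics.** Hours in ideal glycaemic range (5–9 mmol/L for T1D/T2D,
5–7 for GD), distinct NPCs given contraindicated metformin, and
evacuations — all recomputable from the JSONL event log alone.

**Trial statistics.** Flow Short Scale scoring (13 items, 1–7;
flow = mean of items 1–10 = (6·fluency + 4·absorption)/10), pooled and
Welch two-sample t tests from raw data or printed (n, mean, SD)
summaries, Cohen's d = |m₁ − m₂|/s_p, Mann-Whitney U with exact
enumeration for small samples (ties included), Shapiro-Wilk-gated test
selection, and two-means sample-size calculations via the noncentral-t
power function.

## Worked example

```r
library(facilisim)

res <- run_game(game_config(), player_policy(skill = 0.6),
                facilitated = TRUE, seed = 42)
res$metrics
#> Game metrics: mean hours in ideal range 3.31, metformin errors 0,
#>   evacuations 0 (10 NPCs)
```

A mid-skill facilitated player kept the ten NPCs in their ideal ranges for
3.31 of 12 in-game hours on average, gave no contraindicated metformin,
and lost nobody to hospital.  The trial-table reproduction recomputes
every between-arm statistic from the published group summaries
(control n = 26, intervention n = 22, pooled df = 46):

```r
round(reproduce_trial_table()[, c("t", "df", "p_two_sided", "cohens_d")], 3)
#>        t df p_two_sided cohens_d
#> 1 -2.177 46       0.035    0.631   # overall flow
#> 2 -1.516 46       0.136    0.439   # fluency
#> 3 -2.604 46       0.012    0.754   # absorption
#> 4 -0.197 46       0.845    0.057   # importance
#> 5  0.860 46       0.394       NA   # hours in ideal range
#> 6  0.077 46       0.939       NA   # metformin errors
#> 7  2.070 46       0.044       NA   # evacuations
```

Negative t favours the facilitated arm (statistics are control minus
intervention): facilitated players reported higher overall flow (t = −2.18,
d = 0.63), driven by absorption (t = −2.60, d = 0.75), and suffered about
one fewer evacuation per game (t = 2.07).  The power-analysis inputs
(α = 0.05, power 0.90, means 4 vs 5.05, SD 1) give 20 per group by the
normal approximation and 21 by the noncentral-t calculation:

```r
sample_size_two_means(0.05, 0.90, 4, 5.05, 1)
#> $n_per_group     [1] 21
#> $n_normal_approx [1] 20
```

A command-line driver with `simulate`, `experiment`, `metrics`, `stats`,
and `trial-table` subcommands ships at `inst/cli/facilisim.R`:

```sh
Rscript inst/cli/facilisim.R simulate --seed 3 --skill 0.6 --out game_out
Rscript inst/cli/facilisim.R metrics --log game_out/events.jsonl
Rscript inst/cli/facilisim.R trial-table
```

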