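Package: facilisim
Title: Facilitated Diabetes-Management Serious Game: Simulation, Analytics
    and Trial Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A headless re-implementation of a rehearsal-based diabetes
    management serious game for health-professions education.  Simulates a
    community of nonplayer characters (NPCs) with type 1, type 2, or
    gestational diabetes under a discrete glucose-insulin model; scripted
    players of parameterised skill administer insulin, snacks, and oral
    medication while an embedded facilitator moderates difficulty through
    scheduled check-ins (adding, removing, freezing NPCs) and explains
    evacuations.  Computes the gameplay outcomes (hours in ideal glycaemic
    range, contraindicated-metformin errors, evacuations), scores the Flow
    Short Scale, and provides the full quantitative analysis plan of the
    associated two-arm trial: pooled and Welch two-sample t tests from raw
    data or printed summaries, Cohen's d, Mann-Whitney U with exact
    enumeration for small samples, and two-means sample-size calculations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
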