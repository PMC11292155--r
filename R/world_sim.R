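#' Diabetes phenotypes and their ideal glucose ranges
#'
#' Ideal blood glucose is 5--9 mmol/L for type 1 and type 2 diabetes and
#' 5--7 mmol/L for gestational diabetes; both interval boundaries count as
#' in range.
#'
#' @param label one of `"T1D"`, `"T2D"`, `"GD"`.
#' @return a list with `label` and `ideal_range` (closed interval, mmol/L).
#' @export
phenotype <- function(label) {
  label <- match.arg(label, c("T1D", "T2D", "GD"))
  range <- if (label == "GD") c(5, 7) else c(5, 9)
  list(label = label, ideal_range = range)
}

#' Game configuration
#'
#' The default game runs 12 ticks (1 tick = 1 in-game hour, standing for 1
#' real-time minute of play), each subdivided into 12 five-minute sub-steps
#' for the dynamics, with a starting population of 10 NPCs: 7 type 2, 2
#' type 1, and 1 gestational, reflecting phenotype incidence.
#'
#' @param duration_ticks game length in ticks (>= 1).
#' @param substeps_per_tick dynamics sub-steps per tick.
#' @param phenotype_counts named integer vector over T2D/T1D/GD.
#' @param renal_impairment_prevalence probability that a generated NPC has
#'   compromised renal function (metformin contraindication).
#' @param safety a [safety_rules()].
#' @param max_npcs cap on total NPCs including facilitator additions.
#' @return an object of class `game_config`.
#' @export
game_config <- function(duration_ticks = 12L,
                        substeps_per_tick = 12L,
                        phenotype_counts = c(T2D = 7L, T1D = 2L, GD = 1L),
                        renal_impairment_prevalence = 0.3,
                        safety = safety_rules(),
                        max_npcs = 15L) {
  duration_ticks <- as.integer(duration_ticks)
  substeps_per_tick <- as.integer(substeps_per_tick)
  if (is.na(duration_ticks) || duration_ticks < 1L)
    stop("duration_ticks must be a positive integer", call. = FALSE)
  if (is.na(substeps_per_tick) || substeps_per_tick < 1L)
    stop("substeps_per_tick must be a positive integer", call. = FALSE)
  pc <- phenotype_counts
  if (is.null(names(pc)) || !all(names(pc) %in% c("T1D", "T2D", "GD")) ||
      any(is.na(pc)) || any(pc < 0))
    stop("phenotype_counts must be non-negative and named by T1D/T2D/GD",
         call. = FALSE)
  for (lab in c("T2D", "T1D", "GD")) if (!lab %in% names(pc)) pc[lab] <- 0L
  pc <- as.integer(pc[c("T2D", "T1D", "GD")])
  names(pc) <- c("T2D", "T1D", "GD")
  if (renal_impairment_prevalence < 0 || renal_impairment_prevalence > 1)
    stop("renal_impairment_prevalence must lie in [0, 1]", call. = FALSE)
  structure(list(duration_ticks = duration_ticks,
                 substeps_per_tick = substeps_per_tick,
                 phenotype_counts = pc,
                 renal_impairment_prevalence = renal_impairment_prevalence,
                 safety = safety,
                 max_npcs = as.integer(max_npcs)),
            class = "game_config")
}

# Shared dynamics constants, merged into every sampled physiology.  All
# configurable through generate_npc(..., dynamics = ...).
dynamics_defaults <- function() {
  list(glucose_clearance = 0.15,    # per hour; basal relaxation (glucose effectiveness)
       carb_to_glucose = 0.12,      # mmol/L rise per gram absorbed
       bolus_to_action = 1.0,       # X increment per insulin unit
       secretion_max = 2.0,         # saturating endogenous response ceiling
       secretion_halfsat = 3.0,     # mmol/L above basal at half saturation
       metformin_suppression = 0.35,
       metformin_duration_hours = 8)
}

# Per-phenotype sampling distributions for physiology.  Basal glucose sits
# at or above the upper ideal bound for T1D/T2D so an unmanaged game drifts
# hyperglycemic; GD starts inside its tighter target.
sample_physiology <- function(label, prevalence, dynamics = dynamics_defaults()) {
  p <- switch(label,
    T1D = list(basal_glucose = rnorm_trunc(11, 1.5, 7, 16),
               insulin_sensitivity = runif(1, 0.09, 0.15),
               endogenous_secretion = 0,
               insulin_resistance = 1,
               carb_absorption_rate = runif(1, 0.9, 1.1),
               insulin_action_decay = runif(1, 0.4, 0.6),
               activity_uptake_rate = runif(1, 0.5, 1.5)),
    T2D = list(basal_glucose = rnorm_trunc(10.5, 1.3, 8, 14),
               insulin_sensitivity = runif(1, 0.06, 0.12),
               endogenous_secretion = runif(1, 0.3, 0.7),
               insulin_resistance = runif(1, 1.5, 3),
               carb_absorption_rate = runif(1, 0.9, 1.1),
               insulin_action_decay = runif(1, 0.4, 0.6),
               activity_uptake_rate = runif(1, 0.5, 1.5)),
    GD  = list(basal_glucose = rnorm_trunc(6.8, 0.8, 5, 9),
               insulin_sensitivity = runif(1, 0.08, 0.13),
               endogenous_secretion = runif(1, 0.5, 0.9),
               insulin_resistance = runif(1, 1.2, 2),
               carb_absorption_rate = runif(1, 0.9, 1.1),
               insulin_action_decay = runif(1, 0.4, 0.6),
               activity_uptake_rate = runif(1, 0.5, 1.5)))
  p$renal_impaired <- runif(1) < prevalence
  c(p, dynamics)
}

rnorm_trunc <- function(mean, sd, lo, hi) {
  x <- rnorm(1, mean, sd)
  min(max(x, lo), hi)
}

# Random per-NPC activity schedule: meals at three fixed tick offsets (ticks
# 1, 5, 9 when the game is long enough), an optional snack, and
# work/recreation/rest elsewhere.  Returns a data.frame with one row per
# tick: activity, carbs (g), intensity [0,1].
make_schedule <- function(duration_ticks) {
  activity <- character(duration_ticks)
  carbs <- numeric(duration_ticks)
  intensity <- numeric(duration_ticks)
  meal_ticks <- c(1L, 5L, 9L)
  meal_ticks <- meal_ticks[meal_ticks <= duration_ticks]
  for (t in seq_len(duration_ticks)) {
    if (t %in% meal_ticks) {
      activity[t] <- "meal"
      carbs[t] <- round(rnorm_trunc(60, 15, 20, 100))
      intensity[t] <- 0.1
    } else {
      a <- sample(c("work", "recreation", "rest"), 1,
                  prob = c(0.5, 0.3, 0.2))
      activity[t] <- a
      intensity[t] <- switch(a, work = 0.3,
                             recreation = runif(1, 0.4, 0.9), rest = 0.05)
    }
  }
  # optional snack on a non-meal tick
  open <- setdiff(seq_len(duration_ticks), meal_ticks)
  if (length(open) > 0 && runif(1) < 0.4) {
    s <- if (length(open) == 1L) open else sample(open, 1)
    carbs[s] <- round(runif(1, 10, 25))
  }
  data.frame(tick = seq_len(duration_ticks), activity = activity,
             carbs = carbs, intensity = intensity)
}

#' Generate one NPC
#'
#' Samples physiology from the phenotype's configured distributions (type 1
#' NPCs have zero endogenous insulin secretion), draws an activity schedule,
#' and synthesises a short clinical-history text from the sampled
#' parameters.  Uses the current RNG state; callers wanting reproducibility
#' should wrap the call in [withr::with_seed()] (as [init_world()] does).
#'
#' @param label phenotype label, one of `"T1D"`, `"T2D"`, `"GD"`.
#' @param config a [game_config()].
#' @param id stable NPC identifier.
#' @param dynamics shared dynamics constants; see the methods vignette.
#' @return an object of class `npc`.
#' @export
generate_npc <- function(label, config = game_config(), id = "npc1",
                         dynamics = dynamics_defaults()) {
  ph <- phenotype(label)
  phys <- sample_physiology(ph$label, config$renal_impairment_prevalence,
                            dynamics)
  stopifnot(phys$endogenous_secretion >= 0, phys$insulin_resistance >= 1,
            phys$carb_absorption_rate > 0, phys$insulin_action_decay > 0,
            phys$activity_uptake_rate > 0)
  sched <- make_schedule(config$duration_ticks)
  hist_txt <- sprintf(
    "%s: %s diabetes; baseline glucose %.1f mmol/L; renal function %s.%s",
    id, switch(ph$label, T1D = "type 1", T2D = "type 2", GD = "gestational"),
    phys$basal_glucose,
    if (phys$renal_impaired) "impaired (metformin contraindicated)" else "normal",
    if (ph$label == "T1D") " No endogenous insulin secretion." else "")
  structure(list(id = id,
                 phenotype = ph,
                 physiology = phys,
                 schedule = sched,
                 state = glucose_state(phys$basal_glucose),
                 trace = glucose_trace(phys$basal_glucose,
                                       1 / config$substeps_per_tick),
                 status = "active",
                 start_tick = 0L,
                 frozen_at = NA_integer_,
                 clinical_history = hist_txt,
                 action_history = list()),
            class = "npc")
}

# Deterministic derived seeds: one base seed fans out into independent
# streams (NPC generation, policy noise, moderation draws) so that replaying
# logged actions reproduces the same world without re-running the policy.
derive_seed <- function(base, stream, k) {
  ((as.numeric(base) %% 2147483647) * 65537 + stream * 257 + k) %% 2147483647
}

npc_distance_from_range <- function(npc) {
  g <- tail_value(npc$trace)
  r <- npc$phenotype$ideal_range
  max(0, r[1] - g, g - r[2])
}

tail_value <- function(trace) trace$values[length(trace$values)]

log_event <- function(world, kind, tick, substep, npc_id = NULL,
                      payload = list()) {
  world$n_events <- world$n_events + 1L
  world$log[[world$n_events]] <- list(
    seq = world$n_events, tick = as.integer(tick),
    substep = as.integer(substep), kind = kind,
    npc_id = npc_id, payload = payload)
  world
}

#' Initialise a game world
#'
#' Creates the NPC population from the configured phenotype composition
#' (default 10 NPCs: 7 T2D, 2 T1D, 1 GD), sets the clock to tick 0, and logs
#' a single game-start event carrying the roster.  Fully reproducible from
#' the seed: NPC generation runs under per-NPC seeds derived from `seed`.
#'
#' @param config a [game_config()].
#' @param seed integer base seed.
#' @return an object of class `game_world`.
#' @export
init_world <- function(config = game_config(), seed = 1L) {
  stopifnot(inherits(config, "game_config"))
  counts <- config$phenotype_counts
  labels <- rep(names(counts), times = counts)
  npcs <- list()
  for (i in seq_along(labels)) {
    id <- paste0("npc", i)
    npcs[[id]] <- withr::with_seed(
      derive_seed(seed, 1, i),
      generate_npc(labels[i], config, id))
  }
  world <- structure(list(config = config, base_seed = as.integer(seed),
                          tick = 0L, npcs = npcs, log = list(),
                          n_events = 0L, npc_counter = length(labels),
                          game_over = FALSE),
                     class = "game_world")
  roster <- lapply(npcs, function(n) list(
    id = n$id, phenotype = n$phenotype$label,
    ideal_range = n$phenotype$ideal_range,
    initial_glucose = n$state$G))
  log_event(world, "game_start", 0L, 0L, payload = list(
    duration_ticks = config$duration_ticks,
    substeps_per_tick = config$substeps_per_tick,
    phenotype_counts = as.list(config$phenotype_counts),
    seed = as.integer(seed),
    roster = unname(roster)))
}

# status helpers
npc_ids_with_status <- function(world, statuses) {
  names(world$npcs)[vapply(world$npcs, function(n) n$status %in% statuses,
                           logical(1))]
}

#' Advance the world by one tick
#'
#' Order of operations within a tick: facilitator requests first, then
#' player actions, then the glucose dynamics stepped for every active NPC
#' across all sub-steps with the safety rule evaluated after each sub-step.
#' Frozen NPCs' traces are extended flat; evacuated and removed NPCs receive
#' no further samples.  Actions targeting evacuated (or frozen, or missing)
#' NPCs are rejected with a logged warning event rather than an error.
#'
#' @param world a `game_world`.
#' @param player_actions list of [player_action()].
#' @param facilitator_requests list of [facilitator_request()].
#' @return list with elements `world` (advanced) and `events` (the events
#'   appended by this call, in order).
#' @export
advance_tick <- function(world, player_actions = list(),
                         facilitator_requests = list()) {
  cfg <- world$config
  if (world$tick >= cfg$duration_ticks)
    stop("game is over: tick == duration_ticks", call. = FALSE)
  first_new <- world$n_events + 1L
  t <- world$tick
  S <- cfg$substeps_per_tick
  dt <- 1 / S

  for (req in facilitator_requests)
    world <- apply_request(world, req)

  for (act in player_actions) {
    npc <- world$npcs[[act$npc_id]]
    if (is.null(npc) || npc$status %in% c("evacuated", "removed", "frozen")) {
      reason <- if (is.null(npc)) "unknown NPC" else paste(npc$status, "NPC")
      world <- log_event(world, "warning", t, 0L, npc_id = act$npc_id,
                         payload = list(message = paste("action rejected:",
                                                        reason),
                                        kind = act$kind, dose = act$dose))
      next
    }
    res <- apply_action(npc$state, npc$physiology, act)
    npc$state <- res$state
    npc$action_history[[length(npc$action_history) + 1L]] <-
      list(tick = t, kind = act$kind, dose = act$dose,
           contraindicated = res$contraindicated)
    world$npcs[[act$npc_id]] <- npc
    world <- log_event(world, "action", t, 0L, npc_id = act$npc_id,
                       payload = list(kind = act$kind, dose = act$dose,
                                      contraindicated = res$contraindicated))
  }

  new_values <- lapply(world$npcs, function(n) numeric(0))
  sched_now <- lapply(world$npcs, function(n)
    list(carbs = n$schedule$carbs[t + 1L],
         intensity = n$schedule$intensity[t + 1L],
         activity = n$schedule$activity[t + 1L]))
  for (s in seq_len(S)) {
    for (id in names(world$npcs)) {
      npc <- world$npcs[[id]]
      if (npc$status == "active") {
        row <- sched_now[[id]]
        carbs <- if (s == 1L) row$carbs else 0
        if (s == 1L && carbs > 0) {
          world <- log_event(world, "meal", t, s, npc_id = id,
                             payload = list(grams = carbs,
                                            activity = row$activity))
        }
        npc$state <- step_glucose(npc$state, npc$physiology,
                                  stimuli(activity_intensity = row$intensity,
                                          carbs_in = carbs), dt)
        npc$trace$values <- c(npc$trace$values, npc$state$G)
        new_values[[id]] <- c(new_values[[id]], npc$state$G)
        status <- evaluate_safety(npc$trace, cfg$safety)
        if (status != "ok") {
          npc$status <- "evacuated"
          world$npcs[[id]] <- npc
          world <- log_event(world, "faint", t, s, npc_id = id,
                             payload = list(
                               direction = if (status == "faint_hypo")
                                 "hypo" else "hyper",
                               glucose = npc$state$G))
          next
        }
        world$npcs[[id]] <- npc
      } else if (npc$status == "frozen") {
        last <- tail_value(npc$trace)
        npc$trace$values <- c(npc$trace$values, last)
        new_values[[id]] <- c(new_values[[id]], last)
        world$npcs[[id]] <- npc
      }
    }
  }

  for (id in names(new_values)) {
    if (length(new_values[[id]]) > 0)
      world <- log_event(world, "trace", t, S, npc_id = id,
                         payload = list(values = new_values[[id]]))
  }

  world$tick <- t + 1L
  world <- log_event(world, "tick", world$tick, 0L)
  if (world$tick == cfg$duration_ticks) {
    world$game_over <- TRUE
    world <- log_event(world, "game_over", world$tick, 0L)
  }
  list(world = world,
       events = world$log[seq(first_new, world$n_events)])
}

#' Serialize a world snapshot to JSON
#'
#' Deterministic serialization of the full world state (clock, NPC registry
#' with physiology, schedules, traces, statuses, and the event log) for
#' replay and regression tests: identical worlds give byte-identical JSON.
#'
#' @param world a `game_world`.
#' @param include_log include the event log in the snapshot.
#' @return a JSON string.
#' @export
world_to_json <- function(world, include_log = TRUE) {
  snap <- list(tick = world$tick,
               base_seed = world$base_seed,
               npc_counter = world$npc_counter,
               game_over = world$game_over,
               config = unclass_deep(world$config),
               npcs = lapply(unname(world$npcs), unclass_deep))
  if (include_log) snap$log <- world$log
  as.character(jsonlite::toJSON(snap, auto_unbox = TRUE, digits = NA,
                                dataframe = "columns", null = "null"))
}

unclass_deep <- function(x) {
  if (is.list(x)) {
    x <- unclass(x)
    lapply(x, unclass_deep)
  } else x
}
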