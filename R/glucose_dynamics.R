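#' Glucose state of one NPC
#'
#' Bundles the state variables of the per-NPC glucose model: plasma glucose
#' `G` (mmol/L), carbohydrate remaining in the gut `Q_gut` (grams), remote
#' insulin action `X` (dimensionless), and the oral-agent (metformin) effect
#' level `M_eff` in \[0, 1\] together with its remaining duration in in-game
#' hours.
#'
#' @param G plasma glucose, mmol/L (> 0).
#' @param Q_gut carbohydrate in gut, grams (>= 0).
#' @param X remote insulin action (>= 0).
#' @param M_eff oral-agent effect level in \[0, 1\].
#' @param M_remaining remaining hours of oral-agent action.
#' @param M_pending TRUE when a metformin dose was applied but its effect has
#'   not yet switched on (onset is one sub-step after dosing).
#' @return an object of class `glucose_state`.
#' @export
glucose_state <- function(G, Q_gut = 0, X = 0, M_eff = 0,
                          M_remaining = 0, M_pending = FALSE) {
  st <- list(G = as.numeric(G), Q_gut = as.numeric(Q_gut), X = as.numeric(X),
             M_eff = as.numeric(M_eff), M_remaining = as.numeric(M_remaining),
             M_pending = isTRUE(M_pending))
  validate_glucose_state(st)
  structure(st, class = "glucose_state")
}

validate_glucose_state <- function(st) {
  vals <- c(st$G, st$Q_gut, st$X, st$M_eff, st$M_remaining)
  if (!all(is.finite(vals)))
    stop("glucose state contains non-finite values", call. = FALSE)
  if (st$G <= 0) stop("G must be > 0", call. = FALSE)
  if (st$Q_gut < 0 || st$X < 0) stop("Q_gut and X must be >= 0", call. = FALSE)
  if (st$M_eff < 0 || st$M_eff > 1) stop("M_eff must lie in [0, 1]", call. = FALSE)
  invisible(st)
}

#' Stimuli acting on an NPC during one sub-step
#'
#' @param activity_intensity physical intensity of the current activity,
#'   in \[0, 1\].
#' @param carbs_in grams of carbohydrate ingested at this sub-step.
#' @param bolus_units insulin bolus delivered at this sub-step.
#' @param basal_units_per_hour continuous basal insulin rate.
#' @return an object of class `stimuli`.
#' @export
stimuli <- function(activity_intensity = 0, carbs_in = 0, bolus_units = 0,
                    basal_units_per_hour = 0) {
  structure(list(activity_intensity = activity_intensity, carbs_in = carbs_in,
                 bolus_units = bolus_units,
                 basal_units_per_hour = basal_units_per_hour),
            class = "stimuli")
}

#' Safety thresholds for fainting
#'
#' An NPC faints instantly when glucose crosses a severe bound, or when it
#' stays beyond an extended bound for `extended_hours` consecutive in-game
#' hours.  Defaults follow clinically conventional level-2 hypo-/hyperglycemia
#' cutoffs and time-in-range bounds: severe at 3.0 and 20.0 mmol/L, extended
#' at 3.9 and 13.9 mmol/L sustained for 3 hours.
#'
#' @param severe_low,severe_high instant-faint bounds, mmol/L.
#' @param extended_low,extended_high sustained-excursion bounds, mmol/L.
#' @param extended_hours consecutive hours beyond an extended bound that
#'   trigger fainting.
#' @return an object of class `safety_rules`.
#' @export
safety_rules <- function(severe_low = 3.0, severe_high = 20.0,
                         extended_low = 3.9, extended_high = 13.9,
                         extended_hours = 3) {
  if (!(severe_low < extended_low && extended_low < extended_high &&
        extended_high < severe_high))
    stop("require severe_low < extended_low < extended_high < severe_high",
         call. = FALSE)
  if (extended_hours <= 0) stop("extended_hours must be > 0", call. = FALSE)
  structure(list(severe_low = severe_low, severe_high = severe_high,
                 extended_low = extended_low, extended_high = extended_high,
                 extended_hours = extended_hours),
            class = "safety_rules")
}

#' A time-stamped blood-glucose series (AGP)
#'
#' @param values glucose samples, mmol/L; the first sample is the state at
#'   time 0 and each later sample closes one sub-step interval of `dt_hours`.
#' @param dt_hours sub-step duration, in-game hours.
#' @return an object of class `glucose_trace`.
#' @export
glucose_trace <- function(values, dt_hours) {
  structure(list(values = as.numeric(values), dt_hours = dt_hours),
            class = "glucose_trace")
}

#' @export
length.glucose_trace <- function(x) length(x$values)

#' Span of a glucose trace in in-game hours
#' @param trace a `glucose_trace`.
#' @return hours covered by the trace (0 for traces of 0 or 1 sample).
#' @export
trace_span_hours <- function(trace) {
  max(0, length(trace$values) - 1) * trace$dt_hours
}

# Raw one-sub-step update on plain doubles; the hot path of the simulator.
# Model (fixed-step difference system, dt in in-game hours):
#   G      <- G + dt * [ kG*Gb*(1 - m*M_eff) - kG*G
#                        - (SI/IR)*(X + endo*s(G))*G
#                        - a*intensity + cg*kabs*Q_gut ]
#   Q_gut  <- Q_gut*exp(-kabs*dt) + carbs_in
#   X      <- X*exp(-kx*dt) + bolus*ux + basal_rate*dt*ux
# with s(G) a saturating endogenous-secretion term active only above basal.
# kG*Gb plays the role of endogenous glucose production so that G = Gb is an
# equilibrium under zero stimuli; metformin suppresses production
# multiplicatively.
step_core <- function(G, Q_gut, X, M_eff, phys, intensity, carbs_in,
                      bolus, basal_rate, dt) {
  Gb <- phys$basal_glucose
  excess <- G - Gb
  s_G <- if (excess > 0)
    phys$secretion_max * excess / (phys$secretion_halfsat + excess) else 0
  prod <- phys$glucose_clearance * Gb * (1 - phys$metformin_suppression * M_eff)
  dG <- prod - phys$glucose_clearance * G -
    (phys$insulin_sensitivity / phys$insulin_resistance) *
      (X + phys$endogenous_secretion * s_G) * G -
    phys$activity_uptake_rate * intensity +
    phys$carb_to_glucose * phys$carb_absorption_rate * Q_gut
  G2 <- max(G + dt * dG, 0.1)
  Q2 <- Q_gut * exp(-phys$carb_absorption_rate * dt) + carbs_in
  X2 <- X * exp(-phys$insulin_action_decay * dt) +
    bolus * phys$bolus_to_action + basal_rate * dt * phys$bolus_to_action
  c(G2, Q2, X2)
}

#' Advance the glucose model by one sub-step
#'
#' Applies the package's discrete glucose--insulin difference system for one
#' interval of `dt` in-game hours.  Endogenous production is suppressed
#' multiplicatively by the active metformin effect; a pending metformin dose
#' switches on at the *end* of the step, so its onset is one sub-step after
#' dosing.
#'
#' @param state a [glucose_state()].
#' @param physiology a physiology parameter list, see [generate_npc()].
#' @param stim a [stimuli()].
#' @param dt step length, in-game hours (> 0).
#' @return the updated `glucose_state`.
#' @export
step_glucose <- function(state, physiology, stim, dt) {
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("dt must be a single positive finite number", call. = FALSE)
  ins <- c(stim$activity_intensity, stim$carbs_in, stim$bolus_units,
           stim$basal_units_per_hour)
  if (!all(is.finite(ins))) stop("non-finite stimuli", call. = FALSE)
  validate_glucose_state(state)

  out <- step_core(state$G, state$Q_gut, state$X, state$M_eff, physiology,
                   stim$activity_intensity, stim$carbs_in, stim$bolus_units,
                   stim$basal_units_per_hour, dt)

  M_eff <- state$M_eff
  M_remaining <- state$M_remaining
  M_pending <- state$M_pending
  if (M_eff > 0) {
    M_remaining <- M_remaining - dt
    if (M_remaining <= 0) { M_eff <- 0; M_remaining <- 0 }
  }
  if (M_pending) {  # onset one sub-step after dosing
    M_eff <- 1
    M_remaining <- physiology$metformin_duration_hours
    M_pending <- FALSE
  }
  glucose_state(out[1], out[2], out[3], M_eff, M_remaining, M_pending)
}

#' A player action
#'
#' @param kind one of `"bolus"` (insulin units), `"snack"` (carb grams),
#'   `"metformin"` (mg; the game tracks only that a standard dose was given).
#' @param npc_id id of the targeted NPC.
#' @param dose non-negative dose in the kind's unit.
#' @return an object of class `player_action`.
#' @export
player_action <- function(kind, npc_id, dose) {
  kind <- match.arg(kind, c("bolus", "snack", "metformin"))
  if (!is.numeric(dose) || length(dose) != 1L || is.na(dose) || dose < 0)
    stop("dose must be a single non-negative number", call. = FALSE)
  structure(list(kind = kind, npc_id = npc_id, dose = dose),
            class = "player_action")
}

#' Apply a player action to an NPC's glucose state
#'
#' Boluses add to the remote insulin action input, snacks add grams to the
#' gut compartment, and metformin schedules the oral-agent effect (onset one
#' sub-step later, for its configured duration).  Metformin given to an NPC
#' with compromised renal function additionally returns a contraindication
#' flag; the dose still takes effect -- the game records errors, it does not
#' block them.
#'
#' @param state a [glucose_state()].
#' @param physiology the NPC's physiology parameter list.
#' @param action a [player_action()].
#' @return a list with elements `state` (updated `glucose_state`) and
#'   `contraindicated` (logical flag).
#' @export
apply_action <- function(state, physiology, action) {
  stopifnot(inherits(action, "player_action"))
  if (action$dose < 0) stop("negative dose", call. = FALSE)
  contra <- FALSE
  if (action$dose == 0)
    return(list(state = state, contraindicated = FALSE))
  if (action$kind == "bolus") {
    state$X <- state$X + action$dose * physiology$bolus_to_action
  } else if (action$kind == "snack") {
    state$Q_gut <- state$Q_gut + action$dose
  } else {  # metformin
    state$M_pending <- TRUE
    contra <- isTRUE(physiology$renal_impaired)
  }
  list(state = glucose_state(state$G, state$Q_gut, state$X, state$M_eff,
                             state$M_remaining, state$M_pending),
       contraindicated = contra)
}

#' Evaluate the fainting rule on a glucose trace
#'
#' Faints on the latest sample crossing a severe bound, or on a trailing run
#' of consecutive sub-step samples beyond an extended bound spanning at least
#' `extended_hours`.  Each post-initial sample stands for one sub-step
#' interval, so a run of `k` samples spans `k * dt_hours` hours.  The rule is
#' causal: only samples up to the present are inspected.
#'
#' @param trace a [glucose_trace()].
#' @param rules a [safety_rules()].
#' @return `"ok"`, `"faint_hypo"`, or `"faint_hyper"`.
#' @export
evaluate_safety <- function(trace, rules) {
  v <- trace$values
  n <- length(v)
  if (n == 0L) stop("empty trace", call. = FALSE)
  latest <- v[n]
  if (latest < rules$severe_low) return("faint_hypo")
  if (latest > rules$severe_high) return("faint_hyper")
  if (n < 2L) return("ok")
  need <- rules$extended_hours / trace$dt_hours - 1e-9
  iv <- v[-1]  # interval samples
  run_low <- trailing_run(iv < rules$extended_low)
  if (run_low >= need) return("faint_hypo")
  run_high <- trailing_run(iv > rules$extended_high)
  if (run_high >= need) return("faint_hyper")
  "ok"
}

trailing_run <- function(flags) {
  n <- length(flags)
  k <- 0L
  while (k < n && flags[n - k]) k <- k + 1L
  k
}
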