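#' Facilitator check-in schedule
#'
#' The player plays the first three ticks solo; the facilitator checks in on
#' tick 3 and every 2 ticks after, up to (and excluding) the final tick.
#'
#' @param duration_ticks game length in ticks (>= 0).
#' @return integer vector of check-in ticks (possibly empty).
#' @examples
#' checkin_ticks(12)  # 3 5 7 9 11
#' @export
checkin_ticks <- function(duration_ticks) {
  duration_ticks <- as.integer(duration_ticks)
  if (is.na(duration_ticks) || duration_ticks < 0)
    stop("duration_ticks must be a non-negative integer", call. = FALSE)
  if (duration_ticks - 1L < 3L) return(integer(0))
  seq.int(3L, duration_ticks - 1L, by = 2L)
}

#' A facilitator moderation request
#'
#' @param kind one of `"add_npc"`, `"remove_npc"`, `"freeze"`, `"unfreeze"`,
#'   `"no_action"`.
#' @param target NPC id (for remove/freeze/unfreeze) or phenotype label
#'   (for add_npc).
#' @return an object of class `facilitator_request`.
#' @export
facilitator_request <- function(kind, target = NULL) {
  kind <- match.arg(kind, c("add_npc", "remove_npc", "freeze", "unfreeze",
                            "no_action"))
  structure(list(kind = kind, target = target), class = "facilitator_request")
}

#' Player check-in feedback
#'
#' @param status one of `"overwhelmed"`, `"comfortable"`, `"under_challenged"`.
#' @param requested_delta optional signed change in active-NPC count the
#'   player asks for.
#' @return an object of class `checkin_feedback`.
#' @export
checkin_feedback <- function(status, requested_delta = NULL) {
  status <- match.arg(status, c("overwhelmed", "comfortable",
                                "under_challenged"))
  structure(list(status = status, requested_delta = requested_delta),
            class = "checkin_feedback")
}

#' Apply a facilitator request to the world
#'
#' `add_npc` generates a fresh NPC (active from the next sub-step);
#' `remove_npc` detaches an NPC from play, which is recorded distinctly from
#' evacuation; `freeze`/`unfreeze` toggle the frozen status, with the frozen
#' trace held flat.  Invalid requests (unknown or evacuated target, unfreeze
#' of a non-frozen NPC, add beyond `max_npcs`) are rejected with a logged
#' warning event.
#'
#' @param world a `game_world`.
#' @param request a [facilitator_request()].
#' @return the updated `game_world`.
#' @export
apply_request <- function(world, request) {
  stopifnot(inherits(request, "facilitator_request"))
  t <- world$tick
  reject <- function(msg) {
    log_event(world, "warning", t, 0L,
              npc_id = if (request$kind == "add_npc") NULL else request$target,
              payload = list(message = paste("facilitator request rejected:",
                                             msg),
                             kind = request$kind))
  }
  if (request$kind == "no_action")
    return(log_event(world, "facilitator_request", t, 0L,
                     payload = list(kind = "no_action")))
  if (request$kind == "add_npc") {
    n_in_play <- length(npc_ids_with_status(world, c("active", "frozen")))
    if (n_in_play >= world$config$max_npcs)
      return(reject("max_npcs reached"))
    world$npc_counter <- world$npc_counter + 1L
    id <- paste0("npc", world$npc_counter)
    label <- if (is.null(request$target)) "T2D" else request$target
    npc <- withr::with_seed(
      derive_seed(world$base_seed, 1, world$npc_counter),
      generate_npc(label, world$config, id))
    npc$start_tick <- t
    # trace starts at the moment of addition
    world$npcs[[id]] <- npc
    return(log_event(world, "facilitator_request", t, 0L, npc_id = id,
                     payload = list(kind = "add_npc", phenotype = label,
                                    ideal_range = npc$phenotype$ideal_range,
                                    initial_glucose = npc$state$G)))
  }
  npc <- world$npcs[[request$target]]
  if (is.null(npc)) return(reject("unknown NPC"))
  if (npc$status == "evacuated") return(reject("NPC evacuated"))
  if (npc$status == "removed") return(reject("NPC removed"))
  if (request$kind == "remove_npc") {
    npc$status <- "removed"
  } else if (request$kind == "freeze") {
    if (npc$status == "frozen") return(reject("already frozen"))
    npc$status <- "frozen"
    npc$frozen_at <- t
  } else {  # unfreeze
    if (npc$status != "frozen") return(reject("NPC not frozen"))
    npc$status <- "active"
    npc$frozen_at <- NA_integer_
  }
  world$npcs[[request$target]] <- npc
  log_event(world, "facilitator_request", t, 0L, npc_id = request$target,
            payload = list(kind = request$kind))
}

#' Difficulty-moderation rule table
#'
#' Maps player check-in feedback to a facilitator request: an overwhelmed
#' player gets the NPC furthest from its ideal range frozen (or removed if
#' it is already frozen -- freezing is preferred); a comfortable player gets
#' no action; an under-challenged player gets a frozen NPC unfrozen if one
#' exists, otherwise a new NPC with phenotype drawn 7:2:1 (T2D:T1D:GD).
#' The add draw uses the current RNG state.
#'
#' @param feedback a [checkin_feedback()].
#' @param world a `game_world`.
#' @return a [facilitator_request()].
#' @export
moderation_policy <- function(feedback, world) {
  stopifnot(inherits(feedback, "checkin_feedback"))
  if (feedback$status == "comfortable")
    return(facilitator_request("no_action"))
  if (feedback$status == "overwhelmed") {
    active <- npc_ids_with_status(world, "active")
    if (length(active) == 0L) return(facilitator_request("no_action"))
    d <- vapply(active, function(id) npc_distance_from_range(world$npcs[[id]]),
                numeric(1))
    return(facilitator_request("freeze", target = active[which.max(d)]))
  }
  # under_challenged
  frozen <- npc_ids_with_status(world, "frozen")
  if (length(frozen) > 0L) {
    at <- vapply(frozen, function(id) world$npcs[[id]]$frozen_at, integer(1))
    return(facilitator_request("unfreeze", target = frozen[which.min(at)]))
  }
  label <- sample(c("T2D", "T1D", "GD"), 1, prob = c(7, 2, 1))
  facilitator_request("add_npc", target = label)
}

#' Explain why an NPC was evacuated
#'
#' For hypoglycemic faints, attributes the largest insulin bolus given to
#' the NPC within the preceding lookback window; for hyperglycemic faints,
#' the largest uncovered meal or snack (one not followed by a bolus before
#' the faint), falling back to `"unmanaged"`.  Ties break toward the most
#' recent event.
#'
#' @param log event log (list of event records).
#' @param npc_id the evacuated NPC.
#' @param faint_event the faint event record for that NPC.
#' @param lookback_hours attribution window before the faint, in-game hours.
#' @return an object of class `evacuation_explanation` with fields `npc_id`,
#'   `direction`, `attributed_cause` (a list naming the causal event, or the
#'   string `"unmanaged"`), and a one-sentence `message`.
#' @export
attribute_evacuation_cause <- function(log, npc_id, faint_event,
                                       lookback_hours = 3) {
  S <- event_substeps(log)
  ev_time <- function(e) e$tick + e$substep / S
  t_faint <- ev_time(faint_event)
  direction <- faint_event$payload$direction
  in_window <- function(e) {
    tt <- ev_time(e)
    tt >= t_faint - lookback_hours && tt <= t_faint
  }
  mine <- Filter(function(e) identical(e$npc_id, npc_id) && in_window(e), log)

  pick_largest_latest <- function(events, size_of) {
    if (length(events) == 0L) return(NULL)
    sizes <- vapply(events, size_of, numeric(1))
    times <- vapply(events, ev_time, numeric(1))
    best <- which(sizes == max(sizes))
    events[[best[which.max(times[best])]]]
  }

  cause <- NULL
  if (identical(direction, "hypo")) {
    boluses <- Filter(function(e) e$kind == "action" &&
                        identical(e$payload$kind, "bolus"), mine)
    cause <- pick_largest_latest(boluses, function(e) e$payload$dose)
    what <- if (!is.null(cause))
      sprintf("too much bolus insulin (%.3g units) %.1f hours earlier",
              cause$payload$dose, t_faint - ev_time(cause))
  } else {
    carb_events <- Filter(function(e) {
      e$kind == "meal" ||
        (e$kind == "action" && identical(e$payload$kind, "snack"))
    }, mine)
    uncovered <- Filter(function(m) {
      t_m <- ev_time(m)
      !any(vapply(mine, function(e) {
        e$kind == "action" && identical(e$payload$kind, "bolus") &&
          ev_time(e) >= t_m
      }, logical(1)))
    }, carb_events)
    cause <- pick_largest_latest(uncovered, function(e) {
      if (e$kind == "meal") e$payload$grams else e$payload$dose
    })
    what <- if (!is.null(cause)) {
      grams <- if (cause$kind == "meal") cause$payload$grams else
        cause$payload$dose
      sprintf("an uncovered %s (%.3g g carbohydrate) %.1f hours earlier",
              if (cause$kind == "meal") "meal" else "snack",
              grams, t_faint - ev_time(cause))
    }
  }

  attributed <- if (is.null(cause)) "unmanaged" else
    list(seq = cause$seq, kind = cause$kind, tick = cause$tick,
         substep = cause$substep)
  message <- if (is.null(cause)) {
    sprintf("%s fainted from %sglycemia with no recent management and was evacuated.",
            npc_id, direction)
  } else {
    sprintf("%s fainted from %sglycemia after %s and was evacuated.",
            npc_id, direction, what)
  }
  structure(list(npc_id = npc_id, direction = direction,
                 attributed_cause = attributed, message = message),
            class = "evacuation_explanation")
}

# sub-steps per tick as recorded in the game_start event (falls back to 12)
event_substeps <- function(log) {
  for (e in log)
    if (e$kind == "game_start") return(e$payload$substeps_per_tick)
  12L
}
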