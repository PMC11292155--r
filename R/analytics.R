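#' Hours a trace spends in an ideal glucose range
#'
#' Sums the durations of the sub-step intervals whose closing glucose sample
#' lies inside the closed interval `range`.  Bounded above by the trace
#' span; an empty or single-sample trace contributes 0 hours.
#'
#' @param trace a [glucose_trace()].
#' @param range closed interval `c(lo, hi)` in mmol/L.
#' @return in-range time, in-game hours.
#' @export
hours_in_ideal_range <- function(trace, range) {
  v <- trace$values
  if (length(v) < 2L) return(0)
  iv <- v[-1]
  sum(iv >= range[1] & iv <= range[2]) * trace$dt_hours
}

#' Count contraindicated-metformin errors in an event log
#'
#' Number of *distinct* NPCs that received at least one metformin dose while
#' renally impaired (per-NPC, not per-dose, matching the trial's "number of
#' NPCs administered metformin when contraindicated").
#'
#' @param log event log (list of event records).
#' @return integer count.
#' @export
count_metformin_errors <- function(log) {
  ids <- unlist(lapply(log, function(e) {
    if (e$kind == "action" && identical(e$payload$kind, "metformin") &&
        isTRUE(e$payload$contraindicated)) e$npc_id else NULL
  }))
  length(unique(ids))
}

#' Count evacuations in an event log
#'
#' One per faint event; facilitator removals are not evacuations and are
#' never counted.
#'
#' @param log event log.
#' @return integer count.
#' @export
count_evacuations <- function(log) {
  sum(vapply(log, function(e) e$kind == "faint", logical(1)))
}

#' Summarise a finished game into its three outcomes
#'
#' Mean hours in ideal range averages [hours_in_ideal_range()] over every
#' NPC that was ever active -- evacuated and removed NPCs contribute the
#' hours they accrued before exit, and frozen intervals count as in range
#' iff the frozen value lies in range.  Also reports the
#' contraindicated-metformin error count and the evacuation count, plus a
#' per-NPC breakdown table.
#'
#' @param world a finished `game_world`.
#' @return an object of class `game_metrics`: list with `mean_hours_ideal`,
#'   `metformin_errors`, `evacuations`, and `per_npc` (data.frame).
#' @export
summarize_game <- function(world) {
  if (length(world$npcs) == 0L)
    stop("cannot summarise a game with no NPCs", call. = FALSE)
  per <- do.call(rbind, lapply(unname(world$npcs), function(n) {
    data.frame(id = n$id, phenotype = n$phenotype$label,
               status = n$status,
               hours_ideal = hours_in_ideal_range(n$trace,
                                                  n$phenotype$ideal_range))
  }))
  structure(list(mean_hours_ideal = mean(per$hours_ideal),
                 metformin_errors = count_metformin_errors(world$log),
                 evacuations = count_evacuations(world$log),
                 per_npc = per),
            class = "game_metrics")
}

#' @export
print.game_metrics <- function(x, ...) {
  cat(sprintf(paste0("Game metrics: mean hours in ideal range %.2f, ",
                     "metformin errors %d, evacuations %d (%d NPCs)\n"),
              x$mean_hours_ideal, x$metformin_errors, x$evacuations,
              nrow(x$per_npc)))
  invisible(x)
}

#' Recompute game metrics from a serialized event log
#'
#' Rebuilds every NPC's trace and status purely from the log (game-start
#' roster, per-tick trace events, faint events, contraindication-flagged
#' actions) and recomputes [summarize_game()]'s outcomes.  Equality with the
#' in-memory metrics is the log-completeness invariant.
#'
#' @param log event log.
#' @return a `game_metrics` object (without the world attached).
#' @export
metrics_from_log <- function(log) {
  start <- NULL
  for (e in log) if (e$kind == "game_start") { start <- e; break }
  if (is.null(start)) stop("log has no game_start event", call. = FALSE)
  S <- start$payload$substeps_per_tick
  dt <- 1 / S
  traces <- list(); ranges <- list(); phenos <- list(); status <- list()
  for (r in start$payload$roster) {
    traces[[r$id]] <- r$initial_glucose
    ranges[[r$id]] <- unlist(r$ideal_range)
    phenos[[r$id]] <- r$phenotype
    status[[r$id]] <- "active"
  }
  for (e in log) {
    if (e$kind == "facilitator_request") {
      k <- e$payload$kind
      if (identical(k, "add_npc")) {
        traces[[e$npc_id]] <- e$payload$initial_glucose
        ranges[[e$npc_id]] <- unlist(e$payload$ideal_range)
        phenos[[e$npc_id]] <- e$payload$phenotype
        status[[e$npc_id]] <- "active"
      } else if (identical(k, "remove_npc")) status[[e$npc_id]] <- "removed"
      else if (identical(k, "freeze")) status[[e$npc_id]] <- "frozen"
      else if (identical(k, "unfreeze")) status[[e$npc_id]] <- "active"
    } else if (e$kind == "trace") {
      traces[[e$npc_id]] <- c(traces[[e$npc_id]], unlist(e$payload$values))
    } else if (e$kind == "faint") {
      status[[e$npc_id]] <- "evacuated"
    }
  }
  ids <- names(traces)
  per <- do.call(rbind, lapply(ids, function(id) {
    data.frame(id = id, phenotype = phenos[[id]], status = status[[id]],
               hours_ideal = hours_in_ideal_range(
                 glucose_trace(traces[[id]], dt), ranges[[id]]))
  }))
  structure(list(mean_hours_ideal = mean(per$hours_ideal),
                 metformin_errors = count_metformin_errors(log),
                 evacuations = count_evacuations(log),
                 per_npc = per),
            class = "game_metrics")
}

#' Export an NPC's AGP trace as a data frame
#'
#' @param world a `game_world`.
#' @param path optional CSV path; when given, writes columns
#'   `npc_id, time_hours, glucose_mmol_per_L` for every NPC.
#' @return the trace data frame (invisibly when written to `path`).
#' @export
export_traces <- function(world, path = NULL) {
  df <- do.call(rbind, lapply(unname(world$npcs), function(n) {
    v <- n$trace$values
    data.frame(npc_id = n$id,
               time_hours = n$start_tick + (seq_along(v) - 1) * n$trace$dt_hours,
               glucose_mmol_per_L = v)
  }))
  if (!is.null(path)) {
    utils::write.csv(df, path, row.names = FALSE)
    return(invisible(df))
  }
  df
}
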