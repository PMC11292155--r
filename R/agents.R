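#' Scripted-player policy parameters
#'
#' A heuristic threshold policy of parameterised skill that stands in for a
#' human player, so facilitated and unfacilitated games can be simulated at
#' scale.  Skill drives the dosing-error probability (down) and the number
#' of NPCs the player can attend to per tick (up); both can be overridden.
#'
#' @param skill player skill in \[0, 1\].
#' @param reaction_window ticks of recent trace the player inspects.
#' @param misdose_prob probability that a dose is perturbed by
#'   `misdose_factor`; default `0.4 * (1 - skill)`.
#' @param attention_budget maximum NPCs acted on per tick; default
#'   `2 + round(4 * skill)`.
#' @param misdose_factor multiplicative size of a dosing error.
#' @param correction_per_unit mmol/L of glucose lowering the player expects
#'   per insulin unit when sizing a corrective bolus.
#' @param snack_grams base snack size for low glucose, grams.
#' @return an object of class `player_policy`.
#' @export
player_policy <- function(skill = 0.5, reaction_window = 2L,
                          misdose_prob = NULL, attention_budget = NULL,
                          misdose_factor = 2.5, correction_per_unit = 1,
                          snack_grams = 15) {
  if (skill < 0 || skill > 1) stop("skill must lie in [0, 1]", call. = FALSE)
  if (is.null(misdose_prob)) misdose_prob <- 0.4 * (1 - skill)
  if (is.null(attention_budget)) attention_budget <- 2L + as.integer(round(4 * skill))
  if (misdose_prob < 0 || misdose_prob > 1)
    stop("misdose_prob must lie in [0, 1]", call. = FALSE)
  if (attention_budget < 1) stop("attention_budget must be >= 1", call. = FALSE)
  structure(list(skill = skill, reaction_window = as.integer(reaction_window),
                 misdose_prob = misdose_prob,
                 attention_budget = as.integer(attention_budget),
                 misdose_factor = misdose_factor,
                 correction_per_unit = correction_per_unit,
                 snack_grams = snack_grams),
            class = "player_policy")
}

#' The player's view of the world
#'
#' What a player can see: per-NPC recent trace, status, target range, and
#' past actions (players may open each NPC's clinical history, so renal
#' status is visible too).  Evacuated and removed NPCs carry no current
#' state and are excluded.
#'
#' @param world a `game_world`.
#' @param reaction_window ticks of trace to expose.
#' @return list of per-NPC views.
#' @export
world_view <- function(world, reaction_window = 2L) {
  S <- world$config$substeps_per_tick
  keep <- npc_ids_with_status(world, c("active", "frozen"))
  lapply(world$npcs[keep], function(n) {
    v <- n$trace$values
    k <- min(length(v), reaction_window * S + 1L)
    list(id = n$id, status = n$status,
         phenotype = n$phenotype$label,
         ideal_range = n$phenotype$ideal_range,
         recent = v[seq.int(length(v) - k + 1L, length(v))],
         dt_hours = n$trace$dt_hours,
         renal_impaired = n$physiology$renal_impaired,
         had_metformin = any(vapply(n$action_history,
                                    function(a) a$kind == "metformin",
                                    logical(1))))
  })
}

#' Scripted player: decide this tick's actions
#'
#' Acts on at most `attention_budget` NPCs, prioritised by distance from
#' their ideal range: a corrective bolus when above range (sized from the
#' excess), a snack when below.  Type 2 NPCs above range may additionally
#' receive metformin; with probability `skill` the player first checks the
#' clinical history and withholds metformin from renally impaired NPCs,
#' otherwise the contraindicated dose goes through (and is counted as an
#' error by the analytics).  With probability `misdose_prob` a dose is
#' multiplied or divided by `misdose_factor`.  Frozen and evacuated NPCs are
#' never targeted.  Uses the current RNG state.
#'
#' @param view a [world_view()].
#' @param params a [player_policy()].
#' @return list of [player_action()] (possibly empty).
#' @export
scripted_player <- function(view, params) {
  active <- Filter(function(v) v$status == "active", view)
  if (length(active) == 0L) return(list())
  dist <- vapply(active, function(v) {
    g <- v$recent[length(v$recent)]
    max(0, v$ideal_range[1] - g, g - v$ideal_range[2])
  }, numeric(1))
  ord <- order(dist, decreasing = TRUE)
  ord <- ord[dist[ord] > 0]
  ord <- utils::head(ord, params$attention_budget)
  actions <- list()
  perturb <- function(dose) {
    if (runif(1) < params$misdose_prob)
      dose * sample(c(params$misdose_factor, 1 / params$misdose_factor), 1)
    else dose
  }
  for (i in ord) {
    v <- active[[i]]
    g <- v$recent[length(v$recent)]
    lo <- v$ideal_range[1]; hi <- v$ideal_range[2]
    if (g > hi) {
      if (v$phenotype == "T2D" && !v$had_metformin && runif(1) < 0.5) {
        withhold <- v$renal_impaired && runif(1) < params$skill
        if (!withhold)
          actions[[length(actions) + 1L]] <-
            player_action("metformin", v$id, 500)
      }
      dose <- max(1, round((g - hi + 1) / params$correction_per_unit))
      actions[[length(actions) + 1L]] <-
        player_action("bolus", v$id, perturb(dose))
    } else if (g < lo) {
      grams <- params$snack_grams + round(10 * (lo - g))
      actions[[length(actions) + 1L]] <-
        player_action("snack", v$id, perturb(grams))
    }
  }
  actions
}

#' Synthesise check-in feedback for a scripted player
#'
#' Deterministic difficulty self-report: overwhelmed when more active NPCs
#' are out of range than the player's attention budget, under-challenged
#' when everything is in range and fewer NPCs are in play than at game
#' start, comfortable otherwise.
#'
#' @param view a [world_view()].
#' @param params a [player_policy()].
#' @param initial_n NPC count at game start.
#' @return a [checkin_feedback()].
#' @export
checkin_feedback_from_view <- function(view, params, initial_n) {
  active <- Filter(function(v) v$status == "active", view)
  n_out <- sum(vapply(active, function(v) {
    g <- v$recent[length(v$recent)]
    g < v$ideal_range[1] || g > v$ideal_range[2]
  }, logical(1)))
  if (n_out > params$attention_budget)
    checkin_feedback("overwhelmed", requested_delta = -1L)
  else if (n_out == 0L && length(view) < initial_n)
    checkin_feedback("under_challenged", requested_delta = 1L)
  else checkin_feedback("comfortable")
}
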