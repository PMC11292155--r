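test_that("check-in schedule: third tick and every second tick after", {
  expect_equal(checkin_ticks(12), c(3L, 5L, 7L, 9L, 11L))
  expect_equal(checkin_ticks(4), 3L)
  expect_equal(checkin_ticks(2), integer(0))
  expect_equal(checkin_ticks(0), integer(0))
  expect_equal(checkin_ticks(13), c(3L, 5L, 7L, 9L, 11L))
  expect_error(checkin_ticks(-1), "non-negative")
})

test_that("add_npc grows the population and logs the addition", {
  w <- init_world(game_config(), seed = 6)
  n0 <- length(w$npcs)
  w <- apply_request(w, facilitator_request("add_npc", "T2D"))
  expect_length(w$npcs, n0 + 1L)
  adds <- Filter(function(e) e$kind == "facilitator_request" &&
                   identical(e$payload$kind, "add_npc"), w$log)
  expect_length(adds, 1L)
  new_id <- adds[[1]]$npc_id
  expect_equal(w$npcs[[new_id]]$phenotype$label, "T2D")
  expect_equal(w$npcs[[new_id]]$status, "active")
  # the addition is reproducible from the base seed
  w2 <- init_world(game_config(), seed = 6)
  w2 <- apply_request(w2, facilitator_request("add_npc", "T2D"))
  expect_identical(world_to_json(w, include_log = FALSE),
                   world_to_json(w2, include_log = FALSE))
})

test_that("add_npc respects the max_npcs cap with a warning", {
  w <- init_world(game_config(phenotype_counts = c(T2D = 1L, T1D = 0L, GD = 0L),
                              max_npcs = 1L), seed = 1)
  w <- apply_request(w, facilitator_request("add_npc", "GD"))
  expect_length(w$npcs, 1L)
  expect_length(Filter(function(e) e$kind == "warning", w$log), 1L)
})

test_that("remove detaches an NPC distinctly from evacuation", {
  w <- init_world(game_config(), seed = 9)
  id <- names(w$npcs)[3]
  w <- apply_request(w, facilitator_request("remove_npc", id))
  expect_equal(w$npcs[[id]]$status, "removed")
  len0 <- length(w$npcs[[id]]$trace$values)
  w <- advance_tick(w)$world
  expect_equal(length(w$npcs[[id]]$trace$values), len0)
  expect_equal(count_evacuations(w$log), 0L)
  # invalid requests are warnings, not errors
  w <- apply_request(w, facilitator_request("remove_npc", "nope"))
  w <- apply_request(w, facilitator_request("unfreeze", names(w$npcs)[1]))
  warns <- Filter(function(e) e$kind == "warning", w$log)
  expect_length(warns, 2L)
})

test_that("moderation rule table covers every feedback x world combination", {
  w <- init_world(game_config(), seed = 30)

  expect_equal(moderation_policy(checkin_feedback("comfortable"), w)$kind,
               "no_action")

  # overwhelmed: freeze the active NPC furthest from its ideal range; never add
  for (i in 1:5) {
    wi <- advance_tick(w)$world
    req <- moderation_policy(checkin_feedback("overwhelmed"), wi)
    expect_true(req$kind %in% c("freeze", "remove_npc"))
    active <- facilisim:::npc_ids_with_status(wi, "active")
    d <- vapply(wi$npcs[active], function(n)
      facilisim:::npc_distance_from_range(n), numeric(1))
    expect_equal(req$target, active[which.max(d)])
    w <- wi
  }

  # under-challenged with a frozen NPC present: unfreeze exactly that NPC
  frozen_id <- facilisim:::npc_ids_with_status(w, "active")[1]
  wf <- apply_request(w, facilitator_request("freeze", frozen_id))
  req <- moderation_policy(checkin_feedback("under_challenged"), wf)
  expect_equal(req$kind, "unfreeze")
  expect_equal(req$target, frozen_id)

  # under-challenged with none frozen: add with a 7:2:1 phenotype draw
  req <- withr::with_seed(4,
    moderation_policy(checkin_feedback("under_challenged"), w))
  expect_equal(req$kind, "add_npc")
  expect_true(req$target %in% c("T2D", "T1D", "GD"))

  # overwhelmed with no active NPCs degrades to no_action
  we <- w
  for (id in names(we$npcs)) we$npcs[[id]]$status <- "evacuated"
  expect_equal(moderation_policy(checkin_feedback("overwhelmed"), we)$kind,
               "no_action")
})

test_that("hypo evacuation is attributed to the largest recent bolus", {
  log <- list(
    event_rec(1, 0, 0, "game_start",
              payload = list(substeps_per_tick = 12L, roster = list())),
    event_rec(2, 2, 0, "action", "npc1",
              payload = list(kind = "bolus", dose = 6, contraindicated = FALSE)),
    event_rec(3, 3, 0, "action", "npc1",
              payload = list(kind = "bolus", dose = 2, contraindicated = FALSE)),
    event_rec(4, 4, 6, "faint", "npc1",
              payload = list(direction = "hypo", glucose = 2.8)))
  expl <- attribute_evacuation_cause(log, "npc1", log[[4]])
  expect_equal(expl$direction, "hypo")
  expect_equal(expl$attributed_cause$seq, 2L)  # the 6-unit bolus, 2.5 h before
  expect_match(expl$message, "bolus")
})

test_that("equal boluses break ties toward the most recent", {
  log <- list(
    event_rec(1, 0, 0, "game_start",
              payload = list(substeps_per_tick = 12L, roster = list())),
    event_rec(2, 2, 0, "action", "npc1",
              payload = list(kind = "bolus", dose = 5, contraindicated = FALSE)),
    event_rec(3, 3, 0, "action", "npc1",
              payload = list(kind = "bolus", dose = 5, contraindicated = FALSE)),
    event_rec(4, 4, 0, "faint", "npc1",
              payload = list(direction = "hypo", glucose = 2.9)))
  expl <- attribute_evacuation_cause(log, "npc1", log[[4]])
  expect_equal(expl$attributed_cause$seq, 3L)  # -1 h beats -2 h
})

test_that("hyper evacuations name an uncovered meal or fall back to unmanaged", {
  base <- list(
    event_rec(1, 0, 0, "game_start",
              payload = list(substeps_per_tick = 12L, roster = list())),
    event_rec(2, 3, 1, "meal", "npc1",
              payload = list(grams = 80, activity = "meal")),
    event_rec(3, 5, 2, "faint", "npc1",
              payload = list(direction = "hyper", glucose = 20.5)))
  expl <- attribute_evacuation_cause(base, "npc1", base[[3]])
  expect_equal(expl$attributed_cause$seq, 2L)
  expect_match(expl$message, "meal")

  # a covering bolus after the meal blocks the attribution
  covered <- list(
    base[[1]], base[[2]],
    event_rec(3, 4, 0, "action", "npc1",
              payload = list(kind = "bolus", dose = 4,
                             contraindicated = FALSE)),
    event_rec(4, 5, 2, "faint", "npc1",
              payload = list(direction = "hyper", glucose = 20.5)))
  expl <- attribute_evacuation_cause(covered, "npc1", covered[[4]])
  expect_equal(expl$attributed_cause, "unmanaged")

  # empty action history: unmanaged
  empty <- list(
    event_rec(1, 0, 0, "game_start",
              payload = list(substeps_per_tick = 12L, roster = list())),
    event_rec(2, 5, 0, "faint", "npc1",
              payload = list(direction = "hyper", glucose = 21)))
  expl <- attribute_evacuation_cause(empty, "npc1", empty[[2]])
  expect_equal(expl$attributed_cause, "unmanaged")
  expect_match(expl$message, "no recent management")
})

test_that("moderation never adds NPCs in response to overwhelmed feedback", {
  for (s in 1:20) {
    w <- init_world(game_config(), seed = s)
    w <- advance_tick(w)$world
    req <- moderation_policy(checkin_feedback("overwhelmed"), w)
    expect_false(req$kind == "add_npc")
    n_active_before <- length(facilisim:::npc_ids_with_status(w, "active"))
    w2 <- apply_request(w, req)
    expect_lte(length(facilisim:::npc_ids_with_status(w2, "active")),
               n_active_before)
  }
})
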