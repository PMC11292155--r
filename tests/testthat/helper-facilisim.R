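# Shared fixtures and independent oracles for the test suite.  Everything is
# generated in code; no stored data.

# A deterministic physiology for dynamics tests (no sampling involved).
fixed_physiology <- function(basal = 9, endo = 0.5, ...) {
  over <- list(...)
  p <- c(list(basal_glucose = basal,
              insulin_sensitivity = 0.1,
              endogenous_secretion = endo,
              insulin_resistance = 2,
              renal_impaired = FALSE,
              carb_absorption_rate = 1,
              insulin_action_decay = 0.5,
              activity_uptake_rate = 1),
         facilisim:::dynamics_defaults())
  p[names(over)] <- over
  p
}

# Step the discrete model over a horizon with optional impulses, returning
# the glucose series (including the start value).
simulate_discrete <- function(phys, hours, dt, carbs0 = 0, bolus0 = 0,
                              intensity = 0) {
  # impulses enter as initial compartment conditions, mirroring the ODE oracle
  st <- glucose_state(phys$basal_glucose, Q_gut = carbs0,
                      X = bolus0 * phys$bolus_to_action)
  n <- round(hours / dt)
  g <- numeric(n + 1)
  g[1] <- st$G
  for (i in seq_len(n)) {
    st <- step_glucose(st, phys, stimuli(activity_intensity = intensity), dt)
    g[i + 1] <- st$G
  }
  g
}

# Independent fine-resolution oracle: the continuous counterpart of the
# documented model integrated with deSolve; impulses become initial
# conditions on the gut and insulin-action compartments.
simulate_ode_oracle <- function(phys, hours, carbs0 = 0, bolus0 = 0,
                                intensity = 0, n_out = 200) {
  rhs <- function(t, y, parms) {
    G <- y[1]; Q <- y[2]; X <- y[3]
    excess <- G - phys$basal_glucose
    sG <- if (excess > 0)
      phys$secretion_max * excess / (phys$secretion_halfsat + excess) else 0
    dG <- phys$glucose_clearance * phys$basal_glucose -
      phys$glucose_clearance * G -
      (phys$insulin_sensitivity / phys$insulin_resistance) *
        (X + phys$endogenous_secretion * sG) * G -
      phys$activity_uptake_rate * intensity +
      phys$carb_to_glucose * phys$carb_absorption_rate * Q
    list(c(dG, -phys$carb_absorption_rate * Q,
           -phys$insulin_action_decay * X))
  }
  y0 <- c(G = phys$basal_glucose, Q = carbs0,
          X = bolus0 * phys$bolus_to_action)
  times <- seq(0, hours, length.out = n_out)
  out <- deSolve::ode(y0, times, rhs, parms = NULL)
  data.frame(time = out[, "time"], G = out[, "G"])
}

# Brute-force fainting oracle: enumerate every window that ends at the last
# sample and check its span against the sustained rule; severe bounds apply
# to the last sample only.
brute_safety <- function(values, dt, rules) {
  n <- length(values)
  last <- values[n]
  if (last < rules$severe_low) return("faint_hypo")
  if (last > rules$severe_high) return("faint_hyper")
  if (n >= 2) {
    iv <- values[-1]
    m <- length(iv)
    for (k in seq_len(m)) {
      win <- iv[(m - k + 1):m]
      if (k * dt >= rules$extended_hours - 1e-9) {
        if (all(win < rules$extended_low)) return("faint_hypo")
        if (all(win > rules$extended_high)) return("faint_hyper")
      }
    }
  }
  "ok"
}

# Exhaustive Mann-Whitney oracle: U from midrank sums over every labeling.
enum_mw_oracle <- function(x, y) {
  n <- length(x); m <- length(y)
  pool <- c(x, y)
  r <- rank(pool)  # midranks
  U_from_idx <- function(idx) sum(r[idx]) - n * (n + 1) / 2
  U_obs <- U_from_idx(seq_len(n))
  mu <- n * m / 2
  splits <- utils::combn(n + m, n)
  devs <- apply(splits, 2, function(idx) abs(U_from_idx(idx) - mu))
  list(U = U_obs, p = mean(devs >= abs(U_obs - mu) - 1e-9))
}

# Minimal hand-built world for analytics tests: traces and statuses are set
# directly, bypassing the simulator.
toy_world <- function(traces, ranges, statuses, log = list()) {
  npcs <- lapply(seq_along(traces), function(i) {
    structure(list(id = paste0("npc", i),
                   phenotype = list(label = "T2D", ideal_range = ranges[[i]]),
                   trace = traces[[i]], status = statuses[i],
                   start_tick = 0L),
              class = "npc")
  })
  names(npcs) <- vapply(npcs, function(n) n$id, character(1))
  list(npcs = npcs, log = log)
}

event_rec <- function(seq, tick, substep, kind, npc_id = NULL,
                      payload = list()) {
  list(seq = seq, tick = as.integer(tick), substep = as.integer(substep),
       kind = kind, npc_id = npc_id, payload = payload)
}

ticks_of_kind <- function(log, kind) {
  vapply(Filter(function(e) e$kind == kind, log), function(e) e$tick,
         integer(1))
}

quick_config <- function(...) game_config(...)
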