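# ---- internal: flatten an htn_params + strategy into plain numerics --------
#
# Everything the per-cycle step needs, as scalars and per-cycle vectors, so the
# hot loop (and the probabilistic analysis that calls it thousands of times)
# never touches a tibble.
engine_inputs <- function(params, strategy) {
  p <- function(nm) param_value(params, nm)
  cfg <- params$config
  n_cycles <- as.integer(cfg$n_cycles)
  entry <- as.numeric(cfg$cohort_entry_age)
  ages <- entry + seq_len(n_cycles) - 1

  sched_at <- function(nm) {
    sc <- params$schedules[[nm]]
    idx <- match(pmin(ages, max(sc$age)), sc$age)
    if (anyNA(idx)) abort(paste0("schedule '", nm, "' does not cover ages ",
                                 min(ages), "-", max(ages)))
    sc$value[idx]
  }

  chd_dec <- c(p("chd_fatal"), p("chd_mi"), p("chd_sa"), p("chd_ua"))
  str_dec <- c(p("stroke_fatal"), p("stroke_nonfatal"), p("stroke_tia"))
  init <- c(p("init_healthy"), p("init_htn_off_tx"), p("init_htn_on_tx"))
  if (params$renormalized) {
    chd_dec <- renormalize_branch(chd_dec)
    str_dec <- renormalize_branch(str_dec)
    init <- renormalize_branch(init)
  }

  list(
    n_cycles = n_cycles, entry_age = entry, ages = ages,
    screen = as.logical(is_screening_cycle(strategy, ages)),
    strategy = strategy$label,
    # per-cycle schedules
    p_ncv = sched_at("non_cvd_death"),
    p_h_chd = sched_at("healthy_chd"),
    p_h_str = sched_at("healthy_stroke"),
    p_htn = sched_at("htn_incidence"),
    p_u_chd = sched_at("untreated_chd"),
    p_u_str = sched_at("untreated_stroke"),
    uptake = sched_at("treatment_uptake"),
    # screening
    part_h = p("participation_healthy"), part_u = p("participation_untreated"),
    sens = p("sensitivity"), spec = p("specificity"),
    uptake_tp = p("uptake_true_positive"),
    fp_chd = p("event_risk_false_positive_chd"),
    fp_str = p("event_risk_false_positive_stroke"),
    tp_chd = p("event_risk_true_positive_chd"),
    tp_str = p("event_risk_true_positive_stroke"),
    fn_chd = p("event_risk_false_negative_chd"),
    fn_str = p("event_risk_false_negative_stroke"),
    # treatment effects and recurrence
    rr_chd = p("rr_chd_on_treatment"), rr_str = p("rr_stroke_on_treatment"),
    rr_rec_chd = p("rr_chd_recurrence"), p_rec_str = p("p_stroke_recurrence"),
    # event decomposition (renormalized unless disabled)
    chd_dec = chd_dec, str_dec = str_dec,
    # cardiovascular death from post states, in state order 4..8
    cv_death = c(p("cv_death_post_mi"), p("cv_death_post_stroke"),
                 p("cv_death_post_sa"), p("cv_death_post_ua"),
                 p("cv_death_post_tia")),
    # costs
    c_contact = p("screening_contact"), c_confirm = p("confirmatory_workup"),
    c_tx_new_bg = p("tx_new_no_screen"), c_tx_new_scr = p("tx_new_with_screen"),
    c_tx_prev = p("tx_previous"),
    c_event = c(mi = p("cost_event_mi"), stroke = p("cost_event_stroke"),
                sa = p("cost_event_sa"), ua = p("cost_event_ua"),
                tia = p("cost_event_tia")),
    c_post = c(p("cost_post_mi"), p("cost_post_stroke"), p("cost_post_sa"),
               p("cost_post_ua"), p("cost_post_tia")),
    c_death_chd = p("cost_death_chd"), c_death_str = p("cost_death_stroke"),
    # utilities, in state order 1..10
    util = c(p("u_healthy"), p("u_htn_off_tx"), p("u_htn_on_tx"),
             p("u_post_mi"), p("u_post_stroke"), p("u_post_sa"),
             p("u_post_ua"), p("u_post_tia"), 0, 0),
    init_occ = c(init[1], init[2], init[3], rep(0, 7)),
    r_cost = cfg$discount_rate_costs, r_outcome = cfg$discount_rate_outcomes
  )
}

# ---- internal: one annual cycle on a cohort occupancy vector ---------------
#
# Within-cycle ordering: (1) screening splits the healthy and untreated states
# into outcome sub-populations; (2) other-cause death competes first; (3) CHD
# and stroke events fire as within-cycle chance nodes and are decomposed into
# fatal and non-fatal branches immediately; (4) survivors without an event
# progress (hypertension incidence, background treatment uptake, screening
# uptake). Costs attach to flows; the QALY for the cycle uses the end-of-cycle
# state (those dying within the cycle accrue nothing that year).
cycle_step <- function(occ, t, ei, screen = ei$screen[t]) {
  d <- ei$p_ncv[t]
  nxt <- numeric(10)
  chd_flow <- 0
  str_flow <- 0
  cost_screen <- 0
  cost_confirm <- 0
  new_on_bg <- 0
  new_on_scr <- 0

  h <- occ[1]
  off <- occ[2]
  if (screen) {
    part_h <- h * ei$part_h
    tn <- part_h * ei$spec
    fp <- part_h * (1 - ei$spec)
    nh <- h - part_h
    part_u <- off * ei$part_u
    tp <- part_u * ei$sens
    fn <- part_u * (1 - ei$sens)
    nu <- off - part_u
    cost_screen <- (part_h + part_u) * ei$c_contact
    cost_confirm <- (tp + fp) * ei$c_confirm
  } else {
    tn <- fp <- tp <- fn <- 0
    nh <- h
    nu <- off
  }

  # healthy-like sub-populations (false positives carry their own screening-
  # cycle event risks; confirmatory testing returns them to the healthy path)
  for (grp in list(c(nh + tn, ei$p_h_chd[t], ei$p_h_str[t]),
                   c(fp, ei$fp_chd, ei$fp_str))) {
    m <- grp[1]
    if (m == 0) next
    nxt[10] <- nxt[10] + m * d
    alive <- m * (1 - d)
    chd_flow <- chd_flow + alive * grp[2]
    str_flow <- str_flow + alive * grp[3]
    rem <- alive * (1 - grp[2] - grp[3])
    to_off <- rem * ei$p_htn[t]
    nxt[2] <- nxt[2] + to_off
    nxt[1] <- nxt[1] + rem - to_off
  }

  # untreated-like sub-populations; true positives start treatment with
  # probability uptake_tp, everyone else is exposed to background uptake.
  # False negatives keep the untreated state's event risks until the next
  # round (they are undiagnosed untreated hypertensives).
  for (grp in list(list(m = nu + fn, pc = ei$p_u_chd[t], ps = ei$p_u_str[t], tp = FALSE),
                   list(m = tp, pc = ei$tp_chd, ps = ei$tp_str, tp = TRUE))) {
    m <- grp$m
    if (m == 0) next
    nxt[10] <- nxt[10] + m * d
    alive <- m * (1 - d)
    chd_flow <- chd_flow + alive * grp$pc
    str_flow <- str_flow + alive * grp$ps
    rem <- alive * (1 - grp$pc - grp$ps)
    if (grp$tp) {
      to_on <- rem * ei$uptake_tp
      new_on_scr <- new_on_scr + to_on
    } else {
      to_on <- rem * ei$uptake[t]
      new_on_bg <- new_on_bg + to_on
    }
    nxt[3] <- nxt[3] + to_on
    nxt[2] <- nxt[2] + rem - to_on
  }

  # on treatment: event risks are the untreated risks scaled by the RRs
  m <- occ[3]
  if (m > 0) {
    nxt[10] <- nxt[10] + m * d
    alive <- m * (1 - d)
    pc <- ei$p_u_chd[t] * ei$rr_chd
    ps <- ei$p_u_str[t] * ei$rr_str
    chd_flow <- chd_flow + alive * pc
    str_flow <- str_flow + alive * ps
    nxt[3] <- nxt[3] + alive * (1 - pc - ps)
  }

  # post-event states: other-cause death, state-specific cardiovascular
  # death, then recurrent events re-entering the same decomposition
  p_rec_chd <- min(ei$p_h_chd[t] * ei$rr_rec_chd, 1)
  for (k in seq_along(4:8)) {
    s <- 3 + k
    m <- occ[s]
    if (m == 0) next
    nxt[10] <- nxt[10] + m * d
    alive <- m * (1 - d)
    pd <- ei$cv_death[k]
    p_ev <- if (s %in% c(4, 6, 7)) min(p_rec_chd, 1 - pd) else min(ei$p_rec_str, 1 - pd)
    nxt[9] <- nxt[9] + alive * pd
    if (s %in% c(4, 6, 7)) chd_flow <- chd_flow + alive * p_ev
    else str_flow <- str_flow + alive * p_ev
    nxt[s] <- nxt[s] + alive * (1 - pd - p_ev)
  }

  nxt[9] <- nxt[9] + occ[9]
  nxt[10] <- nxt[10] + occ[10]

  # event chance nodes: decompose into fatal and non-fatal branches
  cd <- ei$chd_dec
  sd <- ei$str_dec
  nxt[9] <- nxt[9] + chd_flow * cd[1] + str_flow * sd[1]
  nxt[4] <- nxt[4] + chd_flow * cd[2]
  nxt[6] <- nxt[6] + chd_flow * cd[3]
  nxt[7] <- nxt[7] + chd_flow * cd[4]
  nxt[5] <- nxt[5] + str_flow * sd[2]
  nxt[8] <- nxt[8] + str_flow * sd[3]

  cost_event <- chd_flow * (cd[2] * ei$c_event[["mi"]] +
                            cd[3] * ei$c_event[["sa"]] +
                            cd[4] * ei$c_event[["ua"]]) +
    str_flow * (sd[2] * ei$c_event[["stroke"]] + sd[3] * ei$c_event[["tia"]])
  cost_death <- chd_flow * cd[1] * ei$c_death_chd +
    str_flow * sd[1] * ei$c_death_str
  cost_treat <- occ[3] * ei$c_tx_prev +
    new_on_bg * ei$c_tx_new_bg + new_on_scr * ei$c_tx_new_scr
  cost_post <- sum(occ[4:8] * ei$c_post)
  qaly <- sum(nxt[1:8] * ei$util[1:8])

  list(occ = nxt, qaly = qaly,
       cost_screen = cost_screen, cost_confirm = cost_confirm,
       cost_treat = cost_treat, cost_event = cost_event,
       cost_death = cost_death, cost_post = cost_post)
}

#' One-cycle transition probabilities from a persistent state
#'
#' Marginal distribution over the ten persistent states after one annual
#' cycle, starting from unit mass in `state` at the given attained age —
#' within-cycle chance nodes (screening outcomes, CHD and stroke events with
#' their fatal/non-fatal decomposition) already resolved.
#'
#' @param state A persistent state name (see `states()`).
#' @param age Attained age in years.
#' @param on_screen_cycle Is this a screening round for the occupants of the
#'   screened states?
#' @param params An `htn_params` object.
#' @param strategy A one-row strategy tibble; defaults to no screening (the
#'   strategy only matters through `on_screen_cycle`).
#' @return Named numeric vector over the persistent states, summing to 1.
#' @export
transition_row <- function(state, age, on_screen_cycle, params,
                           strategy = screening_strategy("No screening")) {
  i <- match(state, STATE_NAMES)
  if (is.na(i)) abort(paste0("unknown state: ", state))
  ei <- engine_inputs(params, strategy)
  t <- age - ei$entry_age + 1
  if (t < 1 || t > ei$n_cycles) abort("age outside the modelled horizon")
  occ <- numeric(10)
  occ[i] <- 1
  out <- cycle_step(occ, t, ei, screen = isTRUE(on_screen_cycle))
  row <- out$occ
  if (abs(sum(row) - 1) > 1e-9) {
    abort(sprintf("transition row from %s sums to %.12f", state, sum(row)),
          class = "htn_construction_error")
  }
  setNames(row, STATE_NAMES)
}

#' Persistent state names
#' @return Character vector of the ten persistent states.
#' @export
states <- function() STATE_NAMES

#' Run the cohort simulation for one strategy
#'
#' Propagates the cohort distribution over the ten persistent states for
#' `n_cycles` annual cycles from the entry age, applying screening at the
#' start of qualifying cycles, and accrues per-cycle costs (screening,
#' confirmatory testing, treatment initiation and maintenance, event-year,
#' death-year, and post-event maintenance) and quality-adjusted life years.
#'
#' @param strategy One-row strategy tibble (see [screening_strategy()],
#'   [strategy_roster()]).
#' @param params An `htn_params` object.
#' @return A `cohort_trace`: a tibble with one row per cycle — `cycle` (0
#'   based), `age`, start-of-cycle occupancy in the ten state columns, the
#'   undiscounted cost components, `cost` and `qaly`, and their discounted
#'   versions `cost_disc`, `qaly_disc`.
#' @examples
#' params <- load_parameters(schedules = default_schedule_set(1))
#' trace <- run_cohort(strategy_roster()[1, ], params)
#' accrue(trace, params)
#' @export
run_cohort <- function(strategy, params) {
  ei <- engine_inputs(params, strategy)
  n <- ei$n_cycles
  occ <- matrix(0, nrow = n, ncol = 10, dimnames = list(NULL, STATE_NAMES))
  comp <- matrix(0, nrow = n, ncol = 6,
                 dimnames = list(NULL, c("cost_screen", "cost_confirm",
                                         "cost_treat", "cost_event",
                                         "cost_death", "cost_post")))
  qaly <- numeric(n)
  cur <- ei$init_occ
  for (t in seq_len(n)) {
    occ[t, ] <- cur
    step <- cycle_step(cur, t, ei)
    if (any(step$occ < -1e-12)) {
      abort("negative occupancy produced during propagation",
            class = "htn_propagation_error")
    }
    comp[t, ] <- c(step$cost_screen, step$cost_confirm, step$cost_treat,
                   step$cost_event, step$cost_death, step$cost_post)
    qaly[t] <- step$qaly
    cur <- step$occ
  }
  cost <- rowSums(comp)
  t0 <- seq_len(n) - 1
  df_c <- (1 + ei$r_cost)^(-t0)
  df_o <- (1 + ei$r_outcome)^(-t0)
  trace <- bind_cols(
    tibble(cycle = t0, age = ei$ages),
    as_tibble(occ),
    as_tibble(comp),
    tibble(cost = cost, qaly = qaly,
           cost_disc = cost * df_c, qaly_disc = qaly * df_o)
  )
  structure(trace, class = c("cohort_trace", class(trace)),
            strategy = strategy$label)
}

#' Discounted lifetime totals for a cohort trace
#'
#' Sums the per-cycle cost and QALY streams with annual discounting: the
#' contribution of cycle `t` (0-based) is divided by `(1 + r)^t`, so the
#' first cycle is undiscounted. No half-cycle correction is applied.
#'
#' @param trace A `cohort_trace` from [run_cohort()].
#' @param params An `htn_params` object supplying the discount rates.
#' @return A one-row tibble: `strategy`, `cost`, `qaly` (both discounted,
#'   per person).
#' @export
accrue <- function(trace, params) {
  t0 <- trace$cycle
  df_c <- (1 + params$config$discount_rate_costs)^(-t0)
  df_o <- (1 + params$config$discount_rate_outcomes)^(-t0)
  tibble(
    strategy = attr(trace, "strategy") %||% NA_character_,
    cost = sum(trace$cost * df_c),
    qaly = sum(trace$qaly * df_o)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run every strategy in a roster
#'
#' @param params An `htn_params` object.
#' @param roster Strategy tibble, one row per strategy (default: the full
#'   ten-strategy roster).
#' @return A tibble with columns `strategy`, `cost`, `qaly`.
#' @export
run_strategies <- function(params, roster = strategy_roster()) {
  purrr::map_dfr(seq_len(nrow(roster)), function(i) {
    accrue(run_cohort(roster[i, ], params), params)
  })
}

#' @export
print.cohort_trace <- function(x, ...) {
  cat("<cohort_trace> strategy:", attr(x, "strategy"), "\n")
  NextMethod()
}

#' @rdname run_cohort
#' @param x A `cohort_trace`.
#' @param ... Unused.
#' @export
tidy.cohort_trace <- function(x, ...) {
  as_tibble(x) %>%
    select("cycle", "age", dplyr::all_of(STATE_NAMES)) %>%
    tidyr::pivot_longer(dplyr::all_of(STATE_NAMES),
                        names_to = "state", values_to = "occupancy")
}

#' @rdname run_cohort
#' @export
glance.cohort_trace <- function(x, ...) {
  tibble(
    strategy = attr(x, "strategy"),
    n_cycles = nrow(x),
    cost = sum(x$cost_disc),
    qaly = sum(x$qaly_disc),
    cost_undiscounted = sum(x$cost),
    qaly_undiscounted = sum(x$qaly),
    p_dead_final = x$DEAD_CVD[nrow(x)] + x$DEAD_NON_CVD[nrow(x)]
  )
}
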