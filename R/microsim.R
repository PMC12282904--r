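#' Individual-level microsimulation oracle
#'
#' Simulates individuals through the same per-cycle probabilities as the
#' cohort engine, drawing every branch (screening participation, test
#' outcome, other-cause death, event occurrence, event decomposition,
#' progression) per person per cycle, and accruing the same discounted costs
#' and QALYs. Its sample mean converges to the cohort expectation, which
#' makes it an independent brute-force check on [run_cohort()] + [accrue()].
#'
#' @param strategy One-row strategy tibble.
#' @param params An `htn_params` object.
#' @param n_individuals Number of simulated individuals.
#' @param seed Integer seed.
#' @return A one-row tibble: `strategy`, `cost`, `qaly` (means), `cost_se`,
#'   `qaly_se` (standard errors of the means), `n`.
#' @examples
#' params <- load_parameters(schedules = default_schedule_set(1))
#' params$config$n_cycles <- 5
#' microsim_oracle(strategy_roster()[1, ], params, n_individuals = 1000, seed = 1)
#' @export
microsim_oracle <- function(strategy, params, n_individuals, seed = 1L) {
  stopifnot(n_individuals >= 1)
  ei <- engine_inputs(params, strategy)
  set.seed(as.integer(seed))
  n <- as.integer(n_individuals)

  # initial states sampled from the (renormalized) initial distribution
  init <- ei$init_occ[1:3]
  state <- sample.int(3, n, replace = TRUE, prob = init)
  cost_i <- numeric(n)
  qaly_i <- numeric(n)

  cd <- cumsum(ei$chd_dec) # fatal, mi, sa, ua
  sd_ <- cumsum(ei$str_dec) # fatal, nonfatal stroke, tia
  post_state_of <- c(4, 5, 6, 7, 8) # mi, stroke, sa, ua, tia order of cv_death
  cv_death_by_state <- setNames(ei$cv_death, c("4", "5", "6", "7", "8"))

  for (t in seq_len(ei$n_cycles)) {
    dfc <- (1 + ei$r_cost)^(-(t - 1))
    dfo <- (1 + ei$r_outcome)^(-(t - 1))
    alive <- state <= 8

    # start-of-cycle maintenance costs
    cost_i[state == 3] <- cost_i[state == 3] + ei$c_tx_prev * dfc
    for (k in 1:5) {
      m <- state == (3 + k)
      cost_i[m] <- cost_i[m] + ei$c_post[k] * dfc
    }

    u_part <- runif(n); u_test <- runif(n); u_d <- runif(n)
    u_ev <- runif(n); u_dec <- runif(n); u_prog <- runif(n)

    is_fp <- is_tp <- is_fn <- rep(FALSE, n)
    if (ei$screen[t]) {
      part_h <- alive & state == 1 & u_part < ei$part_h
      cost_i[part_h] <- cost_i[part_h] + ei$c_contact * dfc
      is_fp <- part_h & u_test >= ei$spec
      cost_i[is_fp] <- cost_i[is_fp] + ei$c_confirm * dfc
      part_u <- alive & state == 2 & u_part < ei$part_u
      cost_i[part_u] <- cost_i[part_u] + ei$c_contact * dfc
      is_tp <- part_u & u_test < ei$sens
      is_fn <- part_u & !is_tp
      cost_i[is_tp] <- cost_i[is_tp] + ei$c_confirm * dfc
    }

    die_ncv <- alive & u_d < ei$p_ncv[t]
    active <- alive & !die_ncv
    new_state <- state
    new_state[die_ncv] <- 10L

    # per-individual event (and post-state cardiovascular death) probabilities
    pc <- numeric(n); ps <- numeric(n); pd <- numeric(n)
    grp_h <- active & state == 1 & !is_fp
    pc[grp_h] <- ei$p_h_chd[t]; ps[grp_h] <- ei$p_h_str[t]
    gfp <- active & is_fp
    pc[gfp] <- ei$fp_chd; ps[gfp] <- ei$fp_str
    # false negatives keep the untreated state's event risks
    grp_u <- active & state == 2 & !is_tp
    pc[grp_u] <- ei$p_u_chd[t]; ps[grp_u] <- ei$p_u_str[t]
    gfn <- active & is_fn
    gtp <- active & is_tp
    pc[gtp] <- ei$tp_chd; ps[gtp] <- ei$tp_str
    gon <- active & state == 3
    pc[gon] <- ei$p_u_chd[t] * ei$rr_chd
    ps[gon] <- ei$p_u_str[t] * ei$rr_str
    p_rec_chd <- min(ei$p_h_chd[t] * ei$rr_rec_chd, 1)
    for (s in 4:8) {
      g <- active & state == s
      if (!any(g)) next
      pdk <- cv_death_by_state[[as.character(s)]]
      pd[g] <- pdk
      if (s %in% c(4, 6, 7)) pc[g] <- min(p_rec_chd, 1 - pdk)
      else ps[g] <- min(ei$p_rec_str, 1 - pdk)
    }

    die_cv <- active & u_ev < pd
    ev_chd <- active & !die_cv & u_ev < pd + pc
    ev_str <- active & !die_cv & !ev_chd & u_ev < pd + pc + ps
    new_state[die_cv] <- 9L

    # decompose CHD events
    if (any(ev_chd)) {
      u <- u_dec[ev_chd]
      dest <- ifelse(u < cd[1], 9L, ifelse(u < cd[2], 4L, ifelse(u < cd[3], 6L, 7L)))
      add <- ifelse(dest == 9L, ei$c_death_chd,
                    ifelse(dest == 4L, ei$c_event[["mi"]],
                           ifelse(dest == 6L, ei$c_event[["sa"]], ei$c_event[["ua"]])))
      cost_i[ev_chd] <- cost_i[ev_chd] + add * dfc
      new_state[ev_chd] <- dest
    }
    # decompose stroke events
    if (any(ev_str)) {
      u <- u_dec[ev_str]
      dest <- ifelse(u < sd_[1], 9L, ifelse(u < sd_[2], 5L, 8L))
      add <- ifelse(dest == 9L, ei$c_death_str,
                    ifelse(dest == 5L, ei$c_event[["stroke"]], ei$c_event[["tia"]]))
      cost_i[ev_str] <- cost_i[ev_str] + add * dfc
      new_state[ev_str] <- dest
    }

    no_ev <- active & !die_cv & !ev_chd & !ev_str
    # healthy path: hypertension incidence
    g <- no_ev & (grp_h | gfp)
    inc <- g & u_prog < ei$p_htn[t]
    new_state[inc] <- 2L
    new_state[g & !inc & is_fp] <- 1L # confirmed healthy
    # true positives: screening-driven treatment start
    g <- no_ev & gtp
    st <- g & u_prog < ei$uptake_tp
    cost_i[st] <- cost_i[st] + ei$c_tx_new_scr * dfc
    new_state[st] <- 3L
    new_state[g & !st] <- 2L
    # remaining untreated: background uptake
    g <- no_ev & (grp_u | gfn)
    st <- g & u_prog < ei$uptake[t]
    cost_i[st] <- cost_i[st] + ei$c_tx_new_bg * dfc
    new_state[st] <- 3L
    # on-treatment and post states without events stay put

    qaly_i <- qaly_i + ei$util[new_state] * dfo
    state <- new_state
  }

  tibble(
    strategy = strategy$label,
    cost = mean(cost_i), qaly = mean(qaly_i),
    cost_se = stats::sd(cost_i) / sqrt(n),
    qaly_se = stats::sd(qaly_i) / sqrt(n),
    n = n
  )
}
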