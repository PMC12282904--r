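# Shared fixtures: the synthetic base case, hand-built degenerate parameter
# sets for closed-form checks, and an independent frontier oracle.

base_params <- function(seed = 42, n_cycles = NULL) {
  p <- load_parameters(schedules = default_schedule_set(seed))
  if (!is.null(n_cycles)) p$config$n_cycles <- n_cycles
  p
}

# replace every age schedule with a constant
constant_schedules <- function(params, values) {
  for (nm in names(params$schedules)) {
    v <- if (nm %in% names(values)) values[[nm]] else 0
    params$schedules[[nm]]$value <- rep(v, nrow(params$schedules[[nm]]))
  }
  params
}

# a cohort frozen in one state: no events, no mortality, no progression
frozen_params <- function(state = c("healthy", "on_treatment"), seed = 42) {
  state <- match.arg(state)
  p <- constant_schedules(base_params(seed), list())
  init <- c(init_healthy = 0, init_htn_off_tx = 0, init_htn_on_tx = 0)
  init[[if (state == "healthy") "init_healthy" else "init_htn_on_tx"]] <- 1
  for (nm in names(init)) p <- set_parameter(p, nm, init[[nm]])
  p
}

no_screening <- function() strategy_roster()[1, ]

strategy_by_label <- function(label) {
  ro <- strategy_roster()
  ro[ro$label == label, , drop = FALSE]
}

# Independent frontier oracle: a strategy is absolutely dominated if another
# is strictly cheaper and at least as effective (ties on both keep the
# earlier row); the frontier is the set of strategies that maximize net
# monetary benefit for some willingness to pay, found by scanning the exact
# pairwise-slope breakpoints. Extended dominated = neither.
oracle_frontier <- function(results) {
  n <- nrow(results)
  cost <- results$cost
  qaly <- results$qaly
  status <- rep("undominated", n)
  for (i in seq_len(n)) {
    dominated <- any(cost < cost[i] & qaly >= qaly[i]) ||
      any(cost == cost[i] & qaly == qaly[i] & seq_len(n) < i)
    if (dominated) status[i] <- "absolutely_dominated"
  }
  surv <- which(status == "undominated")
  slopes <- c()
  for (i in surv) {
    for (j in surv) {
      if (qaly[j] > qaly[i]) slopes <- c(slopes, (cost[j] - cost[i]) / (qaly[j] - qaly[i]))
    }
  }
  slopes <- sort(unique(pmax(slopes, 0)))
  grid <- c(0, slopes, if (length(slopes)) 2 * max(slopes) + 1 else 1)
  grid <- sort(unique(c(grid, (head(grid, -1) + tail(grid, -1)) / 2)))
  on_frontier <- logical(n)
  for (w in grid) {
    nb <- w * qaly[surv] - cost[surv]
    best <- surv[nb == max(nb)]
    best <- best[which.min(cost[best])]
    on_frontier[best] <- TRUE
  }
  status[surv[!on_frontier[surv]]] <- "extended_dominated"
  status
}

random_instance <- function(n) {
  tibble::tibble(
    strategy = paste0("S", seq_len(n)),
    cost = round(runif(n, 0, 1000), 4),
    qaly = round(runif(n, 0, 10), 4)
  )
}
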