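#' Incremental analysis versus a fixed baseline
#'
#' For each strategy, the incremental cost, incremental effect and ICER
#' relative to a single comparator (conventionally no screening). The ICER is
#' reported only when the incremental effect is positive; with non-positive
#' incremental effect and positive incremental cost the ratio is left
#' undefined (`NA`) to avoid sign traps.
#'
#' @param results Tibble with columns `strategy`, `cost`, `qaly` (one row per
#'   strategy, unique labels).
#' @param baseline Label of the comparator strategy.
#' @return A tibble with `strategy`, `cost`, `qaly`, `inc_cost`,
#'   `inc_effect`, `icer`, and the dominance `status` from
#'   [frontier_analysis()].
#' @examples
#' res <- readr::read_csv(htn_fixture("reference_cea_iran.csv"),
#'                        show_col_types = FALSE)
#' incremental_vs_baseline(res, "No screening")
#' @export
incremental_vs_baseline <- function(results, baseline = "No screening") {
  if (anyDuplicated(results$strategy)) {
    abort("strategy labels must be unique")
  }
  b <- match(baseline, results$strategy)
  if (is.na(b)) abort(paste0("baseline strategy not found: ", baseline))
  fr <- frontier_analysis(results)
  results %>%
    mutate(
      inc_cost = .data$cost - results$cost[b],
      inc_effect = .data$qaly - results$qaly[b],
      icer = ifelse(.data$inc_effect > 0, .data$inc_cost / .data$inc_effect,
                    NA_real_)
    ) %>%
    left_join(select(fr$rows, "strategy", "status"), by = "strategy")
}

#' Dominance classification and the efficiency frontier
#'
#' A strategy is absolutely dominated when some other strategy costs strictly
#' less while delivering at least as many QALYs (weak dominance is folded in;
#' exact ties on both cost and QALY keep the earlier-listed strategy).
#' Extended dominance is then resolved by the usual iterative repair: the
#' surviving strategies are ordered by effectiveness and any strategy whose
#' step ICER exceeds the next step's is removed until the step ICERs are
#' non-decreasing. The survivors form the efficiency frontier.
#'
#' @param results Tibble with columns `strategy`, `cost`, `qaly`.
#' @return An object of class `cea_frontier`: a list with `rows` (all input
#'   strategies with `status` in `undominated`, `absolutely_dominated`,
#'   `extended_dominated`) and `frontier` (the undominated rows ordered by
#'   increasing QALY, with step `inc_cost`, `inc_effect` and `icer` versus
#'   the previous frontier strategy).
#' @export
frontier_analysis <- function(results) {
  if (nrow(results) < 1) abort("at least one strategy is required")
  if (anyDuplicated(results$strategy)) abort("strategy labels must be unique")
  res <- as_tibble(results)[, c("strategy", "cost", "qaly")]
  n <- nrow(res)
  status <- rep("undominated", n)

  # exact ties on (cost, qaly): keep the earlier-listed strategy
  for (i in seq_len(n)) {
    if (status[i] != "undominated") next
    dup <- which(res$cost == res$cost[i] & res$qaly == res$qaly[i])
    dup <- dup[dup > i]
    status[dup] <- "absolutely_dominated"
  }
  # absolute (strong, with weak folded in) dominance
  for (i in seq_len(n)) {
    if (status[i] == "absolutely_dominated") next
    if (any(res$cost < res$cost[i] & res$qaly >= res$qaly[i])) {
      status[i] <- "absolutely_dominated"
    }
  }

  # extended dominance: iterative ICER-monotonicity repair on the survivors
  surv <- which(status == "undominated")
  ord <- surv[order(res$qaly[surv], res$cost[surv])]
  repeat {
    if (length(ord) <= 2) break
    icers <- diff(res$cost[ord]) / diff(res$qaly[ord])
    bad <- which(diff(icers) < 0)
    if (!length(bad)) break
    # the strategy between a falling pair of step ICERs is extended dominated
    drop_idx <- ord[bad[1] + 1]
    status[drop_idx] <- "extended_dominated"
    ord <- setdiff(ord, drop_idx)
  }

  frontier <- res[ord, , drop = FALSE]
  if (nrow(frontier) > 1) {
    frontier$inc_cost <- c(NA_real_, diff(frontier$cost))
    frontier$inc_effect <- c(NA_real_, diff(frontier$qaly))
    frontier$icer <- frontier$inc_cost / frontier$inc_effect
  } else {
    frontier$inc_cost <- NA_real_
    frontier$inc_effect <- NA_real_
    frontier$icer <- NA_real_
  }
  rows <- res
  rows$status <- status
  structure(list(rows = rows, frontier = frontier), class = "cea_frontier")
}

#' Step ICERs along the efficiency frontier
#'
#' Each undominated strategy's ICER versus its predecessor on the frontier.
#' Accepts either a [frontier_analysis()] result or a pre-ordered ladder
#' tibble with `strategy`, `cost`, `qaly` columns (e.g. a published table of
#' undominated strategies), in which case step differences are taken in the
#' given row order.
#'
#' @param frontier A `cea_frontier` or an ordered tibble.
#' @return A tibble with `strategy`, `inc_cost`, `inc_effect`, `icer` —
#'   one row per frontier step (empty for a single-strategy frontier).
#' @export
step_icers <- function(frontier) {
  lad <- if (inherits(frontier, "cea_frontier")) frontier$frontier
  else as_tibble(frontier)
  if (nrow(lad) < 2) {
    return(tibble(strategy = character(), inc_cost = numeric(),
                  inc_effect = numeric(), icer = numeric()))
  }
  tibble(
    strategy = lad$strategy[-1],
    inc_cost = diff(lad$cost),
    inc_effect = diff(lad$qaly),
    icer = diff(lad$cost) / diff(lad$qaly)
  )
}

#' Net monetary benefit versus a baseline
#'
#' `wtp * (qaly - qaly_baseline) - (cost - cost_baseline)`.
#'
#' @param result,baseline One-row tibbles with `cost` and `qaly`.
#' @param wtp Willingness to pay per QALY (non-negative).
#' @return Net monetary benefit (money).
#' @export
nmb <- function(result, baseline, wtp) {
  stopifnot(wtp >= 0)
  wtp * (result$qaly - baseline$qaly) - (result$cost - baseline$cost)
}

#' Optimal strategy at a willingness-to-pay threshold
#'
#' Walks up the frontier ladder: the most effective strategy whose step ICER
#' does not exceed `wtp` (the frontier's cheapest strategy when none does).
#' This is the net-monetary-benefit maximizer among frontier strategies; ties
#' go to the cheaper strategy.
#'
#' When given a plain tibble, an existing `step_icer`-like column (`step_icer`
#' or `icer`) is used as the ladder if present, otherwise step ICERs are
#' recomputed from `cost` and `qaly` in row order.
#'
#' @param frontier A `cea_frontier` or an ordered ladder tibble.
#' @param wtp Willingness to pay per QALY.
#' @return The optimal strategy's label.
#' @examples
#' ladder <- readr::read_csv(htn_fixture("reference_frontier_iran.csv"),
#'                           show_col_types = FALSE)
#' optimal_at_wtp(ladder, 20652.44)
#' @export
optimal_at_wtp <- function(frontier, wtp) {
  if (inherits(frontier, "cea_frontier")) {
    lad <- frontier$frontier
    step <- lad$icer
  } else {
    lad <- as_tibble(frontier)
    step <- if ("step_icer" %in% names(lad)) lad$step_icer
    else if ("icer" %in% names(lad)) lad$icer
    else c(NA_real_, diff(lad$cost) / diff(lad$qaly))
  }
  if (nrow(lad) == 0) abort("empty frontier")
  best <- 1L
  for (i in seq_len(nrow(lad))[-1]) {
    if (!is.na(step[i]) && step[i] <= wtp) best <- i
  }
  lad$strategy[best]
}

#' @export
print.cea_frontier <- function(x, ...) {
  cat("<cea_frontier> ", nrow(x$frontier), " of ", nrow(x$rows),
      " strategies on the frontier\n", sep = "")
  print(x$rows)
  invisible(x)
}

#' @rdname frontier_analysis
#' @param x A `cea_frontier`.
#' @param ... Unused.
#' @export
tidy.cea_frontier <- function(x, ...) {
  left_join(x$rows,
            select(x$frontier, "strategy", "inc_cost", "inc_effect", "icer"),
            by = "strategy")
}

#' @rdname frontier_analysis
#' @export
glance.cea_frontier <- function(x, ...) {
  tibble(
    n_strategies = nrow(x$rows),
    n_undominated = sum(x$rows$status == "undominated"),
    n_absolutely_dominated = sum(x$rows$status == "absolutely_dominated"),
    n_extended_dominated = sum(x$rows$status == "extended_dominated"),
    max_step_icer = suppressWarnings(max(x$frontier$icer, na.rm = TRUE))
  )
}
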