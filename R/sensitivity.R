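#' Default one-way sensitivity ranges
#'
#' The published one-way analysis varies post-event utilities, the two
#' discount rates, the post-stroke maintenance cost, test sensitivity and
#' specificity, stroke and CHD recurrence, the stroke-event TIA share and CHD
#' event fatality over their 95% CI (or stated) ranges. This returns those
#' specs with the base value taken from the parameter set.
#'
#' @param params An `htn_params` object.
#' @return A tibble with columns `parameter`, `low`, `base`, `high`.
#' @export
owsa_default_specs <- function(params) {
  rows <- list(
    c("cost_post_stroke", 2376.4, 14859.7),
    c("discount_rate_costs", 0.03, 0.07),
    c("discount_rate_outcomes", 0.03, 0.07),
    c("p_stroke_recurrence", 0.0312, 0.069),
    c("u_post_mi", 0.626, 0.894),
    c("u_post_stroke", 0.323, 0.935),
    c("u_post_sa", 0.674, 0.942),
    c("u_post_ua", 0.636, 0.904),
    c("u_htn_off_tx", 0.922, 0.97),
    c("rr_chd_recurrence", 1.9, 2.8),
    c("specificity", 0.479, 0.904),
    c("sensitivity", 0.607, 0.848),
    c("stroke_tia", 0.134, 0.361),
    c("chd_fatal", 0.066, 0.178)
  )
  purrr::map_dfr(rows, function(r) {
    nm <- r[1]
    base <- if (nm %in% names(params$config)) params$config[[nm]]
    else param_value(params, nm)
    tibble(parameter = nm, low = as.numeric(r[2]), base = base,
           high = as.numeric(r[3]))
  })
}

#' One-way deterministic sensitivity analysis (tornado data)
#'
#' Reruns the model with each parameter at its low and high bound, holding
#' everything else at base, and records the chosen outcome for each strategy.
#' The result is ordered by bar width (|outcome at high - outcome at low|,
#' summed over strategies when several are analysed), the tornado-diagram
#' ordering.
#'
#' @param params An `htn_params` object.
#' @param specs Tibble of ranges (`parameter`, `low`, `base`, `high`); see
#'   [owsa_default_specs()].
#' @param strategies Strategy tibble (rows of [strategy_roster()]).
#' @param outcome One of `"nmb"` (net monetary benefit at `wtp` versus
#'   `baseline`; the default), `"cost"`, `"qaly"`, `"icer"` (versus
#'   `baseline`).
#' @param baseline Baseline label used by `"nmb"` and `"icer"`; it must be in
#'   `strategies` for those outcomes.
#' @param wtp Willingness to pay for the NMB outcome; defaults to the
#'   configured threshold.
#' @return A tibble with one row per (parameter, strategy): `parameter`,
#'   `strategy`, `outcome_low`, `outcome_base`, `outcome_high`, `width`,
#'   ordered by descending total width per parameter.
#' @export
run_owsa <- function(params, specs = owsa_default_specs(params),
                     strategies = strategy_roster(),
                     outcome = c("nmb", "cost", "qaly", "icer"),
                     baseline = "No screening",
                     wtp = params$config$wtp_threshold) {
  outcome <- match.arg(outcome)
  for (nm in specs$parameter) {
    if (!nm %in% params$scalars$name && !nm %in% names(params$config)) {
      abort(paste0("unknown parameter in OWSA spec: ", nm))
    }
  }
  if (outcome %in% c("nmb", "icer") && !baseline %in% strategies$label) {
    abort("baseline strategy must be among the analysed strategies")
  }

  outcome_of <- function(res) {
    switch(outcome,
      cost = res$cost,
      qaly = res$qaly,
      nmb = {
        b <- res[res$strategy == baseline, ]
        wtp * (res$qaly - b$qaly) - (res$cost - b$cost)
      },
      icer = {
        inc <- incremental_vs_baseline(res, baseline)
        inc$icer
      }
    )
  }
  eval_at <- function(values) {
    p2 <- params
    for (i in seq_along(specs$parameter)) {
      p2 <- set_parameter(p2, specs$parameter[i], specs$base[i])
    }
    # values overrides one parameter at a time
    if (!is.null(values)) p2 <- set_parameter(p2, values$parameter, values$value)
    res <- run_strategies(p2, strategies)
    outcome_of(res)
  }

  base_out <- eval_at(NULL)
  out <- purrr::map_dfr(seq_len(nrow(specs)), function(i) {
    lo <- eval_at(list(parameter = specs$parameter[i], value = specs$low[i]))
    hi <- eval_at(list(parameter = specs$parameter[i], value = specs$high[i]))
    tibble(parameter = specs$parameter[i], strategy = strategies$label,
           outcome_low = lo, outcome_base = base_out, outcome_high = hi,
           width = abs(hi - lo))
  })
  ord <- out %>%
    group_by(.data$parameter) %>%
    summarise(total_width = sum(.data$width, na.rm = TRUE)) %>%
    arrange(desc(.data$total_width))
  out %>%
    mutate(parameter = factor(.data$parameter, levels = ord$parameter)) %>%
    arrange(.data$parameter) %>%
    mutate(parameter = as.character(.data$parameter))
}

#' Assign probabilistic distributions to parameters
#'
#' Beta distributions for probabilities and utilities and gamma distributions
#' for costs, fitted by the method of moments with the standard deviation
#' inferred from the 95% CI width (`(ci_high - ci_low) / 3.92`, the normal
#' approximation). Parameters without a published CI stay fixed, as do
#' relative risks (the assigned families are restricted to beta and gamma).
#' When the implied variance is infeasible for the beta support the parameter
#' falls back to fixed with a warning.
#'
#' @param params An `htn_params` object.
#' @return A tibble with `parameter`, `family` (`"beta"`, `"gamma"`,
#'   `"fixed"`), `shape1`, `shape2` (beta shapes, or gamma shape and rate),
#'   `mean` (the fitted mean; equals the point estimate for fixed).
#' @export
assign_distributions <- function(params) {
  s <- params$scalars
  purrr::map_dfr(seq_len(nrow(s)), function(i) {
    row <- s[i, ]
    fixed <- tibble(parameter = row$name, family = "fixed",
                    shape1 = NA_real_, shape2 = NA_real_, mean = row$value)
    if (row$fixed) return(fixed)
    sdv <- (row$ci_high - row$ci_low) / 3.92
    m <- row$value
    if (row$kind %in% c("probability", "utility")) {
      v <- sdv^2
      if (v <= 0 || v >= m * (1 - m) || m <= 0 || m >= 1) {
        warn(paste0("infeasible beta moments for ", row$name, "; kept fixed"))
        return(fixed)
      }
      nu <- m * (1 - m) / v - 1
      tibble(parameter = row$name, family = "beta",
             shape1 = m * nu, shape2 = (1 - m) * nu, mean = m)
    } else if (row$kind == "cost") {
      if (sdv <= 0 || m <= 0) {
        warn(paste0("infeasible gamma moments for ", row$name, "; kept fixed"))
        return(fixed)
      }
      tibble(parameter = row$name, family = "gamma",
             shape1 = m^2 / sdv^2, shape2 = m / sdv^2, mean = m)
    } else {
      fixed
    }
  })
}

#' Probabilistic sensitivity analysis
#'
#' Samples every non-fixed parameter from its assigned distribution, rebuilds
#' the parameter set and reruns every strategy, `n_iter` times. Sampled
#' values falling outside a parameter's domain after assembly (possible only
#' through branch renormalization interactions) would trigger a resample;
#' beta and gamma sampling respects the domains by construction, so the
#' resample counter is normally zero.
#'
#' @param params An `htn_params` object.
#' @param strategies Strategy tibble.
#' @param n_iter Number of iterations.
#' @param seed Integer seed.
#' @param distributions Optional pre-computed [assign_distributions()] table
#'   (pass a table with every family set to `"fixed"` for a degenerate PSA).
#' @return An object of class `htn_psa`: list with `costs` and `qalys`
#'   (iteration x strategy matrices), `draws` (iteration x parameter matrix
#'   of sampled values), `strategies`, `n_iter`, `seed`, `n_resampled`.
#' @export
run_psa <- function(params, strategies = strategy_roster(), n_iter = 1000,
                    seed = 1L, distributions = assign_distributions(params)) {
  stopifnot(n_iter >= 1)
  set.seed(as.integer(seed))
  labs <- strategies$label
  sampled <- distributions[distributions$family != "fixed", , drop = FALSE]
  costs <- matrix(NA_real_, n_iter, length(labs), dimnames = list(NULL, labs))
  qalys <- matrix(NA_real_, n_iter, length(labs), dimnames = list(NULL, labs))
  draws <- matrix(NA_real_, n_iter, nrow(sampled),
                  dimnames = list(NULL, sampled$parameter))
  n_resampled <- 0L

  for (it in seq_len(n_iter)) {
    repeat {
      dr <- purrr::map_dbl(seq_len(nrow(sampled)), function(j) {
        if (sampled$family[j] == "beta") {
          rbeta(1, sampled$shape1[j], sampled$shape2[j])
        } else {
          rgamma(1, shape = sampled$shape1[j], rate = sampled$shape2[j])
        }
      })
      p2 <- params
      if (length(dr)) {
        idx <- match(sampled$parameter, p2$scalars$name)
        p2$scalars$value[idx] <- dr
      }
      viol <- validate_parameters(p2)
      if (!nrow(viol)) break
      n_resampled <- n_resampled + 1L
    }
    if (length(dr)) draws[it, ] <- dr
    res <- run_strategies(p2, strategies)
    costs[it, ] <- res$cost
    qalys[it, ] <- res$qaly
  }
  structure(
    list(costs = costs, qalys = qalys, draws = draws,
         strategies = labs, n_iter = n_iter, seed = as.integer(seed),
         n_resampled = n_resampled),
    class = "htn_psa"
  )
}

#' Cost-effectiveness acceptability curves
#'
#' For each willingness-to-pay value on the grid, the fraction of PSA
#' iterations in which each strategy maximizes net monetary benefit
#' (`wtp * qaly - cost`). Per-iteration ties go to the cheaper strategy, so
#' the probabilities sum to one at every grid point.
#'
#' @param psa An `htn_psa` from [run_psa()].
#' @param wtp_grid Numeric vector of willingness-to-pay values.
#' @return A tibble with columns `wtp`, `strategy`, `probability`.
#' @export
ceac <- function(psa, wtp_grid) {
  if (!length(wtp_grid)) abort("wtp_grid must be non-empty")
  labs <- psa$strategies
  purrr::map_dfr(wtp_grid, function(w) {
    nb <- w * psa$qalys - psa$costs
    wins <- integer(psa$n_iter)
    for (it in seq_len(psa$n_iter)) {
      best <- which(nb[it, ] == max(nb[it, ]))
      if (length(best) > 1) best <- best[which.min(psa$costs[it, best])]
      wins[it] <- best
    }
    tibble(wtp = w, strategy = labs,
           probability = tabulate(wins, nbins = length(labs)) / psa$n_iter)
  })
}

#' Acceptability at a single willingness-to-pay threshold
#'
#' The single-threshold slice of [ceac()].
#'
#' @inheritParams ceac
#' @param wtp One willingness-to-pay value.
#' @return A tibble with `strategy` and `probability`.
#' @export
acceptability_at_wtp <- function(psa, wtp) {
  ceac(psa, wtp) %>% select("strategy", "probability")
}

#' Cost-effectiveness plane scatter data
#'
#' Per-iteration incremental cost and effect of every strategy versus the
#' baseline — the simulated cloud plotted on the cost-effectiveness plane.
#'
#' @inheritParams ceac
#' @param baseline Baseline strategy label.
#' @return A tibble with `iteration`, `strategy`, `delta_cost`, `delta_qaly`.
#' @export
scatter_data <- function(psa, baseline = "No screening") {
  b <- match(baseline, psa$strategies)
  if (is.na(b)) abort(paste0("baseline not in PSA strategies: ", baseline))
  purrr::map_dfr(psa$strategies, function(lab) {
    j <- match(lab, psa$strategies)
    tibble(
      iteration = seq_len(psa$n_iter), strategy = lab,
      delta_cost = psa$costs[, j] - psa$costs[, b],
      delta_qaly = psa$qalys[, j] - psa$qalys[, b]
    )
  })
}

#' @export
print.htn_psa <- function(x, ...) {
  cat("<htn_psa> ", x$n_iter, " iterations x ", length(x$strategies),
      " strategies (seed ", x$seed, ", ", ncol(x$draws),
      " sampled parameters, ", x$n_resampled, " resampled)\n", sep = "")
  invisible(x)
}

#' @rdname run_psa
#' @param x An `htn_psa`.
#' @param ... Unused.
#' @export
tidy.htn_psa <- function(x, ...) {
  purrr::map_dfr(x$strategies, function(lab) {
    j <- match(lab, x$strategies)
    tibble(iteration = seq_len(x$n_iter), strategy = lab,
           cost = x$costs[, j], qaly = x$qalys[, j])
  })
}

#' @rdname run_psa
#' @export
glance.htn_psa <- function(x, ...) {
  tibble(
    n_iter = x$n_iter, n_strategies = length(x$strategies),
    n_sampled_parameters = ncol(x$draws), n_resampled = x$n_resampled,
    seed = x$seed
  )
}
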