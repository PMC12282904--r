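psa_test_params <- function() {
  p <- base_params(n_cycles = 10)
  p
}

psa_test_roster <- function() {
  ro <- strategy_roster()
  ro[ro$label %in% c("No screening",
                     "Screening every two years from the age of 30",
                     "Screening every three years from the age of 50"), ]
}

test_that("beta and gamma fits preserve the point estimate as the mean", {
  p <- base_params()
  d <- assign_distributions(p)
  s <- tidy(p)

  betas <- d[d$family == "beta", ]
  for (i in seq_len(nrow(betas))) {
    m <- betas$shape1[i] / (betas$shape1[i] + betas$shape2[i])
    v <- s$value[s$name == betas$parameter[i]]
    expect_lt(abs(m - v) / v, 0.02, label = betas$parameter[i])
  }
  gammas <- d[d$family == "gamma", ]
  for (i in seq_len(nrow(gammas))) {
    m <- gammas$shape1[i] / gammas$shape2[i]
    v <- s$value[s$name == gammas$parameter[i]]
    expect_lt(abs(m - v) / v, 0.02, label = gammas$parameter[i])
  }
  # the inferred sd matches the CI width under the normal approximation
  sens <- betas[betas$parameter == "sensitivity", ]
  sd_fit <- sqrt(sens$shape1 * sens$shape2 /
                 ((sens$shape1 + sens$shape2)^2 * (sens$shape1 + sens$shape2 + 1)))
  expect_equal(sd_fit, (0.848 - 0.607) / 3.92, tolerance = 1e-9)
})

test_that("parameters without CIs and relative risks stay fixed", {
  d <- assign_distributions(base_params())
  fixed <- d$parameter[d$family == "fixed"]
  expect_true(all(c("confirmatory_workup", "u_healthy", "init_healthy") %in% fixed))
  expect_true(all(c("rr_chd_on_treatment", "rr_chd_recurrence") %in% fixed))
  expect_false("sensitivity" %in% fixed)
  expect_false("tx_previous" %in% fixed)
})

test_that("infeasible beta moments fall back to fixed with a warning", {
  p <- base_params()
  i <- which(p$scalars$name == "event_risk_false_positive_stroke")
  p$scalars$ci_low[i] <- 0
  p$scalars$ci_high[i] <- 0.9
  expect_warning(d <- assign_distributions(p), "infeasible beta")
  expect_equal(d$family[d$parameter == "event_risk_false_positive_stroke"],
               "fixed")
})

test_that("one-way sensitivity orders parameters by bar width", {
  p <- psa_test_params()
  ro <- psa_test_roster()
  specs <- tibble::tibble(
    parameter = c("discount_rate_outcomes", "u_post_stroke", "sensitivity"),
    low = c(0.03, 0.323, 0.746),
    base = c(0.05, 0.629, 0.746),
    high = c(0.07, 0.935, 0.746)
  )
  out <- run_owsa(p, specs, ro, outcome = "qaly")
  # a spec with low = base = high has zero width
  expect_true(all(out$width[out$parameter == "sensitivity"] < 1e-12))
  # lower outcome discounting yields more QALYs
  disc <- out[out$parameter == "discount_rate_outcomes", ]
  expect_true(all(disc$outcome_low > disc$outcome_high))
  # ordering by total width, descending (in row order of appearance)
  widths <- vapply(unique(out$parameter),
                   function(nm) sum(out$width[out$parameter == nm]), 0)
  expect_true(all(diff(widths) <= 0))
  expect_error(run_owsa(p, tibble::tibble(parameter = "nope", low = 1,
                                          base = 1, high = 1), ro),
               "unknown parameter")
})

test_that("a degenerate PSA reproduces the base case exactly", {
  p <- psa_test_params()
  ro <- psa_test_roster()
  d <- assign_distributions(p)
  d$family <- "fixed"
  psa <- run_psa(p, ro, n_iter = 4, seed = 3, distributions = d)
  base <- run_strategies(p, ro)
  for (it in 1:4) {
    expect_equal(unname(psa$costs[it, ]), base$cost)
    expect_equal(unname(psa$qalys[it, ]), base$qaly)
  }
  expect_equal(ncol(psa$draws), 0)
  expect_equal(psa$n_resampled, 0L)
})

test_that("the PSA is seed-deterministic, iteration by iteration", {
  p <- psa_test_params()
  ro <- psa_test_roster()
  a <- run_psa(p, ro, n_iter = 3, seed = 21)
  b <- run_psa(p, ro, n_iter = 3, seed = 21)
  expect_identical(a$costs, b$costs)
  expect_identical(a$qalys, b$qalys)
  expect_identical(a$draws, b$draws)
  c <- run_psa(p, ro, n_iter = 3, seed = 22)
  expect_false(identical(a$costs, c$costs))
})

test_that("centered distributions keep PSA means near the base case", {
  p <- psa_test_params()
  ro <- psa_test_roster()[1:2, ]
  psa <- run_psa(p, ro, n_iter = 120, seed = 8)
  base <- run_strategies(p, ro)
  for (j in seq_len(nrow(ro))) {
    se <- stats::sd(psa$costs[, j]) / sqrt(psa$n_iter)
    expect_lt(abs(mean(psa$costs[, j]) - base$cost[j]), 4 * se,
              label = paste(ro$label[j], "cost"))
    se_q <- stats::sd(psa$qalys[, j]) / sqrt(psa$n_iter)
    expect_lt(abs(mean(psa$qalys[, j]) - base$qaly[j]), 4 * se_q,
              label = paste(ro$label[j], "qaly"))
  }
})

test_that("acceptability curves are normalized and honour WTP limits", {
  p <- psa_test_params()
  ro <- psa_test_roster()
  psa <- run_psa(p, ro, n_iter = 40, seed = 5)
  grid <- c(0, 1e3, 1e4, 5e4, 2e5)
  cc <- ceac(psa, grid)
  sums <- cc %>% dplyr::group_by(wtp) %>%
    dplyr::summarise(s = sum(probability)) %>% dplyr::pull(s)
  expect_equal(sums, rep(1, length(grid)), tolerance = 1e-12)

  # at WTP zero only cost-minimizing strategies can win
  at0 <- cc[cc$wtp == 0, ]
  winners <- at0$strategy[at0$probability > 0]
  for (it in seq_len(psa$n_iter)) {
    cheapest <- psa$strategies[which.min(psa$costs[it, ])]
    expect_true(cheapest %in% winners)
  }

  slice <- acceptability_at_wtp(psa, 1e4)
  expect_equal(slice$probability,
               cc$probability[cc$wtp == 1e4], tolerance = 1e-15)
  expect_true(all(slice$probability >= 0 & slice$probability <= 1))
})

test_that("a degenerate PSA yields a 0/1 step acceptability curve", {
  p <- psa_test_params()
  ro <- psa_test_roster()
  d <- assign_distributions(p)
  d$family <- "fixed"
  psa <- run_psa(p, ro, n_iter = 5, seed = 1, distributions = d)
  grid <- seq(0, 1e5, length.out = 21)
  cc <- ceac(psa, grid)
  expect_true(all(cc$probability %in% c(0, 1)))
  # the winner beyond the last frontier ICER stays the winner (monotone tail)
  base <- run_strategies(p, ro)
  fr <- frontier_analysis(base)
  last_icer <- max(fr$frontier$icer, na.rm = TRUE)
  top <- fr$frontier$strategy[nrow(fr$frontier)]
  tail_prob <- cc$probability[cc$strategy == top & cc$wtp > last_icer]
  expect_true(all(tail_prob == 1))
})

test_that("scatter data keep one point per iteration and strategy", {
  p <- psa_test_params()
  ro <- psa_test_roster()
  psa <- run_psa(p, ro, n_iter = 15, seed = 2)
  sc <- scatter_data(psa, "No screening")
  expect_equal(nrow(sc), 15 * nrow(ro))
  b <- sc[sc$strategy == "No screening", ]
  expect_true(all(b$delta_cost == 0 & b$delta_qaly == 0))
  counts <- table(sc$strategy)
  expect_true(all(counts == 15))
})
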