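test_that("transition rows are proper distributions from every state", {
  p <- base_params()
  strat <- strategy_by_label("Screening every two years from the age of 30")
  for (st in states()) {
    for (age in c(30, 45, 70, 95)) {
      for (scr in c(TRUE, FALSE)) {
        row <- transition_row(st, age, scr, p, strat)
        expect_true(all(row >= 0), label = paste(st, age, scr))
        expect_equal(sum(row), 1, tolerance = 1e-12,
                     label = paste(st, age, scr))
      }
    }
  }
})

test_that("dead states are absorbing", {
  p <- base_params()
  for (st in c("DEAD_CVD", "DEAD_NON_CVD")) {
    row <- transition_row(st, 50, FALSE, p)
    expect_equal(unname(row[st]), 1)
  }
})

test_that("treated event risk is the untreated risk scaled by the relative risks", {
  p <- base_params()
  age <- 55
  t <- age - 30 + 1
  d <- p$schedules$non_cvd_death$value[t]
  p_chd <- p$schedules$untreated_chd$value[t]
  p_str <- p$schedules$untreated_stroke$value[t]
  row <- transition_row("HTN_ON_TX", age, FALSE, p)
  str_dec <- renormalize_branch(c(0.1435, 0.518, 0.188))
  chd_dec <- renormalize_branch(c(0.122, 0.261, 0.503, 0.157))
  # total stroke-event mass = survivors x untreated stroke risk x RR 0.622
  stroke_mass <- row[["POST_STROKE"]] / str_dec[2]
  expect_equal(stroke_mass, (1 - d) * p_str * 0.622, tolerance = 1e-12)
  chd_mass <- row[["POST_MI"]] / chd_dec[2]
  expect_equal(chd_mass, (1 - d) * p_chd * 0.675, tolerance = 1e-12)
  # fatal shares follow the renormalized decompositions
  expect_equal(row[["DEAD_CVD"]],
               chd_mass * chd_dec[1] + stroke_mass * str_dec[1],
               tolerance = 1e-12)
})

test_that("untreated occupants face untreated risks outside screening rounds", {
  p <- base_params()
  scr <- strategy_by_label("Annual screening from the age of 30")
  expect_equal(transition_row("HTN_OFF_TX", 50, FALSE, p, scr),
               transition_row("HTN_OFF_TX", 50, FALSE, p, no_screening()))
  # and the screening-cycle false-negative risks equal the true-positive ones
  expect_equal(param_value(p, "event_risk_false_negative_chd"),
               param_value(p, "event_risk_true_positive_chd"))
  expect_equal(param_value(p, "event_risk_false_negative_stroke"),
               param_value(p, "event_risk_true_positive_stroke"))
})

test_that("identity dynamics freeze the occupancy distribution", {
  p <- constant_schedules(base_params(), list())
  tr <- run_cohort(no_screening(), p)
  for (st in states()) {
    expect_true(all(abs(tr[[st]] - tr[[st]][1]) < 1e-15), label = st)
  }
})

test_that("occupancy mass is conserved every cycle for every strategy", {
  p <- base_params()
  ro <- strategy_roster()
  for (i in seq_len(nrow(ro))) {
    tr <- run_cohort(ro[i, ], p)
    sums <- rowSums(as.matrix(tr[, states()]))
    expect_true(all(abs(sums - 1) < 1e-12), label = ro$label[i])
    expect_true(all(as.matrix(tr[, states()]) >= 0))
  }
})

test_that("an uninformative test makes screening a state no-op", {
  p <- base_params()
  p <- set_parameter(p, "sensitivity", 0)
  p <- set_parameter(p, "specificity", 1)
  tr_scr <- run_cohort(strategy_by_label("Annual screening from the age of 30"), p)
  tr_ns <- run_cohort(no_screening(), p)
  for (st in states()) {
    expect_equal(tr_scr[[st]], tr_ns[[st]], tolerance = 1e-12, label = st)
  }
  # contact costs are still incurred by participants
  expect_gt(sum(tr_scr$cost_screen), 0)
  expect_equal(sum(tr_scr$cost_confirm), 0)
})

test_that("QALY accrual matches the closed-form discounted annuity", {
  p <- frozen_params("healthy")
  res <- accrue(run_cohort(no_screening(), p), p)
  expect_equal(res$qaly, sum(1.05^-(0:69)), tolerance = 1e-9)
  expect_equal(res$cost, 0)

  # outcome discount rate of zero gives exactly one QALY per cycle
  p0 <- set_parameter(p, "discount_rate_outcomes", 0)
  expect_equal(accrue(run_cohort(no_screening(), p0), p0)$qaly, 70)
})

test_that("a constant cost stream is discounted cycle by cycle", {
  p <- frozen_params("on_treatment")
  # everyone on maintenance treatment: 57.56 per person-year
  res <- accrue(run_cohort(no_screening(), p), p)
  expect_equal(res$cost, 57.56 * sum(1.05^-(0:69)), tolerance = 1e-9)
  p0 <- set_parameter(p, "discount_rate_costs", 0)
  expect_equal(accrue(run_cohort(no_screening(), p0), p0)$cost, 57.56 * 70,
               tolerance = 1e-9)
})

test_that("zero utilities zero the QALY total", {
  p <- base_params()
  for (nm in grep("^u_", p$scalars$name, value = TRUE)) {
    p <- set_parameter(p, nm, 0)
  }
  res <- accrue(run_cohort(no_screening(), p), p)
  expect_equal(res$qaly, 0)
})

test_that("discounted accruals never exceed undiscounted ones", {
  p <- base_params()
  tr <- run_cohort(strategy_by_label("Screening every three years from the age of 40"), p)
  expect_true(all(tr$cost_disc <= tr$cost + 1e-12))
  expect_true(all(tr$qaly_disc <= tr$qaly + 1e-12))
})

test_that("trace tidiers expose occupancy and totals", {
  p <- base_params(n_cycles = 5)
  tr <- run_cohort(no_screening(), p)
  long <- tidy(tr)
  expect_equal(nrow(long), 5 * 10)
  expect_setequal(unique(long$state), states())
  g <- glance(tr)
  expect_equal(g$n_cycles, 5)
  expect_equal(g$cost, accrue(tr, p)$cost)
})
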