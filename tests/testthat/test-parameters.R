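test_that("the base-case fixture loads with the published point estimates", {
  p <- base_params()
  expect_s3_class(p, "htn_params")
  expect_equal(param_value(p, "specificity"), 0.746)
  expect_equal(1 - param_value(p, "specificity"), 0.254)

  printed <- c(
    participation_healthy = 0.563, participation_untreated = 0.673,
    sensitivity = 0.746, uptake_true_positive = 0.9,
    rr_chd_on_treatment = 0.675, rr_stroke_on_treatment = 0.622,
    rr_chd_recurrence = 2.4, p_stroke_recurrence = 0.0485,
    chd_fatal = 0.122, chd_mi = 0.261, chd_sa = 0.503, chd_ua = 0.157,
    stroke_fatal = 0.1435, stroke_nonfatal = 0.518, stroke_tia = 0.188,
    screening_contact = 1.56, confirmatory_workup = 212.57,
    tx_new_no_screen = 137.85, tx_new_with_screen = 139.41,
    tx_previous = 57.56, cost_event_mi = 16018.61,
    cost_event_stroke = 45152.33, cost_post_stroke = 8618,
    cost_death_chd = 8872.59, cost_death_stroke = 32119.09,
    u_htn_off_tx = 0.946, u_post_mi = 0.760, u_post_stroke = 0.629,
    u_post_sa = 0.808, u_post_ua = 0.770,
    init_healthy = 0.921, init_htn_on_tx = 0.041, init_htn_off_tx = 0.037
  )
  for (nm in names(printed)) {
    expect_identical(param_value(p, nm), printed[[nm]], label = nm)
  }
})

test_that("reversed confidence intervals are oriented without moving the estimate", {
  p <- base_params()
  s <- tidy(p)
  flipped <- s[s$name %in% c("u_htn_off_tx", "u_post_mi", "u_post_stroke",
                             "u_post_sa", "u_post_ua"), ]
  expect_true(all(flipped$ci_low < flipped$ci_high))
  expect_true(all(flipped$ci_low <= flipped$value & flipped$value <= flipped$ci_high))
  expect_setequal(p$ci_reoriented, flipped$name)
  # point estimates unchanged by orientation
  expect_equal(flipped$value[flipped$name == "u_post_stroke"], 0.629)
})

test_that("parameters without a CI are flagged fixed", {
  s <- tidy(base_params())
  expect_true(all(s$fixed[s$name %in% c("confirmatory_workup", "u_healthy",
                                        "init_healthy", "uptake_true_positive")]))
  expect_false(any(s$fixed[s$name %in% c("sensitivity", "tx_previous",
                                         "u_post_stroke")]))
})

test_that("out-of-range values and missing fields are rejected by name", {
  doc <- jsonlite::read_json(htn_fixture("base_case_parameters.json"),
                             simplifyVector = FALSE)
  bad <- doc
  i <- which(vapply(bad$parameters, function(x) x$name, "") == "u_post_mi")
  bad$parameters[[i]]$value <- 1.2
  f <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(bad, f, auto_unbox = TRUE)
  expect_error(
    load_parameters(f, schedules = default_schedule_set(1)),
    "u_post_mi", class = "htn_validation_error"
  )

  bad2 <- doc
  bad2$parameters[[1]]$name <- NULL
  jsonlite::write_json(bad2, f, auto_unbox = TRUE)
  expect_error(load_parameters(f, schedules = default_schedule_set(1)),
               "name", class = "htn_schema_error")

  expect_error(load_parameters(schedules = NULL, schedule_dir = NULL),
               "schedule", class = "htn_schema_error")
})

test_that("validate_parameters reports branch sums when renormalization is off", {
  suppressWarnings(
    p <- load_parameters(schedules = default_schedule_set(1),
                         renormalize = FALSE)
  )
  v <- validate_parameters(p)
  chd <- v[v$parameter == "CHD decomposition", ]
  expect_equal(nrow(chd), 1)
  expect_equal(chd$value, 0.122 + 0.261 + 0.503 + 0.157)
  expect_true("stroke decomposition" %in% v$parameter)
  expect_true("initial distribution" %in% v$parameter)
  # the valid renormalized fixture reports nothing
  expect_equal(nrow(validate_parameters(base_params())), 0)
})

test_that("negative costs are caught by validation", {
  p <- base_params()
  p$scalars$value[p$scalars$name == "tx_previous"] <- -5
  v <- validate_parameters(p)
  expect_true("negative cost" %in% v$rule)
  expect_true(all(v$parameter == "tx_previous"))
})

test_that("renormalize_branch rescales proportionally to unit sum", {
  chd <- c(0.122, 0.261, 0.503, 0.157)
  out <- renormalize_branch(chd)
  expect_equal(sum(out), 1, tolerance = 1e-15)
  expect_equal(out, chd / 1.043, tolerance = 1e-15)
  expect_equal(renormalize_branch(c(0.5, 0.5)), c(0.5, 0.5))
  stroke <- c(0.1435, 0.518, 0.188)
  expect_equal(renormalize_branch(stroke), stroke / 0.8495, tolerance = 1e-15)
  expect_error(renormalize_branch(c(0, 0)), class = "htn_degenerate_branch")
})

test_that("serialize/load round-trips the parameter set field for field", {
  p <- base_params(seed = 3)
  dir <- withr::local_tempdir()
  f <- file.path(dir, "params.json")
  write_parameters(p, f, schedule_dir = file.path(dir, "schedules"))
  p2 <- load_parameters(f, schedule_dir = file.path(dir, "schedules"))
  expect_equal(p2$scalars, p$scalars)
  expect_equal(p2$config, p$config)
  expect_equal(p2$schedules, p$schedules)
  expect_identical(p2$currency, p$currency)
})

test_that("set_parameter reaches scalars and analysis settings", {
  p <- base_params()
  p <- set_parameter(p, "sensitivity", 0.5)
  expect_equal(param_value(p, "sensitivity"), 0.5)
  p <- set_parameter(p, "discount_rate_costs", 0.03)
  expect_equal(p$config$discount_rate_costs, 0.03)
  expect_error(set_parameter(p, "not_a_parameter", 1), "unknown parameter")
})
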