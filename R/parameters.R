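#' Load the model parameter set
#'
#' Reads the scalar parameter file (JSON: probabilities, relative risks, costs,
#' utilities, analysis settings) and the eight age-indexed schedules the engine
#' needs (hypertension and cardiovascular incidence, background treatment
#' uptake, cardiovascular and other-cause mortality). Schedules can come from a
#' directory of `age,value` CSV files or from a pre-built schedule set such as
#' [default_schedule_set()]; with neither, loading fails, because the engine
#' cannot run without them.
#'
#' Confidence intervals printed high-to-low are re-oriented on load (the point
#' estimate is never changed). The CHD and stroke event decompositions and the
#' initial state distribution do not sum exactly to one as printed; with
#' `renormalize = TRUE` (the default) they are rescaled proportionally so the
#' transition structure is row-stochastic. Parameters without a published CI
#' are flagged `fixed` and excluded from probabilistic sampling.
#'
#' @param path Path to the JSON parameter file. Defaults to the base-case
#'   fixture shipped with the package.
#' @param schedule_dir Directory containing one `<name>.csv` per schedule
#'   (columns `age,value`), or `NULL`.
#' @param schedules A named list of schedule tibbles (columns `age`, `value`),
#'   e.g. from [default_schedule_set()]. Takes precedence over `schedule_dir`.
#' @param renormalize Rescale the event-decomposition branches and the initial
#'   distribution to sum to one. Turning this off leaves the printed values
#'   untouched (for sensitivity exploration); [validate_parameters()] will then
#'   report the branch-sum violations.
#' @return An object of class `htn_params`: a list with `scalars` (tibble:
#'   `name`, `value`, `ci_low`, `ci_high`, `kind`, `source`, `fixed`),
#'   `schedules` (named list of tibbles), `config` (list), `currency`, and
#'   `renormalized` (logical).
#' @examples
#' params <- load_parameters(schedules = default_schedule_set(seed = 1))
#' param_value(params, "specificity")
#' @export
load_parameters <- function(path = htn_fixture("base_case_parameters.json"),
                            schedule_dir = NULL,
                            schedules = NULL,
                            renormalize = TRUE) {
  if (!file.exists(path)) {
    abort(paste0("parameter file not found: ", path), class = "htn_schema_error")
  }
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  for (field in c("parameters", "config")) {
    if (is.null(raw[[field]])) {
      abort(paste0("parameter file is missing required field '", field, "'"),
            class = "htn_schema_error")
    }
  }

  scalars <- purrr::map_dfr(raw$parameters, function(p) {
    for (field in c("name", "value", "kind")) {
      if (is.null(p[[field]])) {
        abort(paste0("parameter entry is missing required field '", field, "'"),
              class = "htn_schema_error")
      }
    }
    tibble(
      name = p$name,
      value = as.numeric(p$value),
      ci_low = if (is.null(p$ci_low)) NA_real_ else as.numeric(p$ci_low),
      ci_high = if (is.null(p$ci_high)) NA_real_ else as.numeric(p$ci_high),
      kind = p$kind,
      source = if (is.null(p$source)) "" else p$source
    )
  })
  if (anyDuplicated(scalars$name)) {
    abort("duplicate parameter names in file", class = "htn_schema_error")
  }

  # orient reversed CIs (some are printed high-to-low)
  flipped <- !is.na(scalars$ci_low) & !is.na(scalars$ci_high) &
    scalars$ci_low > scalars$ci_high
  if (any(flipped)) {
    lo <- pmin(scalars$ci_low, scalars$ci_high)
    hi <- pmax(scalars$ci_low, scalars$ci_high)
    scalars$ci_low[flipped] <- lo[flipped]
    scalars$ci_high[flipped] <- hi[flipped]
  }
  scalars$fixed <- is.na(scalars$ci_low) | is.na(scalars$ci_high)

  config <- raw$config
  config_defaults <- list(
    discount_rate_costs = 0.05, discount_rate_outcomes = 0.05,
    n_cycles = 70, cohort_entry_age = 30,
    wtp_threshold = 20652.44, psa_iterations = 1000, rng_seed = 1L
  )
  for (nm in names(config_defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- config_defaults[[nm]]
    config[[nm]] <- as.numeric(config[[nm]])
  }

  sched <- schedules
  if (is.null(sched) && !is.null(schedule_dir)) {
    sched <- read_schedules(schedule_dir)
  }
  if (is.null(sched)) {
    abort(paste0(
      "no age-indexed schedules supplied: pass `schedule_dir` or ",
      "`schedules` (e.g. default_schedule_set(seed))"
    ), class = "htn_schema_error")
  }
  missing <- setdiff(required_schedules(), names(sched))
  if (length(missing)) {
    abort(paste0("missing required schedule(s): ", paste(missing, collapse = ", ")),
          class = "htn_schema_error")
  }
  sched <- purrr::map(sched[required_schedules()], ~ as_tibble(.x)[, c("age", "value")])

  params <- structure(
    list(
      scalars = scalars,
      schedules = sched,
      config = config,
      currency = if (is.null(raw$currency)) "PPP_int$_2020" else raw$currency,
      renormalized = isTRUE(renormalize),
      ci_reoriented = scalars$name[flipped]
    ),
    class = "htn_params"
  )

  viol <- validate_parameters(params)
  hard <- viol[viol$rule != "branch_sum", , drop = FALSE]
  if (nrow(hard)) {
    abort(paste0(
      "invalid parameter value(s): ",
      paste(sprintf("%s=%g (%s)", hard$parameter, hard$value, hard$rule),
            collapse = "; ")
    ), class = "htn_validation_error")
  }
  if (!renormalize && nrow(viol)) {
    warn(paste0("branch sums differ from 1 and renormalization is off: ",
                paste(unique(viol$parameter), collapse = ", ")))
  }
  params
}

#' Path to a packaged fixture file
#' @param file File name under the package's `extdata`.
#' @return Absolute path.
#' @export
htn_fixture <- function(file) {
  system.file("extdata", file, package = "htnscreen", mustWork = TRUE)
}

required_schedules <- function() {
  c("healthy_chd", "healthy_stroke", "htn_incidence",
    "untreated_chd", "untreated_stroke", "treatment_uptake",
    "cvd_death", "non_cvd_death")
}

read_schedules <- function(dir) {
  if (!dir.exists(dir)) {
    abort(paste0("schedule directory not found: ", dir), class = "htn_schema_error")
  }
  files <- list.files(dir, pattern = "\\.csv$", full.names = TRUE)
  sched <- purrr::map(files, function(f) {
    x <- readr::read_csv(f, col_types = readr::cols(
      age = readr::col_double(), value = readr::col_double()
    ))
    as_tibble(x)
  })
  names(sched) <- sub("\\.csv$", "", basename(files))
  sched
}

#' Look up a scalar parameter value by name
#' @param params An `htn_params` object.
#' @param name Parameter name.
#' @return The numeric point estimate.
#' @export
param_value <- function(params, name) {
  i <- match(name, params$scalars$name)
  if (is.na(i)) abort(paste0("unknown parameter: ", name))
  params$scalars$value[i]
}

#' Replace a scalar parameter or analysis setting
#'
#' Accepts either a scalar parameter name from the parameter table or an
#' analysis setting name (e.g. `discount_rate_costs`, `n_cycles`). Used by the
#' deterministic and probabilistic sensitivity analyses.
#'
#' @inheritParams param_value
#' @param value New numeric value.
#' @return The modified `htn_params` object.
#' @export
set_parameter <- function(params, name, value) {
  i <- match(name, params$scalars$name)
  if (!is.na(i)) {
    params$scalars$value[i] <- value
  } else if (name %in% names(params$config)) {
    params$config[[name]] <- value
  } else {
    abort(paste0("unknown parameter: ", name))
  }
  params
}

#' Validate a parameter set
#'
#' Checks every type invariant (probabilities and utilities in \[0, 1\], costs
#' non-negative, relative risks positive, oriented CIs bracketing the point
#' estimate, schedule support and range, event-decomposition branch sums) and
#' reports violations rather than failing.
#'
#' @inheritParams param_value
#' @return A tibble with columns `parameter`, `value`, `rule`; zero rows when
#'   every invariant holds.
#' @export
validate_parameters <- function(params) {
  s <- params$scalars
  v <- list()
  bad <- function(mask, rule) {
    if (any(mask)) {
      v[[length(v) + 1]] <<- tibble(parameter = s$name[mask],
                                    value = s$value[mask], rule = rule)
    }
  }
  bad(s$kind %in% c("probability", "utility") & (s$value < 0 | s$value > 1),
      "probability/utility outside [0, 1]")
  bad(s$kind == "cost" & s$value < 0, "negative cost")
  bad(s$kind == "relative_risk" & s$value <= 0, "relative risk must be positive")
  has_ci <- !is.na(s$ci_low) & !is.na(s$ci_high)
  bad(has_ci & (s$ci_low > s$value | s$value > s$ci_high),
      "oriented CI does not bracket the point estimate")

  if (!params$renormalized) {
    for (branch in list(
      list(names = c("chd_fatal", "chd_mi", "chd_sa", "chd_ua"), label = "CHD decomposition"),
      list(names = c("stroke_fatal", "stroke_nonfatal", "stroke_tia"), label = "stroke decomposition"),
      list(names = c("init_healthy", "init_htn_on_tx", "init_htn_off_tx"), label = "initial distribution")
    )) {
      total <- sum(s$value[match(branch$names, s$name)])
      if (abs(total - 1) > 1e-12) {
        v[[length(v) + 1]] <- tibble(
          parameter = branch$label, value = total, rule = "branch_sum"
        )
      }
    }
  }

  for (nm in names(params$schedules)) {
    sc <- params$schedules[[nm]]
    consecutive <- nrow(sc) > 0 && !anyNA(sc$age) &&
      all(sc$age == seq(min(sc$age), length.out = nrow(sc)))
    if (!consecutive) {
      v[[length(v) + 1]] <- tibble(parameter = nm, value = NA_real_,
                                   rule = "schedule ages not consecutive integers")
    }
    if (any(sc$value < 0 | sc$value > 1)) {
      v[[length(v) + 1]] <- tibble(parameter = nm, value = NA_real_,
                                   rule = "schedule value outside [0, 1]")
    }
  }
  if (length(v)) bind_rows(v) else tibble(parameter = character(),
                                          value = numeric(), rule = character())
}

#' Proportionally renormalize an event-decomposition branch
#'
#' The printed CHD branch probabilities sum to 1.043 and the stroke branch to
#' 0.8495; a row-stochastic model needs each branch to sum to exactly one, so
#' branches are rescaled proportionally.
#'
#' @param probs Non-negative numeric vector with positive sum.
#' @return `probs / sum(probs)`.
#' @examples
#' renormalize_branch(c(0.122, 0.261, 0.503, 0.157))
#' @export
renormalize_branch <- function(probs) {
  if (any(probs < 0)) abort("branch probabilities must be non-negative")
  total <- sum(probs)
  if (total <= 0) abort("degenerate branch: all probabilities are zero",
                        class = "htn_degenerate_branch")
  probs / total
}

#' Serialize a parameter set
#'
#' Writes the scalar table back to JSON (same schema the loader reads) and,
#' optionally, each schedule to `<name>.csv`. `load_parameters()` on the
#' written files reproduces the parameter set field for field.
#'
#' @inheritParams param_value
#' @param path Output JSON path for the scalars.
#' @param schedule_dir Optional directory for the schedule CSVs (created if
#'   needed).
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path, schedule_dir = NULL) {
  s <- params$scalars
  plist <- purrr::pmap(
    list(s$name, s$value, s$ci_low, s$ci_high, s$kind, s$source),
    function(name, value, lo, hi, kind, source) {
      out <- list(name = name, value = value, kind = kind, source = source)
      if (!is.na(lo)) out$ci_low <- lo
      if (!is.na(hi)) out$ci_high <- hi
      out
    }
  )
  doc <- list(currency = params$currency, config = params$config,
              parameters = plist)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(schedule_dir)) write_schedules(params$schedules, schedule_dir)
  invisible(path)
}

#' Write schedules as age,value CSV files
#' @param schedules Named list of schedule tibbles.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_schedules <- function(schedules, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(schedules)) {
    readr::write_csv(schedules[[nm]], file.path(dir, paste0(nm, ".csv")))
  }
  invisible(dir)
}

#' @export
print.htn_params <- function(x, ...) {
  cat("<htn_params> ", nrow(x$scalars), " scalar parameters, ",
      length(x$schedules), " age schedules (",
      x$currency, ")\n", sep = "")
  cat("  cycles:", x$config$n_cycles, " entry age:", x$config$cohort_entry_age,
      " discount:", x$config$discount_rate_costs, "\n")
  invisible(x)
}

#' @rdname load_parameters
#' @param x An `htn_params` object.
#' @param ... Unused.
#' @export
tidy.htn_params <- function(x, ...) {
  x$scalars
}

#' @rdname load_parameters
#' @export
glance.htn_params <- function(x, ...) {
  tibble(
    n_parameters = nrow(x$scalars),
    n_fixed = sum(x$scalars$fixed),
    n_schedules = length(x$schedules),
    n_cycles = x$config$n_cycles,
    cohort_entry_age = x$config$cohort_entry_age,
    discount_rate_costs = x$config$discount_rate_costs,
    discount_rate_outcomes = x$config$discount_rate_outcomes,
    wtp_threshold = x$config$wtp_threshold
  )
}
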