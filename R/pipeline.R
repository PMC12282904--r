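#' Run the full analysis pipeline and write its artifacts
#'
#' One entry point covering a complete evaluation: load (or synthesize) the
#' inputs, run every requested analysis, and write the result tables as CSV
#' plus a JSON manifest (inputs, seed, package version, parameter hash) that
#' makes the run reproducible. On failure, partial outputs are removed.
#'
#' @param config A named list (or path to a YAML file with the same fields):
#'   \describe{
#'     \item{params}{Path to the scalar parameter JSON (default: packaged
#'       base case).}
#'     \item{schedules}{Directory of schedule CSVs, or `NULL` to require
#'       `synthetic = TRUE`.}
#'     \item{synthetic}{Generate schedules with [default_schedule_set()]
#'       seeded by `seed`.}
#'     \item{strategies}{Character vector of roster labels, or `"all"`.}
#'     \item{analyses}{Subset of `c("cea", "owsa", "psa")`.}
#'     \item{psa_iterations}{Overrides the configured iteration count.}
#'     \item{out}{Output directory.}
#'     \item{seed}{Integer seed for schedule synthesis and the PSA.}
#'     \item{overrides}{Named list of parameter/setting overrides.}
#'   }
#' @return Invisibly, the manifest list (also written to `manifest.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  defaults <- list(
    params = htn_fixture("base_case_parameters.json"),
    schedules = NULL, synthetic = FALSE,
    strategies = "all", analyses = "cea",
    psa_iterations = NULL, out = ".", seed = 1L, overrides = list()
  )
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  }
  bad <- setdiff(config$analyses, c("cea", "owsa", "psa"))
  if (length(bad)) {
    abort(paste0("unknown analysis toggle(s): ", paste(bad, collapse = ", ")),
          class = "htn_config_error")
  }
  if (is.null(config$schedules) && !isTRUE(config$synthetic)) {
    abort("no schedules configured: set `schedules` or `synthetic: true`",
          class = "htn_config_error")
  }

  sched <- if (isTRUE(config$synthetic)) default_schedule_set(config$seed) else NULL
  params <- load_parameters(config$params, schedule_dir = config$schedules,
                            schedules = sched)
  for (nm in names(config$overrides)) {
    params <- set_parameter(params, nm, as.numeric(config$overrides[[nm]]))
  }

  roster <- strategy_roster()
  if (!identical(config$strategies, "all")) {
    missing <- setdiff(config$strategies, roster$label)
    if (length(missing)) {
      abort(paste0("unknown strategy label(s): ",
                   paste(missing, collapse = "; ")),
            class = "htn_config_error")
    }
    roster <- roster[roster$label %in% config$strategies, , drop = FALSE]
  }

  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  emit <- function(df, file) {
    path <- file.path(config$out, file)
    readr::write_csv(df, path)
    written <<- c(written, file)
  }

  ok <- FALSE
  on.exit(if (!ok) unlink(file.path(config$out, written)), add = TRUE)

  results <- run_strategies(params, roster)
  emit(results, "strategy_results.csv")

  if ("cea" %in% config$analyses) {
    fr <- frontier_analysis(results)
    inc <- incremental_vs_baseline(results, results$strategy[1])
    files <- render_cea_tables(inc, fr, config$out)
    written <- c(written, files)
    emit(select(fr$rows, "strategy", "cost", "qaly", "status"), "ce_plane.csv")
  }
  if ("owsa" %in% config$analyses) {
    emit(run_owsa(params, strategies = roster), "tornado.csv")
  }
  if ("psa" %in% config$analyses) {
    n_iter <- config$psa_iterations %||% params$config$psa_iterations
    psa <- run_psa(params, roster, n_iter = n_iter, seed = config$seed)
    emit(tidy(psa), "psa_iterations.csv")
    if (ncol(psa$draws)) {
      emit(as_tibble(psa$draws) %>% mutate(iteration = row_number(), .before = 1),
           "psa_draws.csv")
    }
    grid <- seq(0, 2 * params$config$wtp_threshold, length.out = 41)
    emit(tidyr::pivot_wider(ceac(psa, grid), names_from = "strategy",
                            values_from = "probability"), "ceac.csv")
  }

  manifest <- list(
    package = "htnscreen",
    version = as.character(utils::packageVersion("htnscreen")),
    seed = config$seed,
    params_file = config$params,
    synthetic_schedules = isTRUE(config$synthetic),
    analyses = config$analyses,
    strategies = roster$label,
    parameter_hash = parameter_hash(params),
    outputs = sort(unique(written))
  )
  jsonlite::write_json(manifest, file.path(config$out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  ok <- TRUE
  invisible(manifest)
}

# rolling polynomial hash over the serialized parameter content; stable
# across sessions (content fingerprint, not cryptographic)
parameter_hash <- function(params) {
  s <- params$scalars
  txt <- paste(
    paste(s$name, format(s$value, digits = 17), s$kind, collapse = ";"),
    paste(purrr::map_chr(params$schedules, function(x) {
      paste(format(x$value, digits = 17), collapse = ",")
    }), collapse = "|"),
    paste(names(params$config), unlist(params$config), collapse = ","),
    sep = "#"
  )
  h <- 0
  for (b in utf8ToInt(txt)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Write Table-style CEA summaries as CSV
#'
#' Two files mirroring the conventional layout: the incremental comparison of
#' every strategy against the baseline (`cea_vs_baseline.csv`) and the
#' undominated ladder with step ICERs (`cea_frontier.csv`). Money and QALYs
#' are written at full precision; round on presentation.
#'
#' @param rows Output of [incremental_vs_baseline()].
#' @param frontier A `cea_frontier`.
#' @param dir Output directory.
#' @return The written file names, invisibly.
#' @export
render_cea_tables <- function(rows, frontier, dir = ".") {
  f1 <- file.path(dir, "cea_vs_baseline.csv")
  readr::write_csv(
    select(rows, "strategy", "cost", "inc_cost", "qaly", "inc_effect",
           "icer", "status"),
    f1
  )
  lad <- frontier$frontier
  f2 <- file.path(dir, "cea_frontier.csv")
  readr::write_csv(
    select(lad, "strategy", "cost", "inc_cost", "qaly", "inc_effect", "icer"),
    f2
  )
  invisible(c("cea_vs_baseline.csv", "cea_frontier.csv"))
}
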