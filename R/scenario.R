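#' Load and validate a scenario configuration
#'
#' A scenario bundles everything one simulation run needs: the chemical
#' list with reference values, the exposure-factor model, the target-organ
#' groupings, and run settings (iterations, seed, molar volume). Scenarios
#' are YAML files; any omitted top-level section (`chemicals`, `factors`,
#' `groupings`, `iterations`, `seed`, `at_days`, `molar_volume`) is filled
#' from the packaged default scenario (the shipyard-painting configuration),
#' so an empty file yields the default run; a supplied section replaces the
#' default one as a unit. All validation happens before any computation, and
#' every problem found is reported in one itemized error.
#'
#' @param path Path to a YAML (or JSON) scenario file; `NULL` loads the
#'   packaged default.
#' @return An object of class `scenario_config`: list with `chems`,
#'   `model`, `groupings`, `iterations`, `seed`, `molar_volume`.
#' @export
load_scenario <- function(path = NULL) {
  default <- yaml::read_yaml(system.file("extdata", "default_scenario.yaml",
                                         package = "solventrisk", mustWork = TRUE))
  cfg <- if (is.null(path)) default else {
    if (!file.exists(path)) stop(sprintf("scenario file '%s' not found", path), call. = FALSE)
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
    # top-level sections are replaced as units; omitted ones keep defaults
    merged <- default
    merged[names(user)] <- user
    merged
  }
  problems <- character(0)
  note <- function(msg) problems <<- c(problems, msg)

  if (!is.numeric(cfg$iterations) || cfg$iterations < 1)
    note("iterations must be >= 1")
  if (!is.numeric(cfg$at_days) || cfg$at_days <= 0)
    note("at_days must be > 0")

  chems <- list(); conc <- list()
  for (entry in cfg$chemicals) {
    ch <- tryCatch(
      chemical_spec(entry$name, entry$mw,
                    rfc = entry$rfc %||% list(),
                    rfd = entry$rfd %||% list(),
                    count = entry$count %||% 0L),
      error = function(e) { note(conditionMessage(e)); NULL })
    if (is.null(ch)) next
    chems[[ch$name]] <- ch
    cs <- entry$concentration
    if (is.null(cs)) {
      note(sprintf("chemical '%s' has no concentration block", ch$name))
    } else {
      conc[[ch$name]] <- tryCatch(
        moments_to_spec(cs$family %||% "lognormal", cs$mean, cs$sd),
        error = function(e) { note(sprintf("chemical '%s': %s", ch$name,
                                           conditionMessage(e))); NULL })
    }
  }

  factor_spec <- function(block, what) {
    tryCatch(moments_to_spec(block$family, block$mean, block$sd),
             error = function(e) { note(sprintf("%s: %s", what,
                                                conditionMessage(e))); NULL })
  }
  et <- factor_spec(cfg$factors$et, "factor ET")
  ed <- factor_spec(cfg$factors$ed, "factor ED")
  ef <- factor_spec(cfg$factors$ef, "factor EF")

  groupings <- lapply(names(cfg$groupings), function(g)
    tryCatch(toxicity_grouping(g, cfg$groupings[[g]]),
             error = function(e) { note(conditionMessage(e)); NULL }))
  groupings <- stats::setNames(groupings, names(cfg$groupings))

  for (g in groupings) {
    if (is.null(g)) next
    for (m in g$members) {
      if (is.null(chems[[m]])) {
        note(sprintf("grouping '%s' names chemical '%s' absent from the chemical list",
                     g$group_name, m))
        next
      }
      if (is.null(conc[[m]]))
        note(sprintf("grouping member '%s' has no concentration spec", m))
      tryCatch(resolve_reference_concentration(chems[[m]], g$group_name),
               error = function(e) note(conditionMessage(e)))
    }
  }
  if (length(problems))
    stop(paste0("invalid scenario:\n", paste0("  - ", problems, collapse = "\n")),
         call. = FALSE)

  model <- exposure_factor_model(conc, et, ed, ef, as.numeric(cfg$at_days))
  structure(list(chems = chems, model = model, groupings = groupings,
                 iterations = as.integer(cfg$iterations),
                 seed = as.integer(cfg$seed %||% 1L),
                 molar_volume = cfg$molar_volume %||% 24.45),
            class = "scenario_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a loaded scenario
#'
#' Thin wrapper over [run_simulation()] taking a [load_scenario()] result.
#'
#' @param config A `scenario_config`.
#' @param n,seed Optional overrides of the scenario's iteration count and
#'   seed.
#' @return An `hq_simulation`.
#' @export
run_scenario <- function(config, n = config$iterations, seed = config$seed) {
  stopifnot(inherits(config, "scenario_config"))
  run_simulation(config$chems, config$model, config$groupings,
                 n = n, seed = seed, molar_volume = config$molar_volume)
}

#' Write the five study-style result tables
#'
#' Renders a simulation and its sensitivity reports as CSV files in the
#' layout of the study's result tables: per-chemical HQ percentiles with the
#' percent above 1; per-group HI percentiles with the percent above 1; one
#' factor-by-chemical Spearman table for the HQs; and one factor table per
#' hazard-index group. Every file starts with a comment header recording the
#' seed, iteration count and model hash, and numbers are written with four
#' significant digits; two runs with the same configuration and seed produce
#' byte-identical files.
#'
#' @param sim An `hq_simulation`.
#' @param reports The matching [sensitivity_reports()] list; must come from
#'   the same run (seed and iteration count are checked).
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written (named character vector).
#' @export
render_tables <- function(sim, reports, dir) {
  stopifnot(inherits(sim, "hq_simulation"))
  for (r in reports) {
    if (!identical(r$n, sim$n) || !identical(r$seed, sim$seed))
      stop(sprintf("sensitivity report '%s' does not match the simulation run (seed/n differ)",
                   r$label), call. = FALSE)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  header <- sprintf("# seed=%s n=%d model=%s", format(sim$seed), sim$n, sim$model_hash)
  emit <- function(df, file) {
    path <- file.path(dir, file)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(header, con)
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], signif, digits = 4)
    utils::write.csv(df, con, row.names = FALSE)
    path
  }

  chems <- colnames(sim$hq)
  hq_sens <- vapply(chems, function(m) {
    tab <- reports[[paste0("hq: ", m)]]$table
    stats::setNames(tab$rho, sub("^concentration: .*$", "concentration", tab$factor))
  }, numeric(4))
  hq_sens_df <- data.frame(factor = rownames(hq_sens), hq_sens,
                           row.names = NULL, check.names = FALSE)

  paths <- c(
    hq = emit(sim$hq_summary, "table_hq.csv"),
    hi = emit(sim$hi_summary, "table_hi.csv"),
    sensitivity_hq = emit(hq_sens_df, "table_sensitivity_hq.csv"))
  for (g in names(sim$hi)) {
    tab <- reports[[paste0("hi: ", g)]]$table
    paths[[paste0("sensitivity_hi_", g)]] <-
      emit(tab, sprintf("table_sensitivity_hi_%s.csv", gsub("\\W+", "_", g)))
  }
  invisible(paths)
}
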