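#' Generate synthetic workplace-monitoring records for one chemical
#'
#' Emulates the row structure of national workplace-environment monitoring
#' data (year, business / industry / process codes, worker id, chemical,
#' measured airborne concentration in ppm) with concentrations drawn from a
#' supplied distribution. All metadata come from a small fixed synthetic
#' vocabulary — the real codebooks are not public — so records are useful
#' for exercising the fitting and simulation layers, not for lookup.
#'
#' @param chem A [chemical_spec()].
#' @param spec A `dist_spec` supported on positive values (the per-chemical
#'   concentration model, ppm).
#' @param n Number of records (defaults to `chem$count`).
#' @param seed Integer seed; the output is a pure function of
#'   (chem, spec, n, seed).
#' @param year Calendar year stamped on the records.
#' @return A data frame with columns `year`, `business_id`, `industry_code`,
#'   `process_code`, `worker_id`, `chemical`, `concentration_ppm`.
#' @export
generate_measurements <- function(chem, spec, n = chem$count, seed = 1L,
                                  year = 2018L) {
  stopifnot(inherits(chem, "chemical_spec"), inherits(spec, "dist_spec"))
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  if (!(dist_positive_support(spec$family) ||
        spec$family %in% c("logistic", "normal", "point_mass")))
    stop(sprintf("unsupported concentration family '%s'", spec$family), call. = FALSE)
  businesses <- sprintf("SB-%03d", 1:13)        # 13 synthetic shipbuilders
  processes <- c("PNT-SPRAY", "PNT-BRUSH", "PNT-ROLLER")
  with_seed(seed, {
    conc <- draw_positive(spec, n, paste0("concentration (", chem$name, ")"))
    data.frame(
      year = rep(as.integer(year), n),
      business_id = sample(businesses, n, replace = TRUE),
      industry_code = rep("C31111", n),          # steel shipbuilding (synthetic)
      process_code = sample(processes, n, replace = TRUE),
      worker_id = sprintf("W%06d", sample.int(1e6 - 1L, n)),
      chemical = rep(chem$name, n),
      concentration_ppm = conc,
      stringsAsFactors = FALSE)
  })
}

#' Generate the full synthetic monitoring table
#'
#' One [generate_measurements()] block per chemical, with the packaged
#' default record counts, bound into a single table. Each chemical's block
#' gets a sub-seed derived from `seed` so blocks are independent but the
#' whole table is reproducible.
#'
#' @param chems Named list of [chemical_spec()]s.
#' @param model An [exposure_factor_model()] providing the per-chemical
#'   concentration specs.
#' @param seed Integer seed.
#' @return Data frame with one row per measurement record.
#' @export
generate_measurement_table <- function(chems = default_chemicals(),
                                       model = default_exposure_model(),
                                       seed = 1L) {
  blocks <- lapply(seq_along(chems), function(i) {
    chem <- chems[[i]]
    spec <- model$concentration[[chem$name]]
    if (is.null(spec))
      stop(sprintf("no concentration spec for chemical '%s'", chem$name), call. = FALSE)
    sub_seed <- as.integer((as.numeric(seed) * 131 + i) %% 2147483647)
    generate_measurements(chem, spec, seed = sub_seed)
  })
  do.call(rbind, blocks)
}

#' Generate synthetic worker exposure-factor samples
#'
#' Draws (ET, ED, EF) rows from the model's factor distributions — the kind
#' of table the working-conditions survey would yield — suitable as input to
#' the fitting layer for round-trip family-recovery checks.
#'
#' @param model An [exposure_factor_model()].
#' @param n Number of workers (`>= 1`).
#' @param seed Integer seed.
#' @return Data frame with columns `et_hours_day`, `ed_years`,
#'   `ef_days_year`, all positive.
#' @export
generate_worker_factors <- function(model = default_exposure_model(), n, seed = 1L) {
  draws <- sample_factors(model, n, seed)
  data.frame(et_hours_day = draws$et,
             ed_years = draws$ed,
             ef_days_year = draws$ef)
}
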