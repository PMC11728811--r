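#' Chemical reference specification
#'
#' Bundles a solvent's identity with the toxicological reference values used
#' to score its inhalation risk: per-endpoint reference concentrations (RfC,
#' mg/m3) and/or reference doses (RfD, mg/kg/day), the molecular weight used
#' for ppm conversion, and the default number of monitoring records to
#' synthesize for it.
#'
#' @param name Chemical identifier (lower-case, used as a key throughout).
#' @param mw Molecular weight in g/mol; must be positive.
#' @param rfc Named list mapping toxicity label to RfC in mg/m3 (may be empty).
#' @param rfd Named list mapping toxicity label to RfD in mg/kg/day (may be
#'   empty).
#' @param count Default number of monitoring records for the synthetic
#'   generator (nonnegative integer).
#' @return An object of class `chemical_spec`.
#' @export
chemical_spec <- function(name, mw, rfc = list(), rfd = list(), count = 0L) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.numeric(mw) || length(mw) != 1L || mw <= 0)
    stop(sprintf("'%s': molecular weight must be a positive number", name), call. = FALSE)
  rfc <- as.list(rfc); rfd <- as.list(rfd)
  for (set in list(rfc = rfc, rfd = rfd)) {
    v <- unlist(set)
    if (length(v) && any(!is.finite(v) | v <= 0))
      stop(sprintf("'%s': all reference values must be finite and > 0", name), call. = FALSE)
  }
  if (!is.numeric(count) || length(count) != 1L || count < 0 || count != round(count))
    stop(sprintf("'%s': count must be a nonnegative integer", name), call. = FALSE)
  structure(list(name = name, mw = mw, rfc = rfc, rfd = rfd,
                 count = as.integer(count)),
            class = "chemical_spec")
}

#' @export
print.chemical_spec <- function(x, ...) {
  fmt <- function(l) if (length(l))
    paste(sprintf("%s=%.4g", names(l), unlist(l)), collapse = ", ") else "-"
  cat(sprintf("<chemical_spec> %s (MW %.2f g/mol, %d records)\n  RfC [mg/m3]: %s\n  RfD [mg/kg/day]: %s\n",
              x$name, x$mw, x$count, fmt(x$rfc), fmt(x$rfd)))
  invisible(x)
}

#' Target-organ toxicity grouping
#'
#' Names the chemicals whose hazard quotients are summed into one hazard
#' index under the dose-addition assumption for a shared target organ.
#'
#' @param group_name Toxicity label (e.g. `"nervous"`, `"developmental"`);
#'   must match a label present in the member chemicals' reference values.
#' @param members Character vector of chemical names; non-empty, no
#'   duplicates.
#' @return An object of class `toxicity_grouping`.
#' @export
toxicity_grouping <- function(group_name, members) {
  stopifnot(is.character(group_name), length(group_name) == 1L)
  members <- as.character(members)
  if (!length(members)) stop("a toxicity grouping needs at least one member", call. = FALSE)
  if (anyDuplicated(members))
    stop(sprintf("grouping '%s' lists duplicate members", group_name), call. = FALSE)
  structure(list(group_name = group_name, members = members),
            class = "toxicity_grouping")
}

#' Convert an oral reference dose to an inhalation reference concentration
#'
#' Applies the standard body-weight / inhalation-volume conversion for a
#' 70 kg adult breathing 20 m3/day:
#' `RfC (mg/m3) = RfD (mg/kg/day) * 70 kg / 20 m3/day`.
#'
#' @param rfd Reference dose in mg/kg/day; nonnegative, vectorized.
#' @return Reference concentration in mg/m3.
#' @examples
#' rfd_to_rfc(0.1)  # 0.35 mg/m3
#' @export
rfd_to_rfc <- function(rfd) {
  if (!is.numeric(rfd) || any(rfd < 0, na.rm = TRUE))
    stop("rfd must be nonnegative", call. = FALSE)
  rfd * 70 / 20
}

#' Convert airborne concentrations between ppm and mg/m3
#'
#' Uses the ideal-gas molar volume at 25 degrees C and 1 atm
#' (24.45 L/mol by default, the usual occupational-hygiene convention):
#' `mg/m3 = ppm * MW / 24.45`.
#'
#' @param value Concentration value(s); nonnegative.
#' @param mw Molecular weight in g/mol.
#' @param from,to Unit labels, each `"ppm"` or `"mg/m3"`.
#' @param molar_volume Molar volume in L/mol (default 24.45).
#' @return Converted concentration(s).
#' @examples
#' convert_concentration(10, 106.17, "ppm", "mg/m3")
#' @export
convert_concentration <- function(value, mw, from, to, molar_volume = 24.45) {
  units <- c("ppm", "mg/m3")
  if (!(from %in% units)) stop(sprintf("unknown unit '%s'", from), call. = FALSE)
  if (!(to %in% units)) stop(sprintf("unknown unit '%s'", to), call. = FALSE)
  if (!is.numeric(value) || any(value < 0, na.rm = TRUE))
    stop("concentration must be nonnegative", call. = FALSE)
  if (!is.numeric(mw) || mw <= 0) stop("molecular weight must be > 0", call. = FALSE)
  if (from == to) return(value)
  if (from == "ppm") value * mw / molar_volume else value * molar_volume / mw
}

#' Resolve the reference concentration for a chemical and toxicity endpoint
#'
#' Returns the stored RfC for the requested toxicity label when one exists;
#' otherwise converts the stored RfD via [rfd_to_rfc()]. A direct RfC always
#' takes precedence over a converted RfD.
#'
#' @param chem A [chemical_spec()].
#' @param toxicity Toxicity label (e.g. `"nervous"`).
#' @return Reference concentration in mg/m3 (positive scalar).
#' @export
resolve_reference_concentration <- function(chem, toxicity) {
  stopifnot(inherits(chem, "chemical_spec"))
  if (!is.null(chem$rfc[[toxicity]])) return(chem$rfc[[toxicity]])
  if (!is.null(chem$rfd[[toxicity]])) return(rfd_to_rfc(chem$rfd[[toxicity]]))
  stop(sprintf("no RfC or RfD stored for chemical '%s', toxicity '%s'",
               chem$name, toxicity), call. = FALSE)
}

#' Packaged reference chemicals for the shipyard-painting scenario
#'
#' Six organic solvents dominating solvent use in Korean steel-shipbuilding
#' paint shops, with EPA IRIS reference values by toxicity endpoint and the
#' 2018 workplace-monitoring record counts used by the synthetic generator.
#' Molecular weights are standard textbook constants.
#'
#' Endpoints beyond the nervous/developmental groupings (xylene "other",
#' toluene "urinary", ethylbenzene "hepatic"/"urinary") are stored for
#' completeness but excluded from [default_groupings()].
#'
#' @return Named list of [chemical_spec()] objects.
#' @export
default_chemicals <- function() {
  chems <- list(
    chemical_spec("xylene", 106.17,
                  rfc = list(nervous = 0.1),
                  rfd = list(other = 0.2), count = 952L),
    chemical_spec("n-butanol", 74.12,
                  rfd = list(nervous = 0.1), count = 449L),
    chemical_spec("ethylbenzene", 106.17,
                  rfc = list(developmental = 1.0),
                  rfd = list(hepatic = 0.1, urinary = 0.1), count = 868L),
    chemical_spec("isobutyl alcohol", 74.12,
                  rfd = list(nervous = 0.3), count = 172L),
    chemical_spec("toluene", 92.14,
                  rfc = list(nervous = 5.0),
                  rfd = list(urinary = 0.08), count = 427L),
    chemical_spec("mibk", 100.16,
                  rfc = list(developmental = 3.0), count = 290L))
  stats::setNames(chems, vapply(chems, `[[`, "", "name"))
}

#' Default target-organ groupings
#'
#' Neurotoxic solvents (xylene, n-butanol, isobutyl alcohol, toluene) form
#' the nervous-system hazard index; MIBK and ethylbenzene form the
#' developmental one. A chemical belongs to at most one group.
#'
#' @return Named list of [toxicity_grouping()] objects.
#' @export
default_groupings <- function() {
  list(
    nervous = toxicity_grouping(
      "nervous", c("xylene", "n-butanol", "isobutyl alcohol", "toluene")),
    developmental = toxicity_grouping(
      "developmental", c("mibk", "ethylbenzene")))
}
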