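#' Spearman rank correlation
#'
#' Pearson correlation of the rank vectors, with ties assigned average
#' ranks. Invariant under strictly increasing transforms of either argument
#' and bounded in [-1, 1].
#'
#' @param x,y Numeric vectors of equal length `>= 3`.
#' @return The coefficient rho.
#' @examples
#' spearman_rho(1:5, c(2, 1, 4, 3, 5))  # 0.8
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 paired observations", call. = FALSE)
  if (stats::sd(rank(x)) == 0 || stats::sd(rank(y)) == 0)
    stop("rank correlation undefined for a constant input", call. = FALSE)
  stats::cor(x, y, method = "spearman")
}

#' Correlation-strength category
#'
#' Bands on the absolute coefficient: below 0.20 negligible, 0.20-0.40 low,
#' 0.40-0.70 moderate, 0.70-0.90 high, 0.90 and above very high. Intervals
#' are half-open on the right, with the top band closed at 1.
#'
#' @param rho Coefficient(s) in [-1, 1].
#' @return Character vector of categories.
#' @export
categorize_strength <- function(rho) {
  if (any(abs(rho) > 1)) stop("|rho| must not exceed 1", call. = FALSE)
  cut(abs(rho), breaks = c(0, 0.20, 0.40, 0.70, 0.90, 1),
      labels = c("negligible", "low", "moderate", "high", "very high"),
      include.lowest = TRUE, right = FALSE) |>
    as.character() |>
    (\(x) ifelse(abs(rho) == 1, "very high", x))()
}

#' Spearman sensitivity of a simulated output to each input factor
#'
#' Correlates an output vector (a chemical's HQ draws or a group's HI draws)
#' with each relevant input factor from the same Monte Carlo run: the
#' concentration draws of the chemicals named in `chemicals`, plus the
#' shared worker factors ED, ET and EF. No re-sampling takes place; the
#' report is computed on the very draws that produced the output.
#'
#' @param draws A `factor_draws` object (see [sample_factors()]).
#' @param output Numeric vector of length `draws$n`.
#' @param label Output label for the report (e.g. `"HQ xylene"`).
#' @param chemicals Chemical names whose concentration draws enter the
#'   report: the chemical itself for an HQ, the group members for an HI.
#' @return An object of class `sensitivity_report`: data frame `table` with
#'   columns `factor`, `rho`, `strength`, plus `label`, `n`, `seed`.
#' @export
sensitivity_report <- function(draws, output, label, chemicals) {
  stopifnot(inherits(draws, "factor_draws"))
  if (length(output) != draws$n)
    stop("output length must equal the iteration count of the draws", call. = FALSE)
  missing <- setdiff(chemicals, colnames(draws$concentration))
  if (length(missing))
    stop(sprintf("no concentration draws for chemical(s) %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  inputs <- c(
    stats::setNames(lapply(chemicals, function(m) draws$concentration[, m]),
                    paste0("concentration: ", chemicals)),
    list("exposure duration" = draws$ed,
         "daily exposure time" = draws$et,
         "exposure frequency" = draws$ef))
  rho <- vapply(inputs, function(x) spearman_rho(x, output), numeric(1))
  structure(list(
    table = data.frame(factor = names(inputs), rho = unname(rho),
                       strength = categorize_strength(unname(rho)),
                       row.names = NULL),
    label = label, n = draws$n, seed = draws$seed),
    class = "sensitivity_report")
}

#' Sensitivity reports for every output of a simulation
#'
#' Convenience wrapper producing one [sensitivity_report()] per chemical HQ
#' and per group HI of an [run_simulation()] result.
#'
#' @param sim An `hq_simulation`.
#' @return Named list of `sensitivity_report`s (`"hq: <chemical>"` and
#'   `"hi: <group>"`).
#' @export
sensitivity_reports <- function(sim) {
  stopifnot(inherits(sim, "hq_simulation"))
  out <- list()
  for (m in colnames(sim$hq)) {
    out[[paste0("hq: ", m)]] <-
      sensitivity_report(sim$draws, sim$hq[, m], paste0("HQ ", m), m)
  }
  for (g in names(sim$hi)) {
    out[[paste0("hi: ", g)]] <-
      sensitivity_report(sim$draws, sim$hi[[g]], paste0("HI ", g),
                         sim$groupings[[g]]$members)
  }
  out
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat(sprintf("<sensitivity_report> %s (n = %d, seed %s)\n",
              x$label, x$n, format(x$seed)))
  tab <- x$table
  tab$rho <- signif(tab$rho, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}
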