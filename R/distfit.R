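#' Maximum-likelihood fit of one distribution family
#'
#' Fits the requested family to a raw sample. Families with closed-form
#' maximum-likelihood estimators (normal, lognormal, exponential) are solved
#' analytically; logistic, gamma and Weibull fits are numerical
#' (`fitdistrplus::fitdist`) started from moment-matched parameters so the
#' result is deterministic for a given sample.
#'
#' @param samples Numeric vector, at least 10 observations.
#' @param family Distribution family (see [dist_spec()]; not `point_mass`).
#' @return A list with elements `spec` (a `dist_spec`, `source =
#'   "mle_fitted"`), `loglik`, and `k` (number of free parameters).
#' @examples
#' x <- stats::rexp(500, 1 / 11)
#' fit_mle(x, "exponential")
#' @export
fit_mle <- function(samples, family) {
  family <- match.arg(family, setdiff(dist_families(), "point_mass"))
  samples <- as.numeric(samples)
  if (length(samples) < 10L)
    stop("fit_mle needs at least 10 samples", call. = FALSE)
  if (any(!is.finite(samples)))
    stop("samples contain non-finite values", call. = FALSE)
  if (dist_positive_support(family) && any(samples <= 0)) {
    bad <- which(samples <= 0)
    stop(sprintf("family '%s' requires positive samples; offending rows: %s",
                 family, paste(utils::head(bad, 10L), collapse = ", ")),
         call. = FALSE)
  }
  if (stats::sd(samples) == 0)
    stop("samples are all equal: scale parameter degenerate", call. = FALSE)

  n <- length(samples)
  fit <- switch(family,
    normal = {
      m <- mean(samples); s <- sqrt(mean((samples - m)^2))  # MLE uses 1/n
      list(params = list(mean = m, sd = s))
    },
    lognormal = {
      lx <- log(samples)
      m <- mean(lx); s <- sqrt(mean((lx - m)^2))
      list(params = list(meanlog = m, sdlog = s))
    },
    exponential = list(params = list(rate = 1 / mean(samples))),
    {
      start <- moments_to_spec(family, mean(samples), stats::sd(samples))$params
      dname <- switch(family, logistic = "logis", gamma = "gamma",
                      weibull = "weibull")
      f <- fitdistrplus::fitdist(samples, dname, method = "mle", start = start,
                                 control = list(reltol = 1e-8, maxit = 1000L))
      list(params = as.list(f$estimate))
    })
  spec <- dist_spec(family, fit$params, source = "mle_fitted")
  k <- length(fit$params)
  ll <- sum(dist_logdensity(spec, samples))
  list(spec = spec, loglik = ll, k = k)
}

#' Select a distribution family by minimum AIC
#'
#' Fits every applicable candidate family to the sample by maximum
#' likelihood, computes `AIC = 2k - 2 logL`, and selects the family with
#' minimal AIC. Ties are broken by fewest parameters, then by family name.
#' Candidates whose support excludes the data (e.g. lognormal with
#' nonpositive observations) are reported as inapplicable rather than
#' raising an error.
#'
#' @param samples Numeric vector, at least 10 observations.
#' @param candidates Character vector of family names; defaults to the six
#'   non-degenerate families.
#' @return An object of class `fit_ranking`: a list with `table` (one row per
#'   candidate: family, applicable, loglik, k, aic, parameters as a list
#'   column), `selected` (family name), and `fits` (the fitted `dist_spec`s).
#' @export
select_by_aic <- function(samples,
                          candidates = c("normal", "lognormal", "logistic",
                                         "exponential", "gamma", "weibull")) {
  candidates <- unique(match.arg(candidates, setdiff(dist_families(), "point_mass"),
                                 several.ok = TRUE))
  if (!length(candidates)) stop("no candidate families supplied", call. = FALSE)
  rows <- lapply(candidates, function(f) {
    fit <- tryCatch(fit_mle(samples, f), error = function(e) e)
    if (inherits(fit, "error")) {
      list(family = f, applicable = FALSE, loglik = NA_real_, k = NA_integer_,
           aic = NA_real_, spec = NULL, reason = conditionMessage(fit))
    } else {
      list(family = f, applicable = TRUE, loglik = fit$loglik, k = fit$k,
           aic = 2 * fit$k - 2 * fit$loglik, spec = fit$spec, reason = NA_character_)
    }
  })
  tab <- data.frame(
    family = vapply(rows, `[[`, "", "family"),
    applicable = vapply(rows, `[[`, NA, "applicable"),
    loglik = vapply(rows, function(r) as.numeric(r$loglik), 0),
    k = vapply(rows, function(r) as.integer(r$k), 0L),
    aic = vapply(rows, function(r) as.numeric(r$aic), 0),
    stringsAsFactors = FALSE)
  ok <- tab[tab$applicable & is.finite(tab$aic), , drop = FALSE]
  if (!nrow(ok))
    stop("no candidate family is applicable to the sample support", call. = FALSE)
  ok <- ok[order(ok$aic, ok$k, ok$family), , drop = FALSE]
  selected <- ok$family[1L]
  fits <- stats::setNames(lapply(rows, `[[`, "spec"), tab$family)
  structure(list(table = tab[order(tab$aic), , drop = FALSE],
                 selected = selected, fits = fits),
            class = "fit_ranking")
}

#' @export
print.fit_ranking <- function(x, ...) {
  cat("<fit_ranking> selected:", x$selected, "\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}
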