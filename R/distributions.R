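#' Univariate distribution specifications for exposure factors
#'
#' A `dist_spec` records one parametric family together with its parameters,
#' how it was obtained (`moment_matched`, `mle_fitted`, or `fixed`), and the
#' arithmetic mean and standard deviation it implies. It is the unit of
#' currency between the fitting layer and the Monte Carlo engine.
#'
#' Supported families and their parameters:
#' \describe{
#'   \item{`normal`}{`mean`, `sd`}
#'   \item{`lognormal`}{`meanlog`, `sdlog` (log-scale)}
#'   \item{`logistic`}{`location`, `scale`}
#'   \item{`exponential`}{`rate`}
#'   \item{`gamma`}{`shape`, `rate`}
#'   \item{`weibull`}{`shape`, `scale`}
#'   \item{`point_mass`}{`value` (degenerate, SD 0)}
#'   \item{`discrete`}{`values`, `probs` (finite support; mainly a testing
#'     device — exceedance probabilities under fully discrete factors can be
#'     enumerated exactly and compared against Monte Carlo output)}
#' }
#'
#' @param family One of the family names above.
#' @param params Named list of family parameters.
#' @param source Provenance label: `"moment_matched"`, `"mle_fitted"`, or
#'   `"fixed"`.
#' @param note Optional free-text annotation (e.g. a discarded summary
#'   statistic retained as metadata).
#' @return An object of class `dist_spec`.
#' @seealso [moments_to_spec()], [fit_mle()], [dist_draw()]
#' @export
dist_spec <- function(family, params, source = "fixed", note = NULL) {
  family <- match.arg(family, dist_families())
  source <- match.arg(source, c("moment_matched", "mle_fitted", "fixed"))
  params <- as.list(params)
  if (family == "discrete") {
    v <- params$values; pr <- params$probs
    if (is.null(v) || is.null(pr) || length(v) != length(pr) || !length(v))
      stop("discrete family needs equal-length 'values' and 'probs'", call. = FALSE)
    if (any(pr < 0) || abs(sum(pr) - 1) > 1e-9)
      stop("discrete probabilities must be nonnegative and sum to 1", call. = FALSE)
  }
  need <- dist_param_names(family)
  if (!setequal(names(params), need)) {
    stop(sprintf("family '%s' requires parameters {%s}, got {%s}",
                 family, paste(need, collapse = ", "),
                 paste(names(params), collapse = ", ")), call. = FALSE)
  }
  vals <- unlist(params)
  if (any(!is.finite(vals))) stop("distribution parameters must be finite", call. = FALSE)
  pos <- switch(family,
    normal      = "sd",
    lognormal   = "sdlog",
    logistic    = "scale",
    exponential = "rate",
    gamma       = c("shape", "rate"),
    weibull     = c("shape", "scale"),
    point_mass  = character(0))
  bad <- pos[vapply(pos, function(p) params[[p]] <= 0, logical(1))]
  if (length(bad)) {
    stop(sprintf("family '%s': parameter(s) %s must be > 0",
                 family, paste(bad, collapse = ", ")), call. = FALSE)
  }
  structure(
    list(family = family, params = params, source = source,
         mean = dist_mean(family, params), sd = dist_sd(family, params),
         note = note),
    class = "dist_spec")
}

dist_families <- function() {
  c("normal", "lognormal", "logistic", "exponential", "gamma", "weibull",
    "point_mass", "discrete")
}

dist_param_names <- function(family) {
  switch(family,
    normal      = c("mean", "sd"),
    lognormal   = c("meanlog", "sdlog"),
    logistic    = c("location", "scale"),
    exponential = "rate",
    gamma       = c("shape", "rate"),
    weibull     = c("shape", "scale"),
    point_mass  = "value",
    discrete    = c("values", "probs"))
}

# analytic arithmetic mean implied by (family, params)
dist_mean <- function(family, params) {
  with(params, switch(family,
    normal      = mean,
    lognormal   = exp(meanlog + sdlog^2 / 2),
    logistic    = location,
    exponential = 1 / rate,
    gamma       = shape / rate,
    weibull     = scale * gamma(1 + 1 / shape),
    point_mass  = value,
    discrete    = sum(values * probs)))
}

# analytic arithmetic SD implied by (family, params)
dist_sd <- function(family, params) {
  with(params, switch(family,
    normal      = sd,
    lognormal   = exp(meanlog + sdlog^2 / 2) * sqrt(exp(sdlog^2) - 1),
    logistic    = scale * pi / sqrt(3),
    exponential = 1 / rate,
    gamma       = sqrt(shape) / rate,
    weibull     = scale * sqrt(gamma(1 + 2 / shape) - gamma(1 + 1 / shape)^2),
    point_mass  = 0,
    discrete    = sqrt(sum(values^2 * probs) - sum(values * probs)^2)))
}

#' @export
print.dist_spec <- function(x, ...) {
  p <- paste(sprintf("%s = %.6g", names(x$params), unlist(x$params)),
             collapse = ", ")
  cat(sprintf("<dist_spec> %s(%s)  [%s]\n  implied mean %.6g, sd %.6g\n",
              x$family, p, x$source, x$mean, x$sd))
  invisible(x)
}

#' Parameterize a distribution from its arithmetic mean and SD
#'
#' Moment matching: chooses family parameters so that the analytic mean and
#' standard deviation equal the supplied sample statistics. This is how
#' published summary statistics (e.g. a survey's "268 (20.92) days/year") are
#' turned into sampling distributions when the raw records are not available.
#'
#' Closed forms: lognormal `sdlog^2 = log(1 + (sd/mean)^2)`,
#' `meanlog = log(mean) - sdlog^2/2`; logistic `scale = sd * sqrt(3)/pi`;
#' gamma `shape = (mean/sd)^2`, `rate = mean/sd^2`. The exponential family has
#' one parameter, so only the mean is honoured (`rate = 1/mean`) and the
#' supplied SD is kept as a note. The Weibull shape is solved numerically from
#' the coefficient of variation. A zero SD degenerates to a point mass at the
#' mean for every family.
#'
#' @param family Distribution family (see [dist_spec()]).
#' @param mean Arithmetic mean; must be positive for families supported on
#'   the positive half-line.
#' @param sd Arithmetic standard deviation, `>= 0`.
#' @return A `dist_spec` with `source = "moment_matched"`.
#' @examples
#' moments_to_spec("lognormal", 19.66, 51.24)
#' moments_to_spec("logistic", 8, 1.11)
#' @export
moments_to_spec <- function(family, mean, sd) {
  family <- match.arg(family, dist_families())
  stopifnot(is.numeric(mean), length(mean) == 1L, is.numeric(sd), length(sd) == 1L)
  if (sd < 0) stop("sd must be >= 0", call. = FALSE)
  if (family == "discrete")
    stop("the discrete family is parameterized by values/probs, not moments", call. = FALSE)
  if (family %in% c("lognormal", "exponential", "gamma", "weibull") && mean <= 0)
    stop(sprintf("family '%s' requires mean > 0, got %g", family, mean), call. = FALSE)
  if (family == "point_mass" || sd == 0) {
    return(dist_spec("point_mass", list(value = mean), source = "moment_matched"))
  }
  switch(family,
    normal = dist_spec("normal", list(mean = mean, sd = sd), "moment_matched"),
    lognormal = {
      s2 <- log(1 + (sd / mean)^2)
      dist_spec("lognormal",
                list(meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2)),
                "moment_matched")
    },
    logistic = dist_spec("logistic",
                         list(location = mean, scale = sd * sqrt(3) / pi),
                         "moment_matched"),
    exponential = dist_spec("exponential", list(rate = 1 / mean), "moment_matched",
                            note = sprintf("supplied sd %.6g ignored (one-parameter family)", sd)),
    gamma = dist_spec("gamma",
                      list(shape = (mean / sd)^2, rate = mean / sd^2),
                      "moment_matched"),
    weibull = {
      cv <- sd / mean
      # CV is strictly decreasing in shape; bracket then root-find
      cv_of <- function(k) sqrt(gamma(1 + 2 / k) / gamma(1 + 1 / k)^2 - 1)
      shape <- stats::uniroot(function(k) cv_of(k) - cv,
                              lower = 0.05, upper = 200,
                              tol = 1e-12, extendInt = "downX")$root
      dist_spec("weibull",
                list(shape = shape, scale = mean / gamma(1 + 1 / shape)),
                "moment_matched")
    })
}

#' Draw random samples from a distribution specification
#'
#' Uses the current RNG state; callers that need reproducibility should seed
#' via their own interface (see [sample_factors()]).
#'
#' @param spec A `dist_spec`.
#' @param n Number of draws.
#' @return Numeric vector of length `n`.
#' @export
dist_draw <- function(spec, n) {
  stopifnot(inherits(spec, "dist_spec"), n >= 0)
  with(spec$params, switch(spec$family,
    normal      = stats::rnorm(n, mean, sd),
    lognormal   = stats::rlnorm(n, meanlog, sdlog),
    logistic    = stats::rlogis(n, location, scale),
    exponential = stats::rexp(n, rate),
    gamma       = stats::rgamma(n, shape = shape, rate = rate),
    weibull     = stats::rweibull(n, shape = shape, scale = scale),
    point_mass  = rep(value, n),
    discrete    = sample(values, n, replace = TRUE, prob = probs)))
}

#' Log-density of a distribution specification
#'
#' @param spec A `dist_spec` (not `point_mass`).
#' @param x Numeric vector of evaluation points.
#' @return Vector of log-densities (`-Inf` outside the support).
#' @keywords internal
dist_logdensity <- function(spec, x) {
  stopifnot(inherits(spec, "dist_spec"))
  if (spec$family == "point_mass")
    stop("point_mass has no density", call. = FALSE)
  with(spec$params, switch(spec$family,
    normal      = stats::dnorm(x, mean, sd, log = TRUE),
    lognormal   = stats::dlnorm(x, meanlog, sdlog, log = TRUE),
    logistic    = stats::dlogis(x, location, scale, log = TRUE),
    exponential = stats::dexp(x, rate, log = TRUE),
    gamma       = stats::dgamma(x, shape = shape, rate = rate, log = TRUE),
    weibull     = stats::dweibull(x, shape = shape, scale = scale, log = TRUE)))
}

# Families whose support is restricted to (0, Inf)
dist_positive_support <- function(family) {
  family %in% c("lognormal", "exponential", "gamma", "weibull")
}

# run code under a temporary seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      stats::runif(1)
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    set.seed(seed)
  }
  force(code)
}
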