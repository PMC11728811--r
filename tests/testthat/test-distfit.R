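test_that("moment matching hits the published worked values", {
  ln <- moments_to_spec("lognormal", 19.66, 51.24)
  expect_equal(ln$params$meanlog, 1.952, tolerance = 1e-3)
  expect_equal(ln$params$sdlog, 1.433, tolerance = 1e-3)

  lo <- moments_to_spec("logistic", 8, 1.11)
  expect_equal(lo$params$location, 8)
  expect_equal(lo$params$scale, 1.11 * sqrt(3) / pi, tolerance = 1e-12)
  expect_equal(lo$params$scale, 0.612, tolerance = 1e-3)

  ex <- moments_to_spec("exponential", 11, 8.69)
  expect_equal(ex$params$rate, 1 / 11)
  expect_match(ex$note, "ignored")

  expect_identical(moments_to_spec("normal", 5, 0)$family, "point_mass")
  expect_error(moments_to_spec("lognormal", -1, 2), "mean > 0")
})

test_that("moment matching reproduces the requested moments analytically", {
  set.seed(11)
  for (family in c("normal", "lognormal", "logistic", "gamma", "weibull")) {
    for (i in 1:10) {
      m <- runif(1, 0.5, 300)
      s <- runif(1, 0.05, 2.5) * m
      spec <- moments_to_spec(family, m, s)
      expect_equal(spec$mean, m, tolerance = 1e-9)
      expect_equal(spec$sd, s, tolerance = 1e-9)
    }
  }
})

test_that("sampling from a moment-matched spec recovers the mean", {
  n <- 1e5
  set.seed(3)
  for (family in c("normal", "lognormal", "logistic", "gamma", "weibull")) {
    m <- 50; s <- 20
    x <- dist_draw(moments_to_spec(family, m, s), n)
    expect_lt(abs(mean(x) - m), 3 * s / sqrt(n))
  }
})

test_that("lognormal moment matching is scaling-equivariant", {
  base <- moments_to_spec("lognormal", 19.66, 51.24)
  for (k in c(0.1, 2, 37.5)) {
    scaled <- moments_to_spec("lognormal", k * 19.66, k * 51.24)
    expect_equal(scaled$params$meanlog, base$params$meanlog + log(k))
    expect_equal(scaled$params$sdlog, base$params$sdlog)
  }
})

test_that("closed-form and numeric MLE recover generating parameters", {
  set.seed(5)
  x <- rexp(5000, 1 / 11)
  fit <- fit_mle(x, "exponential")
  expect_equal(fit$spec$params$rate, 1 / mean(x))       # exact MLE identity
  expect_lt(abs(fit$spec$params$rate - 1 / 11) / (1 / 11), 0.03)

  y <- rlnorm(5000, 1.952, 1.433)
  fit <- fit_mle(y, "lognormal")
  expect_lt(abs(fit$spec$params$meanlog - 1.952), 0.05)
  expect_lt(abs(fit$spec$params$sdlog - 1.433), 0.05)

  z <- rlogis(5000, 8, 0.612)
  fit <- fit_mle(z, "logistic")
  expect_lt(abs(fit$spec$params$location - 8), 0.1)
  expect_lt(abs(fit$spec$params$scale - 0.612), 0.05)

  expect_error(fit_mle(rep(4, 100), "normal"), "all equal")
  expect_error(fit_mle(c(rep(1, 20), -1), "lognormal"), "offending rows")
  expect_error(fit_mle(rexp(5), "exponential"), "at least 10")
})

test_that("MLE is deterministic for a given sample", {
  set.seed(9)
  x <- rgamma(2000, shape = 2, rate = 0.3)
  f1 <- fit_mle(x, "weibull")
  f2 <- fit_mle(x, "weibull")
  expect_identical(f1, f2)
})

test_that("AIC selection obeys its definition and picks the generating family", {
  set.seed(13)
  x <- rexp(5000, 1 / 11)
  cand <- c("normal", "lognormal", "exponential", "logistic")
  r <- select_by_aic(x, cand)
  expect_s3_class(r, "fit_ranking")
  expect_identical(r$selected, "exponential")
  # AIC = 2k - 2 logL holds row by row
  ok <- r$table[r$table$applicable, ]
  expect_equal(ok$aic, 2 * ok$k - 2 * ok$loglik)
  # selected attains the minimum
  expect_equal(min(ok$aic), ok$aic[ok$family == "exponential"])

  # single candidate
  expect_identical(select_by_aic(x, "lognormal")$selected, "lognormal")

  # permutation invariance
  set.seed(14)
  y <- rlogis(5000, 8, 0.612)
  for (perm in list(cand, rev(cand), c("logistic", "normal", "exponential", "lognormal"))) {
    expect_identical(select_by_aic(y, perm)$selected, "logistic")
  }
})

test_that("support-violating families are inapplicable, not fatal", {
  set.seed(15)
  x <- rnorm(500, 0, 3)                     # mixed signs
  r <- select_by_aic(x, c("normal", "lognormal", "exponential", "logistic"))
  tab <- r$table
  expect_false(tab$applicable[tab$family == "lognormal"])
  expect_false(tab$applicable[tab$family == "exponential"])
  expect_true(all(tab$applicable[tab$family %in% c("normal", "logistic")]))
  expect_true(r$selected %in% c("normal", "logistic"))
  # nothing applicable -> data error
  expect_error(select_by_aic(x, c("lognormal", "exponential")), "no candidate family")
})
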