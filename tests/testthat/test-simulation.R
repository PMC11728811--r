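test_that("exposure concentration follows the time-weighting identity", {
  expect_equal(compute_ec(30.6, 8, 7.62, 267.2, 69408),
               30.6 * 8 * 7.62 * 267.2 / (69408 * 24), tolerance = 1e-12)
  expect_equal(compute_ec(30.6, 8, 7.62, 267.2, 69408), 0.2992, tolerance = 1e-3)
  expect_identical(compute_ec(30.6, 8, 0, 267.2, 69408), 0)
  # continuous exposure over the whole averaging time returns C itself
  expect_equal(compute_ec(3.7, 24, 69408 / 365, 365, 69408), 3.7)
  expect_error(compute_ec(1, 8, 10, 250, 0), "at_days")
  expect_error(compute_ec(-1, 8, 10, 250, 69408), "nonnegative")
})

test_that("hazard quotient and hazard index arithmetic", {
  expect_equal(compute_hq(0.2992, 0.1), 2.992)
  expect_identical(compute_hq(0, 0.1), 0)
  expect_equal(compute_hq(5, 5), 1)
  expect_error(compute_hq(1, 0), "rfc")

  g <- toxicity_grouping("g", c("a", "b"))
  expect_equal(compute_hi(list(a = 0.5, b = 0.3), g), 0.8)
  expect_equal(compute_hi(list(a = 0.7), toxicity_grouping("g", "a")), 0.7)
  nerv <- toxicity_grouping("nervous",
                            c("xylene", "n-butanol", "isobutyl alcohol", "toluene"))
  expect_equal(compute_hi(list(xylene = 2, "n-butanol" = 1,
                               "isobutyl alcohol" = 0.5, toluene = 0.1), nerv), 3.6)
  err <- expect_error(compute_hi(list(a = 1), g))
  expect_match(conditionMessage(err), "b")
})

test_that("factor draws are reproducible, positive, and shared per worker", {
  model <- default_exposure_model()
  d1 <- sample_factors(model, 500, seed = 99)
  d2 <- sample_factors(model, 500, seed = 99)
  expect_identical(d1, d2)
  expect_true(all(d1$et > 0) && all(d1$ed > 0) && all(d1$ef > 0))
  expect_true(all(d1$concentration > 0))
  expect_identical(dim(d1$concentration), c(500L, 6L))

  # point-mass model gives constant columns
  pm <- point_mass_model()
  dpm <- sample_factors(pm, 50, seed = 1)
  expect_identical(unique(dpm$et), 8)
  expect_identical(unique(dpm$concentration[, 1]), 10)

  # exponential ED at n = 1e5: sample mean within 3 standard errors of 11
  big <- sample_factors(model, 1e5, seed = 7)
  expect_lt(abs(mean(big$ed) - 11), 3 * 11 / sqrt(1e5))

  # a distribution mostly below zero must be rejected as misconfigured
  bad <- exposure_factor_model(
    concentration = list(xylene = dist_spec("point_mass", list(value = 1))),
    et = dist_spec("normal", list(mean = -5, sd = 1)),
    ed = dist_spec("point_mass", list(value = 1)),
    ef = dist_spec("point_mass", list(value = 1)),
    at_days = 69408)
  expect_error(sample_factors(bad, 1000, seed = 1), "rejects more than half")
})

test_that("sampling does not disturb the caller's RNG stream", {
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  invisible(sample_factors(default_exposure_model(), 100, seed = 5))
  expect_identical(runif(1), before)
})

test_that("a fully degenerate scenario collapses to one deterministic HQ", {
  sim <- run_simulation(single_chem(), point_mass_model(),
                        single_grouping(), n = 200, seed = 1)
  hq <- compute_hq(compute_ec(10 * 106.17 / 24.45, 8, 10, 250, 69408), 0.1)
  expect_true(all(abs(sim$hq[, "xylene"] - hq) < 1e-12))
  expect_true(all(abs(unlist(sim$hq_summary[paste0("p", c(25, 50, 75, 95))]) - hq) < 1e-12))
  expect_equal(sim$hq_summary$pct_gt_1, if (hq > 1) 100 else 0)
})

test_that("HI equals the member sum and dominates each member HQ", {
  sim <- run_simulation(n = 2000, seed = 21)
  nerv <- c("xylene", "n-butanol", "isobutyl alcohol", "toluene")
  expect_equal(sim$hi$nervous, rowSums(sim$hq[, nerv]), tolerance = 1e-12)
  expect_equal(sim$hi$developmental, rowSums(sim$hq[, c("mibk", "ethylbenzene")]),
               tolerance = 1e-12)
  for (g in names(sim$hi)) {
    mx <- apply(sim$hq[, sim$groupings[[g]]$members, drop = FALSE], 1, max)
    expect_true(all(sim$hi[[g]] >= mx))
  }
  # summaries are monotone along the percentile grid
  for (i in seq_len(nrow(sim$hq_summary))) {
    expect_false(is.unsorted(unlist(sim$hq_summary[i, paste0("p", c(25, 50, 75, 95))])))
  }
})

test_that("halving every reference concentration doubles all draws exactly", {
  chems <- default_chemicals()
  halved <- lapply(chems, function(ch) {
    ch$rfc <- lapply(ch$rfc, `/`, 2)
    ch$rfd <- lapply(ch$rfd, `/`, 2)
    ch
  })
  s1 <- run_simulation(chems, n = 1000, seed = 31)
  s2 <- run_simulation(halved, n = 1000, seed = 31)
  expect_identical(s2$hq, 2 * s1$hq)
  expect_identical(s2$hi$nervous, 2 * s1$hi$nervous)
})

test_that("scaling a chemical's concentration moments scales its HQ draws", {
  k <- 3.7
  m1 <- default_exposure_model()
  m2 <- m1
  m2$concentration[["xylene"]] <- moments_to_spec("lognormal", k * 19.66, k * 51.24)
  s1 <- run_simulation(model = m1, n = 1000, seed = 41)
  s2 <- run_simulation(model = m2, n = 1000, seed = 41)
  expect_equal(s2$hq[, "xylene"], k * s1$hq[, "xylene"], tolerance = 1e-12)
  expect_identical(s2$hq[, "toluene"], s1$hq[, "toluene"])
})

test_that("with degenerate worker factors HQ percentiles are a scaled copy of C percentiles", {
  model <- point_mass_model()
  model$concentration <- list(xylene = moments_to_spec("lognormal", 19.66, 51.24))
  sim <- run_simulation(single_chem(), model, single_grouping(), n = 5000, seed = 51)
  const <- (106.17 / 24.45) * 8 * 10 * 250 / (69408 * 24) / 0.1
  for (q in c(25, 50, 75, 95)) {
    expect_equal(summarize_percentiles(sim$hq[, 1], q),
                 const * summarize_percentiles(sim$draws$concentration[, 1], q),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("exceedance percentile uses the <= convention and complements P(>t)", {
  expect_equal(exceedance_percentile(c(2, 3, 4)), 0)
  expect_equal(exceedance_percentile(1:100, 50.5), 50)
  expect_equal(exceedance_percentile(rep(1, 10), 1), 100)
  set.seed(61)
  x <- rlnorm(5000)
  expect_equal(exceedance_percentile(x, 1) + 100 * mean(x > 1), 100)
})

test_that("percentile summaries interpolate linearly and stay monotone", {
  expect_equal(summarize_percentiles(rep(3.2, 10)),
               c(p25 = 3.2, p50 = 3.2, p75 = 3.2, p95 = 3.2))
  expect_equal(summarize_percentiles(1:99, c(25, 50, 75)),
               c(p25 = 25.5, p50 = 50, p75 = 74.5))
  set.seed(62)
  q <- summarize_percentiles(rlnorm(1000), seq(5, 95, by = 5))
  expect_false(is.unsorted(q))
})

test_that("Monte Carlo exceedance matches exhaustive enumeration on discrete factors", {
  # three-point toy distributions for every factor; one chemical
  cs <- discrete_spec(c(2, 10, 40), c(0.5, 0.3, 0.2))
  et <- discrete_spec(c(4, 8, 12))
  ed <- discrete_spec(c(1, 10, 30), c(0.2, 0.6, 0.2))
  ef <- discrete_spec(c(100, 250, 300))
  model <- exposure_factor_model(list(xylene = cs), et, ed, ef, at_days = 69408)

  # brute-force truth: enumerate all 81 factor combinations
  grid <- expand.grid(ci = 1:3, ti = 1:3, di = 1:3, fi = 1:3)
  hq_all <- mapply(function(ci, ti, di, fi) {
    c_mg <- convert_concentration(cs$params$values[ci], 106.17, "ppm", "mg/m3")
    compute_hq(compute_ec(c_mg, et$params$values[ti], ed$params$values[di],
                          ef$params$values[fi], 69408), 0.1)
  }, grid$ci, grid$ti, grid$di, grid$fi)
  p_all <- cs$params$probs[grid$ci] * et$params$probs[grid$ti] *
    ed$params$probs[grid$di] * ef$params$probs[grid$fi]
  truth <- sum(p_all[hq_all > 1])

  n <- 20000
  sim <- run_simulation(single_chem(), model, single_grouping(), n = n, seed = 71)
  mc <- mean(sim$hq[, 1] > 1)
  expect_lt(abs(mc - truth), 3 * sqrt(truth * (1 - truth) / n))
  expect_equal(exceedance_percentile(sim$hq[, 1]), 100 * (1 - mc))
})

test_that("misconfigured simulations fail before computing", {
  expect_error(run_simulation(groupings = list(
    g = toxicity_grouping("nervous", "benzene"))), "unknown chemical")
  model <- default_exposure_model()
  model$concentration[["xylene"]] <- NULL
  expect_error(run_simulation(model = model), "no concentration spec")
  both <- list(a = toxicity_grouping("nervous", "xylene"),
               b = toxicity_grouping("other", "xylene"))
  expect_error(run_simulation(groupings = both), "more than one grouping")
})
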