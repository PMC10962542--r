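test_that("intensity and anisotropy follow the channel algebra", {
  expect_equal(total_intensity(50, 100, 1), 200)
  expect_equal(total_intensity(0, 100, 2), 100)
  expect_equal(total_intensity(100, 0, 0.5), 100)

  expect_equal(anisotropy(50, 50, 1), 0)       # S = GP
  expect_equal(anisotropy(0, 123), 1)          # upper limit
  expect_equal(anisotropy(50, 100, 1), 0.25)
  expect_error(anisotropy(0, 0), "total intensity")
})

test_that("anisotropy stays within (-0.5, 1] for any physical channels", {
  set.seed(11)
  P <- runif(500, 0, 1e4)
  S <- runif(500, 0, 1e4)
  G <- runif(500, 0.2, 3)
  keep <- S + 2 * G * P > 0
  r <- anisotropy(P[keep], S[keep], G[keep])
  expect_true(all(r > -0.5 & r <= 1))
})

test_that("bound fraction maps the anisotropy window to [0, 1]", {
  expect_equal(bound_fraction(0.02, 0.02, 0.2), 0)
  expect_equal(bound_fraction(0.2, 0.02, 0.2), 1)
  expect_equal(bound_fraction(0.11, 0.02, 0.2), 0.5)  # linear midpoint, lambda 1
  # lambda != 1 bends the map but keeps the endpoints
  expect_equal(bound_fraction(0.2, 0.02, 0.2, lambda = 2), 1)
  expect_error(bound_fraction(0.1, 0.2, 0.2), "degenerate")
  expect_warning(bound_fraction(0.5, 0.02, 0.2), "overshoot")
  expect_equal(suppressWarnings(bound_fraction(0.5, 0.02, 0.2)), 1)
})

test_that("tight-binding quadratic has the right limits", {
  Kd <- 1.5e-6
  x <- 10^seq(-9, -3, length.out = 50)
  # monotone non-decreasing, saturating at 1
  lb <- morrison_bound_fraction(x, Kd, 50e-9)
  expect_true(all(diff(lb) >= 0))
  expect_lt(abs(morrison_bound_fraction(100, Kd, 50e-9) - 1), 1e-6)
  # FL -> 0 collapses to the hyperbolic isotherm
  lb0 <- morrison_bound_fraction(x, Kd, 1e-15)
  expect_equal(lb0, x / (x + Kd), tolerance = 1e-6)
  # half-saturation at x = Kd when FL << Kd
  expect_equal(morrison_bound_fraction(Kd, Kd, 1e-12), 0.5, tolerance = 1e-4)
})

test_that("direct titration fit recovers noiseless parameters", {
  cfg <- sim_config(seed = 7, noise_sd_anisotropy = 0)
  s <- simulate_direct_titration(1.5e-6, r_min = 0.05, r_max = 0.2,
                                 config = cfg)
  f <- fit_direct_titration(s)
  expect_s3_class(f, "fa_direct_fit")
  expect_true(f$converged)
  expect_equal(coef(f)[["Kd"]], 1.5e-6, tolerance = 1e-6)
  expect_equal(coef(f)[["r_min"]], 0.05, tolerance = 1e-6)
  expect_equal(coef(f)[["r_max"]], 0.2, tolerance = 1e-6)
  expect_equal(unname(predict(f)), aggregate_replicates(s)$mean,
               tolerance = 1e-6)
  expect_equal(sum(residuals(f)^2), f$rss)
  # under-determined input
  short <- titration_series(c(1e-6, 2e-6), list(0.1, 0.12), "direct")
  expect_error(fit_direct_titration(short), "under-determined")
})

test_that("competition fit recovers a noiseless 4PL exactly", {
  cfg <- sim_config(seed = 3, noise_sd_anisotropy = 0)
  s <- simulate_competition_logistic(50e-6, p = 1.2, r_min = -0.03,
                                     r_max = 0.12, config = cfg)
  f <- fit_competition(s)
  expect_equal(coef(f)[["IC50"]], 50e-6, tolerance = 1e-6)
  expect_equal(coef(f)[["hill"]], 1.2, tolerance = 1e-6)
  expect_equal(coef(f)[["r_min"]], -0.03, tolerance = 1e-6)
  expect_equal(coef(f)[["r_max"]], 0.12, tolerance = 1e-6)
  expect_length(f$flags, 0)
})

test_that("restrained competition fit pins the displacement floor", {
  # curve that never reaches full displacement within the tested range
  cfg <- sim_config(seed = 9, noise_sd_anisotropy = 0,
                    x_grid = 10^seq(-6, -4.2, length.out = 10))
  s <- simulate_competition_logistic(80e-6, p = 1, r_min = -0.03,
                                     r_max = 0.12, config = cfg)
  f <- fit_competition(s, restrain_rmin = TRUE)
  expect_true(f$restrained_rmin)
  expect_identical(coef(f)[["r_min"]], -0.03)
  expect_equal(coef(f)[["IC50"]], 80e-6, tolerance = 1e-4)
})

test_that("flat displacement data is flagged or rejected", {
  x <- 10^seq(-6, -3, length.out = 12)
  set.seed(4)
  reads <- lapply(x, function(.) 0.12 + rnorm(3, 0, 0.003))
  s <- titration_series(x, reads, "competition")
  res <- tryCatch(fit_competition(s), error = function(e) e)
  if (inherits(res, "error")) {
    succeed("non-convergence reported for flat data")
  } else {
    expect_true(length(res$flags) > 0)
  }
})

test_that("fitted constants scale with the concentration axis", {
  for (c_scale in c(10, 1e3)) {
    cfg <- sim_config(seed = 5, noise_sd_anisotropy = 0)
    s <- simulate_competition_logistic(50e-6, p = 1.3, config = cfg)
    s2 <- s
    s2$x <- s$x * c_scale
    expect_equal(coef(fit_competition(s2))[["IC50"]],
                 coef(fit_competition(s))[["IC50"]] * c_scale,
                 tolerance = 1e-5)
    d <- simulate_direct_titration(1.5e-6, config = cfg)
    d2 <- d
    d2$x <- d$x * c_scale
    d2$tracer_conc <- d$tracer_conc * c_scale
    expect_equal(coef(fit_direct_titration(d2))[["Kd"]],
                 coef(fit_direct_titration(d))[["Kd"]] * c_scale,
                 tolerance = 1e-5)
  }
})

test_that("free-energy differences follow -RT ln(fold-change)", {
  # the 4-fold potency gain worth ~3.5 kJ/mol
  expect_equal(delta_delta_g(199e-6, 49e-6, 298.15), 3.474, tolerance = 1e-3)
  expect_equal(delta_delta_g(1e-4, 1e-4), 0)
  expect_equal(delta_delta_g(100e-6, 25e-6, 298.15),
               8.314 * 298.15 * log(4) / 1000)
  # antisymmetry
  set.seed(2)
  for (i in 1:20) {
    a <- runif(1, 1e-6, 1e-3); b <- runif(1, 1e-6, 1e-3)
    expect_equal(delta_delta_g(a, b), -delta_delta_g(b, a))
  }
  expect_error(delta_delta_g(-1, 1), "positive")
})

test_that("replicate aggregation matches direct mean/SD computation", {
  s <- titration_series(c(1e-6, 2e-6, 4e-6),
                        list(c(0.10, 0.12, 0.14), c(0.2, 0.2, 0.2), 0.3),
                        "competition")
  agg <- aggregate_replicates(s)
  expect_equal(agg$mean[1], 0.12)
  expect_equal(agg$sd[1], 0.02)
  expect_equal(agg$sd[2], 0)   # identical replicates
  expect_equal(agg$sd[3], 0)   # single replicate
  # random triplicates against an independent recomputation
  set.seed(8)
  reads <- lapply(1:5, function(.) rnorm(3, 0.1, 0.01))
  s2 <- titration_series(10^seq(-6, -4, length.out = 5), reads, "competition")
  agg2 <- aggregate_replicates(s2)
  expect_equal(agg2$mean, vapply(reads, function(v) sum(v) / 3, 1))
  expect_equal(agg2$sd, vapply(reads, function(v)
    sqrt(sum((v - mean(v))^2) / 2), 1))
})

test_that("fit objects expose the standard modelling surface", {
  cfg <- sim_config(seed = 13)
  f <- fit_competition(simulate_competition_logistic(50e-6, config = cfg))
  expect_output(print(f), "IC50")
  sm <- summary(f)
  expect_output(print(sm), "Competition")
  expect_true(all(c("Estimate", "Std. Error") %in% colnames(sm$coefficients)))
  expect_equal(length(fitted(f)), 12)
  expect_true(is.finite(f$IC50_sd) && f$IC50_sd > 0)
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(f))
})
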