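test_that("generators are pure functions of parameters and seed", {
  cfg <- sim_config(seed = 21)
  expect_identical(simulate_direct_titration(1e-6, config = cfg),
                   simulate_direct_titration(1e-6, config = cfg))
  expect_identical(simulate_competition_logistic(5e-5, config = cfg),
                   simulate_competition_logistic(5e-5, config = cfg))
  expect_identical(simulate_competition_equilibrium(1.5e-6, 5e-5, config = cfg),
                   simulate_competition_equilibrium(1.5e-6, 5e-5, config = cfg))
  expect_identical(simulate_cd_spectrum(20, 23, config = cfg,
                                        noise_sd_mdeg = 0.05),
                   simulate_cd_spectrum(20, 23, config = cfg,
                                        noise_sd_mdeg = 0.05))
  expect_identical(simulate_shift_profile(rep("A", 5), rep(0.5, 5),
                                          config = cfg, noise_sd_ppm = 0.1),
                   simulate_shift_profile(rep("A", 5), rep(0.5, 5),
                                          config = cfg, noise_sd_ppm = 0.1))
  # different seeds differ
  expect_false(identical(
    simulate_competition_logistic(5e-5, config = sim_config(seed = 1)),
    simulate_competition_logistic(5e-5, config = sim_config(seed = 2))))
  # the generator leaves the caller's RNG stream untouched
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(simulate_direct_titration(1e-6, config = cfg))
  expect_identical(rnorm(1), before)
})

test_that("noiseless direct simulation lies on the quadratic model curve", {
  cfg <- sim_config(seed = 2, noise_sd_anisotropy = 0)
  s <- simulate_direct_titration(1.5e-6, r_min = 0.05, r_max = 0.2,
                                 config = cfg)
  lb <- morrison_bound_fraction(s$x, 1.5e-6, s$tracer_conc)
  expect_equal(vapply(s$r, `[[`, 1, 1), 0.05 + lb * (0.2 - 0.05))
  # saturation limit
  big <- sim_config(seed = 2, noise_sd_anisotropy = 0, x_grid = c(1e-3, 1))
  shi <- simulate_direct_titration(1.5e-6, r_max = 0.2, config = big)
  expect_equal(shi$r[[2]][1], 0.2, tolerance = 1e-5)
})

test_that("logistic simulation hits its midpoint and step limit", {
  cfg <- sim_config(seed = 2, noise_sd_anisotropy = 0,
                    x_grid = c(1e-6, 5e-5, 1e-3))
  s <- simulate_competition_logistic(5e-5, p = 1.4, r_min = -0.03,
                                     r_max = 0.12, config = cfg)
  expect_equal(s$r[[2]][1], (0.12 - 0.03) / 2, tolerance = 1e-12)
  steep <- simulate_competition_logistic(5e-5, p = 50, r_min = -0.03,
                                         r_max = 0.12, config = cfg)
  expect_equal(steep$r[[1]][1], 0.12, tolerance = 1e-4)
  expect_equal(steep$r[[3]][1], -0.03, tolerance = 1e-4)
})

test_that("equilibrium simulator conserves mass and matches the quadratic", {
  cfg <- sim_config(seed = 6)
  s <- simulate_competition_equilibrium(1.5e-6, 5e-5, config = cfg)
  expect_lt(s$truth$mass_balance_rel_err, 1e-10)
  # zero competitor reduces to the single-ligand tight-binding quadratic
  expect_equal(s$truth$bound0,
               morrison_bound_fraction(cfg$protein_conc, 1.5e-6,
                                       cfg$tracer_conc),
               tolerance = 1e-8)
  # an essentially non-binding competitor leaves the curve flat at the top
  weak <- simulate_competition_equilibrium(1.5e-6, 1e3,
                                           config = sim_config(seed = 6,
                                             noise_sd_anisotropy = 0,
                                             x_grid = 10^seq(-7, -3, 1)))
  expect_lt(diff(range(weak$truth$r_noiseless)), 1e-4)
})

test_that("logistic and equilibrium displacement curves agree in shape", {
  # moderate-affinity tracer so the protein does not saturate it
  cfg <- sim_config(seed = 3, noise_sd_anisotropy = 0, protein_conc = 15e-6)
  eq <- simulate_competition_equilibrium(10e-6, 5e-5, config = cfg)
  fit <- fit_competition(eq)
  rms <- sqrt(mean(residuals(fit)^2)) / diff(range(aggregate_replicates(eq)$mean))
  expect_lt(rms, 0.03)
})

test_that("CD simulation respects its construction contract", {
  cd <- simulate_cd_spectrum(35, 23, config = sim_config(seed = 1),
                             noise_sd_mdeg = 0)
  expect_s3_class(cd, "cd_spectrum")
  expect_s3_class(attr(cd, "blank"), "cd_spectrum")
  m <- mre_spectrum(cd, attr(cd, "blank"))
  expect_equal(helicity_from_spectrum(m)$percent_helicity, 35,
               tolerance = 1e-9)
  expect_equal(attr(cd, "truth")$mre222, mre_at(m, 222), tolerance = 1e-9)
})

test_that("shift-profile simulation produces the declared offsets", {
  a0 <- simulate_shift_profile(rep("L", 8), rep(0, 8),
                               config = sim_config(seed = 1))
  expect_equal(secondary_shifts(a0, synthetic_random_coil_table())$dCa,
               rep(0, 8))
  a1 <- simulate_shift_profile(rep("L", 8), rep(1, 8), amplitude_Ca = 3.0,
                               config = sim_config(seed = 1))
  expect_equal(secondary_shifts(a1, synthetic_random_coil_table())$dCa,
               rep(3, 8))
})
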