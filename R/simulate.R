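#' Simulation configuration
#'
#' Shared knobs of the synthetic-data generators, defaulting to the study
#' conditions every stage assumes: 50 nM tracer, 15 uM protein, triplicate
#' reads with Gaussian anisotropy noise of SD 0.003, 12 log-spaced
#' concentrations spanning 0.01-100x the curve midpoint. All generators are
#' pure functions of (parameters, seed).
#'
#' @param seed integer RNG seed.
#' @param noise_sd_anisotropy Gaussian read noise on anisotropy (default
#'   0.003).
#' @param replicates replicate count per concentration (default 3).
#' @param x_grid optional explicit concentration grid (M); default 12
#'   log-spaced points around the model midpoint.
#' @param n_points grid size when `x_grid` is NULL.
#' @param tracer_conc tracer concentration, M (default 50e-9).
#' @param protein_conc protein concentration, M (default 15e-6).
#' @param temperature K (default 298.15).
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, noise_sd_anisotropy = 0.003,
                       replicates = 3L, x_grid = NULL, n_points = 12L,
                       tracer_conc = 50e-9, protein_conc = 15e-6,
                       temperature = 298.15) {
  stopifnot(noise_sd_anisotropy >= 0, replicates >= 1)
  structure(list(seed = as.integer(seed),
                 noise_sd_anisotropy = noise_sd_anisotropy,
                 replicates = as.integer(replicates),
                 x_grid = x_grid, n_points = as.integer(n_points),
                 tracer_conc = tracer_conc, protein_conc = protein_conc,
                 temperature = temperature),
            class = "sim_config")
}

# run expr with a fixed seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

default_grid <- function(config, midpoint) {
  if (!is.null(config$x_grid)) return(sort(config$x_grid))
  exp(seq(log(midpoint * 0.01), log(midpoint * 100),
          length.out = config$n_points))
}

noisy_reads <- function(r_true, config) {
  lapply(r_true, function(r)
    r + stats::rnorm(config$replicates, 0, config$noise_sd_anisotropy))
}

#' Simulate a direct (saturation) anisotropy titration
#'
#' Forward model of [fit_direct_titration()]: tracer bound fraction from the
#' tight-binding quadratic, anisotropy from the intensity-weighted mixing
#' rule, i.i.d. Gaussian read noise on anisotropy.
#'
#' @param Kd dissociation constant, M.
#' @param r_min,r_max free/bound anisotropy asymptotes.
#' @param lambda intensity-change factor (default 1).
#' @param config a [sim_config()].
#' @return a [titration_series()] (direct mode) with `truth` attached.
#' @export
simulate_direct_titration <- function(Kd, r_min = 0.05, r_max = 0.20,
                                      lambda = 1, config = sim_config()) {
  stopifnot(Kd > 0)
  x <- default_grid(config, Kd)
  lb <- morrison_bound_fraction(x, Kd, config$tracer_conc)
  r_true <- anisotropy_from_bound(lb, r_min, r_max, lambda)
  reads <- with_seed(config$seed, noisy_reads(r_true, config))
  titration_series(x, reads, mode = "direct",
                   tracer_conc = config$tracer_conc,
                   temperature = config$temperature,
                   truth = list(Kd = Kd, r_min = r_min, r_max = r_max,
                                lambda = lambda, r_noiseless = r_true))
}

#' Simulate a competition curve from the logistic model
#'
#' Forward 4PL model of [fit_competition()], oriented high-to-low (the
#' displacement direction), with Gaussian anisotropy noise.
#'
#' @param IC50 midpoint concentration, M.
#' @param p Hill exponent.
#' @param r_min,r_max full-displacement floor and zero-competitor ceiling.
#' @param config a [sim_config()].
#' @return a [titration_series()] (competition mode) with `truth` attached.
#' @export
simulate_competition_logistic <- function(IC50, p = 1, r_min = -0.03,
                                          r_max = 0.12,
                                          config = sim_config()) {
  stopifnot(IC50 > 0, p > 0)
  x <- default_grid(config, IC50)
  r_true <- logistic4(x, r_max, r_min, IC50, p)
  reads <- with_seed(config$seed, noisy_reads(r_true, config))
  titration_series(x, reads, mode = "competition",
                   tracer_conc = config$tracer_conc,
                   protein_conc = config$protein_conc,
                   temperature = config$temperature,
                   truth = list(IC50 = IC50, p = p, r_min = r_min,
                                r_max = r_max, r_noiseless = r_true))
}

# free-protein concentration solving the two-ligand one-site competitive
# mass balance; bisection bracket then Newton polish to machine precision
free_protein <- function(P_t, FL_t, C_t, Kd_FL, Kd_C) {
  f <- function(p) p * (1 + FL_t / (p + Kd_FL) + C_t / (p + Kd_C)) - P_t
  root <- stats::uniroot(f, c(0, P_t), tol = P_t * 1e-12)$root
  for (i in 1:4) {
    fp <- 1 + FL_t * Kd_FL / (root + Kd_FL)^2 + C_t * Kd_C / (root + Kd_C)^2
    step <- f(root) / fp
    root <- min(max(root - step, 0), P_t)
  }
  root
}

# tracer bound fraction at one competitor concentration (exact equilibrium)
equilibrium_bound_fraction <- function(C_t, P_t, FL_t, Kd_FL, Kd_C) {
  p <- free_protein(P_t, FL_t, C_t, Kd_FL, Kd_C)
  p / (p + Kd_FL)
}

#' Simulate a competition curve from exact competitive equilibrium
#'
#' Independent thermodynamic oracle for the logistic fit: at each competitor
#' concentration the one-site competitive equilibrium (mass balance over
#' protein, tracer and competitor) is solved to machine precision, the tracer
#' bound fraction converted to anisotropy with the `lambda = 1` mixing rule,
#' and Gaussian noise added. The half-displacement concentration found by
#' bisection is recorded as ground truth alongside the species balances.
#'
#' @param Kd_tracer,Kd_competitor dissociation constants, M.
#' @param r_min,r_max anisotropy of fully displaced / fully bound ends of the
#'   observable window (free-tracer floor and zero-competitor ceiling are
#'   derived from the actual bound fractions).
#' @param config a [sim_config()]; supplies protein and tracer totals.
#' @return a [titration_series()] (competition mode); `truth` carries
#'   `half_displacement` (M), the noiseless curve and the mass-balance check.
#' @export
simulate_competition_equilibrium <- function(Kd_tracer, Kd_competitor,
                                             r_min = -0.03, r_max = 0.12,
                                             config = sim_config()) {
  stopifnot(Kd_tracer > 0, Kd_competitor > 0)
  P_t <- config$protein_conc; FL_t <- config$tracer_conc
  lb0 <- equilibrium_bound_fraction(0, P_t, FL_t, Kd_tracer, Kd_competitor)
  # bisection for the competitor total at which Lb = lb0 / 2
  half <- half_displacement_conc(P_t, FL_t, Kd_tracer, Kd_competitor)
  x <- default_grid(config, half)
  lb <- vapply(x, equilibrium_bound_fraction, 1, P_t = P_t, FL_t = FL_t,
               Kd_FL = Kd_tracer, Kd_C = Kd_competitor)
  # anchor the anisotropy scale: Lb = lb0 maps to r_max, Lb = 0 to r_min
  r_true <- r_min + (r_max - r_min) * lb / lb0
  reads <- with_seed(config$seed, noisy_reads(r_true, config))
  balance <- max(vapply(x, function(ct) {
    p <- free_protein(P_t, FL_t, ct, Kd_tracer, Kd_competitor)
    total <- p + FL_t * p / (p + Kd_tracer) + ct * p / (p + Kd_competitor)
    abs(total - P_t) / P_t
  }, 1))
  titration_series(x, reads, mode = "competition",
                   tracer_conc = FL_t, protein_conc = P_t,
                   temperature = config$temperature,
                   truth = list(Kd_tracer = Kd_tracer,
                                Kd_competitor = Kd_competitor,
                                half_displacement = half,
                                bound0 = lb0, r_noiseless = r_true,
                                mass_balance_rel_err = balance))
}

# competitor total halving the tracer bound fraction, by log-space bisection
half_displacement_conc <- function(P_t, FL_t, Kd_FL, Kd_C) {
  lb0 <- equilibrium_bound_fraction(0, P_t, FL_t, Kd_FL, Kd_C)
  target <- lb0 / 2
  g <- function(lc) equilibrium_bound_fraction(exp(lc), P_t, FL_t,
                                               Kd_FL, Kd_C) - target
  lo <- log(Kd_C * 1e-6); hi <- log(Kd_C * 1e9 + P_t * 1e6)
  while (g(hi) > 0) hi <- hi + log(10)
  exp(stats::uniroot(g, c(lo, hi), tol = 1e-12)$root)
}

# smooth CD basis shapes; only their 222 nm values are contractually
# meaningful (pinned exactly by construction)
helix_shape <- function(w) {
  -(exp(-(w - 222)^2 / 128) + 0.95 * exp(-(w - 208)^2 / 98)) +
    1.9 * exp(-(w - 193)^2 / 72)
}
coil_shape <- function(w) {
  -exp(-(w - 198)^2 / 220) + 0.08 * exp(-(w - 222)^2 / 300)
}

#' Simulate a CD spectrum of a helix/coil mixture
#'
#' Builds a mean-residue-ellipticity curve as a helicity-weighted mix of
#' smooth helix and coil basis shapes whose 222 nm values are pinned so that
#' the percent-helicity formula applied to the noiseless spectrum returns
#' exactly `true_helicity` for the given `n_amide` and temperature, then
#' converts to raw millidegrees via the sample metadata and adds noise. The
#' paired buffer blank is attached.
#'
#' @param true_helicity percent, in \[0, 100\].
#' @param n_amide backbone amide-bond count (> 3).
#' @param temperature degrees C (default 5).
#' @param config a [sim_config()] (seed).
#' @param Mw,conc,pathlength,n_residues sample metadata (g/mol, mg/mL, mm,
#'   count); `n_residues` defaults to `n_amide - 1` (acetyl/amide peptide).
#' @param wavelengths nm grid (default 185:280, 1 nm step).
#' @param noise_sd_mdeg Gaussian noise on raw ellipticity (default 0).
#' @return a [cd_spectrum()] with attributes `blank` (the paired blank) and
#'   `truth`.
#' @export
simulate_cd_spectrum <- function(true_helicity, n_amide, temperature = 5,
                                 config = sim_config(), Mw = 2500,
                                 conc = 0.25, pathlength = 1,
                                 n_residues = n_amide - 1L,
                                 wavelengths = 185:280,
                                 noise_sd_mdeg = 0) {
  stopifnot(true_helicity >= 0, true_helicity <= 100, n_amide > 3)
  coil222 <- coil_baseline(temperature)
  helix222 <- coil222 - 42500 * (1 - 3 / n_amide)
  w <- wavelengths
  # pin both bases exactly at 222 nm (shape minus its own 222 value)
  helix <- (helix_shape(w) - helix_shape(222)) * 12000 + helix222
  coil <- (coil_shape(w) - coil_shape(222)) * 9000 + coil222
  h <- true_helicity / 100
  mre <- h * helix + (1 - h) * coil
  theta <- mre * n_residues * pathlength * conc / Mw
  noise <- with_seed(config$seed,
                     list(s = stats::rnorm(length(w), 0, noise_sd_mdeg),
                          b = stats::rnorm(length(w), 0, noise_sd_mdeg)))
  sample <- cd_spectrum(w, theta + noise$s, Mw = Mw, conc = conc,
                        pathlength = pathlength, n_residues = n_residues,
                        n_amide = n_amide, temperature = temperature)
  blank <- cd_spectrum(w, noise$b, temperature = temperature, is_blank = TRUE)
  attr(sample, "blank") <- blank
  attr(sample, "truth") <- list(helicity = true_helicity,
                                mre222 = h * helix222 + (1 - h) * coil222)
  sample
}

#' Synthetic random-coil reference table
#'
#' Deterministic residue-to-shift table for tests and simulations: arbitrary
#' but fixed, clearly non-physical values so that no check can silently rely
#' on literature numbers.
#'
#' @return a `random_coil_table` data.frame covering the 20 canonical
#'   residues plus `"pS"`.
#' @export
synthetic_random_coil_table <- function() {
  codes <- c(AA1, "pS")
  d <- data.frame(residue = codes,
                  delta_Ca_ppm = 50 + 0.7 * seq_along(codes),
                  delta_Ha_ppm = 4 + 0.03 * seq_along(codes))
  class(d) <- c("random_coil_table", "data.frame")
  attr(d, "provenance") <- "synthetic deterministic table (testing)"
  d
}

#' Simulate a per-residue secondary-shift profile
#'
#' Forward model of the secondary-shift analysis: observed shifts are the
#' random-coil reference plus `f_i * amplitude` for Calpha (downfield) and
#' minus `f_i * amplitude` for Halpha (upfield), with optional Gaussian
#' noise, for a per-residue helix fraction `f`.
#'
#' @param sequence a [peptide_spec()] or character vector of residue codes.
#' @param per_residue_helix_fraction fractions in \[0, 1\], one per residue.
#' @param amplitude_Ca,amplitude_Ha full-helix shift amplitudes, ppm.
#' @param config a [sim_config()].
#' @param table reference table (default [synthetic_random_coil_table()]).
#' @param offset parent numbering of the first residue.
#' @param noise_sd_ppm Gaussian noise on observed shifts (default 0).
#' @return a [shift_assignments()] table with attribute `truth`.
#' @export
simulate_shift_profile <- function(sequence, per_residue_helix_fraction,
                                   amplitude_Ca = 3.0, amplitude_Ha = 0.3,
                                   config = sim_config(),
                                   table = synthetic_random_coil_table(),
                                   offset = 1L, noise_sd_ppm = 0) {
  res <- if (inherits(sequence, "peptide_spec")) {
    offset <- sequence$numbering_offset
    sequence$residues
  } else as.character(sequence)
  f <- per_residue_helix_fraction
  stopifnot(length(f) == length(res), all(f >= 0), all(f <= 1))
  rc <- do.call(rbind, lapply(res, rc_lookup, table = table))
  noise <- with_seed(config$seed,
                     list(ca = stats::rnorm(length(res), 0, noise_sd_ppm),
                          ha = stats::rnorm(length(res), 0, noise_sd_ppm)))
  a <- shift_assignments(
    residue_index = seq_along(res) + offset - 1L,
    residue_type = res,
    delta_Ca = rc$delta_Ca_ppm + f * amplitude_Ca + noise$ca,
    delta_Ha = rc$delta_Ha_ppm - f * amplitude_Ha + noise$ha)
  attr(a, "truth") <- list(helix_fraction = f, amplitude_Ca = amplitude_Ca,
                           amplitude_Ha = amplitude_Ha)
  a
}
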