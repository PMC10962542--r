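#' Total fluorescence intensity from polarized channels
#'
#' `I = 2 P G + S`, with `P` the perpendicular and `S` the parallel channel
#' intensity and `G` the instrument factor balancing detector efficiency.
#'
#' @param P,S channel intensities (arbitrary units, >= 0).
#' @param G instrument factor (> 0).
#' @return total intensity, same length as the inputs.
#' @export
total_intensity <- function(P, S, G = 1) {
  stopifnot(all(P >= 0), all(S >= 0), all(G > 0))
  2 * P * G + S
}

#' Fluorescence anisotropy from polarized channels
#'
#' `r = (S - G P) / (S + 2 G P)`; the denominator is the total intensity.
#' Values lie in (-0.5, 1], with 1 attained only at `P = 0`.
#'
#' @inheritParams total_intensity
#' @return anisotropy values.
#' @export
anisotropy <- function(P, S, G = 1) {
  stopifnot(all(P >= 0), all(S >= 0), all(G > 0))
  tot <- S + 2 * G * P
  if (any(tot <= 0)) stop("anisotropy undefined: zero total intensity")
  (S - G * P) / tot
}

#' Bound fraction from anisotropy
#'
#' `Lb = (r - rmin) / (lambda (rmax - r) + r - rmin)`, where `lambda` is the
#' bound/unbound intensity-change factor (1 when binding does not change the
#' tracer quantum yield). Small overshoots past the asymptotes are clamped to
#' \[0, 1\]; overshoot beyond `tol` raises a warning.
#'
#' @param r observed anisotropy.
#' @param r_min,r_max free- and bound-state anisotropy asymptotes
#'   (`r_max > r_min`).
#' @param lambda intensity-change factor, default 1.
#' @param tol clamping tolerance as a fraction of the window (default 0.05).
#' @return bound fraction in \[0, 1\].
#' @export
bound_fraction <- function(r, r_min, r_max, lambda = 1, tol = 0.05) {
  if (r_max <= r_min) stop("degenerate anisotropy window: r_max must exceed r_min")
  w <- r_max - r_min
  over <- pmax(r_min - r, r - r_max) / w
  if (any(over > tol))
    warning("anisotropy overshoots the [r_min, r_max] window by more than ",
            tol * 100, "% of its width")
  rc <- pmin(pmax(r, r_min), r_max)
  lb <- (rc - r_min) / (lambda * (r_max - rc) + rc - r_min)
  pmin(pmax(lb, 0), 1)
}

# inverse of bound_fraction: anisotropy from bound fraction
anisotropy_from_bound <- function(Lb, r_min, r_max, lambda = 1) {
  (Lb * lambda * r_max + (1 - Lb) * r_min) / (Lb * lambda + 1 - Lb)
}

#' Morrison tight-binding bound fraction
#'
#' Exact single-site bound fraction of a tracer at total concentration `FL`
#' titrated with protein at total concentration `x`, with dissociation
#' constant `Kd` (no free-ligand approximation):
#' `Lb = ((x + FL + Kd) - sqrt((x + FL + Kd)^2 - 4 x FL)) / (2 FL)`,
#' evaluated in a cancellation-free form so the `FL -> 0` limit recovers the
#' hyperbolic isotherm `x / (x + Kd)`.
#'
#' @param x total added protein concentration (M).
#' @param Kd dissociation constant (M).
#' @param FL total tracer (fluorescent ligand) concentration (M).
#' @return tracer bound fraction in \[0, 1\].
#' @export
morrison_bound_fraction <- function(x, Kd, FL) {
  stopifnot(Kd > 0, FL >= 0, all(x >= 0))
  b <- x + FL + Kd
  disc <- pmax(b^2 - 4 * x * FL, 0)
  2 * x / (b + sqrt(disc))
}

#' Titration series container
#'
#' Holds one direct (protein into tracer) or competition (competitor into
#' protein + tracer) anisotropy titration: x-axis concentrations with
#' replicate anisotropy observations and the assay constants.
#'
#' @param x concentrations (M), strictly positive; sorted ascending on
#'   construction. Added protein in direct mode, added competitor in
#'   competition mode.
#' @param r list of per-x replicate anisotropy vectors, or a matrix with one
#'   row per x, or a single vector (one replicate).
#' @param mode `"direct"` or `"competition"`.
#' @param tracer_conc total tracer concentration (M).
#' @param protein_conc total protein concentration (M; competition mode).
#' @param temperature assay temperature (K).
#' @param truth optional list of ground-truth parameters (attached by the
#'   simulators).
#' @return an object of class `titration_series`.
#' @export
titration_series <- function(x, r, mode = c("direct", "competition"),
                             tracer_conc = 50e-9, protein_conc = NA_real_,
                             temperature = 298.15, truth = NULL) {
  mode <- match.arg(mode)
  if (is.matrix(r)) r <- lapply(seq_len(nrow(r)), function(i) r[i, ])
  if (is.numeric(r)) r <- as.list(r)
  stopifnot(length(x) == length(r), all(x > 0))
  if (length(unique(x)) < 2) stop("need at least 2 distinct concentrations")
  if (any(vapply(r, length, 1L) < 1)) stop("each x needs >= 1 replicate")
  ord <- order(x)
  structure(list(x = as.numeric(x)[ord], r = r[ord], mode = mode,
                 tracer_conc = tracer_conc, protein_conc = protein_conc,
                 temperature = temperature, truth = truth),
            class = "titration_series")
}

#' @export
print.titration_series <- function(x, ...) {
  cat(sprintf("<titration_series> %s, %d points, %s replicates, tracer %.3g M%s\n",
              x$mode, length(x$x),
              paste(range(vapply(x$r, length, 1L)), collapse = "-"),
              x$tracer_conc,
              if (is.finite(x$protein_conc))
                sprintf(", protein %.3g M", x$protein_conc) else ""))
  invisible(x)
}

#' Per-concentration replicate mean and SD
#'
#' @param series a [titration_series()].
#' @return data.frame with columns `x`, `mean`, `sd` (0 for a single
#'   replicate), `n`.
#' @export
aggregate_replicates <- function(series) {
  stopifnot(inherits(series, "titration_series"))
  m <- vapply(series$r, mean, 1)
  s <- vapply(series$r, function(v) if (length(v) > 1) stats::sd(v) else 0, 1)
  data.frame(x = series$x, mean = m, sd = s,
             n = vapply(series$r, length, 1L))
}

# deterministic multi-start bounded Levenberg-Marquardt least squares;
# returns the converged fit of smallest deviance, or NULL
multistart_nls <- function(formula, data, starts, lower, upper) {
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nlsLM(
        formula, data = data, start = st, lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 200))),
      error = function(e) NULL)
    if (!is.null(fit) &&
        (is.null(best) || stats::deviance(fit) < stats::deviance(best)))
      best <- fit
  }
  best
}

# x at which the curve through (x, y) crosses the midpoint of its edge levels
half_crossing <- function(x, y) {
  y0 <- y[1]; y1 <- y[length(y)]
  mid <- (y0 + y1) / 2
  s <- sign(y - mid)
  k <- which(s[-1] != s[-length(s)])[1]
  if (is.na(k)) return(exp(mean(log(range(x)))))
  # log-linear interpolation between the bracketing points
  lx <- log(x[k]) + (mid - y[k]) / (y[k + 1] - y[k]) * (log(x[k + 1]) - log(x[k]))
  exp(lx)
}

#' Fit a direct (saturation) anisotropy titration
#'
#' Fits the tight-binding quadratic model: the tracer bound fraction follows
#' [morrison_bound_fraction()] and the observed anisotropy is the
#' intensity-weighted mix of the free (`r_min`) and bound (`r_max`) states
#' with intensity-change factor `lambda` (fixed to 1 by default). Unweighted
#' least squares on per-x replicate means, deterministic multi-start.
#'
#' @param series a [titration_series()] in direct mode.
#' @param lambda intensity-change factor; fixed unless `float_lambda`.
#' @param float_lambda estimate `lambda` as a fourth parameter.
#' @param weighted weight the means by inverse replicate variance.
#' @return an object of class `fa_direct_fit` with components `coefficients`
#'   (`Kd`, `r_min`, `r_max`, and `lambda` if floated), `se`, `vcov`,
#'   `fitted.values`, `residuals`, `converged`, `rss`, `data`, `series`.
#' @export
fit_direct_titration <- function(series, lambda = 1, float_lambda = FALSE,
                                 weighted = FALSE) {
  stopifnot(inherits(series, "titration_series"))
  if (series$mode != "direct") stop("series is not a direct titration")
  if (series$tracer_conc <= 0) stop("tracer_conc must be positive")
  agg <- aggregate_replicates(series)
  npar <- 3L + as.integer(float_lambda)
  if (nrow(agg) < npar)
    stop("under-determined fit: ", nrow(agg), " points for ", npar, " parameters")
  FL <- series$tracer_conc
  dat <- data.frame(x = agg$x, y = agg$mean)
  r0 <- mean(agg$mean[seq_len(max(1, floor(nrow(agg) / 4)))])
  r1 <- mean(agg$mean[seq.int(nrow(agg) - max(1, floor(nrow(agg) / 4)) + 1, nrow(agg))])
  k0 <- half_crossing(agg$x, agg$mean)
  lower <- c(Kd = min(agg$x) * 1e-6, r_min = -0.5, r_max = -0.5)
  upper <- c(Kd = max(agg$x) * 1e6, r_min = 1, r_max = 1)
  mk <- function(k) {
    st <- list(Kd = k, r_min = r0, r_max = r1)
    if (float_lambda) st$lambda <- 1
    st
  }
  starts <- lapply(k0 * c(1, 0.3, 3), mk)
  if (float_lambda) {
    lower <- c(lower, lambda = 0.05); upper <- c(upper, lambda = 20)
    form <- y ~ anisotropy_from_bound(morrison_bound_fraction(x, Kd, FL),
                                      r_min, r_max, lambda)
  } else {
    form <- as_local_formula(substitute(
      y ~ anisotropy_from_bound(morrison_bound_fraction(x, Kd, FL),
                                r_min, r_max, lam),
      list(lam = lambda)), environment())
  }
  if (weighted) dat$w <- 1 / pmax(agg$sd, max(agg$sd) * 1e-3)^2
  fit <- multistart_nls(form, dat, starts, lower, upper)
  if (is.null(fit))
    stop("direct titration fit did not converge")
  cf <- stats::coef(fit)
  if (cf[["r_max"]] <= cf[["r_min"]])
    warning("fitted r_max does not exceed r_min; inverted or flat data?")
  sm <- summary(fit)
  structure(list(coefficients = cf,
                 se = sm$coefficients[, "Std. Error"],
                 vcov = stats::vcov(fit),
                 lambda = if (float_lambda) cf[["lambda"]] else lambda,
                 tracer_conc = FL,
                 fitted.values = stats::fitted(fit),
                 residuals = stats::residuals(fit),
                 rss = stats::deviance(fit),
                 converged = fit$convInfo$isConv %||% TRUE,
                 data = agg, series = series),
            class = "fa_direct_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# turn a substitute()d model call into a formula evaluated in `env`
as_local_formula <- function(call, env) {
  f <- stats::as.formula(call)
  environment(f) <- env
  f
}

# direction-agnostic 4PL: A0 at x -> 0, Ainf at x -> Inf, p > 0
logistic4 <- function(x, A0, Ainf, x0, p) Ainf + (A0 - Ainf) / (1 + (x / x0)^p)

#' Fit a competition (displacement) anisotropy titration
#'
#' Four-parameter logistic fit of mean anisotropy against competitor
#' concentration, `y = rmax + (rmin - rmax) / (1 + (x / x0)^p)` with the
#' asymptotes assigned direction-agnostically: `r_max` is the zero-competitor
#' level and `r_min` the full-displacement floor. `IC50 = x0`. For curves not
#' reaching full displacement the floor can be restrained to a value obtained
#' from fully displacing competitors (-0.03 by default).
#'
#' @param series a [titration_series()] in competition mode.
#' @param restrain_rmin fix the full-displacement asymptote at `rmin_value`.
#' @param rmin_value restraint value (anisotropy units), default -0.03.
#' @param monotonicity_tol fraction of the dynamic range by which successive
#'   means may rise before the non-monotonicity flag is set (default 0.15).
#' @return an object of class `fa_competition_fit` with `coefficients`
#'   (`IC50`, `hill`, `r_min`, `r_max`), `se`, `IC50_sd` (from per-replicate
#'   refits when replicates allow, else the fit SE), `restrained_rmin`,
#'   `flags`, `fitted.values`, `residuals`, `rss`, `converged`, `data`,
#'   `series`.
#' @export
fit_competition <- function(series, restrain_rmin = FALSE, rmin_value = -0.03,
                            monotonicity_tol = 0.15) {
  stopifnot(inherits(series, "titration_series"))
  if (series$mode != "competition") stop("series is not a competition titration")
  agg <- aggregate_replicates(series)
  fit <- fit_4pl(agg$x, agg$mean, restrain_rmin, rmin_value)
  if (is.null(fit$fit))
    stop("competition fit did not converge; flat or pathological data?")
  cf <- fit$cf; se <- fit$se
  rng <- diff(range(agg$mean))
  flags <- character(0)
  rises <- diff(agg$mean) > monotonicity_tol * max(rng, .Machine$double.eps)
  # displacement runs high -> low; rises beyond noise tolerance are suspect
  if (cf[["r_max"]] >= cf[["r_min"]] && agg$mean[1] > agg$mean[nrow(agg)] &&
      any(rises))
    flags <- c(flags, "non_monotonic")
  if (cf[["IC50"]] > max(agg$x)) flags <- c(flags, "ic50_beyond_max_x")
  if (rng < 4 * stats::median(agg$sd) && stats::median(agg$sd) > 0)
    flags <- c(flags, "low_dynamic_range")
  ic50_sd <- per_replicate_ic50_sd(series, restrain_rmin, rmin_value)
  if (is.na(ic50_sd)) ic50_sd <- se[["IC50"]]
  structure(list(coefficients = cf, se = se, IC50_sd = ic50_sd,
                 restrained_rmin = restrain_rmin,
                 rmin_value = rmin_value, flags = flags,
                 fitted.values = fit$fitted, residuals = fit$resid,
                 rss = fit$rss, converged = TRUE,
                 data = agg, series = series),
            class = "fa_competition_fit")
}

# core 4PL fit on (x, y) means; returns relabelled coefficients
fit_4pl <- function(x, y, restrain_rmin, rmin_value) {
  ne <- max(1L, floor(length(x) / 4))
  A0s <- mean(y[seq_len(ne)])
  Ainfs <- mean(y[seq.int(length(y) - ne + 1L, length(y))])
  x00 <- half_crossing(x, y)
  lower <- c(A0 = -0.5, Ainf = -0.5, x0 = min(x) * 1e-3, p = 0.2)
  upper <- c(A0 = 1, Ainf = 1, x0 = max(x) * 1e3, p = 10)
  dat <- data.frame(x = x, y = y)
  if (restrain_rmin) {
    # the restrained quantity is the full-displacement floor, i.e. the
    # smaller asymptote; for a displacement curve that is the x -> Inf end
    if (A0s <= Ainfs) {
      form <- as_local_formula(substitute(y ~ logistic4(x, rv, Ainf, x0, p),
                                          list(rv = rmin_value)),
                               environment())
      drop <- "A0"
    } else {
      form <- as_local_formula(substitute(y ~ logistic4(x, A0, rv, x0, p),
                                          list(rv = rmin_value)),
                               environment())
      drop <- "Ainf"
    }
    lower <- lower[setdiff(names(lower), drop)]
    upper <- upper[setdiff(names(upper), drop)]
    starts <- lapply(x00 * c(1, 0.3, 3), function(k) {
      st <- list(A0 = A0s, Ainf = Ainfs, x0 = k, p = 1)
      st[[drop]] <- NULL
      st
    })
  } else {
    form <- y ~ logistic4(x, A0, Ainf, x0, p)
    drop <- NA_character_
    starts <- lapply(x00 * c(1, 0.3, 3),
                     function(k) list(A0 = A0s, Ainf = Ainfs, x0 = k, p = 1))
  }
  fit <- multistart_nls(form, dat, starts, lower, upper)
  if (is.null(fit)) return(list(fit = NULL))
  cfr <- stats::coef(fit)
  ser <- summary(fit)$coefficients[, "Std. Error"]
  if (restrain_rmin) { cfr[drop] <- rmin_value; ser[drop] <- 0 }
  r_max <- max(cfr[["A0"]], cfr[["Ainf"]])
  r_min <- min(cfr[["A0"]], cfr[["Ainf"]])
  hi <- if (cfr[["A0"]] >= cfr[["Ainf"]]) "A0" else "Ainf"
  lo <- setdiff(c("A0", "Ainf"), hi)
  cf <- c(IC50 = unname(cfr[["x0"]]), hill = unname(cfr[["p"]]),
          r_min = unname(r_min), r_max = unname(r_max))
  se <- c(IC50 = unname(ser[["x0"]]), hill = unname(ser[["p"]]),
          r_min = unname(ser[[lo]]), r_max = unname(ser[[hi]]))
  list(fit = fit, cf = cf, se = se, fitted = stats::fitted(fit),
       resid = stats::residuals(fit), rss = stats::deviance(fit))
}

# SD of IC50 across per-replicate refits; NA when replicates do not allow it
per_replicate_ic50_sd <- function(series, restrain_rmin, rmin_value) {
  nrep <- min(vapply(series$r, length, 1L))
  if (nrep < 2) return(NA_real_)
  ic <- rep(NA_real_, nrep)
  for (k in seq_len(nrep)) {
    yk <- vapply(series$r, `[[`, 1, k)
    fk <- tryCatch(fit_4pl(series$x, yk, restrain_rmin, rmin_value),
                   error = function(e) list(fit = NULL))
    if (!is.null(fk$fit)) ic[k] <- fk$cf[["IC50"]]
  }
  if (sum(!is.na(ic)) < 2) return(NA_real_)
  stats::sd(ic, na.rm = TRUE)
}

#' Free-energy difference from an IC50 ratio
#'
#' `ddG = -R T ln(IC50_new / IC50_ref)` in kJ/mol; positive when the new
#' inhibitor is more potent (smaller IC50). `R = 8.314 J mol^-1 K^-1`.
#'
#' @param ic50_ref,ic50_new IC50 values (any common unit), > 0.
#' @param temperature K, default 298.15.
#' @return energy difference, kJ/mol.
#' @export
delta_delta_g <- function(ic50_ref, ic50_new, temperature = 298.15) {
  if (any(c(ic50_ref, ic50_new, temperature) <= 0))
    stop("IC50 values and temperature must be positive")
  -8.314 * temperature * log(ic50_new / ic50_ref) / 1000
}

## ---- S3 methods for the fit classes ----

#' @export
coef.fa_direct_fit <- function(object, ...) object$coefficients
#' @export
coef.fa_competition_fit <- function(object, ...) object$coefficients
#' @export
vcov.fa_direct_fit <- function(object, ...) object$vcov
#' @export
residuals.fa_direct_fit <- function(object, ...) object$residuals
#' @export
residuals.fa_competition_fit <- function(object, ...) object$residuals
#' @export
fitted.fa_direct_fit <- function(object, ...) object$fitted.values
#' @export
fitted.fa_competition_fit <- function(object, ...) object$fitted.values

#' @export
predict.fa_direct_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$x else
    if (is.data.frame(newdata)) newdata$x else newdata
  cf <- object$coefficients
  anisotropy_from_bound(
    morrison_bound_fraction(x, cf[["Kd"]], object$tracer_conc),
    cf[["r_min"]], cf[["r_max"]], object$lambda)
}

#' @export
predict.fa_competition_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$x else
    if (is.data.frame(newdata)) newdata$x else newdata
  cf <- object$coefficients
  # orient: zero-competitor level is r_max
  logistic4(x, cf[["r_max"]], cf[["r_min"]], cf[["IC50"]], cf[["hill"]])
}

#' @export
print.fa_direct_fit <- function(x, digits = 4, ...) {
  cat("Direct anisotropy titration fit (tight-binding quadratic)\n")
  cat(sprintf("  Kd    = %.*g M (SE %.2g)\n", digits,
              x$coefficients[["Kd"]], x$se[["Kd"]]))
  cat(sprintf("  r_min = %.*g, r_max = %.*g, lambda = %g\n", digits,
              x$coefficients[["r_min"]], digits, x$coefficients[["r_max"]],
              x$lambda))
  invisible(x)
}

#' @export
print.fa_competition_fit <- function(x, digits = 4, ...) {
  cat("Competition anisotropy fit (4-parameter logistic)\n")
  cat(sprintf("  IC50  = %.*g M (replicate SD %.2g)\n", digits,
              x$coefficients[["IC50"]], x$IC50_sd))
  cat(sprintf("  hill  = %.*g, r_min = %.*g%s, r_max = %.*g\n", digits,
              x$coefficients[["hill"]], digits, x$coefficients[["r_min"]],
              if (x$restrained_rmin) " (restrained)" else "",
              digits, x$coefficients[["r_max"]]))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.fa_direct_fit <- function(object, ...) {
  tab <- cbind(Estimate = object$coefficients,
               `Std. Error` = object$se[names(object$coefficients)])
  structure(list(coefficients = tab, rss = object$rss,
                 n = nrow(object$data), converged = object$converged,
                 kind = "direct"),
            class = "summary.fa_fit")
}

#' @export
summary.fa_competition_fit <- function(object, ...) {
  tab <- cbind(Estimate = object$coefficients,
               `Std. Error` = object$se[names(object$coefficients)])
  structure(list(coefficients = tab, rss = object$rss,
                 n = nrow(object$data), converged = object$converged,
                 IC50_sd = object$IC50_sd, flags = object$flags,
                 kind = "competition"),
            class = "summary.fa_fit")
}

#' @export
print.summary.fa_fit <- function(x, ...) {
  cat(sprintf("%s anisotropy fit on %d concentrations (RSS %.3g)\n",
              if (x$kind == "direct") "Direct" else "Competition", x$n, x$rss))
  print(x$coefficients)
  if (!is.null(x$flags) && length(x$flags))
    cat("flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.fa_direct_fit <- function(x, ...) {
  plot_fa_fit(x, xlab = "[protein] (M)", ...)
}
#' @export
plot.fa_competition_fit <- function(x, ...) {
  plot_fa_fit(x, xlab = "[competitor] (M)", ...)
}

plot_fa_fit <- function(x, xlab, ...) {
  agg <- x$data
  graphics::plot(agg$x, agg$mean, log = "x", pch = 19,
                 xlab = xlab, ylab = "anisotropy", ...)
  graphics::arrows(agg$x, agg$mean - agg$sd, agg$x, agg$mean + agg$sd,
                   angle = 90, code = 3, length = 0.03)
  xx <- exp(seq(log(min(agg$x)), log(max(agg$x)), length.out = 200))
  graphics::lines(xx, predict(x, xx), col = "firebrick")
  invisible(x)
}
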