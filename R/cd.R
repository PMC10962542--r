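#' Circular dichroism spectrum container
#'
#' Wavelength-indexed raw ellipticity with the sample metadata needed to
#' normalise it. Two size counts coexist deliberately: `n_residues` enters
#' the mean-residue-ellipticity normalisation, while `n_amide` (backbone
#' amide bonds, residues + 1 for acetyl/amide-capped peptides) enters the
#' percent-helicity formula; they are never conflated.
#'
#' @param wavelength nm grid, strictly monotone (ascending or descending).
#' @param ellipticity observed ellipticity per wavelength, mdeg.
#' @param Mw peptide molecular weight, g/mol.
#' @param conc sample concentration, mg/mL (> 0 unless blank).
#' @param pathlength cuvette pathlength, mm.
#' @param n_residues residue count (normalisation `n` of the MRE formula).
#' @param n_amide backbone amide-bond count (the `n` of the helicity formula).
#' @param temperature measurement temperature, degrees C.
#' @param is_blank buffer-blank flag.
#' @return an object of class `cd_spectrum`.
#' @export
cd_spectrum <- function(wavelength, ellipticity, Mw = NA_real_,
                        conc = NA_real_, pathlength = 1, n_residues = NA_integer_,
                        n_amide = NA_integer_, temperature = 5,
                        is_blank = FALSE) {
  stopifnot(length(wavelength) == length(ellipticity), length(wavelength) >= 2)
  d <- diff(wavelength)
  if (!(all(d > 0) || all(d < 0)))
    stop("wavelength grid must be strictly monotone")
  if (!is_blank) {
    if (!is.finite(conc) || conc <= 0) stop("conc must be positive (mg/mL)")
    if (!is.finite(pathlength) || pathlength <= 0)
      stop("pathlength must be positive (mm)")
  }
  structure(list(wavelength = as.numeric(wavelength),
                 ellipticity = as.numeric(ellipticity),
                 meta = list(Mw = Mw, conc = conc, pathlength = pathlength,
                             n_residues = n_residues, n_amide = n_amide,
                             temperature = temperature),
                 is_blank = is_blank),
            class = "cd_spectrum")
}

#' @export
print.cd_spectrum <- function(x, ...) {
  cat(sprintf("<cd_spectrum%s> %d points, %g-%g nm, T = %g C\n",
              if (x$is_blank) " blank" else "", length(x$wavelength),
              min(x$wavelength), max(x$wavelength), x$meta$temperature))
  invisible(x)
}

#' Mean residue ellipticity spectrum
#'
#' Blank-subtracted, normalised ellipticity:
#' `MRE = (theta_lambda - theta_0) * Mw / (n_residues * l * c)` with `l` in
#' mm and `c` in mg/mL, giving deg cm^2 dmol^-1 res^-1 (the mm-pathlength
#' convention absorbs the usual factor of 10). Blank subtraction is
#' mandatory; pass an explicit zero blank if none was recorded.
#'
#' @param sample a non-blank [cd_spectrum()].
#' @param blank the buffer [cd_spectrum()]; must share the sample grid unless
#'   `interpolate = TRUE`.
#' @param interpolate linearly interpolate the blank onto the sample grid.
#' @return an object of class `mre_spectrum` (wavelength, mre, meta).
#' @export
mre_spectrum <- function(sample, blank, interpolate = FALSE) {
  stopifnot(inherits(sample, "cd_spectrum"), inherits(blank, "cd_spectrum"))
  m <- sample$meta
  if (!is.finite(m$Mw) || !is.finite(m$n_residues))
    stop("sample metadata must include Mw and n_residues")
  if (!isTRUE(all.equal(sample$wavelength, blank$wavelength))) {
    if (!interpolate)
      stop("sample and blank wavelength grids differ; set interpolate = TRUE")
    b <- stats::approx(blank$wavelength, blank$ellipticity,
                       xout = sample$wavelength, rule = 1)$y
    if (anyNA(b)) stop("blank does not span the sample grid")
  } else {
    b <- blank$ellipticity
  }
  mre <- (sample$ellipticity - b) * m$Mw / (m$n_residues * m$pathlength * m$conc)
  structure(list(wavelength = sample$wavelength, mre = mre, meta = m),
            class = "mre_spectrum")
}

#' @export
print.mre_spectrum <- function(x, ...) {
  cat(sprintf("<mre_spectrum> %d points, %g-%g nm\n", length(x$wavelength),
              min(x$wavelength), max(x$wavelength)))
  invisible(x)
}

#' @export
plot.mre_spectrum <- function(x, ...) {
  graphics::plot(x$wavelength, x$mre, type = "l", xlab = "wavelength (nm)",
                 ylab = expression(MRE ~ (deg ~ cm^2 ~ dmol^-1 ~ res^-1)), ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' MRE value at a wavelength (nearest grid point)
#'
#' @param spectrum an `mre_spectrum`.
#' @param wavelength nm; must lie within the grid span.
#' @return MRE at the nearest grid point.
#' @export
mre_at <- function(spectrum, wavelength = 222) {
  w <- spectrum$wavelength
  if (wavelength < min(w) || wavelength > max(w))
    stop("wavelength ", wavelength, " nm outside the grid span ",
         min(w), "-", max(w), " nm")
  spectrum$mre[which.min(abs(w - wavelength))]
}

#' Random-coil MRE baseline at 222 nm
#'
#' Temperature-dependent coil limit `MRE_coil = 640 - 45 T` (T in degrees C),
#' e.g. 415 deg cm^2 dmol^-1 res^-1 at 5 C.
#'
#' @param temperature degrees C.
#' @return MRE_coil, deg cm^2 dmol^-1 res^-1.
#' @export
coil_baseline <- function(temperature) 640 - 45 * temperature

#' Percent helicity from the 222 nm mean residue ellipticity
#'
#' `%helicity = (MRE222 - MRE_coil) * 100 / (-42500 (1 - 3/n))` where `n` is
#' the number of backbone amide bonds including the N-terminal acetyl (see
#' [count_backbone_amides()]) and `MRE_coil` follows [coil_baseline()]. The
#' unrounded value is retained; `rounded_percent` is the nearest integer for
#' comparison with reported tables.
#'
#' @param MRE222 MRE at 222 nm, deg cm^2 dmol^-1 res^-1.
#' @param n_amide backbone amide-bond count (> 3).
#' @param temperature degrees C (default 5, a typical CD temperature for
#'   marginally stable peptides).
#' @return an object of class `helicity_estimate` with fields `MRE222`,
#'   `MRE_coil`, `percent_helicity`, `rounded_percent`.
#' @export
percent_helicity <- function(MRE222, n_amide, temperature = 5) {
  if (n_amide <= 3) stop("n_amide must exceed 3")
  coil <- coil_baseline(temperature)
  pct <- (MRE222 - coil) * 100 / (-42500 * (1 - 3 / n_amide))
  structure(list(MRE222 = MRE222, MRE_coil = coil,
                 percent_helicity = pct,
                 rounded_percent = as.integer(round(pct))),
            class = "helicity_estimate")
}

#' @export
print.helicity_estimate <- function(x, ...) {
  cat(sprintf("helicity: %.2f%% (rounded %d%%), MRE222 = %.1f, coil = %.1f\n",
              x$percent_helicity, x$rounded_percent, x$MRE222, x$MRE_coil))
  invisible(x)
}

#' Helicity estimate straight from a spectrum
#'
#' Convenience wrapper: nearest-grid-point MRE at 222 nm fed through
#' [percent_helicity()] using the spectrum's `n_amide` and temperature.
#'
#' @param spectrum an `mre_spectrum` whose metadata carry `n_amide`.
#' @return a `helicity_estimate`.
#' @export
helicity_from_spectrum <- function(spectrum) {
  m <- spectrum$meta
  if (!is.finite(m$n_amide)) stop("spectrum metadata lack n_amide")
  percent_helicity(mre_at(spectrum, 222), m$n_amide, m$temperature)
}

#' Average replicate CD spectra
#'
#' Pointwise mean of spectra recorded in duplicate (or more). Grids and
#' metadata must agree.
#'
#' @param spectra list of [cd_spectrum()] objects.
#' @return a single [cd_spectrum()].
#' @export
average_duplicate_spectra <- function(spectra) {
  stopifnot(length(spectra) >= 1,
            all(vapply(spectra, inherits, TRUE, "cd_spectrum")))
  ref <- spectra[[1]]
  for (s in spectra[-1]) {
    if (!isTRUE(all.equal(s$wavelength, ref$wavelength)))
      stop("wavelength grids differ between replicates")
    if (!isTRUE(all.equal(s$meta, ref$meta)) || s$is_blank != ref$is_blank)
      stop("replicate metadata differ")
  }
  ell <- rowMeans(vapply(spectra, `[[`, numeric(length(ref$wavelength)),
                         "ellipticity"))
  out <- ref
  out$ellipticity <- ell
  out
}
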