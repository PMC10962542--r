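#' Chemical-shift assignment table
#'
#' Validates a per-residue table of observed Calpha / Halpha shifts. Residue
#' types use one-letter codes plus `"pS"` (phosphoserine) and `"C-mal"`
#' (maleimide-linked cysteine, referenced against the plain Cys coil value
#' downstream).
#'
#' @param residue_index parent-numbering indices, unique.
#' @param residue_type residue codes.
#' @param delta_Ca,delta_Ha observed shifts, ppm (NA allowed, but each row
#'   needs at least one nucleus).
#' @param peak_width optional ppm linewidths used as uncertainty bars.
#' @return a `shift_assignments` data.frame.
#' @export
shift_assignments <- function(residue_index, residue_type,
                              delta_Ca = NA_real_, delta_Ha = NA_real_,
                              peak_width = NA_real_) {
  d <- data.frame(residue_index = as.integer(residue_index),
                  residue_type = as.character(residue_type),
                  delta_Ca = as.numeric(delta_Ca),
                  delta_Ha = as.numeric(delta_Ha),
                  peak_width = as.numeric(peak_width))
  if (anyDuplicated(d$residue_index))
    stop("residue_index values must be unique")
  if (any(is.na(d$delta_Ca) & is.na(d$delta_Ha)))
    stop("every residue needs at least one of delta_Ca / delta_Ha")
  class(d) <- c("shift_assignments", "data.frame")
  d
}

#' Random-coil reference shifts
#'
#' Returns the packaged residue -> (Calpha, Halpha) random-coil table, or
#' reads a user-supplied CSV with columns `residue`, `delta_Ca_ppm`,
#' `delta_Ha_ppm`. The packaged values are approximate transcriptions of
#' widely used disordered-protein coil compilations and are intended as a
#' convenience default: for publication work supply the coil table matched
#' to your conditions. All numerical guarantees of this package are
#' established with synthetic tables, so nothing downstream depends on these
#' particular values.
#'
#' @param path optional CSV path; default uses the packaged table.
#' @return a `random_coil_table` data.frame with a `provenance` attribute.
#' @export
random_coil_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "random_coil_shifts.csv",
                        package = "pepbiophys", mustWork = TRUE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       comment.char = "#")
  stopifnot(all(c("residue", "delta_Ca_ppm", "delta_Ha_ppm") %in% names(d)))
  missing <- setdiff(AA1, d$residue)
  if (length(missing))
    stop("random-coil table lacks canonical residue(s): ",
         paste(missing, collapse = ", "))
  attr(d, "provenance") <- paste(grep("^#", readLines(path, n = 10),
                                      value = TRUE), collapse = " ")
  class(d) <- c("random_coil_table", "data.frame")
  d
}

# resolve a residue type to its coil reference row; "C-mal" uses "C"
rc_lookup <- function(table, code) {
  key <- if (code == "C-mal") "C" else code
  i <- match(key, table$residue)
  if (is.na(i)) stop("no random-coil reference for residue type '", code, "'")
  table[i, c("delta_Ca_ppm", "delta_Ha_ppm")]
}

#' Random-coil-referenced secondary chemical shifts
#'
#' `ddelta = delta_obs - delta_RC` per residue and nucleus. Sustained
#' positive Calpha (downfield) or negative Halpha (upfield) runs indicate
#' helical propensity. Missing nuclei propagate as NA. Helical segments are
#' called with the default [call_helical_segments()] parameters and attached.
#'
#' @param assignments a [shift_assignments()] table.
#' @param table a [random_coil_table()].
#' @return an object of class `secondary_shift_profile`: data.frame with
#'   `residue_index`, `residue_type`, `dCa`, `dHa`, `uncertainty`, plus a
#'   `segments` attribute.
#' @export
secondary_shifts <- function(assignments, table = random_coil_table()) {
  stopifnot(inherits(assignments, "shift_assignments"))
  a <- assignments[order(assignments$residue_index), ]
  rc <- do.call(rbind, lapply(a$residue_type, rc_lookup, table = table))
  prof <- data.frame(residue_index = a$residue_index,
                     residue_type = a$residue_type,
                     dCa = a$delta_Ca - rc$delta_Ca_ppm,
                     dHa = a$delta_Ha - rc$delta_Ha_ppm,
                     uncertainty = a$peak_width)
  class(prof) <- c("secondary_shift_profile", "data.frame")
  attr(prof, "segments") <- call_helical_segments(prof)
  prof
}

#' Call helical segments from a secondary-shift profile
#'
#' Maximal runs of at least `min_run` index-consecutive residues whose
#' `ddelta(Calpha)` exceeds `ca_threshold` (or, in Halpha mode, whose
#' `ddelta(Halpha)` is below `-threshold`). The thresholds are this package's
#' operational defaults: the run-based reading of helical propensity is
#' qualitative in origin, so both are exposed as parameters.
#'
#' @param profile a `secondary_shift_profile`.
#' @param min_run minimum run length (default 4, about one helical turn).
#' @param ca_threshold ppm threshold (default 0.1).
#' @param nucleus `"Ca"` (positive runs) or `"Ha"` (negative runs).
#' @param exclude_cmal drop `"C-mal"` residues before calling (their coil
#'   reference is unreliable); their ddelta values are still reported.
#' @return data.frame with `start`, `end` (parent numbering, inclusive),
#'   `length`, `sense`.
#' @export
call_helical_segments <- function(profile, min_run = 4, ca_threshold = 0.1,
                                  nucleus = c("Ca", "Ha"),
                                  exclude_cmal = FALSE) {
  nucleus <- match.arg(nucleus)
  p <- profile[order(profile$residue_index), ]
  if (exclude_cmal) p <- p[p$residue_type != "C-mal", ]
  if (nrow(p) == 0)
    return(data.frame(start = integer(0), end = integer(0),
                      length = integer(0), sense = character(0)))
  ok <- if (nucleus == "Ca") !is.na(p$dCa) & p$dCa > ca_threshold
        else !is.na(p$dHa) & p$dHa < -ca_threshold
  segs <- list()
  run_start <- NA_integer_
  prev_idx <- NA_integer_
  for (i in seq_len(nrow(p))) {
    contiguous <- !is.na(prev_idx) && p$residue_index[i] == prev_idx + 1L
    if (ok[i] && (is.na(run_start) || !contiguous)) {
      if (!is.na(run_start))
        segs <- c(segs, list(c(run_start, prev_idx)))
      run_start <- p$residue_index[i]
    } else if (!ok[i] && !is.na(run_start)) {
      segs <- c(segs, list(c(run_start, prev_idx)))
      run_start <- NA_integer_
    }
    prev_idx <- p$residue_index[i]
  }
  if (!is.na(run_start)) segs <- c(segs, list(c(run_start, prev_idx)))
  segs <- Filter(function(s) s[2] - s[1] + 1L >= min_run, segs)
  data.frame(start = vapply(segs, `[`, 1L, 1),
             end = vapply(segs, `[`, 1L, 2),
             length = vapply(segs, function(s) s[2] - s[1] + 1L, 1L),
             sense = rep(if (nucleus == "Ca") "downfield-Ca" else "upfield-Ha",
                         length(segs)))
}

#' Per-residue helix-strength classification
#'
#' Bands on the Calpha secondary shift: below 0.1 ppm `"coil-like"`;
#' 0.1 to 2.0 ppm `"weak-helical"` (the range typical of transient peptide
#' helicity); 2.0 ppm and above `"strong-helical"` (heavily stabilised
#' helices). Positive (downfield) sense only; NA propagates.
#'
#' @param profile a `secondary_shift_profile`.
#' @return character vector of labels, one per residue.
#' @export
classify_helix_strength <- function(profile) {
  d <- profile$dCa
  out <- rep(NA_character_, length(d))
  out[!is.na(d) & d < 0.1] <- "coil-like"
  out[!is.na(d) & d >= 0.1 & d < 2.0] <- "weak-helical"
  out[!is.na(d) & d >= 2.0] <- "strong-helical"
  out
}

#' @export
print.secondary_shift_profile <- function(x, ...) {
  cat(sprintf("<secondary_shift_profile> %d residues (%d-%d)\n",
              nrow(x), min(x$residue_index), max(x$residue_index)))
  segs <- attr(x, "segments")
  if (!is.null(segs) && nrow(segs))
    cat("  helical segments:",
        paste(sprintf("%d-%d", segs$start, segs$end), collapse = ", "), "\n")
  else cat("  no helical segments at default thresholds\n")
  invisible(x)
}

#' @export
plot.secondary_shift_profile <- function(x, ...) {
  graphics::barplot(x$dCa, names.arg = x$residue_index,
                    xlab = "residue", ylab = expression(Delta * delta ~
                      C^alpha ~ (ppm)), ...)
  graphics::abline(h = 0)
  invisible(x)
}
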