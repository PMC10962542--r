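## File formats and pipeline orchestration. All concentrations are molar
## internally; column names declare units (x_conc_M, conc_mg_mL, ...).
## CSV dialect: comma-separated, "." decimal, UTF-8, mandatory header.

#' Read a plate-reader anisotropy file
#'
#' Expects columns `well`, `series_id`, `x_conc_M`, `P`, `S`, `G`,
#' `replicate`. Rows with `series_id == "control"` are blank/control wells:
#' their mean `P` and `S` are subtracted from every measurement well before
#' anisotropy is computed (negative channel intensities after subtraction
#' are clamped to zero with a warning). One [titration_series()] is returned
#' per remaining `series_id`.
#'
#' @param path CSV path.
#' @param mode `"direct"` or `"competition"` (applies to all series in the
#'   file).
#' @param tracer_conc,protein_conc,temperature assay constants attached to
#'   each series (M, M, K).
#' @return named list of [titration_series()].
#' @export
read_fa_plate <- function(path, mode = c("competition", "direct"),
                          tracer_conc = 50e-9, protein_conc = 15e-6,
                          temperature = 298.15) {
  mode <- match.arg(mode)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("well", "series_id", "x_conc_M", "P", "S", "G", "replicate")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("plate file lacks column(s): ",
                         paste(miss, collapse = ", "))
  ctrl <- d$series_id == "control"
  p0 <- if (any(ctrl)) mean(d$P[ctrl]) else 0
  s0 <- if (any(ctrl)) mean(d$S[ctrl]) else 0
  d <- d[!ctrl, , drop = FALSE]
  P <- d$P - p0; S <- d$S - s0
  if (any(P < 0) || any(S < 0)) {
    warning("negative intensities after control subtraction clamped to zero")
    P <- pmax(P, 0); S <- pmax(S, 0)
  }
  d$r <- anisotropy(P, S, d$G)
  out <- list()
  for (id in unique(d$series_id)) {
    di <- d[d$series_id == id, ]
    xs <- sort(unique(di$x_conc_M))
    reads <- lapply(xs, function(x) di$r[di$x_conc_M == x])
    out[[id]] <- titration_series(xs, reads, mode = mode,
                                  tracer_conc = tracer_conc,
                                  protein_conc = protein_conc,
                                  temperature = temperature)
  }
  out
}

#' Write a titration series as a plate-reader CSV
#'
#' Inverse of [read_fa_plate()] for simulated data: anisotropy values are
#' encoded back into `P`/`S` channel pairs (G = 1, unit total intensity per
#' well) so the written file exercises the full reader path.
#'
#' @param series a [titration_series()] or named list of them.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_fa_plate <- function(series, path) {
  if (inherits(series, "titration_series")) series <- list(series_1 = series)
  rows <- list()
  wi <- 0L
  for (id in names(series)) {
    s <- series[[id]]
    for (i in seq_along(s$x)) for (k in seq_along(s$r[[i]])) {
      wi <- wi + 1L
      r <- s$r[[i]][k]
      # with I = S + 2GP = 1 and G = 1: S = (1 + 2r)/3, P = (1 - r)/3
      rows[[wi]] <- data.frame(well = sprintf("W%04d", wi), series_id = id,
                               x_conc_M = s$x[i], P = (1 - r) / 3,
                               S = (1 + 2 * r) / 3, G = 1, replicate = k)
    }
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read a two-column CD spectrum file
#'
#' Columns `wavelength_nm`, `ellipticity_mdeg`; sample metadata arrive via
#' arguments (or a YAML sidecar read with [yaml::read_yaml()] upstream).
#'
#' @param path CSV path.
#' @param ... metadata passed to [cd_spectrum()] (`Mw`, `conc`, `pathlength`,
#'   `n_residues`, `n_amide`, `temperature`, `is_blank`).
#' @return a [cd_spectrum()].
#' @export
read_cd_file <- function(path, ...) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("wavelength_nm", "ellipticity_mdeg") %in% names(d)))
  cd_spectrum(d$wavelength_nm, d$ellipticity_mdeg, ...)
}

#' Write a CD spectrum file
#'
#' @param spectrum a [cd_spectrum()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cd_file <- function(spectrum, path) {
  utils::write.csv(data.frame(wavelength_nm = spectrum$wavelength,
                              ellipticity_mdeg = spectrum$ellipticity),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a chemical-shift table
#'
#' Columns `residue_index`, `residue_type`, `delta_Ca_ppm`, `delta_Ha_ppm`
#' and optionally `peak_width_ppm`.
#'
#' @param path CSV path.
#' @return a [shift_assignments()] table.
#' @export
read_shift_table <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("residue_index", "residue_type") %in% names(d)))
  shift_assignments(d$residue_index, d$residue_type,
                    d$delta_Ca_ppm %||% NA_real_,
                    d$delta_Ha_ppm %||% NA_real_,
                    d$peak_width_ppm %||% NA_real_)
}

#' Write a chemical-shift table
#'
#' @param assignments a [shift_assignments()] table.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_shift_table <- function(assignments, path) {
  utils::write.csv(data.frame(residue_index = assignments$residue_index,
                              residue_type = assignments$residue_type,
                              delta_Ca_ppm = assignments$delta_Ca,
                              delta_Ha_ppm = assignments$delta_Ha,
                              peak_width_ppm = assignments$peak_width),
                   path, row.names = FALSE)
  invisible(path)
}

#' Export a variant list as delimited text
#'
#' One row per peptide: name, sequence, offset, constraint positions/state,
#' backbone amide-bond count and molar extinction coefficient.
#'
#' @param variants list of [peptide_spec()] (e.g. from
#'   [enumerate_cys_pair_variants()]).
#' @param path output CSV path.
#' @return the exported data.frame, invisibly.
#' @export
write_variant_table <- function(variants, path) {
  rows <- lapply(variants, function(v) {
    data.frame(name = v$name, sequence = as.character(v),
               offset = v$numbering_offset,
               constraint_i = v$constraint$position_i %||% NA_integer_,
               constraint_j = v$constraint$position_j %||% NA_integer_,
               state = v$constraint$state %||% NA_character_,
               n_amide = count_backbone_amides(v),
               epsilon = molar_extinction(v))
  })
  d <- if (length(rows)) do.call(rbind, rows) else
    data.frame(name = character(0), sequence = character(0),
               offset = integer(0), constraint_i = integer(0),
               constraint_j = integer(0), state = character(0),
               n_amide = integer(0), epsilon = numeric(0))
  utils::write.csv(d, path, row.names = FALSE)
  invisible(d)
}

#' Reported characterization panel of N-Myc peptide variants
#'
#' The packaged panel of 13 N-Myc-derived peptides (truncations, point
#' substitutions and i,i+4 cysteine-pair variants of the Aurora-A-binding
#' region in red/ox/mal constraint states) with their reported competition
#' IC50 values (uM), 222 nm mean residue ellipticities and percent-helicity
#' estimates at 5 C. Used as the desk-scale input for reproducing the
#' helicity and free-energy arithmetic.
#'
#' @return data.frame with columns `name`, `sequence`, `offset`,
#'   `constraint_i`, `constraint_j`, `state`, `ic50_uM`, `ic50_sd_uM`,
#'   `mre222`, `mre222_sd`, `helicity_pct`.
#' @export
nmyc_panel <- function() {
  path <- system.file("extdata", "nmyc_panel.csv", package = "pepbiophys",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Run the design-measure-fit-report pipeline
#'
#' Orchestrates the full workflow over a configuration that is either a list
#' or the path of a YAML file with a `peptides` entry: each peptide record
#' carries `name`, `sequence` (modifier notation, see [parse_peptide()]),
#' `offset`, optionally `constraint` (`i`, `j`, `state`), optionally `fa`
#' (plate `file`, `series_id`, `tracer_conc`, `protein_conc`,
#' `restrain_rmin`) and `cd` (`sample` and `blank` file paths, `conc` mg/mL,
#' `pathlength` mm, `temperature` C, optional `Mw`). A top-level `reference`
#' names the peptide against which free-energy differences are computed.
#' Failures are recorded per peptide in `flags`, never fatal; deterministic
#' inputs give a deterministic report.
#'
#' @param config list or YAML path.
#' @return an object of class `study_report` (a data.frame; one row per
#'   peptide).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  peps <- config$peptides %||% list()
  temperature_K <- config$temperature_K %||% 298.15
  rows <- list()
  for (entry in peps) {
    flags <- character(0); checks <- character(0)
    ic50 <- ic50_sd <- mre222 <- pct <- NA_real_
    rounded <- NA_integer_
    pep <- tryCatch({
      p <- parse_peptide(entry$sequence, offset = entry$offset %||% 1L,
                         name = entry$name)
      if (!is.null(entry$constraint))
        p <- peptide_spec(p$name, p$residues, p$numbering_offset, p$n_term,
                          p$c_term,
                          constraint_spec(entry$constraint$i,
                                          entry$constraint$j,
                                          entry$constraint$state %||% "red"))
      p
    }, error = function(e) { flags <<- c(flags, paste0("peptide: ",
                                                       conditionMessage(e)))
      NULL })
    if (!is.null(pep) && !is.null(entry$fa)) {
      res <- tryCatch({
        series <- read_fa_plate(entry$fa$file, mode = "competition",
                                tracer_conc = entry$fa$tracer_conc %||% 50e-9,
                                protein_conc = entry$fa$protein_conc %||% 15e-6,
                                temperature = temperature_K)
        id <- entry$fa$series_id %||% names(series)[1]
        fit <- fit_competition(series[[id]],
                               restrain_rmin = isTRUE(entry$fa$restrain_rmin))
        checks <- c(checks, file_checksum(entry$fa$file))
        flags <- c(flags, fit$flags)
        list(ic50 = fit$coefficients[["IC50"]], sd = fit$IC50_sd)
      }, error = function(e) { flags <<- c(flags, paste0("fa: ",
                                                         conditionMessage(e)))
        NULL })
      if (!is.null(res)) { ic50 <- res$ic50; ic50_sd <- res$sd }
    }
    if (!is.null(pep) && !is.null(entry$cd)) {
      res <- tryCatch({
        meta <- entry$cd
        mw <- meta$Mw %||% peptide_mw(pep)
        sample <- read_cd_file(meta$sample, Mw = mw, conc = meta$conc,
                               pathlength = meta$pathlength %||% 1,
                               n_residues = length(pep$residues),
                               n_amide = count_backbone_amides(pep),
                               temperature = meta$temperature %||% 5)
        blank <- read_cd_file(meta$blank, is_blank = TRUE,
                              temperature = meta$temperature %||% 5)
        checks <- c(checks, file_checksum(meta$sample),
                    file_checksum(meta$blank))
        helicity_from_spectrum(mre_spectrum(sample, blank))
      }, error = function(e) { flags <<- c(flags, paste0("cd: ",
                                                         conditionMessage(e)))
        NULL })
      if (!is.null(res)) {
        mre222 <- res$MRE222; pct <- res$percent_helicity
        rounded <- res$rounded_percent
      }
    }
    rows[[length(rows) + 1L]] <- data.frame(
      name = entry$name, sequence = if (is.null(pep)) entry$sequence else
        as.character(pep),
      ic50_M = ic50, ic50_sd_M = ic50_sd, mre222 = mre222,
      percent_helicity = pct, rounded_percent = rounded,
      ddG_kJmol = NA_real_,
      flags = paste(flags, collapse = "; "),
      inputs = paste(checks, collapse = ";"),
      stringsAsFactors = FALSE)
  }
  report <- if (length(rows)) do.call(rbind, rows) else
    data.frame(name = character(0), sequence = character(0),
               ic50_M = numeric(0), ic50_sd_M = numeric(0),
               mre222 = numeric(0), percent_helicity = numeric(0),
               rounded_percent = integer(0), ddG_kJmol = numeric(0),
               flags = character(0), inputs = character(0))
  ref <- config$reference
  if (!is.null(ref) && ref %in% report$name &&
      is.finite(report$ic50_M[report$name == ref][1])) {
    ic_ref <- report$ic50_M[report$name == ref][1]
    report$ddG_kJmol <- ifelse(
      is.finite(report$ic50_M),
      delta_delta_g(ic_ref, report$ic50_M, temperature_K), NA_real_)
  }
  class(report) <- c("study_report", "data.frame")
  report
}

file_checksum <- function(path) {
  paste0(basename(path), ":", unname(tools::md5sum(path)))
}

#' Write a study report
#'
#' Emits the per-peptide record table as CSV (fixed column order; SD in its
#' own column, no +/- glyphs in machine-readable fields) and, optionally, as
#' JSON.
#'
#' @param report a `study_report`.
#' @param path CSV output path.
#' @param json_path optional JSON output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, json_path = NULL) {
  utils::write.csv(as.data.frame(report), path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(as.data.frame(report), json_path, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Read a study report written by [write_report()]
#'
#' @param path CSV path.
#' @return a `study_report`.
#' @export
read_report <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(rounded_percent = "integer"))
  class(d) <- c("study_report", "data.frame")
  d
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> %d peptide(s)\n", nrow(x)))
  if (nrow(x)) {
    show <- data.frame(name = x$name,
                       IC50_uM = signif(x$ic50_M * 1e6, 3),
                       helicity = round(x$percent_helicity, 1),
                       ddG_kJmol = round(x$ddG_kJmol, 2),
                       flags = x$flags)
    print(show, row.names = FALSE)
  }
  invisible(x)
}
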