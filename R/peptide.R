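AA1 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
         "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

RESIDUE_CODES <- c(AA1, "pS")

# average residue (monomer minus water) masses, g/mol
RESIDUE_MASS <- c(
  A = 71.0788, C = 103.1388, D = 115.0886, E = 129.1155, F = 147.1766,
  G = 57.0519, H = 137.1411, I = 113.1594, K = 128.1741, L = 113.1594,
  M = 131.1926, N = 114.1038, P = 97.1167, Q = 128.1307, R = 156.1875,
  S = 87.0782, T = 101.1051, V = 99.1326, W = 186.2132, Y = 163.1760,
  pS = 167.0581)

N_TERM_STATES <- c("acetyl", "FAM-Ahx", "free")
C_TERM_STATES <- c("amide", "free")
CONSTRAINT_STATES <- c("red", "ox", "mal")

#' Cysteine-constraint descriptor
#'
#' Describes an i,i+4 (by default) side-chain constraint between two cysteine
#' positions in parent-protein numbering. `state` distinguishes the free-thiol
#' (`"red"`), disulfide (`"ox"`) and dibromomaleimide-bridged (`"mal"`) forms
#' of the same sequence.
#'
#' @param position_i,position_j parent-numbering residue indices, `position_j`
#'   greater than `position_i`.
#' @param state one of `"red"`, `"ox"`, `"mal"`.
#' @param spacing declared spacing; must equal `position_j - position_i`.
#' @return an object of class `constraint_spec`.
#' @export
constraint_spec <- function(position_i, position_j, state = "red",
                            spacing = position_j - position_i) {
  stopifnot(is.numeric(position_i), is.numeric(position_j))
  state <- match.arg(state, CONSTRAINT_STATES)
  if (spacing <= 0 || position_j - position_i != spacing)
    stop("constraint positions must satisfy position_j - position_i == spacing > 0")
  structure(list(position_i = as.integer(position_i),
                 position_j = as.integer(position_j),
                 spacing = as.integer(spacing),
                 state = state),
            class = "constraint_spec")
}

#' Peptide definition
#'
#' The unit every pipeline stage annotates: an ordered residue list (one-letter
#' codes plus `"pS"` for phosphoserine), parent-protein numbering, terminal
#' chemistry and an optional cysteine constraint.
#'
#' @param name peptide name.
#' @param residues character vector of residue codes.
#' @param numbering_offset parent-protein index of the first residue (>= 1).
#' @param n_term `"acetyl"`, `"FAM-Ahx"` or `"free"`.
#' @param c_term `"amide"` or `"free"`.
#' @param constraint optional [constraint_spec()]; both positions must map to
#'   Cys residues of the sequence.
#' @return an object of class `peptide_spec`.
#' @export
peptide_spec <- function(name, residues, numbering_offset = 1L,
                         n_term = "acetyl", c_term = "amide",
                         constraint = NULL) {
  n_term <- match.arg(n_term, N_TERM_STATES)
  c_term <- match.arg(c_term, C_TERM_STATES)
  if (length(residues) == 0L) stop("peptide must contain at least one residue")
  bad <- setdiff(residues, RESIDUE_CODES)
  if (length(bad))
    stop("unknown residue code(s): ", paste(unique(bad), collapse = ", "))
  if (numbering_offset < 1L) stop("numbering_offset must be >= 1")
  p <- structure(list(name = name,
                      residues = as.character(residues),
                      numbering_offset = as.integer(numbering_offset),
                      n_term = n_term, c_term = c_term,
                      constraint = constraint),
                 class = "peptide_spec")
  if (!is.null(constraint)) {
    stopifnot(inherits(constraint, "constraint_spec"))
    for (pos in c(constraint$position_i, constraint$position_j)) {
      if (residue_at(p, pos) != "C")
        stop("constraint position ", pos, " is not a cysteine (found ",
             residue_at(p, pos), ")")
    }
  }
  p
}

parent_range <- function(p) {
  c(p$numbering_offset, p$numbering_offset + length(p$residues) - 1L)
}

local_index <- function(p, position) {
  rng <- parent_range(p)
  if (any(position < rng[1] | position > rng[2]))
    stop("position(s) ", paste(position[position < rng[1] | position > rng[2]],
                               collapse = ", "),
         " outside parent range ", rng[1], "-", rng[2])
  as.integer(position - p$numbering_offset + 1L)
}

residue_at <- function(p, position) p$residues[local_index(p, position)]

#' @export
format.peptide_spec <- function(x, ...) {
  pre <- switch(x$n_term, acetyl = "Ac-", `FAM-Ahx` = "FAM-Ahx-", free = "")
  suf <- if (x$c_term == "amide") "-NH2" else ""
  paste0(pre, paste(x$residues, collapse = ""), suf)
}

#' @export
print.peptide_spec <- function(x, ...) {
  rng <- parent_range(x)
  cat(sprintf("<peptide_spec> %s [%d-%d, %d residues]\n  %s\n",
              x$name, rng[1], rng[2], length(x$residues), format(x)))
  if (!is.null(x$constraint))
    cat(sprintf("  constraint: C%d/C%d (i,i+%d, %s)\n",
                x$constraint$position_i, x$constraint$position_j,
                x$constraint$spacing, x$constraint$state))
  invisible(x)
}

#' @export
as.character.peptide_spec <- function(x, ...) paste(x$residues, collapse = "")

#' Parse a peptide sequence string
#'
#' Accepts one-letter residue codes with the `"pS"` phosphoserine token and
#' optional `"Ac-"` / `"FAM-Ahx-"` prefix and `"-NH2"` suffix, e.g.
#' `"Ac-EPPSWVTEMLLENELWGSPAEE-NH2"`.
#'
#' @param text sequence string.
#' @param offset parent-protein index of the first residue.
#' @param name optional peptide name (defaults to the text).
#' @return a [peptide_spec()].
#' @export
parse_peptide <- function(text, offset = 1L, name = text) {
  s <- gsub("[[:space:]]", "", text)
  n_term <- "free"; c_term <- "free"
  if (startsWith(s, "FAM-Ahx-")) { n_term <- "FAM-Ahx"; s <- sub("^FAM-Ahx-", "", s) }
  else if (startsWith(s, "Ac-")) { n_term <- "acetyl"; s <- sub("^Ac-", "", s) }
  if (grepl("-NH2$", s)) { c_term <- "amide"; s <- sub("-NH2$", "", s) }
  if (nchar(s) == 0L) stop("empty peptide sequence")
  chars <- strsplit(s, "")[[1]]
  residues <- character(0)
  i <- 1L
  while (i <= length(chars)) {
    if (chars[i] == "p" && i < length(chars) && chars[i + 1L] == "S") {
      residues <- c(residues, "pS"); i <- i + 2L
    } else if (chars[i] %in% AA1) {
      residues <- c(residues, chars[i]); i <- i + 1L
    } else {
      stop("unknown residue token '", chars[i], "' at sequence position ", i)
    }
  }
  peptide_spec(name, residues, offset, n_term = n_term, c_term = c_term)
}

#' Truncate a peptide to a parent-numbering range
#'
#' Both ends are inclusive; the result's `numbering_offset` becomes `start`.
#'
#' @param p a [peptide_spec()].
#' @param start,end parent-numbering bounds within the peptide.
#' @return a [peptide_spec()] carrying the contiguous sub-sequence.
#' @export
pep_truncate <- function(p, start, end) {
  if (start > end) stop("start must be <= end")
  idx <- local_index(p, start):local_index(p, end)
  nm <- sprintf("%s_%d-%d", sub("_[0-9]+-[0-9]+$", "", p$name), start, end)
  peptide_spec(nm, p$residues[idx], start, n_term = p$n_term, c_term = p$c_term)
}

#' Substitute one residue (parent numbering)
#'
#' @param p a [peptide_spec()].
#' @param position parent-numbering index.
#' @param new_residue replacement residue code (e.g. `"C"`, `"pS"`).
#' @return the modified [peptide_spec()].
#' @export
pep_substitute <- function(p, position, new_residue) {
  if (!new_residue %in% RESIDUE_CODES)
    stop("invalid residue code: ", new_residue)
  res <- p$residues
  res[local_index(p, position)] <- new_residue
  peptide_spec(p$name, res, p$numbering_offset,
               n_term = p$n_term, c_term = p$c_term, constraint = p$constraint)
}

#' Enumerate i,i+spacing cysteine-pair variants
#'
#' Systematic constraint-position scan: every ordered pair (i, i+spacing)
#' with both positions inside `[region_start, region_end]`, neither position a
#' hot-spot and neither already cysteine, yields one double-Cys variant
#' carrying a `constraint_spec` in the `"red"` state. Hot-spots (interface
#' residues carrying disproportionate binding energy) are caller-supplied and
#' never inferred.
#'
#' @param p parent [peptide_spec()].
#' @param region_start,region_end parent-numbering bounds of the scanned
#'   (helical) region.
#' @param hotspots integer vector of excluded parent positions.
#' @param spacing pair spacing (default 4, one helical turn).
#' @return list of [peptide_spec()] variants ordered by i ascending.
#' @export
enumerate_cys_pair_variants <- function(p, region_start, region_end,
                                        hotspots = integer(0), spacing = 4L) {
  if (spacing <= 0) stop("spacing must be positive")
  rng <- parent_range(p)
  if (region_start < rng[1] || region_end > rng[2] || region_start > region_end)
    stop("region ", region_start, "-", region_end,
         " outside peptide range ", rng[1], "-", rng[2])
  out <- list()
  is <- seq.int(region_start, region_end)
  is <- is[is + spacing <= region_end]
  for (i in is) {
    j <- i + spacing
    if (i %in% hotspots || j %in% hotspots) next
    if (residue_at(p, i) == "C" || residue_at(p, j) == "C") next
    v <- pep_substitute(pep_substitute(p, i, "C"), j, "C")
    v$name <- sprintf("%s-%s%dC/%s%dC", p$name, residue_at(p, i), i,
                      residue_at(p, j), j)
    v$constraint <- constraint_spec(i, j, state = "red", spacing = spacing)
    out[[length(out) + 1L]] <- peptide_spec(v$name, v$residues,
                                            v$numbering_offset, v$n_term,
                                            v$c_term, v$constraint)
  }
  out
}

#' Number of backbone amide bonds
#'
#' Counts the (r-1) inter-residue bonds plus one amide per blocked terminus
#' (N-terminal acetyl or FAM-Ahx label; C-terminal primary amide). This is
#' the `n` entering the percent-helicity formula, distinct from the residue
#' count used for mean residue ellipticity.
#'
#' @param p a [peptide_spec()].
#' @return integer amide-bond count.
#' @export
count_backbone_amides <- function(p) {
  length(p$residues) - 1L +
    (p$n_term != "free") + (p$c_term != "free")
}

#' Chromophore extinction table
#'
#' Molar extinction coefficients (M^-1 cm^-1) used for concentration
#' determination by UV absorbance: tryptophan 5600 and the peptide-bound
#' maleimide 1700 by default; extensible via `...`.
#'
#' @param ... named numeric overrides/additions.
#' @return named numeric vector.
#' @export
chromophore_table <- function(...) {
  tab <- c(Trp = 5600, maleimide = 1700)
  extra <- c(...)
  if (length(extra)) tab[names(extra)] <- extra
  if (any(tab <= 0)) stop("extinction coefficients must be positive")
  tab
}

#' Molar extinction coefficient of a peptide
#'
#' Tryptophan count times the Trp coefficient, plus one maleimide term when
#' the constraint state is `"mal"`. Disulfide (`"ox"`) and free-thiol
#' (`"red"`) states contribute no extra chromophore.
#'
#' @param p a [peptide_spec()].
#' @param table a [chromophore_table()].
#' @return coefficient in M^-1 cm^-1.
#' @export
molar_extinction <- function(p, table = chromophore_table()) {
  n_trp <- sum(p$residues == "W")
  n_mal <- as.integer(!is.null(p$constraint) && p$constraint$state == "mal")
  unname(n_trp * table[["Trp"]] + n_mal * table[["maleimide"]])
}

#' Concentration from absorbance (Beer-Lambert)
#'
#' @param A absorbance (dimensionless).
#' @param epsilon molar extinction coefficient, M^-1 cm^-1.
#' @param pathlength cuvette pathlength, cm.
#' @return molar concentration.
#' @export
concentration_from_absorbance <- function(A, epsilon, pathlength = 1) {
  if (epsilon <= 0) stop("undefined concentration: epsilon must be positive")
  if (pathlength <= 0) stop("pathlength must be positive")
  A / (epsilon * pathlength)
}

#' Average molecular weight of a peptide
#'
#' Sum of average residue masses plus water, adjusted for terminal chemistry
#' (acetyl +42.0367; C-terminal amide -0.9847). The FAM-Ahx label mass is not
#' built in and must be supplied via `label_mass` when present.
#'
#' @param p a [peptide_spec()].
#' @param label_mass added mass (g/mol) of an N-terminal label, required when
#'   `n_term == "FAM-Ahx"`.
#' @return average molecular weight, g/mol.
#' @export
peptide_mw <- function(p, label_mass = NULL) {
  m <- sum(RESIDUE_MASS[p$residues]) + 18.0153
  if (p$n_term == "acetyl") m <- m + 42.0367
  if (p$n_term == "FAM-Ahx") {
    if (is.null(label_mass))
      stop("supply label_mass for FAM-Ahx-labelled peptides")
    m <- m + label_mass
  }
  if (p$c_term == "amide") m <- m - 0.9847
  unname(m)
}
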