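test_that("sequence parsing handles modifier notation, pS and errors", {
  p <- parse_peptide("Ac-EPPSWVTEMLLENELWGSPAEE-NH2", 73)
  expect_length(p$residues, 22)
  expect_equal(p$n_term, "acetyl")
  expect_equal(p$c_term, "amide")
  expect_equal(p$numbering_offset, 73L)

  q <- parse_peptide("Ac-pSPPSWVTEMLLENELWG-NH2", 73)
  expect_length(q$residues, 17)
  expect_equal(q$residues[1], "pS")

  fam <- parse_peptide("FAM-Ahx-LSPSRGFAEHSSEPPSWVTEMLLENELWG-NH2", 61)
  expect_equal(fam$n_term, "FAM-Ahx")

  expect_error(parse_peptide("", 73), "empty")
  expect_error(parse_peptide("Ac-EPZQ-NH2", 1), "Z")
})

test_that("truncation extracts parent-numbered subsequences and composes", {
  full <- parse_peptide("Ac-LSPSRGFAEHSSEPPSWVTEMLLENELWG-NH2", 61,
                        "N-Myc_61-89")
  t1 <- pep_truncate(full, 73, 89)
  expect_equal(as.character(t1), "EPPSWVTEMLLENELWG")
  expect_equal(t1$numbering_offset, 73L)
  expect_equal(as.character(pep_truncate(full, 76, 89)), "SWVTEMLLENELWG")
  expect_length(pep_truncate(full, 76, 89)$residues, 14)
  # identity
  expect_equal(as.character(pep_truncate(full, 61, 89)), as.character(full))
  # composition equals single truncate to the intersection
  expect_equal(as.character(pep_truncate(pep_truncate(full, 70, 89), 73, 85)),
               as.character(pep_truncate(full, 73, 85)))
  expect_error(pep_truncate(full, 50, 89), "outside")
})

test_that("substitution replaces a single parent-numbered residue", {
  p <- pep_truncate(parse_peptide("Ac-LSPSRGFAEHSSEPPSWVTEMLLENELWG-NH2", 61),
                    73, 89)
  ps <- pep_substitute(p, 73, "pS")
  expect_equal(ps$residues[1], "pS")
  expect_equal(ps$residues[-1], p$residues[-1])
  expect_equal(pep_substitute(p, 77, "W")$residues, p$residues)
  p94 <- parse_peptide("Ac-EPPSWVTEMLLENELWGSPAEE-NH2", 73)
  dc <- pep_substitute(pep_substitute(p94, 85, "C"), 89, "C")
  expect_equal(as.character(dc), "EPPSWVTEMLLECELWCSPAEE")
  expect_error(pep_substitute(p, 73, "Z"), "invalid residue")
  expect_error(pep_substitute(p, 60, "A"), "outside")
})

test_that("cysteine-pair scan matches the named pairs and the oracle", {
  p94 <- parse_peptide("Ac-EPPSWVTEMLLENELWGSPAEE-NH2", 73, "N-Myc_73-94")
  v <- enumerate_cys_pair_variants(p94, 85, 90, hotspots = c(77, 88))
  expect_length(v, 2)
  expect_equal(vapply(v, function(x) x$constraint$position_i, 1L), c(85L, 86L))
  expect_equal(vapply(v, function(x) x$constraint$position_j, 1L), c(89L, 90L))
  expect_equal(as.character(v[[1]]), "EPPSWVTEMLLECELWCSPAEE")
  # region narrower than the spacing
  expect_length(enumerate_cys_pair_variants(p94, 85, 87), 0)
  # the 29-mer scan over the helical region yields 8 candidate pairs
  p29 <- parse_peptide("Ac-LSPSRGFAEHSSEPPSWVTEMLLENELWG-NH2", 61,
                       "N-Myc_61-89")
  v8 <- enumerate_cys_pair_variants(p29, 76, 89, hotspots = c(77, 88))
  expect_length(v8, 8)
  expect_error(enumerate_cys_pair_variants(p29, 50, 89), "outside")
})

test_that("cysteine-pair scan equals exhaustive enumeration on random inputs", {
  set.seed(42)
  p29 <- parse_peptide("Ac-LSPSRGFAEHSSEPPSWVTEMLLENELWG-NH2", 61)
  for (rep in 1:40) {
    rs <- sample(61:85, 1)
    re <- sample(rs:89, 1)
    hot <- sample(61:89, sample(0:6, 1))
    spacing <- sample(2:5, 1)
    v <- enumerate_cys_pair_variants(p29, rs, re, hot, spacing)
    oracle <- brute_force_cys_pairs(p29, rs, re, hot, spacing)
    expect_length(v, length(oracle))
    if (length(v)) {
      got <- lapply(v, function(x) c(x$constraint$position_i,
                                     x$constraint$position_j))
      expect_equal(got, oracle)
      for (x in v) {
        # every variant satisfies the container invariants
        expect_s3_class(x, "peptide_spec")
        expect_equal(x$residues[x$constraint$position_i - x$numbering_offset + 1], "C")
        expect_equal(x$residues[x$constraint$position_j - x$numbering_offset + 1], "C")
        expect_equal(x$constraint$spacing, spacing)
      }
    }
  }
})

test_that("backbone amide-bond count follows the terminal chemistry", {
  mk <- function(r, nt = "acetyl", ct = "amide")
    peptide_spec("x", rep("A", r), 1, n_term = nt, c_term = ct)
  for (r in 1:30) expect_equal(count_backbone_amides(mk(r)), r + 1L)
  expect_equal(count_backbone_amides(mk(1)), 2L)
  expect_equal(count_backbone_amides(mk(10, nt = "free")), 10L)
  expect_equal(count_backbone_amides(mk(10, ct = "free")), 10L)
  expect_equal(count_backbone_amides(mk(10, "free", "free")), 9L)
  # the 22-mer and the 17-mer pS variant used throughout
  expect_equal(count_backbone_amides(
    parse_peptide("Ac-EPPSWVTEMLLENELWGSPAEE-NH2", 73)), 23L)
  expect_equal(count_backbone_amides(
    parse_peptide("Ac-pSPPSWVTEMLLENELWG-NH2", 73)), 18L)
})

test_that("extinction coefficients count Trp and the maleimide chromophore", {
  p94 <- parse_peptide("Ac-EPPSWVTEMLLENELWGSPAEE-NH2", 73)
  expect_equal(molar_extinction(p94), 11200)
  mal <- enumerate_cys_pair_variants(p94, 85, 90, c(77, 88))[[1]]
  mal$constraint$state <- "mal"
  expect_equal(molar_extinction(mal), 12900)
  # red / ox states add no chromophore
  expect_equal(molar_extinction(enumerate_cys_pair_variants(
    p94, 85, 90, c(77, 88))[[1]]), 11200)
  no_trp <- peptide_spec("x", c("A", "E", "K"), 1)
  expect_equal(molar_extinction(no_trp), 0)
})

test_that("Beer-Lambert concentration and molecular weight behave", {
  expect_equal(concentration_from_absorbance(0, 5600), 0)
  expect_equal(concentration_from_absorbance(0.56, 5600, 1), 100e-6)
  expect_equal(concentration_from_absorbance(1.29, 12900, 1), 100e-6)
  expect_error(concentration_from_absorbance(1, 0), "epsilon")
  p <- parse_peptide("Ac-ASA-NH2", 1)
  ps <- pep_substitute(p, 2, "pS")
  expect_equal(peptide_mw(ps) - peptide_mw(p), 79.9799, tolerance = 1e-6)
  expect_error(peptide_mw(parse_peptide("FAM-Ahx-AAA-NH2", 1)), "label_mass")
})
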