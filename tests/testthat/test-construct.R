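test_that("intact masses reproduce hand-computed values and additivity", {
  # free glycine: residue 57.05 + water 18.02
  expect_equal(intact_mass("G"), 75.07, tolerance = 0.005)
  # serine/alanine residue difference is one oxygen (average scale)
  expect_equal(intact_mass("SA") - intact_mass("AA"), 15.9994,
               tolerance = 1e-4)
  # mass additivity: concatenation loses one water
  s1 <- random_sequence(25, seed = 11, with_proline = TRUE)
  s2 <- random_sequence(40, seed = 12, with_proline = TRUE)
  expect_equal(intact_mass(paste0(s1, s2)),
               intact_mass(s1) + intact_mass(s2) - water_mass(),
               tolerance = 1e-6)
  # monoisotopic scale is consistently lighter for typical peptides
  expect_lt(intact_mass(s1, mass_options("monoisotopic")), intact_mass(s1))
  # residue-sum mode drops the water
  expect_equal(intact_mass(s1, mass_options(include_water = FALSE)),
               intact_mass(s1) - water_mass(), tolerance = 1e-9)
})

test_that("unknown residues are rejected with their position", {
  expect_error(construct("ACDX"), "position 4")
  expect_error(intact_mass(construct("ACD")), NA)
})

test_that("modifications shift mass by standard values and are validated", {
  cs <- construct("ASTYK", modifications = data.frame(
    kind = c("phospho", "acetyl"), position = c(2, 5)))
  base <- intact_mass(construct("ASTYK"))
  expect_equal(intact_mass(cs), base + 79.98 + 42.04, tolerance = 0.01)
  expect_error(construct("AAAAA", modifications = data.frame(
    kind = "phospho", position = 3)), "non-S/T/Y")
  expect_error(construct("ASA", modifications = data.frame(
    kind = "acetyl", position = 2)), "acetyl")
})

test_that("CK2 consensus scan matches a brute-force oracle", {
  expect_equal(find_ck2_consensus("ASDDE"),
               data.frame(position = 2L, residue = "S"))
  expect_equal(nrow(find_ck2_consensus("SPPA")), 0L)
  # short input yields an empty frame, not an error
  expect_equal(nrow(find_ck2_consensus("STD")), 0L)
  for (seed in 1:50) {
    s <- random_sequence(200, seed = seed, with_proline = TRUE)
    got <- find_ck2_consensus(s)
    want <- ck2_oracle(s)
    expect_equal(got$position, want$position)
    expect_equal(got$residue, want$residue)
  }
  # numbering offset is honoured
  s <- "ASDDE"
  expect_equal(find_ck2_consensus(s, offset = 100L)$position, 101L)
})

test_that("substitutions preserve numbering and are reversible", {
  cs <- construct("ASDDE", offset = 10L)
  sub <- apply_substitutions(cs, 11, "A", expected = "S")
  expect_equal(sub$sequence, "AADDE")
  expect_equal(intact_mass(cs) - intact_mass(sub), 15.9994,
               tolerance = 1e-4)
  # empty substitution list is the identity
  expect_identical(apply_substitutions(cs, integer(0), character(0)), cs)
  # reverse substitution restores the original mass exactly
  back <- apply_substitutions(sub, 11, "S", expected = "A")
  expect_identical(back$sequence, cs$sequence)
  expect_equal(intact_mass(back), intact_mass(cs), tolerance = 1e-12)
  # errors: out of range and original-residue mismatch
  expect_error(apply_substitutions(cs, 30, "A"), "outside")
  expect_error(apply_substitutions(cs, 11, "A", expected = "T"),
               "expected residue")
})

test_that("region replacement splices a linker", {
  cs <- construct("AAAAACCCCCDDDDD")
  out <- replace_region(cs, 6, 10, "GS")
  expect_equal(out$sequence, "AAAAAGSDDDDD")
  expect_equal(intact_mass(out),
               intact_mass(cs) - 5 * aa_residue_masses()[["C"]] +
                 aa_residue_masses()[["G"]] + aa_residue_masses()[["S"]],
               tolerance = 1e-9)
})

test_that("heptad counting and register scoring behave", {
  # count is floor(length/7) and translation-invariant
  expect_equal(count_complete_heptads(506, 527), 3L)
  expect_equal(count_complete_heptads(1, 6), 0L)
  for (seed in 1:20) {
    set.seed(seed)
    a <- sample(1000, 1); len <- sample(0:40, 1)
    expect_equal(count_complete_heptads(a, a + len),
                 count_complete_heptads(a + 57, a + 57 + len))
    expect_equal(count_complete_heptads(a, a + len), (len + 1L) %/% 7L)
  }
  # poly-L scores 1 in every register
  hs <- heptad_register_score(strrep("L", 21), 1, 21)
  expect_equal(hs$score, 1)
  # polar sequence scores 0
  expect_equal(heptad_register_score(strrep("S", 21), 1, 21)$score, 0)
  # ties broken by the smallest phase
  expect_equal(hs$register, 0L)
  expect_error(heptad_register_score("LLL", 1, 10), "outside")
})

test_that("construct windows keep numbering and FASTA round-trips", {
  cs <- construct(random_sequence(60, seed = 5), name = "rt",
                  regions = data.frame(label = "x", start = 10, end = 20))
  w <- construct_window(cs, 10, 30)
  expect_equal(w$offset, 10L)
  expect_equal(length(w), 21L)
  expect_equal(w$regions$label, "x")
  path <- withr::local_tempfile(fileext = ".fasta")
  write_construct_fasta(cs, path)
  back <- read_construct_fasta(path)
  expect_equal(back$sequence, cs$sequence)
  expect_equal(back$name, "rt")
})

test_that("packaged BRD4 fixture carries the expected landmarks", {
  cs <- brd4_construct()
  expect_equal(length(cs), 722L)
  # lysine 519 sits inside the predicted coiled coil
  expect_equal(hdxdimer:::construct_residue(cs, 519), "K")
  # the WPF shelf of the second bromodomain
  expect_equal(paste(hdxdimer:::construct_residue(cs, 374:376),
                     collapse = ""), "WPF")
  # 7 consensus serines in NPS, 6 in CPS (the 7A/6A mutant sites)
  sites <- find_ck2_consensus(cs)
  ser <- sites[sites$residue == "S", ]
  expect_equal(sum(ser$position >= 484 & ser$position <= 504), 7L)
  expect_equal(sum(ser$position >= 690 & ser$position <= 720), 6L)
})

test_that("BRD4 construct masses are internally consistent across variants", {
  cs722 <- brd4_construct()
  m530 <- intact_mass(brd4_construct(c(1, 530)))
  m579 <- intact_mass(brd4_construct(c(1, 579)))
  m722 <- intact_mass(cs722)
  # segment masses between the three construct boundaries
  expect_equal(m579 - m530, 5863.8, tolerance = 0.1)
  expect_equal(m722 - m579, 16038.8, tolerance = 0.1)
  # phospho-deficient mutants: every consensus serine of one cluster to Ala
  ser <- find_ck2_consensus(cs722)
  nps <- ser$position[ser$residue == "S" & ser$position >= 484 &
                        ser$position <= 504]
  cps <- ser$position[ser$residue == "S" & ser$position >= 690 &
                        ser$position <= 720]
  m7a <- intact_mass(apply_substitutions(cs722, nps, "A", expected = "S"))
  m6a <- intact_mass(apply_substitutions(cs722, cps, "A", expected = "S"))
  expect_equal(m722 - m7a, 7 * 15.9994, tolerance = 1e-3)
  expect_equal(m722 - m6a, 6 * 15.9994, tolerance = 1e-3)
  # replacing the coiled coil by a 12-mer GS linker (9 Gly + 3 Ser);
  # construct-mass differences cancel any shared N-terminal adduct
  d506 <- replace_region(cs722, 506, 530, "GGSGGGSGGSGG")
  expect_equal(m722 - intact_mass(d506), 82472.3 - 80404.9, tolerance = 0.35)
})
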