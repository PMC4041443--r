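# Screening, pi-pi validation, tilt/edge classification, and the sugar-edge
# taxonomy.

test_that("tilt bins are half-open with errors outside [0, 90]", {
  expect_equal(classify_tilt(7), "stacked")
  expect_equal(classify_tilt(45), "inclined")
  expect_equal(classify_tilt(20), "inclined")
  expect_equal(classify_tilt(70), "t_shaped")
  expect_equal(classify_tilt(90), "t_shaped")
  expect_error(classify_tilt(-1), "outside")
  expect_error(classify_tilt(91), "outside")
})

test_that("screening is strict at the cutoff and monotone in it", {
  at_cut <- build_pi_dimer("DT", "PHE", omega = 0, rise = 5.0)
  mo <- extract_moieties(at_cut$atoms)$moieties
  # cutoff exactly equal to the realized separation: strictly excluded
  d0 <- min_heavy_distance(pisurvey:::moiety_screen_xyz(mo[[1]]),
                           pisurvey:::moiety_screen_xyz(mo[[2]]))
  expect_length(screen_candidates(mo, d0), 0L)
  expect_length(screen_candidates(mo, d0 + 1e-9), 1L)
  inside <- build_pi_dimer("DT", "PHE", omega = 0, rise = 4.999)
  expect_length(screen_candidates(extract_moieties(inside$atoms)$moieties, 5.0), 1L)
  # candidate set at a smaller cutoff is a subset of that at a larger one
  d <- build_pi_dimer("DA", "TYR", omega = 30, rise = 3.3)
  mo2 <- extract_moieties(d$atoms)$moieties
  keys <- function(cands) vapply(cands, function(cc)
    paste(cc$aa$id, cc$partner$id), character(1))
  for (cuts in list(c(3.0, 4.0), c(3.4, 5.0), c(4.0, 8.0)))
    expect_true(all(keys(screen_candidates(mo2, cuts[1])) %in%
                    keys(screen_candidates(mo2, cuts[2]))))
})

test_that("DNA-only and protein-only structures yield no candidates", {
  d <- build_pi_dimer("DT", "PHE", omega = 0, rise = 3.4)
  dna <- d$atoms[d$atoms$resid == "DT", ]
  protein <- d$atoms[d$atoms$resid == "PHE", ]
  expect_length(screen_candidates(extract_moieties(dna)$moieties), 0L)
  expect_equal(nrow(survey_structure(protein)$pi_pi), 0L)
  expect_equal(nrow(survey_structure(protein)$sugar_pi), 0L)
})

test_that("face-to-face dimers validate; coplanar side-by-side pairs are rejected", {
  ok <- build_pi_dimer("DT", "PHE", omega = 0, rise = 3.4, slide = 1.0)
  mo <- extract_moieties(ok$atoms)$moieties
  aa <- mo[[which(vapply(mo, `[[`, "", "kind") == "aromatic_aa_ring")]]
  base <- mo[[which(vapply(mo, `[[`, "", "kind") == "nucleobase_ring")]]
  expect_true(validate_pi_pi(aa, base)$valid)
  cop <- pisurvey:::build_decoy("coplanar")
  mo2 <- extract_moieties(cop$atoms)$moieties
  aa2 <- mo2[[which(vapply(mo2, `[[`, "", "kind") == "aromatic_aa_ring")]]
  b2 <- mo2[[which(vapply(mo2, `[[`, "", "kind") == "nucleobase_ring")]]
  v <- validate_pi_pi(aa2, b2)
  expect_false(v$valid)
  expect_match(v$reason, "participation")
  # the coplanar pair is inside the screening cutoff, so rejection is the
  # validator's doing, not the screen's
  expect_length(screen_candidates(mo2, 5.0), 1L)
})

test_that("edge roles follow the participating monomer", {
  tb <- build_pi_dimer("DT", "PHE", omega = 88, rise = 3.4)
  r <- survey_structure(tb$atoms)$pi_pi
  expect_true(r$valid)
  expect_equal(r$category, "t_shaped")
  expect_equal(r$edge_role, "nucleobase_edge")
  # mirror construction: Phe CE1-CZ edge over an adenine face
  ta <- build_pi_dimer("DA", "PHE", omega = 85, rise = 3.4,
                       edge_monomer = "amino_acid",
                       edge_atoms = c("CE1", "CZ"))
  r2 <- survey_structure(ta$atoms)$pi_pi
  expect_equal(r2$edge_role, "amino_acid_edge")
  # thymine C5-C6 edge (methyl-bearing edge) over a benzene face
  tc <- build_pi_dimer("DT", "PHE", omega = 85, rise = 3.15,
                       edge_atoms = c("C5", "C6"))
  r3 <- survey_structure(tc$atoms)$pi_pi
  expect_equal(r3$edge_role, "nucleobase_edge")
  # stacked contacts are face-to-face by definition
  st <- build_pi_dimer("DT", "PHE", omega = 5, rise = 3.4)
  expect_equal(survey_structure(st$atoms)$pi_pi$edge_role, "face_face")
})

test_that("sugar atoms get seven hydrogen labels plus O4', stable under rigid motion", {
  sug <- pisurvey:::sugar_fixture_residue()
  m <- extract_moieties(sug)$moieties[[1]]
  lab <- label_sugar_atoms(m)
  expect_equal(lab$label, c("H1a", "H2a", "H2b", "H3", "H4", "H5a", "H5b", "O4'"))
  expect_equal(sum(lab$element == "H"), 7L)
  set.seed(71)
  for (k in 1:5) {
    moved <- rigid_move_atoms(sug)
    m2 <- extract_moieties(moved)$moieties[[1]]
    lab2 <- label_sugar_atoms(m2)
    expect_equal(lab2$label, lab$label)
    expect_equal(lab2$parent, lab$parent)
  }
  # broken sugar errors
  broken <- sug[sug$elety != "O5'", ]
  mb <- extract_moieties(broken)$moieties[[1]]
  expect_error(label_sugar_atoms(mb), "missing heavy atoms")
})

test_that("mirror inversion swaps the a/b labels at C2' and C5'", {
  sug <- pisurvey:::sugar_fixture_residue()
  m <- extract_moieties(sug)$moieties[[1]]
  lab <- label_sugar_atoms(m)
  mir <- sug; mir$z <- -mir$z
  mm <- extract_moieties(mir)$moieties[[1]]
  lab_m <- label_sugar_atoms(mm)
  h <- function(l, name) unlist(l[l$label == name, c("x", "y", "z")])
  flip <- function(v) c(v[1], v[2], -v[3])
  # the mirrored H2a sits where H2b's mirror image is, and vice versa
  expect_equal(unname(h(lab_m, "H2a")), unname(flip(h(lab, "H2b"))),
               tolerance = 1e-9)
  expect_equal(unname(h(lab_m, "H5a")), unname(flip(h(lab, "H5b"))),
               tolerance = 1e-9)
  # the achiral labels mirror in place
  expect_equal(unname(h(lab_m, "H3")), unname(flip(h(lab, "H3"))),
               tolerance = 1e-9)
})

test_that("the five sugar edge classes classify with their requested labels", {
  cases <- list(
    list("face", "H4-H5a-H5b", "TRP"),
    list("lone_pair", "O4'", "HIS"),
    list("single_proton", "H3", "TYR"),
    list("bridged", "H1a-H2a", "PHE"),
    list("lone_pair_proton", "H1a-O4'", "PHE"))
  for (cs in cases) {
    fx <- build_sugar_fixture(cs[[1]], cs[[2]], cs[[3]], 2.8)
    s <- survey_structure(fx$atoms)$sugar_pi
    expect_equal(nrow(s), 1L)
    expect_true(s$valid)
    expect_equal(s$edge_class, cs[[1]])
    expect_equal(s$atom_labels, cs[[2]])
  }
  expect_error(build_sugar_fixture("bridged", "H1a"), "inconsistent")
})

test_that("sugar participation geometry is reported per atom", {
  fx <- build_sugar_fixture("face", "H4-H5a-H5b", "TRP", 2.8)
  mo <- extract_moieties(fx$atoms)$moieties
  aa <- mo[[which(vapply(mo, `[[`, "", "kind") == "aromatic_aa_ring")]]
  sug <- mo[[which(vapply(mo, `[[`, "", "kind") == "deoxyribose")]]
  sc <- classify_sugar_contact(aa, sug)
  expect_s3_class(sc, "sugar_pi_contact")
  g <- sc$geometry
  expect_equal(nrow(g), 8L)
  part <- g$label[g$participates]
  expect_setequal(part, c("H4", "H5a", "H5b"))
  crit <- validity_criteria()
  expect_true(all(abs(g$height[g$participates]) <= crit$sugar_max_height))
  expect_true(all(g$offset[g$participates] <= crit$sugar_max_lateral_offset))
  expect_true(all(g$ch_angle[g$participates & g$label != "O4'"] <=
                  crit$sugar_ch_max_angle))
})

test_that("classifications are invariant under rigid motion and chain relabeling", {
  set.seed(81)
  fixtures <- list(
    build_pi_dimer("DC", "HIS", omega = 12, rise = 3.3)$atoms,
    build_pi_dimer("DG", "TYR", omega = 47, rise = 3.4)$atoms,
    build_sugar_fixture("bridged", "H1a-H2a", "TYR", 2.8)$atoms)
  for (atoms in fixtures) {
    ref <- survey_structure(atoms)
    for (k in 1:5) {
      moved <- rigid_move_atoms(atoms)
      moved$chain <- chartr("AB", "XY", moved$chain)
      got <- survey_structure(moved)
      if (nrow(ref$pi_pi)) {
        expect_equal(got$pi_pi$omega_deg, ref$pi_pi$omega_deg, tolerance = 1e-6)
        expect_equal(got$pi_pi$d_min_angstrom, ref$pi_pi$d_min_angstrom,
                     tolerance = 1e-6)
        expect_equal(got$pi_pi$category, ref$pi_pi$category)
        expect_equal(got$pi_pi$edge_role, ref$pi_pi$edge_role)
      }
      if (nrow(ref$sugar_pi)) {
        expect_equal(got$sugar_pi$edge_class, ref$sugar_pi$edge_class)
        expect_equal(got$sugar_pi$atom_labels, ref$sugar_pi$atom_labels)
      }
    }
  }
})

test_that("survey criteria round-trip through YAML", {
  crit <- validity_criteria(cutoff = 4.2, min_participating_atoms = 3)
  p <- tempfile(fileext = ".yaml")
  write_survey_config(crit, p)
  back <- read_survey_config(p)
  expect_equal(unclass(back), unclass(crit))
})
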