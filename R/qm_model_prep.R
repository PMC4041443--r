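# Truncated (hydrogen-capped) dimer models for external quantum-chemistry
# engines, and the interaction-energy arithmetic: Delta-E bookkeeping,
# two-point correlation-energy CBS extrapolation, and the CCSD(T) correction
# composite. No electronic-structure code is run here; geometries go out as
# XYZ + a JSON sidecar, energies come back as CSV.

HARTREE_KJMOL <- 2625.4996

CAP_NH <- 1.01
CAP_OH <- 0.96
CAP_CH <- 1.09

new_capped_monomer <- function(kind, resid, names, elements, xyz, cap_idx,
                               variant = "none", charge = 0,
                               frozen_dihedrals = list(), flags = character(0L)) {
  atoms <- data.frame(elety = names, elesy = elements,
                      x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
                      stringsAsFactors = FALSE)
  structure(list(kind = kind, resid = resid, atoms = atoms,
                 cap_atoms = cap_idx, variant_tag = variant, charge = charge,
                 frozen_dihedrals = frozen_dihedrals, flags = flags),
            class = "capped_monomer")
}

#' @export
print.capped_monomer <- function(x, ...) {
  f <- table(x$atoms$elesy)
  cat(sprintf("capped %s model of %s (%s): %d atoms (%s), charge %+d\n",
              x$kind, x$resid, x$variant_tag, nrow(x$atoms),
              paste0(names(f), f, collapse = ""), x$charge))
  invisible(x)
}

ring_neighbors <- function(ring, atom) {
  i <- match(atom, ring); n <- length(ring)
  ring[c(if (i == 1L) n else i - 1L, if (i == n) 1L else i + 1L)]
}

# hydrogens carried by each free base (beyond the glycosidic cap)
BASE_HYDROGENS <- list(
  DA = list(sp2C = c("C8", "C2"), ringNH = character(0L), amino = "N6",
            methyl = character(0L)),
  DG = list(sp2C = "C8", ringNH = "N1", amino = "N2", methyl = character(0L)),
  DC = list(sp2C = c("C5", "C6"), ringNH = character(0L), amino = "N4",
            methyl = character(0L)),
  DT = list(sp2C = "C6", ringNH = "N3", amino = character(0L), methyl = "C7"))

AMINO_PARENT <- c(N6 = "C6", N4 = "C4", N2 = "C2")

hnum <- function(atom) gsub("[^0-9']", "", atom)

#' Cap a nucleotide to the free nucleobase
#'
#' Truncates a nucleotide at the glycosidic bond: a hydrogen replaces the
#' sugar, placed along the former N-C1' direction at 1.01 A, and the
#' remaining base hydrogens are built at idealized in-plane (sp2) or
#' staggered methyl positions. Yields adenine (15 atoms), cytosine (13),
#' guanine (16) or thymine (15).
#'
#' @param residue_atoms atom table rows of one nucleotide (base heavy atoms
#'   complete; C1' used for the cap direction when present).
#' @return a `capped_monomer` (kind `"nucleobase"`).
#' @export
cap_nucleobase <- function(residue_atoms) {
  resid <- normalize_resid(residue_atoms$resid[1L])
  if (!resid %in% NUCLEOTIDES) stop("not a standard nucleotide: ", resid)
  ring <- BASE_RING[[resid]]
  heavies <- c(ring, BASE_EXOCYCLIC[[resid]])
  miss <- setdiff(heavies, residue_atoms$elety)
  if (length(miss)) stop("missing base atoms: ", paste(miss, collapse = ","))
  xyz <- as.matrix(residue_atoms[, c("x", "y", "z")])
  rownames(xyz) <- residue_atoms$elety
  plane <- fit_ring_plane(xyz[ring, ])
  glyc <- if (is_purine(resid)) "N9" else "N1"
  flags <- character(0L)
  if ("C1'" %in% rownames(xyz)) {
    cap <- xyz[glyc, ] + CAP_NH * vunit(xyz["C1'", ] - xyz[glyc, ])
  } else {
    nb <- ring_neighbors(ring, glyc)
    cap <- build_sp2_hydrogen(xyz[glyc, ], xyz[nb[1L], ], xyz[nb[2L], ], "N")
    flags <- "glycosidic cap placed on the ring bisector (no C1' present)"
  }
  hd <- BASE_HYDROGENS[[resid]]
  hn <- paste0("H", hnum(glyc)); hx <- rbind(cap)
  for (a in c(hd$sp2C, hd$ringNH)) {
    nb <- ring_neighbors(ring, a)
    hx <- rbind(hx, build_sp2_hydrogen(xyz[a, ], xyz[nb[1L], ], xyz[nb[2L], ],
                                       element_of(a)))
    hn <- c(hn, paste0("H", hnum(a)))
  }
  for (a in hd$amino) {
    parent <- AMINO_PARENT[[a]]
    dir0 <- vunit(xyz[a, ] - xyz[parent, ])
    for (k in 1:2) {
      rot <- rotation_about_axis(plane$normal, c(60, -60)[k])
      hx <- rbind(hx, xyz[a, ] + CAP_NH * as.numeric(rot %*% dir0))
      hn <- c(hn, paste0("H", hnum(a), k))
    }
  }
  for (a in hd$methyl) {  # thymine C7: staggered about the C5-C7 bond
    hs <- build_hydrogens(xyz[a, ], xyz["C5", , drop = FALSE], 3L,
                          dihedral_ref = xyz["C4", ], reference_dihedral = 60)
    hx <- rbind(hx, hs)
    hn <- c(hn, paste0("H", hnum(a), 1:3))
  }
  new_capped_monomer("nucleobase", resid,
                     c(heavies, hn),
                     c(element_of(heavies), rep("H", length(hn))),
                     rbind(xyz[heavies, ], hx),
                     cap_idx = length(heavies) + 1L, flags = flags)
}

#' Applicable capped-model variants for a residue
#'
#' His is modelled as two neutral tautomers plus the cation; the Tyr
#' hydroxyl is oriented clockwise or counter-clockwise. Everything else has
#' a single model.
#'
#' @param resid residue name.
#' @return character vector of variant tags.
#' @export
cap_variants <- function(resid) {
  switch(toupper(resid),
         HIS = c("His_delta", "His_epsilon", "His_plus"),
         TYR = c("Tyr_CW", "Tyr_CCW"),
         "none")
}

#' Cap an aromatic amino acid to its ring model
#'
#' Truncates the side chain at the ring: a hydrogen replaces the C-beta link
#' and the remaining ring hydrogens are built in plane, giving benzene
#' (Phe, 12 atoms), phenol (Tyr, 13), imidazole/imidazolium (His) or indole
#' (Trp, 16).
#'
#' @param residue_atoms atom table rows of one residue (ring atoms complete;
#'   CB used for the cap direction when present, OH required for Tyr).
#' @param variant variant tag; defaults to the first of [cap_variants()].
#' @return a `capped_monomer` (kind `"aromatic_aa"`).
#' @export
cap_amino_acid <- function(residue_atoms, variant = NULL) {
  resid <- toupper(residue_atoms$resid[1L])
  if (!resid %in% AROMATIC_AA) stop("not an aromatic residue: ", resid)
  if (is.null(variant)) variant <- cap_variants(resid)[1L]
  if (!variant %in% cap_variants(resid))
    stop("variant ", variant, " not applicable to ", resid)
  ring <- AA_RING[[resid]]
  miss <- setdiff(ring, residue_atoms$elety)
  if (length(miss)) stop("missing ring atoms: ", paste(miss, collapse = ","))
  xyz <- as.matrix(residue_atoms[, c("x", "y", "z")])
  rownames(xyz) <- residue_atoms$elety
  flags <- character(0L)
  if ("CB" %in% rownames(xyz)) {
    cap <- xyz["CG", ] + CAP_CH * vunit(xyz["CB", ] - xyz["CG", ])
  } else {
    nb <- ring_neighbors(ring, "CG")
    cap <- build_sp2_hydrogen(xyz["CG", ], xyz[nb[1L], ], xyz[nb[2L], ])
    flags <- "CB cap placed on the ring bisector (no CB present)"
  }
  h_on <- switch(resid,
    PHE = c("CD1", "CE1", "CZ", "CE2", "CD2"),
    TYR = c("CD1", "CE1", "CE2", "CD2"),
    TRP = c("CD1", "NE1", "CE3", "CZ2", "CZ3", "CH2"),
    HIS = c("CE1", "CD2",
            switch(variant, His_delta = "ND1", His_epsilon = "NE2",
                   His_plus = c("ND1", "NE2"))))
  hx <- rbind(cap); hn <- "HB"
  for (a in h_on) {
    nb <- ring_neighbors(ring, a)
    hx <- rbind(hx, build_sp2_hydrogen(xyz[a, ], xyz[nb[1L], ], xyz[nb[2L], ],
                                       element_of(a)))
    hn <- c(hn, paste0("H", substring(a, 2L)))
  }
  heavies <- ring
  if (resid == "TYR") {
    if (!"OH" %in% rownames(xyz)) stop("Tyr missing OH")
    heavies <- c(ring, "OH")
    # in-plane hydroxyl, the two orientations differing by 180 degrees
    dih <- if (variant == "Tyr_CW") 0 else 180
    hx <- rbind(hx, place_internal(xyz["CE1", ], xyz["CZ", ], xyz["OH", ],
                                   CAP_OH, 109.5, dih))
    hn <- c(hn, "HO")
  }
  new_capped_monomer("aromatic_aa", resid,
                     c(heavies, hn),
                     c(element_of(heavies), rep("H", length(hn))),
                     rbind(xyz[heavies, ], hx),
                     cap_idx = length(heavies) + 1L,
                     variant = variant,
                     charge = if (identical(variant, "His_plus")) 1L else 0L,
                     flags = flags)
}

#' Cap a nucleotide to the free deoxyribose model
#'
#' Truncates the sugar: hydrogens replace the nucleobase at C1' and the 5'
#' and 3' phosphorus atoms at O5'/O3'. The hydroxyl-defining dihedrals
#' (C4'-C5'-O5'-H) and (C4'-C3'-O3'-H) are frozen to the crystal O-P
#' directions and recorded. Yields the 18-atom C5H10O3 model.
#'
#' @param residue_atoms atom table rows of one nucleotide (sugar heavy atoms
#'   plus O5'/O3' required; a 5'-phosphorus may be among them).
#' @param p3 optional 3-vector: the phosphorus bonded to O3' (it belongs to
#'   the next residue in a chain).
#' @param default_dihedral degrees used for a truncation hydroxyl whose
#'   phosphorus is absent (terminal residues); flagged.
#' @return a `capped_monomer` (kind `"deoxyribose"`) with
#'   `frozen_dihedrals`.
#' @export
cap_sugar <- function(residue_atoms, p3 = NULL, default_dihedral = 180) {
  resid <- normalize_resid(residue_atoms$resid[1L])
  need <- c(SUGAR_RING, "C5'", "O5'", "O3'")
  miss <- setdiff(need, residue_atoms$elety)
  if (length(miss)) stop("missing sugar atoms: ", paste(miss, collapse = ","))
  xyz <- as.matrix(residue_atoms[, c("x", "y", "z")])
  rownames(xyz) <- residue_atoms$elety
  glyc <- intersect(c("N9", "N1"), rownames(xyz))[1L]
  flags <- character(0L)
  # cap replacing the base at C1'
  if (!is.na(glyc)) {
    h1b <- xyz["C1'", ] + CAP_CH * vunit(xyz[glyc, ] - xyz["C1'", ])
    h1a <- build_hydrogens(xyz["C1'", ], xyz[c("O4'", "C2'", glyc), ], 1L)
  } else {
    hh <- build_hydrogens(xyz["C1'", ], xyz[c("O4'", "C2'"), ], 2L)
    h1a <- hh[1L, , drop = FALSE]; h1b <- hh[2L, ]
    flags <- "no glycosidic nitrogen: C1' hydrogens placed tetrahedrally"
  }
  frozen <- list()
  cap_hydroxyl <- function(o_atom, c_atom, a_atom, p_xyz) {
    quad <- c("C4'", c_atom, o_atom, "H")
    if (!is.null(p_xyz)) {
      dih <- dihedral(xyz[a_atom, ], xyz[c_atom, ], xyz[o_atom, ], p_xyz)
    } else {
      dih <- default_dihedral
      flags <<- c(flags, paste0("no phosphorus bonded to ", o_atom,
                                ": cap placed at the default dihedral"))
    }
    frozen[[length(frozen) + 1L]] <<- list(atoms = quad, degrees = dih)
    place_internal(xyz[a_atom, ], xyz[c_atom, ], xyz[o_atom, ],
                   CAP_OH, 109.5, dih)
  }
  p5 <- if ("P" %in% rownames(xyz)) xyz["P", ] else NULL
  h5p <- cap_hydroxyl("O5'", "C5'", "C4'", p5)
  h3p <- cap_hydroxyl("O3'", "C3'", "C4'",
                      if (!is.null(p3)) as.numeric(p3) else NULL)
  h2 <- build_hydrogens(xyz["C2'", ], xyz[c("C1'", "C3'"), ], 2L)
  h3 <- build_hydrogens(xyz["C3'", ], xyz[c("C2'", "C4'", "O3'"), ], 1L)
  h4 <- build_hydrogens(xyz["C4'", ], xyz[c("C3'", "O4'", "C5'"), ], 1L)
  h5 <- build_hydrogens(xyz["C5'", ], xyz[c("C4'", "O5'"), ], 2L)
  hn <- c("H1'", "H1''", "HO5'", "HO3'", "H2'", "H2''", "H3'", "H4'",
          "H5'", "H5''")
  hx <- rbind(h1a, h1b, h5p, h3p, h2, h3, h4, h5)
  new_capped_monomer("deoxyribose", resid,
                     c(need, hn),
                     c(element_of(need), rep("H", length(hn))),
                     rbind(xyz[need, ], hx),
                     cap_idx = match(c("H1''", "HO5'", "HO3'"),
                                     c(need, hn)),
                     frozen_dihedrals = frozen, flags = flags)
}

#' Overlay a reference monomer template onto a crystal monomer
#'
#' Rigidly positions an (externally optimized or idealized) template in the
#' crystal frame by RMS fitting of the shared ring heavy atoms; the template
#' internal geometry is untouched.
#'
#' @param template data.frame with `elety`, `x`, `y`, `z` (e.g. from
#'   [monomer_template()]).
#' @param crystal_atoms atom table rows of the crystal residue.
#' @param ring_names atom names used for the fit (default: all template
#'   atom names present in the crystal residue).
#' @return list with `atoms` (the positioned template) and `rmsd` of the fit.
#' @export
overlay_reference <- function(template, crystal_atoms, ring_names = NULL) {
  if (is.null(ring_names))
    ring_names <- intersect(template$elety, crystal_atoms$elety)
  if (length(ring_names) < 3L)
    stop("fewer than 3 corresponding ring atoms")
  it <- match(ring_names, template$elety)
  ic <- match(ring_names, crystal_atoms$elety)
  if (anyNA(it) || anyNA(ic)) stop("ring-atom correspondence mismatch")
  tf <- superpose(as.matrix(template[it, c("x", "y", "z")]),
                  as.matrix(crystal_atoms[ic, c("x", "y", "z")]))
  out <- template
  m <- apply_transform(as.matrix(template[, c("x", "y", "z")]), tf)
  out$x <- m[, 1L]; out$y <- m[, 2L]; out$z <- m[, 3L]
  list(atoms = out, rmsd = tf$rmsd)
}

#' Interaction-energy record
#'
#' @param E_dimer,E_aa,E_nt electronic energies of the dimer and the two
#'   monomers.
#' @param unit `"hartree"` or `"kJ/mol"`.
#' @param level_tag free-text method/basis tag (e.g.
#'   `"M06-2X/6-31+G(d,p)"`); [binding_energy()] refuses to mix tags.
#' @return object of class `energy_record`.
#' @export
energy_record <- function(E_dimer, E_aa, E_nt, unit = c("hartree", "kJ/mol"),
                          level_tag = "unspecified") {
  unit <- match.arg(unit)
  structure(list(E_dimer = E_dimer, E_aa = E_aa, E_nt = E_nt, unit = unit,
                 level_tag = level_tag),
            class = "energy_record")
}

#' Dimer binding energy
#'
#' Delta E = E(dimer) - E(amino acid) - E(nucleotide moiety), reported in
#' kJ/mol; negative values are attractive.
#'
#' @param record an [energy_record()], or the dimer energy with `E_aa`,
#'   `E_nt` given separately.
#' @param E_aa,E_nt,unit,level_tag used when `record` is a bare number.
#' @return Delta E in kJ/mol.
#' @export
binding_energy <- function(record, E_aa = NULL, E_nt = NULL,
                           unit = "hartree", level_tag = "unspecified") {
  if (!inherits(record, "energy_record"))
    record <- energy_record(record, E_aa, E_nt, unit, level_tag)
  if (length(unique(record$level_tag)) != 1L)
    stop("mixed level tags in one record")
  de <- record$E_dimer - record$E_aa - record$E_nt
  if (record$unit == "hartree") de <- de * HARTREE_KJMOL
  de
}

#' Two-point complete-basis-set extrapolation
#'
#' Extrapolates the correlation energy with the inverse-cube cardinal-number
#' model: E_corr(CBS) = (Y^3 E_Y - X^3 E_X) / (Y^3 - X^3) for consecutive
#' cardinal numbers X < Y (aug-cc-pVDZ/aug-cc-pVTZ: X = 2, Y = 3). The
#' mean-field reference at the larger basis is taken as the CBS reference.
#'
#' @param E_X,E_Y correlation energies at cardinal numbers X and Y.
#' @param X,Y cardinal numbers, X >= 2, Y = X + 1.
#' @param E_ref_Y reference (mean-field) energy at the larger basis
#'   (default 0: pure correlation extrapolation).
#' @return E_ref_Y + extrapolated correlation energy.
#' @export
cbs_extrapolate <- function(E_X, E_Y, X = 2L, Y = X + 1L, E_ref_Y = 0) {
  if (X >= Y) stop("cardinal numbers must satisfy X < Y")
  if (X < 2L) stop("cardinal number X must be >= 2")
  E_ref_Y + (Y^3 * E_Y - X^3 * E_X) / (Y^3 - X^3)
}

#' CCSD(T)/CBS composite estimate
#'
#' Adds the small-basis CCSD(T)-MP2 difference to the MP2/CBS energy:
#' E = E(MP2/CBS) + \[E(CCSD(T)/small) - E(MP2/small)\].
#'
#' @param E_mp2_cbs MP2 energy at the CBS limit.
#' @param E_cc_small,E_mp2_small CCSD(T) and MP2 energies in the small basis
#'   (counterpoise-corrected in the intended use).
#' @return composite estimate, same units as the inputs.
#' @export
ccsdt_cbs_estimate <- function(E_mp2_cbs, E_cc_small, E_mp2_small) {
  E_mp2_cbs + (E_cc_small - E_mp2_small)
}

#' Write a capped dimer as XYZ (+ JSON sidecar)
#'
#' Standard two-header-line XYZ; the comment line carries the entry ID,
#' residues and variant tags. The sidecar records monomer fragment ranges
#' (for counterpoise fragment definitions), charges and frozen dihedrals.
#'
#' @param monomer_a,monomer_b `capped_monomer` objects (a = amino acid,
#'   b = nucleotide moiety, by convention).
#' @param path output `.xyz` path.
#' @param entry_id structure identifier written to the comment line.
#' @param sidecar write `<path>.json`? (default TRUE)
#' @return `path`, invisibly.
#' @export
write_dimer_geometry <- function(monomer_a, monomer_b, path,
                                 entry_id = "dimer", sidecar = TRUE) {
  ab <- rbind(monomer_a$atoms, monomer_b$atoms)
  na <- nrow(monomer_a$atoms); nb <- nrow(monomer_b$atoms)
  comment <- sprintf("%s %s(%s) + %s(%s) fragments 1-%d / %d-%d",
                     entry_id, monomer_a$resid, monomer_a$variant_tag,
                     monomer_b$resid, monomer_b$variant_tag,
                     na, na + 1L, na + nb)
  lines <- c(sprintf("%d", na + nb), comment,
             sprintf("%-2s %14.8f %14.8f %14.8f", ab$elesy, ab$x, ab$y, ab$z))
  writeLines(lines, path)
  if (sidecar) {
    jsonlite::write_json(list(
      entry_id = entry_id,
      fragments = list(
        a = list(resid = monomer_a$resid, variant = monomer_a$variant_tag,
                 range = c(1L, na), charge = monomer_a$charge),
        b = list(resid = monomer_b$resid, variant = monomer_b$variant_tag,
                 range = c(na + 1L, na + nb), charge = monomer_b$charge)),
      frozen_dihedrals = c(monomer_a$frozen_dihedrals,
                           monomer_b$frozen_dihedrals)),
      paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read an XYZ file
#' @param path `.xyz` file.
#' @return list with `comment` and `atoms` (`elesy`, `x`, `y`, `z`).
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  n <- as.integer(lines[1L])
  flds <- do.call(rbind, strsplit(trimws(lines[3:(2 + n)]), "\\s+"))
  list(comment = lines[2L],
       atoms = data.frame(elesy = flds[, 1L],
                          x = as.numeric(flds[, 2L]),
                          y = as.numeric(flds[, 3L]),
                          z = as.numeric(flds[, 4L]),
                          stringsAsFactors = FALSE))
}

#' Ingest engine energies and compute binding energies
#'
#' Reads a plain CSV with columns `level_tag`, `E_dimer`, `E_aa`, `E_nt`
#' (hartree; optional logical `counterpoise`) and appends `delta_E_kjmol`.
#'
#' @param path CSV file.
#' @return data.frame with `delta_E_kjmol` added.
#' @export
read_energy_table <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("level_tag", "E_dimer", "E_aa", "E_nt")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("energy CSV missing columns: ",
                         paste(miss, collapse = ","))
  d$delta_E_kjmol <- (d$E_dimer - d$E_aa - d$E_nt) * HARTREE_KJMOL
  d
}
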