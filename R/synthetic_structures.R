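# Synthetic coordinate fixtures with fully known ground truth: idealized
# base/amino-acid dimers at controlled tilt, rise and lateral offset;
# deoxyribose units presenting a chosen atom set to an aromatic face; decoy
# placements; and whole corpora with a manifest that is the single source of
# truth for the tests.

template_atoms <- function(tmpl, resid, chain, resno) {
  data.frame(elety = tmpl$elety, elesy = tmpl$elesy, resid = resid,
             chain = chain, resno = resno, insert = "", alt = "",
             x = tmpl$x, y = tmpl$y, z = tmpl$z, o = 1,
             stringsAsFactors = FALSE)
}

atoms_xyz <- function(atoms) as.matrix(atoms[, c("x", "y", "z")])

set_xyz <- function(atoms, m) {
  atoms$x <- m[, 1L]; atoms$y <- m[, 2L]; atoms$z <- m[, 3L]
  atoms
}

transform_atoms <- function(atoms, tf) set_xyz(atoms, apply_transform(atoms_xyz(atoms), tf))

shift_atoms <- function(atoms, v) {
  atoms$x <- atoms$x + v[1L]; atoms$y <- atoms$y + v[2L]
  atoms$z <- atoms$z + v[3L]
  atoms
}

# ring bonds free of heavy exocyclic substituents, given the atoms a fixture
# emits; used to pick the contact edge of the tilted monomer
clean_edge_bond <- function(resid, kind) {
  if (kind == "aa") {
    return(switch(resid, PHE = c("CE1", "CZ"), TYR = c("CD1", "CE1"),
                  TRP = c("CZ3", "CH2"), HIS = c("CE1", "NE2")))
  }
  # bases emitted without a sugar: the glycosidic nitrogen is bare
  switch(resid, DT = c("N1", "C6"), DC = c("C5", "C6"),
         DA = c("C2", "N3"), DG = c("N9", "C8"))
}

screen_xyz_of <- function(atoms) {
  ex <- extract_moieties(atoms)
  stopifnot(length(ex$moieties) == 1L)
  moiety_screen_xyz(ex$moieties[[1L]])
}

#' Build an idealized base-amino-acid pi dimer
#'
#' Places planar idealized monomer templates so that the measured interplanar
#' tilt equals `omega` and (at `slide = 0`) the closest heavy-atom distance
#' equals `rise`. The tilted ("edge") monomer is rotated about a ring bond
#' carrying no heavy exocyclic substituents (or about `edge_atoms`), so its
#' edge points at the other monomer's face -- the T-shaped archetype at high
#' tilt, face-to-face stacking at low tilt.
#'
#' @param base `"DA"`, `"DC"`, `"DG"` or `"DT"` (or A/C/G/T).
#' @param aa `"PHE"`, `"TYR"`, `"TRP"` or `"HIS"`.
#' @param omega requested tilt, degrees in \[0, 90\].
#' @param rise requested closest heavy-atom separation, Angstrom (> 0).
#' @param slide lateral offset applied to the tilted monomer, Angstrom.
#' @param twist in-plane rotation of the tilted monomer, degrees.
#' @param edge_monomer which monomer presents its edge (is tilted):
#'   `"nucleobase"` (default) or `"amino_acid"`; determines the ground-truth
#'   edge role at tilts of 20 degrees or more.
#' @param edge_atoms optional explicit pair of adjacent ring atom names of
#'   the tilted monomer to rotate about.
#' @param chain_base,chain_aa,resno_base,resno_aa residue bookkeeping.
#' @return list with `atoms` (atom table, PDB-convention names so the full
#'   pipeline runs unmodified) and `manifest` (ground truth: requested
#'   tilt/rise, category, edge role, residue ids).
#' @export
build_pi_dimer <- function(base, aa, omega, rise, slide = 0, twist = 0,
                           edge_monomer = c("nucleobase", "amino_acid"),
                           edge_atoms = NULL,
                           chain_base = "B", chain_aa = "A",
                           resno_base = 1L, resno_aa = 1L) {
  base <- normalize_resid(base); aa <- toupper(aa)
  if (!base %in% NUCLEOTIDES) stop("unknown nucleotide: ", base)
  if (!aa %in% AROMATIC_AA) stop("unknown aromatic residue: ", aa)
  stopifnot(omega >= 0, omega <= 90, rise > 0)
  edge_monomer <- match.arg(edge_monomer)

  base_atoms <- template_atoms(template_base(base), base, chain_base, resno_base)
  aa_atoms <- template_atoms(template_aa(aa), aa, chain_aa, resno_aa)
  if (edge_monomer == "nucleobase") {
    face <- aa_atoms; edge <- base_atoms
    bond <- if (is.null(edge_atoms)) clean_edge_bond(base, "base") else edge_atoms
  } else {
    face <- base_atoms; edge <- aa_atoms
    bond <- if (is.null(edge_atoms)) clean_edge_bond(aa, "aa") else edge_atoms
  }
  em <- atoms_xyz(edge)
  a1 <- em[match(bond[1L], edge$elety), ]
  a2 <- em[match(bond[2L], edge$elety), ]
  # bond to the x axis, molecule into y > 0
  em <- sweep(em, 2L, a1)
  ang <- atan2(a2[2L] - a1[2L], a2[1L] - a1[1L]) * DEG
  em <- em %*% t(rotation_about_axis(c(0, 0, 1), -ang))
  if (mean(em[, 2L]) < 0)
    em <- em %*% t(rotation_about_axis(c(1, 0, 0), 180))
  # tilt about the bond, then twist about the vertical through the bond
  em <- em %*% t(rotation_about_axis(c(1, 0, 0), omega))
  em <- em %*% t(rotation_about_axis(c(0, 0, 1), twist))
  # bond midpoint over the face centroid, at the requested slide
  fxyz <- atoms_xyz(face)
  fctr <- colMeans(fxyz[match(intersect(
    if (edge_monomer == "nucleobase") AA_RING[[aa]] else BASE_RING[[base]],
    face$elety), face$elety), , drop = FALSE])
  mid <- (em[match(bond[1L], edge$elety), ] + em[match(bond[2L], edge$elety), ]) / 2
  em <- sweep(em, 2L, mid, "-")
  em <- sweep(em, 2L, c(fctr[1L] + slide, fctr[2L], fctr[3L]), "+")
  edge <- set_xyz(edge, em)
  # vertical shift so the measured closest heavy-atom distance is exactly
  # `rise` (monotone in the shift; solved by bisection)
  f_scr <- screen_xyz_of(face); e_scr0 <- screen_xyz_of(edge)
  f <- function(h) min_heavy_distance(f_scr, sweep(e_scr0, 2L, c(0, 0, h), "+")) - rise
  h <- stats::uniroot(f, c(0.2, rise + 5), tol = 1e-10)$root
  edge <- shift_atoms(edge, c(0, 0, h))

  category <- classify_tilt(omega)
  role <- if (category == "stacked") "face_face" else
    if (edge_monomer == "nucleobase") "nucleobase_edge" else "amino_acid_edge"
  atoms <- rbind(if (edge_monomer == "nucleobase") face else edge,
                 if (edge_monomer == "nucleobase") edge else face)
  list(atoms = atoms,
       manifest = list(type = "pi_pi", base = base, aa = aa,
                       omega = omega, rise = rise, slide = slide,
                       twist = twist, category = category, edge_role = role,
                       base_id = moiety_id(chain_base, base, resno_base),
                       aa_id = moiety_id(chain_aa, aa, resno_aa)))
}

SUGAR_CLASSES <- c("single_proton", "bridged", "face", "lone_pair",
                   "lone_pair_proton")

default_sugar_labels <- function(edge_class) {
  switch(edge_class,
         single_proton = "H3", bridged = "H1a-H2a", face = "H4-H5a-H5b",
         lone_pair = "O4'", lone_pair_proton = "H1a-O4'",
         stop("unknown sugar edge class: ", edge_class))
}

sugar_fixture_residue <- function(chain = "B", resno = 1L) {
  tmpl <- template_sugar(glycosidic_n = "N1")
  template_atoms(tmpl, "DT", chain, resno)
}

# orientation cache: canonical placements are found once per
# (class, labels, aa, height) and reused under random rigid motions
.sugar_cache <- new.env(parent = emptyenv())

# find a rigid placement of the sugar residue over the aromatic face such
# that exactly `labels` participate; deterministic grid refinement around the
# mean direction of the requested atoms
orient_sugar_over_face <- function(aa, labels, height,
                                   criteria = validity_criteria()) {
  key <- paste(aa, paste(labels, collapse = "+"), format(height), sep = "|")
  if (!is.null(.sugar_cache[[key]])) return(.sugar_cache[[key]])
  aa_atoms <- template_atoms(template_aa(aa), aa, "A", 1L)
  sug <- sugar_fixture_residue()
  sug_m <- extract_moieties(sug)$moieties[[1L]]
  lab <- label_sugar_atoms(sug_m)
  pts <- as.matrix(lab[, c("x", "y", "z")])
  rownames(pts) <- lab$label
  sxyz <- atoms_xyz(sug)
  rownames(sxyz) <- sug$elety
  dirs <- lapply(labels, function(l) {
    if (l == "O4'") {
      -vunit(vunit(sxyz["C1'", ] - sxyz["O4'", ]) +
             vunit(sxyz["C4'", ] - sxyz["O4'", ]))
    } else vunit(pts[l, ] - sxyz[lab$parent[lab$label == l], ])
  })
  v <- vunit(Reduce(`+`, dirs))
  # rotation taking v to -z
  axis <- vcross(v, c(0, 0, -1))
  rot0 <- if (vnorm(axis) < 1e-9) diag(3L) else
    rotation_about_axis(axis, acos(clamp1(sum(v * c(0, 0, -1)))) * DEG)
  target <- paste(sort(labels), collapse = "+")
  try_orientation <- function(ax, ay, h) {
    rot <- rotation_about_axis(c(0, 1, 0), ay) %*%
           rotation_about_axis(c(1, 0, 0), ax) %*% rot0
    m <- atoms_xyz(sug) %*% t(rot)
    # anchor: centroid of the participating atoms at the requested height
    pm <- pts %*% t(rot)
    rownames(pm) <- lab$label
    anchor <- colMeans(pm[labels, , drop = FALSE])
    off <- c(-anchor[1L], -anchor[2L], h - anchor[3L])
    cand <- shift_atoms(set_xyz(sug, m), off)
    res <- survey_structure(rbind(aa_atoms, cand), criteria, entry_id = "probe")
    s <- res$sugar_pi
    if (nrow(s) == 1L && s$valid &&
        identical(paste(sort(strsplit(s$atom_labels, "-", fixed = TRUE)[[1L]]),
                        collapse = "+"), target))
      cand else NULL
  }
  grid <- expand.grid(ax = seq(0, 45, by = 5), ay = seq(0, 45, by = 5))
  grid <- grid[order(grid$ax^2 + grid$ay^2), ]
  # the height is raised in small steps when the requested set cannot be
  # isolated at the nominal height (peripheral atoms leave the 4 A band)
  for (dh in seq(0, 1.2, by = 0.3)) {
    for (i in seq_len(nrow(grid))) {
      for (sx in if (grid$ax[i] == 0) 1 else c(1, -1))
        for (sy in if (grid$ay[i] == 0) 1 else c(1, -1)) {
          cand <- try_orientation(sx * grid$ax[i], sy * grid$ay[i],
                                  height + dh)
          if (!is.null(cand)) {
            out <- list(atoms = cand, height = height + dh)
            .sugar_cache[[key]] <- out
            return(out)
          }
        }
    }
  }
  stop("could not realize sugar fixture: ", target, " over ", aa,
       " at height ", height)
}

#' Build a deoxyribose-aromatic fixture with a requested sugar edge
#'
#' Orients the C2'-endo deoxyribose template over an aromatic face so that
#' exactly the requested atoms satisfy the participation test, yielding a
#' ground-truth example of one of the five sugar-edge classes.
#'
#' @param edge_class one of `"single_proton"`, `"bridged"`, `"face"`,
#'   `"lone_pair"`, `"lone_pair_proton"`.
#' @param atom_labels label string (e.g. `"H1a-H2b"`); `NULL` uses a default
#'   set consistent with the class.
#' @param aa aromatic residue name.
#' @param height Angstrom: height of the participating atoms above the
#'   aromatic plane.
#' @param criteria [validity_criteria()] the fixture must satisfy.
#' @param chain_sugar,chain_aa,resno_sugar,resno_aa residue bookkeeping.
#' @return list with `atoms` and `manifest` (class, labels, residue ids).
#' @export
build_sugar_fixture <- function(edge_class, atom_labels = NULL, aa = "TYR",
                                height = 2.8,
                                criteria = validity_criteria(),
                                chain_sugar = "B", chain_aa = "A",
                                resno_sugar = 1L, resno_aa = 1L) {
  edge_class <- match.arg(edge_class, SUGAR_CLASSES)
  aa <- toupper(aa)
  if (is.null(atom_labels)) atom_labels <- default_sugar_labels(edge_class)
  labels <- strsplit(atom_labels, "-", fixed = TRUE)[[1L]]
  nh <- sum(labels != "O4'"); o4 <- "O4'" %in% labels
  ok <- switch(edge_class, single_proton = nh == 1L && !o4,
               bridged = nh == 2L && !o4, face = nh == 3L && !o4,
               lone_pair = nh == 0L && o4, lone_pair_proton = nh >= 1L && o4)
  if (!ok) stop("atom labels '", atom_labels, "' inconsistent with class ",
                edge_class)
  or <- orient_sugar_over_face(aa, labels, height, criteria)
  sug <- or$atoms
  sug$chain <- chain_sugar; sug$resno <- resno_sugar
  aa_atoms <- template_atoms(template_aa(aa), aa, chain_aa, resno_aa)
  labels <- labels[order(match(labels, SUGAR_LABEL_ORDER))]
  list(atoms = rbind(aa_atoms, sug),
       manifest = list(type = "sugar_pi", edge_class = edge_class,
                       atom_labels = paste(labels, collapse = "-"),
                       aa = aa, height = or$height,
                       sugar_id = moiety_id(chain_sugar, "DT", resno_sugar),
                       aa_id = moiety_id(chain_aa, aa, resno_aa)))
}

# decoy placements: screened-out pairs, coplanar side-by-side traps, and
# sugar approaches whose atoms all fail the participation test
build_decoy <- function(kind = c("far", "coplanar", "sugar_averted"),
                        aa = "PHE", base = "DT",
                        chain_partner = "B", chain_aa = "A",
                        resno_partner = 1L, resno_aa = 1L) {
  kind <- match.arg(kind)
  if (kind == "far") {
    d <- build_pi_dimer(base, aa, omega = 0, rise = 6.5,
                        chain_base = chain_partner, chain_aa = chain_aa,
                        resno_base = resno_partner, resno_aa = resno_aa)
    return(list(atoms = d$atoms,
                manifest = list(type = "decoy", decoy_kind = "far",
                                aa = aa, partner = base)))
  }
  if (kind == "coplanar") {
    aa_atoms <- template_atoms(template_aa(aa), aa, chain_aa, resno_aa)
    base_atoms <- template_atoms(template_base(normalize_resid(base)),
                                 normalize_resid(base),
                                 chain_partner, resno_partner)
    # same plane, side by side: closest heavy atoms ~2.5 A apart
    span <- max(atoms_xyz(aa_atoms)[, 1L]) - min(atoms_xyz(base_atoms)[, 1L])
    base_atoms <- shift_atoms(base_atoms, c(span + 2.5, 0, 0))
    return(list(atoms = rbind(aa_atoms, base_atoms),
                manifest = list(type = "decoy", decoy_kind = "coplanar",
                                aa = aa, partner = base)))
  }
  # sugar_averted: hydrogens point away from the face; heavy atoms inside
  # the screening cutoff but no atom passes the participation test
  aa_atoms <- template_atoms(template_aa(aa), aa, chain_aa, resno_aa)
  sug <- sugar_fixture_residue(chain_partner, resno_partner)
  sug_m <- extract_moieties(sug)$moieties[[1L]]
  lab <- label_sugar_atoms(sug_m)
  # mean C-H direction up (+z): bonds point away from the ring below
  v <- vunit(colSums(as.matrix(lab[lab$element == "H", c("x", "y", "z")])) -
             nrow(lab[lab$element == "H", ]) *
               colMeans(atoms_xyz(sug)[match(unique(stats::na.omit(lab$parent)),
                                             sug$elety), ]))
  axis <- vcross(v, c(0, 0, 1))
  rot <- if (vnorm(axis) < 1e-9) diag(3L) else
    rotation_about_axis(axis, acos(clamp1(sum(v * c(0, 0, 1)))) * DEG)
  m <- atoms_xyz(sug) %*% t(rot)
  m <- sweep(m, 2L, colMeans(m), "-")
  for (h in seq(4.4, 6.0, by = 0.1)) {
    cand <- set_xyz(sug, sweep(m, 2L, c(0, 0, h), "+"))
    res <- survey_structure(rbind(aa_atoms, cand), entry_id = "probe")
    s <- res$sugar_pi
    if (nrow(s) == 1L && !any(s$valid)) {
      return(list(atoms = rbind(aa_atoms, cand),
                  manifest = list(type = "decoy", decoy_kind = "sugar_averted",
                                  aa = aa, partner = "DT")))
    }
  }
  # fall back: beyond-cutoff sugar
  cand <- set_xyz(sug, sweep(m, 2L, c(0, 0, 7), "+"))
  list(atoms = rbind(aa_atoms, cand),
       manifest = list(type = "decoy", decoy_kind = "sugar_averted",
                       aa = aa, partner = "DT"))
}

PI_CLASS_NAMES <- c("pi_stacked", "pi_inclined", "pi_tshaped_base_edge",
                    "pi_tshaped_aa_edge")
DECOY_CLASS_NAMES <- c("decoy_far", "decoy_coplanar", "decoy_sugar_averted")

#' Default corpus class mixture
#'
#' Relative frequencies used by [build_survey_corpus()], chosen to echo the
#' composition observed in the crystal-structure survey: pi-pi contacts
#' outnumber sugar-pi contacts ~60:40; within pi-pi, stacked ~58%, inclined
#' ~29%, T-shaped ~13% (predominantly nucleobase-edge); within sugar-pi,
#' bridged and face dominate, lone-pair-proton is rare. A 10% decoy fraction
#' exercises the rejection paths.
#' @return named numeric vector summing to 1.
#' @export
default_class_mixture <- function() {
  m <- c(pi_stacked = 0.31, pi_inclined = 0.16,
         pi_tshaped_base_edge = 0.05, pi_tshaped_aa_edge = 0.02,
         sugar_single_proton = 0.07, sugar_bridged = 0.12,
         sugar_face = 0.11, sugar_lone_pair = 0.05,
         sugar_lone_pair_proton = 0.01,
         decoy_far = 0.04, decoy_coplanar = 0.03, decoy_sugar_averted = 0.03)
  m / sum(m)
}

# largest-remainder allocation of n slots to the mixture
allocate_classes <- function(n, mixture) {
  mixture <- mixture / sum(mixture)
  base <- floor(n * mixture)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- n * mixture - base
    add <- order(-frac)[seq_len(rem)]
    base[add] <- base[add] + 1L
  }
  rep(names(mixture), times = base)
}

pi_omega_range <- list(pi_stacked = c(0, 18), pi_inclined = c(22, 68),
                       pi_tshaped_base_edge = c(72, 90),
                       pi_tshaped_aa_edge = c(72, 90))

sample_weighted <- function(x, w) x[sample.int(length(x), 1L, prob = w)]

#' Generate a reproducible survey corpus with ground truth
#'
#' Writes `n_structures` PDB files, each holding one or more contact (or
#' decoy) units placed far apart, plus a JSON manifest recording every
#' requested contact: the single source of truth for recovery tests. Class
#' counts follow `class_mixture` exactly (largest-remainder allocation, not
#' sampling), tilts are drawn at least 2 degrees from the 20/70 degree bin
#' boundaries, separations from 3.2-3.6 Angstrom, and every structure is
#' given a random global rigid motion. Residue identities are drawn with the
#' frequencies observed in the survey (e.g. T the most common base; Phe/Tyr
#' the most common amino acids).
#'
#' @param n_structures number of structures to generate.
#' @param dir output directory (created if needed).
#' @param class_mixture named frequencies over
#'   `pi_stacked`, `pi_inclined`, `pi_tshaped_base_edge`,
#'   `pi_tshaped_aa_edge`, `sugar_*` and `decoy_*` classes; defaults to
#'   [default_class_mixture()].
#' @param seed integer; the corpus is a deterministic function of
#'   (parameters, seed).
#' @param contacts_per_structure integer vector recycled over structures.
#' @param jitter_sd Gaussian coordinate jitter, Angstrom (default 0: exact).
#' @return the manifest, invisibly: list with `structures` (data.frame
#'   `entry_id`, `path`, `n_units`), `contacts` and `decoys` data.frames.
#'   Also written to `manifest.json` in `dir`.
#' @export
build_survey_corpus <- function(n_structures, dir,
                                class_mixture = default_class_mixture(),
                                seed = 1L, contacts_per_structure = 1L,
                                jitter_sd = 0) {
  stopifnot(n_structures >= 1L, all(class_mixture >= 0))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  n_units <- rep_len(as.integer(contacts_per_structure), n_structures)
  slots <- allocate_classes(sum(n_units), class_mixture)
  # deterministic round-robin assignment of class slots to structures
  slot_of <- split(slots, rep.int(seq_len(n_structures), n_units))
  contacts <- list(); decoys <- list(); structures <- list()
  base_w <- c(DT = 0.37, DC = 0.21, DA = 0.21, DG = 0.21)
  aa_pi_w <- c(PHE = 0.44, TYR = 0.32, TRP = 0.13, HIS = 0.11)
  aa_sug_w <- c(TYR = 0.45, PHE = 0.36, TRP = 0.14, HIS = 0.05)
  for (si in seq_len(n_structures)) {
    entry_id <- sprintf("SYN%04d", si)
    atoms <- NULL
    for (ui in seq_along(slot_of[[si]])) {
      cls <- slot_of[[si]][ui]
      offset <- c(60 * (ui - 1L), 0, 0)
      aa_chain <- "A"; pt_chain <- "B"
      aa_resno <- 100L + ui; pt_resno <- ui
      if (cls %in% PI_CLASS_NAMES) {
        rng <- pi_omega_range[[cls]]
        omega <- stats::runif(1L, rng[1L], rng[2L])
        rise <- stats::runif(1L, 3.2, 3.6)
        twist <- stats::runif(1L, 0, 360)
        b <- sample_weighted(names(base_w), base_w)
        a <- sample_weighted(names(aa_pi_w), aa_pi_w)
        d <- build_pi_dimer(b, a, omega, rise, twist = twist,
                            edge_monomer = if (cls == "pi_tshaped_aa_edge")
                              "amino_acid" else "nucleobase",
                            chain_base = pt_chain, chain_aa = aa_chain,
                            resno_base = pt_resno, resno_aa = aa_resno)
        contacts[[length(contacts) + 1L]] <- data.frame(
          entry_id = entry_id, type = "pi_pi", class = d$manifest$category,
          edge_role = d$manifest$edge_role, base_or_sugar = b, aa = a,
          omega = omega, rise = rise, atom_labels = "",
          partner_id = d$manifest$base_id, aa_id = d$manifest$aa_id,
          stringsAsFactors = FALSE)
        unit <- d$atoms
      } else if (startsWith(cls, "sugar_")) {
        ec <- sub("^sugar_", "", cls)
        a <- sample_weighted(names(aa_sug_w), aa_sug_w)
        # nominal approach height is fixed; orientational variety enters
        # through the per-structure random rigid motion
        height <- 2.8
        d <- build_sugar_fixture(ec, NULL, a, height,
                                 chain_sugar = pt_chain, chain_aa = aa_chain,
                                 resno_sugar = pt_resno, resno_aa = aa_resno)
        contacts[[length(contacts) + 1L]] <- data.frame(
          entry_id = entry_id, type = "sugar_pi", class = ec,
          edge_role = "", base_or_sugar = "DT", aa = a,
          omega = NA_real_, rise = NA_real_,
          atom_labels = d$manifest$atom_labels,
          partner_id = d$manifest$sugar_id, aa_id = d$manifest$aa_id,
          stringsAsFactors = FALSE)
        unit <- d$atoms
      } else {
        kind <- sub("^decoy_", "", cls)
        d <- build_decoy(kind,
                         aa = sample_weighted(names(aa_pi_w), aa_pi_w),
                         base = sample_weighted(names(base_w), base_w),
                         chain_partner = pt_chain, chain_aa = aa_chain,
                         resno_partner = pt_resno, resno_aa = aa_resno)
        decoys[[length(decoys) + 1L]] <- data.frame(
          entry_id = entry_id, decoy_kind = d$manifest$decoy_kind,
          aa = d$manifest$aa, partner = d$manifest$partner,
          stringsAsFactors = FALSE)
        unit <- d$atoms
      }
      atoms <- rbind(atoms, shift_atoms(unit, offset))
    }
    tf <- random_rigid_transform()
    atoms <- transform_atoms(atoms, tf)
    if (jitter_sd > 0)
      atoms <- set_xyz(atoms, atoms_xyz(atoms) +
                         matrix(stats::rnorm(3L * nrow(atoms), 0, jitter_sd),
                                ncol = 3L))
    path <- file.path(dir, paste0(entry_id, ".pdb"))
    write_structure(atoms, path)
    structures[[si]] <- data.frame(entry_id = entry_id, path = path,
                                   n_units = n_units[si],
                                   stringsAsFactors = FALSE)
  }
  manifest <- list(
    seed = seed, n_structures = n_structures,
    structures = do.call(rbind, structures),
    contacts = if (length(contacts)) do.call(rbind, contacts) else NULL,
    decoys = if (length(decoys)) do.call(rbind, decoys) else NULL)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       dataframe = "columns", auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Read a corpus manifest
#' @param dir corpus directory (containing `manifest.json`).
#' @return manifest list as written by [build_survey_corpus()].
#' @export
read_corpus_manifest <- function(dir) {
  m <- jsonlite::read_json(file.path(dir, "manifest.json"),
                           simplifyVector = TRUE)
  for (nm in c("structures", "contacts", "decoys"))
    if (!is.null(m[[nm]])) m[[nm]] <- as.data.frame(m[[nm]])
  m
}
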