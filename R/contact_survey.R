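# The survey procedure: 5.0 A heavy-atom screening of aromatic/nucleobase and
# aromatic/deoxyribose pairs, algorithmic validation that a candidate is a
# genuine pi-interaction, tilt-bin and edge-role classification of pi-pi
# contacts, and the five-class sugar-edge taxonomy with participating-atom
# labels.

#' Validity criteria for the contact survey
#'
#' Thresholds for the algorithmic surrogate of visual contact inspection.
#' A candidate pi-pi pair is accepted when at least `min_participating_atoms`
#' ring atoms of one monomer lie within `max_perpendicular_height` of the
#' other monomer's best-fit plane while projecting inside its ring polygon
#' expanded by `max_lateral_offset`; this rejects coplanar side-by-side
#' false positives. A sugar hydrogen participates in a sugar-pi contact when
#' it is within `sugar_max_height` of the aromatic plane, projects within
#' the ring polygon + `sugar_max_lateral_offset`, and its X-H bond points at
#' the ring within `sugar_ch_max_angle` degrees of the plane perpendicular
#' (C-H...pi directionality); the O4' lone-pair test drops the directionality
#' condition.
#'
#' @param cutoff screening distance, Angstrom (pairs at or beyond are never
#'   candidates).
#' @param max_perpendicular_height Angstrom, pi-pi participation.
#' @param max_lateral_offset Angstrom beyond the ring polygon, pi-pi.
#' @param min_participating_atoms minimum count for a valid pi-pi contact.
#' @param sugar_max_height Angstrom, sugar-atom participation.
#' @param sugar_max_lateral_offset Angstrom beyond the ring polygon, sugar.
#' @param sugar_ch_max_angle degrees, maximum angle between the X-H vector
#'   and the (inward) plane perpendicular.
#' @param score_o3_o5_lone_pairs also score O3'/O5' as lone-pair donors
#'   (exploratory; off by default -- surveyed lone-pair contacts involve O4').
#' @return object of class `validity_criteria`.
#' @export
validity_criteria <- function(cutoff = 5.0,
                              max_perpendicular_height = 4.5,
                              max_lateral_offset = 1.5,
                              min_participating_atoms = 2L,
                              sugar_max_height = 4.0,
                              sugar_max_lateral_offset = 1.5,
                              sugar_ch_max_angle = 60,
                              score_o3_o5_lone_pairs = FALSE) {
  crit <- list(cutoff = cutoff,
               max_perpendicular_height = max_perpendicular_height,
               max_lateral_offset = max_lateral_offset,
               min_participating_atoms = as.integer(min_participating_atoms),
               sugar_max_height = sugar_max_height,
               sugar_max_lateral_offset = sugar_max_lateral_offset,
               sugar_ch_max_angle = sugar_ch_max_angle,
               score_o3_o5_lone_pairs = isTRUE(score_o3_o5_lone_pairs))
  stopifnot(all(vapply(crit[1:7], function(v) is.numeric(v) && v > 0,
                       logical(1L))))
  structure(crit, class = "validity_criteria")
}

#' @export
print.validity_criteria <- function(x, ...) {
  cat("contact-survey validity criteria:\n")
  for (nm in names(x)) cat(sprintf("  %-26s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Write / read survey criteria as YAML
#' @param criteria a [validity_criteria()] object.
#' @param path YAML file.
#' @return the criteria (read) or `path` invisibly (write).
#' @export
write_survey_config <- function(criteria, path) {
  yaml::write_yaml(unclass(criteria), path)
  invisible(path)
}

#' @rdname write_survey_config
#' @export
read_survey_config <- function(path) {
  do.call(validity_criteria, yaml::read_yaml(path))
}

ring_plane_of <- function(m) fit_ring_plane(moiety_xyz(m, m$ring), m$ring)

# heights, lateral offsets and (optionally) X-H directionality of points
# against an aromatic moiety's face
face_geometry <- function(points, aromatic_moiety, plane = NULL) {
  if (is.null(plane)) plane <- ring_plane_of(aromatic_moiety)
  basis <- plane_basis(plane)
  pr <- project_to_plane(points, plane, basis)
  ring_xy <- project_to_plane(moiety_xyz(aromatic_moiety,
                                         aromatic_moiety$ring),
                              plane, basis)$xy
  list(plane = plane, height = pr$height,
       offset = polygon_offset(pr$xy, ring_xy))
}

count_face_participation <- function(points, aromatic_moiety, max_h, buffer) {
  g <- face_geometry(points, aromatic_moiety)
  sum(abs(g$height) <= max_h & g$offset <= buffer)
}

#' Screen candidate moiety pairs at a distance cutoff
#'
#' Returns every (aromatic ring, nucleobase ring) and (aromatic ring,
#' deoxyribose) pair whose closest heavy-atom distance is strictly below the
#' cutoff. Heavy atoms of a moiety are its ring atoms plus exocyclic
#' substituents (for sugars, C5'; backbone O5'/O3'/P excluded).
#'
#' @param moieties list of `moiety` objects (one structure).
#' @param cutoff Angstrom, strict upper bound.
#' @return list of candidates, each `list(aa, partner, type, d_min)` with
#'   `type` either `"pi_pi"` or `"sugar_pi"`.
#' @export
screen_candidates <- function(moieties, cutoff = 5.0) {
  stopifnot(cutoff > 0)
  kinds <- vapply(moieties, function(m) m$kind, character(1L))
  aas <- moieties[kinds == "aromatic_aa_ring"]
  partners <- moieties[kinds %in% c("nucleobase_ring", "deoxyribose")]
  out <- list()
  if (!length(aas) || !length(partners)) return(out)
  axyz <- lapply(aas, moiety_screen_xyz)
  pxyz <- lapply(partners, moiety_screen_xyz)
  actr <- lapply(axyz, colMeans)
  pctr <- lapply(pxyz, colMeans)
  for (i in seq_along(aas)) for (j in seq_along(partners)) {
    if (vnorm(actr[[i]] - pctr[[j]]) > cutoff + 10) next
    d <- min_heavy_distance(axyz[[i]], pxyz[[j]])
    if (d < cutoff) {
      out[[length(out) + 1L]] <- list(
        aa = aas[[i]], partner = partners[[j]],
        type = if (partners[[j]]$kind == "deoxyribose") "sugar_pi" else "pi_pi",
        d_min = d)
    }
  }
  out
}

#' Validate a base-amino-acid candidate as a pi-pi interaction
#'
#' Algorithmic surrogate for visual inspection: accepted when at least
#' `min_participating_atoms` ring atoms of one monomer lie within
#' `max_perpendicular_height` of the other monomer's plane and project within
#' its ring polygon expanded by `max_lateral_offset`. Coplanar side-by-side
#' geometries fail the lateral-offset condition and are rejected.
#'
#' @param aa_moiety,base_moiety `moiety` objects.
#' @param criteria [validity_criteria()].
#' @return list with `valid`, `reason`, and the participation counts
#'   `n_base_on_aa`, `n_aa_on_base`.
#' @export
validate_pi_pi <- function(aa_moiety, base_moiety, criteria = validity_criteria()) {
  nb <- count_face_participation(moiety_xyz(base_moiety, base_moiety$ring),
                                 aa_moiety,
                                 criteria$max_perpendicular_height,
                                 criteria$max_lateral_offset)
  na <- count_face_participation(moiety_xyz(aa_moiety, aa_moiety$ring),
                                 base_moiety,
                                 criteria$max_perpendicular_height,
                                 criteria$max_lateral_offset)
  need <- criteria$min_participating_atoms
  if (max(na, nb) >= need)
    list(valid = TRUE, reason = "", n_base_on_aa = nb, n_aa_on_base = na)
  else
    list(valid = FALSE,
         reason = sprintf(
           "no face participation (%d base atoms on aa face, %d aa atoms on base face, need %d)",
           nb, na, need),
         n_base_on_aa = nb, n_aa_on_base = na)
}

#' Classify a tilt angle into stacked / inclined / T-shaped
#'
#' Half-open bins: stacked for tilt in \[0, 20), inclined \[20, 70),
#' T-shaped \[70, 90\], so every angle falls in exactly one class.
#'
#' @param omega tilt in degrees, within \[0, 90\].
#' @return `"stacked"`, `"inclined"` or `"t_shaped"`.
#' @export
classify_tilt <- function(omega) {
  if (any(!is.finite(omega) | omega < 0 | omega > 90))
    stop("tilt angle outside [0, 90]: ", paste(omega, collapse = ", "))
  ifelse(omega < 20, "stacked", ifelse(omega < 70, "inclined", "t_shaped"))
}

#' Assign the edge role of a validated pi-pi contact
#'
#' For stacked contacts the arrangement is face-to-face. Otherwise the edge
#' monomer is the one whose ring atoms satisfy the face-participation test
#' against the other monomer's plane; if both qualify, the one with more
#' participating atoms, then the nucleobase.
#'
#' @param aa_moiety,base_moiety `moiety` objects.
#' @param omega tilt, degrees.
#' @param criteria [validity_criteria()].
#' @return `"face_face"`, `"nucleobase_edge"` or `"amino_acid_edge"`.
#' @export
assign_edge_role <- function(aa_moiety, base_moiety, omega,
                             criteria = validity_criteria()) {
  if (classify_tilt(omega) == "stacked") return("face_face")
  nb <- count_face_participation(moiety_xyz(base_moiety, base_moiety$ring),
                                 aa_moiety,
                                 criteria$max_perpendicular_height,
                                 criteria$max_lateral_offset)
  na <- count_face_participation(moiety_xyz(aa_moiety, aa_moiety$ring),
                                 base_moiety,
                                 criteria$max_perpendicular_height,
                                 criteria$max_lateral_offset)
  if (nb >= na) "nucleobase_edge" else "amino_acid_edge"
}

SUGAR_H_LABELS <- c("H1a", "H2a", "H2b", "H3", "H4", "H5a", "H5b")
SUGAR_LABEL_ORDER <- c(SUGAR_H_LABELS, "O4'")

# chirality-sensitive reference normal of the sugar (flips under mirror
# inversion): cross(O4'->C1', O4'->C4')
sugar_ref_normal <- function(xyz) {
  vunit(vcross(xyz["C1'", ] - xyz["O4'", ], xyz["C4'", ] - xyz["O4'", ]))
}

#' Label the deoxyribose hydrogens and ring oxygen
#'
#' Builds the seven sugar hydrogens at idealized positions (crystal
#' structures at survey resolution lack protons) and labels them H1a,
#' H2a/H2b, H3, H4, H5a/H5b plus the ring oxygen O4'. At the prochiral
#' centers C2' and C5', label "a" goes to the hydrogen on the positive side
#' of the chirality reference normal cross(O4'-C1', O4'-C4') (sign of the
#' triple product), which is deterministic, invariant under rigid motion,
#' and swaps under mirror inversion.
#'
#' @param sugar_moiety a `deoxyribose` moiety whose residue atoms include
#'   C5', O5', O3' and the glycosidic nitrogen.
#' @return data.frame `label`, `parent`, `element`, `x`, `y`, `z` (eight
#'   rows: seven hydrogens and O4').
#' @export
label_sugar_atoms <- function(sugar_moiety) {
  a <- sugar_moiety$atoms
  xyz <- as.matrix(a[, c("x", "y", "z")])
  rownames(xyz) <- a$elety
  glyc <- if ("N9" %in% a$elety) "N9" else "N1"
  need <- c(SUGAR_RING, "C5'", "O5'", "O3'", glyc)
  miss <- setdiff(need, a$elety)
  if (length(miss))
    stop("sugar ", sugar_moiety$id, " missing heavy atoms: ",
         paste(miss, collapse = ","))
  nref <- sugar_ref_normal(xyz)
  ab_order <- function(hs, parent) {
    s <- as.numeric((hs - rep(xyz[parent, ], each = 2L)) %*% nref)
    hs[order(-s), , drop = FALSE]   # "a" = positive side of the reference
  }
  h1 <- build_hydrogens(xyz["C1'", ],
                        xyz[c("O4'", "C2'", glyc), ], 1L)
  h2 <- ab_order(build_hydrogens(xyz["C2'", ], xyz[c("C1'", "C3'"), ], 2L), "C2'")
  h3 <- build_hydrogens(xyz["C3'", ], xyz[c("C2'", "C4'", "O3'"), ], 1L)
  h4 <- build_hydrogens(xyz["C4'", ], xyz[c("C3'", "O4'", "C5'"), ], 1L)
  h5 <- ab_order(build_hydrogens(xyz["C5'", ], xyz[c("C4'", "O5'"), ], 2L), "C5'")
  pos <- rbind(h1, h2, h3, h4, h5, xyz["O4'", , drop = FALSE])
  data.frame(label = SUGAR_LABEL_ORDER,
             parent = c("C1'", "C2'", "C2'", "C3'", "C4'", "C5'", "C5'", NA),
             element = c(rep("H", 7L), "O"),
             x = pos[, 1L], y = pos[, 2L], z = pos[, 3L],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Classify a sugar-aromatic candidate by its interacting sugar edge
#'
#' Applies the participation test of [validity_criteria()] to each labelled
#' hydrogen and to O4' against the aromatic face, then classifies by the
#' participating set: one/two/three hydrogens give single proton / bridged /
#' face; O4' alone a lone pair; O4' plus hydrogens a lone pair-proton
#' contact. More than three participating hydrogens is reported as a face
#' using the three closest to the plane (noted in `reason`).
#'
#' @param aa_moiety aromatic `moiety`.
#' @param sugar_moiety `deoxyribose` moiety.
#' @param criteria [validity_criteria()].
#' @param d_min optional precomputed closest heavy-atom distance.
#' @return object of class `sugar_pi_contact`: list with `valid`,
#'   `edge_class`, `atom_labels` (canonical-order string such as
#'   `"H1a-H2b"`), `d_min`, per-atom `geometry` (label, height, offset,
#'   ch_angle, participates) and `reason`.
#' @export
classify_sugar_contact <- function(aa_moiety, sugar_moiety,
                                   criteria = validity_criteria(),
                                   d_min = NULL) {
  lab <- label_sugar_atoms(sugar_moiety)
  pts <- as.matrix(lab[, c("x", "y", "z")])
  g <- face_geometry(pts, aa_moiety)
  n <- g$plane$normal
  # X-H directionality: angle between the X->H vector and the inward plane
  # perpendicular on the hydrogen's side
  ch_angle <- rep(NA_real_, nrow(lab))
  for (i in which(lab$element == "H")) {
    parent_xyz <- as.numeric(
      moiety_xyz(sugar_moiety, lab$parent[i]))
    u <- vunit(pts[i, ] - parent_xyz)
    n_side <- n * sign(g$height[i])
    ch_angle[i] <- acos(clamp1(sum(u * (-n_side)))) * DEG
  }
  part <- abs(g$height) <= criteria$sugar_max_height &
    g$offset <= criteria$sugar_max_lateral_offset &
    (lab$element != "H" | ch_angle <= criteria$sugar_ch_max_angle)
  geom <- data.frame(label = lab$label, height = g$height,
                     offset = g$offset, ch_angle = ch_angle,
                     participates = part, stringsAsFactors = FALSE)
  hs <- lab$label[part & lab$element == "H"]
  o4 <- any(part & lab$label == "O4'")
  reason <- ""
  if (length(hs) > 3L && !o4) {
    keep <- order(abs(g$height)[match(hs, lab$label)])[1:3]
    reason <- sprintf("%d participating hydrogens; classified as face using the 3 closest", length(hs))
    hs <- hs[sort(keep)]
  }
  cls <- if (o4 && length(hs) >= 1L) "lone_pair_proton"
    else if (o4) "lone_pair"
    else if (length(hs) == 1L) "single_proton"
    else if (length(hs) == 2L) "bridged"
    else if (length(hs) >= 3L) "face"
    else NA_character_
  labels <- c(hs, if (o4) "O4'")
  labels <- labels[order(match(labels, SUGAR_LABEL_ORDER))]
  if (is.null(d_min))
    d_min <- min_heavy_distance(moiety_screen_xyz(aa_moiety),
                                moiety_screen_xyz(sugar_moiety))
  structure(list(
    valid = !is.na(cls),
    edge_class = cls,
    atom_labels = if (is.na(cls)) "" else paste(labels, collapse = "-"),
    d_min = d_min, geometry = geom,
    reason = if (is.na(cls)) "no participating sugar atom" else reason),
    class = "sugar_pi_contact")
}

#' @export
print.sugar_pi_contact <- function(x, ...) {
  if (x$valid)
    cat(sprintf("sugar-pi contact: %s (%s), d_min %.2f A\n",
                x$edge_class, x$atom_labels, x$d_min))
  else cat("rejected sugar-pi candidate:", x$reason, "\n")
  invisible(x)
}

empty_pi_table <- function() data.frame(
  entry_id = character(0L), base_id = character(0L), aa_id = character(0L),
  base = character(0L), aa = character(0L), omega_deg = numeric(0L),
  d_min_angstrom = numeric(0L), category = character(0L),
  edge_role = character(0L), valid = logical(0L), reason = character(0L),
  stringsAsFactors = FALSE)

empty_sugar_table <- function() data.frame(
  entry_id = character(0L), sugar_id = character(0L), aa_id = character(0L),
  aa = character(0L), edge_class = character(0L), atom_labels = character(0L),
  d_min_angstrom = numeric(0L), valid = logical(0L), reason = character(0L),
  stringsAsFactors = FALSE)

#' Survey one structure for pi-pi and sugar-pi contacts
#'
#' Runs the whole per-structure procedure: moiety extraction, distance
#' screening, pi-pi validation + tilt/edge classification, and sugar-edge
#' classification. Candidates failing validation are kept as rows with
#' `valid = FALSE` and a reason.
#'
#' @param input path to a PDB file, or an atom table from [read_structure()].
#' @param criteria [validity_criteria()].
#' @param entry_id identifier written into the contact rows (defaults to the
#'   file base name).
#' @return list with data.frames `pi_pi` and `sugar_pi`, and the moiety
#'   `skipped` log.
#' @export
survey_structure <- function(input, criteria = validity_criteria(),
                             entry_id = NULL) {
  if (is.character(input) && length(input) == 1L) {
    if (is.null(entry_id))
      entry_id <- tools::file_path_sans_ext(basename(input))
    atoms <- read_structure(input)
  } else {
    atoms <- input
    if (is.null(entry_id)) entry_id <- "structure"
  }
  ex <- extract_moieties(atoms)
  cands <- screen_candidates(ex$moieties, criteria$cutoff)
  pis <- list(); sugars <- list()
  for (cand in cands) {
    if (cand$type == "pi_pi") {
      v <- validate_pi_pi(cand$aa, cand$partner, criteria)
      omega <- tilt_angle(ring_plane_of(cand$aa), ring_plane_of(cand$partner))
      role <- if (v$valid)
        assign_edge_role(cand$aa, cand$partner, omega, criteria) else ""
      pis[[length(pis) + 1L]] <- data.frame(
        entry_id = entry_id, base_id = cand$partner$id, aa_id = cand$aa$id,
        base = cand$partner$resid, aa = cand$aa$resid,
        omega_deg = omega, d_min_angstrom = cand$d_min,
        category = if (v$valid) classify_tilt(omega) else "",
        edge_role = role, valid = v$valid, reason = v$reason,
        stringsAsFactors = FALSE)
    } else {
      sc <- tryCatch(
        classify_sugar_contact(cand$aa, cand$partner, criteria, cand$d_min),
        error = function(e) structure(list(
          valid = FALSE, edge_class = NA_character_, atom_labels = "",
          d_min = cand$d_min, geometry = NULL,
          reason = conditionMessage(e)), class = "sugar_pi_contact"))
      sugars[[length(sugars) + 1L]] <- data.frame(
        entry_id = entry_id, sugar_id = cand$partner$id, aa_id = cand$aa$id,
        aa = cand$aa$resid,
        edge_class = if (sc$valid) sc$edge_class else "",
        atom_labels = sc$atom_labels,
        d_min_angstrom = sc$d_min, valid = sc$valid, reason = sc$reason,
        stringsAsFactors = FALSE)
    }
  }
  list(pi_pi = if (length(pis)) do.call(rbind, pis) else empty_pi_table(),
       sugar_pi = if (length(sugars)) do.call(rbind, sugars) else
         empty_sugar_table(),
       skipped = ex$skipped)
}

#' Survey a set of structures
#'
#' @param paths character vector of PDB files (sorted internally so results
#'   are independent of input order).
#' @param criteria [validity_criteria()].
#' @return list of combined `pi_pi` and `sugar_pi` contact tables, `skipped`
#'   log, and `n_structures`.
#' @export
scan_structures <- function(paths, criteria = validity_criteria()) {
  paths <- sort(paths)
  res <- lapply(paths, survey_structure, criteria = criteria)
  list(pi_pi = do.call(rbind, c(lapply(res, `[[`, "pi_pi"),
                                list(empty_pi_table()))),
       sugar_pi = do.call(rbind, c(lapply(res, `[[`, "sugar_pi"),
                                   list(empty_sugar_table()))),
       skipped = do.call(rbind, lapply(res, `[[`, "skipped")),
       n_structures = length(paths))
}
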