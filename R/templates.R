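# Idealized monomer templates: planar aromatic side chains and nucleobases,
# and a C2'-endo deoxyribose. These are synthetic, idealized geometries
# (regular polygons with standard bond lengths, sugar pucker from a
# pseudorotation-style out-of-plane pattern). They serve as construction
# material for the fixture generator and as overlay references for the
# QM model preparation; fidelity to any particular experimental geometry is
# not required for classifier testing.

regular_polygon <- function(n, side, start_angle = 90) {
  r <- side / (2 * sin(pi / n))
  th <- (start_angle - 360 * (seq_len(n) - 1L) / n) / DEG
  cbind(r * cos(th), r * sin(th), 0)
}

# Vertices of a regular n-gon whose first edge is A -> B, remaining vertices
# on the side of A->B away from `away_from` (a 2D/3D point, z ignored).
polygon_on_edge <- function(a, b, n, away_from) {
  r <- vnorm(b - a) / (2 * sin(pi / n))
  apo <- r * cos(pi / n)
  mid <- (a + b) / 2
  perp <- c(-(b - a)[2L], (b - a)[1L], 0)
  perp <- perp / vnorm(perp)
  c1 <- mid + apo * perp; c2 <- mid - apo * perp
  ctr <- if (vnorm(c1[1:2] - away_from[1:2]) >= vnorm(c2[1:2] - away_from[1:2]))
    c1 else c2
  step <- 360 / n
  # rotation direction taking a to b about ctr
  rot <- rotation_about_axis(c(0, 0, 1), step)
  sgn <- if (vnorm(as.numeric(rot %*% (a - ctr)) + ctr - b) < 1e-6) 1 else -1
  out <- matrix(0, n, 3L)
  v <- a - ctr
  for (k in seq_len(n)) {
    out[k, ] <- ctr + v
    v <- as.numeric(rotation_about_axis(c(0, 0, 1), sgn * step) %*% v)
  }
  out
}

radial_out <- function(pos, center, dist) {
  as.numeric(pos + dist * vunit(pos - center))
}

tmpl_df <- function(names, xyz) {
  data.frame(elety = names, elesy = element_of(names),
             x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
             stringsAsFactors = FALSE)
}

template_aa <- function(resid) {
  switch(resid,
    PHE = , TYR = {
      ring <- regular_polygon(6L, 1.39)
      ctr <- colMeans(ring)
      nm <- AA_RING$PHE
      xyz <- ring
      extra <- rbind(radial_out(ring[1L, ], ctr, 1.51))        # CB on CG
      enm <- "CB"
      if (resid == "TYR") {
        extra <- rbind(extra, radial_out(ring[4L, ], ctr, 1.36))  # OH on CZ
        enm <- c(enm, "OH")
      }
      tmpl_df(c(nm, enm), rbind(xyz, extra))
    },
    HIS = {
      ring <- regular_polygon(5L, 1.37)
      ctr <- colMeans(ring)
      tmpl_df(c(AA_RING$HIS, "CB"),
              rbind(ring, radial_out(ring[1L, ], ctr, 1.50)))
    },
    TRP = {
      hex <- regular_polygon(6L, 1.39)   # CD2, CE2, CZ2, CH2, CZ3, CE3
      hctr <- colMeans(hex)
      pent <- polygon_on_edge(hex[2L, ], hex[1L, ], 5L, hctr)  # CE2,CD2,CG,CD1,NE1
      pctr <- colMeans(pent)
      nm <- c("CD2", "CE2", "CZ2", "CH2", "CZ3", "CE3", "CG", "CD1", "NE1", "CB")
      xyz <- rbind(hex, pent[3:5, ], radial_out(pent[3L, ], pctr, 1.50))
      tmpl_df(nm, xyz)
    },
    stop("unknown aromatic residue: ", resid))
}

template_base <- function(resid) {
  if (resid %in% c("DC", "DT")) {
    ring <- regular_polygon(6L, 1.37)    # N1, C2, N3, C4, C5, C6
    ctr <- colMeans(ring)
    nm <- BASE_RING$DC
    if (resid == "DT") {
      extra <- rbind(radial_out(ring[2L, ], ctr, 1.23),  # O2
                     radial_out(ring[4L, ], ctr, 1.23),  # O4
                     radial_out(ring[5L, ], ctr, 1.50))  # C7 methyl
      enm <- c("O2", "O4", "C7")
    } else {
      extra <- rbind(radial_out(ring[2L, ], ctr, 1.23),  # O2
                     radial_out(ring[4L, ], ctr, 1.34))  # N4
      enm <- c("O2", "N4")
    }
    out <- tmpl_df(c(nm, enm), rbind(ring, extra))
    attr(out, "glycosidic") <- "N1"
    attr(out, "glyc_dir") <- vunit(ring[1L, ] - ctr)
  } else if (resid %in% c("DA", "DG")) {
    hex <- regular_polygon(6L, 1.37)     # N1, C2, N3, C4, C5, C6
    hctr <- colMeans(hex)
    pent <- polygon_on_edge(hex[5L, ], hex[4L, ], 5L, hctr)  # C5,C4,N9,C8,N7
    pctr <- colMeans(pent)
    nm <- c("N1", "C2", "N3", "C4", "C5", "C6", "N9", "C8", "N7")
    xyz <- rbind(hex, pent[3:5, ])
    if (resid == "DA") {
      xyz <- rbind(xyz, radial_out(hex[6L, ], hctr, 1.34))   # N6 on C6
      nm <- c(nm, "N6")
    } else {
      xyz <- rbind(xyz,
                   radial_out(hex[6L, ], hctr, 1.23),        # O6 on C6
                   radial_out(hex[2L, ], hctr, 1.34))        # N2 on C2
      nm <- c(nm, "O6", "N2")
    }
    out <- tmpl_df(nm, xyz)
    attr(out, "glycosidic") <- "N9"
    attr(out, "glyc_dir") <- vunit(pent[3L, ] - pctr)
  } else stop("unknown nucleotide: ", resid)
  out
}

# C2'-endo deoxyribose heavy atoms. Ring: near-regular pentagon with an
# out-of-plane twist (C2' displaced toward the C5' side); exocyclic atoms
# from internal coordinates with B-DNA-like torsions (gamma ~ +54 deg,
# delta ~ 140 deg).
template_sugar <- function(with_phosphorus = FALSE, glycosidic_n = "N1") {
  ring0 <- regular_polygon(5L, 1.42)           # C1', C2', C3', C4', O4'
  z <- c(-0.12, 0.32, -0.29, 0.10, -0.01)      # C2'-endo / C3'-exo twist
  ring <- ring0; ring[, 3L] <- z
  c1 <- ring[1L, ]; c2 <- ring[2L, ]; c3 <- ring[3L, ]
  c4 <- ring[4L, ]; o4 <- ring[5L, ]
  c5 <- place_internal(c3, o4, c4, 1.51, 116, 120)
  # pick the branch on the C2'-endo side (above the mean ring plane)
  if (c5[3L] < mean(z)) c5 <- place_internal(c3, o4, c4, 1.51, 116, -120)
  o5 <- place_internal(c3, c4, c5, 1.42, 110.5, 54)
  o3 <- place_internal(c5, c4, c3, 1.42, 110.0, 140)
  ng <- place_internal(c4, o4, c1, 1.48, 108, -120)
  nm <- c(SUGAR_RING, "C5'", "O5'", "O3'", glycosidic_n)
  xyz <- rbind(ring, c5, o5, o3, ng)
  if (with_phosphorus) {
    p5 <- place_internal(c4, c5, o5, 1.59, 119, -175)
    xyz <- rbind(xyz, p5)
    nm <- c(nm, "P")
  }
  tmpl_df(nm, xyz)
}

#' Idealized monomer template geometries
#'
#' Returns the package's built-in idealized (synthetic) heavy-atom template
#' for an aromatic amino-acid side chain, a nucleobase, or the C2'-endo
#' deoxyribose. Rings are regular polygons with standard bond lengths; these
#' templates stand in for externally optimized monomer geometries in
#' [overlay_reference()] and are the construction material of the fixture
#' generator.
#'
#' @param name one of `"PHE"`, `"TYR"`, `"TRP"`, `"HIS"`, `"DA"`, `"DC"`,
#'   `"DG"`, `"DT"`, `"deoxyribose"`.
#' @return data.frame with columns `elety`, `elesy`, `x`, `y`, `z`.
#' @export
monomer_template <- function(name) {
  name <- toupper(name)
  if (name %in% AROMATIC_AA) return(template_aa(name))
  if (name %in% NUCLEOTIDES) return(template_base(name))
  if (name %in% c("DEOXYRIBOSE", "SUGAR")) return(template_sugar())
  stop("no template for: ", name)
}
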