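# Shared helpers: random geometry, rigid motions applied to atom tables,
# and tiny inline PDB fixtures.

random_points <- function(n, scale = 10) {
  matrix(stats::runif(3L * n, -scale, scale), ncol = 3L)
}

rigid_move_atoms <- function(atoms, tf = pisurvey:::random_rigid_transform()) {
  m <- apply_transform(as.matrix(atoms[, c("x", "y", "z")]), tf)
  atoms$x <- m[, 1L]; atoms$y <- m[, 2L]; atoms$z <- m[, 3L]
  atoms
}

# minimal hand-written PDB records (fixed-width per the format spec)
pdb_atom_line <- function(serial, name, resid, chain, resno, x, y, z,
                          occ = 1, alt = " ", elem = substr(name, 1, 1)) {
  sprintf("ATOM  %5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, ifelse(nchar(name) < 4, paste0(" ", name), name),
          alt, resid, chain, resno, x, y, z, occ, 0, elem)
}

write_pdb_lines <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}

# hexagon of radius r in the z = 0 plane
hexagon_points <- function(r = 1.39) {
  th <- (0:5) * pi / 3
  cbind(r * cos(th), r * sin(th), 0)
}

write_fixture_structure <- function(atoms, path = tempfile(fileext = ".pdb")) {
  pisurvey::write_structure(atoms, path)
  path
}

manifest_key <- function(entry, partner, aa) paste(entry, partner, aa)
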