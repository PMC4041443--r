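# Coordinate input: PDB parsing (via bio3d), alternate-location and model
# resolution, dataset-manifest filtering, and extraction of the surveyed
# moieties through the fixed atom-name dictionaries.

#' Read a coordinate file into an atom table
#'
#' Parses a PDB file and resolves alternate locations and models to a single
#' deterministic conformer set: model 1 only, and for each alternate-location
#' group the conformer with the highest occupancy (ties broken by altloc
#' letter, "A" first). Waters and ions are irrelevant downstream and are kept
#' here; moiety extraction ignores them.
#'
#' @param path path to a PDB file.
#' @param altloc_policy `"occupancy"` (default, highest occupancy wins) or
#'   `"first"` (lowest altloc letter wins).
#' @return a data.frame of atoms with columns `elety` (atom name), `elesy`
#'   (element), `resid`, `chain`, `resno`, `insert`, `alt`, `x`, `y`, `z`,
#'   `o` (occupancy). Coordinates in Angstrom.
#' @export
read_structure <- function(path, altloc_policy = c("occupancy", "first")) {
  altloc_policy <- match.arg(altloc_policy)
  if (!file.exists(path)) stop("no such file: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("unparsable coordinate file '", path, "': ",
                             conditionMessage(e)))
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0L) stop("empty structure: ", path)
  atoms <- data.frame(
    elety = normalize_elety(at$elety),
    elesy = ifelse(is.na(at$elesy) | at$elesy == "",
                   element_of(at$elety), trimws(at$elesy)),
    resid = normalize_resid(at$resid),
    chain = ifelse(is.na(at$chain), " ", at$chain),
    resno = at$resno,
    insert = ifelse(is.na(at$insert), "", at$insert),
    alt = ifelse(is.na(at$alt), "", at$alt),
    x = at$x, y = at$y, z = at$z,
    o = ifelse(is.na(at$o), 1, at$o),
    stringsAsFactors = FALSE)
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite coordinates in ", path)
  resolve_altlocs(atoms, altloc_policy)
}

resolve_altlocs <- function(atoms, altloc_policy = "occupancy") {
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$resid,
               atoms$elety, sep = "\r")
  keep <- unlist(lapply(split(seq_len(nrow(atoms)), key), function(idx) {
    if (length(idx) == 1L) return(idx)
    sub <- atoms[idx, ]
    ord <- if (altloc_policy == "occupancy")
      order(-sub$o, sub$alt) else order(sub$alt)
    idx[ord[1L]]
  }), use.names = FALSE)
  out <- atoms[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write an atom table back to PDB
#'
#' @param atoms atom table as returned by [read_structure()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_structure <- function(atoms, path) {
  n <- nrow(atoms)
  bio3d::write.pdb(pdb = NULL, file = path,
                   xyz = as.numeric(t(as.matrix(atoms[, c("x", "y", "z")]))),
                   type = rep("ATOM", n),
                   resno = atoms$resno, resid = atoms$resid,
                   eleno = seq_len(n), elety = atoms$elety,
                   chain = atoms$chain,
                   insert = ifelse(atoms$insert == "", NA, atoms$insert),
                   o = atoms$o, b = rep(0, n), elesy = atoms$elesy)
  invisible(path)
}

#' Filter a dataset manifest to the survey selection
#'
#' Keeps X-ray entries with resolution strictly better (smaller) than
#' `max_resolution`, sequence identity below `max_identity` and release date
#' before `cutoff_date`.
#'
#' @param manifest data.frame with columns `entry_id`, `method`,
#'   `resolution`, `identity_cluster` (fraction or percent), `release_date`.
#' @param max_resolution Angstrom; default 2.0.
#' @param max_identity fraction; default 0.90.
#' @param method experimental method to keep (prefix-matched,
#'   case-insensitive); default X-ray.
#' @param cutoff_date keep entries released strictly before this date.
#' @return character vector of entry IDs, lexicographically sorted.
#' @export
select_dataset <- function(manifest, max_resolution = 2.0, max_identity = 0.90,
                           method = "X-ray", cutoff_date = "2011-05-24") {
  if (is.null(manifest) || nrow(manifest) == 0L) return(character(0L))
  meth <- toupper(gsub("[^A-Za-z]", "", manifest$method))
  want <- toupper(gsub("[^A-Za-z]", "", method))
  ident <- as.numeric(manifest$identity_cluster)
  ident <- ifelse(!is.na(ident) & ident > 1, ident / 100, ident)  # percent in
  keep <- startsWith(meth, want) &
    is.finite(manifest$resolution) & manifest$resolution < max_resolution &
    !is.na(ident) & ident < max_identity &
    as.Date(manifest$release_date) < as.Date(cutoff_date)
  sort(as.character(manifest$entry_id[keep & !is.na(keep)]))
}

moiety_id <- function(chain, resid, resno, insert = "") {
  sprintf("%s:%s%d%s", chain, resid, resno, insert)
}

new_moiety <- function(kind, resid, chain, resno, insert, atoms, ring,
                       exocyclic_present = character(0L)) {
  structure(list(kind = kind, resid = resid, chain = chain, resno = resno,
                 insert = insert, id = moiety_id(chain, resid, resno, insert),
                 atoms = atoms, ring = ring,
                 exocyclic_present = exocyclic_present),
            class = "moiety")
}

#' @export
print.moiety <- function(x, ...) {
  cat(sprintf("%s moiety %s (%d atoms, ring of %d)\n",
              x$kind, x$id, nrow(x$atoms), length(x$ring)))
  invisible(x)
}

moiety_xyz <- function(m, names = NULL) {
  a <- m$atoms
  if (!is.null(names)) a <- a[match(names, a$elety), , drop = FALSE]
  as.matrix(a[, c("x", "y", "z")])
}

# heavy atoms of the moiety used for the distance screen: ring plus present
# exocyclic substituents (for sugars: C5' but not O5'/O3'/P, which belong to
# the backbone rather than the sugar edge)
moiety_screen_xyz <- function(m) {
  nm <- c(m$ring, if (m$kind == "deoxyribose") "C5'" else m$exocyclic_present)
  nm <- intersect(nm, m$atoms$elety)
  moiety_xyz(m, nm)
}

#' Extract surveyed moieties from an atom table
#'
#' Walks the residues of one model and instantiates every complete aromatic
#' amino-acid ring, nucleobase ring and deoxyribose unit per the fixed
#' dictionaries ([moiety_definitions()]). Residues missing ring atoms are
#' skipped with a reason rather than raising. RNA residues, waters and ions
#' are ignored. Modified/damaged nucleobases are not recognized unless their
#' residue names are supplied via `extra_base_residues`.
#'
#' @param atoms atom table from [read_structure()].
#' @param extra_base_residues optional character vector of additional residue
#'   names to treat as nucleotides (ring set chosen by atom presence).
#' @return list with `moieties` (list of `moiety` objects) and `skipped`
#'   (data.frame `id`, `kind`, `reason`).
#' @export
extract_moieties <- function(atoms, extra_base_residues = character(0L)) {
  moieties <- list()
  skipped <- list()
  add_skip <- function(id, kind, reason)
    skipped[[length(skipped) + 1L]] <<- data.frame(
      id = id, kind = kind, reason = reason, stringsAsFactors = FALSE)
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$resid, sep = "\r")
  for (idx in split(seq_len(nrow(atoms)), factor(key, unique(key)))) {
    res <- atoms[idx, , drop = FALSE]
    resid <- res$resid[1L]
    chain <- res$chain[1L]; resno <- res$resno[1L]; insert <- res$insert[1L]
    id <- moiety_id(chain, resid, resno, insert)
    if (resid %in% AROMATIC_AA) {
      ring <- AA_RING[[resid]]
      if (all(ring %in% res$elety)) {
        exo <- intersect(AA_EXOCYCLIC[[resid]], res$elety)
        moieties[[length(moieties) + 1L]] <-
          new_moiety("aromatic_aa_ring", resid, chain, resno, insert,
                     res, ring, exo)
      } else {
        add_skip(id, "aromatic_aa_ring",
                 paste("missing ring atoms:",
                       paste(setdiff(ring, res$elety), collapse = ",")))
      }
    } else if (resid %in% NUCLEOTIDES ||
               resid %in% extra_base_residues) {
      base_res <- if (resid %in% NUCLEOTIDES) resid else
        if (all(BASE_RING$DA %in% res$elety)) "DA" else "DC"
      ring <- BASE_RING[[base_res]]
      if (all(ring %in% res$elety)) {
        exo <- intersect(BASE_EXOCYCLIC[[base_res]], res$elety)
        moieties[[length(moieties) + 1L]] <-
          new_moiety("nucleobase_ring", resid, chain, resno, insert,
                     res, ring, exo)
      } else {
        add_skip(id, "nucleobase_ring",
                 paste("missing ring atoms:",
                       paste(setdiff(ring, res$elety), collapse = ",")))
      }
      if (all(SUGAR_RING %in% res$elety)) {
        exo <- intersect(c(SUGAR_EXOCYCLIC, "P"), res$elety)
        moieties[[length(moieties) + 1L]] <-
          new_moiety("deoxyribose", resid, chain, resno, insert,
                     res, SUGAR_RING, exo)
      } else if (any(SUGAR_RING %in% res$elety)) {
        add_skip(id, "deoxyribose",
                 paste("missing ring atoms:",
                       paste(setdiff(SUGAR_RING, res$elety), collapse = ",")))
      }
    }
  }
  list(moieties = moieties,
       skipped = if (length(skipped)) do.call(rbind, skipped) else
         data.frame(id = character(0L), kind = character(0L),
                    reason = character(0L), stringsAsFactors = FALSE))
}

#' Write a skip log
#' @param skipped the `skipped` component of [extract_moieties()].
#' @param path output text file (one line per skipped moiety).
#' @return `path`, invisibly.
#' @export
write_skip_log <- function(skipped, path) {
  writeLines(sprintf("%s\t%s\t%s", skipped$id, skipped$kind, skipped$reason),
             path)
  invisible(path)
}
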