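#' @importFrom rlang .data abort warn
#' @importFrom tibble tibble as_tibble
NULL

# Bondi (1964) van der Waals radii, Angstrom. Pinned so SASA is reproducible.
.bondi_radii <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
  P = 1.80, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98,
  SE = 1.90, ZN = 1.39, FE = 1.40, MG = 1.73, CA = 2.31,
  `NA` = 2.27, K = 2.75
)

# Standard atomic masses (u), used for mass-weighted Rg.
.atomic_masses <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
  P = 30.974, F = 18.998, CL = 35.45, BR = 79.904, I = 126.904,
  SE = 78.971, ZN = 65.38, FE = 55.845, MG = 24.305, CA = 40.078,
  `NA` = 22.990, K = 39.098
)

#' Van der Waals radius lookup
#'
#' Returns the pinned Bondi radius for each element symbol. Unknown elements
#' fall back to the carbon radius (1.70 Angstrom) with a warning, so that
#' SASA stays computable on unusual atoms while remaining reproducible.
#'
#' @param element character vector of element symbols (e.g. "C", "N", "FE").
#' @return numeric vector of radii in Angstrom.
#' @export
vdw_radius <- function(element) {
  key <- toupper(element)
  r <- .bondi_radii[key]
  if (anyNA(r)) {
    bad <- unique(key[is.na(r)])
    warn(paste0("unknown element(s) ", paste(bad, collapse = ", "),
                "; using carbon radius 1.70 A"))
    r[is.na(r)] <- 1.70
  }
  unname(r)
}

.guess_element <- function(name, elesy) {
  el <- toupper(trimws(elesy))
  miss <- is.na(el) | el == ""
  if (any(miss)) {
    # strip digits, take the leading alphabetic run of the atom name
    nm <- gsub("[^A-Za-z]", "", name[miss])
    two <- toupper(substr(nm, 1, 2))
    one <- toupper(substr(nm, 1, 1))
    el[miss] <- ifelse(two %in% names(.bondi_radii) &
                         !(one %in% c("C", "N", "O", "H", "S", "P")),
                       two, one)
  }
  el
}

#' Build a topology from an atom table
#'
#' The topology is the fixed part of a trajectory: atom identities, residue
#' bookkeeping (author numbering preserved), per-residue backbone indices and
#' a completeness flag used by the DSSP stage.
#'
#' @param atoms a data frame with columns `serial`, `name`, `element`,
#'   `resid`, `resname`, `chain`; optionally `occupancy`.
#' @return an object of class `topology`: a list with `atoms` (tibble,
#'   including a `vdw_radius` column), `residues` (tibble with per-residue
#'   `complete` flag) and `backbone` (list of named index vectors N/CA/C/O,
#'   `NA` where absent).
#' @export
topology <- function(atoms) {
  atoms <- as_tibble(atoms)
  need <- c("serial", "name", "element", "resid", "resname", "chain")
  missing_cols <- setdiff(need, names(atoms))
  if (length(missing_cols) > 0) {
    abort(paste("atom table lacks columns:", paste(missing_cols, collapse = ", ")))
  }
  atoms$vdw_radius <- vdw_radius(atoms$element)
  key <- paste(atoms$chain, atoms$resid, sep = "|")
  ukey <- unique(key)
  ord <- match(ukey, key)
  residues <- tibble(
    chain = atoms$chain[ord],
    resid = atoms$resid[ord],
    resname = atoms$resname[ord]
  )
  backbone <- lapply(ukey, function(k) {
    idx <- which(key == k)
    nm <- atoms$name[idx]
    c(N = idx[match("N", nm)], CA = idx[match("CA", nm)],
      C = idx[match("C", nm)], O = idx[match("O", nm)])
  })
  residues$complete <- vapply(backbone, function(b) !anyNA(b), logical(1))
  # author numbering must be monotone non-decreasing within a chain
  for (ch in unique(residues$chain)) {
    r <- residues$resid[residues$chain == ch]
    if (is.unsorted(r)) abort(paste0("residue numbering not monotone in chain ", ch))
  }
  structure(list(atoms = atoms, residues = residues, backbone = backbone),
            class = "topology")
}

#' @export
print.topology <- function(x, ...) {
  cat("<topology> ", nrow(x$atoms), " atoms, ", nrow(x$residues),
      " residues (", sum(x$residues$complete), " with complete backbone)\n",
      sep = "")
  invisible(x)
}

n_atoms <- function(top) nrow(top$atoms)

#' Construct a trajectory object
#'
#' A trajectory couples a fixed topology with an ordered set of coordinate
#' frames stored as an `n_frames x 3*n_atoms` matrix (columns x1,y1,z1,x2,...),
#' the layout used throughout the package.
#'
#' @param top a [topology()].
#' @param xyz numeric matrix, `n_frames` rows by `3 * n_atoms` columns, in
#'   Angstrom.
#' @param dt frame spacing in ps (default 100, a typical save interval).
#' @param label condition name, e.g. `"wild"` or `"T46I"`.
#' @param replicate integer replicate index.
#' @param ref_xyz optional reference coordinates (length `3 * n_atoms`), used
#'   by [rmsd_series()] when `reference = "input_structure"`.
#' @return an object of class `trajectory`.
#' @export
trajectory <- function(top, xyz, dt = 100, label = "traj", replicate = 1L,
                       ref_xyz = NULL) {
  if (!inherits(top, "topology")) abort("`top` must be a topology")
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L * n_atoms(top)) {
    abort(sprintf("coordinate width %d does not match 3 x %d atoms",
                  ncol(xyz), n_atoms(top)))
  }
  if (!all(is.finite(xyz))) abort("non-finite coordinates")
  if (dt <= 0) abort("dt must be positive")
  structure(list(topology = top, xyz = xyz, dt = dt, label = label,
                 replicate = as.integer(replicate), ref_xyz = ref_xyz),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory> '", x$label, "' replicate ", x$replicate, ": ",
      nrow(x$xyz), " frames x ", n_atoms(x$topology), " atoms, dt = ",
      x$dt, " ps\n", sep = "")
  invisible(x)
}

n_frames <- function(traj) nrow(traj$xyz)

# frame i as an n_atoms x 3 matrix
frame_coords <- function(traj, i) {
  matrix(traj$xyz[i, ], ncol = 3, byrow = TRUE)
}

xyz_to_coords <- function(v) matrix(v, ncol = 3, byrow = TRUE)
coords_to_xyz <- function(m) as.numeric(t(m))

.atoms_from_bio3d <- function(at) {
  tibble(
    serial = as.integer(at$eleno),
    name = trimws(at$elety),
    element = .guess_element(trimws(at$elety), at$elesy),
    resid = as.integer(at$resno),
    resname = trimws(at$resid),
    chain = ifelse(is.na(at$chain) | at$chain == "", "A", at$chain),
    occupancy = ifelse(is.na(at$o), 1, as.numeric(at$o))
  )
}

#' Read a structure file
#'
#' Parses a PDB file into a [topology()] plus the first coordinate frame.
#' Alternate locations are collapsed to the highest-occupancy copy (ties keep
#' the first). Insertion codes are rejected. Non-protein records (waters,
#' ions, ligands) are dropped by default. Residues missing any of N, CA, C, O
#' are flagged incomplete with a warning; the DSSP stage assigns them "-".
#'
#' @param path PDB file path.
#' @param strip_nonprotein drop non-protein atoms (default TRUE).
#' @return list with elements `topology` and `xyz` (first frame, length
#'   `3 * n_atoms`).
#' @export
read_structure <- function(path, strip_nonprotein = TRUE) {
  if (!file.exists(path)) abort(paste("file not found:", path))
  pdb <- bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)
  at <- pdb$atom
  if (strip_nonprotein) {
    keep <- bio3d::atom.select(pdb, "protein", verbose = FALSE)$atom
    at <- at[keep, , drop = FALSE]
  }
  if (nrow(at) == 0) abort("no (protein) atoms in file")
  if (any(!is.na(at$insert) & at$insert != "")) {
    abort("insertion codes are not supported")
  }
  # altloc: highest occupancy wins within (chain, resno, atom name)
  alt <- !is.na(at$alt) & at$alt != ""
  if (any(alt)) {
    key <- paste(at$chain, at$resno, at$elety, sep = "|")
    occ <- ifelse(is.na(at$o), 1, at$o)
    ord <- order(key, -occ)
    at <- at[ord[!duplicated(key[ord])], , drop = FALSE]
    at <- at[order(at$eleno), , drop = FALSE]
  }
  atoms <- .atoms_from_bio3d(at)
  top <- topology(atoms)
  if (!all(top$residues$complete)) {
    inc <- top$residues[!top$residues$complete, ]
    warn(paste0("residue(s) with incomplete backbone: ",
                paste(paste0(inc$chain, ":", inc$resid), collapse = ", ")))
  }
  list(topology = top, xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))))
}

#' Read a coordinate trajectory
#'
#' Supports multi-model PDB and DCD. The atom count of every frame must equal
#' the topology's; a mismatch is an error naming both counts. XTC is not
#' supported by any available reader and raises an informative error.
#'
#' @param path trajectory file.
#' @param top the [topology()] the frames belong to.
#' @param format `"auto"` (by extension), `"pdb"` or `"dcd"`.
#' @param dt frame spacing in ps (headers of these formats do not reliably
#'   carry a physical time step).
#' @inheritParams trajectory
#' @return a [trajectory()].
#' @export
read_trajectory <- function(path, top, format = c("auto", "pdb", "dcd", "xtc"),
                            dt = 100, label = "traj", replicate = 1L) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("dcd")) "dcd" else if (ext == "xtc") "xtc" else "pdb"
  }
  if (format == "xtc") {
    abort("XTC reading is not supported; convert to DCD or multi-model PDB")
  }
  xyz <- if (format == "dcd") {
    unclass(bio3d::read.dcd(path, verbose = FALSE))
  } else {
    pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
    m <- pdb$xyz
    if (is.null(dim(m))) m <- matrix(m, nrow = 1)
    unclass(m)
  }
  expect <- 3L * n_atoms(top)
  if (ncol(xyz) != expect) {
    abort(sprintf("atom-count mismatch: topology has %d atoms (%d coords), trajectory frames have %d coords",
                  n_atoms(top), expect, ncol(xyz)))
  }
  trajectory(top, xyz, dt = dt, label = label, replicate = replicate)
}

#' Write a trajectory as a multi-model PDB
#'
#' @param traj a [trajectory()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectory_pdb <- function(traj, path) {
  at <- traj$topology$atoms
  bio3d::write.pdb(
    file = path,
    xyz = traj$xyz,
    type = rep("ATOM", nrow(at)),
    eleno = at$serial,
    elety = at$name,
    resid = at$resname,
    chain = at$chain,
    resno = at$resid,
    elesy = at$element
  )
  invisible(path)
}

#' Write a trajectory in DCD format
#'
#' Emits a CHARMM-style binary DCD (little-endian, 32-bit float
#' coordinates, Fortran record framing). Single precision limits the
#' round-trip accuracy to roughly 1e-5 Angstrom at protein-scale
#' coordinates.
#'
#' @inheritParams write_trajectory_pdb
#' @export
write_trajectory_dcd <- function(traj, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  rec <- function(payload_writer, nbytes) {
    writeBin(as.integer(nbytes), con, size = 4, endian = "little")
    payload_writer()
    writeBin(as.integer(nbytes), con, size = 4, endian = "little")
  }
  nf <- n_frames(traj); na <- n_atoms(traj$topology)
  icntrl <- integer(20)
  icntrl[1] <- nf           # frames
  icntrl[2] <- 1L           # first step
  icntrl[3] <- 1L           # save interval
  icntrl[4] <- nf
  icntrl[20] <- 24L         # CHARMM version stamp
  rec(function() {
    writeChar("CORD", con, nchars = 4, eos = NULL)
    writeBin(icntrl, con, size = 4, endian = "little")
  }, 84)
  title <- formatC("written by mdcompare", width = -80)
  rec(function() {
    writeBin(1L, con, size = 4, endian = "little")
    writeChar(title, con, nchars = 80, eos = NULL)
  }, 84)
  rec(function() writeBin(as.integer(na), con, size = 4, endian = "little"), 4)
  for (i in seq_len(nf)) {
    co <- frame_coords(traj, i)
    for (ax in 1:3) {
      rec(function() writeBin(as.numeric(co[, ax]), con, size = 4,
                              endian = "little"), 4 * na)
    }
  }
  invisible(path)
}

#' Write a single structure (one frame) as PDB
#'
#' @param top a [topology()].
#' @param xyz coordinates, length `3 * n_atoms`.
#' @param path output file.
#' @export
write_structure <- function(top, xyz, path) {
  at <- top$atoms
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(xyz),
    type = rep("ATOM", nrow(at)),
    eleno = at$serial,
    elety = at$name,
    resid = at$resname,
    chain = at$chain,
    resno = at$resid,
    elesy = at$element
  )
  invisible(path)
}
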