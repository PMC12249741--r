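#' Synthetic trajectory generators
#'
#' These generators plant known statistical structure (inter-residue
#' correlation blocks, metastable basins with set occupancies, ideal
#' secondary-structure geometry) so that every downstream analysis stage has
#' a ground-truth recovery test without any external data. All generators
#' are seed-deterministic: the same seed yields bitwise-identical output.
#'
#' @name synthetic
NULL

# A compact non-collinear Calpha reference trace: a coarse helix with
# ~3.8 A between consecutive residues. Used by the Calpha-only generators.
ca_reference <- function(n_residues) {
  t <- seq_len(n_residues)
  step <- 100 * pi / 180
  cbind(2.3 * cos(step * t), 2.3 * sin(step * t), 1.63 * t)
}

#' Unweighted radius of gyration of the synthetic reference trace
#'
#' Basin centres in a [basin_spec()] are targets in the (RMSD, Rg) plane;
#' feasible Rg targets sit near this value (the breathing mode scales the
#' trace, and scaling by `s` alone already costs `|s - 1| * reference_rg`
#' of the RMSD budget).
#'
#' @param n_residues chain length.
#' @return Rg of the reference trace, Angstrom.
#' @export
reference_rg <- function(n_residues) {
  ref <- ca_reference(n_residues)
  refc <- sweep(ref, 2, colMeans(ref))
  sqrt(mean(rowSums(refc^2)))
}

ca_topology <- function(n_residues, chain = "A") {
  topology(tibble::tibble(
    serial = seq_len(n_residues),
    name = "CA",
    element = "C",
    resid = seq_len(n_residues),
    resname = "ALA",
    chain = chain
  ))
}

#' Specification of planted inter-residue correlations
#'
#' Defines a target residue-residue correlation matrix: unit diagonal plus
#' rectangular blocks of constant signed correlation. Positive-semidefinitenes
#' of the target is checked at build time.
#'
#' @param n_residues chain length.
#' @param blocks list of blocks, each `list(a = c(lo, hi), b = c(lo, hi),
#'   sign = +1 or -1, strength = value in (0, 1])`.
#' @param base_amplitude per-coordinate fluctuation SD, Angstrom.
#' @param seed RNG seed.
#' @param amplitudes optional per-residue amplitude multipliers (length
#'   `n_residues`), for planting high-mobility regions.
#' @return object of class `planted_cov_spec` carrying the validated target
#'   correlation matrix.
#' @export
planted_cov_spec <- function(n_residues, blocks = list(), base_amplitude = 1,
                             seed = 1L, amplitudes = NULL) {
  R <- diag(n_residues)
  for (bi in seq_along(blocks)) {
    b <- blocks[[bi]]
    if (any(c(b$a, b$b) < 1) || any(c(b$a, b$b) > n_residues)) {
      rlang::abort(sprintf("block %d outside [1, %d]", bi, n_residues))
    }
    if (abs(b$sign) != 1 || b$strength <= 0 || b$strength > 1) {
      rlang::abort(sprintf("block %d: sign must be +/-1, strength in (0,1]", bi))
    }
    ia <- seq(b$a[1], b$a[2]); ib <- seq(b$b[1], b$b[2])
    R[ia, ib] <- b$sign * b$strength
    R[ib, ia] <- b$sign * b$strength
  }
  diag(R) <- 1
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) {
    # identify a culpable block by removing each in turn
    for (bi in seq_along(blocks)) {
      R2 <- planted_cov_spec(n_residues, blocks[-bi], base_amplitude, seed,
                             amplitudes = NULL)$target
      if (min(eigen(R2, symmetric = TRUE, only.values = TRUE)$values) >= -1e-10) {
        rlang::abort(sprintf("target correlation not positive semidefinite; block %d is implicated", bi))
      }
    }
    rlang::abort("target correlation matrix is not positive semidefinite")
  }
  if (!is.null(amplitudes) && length(amplitudes) != n_residues) {
    rlang::abort("amplitudes must have one entry per residue")
  }
  structure(list(n_residues = n_residues, blocks = blocks, target = R,
                 base_amplitude = base_amplitude, seed = as.integer(seed),
                 amplitudes = amplitudes),
            class = "planted_cov_spec")
}

#' Generate a Calpha trajectory with planted correlations
#'
#' Frames are the reference trace plus zero-mean Gaussian displacements whose
#' population residue-residue correlation equals the spec's target exactly
#' (each Cartesian axis is sampled independently with covariance
#' `amplitude^2 * target`, so displacement-vector correlations equal the
#' target entries).
#'
#' @param spec a [planted_cov_spec()].
#' @param n_frames number of frames; fewer than `10 * n_residues` triggers a
#'   sampling-noise warning.
#' @param dt frame spacing, ps.
#' @return a Calpha-only [trajectory()] labelled `"synthetic-correlated"`.
#' @export
make_correlated_trajectory <- function(spec, n_frames, dt = 100) {
  stopifnot(inherits(spec, "planted_cov_spec"))
  n <- spec$n_residues
  if (n_frames < 10 * n) {
    rlang::warn("n_frames < 10 * n_residues: sample correlations will be noisy")
  }
  ref <- ca_reference(n)
  amp <- spec$base_amplitude
  if (!is.null(spec$amplitudes)) amp <- amp * spec$amplitudes
  U <- chol(spec$target + diag(1e-9, n))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  xyz <- matrix(0, n_frames, 3 * n)
  for (axis in 1:3) {
    Z <- matrix(stats::rnorm(n_frames * n), n_frames, n)
    D <- Z %*% U                                     # cov = target
    D <- sweep(D, 2, rep_len(amp, n), "*")
    xyz[, seq(axis, 3 * n, by = 3)] <- sweep(D, 2, ref[, axis], "+")
  }
  top <- ca_topology(n)
  trajectory(top, xyz, dt = dt, label = "synthetic-correlated",
             ref_xyz = coords_to_xyz(ref))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Specification of planted free-energy basins
#'
#' Each basin is a metastable state with a target position in the
#' (RMSD-to-reference, Rg) plane, a stationary occupancy and a mean dwell
#' time in frames. State switching follows a hidden Markov chain whose
#' stationary distribution equals `occupancies`.
#'
#' @param centers matrix or list of `(rmsd, rg)` targets, Angstrom.
#' @param occupancies probability vector, one entry per centre, summing to 1.
#' @param dwell mean frames per visit.
#' @param seed RNG seed.
#' @return object of class `basin_spec`.
#' @export
basin_spec <- function(centers, occupancies = NULL, dwell = 50, seed = 1L) {
  if (is.list(centers)) centers <- do.call(rbind, centers)
  centers <- matrix(as.numeric(centers), ncol = 2)
  k <- nrow(centers)
  if (is.null(occupancies)) occupancies <- rep(1 / k, k)
  if (length(occupancies) != k || abs(sum(occupancies) - 1) > 1e-8 ||
      any(occupancies <= 0)) {
    rlang::abort("occupancies must be positive and sum to 1")
  }
  if (anyDuplicated(round(centers, 6))) rlang::abort("basin centres must be distinct")
  if (any(centers[, 2] <= 0)) rlang::abort("target Rg must be positive")
  structure(list(centers = centers, occupancies = occupancies,
                 dwell = dwell, seed = as.integer(seed)),
            class = "basin_spec")
}

#' Generate a multi-basin trajectory
#'
#' Conformations are produced from two analytic modes: a breathing mode
#' (uniform radial scaling about the centroid, which sets Rg) and a fixed
#' random displacement field orthogonal to it (which sets the remaining
#' RMSD), plus small isotropic noise. The (RMSD-to-reference, Rg)
#' coordinates of each frame therefore concentrate at the active basin's
#' centre. An Rg centre implying a negative residual RMSD budget is
#' geometrically unreachable and raises an error.
#'
#' @param spec a [basin_spec()].
#' @param n_frames number of frames (should be much larger than
#'   `n_basins * dwell`).
#' @param n_residues chain length of the synthetic Calpha trace.
#' @param noise_sd per-coordinate isotropic noise SD, Angstrom.
#' @param spread SD of the per-frame scatter of each basin's (RMSD, Rg)
#'   around its centre, Angstrom; gives basins a smooth footprint on the
#'   landscape instead of a delta spike.
#' @param dt frame spacing, ps.
#' @return a Calpha-only [trajectory()] with the reference structure stored
#'   in `ref_xyz` and the hidden state sequence in attribute `states`.
#' @export
make_basin_trajectory <- function(spec, n_frames, n_residues = 40,
                                  noise_sd = 0.02, spread = 0.08, dt = 100) {
  stopifnot(inherits(spec, "basin_spec"))
  k <- nrow(spec$centers)
  ref <- ca_reference(n_residues)
  cen <- colMeans(ref)
  refc <- sweep(ref, 2, cen)
  rg0 <- sqrt(mean(rowSums(refc^2)))           # unweighted Rg of the trace
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  # displacement field: Gaussian, centred per axis, orthogonalised against
  # the breathing mode and the three infinitesimal rotations, unit RMS
  D <- matrix(stats::rnorm(3 * n_residues), n_residues, 3)
  D <- sweep(D, 2, colMeans(D))
  base <- list(refc)
  rot_gen <- list(cbind(-refc[, 2], refc[, 1], 0),
                  cbind(-refc[, 3], 0, refc[, 1]),
                  cbind(0, -refc[, 3], refc[, 2]))
  for (g in c(base, rot_gen)) {
    gn <- sum(g * g)
    if (gn > 1e-12) D <- D - g * (sum(D * g) / gn)
  }
  D <- D / sqrt(mean(rowSums(D^2)))            # RMS displacement 1 A
  # per-basin mode amplitudes
  s <- spec$centers[, 2] / rg0                 # radial scale factors
  rmsd_radial <- abs(s - 1) * rg0
  resid2 <- spec$centers[, 1]^2 - rmsd_radial^2
  if (any(resid2 < -1e-9)) {
    bad <- which(resid2 < -1e-9)[1]
    rlang::abort(sprintf(
      "basin %d unreachable: Rg target %.2f A alone forces RMSD %.2f A > target %.2f A",
      bad, spec$centers[bad, 2], rmsd_radial[bad], spec$centers[bad, 1]))
  }
  a <- sqrt(pmax(resid2, 0))
  # Markov chain with stationary distribution = occupancies
  p_switch <- min(1, 1 / spec$dwell)
  states <- integer(n_frames)
  states[1] <- sample.int(k, 1, prob = spec$occupancies)
  if (n_frames > 1) {
    u <- stats::runif(n_frames)
    draw <- sample.int(k, n_frames, replace = TRUE, prob = spec$occupancies)
    for (t in 2:n_frames) {
      states[t] <- if (u[t] < p_switch) draw[t] else states[t - 1]
    }
  }
  # scatter each frame's target reaction coordinates around its centre,
  # then assemble all frames in one set of outer products
  rt <- spec$centers[states, 1] + stats::rnorm(n_frames, sd = spread)
  gt <- pmax(spec$centers[states, 2] + stats::rnorm(n_frames, sd = spread), 1e-3)
  s_t <- gt / rg0
  a_t <- sqrt(pmax(rt^2 - ((s_t - 1) * rg0)^2, 0))
  f_ref <- coords_to_xyz(refc)
  f_D <- coords_to_xyz(D)
  xyz <- outer(s_t, f_ref) + outer(a_t, f_D) +
    matrix(rep(cen, n_residues), n_frames, 3 * n_residues, byrow = TRUE) +
    matrix(stats::rnorm(n_frames * 3 * n_residues, sd = noise_sd),
           n_frames, 3 * n_residues)
  top <- ca_topology(n_residues)
  out <- trajectory(top, xyz, dt = dt, label = "synthetic-basins",
                    ref_xyz = coords_to_xyz(ref))
  attr(out, "states") <- states
  out
}

#' Specification of an ideal-geometry fixture
#'
#' @param kind `"alpha_helix"`, `"beta_hairpin"` or `"coil"`.
#' @param length number of residues (>= 4 for a helix, >= 6 for a hairpin).
#' @param phi,psi backbone dihedrals in degrees; defaults depend on `kind`.
#'   Scalars set a uniform geometry; vectors of length `length` give full
#'   per-residue control (e.g. a helical stretch inside a coil). For
#'   `beta_hairpin` scalars set the strand dihedrals around the built-in
#'   turn.
#' @param seed seed for the `"coil"` dihedral draw.
#' @return object of class `ideal_geometry_spec`.
#' @export
ideal_geometry_spec <- function(kind = c("alpha_helix", "beta_hairpin", "coil"),
                                length = 12, phi = NULL, psi = NULL,
                                seed = 1L) {
  kind <- match.arg(kind)
  if (kind == "alpha_helix" && length < 4) rlang::abort("helix needs length >= 4")
  if (kind == "beta_hairpin" && length < 6) rlang::abort("hairpin needs length >= 6")
  if (is.null(phi)) phi <- switch(kind, alpha_helix = -57, beta_hairpin = -139, coil = NA)
  if (is.null(psi)) psi <- switch(kind, alpha_helix = -47, beta_hairpin = 135, coil = NA)
  structure(list(kind = kind, length = as.integer(length), phi = phi,
                 psi = psi, seed = as.integer(seed)),
            class = "ideal_geometry_spec")
}

# place atom d given a, b, c and internal coordinates (NeRF construction)
place_atom <- function(a, b, c, bond, angle_deg, dihedral_deg) {
  ang <- angle_deg * pi / 180
  dih <- dihedral_deg * pi / 180
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- pracma_cross(ab, bc); n <- n / sqrt(sum(n^2))
  m <- pracma_cross(n, bc)
  d2 <- c(-bond * cos(ang), bond * sin(ang) * cos(dih), bond * sin(ang) * sin(dih))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3], u[1] * v[2] - u[2] * v[1])
}

# build an N/CA/C/O backbone from phi/psi vectors (omega fixed at 180)
build_backbone <- function(phi, psi) {
  n <- length(phi)
  # ideal geometry (Engh-Huber-like values)
  bNCA <- 1.458; bCAC <- 1.525; bCN <- 1.329; bCO <- 1.231
  aNCAC <- 111.2; aCACN <- 116.2; aCNCA <- 121.7; aCACO <- 120.8
  N <- matrix(0, n, 3); CA <- matrix(0, n, 3); C <- matrix(0, n, 3)
  O <- matrix(0, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(bNCA, 0, 0)
  ang <- aNCAC * pi / 180
  C[1, ] <- CA[1, ] + c(-bCAC * cos(ang), bCAC * sin(ang), 0)
  # rebuild C1 using phi[1] against a virtual previous C
  virtC <- c(-cos(aCNCA * pi / 180) * bCN, -sin(aCNCA * pi / 180) * bCN, 0)
  C[1, ] <- place_atom(virtC, N[1, ], CA[1, ], bCAC, aNCAC, phi[1])
  for (i in seq_len(n - 1)) {
    N[i + 1, ] <- place_atom(N[i, ], CA[i, ], C[i, ], bCN, aCACN, psi[i])
    CA[i + 1, ] <- place_atom(CA[i, ], C[i, ], N[i + 1, ], bNCA, aCNCA, 180)
    C[i + 1, ] <- place_atom(C[i, ], N[i + 1, ], CA[i + 1, ], bCAC, aNCAC, phi[i + 1])
  }
  for (i in seq_len(n)) {
    # carbonyl O anti to the next N (dihedral psi + 180 about N-CA-C)
    O[i, ] <- place_atom(N[i, ], CA[i, ], C[i, ], bCO, aCACO, psi[i] + 180)
  }
  list(N = N, CA = CA, C = C, O = O)
}

#' Build an ideal-geometry structure
#'
#' Constructs a full N/CA/C/O backbone from ideal bond lengths and angles at
#' the requested dihedrals: a canonical alpha helix, a two-strand antiparallel
#' beta hairpin joined by a tight turn, or an irregular coil whose dihedrals
#' are drawn away from the helical and strand regions.
#'
#' @param spec an [ideal_geometry_spec()].
#' @return list with `topology` and `xyz` (one frame), as [read_structure()].
#' @export
make_ideal_structure <- function(spec) {
  stopifnot(inherits(spec, "ideal_geometry_spec"))
  n <- spec$length
  if (length(spec$phi) == n && length(spec$psi) == n && !anyNA(spec$phi)) {
    phi <- spec$phi; psi <- spec$psi
  } else if (spec$kind == "alpha_helix") {
    phi <- rep(spec$phi, n); psi <- rep(spec$psi, n)
  } else if (spec$kind == "beta_hairpin") {
    half <- floor((n - 2) / 2)
    phi <- rep(spec$phi, n); psi <- rep(spec$psi, n)
    # type II' turn at the two central residues
    t1 <- half + 1; t2 <- half + 2
    phi[t1] <- 60;  psi[t1] <- -120
    phi[t2] <- -80; psi[t2] <- 0
  } else {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(spec$seed)
    # polyproline-II-adjacent but jittered: far from helix and sheet minima
    phi <- stats::runif(n, -100, -70)
    psi <- stats::runif(n, 150, 180)
    psi[seq(2, n, by = 2)] <- stats::runif(length(seq(2, n, by = 2)), 60, 90)
  }
  bb <- build_backbone(phi, psi)
  atoms <- tibble::tibble(
    serial = seq_len(4 * n),
    name = rep(c("N", "CA", "C", "O"), n),
    element = rep(c("N", "C", "C", "O"), n),
    resid = rep(seq_len(n), each = 4),
    resname = "ALA",
    chain = "A"
  )
  co <- matrix(0, 4 * n, 3)
  co[seq(1, 4 * n, 4), ] <- bb$N
  co[seq(2, 4 * n, 4), ] <- bb$CA
  co[seq(3, 4 * n, 4), ] <- bb$C
  co[seq(4, 4 * n, 4), ] <- bb$O
  list(topology = topology(atoms), xyz = coords_to_xyz(co))
}
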