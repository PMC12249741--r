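# Shared fixtures and oracles, built in code at test time.

# replicate a single structure into a trajectory with small isotropic jitter
jitter_traj <- function(st, n_frames, sd = 0.01, seed = 1, label = "fix",
                        replicate = 1) {
  set.seed(seed)
  xyz <- t(replicate(n_frames, st$xyz + stats::rnorm(length(st$xyz), sd = sd)))
  trajectory(st$topology, xyz, label = label, replicate = replicate,
             ref_xyz = st$xyz)
}

# coil backbone with a helical stretch planted at `helix_resids`
sse_switch_structure <- function(n = 60, helix_resids = integer()) {
  phi <- rep(-80, n); psi <- rep(150, n)
  phi[helix_resids] <- -57; psi[helix_resids] <- -47
  make_ideal_structure(ideal_geometry_spec("coil", n, phi, psi))
}

# hand-written 3-residue PDB fixture (full backbone, one CB)
write_three_residue_pdb <- function(path) {
  lines <- c(
    "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1      11.639   6.071  -5.147  1.00  0.00           C",
    "ATOM      3  C   ALA A   1      10.674   6.661  -4.124  1.00  0.00           C",
    "ATOM      4  O   ALA A   1       9.462   6.504  -4.234  1.00  0.00           O",
    "ATOM      5  N   GLY A   2      11.220   7.343  -3.128  1.00  0.00           N",
    "ATOM      6  CA  GLY A   2      10.431   7.959  -2.075  1.00  0.00           C",
    "ATOM      7  C   GLY A   2      10.866   7.408  -0.722  1.00  0.00           C",
    "ATOM      8  O   GLY A   2      12.031   7.048  -0.533  1.00  0.00           O",
    "ATOM      9  N   SER A   3       9.926   7.323   0.215  1.00  0.00           N",
    "ATOM     10  CA  SER A   3      10.210   6.799   1.549  1.00  0.00           C",
    "ATOM     11  C   SER A   3       9.443   7.576   2.612  1.00  0.00           C",
    "ATOM     12  O   SER A   3       8.289   7.964   2.410  1.00  0.00           O",
    "ATOM     13  CB  SER A   3       9.825   5.319   1.621  1.00  0.00           C",
    "END")
  writeLines(lines, path)
  path
}

# reference DSSP oracle: mdtraj's full 8-class assignment on a PDB file
mdtraj_dssp <- function(pdb_path) {
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import sys, mdtraj",
    "t = mdtraj.load(sys.argv[1])",
    "ss = mdtraj.compute_dssp(t, simplified=False)",
    "for row in ss:",
    "    print(''.join('-' if c in (' ', '') else c for c in row))"
  ), script)
  out <- system2("python", c(script, pdb_path), stdout = TRUE)
  do.call(rbind, strsplit(out, ""))
}

# reference SASA oracle: mdtraj Shrake-Rupley, total area in A^2 per frame
mdtraj_sasa <- function(pdb_path, n_points = 960) {
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import sys, mdtraj",
    "t = mdtraj.load(sys.argv[1])",
    sprintf("sa = mdtraj.shrake_rupley(t, n_sphere_points=%d)", n_points),
    "for v in sa.sum(axis=1) * 100:",   # nm^2 -> A^2
    "    print(repr(float(v)))"
  ), script)
  as.numeric(system2("python", c(script, pdb_path), stdout = TRUE))
}

# brute-force RMSD minimisation over rotations parameterised by quaternions
brute_force_rmsd <- function(mobile, reference) {
  cm <- colMeans(mobile); cr <- colMeans(reference)
  A <- sweep(mobile, 2, cm); B <- sweep(reference, 2, cr)
  obj <- function(q) {
    q <- q / sqrt(sum(q^2))
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    R <- matrix(c(
      1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
      2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
      2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
    ), 3, 3, byrow = TRUE)
    sqrt(mean(rowSums((A %*% t(R) - B)^2)))
  }
  best <- Inf
  set.seed(42)
  for (i in 1:40) {
    r <- stats::optim(stats::rnorm(4), obj, method = "BFGS",
                      control = list(maxit = 500))
    best <- min(best, r$value)
  }
  best
}
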