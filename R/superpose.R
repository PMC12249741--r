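#' Kabsch least-squares superposition
#'
#' Finds the proper rotation and translation minimising the (weighted) sum of
#' squared deviations between `mobile` and `reference`. Reflections are
#' excluded by the usual determinant sign correction, so `det(rotation)` is
#' always +1.
#'
#' @param mobile,reference `n x 3` coordinate matrices (Angstrom), `n >= 3`.
#' @param weights optional non-negative per-atom weights.
#' @return a list of class `superposition`: `rotation` (3x3, applied on the
#'   right of centred coordinates), `translation` (3-vector), `rmsd`
#'   (Angstrom).
#' @export
kabsch <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  n <- nrow(mobile)
  if (n < 3 || nrow(reference) != n) {
    rlang::abort("need matching coordinate sets with at least 3 atoms")
  }
  w <- if (is.null(weights)) rep(1, n) else as.numeric(weights)
  if (any(w < 0) || sum(w) <= 0) rlang::abort("invalid weights")
  w <- w / sum(w)
  cm <- colSums(mobile * w)
  cr <- colSums(reference * w)
  A <- sweep(mobile, 2, cm)
  B <- sweep(reference, 2, cr)
  H <- t(A * w) %*% B
  sv <- svd(H)
  # degenerate (e.g. collinear) input: the optimal rotation is not unique
  if (sv$d[2] < 1e-10 * max(sv$d[1], 1e-30)) {
    rlang::abort("degenerate coordinates: superposition is not unique")
  }
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$u %*% D %*% t(sv$v)     # A %*% R aligns onto B
  fitted <- A %*% R
  rmsd <- sqrt(sum(w * rowSums((fitted - B)^2)))
  structure(list(rotation = R, translation = cr - cm %*% R, rmsd = rmsd),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat("<superposition> rmsd =", format(x$rmsd, digits = 6), "A\n")
  invisible(x)
}

# apply a kabsch fit (computed on fit_idx atoms) to all atoms of a frame
apply_fit <- function(coords, fit) {
  sweep(coords %*% fit$rotation, 2, -as.numeric(fit$translation))
}

# Superpose every frame of an xyz matrix onto ref (coords of the mask atoms),
# fitting on mask columns but transforming all atoms.
superpose_xyz <- function(xyz, ref_mask_coords, mask_idx) {
  out <- xyz
  for (i in seq_len(nrow(xyz))) {
    fr <- xyz_to_coords(xyz[i, ])
    fit <- kabsch(fr[mask_idx, , drop = FALSE], ref_mask_coords)
    out[i, ] <- coords_to_xyz(apply_fit(fr, fit))
  }
  out
}

#' Superpose a trajectory onto its iteratively refined mean structure
#'
#' Frames are fitted on the mask atoms; the mean structure is recomputed and
#' the fit repeated until the mean moves by less than `tol` (RMS, Angstrom).
#' Two iterations typically suffice. This removes the six rigid-body degrees
#' of freedom before any fluctuation analysis (RMSF, DCCM, PCA).
#'
#' @param traj a [trajectory()].
#' @param mask selection (string or [select_atoms()] result) fit on.
#' @param tol convergence tolerance on the mean structure, Angstrom.
#' @param max_iter iteration cap.
#' @return list: `xyz` (superposed frames), `mean` (mask-atom mean coords,
#'   `n_mask x 3`), `mask` (resolved indices).
#' @export
superpose_mean <- function(traj, mask = "CA", tol = 1e-6, max_iter = 10) {
  idx <- resolve_mask(traj$topology, mask)
  xyz <- traj$xyz
  if (nrow(xyz) < 2) rlang::abort("need at least 2 frames")
  ref <- xyz_to_coords(xyz[1, ])[idx, , drop = FALSE]
  for (it in seq_len(max_iter)) {
    xyz <- superpose_xyz(traj$xyz, ref, idx)
    msub <- colMeans(xyz)
    newref <- xyz_to_coords(msub)[idx, , drop = FALSE]
    shift <- sqrt(mean((newref - ref)^2))
    ref <- newref
    if (shift < tol) break
  }
  list(xyz = xyz, mean = ref, mask = idx)
}

# mask atom coordinates of every frame as frames x (3*n_mask), column order
# x1,y1,z1,x2,...
mask_xyz <- function(xyz, idx) {
  cols <- as.integer(vapply(idx, function(i) 3 * (i - 1) + 1:3, numeric(3)))
  xyz[, cols, drop = FALSE]
}
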