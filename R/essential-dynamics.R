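#' Essential-dynamics principal component analysis
#'
#' Eigendecomposition of the 3N x 3N covariance matrix of the masked
#' coordinates after iterative superposition onto the mean structure (which
#' removes the six rigid-body degrees of freedom, so at least six trailing
#' eigenvalues are near zero). Eigenvector signs are fixed by making each
#' vector's largest-magnitude component positive, so porcupine output is
#' reproducible.
#'
#' @param traj a [trajectory()].
#' @param mask atom selection (default `"CA"`).
#' @return object of class `essential_subspace`: `values` (eigenvalues,
#'   A^2, descending), `vectors` (3N x 3N orthonormal columns), `mean`
#'   (mask mean structure, n x 3), `variance_fraction`, `projections`
#'   (frames x 3N, A), `resid`, `label`.
#' @export
essential_dynamics <- function(traj, mask = "CA") {
  if (n_frames(traj) < 2) rlang::abort("PCA needs at least 2 frames")
  sp <- superpose_mean(traj, mask)
  X <- mask_xyz(sp$xyz, sp$mask)
  nf <- nrow(X)
  if (nf <= ncol(X)) {
    rlang::warn(sprintf("n_frames (%d) <= 3N (%d): covariance is rank-deficient",
                        nf, ncol(X)))
  }
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  C <- crossprod(Xc) / nf
  eg <- eigen(C, symmetric = TRUE)
  vals <- pmax(eg$values, 0)
  vecs <- eg$vectors
  # sign convention: largest-magnitude component positive
  for (k in seq_len(ncol(vecs))) {
    m <- which.max(abs(vecs[, k]))
    if (vecs[m, k] < 0) vecs[, k] <- -vecs[, k]
  }
  proj <- Xc %*% vecs
  structure(list(
    values = vals,
    vectors = vecs,
    mean = xyz_to_coords(mu),
    variance_fraction = if (sum(vals) > 0) vals / sum(vals) else vals,
    projections = proj,
    resid = mask_resids(traj$topology, sp$mask),
    label = traj$label,
    replicate = traj$replicate
  ), class = "essential_subspace")
}

#' @export
print.essential_subspace <- function(x, ...) {
  vf <- 100 * x$variance_fraction[1:min(3, length(x$values))]
  cat("<essential_subspace> '", x$label, "': ", length(x$values),
      " modes; PC1-3 variance ", paste(sprintf("%.1f%%", vf), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Per-residue displacement profile of one PC
#'
#' Euclidean norm of each residue's (x, y, z) eigenvector triple scaled by
#' the mode's RMS amplitude `sqrt(eigenvalue)`.
#'
#' @param es an `essential_subspace`.
#' @param pc PC index (1-based).
#' @return tibble (class `pc_profile`) with `resid`, `value` (A), `pc`.
#' @export
pc_profile <- function(es, pc = 1) {
  stopifnot(inherits(es, "essential_subspace"))
  if (pc < 1 || pc > length(es$values)) rlang::abort("PC index out of range")
  v <- matrix(es$vectors[, pc], ncol = 3, byrow = TRUE)
  out <- tibble::tibble(
    resid = es$resid,
    value = sqrt(es$values[pc]) * sqrt(rowSums(v^2)),
    pc = pc,
    label = es$label
  )
  class(out) <- c("pc_profile", class(out))
  out
}

#' Porcupine vectors for one PC
#'
#' Per-residue mode vectors anchored at the mean Calpha positions:
#' `scale * sqrt(eigenvalue) * eigenvector triple`. Note the overall sign of
#' an eigenvector is a convention (fixed here by the largest component), so
#' flipping it flips every arrow.
#'
#' @inheritParams pc_profile
#' @param scale arrow scale factor.
#' @return tibble with anchor coordinates `x, y, z` and components
#'   `dx, dy, dz`.
#' @export
porcupine <- function(es, pc = 1, scale = 1) {
  stopifnot(inherits(es, "essential_subspace"))
  if (pc < 1 || pc > length(es$values)) rlang::abort("PC index out of range")
  v <- matrix(es$vectors[, pc], ncol = 3, byrow = TRUE) *
    scale * sqrt(es$values[pc])
  tibble::tibble(
    resid = es$resid,
    x = es$mean[, 1], y = es$mean[, 2], z = es$mean[, 3],
    dx = v[, 1], dy = v[, 2], dz = v[, 3],
    pc = pc
  )
}

#' Write porcupine vectors as a two-model PDB
#'
#' Model 1 holds the anchors (mean structure), model 2 the arrow tips, so
#' any viewer can draw the mode vectors between matched atoms.
#'
#' @param pq result of [porcupine()].
#' @param path output file.
#' @export
write_porcupine_pdb <- function(pq, path) {
  n <- nrow(pq)
  top <- ca_topology(n)
  top$atoms$resid <- pq$resid
  anchors <- coords_to_xyz(as.matrix(pq[, c("x", "y", "z")]))
  tips <- coords_to_xyz(as.matrix(pq[, c("x", "y", "z")]) +
                          as.matrix(pq[, c("dx", "dy", "dz")]))
  traj <- trajectory(top, rbind(anchors, tips), label = "porcupine")
  write_trajectory_pdb(traj, path)
}

#' Root-mean-square inner product of two essential subspaces
#'
#' \deqn{RMSIP = \sqrt{\frac{1}{k}\sum_{i\le k}\sum_{j\le k}
#'   (\eta_i \cdot \nu_j)^2}}
#' over the first `k` eigenvectors of each subspace. 1 for identical
#' subspaces, 0 for mutually orthogonal ones; random k-dimensional
#' subspaces of a D-dimensional space concentrate near `sqrt(k/D)`.
#'
#' @param a,b `essential_subspace` objects over the same residue range.
#' @param k subspace size (default 10).
#' @return object of class `rmsip_result`: `value`, `k`, `matrix` (k x k of
#'   squared inner products).
#' @export
rmsip <- function(a, b, k = 10) {
  stopifnot(inherits(a, "essential_subspace"), inherits(b, "essential_subspace"))
  if (nrow(a$vectors) != nrow(b$vectors)) {
    rlang::abort("subspaces have different dimensionality")
  }
  if (k > ncol(a$vectors) || k > ncol(b$vectors)) {
    rlang::abort("k exceeds the retained mode count")
  }
  P <- crossprod(a$vectors[, 1:k, drop = FALSE],
                 b$vectors[, 1:k, drop = FALSE])^2
  structure(list(value = sqrt(sum(P) / k), k = k, matrix = P,
                 labels = c(a = a$label, b = b$label)),
            class = "rmsip_result")
}

#' @export
print.rmsip_result <- function(x, ...) {
  cat("<rmsip_result> ", x$labels[["a"]], " vs ", x$labels[["b"]], " (k = ",
      x$k, "): ", sprintf("%.4f", x$value), "\n", sep = "")
  invisible(x)
}

#' Cosine content of a PC projection
#'
#' Similarity of the projection's time course to a half-period cosine
#' (Hess's diagnostic): values near 1 indicate random-diffusion-like,
#' unconverged sampling; values well below 0.7 support converged sampling.
#' \deqn{c_i = \frac{2}{T}\left(\int_0^T \cos(i\pi t/T)\, p_i(t)\,
#'   dt\right)^2 \Big/ \int_0^T p_i^2(t)\, dt}
#' evaluated by the trapezoidal rule on the frame grid. Order-sensitive by
#' design: permuting frames changes the value.
#'
#' @param es an `essential_subspace` (its stored projections are used) or a
#'   numeric vector of projections.
#' @param pc PC index when `es` is a subspace.
#' @return cosine content in \[0, 1\].
#' @export
cosine_content <- function(es, pc = 1) {
  p <- if (inherits(es, "essential_subspace")) {
    if (pc < 1 || pc > ncol(es$projections)) rlang::abort("PC index out of range")
    es$projections[, pc]
  } else as.numeric(es)
  nf <- length(p)
  if (nf < 4) rlang::abort("cosine content needs at least 4 frames")
  p <- p - mean(p)        # projections are zero-mean; enforce for raw input
  denom_raw <- sum(p^2)
  if (denom_raw <= 1e-24) {
    rlang::warn("zero-variance projection; cosine content defined as 0")
    return(0)
  }
  t <- seq(0, 1, length.out = nf)
  w <- rep(1, nf); w[c(1, nf)] <- 0.5        # trapezoid weights (dt = 1/(nf-1))
  cosv <- cos(pc * pi * t)
  num <- 2 * (sum(w * cosv * p) / (nf - 1))^2
  den <- sum(w * p^2) / (nf - 1)
  min(max(num / den, 0), 1)
}
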