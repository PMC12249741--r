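#' Per-frame RMSD series
#'
#' Kabsch-superposed RMSD of the masked atoms against either the first frame
#' (the default, matching per-replicate equilibration plots) or the input
#' structure stored on the trajectory (`ref_xyz`, e.g. the starting crystal
#' structure).
#'
#' @param traj a [trajectory()].
#' @param mask atom selection (default `"CA"`).
#' @param reference `"first_frame"` or `"input_structure"`.
#' @return a tibble (class `metric_series`) with columns `frame`, `time`
#'   (ps), `value` (Angstrom), `kind`, `label`, `replicate`.
#' @export
rmsd_series <- function(traj, mask = "CA",
                        reference = c("first_frame", "input_structure")) {
  reference <- match.arg(reference)
  idx <- resolve_mask(traj$topology, mask)
  ref_xyz <- if (reference == "first_frame") traj$xyz[1, ] else {
    if (is.null(traj$ref_xyz)) rlang::abort("trajectory carries no input structure (ref_xyz)")
    traj$ref_xyz
  }
  ref <- xyz_to_coords(ref_xyz)[idx, , drop = FALSE]
  vals <- vapply(seq_len(n_frames(traj)), function(i) {
    kabsch(xyz_to_coords(traj$xyz[i, ])[idx, , drop = FALSE], ref)$rmsd
  }, numeric(1))
  new_metric_series(vals, "rmsd", traj)
}

new_metric_series <- function(values, kind, traj) {
  out <- tibble::tibble(
    frame = seq_along(values),
    time = (seq_along(values) - 1) * traj$dt,
    value = values,
    kind = kind,
    label = traj$label,
    replicate = traj$replicate
  )
  class(out) <- c("metric_series", class(out))
  out
}

#' Per-residue RMSF profile
#'
#' Root-mean-square fluctuation of each masked atom about its time-mean
#' position, after iterative superposition onto the mean structure (so the
#' profile is invariant to rigid-body motion added to every frame).
#'
#' @inheritParams rmsd_series
#' @return a tibble (class `rmsf_profile`) with columns `resid` (author
#'   numbering), `value` (Angstrom), `label`, `replicate`.
#' @export
rmsf_profile <- function(traj, mask = "CA") {
  if (n_frames(traj) < 2) rlang::abort("RMSF needs at least 2 frames")
  sp <- superpose_mean(traj, mask)
  X <- mask_xyz(sp$xyz, sp$mask)
  Xc <- sweep(X, 2, colMeans(X))
  msd <- colMeans(Xc^2)                       # per coordinate
  per_atom <- sqrt(rowSums(matrix(msd, ncol = 3, byrow = TRUE)))
  out <- tibble::tibble(
    resid = mask_resids(traj$topology, sp$mask),
    value = per_atom,
    label = traj$label,
    replicate = traj$replicate
  )
  class(out) <- c("rmsf_profile", class(out))
  out
}

#' Per-frame radius of gyration
#'
#' Rg about the (optionally mass-weighted) centroid of the masked atoms.
#' Superposition-independent by construction.
#'
#' @inheritParams rmsd_series
#' @param mass_weighted weight atoms by standard atomic mass (default TRUE).
#' @return a `metric_series` tibble, `kind = "rg"`.
#' @export
rg_series <- function(traj, mask = "all", mass_weighted = TRUE) {
  idx <- resolve_mask(traj$topology, mask)
  w <- if (mass_weighted) {
    m <- .atomic_masses[toupper(traj$topology$atoms$element[idx])]
    m[is.na(m)] <- 12.011
    m
  } else rep(1, length(idx))
  w <- w / sum(w)
  vals <- vapply(seq_len(n_frames(traj)), function(i) {
    co <- xyz_to_coords(traj$xyz[i, ])[idx, , drop = FALSE]
    ce <- colSums(co * w)
    sqrt(sum(w * rowSums(sweep(co, 2, ce)^2)))
  }, numeric(1))
  new_metric_series(vals, "rg", traj)
}

# deterministic quasi-uniform points on the unit sphere (Fibonacci lattice)
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# Shrake-Rupley accessible surface for one frame.
# coords: n x 3; radii: vdW radii; returns per-atom areas (A^2)
shrake_rupley <- function(coords, radii, probe = 1.4, n_points = 960) {
  pts <- sphere_points(n_points)
  n <- nrow(coords)
  ri <- radii + probe
  area <- numeric(n)
  # neighbour lists from the pairwise distance matrix (fine for <= ~2000 atoms)
  d2 <- as.matrix(stats::dist(coords))^2
  for (i in seq_len(n)) {
    cut <- (ri[i] + ri)^2
    nb <- which(d2[i, ] < cut & seq_len(n) != i)
    if (length(nb) == 0) { area[i] <- 4 * pi * ri[i]^2; next }
    sp <- sweep(pts * ri[i], 2, coords[i, ], "+")
    # a point is accessible if outside every neighbour's expanded sphere
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      dj <- sweep(sp, 2, coords[j, ])
      acc <- acc & (rowSums(dj^2) > ri[j]^2)
      if (!any(acc)) break
    }
    area[i] <- 4 * pi * ri[i]^2 * sum(acc) / n_points
  }
  area
}

#' Per-frame solvent-accessible surface area
#'
#' Shrake-Rupley SASA over protein heavy atoms (default selection), with a
#' 1.4 Angstrom water probe and a deterministic Fibonacci sphere point set,
#' using the pinned Bondi radius table. Deterministic for a fixed point
#' count.
#'
#' @inheritParams rmsd_series
#' @param probe_radius probe sphere radius, Angstrom.
#' @param n_points sphere quadrature points per atom (>= 32).
#' @return a `metric_series` tibble, `kind = "sasa"`, values in Angstrom^2.
#' @export
sasa_series <- function(traj, mask = "heavy", probe_radius = 1.4,
                        n_points = 960) {
  if (n_points < 32) rlang::abort("n_points must be at least 32")
  idx <- resolve_mask(traj$topology, mask)
  radii <- traj$topology$atoms$vdw_radius[idx]
  vals <- vapply(seq_len(n_frames(traj)), function(i) {
    co <- xyz_to_coords(traj$xyz[i, ])[idx, , drop = FALSE]
    sum(shrake_rupley(co, radii, probe = probe_radius, n_points = n_points))
  }, numeric(1))
  new_metric_series(vals, "sasa", traj)
}

#' Summary statistics for a metric series
#'
#' Mean, SD and quartiles per (kind, label, replicate) group, the table
#' backing violin/distribution plots.
#'
#' @param x a `metric_series` tibble (rows from several series may be bound
#'   together).
#' @return a tibble with one row per group.
#' @export
summarise_metric <- function(x) {
  dplyr::summarise(
    dplyr::group_by(x, .data$kind, .data$label, .data$replicate),
    mean = mean(.data$value), sd = stats::sd(.data$value),
    q25 = stats::quantile(.data$value, 0.25), median = stats::median(.data$value),
    q75 = stats::quantile(.data$value, 0.75),
    n = dplyr::n(), .groups = "drop"
  )
}
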