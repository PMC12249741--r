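.kB <- 0.0019872041   # Boltzmann constant, kcal/mol/K

#' Free-energy landscape by Boltzmann inversion
#'
#' Bins two reaction-coordinate series (RMSD and Rg by convention) on an
#' equal-width 2-D grid spanning the data range and converts counts to Gibbs
#' energies, `G_i = -kB T ln(N_i / N_max)`, so the most-populated bin sits
#' exactly at 0. Empty bins carry `NA` energy (rendered at a display
#' ceiling, never treated as minima).
#'
#' @param rmsd,rg `metric_series` tibbles (or numeric vectors) of equal
#'   length; reaction coordinates 1 and 2.
#' @param n_bins bins per axis (>= 10; default 50).
#' @param temperature kelvin (default 300).
#' @return object of class `fel_grid`: `rc1_edges`, `rc2_edges`, `counts`,
#'   `energy` (n_bins x n_bins, NA where unpopulated), `frame_bin`
#'   (per-frame linear bin index), `temperature`.
#' @export
fel <- function(rmsd, rg, n_bins = 50, temperature = 300) {
  x <- if (is.data.frame(rmsd)) rmsd$value else as.numeric(rmsd)
  y <- if (is.data.frame(rg)) rg$value else as.numeric(rg)
  if (length(x) != length(y)) rlang::abort("reaction coordinates differ in length")
  if (n_bins < 10) rlang::abort("n_bins must be at least 10")
  if (diff(range(x)) == 0 || diff(range(y)) == 0) {
    rlang::abort("constant reaction coordinate: zero range cannot be binned")
  }
  ex <- seq(min(x), max(x), length.out = n_bins + 1)
  ey <- seq(min(y), max(y), length.out = n_bins + 1)
  ix <- pmin(findInterval(x, ex, rightmost.closed = TRUE), n_bins)
  iy <- pmin(findInterval(y, ey, rightmost.closed = TRUE), n_bins)
  counts <- matrix(0L, n_bins, n_bins)
  for (t in seq_along(ix)) counts[ix[t], iy[t]] <- counts[ix[t], iy[t]] + 1L
  nmax <- max(counts)
  energy <- matrix(NA_real_, n_bins, n_bins)
  pop <- counts > 0
  energy[pop] <- -.kB * temperature * log(counts[pop] / nmax)
  structure(list(rc1_edges = ex, rc2_edges = ey, counts = counts,
                 energy = energy, frame_bin = (iy - 1L) * n_bins + ix,
                 temperature = temperature, n_bins = n_bins),
            class = "fel_grid")
}

#' @export
print.fel_grid <- function(x, ...) {
  cat("<fel_grid> ", x$n_bins, "x", x$n_bins, " bins, ",
      sum(x$counts > 0), " populated; max G = ",
      sprintf("%.2f", max(x$energy, na.rm = TRUE)), " kcal/mol at T = ",
      x$temperature, " K\n", sep = "")
  invisible(x)
}

# 8-connected components over a logical matrix; returns integer labels
connected_components8 <- function(mask) {
  n1 <- nrow(mask); n2 <- ncol(mask)
  lab <- matrix(0L, n1, n2)
  cur <- 0L
  for (s1 in seq_len(n1)) for (s2 in seq_len(n2)) {
    if (!mask[s1, s2] || lab[s1, s2] != 0L) next
    cur <- cur + 1L
    queue <- list(c(s1, s2))
    lab[s1, s2] <- cur
    while (length(queue) > 0) {
      q <- queue[[length(queue)]]
      queue[[length(queue)]] <- NULL
      for (d1 in -1:1) for (d2 in -1:1) {
        a <- q[1] + d1; b <- q[2] + d2
        if (a < 1 || a > n1 || b < 1 || b > n2) next
        if (mask[a, b] && lab[a, b] == 0L) {
          lab[a, b] <- cur
          queue[[length(queue) + 1]] <- c(a, b)
        }
      }
    }
  }
  lab
}

# 3x3 box smoothing with edge renormalisation
box_smooth3 <- function(m) {
  n1 <- nrow(m); n2 <- ncol(m)
  p <- matrix(0, n1 + 2, n2 + 2)
  p[2:(n1 + 1), 2:(n2 + 1)] <- m
  w <- matrix(0, n1 + 2, n2 + 2)
  w[2:(n1 + 1), 2:(n2 + 1)] <- 1
  acc <- matrix(0, n1, n2); den <- matrix(0, n1, n2)
  for (d1 in 0:2) for (d2 in 0:2) {
    acc <- acc + p[d1 + seq_len(n1), d2 + seq_len(n2)]
    den <- den + w[d1 + seq_len(n1), d2 + seq_len(n2)]
  }
  acc / den
}

#' Segment a free-energy landscape into basins
#'
#' Candidate cells are bins whose energy, evaluated on a lightly smoothed
#' (3 x 3 box) count grid, lies at or below `depth_cutoff`; the smoothing
#' suppresses shot-noise fragmentation of sparse histograms and does not
#' alter the reported energies, which stay raw. 8-connected components of
#' candidate cells are the basins, ranked 1, 2, ... by ascending minimum
#' raw energy (rank 1 = global minimum). Frames are assigned to basins
#' through their bin.
#'
#' Components holding fewer than `min_frames` frames are dissolved: they are
#' isolated outlier frames, not metastable states.
#'
#' @param grid a [fel()] result.
#' @param depth_cutoff kcal/mol above the global minimum (default 1.0).
#' @param min_frames smallest frame count a basin may hold (default 0.2% of
#'   the trajectory, at least 2).
#' @return object of class `basin_set`: tibble `basins` (rank, min_energy,
#'   n_bins, n_frames), `bin_label` matrix, `frame_basin` (per-frame rank,
#'   NA outside every basin).
#' @export
segment_basins <- function(grid, depth_cutoff = 1.0, min_frames = NULL) {
  stopifnot(inherits(grid, "fel_grid"))
  if (is.null(min_frames)) {
    min_frames <- max(2, ceiling(0.002 * sum(grid$counts)))
  }
  sm <- box_smooth3(grid$counts)
  e_sm <- -.kB * grid$temperature * log(pmax(sm, 1e-300) / max(sm))
  cand <- sm > 0 & e_sm <= depth_cutoff
  if (!any(cand & grid$counts > 0)) {
    rlang::abort("no bins at or below depth_cutoff; increase the cutoff")
  }
  lab <- connected_components8(cand)
  # dissolve components that are empty or hold fewer than min_frames frames
  if (max(lab) > 0) {
    fr <- vapply(seq_len(max(lab)), function(l)
      sum(grid$counts[lab == l]), numeric(1))
    keep <- which(fr >= min_frames)
  } else keep <- integer()
  if (length(keep) == 0) {
    rlang::abort("no basin holds min_frames frames; increase depth_cutoff")
  }
  lab[!(lab %in% keep)] <- 0L
  lab[lab > 0] <- match(lab[lab > 0], keep)
  k <- length(keep)
  min_e <- vapply(seq_len(k), function(l)
    min(grid$energy[lab == l], na.rm = TRUE), numeric(1))
  rank_of <- match(seq_len(k), order(min_e))
  ranked <- matrix(0L, nrow(lab), ncol(lab))
  ranked[lab > 0] <- rank_of[lab[lab > 0]]
  lin_label <- as.integer(ranked)            # column-major = linear bin index
  frame_basin <- lin_label[grid$frame_bin]
  frame_basin[frame_basin == 0L] <- NA_integer_
  basins <- tibble::tibble(
    rank = seq_len(k),
    min_energy = sort(min_e),
    n_bins = vapply(seq_len(k), function(r) sum(ranked == r), integer(1)),
    n_frames = vapply(seq_len(k), function(r)
      sum(frame_basin == r, na.rm = TRUE), integer(1))
  )
  structure(list(basins = basins, bin_label = ranked,
                 frame_basin = frame_basin, depth_cutoff = depth_cutoff,
                 grid = grid),
            class = "basin_set")
}

#' @export
print.basin_set <- function(x, ...) {
  cat("<basin_set> ", nrow(x$basins), " basin(s) at depth cutoff ",
      x$depth_cutoff, " kcal/mol\n", sep = "")
  print(x$basins)
  invisible(x)
}

#' Count basins across several bin resolutions
#'
#' Basin counts depend on the histogram resolution; this reports the count
#' at each requested binning so the sensitivity is visible.
#'
#' @inheritParams fel
#' @param bins vector of bin counts (default 30, 50, 70).
#' @param depth_cutoff passed to [segment_basins()].
#' @return tibble with `n_bins` and `n_basins`.
#' @export
basin_count_sensitivity <- function(rmsd, rg, bins = c(30, 50, 70),
                                    depth_cutoff = 1.0, temperature = 300) {
  tibble::tibble(
    n_bins = bins,
    n_basins = vapply(bins, function(b) {
      nrow(segment_basins(fel(rmsd, rg, n_bins = b, temperature = temperature),
                          depth_cutoff)$basins)
    }, integer(1))
  )
}

#' Extract the frames of one basin
#'
#' Returns the member frames as a sub-trajectory (original order preserved)
#' together with the basin's representative conformer: the mean structure
#' after superposition and the medoid frame (the member with least RMSD to
#' that mean; geometrically valid, unlike the mean).
#'
#' @param traj the [trajectory()] the landscape was computed from.
#' @param basins a [segment_basins()] result.
#' @param rank basin rank to extract (default 1, the global minimum).
#' @param mask selection used for superposition and the medoid RMSD.
#' @return list: `trajectory` (sub-trajectory), `conformer` (class
#'   `basin_conformer`: `medoid_frame` as index into the sub-trajectory,
#'   `medoid_frame_global`, `mean` coords, `rank`), `frames` (global
#'   indices).
#' @export
extract_basin <- function(traj, basins, rank = 1, mask = "CA") {
  stopifnot(inherits(basins, "basin_set"))
  if (!rank %in% basins$basins$rank) rlang::abort("no basin with that rank")
  frames <- which(!is.na(basins$frame_basin) & basins$frame_basin == rank)
  sub <- trajectory(traj$topology, traj$xyz[frames, , drop = FALSE],
                    dt = traj$dt, label = paste0(traj$label, "/basin", rank),
                    replicate = traj$replicate, ref_xyz = traj$ref_xyz)
  if (length(frames) == 1) {
    idx <- resolve_mask(traj$topology, mask)
    co <- xyz_to_coords(sub$xyz[1, ])
    conf <- structure(list(medoid_frame = 1L, medoid_frame_global = frames,
                           mean = co[idx, , drop = FALSE], rank = rank,
                           mean_full = co),
                      class = "basin_conformer")
    return(list(trajectory = sub, conformer = conf, frames = frames))
  }
  sp <- superpose_mean(sub, mask)
  mean_mask <- sp$mean
  d <- vapply(seq_along(frames), function(i) {
    sqrt(mean(rowSums((xyz_to_coords(sp$xyz[i, ])[sp$mask, , drop = FALSE] -
                         mean_mask)^2)))
  }, numeric(1))
  med <- which.min(d)
  conf <- structure(list(medoid_frame = med,
                         medoid_frame_global = frames[med],
                         mean = mean_mask, rank = rank,
                         mean_full = xyz_to_coords(colMeans(sp$xyz))),
                    class = "basin_conformer")
  list(trajectory = sub, conformer = conf, frames = frames)
}

#' Re-analyse a basin's member frames
#'
#' Re-runs the superposition metrics (RMSD, Rg, RMSF; SASA optional) and,
#' when the topology has complete backbones, the DSSP occupancy, on the
#' member frames only. DSSP and SASA on a Calpha-only trajectory is a clear
#' error rather than a silent skip.
#'
#' @param sub a sub-trajectory from [extract_basin()].
#' @param mask selection for RMSD/RMSF.
#' @param dssp run DSSP occupancy (default auto: only if backbone present).
#' @param sasa include SASA series (slower; default FALSE).
#' @return list with `metrics` (bound `metric_series` rows), `rmsf` (`NULL`
#'   for a single-frame basin), and optionally `occupancy`.
#' @export
basin_report <- function(sub, mask = "CA", dssp = NULL, sasa = FALSE) {
  has_bb <- any(sub$topology$residues$complete)
  if (is.null(dssp)) dssp <- has_bb
  if (dssp && !has_bb) {
    rlang::abort("DSSP requested but the trajectory has no complete backbone (Calpha-only input?)")
  }
  metrics <- dplyr::bind_rows(
    rmsd_series(sub, mask),
    rg_series(sub, mask = if (has_bb) "heavy" else "all")
  )
  if (sasa) {
    if (!has_bb) rlang::abort("SASA requires heavy-atom topology, not Calpha-only input")
    metrics <- dplyr::bind_rows(metrics, sasa_series(sub))
  }
  out <- list(metrics = metrics,
              rmsf = if (n_frames(sub) >= 2) rmsf_profile(sub, mask))
  if (dssp) out$occupancy <- sse_occupancy(assign_dssp_trajectory(sub))
  out
}
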