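kB300 <- 0.0019872041 * 300

test_that("fel energies match the Boltzmann inversion formula on a hand histogram", {
  # 8 points in 2 x 2 bins: counts 4, 2, 1, 1
  x <- c(1, 1, 1, 1, 9, 9, 1.2, 9.1)
  y <- c(1, 1.1, 0.9, 1, 1, 1.05, 9, 9)
  g <- fel(x, y, n_bins = 10)
  # the n_bins = 10 grid collapses these onto 4 populated corner bins
  counts <- sort(g$counts[g$counts > 0], decreasing = TRUE)
  expect_equal(counts, c(4, 2, 1, 1))
  nmax <- 4
  expected <- -kB300 * log(counts / nmax)
  got <- sort(g$energy[!is.na(g$energy)])
  expect_equal(got, sort(expected), tolerance = 1e-12)
  # zero point at the most populated bin, exactly
  expect_equal(min(g$energy, na.rm = TRUE), 0)
  # N_i = N_max / e  ->  G = kB * T
  expect_equal(-kB300 * log((nmax / exp(1)) / nmax), kB300, tolerance = 1e-15)
  expect_equal(kB300, 0.5962, tolerance = 1e-4)
})

test_that("fel rejects degenerate input and is frame-order free", {
  expect_error(fel(rep(1, 100), rnorm(100)), "zero range")
  expect_error(fel(rnorm(100), rnorm(99)), "length")
  expect_error(fel(rnorm(100), rnorm(100), n_bins = 5), "at least 10")

  set.seed(3)
  x <- rnorm(500); y <- rnorm(500)
  g1 <- fel(x, y)
  perm <- sample(500)
  g2 <- fel(x[perm], y[perm])
  expect_equal(g1$counts, g2$counts)
  expect_equal(g1$energy, g2$energy)
})

test_that("basin segmentation recovers planted state counts and ranks by energy", {
  rg0 <- reference_rg(40)
  run <- function(centers, occ, seed, nf = 6000) {
    sp <- basin_spec(centers, occ, dwell = 40, seed = seed)
    tr <- make_basin_trajectory(sp, nf)
    g <- fel(rmsd_series(tr, "CA", reference = "input_structure"),
             rg_series(tr, mask = "CA", mass_weighted = FALSE))
    segment_basins(g)
  }
  b1 <- run(rbind(c(2, rg0 + 1)), NULL, 1)
  expect_equal(nrow(b1$basins), 1)
  expect_equal(b1$basins$min_energy, 0)

  b2 <- run(rbind(c(1.5, rg0 + 1), c(4, rg0 - 2)), c(0.7, 0.3), 2)
  expect_equal(nrow(b2$basins), 2)
  # rank 1 is the 0.7 state: its relative occupancy among assigned frames
  rel <- b2$basins$n_frames[1] / sum(b2$basins$n_frames)
  se <- sqrt(0.7 * 0.3 / (6000 / (2 * 40)))
  expect_lt(abs(rel - 0.7), 3 * se)

  b4 <- run(cbind(c(1, 3, 5, 7), rg0 + c(1, -2, 3, -4)), rep(0.25, 4), 3)
  expect_equal(nrow(b4$basins), 4)
  # ranks are a permutation ordered by minimum energy
  expect_equal(b4$basins$rank, 1:4)
  expect_true(all(diff(b4$basins$min_energy) >= 0))
})

test_that("lowering the depth cutoff never grows basin membership", {
  rg0 <- reference_rg(40)
  sp <- basin_spec(rbind(c(1.5, rg0 + 1), c(4, rg0 - 2)), c(0.6, 0.4),
                   dwell = 40, seed = 5)
  tr <- make_basin_trajectory(sp, 4000)
  g <- fel(rmsd_series(tr, "CA", reference = "input_structure"),
           rg_series(tr, mask = "CA", mass_weighted = FALSE))
  sizes <- vapply(c(1.5, 1.0, 0.5, 0.25), function(cut) {
    sum(segment_basins(g, cut)$basins$n_bins)
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
  expect_error(segment_basins(g, -5), "depth_cutoff")
})

test_that("basin extraction yields the medoid and basin-restricted dynamics", {
  rg0 <- reference_rg(40)
  sp <- basin_spec(rbind(c(1.5, rg0 + 1), c(5, rg0 - 2)), c(0.7, 0.3),
                   dwell = 40, seed = 9)
  tr <- make_basin_trajectory(sp, 4000)
  rs <- rmsd_series(tr, "CA", reference = "input_structure")
  gs <- rg_series(tr, mask = "CA", mass_weighted = FALSE)
  b <- segment_basins(fel(rs, gs))
  ext <- extract_basin(tr, b, rank = 1)
  # medoid is a member and minimises RMSD to the basin mean
  expect_true(ext$conformer$medoid_frame_global %in% ext$frames)
  sp_sub <- superpose_mean(ext$trajectory, "CA")
  d <- vapply(seq_len(nrow(sp_sub$xyz)), function(i) {
    sqrt(mean(rowSums((matrix(sp_sub$xyz[i, ], ncol = 3, byrow = TRUE)[sp_sub$mask, ] -
                         sp_sub$mean)^2)))
  }, numeric(1))
  expect_equal(which.min(d), ext$conformer$medoid_frame)
  # members sit near the planted rank-1 centre
  expect_lt(abs(median(rs$value[ext$frames]) - 1.5), 0.2)
  # basin-restricted fluctuations are smaller than the two-state mixture
  rep1 <- basin_report(ext$trajectory)
  global_rmsf <- rmsf_profile(tr)
  expect_lt(mean(rep1$rmsf$value), mean(global_rmsf$value))
})

test_that("a single-basin report reproduces the global analysis", {
  rg0 <- reference_rg(30)
  sp <- basin_spec(rbind(c(2, rg0 + 1)), dwell = 40, seed = 12)
  tr <- make_basin_trajectory(sp, 2000, n_residues = 30)
  rs <- rmsd_series(tr, "CA", reference = "input_structure")
  gs <- rg_series(tr, mask = "CA", mass_weighted = FALSE)
  b <- segment_basins(fel(rs, gs))
  expect_equal(nrow(b$basins), 1)
  ext <- extract_basin(tr, b)
  # most frames belong to the single basin at the default cutoff
  expect_gt(length(ext$frames) / 2000, 0.6)
  # the basin report of the full trajectory is the global analysis
  rep_all <- basin_report(tr)
  expect_equal(mean(rep_all$rmsf$value), mean(rmsf_profile(tr)$value),
               tolerance = 1e-10)
  expect_equal(rep_all$metrics$value[rep_all$metrics$kind == "rmsd"],
               rmsd_series(tr, "CA")$value, tolerance = 1e-12)
  # Calpha-only input cannot be DSSP'd
  expect_error(basin_report(ext$trajectory, dssp = TRUE), "backbone")
})

test_that("basin counts respond to binning and the sensitivity table reports it", {
  rg0 <- reference_rg(40)
  sp <- basin_spec(rbind(c(1.5, rg0 + 1), c(4, rg0 - 2)), c(0.6, 0.4),
                   dwell = 40, seed = 14)
  tr <- make_basin_trajectory(sp, 4000)
  rs <- rmsd_series(tr, "CA", reference = "input_structure")
  gs <- rg_series(tr, mask = "CA", mass_weighted = FALSE)
  sens <- basin_count_sensitivity(rs, gs)
  expect_equal(sens$n_bins, c(30, 50, 70))
  expect_true(all(sens$n_basins >= 1))
})
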