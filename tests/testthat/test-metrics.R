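rigid_rotate <- function(co, angle = pi / 3, shift = c(1, -2, 3)) {
  R <- matrix(c(cos(angle), sin(angle), 0,
                -sin(angle), cos(angle), 0,
                0, 0, 1), 3, 3)
  sweep(co %*% R, 2, shift, "+")
}

test_that("kabsch recovers rigid motions exactly and matches a quaternion search", {
  set.seed(1)
  A <- matrix(rnorm(30), 10, 3)
  expect_equal(kabsch(A, A)$rmsd, 0, tolerance = 1e-12)
  expect_equal(kabsch(A, A)$rotation, diag(3), tolerance = 1e-8)

  B <- rigid_rotate(A)
  fit <- kabsch(B, A)
  expect_lt(fit$rmsd, 1e-10)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-10)

  # independent numeric minimisation over quaternion-parameterised rotations
  C <- matrix(rnorm(30), 10, 3)
  expect_equal(kabsch(A, C)$rmsd, brute_force_rmsd(A, C), tolerance = 1e-6)

  # symmetry
  expect_equal(kabsch(A, C)$rmsd, kabsch(C, A)$rmsd, tolerance = 1e-10)
  # invariance to pre-rotation of either input
  expect_equal(kabsch(rigid_rotate(A), C)$rmsd, kabsch(A, C)$rmsd,
               tolerance = 1e-10)

  expect_error(kabsch(matrix(c(0, 0, 0, 1, 1, 1, 2, 2, 2), 3, 3, byrow = TRUE),
                      matrix(rnorm(9), 3, 3)), "degenerate")
})

test_that("rmsd series vanishes for static and rigid-body trajectories", {
  top <- mdcompare:::ca_topology(12)
  ref <- mdcompare:::ca_reference(12)
  static <- trajectory(top, t(replicate(4, as.numeric(t(ref)))), label = "s")
  expect_equal(rmsd_series(static)$value, rep(0, 4), tolerance = 1e-10)

  rigid <- trajectory(top, t(vapply(1:4, function(i) {
    as.numeric(t(rigid_rotate(ref, angle = i / 3, shift = c(i, 0, -i))))
  }, numeric(36))), label = "r")
  expect_equal(rmsd_series(rigid)$value, rep(0, 4), tolerance = 1e-8)
})

test_that("rmsd histogram of a two-basin trajectory is bimodal at the planted centres", {
  rg0 <- reference_rg(40)
  sp <- basin_spec(rbind(c(1.5, rg0 + 1), c(4, rg0 - 1.5)), c(0.5, 0.5),
                   dwell = 40, seed = 8)
  tr <- make_basin_trajectory(sp, 4000)
  rs <- rmsd_series(tr, "CA", reference = "input_structure")$value
  h <- hist(rs, breaks = 40, plot = FALSE)
  modes <- h$mids[h$counts > max(h$counts) / 3]
  expect_true(any(abs(modes - 1.5) < 0.3))
  expect_true(any(abs(modes - 4.0) < 0.3))
  expect_equal(sum(abs(diff(h$counts > max(h$counts) / 3))), 4)  # two humps
})

test_that("rmsf matches the closed form for isotropic displacements", {
  sigma <- 0.8
  spec <- planted_cov_spec(30, list(), base_amplitude = sigma, seed = 17)
  nf <- 10000
  tr <- make_correlated_trajectory(spec, nf)
  rf <- rmsf_profile(tr)
  # per-residue RMSF -> sigma * sqrt(3), deflated by the 6 rigid-body degrees
  # of freedom the superposition removes: total variance 3n sigma^2 drops by
  # 6 sigma^2, i.e. a factor sqrt(1 - 2/n) on the per-residue RMSF
  n_res <- 30
  expect_equal(mean(rf$value), sigma * sqrt(3) * sqrt(1 - 2 / n_res),
               tolerance = 3 / sqrt(2 * nf))
  # Parseval-type identity: mean squared RMSF equals mean squared deviation
  sp <- superpose_mean(tr, "CA")
  X <- mdcompare:::mask_xyz(sp$xyz, sp$mask)
  Xc <- sweep(X, 2, colMeans(X))
  expect_equal(mean(rf$value^2), sum(colMeans(Xc^2)) / 30, tolerance = 1e-10)
})

test_that("rmsf is invariant to rigid-body motion and zero for static input", {
  top <- mdcompare:::ca_topology(10)
  ref <- mdcompare:::ca_reference(10)
  static <- trajectory(top, t(replicate(3, as.numeric(t(ref)))), label = "s")
  expect_equal(rmsf_profile(static)$value, rep(0, 10), tolerance = 1e-10)

  spec <- planted_cov_spec(10, list(), base_amplitude = 0.3, seed = 3)
  tr <- suppressWarnings(make_correlated_trajectory(spec, 50))
  moved <- tr
  moved$xyz <- t(vapply(seq_len(50), function(i) {
    as.numeric(t(rigid_rotate(matrix(tr$xyz[i, ], ncol = 3, byrow = TRUE),
                              angle = i / 10, shift = c(i, -i, 2 * i))))
  }, numeric(30)))
  expect_equal(rmsf_profile(tr)$value, rmsf_profile(moved)$value,
               tolerance = 1e-6)
})

test_that("a planted high-mobility block carries the top RMSF values", {
  amp <- rep(1, 90); amp[83:85] <- 4
  spec <- planted_cov_spec(90, list(), base_amplitude = 0.5, seed = 6,
                           amplitudes = amp)
  tr <- make_correlated_trajectory(spec, 2000)
  rf <- rmsf_profile(tr)
  expect_setequal(rf$resid[order(-rf$value)][1:3], 83:85)
})

test_that("rg matches closed forms and is superposition-independent", {
  top <- mdcompare:::ca_topology(2)
  d <- 3.4
  xyz <- matrix(c(0, 0, 0, d, 0, 0), 1)
  tr <- trajectory(top, rbind(xyz, xyz), label = "pair")
  expect_equal(rg_series(tr, mask = "all", mass_weighted = FALSE)$value[1],
               d / 2, tolerance = 1e-12)

  coincident <- trajectory(top, matrix(c(1, 2, 3, 1, 2, 3), 1), label = "c")
  expect_equal(rg_series(coincident, mask = "all")$value, 0, tolerance = 1e-12)

  # uniform points on a sphere of radius R -> Rg -> R
  set.seed(11)
  R <- 9
  n <- 4000
  v <- matrix(rnorm(3 * n), n, 3)
  v <- R * v / sqrt(rowSums(v^2))
  tops <- mdcompare:::ca_topology(n)
  trs <- trajectory(tops, matrix(as.numeric(t(v)), 1), label = "sphere")
  expect_equal(rg_series(trs, mask = "all", mass_weighted = FALSE)$value, R,
               tolerance = 0.02)

  # rigid motion leaves Rg untouched
  trs2 <- trs
  trs2$xyz <- matrix(as.numeric(t(rigid_rotate(v))), 1)
  expect_equal(rg_series(trs2, mask = "all", mass_weighted = FALSE)$value,
               rg_series(trs, mask = "all", mass_weighted = FALSE)$value,
               tolerance = 1e-9)
})

test_that("sasa matches the isolated-sphere closed form and is additive when far apart", {
  top1 <- mdcompare:::ca_topology(1)
  tr1 <- trajectory(top1, matrix(c(0, 0, 0), 1), label = "atom")
  tr1$topology$atoms$vdw_radius <- 1.9
  s1 <- sasa_series(tr1, mask = "all")$value
  expect_equal(s1, 4 * pi * (1.9 + 1.4)^2, tolerance = 1e-6)

  top2 <- mdcompare:::ca_topology(2)
  tr2 <- trajectory(top2, matrix(c(0, 0, 0, 100, 0, 0), 1), label = "pair")
  tr2$topology$atoms$vdw_radius <- c(1.9, 1.7)
  s2 <- sasa_series(tr2, mask = "all")$value
  expect_equal(s2, 4 * pi * (3.3^2 + 3.1^2), tolerance = 1e-6)

  expect_error(sasa_series(tr1, n_points = 16), "at least 32")
})

test_that("sasa agrees with an independent implementation on a real protein", {
  f <- system.file("examples/1hel.pdb", package = "bio3d")
  st <- read_structure(f)
  tr <- trajectory(st$topology, matrix(st$xyz, 1), label = "1hel")
  mine <- sasa_series(tr, n_points = 480)$value
  oracle <- mdtraj_sasa(f, n_points = 480)
  expect_lt(abs(mine - oracle) / oracle, 0.02)
})
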