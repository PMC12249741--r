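# synthetic essential_subspace built directly from an orthonormal basis
fake_subspace <- function(vectors, values, label = "fake") {
  n <- nrow(vectors) / 3
  structure(list(values = values, vectors = vectors,
                 mean = matrix(0, n, 3),
                 variance_fraction = values / sum(values),
                 projections = matrix(0, 2, ncol(vectors)),
                 resid = seq_len(n), label = label, replicate = 1L),
            class = "essential_subspace")
}

# a trajectory oscillating along one planted unit mode on residues 76:79;
# the mode is orthogonalised against the rigid-body degrees of freedom so
# superposition cannot absorb any of it
planted_mode_traj <- function(n = 90, amp = 2, nf = 600, mode_res = 76:79,
                              noise = 0.02, seed = 3) {
  set.seed(seed)
  ref <- mdcompare:::ca_reference(n)
  refc <- sweep(ref, 2, colMeans(ref))
  mode <- matrix(0, n, 3)
  mode[mode_res, 1] <- 1
  rigid <- cbind(
    as.numeric(matrix(rep(c(1, 0, 0), each = n), n, 3)),
    as.numeric(matrix(rep(c(0, 1, 0), each = n), n, 3)),
    as.numeric(matrix(rep(c(0, 0, 1), each = n), n, 3)),
    as.numeric(cbind(-refc[, 2], refc[, 1], 0)),
    as.numeric(cbind(-refc[, 3], 0, refc[, 1])),
    as.numeric(cbind(0, -refc[, 3], refc[, 2]))
  )
  Qr <- qr.Q(qr(rigid))
  mv <- as.numeric(mode)
  mv <- mv - Qr %*% crossprod(Qr, mv)
  mode <- matrix(mv, n, 3)
  mode <- mode / sqrt(sum(mode^2))
  xyz <- t(vapply(seq_len(nf), function(t) {
    a <- amp * sin(2 * pi * 7 * t / nf)   # several periods: stationary-ish
    as.numeric(t(ref + a * mode + matrix(rnorm(3 * n, sd = noise), n, 3)))
  }, numeric(3 * n)))
  trajectory(mdcompare:::ca_topology(n), xyz, label = "mode",
             ref_xyz = as.numeric(t(ref)))
}

test_that("pca recovers a planted single mode", {
  amp <- 2
  tr <- planted_mode_traj(amp = amp)
  es <- suppressWarnings(essential_dynamics(tr))
  expect_gt(es$variance_fraction[1], 0.9)
  # variance of a * sin(...) is amp^2 / 2 for whole periods
  expect_equal(es$values[1], amp^2 / 2, tolerance = 0.1)
  prof <- pc_profile(es, 1)
  expect_setequal(prof$resid[order(-prof$value)][1:4], 76:79)
})

test_that("subspace satisfies its spectral invariants", {
  spec <- planted_cov_spec(20, list(list(a = c(3, 9), b = c(3, 9), sign = 1,
                                         strength = 0.8)), seed = 12)
  tr <- make_correlated_trajectory(spec, 400)
  es <- essential_dynamics(tr)
  # orthonormal eigenvectors
  G <- crossprod(es$vectors)
  expect_equal(G, diag(ncol(es$vectors)), tolerance = 1e-8)
  # trace conservation: sum of eigenvalues = total variance
  sp <- superpose_mean(tr, "CA")
  X <- mdcompare:::mask_xyz(sp$xyz, sp$mask)
  Xc <- sweep(X, 2, colMeans(X))
  expect_equal(sum(es$values), sum(Xc^2) / nrow(Xc),
               tolerance = 1e-8 * sum(es$values))
  # variance fractions sum to 1; eigenvalues descending
  expect_equal(sum(es$variance_fraction), 1, tolerance = 1e-12)
  expect_true(all(diff(es$values) <= 1e-10))
  # at least 6 near-zero trailing eigenvalues (rigid-body DOF removed)
  expect_lt(es$values[length(es$values) - 5], 1e-3 * es$values[1])
  # projection variance equals the eigenvalue; projections uncorrelated
  pv <- apply(es$projections, 2, function(p) mean(p^2) - mean(p)^2)
  expect_equal(pv[1:10], es$values[1:10], tolerance = 1e-8 * es$values[1])
  cp <- crossprod(es$projections[, 1:5]) / nrow(es$projections)
  expect_equal(cp - diag(diag(cp)), matrix(0, 5, 5),
               tolerance = 1e-8 * es$values[1])
})

test_that("pca matches the bio3d implementation", {
  spec <- planted_cov_spec(15, list(), seed = 22)
  tr <- make_correlated_trajectory(spec, 300)
  es <- essential_dynamics(tr)
  sp <- superpose_mean(tr, "CA")
  ref <- bio3d::pca.xyz(mdcompare:::mask_xyz(sp$xyz, sp$mask))
  # bio3d uses the n-1 divisor; rescale
  expect_equal(es$values[1:10], ref$L[1:10] * (299 / 300), tolerance = 1e-6)
  # leading eigenvector agrees up to sign
  expect_equal(abs(sum(es$vectors[, 1] * ref$U[, 1])), 1, tolerance = 1e-6)
})

test_that("static trajectories give an all-zero spectrum", {
  top <- mdcompare:::ca_topology(8)
  ref <- mdcompare:::ca_reference(8)
  tr <- trajectory(top, t(replicate(5, as.numeric(t(ref)))), label = "s")
  es <- suppressWarnings(essential_dynamics(tr))
  expect_equal(es$values, rep(0, 24), tolerance = 1e-12)
  expect_equal(pc_profile(es, 1)$value, rep(0, 8), tolerance = 1e-12)
})

test_that("pca is frame-order invariant but cosine content is not", {
  tr <- planted_mode_traj(n = 30, nf = 300, mode_res = 10:12)
  es <- suppressWarnings(essential_dynamics(tr))
  set.seed(1)
  perm <- sample(300)
  tr2 <- tr
  tr2$xyz <- tr$xyz[perm, ]
  es2 <- suppressWarnings(essential_dynamics(tr2))
  expect_equal(es$values, es2$values, tolerance = 1e-9)
  expect_equal(abs(diag(crossprod(es$vectors[, 1:3], es2$vectors[, 1:3]))),
               rep(1, 3), tolerance = 1e-4)
  # order sensitivity of the convergence diagnostic
  drift <- cumsum(rep(0.1, 400))
  expect_gt(cosine_content(drift), 0.8)
  expect_false(isTRUE(all.equal(cosine_content(drift),
                                cosine_content(sample(drift)))))
})

test_that("porcupine vectors align with the planted mode direction", {
  tr <- planted_mode_traj(amp = 3, noise = 0.02)
  es <- suppressWarnings(essential_dynamics(tr))
  pq <- porcupine(es, 1, scale = 2)
  v <- as.matrix(pq[pq$resid %in% 76:79, c("dx", "dy", "dz")])
  lens <- sqrt(rowSums(v^2))
  cosang <- abs(v[, 1]) / lens             # planted direction is +x
  expect_true(all(cosang > 0.99))
  # arrows scale linearly and vanish at zero scale
  pq0 <- porcupine(es, 1, scale = 0)
  expect_true(all(pq0$dx == 0 & pq0$dy == 0 & pq0$dz == 0))
  pq1 <- porcupine(es, 1, scale = 1)
  expect_equal(pq$dx, 2 * pq1$dx, tolerance = 1e-12)
  # unscaled squared norms sum to one per PC (orthonormality)
  raw <- matrix(es$vectors[, 1], ncol = 3, byrow = TRUE)
  expect_equal(sum(rowSums(raw^2)), 1, tolerance = 1e-10)
})

test_that("rmsip hits its limiting values and concentrates for random subspaces", {
  D <- 375
  Q <- qr.Q(qr(matrix(rnorm(D * 30), D, 30)))
  a <- fake_subspace(Q[, 1:10], values = seq(10, 1), label = "a")
  expect_equal(rmsip(a, a, k = 10)$value, 1, tolerance = 1e-10)
  b <- fake_subspace(Q[, 11:20], values = seq(10, 1), label = "b")
  expect_equal(rmsip(a, b, k = 10)$value, 0, tolerance = 1e-10)
  # symmetry
  c_ <- fake_subspace(Q[, 21:30], values = seq(10, 1))
  expect_equal(rmsip(a, c_)$value, rmsip(c_, a)$value, tolerance = 1e-12)

  # random-subspace concentration near sqrt(k/D)
  set.seed(99)
  vals <- replicate(60, {
    qa <- qr.Q(qr(matrix(rnorm(D * 10), D, 10)))
    qb <- qr.Q(qr(matrix(rnorm(D * 10), D, 10)))
    rmsip(fake_subspace(qa, 10:1), fake_subspace(qb, 10:1), k = 10)$value
  })
  expect_lt(abs(mean(vals) - sqrt(10 / D)), 0.03)

  # monotone non-decreasing in k against a fixed partner
  r_k <- vapply(1:10, function(k) rmsip(a, c_, k = k)$value * sqrt(k),
                numeric(1))
  expect_true(all(diff(r_k^2) >= -1e-12))

  expect_error(rmsip(a, b, k = 11), "exceeds")
})

test_that("rmsip matches the bio3d implementation", {
  s1 <- planted_cov_spec(20, list(list(a = c(1, 6), b = c(1, 6), sign = 1,
                                       strength = 0.8)), seed = 41)
  s2 <- planted_cov_spec(20, list(list(a = c(10, 16), b = c(10, 16), sign = 1,
                                       strength = 0.8)), seed = 42)
  ea <- essential_dynamics(make_correlated_trajectory(s1, 300))
  eb <- essential_dynamics(make_correlated_trajectory(s2, 300))
  mine <- rmsip(ea, eb, k = 10)$value
  ref <- bio3d::rmsip(ea$vectors, eb$vectors, subset = 10)$rmsip
  expect_equal(mine, ref, tolerance = 1e-10)
})

test_that("cosine content separates cosine, noise and stationary sampling", {
  nf <- 2000
  t <- seq(0, 1, length.out = nf)
  expect_equal(cosine_content(cos(pi * t)), 1, tolerance = 1e-3)
  # second-mode cosine peaks at pc = 2 but not pc = 1
  expect_equal(cosine_content(cos(2 * pi * t), pc = 2), 1, tolerance = 1e-3)
  expect_lt(cosine_content(cos(2 * pi * t), pc = 1), 0.05)

  set.seed(7)
  cc_noise <- replicate(50, cosine_content(rnorm(10000)))
  expect_gte(mean(cc_noise < 0.05), 0.95)

  # stationary planted-mode sampling passes the < 0.7 convergence criterion
  cc_stat <- vapply(1:10, function(s) {
    tr <- planted_mode_traj(n = 30, nf = 500, mode_res = 10:12, seed = s)
    es <- suppressWarnings(essential_dynamics(tr))
    cosine_content(es, 1)
  }, numeric(1))
  expect_gte(mean(cc_stat < 0.7), 0.95)

  expect_warning(z <- cosine_content(rep(0, 100)), "zero-variance")
  expect_equal(z, 0)
})
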