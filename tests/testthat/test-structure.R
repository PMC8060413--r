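test_that("Kabsch RMSD is zero under rigid motion and matches a quaternion oracle", {
  set.seed(1)
  a <- matrix(rnorm(60), ncol = 3)
  expect_equal(kabsch_rmsd(a, a), 0, tolerance = 1e-12)
  expect_lt(kabsch_rmsd(a, random_rigid(a, 7)), 1e-10)
  for (seed in 1:6) {
    set.seed(seed)
    x <- matrix(rnorm(15), ncol = 3)
    y <- matrix(rnorm(15), ncol = 3)
    expect_equal(kabsch_rmsd(x, y), quaternion_rmsd(x, y), tolerance = 1e-9)
  }
  # reflections are not allowed: mirrored coordinates give nonzero RMSD
  set.seed(2)
  x <- matrix(rnorm(30), ncol = 3)
  mirrored <- x %*% diag(c(-1, 1, 1))
  expect_gt(kabsch_rmsd(x, mirrored), 0.1)
  expect_error(kabsch_rmsd(x[1:2, ], x[1:2, ]), ">= 3")
  line <- cbind(1:5, 2 * (1:5), -1 * (1:5))
  expect_error(kabsch_rmsd(line, line), "collinear")
})

test_that("gromos clustering matches a brute-force oracle and honors edge cases", {
  # single frame
  one <- make_helix_ensemble(n_residues = 10, n_frames = 1, seed = 1)
  cs1 <- gromos_cluster(one, 0.15)
  expect_equal(cs1$assignments, 1L)
  expect_equal(cs1$sizes, 1L)
  # cutoff above the ensemble diameter: everything in one cluster
  e <- make_helix_ensemble(n_residues = 10, n_frames = 15, jitter_sigma = 0.03,
                           seed = 2)
  big <- gromos_cluster(e, cutoff = 100)
  expect_equal(big$assignments, rep(1L, 15))
  # oracle equivalence over seeded random ensembles
  for (seed in 1:5) {
    ens <- make_helix_ensemble(n_residues = 8, n_frames = 20,
                               jitter_sigma = 0.12, seed = seed)
    m <- rmsd_matrix(ens)
    cutoff <- stats::median(m[upper.tri(m)])
    expect_identical(gromos_cluster(m, cutoff)$assignments,
                     bruteforce_gromos(m, cutoff))
  }
})

test_that("gromos partitions are stable under frame permutation on tie-free inputs", {
  ens <- make_helix_ensemble(n_residues = 8, n_frames = 18, jitter_sigma = 0.1,
                             seed = 3)
  m <- rmsd_matrix(ens)
  cutoff <- stats::median(m[upper.tri(m)])
  base <- gromos_cluster(m, cutoff)$assignments
  set.seed(4)
  perm <- sample(18)
  permuted <- gromos_cluster(m[perm, perm], cutoff)$assignments
  # same partition up to label names
  expect_equal(length(unique(base)), length(unique(permuted)))
  same_cluster <- function(a) outer(a, a, "==")
  expect_identical(same_cluster(base[perm]), same_cluster(permuted))
})

test_that("pseudo-label distance samples have the Monte-Carlo moments", {
  # two fixed points 3 nm apart
  ca <- array(0, c(1, 2, 3)); ca[1, 2, 1] <- 3
  ens <- conformer_ensemble(ca)
  # label_sigma 0: exact frame distances
  expect_equal(site_distance_samples(ens, 1, 2, label_sigma = 0), 3)
  smp <- site_distance_samples(ens, 1, 2, label_sigma = 0.25, n_draws = 4e4,
                               seed = 5)
  # MC oracle with independent RNG stream
  set.seed(99)
  d <- matrix(rnorm(3 * 1e6, 0, 0.25 * sqrt(2)), ncol = 3)
  d[, 1] <- d[, 1] + 3
  oracle <- sqrt(rowSums(d^2))
  expect_equal(mean(smp), mean(oracle), tolerance = 0.02 / 3)
  expect_equal(sd(smp), sd(oracle), tolerance = 0.05)
  # determinism
  expect_identical(smp, site_distance_samples(ens, 1, 2, 0.25, 4e4, seed = 5))
  expect_error(site_distance_samples(ens, 1, 9), "not found")
})

test_that("KDE discretization is normalized and preserves symmetric bimodality", {
  g <- distance_grid(1.5, 8, 256)
  single <- samples_to_distribution(3.5, g, bandwidth = 0.2)
  expect_equal(trapz_grid(single$r, single$p), 1, tolerance = 1e-9)
  expect_lt(abs(single$r[which.max(single$p)] - 3.5), 0.1)
  set.seed(6)
  two <- c(rnorm(5000, 3, 0.15), rnorm(5000, 5, 0.15))
  d2 <- samples_to_distribution(two, g)
  half <- trapz_grid(d2$r[d2$r <= 4], d2$p[d2$r <= 4])
  expect_equal(half, 0.5, tolerance = 0.02)
  # two local maxima
  p <- d2$p
  peaks <- which(diff(sign(diff(p))) == -2) + 1
  expect_gte(length(peaks), 2)
  expect_error(samples_to_distribution(20, g), "outside")
})

test_that("cluster-size-weighted averaging matches arithmetic on equal clusters", {
  g <- distance_grid(1.5, 8, 128)
  p1 <- make_pr(list(c(3, 0.3, 1)), g)
  p2 <- make_pr(list(c(5, 0.3, 1)), g)
  avg <- cluster_weighted_average(list(p1, p2), c(100, 100))
  expect_equal(avg$mean$p, (p1$p + p2$p) / 2, tolerance = 1e-9)
  expect_true(all(avg$band_low >= 0))
  expect_true(all(avg$band_low <= avg$mean$p + 1e-12))
  expect_true(all(avg$band_high >= avg$mean$p - 1e-12))
  # single cluster: zero-width band
  avg1 <- cluster_weighted_average(list(p1), 100)
  expect_equal(avg1$mean$p, p1$p)
  expect_equal(avg1$band_low, pmax(p1$p, 0))
  expect_equal(avg1$band_high, p1$p)
  expect_error(cluster_weighted_average(list(), integer(0)), "filter")
})

test_that("helix-ensemble prediction peaks at the closed-form helix distance", {
  sep <- 8
  ens <- make_helix_ensemble(n_residues = 20, n_frames = 60,
                             jitter_sigma = 0.02, seed = 11)
  g <- distance_grid(1, 4, 256)
  pred <- predict_distances(ens, 5, 5 + sep, cutoff = 0.15, grid = g,
                            label_sigma = 0.1, n_draws = 400, seed = 12)
  ideal <- ideal_helix_distance(sep)
  mode <- pred$distribution$r[which.max(pred$distribution$p)]
  expect_lt(abs(mode - ideal), 0.2)
  expect_true(all(pred$band_low >= 0))
  w <- pred$clusters$sizes[pred$clusters$kept]
  expect_equal(sum(w / sum(w)), 1)
})

test_that("jitter-free helices are identical frames with the closed-form geometry", {
  ens <- make_helix_ensemble(n_residues = 15, n_frames = 4, jitter_sigma = 0,
                             seed = 1)
  expect_equal(ens$ca[1, , ], ens$ca[4, , ])
  d <- site_distance_samples(ens, 2, 12, label_sigma = 0)
  expect_equal(unique(round(d, 12)), ideal_helix_distance(10), tolerance = 1e-9)
})

test_that("unfolded ensembles spread inter-site distances far beyond helical ones", {
  hel <- make_helix_ensemble(n_residues = 35, n_frames = 120,
                             jitter_sigma = 0.05, seed = 13)
  unf <- make_helix_ensemble(n_residues = 35, n_frames = 120, unfolded = TRUE,
                             seed = 13)
  dh <- site_distance_samples(hel, 3, 33, label_sigma = 0)
  du <- site_distance_samples(unf, 3, 33, label_sigma = 0)
  expect_gte(sd(du), 3 * sd(dh))
  # reproducibility
  unf2 <- make_helix_ensemble(n_residues = 35, n_frames = 120, unfolded = TRUE,
                              seed = 13)
  expect_identical(unf$ca, unf2$ca)
})

test_that("conformer ensembles round-trip through multi-model PDB", {
  ens <- make_helix_ensemble(n_residues = 12, n_frames = 5,
                             jitter_sigma = 0.04, seed = 8)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_ensemble_pdb(ens, path)
  back <- read_ensemble_pdb(path)
  expect_equal(dim(back$ca), dim(ens$ca))
  # PDB stores 3 decimals in Angstrom = 1e-4 nm resolution
  expect_equal(back$ca, ens$ca, tolerance = 1e-3)
  expect_equal(back$cb, ens$cb, tolerance = 1e-3)
})
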