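# projected-gradient reference solver for the same penalized non-negative
# least-squares problem, used as an independent route to check the
# active-set (NNLS) implementation
pg_tikhonov <- function(f, K, r, alpha, iters = 4000) {
  L <- eprdist:::.second_difference(ncol(K))
  H <- crossprod(K) + alpha^2 * crossprod(L)
  g <- crossprod(K, f)
  step <- 1 / max(eigen(H, symmetric = TRUE, only.values = TRUE)$values)
  p <- rep(mean(f) / ncol(K), ncol(K))
  for (i in seq_len(iters)) p <- pmax(p + step * (g - H %*% p), 0)
  w <- c(diff(r) / 2, 0) + c(0, diff(r) / 2)
  distance_distribution(r, drop(p) / w)
}

test_that("the tail fit recovers background rate and modulation depth", {
  P <- make_pr(list(c(3.5, 0.3, 1)))
  tr <- simulate_deer(P, time_grid(), 0.3, background_model(0.05))
  fit <- fit_background(tr)
  expect_equal(fit$bg$k, 0.05, tolerance = 0.05)
  expect_equal(fit$lambda, 0.3, tolerance = 0.02)
  # lambda = 0 trace
  tr0 <- simulate_deer(P, time_grid(), 0, background_model(0.05))
  expect_lte(fit_background(tr0)$lambda, 0.02)
  # flat noiseless trace: B recovered as 1
  flat <- simulate_deer(P, time_grid(), 0, background_model(0))
  fit_flat <- fit_background(flat)
  expect_equal(deer_background(time_grid(), fit_flat$bg),
               rep(1, 251), tolerance = 1e-4)
  expect_error(fit_background(tr, 0.9), "fit_start_fraction")
  short <- deer_trace(time_grid(4, 12), rep(1, 12))
  expect_error(fit_background(short, 0.8), "10 points")
})

test_that("Tikhonov inversion recovers a noiseless Gaussian and returns a normalized density", {
  r <- distance_grid(1.5, 6.3, 128)
  t <- time_grid()
  P <- make_pr(list(c(3.5, 0.3, 1)), r)
  K <- kernel_matrix(t, r)
  p <- eprdist:::.density_to_weights(P)
  f <- drop(K %*% p)
  rec <- tikhonov_invert(f, K, r, alpha = 0.1)
  expect_lte(abs(rec$r[which.max(rec$p)] - 3.5), diff(r[1:2]) + 1e-9)
  expect_true(all(rec$p >= 0))
  expect_equal(trapz_grid(rec$r, rec$p), 1, tolerance = 1e-9)
  expect_error(tikhonov_invert(f, K, r, alpha = -1), "alpha")
})

test_that("roughness decreases and residual increases along the alpha ladder", {
  set.seed(31)
  ds <- make_deer_dataset(deer_ground_truth(seed = 31))
  tr <- ds$trace
  r <- distance_grid(1.5, 6.3, 96)
  K <- kernel_matrix(tr$t, r)
  f <- form_factor(deer_trace(tr$t, tr$v / tr$v[1]),
                   background_model(0.05), 0.3)$f_norm
  L <- eprdist:::.second_difference(ncol(K))
  alphas <- 10^seq(-3, 3, length.out = 13)
  rough <- resid <- numeric(length(alphas))
  for (i in seq_along(alphas)) {
    p <- eprdist:::.tikhonov_solve(f, K, alphas[i], L)
    rough[i] <- sqrt(sum(drop(L %*% p)^2))
    resid[i] <- sqrt(sum((drop(K %*% p) - f)^2))
  }
  expect_true(all(diff(rough) <= 1e-9))
  expect_true(all(diff(resid) >= -1e-9))
})

test_that("the L-curve corner sits inside the grid and matches a dense curvature scan", {
  r <- distance_grid(1.5, 6.3, 96)
  for (seed in c(201, 202, 203)) {
    ds <- make_deer_dataset(deer_ground_truth(seed = seed))
    tr <- ds$trace
    K <- kernel_matrix(tr$t, r)
    f <- form_factor(deer_trace(tr$t, tr$v / tr$v[1]),
                     background_model(0.05), 0.3)$f_norm
    coarse_grid <- 10^seq(-3, 3, length.out = 25)
    coarse <- l_curve_corner(f, K, coarse_grid)
    expect_gt(coarse$alpha, min(coarse_grid))
    expect_lt(coarse$alpha, max(coarse_grid))
    dense <- l_curve_corner(f, K, 10^seq(-3, 3, length.out = 241))
    # dense-scan corner within one coarse-grid step (factor 10^(6/24))
    step <- 10^(6 / 24)
    expect_lte(abs(log10(dense$alpha) - log10(coarse$alpha)), log10(step) + 1e-9)
  }
  # degenerate curve errors (all-zero form factor fits exactly at every alpha)
  K1 <- kernel_matrix(time_grid(4, 64), r)
  expect_error(l_curve_corner(rep(0, 64), K1, 10^seq(-3, 3, length.out = 20)),
               "degenerate")
  expect_error(l_curve_corner(rep(1, 64), K1, 1:5), ">= 20")
})

test_that("the full inversion recovers seeded Gaussian truths end to end", {
  cases <- list(c(3.0, 0.35), c(3.8, 0.25), c(4.4, 0.45))
  for (j in seq_along(cases)) {
    truth <- cases[[j]]
    ds <- make_deer_dataset(deer_ground_truth(
      components = list(c(truth[1], truth[2], 1)), seed = 300 + j))
    inv <- invert_deer(ds$trace)
    m <- distribution_moments(inv$distribution)
    expect_lte(abs(m[["mean"]] - truth[1]), 0.15)
    expect_lte(abs(m[["sd"]] - truth[2]), 0.15)
    expect_equal(trapz_grid(inv$distribution$r, inv$distribution$p), 1,
                 tolerance = 1e-9)
    # noise estimate close to the injected level (lambda/snr = 0.01)
    expect_equal(inv$noise, 0.01, tolerance = 0.35)
  }
})

test_that("bimodal distributions are resolved at high signal-to-noise", {
  ds <- make_deer_dataset(deer_ground_truth(
    components = list(c(3.0, 0.25, 0.5), c(4.2, 0.25, 0.5)), snr = 50,
    seed = 77))
  inv <- invert_deer(ds$trace)
  p <- inv$distribution$p
  peaks <- which(diff(sign(diff(p))) == -2) + 1
  peaks <- peaks[p[peaks] > 0.1 * max(p)]
  expect_gte(length(peaks), 2)
  modes <- sort(inv$distribution$r[peaks])
  expect_lt(abs(modes[1] - 3.0), 0.2)
  expect_lt(abs(modes[length(modes)] - 4.2), 0.2)
})

test_that("active-set and projected-gradient solvers agree on recovered distributions", {
  r <- distance_grid(1.5, 6.3, 80)
  for (seed in c(41, 42, 43)) {
    ds <- make_deer_dataset(deer_ground_truth(seed = seed))
    tr <- ds$trace
    K <- kernel_matrix(tr$t, r)
    f <- form_factor(deer_trace(tr$t, tr$v / tr$v[1]),
                     background_model(0.05), 0.3)$f_norm
    a <- tikhonov_invert(f, K, r, alpha = 10)
    b <- pg_tikhonov(f, K, r, alpha = 10)
    expect_gte(distribution_overlap(a, b), 0.85)
  }
})

test_that("the validation ensemble band is conservative and honors its defaults", {
  expect_equal(eval(formals(validate_uncertainty)$n_noise), 5)
  # zero noise, single background, single realization: zero-width band
  ds0 <- make_deer_dataset(deer_ground_truth(snr = Inf, seed = 51))
  inv0 <- invert_deer(ds0$trace)
  val0 <- validate_uncertainty(inv0, n_backgrounds = 1, n_noise = 1)
  expect_equal(val0$band_low, val0$band_high, tolerance = 1e-12)
  expect_true(all(val0$band_low >= 0))
  # noisy trace, small ensemble: point estimate inside the band
  ds <- make_deer_dataset(deer_ground_truth(seed = 52))
  inv <- invert_deer(ds$trace)
  val <- validate_uncertainty(inv, n_backgrounds = 3, n_noise = 2, seed = 9)
  expect_true(all(val$band_low <= val$distribution$p + 1e-12))
  expect_true(all(val$band_high >= val$distribution$p - 1e-12))
  expect_true(all(val$band_low >= 0))
})
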