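# Synthetic-data generators with known ground truth: Gaussian-mixture
# distance distributions, DEER traces, two-component nitroxide CW spectra,
# and helical / unfolded conformer ensembles. Every generator is
# reproducible under a fixed seed and emits a machine-readable truth
# record.

#' Gaussian-mixture distance distribution
#'
#' @param components list of `c(mean, sigma, weight)` triples (nm, nm,
#'   unitless); weights are renormalized to sum to 1
#' @param grid a `distance_grid`
#' @return a `distance_distribution`
#' @export
make_pr <- function(components, grid = distance_grid()) {
  stopifnot(length(components) >= 1)
  r <- assert_distance_grid(grid)
  w <- vapply(components, `[`, numeric(1), 3)
  if (any(w <= 0) || any(vapply(components, `[`, numeric(1), 2) <= 0))
    stop("component sigmas and weights must be > 0")
  w <- w / sum(w)
  dens <- rep(0, length(r))
  for (i in seq_along(components)) {
    cmp <- components[[i]]
    dens <- dens + w[i] * stats::dnorm(r, cmp[1], cmp[2])
  }
  distance_distribution(r, dens)
}

#' DEER ground-truth record
#'
#' Bundles the parameters of a simulated DEER measurement. `snr` is the
#' modulation-referenced signal-to-noise ratio: the additive trace noise is
#' `lambda / snr` (the dipolar information lives in the modulated part of
#' the echo amplitude).
#'
#' @param components Gaussian mixture components, as in [make_pr()]
#' @param lambda modulation depth in [0, 1]
#' @param k,d background decay rate and dimensionality
#' @param snr modulation-referenced signal-to-noise ratio (Inf = noiseless)
#' @param seed integer RNG seed
#' @return list of class `deer_ground_truth`
#' @export
deer_ground_truth <- function(components = list(c(3.5, 0.3, 1)),
                              lambda = 0.3, k = 0.05, d = 3, snr = 30,
                              seed = 1L) {
  stopifnot(lambda >= 0, lambda <= 1, snr > 0)
  structure(list(components = components, lambda = lambda, k = k, d = d,
                 snr = snr, noise_sigma = if (is.finite(snr)) lambda / snr else 0,
                 seed = as.integer(seed)),
            class = "deer_ground_truth")
}

#' Simulate a DEER dataset with truth side-car
#'
#' Builds the ground-truth distribution, simulates the trace via the
#' forward model, and (optionally) writes the trace file plus a
#' `truth.json` record to a directory.
#'
#' @param truth a `deer_ground_truth`
#' @param t time grid (default 4 us window)
#' @param grid distance grid for the truth distribution
#' @param dir output directory (NULL: no files written)
#' @return list with `trace` (a `deer_trace`), `pr` (the true
#'   `distance_distribution`) and `truth`
#' @export
make_deer_dataset <- function(truth = deer_ground_truth(), t = time_grid(),
                              grid = distance_grid(), dir = NULL) {
  stopifnot(inherits(truth, "deer_ground_truth"))
  pr <- make_pr(truth$components, grid)
  trace <- simulate_deer(pr, t, lambda = truth$lambda,
                         bg = background_model(truth$k, truth$d),
                         noise_sigma = truth$noise_sigma, seed = truth$seed)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_deer_trace(trace, file.path(dir, "trace.dat"))
    jsonlite::write_json(unclass(truth), file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(trace = trace, pr = pr, truth = truth)
}

#' CW ground-truth record
#'
#' Parameters of a synthetic two-component (mobile/immobilized) nitroxide
#' spectrum. The mobile component is a narrow derivative-Lorentzian triplet
#' split by the isotropic nitrogen hyperfine coupling `a_N`; the
#' immobilized component is a broad derivative-Gaussian triplet whose outer
#' extrema sit at the effective splitting `A_zz_eff` from the center field
#' (the EPR convention of reading 2 Azz' between the outer extrema of the
#' derivative spectrum).
#'
#' @param immobilized_fraction fraction of spins in the slow component,
#'   in [0, 1]
#' @param a_N isotropic nitrogen hyperfine splitting, G (default 17.0)
#' @param A_zz_eff effective immobilized splitting, G (default 27.7); must
#'   exceed `a_N`
#' @param mobile_width Lorentzian half-width at half-maximum of the mobile
#'   lines, G
#' @param immob_width_outer,immob_width_center Gaussian sd of the
#'   immobilized outer/center lines, G
#' @param immob_outer_amp amplitude of the outer immobilized lines relative
#'   to the central one
#' @param g center g-value (default 2.0059, nitroxide)
#' @param mw_frequency microwave frequency, GHz
#' @param noise_sigma additive Gaussian noise sd (relative to unit
#'   component amplitude)
#' @param seed integer RNG seed
#' @return list of class `cw_ground_truth`
#' @export
cw_ground_truth <- function(immobilized_fraction = 0, a_N = 17.0,
                            A_zz_eff = 27.7, mobile_width = 1.2,
                            immob_width_outer = 6, immob_width_center = 12,
                            immob_outer_amp = 0.35, g = 2.0059,
                            mw_frequency = 9.6355, noise_sigma = 0,
                            seed = 1L) {
  if (immobilized_fraction < 0 || immobilized_fraction > 1)
    stop("immobilized_fraction must lie in [0, 1]")
  if (a_N >= A_zz_eff) stop("a_N must be smaller than A_zz_eff")
  structure(list(immobilized_fraction = immobilized_fraction, a_N = a_N,
                 A_zz_eff = A_zz_eff, mobile_width = mobile_width,
                 immob_width_outer = immob_width_outer,
                 immob_width_center = immob_width_center,
                 immob_outer_amp = immob_outer_amp, g = g,
                 mw_frequency = mw_frequency, noise_sigma = noise_sigma,
                 seed = as.integer(seed)),
            class = "cw_ground_truth")
}

# unit-maximum derivative Lorentzian (HWHM gamma) and derivative Gaussian
# (sd sigma), as functions of the offset from the line center
.dlorentz <- function(x, gamma) (-x / (x^2 + gamma^2)^2) / (9 / (16 * sqrt(3) * gamma^3))
.dgauss <- function(x, sigma) (-(x / sigma^2) * exp(-x^2 / (2 * sigma^2))) /
  (exp(-0.5) / sigma)

# immobilized-component triplet; the outer-line centers are calibrated
# numerically so the component's low/high-field extrema sit exactly at
# b0 -/+ A_zz_eff (the convention of reading 2 Azz' between the outer
# extrema of the derivative spectrum), despite the overlap with the broad
# central line
.immob_component <- function(field, truth, b0) {
  so <- truth$immob_width_outer
  target <- b0 - truth$A_zz_eff
  build <- function(center_lo) {
    truth$immob_outer_amp * .dgauss(field - center_lo, so) +
      .dgauss(field - b0, truth$immob_width_center) +
      truth$immob_outer_amp * .dgauss(field - (2 * b0 - center_lo), so)
  }
  fine <- seq(target - 8, target + 8, by = 0.01)
  center_lo <- target + so
  for (it in 1:8) {
    comp <- truth$immob_outer_amp * .dgauss(fine - center_lo, so) +
      .dgauss(fine - b0, truth$immob_width_center) +
      truth$immob_outer_amp * .dgauss(fine - (2 * b0 - center_lo), so)
    peak <- fine[which.max(comp)]
    if (abs(peak - target) < 0.02) break
    center_lo <- center_lo + (target - peak)
  }
  build(center_lo)
}

#' Landmark fields of the synthetic two-component spectrum
#'
#' Fields of the mobile and immobilized low-field extrema of the generated
#' spectrum, for use as the LFPR lookup fields on synthetic data (on
#' measured spectra the landmarks are read off the spectra themselves).
#'
#' @param truth a `cw_ground_truth`
#' @return named vector with `mobile` and `immobile` fields (G)
#' @export
cw_landmarks <- function(truth = cw_ground_truth()) {
  b0 <- .center_field_gauss(truth$mw_frequency, truth$g)
  c(mobile = b0 - truth$a_N - truth$mobile_width / sqrt(3),
    immobile = b0 - truth$A_zz_eff)
}

#' Simulate a two-component CW nitroxide spectrum
#'
#' Spectrum = (1 - f) * mobile + f * immobilized + noise on a field grid.
#' The mobile component is three derivative-Lorentzian lines at
#' B0 + {-a_N, 0, +a_N}; the immobilized component is three broad
#' derivative-Gaussian lines whose outer extrema are anchored at
#' B0 -/+ A_zz_eff. B0 = h nu / (g muB).
#'
#' @param truth a `cw_ground_truth`
#' @param field field grid in gauss (default 3330--3530 G, 0.1 G steps)
#' @param dir output directory for `spectrum.dat` + `truth.json`
#'   (NULL: no files)
#' @return a `cw_spectrum`
#' @export
make_cw_spectrum <- function(truth = cw_ground_truth(),
                             field = seq(3330, 3530, by = 0.1), dir = NULL) {
  stopifnot(inherits(truth, "cw_ground_truth"))
  b0 <- .center_field_gauss(truth$mw_frequency, truth$g)
  span <- truth$A_zz_eff + 3 * truth$immob_width_center
  if (min(field) > b0 - span || max(field) < b0 + span)
    stop("field grid does not cover the spectrum (B0 +/- A_zz_eff + 3 widths)")
  mobile <- .dlorentz(field - (b0 - truth$a_N), truth$mobile_width) +
    .dlorentz(field - b0, truth$mobile_width) +
    .dlorentz(field - (b0 + truth$a_N), truth$mobile_width)
  immob <- .immob_component(field, truth, b0)
  f <- truth$immobilized_fraction
  intensity <- (1 - f) * mobile + f * immob
  if (truth$noise_sigma > 0) {
    set.seed(truth$seed)
    intensity <- intensity + stats::rnorm(length(field), 0, truth$noise_sigma)
  }
  s <- cw_spectrum(field, intensity, truth$mw_frequency)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_cw_spectrum(s, file.path(dir, "spectrum.dat"))
    jsonlite::write_json(unclass(truth), file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  s
}

# ideal alpha-helix geometry (nm): rise per residue, twist per residue,
# alpha-carbon helix radius, and the radial/axial offset used to place the
# label reference (beta-carbon) atom
.helix <- list(rise = 0.15, twist = 100 * pi / 180, radius = 0.23,
               cb_radial = 0.145, cb_axial = -0.05)

.helix_coords <- function(n_residues) {
  h <- .helix
  theta <- h$twist * (seq_len(n_residues) - 1)
  z <- h$rise * (seq_len(n_residues) - 1)
  ca <- cbind(h$radius * cos(theta), h$radius * sin(theta), z)
  rr <- h$radius + h$cb_radial
  cb <- cbind(rr * cos(theta), rr * sin(theta), z + h$cb_axial)
  list(ca = ca, cb = cb)
}

#' Closed-form label-site distance on an ideal helix
#'
#' Distance between the label reference atoms of two residues `sep` apart
#' on the ideal helix used by [make_helix_ensemble()] (rise 0.15 nm,
#' 100 deg twist, 0.23 nm alpha-carbon radius).
#'
#' @param sep residue separation (integer >= 1)
#' @param site "cb" (label reference, default) or "ca"
#' @return distance in nm
#' @export
ideal_helix_distance <- function(sep, site = c("cb", "ca")) {
  site <- match.arg(site)
  h <- .helix
  r <- if (site == "cb") h$radius + h$cb_radial else h$radius
  sqrt(2 * r^2 * (1 - cos(h$twist * sep)) + (h$rise * sep)^2)
}

# one self-avoiding random-walk chain with the helix's virtual bond length;
# restarts from the last accepted residue on clashes
.random_walk_chain <- function(n_residues, bond = NULL, min_sep = 0.35,
                               max_tries = 200) {
  if (is.null(bond)) bond <- ideal_helix_distance(1, "ca")
  coords <- matrix(0, n_residues, 3)
  for (i in 2:n_residues) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
      cand <- coords[i - 1, ] + bond * u
      prior <- coords[seq_len(max(i - 2, 1)), , drop = FALSE]
      if (i == 2 || min(sqrt(rowSums(sweep(prior, 2, cand)^2))) >= min_sep) {
        coords[i, ] <- cand; ok <- TRUE; break
      }
    }
    if (!ok) coords[i, ] <- cand   # accept the clash rather than loop forever
  }
  coords
}

#' Synthetic helical (or unfolded) conformer ensemble
#'
#' Helical mode: an ideal alpha-helix backbone (rise 0.15 nm/residue,
#' 100 deg/residue, 0.23 nm radius) with independent Gaussian coordinate
#' jitter per frame. Unfolded mode: per-frame self-avoiding random walks
#' with the helix's virtual bond length, emulating the loss of secondary
#' structure of a proline-disrupted helix and producing a broad inter-site
#' distance spread.
#'
#' @param n_residues chain length (default 40)
#' @param n_frames number of conformers (default 200)
#' @param jitter_sigma per-axis Gaussian jitter sd in nm (helical mode;
#'   default 0.05)
#' @param unfolded replace the helix by random walks (default FALSE)
#' @param seed integer RNG seed
#' @return a `conformer_ensemble`
#' @export
make_helix_ensemble <- function(n_residues = 40, n_frames = 200,
                                jitter_sigma = 0.05, unfolded = FALSE,
                                seed = 1L) {
  stopifnot(n_residues >= 3, n_frames >= 1, jitter_sigma >= 0)
  if (!is.null(seed)) set.seed(as.integer(seed))
  ca <- array(NA_real_, c(n_frames, n_residues, 3))
  cb <- array(NA_real_, c(n_frames, n_residues, 3))
  base <- .helix_coords(n_residues)
  for (fr in seq_len(n_frames)) {
    if (unfolded) {
      chain <- .random_walk_chain(n_residues)
      # label reference offset in a random direction per residue
      dirs <- matrix(stats::rnorm(3 * n_residues), ncol = 3)
      dirs <- dirs / sqrt(rowSums(dirs^2))
      ca[fr, , ] <- chain
      cb[fr, , ] <- chain + 0.153 * dirs
    } else {
      jit <- if (jitter_sigma > 0)
        array(stats::rnorm(n_residues * 3, 0, jitter_sigma),
              c(n_residues, 3)) else 0
      ca[fr, , ] <- base$ca + jit
      cb[fr, , ] <- base$cb + jit
    }
  }
  conformer_ensemble(ca, cb)
}
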