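# CW-EPR spectral preprocessing and the low-field peak ratio (LFPR)
# mobility statistic: field-axis recalculation to a common microwave
# frequency, center-peak normalization, optional Savitzky-Golay smoothing,
# the intensity ratio at the mobile/immobilized low-field landmarks, and a
# baseline-noise error estimate.

#' CW-EPR spectrum container
#'
#' First-derivative absorption spectrum over a magnetic-field axis in gauss
#' with the recording microwave frequency as metadata.
#'
#' @param field magnetic field axis in gauss, strictly increasing,
#'   >= 201 points
#' @param intensity first-derivative intensity, arbitrary units
#' @param mw_frequency microwave frequency in GHz (X band: 9--10 GHz)
#' @return object of class `cw_spectrum`
#' @export
cw_spectrum <- function(field, intensity, mw_frequency) {
  field <- as.numeric(field); intensity <- as.numeric(intensity)
  if (length(field) != length(intensity) || length(field) < 201)
    stop("field and intensity must have equal length >= 201")
  if (any(diff(field) <= 0)) stop("field axis must be strictly increasing")
  if (!is.numeric(mw_frequency) || is.na(mw_frequency))
    stop("microwave frequency is required")
  if (mw_frequency < 9.0 || mw_frequency > 10.0)
    stop("mw_frequency outside the X band (9-10 GHz)")
  structure(list(field = field, intensity = intensity,
                 mw_frequency = mw_frequency), class = "cw_spectrum")
}

#' @export
print.cw_spectrum <- function(x, ...) {
  cat(sprintf("<cw_spectrum> %d points, %.1f-%.1f G at %.4f GHz\n",
              length(x$field), min(x$field), max(x$field), x$mw_frequency))
  invisible(x)
}

#' Recalculate the field axis to a reference microwave frequency
#'
#' Rescales the magnetic-field axis by ref_frequency / mw_frequency so that
#' spectra recorded at slightly different microwave frequencies share a
#' common, g-value-preserving field axis (the resonance condition
#' h nu = g muB B is linear in both nu and B).
#'
#' @param s a `cw_spectrum`
#' @param ref_frequency target frequency in GHz (default 9.6355)
#' @return the rescaled `cw_spectrum` with `mw_frequency = ref_frequency`
#' @export
rescale_field_axis <- function(s, ref_frequency = 9.6355) {
  stopifnot(inherits(s, "cw_spectrum"))
  cw_spectrum(s$field * (ref_frequency / s$mw_frequency), s$intensity,
              ref_frequency)
}

# center-field of the nitroxide triplet from the resonance condition
.center_field_gauss <- function(mw_frequency_ghz, g = .g_nitroxide) {
  .h * mw_frequency_ghz * 1e9 / (g * .muB) * 1e4
}

#' Normalize a spectrum to its center-field peak amplitude
#'
#' Locates the central nitroxide line (the derivative zero crossing nearest
#' the g ~ 2.006 resonance field) and divides the intensity by the maximum
#' within +/- 8 G of it, so the center-line maximum equals 1.
#'
#' @param s a `cw_spectrum`
#' @param window half-width of the search window around the central line, G
#' @return the normalized `cw_spectrum`
#' @export
normalize_center_peak <- function(s, window = 8) {
  stopifnot(inherits(s, "cw_spectrum"))
  b0 <- .center_field_gauss(s$mw_frequency)
  # downward zero crossing (derivative line center) nearest the resonance field
  sgn <- sign(s$intensity)
  idx <- which(sgn[-length(sgn)] > 0 & sgn[-1] <= 0)
  if (length(idx) == 0) stop("no derivative zero crossing found")
  cross <- s$field[idx]
  center <- cross[which.min(abs(cross - b0))]
  sel <- abs(s$field - center) <= window
  peak <- max(s$intensity[sel])
  if (!is.finite(peak) || peak <= 0)
    stop("no positive center-peak maximum within the search window")
  cw_spectrum(s$field, s$intensity / peak, s$mw_frequency)
}

#' Savitzky-Golay smoothing of a spectrum
#'
#' Polynomial least-squares smoothing preserving the spectrum length.
#' Defaults follow common practice for low-signal nitroxide spectra:
#' order 2, frame 101.
#'
#' @param s a `cw_spectrum`
#' @param order polynomial order (default 2)
#' @param frame odd window length in points (default 101), > order and
#'   < spectrum length
#' @return the smoothed `cw_spectrum`
#' @export
smooth_spectrum <- function(s, order = 2, frame = 101) {
  stopifnot(inherits(s, "cw_spectrum"))
  if (frame %% 2 != 1) stop("frame must be odd")
  if (frame <= order) stop("frame must exceed the polynomial order")
  if (frame >= length(s$field)) stop("frame must be shorter than the spectrum")
  cw_spectrum(s$field, signal::sgolayfilt(s$intensity, p = order, n = frame),
              s$mw_frequency)
}

# linear interpolation of intensity at a field value
.intensity_at <- function(s, field) {
  if (field < min(s$field) || field > max(s$field))
    stop(sprintf("field %.1f G outside the spectrum axis", field))
  stats::approx(s$field, s$intensity, xout = field)$y
}

#' Low-field peak ratio (LFPR)
#'
#' Intensity ratio I(field_mobile) / I(field_immobile) at the two low-field
#' landmarks of a two-component nitroxide spectrum: the mobile component's
#' low-field peak and the characteristic peak of the slow (immobilized)
#' component. The spectrum should be field-rescaled and center-peak
#' normalized first. Intensities are looked up by linear interpolation.
#'
#' @param s a `cw_spectrum`
#' @param field_mobile field of the mobile-component peak, G
#'   (default 3415.3)
#' @param field_immobile field of the immobilized-component peak, G
#'   (default 3404.6)
#' @param floor smallest admissible |denominator| (default 1e-6); below it
#'   the ratio is undefined and an error is raised
#' @return the raw intensity ratio (dimensionless)
#' @export
lfpr <- function(s, field_mobile = 3415.3, field_immobile = 3404.6,
                 floor = 1e-6) {
  stopifnot(inherits(s, "cw_spectrum"))
  num <- .intensity_at(s, field_mobile)
  den <- .intensity_at(s, field_immobile)
  if (abs(den) < floor)
    stop("intensity at the immobilized-component field is below the floor; LFPR undefined")
  num / den
}

#' Normalize an LFPR against a reference spectrum's LFPR
#'
#' Ratios are reported relative to the same labeled protein free in
#' solution, so that 1 means "no mobility change".
#'
#' @param sample raw LFPR of the sample spectrum
#' @param reference raw LFPR of the reference (solution) spectrum
#' @return normalized ratio sample / reference
#' @export
normalize_lfpr <- function(sample, reference) {
  if (!is.finite(reference) || reference == 0)
    stop("reference LFPR must be finite and non-zero")
  sample / reference
}

#' Noise-based error estimate for an LFPR
#'
#' Estimates the spectrum noise over the outermost baseline margins of the
#' field axis (default 5% per side, where no nitroxide signal lies) with
#' the successive-difference estimator sd(diff)/sqrt(2), which is
#' insensitive to smooth baseline trends, and reports it relative to the
#' magnitude of the intensity at the immobilized-component low-field peak
#' (the ratio denominator).
#'
#' @param s a `cw_spectrum`
#' @param field_immobile denominator landmark field, G (default 3404.6)
#' @param margin_fraction baseline width per side as a fraction of the axis
#'   (default 0.05)
#' @return noise / |I(field_immobile)|, dimensionless, >= 0
#' @export
lfpr_error <- function(s, field_immobile = 3404.6, margin_fraction = 0.05) {
  stopifnot(inherits(s, "cw_spectrum"))
  n <- length(s$field)
  m <- floor(margin_fraction * n)
  if (m < 10) stop("baseline margin shorter than 10 points")
  lo <- s$intensity[seq_len(m)]
  hi <- s$intensity[seq(n - m + 1, n)]
  noise <- stats::sd(c(diff(lo), diff(hi))) / sqrt(2)
  den <- abs(.intensity_at(s, field_immobile))
  if (den == 0) stop("zero intensity at the immobilized-component field")
  noise / den
}

#' LFPR analysis of a sample/reference spectrum pair
#'
#' Runs the full chain: field rescale to the reference frequency,
#' center-peak normalization, optional Savitzky-Golay smoothing of the
#' sample, LFPR of both spectra, normalization, and the noise error bar.
#'
#' @param sample,reference `cw_spectrum` objects (reference: same label
#'   site free in solution)
#' @param smooth apply Savitzky-Golay smoothing (order 2, frame 101) to the
#'   sample spectrum before the ratio (default FALSE)
#' @param ref_frequency common field-axis frequency, GHz
#' @param field_mobile,field_immobile landmark fields, G
#' @return list with `raw_ratio`, `reference_ratio`, `normalized_ratio`,
#'   `error`
#' @export
lfpr_analysis <- function(sample, reference, smooth = FALSE,
                          ref_frequency = 9.6355,
                          field_mobile = 3415.3, field_immobile = 3404.6) {
  prep <- function(s, do_smooth) {
    s <- rescale_field_axis(s, ref_frequency)
    s <- normalize_center_peak(s)
    if (do_smooth) s <- smooth_spectrum(s)
    s
  }
  sam <- prep(sample, smooth)
  ref <- prep(reference, FALSE)
  raw <- lfpr(sam, field_mobile, field_immobile)
  rr <- lfpr(ref, field_mobile, field_immobile)
  list(raw_ratio = raw, reference_ratio = rr,
       normalized_ratio = normalize_lfpr(raw, rr),
       error = lfpr_error(sam, field_immobile))
}

#' Write a CW spectrum as two-column ASCII
#' @param s a `cw_spectrum`
#' @param path output file
#' @export
write_cw_spectrum <- function(s, path) {
  hdr <- c("# eprdist CW spectrum",
           sprintf("# mw_frequency = %s", format(s$mw_frequency, digits = 15)),
           "# columns: field_G intensity")
  writeLines(c(hdr, sprintf("%.6f %.12g", s$field, s$intensity)), path)
  invisible(path)
}

#' Read a CW spectrum from two-column ASCII
#'
#' Whitespace- or comma-separated columns (field in G, intensity) with a
#' '#'-prefixed `mw_frequency = <GHz>` header line.
#'
#' @param path input file
#' @return a `cw_spectrum`
#' @export
read_cw_spectrum <- function(path) {
  d <- .read_ascii_xy(path)
  if (is.null(d$meta$mw_frequency))
    stop("spectrum file lacks an mw_frequency header")
  cw_spectrum(d$x, d$y, as.numeric(d$meta$mw_frequency))
}
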