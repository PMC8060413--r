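# Forward physics of four-pulse DEER: point-dipole frequency, powder-average
# kernel, intermolecular background, trace simulation. Units are fixed
# package-wide: times us, distances nm, frequencies MHz.

# CODATA physical constants (SI)
.mu0 <- 1.25663706212e-6   # vacuum permeability, N A^-2
.muB <- 9.2740100783e-24   # Bohr magneton, J T^-1
.h   <- 6.62607015e-34     # Planck constant, J s
.g_e <- 2.00231930436      # free-electron g-factor
.g_nitroxide <- 2.0059     # isotropic nitroxide g (CW center field)

# dipolar constant D in MHz nm^3, computed from constants (approx 52.041)
.dipolar_D <- .mu0 * .g_e^2 * .muB^2 / (4 * pi * .h) * 1e27 / 1e6

#' Point-dipole coupling frequency of a spin pair
#'
#' Returns the dipolar frequency nu_dd = D / r^3 for two electron spins a
#' distance r apart, with D = mu0 g^2 muB^2 / (4 pi h) evaluated from CODATA
#' constants at the free-electron g (approx 52.04 MHz nm^3).
#'
#' @param r inter-spin distance(s) in nm, > 0
#' @return frequency in MHz
#' @export
dipolar_frequency <- function(r) {
  r <- as.numeric(r)
  if (any(!is.finite(r)) || any(r <= 0)) stop("distance must be positive and finite")
  .dipolar_D / r^3
}

# powder-average kernel value for angular frequency*time products wt >= 0,
# via Fresnel sine/cosine integrals:
#   K = int_0^1 cos((1 - 3 z^2) wt) dz = [cos(wt) C(u) + sin(wt) S(u)] / u,
#   u = sqrt(6 wt / pi)
.kernel_fresnel <- function(wt) {
  out <- rep(1, length(wt))
  pos <- wt > 1e-12
  if (any(pos)) {
    u <- sqrt(6 * wt[pos] / pi)
    out[pos] <- (cos(wt[pos]) * pracma::fresnelC(u) +
                 sin(wt[pos]) * pracma::fresnelS(u)) / u
  }
  out
}

# fixed-order Gauss-Legendre quadrature fallback for the same integral
.kernel_quadrature <- function(wt, n_nodes = 1001L) {
  gl <- pracma::gaussLegendre(n_nodes, 0, 1)
  vapply(wt, function(w) sum(gl$w * cos((1 - 3 * gl$x^2) * w)), numeric(1))
}

#' Dipolar kernel matrix
#'
#' Builds the forward operator K with K[i, j] the powder-averaged dipolar
#' modulation for evolution time t_i and inter-spin distance r_j,
#' K(t, r) = int_0^1 cos[(1 - 3 z^2) 2 pi nu_dd(r) t] dz, evaluated in
#' closed form via Fresnel integrals (or fixed-order Gauss-Legendre
#' quadrature). Every column equals 1 at t = 0.
#'
#' @param t time grid (us), first point 0
#' @param r distance grid (nm)
#' @param method "fresnel" (closed form, default) or "quadrature"
#' @return numeric matrix, length(t) x length(r)
#' @export
kernel_matrix <- function(t, r, method = c("fresnel", "quadrature")) {
  method <- match.arg(method)
  t <- assert_time_grid(t)
  r <- assert_distance_grid(r)
  wt <- outer(t, 2 * pi * dipolar_frequency(r))   # angular freq * time
  K <- if (method == "fresnel") .kernel_fresnel(wt) else .kernel_quadrature(wt)
  matrix(K, nrow = length(t), ncol = length(r))
}

#' Intermolecular background model
#'
#' Stretched-exponential background B(t) = exp(-k t^(d/3)) of a homogeneous
#' d-dimensional distribution of surrounding spins; d = 3 is the ordinary
#' exponential background of a frozen solution.
#'
#' @param k decay rate (us^(-d/3)), >= 0
#' @param d effective dimensionality in [1, 6] (default 3)
#' @return object of class `background_model`
#' @export
background_model <- function(k = 0.05, d = 3) {
  stopifnot(is.numeric(k), is.numeric(d))
  if (k < 0) stop("background decay rate k must be >= 0")
  if (d < 1 || d > 6) stop("background dimensionality d must lie in [1, 6]")
  structure(list(k = k, d = d), class = "background_model")
}

#' Evaluate a background model on a time grid
#' @param t time grid (us)
#' @param model a `background_model`
#' @return background values, B(0) = 1
#' @export
deer_background <- function(t, model) {
  stopifnot(inherits(model, "background_model"))
  t <- as.numeric(t)
  exp(-model$k * t^(model$d / 3))
}

#' DEER trace container
#'
#' @param t time grid (us)
#' @param amplitude echo amplitudes
#' @param lambda modulation depth in [0, 1] (optional metadata)
#' @param noise_sigma noise level used in simulation (optional)
#' @param seed RNG seed used in simulation (optional)
#' @return object of class `deer_trace`
#' @export
deer_trace <- function(t, amplitude, lambda = NA_real_, noise_sigma = NA_real_,
                       seed = NA_integer_) {
  t <- assert_time_grid(t)
  amplitude <- as.numeric(amplitude)
  stopifnot(length(amplitude) == length(t))
  if (any(!is.finite(amplitude))) stop("trace amplitude must be finite")
  structure(list(t = t, v = amplitude,
                 lambda = lambda, noise_sigma = noise_sigma, seed = seed),
            class = "deer_trace")
}

#' @export
print.deer_trace <- function(x, ...) {
  cat(sprintf("<deer_trace> %d points, window %.2f us%s\n", length(x$t),
              max(x$t),
              if (is.finite(x$lambda)) sprintf(", lambda %.2f", x$lambda) else ""))
  invisible(x)
}

# discretize a density into kernel weights p so that sum(p) = 1 = (K p)(0);
# trapezoid rule on the distribution's grid
.density_to_weights <- function(dist) {
  r <- dist$r
  n <- length(r)
  w <- c(diff(r) / 2, 0) + c(0, diff(r) / 2)  # trapezoid weights
  p <- dist$p * w
  p / sum(p)
}

#' Simulate a four-pulse DEER trace
#'
#' Forward model V(t) = [(1 - lambda) + lambda (K p)] B(t) + eps with K the
#' powder-average dipolar kernel, p the distance distribution discretized
#' with trapezoid weights (so K p = 1 at t = 0), B the intermolecular
#' background and eps i.i.d. Gaussian noise.
#'
#' @param P a `distance_distribution`
#' @param t time grid (us)
#' @param lambda modulation depth in [0, 1]
#' @param bg a `background_model`
#' @param noise_sigma Gaussian noise standard deviation (>= 0)
#' @param seed integer RNG seed for reproducible noise (optional)
#' @return a `deer_trace` with V(0) = 1 before noise
#' @export
simulate_deer <- function(P, t = time_grid(), lambda = 0.3,
                          bg = background_model(), noise_sigma = 0,
                          seed = NULL) {
  stopifnot(inherits(P, "distance_distribution"))
  if (lambda < 0 || lambda > 1) stop("modulation depth lambda must lie in [0, 1]")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  t <- assert_time_grid(t)
  K <- kernel_matrix(t, P$r)
  p <- .density_to_weights(P)
  v <- ((1 - lambda) + lambda * drop(K %*% p)) * deer_background(t, bg)
  if (noise_sigma > 0) {
    if (!is.null(seed)) set.seed(as.integer(seed))
    v <- v + stats::rnorm(length(v), 0, noise_sigma)
  }
  deer_trace(t, v, lambda = lambda, noise_sigma = noise_sigma,
             seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

#' Form factor of a DEER trace
#'
#' Divides the trace by its intermolecular background, F(t) = V(t)/B(t), and
#' normalizes the modulated part to the modulation depth so the dipolar
#' oscillation spans [0, 1]: Ftilde = (F - (1 - lambda)) / lambda.
#'
#' @param trace a `deer_trace`
#' @param bg fitted or known `background_model`
#' @param lambda modulation depth in (0, 1]
#' @return list with `t`, `f` (raw form factor) and `f_norm`
#'   (modulation-depth-normalized form factor)
#' @export
form_factor <- function(trace, bg, lambda) {
  stopifnot(inherits(trace, "deer_trace"))
  if (lambda <= 0 || lambda > 1) stop("lambda must lie in (0, 1]")
  B <- deer_background(trace$t, bg)
  if (any(B == 0)) stop("background vanishes on the time grid")
  f <- trace$v / B
  list(t = trace$t, f = f, f_norm = (f - (1 - lambda)) / lambda)
}

#' Write a DEER trace as two-column ASCII
#'
#' Emits '#'-prefixed header lines with metadata followed by
#' whitespace-separated columns t (us) and V.
#'
#' @param trace a `deer_trace`
#' @param path output file
#' @export
write_deer_trace <- function(trace, path) {
  hdr <- c("# eprdist DEER trace",
           sprintf("# lambda = %s", format(trace$lambda, digits = 15)),
           sprintf("# noise_sigma = %s", format(trace$noise_sigma, digits = 15)),
           sprintf("# seed = %s", format(trace$seed)),
           "# columns: t_us V")
  body <- sprintf("%.10g %.17g", trace$t, trace$v)
  writeLines(c(hdr, body), path)
  invisible(path)
}

# parse "# key = value" headers from a two-column ASCII file
.read_ascii_xy <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^\\s*#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    m <- regmatches(h, regexec("^\\s*#\\s*([A-Za-z_][A-Za-z0-9_]*)\\s*=\\s*(\\S+)", h))[[1]]
    if (length(m) == 3) meta[[m[2]]] <- m[3]
  }
  body <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  body <- gsub(",", " ", body)   # tolerate comma separators
  xy <- do.call(rbind, lapply(strsplit(trimws(body), "\\s+"), function(f)
    as.numeric(f[1:2])))
  list(x = xy[, 1], y = xy[, 2], meta = meta)
}

#' Read a DEER trace from two-column ASCII
#'
#' Accepts whitespace- or comma-separated columns (t in us, echo amplitude)
#' with optional '#'-prefixed `key = value` header lines (lambda,
#' noise_sigma, seed).
#'
#' @param path input file
#' @return a `deer_trace`
#' @export
read_deer_trace <- function(path) {
  d <- .read_ascii_xy(path)
  num <- function(k) if (is.null(d$meta[[k]])) NA_real_ else as.numeric(d$meta[[k]])
  deer_trace(d$x, d$y, lambda = num("lambda"), noise_sigma = num("noise_sigma"),
             seed = if (is.null(d$meta$seed)) NA_integer_ else
               suppressWarnings(as.integer(d$meta$seed)))
}
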