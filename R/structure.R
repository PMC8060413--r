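# Distance-distribution prediction from conformer ensembles of a structural
# model: Kabsch superposition RMSD, gromos clustering, pseudo-label
# broadening of inter-site distances, kernel density estimation, and
# cluster-size-weighted averaging with an uncertainty band.

#' Conformer ensemble container
#'
#' Per-frame coordinates of a chain's alpha carbons (superposition/RMSD
#' reference) and label-attachment reference atoms (beta carbons, falling
#' back to the alpha carbon where absent). All coordinates in nm.
#'
#' @param ca numeric array n_frames x n_residues x 3 of alpha-carbon
#'   coordinates (nm)
#' @param cb like `ca`, label reference atoms (default: `ca`)
#' @param residues residue identifiers (default 1..n_residues)
#' @return object of class `conformer_ensemble`
#' @export
conformer_ensemble <- function(ca, cb = ca, residues = NULL) {
  stopifnot(is.array(ca), length(dim(ca)) == 3, dim(ca)[3] == 3)
  stopifnot(identical(dim(ca), dim(cb)))
  if (dim(ca)[1] < 1) stop("ensemble needs >= 1 frame")
  if (is.null(residues)) residues <- seq_len(dim(ca)[2])
  stopifnot(length(residues) == dim(ca)[2])
  structure(list(ca = ca, cb = cb, residues = residues),
            class = "conformer_ensemble")
}

#' @export
print.conformer_ensemble <- function(x, ...) {
  cat(sprintf("<conformer_ensemble> %d frames x %d residues\n",
              dim(x$ca)[1], dim(x$ca)[2]))
  invisible(x)
}

n_frames <- function(e) dim(e$ca)[1]

.frame_coords <- function(e, i, what = "ca") {
  matrix(e[[what]][i, , ], ncol = 3)
}

.check_nondegenerate <- function(m) {
  if (nrow(m) < 3) stop("superposition needs >= 3 atoms")
  sv <- svd(scale(m, scale = FALSE))$d
  if (sv[2] < 1e-10 * max(sv[1], 1e-300))
    stop("degenerate (collinear) coordinate set: superposition not defined")
}

#' Optimal-superposition RMSD (Kabsch)
#'
#' Root-mean-square deviation after optimal rigid-body alignment
#' (translation plus proper rotation; reflections excluded) of two
#' equally-sized coordinate sets.
#'
#' @param a,b numeric matrices N x 3 (nm), N >= 3, matching atom order
#' @param selection optional index vector of rows to superpose on
#' @return RMSD in nm
#' @export
kabsch_rmsd <- function(a, b, selection = NULL) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!is.null(selection)) { a <- a[selection, , drop = FALSE]
                             b <- b[selection, , drop = FALSE] }
  if (nrow(a) != nrow(b)) stop("coordinate sets must have equal atom counts")
  .check_nondegenerate(a); .check_nondegenerate(b)
  a0 <- scale(a, scale = FALSE); b0 <- scale(b, scale = FALSE)
  sv <- svd(crossprod(a0, b0))
  d <- sign(det(sv$u %*% t(sv$v)))
  # ||a0||^2 + ||b0||^2 - 2 tr(Sigma') with the smallest singular value
  # sign-flipped when the optimal orthogonal map would be a reflection
  s <- sv$d; s[3] <- s[3] * d
  msd <- (sum(a0^2) + sum(b0^2) - 2 * sum(s)) / nrow(a)
  sqrt(max(msd, 0))
}

#' Pairwise alpha-carbon RMSD matrix of an ensemble
#' @param ensemble a `conformer_ensemble`
#' @return symmetric n_frames x n_frames matrix (nm)
#' @export
rmsd_matrix <- function(ensemble) {
  n <- n_frames(ensemble)
  frames <- lapply(seq_len(n), function(i) .frame_coords(ensemble, i))
  m <- matrix(0, n, n)
  if (n > 1) for (i in 1:(n - 1)) for (j in (i + 1):n)
    m[i, j] <- m[j, i] <- kabsch_rmsd(frames[[i]], frames[[j]])
  m
}

#' gromos clustering of a conformer ensemble
#'
#' Greedy geometric clustering on the pairwise alpha-carbon RMSD matrix:
#' repeatedly take the unassigned frame with the most neighbors within the
#' cutoff as a cluster center, assign it and its neighbors to a new
#' cluster, remove them, and repeat until no frame remains. Ties in the
#' neighbor count are broken toward the lowest frame index.
#'
#' @param ensemble a `conformer_ensemble` (or a precomputed RMSD matrix)
#' @param cutoff RMSD neighborhood cutoff in nm (> 0); 0.15 nm suits
#'   compact helical bundles, 0.2 nm looser ensembles
#' @param min_members size filter for `kept`: clusters need more than this
#'   many members; default scales the 50-of-1000 convention as 5% of the
#'   frame count
#' @return object of class `cluster_set`: fields `assignments` (frame ->
#'   cluster id, in discovery order), `sizes`, `centers` (frame index per
#'   cluster), `kept` (cluster ids passing the size filter), `cutoff`,
#'   `min_members`
#' @export
gromos_cluster <- function(ensemble, cutoff = 0.15, min_members = NULL) {
  if (cutoff <= 0) stop("cutoff must be > 0")
  m <- if (is.matrix(ensemble)) ensemble else rmsd_matrix(ensemble)
  n <- nrow(m)
  if (is.null(min_members)) min_members <- 0.05 * n
  assignments <- rep(NA_integer_, n)
  centers <- integer(0)
  remaining <- seq_len(n)
  cl <- 0L
  while (length(remaining) > 0) {
    cl <- cl + 1L
    neigh <- lapply(remaining, function(i)
      remaining[m[i, remaining] <= cutoff])   # includes i itself
    counts <- lengths(neigh)
    center <- remaining[which.max(counts)]    # which.max: first max = lowest index
    members <- neigh[[which.max(counts)]]
    assignments[members] <- cl
    centers[cl] <- center
    remaining <- setdiff(remaining, members)
  }
  sizes <- as.integer(table(factor(assignments, levels = seq_len(cl))))
  structure(list(assignments = assignments, sizes = sizes, centers = centers,
                 kept = which(sizes > min_members), cutoff = cutoff,
                 min_members = min_members),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("<cluster_set> %d clusters over %d frames (cutoff %.3g nm); %d kept (> %g members)\n",
              length(x$sizes), length(x$assignments), x$cutoff,
              length(x$kept), x$min_members))
  invisible(x)
}

#' Inter-site distance samples with pseudo-label broadening
#'
#' For each selected frame, takes the inter-site distance between the two
#' label reference atoms (beta carbons, alpha-carbon fallback) and draws
#' `n_draws` realizations in which each effective label position is
#' displaced by independent Gaussian noise of `label_sigma` per axis. The
#' broadening emulates the conformational spread of the nitroxide label
#' tether without a rotamer library.
#'
#' @param ensemble a `conformer_ensemble`
#' @param site_i,site_j residue identifiers of the two labeled sites
#' @param label_sigma per-site, per-axis label displacement sd in nm
#'   (default 0.25)
#' @param n_draws draws per frame (default 200)
#' @param seed integer RNG seed
#' @param frames frame indices to use (default all)
#' @return numeric vector of distance samples (nm)
#' @export
site_distance_samples <- function(ensemble, site_i, site_j,
                                  label_sigma = 0.25, n_draws = 200,
                                  seed = NULL, frames = NULL) {
  stopifnot(inherits(ensemble, "conformer_ensemble"))
  if (label_sigma < 0) stop("label_sigma must be >= 0")
  ii <- match(site_i, ensemble$residues)
  jj <- match(site_j, ensemble$residues)
  if (is.na(ii) || is.na(jj)) stop("labeled site not found in the ensemble")
  if (ii == jj) stop("the two labeled sites must differ")
  if (is.null(frames)) frames <- seq_len(n_frames(ensemble))
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (label_sigma == 0) n_draws <- 1L
  out <- numeric(0)
  for (fr in frames) {
    pi <- ensemble$cb[fr, ii, ]; pj <- ensemble$cb[fr, jj, ]
    if (label_sigma == 0) { out <- c(out, sqrt(sum((pi - pj)^2))); next }
    di <- matrix(stats::rnorm(3 * n_draws, 0, label_sigma), ncol = 3)
    dj <- matrix(stats::rnorm(3 * n_draws, 0, label_sigma), ncol = 3)
    delta <- sweep(di - dj, 2, pi - pj, "+")
    out <- c(out, sqrt(rowSums(delta^2)))
  }
  out
}

#' Kernel density estimate of distance samples on a grid
#'
#' Gaussian KDE evaluated on the distance grid and renormalized to unit
#' trapezoid integral. Default bandwidth: Silverman's rule on the pooled
#' samples.
#'
#' @param samples distance samples in nm
#' @param grid a `distance_grid`
#' @param bandwidth kernel sd in nm (default: Silverman via
#'   [stats::bw.nrd0()])
#' @return a `distance_distribution`
#' @export
samples_to_distribution <- function(samples, grid = distance_grid(),
                                    bandwidth = NULL) {
  samples <- as.numeric(samples)
  if (length(samples) < 1) stop("need >= 1 sample")
  r <- assert_distance_grid(grid)
  if (all(samples < min(r) | samples > max(r)))
    stop("all samples fall outside the distance grid")
  if (is.null(bandwidth))
    bandwidth <- if (length(samples) > 1 && stats::sd(samples) > 0)
      stats::bw.nrd0(samples) else 0.05
  dens <- vapply(r, function(x)
    mean(stats::dnorm(x, mean = samples, sd = bandwidth)), numeric(1))
  distance_distribution(r, dens)
}

#' Cluster-size-weighted average of predicted distributions
#'
#' Averages the per-cluster distance distributions with weights
#' proportional to cluster size; the uncertainty band is the pointwise
#' weighted standard deviation around the mean, with the lower boundary
#' clipped at 0. The mean is renormalized to unit integral.
#'
#' @param per_cluster list of `distance_distribution` objects on a shared
#'   grid (one per kept cluster)
#' @param sizes cluster sizes, same length
#' @return list with `mean` (a `distance_distribution`), `band_low`,
#'   `band_high`
#' @export
cluster_weighted_average <- function(per_cluster, sizes) {
  if (length(per_cluster) < 1)
    stop("no cluster passed the size filter; lower min_members")
  stopifnot(length(per_cluster) == length(sizes), all(sizes > 0))
  r <- per_cluster[[1]]$r
  for (d in per_cluster) if (!isTRUE(all.equal(d$r, r)))
    stop("per-cluster distributions must share a grid")
  w <- sizes / sum(sizes)
  dens <- do.call(rbind, lapply(per_cluster, `[[`, "p"))
  mu <- drop(w %*% dens)
  sdv <- sqrt(drop(w %*% sweep(dens, 2, mu)^2))
  list(mean = distance_distribution(r, mu),
       band_low = pmax(mu - sdv, 0), band_high = mu + sdv)
}

#' Structure-model distance-distribution prediction
#'
#' Full prediction pipeline: gromos clustering of the ensemble, size filter
#' (more than `min_members` members), pseudo-label distance sampling from
#' each kept cluster's center frame, KDE, and cluster-size-weighted
#' averaging with an uncertainty band.
#'
#' @inheritParams gromos_cluster
#' @inheritParams site_distance_samples
#' @param grid distance grid for the prediction
#' @param bandwidth KDE bandwidth (nm), NULL for Silverman
#' @return list with `distribution`, `band_low`, `band_high`, `clusters`
#'   (the `cluster_set`)
#' @export
predict_distances <- function(ensemble, site_i, site_j, cutoff = 0.15,
                              grid = distance_grid(), label_sigma = 0.25,
                              n_draws = 200, seed = NULL,
                              min_members = NULL, bandwidth = NULL) {
  cs <- gromos_cluster(ensemble, cutoff, min_members)
  if (length(cs$kept) == 0)
    stop("no cluster passed the size filter; lower min_members or the cutoff")
  if (!is.null(seed)) set.seed(as.integer(seed))
  per_cluster <- lapply(cs$kept, function(cl)
    samples_to_distribution(
      site_distance_samples(ensemble, site_i, site_j, label_sigma, n_draws,
                            seed = NULL, frames = cs$centers[cl]),
      grid, bandwidth))
  avg <- cluster_weighted_average(per_cluster, cs$sizes[cs$kept])
  list(distribution = avg$mean, band_low = avg$band_low,
       band_high = avg$band_high, clusters = cs)
}

#' Write a conformer ensemble as a multi-model PDB file
#'
#' One MODEL per frame with CA and CB ATOM records (residue type ALA,
#' chain A); coordinates converted nm -> Angstrom.
#'
#' @param ensemble a `conformer_ensemble`
#' @param path output file
#' @export
write_ensemble_pdb <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "conformer_ensemble"))
  con <- file(path, "w")
  on.exit(close(con))
  nr <- dim(ensemble$ca)[2]
  for (fr in seq_len(n_frames(ensemble))) {
    writeLines(sprintf("MODEL     %4d", fr), con)
    serial <- 0L
    for (res in seq_len(nr)) {
      for (atom in c("CA", "CB")) {
        serial <- serial + 1L
        xyz <- ensemble[[tolower(atom)]][fr, res, ] * 10   # nm -> Angstrom
        writeLines(sprintf(
          "ATOM  %5d  %-3s ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
          serial, atom, ensemble$residues[res], xyz[1], xyz[2], xyz[3]), con)
      }
    }
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a conformer ensemble from a multi-model PDB file
#'
#' Extracts CA (and CB where present; alpha-carbon fallback otherwise) per
#' residue from each MODEL; coordinates converted Angstrom -> nm.
#'
#' @param path multi-model PDB file
#' @return a `conformer_ensemble`
#' @export
read_ensemble_pdb <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE)
  xyz <- pdb$xyz                      # n_frames x 3*n_atoms
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  ca_sel <- bio3d::atom.select(pdb, elety = "CA")
  resno <- pdb$atom$resno[ca_sel$atom]
  nfr <- nrow(xyz); nres <- length(resno)
  grab <- function(sel_xyz) {
    arr <- array(NA_real_, c(nfr, length(sel_xyz) / 3, 3))
    for (fr in seq_len(nfr)) arr[fr, , ] <- matrix(xyz[fr, sel_xyz],
                                                   ncol = 3, byrow = TRUE)
    arr / 10                          # Angstrom -> nm
  }
  ca <- grab(ca_sel$xyz)
  cb <- ca
  cb_sel <- bio3d::atom.select(pdb, elety = "CB")
  if (length(cb_sel$atom) > 0) {
    cb_resno <- pdb$atom$resno[cb_sel$atom]
    cb_arr <- grab(cb_sel$xyz)
    idx <- match(cb_resno, resno)
    cb[, idx[!is.na(idx)], ] <- cb_arr[, !is.na(idx), , drop = FALSE]
  }
  conformer_ensemble(ca, cb, residues = resno)
}
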