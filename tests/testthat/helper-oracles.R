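# Independent oracles used across the suite.

# stratified Monte-Carlo powder average of the dipolar modulation for one
# (t, r) pair: one uniform draw per stratum of z in [0, 1]
mc_kernel <- function(t_us, r_nm, n = 2e5, seed = 1) {
  set.seed(seed)
  z <- (seq_len(n) - stats::runif(n)) / n
  w <- 2 * pi * dipolar_frequency(r_nm)
  mean(cos((1 - 3 * z^2) * w * t_us))
}

# quaternion (Horn) superposition RMSD, independent of the SVD route
quaternion_rmsd <- function(a, b) {
  a0 <- scale(a, scale = FALSE); b0 <- scale(b, scale = FALSE)
  M <- crossprod(a0, b0)
  Sxx <- M[1,1]; Sxy <- M[1,2]; Sxz <- M[1,3]
  Syx <- M[2,1]; Syy <- M[2,2]; Syz <- M[2,3]
  Szx <- M[3,1]; Szy <- M[3,2]; Szz <- M[3,3]
  N <- matrix(c(
    Sxx+Syy+Szz, Syz-Szy,      Szx-Sxz,      Sxy-Syx,
    Syz-Szy,     Sxx-Syy-Szz,  Sxy+Syx,      Szx+Sxz,
    Szx-Sxz,     Sxy+Syx,     -Sxx+Syy-Szz,  Syz+Szy,
    Sxy-Syx,     Szx+Sxz,      Syz+Szy,     -Sxx-Syy+Szz), 4, 4)
  lam <- max(eigen(N, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(a0^2) + sum(b0^2) - 2 * lam) / nrow(a)
  sqrt(max(msd, 0))
}

# brute-force gromos clustering that recomputes neighbor counts from the
# full matrix at every round
bruteforce_gromos <- function(m, cutoff) {
  n <- nrow(m)
  assignments <- rep(NA_integer_, n)
  cl <- 0L
  repeat {
    remaining <- which(is.na(assignments))
    if (length(remaining) == 0) break
    cl <- cl + 1L
    counts <- sapply(remaining, function(i) sum(m[i, remaining] <= cutoff))
    center <- remaining[which(counts == max(counts))[1]]
    members <- remaining[m[center, remaining] <= cutoff]
    assignments[members] <- cl
  }
  assignments
}

# random rigid-body transform of a coordinate matrix
random_rigid <- function(x, seed) {
  set.seed(seed)
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  R <- matrix(c(
    1-2*(q[3]^2+q[4]^2), 2*(q[2]*q[3]-q[1]*q[4]), 2*(q[2]*q[4]+q[1]*q[3]),
    2*(q[2]*q[3]+q[1]*q[4]), 1-2*(q[2]^2+q[4]^2), 2*(q[3]*q[4]-q[1]*q[2]),
    2*(q[2]*q[4]-q[1]*q[3]), 2*(q[3]*q[4]+q[1]*q[2]), 1-2*(q[2]^2+q[3]^2)),
    3, 3, byrow = TRUE)
  sweep(x %*% t(R), 2, stats::rnorm(3), "+")
}
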