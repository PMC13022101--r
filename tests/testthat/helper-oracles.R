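# Independent oracles and tiny fixtures shared across test files.  Oracles
# deliberately avoid the code paths they check: the quaternion RMSD uses an
# eigen-decomposition (not SVD/Kabsch), the lDDT oracle is a plain double
# loop, and the RMSF oracle is a literal transcription of the definition.

# Horn's quaternion method: minimal RMSD between paired point sets from the
# largest eigenvalue of the 4x4 key matrix.
quaternion_rmsd <- function(mobile, ref) {
  n <- nrow(mobile)
  p <- sweep(mobile, 2, colMeans(mobile))
  q <- sweep(ref, 2, colMeans(ref))
  M <- t(p) %*% q
  K <- matrix(c(
    M[1, 1] + M[2, 2] + M[3, 3], M[2, 3] - M[3, 2],
    M[3, 1] - M[1, 3], M[1, 2] - M[2, 1],
    M[2, 3] - M[3, 2], M[1, 1] - M[2, 2] - M[3, 3],
    M[1, 2] + M[2, 1], M[3, 1] + M[1, 3],
    M[3, 1] - M[1, 3], M[1, 2] + M[2, 1],
    -M[1, 1] + M[2, 2] - M[3, 3], M[2, 3] + M[3, 2],
    M[1, 2] - M[2, 1], M[3, 1] + M[1, 3],
    M[2, 3] + M[3, 2], -M[1, 1] - M[2, 2] + M[3, 3]), 4, 4, byrow = TRUE)
  lambda <- max(eigen(K, symmetric = TRUE)$values)
  sqrt(max((sum(p^2) + sum(q^2) - 2 * lambda) / n, 0))
}

# Literal per-residue RMSF: loop transcription of
# sqrt(mean_t ||r_i(t) - <r_i>||^2) on an n x 3 x T array.
naive_rmsf <- function(coords) {
  n <- dim(coords)[1]; T <- dim(coords)[3]
  out <- numeric(n)
  for (i in seq_len(n)) {
    mu <- c(mean(coords[i, 1, ]), mean(coords[i, 2, ]), mean(coords[i, 3, ]))
    acc <- 0
    for (t in seq_len(T)) acc <- acc + sum((coords[i, , t] - mu)^2)
    out[i] <- sqrt(acc / T)
  }
  out
}

# Brute-force per-residue lDDT by pair enumeration (one atom per residue).
naive_lddt <- function(ref, frame, r0 = 15, thresholds = c(0.5, 1, 2, 4)) {
  n <- nrow(ref)
  scores <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    kept <- 0L; total <- 0L
    for (j in seq_len(n)) {
      if (j == i) next
      d0 <- sqrt(sum((ref[i, ] - ref[j, ])^2))
      if (d0 >= r0) next
      dt <- sqrt(sum((frame[i, ] - frame[j, ])^2))
      for (tau in thresholds) {
        total <- total + 1L
        if (abs(d0 - dt) < tau) kept <- kept + 1L
      }
    }
    if (total > 0) scores[i] <- kept / total
  }
  scores
}

# Direct covariance-formula Pearson correlation.
naive_pearson <- function(x, y) {
  n <- length(x)
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# Random rigid transform applied to an n x 3 matrix.
random_rigid <- function(coords, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  rot <- q %*% diag(c(1, 1, det(q)))
  sweep(coords %*% t(rot), 2, rnorm(3, sd = 10), `+`)
}

# Small deterministic non-degenerate point cloud.
point_cloud <- function(n, seed) {
  set.seed(seed)
  matrix(rnorm(3 * n, sd = 3), n, 3)
}

# Convenience: tiny stationary synthetic system.
tiny_system <- function(n_residues = 8, n_frames = 30, sigma = 0.25,
                        seed = 42, ...) {
  generate_trajectory(synthetic_spec(n_residues = n_residues,
                                     n_frames = n_frames, sigma = sigma,
                                     seed = seed, ...))
}
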