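# Independent oracles used across the suite.

# Quaternion (Horn) superposition: rmsd of B onto A via the largest
# eigenvalue of the 4x4 key matrix.  Independent of the SVD-based
# implementation under test.
quaternion_rmsd <- function(A, B) {
  A0 <- sweep(A, 2, colMeans(A))
  B0 <- sweep(B, 2, colMeans(B))
  M <- t(B0) %*% A0
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  K <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy, Szx - Sxz, Sxy - Syx,
    Syz - Szy, Sxx - Syy - Szz, Sxy + Syx, Szx + Sxz,
    Szx - Sxz, Sxy + Syx, -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx, Szx + Sxz, Syz + Szy, -Sxx - Syy + Szz
  ), 4, 4, byrow = TRUE)
  lambda <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(A0^2) + sum(B0^2) - 2 * lambda) / nrow(A)
  sqrt(max(msd, 0))
}

# O(n^2) dominance oracle: TRUE where some other point is <= on both
# axes and strictly < on at least one.
brute_force_dominated <- function(x, y) {
  n <- length(x)
  vapply(seq_len(n), function(i) {
    any(vapply(seq_len(n), function(j) {
      j != i && x[j] <= x[i] && y[j] <= y[i] &&
        (x[j] < x[i] || y[j] < y[i])
    }, TRUE))
  }, TRUE)
}

# brute-force repulsive energy over all heavy-atom pairs, with the same
# exclusion rule (bonded graph distance <= 3), written against the
# documented closed form rather than the C++ path
brute_force_rep <- function(s) {
  ns <- getNamespace("scaffrelax")
  tmpl <- ns$.aa_templates()
  n <- nrow(s$atom)
  res <- s$atom$res
  rad <- numeric(n)
  ai <- integer(n)
  for (r in seq_len(max(res))) {
    idx <- which(res == r)
    ai[idx] <- seq_along(idx)
    rad[idx] <- tmpl[[s$resname[r]]]$radius
  }
  total <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      r1 <- res[i]; r2 <- res[j]
      if (r1 == r2) {
        if (tmpl[[s$resname[r1]]]$gdist[ai[i], ai[j]] <= 3) next
      } else if (abs(r1 - r2) == 1) {
        lo <- min(r1, r2)
        hi <- max(r1, r2)
        alo <- if (r1 < r2) ai[i] else ai[j]
        ahi <- if (r1 < r2) ai[j] else ai[i]
        if (tmpl[[s$resname[lo]]]$gdist[alo, 3] + 1 +
          tmpl[[s$resname[hi]]]$gdist[ahi, 1] <= 3) {
          next
        }
      }
      d <- sqrt(sum((s$xyz[i, ] - s$xyz[j, ])^2))
      sigma <- rad[i] + rad[j]
      if (d >= sigma) next
      if (d >= 0.6 * sigma) {
        total <- total + (sigma / d)^12 - 1
      } else {
        t12 <- (1 / 0.6)^12
        total <- total + (t12 - 1) - 12 * t12 / (0.6 * sigma) * (d - 0.6 * sigma)
      }
    }
  }
  total
}

# random rigid motion applied to an n x 3 coordinate matrix
random_rigid <- function(X, seed) {
  set.seed(seed)
  ax <- stats::rnorm(3)
  ax <- ax / sqrt(sum(ax^2))
  th <- stats::runif(1, 0, 2 * pi)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3,
    byrow = TRUE
  )
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  t(R %*% t(X)) + matrix(stats::rnorm(3, 0, 5), nrow(X), 3, byrow = TRUE)
}
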