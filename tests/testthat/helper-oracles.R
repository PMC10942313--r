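# Independent oracles used across the suite. Each reimplements the checked
# quantity by a different route than the package (brute force, enumeration,
# closed form, Monte Carlo) and stays deliberately simple.

# Front partition by explicit dominator counting and peeling: a point joins
# the current front iff no remaining point strictly dominates it.
peel_fronts_oracle <- function(obj) {
  n <- nrow(obj)
  remaining <- seq_len(n)
  fronts <- list()
  while (length(remaining) > 0L) {
    sub <- obj[remaining, , drop = FALSE]
    nondom <- vapply(seq_along(remaining), function(i) {
      dominators <- vapply(seq_along(remaining), function(j) {
        all(sub[j, ] <= sub[i, ]) && any(sub[j, ] < sub[i, ])
      }, logical(1))
      sum(dominators) == 0L
    }, logical(1))
    fronts[[length(fronts) + 1L]] <- remaining[nondom]
    remaining <- remaining[!nondom]
  }
  fronts
}

# Same peeling idea, vectorized for larger instances: build the full
# domination matrix, count dominators per point, peel the zero-count set.
peel_fronts_matrix_oracle <- function(obj) {
  n <- nrow(obj)
  m <- ncol(obj)
  D <- matrix(FALSE, n, n)  # D[i, j]: i dominates j
  for (i in seq_len(n)) {
    le <- rowSums(matrix(obj[i, ], n, m, byrow = TRUE) <= obj) == m
    lt <- rowSums(matrix(obj[i, ], n, m, byrow = TRUE) < obj) > 0
    D[i, ] <- le & lt
  }
  remaining <- rep(TRUE, n)
  fronts <- list()
  while (any(remaining)) {
    idx <- which(remaining)
    counts <- colSums(D[idx, idx, drop = FALSE])
    front <- idx[counts == 0L]
    fronts[[length(fronts) + 1L]] <- front
    remaining[front] <- FALSE
  }
  fronts
}

# Horn's quaternion method for optimal rigid superposition RMSD.
quaternion_rmsd_oracle <- function(a, b) {
  a <- scale(a, scale = FALSE)
  b <- scale(b, scale = FALSE)
  M <- crossprod(a, b)
  Sxx <- M[1,1]; Sxy <- M[1,2]; Sxz <- M[1,3]
  Syx <- M[2,1]; Syy <- M[2,2]; Syz <- M[2,3]
  Szx <- M[3,1]; Szy <- M[3,2]; Szz <- M[3,3]
  N <- matrix(c(
    Sxx+Syy+Szz, Syz-Szy,     Szx-Sxz,     Sxy-Syx,
    Syz-Szy,     Sxx-Syy-Szz, Sxy+Syx,     Szx+Sxz,
    Szx-Sxz,     Sxy+Syx,    -Sxx+Syy-Szz, Syz+Szy,
    Sxy-Syx,     Szx+Sxz,     Syz+Szy,    -Sxx-Syy+Szz), 4, 4, byrow = TRUE)
  lam <- max(eigen(N, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(a^2) + sum(b^2) - 2 * lam) / nrow(a)
  sqrt(max(0, msd))
}

# Monte Carlo rejection estimate of the 2-D dominated area (minimization).
# Samples uniformly in the box spanned by the points' minima and the
# reference; returns the estimate and its standard error.
mc_hypervolume_oracle <- function(points, reference, n_samples = 1e6) {
  keep <- points[, 1] < reference[1] & points[, 2] < reference[2]
  points <- points[keep, , drop = FALSE]
  if (nrow(points) == 0L) return(list(hv = 0, se = 0))
  lo <- c(min(points[, 1]), min(points[, 2]))
  box <- (reference[1] - lo[1]) * (reference[2] - lo[2])
  u1 <- runif(n_samples, lo[1], reference[1])
  u2 <- runif(n_samples, lo[2], reference[2])
  dominated <- rep(FALSE, n_samples)
  for (i in seq_len(nrow(points))) {
    dominated <- dominated | (points[i, 1] <= u1 & points[i, 2] <= u2)
  }
  p <- mean(dominated)
  list(hv = p * box, se = sqrt(p * (1 - p) / n_samples) * box)
}

# Convenience: a small random design problem over a reduced alphabet.
random_toy_design_problem <- function(L = 8, n_designable = 4, A = 6) {
  alphabet <- aa_alphabet()[seq_len(A)]
  ref <- paste(sample(alphabet, L, replace = TRUE), collapse = "")
  make_problem(ref, sort(sample.int(L, n_designable)), alphabet = alphabet)
}
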