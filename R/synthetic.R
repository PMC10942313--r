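#' Build a toy two-state design problem
#'
#' Generates a fully enumerable two-state design task that emulates the
#' tension of multistate design: `L` designable positions over an alphabet
#' of size `A`, with two state-conditioned PSSMs. A configurable fraction of
#' positions is "conflicting" (the two states prefer different modal
#' residues, creating genuine objective tradeoffs) and the rest
#' "non-conflicting" (the modal residue agrees). Modal probability is
#' controlled by a sharpness parameter applied as an inverse softmax
#' temperature on random logits. The problem's reference sequence is the
#' modal sequence of the first state, so at conflict fraction 0 it is modal
#' for both states (the ideal point is attainable); the two procedurally
#' built toy backbones (helix-like and strand-like) stand in for the two
#' conformational states.
#'
#' @param L Number of designable positions (>= 2, default 6).
#' @param A Alphabet size (2..20, default 4; the first `A` standard amino
#'   acids are used).
#' @param conflict_fraction Fraction of positions with disagreeing state
#'   modes, realized exactly after rounding (default 0.5).
#' @param sharpness Inverse softmax temperature > 0 applied to standard
#'   normal logits (default 2; larger values concentrate probability on the
#'   modal residue).
#' @param seed Integer seed; the generator is deterministic given it.
#' @return Object of class `toy_problem`: list with `problem`
#'   (a [make_problem()] result over states `"alpha"` and `"beta"`),
#'   `pssms` (named list of two L x A row-stochastic matrices),
#'   `structures` (two toy `state_structure`s), `conflict_positions`, and
#'   `modal_sequences` (per-state modal strings).
#' @export
make_toy_problem <- function(L = 6L, A = 4L, conflict_fraction = 0.5,
                             sharpness = 2, seed = 1L) {
  L <- as.integer(L); A <- as.integer(A)
  if (L < 2L) stop("L must be >= 2")
  if (A < 2L || A > 20L) stop("A must lie in [2, 20]")
  if (!is.finite(conflict_fraction) || conflict_fraction < 0 || conflict_fraction > 1) {
    stop("conflict_fraction must lie in [0, 1]")
  }
  if (!is.finite(sharpness) || sharpness <= 0) stop("sharpness must be positive")
  alphabet <- aa_alphabet()[seq_len(A)]
  set.seed(seed)

  n_conflict <- round(conflict_fraction * L)
  conflict_positions <- if (n_conflict > 0) sort(sample.int(L, n_conflict)) else integer(0)

  modal_a <- sample.int(A, L, replace = TRUE)
  modal_b <- modal_a
  for (p in conflict_positions) {
    modal_b[p] <- sample(setdiff(seq_len(A), modal_a[p]), 1L)
  }

  pseudo <- 1e-4
  build_pssm <- function(modal) {
    pssm <- matrix(NA_real_, L, A, dimnames = list(NULL, alphabet))
    for (p in seq_len(L)) {
      z <- stats::rnorm(A)
      # force the designated modal residue to carry the largest logit
      top <- which.max(z)
      tmp <- z[modal[p]]; z[modal[p]] <- z[top]; z[top] <- tmp
      w <- exp(sharpness * (z - max(z)))
      probs <- w / sum(w)
      probs <- (probs + pseudo) / (1 + A * pseudo)
      pssm[p, ] <- probs
    }
    pssm
  }
  pssm_a <- build_pssm(modal_a)
  pssm_b <- build_pssm(modal_b)

  reference <- paste(alphabet[modal_a], collapse = "")
  problem <- make_problem(reference, seq_len(L), alphabet = alphabet,
                          state_names = c("alpha", "beta"))
  structures <- list(
    alpha = make_toy_structure(max(3L, L), "helix", seed = seed),
    beta = make_toy_structure(max(3L, L), "strand", seed = seed + 1L)
  )
  structures$alpha$state <- "alpha"
  structures$beta$state <- "beta"
  structure(list(problem = problem,
                 pssms = list(alpha = pssm_a, beta = pssm_b),
                 structures = structures,
                 conflict_positions = conflict_positions,
                 modal_sequences = c(alpha = paste(alphabet[modal_a], collapse = ""),
                                     beta = paste(alphabet[modal_b], collapse = "")),
                 seed = as.integer(seed)),
            class = "toy_problem")
}

#' @export
print.toy_problem <- function(x, ...) {
  cat("Toy two-state problem: L =", x$problem$n_designable,
      ", |alphabet| =", length(x$problem$alphabet),
      ",", length(x$conflict_positions), "conflicting position(s)\n")
  invisible(x)
}

#' Exhaustively enumerate the true Pareto front of a toy problem
#'
#' Evaluates every sequence in the design space on both state objectives
#' (negative mean log-likelihood per state) and returns the exact
#' non-dominated set via a brute-force domination peel. Enumeration is
#' capped at one million sequences.
#'
#' @param toy A `toy_problem`.
#' @return List with `sequences` (character vector of Pareto-optimal
#'   designed strings), `objectives` (matrix of their objective vectors) and
#'   `n_enumerated`.
#' @export
enumerate_pareto_front <- function(toy) {
  problem <- toy$problem
  L <- problem$n_designable
  A <- length(problem$alphabet)
  total <- A^L
  if (total > 1e6) {
    stop(sprintf("enumeration of %g sequences exceeds the 1e6 bound", total))
  }
  grid <- as.matrix(expand.grid(rep(list(seq_len(A)), L)))[, L:1, drop = FALSE]
  lpa <- log(toy$pssms$alpha); lpb <- log(toy$pssms$beta)
  f1 <- f2 <- numeric(total)
  for (p in seq_len(L)) {
    f1 <- f1 + lpa[p, grid[, p]]
    f2 <- f2 + lpb[p, grid[, p]]
  }
  obj <- cbind(alpha = -f1 / L, beta = -f2 / L)
  # sweep in ascending (f1, f2): candidates are points whose f2 does not
  # exceed the best f2 seen so far (ties kept), then verified exactly
  nd <- logical(total)
  ord <- order(obj[, 1], obj[, 2])
  best2 <- Inf
  for (i in ord) {
    nd[i] <- obj[i, 2] <= best2
    if (obj[i, 2] < best2) best2 <- obj[i, 2]
  }
  cand <- which(nd)
  keep <- vapply(cand, function(i) {
    !any(obj[, 1] <= obj[i, 1] & obj[, 2] <= obj[i, 2] &
           (obj[, 1] < obj[i, 1] | obj[, 2] < obj[i, 2]))
  }, logical(1))
  idx <- cand[keep]
  seqs <- apply(grid[idx, , drop = FALSE], 1L, function(r) {
    paste(problem$alphabet[r], collapse = "")
  })
  list(sequences = unname(seqs),
       objectives = obj[idx, , drop = FALSE],
       n_enumerated = total)
}

#' Procedurally build a toy backbone structure
#'
#' Ideal-parameter backbone traces (N, CA, C, O per residue) in valid PDB
#' fields, deterministic given the seed. The helix-like geometry uses a
#' 2.3 Angstrom helical radius, 1.5 Angstrom rise and 100 degrees of twist
#' per residue; the strand-like geometry an extended 3.46 Angstrom rise with
#' an alternating 0.8 Angstrom pleat. Both give consecutive-CA distances of
#' about 3.8 Angstrom. Residue identities are poly-alanine placeholders;
#' residues are numbered 1..n.
#'
#' @param n_residues Number of residues (>= 3).
#' @param geometry `"helix"` or `"strand"`.
#' @param seed Integer seed for the small coordinate jitter (0.02 Angstrom
#'   s.d.) that keeps fixtures from being perfectly degenerate.
#' @param chain Chain identifier (default "A").
#' @return A `state_structure`.
#' @export
make_toy_structure <- function(n_residues, geometry = c("helix", "strand"),
                               seed = 1L, chain = "A") {
  geometry <- match.arg(geometry)
  n_residues <- as.integer(n_residues)
  if (n_residues < 3L) stop("n_residues must be >= 3")
  set.seed(seed)
  i <- seq_len(n_residues)
  if (geometry == "helix") {
    theta <- (i - 1L) * 100 * pi / 180
    ca <- cbind(2.3 * cos(theta), 2.3 * sin(theta), 1.5 * (i - 1L))
  } else {
    ca <- cbind(3.46 * (i - 1L), 0.8 * (-1)^i, rep(0, n_residues))
  }
  ca <- ca + matrix(stats::rnorm(3 * n_residues, sd = 0.02), ncol = 3)
  # place N/C along the chain direction, O off the carbonyl carbon
  dir <- rbind(ca[2, ] - ca[1, ], ca[-1, , drop = FALSE] - ca[-n_residues, , drop = FALSE])
  dir <- dir / sqrt(rowSums(dir^2))
  n_at <- ca - 1.45 * dir
  c_at <- ca + 1.52 * dir
  o_at <- c_at + matrix(rep(c(0, 0, 1.23), each = n_residues), ncol = 3)
  atoms <- do.call(rbind, lapply(i, function(r) {
    data.frame(elety = c("N", "CA", "C", "O"),
               resid = "ALA", chain = chain, resno = r,
               x = c(n_at[r, 1], ca[r, 1], c_at[r, 1], o_at[r, 1]),
               y = c(n_at[r, 2], ca[r, 2], c_at[r, 2], o_at[r, 2]),
               z = c(n_at[r, 3], ca[r, 3], c_at[r, 3], o_at[r, 3]),
               stringsAsFactors = FALSE)
  }))
  state_structure(geometry, atoms)
}

#' Generate reference sequence sets at two divergence levels
#'
#' Stand-ins for annotated sequence databases split into a "like" set (low
#' divergence from the toy reference) and an "unlike" set (high
#' divergence): each sequence mutates the reference independently per
#' position, with per-position mutation probability `divergence` for the
#' like set and `min(1, 3 * divergence)` for the unlike set. These sets are
#' synthetic; they exercise the similarity metrics, not real annotations.
#'
#' @param problem A `design_problem` whose designable-region reference is
#'   mutated.
#' @param n_like,n_unlike Set sizes.
#' @param divergence Per-position mutation probability in \[0, 1) for the
#'   like set.
#' @param seed Integer seed.
#' @return List with `like` and `unlike` character vectors.
#' @export
make_reference_sequence_sets <- function(problem, n_like = 50L, n_unlike = 50L,
                                         divergence = 0.2, seed = 1L) {
  if (!is.finite(divergence) || divergence < 0 || divergence >= 1) {
    stop("divergence must lie in [0, 1)")
  }
  set.seed(seed)
  ref <- strsplit(reference_designed(problem), "")[[1]]
  A <- problem$alphabet
  mutate_set <- function(n, rate) {
    vapply(seq_len(n), function(i) {
      chars <- ref
      hit <- which(stats::runif(length(ref)) < rate)
      for (p in hit) chars[p] <- sample(setdiff(A, ref[p]), 1L)
      paste(chars, collapse = "")
    }, character(1))
  }
  list(like = mutate_set(n_like, divergence),
       unlike = mutate_set(n_unlike, min(1, 3 * divergence)))
}
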