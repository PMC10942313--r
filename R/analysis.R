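#' Native sequence recovery
#'
#' The fraction of designable positions at which a designed sequence is
#' identical to the wild-type (reference) sequence. The population mean of
#' this fraction is the standard per-iteration performance metric.
#'
#' @param designed Designed string, or a `population`.
#' @param problem A `design_problem` (taken from the population if omitted).
#' @return Numeric recovery fraction(s) in \[0, 1\].
#' @export
#' @examples
#' p <- make_problem("ACDEFG", c(2, 4))
#' native_recovery("CD", p)  # 1.0
native_recovery <- function(designed, problem = NULL) {
  if (inherits(designed, "population")) {
    if (is.null(problem)) problem <- designed$problem
    designed <- designed$sequences
  }
  ref <- strsplit(reference_designed(problem), "")[[1]]
  vapply(designed, function(s) {
    chars <- strsplit(s, "")[[1]]
    if (length(chars) != length(ref)) stop("designed length does not match the problem")
    mean(chars == ref)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Per-position sequence entropy
#'
#' Shannon entropy (natural log) of the empirical residue distribution at
#' each designable position of a population: 0 for a conserved column,
#' `log(20)` for a uniformly random 20-letter column.
#'
#' @param sequences Character vector of equal-length sequences, or a
#'   `population`.
#' @return Numeric vector of per-position entropies in nats.
#' @export
positional_entropy <- function(sequences) {
  if (inherits(sequences, "population")) sequences <- sequences$sequences
  if (length(sequences) == 0L) stop("population must be non-empty")
  m <- sequence_matrix(sequences)
  apply(m, 2L, function(col) {
    p <- table(col) / length(col)
    -sum(p * log(p))
  })
}

#' Empirical CDF of per-position entropies
#'
#' @inheritParams positional_entropy
#' @return A `stats::ecdf` function over the per-position entropies.
#' @export
entropy_ecdf <- function(sequences) {
  stats::ecdf(positional_entropy(sequences))
}

#' Exact 2-D hypervolume (minimization)
#'
#' The area of objective space dominated by a point set relative to a
#' reference point, for two minimized objectives: only points that strictly
#' dominate the reference contribute; the non-dominated subset is swept in
#' ascending first coordinate and rectangle areas to the reference are
#' accumulated. Duplicated and dominated points never change the value.
#' Dimensions other than 2 are rejected (higher-dimensional subspaces are
#' out of scope).
#'
#' @param points Numeric matrix with 2 columns (one row per point), or a
#'   length-2 vector for a single point.
#' @param reference Finite length-2 reference point (e.g. `c(0, 0)` for
#'   negated composite-score subspaces, `c(4, 4)` for negative
#'   log-likelihood subspaces).
#' @return The dominated area (>= 0).
#' @export
#' @examples
#' hypervolume_2d(c(-0.8, -0.7), c(0, 0))  # 0.56
hypervolume_2d <- function(points, reference) {
  if (length(reference) != 2L || any(!is.finite(reference))) {
    stop("reference must be a finite length-2 point")
  }
  if (is.null(dim(points))) points <- matrix(points, ncol = length(points))
  points <- as.matrix(points)
  if (ncol(points) != 2L) {
    stop(sprintf("hypervolume is implemented for 2 objectives, got %d", ncol(points)))
  }
  if (nrow(points) == 0L) return(0)
  keep <- points[, 1] < reference[1] & points[, 2] < reference[2]
  points <- points[keep, , drop = FALSE]
  if (nrow(points) == 0L) return(0)
  nd <- fast_non_dominated_sort(points)$rank == 1L
  p <- unique(points[nd, , drop = FALSE])
  p <- p[order(p[, 1], p[, 2]), , drop = FALSE]
  n <- nrow(p)
  area <- 0
  for (i in seq_len(n)) {
    right <- if (i < n) p[i + 1, 1] else reference[1]
    area <- area + (right - p[i, 1]) * (reference[2] - p[i, 2])
  }
  unname(as.numeric(area))
}

# normalized BLOSUM62 lookup tables (built once per session)
blosum_env <- new.env(parent = emptyenv())

blosum62_normalized <- function() {
  if (is.null(blosum_env$mat)) {
    B <- get_blosum62()[aa_alphabet(), aa_alphabet()]
    d <- sqrt(diag(B))
    blosum_env$mat <- B / outer(d, d)
  }
  blosum_env$mat
}

get_blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

#' Normalized BLOSUM62 sequence similarity
#'
#' Mean per-position BLOSUM62 substitution score over the designable
#' positions, normalized so that self-similarity is exactly 1: each
#' per-position score `s(a, b)` is divided by `sqrt(s(a, a) * s(b, b))`
#' before averaging. The measure is symmetric. Because the published
#' description fixes only "normalized", absolute values under other
#' normalizations will differ; relative comparisons are unaffected.
#'
#' @param seq_a,seq_b Equal-length sequences over residues present in
#'   BLOSUM62.
#' @return Normalized similarity (self-similarity 1).
#' @export
blosum_similarity <- function(seq_a, seq_b) {
  a <- strsplit(seq_a, "")[[1]]
  b <- strsplit(seq_b, "")[[1]]
  if (length(a) != length(b)) stop("sequences must have equal length")
  M <- blosum62_normalized()
  if (any(!(a %in% rownames(M))) || any(!(b %in% rownames(M)))) {
    bad <- setdiff(unique(c(a, b)), rownames(M))
    stop(sprintf("residue '%s' not present in the substitution matrix", bad[1]))
  }
  mean(M[cbind(a, b)])
}

#' Pairwise similarity (affinity) matrix of a sequence set
#'
#' Symmetric matrix of normalized BLOSUM62 similarities with unit diagonal,
#' suitable as a precomputed affinity for spectral embedding.
#'
#' @param sequences Character vector of equal-length sequences, or a
#'   `population`.
#' @return Symmetric numeric matrix with unit diagonal.
#' @export
similarity_matrix <- function(sequences) {
  if (inherits(sequences, "population")) sequences <- sequences$sequences
  n <- length(sequences)
  M <- blosum62_normalized()
  chars <- lapply(sequences, function(s) strsplit(s, "")[[1]])
  S <- diag(1, n)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        s <- mean(M[cbind(chars[[i]], chars[[j]])])
        S[i, j] <- s; S[j, i] <- s
      }
    }
  }
  S
}

#' Laplacian-eigenmaps embedding from a precomputed affinity matrix
#'
#' Shifts the affinities to \[0, 1\] by min-max scaling (substitution-based
#' similarities can be negative), forms the symmetric normalized graph
#' Laplacian `I - D^{-1/2} W D^{-1/2}`, and returns the eigenvectors of its
#' smallest nontrivial eigenvalues as embedding coordinates. Signs are fixed
#' by making each eigenvector's largest-magnitude entry positive, so the
#' embedding is deterministic; permuting the input rows permutes the output
#' rows identically.
#'
#' @param affinity Square symmetric affinity matrix (e.g.
#'   [similarity_matrix()]).
#' @param dims Number of embedding dimensions (< nrow(affinity)).
#' @return Numeric matrix (n rows, `dims` columns).
#' @export
spectral_embed <- function(affinity, dims = 2L) {
  affinity <- as.matrix(affinity)
  n <- nrow(affinity)
  if (n != ncol(affinity) || any(abs(affinity - t(affinity)) > 1e-8)) {
    stop("affinity matrix must be square and symmetric")
  }
  dims <- as.integer(dims)
  if (dims >= n) stop(sprintf("dims = %d must be smaller than the matrix size %d", dims, n))
  rng <- range(affinity)
  W <- if (rng[2] > rng[1]) (affinity - rng[1]) / (rng[2] - rng[1]) else
    matrix(1, n, n)
  deg <- rowSums(W)
  if (any(deg <= 0)) stop("affinity matrix has an isolated vertex (zero degree)")
  Dhalf <- 1 / sqrt(deg)
  Lsym <- diag(n) - (Dhalf * W) %*% diag(Dhalf)
  Lsym <- (Lsym + t(Lsym)) / 2
  eig <- eigen(Lsym, symmetric = TRUE)
  # eigenvalues descending; smallest is the trivial component
  idx <- seq.int(n - 1L, by = -1L, length.out = dims)
  coords <- eig$vectors[, idx, drop = FALSE] * Dhalf
  for (j in seq_len(ncol(coords))) {
    k <- which.max(abs(coords[, j]))
    if (coords[k, j] < 0) coords[, j] <- -coords[, j]
  }
  colnames(coords) <- paste0("dim", seq_len(dims))
  coords
}

#' Post hoc non-dominated filtering
#'
#' Returns the indices of the non-dominated subset (front 1) of a set of
#' objective vectors — the post hoc approximation of the Pareto front from a
#' pooled population. Idempotent: filtering a filtered set changes nothing.
#'
#' @param objectives Numeric objective matrix (minimization scale).
#' @return Integer vector of non-dominated row indices.
#' @export
posthoc_nondominated_filter <- function(objectives) {
  fast_non_dominated_sort(objectives)$fronts[[1]]
}

#' Trim an alignment to the reference's designable region
#'
#' Identifies the alignment columns where the reference row carries its
#' designable residues, extracts those columns from every aligned sequence,
#' and discards sequences whose extracted region contains any gap. Gaps are
#' `-` or `.`.
#'
#' @param aligned Named character vector of aligned (equal-length)
#'   sequences, or an `AAStringSet`.
#' @param reference_name Name of the reference row in `aligned`.
#' @param designable_positions 1-based positions into the ungapped reference
#'   sequence.
#' @return List with `sequences` (named character vector of retained
#'   trimmed sequences, gap-free, length = number of designable positions),
#'   `retained`, `dropped` (counts) and `columns` (the alignment columns
#'   used).
#' @export
trim_alignment_to_reference <- function(aligned, reference_name,
                                        designable_positions) {
  if (inherits(aligned, "XStringSet")) {
    aligned <- stats::setNames(as.character(aligned), names(aligned))
  }
  if (!(reference_name %in% names(aligned))) {
    stop(sprintf("reference row '%s' absent from the alignment", reference_name))
  }
  widths <- nchar(aligned)
  if (length(unique(widths)) != 1L) stop("aligned sequences must have equal width")
  ref <- strsplit(aligned[[reference_name]], "")[[1]]
  is_gap <- ref %in% c("-", ".")
  # map ungapped reference position -> alignment column
  col_of <- which(!is_gap)
  pos <- as.integer(designable_positions)
  if (any(pos < 1L | pos > length(col_of))) {
    stop("designable position outside the ungapped reference length")
  }
  columns <- col_of[pos]
  mat <- sequence_matrix(unname(aligned))
  sub <- mat[, columns, drop = FALSE]
  has_gap <- apply(sub, 1L, function(r) any(r %in% c("-", ".")))
  kept <- which(!has_gap)
  seqs <- apply(sub[kept, , drop = FALSE], 1L, paste, collapse = "")
  names(seqs) <- names(aligned)[kept]
  list(sequences = seqs, retained = length(kept),
       dropped = length(aligned) - length(kept), columns = columns)
}

#' Percentile similarity of a candidate to a reference set
#'
#' Computes the normalized BLOSUM62 similarity of the candidate to every
#' sequence in a reference set and returns the `q`-th percentile (default
#' 95). Percentiles use linear interpolation between closest ranks (R's
#' default quantile convention, type 7).
#'
#' @param candidate Designed/trimmed sequence.
#' @param reference_set Non-empty character vector of equal-length
#'   sequences.
#' @param q Percentile in (0, 100\].
#' @return The percentile similarity.
#' @export
percentile_similarity_to_set <- function(candidate, reference_set, q = 95) {
  if (length(reference_set) == 0L) stop("reference set must be non-empty")
  if (!is.finite(q) || q <= 0 || q > 100) stop("q must lie in (0, 100]")
  sims <- vapply(reference_set, function(s) blosum_similarity(candidate, s),
                 numeric(1), USE.NAMES = FALSE)
  unname(stats::quantile(sims, q / 100, type = 7))
}

#' Per-position residue frequency profile of a population
#'
#' The relative frequency of each alphabet residue at each designable
#' position — the matrix behind a sequence logo. Rows (positions) sum to 1.
#'
#' @param sequences Character vector of equal-length sequences, or a
#'   `population`.
#' @param alphabet Residue alphabet for the columns (default: the 20
#'   standard amino acids, or the population's problem alphabet).
#' @return Numeric matrix: positions x alphabet, rows summing to 1.
#' @export
profile_matrix <- function(sequences, alphabet = NULL) {
  if (inherits(sequences, "population")) {
    if (is.null(alphabet)) alphabet <- sequences$problem$alphabet
    sequences <- sequences$sequences
  }
  if (is.null(alphabet)) alphabet <- aa_alphabet()
  if (length(sequences) == 0L) stop("population must be non-empty")
  m <- sequence_matrix(sequences)
  prof <- t(apply(m, 2L, function(col) {
    tab <- table(factor(col, levels = alphabet))
    as.numeric(tab) / length(col)
  }))
  colnames(prof) <- alphabet
  rownames(prof) <- seq_len(nrow(prof))
  prof
}
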