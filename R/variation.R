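#' n-point crossover of two designed sequences
#'
#' Chooses `n` distinct cut points uniformly at random among the `L - 1`
#' junctions of the parents and swaps alternating segments, producing two
#' complementary children: at every position each child carries one parent's
#' residue and its sibling the other's.
#'
#' @param parent_a,parent_b Equal-length designed strings.
#' @param n Number of cut points, `1 <= n < L` (default 2).
#' @return Character vector of the two children.
#' @export
#' @examples
#' set.seed(1)
#' n_point_crossover("AAAA", "BBBB", 2)
n_point_crossover <- function(parent_a, parent_b, n = 2L) {
  L <- nchar(parent_a)
  if (nchar(parent_b) != L) stop("parents must have equal length")
  n <- as.integer(n)
  if (n < 1L || n >= L) stop(sprintf("n = %d cut points invalid for length %d", n, L))
  cuts <- sort(sample.int(L - 1L, n))       # junction i = between position i and i+1
  a <- strsplit(parent_a, "")[[1]]
  b <- strsplit(parent_b, "")[[1]]
  # segment index per position; odd segments from parent A, even swapped
  seg <- findInterval(seq_len(L) - 1L, cuts)
  swap <- seg %% 2L == 1L
  child_a <- a; child_a[swap] <- b[swap]
  child_b <- b; child_b[swap] <- a[swap]
  c(paste(child_a, collapse = ""), paste(child_b, collapse = ""))
}

#' Random position selection for mutation
#'
#' Each designable position is independently considered for redesign with
#' probability `mu`; if the draw leaves no position selected, a single
#' designable position is picked uniformly at random, so the selection is
#' never empty. The selected-position count therefore follows a
#' Binomial(n, mu) law with its zero mass moved to k = 1.
#'
#' @param problem A `design_problem`.
#' @param mu Mutation rate in \[0, 1\].
#' @return Integer vector of selected positions (indices into the designed
#'   string, ascending).
#' @export
select_positions_random <- function(problem, mu) {
  if (!is.finite(mu) || mu < 0 || mu > 1) stop("mu must lie in [0, 1]")
  n <- problem$n_designable
  sel <- which(stats::runif(n) < mu)
  if (length(sel) == 0L) sel <- sample.int(n, 1L)
  sel
}

#' Ranked position selection for mutation
#'
#' Scores the candidate's full spliced sequence once with a position ranker
#' (one finite score per designable position, higher = more native-like),
#' sorts positions ascending by score, and selects the `k` lowest-scoring
#' positions with `k = max(1, Binomial(n, mu))`. Ties in score are broken by
#' position order (stable sort), so the selection is deterministic given the
#' scores and the drawn `k`.
#'
#' @param problem A `design_problem`.
#' @param designed Designed string.
#' @param ranker Function `(full_sequence, problem) -> numeric` of length
#'   `n_designable`.
#' @param mu Mutation rate in \[0, 1\].
#' @return Integer vector of selected positions (ascending).
#' @export
select_positions_ranked <- function(problem, designed, ranker, mu) {
  if (!is.finite(mu) || mu < 0 || mu > 1) stop("mu must lie in [0, 1]")
  n <- problem$n_designable
  full <- to_full_sequence(problem, designed)
  scores <- ranker(full, problem)
  if (length(scores) != n || any(!is.finite(scores))) {
    stop(sprintf("ranker must return %d finite scores, got %d", n, length(scores)))
  }
  k <- max(1L, stats::rbinom(1L, n, mu))
  ord <- order(scores, seq_len(n))   # stable: ties by position index
  sort(ord[seq_len(k)])
}

#' Uniform residue proposal
#'
#' Draws a replacement residue independently and uniformly from the alphabet
#' for each selected position; the current residue may be re-drawn.
#'
#' @param selection Integer vector of selected positions.
#' @param alphabet Character vector of residues.
#' @return Character vector of replacement residues, one per selected
#'   position.
#' @export
propose_uniform <- function(selection, alphabet) {
  if (length(selection) == 0L) stop("selection must be non-empty")
  sample(alphabet, length(selection), replace = TRUE)
}

#' Composite mutation operator
#'
#' The two-stage mutation used in the design loop: a position selector picks
#' which designable positions to redesign, then a residue proposer generates
#' replacements for exactly those positions, conditioned on the full spliced
#' sequence context. The returned candidate differs from the input only at
#' selected positions.
#'
#' @param problem A `design_problem`.
#' @param designed Designed string.
#' @param selector Function `(problem, designed) -> integer vector` of
#'   selected positions.
#' @param proposer Function `(full_sequence, selection, problem) ->
#'   character vector` of replacement residues (all in the alphabet).
#' @return The mutated designed string.
#' @export
mutate <- function(problem, designed, selector, proposer) {
  sel <- selector(problem, designed)
  if (length(sel) == 0L) stop("selector returned an empty selection")
  full <- to_full_sequence(problem, designed)
  res <- proposer(full, sel, problem)
  if (length(res) != length(sel)) {
    stop(sprintf("proposer returned %d residues for %d selected positions",
                 length(res), length(sel)))
  }
  if (any(!(res %in% problem$alphabet))) {
    stop("proposer returned a residue outside the alphabet")
  }
  chars <- strsplit(designed, "")[[1]]
  chars[sel] <- res
  paste(chars, collapse = "")
}

#' PSSM-based position ranker
#'
#' Ranks positions by the log-probability of the current residue under one
#' or more state PSSMs (averaged over states). Low scores flag positions
#' whose current residue is unlikely under the state-conditioned sequence
#' model — the surrogate analogue of ranking positions with a protein
#' language model in a single forward pass without masking.
#'
#' @param pssms A single PSSM matrix or list of PSSM matrices
#'   (`n_designable` rows, one column per alphabet symbol; see
#'   [make_toy_problem()]).
#' @return A ranker function `(full_sequence, problem) -> numeric`.
#' @export
pssm_position_ranker <- function(pssms) {
  if (is.matrix(pssms)) pssms <- list(pssms)
  function(full_sequence, problem) {
    designed <- from_full_sequence(problem, full_sequence)
    chars <- strsplit(designed, "")[[1]]
    idx <- match(chars, problem$alphabet)
    scores <- rep(0, problem$n_designable)
    for (p in pssms) {
      scores <- scores + log(p[cbind(seq_along(idx), idx)])
    }
    scores / length(pssms)
  }
}

# --- plugin registry -------------------------------------------------------

the_registry <- new.env(parent = emptyenv())
the_registry$proposers <- list()
the_registry$rankers <- list()
the_registry$scorers <- list()

#' Register a plugin residue proposer
#'
#' Plugin proposers supply context-aware replacement residues (e.g. an
#' inverse-folding model decoding tied multistate structures). The function
#' must accept `(full_sequence, selection, problem)` and return one alphabet
#' residue per selected position; arity is checked at registration.
#'
#' @param name Plugin name (referenced as `plugin:<name>` in configs).
#' @param fn The proposer function.
#' @return `name`, invisibly.
#' @export
register_proposer <- function(name, fn) {
  if (!is.function(fn) || length(formals(fn)) < 3L) {
    stop("proposer must be a function of (full_sequence, selection, problem)")
  }
  the_registry$proposers[[name]] <- fn
  invisible(name)
}

#' Register a plugin position ranker
#'
#' The function must accept `(full_sequence, problem)` and return one finite
#' score per designable position; arity is checked at registration.
#'
#' @param name Plugin name.
#' @param fn The ranker function.
#' @return `name`, invisibly.
#' @export
register_ranker <- function(name, fn) {
  if (!is.function(fn) || length(formals(fn)) < 2L) {
    stop("ranker must be a function of (full_sequence, problem)")
  }
  the_registry$rankers[[name]] <- fn
  invisible(name)
}

#' Look up a registered ranker
#' @param name Plugin name.
#' @return The ranker function.
#' @export
get_ranker <- function(name) {
  fn <- the_registry$rankers[[name]]
  if (is.null(fn)) stop(sprintf("no ranker registered under '%s'", name))
  fn
}

# Resolve a proposer spec ("uniform" or "plugin:<name>") to a function.
# Missing plugins fail here, before any evaluation starts.
resolve_proposer <- function(spec) {
  if (is.function(spec)) return(spec)
  if (identical(spec, "uniform")) {
    return(function(full_sequence, selection, problem) {
      propose_uniform(selection, problem$alphabet)
    })
  }
  if (startsWith(spec, "plugin:")) {
    name <- sub("^plugin:", "", spec)
    fn <- the_registry$proposers[[name]]
    if (is.null(fn)) stop(sprintf("no proposer plugin registered under '%s'", name))
    return(fn)
  }
  stop(sprintf("unknown proposer '%s' (use 'uniform' or 'plugin:<name>')", spec))
}
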