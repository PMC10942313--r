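#' Declare an objective
#'
#' An objective pairs a name (conventionally the state it targets) with a
#' batch evaluator. All objectives follow the minimization convention:
#' maximization scores (likelihoods, folding-propensity composites) are
#' negated by their evaluators, never affinely rescaled, so reported values
#' keep their natural units with the sign flipped.
#'
#' @param name Objective name (appears in FASTA headers and metrics).
#' @param evaluate Function mapping a character vector of full-length
#'   sequences to a numeric vector of finite objective values
#'   (minimization scale).
#' @param state Optional state identifier the objective targets.
#' @return Object of class `objective_spec`.
#' @export
objective_spec <- function(name, evaluate, state = NULL) {
  stopifnot(is.character(name), length(name) == 1L, is.function(evaluate))
  structure(list(name = name, evaluate = evaluate, state = state),
            class = "objective_spec")
}

#' Composite folding-propensity score
#'
#' The product of the mean predicted per-residue confidence (pLDDT, scaled
#' to \[0, 1\]), the predicted TM-score (pTM), and the TM-score between the
#' template and the predicted structure. Each component lies in \[0, 1\], so
#' the composite is bounded in \[0, 1\] with higher values indicating greater
#' folding propensity; as an objective it is negated.
#'
#' @param mean_plddt,ptm,tm_to_template Component scores in \[0, 1\].
#' @return The composite score in \[0, 1\].
#' @export
#' @examples
#' composite_fold_score(0.8, 0.9, 0.5)  # 0.36
composite_fold_score <- function(mean_plddt, ptm, tm_to_template) {
  comps <- c(mean_plddt = mean_plddt, ptm = ptm, tm_to_template = tm_to_template)
  bad <- which(!is.finite(comps) | comps < 0 | comps > 1)
  if (length(bad) > 0L) {
    stop(sprintf("component '%s' = %g lies outside [0, 1]",
                 names(comps)[bad[1]], comps[bad[1]]))
  }
  mean_plddt * ptm * tm_to_template
}

#' Optimal rigid superposition (Kabsch)
#'
#' Least-squares superposition of two equal-length coordinate sets with a
#' fixed one-to-one correspondence, via SVD of the covariance matrix with
#' the usual determinant correction to guarantee a proper rotation
#' (no reflection).
#'
#' @param coords_a,coords_b Numeric n x 3 matrices (n >= 3). `coords_a` is
#'   rotated/translated onto `coords_b`.
#' @return List with `rotation` (3 x 3, det +1), `translation` (length 3;
#'   the transform is `coords_a %*% rotation + translation`), and `rmsd`.
#' @export
kabsch_superpose <- function(coords_a, coords_b) {
  coords_a <- as.matrix(coords_a); coords_b <- as.matrix(coords_b)
  if (!all(dim(coords_a) == dim(coords_b)) || ncol(coords_a) != 3L) {
    stop("coordinate sets must be equal-size n x 3 matrices")
  }
  n <- nrow(coords_a)
  if (n < 3L) stop("at least 3 points are required")
  ca <- colMeans(coords_a); cb <- colMeans(coords_b)
  A <- sweep(coords_a, 2, ca); B <- sweep(coords_b, 2, cb)
  H <- crossprod(A, B)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  rotation <- s$u %*% D %*% t(s$v)    # A %*% rotation ~ B (centered)
  fitted <- A %*% rotation
  rmsd <- sqrt(mean(rowSums((fitted - B)^2)))
  translation <- cb - as.numeric(ca %*% rotation)
  list(rotation = rotation, translation = translation, rmsd = rmsd)
}

# TM-score length normalization d0, floored at 0.5 Angstrom
tm_d0 <- function(L) {
  if (L > 15) max(0.5, 1.24 * (L - 15)^(1/3) - 1.8) else 0.5
}

tm_eval <- function(model, reference, idx, d0) {
  # superpose model onto reference using subset idx, score all residues
  if (length(idx) < 3L) return(NULL)
  fit <- kabsch_superpose(model[idx, , drop = FALSE], reference[idx, , drop = FALSE])
  moved <- sweep(model %*% fit$rotation, 2, fit$translation, `+`)
  d <- sqrt(rowSums((moved - reference)^2))
  list(tm = mean(1 / (1 + (d / d0)^2)), d = d)
}

#' TM-score with fixed residue correspondence
#'
#' Template-modelling score between two equal-length CA traces with a fixed
#' one-to-one correspondence: the maximum over candidate rigid
#' superpositions of `mean(1 / (1 + (d_i/d0)^2))` with the standard
#' length-dependent normalization `d0(L) = 1.24 (L - 15)^(1/3) - 1.8`
#' floored at 0.5 Angstrom. The search superposes on contiguous fragment
#' seeds (lengths L, L/2, L/4, minimum 4) and refines each seed by
#' iteratively re-superposing on the residues within a distance cutoff,
#' mirroring the canonical algorithm. The score lies in (0, 1] and equals 1
#' for identical structures; it is invariant to rigid transforms of either
#' argument.
#'
#' @param coords_model,coords_reference Numeric L x 3 CA coordinate
#'   matrices, L >= 3.
#' @return TM-score in (0, 1].
#' @export
tm_score <- function(coords_model, coords_reference) {
  coords_model <- as.matrix(coords_model)
  coords_reference <- as.matrix(coords_reference)
  if (!all(dim(coords_model) == dim(coords_reference))) {
    stop("model and reference must have the same number of CA atoms")
  }
  L <- nrow(coords_model)
  if (L < 3L) stop("at least 3 CA atoms are required")
  d0 <- tm_d0(L)
  frag_lengths <- unique(pmax(4L, c(L, floor(L / 2), floor(L / 4))))
  frag_lengths <- frag_lengths[frag_lengths <= L]
  if (length(frag_lengths) == 0L) frag_lengths <- L
  best <- 0
  for (fl in frag_lengths) {
    starts <- seq.int(1L, L - fl + 1L, by = max(1L, floor(fl / 2)))
    if (!((L - fl + 1L) %in% starts)) starts <- c(starts, L - fl + 1L)
    for (st in starts) {
      idx <- st:(st + fl - 1L)
      res <- tm_eval(coords_model, coords_reference, idx, d0)
      if (is.null(res)) next
      if (res$tm > best) best <- res$tm
      # distance-cutoff refinement
      for (iter in 1:20) {
        cut <- max(d0, 1)
        sel <- which(res$d < cut)
        while (length(sel) < 3L) {
          cut <- cut + 0.5
          sel <- which(res$d < cut)
        }
        if (identical(sel, idx)) break
        idx <- sel
        res2 <- tm_eval(coords_model, coords_reference, idx, d0)
        if (is.null(res2)) break
        res <- res2
        if (res$tm > best) best <- res$tm
      }
    }
  }
  best
}

#' Mean log-likelihood of a designed sequence under a state PSSM
#'
#' The surrogate state-conditioned sequence likelihood: the mean over
#' designable positions of the natural log probability of the candidate
#' residue under the state's position-specific scoring matrix.
#' Pseudo-counts in the PSSM guarantee finiteness. As an objective the value
#' is negated (negative mean log-likelihood, minimized).
#'
#' @param designed Designed string (or character vector of them).
#' @param pssm PSSM matrix: `n_designable` rows, one column per alphabet
#'   symbol, rows summing to 1.
#' @param alphabet Character vector matching the PSSM columns.
#' @return Numeric vector of mean log-likelihoods (one per sequence).
#' @export
pssm_log_likelihood <- function(designed, pssm, alphabet = colnames(pssm)) {
  chars <- sequence_matrix(designed)
  if (ncol(chars) != nrow(pssm)) stop("sequence length does not match the PSSM")
  idx <- matrix(match(chars, alphabet), nrow = nrow(chars))
  lp <- matrix(log(pssm)[cbind(rep(seq_len(ncol(chars)), each = nrow(chars)),
                               as.vector(idx))], nrow = nrow(chars))
  rowMeans(lp)
}

#' Bounded surrogate folding-propensity score
#'
#' A smooth surrogate with the range and saturating behaviour of the
#' composite folding-propensity score:
#' `exp(mean log-likelihood - max attainable mean log-likelihood)` under a
#' state PSSM. The PSSM's modal sequence scores exactly 1 and every other
#' sequence lies in (0, 1]; improving any position's probability never
#' lowers the score. It makes no biophysical claim — it exists so that
#' bounded, saturating objectives can be exercised end-to-end at desk
#' scale. As an objective it is negated.
#'
#' @inheritParams pssm_log_likelihood
#' @return Numeric vector of scores in (0, 1].
#' @export
surrogate_composite <- function(designed, pssm, alphabet = colnames(pssm)) {
  best <- mean(log(apply(pssm, 1L, max)))
  exp(pssm_log_likelihood(designed, pssm, alphabet) - best)
}

#' Build the two surrogate objectives of a toy two-state problem
#'
#' One objective per state: the negative mean log-likelihood of the designed
#' residues under that state's PSSM (minimization scale, lower = more
#' state-compatible).
#'
#' @param toy A toy two-state problem from [make_toy_problem()].
#' @param kind `"nll"` (negative mean log-likelihood) or `"composite"`
#'   (negated bounded surrogate composite score).
#' @return List of two [objective_spec()]s.
#' @export
toy_objectives <- function(toy, kind = c("nll", "composite")) {
  kind <- match.arg(kind)
  problem <- toy$problem
  mk <- function(state) {
    pssm <- toy$pssms[[state]]
    objective_spec(
      name = state,
      state = state,
      evaluate = function(full_sequences) {
        designed <- vapply(full_sequences,
                           function(s) from_full_sequence(problem, s),
                           character(1), USE.NAMES = FALSE)
        if (kind == "nll") {
          -pssm_log_likelihood(designed, pssm, problem$alphabet)
        } else {
          -surrogate_composite(designed, pssm, problem$alphabet)
        }
      })
  }
  lapply(problem$state_names, mk)
}

# --- neural scorer plugin contracts ---------------------------------------

#' Plugin contracts for neural scorers
#'
#' The three neural scoring backends attach through named contracts; the
#' models themselves are never bundled or reimplemented. Each contract
#' documents the expected callable signature, output arity, the fixed
#' hyperparameters of the published protocol, and the determinism
#' expectation (a single value, deterministic given the plugin's seed).
#' Registering a conforming function under the contract name (see
#' [register_scorer()]) makes it available to objective configuration as
#' `plugin:<name>`.
#'
#' * `pmpnn_sd_score`: inverse-folding negative log-likelihood of a state.
#'   Input: full sequence and the state's (combined) structure. The score is
#'   computed from all residue positions and averaged over 5 repeats;
#'   sampling uses temperature 0.3 (scores themselves are
#'   temperature-independent). Output: one finite value per sequence.
#' * `esm_position_scores`: per-position language-model scores from a single
#'   forward pass with no masking; the mean per-position score serves as the
#'   sequence pseudo-likelihood. Output: one finite score per designable
#'   position (ranker contract) or the averaged scalar (objective contract).
#' * `af2rank_score`: structure-prediction composite score
#'   ([composite_fold_score()]). The state structure is supplied as a
#'   template after replacing the template sequence with gap tokens,
#'   deleting sidechain atoms, and imputing CB positions for glycine
#'   residues; prediction uses 1 recycle and no multiple sequence alignment.
#'   Output: one finite value in \[0, 1\] per sequence (negated as an
#'   objective).
#'
#' @return A named list of contract descriptors (signature, arity,
#'   hyperparameters, determinism note).
#' @export
plugin_contracts <- function() {
  list(
    pmpnn_sd_score = list(
      signature = "function(full_sequences, structure) -> numeric(length(full_sequences))",
      arity = 2L,
      hyperparameters = list(temperature = 0.3, score_repeats = 5L,
                             positions = "all residue positions"),
      determinism = "one finite value per sequence, deterministic given the plugin seed"
    ),
    esm_position_scores = list(
      signature = "function(full_sequence, problem) -> numeric(n_designable)",
      arity = 2L,
      hyperparameters = list(forward_passes = 1L, masking = "none",
                             aggregation = "mean over positions for sequence-level score"),
      determinism = "deterministic single forward pass"
    ),
    af2rank_score = list(
      signature = "function(full_sequences, structure) -> numeric in [0, 1]",
      arity = 2L,
      hyperparameters = list(recycles = 1L, msa = "none",
                             template = "sequence replaced by gap tokens; sidechains deleted; glycine CB imputed"),
      determinism = "one finite value per sequence, deterministic given the plugin seed"
    )
  )
}

#' Register a plugin scorer
#'
#' Validates the function's arity against the named contract from
#' [plugin_contracts()] (custom names require only a function of at least
#' one argument) and stores it in the plugin registry. Arity mismatches are
#' rejected at registration, before any evaluation.
#'
#' @param name Contract or custom scorer name.
#' @param fn The scoring function.
#' @return `name`, invisibly.
#' @export
register_scorer <- function(name, fn) {
  if (!is.function(fn)) stop("scorer must be a function")
  contracts <- plugin_contracts()
  if (name %in% names(contracts)) {
    need <- contracts[[name]]$arity
    if (length(formals(fn)) < need) {
      stop(sprintf("scorer '%s' must accept at least %d arguments (contract: %s)",
                   name, need, contracts[[name]]$signature))
    }
  } else if (length(formals(fn)) < 1L) {
    stop("scorer must accept at least one argument")
  }
  the_registry$scorers[[name]] <- fn
  invisible(name)
}

#' Look up a registered scorer
#' @param name Scorer name.
#' @return The scoring function.
#' @export
get_scorer <- function(name) {
  fn <- the_registry$scorers[[name]]
  if (is.null(fn)) stop(sprintf("no scorer registered under '%s'", name))
  fn
}
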