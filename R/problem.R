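#' The twenty standard amino acids
#'
#' Returns the default design alphabet: the 20 standard amino acids in
#' one-letter code, alphabetical order.
#'
#' @return Character vector of length 20.
#' @export
#' @examples
#' aa_alphabet()
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' Validate a design alphabet
#'
#' An alphabet is an ordered set of unique, uppercase, single-character
#' residue symbols. The default is the 20 standard amino acids.
#'
#' @param symbols Character vector of single uppercase characters.
#' @return The validated character vector.
#' @export
make_alphabet <- function(symbols = aa_alphabet()) {
  if (length(symbols) < 1L) stop("alphabet must be non-empty")
  if (any(nchar(symbols) != 1L)) stop("alphabet symbols must be single characters")
  if (any(symbols != toupper(symbols))) stop("alphabet symbols must be uppercase")
  if (anyDuplicated(symbols)) stop("alphabet symbols must be unique")
  as.character(symbols)
}

#' Define a multistate sequence design problem
#'
#' A design problem fixes the full-length reference (wild-type) sequence, the
#' set of designable positions within it, the residue alphabet, and the names
#' of the conformational states considered. Positions are 1-based residue
#' indices into the reference sequence, matching PDB numbering conventions
#' (e.g. a C-terminal domain spanning residues 119 to 154 gives 36 designable
#' positions). Residues outside the designable region are passed through
#' verbatim and may be noncanonical; designable residues must belong to the
#' alphabet.
#'
#' @param reference_sequence Full-length amino-acid string.
#' @param designable_positions Integer vector of unique 1-based positions.
#' @param alphabet Character vector of allowed residues (default the 20
#'   standard amino acids).
#' @param state_names Character vector naming the conformational states.
#' @return An object of class `design_problem` with fields
#'   `reference_sequence`, `designable_positions`, `alphabet`, `state_names`
#'   and `n_designable`.
#' @export
#' @examples
#' make_problem("ACDEFG", c(2, 4), state_names = c("alpha", "beta"))
make_problem <- function(reference_sequence, designable_positions,
                         alphabet = aa_alphabet(),
                         state_names = "state1") {
  stopifnot(is.character(reference_sequence), length(reference_sequence) == 1L)
  alphabet <- make_alphabet(alphabet)
  L <- nchar(reference_sequence)
  pos <- as.integer(designable_positions)
  if (length(pos) < 1L) stop("at least one designable position is required")
  if (anyDuplicated(pos)) stop("designable positions must be unique")
  if (is.unsorted(pos)) pos <- sort(pos)
  bad <- pos[pos < 1L | pos > L]
  if (length(bad) > 0L) {
    stop(sprintf("position %d out of range [1, %d]", bad[1], L))
  }
  ref_chars <- strsplit(reference_sequence, "")[[1]]
  ref_design <- ref_chars[pos]
  off <- which(!(ref_design %in% alphabet))
  if (length(off) > 0L) {
    stop(sprintf("reference residue '%s' at designable position %d is not in the alphabet",
                 ref_design[off[1]], pos[off[1]]))
  }
  structure(list(
    reference_sequence = reference_sequence,
    designable_positions = pos,
    alphabet = alphabet,
    state_names = as.character(state_names),
    n_designable = length(pos)
  ), class = "design_problem")
}

#' @export
print.design_problem <- function(x, ...) {
  cat("Design problem:", nchar(x$reference_sequence), "residues,",
      x$n_designable, "designable,",
      length(x$alphabet), "letter alphabet,",
      length(x$state_names), "state(s)\n")
  invisible(x)
}

#' Extract the reference residues at the designable positions
#'
#' @param problem A `design_problem`.
#' @return String of length `n_designable`.
#' @export
reference_designed <- function(problem) {
  chars <- strsplit(problem$reference_sequence, "")[[1]]
  paste(chars[problem$designable_positions], collapse = "")
}

validate_designed <- function(problem, designed) {
  if (nchar(designed) != problem$n_designable) {
    stop(sprintf("designed sequence length %d does not match the %d designable positions",
                 nchar(designed), problem$n_designable))
  }
  chars <- strsplit(designed, "")[[1]]
  bad <- which(!(chars %in% problem$alphabet))
  if (length(bad) > 0L) {
    stop(sprintf("residue '%s' at designed position %d is not in the alphabet",
                 chars[bad[1]], bad[1]))
  }
  invisible(designed)
}

#' Construct a population of design candidates
#'
#' A population is an ordered collection of designed sequences (strings over
#' the designable positions), optionally annotated with objective values on
#' the minimization scale and a provenance tag recording the operator that
#' produced each member. Duplicate sequences are permitted and retained;
#' population-level statistics (entropy, eCDFs) are computed over the full
#' multiset.
#'
#' @param problem A `design_problem`.
#' @param sequences Character vector of designed sequences.
#' @param objectives Optional numeric matrix (one row per member, one column
#'   per objective, minimization scale, all finite).
#' @param provenance Optional character vector of per-member tags.
#' @param iteration Non-negative integer iteration label.
#' @return An object of class `population`.
#' @export
population <- function(problem, sequences, objectives = NULL,
                       provenance = NULL, iteration = 0L) {
  sequences <- as.character(sequences)
  for (s in sequences) validate_designed(problem, s)
  n <- length(sequences)
  if (!is.null(objectives)) {
    objectives <- as.matrix(objectives)
    if (nrow(objectives) != n) stop("objectives must have one row per member")
    if (any(!is.finite(objectives))) stop("objective values must be finite")
  }
  if (is.null(provenance)) provenance <- rep(NA_character_, n)
  structure(list(
    sequences = sequences,
    objectives = objectives,
    provenance = as.character(provenance),
    iteration = as.integer(iteration),
    problem = problem
  ), class = "population")
}

#' @export
print.population <- function(x, ...) {
  cat("Population of", length(x$sequences), "candidates (iteration",
      x$iteration, ")")
  if (!is.null(x$objectives)) cat(",", ncol(x$objectives), "objectives")
  cat("\n")
  invisible(x)
}

#' @export
length.population <- function(x) length(x$sequences)

#' Draw a fully randomized initial population
#'
#' Every designable position of every candidate is drawn independently and
#' uniformly from the alphabet, matching the fully randomized initialization
#' used at the start of a design simulation. Draws come from R's global
#' random number stream, so results are reproducible under `set.seed()`.
#'
#' @param problem A `design_problem`.
#' @param size Number of candidates (>= 1).
#' @return A `population` with `size` members and no objective values.
#' @export
#' @examples
#' p <- make_problem("ACDEFG", c(2, 4))
#' set.seed(1)
#' random_population(p, 5)
random_population <- function(problem, size) {
  size <- as.integer(size)
  if (is.na(size) || size < 1L) stop("population size must be >= 1")
  L <- problem$n_designable
  draws <- sample(problem$alphabet, size * L, replace = TRUE)
  m <- matrix(draws, nrow = size, ncol = L)
  seqs <- apply(m, 1L, paste, collapse = "")
  population(problem, seqs, iteration = 0L)
}

#' Splice a designed sequence into the full reference context
#'
#' Returns the reference sequence with the designable positions replaced by
#' the candidate's residues; all other positions are unchanged. This is the
#' full-length sequence handed to context-aware scorers and proposers.
#'
#' @param problem A `design_problem`.
#' @param designed Designed string of length `n_designable`.
#' @return Full-length sequence string.
#' @export
#' @examples
#' p <- make_problem("ACDEFG", c(2, 4))
#' to_full_sequence(p, "WY")  # "AWDYFG"
to_full_sequence <- function(problem, designed) {
  validate_designed(problem, designed)
  chars <- strsplit(problem$reference_sequence, "")[[1]]
  chars[problem$designable_positions] <- strsplit(designed, "")[[1]]
  paste(chars, collapse = "")
}

#' Extract the designable positions from a full-length sequence
#'
#' Inverse of [to_full_sequence()].
#'
#' @param problem A `design_problem`.
#' @param full_sequence Full-length sequence string.
#' @return Designed string of length `n_designable`.
#' @export
from_full_sequence <- function(problem, full_sequence) {
  if (nchar(full_sequence) != nchar(problem$reference_sequence)) {
    stop("full sequence length does not match the reference")
  }
  chars <- strsplit(full_sequence, "")[[1]]
  paste(chars[problem$designable_positions], collapse = "")
}

# character matrix view of a set of designed strings (rows = members)
sequence_matrix <- function(sequences) {
  if (length(sequences) == 0L) return(matrix(character(), 0, 0))
  do.call(rbind, strsplit(sequences, ""))
}

#' Write a population to FASTA
#'
#' One record per candidate. Headers carry the iteration, provenance and
#' objective values as `key=value` pairs, e.g.
#' `>cand_3 iteration=12 provenance=mutate obj_alpha=1.25 obj_beta=0.80`.
#' Objective values are on the minimization scale exactly as evaluated.
#'
#' @param pop A `population`.
#' @param path Output file path.
#' @param objective_names Optional character vector of objective names used
#'   in headers (defaults to `obj1`, `obj2`, ...).
#' @return `path`, invisibly.
#' @export
write_population_fasta <- function(pop, path, objective_names = NULL) {
  n <- length(pop$sequences)
  headers <- sprintf("cand_%d iteration=%d provenance=%s", seq_len(n),
                     pop$iteration, ifelse(is.na(pop$provenance), "none", pop$provenance))
  if (!is.null(pop$objectives)) {
    m <- ncol(pop$objectives)
    if (is.null(objective_names)) objective_names <- paste0("obj", seq_len(m))
    for (j in seq_len(m)) {
      headers <- paste0(headers, sprintf(" obj_%s=%.12g", objective_names[j],
                                         pop$objectives[, j]))
    }
  }
  x <- Biostrings::AAStringSet(pop$sequences)
  names(x) <- headers
  Biostrings::writeXStringSet(x, filepath = path)
  invisible(path)
}

#' Read a population from FASTA
#'
#' Parses headers written by [write_population_fasta()]; `obj_*` key=value
#' pairs are recovered into the objective matrix.
#'
#' @param path FASTA file path.
#' @param problem A `design_problem` the sequences belong to.
#' @return A `population`.
#' @export
read_population_fasta <- function(path, problem) {
  x <- Biostrings::readAAStringSet(path)
  seqs <- as.character(x)
  headers <- names(x)
  n <- length(seqs)
  iteration <- 0L
  provenance <- rep(NA_character_, n)
  obj_list <- vector("list", n)
  for (i in seq_len(n)) {
    fields <- strsplit(headers[i], "\\s+")[[1]]
    kv <- fields[grepl("=", fields, fixed = TRUE)]
    if (length(kv) == 0L) next
    keys <- sub("=.*$", "", kv)
    vals <- sub("^[^=]*=", "", kv)
    if ("iteration" %in% keys) iteration <- as.integer(vals[keys == "iteration"][1])
    if ("provenance" %in% keys) {
      pv <- vals[keys == "provenance"][1]
      provenance[i] <- if (identical(pv, "none")) NA_character_ else pv
    }
    is_obj <- startsWith(keys, "obj_")
    if (any(is_obj)) {
      v <- as.numeric(vals[is_obj])
      names(v) <- sub("^obj_", "", keys[is_obj])
      obj_list[[i]] <- v
    }
  }
  objectives <- NULL
  if (!is.null(obj_list[[1]])) {
    objectives <- do.call(rbind, obj_list)
    if (is.null(objectives) || nrow(objectives) != n) {
      stop(sprintf("malformed FASTA header in record %d: inconsistent objective fields",
                   which(vapply(obj_list, is.null, logical(1)))[1]))
    }
  }
  population(problem, seqs, objectives = objectives,
             provenance = provenance, iteration = iteration)
}

#' Write a population as a flat CSV table
#'
#' One row per candidate: sequence, iteration, provenance, and one column
#' per objective.
#'
#' @inheritParams write_population_fasta
#' @return `path`, invisibly.
#' @export
write_population_csv <- function(pop, path, objective_names = NULL) {
  df <- data.frame(sequence = pop$sequences,
                   iteration = pop$iteration,
                   provenance = pop$provenance,
                   stringsAsFactors = FALSE)
  if (!is.null(pop$objectives)) {
    m <- ncol(pop$objectives)
    if (is.null(objective_names)) objective_names <- paste0("obj", seq_len(m))
    for (j in seq_len(m)) df[[objective_names[j]]] <- pop$objectives[, j]
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
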