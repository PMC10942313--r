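#' Construct a state structure
#'
#' A per-state backbone structure: a table of ATOM records (atom name,
#' residue name/number, chain, coordinates in Angstrom) labelled with the
#' state's name. Coordinates must be finite and (chain, residue number,
#' atom name) triples unique.
#'
#' @param state State name.
#' @param atoms Data frame with columns `elety` (atom name), `resid`
#'   (3-letter residue name), `chain`, `resno`, `x`, `y`, `z`.
#' @return Object of class `state_structure`.
#' @export
state_structure <- function(state, atoms) {
  need <- c("elety", "resid", "chain", "resno", "x", "y", "z")
  if (!all(need %in% names(atoms))) {
    stop("atoms must have columns ", paste(need, collapse = ", "))
  }
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("atom coordinates must be finite")
  }
  key <- paste(atoms$chain, atoms$resno, atoms$elety)
  dup <- which(duplicated(key))
  if (length(dup) > 0L) {
    stop(sprintf("duplicate atom record (chain %s, residue %d, atom %s)",
                 atoms$chain[dup[1]], atoms$resno[dup[1]], atoms$elety[dup[1]]))
  }
  structure(list(state = state, atoms = atoms), class = "state_structure")
}

#' @export
print.state_structure <- function(x, ...) {
  cat("State structure '", x$state, "': ", nrow(x$atoms), " atoms, ",
      length(unique(paste(x$atoms$chain, x$atoms$resno))), " residues\n", sep = "")
  invisible(x)
}

#' Read a backbone structure from a PDB file
#'
#' Parses standard ATOM records (HETATM records, waters included, are
#' ignored). Atom names, residue names and numbers, chain identifiers and
#' coordinates are preserved; gaps in residue numbering (unmodelled loops)
#' are accepted as-is. Duplicate (chain, residue, atom) records raise an
#' error.
#'
#' @param path PDB file path.
#' @param state State name attached to the structure (default: file name
#'   without extension).
#' @return A `state_structure`.
#' @export
read_pdb <- function(path, state = NULL) {
  if (is.null(state)) state <- sub("\\.[^.]*$", "", basename(path))
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) stop(sprintf("failed to parse '%s': %s",
                                                   path, conditionMessage(e))))
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) stop(sprintf("no ATOM records in '%s'", path))
  atoms <- data.frame(elety = at$elety, resid = at$resid,
                      chain = ifelse(is.na(at$chain), "A", at$chain),
                      resno = at$resno,
                      x = at$x, y = at$y, z = at$z,
                      stringsAsFactors = FALSE)
  state_structure(state, atoms)
}

#' Write one or more structures to a PDB file
#'
#' Writes standard ATOM records at PDB precision (3 decimals). When a layout
#' is given, each structure is translated by its offset before writing (the
#' combined multistate file convention).
#'
#' @param structures A `state_structure` or list of them.
#' @param path Output PDB path.
#' @param layout Optional [layout_offsets()] result; its translation vectors
#'   are applied per structure in order.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(structures, path, layout = NULL) {
  if (inherits(structures, "state_structure")) structures <- list(structures)
  all_atoms <- NULL
  for (i in seq_along(structures)) {
    a <- structures[[i]]$atoms
    if (!is.null(layout)) {
      off <- layout$offsets[[i]]
      a$x <- a$x + off[1]; a$y <- a$y + off[2]; a$z <- a$z + off[3]
    }
    all_atoms <- rbind(all_atoms, a)
  }
  n <- nrow(all_atoms)
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(all_atoms[, c("x", "y", "z")]))),
                   resno = all_atoms$resno,
                   chain = all_atoms$chain,
                   resid = all_atoms$resid,
                   elety = all_atoms$elety,
                   o = rep(1, n), b = rep(0, n))
  invisible(path)
}

# CA coordinate matrix of a structure, ordered by (chain, resno)
ca_coords <- function(structure) {
  a <- structure$atoms
  ca <- a[a$elety == "CA", , drop = FALSE]
  if (nrow(ca) == 0L) stop("structure contains no CA atoms")
  ca <- ca[order(ca$chain, ca$resno), , drop = FALSE]
  as.matrix(ca[, c("x", "y", "z")])
}

#' Maximum CA distance from the CA centroid
#'
#' The structure's radius for layout purposes: the centroid is computed over
#' CA atoms and the maximum CA-to-centroid distance returned.
#'
#' @param structure A `state_structure`.
#' @return Distance in Angstrom.
#' @export
max_centroid_radius <- function(structure) {
  ca <- ca_coords(structure)
  centroid <- colMeans(ca)
  max(sqrt(rowSums(sweep(ca, 2, centroid)^2)))
}

#' Collinear layout offsets for combined multistate structures
#'
#' Places the states along the +x axis, in input order, so that every pair
#' of (translated) centroids satisfies
#' `r_ij >= 2 * max(r_i, r_j) + r_min`. With cumulative gaps of
#' `2 * max(r_i, r_{i+1}) + r_min` between neighbours, every non-adjacent
#' pair satisfies its constraint as well; the layout is deterministic.
#'
#' @param radii Numeric vector of per-state radii (>= 0), e.g. from
#'   [max_centroid_radius()].
#' @param r_min Minimum clearance in Angstrom (default 24, the distance
#'   beyond which backbone atom pairs exceed the range encodable as
#'   inverse-folding edge features).
#' @return Object of class `layout_spec`: list with `offsets` (list of
#'   length-3 translation vectors), `radii` and `r_min`.
#' @export
layout_offsets <- function(radii, r_min = 24) {
  if (any(radii < 0)) stop("radii must be non-negative")
  if (r_min <= 0) stop("r_min must be positive")
  k <- length(radii)
  xs <- numeric(k)
  for (i in seq_len(k)[-1]) {
    xs[i] <- xs[i - 1] + 2 * max(radii[i - 1], radii[i]) + r_min
  }
  structure(list(offsets = lapply(xs, function(x) c(x, 0, 0)),
                 radii = radii, r_min = r_min),
            class = "layout_spec")
}

#' Combine state structures for tied multistate decoding
#'
#' Translates each state's structure by a collinear layout that guarantees a
#' minimum inter-state atom separation of `r_min`, renames chains so all
#' states carry distinct chain identifiers, merges the atom records, and
#' emits the tie map linking each designable position to its residue in
#' every state. The combination is translation-only: intra-state geometry is
#' preserved exactly. The layout radius per state is the larger of the
#' CA-centroid radius and the all-atom centroid radius, so the separation
#' guarantee holds at the atom level.
#'
#' @param states List of `state_structure`s, one per problem state. Each
#'   must contain every designable position as a residue number.
#' @param problem A `design_problem`.
#' @param r_min Minimum inter-state clearance in Angstrom (default 24).
#' @return List with `combined` (a `state_structure` holding all translated
#'   atoms), `tie_map` (list: position -> data frame of (state, chain,
#'   resno)), `layout` (the `layout_spec` of centroid target positions),
#'   `translations` (the per-state translation vectors actually applied)
#'   and `chain_map` (per-state chain renaming).
#' @export
combine_structures <- function(states, problem, r_min = 24) {
  if (inherits(states, "state_structure")) states <- list(states)
  k <- length(states)
  # effective radius: max of CA radius and all-atom radius about CA centroid
  centroids <- lapply(states, function(s) colMeans(ca_coords(s)))
  radii <- vapply(seq_len(k), function(i) {
    xyz <- as.matrix(states[[i]]$atoms[, c("x", "y", "z")])
    max(max_centroid_radius(states[[i]]),
        max(sqrt(rowSums(sweep(xyz, 2, centroids[[i]])^2))))
  }, numeric(1))
  layout <- layout_offsets(radii, r_min)
  # move each state's CA centroid onto its prescribed layout position
  # (a single state is left untouched)
  translations <- if (k == 1L) list(c(0, 0, 0)) else {
    lapply(seq_len(k), function(i) layout$offsets[[i]] - centroids[[i]])
  }

  pool <- c(LETTERS, letters, as.character(0:9))
  used <- character(0)
  chain_map <- vector("list", k)
  all_atoms <- NULL
  for (i in seq_len(k)) {
    a <- states[[i]]$atoms
    old <- unique(a$chain)
    new <- character(length(old))
    for (j in seq_along(old)) {
      cand <- if (!(old[j] %in% used)) old[j] else setdiff(pool, used)[1]
      if (is.na(cand)) stop("chain-id pool exhausted while renaming chains")
      new[j] <- cand
      used <- c(used, cand)
    }
    names(new) <- old
    chain_map[[i]] <- new
    a$chain <- unname(new[a$chain])
    off <- translations[[i]]
    a$x <- a$x + off[1]; a$y <- a$y + off[2]; a$z <- a$z + off[3]
    all_atoms <- rbind(all_atoms, a)
  }

  tie_map <- list()
  for (pos in problem$designable_positions) {
    rows <- NULL
    for (i in seq_len(k)) {
      a <- states[[i]]$atoms
      hit <- a[a$resno == pos, , drop = FALSE]
      if (nrow(hit) == 0L) {
        stop(sprintf("designable position %d absent from state '%s'",
                     pos, states[[i]]$state))
      }
      rows <- rbind(rows, data.frame(state = states[[i]]$state,
                                     chain = unname(chain_map[[i]][hit$chain[1]]),
                                     resno = pos, stringsAsFactors = FALSE))
    }
    tie_map[[as.character(pos)]] <- rows
  }

  list(combined = state_structure("combined", all_atoms),
       tie_map = tie_map, layout = layout, translations = translations,
       chain_map = chain_map)
}

#' Export a tie map as JSON
#'
#' Writes `{position: [[state, chain, resno], ...], ...}`, mirroring the
#' tied-positions input convention of inverse-folding tools. The exact JSON
#' dialect expected by a given tool may differ; this export is the package's
#' documented local convention.
#'
#' @param tie_map Tie map from [combine_structures()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_tie_map <- function(tie_map, path) {
  out <- lapply(tie_map, function(df) {
    lapply(seq_len(nrow(df)), function(i) {
      list(df$state[i], df$chain[i], df$resno[i])
    })
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Minimum atom distance between two structures
#'
#' @param a,b `state_structure`s (or atom tables with x/y/z columns).
#' @return The smallest pairwise atom distance in Angstrom.
#' @export
min_interstate_distance <- function(a, b) {
  xa <- as.matrix((if (inherits(a, "state_structure")) a$atoms else a)[, c("x", "y", "z")])
  xb <- as.matrix((if (inherits(b, "state_structure")) b$atoms else b)[, c("x", "y", "z")])
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), `+`) - 2 * xa %*% t(xb)
  sqrt(max(0, min(d2)))
}
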