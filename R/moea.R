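#' Pareto domination test (minimization)
#'
#' `a` dominates `b` when `a` is no worse than `b` on every objective and
#' strictly better on at least one. All objectives are on the minimization
#' scale.
#'
#' @param a,b Numeric objective vectors of equal length, all finite.
#' @return Logical scalar.
#' @export
#' @examples
#' dominates(c(1, 2), c(2, 3))  # TRUE
#' dominates(c(1, 2), c(2, 1))  # FALSE (incomparable)
dominates <- function(a, b) {
  if (length(a) != length(b)) stop("objective vectors must have equal length")
  if (any(!is.finite(a)) || any(!is.finite(b))) stop("objective values must be finite")
  all(a <= b) && any(a < b)
}

#' Fast non-dominated sorting
#'
#' Partitions a set of objective vectors into successive Pareto fronts using
#' the bookkeeping of the NSGA-II fast sort: each point records the set of
#' points it dominates and a count of its dominators; front 1 is the set with
#' zero dominators, and successive fronts are peeled by decrementing the
#' counts. The partition is deterministic for a given row ordering.
#'
#' @param objectives Numeric matrix, one row per point, one column per
#'   objective (minimization scale), at least one row, all finite.
#' @return Object of class `front_partition`: a list with `fronts` (list of
#'   integer index vectors, front 1 first) and `rank` (integer vector giving
#'   each row's front number).
#' @export
fast_non_dominated_sort <- function(objectives) {
  objectives <- as.matrix(objectives)
  n <- nrow(objectives)
  if (n < 1L) stop("at least one point is required")
  if (any(!is.finite(objectives))) stop("objective values must be finite")
  m <- ncol(objectives)

  dominated_by <- vector("list", n)  # points each i dominates
  n_dom <- integer(n)                # number of points dominating i
  for (i in seq_len(n)) {
    le <- rowSums(objectives >= matrix(objectives[i, ], n, m, byrow = TRUE)) == m
    lt <- rowSums(objectives >  matrix(objectives[i, ], n, m, byrow = TRUE)) > 0L
    dom_i <- which(le & lt)          # points dominated by i
    dominated_by[[i]] <- dom_i
    n_dom[dom_i] <- n_dom[dom_i] + 1L
  }

  rank <- integer(n)
  fronts <- list()
  current <- which(n_dom == 0L)
  f <- 0L
  while (length(current) > 0L) {
    f <- f + 1L
    rank[current] <- f
    fronts[[f]] <- current
    nxt <- integer(0)
    for (i in current) {
      for (j in dominated_by[[i]]) {
        n_dom[j] <- n_dom[j] - 1L
        if (n_dom[j] == 0L) nxt <- c(nxt, j)
      }
    }
    current <- sort(nxt)
  }
  structure(list(fronts = fronts, rank = rank), class = "front_partition")
}

#' Crowding distance within a front
#'
#' For each objective, members of the front are sorted by value; the two
#' boundary members receive infinite distance and each interior member the
#' gap between its neighbours normalized by the objective's range. Distances
#' are summed over objectives. A degenerate objective (zero range)
#' contributes 0. Ties in objective value are resolved by stable sort order.
#'
#' @param objectives Numeric matrix of the front's objective vectors (one row
#'   per member).
#' @return Numeric vector of crowding distances (may contain `Inf`).
#' @export
crowding_distance <- function(objectives) {
  objectives <- as.matrix(objectives)
  n <- nrow(objectives)
  if (n < 1L) stop("front must be non-empty")
  if (n <= 2L) return(rep(Inf, n))
  d <- numeric(n)
  for (j in seq_len(ncol(objectives))) {
    v <- objectives[, j]
    ord <- order(v)           # stable: ties keep original relative order
    rng <- v[ord[n]] - v[ord[1]]
    d[ord[1]] <- Inf
    d[ord[n]] <- Inf
    if (rng > 0) {
      interior <- ord[2:(n - 1L)]
      d[interior] <- d[interior] + (v[ord[3:n]] - v[ord[1:(n - 2L)]]) / rng
    }
  }
  d
}

#' Binary tournament selection
#'
#' Draws two distinct members uniformly at random; the winner is the one on
#' the better (lower) front, ties broken by larger crowding distance, and
#' remaining ties by a fair coin. A population of size 1 returns that member.
#'
#' @param rank Integer vector of front ranks (1 = non-dominated).
#' @param distance Numeric vector of crowding distances.
#' @return The selected member index.
#' @export
binary_tournament <- function(rank, distance) {
  n <- length(rank)
  if (n == 1L) return(1L)
  pair <- sample.int(n, 2L)
  a <- pair[1L]; b <- pair[2L]
  if (rank[a] != rank[b]) return(if (rank[a] < rank[b]) a else b)
  if (distance[a] != distance[b]) return(if (distance[a] > distance[b]) a else b)
  if (stats::runif(1) < 0.5) a else b
}

#' Elitist environmental selection
#'
#' Forms the next generation from a combined parent+offspring pool: whole
#' Pareto fronts are admitted in order until the population limit would be
#' exceeded; the last front is truncated by descending crowding distance
#' (computed within that front), with stable order on ties.
#'
#' @param objectives Numeric matrix of the combined pool's objective vectors.
#' @param n Target population size.
#' @return Integer vector of `n` selected row indices.
#' @export
environmental_selection <- function(objectives, n) {
  objectives <- as.matrix(objectives)
  if (nrow(objectives) < n) stop("combined pool is smaller than the target size")
  part <- fast_non_dominated_sort(objectives)
  selected <- integer(0)
  for (front in part$fronts) {
    if (length(selected) + length(front) <= n) {
      selected <- c(selected, front)
      if (length(selected) == n) break
    } else {
      k <- n - length(selected)
      cd <- crowding_distance(objectives[front, , drop = FALSE])
      keep <- front[order(-cd)][seq_len(k)]
      selected <- c(selected, keep)
      break
    }
  }
  selected
}

#' Run configuration for a design simulation
#'
#' Bundles every hyperparameter of the NSGA-II run. Defaults follow the
#' benchmark setup used throughout: population size 100, 50 iterations,
#' crossover applied with probability 0.9 (2 cut points) and mutation with
#' probability 1.0; the mutation rate `mu` controls how many designable
#' positions are redesigned per mutation event.
#'
#' @param population_size Positive integer (default 100).
#' @param iterations Positive integer (default 50).
#' @param mutation_rate Per-position redesign rate `mu` in \[0, 1\].
#' @param crossover_probability Probability the crossover operator is applied
#'   to a parent pair (default 0.9); skipped pairs yield verbatim copies.
#' @param mutation_probability Probability the mutation operator is applied
#'   to an offspring (default 1.0).
#' @param n_crossover_points Number of crossover cut points (default 2); must
#'   be smaller than the designed length.
#' @param seed Integer seed for the run's single RNG stream.
#' @param selector Position-selection mode: `"random"` (independent
#'   Bernoulli(mu) per position, patched to one random position when empty)
#'   or `"ranked"` (the k lowest-scoring positions under a position ranker,
#'   k = max(1, Binomial(n, mu))).
#' @param proposer Residue proposal mode: `"uniform"` or the name of a
#'   registered plugin proposer (see [register_proposer()]).
#' @param hv_reference Numeric length-2 reference point for the per-iteration
#'   hypervolume metric over the first two objectives (default `c(4, 4)`,
#'   the convention for negative-log-likelihood objective subspaces; use
#'   `c(0, 0)` for negated composite-score subspaces).
#' @return Object of class `run_config`.
#' @export
run_config <- function(population_size = 100L, iterations = 50L,
                       mutation_rate = 0.3, crossover_probability = 0.9,
                       mutation_probability = 1.0, n_crossover_points = 2L,
                       seed = 1L, selector = c("random", "ranked"),
                       proposer = "uniform", hv_reference = c(4, 4)) {
  selector <- match.arg(selector)
  population_size <- as.integer(population_size)
  iterations <- as.integer(iterations)
  if (population_size < 1L) stop("population_size must be >= 1")
  if (iterations < 1L) stop("iterations must be >= 1")
  for (p in c(mutation_rate, crossover_probability, mutation_probability)) {
    if (!is.finite(p) || p < 0 || p > 1) {
      stop("mutation_rate, crossover_probability and mutation_probability must lie in [0, 1]")
    }
  }
  if (as.integer(n_crossover_points) < 1L) stop("n_crossover_points must be >= 1")
  if (length(hv_reference) != 2L || any(!is.finite(hv_reference))) {
    stop("hv_reference must be a finite length-2 point")
  }
  structure(list(
    population_size = population_size, iterations = iterations,
    mutation_rate = mutation_rate,
    crossover_probability = crossover_probability,
    mutation_probability = mutation_probability,
    n_crossover_points = as.integer(n_crossover_points),
    seed = as.integer(seed), selector = selector, proposer = proposer,
    hv_reference = as.numeric(hv_reference)
  ), class = "run_config")
}

# Evaluate a batch of designed sequences through the objective specs,
# caching per unique designed sequence. The cache never changes results
# because evaluators are required to be deterministic functions of the
# sequence. All evaluation funnels through `evaluate` over a character
# vector — the one contract point — so concurrent backends plug in without
# changing results.
evaluate_batch <- function(problem, sequences, objective_specs, cache) {
  n <- length(sequences)
  m <- length(objective_specs)
  out <- matrix(NA_real_, n, m)
  miss <- !vapply(sequences, function(s) !is.null(cache[[s]]), logical(1))
  if (any(miss)) {
    uniq <- unique(sequences[miss])
    fulls <- vapply(uniq, function(s) to_full_sequence(problem, s), character(1))
    vals <- matrix(NA_real_, length(uniq), m)
    for (j in seq_len(m)) {
      v <- objective_specs[[j]]$evaluate(fulls)
      if (length(v) != length(uniq)) {
        stop(sprintf("objective '%s' returned %d values for %d sequences",
                     objective_specs[[j]]$name, length(v), length(uniq)))
      }
      vals[, j] <- v
    }
    for (i in seq_along(uniq)) {
      if (any(!is.finite(vals[i, ]))) {
        bad <- which(!is.finite(vals[i, ]))[1]
        stop(sprintf("objective '%s' returned a non-finite value for sequence '%s'",
                     objective_specs[[bad]]$name, uniq[i]))
      }
      cache[[uniq[i]]] <- vals[i, ]
    }
  }
  for (i in seq_len(n)) out[i, ] <- cache[[sequences[i]]]
  colnames(out) <- vapply(objective_specs, function(s) s$name, character(1))
  out
}

# One generation of offspring: tournament pairs, n-point crossover with
# probability p_c (else verbatim copies), then mutation with probability p_m
# per child. Parent pairs are drawn until exactly N offspring exist; with odd
# N the final pair contributes a single child.
make_offspring <- function(problem, pop, rank, distance, config, selector_fn,
                           proposer_fn) {
  n <- config$population_size
  L <- problem$n_designable
  children <- character(0)
  prov <- character(0)
  while (length(children) < n) {
    i1 <- binary_tournament(rank, distance)
    i2 <- binary_tournament(rank, distance)
    p1 <- pop$sequences[i1]
    p2 <- pop$sequences[i2]
    if (stats::runif(1) < config$crossover_probability && L > config$n_crossover_points) {
      kids <- n_point_crossover(p1, p2, config$n_crossover_points)
      tag <- "crossover"
    } else {
      kids <- c(p1, p2)
      tag <- "copy"
    }
    for (kid in kids) {
      if (length(children) >= n) break
      ktag <- tag
      if (stats::runif(1) < config$mutation_probability) {
        kid <- mutate(problem, kid, selector_fn, proposer_fn)
        ktag <- paste0(ktag, "+mutate")
      }
      children <- c(children, kid)
      prov <- c(prov, ktag)
    }
  }
  list(sequences = children, provenance = prov)
}

#' Run an NSGA-II design simulation
#'
#' Initializes a fully randomized population, evaluates it, then iterates:
#' binary tournament selection, n-point crossover, mutation (doubling the
#' population), evaluation of the offspring, and elitist environmental
#' selection of the combined pool back down to the population size. All
#' stochastic draws come from a single RNG stream seeded from
#' `config$seed`, in a fixed order (initialization, then per offspring:
#' tournament, crossover, mutation), so runs are exactly reproducible.
#' Objective values are cached per unique designed sequence within the run.
#'
#' @param problem A `design_problem`.
#' @param config A [run_config()].
#' @param objective_specs List of objective specifications (see
#'   [objective_spec()]); each evaluator must return one finite value per
#'   sequence on the minimization scale.
#' @param ranker Position ranker used when `config$selector == "ranked"`:
#'   a function `(full_sequence, problem) -> numeric` of length
#'   `n_designable` (higher = more native-like), e.g.
#'   [pssm_position_ranker()].
#' @param initial Optional starting `population` (used for restarts);
#'   default is a fresh fully randomized population.
#' @return Object of class `run_history`: list with `config`, `problem`,
#'   `objective_names`, `iterations` (one record per completed iteration
#'   holding the population snapshot, the metrics row and an RNG-state
#'   checkpoint) and `final` (the final population).
#' @export
evolve <- function(problem, config, objective_specs, ranker = NULL,
                   initial = NULL) {
  stopifnot(inherits(problem, "design_problem"), inherits(config, "run_config"))
  if (length(objective_specs) < 1L) stop("at least one objective is required")
  if (inherits(objective_specs[[1]], "objective_spec")) {
    # fine; also accept a bare list of such
  }
  if (config$selector == "ranked" && is.null(ranker)) {
    stop("selector 'ranked' requires a position ranker")
  }
  if (config$n_crossover_points >= problem$n_designable) {
    stop("n_crossover_points must be smaller than the designed length")
  }
  proposer_fn <- resolve_proposer(config$proposer)
  selector_fn <- if (config$selector == "random") {
    function(problem, designed) select_positions_random(problem, config$mutation_rate)
  } else {
    function(problem, designed) {
      select_positions_ranked(problem, designed, ranker, config$mutation_rate)
    }
  }

  set.seed(config$seed)
  cache <- new.env(parent = emptyenv())
  obj_names <- vapply(objective_specs, function(s) s$name, character(1))

  pop <- if (is.null(initial)) random_population(problem, config$population_size) else initial
  obj <- evaluate_batch(problem, pop$sequences, objective_specs, cache)
  pop <- population(problem, pop$sequences, objectives = obj,
                    provenance = pop$provenance, iteration = pop$iteration)

  records <- vector("list", config$iterations)
  ref_designed <- reference_designed(problem)
  for (iter in seq_len(config$iterations)) {
    part <- fast_non_dominated_sort(pop$objectives)
    dist <- numeric(length(pop))
    for (front in part$fronts) {
      dist[front] <- crowding_distance(pop$objectives[front, , drop = FALSE])
    }
    off <- make_offspring(problem, pop, part$rank, dist, config, selector_fn,
                          proposer_fn)
    off_obj <- evaluate_batch(problem, off$sequences, objective_specs, cache)

    pool_seqs <- c(pop$sequences, off$sequences)
    pool_obj <- rbind(pop$objectives, off_obj)
    pool_prov <- c(pop$provenance, off$provenance)
    pool_part <- fast_non_dominated_sort(pool_obj)
    keep <- environmental_selection(pool_obj, config$population_size)
    pop <- population(problem, pool_seqs[keep],
                      objectives = pool_obj[keep, , drop = FALSE],
                      provenance = pool_prov[keep], iteration = iter)

    front0 <- which(fast_non_dominated_sort(pop$objectives)$rank == 1L)
    hv <- hypervolume_2d(pop$objectives[front0, 1:2, drop = FALSE],
                         config$hv_reference)
    recov <- mean(vapply(pop$sequences, function(s) {
      mean(strsplit(s, "")[[1]] == strsplit(ref_designed, "")[[1]])
    }, numeric(1)))
    metrics <- c(iteration = iter, mean_recovery = recov,
                 stats::setNames(colMeans(pop$objectives),
                                 paste0("mean_", obj_names)),
                 hv_front0 = hv,
                 front0_size = length(front0),
                 pool_front0_size = length(pool_part$fronts[[1]]))
    records[[iter]] <- list(population = pop, metrics = metrics,
                            rng_state = .Random.seed)
  }
  out <- structure(list(config = config, problem = problem,
                        objective_names = obj_names,
                        iterations = records, final = pop),
                   class = "run_history")
  attr(out, "objective_specs") <- objective_specs
  attr(out, "ranker") <- ranker
  out
}

#' @export
print.run_history <- function(x, ...) {
  cat("Design run:", length(x$iterations), "iterations, population",
      x$config$population_size, "\n")
  last <- x$iterations[[length(x$iterations)]]$metrics
  cat("  final mean recovery:", signif(last[["mean_recovery"]], 4),
      " front-0 hypervolume:", signif(last[["hv_front0"]], 4), "\n")
  invisible(x)
}

#' Resume a design run from its last checkpoint
#'
#' Restores the RNG state recorded at the final completed iteration and
#' continues for `extra_iterations` more generations; a straight-through run
#' of `n1 + n2` iterations and a run of `n1` resumed for `n2` produce
#' identical histories.
#'
#' @param history A `run_history`.
#' @param extra_iterations Number of additional iterations.
#' @return A new `run_history` covering the combined trajectory.
#' @export
resume_run <- function(history, extra_iterations) {
  last <- history$iterations[[length(history$iterations)]]
  config2 <- history$config
  config2$iterations <- as.integer(extra_iterations)
  # evolve() reseeds from config$seed; override the stream by restoring the
  # checkpointed state right after that reseed via a wrapper evaluator-free
  # path: simplest faithful restore is to rebuild the cache and state here.
  specs <- attr(history, "objective_specs")
  if (is.null(specs)) stop("history does not carry its objective specs")
  ranker <- attr(history, "ranker")
  assign(".Random.seed", last$rng_state, envir = globalenv())
  cont <- evolve_continue(history$problem, config2, specs, ranker,
                          last$population)
  combined <- history
  combined$iterations <- c(history$iterations, cont$iterations)
  combined$final <- cont$final
  combined
}

# Internal: like evolve() but continues from an existing evaluated population
# and the current RNG state (no reseed, no fresh initialization).
evolve_continue <- function(problem, config, objective_specs, ranker, pop) {
  proposer_fn <- resolve_proposer(config$proposer)
  selector_fn <- if (config$selector == "random") {
    function(problem, designed) select_positions_random(problem, config$mutation_rate)
  } else {
    function(problem, designed) {
      select_positions_ranked(problem, designed, ranker, config$mutation_rate)
    }
  }
  cache <- new.env(parent = emptyenv())
  obj_names <- vapply(objective_specs, function(s) s$name, character(1))
  records <- vector("list", config$iterations)
  ref_designed <- reference_designed(problem)
  start_iter <- pop$iteration
  for (k in seq_len(config$iterations)) {
    iter <- start_iter + k
    part <- fast_non_dominated_sort(pop$objectives)
    dist <- numeric(length(pop))
    for (front in part$fronts) {
      dist[front] <- crowding_distance(pop$objectives[front, , drop = FALSE])
    }
    off <- make_offspring(problem, pop, part$rank, dist, config, selector_fn,
                          proposer_fn)
    off_obj <- evaluate_batch(problem, off$sequences, objective_specs, cache)
    pool_seqs <- c(pop$sequences, off$sequences)
    pool_obj <- rbind(pop$objectives, off_obj)
    pool_prov <- c(pop$provenance, off$provenance)
    pool_part <- fast_non_dominated_sort(pool_obj)
    keep <- environmental_selection(pool_obj, config$population_size)
    pop <- population(problem, pool_seqs[keep],
                      objectives = pool_obj[keep, , drop = FALSE],
                      provenance = pool_prov[keep], iteration = iter)
    front0 <- which(fast_non_dominated_sort(pop$objectives)$rank == 1L)
    hv <- hypervolume_2d(pop$objectives[front0, 1:2, drop = FALSE],
                         config$hv_reference)
    recov <- mean(vapply(pop$sequences, function(s) {
      mean(strsplit(s, "")[[1]] == strsplit(ref_designed, "")[[1]])
    }, numeric(1)))
    metrics <- c(iteration = iter, mean_recovery = recov,
                 stats::setNames(colMeans(pop$objectives),
                                 paste0("mean_", obj_names)),
                 hv_front0 = hv,
                 front0_size = length(front0),
                 pool_front0_size = length(pool_part$fronts[[1]]))
    records[[k]] <- list(population = pop, metrics = metrics,
                         rng_state = .Random.seed)
  }
  list(iterations = records, final = pop)
}

#' Per-iteration metrics of a run as a data frame
#'
#' @param history A `run_history`.
#' @return Data frame with one row per iteration: mean native recovery, mean
#'   value of each objective, front-0 hypervolume (first two objectives,
#'   configured reference point) and front sizes.
#' @export
run_metrics <- function(history) {
  rows <- lapply(history$iterations, function(r) as.data.frame(as.list(r$metrics)))
  do.call(rbind, rows)
}

#' Serialize a design run to a directory
#'
#' Writes one FASTA population snapshot per iteration, `metrics.csv`, a YAML
#' echo of the configuration and a JSON manifest (seed, iteration count,
#' objective names, final RNG state), making the run directory
#' self-describing.
#'
#' @param history A `run_history`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_run <- function(history, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(history$iterations)) {
    rec <- history$iterations[[i]]
    write_population_fasta(rec$population,
                           file.path(dir, sprintf("population_iter%03d.fasta", i)),
                           objective_names = history$objective_names)
  }
  utils::write.csv(run_metrics(history), file.path(dir, "metrics.csv"),
                   row.names = FALSE)
  cfg <- unclass(history$config)
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  manifest <- list(
    package = "evodesign",
    version = as.character(utils::packageVersion("evodesign")),
    seed = history$config$seed,
    iterations = length(history$iterations),
    population_size = history$config$population_size,
    objectives = history$objective_names,
    final_rng_state = history$iterations[[length(history$iterations)]]$rng_state
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
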