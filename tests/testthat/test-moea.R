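test_that("domination follows the strict componentwise definition", {
  expect_true(dominates(c(1, 2), c(2, 3)))
  expect_false(dominates(c(1, 2), c(2, 1)))
  expect_false(dominates(c(2, 1), c(1, 2)))
  expect_false(dominates(c(1, 2), c(1, 2)))
  expect_true(dominates(c(1, 2), c(1, 3)))
  expect_error(dominates(c(1, 2), c(1, 2, 3)), "equal length")
  expect_error(dominates(c(1, NA), c(1, 2)), "finite")
})

test_that("fast non-dominated sort matches hand-checkable partitions", {
  one <- fast_non_dominated_sort(matrix(c(3, 1), 1))
  expect_equal(one$fronts, list(1L))

  part <- fast_non_dominated_sort(rbind(c(1, 2), c(2, 1), c(3, 3)))
  expect_equal(part$fronts, list(c(1L, 2L), 3L))
  expect_equal(part$rank, c(1L, 1L, 2L))
  expect_error(fast_non_dominated_sort(matrix(numeric(), 0, 2)), "at least one")
})

test_that("fast non-dominated sort equals the peeling oracle on random instances", {
  set.seed(101)
  for (i in 1:25) {
    n <- sample(5:120, 1)
    m <- sample(2:4, 1)
    obj <- matrix(round(rnorm(n * m), sample(1:3, 1)), n, m)  # rounding forces ties
    part <- fast_non_dominated_sort(obj)
    oracle <- peel_fronts_oracle(obj)
    expect_equal(lapply(part$fronts, sort), lapply(oracle, sort))
    # partition invariants: disjoint cover
    expect_equal(sort(unlist(part$fronts)), seq_len(n))
  }
})

test_that("crowding distance follows the normalized-gap formula", {
  expect_equal(crowding_distance(rbind(c(1, 1))), Inf)
  expect_equal(crowding_distance(rbind(c(1, 2), c(2, 1))), c(Inf, Inf))

  d <- crowding_distance(rbind(c(0, 2), c(1, 1), c(2, 0)))
  expect_equal(d, c(Inf, 2, Inf))           # middle: (2-0)/2 + (2-0)/2

  # degenerate range contributes 0, not NaN
  d2 <- crowding_distance(rbind(c(0, 5), c(1, 5), c(2, 5)))
  expect_equal(d2, c(Inf, 1, Inf))
  same <- crowding_distance(matrix(1, 4, 2))
  expect_equal(same[2:3], c(0, 0))
  expect_equal(same[c(1, 4)], c(Inf, Inf))
})

test_that("binary tournament prefers rank, then crowding, then a fair coin", {
  rank <- c(1L, 2L)
  dist <- c(0.1, 5)
  set.seed(1)
  wins <- replicate(200, binary_tournament(rank, dist))
  expect_true(all(wins == 1L))              # lower rank always wins

  rank2 <- c(1L, 1L); dist2 <- c(Inf, 0.5)
  wins2 <- replicate(200, binary_tournament(rank2, dist2))
  expect_true(all(wins2 == 1L))             # crowding tiebreak

  rank3 <- c(1L, 1L); dist3 <- c(1, 1)
  set.seed(42)
  wins3 <- replicate(10000, binary_tournament(rank3, dist3))
  expect_lt(abs(mean(wins3 == 1L) - 0.5), 0.02)

  expect_equal(binary_tournament(1L, Inf), 1L)   # singleton population
})

test_that("environmental selection admits whole fronts then truncates by crowding", {
  # |front 0| = N: next generation is exactly front 0
  obj <- rbind(c(0, 3), c(1, 2), c(2, 1), c(3, 0), c(5, 5), c(6, 6))
  sel <- environmental_selection(obj, 4)
  expect_setequal(sel, 1:4)

  # |front 0| = N + 2: the N members with the largest crowding distances,
  # cross-checked by exhaustive ranking on a 6-point front
  front <- rbind(c(0, 10), c(1, 6), c(2, 5.9), c(3, 3), c(6, 1), c(10, 0))
  cd <- crowding_distance(front)
  expected <- sort(order(-cd)[1:4])
  expect_setequal(environmental_selection(front, 4), expected)

  # |front 0| = 3, |front 1| = 5, N = 5
  f0 <- rbind(c(0, 2), c(1, 1), c(2, 0))
  f1 <- rbind(c(1, 4), c(2, 3), c(3, 2.5), c(4, 2.2), c(5, 2.1))
  pool <- rbind(f0, f1)
  sel2 <- environmental_selection(pool, 5)
  expect_true(all(1:3 %in% sel2))
  cd1 <- crowding_distance(f1)
  expect_setequal(setdiff(sel2, 1:3) - 3L, order(-cd1)[1:2])

  expect_error(environmental_selection(obj, 10), "smaller")
})

test_that("environmental selection always retains front 0 when it fits", {
  set.seed(5)
  for (i in 1:20) {
    obj <- matrix(runif(60), 30, 2)
    f0 <- fast_non_dominated_sort(obj)$fronts[[1]]
    n <- max(length(f0), 15L)
    expect_true(all(f0 %in% environmental_selection(obj, n)))
  }
})

test_that("evolve is reproducible, keeps N constant, and caches harmlessly", {
  toy <- make_toy_problem(L = 5, A = 3, conflict_fraction = 0.4, seed = 9)
  specs <- toy_objectives(toy)
  cfg <- run_config(population_size = 30, iterations = 8, mutation_rate = 0.3,
                    seed = 123)
  h1 <- evolve(toy$problem, cfg, specs)
  h2 <- evolve(toy$problem, cfg, specs)
  expect_identical(lapply(h1$iterations, function(r) r$population$sequences),
                   lapply(h2$iterations, function(r) r$population$sequences))
  expect_identical(run_metrics(h1), run_metrics(h2))
  sizes <- vapply(h1$iterations, function(r) length(r$population), integer(1))
  expect_true(all(sizes == 30L))
})

test_that("evolve rejects non-finite evaluators with a named objective", {
  toy <- make_toy_problem(L = 4, A = 3, seed = 2)
  bad <- list(objective_spec("broken", function(fulls) rep(NaN, length(fulls))))
  cfg <- run_config(population_size = 5, iterations = 1, seed = 1)
  expect_error(evolve(toy$problem, cfg, bad), "broken")
})

test_that("a neutral configuration leaves a converged population invariant", {
  # crossover off, proposer returns the current residue: mutation is a
  # fixed point, so a uniform population passes through selection unchanged
  toy <- make_toy_problem(L = 5, A = 3, conflict_fraction = 0, seed = 4)
  specs <- toy_objectives(toy)
  identity_proposer <- function(full_sequence, selection, problem) {
    strsplit(from_full_sequence(problem, full_sequence), "")[[1]][selection]
  }
  cfg <- run_config(population_size = 10, iterations = 3,
                    crossover_probability = 0, proposer = identity_proposer,
                    seed = 5)
  start <- population(toy$problem,
                      rep(toy$modal_sequences[["alpha"]], 10))
  h <- evolve(toy$problem, cfg, specs, initial = start)
  expect_true(all(h$final$sequences == toy$modal_sequences[["alpha"]]))
})

test_that("checkpoint restart reproduces a straight-through run exactly", {
  toy <- make_toy_problem(L = 5, A = 3, conflict_fraction = 0.4, seed = 9)
  specs <- toy_objectives(toy)
  full <- evolve(toy$problem,
                 run_config(population_size = 20, iterations = 6, seed = 77),
                 specs)
  part <- evolve(toy$problem,
                 run_config(population_size = 20, iterations = 3, seed = 77),
                 specs)
  resumed <- resume_run(part, 3)
  expect_identical(resumed$final$sequences, full$final$sequences)
  expect_equal(run_metrics(resumed), run_metrics(full))
})

test_that("run directories are self-describing and populations re-readable", {
  toy <- make_toy_problem(L = 5, A = 3, seed = 9)
  specs <- toy_objectives(toy)
  h <- evolve(toy$problem, run_config(population_size = 15, iterations = 4,
                                      seed = 3), specs)
  dir <- file.path(tempdir(), "run_serialize_test")
  save_run(h, dir)
  expect_true(file.exists(file.path(dir, "metrics.csv")))
  expect_true(file.exists(file.path(dir, "config.yaml")))
  expect_true(file.exists(file.path(dir, "manifest.json")))
  expect_length(list.files(dir, pattern = "^population_iter"), 4L)
  pop <- read_population_fasta(file.path(dir, "population_iter004.fasta"),
                               toy$problem)
  expect_identical(pop$sequences, h$final$sequences)
  expect_equal(unname(pop$objectives), unname(h$final$objectives),
               tolerance = 1e-9)
  unlink(dir, recursive = TRUE)
})
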