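test_that("composite folding score is the bounded product of its components", {
  expect_equal(composite_fold_score(1, 1, 1), 1)
  expect_equal(composite_fold_score(0, 0.5, 0.9), 0)
  expect_equal(composite_fold_score(0.8, 0.9, 0.5), 0.36)
  expect_error(composite_fold_score(1.2, 0.5, 0.5), "outside")
  expect_error(composite_fold_score(0.5, -0.1, 0.5), "ptm")

  # monotone non-decreasing in each component
  set.seed(2)
  for (i in 1:50) {
    x <- runif(3)
    j <- sample(3, 1)
    y <- x; y[j] <- min(1, x[j] + runif(1, 0, 1 - x[j]))
    expect_gte(composite_fold_score(y[1], y[2], y[3]),
               composite_fold_score(x[1], x[2], x[3]))
  }
})

test_that("Kabsch superposition recovers rigid transforms and matches the quaternion oracle", {
  set.seed(4)
  a <- matrix(rnorm(30), 10, 3)
  same <- kabsch_superpose(a, a)
  expect_lt(same$rmsd, 1e-10)
  expect_equal(same$rotation, diag(3), tolerance = 1e-8)

  # random proper rotation + translation: rmsd ~ 0, det(R) = +1
  for (i in 1:10) {
    q <- rnorm(4); q <- q / sqrt(sum(q^2))
    R <- matrix(c(
      1 - 2*(q[3]^2 + q[4]^2), 2*(q[2]*q[3] - q[1]*q[4]), 2*(q[2]*q[4] + q[1]*q[3]),
      2*(q[2]*q[3] + q[1]*q[4]), 1 - 2*(q[2]^2 + q[4]^2), 2*(q[3]*q[4] - q[1]*q[2]),
      2*(q[2]*q[4] - q[1]*q[3]), 2*(q[3]*q[4] + q[1]*q[2]), 1 - 2*(q[2]^2 + q[3]^2)),
      3, 3, byrow = TRUE)
    b <- a %*% t(R) + matrix(rnorm(3), 10, 3, byrow = TRUE)
    fit <- kabsch_superpose(a, b)
    expect_lt(fit$rmsd, 1e-6)
    expect_equal(det(fit$rotation), 1, tolerance = 1e-8)
  }

  # random clouds: rmsd equals Horn's quaternion closed form
  for (i in 1:20) {
    x <- matrix(rnorm(30), 10, 3)
    y <- matrix(rnorm(30), 10, 3)
    expect_equal(kabsch_superpose(x, y)$rmsd, quaternion_rmsd_oracle(x, y),
                 tolerance = 1e-8)
  }
  expect_error(kabsch_superpose(a, a[1:5, ]), "equal-size")
})

test_that("TM-score is 1 for identical inputs and rigid-invariant", {
  set.seed(6)
  helix <- evodesign:::ca_coords(make_toy_structure(20, "helix", seed = 1))
  expect_equal(tm_score(helix, helix), 1.0, tolerance = 1e-12)

  theta <- 0.7
  R <- rbind(c(cos(theta), -sin(theta), 0),
             c(sin(theta),  cos(theta), 0),
             c(0, 0, 1))
  moved <- helix %*% t(R) + matrix(c(5, -3, 12), 20, 3, byrow = TRUE)
  expect_equal(tm_score(moved, helix), 1.0, tolerance = 1e-6)
  expect_error(tm_score(helix, helix[1:10, ]), "same number")
})

test_that("TM-score with one displaced residue matches the closed form", {
  set.seed(12)
  L <- 24L
  ref <- evodesign:::ca_coords(make_toy_structure(L, "strand", seed = 3))
  model <- ref
  model[L, ] <- model[L, ] + c(0, 500, 0)   # one residue flung far away
  tm <- tm_score(model, ref)
  d0 <- evodesign:::tm_d0(L)
  # superposition excluding the outlier: L-1 zero-distance terms + 1 tiny term
  closed_form <- (L - 1) / L
  expect_equal(tm, closed_form, tolerance = 2e-3)
  expect_gt(tm, (L - 1) / L - 1e-6)
})

test_that("PSSM log-likelihood matches closed forms and a brute-force sum", {
  alphabet <- aa_alphabet()
  L <- 5L
  uniform <- matrix(1 / 20, L, 20, dimnames = list(NULL, alphabet))
  seqs <- c("ACDEF", "WWWWW")
  ll <- pssm_log_likelihood(seqs, uniform, alphabet)
  expect_equal(ll, rep(log(1 / 20), 2))

  # near-one-hot PSSM matching the candidate
  eps <- 1e-4
  onehot <- matrix(eps, L, 20, dimnames = list(NULL, alphabet))
  chars <- strsplit("ACDEF", "")[[1]]
  for (p in seq_len(L)) onehot[p, chars[p]] <- 1 - 19 * eps
  expect_equal(pssm_log_likelihood("ACDEF", onehot, alphabet),
               log(1 - 19 * eps), tolerance = 1e-12)

  # random case: position-by-position hand sum
  set.seed(17)
  raw <- matrix(rexp(L * 20), L, 20)
  pssm <- raw / rowSums(raw); colnames(pssm) <- alphabet
  s <- "MKLVA"
  sc <- strsplit(s, "")[[1]]
  hand <- mean(vapply(seq_len(L), function(p) log(pssm[p, sc[p]]), numeric(1)))
  expect_equal(pssm_log_likelihood(s, pssm, alphabet), hand, tolerance = 1e-12)
})

test_that("surrogate composite saturates at the modal sequence and is monotone", {
  toy <- make_toy_problem(L = 4, A = 4, conflict_fraction = 0.5, seed = 5)
  pssm <- toy$pssms$alpha
  alphabet <- toy$problem$alphabet
  modal <- toy$modal_sequences[["alpha"]]
  expect_equal(surrogate_composite(modal, pssm, alphabet), 1.0, tolerance = 1e-12)

  set.seed(23)
  for (i in 1:50) {
    s <- paste(sample(alphabet, 4, replace = TRUE), collapse = "")
    v <- surrogate_composite(s, pssm, alphabet)
    expect_true(v > 0 && v <= 1)
  }

  # improving one position's probability never lowers the score
  for (i in 1:20) {
    s <- paste(sample(alphabet, 4, replace = TRUE), collapse = "")
    chars <- strsplit(s, "")[[1]]
    p <- sample(4, 1)
    better <- chars
    better[p] <- alphabet[which.max(pssm[p, ])]
    expect_gte(surrogate_composite(paste(better, collapse = ""), pssm, alphabet),
               surrogate_composite(s, pssm, alphabet))
  }
})

test_that("objective evaluators stay finite over fuzzed alphabet sequences", {
  toy <- make_toy_problem(L = 6, A = 4, conflict_fraction = 0.7, seed = 31)
  specs <- toy_objectives(toy)
  set.seed(41)
  fulls <- vapply(1:100, function(i) {
    to_full_sequence(toy$problem,
                     paste(sample(toy$problem$alphabet, 6, replace = TRUE),
                           collapse = ""))
  }, character(1))
  for (spec in specs) {
    expect_true(all(is.finite(spec$evaluate(fulls))))
  }
})

test_that("scorer plugin contracts document hyperparameters and gate arity", {
  contracts <- plugin_contracts()
  expect_setequal(names(contracts),
                  c("pmpnn_sd_score", "esm_position_scores", "af2rank_score"))
  expect_equal(contracts$pmpnn_sd_score$hyperparameters$temperature, 0.3)
  expect_equal(contracts$pmpnn_sd_score$hyperparameters$score_repeats, 5L)
  expect_equal(contracts$af2rank_score$hyperparameters$recycles, 1L)
  expect_match(contracts$af2rank_score$hyperparameters$template, "gap tokens")
  expect_equal(contracts$esm_position_scores$hyperparameters$masking, "none")

  expect_error(register_scorer("pmpnn_sd_score", function(x) x), "at least 2")
  register_scorer("pmpnn_sd_score", function(seqs, structure) rep(1, length(seqs)))
  expect_silent(get_scorer("pmpnn_sd_score"))
})

test_that("a mock constant plugin drives a full design run end-to-end", {
  toy <- make_toy_problem(L = 5, A = 3, seed = 3)
  register_scorer("mock_const", function(fulls) rep(0.5, length(fulls)))
  specs <- list(
    objective_spec("mock", get_scorer("mock_const")),
    toy_objectives(toy)[[1]]
  )
  cfg <- run_config(population_size = 10, iterations = 2, seed = 19)
  h <- evolve(toy$problem, cfg, specs)
  expect_equal(ncol(h$final$objectives), 2L)
  expect_true(all(h$final$objectives[, 1] == 0.5))
})

test_that("swapping surrogate for an equal-valued plugin leaves the trajectory unchanged", {
  toy <- make_toy_problem(L = 5, A = 3, conflict_fraction = 0.4, seed = 3)
  surro <- toy_objectives(toy)
  plug <- list(
    objective_spec("alpha", surro[[1]]$evaluate),
    objective_spec("beta", surro[[2]]$evaluate)
  )
  cfg <- run_config(population_size = 15, iterations = 4, seed = 29)
  h1 <- evolve(toy$problem, cfg, surro)
  h2 <- evolve(toy$problem, cfg, plug)
  expect_identical(h1$final$sequences, h2$final$sequences)
})
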