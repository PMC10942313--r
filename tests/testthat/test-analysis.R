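test_that("native recovery is the fraction of matching designable positions", {
  ref <- paste(rep(c("A", "C"), 18), collapse = "")   # 36 residues
  problem <- make_problem(ref, 1:36)
  expect_equal(native_recovery(reference_designed(problem), problem), 1.0)

  flipped <- chartr("AC", "CA", ref)
  expect_equal(native_recovery(flipped, problem), 0.0)

  half <- paste0(substr(ref, 1, 18), substr(flipped, 19, 36))
  expect_equal(native_recovery(half, problem), 0.5)   # 18 of 36 match
})

test_that("positional entropy hits its closed forms", {
  const <- rep("AAAA", 10)
  expect_equal(unname(positional_entropy(const)), rep(0, 4))

  half <- c(rep("A", 5), rep("C", 5))
  expect_equal(unname(positional_entropy(paste0(half, "A"))), c(log(2), 0))

  unif20 <- vapply(aa_alphabet(), function(a) paste0(a, a), character(1))
  expect_equal(unname(positional_entropy(unif20)), rep(log(20), 2),
               tolerance = 1e-12)

  ec <- entropy_ecdf(c(rep("AA", 3), rep("AC", 3)))
  expect_equal(ec(0), 0.5)     # one conserved column of two
})

test_that("2-D hypervolume matches closed forms and ignores dominated points", {
  expect_equal(hypervolume_2d(c(-0.8, -0.7), c(0, 0)), 0.56)
  expect_equal(hypervolume_2d(rbind(c(-2, -1), c(-1, -2)), c(0, 0)), 3)

  # adding a dominated or duplicated point changes nothing
  base <- rbind(c(1, 2), c(2, 1))
  hv <- hypervolume_2d(base, c(4, 4))
  expect_equal(hypervolume_2d(rbind(base, c(3, 3)), c(4, 4)), hv)
  expect_equal(hypervolume_2d(rbind(base, base), c(4, 4)), hv)

  # points outside the reference box contribute nothing
  expect_equal(hypervolume_2d(rbind(base, c(5, 0.5), c(0.5, 9)), c(4, 4)), hv)
  expect_equal(hypervolume_2d(rbind(c(9, 9)), c(4, 4)), 0)

  # adding a non-dominated point inside the box is monotone non-decreasing
  set.seed(3)
  for (i in 1:20) {
    pts <- matrix(runif(20, 0, 4), 10, 2)
    h0 <- hypervolume_2d(pts, c(4, 4))
    extra <- runif(2, 0, 4)
    expect_gte(hypervolume_2d(rbind(pts, extra), c(4, 4)), h0 - 1e-12)
  }
  expect_error(hypervolume_2d(matrix(1, 2, 3), c(0, 0)), "2 objectives")
  expect_error(hypervolume_2d(c(1, 2), c(Inf, 0)), "finite")
})

test_that("hypervolume agrees with a Monte Carlo rejection oracle", {
  set.seed(9)
  for (i in 1:5) {
    pts <- matrix(runif(30, 0, 4), 15, 2)
    mc <- mc_hypervolume_oracle(pts, c(4, 4), n_samples = 2e5)
    expect_lt(abs(hypervolume_2d(pts, c(4, 4)) - mc$hv), 3 * mc$se + 1e-9)
  }
})

test_that("normalized BLOSUM62 similarity has unit diagonal, symmetry, and table values", {
  expect_equal(blosum_similarity("ACDE", "ACDE"), 1.0)
  set.seed(21)
  for (i in 1:10) {
    a <- paste(sample(aa_alphabet(), 8, replace = TRUE), collapse = "")
    b <- paste(sample(aa_alphabet(), 8, replace = TRUE), collapse = "")
    expect_equal(blosum_similarity(a, b), blosum_similarity(b, a))
  }
  # hand computation from published BLOSUM62 entries:
  # s(A,R) = -1, s(A,A) = 4, s(R,R) = 5; s(W,W) = 11
  hand <- mean(c(-1 / sqrt(4 * 5), 1))
  expect_equal(blosum_similarity("AW", "RW"), hand, tolerance = 1e-12)
  expect_error(blosum_similarity("AO", "AA"), "substitution matrix")
  expect_error(blosum_similarity("AAA", "AA"), "equal length")

  S <- similarity_matrix(c("ACDE", "ACDF", "WYWY"))
  expect_equal(diag(S), rep(1, 3))
  expect_equal(S, t(S))
})

test_that("spectral embedding separates blocks and is permutation-equivariant", {
  # two weakly connected blocks; the inter-block affinities vary so min-max
  # scaling zeroes only the single weakest edge and the graph stays connected
  set.seed(61)
  n <- 8
  W <- matrix(runif(n * n, 0.05, 0.15), n, n)
  W[1:4, 1:4] <- runif(16, 0.8, 0.9)
  W[5:8, 5:8] <- runif(16, 0.8, 0.9)
  W <- (W + t(W)) / 2
  diag(W) <- 1
  emb <- spectral_embed(W, dims = 2)
  s <- sign(emb[, 1])
  expect_true(all(s[1:4] == s[1]) && all(s[5:8] == s[5]) && s[1] != s[5])

  # eigen-decomposition oracle: coordinates reproduce the Laplacian eigenvectors
  rng <- range(W); Wn <- (W - rng[1]) / (rng[2] - rng[1])
  deg <- rowSums(Wn)
  Ls <- diag(n) - diag(1 / sqrt(deg)) %*% Wn %*% diag(1 / sqrt(deg))
  ev <- eigen((Ls + t(Ls)) / 2, symmetric = TRUE)
  v <- ev$vectors[, n - 1] / sqrt(deg)
  expect_equal(abs(cor(emb[, 1], v)), 1, tolerance = 1e-8)

  perm <- sample(n)
  emb_p <- spectral_embed(W[perm, perm], dims = 2)
  expect_equal(emb_p, emb[perm, ], tolerance = 1e-8)

  expect_error(spectral_embed(W, dims = 8), "smaller")
  expect_error(spectral_embed(matrix(runif(9), 3, 3), 1), "symmetric")
})

test_that("post hoc non-dominated filtering equals front 0 and is idempotent", {
  set.seed(33)
  for (i in 1:10) {
    obj <- matrix(runif(40), 20, 2)
    nd <- posthoc_nondominated_filter(obj)
    expect_equal(sort(nd), sort(peel_fronts_oracle(obj)[[1]])) # oracle match
    again <- posthoc_nondominated_filter(obj[nd, , drop = FALSE])
    expect_equal(sort(nd[again]), sort(nd))                    # idempotent
  }
})

test_that("alignment trimming keeps reference designable columns and drops gapped rows", {
  aligned <- c(
    ref   = "MK-LVAG-DE",
    seq_a = "MKQLVAGWDE",
    seq_b = "MK-L-AGWDE",    # gap inside the designable region
    seq_c = "MKWLVAAEDE"
  )
  # ungapped reference "MKLVAGDE"; designable positions 3..6 = "LVAG"
  res <- trim_alignment_to_reference(aligned, "ref", 3:6)
  expect_equal(res$retained, 3L)
  expect_equal(res$dropped, 1L)
  expect_false("seq_b" %in% names(res$sequences))
  expect_equal(unname(res$sequences[["ref"]]), "LVAG")
  expect_equal(unname(res$sequences[["seq_a"]]), "LVAG")
  expect_equal(unname(res$sequences[["seq_c"]]), "LVAA")

  # column extraction against a hand-built index map
  ref_chars <- strsplit(aligned[["ref"]], "")[[1]]
  hand_cols <- which(!(ref_chars %in% c("-", ".")))[3:6]
  expect_equal(res$columns, hand_cols)

  expect_error(trim_alignment_to_reference(aligned, "missing", 1:2),
               "absent")
  expect_error(trim_alignment_to_reference(aligned, "ref", 1:9),
               "outside")
})

test_that("percentile similarity follows the linear-interpolation convention", {
  problem <- make_problem("ACDEFGHIKL", 1:10)
  ref <- reference_designed(problem)
  expect_equal(percentile_similarity_to_set(ref, c(ref), 95), 1.0)
  single <- percentile_similarity_to_set(ref, "CADEFGHIKL", 20)
  expect_equal(single, blosum_similarity(ref, "CADEFGHIKL"))

  # 100 distinct values: closed form of R's type-7 quantile
  set.seed(51)
  refs <- vapply(1:100, function(i) {
    paste(sample(aa_alphabet(), 10, replace = TRUE), collapse = "")
  }, character(1))
  sims <- sort(vapply(refs, blosum_similarity, numeric(1), seq_a = ref,
                      USE.NAMES = FALSE))
  h <- (100 - 1) * 0.95 + 1
  closed <- sims[floor(h)] + (h - floor(h)) * (sims[ceiling(h)] - sims[floor(h)])
  expect_equal(percentile_similarity_to_set(ref, refs, 95), closed,
               tolerance = 1e-12)
  expect_error(percentile_similarity_to_set(ref, character(0)), "non-empty")
})

test_that("profile matrices are row-stochastic counts", {
  prof1 <- profile_matrix("ACD", alphabet = aa_alphabet())
  expect_equal(unname(prof1[1, "A"]), 1)
  expect_true(all(rowSums(prof1) == 1))

  pop <- c("AAC", "ACC", "AAC")
  prof <- profile_matrix(pop, alphabet = c("A", "C"))
  expect_equal(unname(prof[, "A"]), c(1, 2 / 3, 0))
  expect_equal(unname(prof[, "C"]), c(0, 1 / 3, 1))
  expect_true(all(abs(rowSums(prof) - 1) < 1e-9))
})
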