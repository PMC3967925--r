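test_that("viterbi_align: identity, tie-break and brute-force optimality", {
  # strongly diagonal scores -> identity alignment, all M
  s <- random_scores(4, 4, sd = 0)
  s$sM <- diag(4) * 10 - 1
  aln <- viterbi_align(s)
  expect_equal(aln$aligned_pairs, cbind(1:4, 1:4), ignore_attr = TRUE)
  expect_true(all(aln$triples[, 3] == 1))

  # all-equal scores: canonical all-M diagonal path via the tie rule
  s0 <- list(sM = matrix(0, 3, 3), sIT = matrix(0, 3, 4),
             sIS = matrix(0, 4, 3), trans = matrix(0, 3, 3))
  s0$trans[2, 3] <- s0$trans[3, 2] <- -Inf
  aln0 <- viterbi_align(s0)
  expect_equal(aln0$triples[, 3], rep(1L, 3))

  withr::with_seed(101, {
    for (rep in 1:20) {
      nT <- sample(2:4, 1); nS <- sample(2:4, 1)
      sc <- random_scores(nT, nS)
      v <- viterbi_align(sc)
      paths <- enumerate_paths(nT, nS)
      best <- max(vapply(paths, oracle_path_score, numeric(1), scores = sc))
      expect_equal(v$score, best, tolerance = 1e-10)
      expect_equal(oracle_path_score(v$triples, sc), v$score,
                   tolerance = 1e-10)
    }
  })
})

test_that("path validation enforces monotonicity and endpoints", {
  expect_error(validate_path(rbind(c(1, 1, 1), c(3, 2, 2)), 3, 2), "contract")
  expect_error(validate_path(rbind(c(1, 1, 1)), 2, 2), "contract")
  # direct I_T -> I_S toggle is invalid
  expect_error(validate_path(rbind(c(1, 0, 2), c(1, 1, 3), c(2, 2, 1)),
                             2, 2), "contract")
  expect_silent(validate_path(rbind(c(1, 1, 1), c(2, 1, 2), c(3, 2, 1)),
                              3, 2))
})

test_that("objective_p1 equals node score with zero edges and hand sums with edges", {
  withr::with_seed(7, {
    sc <- random_scores(5, 5)
    tab0 <- zero_edge_table(5, 5, 3)
  })
  v <- viterbi_align(sc)
  expect_equal(objective_p1(v, sc, tab0), v$score, tolerance = 1e-12)

  withr::with_seed(8, tab <- random_edge_table(5, 5, nbins = 3,
                                               min_separation = 1))
  # 4-match toy, hand-summed edge term
  path <- rbind(c(1, 1, 1), c(2, 2, 1), c(3, 3, 1), c(4, 3, 2), c(5, 4, 1),
                c(5, 5, 3))
  m <- path[path[, 3] == 1, 1:2]
  hand <- 0
  for (a in 1:3) for (b in (a + 1):4)
    hand <- hand + edge_potential_at(tab, m[a, 1], m[b, 1], m[a, 2], m[b, 2])
  expect_equal(objective_p1(path, sc, tab),
               oracle_path_score(path, sc) + hand / nrow(path),
               tolerance = 1e-10)
  # fewer than 2 matches: node term only
  p1m <- rbind(c(0, 1, 3), c(0, 2, 3), c(0, 3, 3), c(0, 4, 3), c(1, 5, 1),
               c(2, 5, 2), c(3, 5, 2), c(4, 5, 2), c(5, 5, 2))
  expect_equal(objective_p1(p1m, sc, tab), oracle_path_score(p1m, sc),
               tolerance = 1e-12)
})

test_that("linearized SP scores reduce correctly and their DP solves the SP objective", {
  withr::with_seed(9, {
    sc <- random_scores(4, 4)
    tab <- random_edge_table(4, 4, nbins = 3, min_separation = 1)
  })
  nT <- 4; nS <- 4
  empty <- mrfaln:::zero_indicators(nT, nS)
  lam0 <- mrfaln:::zero_indicators(nT, nS)
  red <- linearized_dp_scores(empty, lam0, 0, sc, tab, 5)
  expect_equal(red$sM, sc$sM, tolerance = 1e-12)
  expect_equal(red$sIT, sc$sIT, tolerance = 1e-12)

  # single fixed M-cell: each candidate gains its (1/L)-scaled potential
  one <- mrfaln:::zero_indicators(nT, nS)
  one$M[2, 2] <- 1
  L <- 4
  red1 <- linearized_dp_scores(one, lam0, 0, sc, tab, L)
  gain <- red1$sM - sc$sM - 0 * 0.5
  expect_equal(gain[4, 3], edge_potential_at(tab, 4, 2, 3, 2) / L,
               tolerance = 1e-10)

  # DP on linearised scores = brute-force max of the SP objective
  withr::with_seed(10, {
    for (rep in 1:10) {
      z_path <- viterbi_align(random_scores(nT, nS))$triples
      z <- mrfaln:::path_indicators(z_path, nT, nS)
      lam <- list(M = matrix(rnorm(nT * nS, 0, 0.3), nT, nS),
                  IT = matrix(rnorm(nT * (nS + 1), 0, 0.3), nT, nS + 1),
                  IS = matrix(rnorm((nT + 1) * nS, 0, 0.3), nT + 1, nS))
      rho <- 0.5
      spsc <- linearized_dp_scores(z, lam, rho, sc, tab, nrow(z_path))
      y <- viterbi_align(spsc)
      paths <- enumerate_paths(nT, nS)
      best <- max(vapply(paths, oracle_path_score, numeric(1), scores = spsc))
      expect_equal(y$score, best, tolerance = 1e-9)
    }
  })
})

test_that("ADMM with zero edge potential converges at iteration 1 to Viterbi", {
  withr::with_seed(11, sc <- random_scores(6, 5))
  tab0 <- zero_edge_table(6, 5, 3)
  res <- admm_align(edge_tab = tab0, scores = sc)
  v <- viterbi_align(sc)
  expect_true(res$converged)
  expect_equal(res$iterations, 1L)
  expect_identical(res$alignment$triples, v$triples)
  expect_equal(res$objective, v$score, tolerance = 1e-12)
})

test_that("ADMM soundness on random instances: feasible, bounded, deterministic", {
  withr::with_seed(12, {
    for (rep in 1:15) {
      nT <- sample(3:5, 1); nS <- sample(3:5, 1)
      sc <- random_scores(nT, nS)
      tab <- random_edge_table(nT, nS, nbins = 3, min_separation = 1)
      res <- admm_align(edge_tab = tab, scores = sc, max_iter = 20)
      # feasibility of returned path
      expect_silent(validate_path(res$alignment$triples, nT, nS))
      # best-seen at least the node-only P1 of the Viterbi initialisation
      expect_gte(res$objective,
                 objective_p1(viterbi_align(sc), sc, tab) - 1e-9)
      # exhaustive optimum is an upper bound
      opt <- oracle_p1_optimum(sc, tab)
      expect_lte(res$objective, opt + 1e-9)
      # per-iteration Lagrangian upper-bounds the P1 of its own iterates
      expect_true(all(res$trace$lagrangian >=
                        pmax(res$trace$obj_y, res$trace$obj_z) - 1e-9))
      # determinism
      res2 <- admm_align(edge_tab = tab, scores = sc, max_iter = 20)
      expect_identical(res$alignment$triples, res2$alignment$triples)
      expect_equal(res$objective, res2$objective)
    }
  })
})

test_that("a strong planted edge signal pulls ADMM away from a misleading Viterbi", {
  # node scores weakly favour a shifted alignment; edge potentials strongly
  # reward the consistent diagonal -- ADMM must recover a better P1 value
  nT <- 6; nS <- 6
  sc <- list(sM = matrix(0, nT, nS), sIT = matrix(-0.1, nT, nS + 1),
             sIS = matrix(-0.1, nT + 1, nS), trans = matrix(0, 3, 3))
  sc$trans[2, 3] <- sc$trans[3, 2] <- -Inf
  sc$sM[cbind(1:5, 2:6)] <- 0.4 # misleading off-diagonal node preference
  nb <- 2
  st <- structure(list(bins = structure(list(edges = 1, nbins = 2),
                                        class = "distance_bins"),
                       p_background = c(0.5, 0.5),
                       p_aligned = matrix(c(0.45, 0.05, 0.05, 0.45), 2),
                       min_separation = 1, alpha = 1),
                  class = "distance_stats")
  point <- function(b) { p <- c(0.02, 0.02); p[b] <- 0.98; p / sum(p) }
  arr <- array(0, dim = c(6, 6, 2))
  withr::with_seed(31, bins_of_pairs <- matrix(sample(1:2, 36, TRUE), 6))
  bins_of_pairs <- pmax(bins_of_pairs, t(bins_of_pairs))
  for (i in 1:6) for (k in 1:6) arr[i, k, ] <- point(bins_of_pairs[i, k])
  tab <- edge_table(arr, arr, st, min_separation = 1, center = FALSE)
  res <- admm_align(edge_tab = tab, scores = sc, rho = 0.5, max_iter = 30)
  v <- viterbi_align(sc)
  expect_gte(res$objective, objective_p1(v, sc, tab))
  # and the diagonal (edge-consistent) alignment scores at least as well
  expect_gte(res$objective,
             objective_p1(mrfaln:::path_from_pairs(cbind(1:6, 1:6), 6, 6),
                          sc, tab) - 1e-9)
})

test_that("with external-quality distance distributions the edge potential improves recall", {
  # the pluggable-predictor route: per-edge distributions of stated
  # fidelity derived from the planted scaffolds (the stand-in for an
  # external distance-potential tool)
  bench <- generate_benchmark(24, seed = 99)
  bench$pairs <- build_benchmark_mrfs(bench$pairs)
  bins <- distance_bins()
  stats <- distance_stats(
    count_background(lapply(bench$pairs, function(sp) sp$coords_T), bins),
    count_aligned(lapply(bench$pairs, function(sp)
      list(structure_T = sp$coords_T, structure_S = sp$coords_S,
           pairs = sp$true_alignment)), bins))
  evb <- generate_benchmark(20, seed = 4242)
  evb$pairs <- build_benchmark_mrfs(evb$pairs)
  sc <- new_profile_scorer()
  recs <- sapply(evb$pairs, function(sp) {
    scores <- pair_scores(sc, sp$mrf_T, sp$mrf_S)
    r0 <- viterbi_align(scores)
    tab <- edge_table(structure_edge_distributions(sp$coords_T, bins),
                      structure_edge_distributions(sp$coords_S, bins), stats)
    r1 <- admm_align(edge_tab = tab, scores = scores)
    c(node = compare_alignments(r0, sp$true_alignment)$recall,
      edge = compare_alignments(r1$alignment, sp$true_alignment)$recall)
  })
  expect_gt(mean(recs["edge", ]), mean(recs["node", ]))
  expect_equal(sum(recs["edge", ] < recs["node", ]), 0)
})
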