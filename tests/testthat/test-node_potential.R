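make_toy_mrf <- function(seqs, w = 1) build_mrf(new_msa(seqs), w = w,
                                                max_power = 2,
                                                min_separation = 2)

test_that("score_vertex contracts and the zero-network baseline", {
  sc <- new_cnf_scorer(w = 1, hidden = 3) # all-zero weights
  ctx <- matrix(runif(3 * 21), 3, 21)
  expect_equal(score_vertex(sc, ctx, ctx, "M"), 0)
  expect_equal(score_vertex(sc, context_T = ctx, state = "I_T"), 0)
  expect_equal(score_vertex(sc, context_S = ctx, state = "I_S"), 0)
  expect_error(score_vertex(sc, context_T = ctx, state = "M"), "contract")
  expect_error(score_vertex(sc, context_S = ctx, state = "I_T"), "contract")
})

test_that("a hand-set two-unit network reproduces explicit forward-pass arithmetic", {
  w <- 1; d <- 3 * 21
  sc <- new_cnf_scorer(w = w, hidden = 2)
  sc$Wm_a <- matrix(0.01, 2, d); sc$Wm_b <- matrix(-0.02, 2, d)
  sc$bm <- c(0.3, -0.1); sc$vm <- c(1.5, -2); sc$cm <- 0.25
  ctxT <- matrix(0.02, 3, 21); ctxS <- matrix(0.04, 3, 21)
  xT <- rep(0.02, d); xS <- rep(0.04, d)
  h <- tanh(c(sum(0.01 * xT) + sum(-0.02 * xS) + 0.3,
              sum(0.01 * xT) + sum(-0.02 * xS) - 0.1))
  expect_equal(score_vertex(sc, ctxT, ctxS, "M"),
               sum(h * c(1.5, -2)) + 0.25, tolerance = 1e-12)
})

test_that("estimate_background is the sampled mean, deterministic, exact when constant", {
  sc <- new_cnf_scorer(w = 1, hidden = 2)
  sc$cm <- 1.7; sc$ct <- -0.3; sc$cs <- 0.4 # constant-output networks
  pool <- lapply(1:4, function(i) matrix(runif(63), 3, 21))
  sc2 <- estimate_background(sc, pool, n_samples = 50, seed = 3)
  expect_equal(unname(sc2$background["M"]), 1.7)
  expect_equal(unname(sc2$background["I_T"]), -0.3)
  expect_equal(unname(sc2$background["I_S"]), 0.4)
  # after offsetting, scores are centred
  expect_equal(score_vertex(sc2, pool[[1]], pool[[2]], "M"), 0)

  sc3 <- new_cnf_scorer(w = 1, hidden = 2, init_sd = 0.3, seed = 9)
  a <- estimate_background(sc3, pool, n_samples = 200, seed = 11)
  b <- estimate_background(sc3, pool, n_samples = 200, seed = 11)
  expect_identical(a$background, b$background)
  expect_error(estimate_background(sc3, pool, n_samples = 0), "parameter")
})

test_that("forward log Z equals explicit path-sum enumeration on small lattices", {
  withr::with_seed(17, {
    for (dims in list(c(2, 3), c(3, 3), c(4, 4), c(4, 2))) {
      scores <- random_scores(dims[1], dims[2])
      lz <- mrfaln:::.forward_logz(scores$sM, scores$sIT, scores$sIS,
                                   scores$trans)
      expect_equal(lz, oracle_logz(scores), tolerance = 1e-8)
    }
  })
})

test_that("forward-backward posteriors are consistent with the lattice", {
  withr::with_seed(23, scores <- random_scores(4, 3))
  fb <- mrfaln:::.forward_backward(scores$sM, scores$sIT, scores$sIS,
                                   scores$trans)
  # posterior of any cell = sum over paths through it / total, via oracle
  paths <- enumerate_paths(4, 3)
  vals <- vapply(paths, oracle_path_score, numeric(1), scores = scores)
  wts <- exp(vals - max(vals)); wts <- wts / sum(wts)
  pm_oracle <- matrix(0, 4, 3)
  for (p in seq_along(paths)) {
    m <- paths[[p]][paths[[p]][, 3] == 1L, , drop = FALSE]
    if (nrow(m) > 0)
      pm_oracle[m[, 1:2, drop = FALSE]] <-
        pm_oracle[m[, 1:2, drop = FALSE]] + wts[p]
  }
  expect_equal(fb$post_M, pm_oracle, tolerance = 1e-8)
})

test_that("training fits a single reference alignment and its loss is monotone", {
  withr::with_seed(31, {
    seqsT <- replicate(10, paste0(sample(c("A", "R", "N", "D"), 6,
                                         replace = TRUE), collapse = ""))
    seqsS <- vapply(seqsT, function(s) {
      ch <- strsplit(s, "")[[1]]
      flip <- runif(6) < 0.2
      ch[flip] <- sample(c("A", "R", "N", "D"), sum(flip), replace = TRUE)
      paste0(ch, collapse = "")
    }, character(1))
  })
  mT <- make_toy_mrf(seqsT)
  mS <- make_toy_mrf(unname(seqsS))
  ref <- cbind(1:6, 1:6)
  tp <- list(list(T = mT, S = mS, ref = ref))
  sc <- train_scorer(tp, l2_lambda = 1e-4, epochs = 120, hidden = 6,
                     seed = 4, lr = 0.1, bg_samples = 200)
  trace <- attr(sc, "loss_trace")
  expect_true(all(diff(trace) <= 1e-9)) # non-increasing under step halving
  post <- alignment_posterior(sc, mT, mS, ref)
  expect_gt(post, 0.9)
})

test_that("heavy regularisation shrinks the scorer toward zero output", {
  withr::with_seed(41, {
    seqs <- replicate(6, paste0(sample(c("A", "R", "N"), 5,
                                      replace = TRUE), collapse = ""))
  })
  m <- make_toy_mrf(seqs)
  tp <- list(list(T = m, S = m, ref = cbind(1:5, 1:5)))
  sc <- train_scorer(tp, l2_lambda = 1e6, epochs = 40, hidden = 4, seed = 2,
                     bg_samples = 50)
  ctx <- profile_context(m, 3, w = 1)
  expect_lt(abs(score_vertex(sc, ctx, ctx, "M")), 0.05)
})

test_that("pair_scores matches score_vertex cell by cell (padding included)", {
  withr::with_seed(5, {
    seqsT <- replicate(6, paste0(sample(c("A", "C", "G"), 5,
                                        replace = TRUE), collapse = ""))
    seqsS <- replicate(6, paste0(sample(c("A", "C", "G"), 4,
                                        replace = TRUE), collapse = ""))
  })
  mT <- make_toy_mrf(seqsT)
  mS <- make_toy_mrf(seqsS)
  sc <- new_cnf_scorer(w = 1, hidden = 4, init_sd = 0.2, seed = 8)
  sc$background <- c(M = 0.2, I_T = -0.1, I_S = 0.05)
  ps <- pair_scores(sc, mT, mS)
  for (i in c(1, 3, 5)) {
    for (j in c(1, 4)) {
      expect_equal(ps$sM[i, j],
                   score_vertex(sc, profile_context(mT, i, 1),
                                profile_context(mS, j, 1), "M"),
                   tolerance = 1e-10)
    }
    expect_equal(ps$sIT[i, 1],
                 score_vertex(sc, context_T = profile_context(mT, i, 1),
                              state = "I_T"), tolerance = 1e-10)
  }
})
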