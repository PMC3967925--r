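toy_stats <- function(p_aligned, p_bg) {
  nb <- length(p_bg)
  structure(list(bins = structure(list(edges = seq_len(nb - 1), nbins = nb),
                                  class = "distance_bins"),
                 p_background = p_bg, p_aligned = p_aligned,
                 min_separation = 1, alpha = 1),
            class = "distance_stats")
}

test_that("edge_kernel: independence null, hand arithmetic, monotonicity", {
  # factorized p_aligned -> kernel identically 0
  p_bg <- c(0.2, 0.3, 0.5)
  st <- toy_stats(outer(p_bg, p_bg), p_bg)
  expect_lt(max(abs(edge_kernel(st))), 1e-12)

  # 2-bin hand arithmetic
  st2 <- toy_stats(matrix(c(0.4, 0.1, 0.1, 0.4), 2), c(0.5, 0.5))
  expect_equal(edge_kernel(st2),
               matrix(log(c(1.6, 0.4, 0.4, 1.6)), 2), tolerance = 1e-12)
  # diagonal-heavy p_aligned -> diagonal kernel dominates
  K <- edge_kernel(st2)
  expect_true(all(diag(K) > K[1, 2]))

  st_bad <- toy_stats(matrix(c(0.5, 0, 0.25, 0.25), 2), c(0.5, 0.5))
  expect_error(edge_kernel(st_bad), "contract")
})

test_that("edge_potential: zero kernel, point masses, bilinearity, summation oracle", {
  K <- matrix(0, 3, 3)
  expect_equal(edge_potential(c(1, 0, 0), c(0, 1, 0), K), 0)

  withr::with_seed(13, K2 <- matrix(rnorm(9), 3, 3))
  expect_equal(edge_potential(c(0, 1, 0), c(0, 0, 1), K2), K2[2, 3])

  withr::with_seed(14, {
    P1 <- runif(3); P1 <- P1 / sum(P1)
    P2 <- runif(3); P2 <- P2 / sum(P2)
    Q <- runif(3); Q <- Q / sum(Q)
  })
  # double-loop oracle
  oracle <- 0
  for (a in 1:3) for (b in 1:3) oracle <- oracle + P1[a] * Q[b] * K2[a, b]
  expect_equal(edge_potential(P1, Q, K2), oracle, tolerance = 1e-12)
  # bilinearity
  al <- 0.3
  expect_equal(edge_potential(al * P1 + (1 - al) * P2, Q, K2),
               al * edge_potential(P1, Q, K2) +
                 (1 - al) * edge_potential(P2, Q, K2), tolerance = 1e-12)
  expect_error(edge_potential(P1, c(0.5, 0.5), K2), "contract")
})

test_that("edge_table accessor agrees with edge_potential and is swap-symmetric", {
  withr::with_seed(15, tab <- random_edge_table(6, 5, nbins = 3,
                                                min_separation = 2))
  K <- tab$kernel
  # reconstruct the raw distributions from XT = PT %*% K
  for (cell in list(c(1, 4, 2, 5), c(2, 6, 1, 3))) {
    i <- cell[1]; k <- cell[2]; j <- cell[3]; l <- cell[4]
    PT <- solve(t(K), tab$XT[i, k, ])
    pot <- edge_potential(PT, tab$PS[j, l, ], K)
    expect_equal(edge_potential_at(tab, i, k, j, l), pot, tolerance = 1e-9)
    # simultaneous endpoint swap leaves the potential unchanged
    expect_equal(edge_potential_at(tab, k, i, l, j),
                 edge_potential_at(tab, i, k, j, l), tolerance = 1e-12)
  }
  # below the separation cutoff the potential is 0
  expect_equal(edge_potential_at(tab, 3, 4, 1, 5), 0)
})

test_that("centring removes the mean over admissible pairs", {
  withr::with_seed(16, {
    nb <- 4
    p_bg <- rep(0.25, 4)
    p_al <- matrix(runif(16, 0.5, 1.5), 4); p_al <- (p_al + t(p_al)) / 2
    p_al <- p_al / sum(p_al)
    st <- toy_stats(p_al, p_bg)
    rand_pred <- function(n) {
      arr <- array(0, dim = c(n, n, nb))
      for (i in 1:n) for (k in 1:n) {
        v <- runif(nb, 0.2, 1); arr[i, k, ] <- v / sum(v)
      }
      arr
    }
    tab <- edge_table(rand_pred(7), rand_pred(7), st, min_separation = 3,
                      center = TRUE)
  })
  vals <- c()
  for (i in 1:7) for (k in 1:7) for (j in 1:7) for (l in 1:7) {
    if (abs(i - k) >= 3 && abs(j - l) >= 3)
      vals <- c(vals, edge_potential_at(tab, i, k, j, l))
  }
  expect_lt(abs(mean(vals)), 1e-10)
})

test_that("MI shortlist restricts scored edges to the strongest", {
  withr::with_seed(18, {
    nb <- 3
    st <- toy_stats(matrix(1 / 9, 3, 3) + diag(3) * 0.05, rep(1 / 3, 3))
    st$p_aligned <- st$p_aligned / sum(st$p_aligned)
    arr <- array(1 / 3, dim = c(8, 8, 3))
    mi <- matrix(runif(64), 8); mi <- (mi + t(mi)) / 2; diag(mi) <- 0
  })
  tab <- edge_table(arr, arr, st, min_separation = 2, shortlist_q = 3,
                    mi_T = mi, mi_S = mi)
  expect_equal(sum(tab$maskT[upper.tri(tab$maskT)]), 3)
})
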