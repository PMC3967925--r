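# Independent oracles: brute-force path enumeration and scoring for the
# three-state alignment lattice, naive matrix multiplication, and direct
# joint-count mutual information.  These deliberately share no code with the
# package internals they check.

# All monotone three-state paths from (0,0) to (nT,nS); direct I_T <-> I_S
# toggling disallowed.  Each path is a matrix of (i, j, state) rows with
# state 1 = M, 2 = I_T, 3 = I_S.
enumerate_paths <- function(nT, nS) {
  out <- list()
  recurse <- function(i, j, prev, rows) {
    if (i == nT && j == nS) {
      out[[length(out) + 1]] <<- do.call(rbind, rows)
      return(invisible(NULL))
    }
    if (i < nT && j < nS)
      recurse(i + 1, j + 1, 1L, c(rows, list(c(i + 1, j + 1, 1L))))
    if (i < nT && prev != 3L)
      recurse(i + 1, j, 2L, c(rows, list(c(i + 1, j, 2L))))
    if (j < nS && prev != 2L)
      recurse(i, j + 1, 3L, c(rows, list(c(i, j + 1, 3L))))
  }
  recurse(0L, 0L, 0L, list())
  out
}

# path score under pair score matrices (sM nT x nS, sIT nT x (nS+1),
# sIS (nT+1) x nS, trans 3x3), written as a plain loop
oracle_path_score <- function(path, scores) {
  total <- 0
  prev <- 0L
  for (r in seq_len(nrow(path))) {
    i <- path[r, 1]; j <- path[r, 2]; u <- path[r, 3]
    total <- total + if (u == 1L) scores$sM[i, j] else
      if (u == 2L) scores$sIT[i, j + 1] else scores$sIS[i + 1, j]
    if (prev != 0L) total <- total + scores$trans[prev, u]
    prev <- u
  }
  total
}

# exhaustive P1 optimum: max over all paths of node score + (1/L_path) x
# sum over unordered M-cell pairs of the table potential
oracle_p1_optimum <- function(scores, tab, paths = NULL) {
  nT <- nrow(scores$sM); nS <- ncol(scores$sM)
  if (is.null(paths)) paths <- enumerate_paths(nT, nS)
  best <- -Inf
  for (p in paths) {
    v <- oracle_path_score(p, scores)
    m <- p[p[, 3] == 1L, , drop = FALSE]
    if (nrow(m) >= 2) {
      es <- 0
      for (a in seq_len(nrow(m) - 1)) {
        for (b in (a + 1):nrow(m)) {
          es <- es + edge_potential_at(tab, m[a, 1], m[b, 1],
                                       m[a, 2], m[b, 2])
        }
      }
      v <- v + es / nrow(p)
    }
    if (v > best) best <- v
  }
  best
}

# log of the explicit sum over all alignment paths of exp(score)
oracle_logz <- function(scores) {
  paths <- enumerate_paths(nrow(scores$sM), ncol(scores$sM))
  vals <- vapply(paths, oracle_path_score, numeric(1), scores = scores)
  m <- max(vals)
  m + log(sum(exp(vals - m)))
}

# naive cubic-time matrix product
naive_matmul <- function(A, B) {
  n <- nrow(A); m <- ncol(B); p <- ncol(A)
  out <- matrix(0, n, m)
  for (i in seq_len(n))
    for (j in seq_len(m))
      for (k in seq_len(p)) out[i, j] <- out[i, j] + A[i, k] * B[k, j]
  out
}

# mutual information of two character columns by direct joint counting
# (21-letter alphabet, pseudocount spread uniformly over the joint)
oracle_mi_pair <- function(col_a, col_b, pc = 0) {
  alphabet <- c(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]], "-")
  n <- length(col_a)
  joint <- matrix(0, 21, 21, dimnames = list(alphabet, alphabet))
  for (s in seq_len(n)) joint[col_a[s], col_b[s]] <- joint[col_a[s], col_b[s]] + 1
  P <- (joint + pc / 441) / (n + pc)
  pa <- rowSums(P); pb <- colSums(P)
  total <- 0
  for (a in 1:21) {
    for (b in 1:21) {
      if (P[a, b] > 0)
        total <- total + P[a, b] * log(P[a, b] / (pa[a] * pb[b]))
    }
  }
  unname(total)
}

# random pair-score list for a given size (finite, fixed gap model)
random_scores <- function(nT, nS, sd = 1.5, gap_open = -1, gap_extend = -0.4) {
  trans <- matrix(0, 3, 3)
  trans[1, 2] <- trans[1, 3] <- gap_open
  trans[2, 2] <- trans[3, 3] <- gap_extend
  trans[2, 3] <- trans[3, 2] <- -Inf
  list(sM = matrix(rnorm(nT * nS, 0, sd), nT, nS),
       sIT = matrix(rnorm(nT * (nS + 1), 0, sd / 3), nT, nS + 1),
       sIS = matrix(rnorm((nT + 1) * nS, 0, sd / 3), nT + 1, nS),
       trans = trans)
}

# random edge-potential table with dense potentials for small instances
random_edge_table <- function(nT, nS, nbins = 3, min_separation = 1,
                              scale = 1) {
  p_bg <- rep(1 / nbins, nbins)
  p_al <- matrix(runif(nbins^2, 0.5, 1.5), nbins, nbins)
  p_al <- (p_al + t(p_al)) / 2
  p_al <- p_al / sum(p_al)
  stats <- structure(list(bins = structure(list(edges = seq_len(nbins - 1),
                                                nbins = nbins),
                                           class = "distance_bins"),
                          p_background = p_bg, p_aligned = p_al,
                          min_separation = min_separation, alpha = 1),
                     class = "distance_stats")
  rand_pred <- function(n) {
    arr <- array(runif(n * n * nbins, 0.2, 1), dim = c(n, n, nbins))
    for (i in seq_len(n)) {
      for (k in seq_len(n)) {
        v <- arr[i, k, ] * scale
        v <- v / sum(v)
        arr[i, k, ] <- v
        arr[k, i, ] <- v
      }
    }
    arr
  }
  edge_table(rand_pred(nT), rand_pred(nS), stats,
             min_separation = min_separation, center = FALSE)
}

# small deterministic MSA fixtures
tiny_msa <- function(seqs) new_msa(seqs)

expect_prob_rows <- function(m, tol = 1e-9) {
  expect_true(all(abs(rowSums(m) - 1) < tol))
  expect_true(all(m >= 0))
}
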