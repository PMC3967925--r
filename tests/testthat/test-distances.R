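test_that("bin_of implements the printed interval list, left-closed", {
  bins <- distance_bins()
  expect_equal(bins$nbins, 13)
  expect_equal(bin_of(3.2, bins), 1)
  expect_equal(bin_of(4.0, bins), 2) # boundary: [4, 5)
  expect_equal(bin_of(4.999, bins), 2)
  expect_equal(bin_of(14.5, bins), 12)
  expect_equal(bin_of(20, bins), 13)
  expect_error(bin_of(-1, bins), "contract")
  # total on a grid and consistent with the enumeration
  d <- seq(0, 30, by = 0.25)
  expect_true(all(bin_of(d, bins) %in% 1:13))
  expect_true(all(diff(bin_of(d, bins)) >= 0))
})

test_that("count_background histograms match a direct loop-count oracle", {
  bins <- distance_bins()
  # single 2-residue structure at 7.3 A: all mass in bin [7,8) pre-smoothing
  s1 <- rbind(c(0, 0, 0), c(7.3, 0, 0))
  cb <- count_background(list(s1), bins, min_separation = 1, alpha = 0)
  expect_equal(which(cb$counts_background > 0), bin_of(7.3, bins))
  # smoothing on empty counts -> uniform
  cb0 <- count_background(list(rbind(c(0, 0, 0), c(1, 0, 0))), bins,
                          min_separation = 5, alpha = 1)
  expect_equal(cb0$p_background, rep(1 / 13, 13))

  withr::with_seed(19, chain <- apply(matrix(rnorm(90), 30, 3), 2, cumsum) * 2)
  cb2 <- count_background(list(chain), bins, min_separation = 6, alpha = 1)
  oracle <- numeric(13)
  D <- as.matrix(dist(chain))
  for (i in 1:29) for (k in (i + 1):30) if (k - i >= 6) {
    b <- bin_of(D[i, k], bins)
    oracle[b] <- oracle[b] + 1
  }
  expect_equal(cb2$counts_background, oracle)
  expect_equal(sum(cb2$p_background), 1, tolerance = 1e-9)
  expect_true(all(cb2$p_background > 0))
  # duplicating a structure counts twice
  cb3 <- count_background(list(chain, chain), bins, 6, alpha = 1)
  expect_equal(cb3$counts_background, 2 * oracle)
})

test_that("count_aligned counts cells symmetrically and validates indices", {
  bins <- distance_bins()
  chain <- cbind(seq(0, 3.8 * 19, by = 3.8), 0, 0)[1:20, ]
  # identical structures aligned to themselves: mass only on diagonal cells
  ca <- count_aligned(list(list(structure_T = chain, structure_S = chain,
                                pairs = cbind(1:20, 1:20))), bins,
                      min_separation = 6, alpha = 0)
  expect_true(all(ca$counts_aligned[upper.tri(ca$counts_aligned)] == 0))
  expect_true(sum(diag(ca$counts_aligned)) > 0)

  # one aligned pair with dT = 4.5, dS = 9.5: cells (2, 7) and (7, 2)
  sT <- rbind(c(0, 0, 0), matrix(1e3, 5, 3), c(4.5, 0, 0))
  sS <- rbind(c(0, 0, 0), matrix(-1e3, 5, 3), c(9.5, 0, 0))
  ca2 <- count_aligned(list(list(structure_T = sT, structure_S = sS,
                                 pairs = cbind(c(1, 7), c(1, 7)))), bins,
                       min_separation = 6, alpha = 0)
  expect_equal(ca2$counts_aligned[2, 7], 1)
  expect_equal(ca2$counts_aligned[7, 2], 1)
  expect_equal(sum(ca2$counts_aligned), 2)

  expect_error(count_aligned(list(list(structure_T = sT, structure_S = sS,
                                       pairs = cbind(8, 1))), bins),
               "data error")
})

test_that("distance stats TSV round trip preserves the distributions", {
  bins <- distance_bins()
  withr::with_seed(9, chain <- apply(matrix(rnorm(120), 40, 3), 2, cumsum) * 2)
  stats <- distance_stats(
    count_background(list(chain), bins),
    count_aligned(list(list(structure_T = chain,
                            structure_S = chain + rnorm(120, 0, 0.5),
                            pairs = cbind(1:40, 1:40))), bins))
  f <- tempfile(fileext = ".tsv")
  write_distance_stats(stats, f)
  back <- read_distance_stats(f)
  expect_equal(back$p_background, stats$p_background, tolerance = 1e-12)
  expect_equal(back$p_aligned, stats$p_aligned, tolerance = 1e-12)
  expect_equal(back$bins$edges, stats$bins$edges)
})

test_that("PDB write / read round trip recovers coordinates", {
  withr::with_seed(2, xyz <- apply(matrix(rnorm(45), 15, 3), 2, cumsum) * 2)
  f <- tempfile(fileext = ".pdb")
  write_pdb(xyz, f)
  back <- read_pdb(f)
  expect_equal(back, unname(round(xyz, 3)), tolerance = 1e-9)
})

test_that("untrained predictor is uniform; hand-set predictor matches softmax arithmetic", {
  bins <- distance_bins()
  pred <- new_distance_predictor(w = 1, n_mi = 2, hidden = 2, bins = bins)
  ctx <- matrix(0.1, 3, 21)
  p <- predict_edge_distribution(pred, ctx, ctx, c(0.5, 0.2), separation = 7)
  expect_equal(p, rep(1 / 13, 13), tolerance = 1e-12)

  # one hidden unit, hand arithmetic
  pred2 <- new_distance_predictor(w = 1, n_mi = 1, hidden = 1, bins = bins)
  pred2$W1 <- matrix(0.01, 1, pred2$d)
  pred2$W2 <- matrix(seq(-0.6, 0.6, length.out = 13), 13, 1)
  pred2$b2 <- rep(0, 13)
  x <- c(rep(0.1, 63), rep(0.1, 63), 0.3, log(7))
  h <- tanh(sum(0.01 * x))
  expected <- exp(pred2$W2[, 1] * h)
  expected <- expected / sum(expected)
  expect_equal(predict_edge_distribution(pred2, ctx, ctx, 0.3, separation = 7),
               expected, tolerance = 1e-12)
})

test_that("trained predictor ranks planted contacts as closer than background pairs", {
  bench <- generate_benchmark(4, params = list(n_seqs = 48, n_parent = 45),
                              seed = 61)
  bench$pairs <- build_benchmark_mrfs(bench$pairs, w = 2, max_power = 4)
  fams <- unlist(lapply(bench$pairs, function(sp) list(
    list(mrf = sp$mrf_T, coords = sp$coords_T),
    list(mrf = sp$mrf_S, coords = sp$coords_S))), recursive = FALSE)
  bins <- distance_bins()
  ex <- sample_edge_examples(fams, bins, n_per_family = 250, seed = 3)
  pred <- train_distance_predictor(ex$X, ex$y, w = 2, n_mi = 4, hidden = 8,
                                   epochs = 300, seed = 5)
  trace <- attr(pred, "loss_trace")
  expect_lt(trace[length(trace)], trace[1])

  sp <- generate_pair(n_parent = 45, n_seqs = 48, seed = 71)
  mT <- build_mrf(sp$msa_T, w = 2, max_power = 4)
  arr <- family_edge_distributions(pred, mT)
  expect_equal(apply(arr, c(1, 2), sum),
               matrix(1, mT$ncol, mT$ncol), tolerance = 1e-9)
  mean_bin <- function(p) sum(p * seq_len(13))
  cp <- sp$contacts_T
  expect_gte(nrow(cp), 3)
  mb_contact <- mean(apply(cp, 1, function(p) mean_bin(arr[p[1], p[2], ])))
  far <- mrf_edges(mT)
  far <- far[!(paste(far[, 1], far[, 2]) %in% paste(cp[, 1], cp[, 2])), ]
  mb_far <- mean(apply(far, 1, function(p) mean_bin(arr[p[1], p[2], ])))
  expect_lt(mb_contact, mb_far)
})

test_that("structure-informed stand-in concentrates on the true bin", {
  bins <- distance_bins()
  chain <- cbind(seq(0, 3.8 * 9, by = 3.8), 0, 0)[1:10, ]
  arr <- structure_edge_distributions(chain, bins, smear = 0, floor = 0)
  D <- as.matrix(dist(chain))
  expect_equal(which.max(arr[1, 8, ]), bin_of(D[1, 8], bins))
  expect_equal(sum(arr[1, 8, ]), 1, tolerance = 1e-9)
})
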