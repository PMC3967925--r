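# End-to-end recovery benchmark on synthetic families: the full pipeline
# (generate families, distance statistics, predictor training, ablation
# alignment runs) packaged so that tests and the acceptance report run the
# identical, reproducible experiment.

#' Run the planted-alignment recovery benchmark
#'
#' Generates a training benchmark (distance statistics and distance-predictor
#' training: MI-enabled and MI-zeroed variants) and an evaluation benchmark,
#' then runs the node-only / node+edge / node+edge+MI ablation over the
#' evaluation pairs with the ADMM aligner at the given `rho`.  The node
#' potential is the untrained profile-similarity scorer (the package
#' default).
#'
#' The evaluation benchmark's master seed defaults to 42 and the coupling
#' strength to 0.6 (the stated benchmark conditions); `seed` drives every
#' remaining source of randomness (training benchmark, predictor
#' initialisation, example sampling).
#'
#' @param master_seed Master seed of the evaluation benchmark (default 42).
#' @param seed Seed for training-side randomness (default 1).
#' @param n_eval Number of evaluation pairs (default 100).
#' @param n_train Number of training pairs (default 24).
#' @param params Generator parameter overrides for both benchmarks.
#' @param rho,max_iter ADMM controls.
#' @param epochs Adam epochs for predictor training (default 800).
#' @return List: `ablation` (the [run_ablation()] table, with per-pair
#'   details in its attribute), `iterations` and `converged` (per evaluation
#'   pair, from the full node+edge+MI configuration), `stats`,
#'   `manifest`.
#' @export
run_recovery_benchmark <- function(master_seed = 42, seed = 1, n_eval = 100,
                                   n_train = 24, params = list(),
                                   rho = 0.5, max_iter = 50, epochs = 800) {
  train_seed <- (seed * 7919L + 1L) %% 2000000000L
  train <- generate_benchmark(n_train, params = params, seed = train_seed)
  train$pairs <- build_benchmark_mrfs(train$pairs)
  bins <- distance_bins()
  fams <- unlist(lapply(train$pairs, function(sp) list(
    list(mrf = sp$mrf_T, coords = sp$coords_T),
    list(mrf = sp$mrf_S, coords = sp$coords_S))), recursive = FALSE)
  stats <- distance_stats(
    count_background(lapply(fams, `[[`, "coords"), bins),
    count_aligned(lapply(train$pairs, function(sp)
      list(structure_T = sp$coords_T, structure_S = sp$coords_S,
           pairs = sp$true_alignment)), bins))
  ex <- sample_edge_examples(fams, bins, n_per_family = 500, seed = seed)
  pred_mi <- train_distance_predictor(ex$X, ex$y, epochs = epochs,
                                      hidden = 24, l2 = 3e-4, seed = seed)
  pred_nomi <- train_distance_predictor(ex$X, ex$y, use_mi = FALSE,
                                        epochs = epochs, hidden = 24,
                                        l2 = 3e-4, seed = seed)

  eval_bench <- generate_benchmark(n_eval, params = params,
                                   seed = master_seed)
  eval_bench$pairs <- build_benchmark_mrfs(eval_bench$pairs)
  scorer <- new_profile_scorer()
  abl <- run_ablation(eval_bench$pairs, scorer, stats, pred_mi, pred_nomi,
                      rho = rho, max_iter = max_iter)
  pp <- attr(abl, "per_pair")
  list(ablation = abl,
       iterations = pp$iterations[, "node_edge_mi"],
       converged = pp$converged[, "node_edge_mi"] > 0,
       stats = stats, manifest = eval_bench$manifest,
       predictor_mi = pred_mi, predictor_nomi = pred_nomi)
}
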