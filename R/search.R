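# Homology search driver: a fast Viterbi prefilter over the whole library
# (node potential only), then full ADMM realignment and reranking of the
# top-K candidates.

#' Search a query MRF against a library
#'
#' Every library entry is first scored with the Viterbi alignment objective
#' (no edge potential).  The `top_k` best candidates are realigned with the
#' full ADMM aligner and reranked by their P1 objective; the remaining
#' entries follow in prefilter order.  Ranking uses the raw best alignment
#' score (optionally normalised by the geometric mean family length); no
#' E-value calibration is attempted.  Self-hits are retained.
#'
#' @param query An `mrf_model`.
#' @param library Named list of `mrf_model`s.
#' @param scorer A node scorer.
#' @param predictor A `distance_predictor` (needed when `use_edge`).
#' @param stats A `distance_stats` (needed when `use_edge`).
#' @param top_k Number of candidates to rerank (default 200).
#' @param use_edge Use the edge potential in the rerank stage (default TRUE).
#'   With `use_edge = FALSE` the final ranking equals the prefilter ranking.
#' @param normalize Divide scores by `sqrt(nT * nS)` (default FALSE).
#' @param rho,max_iter ADMM controls.
#' @return A data.frame of hits: `rank`, `target`, `prefilter_score`,
#'   `prefilter_rank`, `final_score`, `aligned_cols`, `iterations`,
#'   `converged`, sorted by final ranking.
#' @export
mrf_search <- function(query, library, scorer, predictor = NULL,
                       stats = NULL, top_k = 200, use_edge = TRUE,
                       normalize = FALSE, rho = 0.5, max_iter = 50) {
  if (length(library) == 0) stop("empty library")
  if (top_k < 1) stop("parameter error: top_k must be >= 1")
  ids <- names(library)
  if (is.null(ids)) ids <- paste0("target", seq_along(library))

  norm_of <- function(target) if (normalize)
    sqrt(query$ncol * target$ncol) else 1

  pre <- vapply(seq_along(library), function(t) {
    viterbi_align(pair_scores(scorer, query, library[[t]]))$score /
      norm_of(library[[t]])
  }, numeric(1))
  ord <- order(pre, decreasing = TRUE)
  prefilter_rank <- match(seq_along(library), ord)

  k <- min(top_k, length(library))
  rerank_idx <- ord[seq_len(k)]

  final <- pre
  aligned_cols <- integer(length(library))
  iterations <- integer(length(library))
  conv <- rep(NA, length(library))

  if (use_edge) {
    stopifnot(!is.null(predictor), !is.null(stats))
    predQ <- family_edge_distributions(predictor, query)
    for (t in rerank_idx) {
      target <- library[[t]]
      predT <- family_edge_distributions(predictor, target)
      tab <- edge_table(predQ, predT, stats,
                        min_separation = max(query$min_separation,
                                             target$min_separation))
      res <- admm_align(query, target, scorer, tab, rho = rho,
                        max_iter = max_iter)
      final[t] <- res$objective / norm_of(target)
      aligned_cols[t] <- nrow(res$alignment$aligned_pairs)
      iterations[t] <- res$iterations
      conv[t] <- res$converged
    }
    # reranked block first (by final score), then the rest in prefilter order
    rest <- ord[-seq_len(k)]
    order_final <- c(rerank_idx[order(final[rerank_idx], decreasing = TRUE)],
                     rest)
  } else {
    order_final <- ord
  }

  out <- data.frame(rank = seq_along(library),
                    target = ids[order_final],
                    prefilter_score = pre[order_final],
                    prefilter_rank = prefilter_rank[order_final],
                    final_score = final[order_final],
                    aligned_cols = aligned_cols[order_final],
                    iterations = iterations[order_final],
                    converged = conv[order_final])
  rownames(out) <- NULL
  out
}
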