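# MRF family model: node marginals plus pairwise interaction features.
# Interaction strength is quantified by the mutual-information matrix and its
# matrix powers (MI, MI^2, ..., MI^K); explicit pairwise preference functions
# are not fitted -- the MI power series stands in for them.

#' Mutual information matrix of MSA columns
#'
#' MI over the 21-letter alphabet (20 amino acids + gap).  The joint
#' distribution of a column pair uses the same pseudocount weight as
#' [column_marginals()], spread uniformly over the 21 x 21 joint; the
#' marginals entering MI are the joint's own marginals, so MI is nonnegative
#' up to floating point error.  The diagonal is set to 0 by convention.
#'
#' @param msa An `msa` object.
#' @param weights Per-sequence weights (default: all 1).
#' @param pseudocount_weight Pseudocount weight for the joint (default 1).
#' @return Symmetric `ncol` x `ncol` matrix.
#' @export
mutual_information <- function(msa, weights = NULL, pseudocount_weight = 1) {
  n <- msa$ncol
  if (is.null(weights)) weights <- rep(1, msa$nseq)
  stopifnot(length(weights) == msa$nseq, all(weights >= 0))
  enc <- encode_msa(msa)
  W <- sum(weights)
  J <- crossprod(enc * weights, enc) # (21n) x (21n), block (i,k) = joint counts
  P <- (J + pseudocount_weight / N_ALPHA^2) / (W + pseudocount_weight)
  T1 <- P * log(pmax(P, .Machine$double.xmin))
  T1[P == 0] <- 0
  U <- matrix(0, N_ALPHA * n, n)
  U[cbind(seq_len(N_ALPHA * n), rep(seq_len(n), each = N_ALPHA))] <- 1
  Hjoint <- -crossprod(U, T1 %*% U) # block sums: n x n
  # column entropies from the joint's own marginals
  counts <- matrix(crossprod(enc, weights), n, N_ALPHA, byrow = TRUE)
  pmarg <- (counts + pseudocount_weight / N_ALPHA) / (W + pseudocount_weight)
  Hcol <- -rowSums(ifelse(pmarg > 0, pmarg * log(pmax(pmarg, .Machine$double.xmin)), 0))
  mi <- outer(Hcol, Hcol, "+") - Hjoint
  mi <- (mi + t(mi)) / 2
  diag(mi) <- 0
  mi
}

#' Matrix power series of an MI matrix
#'
#' @param mi Square matrix.
#' @param max_power Highest power K (default 11).
#' @return List `[MI^1, MI^2, ..., MI^K]`.
#' @export
mi_power_series <- function(mi, max_power = 11) {
  if (!is.numeric(max_power) || max_power < 1)
    stop("parameter error: max_power must be >= 1")
  stopifnot(is.matrix(mi), nrow(mi) == ncol(mi))
  out <- vector("list", max_power)
  out[[1]] <- mi
  if (max_power > 1)
    for (p in 2:max_power) out[[p]] <- out[[p - 1]] %*% mi
  out
}

#' Build an MRF model of a protein family
#'
#' Nodes carry the column marginal distributions; edges (all column pairs
#' with sequence separation at least `min_separation`) carry the MI power
#' series as interaction-strength features.
#'
#' @param msa An `msa` object.
#' @param w Half-width of the sequence profile context window (the context of
#'   node i spans columns i-w .. i+w; default 5).
#' @param max_power Number of MI powers K (default 11).
#' @param min_separation Minimum |i - k| for an edge (default 6; very
#'   short-range correlation is ignored as uninformative).
#' @param pc Pseudocount weight for marginals and MI (default 1).
#' @param seq_weighting Sequence weighting scheme (see [column_marginals()]).
#' @return An object of class `mrf_model`.
#' @export
build_mrf <- function(msa, w = 5, max_power = 11, min_separation = 6, pc = 1,
                      seq_weighting = c("henikoff", "none")) {
  seq_weighting <- match.arg(seq_weighting)
  marg <- column_marginals(msa, pseudocount_weight = pc,
                           seq_weighting = seq_weighting)
  mi <- mutual_information(msa, weights = marg$weights,
                           pseudocount_weight = pc)
  structure(list(marginals = marg, mi_powers = mi_power_series(mi, max_power),
                 ncol = msa$ncol, w = w, min_separation = min_separation,
                 pc = pc, neff = marg$neff, format_version = 1L),
            class = "mrf_model")
}

#' @export
print.mrf_model <- function(x, ...) {
  cat("MRF model:", x$ncol, "nodes, K =", length(x$mi_powers),
      "MI powers, w =", x$w, ", min_separation =", x$min_separation, "\n")
  invisible(x)
}

#' Sequence profile context of a node
#'
#' The `(2w+1) x 21` matrix of marginal rows for columns `i-w .. i+w`; rows
#' whose column index falls outside the family are all zero.
#'
#' @param model An `mrf_model` (or a `column_marginals` object).
#' @param i Column index (1-based).
#' @param w Context half-width (defaults to the model's `w`).
#' @return A `(2w+1) x 21` matrix.
#' @export
profile_context <- function(model, i, w = NULL) {
  probs <- if (inherits(model, "mrf_model")) model$marginals$probs else
    model$probs
  if (is.null(w)) w <- if (inherits(model, "mrf_model")) model$w else
    stop("w must be given")
  n <- nrow(probs)
  stopifnot(i >= 1, i <= n)
  ctx <- matrix(0, 2 * w + 1, N_ALPHA, dimnames = list(NULL, ALPHABET))
  src <- (i - w):(i + w)
  ok <- src >= 1 & src <= n
  ctx[ok, ] <- probs[src[ok], , drop = FALSE]
  ctx
}

# n x ((2w+1)*21) matrix of flattened contexts, one row per node.
#' @keywords internal
#' @noRd
context_matrix <- function(model, w = NULL) {
  n <- model$ncol
  if (is.null(w)) w <- model$w
  probs <- model$marginals$probs
  d <- (2 * w + 1) * N_ALPHA
  out <- matrix(0, n, d)
  for (o in -w:w) {
    src <- seq_len(n) + o
    ok <- src >= 1 & src <= n
    cols <- (o + w) * N_ALPHA + seq_len(N_ALPHA)
    out[ok, cols] <- probs[src[ok], , drop = FALSE]
  }
  out
}

#' Edges of an MRF model
#'
#' @param model An `mrf_model`.
#' @return Two-column matrix of node pairs (i < k) with
#'   `|i - k| >= min_separation`.
#' @export
mrf_edges <- function(model) {
  n <- model$ncol
  s <- model$min_separation
  idx <- which(outer(seq_len(n), seq_len(n),
                     function(i, k) k - i >= s), arr.ind = TRUE)
  colnames(idx) <- c("i", "k")
  idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
}

# K-vector of MI power features for node pair (i, k).
#' @keywords internal
#' @noRd
mi_features <- function(model, i, k) {
  vapply(model$mi_powers, function(m) m[i, k], numeric(1))
}

#' Save / load an MRF model
#'
#' Models are persisted as RDS with a format version tag.
#' @param model An `mrf_model`.
#' @param path File path.
#' @return `path` (write) or the model (read).
#' @export
write_mrf <- function(model, path) {
  stopifnot(inherits(model, "mrf_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname write_mrf
#' @export
read_mrf <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "mrf_model") || is.null(model$format_version))
    stop("not an mrfaln model file: ", path)
  model
}
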