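# Edge alignment potential: the expected log-odds, under the two edges'
# predicted distance distributions, of their binned distances co-occurring
# in reference alignments versus background.

#' Log-ratio kernel of distance statistics
#'
#' `kernel[d1, d2] = log(p_aligned[d1, d2] / (p_background[d1] * p_background[d2]))`.
#' Smoothing guarantees finiteness.
#'
#' @param stats A `distance_stats` object (strictly positive tables).
#' @return nbins x nbins matrix.
#' @export
edge_kernel <- function(stats) {
  if (any(stats$p_background <= 0) || any(stats$p_aligned <= 0))
    stop("contract error: distance statistics must be strictly positive")
  log(stats$p_aligned / outer(stats$p_background, stats$p_background))
}

#' Edge alignment potential of two edges
#'
#' The expectation of the log-ratio kernel under the two edges' predicted
#' distance distributions:
#' `sum_{d1,d2} P_T(d1) * P_S(d2) * kernel[d1, d2]`.  Bilinear in the two
#' distributions.
#'
#' @param PT_ik,PS_jl Normalised distance-bin probability vectors.
#' @param kernel Matrix from [edge_kernel()].
#' @return A single number.
#' @export
edge_potential <- function(PT_ik, PS_jl, kernel) {
  if (length(PT_ik) != nrow(kernel) || length(PS_jl) != ncol(kernel))
    stop("contract error: shape mismatch")
  as.numeric(PT_ik %*% kernel %*% PS_jl)
}

#' Precomputed edge-potential table for a family pair
#'
#' Stores, for family T, the kernel-transformed distributions
#' `XT[i,k,] = PT[i,k,] %*% kernel` so that the potential of any edge pair is
#' the inner product `XT[i,k,] . PS[j,l,]`.  Edge pairs are only scored when
#' both `|i-k|` and `|j-l|` are at least `min_separation`.
#'
#' An optional shortlist keeps only the `shortlist_q` strongest-MI edges per
#' family (cost bound); off by default.
#'
#' @param predT,predS Arrays from [family_edge_distributions()] (or any
#'   external predictor's per-pair distributions).
#' @param stats A `distance_stats` object.
#' @param min_separation Minimum separation on both sides (default 6).
#' @param shortlist_q If not `NULL`, keep only the `shortlist_q` top edges
#'   per family, ranked by `mi_T` / `mi_S`.
#' @param mi_T,mi_S MI matrices used for the shortlist ranking.
#' @param center If `TRUE` (default), subtract the mean potential over all
#'   admissible edge pairs (computed exactly via bilinearity), the edge
#'   analogue of the node potential's sampled background offset.  Without
#'   it, imperfect predictors give every edge pair a shared negative bias,
#'   and because pairs below the separation cutoff contribute zero instead,
#'   misaligned match cells (which have more masked pairs) are artificially
#'   favoured.
#' @return Object of class `edge_table`.
#' @export
edge_table <- function(predT, predS, stats, min_separation = 6,
                       shortlist_q = NULL, mi_T = NULL, mi_S = NULL,
                       center = TRUE) {
  K <- edge_kernel(stats)
  nT <- dim(predT)[1]; nS <- dim(predS)[1]; nb <- dim(predT)[3]
  stopifnot(dim(predS)[3] == nb, nb == stats$bins$nbins)
  XT <- array(matrix(predT, nT * nT, nb) %*% K, dim = c(nT, nT, nb))
  maskT <- abs(outer(seq_len(nT), seq_len(nT), "-")) >= min_separation
  maskS <- abs(outer(seq_len(nS), seq_len(nS), "-")) >= min_separation
  shortlist_mask <- function(mi, q, mask) {
    keep <- matrix(FALSE, nrow(mi), ncol(mi))
    ut <- which(upper.tri(mi) & mask, arr.ind = TRUE)
    str <- mi[ut]
    top <- ut[order(str, decreasing = TRUE)[seq_len(min(q, nrow(ut)))], ,
              drop = FALSE]
    keep[top] <- TRUE
    keep | t(keep)
  }
  if (!is.null(shortlist_q)) {
    if (!is.null(mi_T)) maskT <- maskT & shortlist_mask(mi_T, shortlist_q, maskT)
    if (!is.null(mi_S)) maskS <- maskS & shortlist_mask(mi_S, shortlist_q, maskS)
  }
  offset <- 0
  if (center) {
    idxT <- which(maskT, arr.ind = TRUE)
    idxS <- which(maskS, arr.ind = TRUE)
    if (nrow(idxT) > 0 && nrow(idxS) > 0) {
      mT <- colMeans(matrix(predT[cbind(rep(idxT[, 1], nb), rep(idxT[, 2], nb),
                                        rep(seq_len(nb), each = nrow(idxT)))],
                            nrow(idxT), nb))
      mS <- colMeans(matrix(predS[cbind(rep(idxS[, 1], nb), rep(idxS[, 2], nb),
                                        rep(seq_len(nb), each = nrow(idxS)))],
                            nrow(idxS), nb))
      offset <- as.numeric(mT %*% K %*% mS)
    }
  }
  structure(list(XT = XT, PS = predS, kernel = K, nbins = nb,
                 nT = nT, nS = nS, min_separation = min_separation,
                 maskT = maskT, maskS = maskS, offset = offset),
            class = "edge_table")
}

#' Potential of a specific edge pair from a table
#'
#' @param table An `edge_table`.
#' @param i,k Nodes of the T edge; @param j,l nodes of the S edge.
#' @return The (centred) potential, or 0 if either side is below the
#'   separation cutoff (or shortlisted out).
#' @export
edge_potential_at <- function(table, i, k, j, l) {
  if (!table$maskT[i, k] || !table$maskS[j, l]) return(0)
  sum(table$XT[i, k, ] * table$PS[j, l, ]) - table$offset
}

#' A zero edge-potential table (node-only alignment)
#'
#' @param nT,nS Family lengths.
#' @param nbins Number of distance bins.
#' @return An `edge_table` whose potentials are all zero.
#' @export
zero_edge_table <- function(nT, nS, nbins = 13) {
  structure(list(XT = array(0, dim = c(nT, nT, nbins)),
                 PS = array(0, dim = c(nS, nS, nbins)),
                 kernel = matrix(0, nbins, nbins), nbins = nbins,
                 nT = nT, nS = nS, min_separation = 1,
                 maskT = matrix(TRUE, nT, nT), maskS = matrix(TRUE, nS, nS),
                 offset = 0),
            class = "edge_table")
}
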