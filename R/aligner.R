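# MRF-MRF alignment.  The best alignment maximises the quadratic objective
#
#   P1(z) = sum_cells z * node_potential  +  (1/L) sum_{u<v M-cells} edge_potential
#
# (transition biases are part of the vertex term; L is the alignment length,
# which rescales the accumulated edge potential onto the node-potential
# scale).  P1 is solved approximately by ADMM: a copy y of the indicator
# vector z is introduced, the coupling z = y is enforced by multipliers
# lambda and a quadratic penalty rho, and the two resulting subproblems
# (SP1 in y, SP2 in z) are linear in their variable, hence solvable exactly
# by the classical three-state dynamic program.

#' Alignment path object
#'
#' @param triples Integer matrix with columns `i`, `j`, `state`
#'   (1 = M, 2 = I_T, 3 = I_S).
#' @param nT,nS Family lengths.
#' @param score Optional score annotation.
#' @return Object of class `alignment_path` with `triples`, `aligned_pairs`
#'   (the M-state (i, j) list) and `L` (number of triples).
#' @export
new_alignment_path <- function(triples, nT, nS, score = NA_real_) {
  validate_path(triples, nT, nS)
  m <- triples[triples[, 3] == 1L, c(1, 2), drop = FALSE]
  structure(list(triples = triples, aligned_pairs = m,
                 L = nrow(triples), nT = nT, nS = nS, score = score),
            class = "alignment_path")
}

#' @export
print.alignment_path <- function(x, ...) {
  cat("Alignment path: L =", x$L, ",", nrow(x$aligned_pairs),
      "matched pairs (", x$nT, "x", x$nS, ")\n")
  invisible(x)
}

#' Validate alignment path monotonicity
#'
#' A valid path starts at the (0,0) dummy, moves M (+1,+1), I_T (+1,0) or
#' I_S (0,+1), never toggles directly between I_T and I_S, and ends at
#' (nT, nS).
#'
#' @param triples Path triples matrix.
#' @param nT,nS Family lengths.
#' @return `TRUE` invisibly; stops with a contract error otherwise.
#' @export
validate_path <- function(triples, nT, nS) {
  ci <- 0L; cj <- 0L; prev <- 0L
  for (r in seq_len(nrow(triples))) {
    i <- triples[r, 1]; j <- triples[r, 2]; u <- triples[r, 3]
    ok <- switch(u,
                 i == ci + 1L && j == cj + 1L,           # M
                 i == ci + 1L && j == cj && prev != 3L,  # I_T
                 i == ci && j == cj + 1L && prev != 2L)  # I_S
    if (!isTRUE(ok))
      stop("contract error: invalid path step at row ", r)
    ci <- i; cj <- j; prev <- u
  }
  if (ci != nT || cj != nS)
    stop("contract error: path ends at (", ci, ",", cj, ") not (",
         nT, ",", nS, ")")
  invisible(TRUE)
}

# node + transition score of a full path under pair score matrices
#' @keywords internal
#' @noRd
path_node_score <- function(triples, scores) {
  s <- 0
  prev <- 0L
  for (r in seq_len(nrow(triples))) {
    i <- triples[r, 1]; j <- triples[r, 2]; u <- triples[r, 3]
    s <- s + switch(u, scores$sM[i, j], scores$sIT[i, j + 1],
                    scores$sIS[i + 1, j])
    if (prev != 0L) s <- s + scores$trans[prev, u]
    prev <- u
  }
  s
}

#' Viterbi alignment (node potential only)
#'
#' Maximum-score three-state alignment by dynamic programming, ignoring the
#' edge alignment potential.  Deterministic tie-break: prefer M over I_T
#' over I_S.
#'
#' @param node_scores Score matrices from [pair_scores()] (or any list with
#'   `sM`, `sIT`, `sIS`, `trans`).
#' @return An `alignment_path` with `score` set to the DP optimum.
#' @export
viterbi_align <- function(node_scores) {
  r <- .viterbi_dp(node_scores$sM, node_scores$sIT, node_scores$sIS,
                   node_scores$trans)
  new_alignment_path(r$path, nrow(node_scores$sM), ncol(node_scores$sM),
                     score = r$score)
}

# sum of edge potentials over unordered pairs of M-cells of a path
#' @keywords internal
#' @noRd
edge_pair_sum <- function(table, matches) {
  m <- nrow(matches)
  if (m < 2) return(0)
  cmb <- which(upper.tri(diag(m)), arr.ind = TRUE)
  ia <- matches[cmb[, 1], 1]; ja <- matches[cmb[, 1], 2]
  ib <- matches[cmb[, 2], 1]; jb <- matches[cmb[, 2], 2]
  ok <- table$maskT[cbind(ia, ib)] & table$maskS[cbind(ja, jb)]
  if (!any(ok)) return(0)
  ia <- ia[ok]; ja <- ja[ok]; ib <- ib[ok]; jb <- jb[ok]
  np <- length(ia); nb <- table$nbins
  bb <- rep(seq_len(nb), each = np)
  vT <- matrix(table$XT[cbind(rep(ia, nb), rep(ib, nb), bb)], np, nb)
  vS <- matrix(table$PS[cbind(rep(ja, nb), rep(jb, nb), bb)], np, nb)
  sum(vT * vS) - np * table$offset
}

#' The P1 alignment objective
#'
#' Vertex potentials (node scores plus transition biases) plus the
#' edge-potential sum over unordered pairs of match cells whose separation
#' on both sides is at least the table's cutoff, scaled by `1/L`.
#'
#' @param path An `alignment_path` (or triples matrix).
#' @param node_scores Score matrices from [pair_scores()].
#' @param edge_table An `edge_table`.
#' @param L Alignment length for the edge rescaling; default: the path's own
#'   length.
#' @return The objective value.
#' @export
objective_p1 <- function(path, node_scores, edge_table, L = NULL) {
  trip <- if (inherits(path, "alignment_path")) path$triples else path
  validate_path(trip, nrow(node_scores$sM), ncol(node_scores$sM))
  if (is.null(L)) L <- nrow(trip)
  stopifnot(L >= 1)
  matches <- trip[trip[, 3] == 1L, c(1, 2), drop = FALSE]
  path_node_score(trip, node_scores) +
    edge_pair_sum(edge_table, matches) / L
}

# (1/L)-scaled linear edge term: E[i, j] = sum over fixed matches (k, l) of
# the potential between T-edge (i, k) and S-edge (j, l), separation-masked.
#' @keywords internal
#' @noRd
edge_linear_term <- function(table, fixed_matches, L) {
  nT <- table$nT; nS <- table$nS
  E <- matrix(0, nT, nS)
  for (r in seq_len(nrow(fixed_matches))) {
    k <- fixed_matches[r, 1]; l <- fixed_matches[r, 2]
    Xk <- table$XT[, k, , drop = TRUE]
    if (is.null(dim(Xk))) Xk <- matrix(Xk, nT, table$nbins)
    Pl <- table$PS[, l, , drop = TRUE]
    if (is.null(dim(Pl))) Pl <- matrix(Pl, nS, table$nbins)
    C <- tcrossprod(Xk, Pl) - table$offset
    C[!table$maskT[, k], ] <- 0
    C[, !table$maskS[, l]] <- 0
    E <- E + C
  }
  E / L
}

#' Linearised per-cell scores for one ADMM subproblem
#'
#' With the complementary copy fixed, the subproblem objective is linear in
#' the free indicator: each cell's effective score is its node score, plus
#' (for match cells) the `1/L`-scaled sum of edge potentials to the fixed
#' active match cells, plus the multiplier `lambda` and the expanded
#' quadratic-penalty terms (`z^2 = z` for binaries):
#' `+ rho * fixed_cell - rho/2` per cell.
#'
#' @param fixed_assignment Indicator list (`M`, `IT`, `IS`) of the fixed
#'   copy, or a triples matrix.
#' @param lambda Multiplier list with the same shapes, already signed for
#'   the subproblem (`+lambda` in SP1, `-lambda` in SP2).
#' @param rho Penalty constant.
#' @param node_scores Score matrices from [pair_scores()].
#' @param edge_table An `edge_table`.
#' @param L Current alignment-length estimate.
#' @return A score list suitable for [viterbi_align()].
#' @export
linearized_dp_scores <- function(fixed_assignment, lambda, rho, node_scores,
                                 edge_table, L) {
  if (is.matrix(fixed_assignment))
    fixed_assignment <- path_indicators(fixed_assignment,
                                        nrow(node_scores$sM),
                                        ncol(node_scores$sM))
  fm <- which(fixed_assignment$M == 1, arr.ind = TRUE)
  E <- edge_linear_term(edge_table, fm, L)
  list(sM = node_scores$sM + E + lambda$M + rho * fixed_assignment$M - rho / 2,
       sIT = node_scores$sIT + lambda$IT + rho * fixed_assignment$IT - rho / 2,
       sIS = node_scores$sIS + lambda$IS + rho * fixed_assignment$IS - rho / 2,
       trans = node_scores$trans)
}

#' @keywords internal
#' @noRd
zero_indicators <- function(nT, nS) {
  list(M = matrix(0, nT, nS), IT = matrix(0, nT, nS + 1),
       IS = matrix(0, nT + 1, nS))
}

#' Align two MRFs by ADMM
#'
#' Initialises with the Viterbi alignment (no edge potential), then
#' alternates: solve SP1 for `y` by dynamic programming with `z` fixed,
#' solve SP2 for `z` with `y` fixed, stop when `z = y`; otherwise update the
#' alignment length `L` to the length of the most recent (SP2) alignment and
#' the multipliers by the subgradient step `lambda <- lambda + rho (z - y)`,
#' and iterate.  Returns the feasible alignment with the best P1 objective
#' seen across iterations (including the initialisation), so behaviour is
#' anytime: on non-convergence the best feasible alignment found is still
#' returned.
#'
#' The recorded per-iteration Lagrangian is scaled to the P1 scale (the
#' symmetrised objective double-counts node terms); at convergence it equals
#' the P1 value of the converged alignment.
#'
#' @param mrfT,mrfS `mrf_model` objects (alternatively pass precomputed
#'   `scores`).
#' @param scorer A node scorer (ignored when `scores` given).
#' @param edge_tab An `edge_table` for the pair.
#' @param rho Penalty constant (default 0.5).
#' @param max_iter Maximum ADMM iterations (default 50).
#' @param scores Optional precomputed [pair_scores()] result.
#' @return Object of class `admm_result`: `alignment` (best feasible path),
#'   `objective` (its P1 value), `iterations`, `converged`, and `trace`
#'   (per-iteration objectives, Lagrangian and `||z - y||_1`).
#' @export
admm_align <- function(mrfT = NULL, mrfS = NULL, scorer = NULL, edge_tab,
                       rho = 0.5, max_iter = 50, scores = NULL) {
  if (is.null(scores)) scores <- pair_scores(scorer, mrfT, mrfS)
  nT <- nrow(scores$sM); nS <- ncol(scores$sM)
  stopifnot(edge_tab$nT == nT, edge_tab$nS == nS)

  init <- viterbi_align(scores)
  z_path <- init$triples
  z <- path_indicators(z_path, nT, nS)
  L <- max(1L, nrow(z_path))
  lambda <- zero_indicators(nT, nS)

  best_obj <- objective_p1(init, scores, edge_tab)
  best_path <- init
  trace <- data.frame(iter = integer(), obj_y = numeric(), obj_z = numeric(),
                      lagrangian = numeric(), disagreement = numeric())
  converged <- FALSE
  iterations <- 0L

  for (it in seq_len(max_iter)) {
    iterations <- it
    # SP1: solve for y with z fixed (+lambda)
    sp1 <- linearized_dp_scores(z, lambda, rho, scores, edge_tab, L)
    y_aln <- viterbi_align(sp1)
    y <- path_indicators(y_aln$triples, nT, nS)
    obj_y <- objective_p1(y_aln, scores, edge_tab)
    if (obj_y > best_obj) { best_obj <- obj_y; best_path <- y_aln }

    # SP2: solve for z with y fixed (-lambda)
    neg_lambda <- lapply(lambda, function(m) -m)
    sp2 <- linearized_dp_scores(y, neg_lambda, rho, scores, edge_tab, L)
    z_aln <- viterbi_align(sp2)
    z <- path_indicators(z_aln$triples, nT, nS)
    obj_z <- objective_p1(z_aln, scores, edge_tab)
    if (obj_z > best_obj) { best_obj <- obj_z; best_path <- z_aln }

    # Lagrangian of the symmetrised objective at the current iterates,
    # reported on the P1 scale (/2).
    Ey <- edge_linear_term(edge_tab, y_aln$aligned_pairs, L)
    cross <- sum(Ey[z_aln$aligned_pairs])
    dM <- z$M - y$M; dIT <- z$IT - y$IT; dIS <- z$IS - y$IS
    disagree <- sum(abs(dM)) + sum(abs(dIT)) + sum(abs(dIS))
    lag_raw <- path_node_score(z_aln$triples, scores) +
      path_node_score(y_aln$triples, scores) + cross -
      (sum(lambda$M * dM) + sum(lambda$IT * dIT) + sum(lambda$IS * dIS)) -
      (rho / 2) * disagree
    trace <- rbind(trace, data.frame(iter = it, obj_y = obj_y, obj_z = obj_z,
                                     lagrangian = lag_raw / 2,
                                     disagreement = disagree))

    if (disagree == 0) {
      converged <- TRUE
      break
    }
    # step 3: update L from the most recent (SP2) alignment, then lambda
    L <- max(1L, z_aln$L)
    lambda$M <- lambda$M + rho * dM
    lambda$IT <- lambda$IT + rho * dIT
    lambda$IS <- lambda$IS + rho * dIS
  }

  structure(list(alignment = best_path, objective = best_obj,
                 iterations = iterations, converged = converged,
                 trace = trace, init = init),
            class = "admm_result")
}

#' @export
print.admm_result <- function(x, ...) {
  cat("ADMM alignment: objective", format(x$objective, digits = 6),
      "|", x$iterations, "iterations |",
      if (x$converged) "converged" else "not converged", "\n")
  invisible(x)
}

#' Align two families end to end
#'
#' Convenience driver: computes node scores, predicts per-edge distance
#' distributions for both families, assembles the edge table and runs
#' [admm_align()] (or plain [viterbi_align()] when `use_edge = FALSE`).
#'
#' @param mrfT,mrfS `mrf_model` objects.
#' @param scorer A node scorer.
#' @param predictor A `distance_predictor` (required when `use_edge`).
#' @param stats A `distance_stats` object (required when `use_edge`).
#' @param use_edge Include the edge alignment potential? (default TRUE)
#' @param rho,max_iter ADMM controls.
#' @return An `admm_result` (for `use_edge = FALSE` a degenerate one that
#'   converged at iteration 0 with the Viterbi alignment).
#' @export
align_families <- function(mrfT, mrfS, scorer, predictor = NULL,
                           stats = NULL, use_edge = TRUE, rho = 0.5,
                           max_iter = 50) {
  scores <- pair_scores(scorer, mrfT, mrfS)
  if (!use_edge) {
    aln <- viterbi_align(scores)
    return(structure(list(alignment = aln, objective = aln$score,
                          iterations = 0L, converged = TRUE,
                          trace = NULL, init = aln),
                     class = "admm_result"))
  }
  stopifnot(!is.null(predictor), !is.null(stats))
  predT <- family_edge_distributions(predictor, mrfT)
  predS <- family_edge_distributions(predictor, mrfS)
  tab <- edge_table(predT, predS, stats,
                    min_separation = max(mrfT$min_separation,
                                         mrfS$min_separation))
  admm_align(edge_tab = tab, rho = rho, max_iter = max_iter, scores = scores)
}
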