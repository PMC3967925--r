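# Node alignment potential.  A one-hidden-layer neural scorer (CNF) yields
# the log-likelihood of a vertex (i, j, state) in the alignment path from the
# sequence profile contexts of the nodes involved; the vertex potential is
# that output minus its sampled background expectation.  An untrained
# profile-similarity scorer ships as the default so alignment works without a
# training step (it is NOT the trained CNF scorer).

STATES <- c("M", "I_T", "I_S")

# 3x3 transition bias matrix; direct I_T <-> I_S toggling is disallowed
# (standard affine convention).
#' @keywords internal
#' @noRd
default_trans <- function(gap_open = 0, gap_extend = 0) {
  tr <- matrix(0, 3, 3, dimnames = list(STATES, STATES))
  tr["M", "I_T"] <- tr["M", "I_S"] <- gap_open
  tr["I_T", "I_T"] <- tr["I_S", "I_S"] <- gap_extend
  tr["I_T", "I_S"] <- tr["I_S", "I_T"] <- -Inf
  tr
}

#' Profile-similarity fallback node scorer
#'
#' A log-odds dot product of the two columns' amino-acid marginals (gap mass
#' excluded, uniform 1/20 background): `log(20 * sum_a p_i(a) q_j(a))`.
#' Insertions score 0; gap costs are carried by the transition biases.  This
#' scorer requires no training and is clearly not the trained CNF scorer; it
#' exists so that the aligner is usable out of the box.
#'
#' @param gap_open Transition bias M -> insert (default -3).
#' @param gap_extend Transition bias insert -> insert (default -0.5).
#' @param w Context half-width the scorer expects (default 5; only the centre
#'   row of each context is used).
#' @return An object of classes `profile_scorer`, `mrf_node_scorer`.
#' @export
new_profile_scorer <- function(gap_open = -3, gap_extend = -0.5, w = 5) {
  structure(list(w = w, trans = default_trans(gap_open, gap_extend),
                 background = c(M = 0, I_T = 0, I_S = 0)),
            class = c("profile_scorer", "mrf_node_scorer"))
}

#' Untrained CNF node scorer
#'
#' One hidden layer (tanh), linear output.  The match network takes the
#' concatenated profile contexts of the two nodes; each insertion network
#' takes a single context.  All weights zero gives output 0 everywhere.
#'
#' @param w Context half-width (default 5).
#' @param hidden Hidden layer size H (default 20).
#' @param init_sd If > 0, initialise weights from N(0, init_sd^2) (seeded).
#' @param seed RNG seed for initialisation.
#' @return An object of classes `cnf_scorer`, `mrf_node_scorer`.
#' @export
new_cnf_scorer <- function(w = 5, hidden = 20, init_sd = 0, seed = 1) {
  d <- (2 * w + 1) * N_ALPHA
  mk <- function(nr, nc) {
    if (init_sd > 0) matrix(rnorm(nr * nc, 0, init_sd), nr, nc) else
      matrix(0, nr, nc)
  }
  sc <- withr::with_seed(seed, list(
    w = w, hidden = hidden, d = d,
    Wm_a = mk(hidden, d), Wm_b = mk(hidden, d), bm = numeric(hidden),
    vm = if (init_sd > 0) rnorm(hidden, 0, init_sd) else numeric(hidden),
    cm = 0,
    Wt = mk(hidden, d), bt = numeric(hidden),
    vt = if (init_sd > 0) rnorm(hidden, 0, init_sd) else numeric(hidden),
    ct = 0,
    Ws = mk(hidden, d), bs = numeric(hidden),
    vs = if (init_sd > 0) rnorm(hidden, 0, init_sd) else numeric(hidden),
    cs = 0,
    trans = default_trans(),
    background = c(M = 0, I_T = 0, I_S = 0),
    l2_lambda = 0))
  class(sc) <- c("cnf_scorer", "mrf_node_scorer")
  sc
}

# ---- raw network outputs (no background offset) ------------------------

# Flatten a (2w+1) x 21 context into a feature row.
#' @keywords internal
#' @noRd
flatten_context <- function(ctx) as.numeric(t(ctx))

# Raw match output for paired feature rows XT, XS (m x d each).
#' @keywords internal
#' @noRd
raw_match <- function(scorer, XT, XS) UseMethod("raw_match")

#' @export
raw_match.cnf_scorer <- function(scorer, XT, XS) {
  H <- tanh(XT %*% t(scorer$Wm_a) + XS %*% t(scorer$Wm_b) +
              matrix(scorer$bm, nrow(XT), scorer$hidden, byrow = TRUE))
  as.numeric(H %*% scorer$vm + scorer$cm)
}

#' @export
raw_match.profile_scorer <- function(scorer, XT, XS) {
  ctr <- scorer$w * N_ALPHA + seq_len(20) # centre row, amino acids only
  log(20 * rowSums(XT[, ctr, drop = FALSE] * XS[, ctr, drop = FALSE]) + 1e-10)
}

#' @keywords internal
#' @noRd
raw_insert <- function(scorer, X, side) UseMethod("raw_insert")

#' @export
raw_insert.cnf_scorer <- function(scorer, X, side) {
  if (side == "I_T") {
    H <- tanh(X %*% t(scorer$Wt) +
                matrix(scorer$bt, nrow(X), scorer$hidden, byrow = TRUE))
    as.numeric(H %*% scorer$vt + scorer$ct)
  } else {
    H <- tanh(X %*% t(scorer$Ws) +
                matrix(scorer$bs, nrow(X), scorer$hidden, byrow = TRUE))
    as.numeric(H %*% scorer$vs + scorer$cs)
  }
}

#' @export
raw_insert.profile_scorer <- function(scorer, X, side) numeric(nrow(X))

#' Score a single alignment vertex
#'
#' Returns the vertex potential `G(inputs) - background(state)` for a match
#' or insertion vertex.  State `"M"` requires both contexts; `"I_T"` /
#' `"I_S"` require the corresponding single context.
#'
#' @param scorer A node scorer.
#' @param context_T Profile context of the node in T (or `NULL`).
#' @param context_S Profile context of the node in S (or `NULL`).
#' @param state One of `"M"`, `"I_T"`, `"I_S"`.
#' @return A single finite number.
#' @export
score_vertex <- function(scorer, context_T = NULL, context_S = NULL,
                         state = c("M", "I_T", "I_S")) {
  state <- match.arg(state)
  if (state == "M") {
    if (is.null(context_T) || is.null(context_S))
      stop("contract error: state M requires both contexts")
    raw <- raw_match(scorer, rbind(flatten_context(context_T)),
                     rbind(flatten_context(context_S)))
  } else if (state == "I_T") {
    if (is.null(context_T))
      stop("contract error: state I_T requires context_T")
    raw <- raw_insert(scorer, rbind(flatten_context(context_T)), "I_T")
  } else {
    if (is.null(context_S))
      stop("contract error: state I_S requires context_S")
    raw <- raw_insert(scorer, rbind(flatten_context(context_S)), "I_S")
  }
  as.numeric(raw) - scorer$background[[state]]
}

# Raw score matrices for a family pair: out_M (nT x nS), out_IT (length nT),
# out_IS (length nS).  No background offset (training operates on these).
#' @keywords internal
#' @noRd
raw_score_matrices <- function(scorer, CT, CS) {
  nT <- nrow(CT); nS <- nrow(CS)
  out_M <- matrix(0, nT, nS)
  if (inherits(scorer, "cnf_scorer")) {
    A <- CT %*% t(scorer$Wm_a)
    B <- CS %*% t(scorer$Wm_b)
    for (i in seq_len(nT)) {
      Hi <- tanh(sweep(B, 2, A[i, ] + scorer$bm, "+"))
      out_M[i, ] <- Hi %*% scorer$vm + scorer$cm
    }
  } else {
    ctr <- scorer$w * N_ALPHA + seq_len(20)
    out_M <- log(20 * tcrossprod(CT[, ctr, drop = FALSE],
                                 CS[, ctr, drop = FALSE]) + 1e-10)
  }
  list(out_M = out_M,
       out_IT = raw_insert(scorer, CT, "I_T"),
       out_IS = raw_insert(scorer, CS, "I_S"))
}

#' Node score matrices for a family pair
#'
#' Background-offset vertex potentials in the layout the lattice kernels
#' expect: `sM` (nT x nS), `sIT` (nT x (nS+1), column j+1 is S-progress j),
#' `sIS` ((nT+1) x nS), plus the scorer's transition bias matrix.
#'
#' @param scorer A node scorer.
#' @param mrfT,mrfS `mrf_model` objects.
#' @param free_end_gaps If `TRUE`, terminal insertion cells score 0.
#' @return List with `sM`, `sIT`, `sIS`, `trans`, `nT`, `nS`.
#' @export
pair_scores <- function(scorer, mrfT, mrfS, free_end_gaps = FALSE) {
  CT <- context_matrix(mrfT)
  CS <- context_matrix(mrfS)
  raw <- raw_score_matrices(scorer, CT, CS)
  nT <- mrfT$ncol; nS <- mrfS$ncol
  bg <- scorer$background
  sM <- raw$out_M - bg[["M"]]
  sIT <- matrix(raw$out_IT - bg[["I_T"]], nT, nS + 1)
  sIS <- matrix(rep(raw$out_IS - bg[["I_S"]], each = nT + 1), nT + 1, nS)
  if (free_end_gaps) {
    sIT[, c(1, nS + 1)] <- 0
    sIS[c(1, nT + 1), ] <- 0
  }
  list(sM = sM, sIT = sIT, sIS = sIS, trans = scorer$trans, nT = nT, nS = nS)
}

#' Partition function of the alignment CNF
#'
#' Log of the sum, over all three-state alignment paths between the two
#' families, of the exponentiated path score (raw network outputs plus
#' transition biases; no background offset).
#'
#' @param scorer A node scorer.
#' @param mrfT,mrfS `mrf_model` objects.
#' @return `log Z(T, S)`.
#' @export
cnf_logZ <- function(scorer, mrfT, mrfS) {
  raw <- raw_score_matrices(scorer, context_matrix(mrfT), context_matrix(mrfS))
  nT <- mrfT$ncol; nS <- mrfS$ncol
  .forward_logz(raw$out_M, matrix(raw$out_IT, nT, nS + 1),
                matrix(rep(raw$out_IS, each = nT + 1), nT + 1, nS),
                scorer$trans)
}

#' Posterior probability of aligned pairs under the CNF
#'
#' Mean posterior match probability of the given reference pairs under the
#' alignment distribution of Eq-style CNF scoring (raw outputs).
#'
#' @param scorer A node scorer.
#' @param mrfT,mrfS `mrf_model` objects.
#' @param pairs Two-column matrix of matched column indices (1-based).
#' @return Mean posterior over the pairs.
#' @export
alignment_posterior <- function(scorer, mrfT, mrfS, pairs) {
  raw <- raw_score_matrices(scorer, context_matrix(mrfT), context_matrix(mrfS))
  nT <- mrfT$ncol; nS <- mrfS$ncol
  fb <- .forward_backward(raw$out_M, matrix(raw$out_IT, nT, nS + 1),
                          matrix(rep(raw$out_IS, each = nT + 1), nT + 1, nS),
                          scorer$trans)
  mean(fb$post_M[as.matrix(pairs[, 1:2, drop = FALSE])])
}

# ---- reference alignments ----------------------------------------------

#' Canonical full state path through a set of matched pairs
#'
#' Expands a reference alignment (matched column pairs, strictly increasing
#' in both coordinates) into a full three-state lattice path.  Regions left
#' unaligned on both sides cannot be traversed by insertions alone (direct
#' I_T <-> I_S toggling is disallowed), so min(gap_T, gap_S) diagonal M steps
#' are inserted first, then the remaining single-sided insertions.  The extra
#' M cells are path plumbing, not reference matches.
#'
#' @param pairs Two-column matrix of matched indices (may have 0 rows).
#' @param nT,nS Family lengths.
#' @return Integer matrix with columns `i`, `j`, `state` (1=M, 2=I_T, 3=I_S).
#' @export
path_from_pairs <- function(pairs, nT, nS) {
  pairs <- as.matrix(pairs)
  if (nrow(pairs) > 0) {
    stopifnot(all(diff(pairs[, 1]) > 0), all(diff(pairs[, 2]) > 0),
              all(pairs[, 1] >= 1), all(pairs[, 1] <= nT),
              all(pairs[, 2] >= 1), all(pairs[, 2] <= nS))
  }
  trip <- matrix(0L, 0, 3)
  ci <- 0L; cj <- 0L
  step_to <- function(ti, tj, trip, ci, cj) {
    di <- ti - ci; dj <- tj - cj
    m <- min(di, dj)
    if (m > 0)
      trip <- rbind(trip, cbind(ci + seq_len(m), cj + seq_len(m), 1L))
    ci <- ci + m; cj <- cj + m
    if (di > m)
      trip <- rbind(trip, cbind(ci + seq_len(di - m), cj, 2L))
    if (dj > m)
      trip <- rbind(trip, cbind(ti, cj + seq_len(dj - m), 3L))
    list(trip = trip, ci = ti, cj = tj)
  }
  for (r in seq_len(nrow(pairs))) {
    ti <- pairs[r, 1] - 1L; tj <- pairs[r, 2] - 1L
    st <- step_to(ti, tj, trip, ci, cj)
    trip <- rbind(st$trip, cbind(pairs[r, 1], pairs[r, 2], 1L))
    ci <- pairs[r, 1]; cj <- pairs[r, 2]
  }
  st <- step_to(nT, nS, trip, ci, cj)
  trip <- st$trip
  colnames(trip) <- c("i", "j", "state")
  storage.mode(trip) <- "integer"
  trip
}

# Indicator matrices (lattice layout) for a full state path.
#' @keywords internal
#' @noRd
path_indicators <- function(trip, nT, nS) {
  zM <- matrix(0, nT, nS)
  zIT <- matrix(0, nT, nS + 1)
  zIS <- matrix(0, nT + 1, nS)
  for (r in seq_len(nrow(trip))) {
    i <- trip[r, 1]; j <- trip[r, 2]; u <- trip[r, 3]
    if (u == 1L) zM[i, j] <- 1
    else if (u == 2L) zIT[i, j + 1] <- 1
    else zIS[i + 1, j] <- 1
  }
  list(M = zM, IT = zIT, IS = zIS)
}

# Observed transition counts (3x3, M/IT/IS order) along a full path,
# excluding the transition out of the dummy vertex.
#' @keywords internal
#' @noRd
path_trans_counts <- function(trip) {
  ct <- matrix(0, 3, 3, dimnames = list(STATES, STATES))
  if (nrow(trip) >= 2)
    for (r in 2:nrow(trip))
      ct[trip[r - 1, 3], trip[r, 3]] <- ct[trip[r - 1, 3], trip[r, 3]] + 1
  ct
}

# ---- training -----------------------------------------------------------

# parameter names subject to gradient updates and the L2 penalty
.CNF_PAR <- c("Wm_a", "Wm_b", "bm", "vm", "cm",
              "Wt", "bt", "vt", "ct", "Ws", "bs", "vs", "cs")

#' Train the CNF node scorer on reference alignments
#'
#' Maximises the regularised log-likelihood
#' `sum_pairs log P(A_ref | T, S) - lambda * ||theta||^2`, where the
#' probability of an alignment is its exponentiated path score normalised by
#' the partition function over all paths (computed by the forward algorithm
#' on the three-state lattice).  Batch gradient ascent with step-size
#' halving: a step that worsens the penalised loss is retried at half the
#' step size, so the monitored loss is non-increasing.  Transition biases are
#' trained alongside the network weights.  Background constants are estimated
#' by sampling from the training contexts after training.
#'
#' @param training_pairs List of `list(T=, S=, ref=)`: two `mrf_model`s and a
#'   two-column matrix of reference matched pairs.
#' @param l2_lambda L2 regularisation weight (default 0.1).
#' @param epochs Number of epochs (default 150).
#' @param seed RNG seed (initialisation and background sampling).
#' @param hidden Hidden layer size (default 20).
#' @param lr Initial step size.
#' @param bg_samples Node-pair samples for the background estimate
#'   (default 10000).
#' @return A trained `cnf_scorer`; attribute `"loss_trace"` holds the
#'   per-epoch penalised loss.
#' @export
train_scorer <- function(training_pairs, l2_lambda = 0.1, epochs = 150,
                         seed = 1, hidden = 20, lr = 0.05,
                         bg_samples = 10000) {
  stopifnot(length(training_pairs) >= 1)
  w <- training_pairs[[1]]$T$w
  scorer <- new_cnf_scorer(w = w, hidden = hidden, init_sd = 0.05, seed = seed)
  scorer$l2_lambda <- l2_lambda

  prep <- lapply(training_pairs, function(tp) {
    nT <- tp$T$ncol; nS <- tp$S$ncol
    trip <- path_from_pairs(tp$ref, nT, nS)
    ind <- path_indicators(trip, nT, nS)
    list(CT = context_matrix(tp$T), CS = context_matrix(tp$S),
         nT = nT, nS = nS, ind = ind, tcounts = path_trans_counts(trip))
  })

  loss_grad <- function(sc, want_grad = TRUE) {
    ll <- 0
    g <- NULL
    if (want_grad) {
      g <- lapply(sc[.CNF_PAR], function(p) p * 0)
      g$trans <- matrix(0, 3, 3)
    }
    for (pp in prep) {
      nT <- pp$nT; nS <- pp$nS
      A <- pp$CT %*% t(sc$Wm_a)
      B <- pp$CS %*% t(sc$Wm_b)
      out_M <- matrix(0, nT, nS)
      Hlist <- vector("list", nT)
      for (i in seq_len(nT)) {
        Hi <- tanh(sweep(B, 2, A[i, ] + sc$bm, "+"))
        Hlist[[i]] <- Hi
        out_M[i, ] <- Hi %*% sc$vm + sc$cm
      }
      Ht <- tanh(sweep(pp$CT %*% t(sc$Wt), 2, sc$bt, "+"))
      out_IT <- as.numeric(Ht %*% sc$vt + sc$ct)
      Hs <- tanh(sweep(pp$CS %*% t(sc$Ws), 2, sc$bs, "+"))
      out_IS <- as.numeric(Hs %*% sc$vs + sc$cs)

      sIT <- matrix(out_IT, nT, nS + 1)
      sIS <- matrix(rep(out_IS, each = nT + 1), nT + 1, nS)
      fb <- .forward_backward(out_M, sIT, sIS, sc$trans)

      tr_ok <- is.finite(sc$trans)
      ll <- ll + sum(pp$ind$M * out_M) +
        sum(rowSums(pp$ind$IT) * out_IT) +
        sum(colSums(pp$ind$IS) * out_IS) +
        sum(pp$tcounts[tr_ok] * sc$trans[tr_ok]) - fb$logZ

      if (want_grad) {
        GM <- pp$ind$M - fb$post_M
        gIT <- rowSums(pp$ind$IT) - rowSums(fb$post_IT)
        gIS <- colSums(pp$ind$IS) - colSums(fb$post_IS)
        gtr <- pp$tcounts - fb$expected_trans
        gtr[!tr_ok] <- 0
        g$trans <- g$trans + gtr
        # match net backprop
        for (i in seq_len(nT)) {
          gi <- GM[i, ]
          if (all(gi == 0) && FALSE) next
          Hi <- Hlist[[i]]
          g$vm <- g$vm + as.numeric(t(Hi) %*% gi)
          g$cm <- g$cm + sum(gi)
          Dpre <- (gi %o% sc$vm) * (1 - Hi^2) # nS x H
          cs_ <- colSums(Dpre)
          g$Wm_a <- g$Wm_a + cs_ %o% pp$CT[i, ]
          g$Wm_b <- g$Wm_b + t(Dpre) %*% pp$CS
          g$bm <- g$bm + cs_
        }
        # insert nets
        g$vt <- g$vt + as.numeric(t(Ht) %*% gIT)
        g$ct <- g$ct + sum(gIT)
        Dt <- (gIT %o% sc$vt) * (1 - Ht^2)
        g$Wt <- g$Wt + t(Dt) %*% pp$CT
        g$bt <- g$bt + colSums(Dt)
        g$vs <- g$vs + as.numeric(t(Hs) %*% gIS)
        g$cs <- g$cs + sum(gIS)
        Ds <- (gIS %o% sc$vs) * (1 - Hs^2)
        g$Ws <- g$Ws + t(Ds) %*% pp$CS
        g$bs <- g$bs + colSums(Ds)
      }
    }
    pen <- l2_lambda * (sum(vapply(sc[.CNF_PAR],
                                   function(p) sum(p^2), numeric(1))) +
                          sum(sc$trans[is.finite(sc$trans)]^2))
    loss <- -ll + pen
    if (!is.finite(loss)) stop("training failure: non-finite loss")
    if (want_grad) {
      for (nm in .CNF_PAR) g[[nm]] <- -g[[nm]] + 2 * l2_lambda * sc[[nm]]
      gt <- -g$trans
      gt[is.finite(sc$trans)] <- gt[is.finite(sc$trans)] +
        2 * l2_lambda * sc$trans[is.finite(sc$trans)]
      gt[!is.finite(sc$trans)] <- 0
      g$trans <- gt
    }
    list(loss = loss, grad = g)
  }

  cur <- loss_grad(scorer)
  trace <- numeric(epochs + 1)
  trace[1] <- cur$loss
  for (ep in seq_len(epochs)) {
    accepted <- FALSE
    for (try in seq_len(40)) {
      cand <- scorer
      for (nm in .CNF_PAR) cand[[nm]] <- scorer[[nm]] - lr * cur$grad[[nm]]
      tr_new <- scorer$trans
      ok <- is.finite(tr_new)
      tr_new[ok] <- tr_new[ok] - lr * cur$grad$trans[ok]
      cand$trans <- tr_new
      new <- loss_grad(cand)
      if (new$loss <= cur$loss + 1e-12) {
        scorer <- cand
        cur <- new
        lr <- lr * 1.1
        accepted <- TRUE
        break
      }
      lr <- lr / 2
    }
    trace[ep + 1] <- cur$loss
    if (!accepted) {
      trace <- trace[seq_len(ep + 1)]
      break
    }
  }

  # background constants from the training contexts
  pool <- do.call(rbind, lapply(prep, function(pp) rbind(pp$CT, pp$CS)))
  scorer <- estimate_background(scorer, pool, n_samples = bg_samples,
                                seed = seed)
  attr(scorer, "loss_trace") <- trace
  scorer
}

#' Estimate background score offsets by sampling
#'
#' Samples random node pairs (for the match state) and single nodes (for the
#' insertion states) from a pool of profile contexts, and sets each state's
#' background to the mean raw network output over the samples.
#'
#' @param scorer A node scorer.
#' @param pool Either a list of profile context matrices or a matrix of
#'   flattened context rows.
#' @param n_samples Number of samples (default 10000).
#' @param seed RNG seed (reproducible).
#' @return The scorer with its `background` field updated.
#' @export
estimate_background <- function(scorer, pool, n_samples = 10000, seed = 1) {
  if (n_samples < 1) stop("parameter error: n_samples must be >= 1")
  X <- if (is.list(pool)) do.call(rbind, lapply(pool, flatten_context)) else
    pool
  if (nrow(X) == 0) stop("empty context pool")
  withr::with_seed(seed, {
    ia <- sample.int(nrow(X), n_samples, replace = TRUE)
    ib <- sample.int(nrow(X), n_samples, replace = TRUE)
    ic <- sample.int(nrow(X), n_samples, replace = TRUE)
  })
  scorer$background <- c(
    M = mean(raw_match(scorer, X[ia, , drop = FALSE], X[ib, , drop = FALSE])),
    I_T = mean(raw_insert(scorer, X[ic, , drop = FALSE], "I_T")),
    I_S = mean(raw_insert(scorer, X[ic, , drop = FALSE], "I_S")))
  scorer
}
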