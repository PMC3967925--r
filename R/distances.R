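# Inter-residue distance machinery for the edge alignment potential:
# the distance-bin schema, background and aligned-pair distance statistics
# counted from structures and reference alignments, and a pluggable
# per-edge distance-distribution predictor.

#' Distance bin schema
#'
#' Inter-residue distance is discretised into the intervals
#' `<4, [4,5), [5,6), ..., [14,15), >=15` Angstrom.  The enumerated
#' boundaries yield 13 intervals; boundaries are left-closed.
#'
#' @param edges Strictly increasing bin boundaries in Angstrom
#'   (default `4:15`).
#' @return Object of class `distance_bins` with `edges` and `nbins`
#'   (`length(edges) + 1`).
#' @export
distance_bins <- function(edges = 4:15) {
  stopifnot(all(diff(edges) > 0))
  structure(list(edges = as.numeric(edges), nbins = length(edges) + 1L),
            class = "distance_bins")
}

#' Bin index of a distance
#'
#' @param distance Distance(s) in Angstrom, nonnegative.
#' @param bins A `distance_bins` object.
#' @return Integer bin index in `1..nbins` (vectorised).
#' @export
bin_of <- function(distance, bins = distance_bins()) {
  if (any(distance < 0)) stop("contract error: negative distance")
  findInterval(distance, bins$edges) + 1L
}

# representative-point pairwise distance matrix
#' @keywords internal
#' @noRd
pairwise_distances <- function(coords) as.matrix(dist(coords))

#' Background distance distribution from structures
#'
#' Histogram of binned inter-residue distances over all residue pairs with
#' `|i - k| >= min_separation`, additively smoothed and normalised.  Each
#' structure supplies one representative coordinate per residue (the
#' convention for real chains is C-beta, C-alpha for glycine); duplicated
#' structures count twice.
#'
#' @param structures List of n x 3 coordinate matrices.
#' @param bins A `distance_bins` object.
#' @param min_separation Minimum sequence separation (default 6).
#' @param alpha Additive smoothing weight (default 1).
#' @return List with `p_background` (sums to 1, strictly positive),
#'   `counts_background`, `bins`, `min_separation`, `alpha`.
#' @export
count_background <- function(structures, bins = distance_bins(),
                             min_separation = 6, alpha = 1) {
  if (length(structures) == 0) stop("empty structure set")
  counts <- numeric(bins$nbins)
  for (xyz in structures) {
    D <- pairwise_distances(xyz)
    n <- nrow(D)
    sep <- abs(outer(seq_len(n), seq_len(n), "-"))
    d <- D[sep >= min_separation & upper.tri(D)]
    if (length(d) > 0)
      counts <- counts + tabulate(bin_of(d, bins), nbins = bins$nbins)
  }
  p <- (counts + alpha) / sum(counts + alpha)
  list(p_background = p, counts_background = counts, bins = bins,
       min_separation = min_separation, alpha = alpha)
}

#' Aligned-pair distance distribution from reference alignments
#'
#' For every pair of aligned positions (i<->j, k<->l) with sequence
#' separation at least `min_separation` on both sides, the cell
#' `(bin(d_ik), bin(d_jl))` and its transpose are incremented (the order of
#' the two proteins in a pair is arbitrary, so counts are symmetrised).
#'
#' @param reference_pairs List of `list(structure_T=, structure_S=, pairs=)`:
#'   coordinate matrices and a two-column matrix of aligned positions.
#' @param bins A `distance_bins` object.
#' @param min_separation Minimum separation on both sides (default 6).
#' @param alpha Additive smoothing weight (default 1).
#' @return List with `p_aligned` (nbins x nbins, sums to 1, strictly
#'   positive), `counts_aligned`, `bins`, `min_separation`, `alpha`.
#' @export
count_aligned <- function(reference_pairs, bins = distance_bins(),
                          min_separation = 6, alpha = 1) {
  if (length(reference_pairs) == 0) stop("empty reference set")
  counts <- matrix(0, bins$nbins, bins$nbins)
  for (rp in reference_pairs) {
    pairs <- as.matrix(rp$pairs)
    nT <- nrow(rp$structure_T); nS <- nrow(rp$structure_S)
    if (nrow(pairs) > 0 &&
        (max(pairs[, 1]) > nT || max(pairs[, 2]) > nS || min(pairs) < 1))
      stop("data error: alignment index out of structure range")
    if (nrow(pairs) < 2) next
    DT <- pairwise_distances(rp$structure_T)
    DS <- pairwise_distances(rp$structure_S)
    np <- nrow(pairs)
    for (a in seq_len(np - 1)) {
      for (b in (a + 1):np) {
        i <- pairs[a, 1]; j <- pairs[a, 2]
        k <- pairs[b, 1]; l <- pairs[b, 2]
        if (abs(i - k) < min_separation || abs(j - l) < min_separation) next
        b1 <- bin_of(DT[i, k], bins)
        b2 <- bin_of(DS[j, l], bins)
        counts[b1, b2] <- counts[b1, b2] + 1
        counts[b2, b1] <- counts[b2, b1] + 1
      }
    }
  }
  p <- (counts + alpha) / sum(counts + alpha)
  list(p_aligned = p, counts_aligned = counts, bins = bins,
       min_separation = min_separation, alpha = alpha)
}

#' Assemble distance statistics
#'
#' @param background Result of [count_background()].
#' @param aligned Result of [count_aligned()].
#' @return Object of class `distance_stats` combining both tables.
#' @export
distance_stats <- function(background, aligned) {
  stopifnot(background$bins$nbins == aligned$bins$nbins)
  structure(list(bins = background$bins,
                 p_background = background$p_background,
                 p_aligned = aligned$p_aligned,
                 counts_background = background$counts_background,
                 counts_aligned = aligned$counts_aligned,
                 min_separation = background$min_separation,
                 alpha = background$alpha),
            class = "distance_stats")
}

#' Write / read distance statistics as TSV
#'
#' Long format with columns `table` (`edges`, `background`, `aligned`),
#' `d1`, `d2`, `value`; counts are stored and re-smoothed on read.
#'
#' @param stats A `distance_stats` object.
#' @param path File path.
#' @return `path` (write) or a `distance_stats` (read).
#' @export
write_distance_stats <- function(stats, path) {
  nb <- stats$bins$nbins
  df <- rbind(
    data.frame(table = "edges", d1 = seq_along(stats$bins$edges), d2 = NA,
               value = stats$bins$edges),
    data.frame(table = "alpha", d1 = 0, d2 = NA, value = stats$alpha),
    data.frame(table = "min_separation", d1 = 0, d2 = NA,
               value = stats$min_separation),
    data.frame(table = "background", d1 = seq_len(nb), d2 = NA,
               value = stats$counts_background),
    data.frame(table = "aligned",
               d1 = rep(seq_len(nb), nb), d2 = rep(seq_len(nb), each = nb),
               value = as.numeric(stats$counts_aligned)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distance_stats
#' @export
read_distance_stats <- function(path) {
  df <- read.delim(path)
  bins <- distance_bins(df$value[df$table == "edges"])
  alpha <- df$value[df$table == "alpha"]
  msep <- df$value[df$table == "min_separation"]
  nb <- bins$nbins
  cb <- df$value[df$table == "background"]
  ca <- matrix(0, nb, nb)
  al <- df[df$table == "aligned", ]
  ca[cbind(al$d1, al$d2)] <- al$value
  structure(list(bins = bins,
                 p_background = (cb + alpha) / sum(cb + alpha),
                 p_aligned = (ca + alpha) / sum(ca + alpha),
                 counts_background = cb, counts_aligned = ca,
                 min_separation = msep, alpha = alpha),
            class = "distance_stats")
}

# ---- PDB coordinate reading / writing ----------------------------------

#' Read representative-atom coordinates from a PDB file
#'
#' Extracts one coordinate per residue from ATOM records of a single chain:
#' C-beta, falling back to C-alpha (glycine or missing C-beta).
#'
#' @param path PDB file path.
#' @param chain Chain identifier (default: first chain encountered).
#' @return n x 3 coordinate matrix.
#' @export
read_pdb <- function(path, chain = NULL) {
  lines <- readLines(path)
  atoms <- lines[startsWith(lines, "ATOM")]
  if (length(atoms) == 0) stop("no ATOM records in ", path)
  f <- function(l, a, b) substr(l, a, b)
  name <- trimws(f(atoms, 13, 16))
  ch <- f(atoms, 22, 22)
  if (is.null(chain)) chain <- ch[1]
  keep <- ch == chain & name %in% c("CA", "CB")
  atoms <- atoms[keep]; name <- name[keep]
  resno <- as.integer(f(atoms, 23, 26))
  x <- as.numeric(f(atoms, 31, 38))
  y <- as.numeric(f(atoms, 39, 46))
  z <- as.numeric(f(atoms, 47, 54))
  res <- unique(resno)
  out <- matrix(NA_real_, length(res), 3)
  for (r in seq_along(res)) {
    sel <- which(resno == res[r])
    pick <- sel[match("CB", name[sel])]
    if (is.na(pick)) pick <- sel[match("CA", name[sel])]
    out[r, ] <- c(x[pick], y[pick], z[pick])
  }
  out
}

#' Write a coordinate chain as a CA-trace PDB file
#'
#' @param coords n x 3 coordinate matrix.
#' @param path Output path.
#' @param chain Chain identifier (default "A").
#' @return `path`, invisibly.
#' @export
write_pdb <- function(coords, path, chain = "A") {
  lines <- vapply(seq_len(nrow(coords)), function(i) {
    sprintf("ATOM  %5d  CA  GLY %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            i, chain, i, coords[i, 1], coords[i, 2], coords[i, 3])
  }, character(1))
  writeLines(c(lines, "END"), path)
  invisible(path)
}

# ---- pluggable per-edge distance predictor ------------------------------

#' Structure-informed per-edge distance distributions (external-tool stand-in)
#'
#' The per-edge distance predictor is a pluggable component: in a production
#' pipeline the distributions come from an external context-specific
#' distance-potential tool.  This stand-in emulates such a tool at a stated
#' fidelity when a representative structure is available (as it is for
#' synthetic families): each pair's distribution is a discretised Gaussian
#' centred on the true binned distance with standard deviation `smear` bins,
#' mixed with `floor` of uniform mass.
#'
#' @param coords n x 3 representative-atom coordinates.
#' @param bins A `distance_bins` object.
#' @param smear Standard deviation of the bin-level smear (default 1;
#'   0 gives near point masses).
#' @param floor Uniform mixture weight (default 0.05).
#' @return Array `n x n x nbins` suitable for [edge_table()].
#' @export
structure_edge_distributions <- function(coords, bins = distance_bins(),
                                         smear = 1, floor = 0.05) {
  D <- pairwise_distances(coords)
  n <- nrow(D)
  nb <- bins$nbins
  out <- array(1 / nb, dim = c(n, n, nb))
  centres <- seq_len(nb)
  for (i in seq_len(n - 1)) {
    for (k in (i + 1):n) {
      b <- bin_of(D[i, k], bins)
      w <- if (smear > 0) exp(-((centres - b)^2) / (2 * smear^2)) else
        as.numeric(centres == b)
      p <- floor / nb + (1 - floor) * w / sum(w)
      out[i, k, ] <- p
      out[k, i, ] <- p
    }
  }
  out
}

#' Untrained per-edge distance distribution predictor
#'
#' A one-hidden-layer probabilistic network with softmax output over the
#' distance bins.  Input features for a node pair (i, k) are the two
#' flattened profile contexts plus the K mutual-information power features;
#' with all-zero weights the prediction is uniform.  The predictor interface
#' is pluggable: any external tool's per-pair distributions can be
#' substituted (see [edge_table()]).
#'
#' @param w Context half-width used by the predictor (default 2; narrower
#'   than the node scorer's window to limit overfitting).
#' @param n_mi Number of MI power features (default 11).
#' @param hidden Hidden layer size (default 16).
#' @param bins A `distance_bins` object.
#' @param use_mi If `FALSE`, the MI features are zeroed on input (the
#'   "no mutual information" ablation).
#'
#' The feature vector also carries `log(|i - k|)`: inter-residue distance
#' statistics are strongly separation-dependent, and context-specific
#' distance potentials condition on separation.
#' @return Object of class `distance_predictor`.
#' @export
new_distance_predictor <- function(w = 2, n_mi = 11, hidden = 16,
                                   bins = distance_bins(), use_mi = TRUE) {
  d <- 2 * (2 * w + 1) * N_ALPHA + n_mi + 1L
  structure(list(w = w, n_mi = n_mi, hidden = hidden, d = d, bins = bins,
                 use_mi = use_mi, proj = NULL,
                 center = numeric(d), scale = rep(1, d),
                 W1 = matrix(0, hidden, d), b1 = numeric(hidden),
                 W2 = matrix(0, bins$nbins, hidden),
                 b2 = numeric(bins$nbins)),
            class = "distance_predictor")
}

# softmax over rows
#' @keywords internal
#' @noRd
row_softmax <- function(L) {
  L <- L - apply(L, 1, max)
  E <- exp(L)
  E / rowSums(E)
}

# Project the context blocks of a raw feature matrix onto the stored basis
# (PCA of column-marginal rows, fit on the training set).  Marginal-row
# principal components capture shared residue-class structure and discard
# family-specific letter fingerprints that invite memorisation.
#' @keywords internal
#' @noRd
project_features <- function(model, X) {
  if (is.null(model$proj)) return(X)
  nb <- 2 * (2 * model$w + 1)
  q <- ncol(model$proj)
  out <- matrix(0, nrow(X), nb * q + model$n_mi + 1L)
  for (b in seq_len(nb)) {
    blk <- X[, (b - 1) * N_ALPHA + seq_len(N_ALPHA), drop = FALSE]
    out[, (b - 1) * q + seq_len(q)] <- blk %*% model$proj
  }
  out[, nb * q + seq_len(model$n_mi + 1L)] <-
    X[, nb * N_ALPHA + seq_len(model$n_mi + 1L)]
  out
}

# predicted distributions for a raw feature matrix (m x d) -> m x nbins
#' @keywords internal
#' @noRd
predictor_probs <- function(model, X) {
  if (!model$use_mi && model$n_mi > 0)
    X[, model$d - 1L - model$n_mi + seq_len(model$n_mi)] <- 0
  X <- project_features(model, X)
  X <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
  H <- tanh(X %*% t(model$W1) +
              matrix(model$b1, nrow(X), model$hidden, byrow = TRUE))
  P <- row_softmax(H %*% t(model$W2) +
                     matrix(model$b2, nrow(X), model$bins$nbins, byrow = TRUE))
  if (any(!is.finite(P))) stop("numeric error: unnormalizable prediction")
  P
}

#' Predict the distance distribution of one node pair
#'
#' @param model A `distance_predictor`.
#' @param context_i,context_k Profile contexts of the two nodes.
#' @param mi_features Numeric vector of K MI power features for (i, k).
#' @param separation Sequence separation `|i - k|` (default: the model's
#'   minimum useful value, 1).
#' @return Normalised probability vector over the distance bins.
#' @export
predict_edge_distribution <- function(model, context_i, context_k,
                                      mi_features, separation = 1) {
  stopifnot(all(is.finite(mi_features)))
  x <- c(flatten_context(context_i), flatten_context(context_k), mi_features,
         log(separation))
  stopifnot(length(x) == model$d)
  as.numeric(predictor_probs(model, rbind(x)))
}

# feature rows for node pairs of one family (canonical order i < k).
# Raw matrix powers of MI grow geometrically with the power (spectral-radius
# scaling), which would saturate the tanh hidden layer, so power p is
# rescaled by ||MI||_2^(p-1): all K features live on the MI scale.
#' @keywords internal
#' @noRd
edge_features <- function(mrf, pairs, w = 2) {
  CT <- context_matrix(mrf, w = w)
  K <- length(mrf$mi_powers)
  nrm <- max(norm(mrf$mi_powers[[1]], "2"), 1e-8)
  mi <- vapply(seq_len(K), function(p) {
    mrf$mi_powers[[p]][pairs] / nrm^(p - 1)
  }, numeric(nrow(pairs)))
  if (nrow(pairs) == 1) mi <- matrix(mi, 1, K)
  cbind(CT[pairs[, 1], , drop = FALSE], CT[pairs[, 2], , drop = FALSE], mi,
        log(abs(pairs[, 2] - pairs[, 1])))
}

#' Predicted distance distributions for all edges of a family
#'
#' @param model A `distance_predictor`.
#' @param mrf An `mrf_model`.
#' @return Array `ncol x ncol x nbins`; entries for pairs below the
#'   separation cutoff are uniform placeholders (they are masked out of all
#'   downstream sums).
#' @export
family_edge_distributions <- function(model, mrf) {
  n <- mrf$ncol
  nb <- model$bins$nbins
  out <- array(1 / nb, dim = c(n, n, nb))
  pairs <- mrf_edges(mrf)
  if (nrow(pairs) > 0) {
    P <- predictor_probs(model, edge_features(mrf, pairs, w = model$w))
    for (r in seq_len(nrow(pairs))) {
      out[pairs[r, 1], pairs[r, 2], ] <- P[r, ]
      out[pairs[r, 2], pairs[r, 1], ] <- P[r, ]
    }
  }
  out
}

#' Train the distance predictor
#'
#' Cross-entropy training of the softmax network against binned true
#' distances, by full-batch Adam.  Features are standardised (centre/scale
#' stored in the model and applied again at predict time).
#'
#' @param X Feature matrix (rows as in [edge_features()]).
#' @param y Integer vector of true bin indices.
#' @param w,n_mi,hidden,bins,use_mi Architecture (see
#'   [new_distance_predictor()]).
#' @param epochs,lr,l2 Optimisation controls.
#' @param q Number of marginal-row principal components per context column
#'   (default 4); the basis is fit on the training features and stored.
#' @param seed RNG seed for initialisation.
#' @return A trained `distance_predictor` with attribute `"loss_trace"`.
#' @export
train_distance_predictor <- function(X, y, w = 2, n_mi = 11, hidden = 16,
                                     bins = distance_bins(), use_mi = TRUE,
                                     epochs = 1000, lr = 0.01, l2 = 1e-5,
                                     q = 4, seed = 1) {
  model <- new_distance_predictor(w, n_mi, hidden, bins, use_mi)
  stopifnot(ncol(X) == model$d, all(y >= 1), all(y <= bins$nbins))
  if (!use_mi && n_mi > 0) X[, model$d - 1L - n_mi + seq_len(n_mi)] <- 0
  # context basis: PCA of the stacked column-marginal rows
  nb <- 2 * (2 * w + 1)
  blocks <- do.call(rbind, lapply(seq_len(nb), function(b)
    X[, (b - 1) * N_ALPHA + seq_len(N_ALPHA), drop = FALSE]))
  ev <- eigen(stats::cov(blocks), symmetric = TRUE)
  model$proj <- ev$vectors[, seq_len(q), drop = FALSE]
  X <- project_features(model, X)
  dred <- ncol(X)
  withr::with_seed(seed, {
    model$W1 <- matrix(rnorm(hidden * dred, 0, 0.1), hidden, dred)
    model$W2 <- matrix(rnorm(bins$nbins * hidden, 0, 0.1), bins$nbins, hidden)
  })
  # per-feature standardisation (stored in the model, applied at predict time)
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  scl[scl < 1e-8] <- 1
  model$center <- ctr
  model$scale <- scl
  X <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  m <- nrow(X)
  Y <- matrix(0, m, bins$nbins)
  Y[cbind(seq_len(m), y)] <- 1

  loss_grad <- function(md) {
    H <- tanh(X %*% t(md$W1) + matrix(md$b1, m, hidden, byrow = TRUE))
    P <- row_softmax(H %*% t(md$W2) +
                       matrix(md$b2, m, bins$nbins, byrow = TRUE))
    loss <- -sum(Y * log(pmax(P, 1e-300))) / m +
      l2 * (sum(md$W1^2) + sum(md$W2^2))
    G <- (P - Y) / m
    gW2 <- t(G) %*% H + 2 * l2 * md$W2
    gb2 <- colSums(G)
    D <- (G %*% md$W2) * (1 - H^2)
    gW1 <- t(D) %*% X + 2 * l2 * md$W1
    gb1 <- colSums(D)
    list(loss = loss, g = list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2))
  }

  pars <- c("W1", "b1", "W2", "b2")
  mom1 <- mom2 <- setNames(lapply(pars, function(p) model[[p]] * 0), pars)
  b1a <- 0.9; b2a <- 0.999; eps <- 1e-8
  trace <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    cur <- loss_grad(model)
    trace[ep] <- cur$loss
    for (p in pars) {
      mom1[[p]] <- b1a * mom1[[p]] + (1 - b1a) * cur$g[[p]]
      mom2[[p]] <- b2a * mom2[[p]] + (1 - b2a) * cur$g[[p]]^2
      m1 <- mom1[[p]] / (1 - b1a^ep)
      m2 <- mom2[[p]] / (1 - b2a^ep)
      model[[p]] <- model[[p]] - lr * m1 / (sqrt(m2) + eps)
    }
  }
  if (!is.finite(utils::tail(trace, 1))) stop("training failure: non-finite loss")
  attr(model, "loss_trace") <- trace
  model
}

#' Build a distance-predictor training set from families with structures
#'
#' Samples node pairs (separation at least the family's cutoff) from each
#' family, pairing edge features with the binned true inter-residue distance
#' of the family's representative structure.
#'
#' Sampling is stratified toward moderate separations (half the draws from
#' `|i - k| <= 15`), where distances are most predictable and alignment
#' register matters; since separation is itself an input feature this does
#' not bias the conditional distribution being learned.
#'
#' @param families List of `list(mrf=, coords=)`.
#' @param bins A `distance_bins` object.
#' @param n_per_family Maximum sampled pairs per family (default 300).
#' @param seed RNG seed.
#' @return List with feature matrix `X` and label vector `y`.
#' @export
sample_edge_examples <- function(families, bins = distance_bins(),
                                 n_per_family = 300, seed = 1, w = 2) {
  Xs <- list(); ys <- list()
  withr::with_seed(seed, {
    for (f in seq_along(families)) {
      mrf <- families[[f]]$mrf
      D <- pairwise_distances(families[[f]]$coords)
      pairs <- mrf_edges(mrf)
      if (nrow(pairs) == 0) next
      if (nrow(pairs) > n_per_family) {
        sep <- pairs[, 2] - pairs[, 1]
        short <- which(sep <= 15)
        ns <- min(length(short), ceiling(n_per_family / 2))
        take <- c(sample(short, ns),
                  sample.int(nrow(pairs), n_per_family - ns))
        pairs <- pairs[take, , drop = FALSE]
      }
      Xs[[length(Xs) + 1]] <- edge_features(mrf, pairs, w = w)
      ys[[length(ys) + 1]] <- bin_of(D[pairs], bins)
    }
  })
  list(X = do.call(rbind, Xs), y = unlist(ys))
}
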