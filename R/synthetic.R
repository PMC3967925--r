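# Synthetic family-pair generator.  A coarse self-avoiding chain (3.8 A
# steps, confined to a sphere to force long-range contacts) plays the role
# of a protein structure; two families are derived from a shared parent by
# consensus divergence and small indel plans, and sequences are sampled so
# that contacting positions mutate with coupled amino-acid preferences.
# Every downstream stage (marginals, MI, distance statistics, predictor
# training, alignment, evaluation) is therefore testable with no external
# data, with a known true alignment and a planted contact scaffold.

# Self-avoiding confined chain with secondary-structure-like segments, one
# coordinate per residue.  Helix segments follow an ideal helical curve
# (rise 1.5 A, radius 2.3 A, 100 degrees per residue), extended segments are
# near-straight, loops are random walk; the whole chain is confined to a
# sphere (forcing tertiary contacts) and self-avoiding.  Returns coordinates
# plus the per-residue segment type, which drives residue-class propensities
# so that local geometry is predictable from sequence profiles.
#' @keywords internal
#' @noRd
gen_scaffold <- function(n, step = 3.8, clash = 3.5, radius_coef = 3.4,
                         max_restarts = 200) {
  R <- radius_coef * n^(1 / 3)
  seg_plan <- function() {
    types <- character(0); lens <- integer(0)
    while (sum(lens) < n) {
      types <- c(types, sample(c("H", "E", "L"), 1,
                               prob = c(0.50, 0.38, 0.12)))
      lens <- c(lens, sample(6:14, 1))
    }
    lens[length(lens)] <- lens[length(lens)] - (sum(lens) - n)
    rep(types, lens)
  }
  unit <- function() { v <- rnorm(3); v / sqrt(sum(v^2)) }
  ok_point <- function(cand, xyz, t) {
    if (sqrt(sum(cand^2)) > R) return(FALSE)
    if (t > 2) {
      d2 <- rowSums(sweep(xyz[seq_len(t - 2), , drop = FALSE], 2, cand)^2)
      if (min(d2) < clash^2) return(FALSE)
    }
    TRUE
  }
  for (restart in seq_len(max_restarts)) {
    type <- seg_plan()
    xyz <- matrix(NA_real_, n, 3)
    xyz[1, ] <- rnorm(3, 0, 1)
    t <- 2L
    seg_frame <- NULL
    seg_t <- 0L
    dead <- FALSE
    while (t <= n) {
      new_seg <- t == 2L || type[t] != type[t - 1]
      placed <- FALSE
      for (try in seq_len(40)) {
        if (new_seg || is.null(seg_frame) || try > 1) {
          a <- unit()
          u0 <- unit(); u <- u0 - sum(u0 * a) * a; u <- u / sqrt(sum(u^2))
          v <- c(a[2] * u[3] - a[3] * u[2], a[3] * u[1] - a[1] * u[3],
                 a[1] * u[2] - a[2] * u[1])
          seg_frame <- list(a = a, u = u, v = v, origin = xyz[t - 1, ])
          seg_t <- 0L
        }
        st <- seg_t + 1L
        cand <- switch(type[t],
          H = { # ideal helix relative to the segment origin
            ang <- 1.745 * st
            seg_frame$origin + seg_frame$a * 1.5 * st +
              2.3 * (cos(ang) * seg_frame$u + sin(ang) * seg_frame$v) -
              2.3 * seg_frame$u
          },
          E = seg_frame$origin + seg_frame$a * step * st +
            rnorm(3, 0, 0.3),
          L = xyz[t - 1, ] + step * unit())
        if (ok_point(cand, xyz, t)) {
          xyz[t, ] <- cand
          seg_t <- st
          placed <- TRUE
          break
        }
      }
      if (!placed) { dead <- TRUE; break }
      t <- t + 1L
    }
    if (!dead) return(list(xyz = xyz, type = type))
  }
  stop("generation error: chain growth infeasible after ", max_restarts,
       " restarts (n = ", n, ")")
}

# Coupled-pair plan: a greedy matching over spatially close pairs (closest
# first, each position in at most one pair), with a coupling-strength
# factor that decays with distance -- contacts coevolve strongly,
# near-contacts weakly, distant pairs not at all.
#' @keywords internal
#' @noRd
contact_couplings <- function(coords, threshold = 8, min_separation = 6,
                              far_threshold = 12) {
  D <- pairwise_distances(coords)
  n <- nrow(D)
  cand <- which(upper.tri(D) & D < far_threshold &
                  abs(outer(seq_len(n), seq_len(n), "-")) >= min_separation,
                arr.ind = TRUE)
  if (nrow(cand) == 0)
    return(list(pairs = cand, d = numeric(0), factor = numeric(0)))
  cand <- cand[order(D[cand]), , drop = FALSE]
  used <- logical(n)
  keep <- logical(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    i <- cand[r, 1]; k <- cand[r, 2]
    if (!used[i] && !used[k]) {
      keep[r] <- TRUE
      used[i] <- TRUE; used[k] <- TRUE
    }
  }
  cand <- cand[keep, , drop = FALSE]
  d <- D[cand]
  factor <- ifelse(d < threshold, 1, ifelse(d < threshold + 2, 0.6, 0.3))
  list(pairs = cand, d = d, factor = factor)
}

#' Generate one synthetic family pair with a planted true alignment
#'
#' A parent scaffold (secondary-structure segments, confined self-avoiding
#' chain) and a parent consensus (segment-class pools with a
#' hydrophobic-burial tilt) are drawn.  The two families each apply (i)
#' consensus divergence at rate `divergence`, mostly class-preserving
#' (emulating remote homology: profiles diverge but local-structure
#' propensities persist); (ii) an indel plan at rate `indel_rate`
#' (deletions and short insertions, defining the true alignment); and (iii)
#' per-sequence sampling in which each coupled pair (a greedy matching over
#' spatially close position pairs, coupling decaying with distance) adopts
#' one of its two amino-acid pair options with probability equal to its
#' coupling strength.  The pair options are family-specific while the set
#' of coupled positions follows the shared scaffold: remote homologs
#' conserve the interaction pattern, not the interacting residues.
#' Uncoupled positions mutate independently at `mutation_rate`, and cells
#' are gapped at `gap_rate`.
#'
#' @param n_parent Parent chain length (>= 10; default 60).
#' @param n_seqs Sequences per family (>= 5; default 256, the family depth
#'   at which mutual information becomes a reliable coevolution signal).
#' @param indel_rate Total per-position indel probability (default 0.1).
#' @param coupling_strength Probability a coupled pair adopts a pair option
#'   (default 0.6; 0 plants no covariation signal).
#' @param mutation_rate Per-sequence substitution rate off the family
#'   consensus (default 0.25).
#' @param seed RNG seed; the output is byte-identical for a fixed seed.
#' @param divergence Consensus substitution rate between the two families
#'   (default 0.5, i.e. roughly 25-30 percent consensus identity, the
#'   remote-homology regime).
#' @param gap_rate Per-cell gap probability in the MSAs (default 0.02).
#' @param contact_threshold Contact distance in Angstrom (default 8).
#' @param min_separation Minimum contact sequence separation (default 6).
#' @param structure_noise Per-coordinate Gaussian noise (Angstrom) applied
#'   to each family's copy of the parent scaffold (default 0.7: remote
#'   homologs deviate structurally by a few Angstrom).
#' @return Object of class `synthetic_pair`: `msa_T`, `msa_S`, `coords_T`,
#'   `coords_S`, `true_alignment` (pairs matrix), `contacts_parent`,
#'   `contacts_T`, `contacts_S`, `params`.
#' @export
generate_pair <- function(n_parent = 60, n_seqs = 256, indel_rate = 0.1,
                          coupling_strength = 0.6, mutation_rate = 0.25,
                          seed = 1, divergence = 0.5, gap_rate = 0.02,
                          contact_threshold = 8, min_separation = 6,
                          structure_noise = 0.7) {
  stopifnot(n_parent >= 10, n_seqs >= 5)
  # residue-class propensities by secondary-structure segment type: local
  # geometry is readable from the profile context, as in real families
  POOL <- list(H = c("A", "L", "M", "E", "Q", "K", "R", "H"),
               E = c("V", "I", "F", "Y", "W", "T", "C"),
               L = c("G", "P", "N", "D", "S"))
  HYDRO <- c("A", "V", "L", "I", "F", "M", "W", "C")
  withr::with_seed(seed, {
    scaffold <- gen_scaffold(n_parent)
    coords0 <- scaffold$xyz
    stype <- scaffold$type
    coup <- contact_couplings(coords0, contact_threshold, min_separation)
    contacts <- coup$pairs[coup$factor == 1, , drop = FALSE]
    # hydrophobic-core tilt: buried positions (small radius) prefer the
    # hydrophobic members of their segment pool, surface ones the polar
    # members -- pairwise distance is partly readable from burial
    centre <- colMeans(coords0)
    radius <- sqrt(rowSums(sweep(coords0, 2, centre)^2))
    burial <- 1 - (rank(radius) - 1) / (n_parent - 1) # 1 = most buried
    pick_letter <- function(p) {
      pool <- POOL[[stype[p]]]
      wgt <- exp(2.5 * (burial[p] - 0.5) * ifelse(pool %in% HYDRO, 1, -1))
      sample(pool, 1, prob = wgt)
    }
    consensus0 <- vapply(seq_len(n_parent), pick_letter, character(1))

    make_family <- function() {
      # indel plan
      repeat {
        del <- runif(n_parent) < indel_rate / 2
        if (sum(!del) >= 10) break
      }
      ins_after <- ifelse(runif(n_parent + 1) < indel_rate / 2,
                          1 + rgeom(n_parent + 1, 0.5), 0)
      # family position list: 0 = insertion, >0 = parent index
      src <- integer(0)
      if (ins_after[1] > 0) src <- rep(0L, ins_after[1])
      for (p in seq_len(n_parent)) {
        if (!del[p]) src <- c(src, p)
        if (ins_after[p + 1] > 0) src <- c(src, rep(0L, ins_after[p + 1]))
      }
      nf <- length(src)
      # consensus with divergence; insertions random
      cons <- character(nf)
      for (q in seq_len(nf)) {
        if (src[q] == 0L) {
          cons[q] <- sample(POOL$L, 1) # insertions are surface loops
        } else if (runif(1) < divergence) {
          # substitutions mostly preserve the segment-class propensity and
          # the burial preference
          if (runif(1) < 0.8) {
            pool <- POOL[[stype[src[q]]]]
            wgt <- exp(2.5 * (burial[src[q]] - 0.5) *
                         ifelse(pool %in% HYDRO, 1, -1))
            wgt <- wgt[pool != consensus0[src[q]]]
            pool <- setdiff(pool, consensus0[src[q]])
            cons[q] <- sample(pool, 1, prob = wgt)
          } else {
            cons[q] <- sample(setdiff(AA, consensus0[src[q]]), 1)
          }
        } else {
          cons[q] <- consensus0[src[q]]
        }
      }
      # coordinates: perturbed parent, insertions hang off the neighbour
      xyz <- matrix(NA_real_, nf, 3)
      for (q in seq_len(nf)) {
        if (src[q] > 0L) {
          xyz[q, ] <- coords0[src[q], ] + rnorm(3, 0, structure_noise)
        } else {
          anchor <- if (q > 1) xyz[q - 1, ] else coords0[1, ]
          v <- rnorm(3)
          xyz[q, ] <- anchor + 3.8 * v / sqrt(sum(v^2))
        }
      }
      # coupled pairs surviving in this family, with their decay factors
      fam_idx <- match(seq_len(n_parent), src)
      keep <- which(!is.na(fam_idx[coup$pairs[, 1]]) &
                      !is.na(fam_idx[coup$pairs[, 2]]))
      cpairs <- cbind(fam_idx[coup$pairs[keep, 1]],
                      fam_idx[coup$pairs[keep, 2]])
      cstrength <- coupling_strength * coup$factor[keep]
      # family-specific two-option rule per surviving coupled pair: remote
      # homologs conserve the interaction pattern (which pairs covary, set
      # by the shared scaffold), not the residue identities
      rule <- lapply(seq_len(nrow(cpairs)), function(r) {
        q1 <- cpairs[r, 1]; q2 <- cpairs[r, 2]
        a1 <- cons[q1]; b1 <- cons[q2]
        # alternate letters stay inside the segment pool, so covariation
        # does not erase the local-structure signal in the profiles
        pool1 <- if (src[q1] > 0) POOL[[stype[src[q1]]]] else POOL$L
        pool2 <- if (src[q2] > 0) POOL[[stype[src[q2]]]] else POOL$L
        p1 <- setdiff(pool1, a1); if (length(p1) == 0) p1 <- setdiff(AA, a1)
        p2 <- setdiff(pool2, b1); if (length(p2) == 0) p2 <- setdiff(AA, b1)
        list(A = c(a1, b1), B = c(sample(p1, 1), sample(p2, 1)))
      })
      # sample sequences: each position draws its family-consensus letter
      # with probability 1 - mutation_rate (else a uniform random residue);
      # each coupled pair then adopts one of its two amino-acid pair
      # options, with probability equal to its coupling strength
      chars <- matrix("", n_seqs, nf)
      for (s in seq_len(n_seqs)) {
        row <- ifelse(runif(nf) < mutation_rate,
                      sample(AA, nf, replace = TRUE), cons)
        for (ci in seq_len(nrow(cpairs))) {
          if (runif(1) < cstrength[ci]) {
            opt <- rule[[ci]][[if (runif(1) < 0.5) "A" else "B"]]
            row[cpairs[ci, 1]] <- opt[1]
            row[cpairs[ci, 2]] <- opt[2]
          }
        }
        chars[s, ] <- row
      }
      chars[matrix(runif(n_seqs * nf) < gap_rate, n_seqs, nf)] <- GAP
      seqs <- apply(chars, 1, paste0, collapse = "")
      seqs[1] <- paste0(cons, collapse = "") # query = consensus
      list(msa = new_msa(seqs), coords = xyz, src = src,
           contacts = cpairs[coup$factor[keep] == 1, , drop = FALSE],
           rule_idx = keep)
    }

    famT <- make_family()
    famS <- make_family()
    mapT <- match(seq_len(n_parent), famT$src)
    mapS <- match(seq_len(n_parent), famS$src)
    both <- which(!is.na(mapT) & !is.na(mapS))
    truth <- cbind(mapT[both], mapS[both])
    colnames(truth) <- c("i", "j")

    structure(list(msa_T = famT$msa, msa_S = famS$msa,
                   coords_T = famT$coords, coords_S = famS$coords,
                   segments_parent = stype,
                   true_alignment = truth,
                   contacts_parent = contacts,
                   contacts_T = famT$contacts, contacts_S = famS$contacts,
                   params = list(n_parent = n_parent, n_seqs = n_seqs,
                                 indel_rate = indel_rate,
                                 coupling_strength = coupling_strength,
                                 mutation_rate = mutation_rate,
                                 divergence = divergence,
                                 gap_rate = gap_rate,
                                 contact_threshold = contact_threshold,
                                 min_separation = min_separation,
                                 structure_noise = structure_noise,
                                 seed = seed)),
              class = "synthetic_pair")
  })
}

#' @export
print.synthetic_pair <- function(x, ...) {
  cat("Synthetic family pair:", x$msa_T$ncol, "x", x$msa_S$ncol, "columns,",
      nrow(x$true_alignment), "true pairs,",
      nrow(x$contacts_parent), "coupled contacts\n")
  invisible(x)
}

#' Generate a seeded synthetic benchmark
#'
#' Per-pair seeds are derived from the master seed, so streams are
#' independent and the manifest suffices to regenerate every pair exactly.
#'
#' @param n_pairs Number of family pairs.
#' @param params Named list overriding [generate_pair()] defaults;
#'   `len_range` (default `c(45, 78)`) sets the parent-length range.
#' @param seed Master seed.
#' @return List with `pairs` (list of `synthetic_pair`) and `manifest`
#'   (data.frame of all per-pair parameters).
#' @export
generate_benchmark <- function(n_pairs, params = list(), seed = 42) {
  len_range <- params$len_range %||% c(45, 78)
  params$len_range <- NULL
  fixed_len <- params$n_parent
  params$n_parent <- NULL
  withr::with_seed(seed, {
    pair_seeds <- sample.int(2^31 - 2, n_pairs)
    lens <- if (is.null(fixed_len))
      sample(seq(len_range[1], len_range[2]), n_pairs, replace = TRUE) else
      rep(fixed_len, n_pairs)
  })
  pairs <- vector("list", n_pairs)
  for (p in seq_len(n_pairs)) {
    args <- c(list(n_parent = lens[p], seed = pair_seeds[p]), params)
    pairs[[p]] <- do.call(generate_pair, args)
  }
  manifest <- do.call(rbind, lapply(seq_len(n_pairs), function(p) {
    data.frame(pair = p, seed = pair_seeds[p], n_parent = lens[p],
               ncol_T = pairs[[p]]$msa_T$ncol, ncol_S = pairs[[p]]$msa_S$ncol,
               n_true = nrow(pairs[[p]]$true_alignment))
  }))
  list(pairs = pairs, manifest = manifest, master_seed = seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build MRF models for a list of synthetic pairs
#'
#' @param pairs List of `synthetic_pair`s.
#' @param ... Passed to [build_mrf()].
#' @return The list with `mrf_T` / `mrf_S` elements added to each pair.
#' @export
build_benchmark_mrfs <- function(pairs, ...) {
  lapply(pairs, function(sp) {
    sp$mrf_T <- build_mrf(sp$msa_T, ...)
    sp$mrf_S <- build_mrf(sp$msa_S, ...)
    sp
  })
}

#' Mean MI on planted contact pairs versus background pairs
#'
#' Generation-time sanity summary for one family of a synthetic pair.
#'
#' @param sp A `synthetic_pair`.
#' @param family `"T"` or `"S"`.
#' @param pc Pseudocount for the MI computation.
#' @return List with `mi_contact`, `mi_background`.
#' @export
contact_mi_summary <- function(sp, family = c("T", "S"), pc = 1) {
  family <- match.arg(family)
  msa <- if (family == "T") sp$msa_T else sp$msa_S
  cp <- if (family == "T") sp$contacts_T else sp$contacts_S
  mi <- mutual_information(msa, pseudocount_weight = pc)
  n <- msa$ncol
  s <- sp$params$min_separation
  mask <- abs(outer(seq_len(n), seq_len(n), "-")) >= s & upper.tri(mi)
  is_contact <- matrix(FALSE, n, n)
  if (nrow(cp) > 0) {
    is_contact[cp] <- TRUE
    is_contact[cp[, c(2, 1), drop = FALSE]] <- TRUE
  }
  list(mi_contact = mean(mi[mask & is_contact]),
       mi_background = mean(mi[mask & !is_contact]))
}

#' Write a synthetic pair as standard-format fixture files
#'
#' Aligned FASTA for the two MSAs, CA-trace PDB for the two scaffolds and a
#' TSV of the true alignment.  All files are tagged as synthetic by name.
#'
#' @param sp A `synthetic_pair`.
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix (default "synthetic").
#' @return Invisibly, the vector of file paths.
#' @export
write_synthetic_fixture <- function(sp, dir, prefix = "synthetic") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(prefix, c("_T.fasta", "_S.fasta",
                                           "_T.pdb", "_S.pdb",
                                           "_true_alignment.tsv")))
  write_msa(sp$msa_T, paths[1])
  write_msa(sp$msa_S, paths[2])
  write_pdb(sp$coords_T, paths[3])
  write_pdb(sp$coords_S, paths[4])
  write.table(as.data.frame(sp$true_alignment), paths[5], sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(paths)
}
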