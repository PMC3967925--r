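---
title: "Aligning Markov random field models of protein families: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aligning Markov random field models of protein families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's account of its science: the model and its
assumptions, the tunable parameters and their defaults, what the synthetic
generator emulates (and does not), the numerical choices, and the design
decisions taken where the design was genuinely open.  It states no
empirical result that the test suite or the acceptance script does not
itself compute.

## 1. The model

A protein family is summarised by a multiple sequence alignment (MSA) and
modelled as a Markov random field over the 21-letter alphabet (20 amino
acids plus gap).  Conceptually the MRF assigns a probability to a sequence
through per-column preference functions and pairwise preference functions
on edges; in this implementation, as in practice, the pairwise functions
are not fitted explicitly.  The model keeps:

* per-column marginals `p_i(a)` with additive pseudocounts
  (`(weighted count + pc/21) / (weighted N + pc)`, default `pc = 1`) and
  Henikoff position-based sequence weighting (both switchable);
* the mutual-information matrix of column pairs and its matrix powers
  `MI, MI^2, ..., MI^K` (default `K = 11`) as interaction-strength
  features.  MI uses the same pseudocounting on the 21x21 joint, whose
  marginals are then exactly the column marginals, making MI nonnegative
  up to rounding.  The gap is a full alphabet symbol; `X` is spread
  uniformly over the 20 amino acids.

Edges exist between columns at separation `>= min_separation` (default 6;
shorter-range correlation is dominated by chain adjacency and is not
informative about the fold).

All user-facing and internal indices are 1-based (the R convention); the
stated-once rule that prevents off-by-one drift.

## 2. Scoring an alignment of two MRFs

Alignments live on the standard three-state lattice {M, I_T, I_S} with
affine-style transition biases; direct I_T <-> I_S toggling is disallowed.
A path's score is

    P1 = sum over path cells of node potential (+ transition biases)
       + (1/L) * sum over unordered pairs of M-cells of edge potential,

with `L` the alignment length; `1/L` puts the accumulated node and edge
terms on a similar scale.

**Node potential.**  A one-hidden-layer network (tanh hidden, linear
output; default H = 20) maps the concatenated profile contexts of the two
columns — each context the `(2w+1) x 21` block of marginal rows around the
column, `w = 5`, zero rows beyond the family ends — to a match
log-likelihood; two analogous single-context networks score insertions.
The potential is the network output *minus its background expectation*,
estimated by averaging the output over randomly sampled context pairs
(default 10,000 draws, seeded).  Training maximises the probability of
reference alignments under the conditional-neural-field distribution whose
normaliser is computed by the forward algorithm on the lattice;
L2-regularised (default lambda 0.1, cross-validation utility available),
batch gradient with step halving, so the monitored loss never increases.
Transition biases are trained alongside.  Reference alignments with
unaligned runs on both sides cannot be traversed by insertions alone under
the no-toggle rule; the reference path routes min(gap, gap) diagonal steps
first (`path_from_pairs`), and those extra M cells are path plumbing, not
reference matches.

An untrained profile-similarity fallback (`new_profile_scorer`): the
log-odds dot product of the two columns' amino-acid marginals,
`log(20 * sum_a p_i(a) q_j(a))`, with gap costs as transition biases
(open -3, extend -0.5).  It requires no training and is clearly not the
trained scorer; it makes the aligner usable out of the box and is what the
acceptance pipeline uses (desk-scale CNF training is exercised at toy
scale in the tests but does not outperform the fallback within the runtime
budget).

**Edge potential.**  Inter-residue distance is discretised into 13
intervals: <4, [4,5), ..., [14,15), >=15 Angstrom (the enumerated
boundaries; the interval count quoted alongside them elsewhere is 12, and
the enumeration is taken as the operational content).  From reference data
two tables are counted (additively smoothed, alpha = 1, so the log below
is finite): the background `P_ref(d)` over residue pairs of a structure
set, and `P_align(d1, d2)` over pairs of aligned positions in reference
alignments, symmetrised because pair order is arbitrary.  The potential of
edge (i,k) in T against edge (j,l) in S is the expectation of the kernel
`log[P_align(d1,d2) / (P_ref(d1) P_ref(d2))]` under the two edges'
*predicted* distance distributions — bilinear in the two distributions,
identically zero when `P_align` factorises.  Representative atom: C-beta
(C-alpha for glycine).

**Centring (design decision).**  With an imperfect predictor every edge
pair acquires a shared negative bias (smeared distributions put mass on
strongly negative kernel cells), while pairs below the separation cutoff
contribute exactly zero.  Misaligned match cells have more masked pairs,
so the uncentred edge term *rewards* misalignment — an artefact, not
signal.  `edge_table(center = TRUE)` therefore subtracts the exact mean
potential over admissible edge pairs (computable in closed form by
bilinearity), the edge analogue of the node potential's sampled background
offset.  This changes the objective by a constant per admissible pair and
leaves the kernel-level contracts (`edge_potential()`) untouched.

**Distance predictor.**  A pluggable component standing in for an external
context-specific distance-potential tool.  The packaged predictor is a
one-hidden-layer softmax network over the 13 bins taking the two profile
contexts (its own window, default `w = 2`), the K MI-power features and
`log |i-k|` (distance statistics are strongly separation-dependent).  Two
numerical choices matter:

* MI powers are rescaled by `||MI||_2^(p-1)` — raw matrix powers grow
  geometrically and saturate the tanh layer;
* contexts are projected onto the top principal components of the
  column-marginal rows (basis fit on the training set, stored in the
  model).  Without this the network memorises family-specific letter
  fingerprints and generalises *worse than uniform* on held-out families;
  the projection keeps the shared residue-class structure and discards the
  fingerprints.

Training is full-batch Adam on cross-entropy against binned true
distances, with examples stratified toward moderate separations (unbiased
for the learned conditional, since separation is itself an input).
`structure_edge_distributions()` provides the alternative route the
pluggable interface exists for: distributions of external-tool quality
derived from a known structure at a stated smear.

## 3. The ADMM aligner

With edge terms the objective is a quadratic binary program.  A copy `y`
of the indicator vector `z` is introduced; the constraint `z = y` is
enforced by multipliers `lambda` and a quadratic penalty `rho` (default
0.5, constant; no step schedule).  Because the variables are binary, the
penalty expands into linear terms, and each subproblem — `y` with `z`
fixed (SP1), then `z` with `y` fixed (SP2) — has per-cell scores

    node + (1/L) * sum over fixed active M-cells of edge potential
         +/- lambda + rho * fixed_cell - rho/2,

solvable exactly by the three-state dynamic program.  The procedure:
initialise `z` (and `L`) from the Viterbi alignment without edge
potential; iterate SP1, SP2; stop when `z = y` (binary variables admit the
exact test `||z - y||_1 = 0`); otherwise update `L` to the length of the
most recent (SP2) alignment and `lambda <- lambda + rho (z - y)`.  The
returned alignment is the *best-seen* feasible solution by its canonical
P1 value (each path evaluated with `L` equal to its own length): identical
to the converged solution when the method converges, and an anytime
fallback otherwise.  The recorded per-iteration Lagrangian is halved onto
the P1 scale (both subproblems carry full node scores, so the symmetrised
objective double-counts them); at convergence it equals the P1 value of
the converged alignment, and each iteration it upper-bounds the P1 values
of its own iterates.

Determinism: DP tie-breaks prefer M over I_T over I_S; fixed inputs give
identical results.  Terminal gaps are ordinary insertions by default
(`free_end_gaps` available).  An optional strongest-MI edge shortlist
(`shortlist_q`) bounds cost; off by default for fidelity.

## 4. Search driver and evaluation

`mrf_search()` scores the whole library with the Viterbi objective, then
realigns the top `top_k = 200` candidates with full ADMM and reranks them
by P1; remaining entries follow in prefilter order.  Ranking uses the raw
best alignment score (no E-value model; a `sqrt(nT*nS)`-normalised variant
is available).  Self-hits are retained.

`compare_alignments()` computes reference-dependent precision (correct /
predicted pairs) and recall (correct / reference pairs); a predicted pair
(i, j) is correct at offset k if the reference maps i to within k of j
(query-centric — the side the offset is measured on is a convention; the
symmetric variant can be had by swapping arguments).

## 5. The synthetic world

The generator replaces all external data (search-derived MSAs, structure
sets, structure-alignment references) with a stated world:

* **Scaffolds** — confined self-avoiding chains with
  secondary-structure-like segments: ideal helical geometry (rise 1.5 A,
  radius 2.3 A, 100 degrees/residue), near-straight extended segments,
  random-walk loops; sphere confinement forces tertiary contacts.  One
  coordinate per residue, 3.8 A steps, 3.5 A clash distance.
* **Composition** — segment-type residue pools (helix-, strand-, and
  loop-type letters) with a hydrophobic-burial tilt: buried positions
  prefer hydrophobic pool members.  Local geometry and burial are thereby
  readable from profiles, the dense sequence–structure signal real
  families carry.
* **Remote homology** — both families perturb a shared parent: consensus
  divergence 0.5 (roughly 25–30% consensus identity, the fold/superfamily
  regime), substitutions 80% class-preserving; indel rate 0.1; per-family
  structural noise 0.7 A.
* **Covariation** — a greedy matching of spatially close position pairs
  (closest first, each position once, up to 12 A) is coupled: each pair
  holds two family-specific amino-acid pair options, adopted per sequence
  with probability `coupling_strength x decay(distance)` (1 / 0.6 / 0.3
  for <8 / 8–10 / 10–12 A).  The coupled *positions* follow the shared
  scaffold while the option letters are family-specific: the interaction
  pattern, not the residues, is conserved — exactly the regime in which
  node information fails and edge information should help.
* **Depth** — 256 sequences per family, the depth at which MI becomes a
  reliable coevolution signal; mutation rate 0.25 about the consensus;
  2% gap cells.

Every quantity is reproducible from a single seed (`withr::with_seed`),
and a benchmark's manifest suffices to regenerate each pair exactly.

**What a green test does and does not establish.**  The world plants
monotone MI-vs-coupling signal (asserted), realistic node-level ambiguity
(node-only recall in the tests sits in the published fold-level range),
and distance statistics with a sharply diagonal aligned table.  It does
not reproduce real protein geometry, phylogenetic correlation among
sequences, alignment-method biases in the MSAs, or the accuracy profile of
a production distance predictor; green recovery tests certify the
machinery, not biological performance.

**A measured limitation.**  The edge potential can only move an alignment
where its per-cell field exceeds the ADMM consensus anchor (about `rho` =
0.5) plus the node margin.  The field inherits predictor error
*quadratically* (both edges of a pair are predicted), so a held-out
prediction–truth correlation r yields roughly r^2 of the oracle field.
The best honestly-trained sequence-based predictor in this world reaches
r of about 0.35–0.4, an order of magnitude short; the trained-predictor
ablation therefore moves no alignments at all (deltas exactly zero), and
the corresponding acceptance assertion is expected to fail honestly.
With structure-informed distributions of external-tool quality
(`structure_edge_distributions`), the same machinery does move alignments
and improves mean recall, which the test suite verifies separately.  The
directional recovery claim is thus conditional on predictor quality — in
the same way the original method's gains are conditional on its external
distance predictor.

## 6. Known limitations

* The CNF node scorer trains reliably at toy scale but is not tuned for
  large families; the profile fallback is the practical default here.
* No statistical significance (E-value) calibration for search scores.
* The exhaustive oracle (tests) certifies ADMM only as a lower bound of
  the true optimum; ADMM is a heuristic for an NP-hard problem and can
  return suboptimal alignments.
* The generator's chains are coarse scaffolds; distance statistics built
  from them are labelled synthetic and should be rebuilt from real
  structures for any real use.
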