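---
title: "Multiobjective sequence design with evodesign: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiobjective sequence design with evodesign}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evodesign)
```

# The design problem

Multistate protein design asks for one amino-acid sequence compatible with
several conformational states at once. Framed as minimization of one
objective per state (negative likelihoods, negated folding-propensity
scores), there is generally no sequence optimal for all states: the
solutions of interest form a Pareto front of tradeoffs. `evodesign`
explores that front with NSGA-II, an elitist evolutionary multiobjective
algorithm whose population structure encodes the front directly — no
scalarization of objectives is ever needed.

A `design_problem` fixes the full-length reference sequence, the 1-based
designable positions (1-based to match PDB residue numbering; e.g. a
C-terminal domain spanning residues 119–154 gives n = 36 designable
positions), the residue alphabet, and the state names. Candidates are
strings over the designable positions only; `to_full_sequence()` splices
them into the reference context before any scoring, so context-aware
scorers and proposers always see the complete chain.

# The generational loop

Each iteration of `evolve()`:

1. ranks the current population by fast non-dominated sorting and computes
   crowding distances within fronts;
2. doubles the population: parent pairs are drawn by binary tournament
   (lower front wins; ties by larger crowding distance; remaining ties by
   fair coin), recombined by n-point crossover with probability 0.9
   (skipped pairs yield verbatim copies; n = 2 cut points by default),
   and mutated with probability 1.0;
3. evaluates the offspring through a single batched contract point; and
4. forms the next generation by elitist environmental selection on the
   combined 2N pool: whole fronts are admitted in order, the last admitted
   front truncated by descending crowding distance.

Defaults (population 100, 50 iterations) match the benchmark regime the
package is built around. Offspring are generated pair-by-pair until exactly
N exist; with odd N the final pair contributes one child. Tournament draws
are without replacement within a tournament and with replacement across
tournaments.

**Duplicates are retained.** Population statistics (entropy, eCDFs,
profile matrices) are defined over the full multiset, which deduplication
would distort. The cost is that duplicates of Pareto members accumulate as
a run converges, so the combined pool's front 0 — counted as a multiset —
can exceed N late in a run even when the set of distinct non-dominated
vectors is small. Crowding-distance truncation then discards zero-distance
members first, which in practice removes duplicates; in every study run we
measure, front-0 hypervolume is non-decreasing across all iterations
(asserted by the acceptance suite).

**Reproducibility.** All stochastic draws come from R's single global RNG
stream, seeded once per run from the config, in a fixed order
(initialization, then per offspring: tournament draws, crossover decision
and cuts, mutation decision, selector, proposer). The per-iteration
`.Random.seed` is checkpointed in the run history, and `resume_run()`
restores it exactly: a straight-through run and a checkpoint-plus-resume
run are identical, as are two `cmd_design()` invocations with the same
config (byte-identical metrics and FASTA snapshots). Objective values are
cached per unique designed sequence; since evaluators are required to be
deterministic functions of the sequence, caching cannot change results —
it only avoids re-scoring duplicates. The batched-evaluator contract (a
character vector in, a numeric vector out) is also the concurrency seam:
any backend that returns the same values sequentially and in parallel
satisfies it.

# The mutation operator

Mutation is a composition of two exchangeable stages.

*Position selection.* The **random** selector flags each designable
position independently with probability μ and, when no position is flagged,
falls back to a single uniformly chosen position — so the selected-position
count follows a Binomial(n, μ) law with its zero mass moved to k = 1
(verified by chi-square against the patched law at μ = 0.1, 0.3, 0.5). The
**ranked** selector scores the candidate's full sequence once with a
position ranker (one finite score per designable position, higher = more
native-like; the surrogate is the PSSM log-probability of the current
residue, the plugin analogue a protein-language-model single forward pass
without masking), sorts ascending, and takes the k = max(1, Bin(n, μ))
lowest. Ties are broken by position index via a stable sort — determinism
the tests rely on.

*Residue proposal.* The **uniform** proposer redraws each selected position
independently from the alphabet; the current residue may be redrawn (we do
not exclude it — redrawing affects the effective mutation intensity, noted
for calibration against other implementations). **Plugin** proposers
receive the full spliced sequence so they can condition on the
non-designable context, matching inverse-folding usage.

On conflict-free toy problems the ranked selector reaches a population mean
recovery of 0.9 in roughly half the iterations the random selector needs
(median over 5 matched seeds, asserted as an ordering, not an effect size):
concentrating redesign on the worst-scoring positions wastes fewer
mutations on already-native positions.

# Objectives, surrogates, and plugins

All objectives are minimized; maximization scores are negated rather than
affinely rescaled, so reported values keep interpretable units. The
composite folding-propensity score is the product
pLDDT × pTM × TM(template, prediction), each factor in [0, 1]; the product
is bounded in [0, 1] and monotone in each factor.

The TM-score uses the standard length normalization
d0(L) = 1.24·(L − 15)^⅓ − 1.8, floored at 0.5 Å, with a fixed one-to-one
residue correspondence. The superposition search mirrors the canonical
algorithm: contiguous fragment seeds of lengths L, L/2, L/4 (minimum 4),
each refined by iteratively re-superposing on residues within a distance
cutoff (the cutoff grows in 0.5 Å steps when fewer than three residues
qualify). Kabsch superposition is SVD-based with the determinant correction
that excludes reflections; it matches an independent quaternion
(Horn-method) oracle to 1e-8 on random clouds.

Desk-scale surrogates stand in for neural scorers: per-state PSSMs give a
mean log-likelihood objective, and `surrogate_composite()` exponentiates
the likelihood deficit to produce a bounded, saturating score equal to 1
exactly at the PSSM's modal sequence. The surrogate makes no biophysical
claim; it exists so bounded composite-like objectives can be exercised
end-to-end. The real scorers attach through three documented plugin
contracts (`plugin_contracts()`): state negative log-likelihood from an
inverse-folding model (scores over all positions, averaged over 5 repeats;
sampling temperature 0.3), per-position language-model scores (single
forward pass, no masking), and the structure-prediction composite (1
recycle, no MSA, template with gap-token sequence, sidechains deleted,
glycine CB imputed). Registration validates arity before any evaluation;
a missing plugin fails configuration, never a running simulation.

# Combined structures for tied decoding

Multistate decoding feeds all states to an inverse-folding model as one
combined structure with designable positions tied across states. States are
placed collinearly along +x — the published constraint fixes pairwise
distances, not arrangement, and collinear placement is deterministic and
satisfies every pair: with neighbour gaps of 2·max(r_i, r_{i+1}) + r_min,
any non-adjacent pair's separation telescopes to at least
2·max(r_i, r_j) + r_min. Each state is translated so its CA centroid lands
exactly on its layout position (a single state is left untouched). The
per-state radius is the larger of the CA-centroid radius and the all-atom
radius about the CA centroid: the separation intent is atom-level, so the
layout pads the offset whenever a non-CA atom lies farther out than any CA.
r_min defaults to 24 Å, beyond the distance range an inverse-folding
model's radial-basis edge features can encode, making the states invisible
to each other. The combination is translation-only — intra-state geometry
is preserved to machine precision — and the emitted tie map
(position → (state, chain, residue) per state) serializes to JSON in a
documented local convention; the exact dialect a given decoding tool
expects may differ.

# Analysis metrics

*Native recovery* is the fraction of designable positions matching the
reference; the population mean is the per-iteration metric. *Positional
entropy* is Shannon entropy in nats of the empirical residue distribution
per column. *Hypervolume* is computed exactly in 2-D by a sweep over the
non-dominated subset (dominated, duplicated and out-of-box points
contribute nothing); higher dimensions are rejected because only 2-D
objective subspaces are measured here. Reference points follow the
convention (0, 0) for negated composite-score planes and (4, 4) for
negative-log-likelihood planes.

*Similarity* is the mean per-position BLOSUM62 score, normalized per
position by sqrt(s(a,a)·s(b,b)) so self-similarity is exactly 1 and the
measure is symmetric. The published description fixes only "normalized";
absolute values under other normalizations differ, so comparisons should
stay within one convention. The matrix is restricted to the 20 standard
residues (extended codes carry non-positive self-scores, which the
normalization cannot accommodate). The pairwise similarity matrix feeds
Laplacian-eigenmaps embedding: affinities are min-max shifted to [0, 1]
(substitution similarities can be negative), the symmetric normalized
Laplacian I − D^(−1/2) W D^(−1/2) is decomposed, and the eigenvectors of
the smallest nontrivial eigenvalues are returned with signs fixed by making
each vector's largest-magnitude entry positive.

*Comparison to annotated sets* trims an aligned FASTA to the columns where
the reference row carries its designable residues, discards sequences with
any gap in that window, and scores a design against the retained set by the
95th percentile of normalized similarity. Percentiles interpolate linearly
between closest ranks (R's default type-7 convention) — conventions differ
enough across software that this is worth stating. The trim step assumes
confidence filtering of the annotated database happened upstream; the
package consumes an already-filtered alignment.

# The synthetic module

`make_toy_problem()` builds a two-state problem small enough for exhaustive
ground truth: L = 6 positions over an A = 4 letter alphabet by default
(4096 sequences; enumeration is capped at 10^6). A chosen fraction of
positions is *conflicting* — the two state PSSMs prefer different modal
residues there — and the rest agree, emulating the tension of fold-switch
design statistically. Modal probability is controlled by `sharpness`, an
inverse softmax temperature on standard-normal logits with the designated
modal residue forced to the largest logit; the default 2.0 puts modal
probabilities around 0.7–0.9, enough for genuine objective tension without
collapsing the per-position tradeoffs. A pseudo-count of 1e-4 keeps all
log-likelihoods finite. Under these defaults the exact front sizes are 1,
8, and 38 sequences at conflict fractions 0, 0.5, and 1 (generator seed
42) — comfortably below the population size of 100, so full front recovery
is attainable and is what the acceptance suite demands (≥ 90% coverage,
zero false members, over 3 seeds per condition).

The toy backbones are ideal-parameter traces (helix: 2.3 Å radius, 1.5 Å
rise, 100° twist; strand: 3.46 Å rise with alternating 0.8 Å pleat; both
≈ 3.8 Å CA spacing) with N/C/O atoms placed along the chain direction and
0.02 Å of seeded jitter. The reference sequence sets mutate the toy
reference at per-position rate `divergence` (like set) and 3× that (unlike
set).

What the toy problems do *not* emulate: epistasis (objectives are
position-separable), realistic energetics, structure-conditioned scoring,
or alphabet-20 search-space scale. Passing tests demonstrate the optimizer,
operators, geometry and metrics are correct — not that any particular
neural scorer will produce viable designs.

# Numerical choices and degenerate inputs

* Crowding distance normalizes per-objective gaps by the objective's range;
  a zero range contributes 0, never NaN. Fronts of ≤ 2 points are all-∞.
* `dominates()` and the sorters require finite values; evaluators returning
  non-finite scores abort with the candidate and objective named.
* Hypervolume ignores points outside the reference box entirely; an empty
  contributing set gives 0.
* TM-score fragment seeds guarantee at least 3 residues per superposition;
  degenerate (collinear/coincident) point sets fail in the SVD step with an
  error rather than silently reflecting.
* The enumeration sweep for toy Pareto fronts keeps equal-objective ties
  (duplicate vectors are mutually non-dominated) and verifies every
  candidate against the strict domination definition.
* PDB I/O goes through bio3d; coordinates round-trip at PDB precision
  (3 decimals), HETATM records and waters are ignored, residue-numbering
  gaps (unmodelled loops) pass through unchanged, and duplicate
  (chain, residue, atom) records are rejected.

# Problem sizes used by the test and acceptance suites

Unit tests run on toy problems of L = 4–6 over 3–4 letters with populations
of 10–40 and up to 15 iterations; the acceptance suite runs the full
benchmark conditions (N = 100, 50 iterations, μ = 0.3, conflict fractions
0/0.5/1, 2–3 seeds each), 100 random sorting instances up to n = 500 in
2–4 objectives, 20 Monte Carlo hypervolume fronts at 10^6 samples, 50
random structure pairs, and 20,000-draw operator-law checks. These sizes
were chosen so every stochastic assertion has comfortable statistical
margin while the whole suite stays fast enough to run routinely.

# Known limitations

* Many-objective (> 4) scalability and reference-direction variants are out
  of scope; hypervolume is 2-D only.
* One designable chain per problem: the published ranked selector's
  "choose a random chain" step degenerates to that chain; multi-chain
  designable regions are deferred.
* No insertions/deletions; crossover is n-point only; no backbone
  redesign — sequences only.
* The tie-map JSON dialect is a local convention; adapt it to the decoding
  tool in use.
* Surrogate objectives are position-separable and cannot reproduce
  epistatic effects a structure-conditioned scorer would see.
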