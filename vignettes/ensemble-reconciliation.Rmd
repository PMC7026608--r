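---
title: "Reconciling RNA ensembles with sparse NOE data: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconciling RNA ensembles with sparse NOE data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(noetools)
```

This vignette is the package's own account of the science it implements:
the models, their assumptions, the tunable parameters and the design
choices made where the design was genuinely open. Every empirical number
quoted here is computed by the package's test suite or by
`scripts/acceptance.R`; nothing else is asserted.

## The NOE forward model

An NOE cross-peak between two protons reports cross-relaxation that decays
as the sixth power of their distance. Under the assumption that
conformational exchange is much slower than molecular tumbling — adopted
as-is; the package does not attempt relaxation-matrix back-calculation or
spin-diffusion corrections — the forward model for restraint $i$ in
snapshot $t$ is simply $f(d_{i,t}) = d_{i,t}^{-6}$, and what the experiment
bounds is the *ensemble average*:

$$\langle f(d_i)\rangle_w \;=\; \sum_{t=1}^{T} w_t\, f(d_{i,t})
\;\ge\; f(d_{i,\mathrm{exp}}).$$

Signal classes map to maximum distances strong = 3.6 Å, medium = 5.0 Å,
weak = 6.5 Å. Signals are carried in nm$^{-6}$ throughout so the error
scale of the reweighting step (below) needs no conversion; restraint files
give Ångström and are converted on load. Minimum-distance columns in
restraint files are parsed and discarded with a message: only the upper
bounds act as restraints. A ratio
$\langle f\rangle_w / f_\mathrm{exp} < 1$ flags a violation;
`violation_score()` aggregates shortfalls as
$\sum_i \max(0, 1 - \mathrm{ratio}_i)$. This aggregate is a package
decision (several conventions exist in the literature); the mode is
recorded in pipeline metadata so downstream consumers know which was used.

## Maximum-entropy reweighting with inequality restraints

Given prior snapshot weights (uniform for a plain trajectory), the
reweighted ensemble is the minimal-information perturbation that satisfies
every bound:

$$w_t \;\propto\; \mathrm{prior}_t\,
  \exp\!\Big(-\sum_i \lambda_i f(d_{i,t})\Big),\qquad \lambda_i \le 0,$$

with multipliers minimizing the convex dual
$\Gamma(\lambda) = \ln \sum_t \mathrm{prior}_t e^{-\sum_i \lambda_i f_{it}}
+ \sum_i \lambda_i f_{\mathrm{exp},i}
+ \tfrac{\sigma^2}{2}\sum_i \lambda_i^2$.
The sign constraint makes the restraints one-sided: a bound whose average
is already satisfied leaves the ensemble untouched ($\lambda_i = 0$), and
an active bound pulls its average up to exactly
$f_{\mathrm{exp},i} + \sigma^2\lambda_i$. The Gaussian error prior of
scale $\sigma$ (default **0.5 nm$^{-6}$**) absorbs experimental and
forward-model error; $\sigma = 0$ gives hard inequalities and is supported,
with divergence of the multipliers on infeasible data reported explicitly
rather than silently.

*Solver.* The functional form fixes the estimator but not the algorithm.
The dual Hessian is $\mathrm{Cov}_w(f_i, f_j) + \sigma^2 I$, positive
definite, so the package uses a projected Newton iteration with
backtracking line search, starting from $\lambda = 0$, with log-sum-exp
stabilization of the weight evaluation. Convergence is declared when the
Karush–Kuhn–Tucker residual of the dual gradient
$f_{\mathrm{exp},i} - \langle f_i\rangle_\lambda + \sigma^2\lambda_i$,
relative to $\max(1, \max_i f_{\mathrm{exp},i})$, falls below the
tolerance (default $10^{-8}$). On the planted fixtures used in the tests
this converges in well under twenty iterations.

*Diagnostics.* The normalized Kish effective sample size
$s = \langle w\rangle^2 / \langle w^2\rangle \in (0, 1]$ measures how much
of the ensemble survives reweighting ($s = 1$ for uniform weights, $1/T$
for a single surviving snapshot). `kish_trace()` recomputes it on snapshot
prefixes, the practical criterion for judging whether a simulation was run
long enough.

## Two-stage clustering

Interpreting a reweighted ensemble requires grouping snapshots into
conformational states. Two metrics are combined:

* **χ bitstring.** The glycosidic torsion (O4′–C1′–N9–C4 for purines,
  O4′–C1′–N1–C2 for pyrimidines) is computed in $[0°, 360°)$ — the range
  convention matters, because the *syn* window is the open interval
  $0 < \chi < 115°$ and high-anti conformations (≈270–300°) must fall in
  the *anti* class. Each snapshot maps to a bitstring (1 = syn per
  residue), and snapshots with different bitstrings are never clustered
  together. This prevents a rare syn structure from being averaged into an
  anti cluster, where its short intra-residue H–H1′ distance would
  dominate the cluster's $d^{-6}$ averages.
* **eRMSD.** Within each bitstring pre-cluster, pairs are compared with
  the base-centred eRMSD: each base carries a local frame in its
  six-membered ring, relative base positions are scaled anisotropically
  (x/5, y/5, z/3 Å — flattening the stacking direction), mapped through a
  smooth 4-vector $G$ with cutoff 2.4 in scaled units, and the metric is
  the RMS difference of all pairwise $G$ vectors. The constants are those
  of the metric's published definition, since the clustering cutoff
  **0.7** (below which two structures share an essentially identical
  base-base contact map) and the motif cutoff **1.0** are calibrated to
  them. Frame handedness is kept consistent across base families by
  ordering the ring atoms (C2, C6, C4) for purines and (C2, C4, C6) for
  pyrimidines. The implementation flattens each snapshot's $G$ tensor once,
  so a full pairwise matrix is a single Euclidean `dist()` call.

Clusters are extracted by repeatedly removing the **maximum-total-weight
clique** of the graph whose edges join snapshots with eRMSD < 0.7, so
every emitted cluster is homogeneous by construction: pairwise eRMSD below
the cutoff *and* identical χ pattern. The clique search is an exact
branch-and-bound (pre-clusters are modest after partitioning); a greedy
method is available behind a flag for very large graphs and is recorded in
the output. Determinism is guaranteed by resolving equal-weight ties
toward the lexicographically smallest member set; degenerate pre-clusters
whose members all carry zero weight after reweighting are emitted as
zero-population singletons. Clustering the pre-clusters jointly or
separately is equivalent — clusters cannot cross bitstring boundaries — so
the package works per pre-cluster for tractability. Cluster populations
$P_c = \sum_{t\in c} w_t$ sum to 1 over all clusters; clusters are
numbered 1, 2, … by descending population.

Per-cluster signal summaries use the weighted average
$\langle f(d_i)\rangle_{wc}$ and a weighted median defined as the largest
signal whose cumulative relative weight (that value and all lower ones)
stays strictly below 0.5 — when already the smallest value carries half
the mass, the smallest signal is returned. Comparing the two reveals
clusters whose average is dominated by a few extreme $d^{-6}$ values.

## Minimal cluster sets (maximum parsimony)

Clusters with population above a floor (default **0.002**) enter a grid
search: for growing set size $Y$, every subset of clusters and every
composition of weights $w'_y \in \{0.01, 0.02, \dots\}$, each at least
0.01 and summing to 1, is tested against
$\sum_y w'_y\langle f(d_i)\rangle_{wy} \ge f_{\mathrm{exp},i}$ (with
relative tolerance $10^{-12}$ at the boundary to absorb floating-point
noise). The smallest feasible $Y$ is reported with *all* feasible sets at
that size, ranked by $D_{KL}(w'\|P) = \sum_y w'_y \ln(w'_y/P_y)$ against
the clusters' original populations — deliberately *unrenormalized*, so a
set that inflates a tiny cluster pays for it; a renormalized variant is
available behind a flag for sensitivity analysis.

Exhaustive enumeration over all subsets times the full grid explodes
combinatorially, so the default mode first tests each subset by linear
feasibility over the continuous simplex with per-weight lower bound 0.01
(`boot::simplex`) and only enumerates the grid inside feasible subsets.
The relaxation can only over-admit — a grid point is a fortiori a
continuous point — so both modes return identical results; the test suite
verifies this equivalence on random instances, and a solver failure is
treated as "admit", never as "reject".

## Motif search

A contiguous fragment (for hairpin work, the nine central loop residues,
positions 11–19 of the 29-mer) is searched against a structure library by
sliding a window of equal length over every chain of every model.
Comparing *every* ensemble snapshot against *every* window is avoided via
the triangle inequality: the ensemble centroid (minimum mean-square eRMSD
to all members, ties to the lowest index) is scanned with threshold
$1.0 + \max_t \mathrm{eRMSD}(\mathrm{centroid}, t)$, which provably
retains every window within 1.0 of *any* member; a refinement pass over
the candidates then recovers the exact per-snapshot matches. Matches must
also reproduce the query's χ bitstring exactly and pass an O3′(i)–P(i+1)
connectivity check with a 2.0 Å cutoff — the covalent distance is ≈1.6 Å,
and the slack tolerates refinement noise without accepting chain breaks;
the published protocol checks connectivity without stating a number, so
the cutoff is a package choice. Multi-model library entries contribute
each model as a separate searchable structure, and the χ filter is
evaluated per model. Outputs are canonically sorted, so results do not
depend on library file ordering.

## The synthetic generator: what it emulates, and what not

`generate_toy_ensemble()` builds short RNA-like chains from an idealized
planar-base template via internal coordinates, carrying exactly the atoms
the implemented metrics touch: χ atoms, the base six-ring (for the eRMSD),
H1′/H6/H8 (for NOEs) and O3′/P (for connectivity). Metastable states are
planted as per-residue χ targets — *syn* ≈ 70°, *anti* ≈ 200°, jittered
uniformly by ±8° but kept 10° clear of the 115° boundary so
classification is never ambiguous — plus an optional backbone hinge bend
distinguishing states that share a χ pattern. Within-state coordinate
noise (0.06 Å) keeps same-state pairs well below eRMSD 0.7 while distinct
states sit well above; this separation is *verified post hoc* on every
generated ensemble and the ensemble is regenerated (up to 10 fresh draws)
if violated, so fixtures are valid by construction, not by hope. On this
template the intra-residue base-H to H1′ distance is ≈2.5–2.8 Å in *syn*
and ≈3.6–3.8 Å in *anti* — the physically meaningful contrast that makes
these NOEs χ-sensitive in real RNA.

`generate_mixture_restraints()` derives thresholds from a planted state
mixture as $f_\mathrm{exp} = (1-\mathrm{slack})\sum_s p_s\langle
f\rangle_s$ (slack default 0.02), which guarantees the planted mixture is
feasible while individual states generally are not: each state carries at
least one restraint — its unique syn residue, or the bent-backbone contact
pattern — that only it can satisfy, so the planted minimal cluster set is
exactly the set of state clusters. In class mode the implied distance is
snapped to the nearest class distance *not below* it; plain
nearest-rounding could tighten a threshold and silently break the planted
feasibility guarantee, which is why snapping is upward only.

What the toys do **not** emulate: sugar pucker and a full backbone,
base-pairing and stacking energetics, solvent, and the slow collective
rearrangements of a real trajectory. Passing the recovery tests therefore
shows that the estimator chain is correct and well-conditioned at
realistic signal contrasts — not that any particular force field or
sampling scheme is adequate for real RNA.

## Problem sizes and numerical choices

The validation suite uses 200-snapshot, 6-residue mixtures for the
recovery experiments (ten seeds, 2- and 3-state), 100 random graphs of up
to 10 nodes for the clique oracle, 10 random instances for the parsimony
mode-equivalence check, and 4-entry planted libraries for the motif
oracle — sizes at which every exhaustive oracle is itself exact and fast.
Key numerical decisions, collected: log-sum-exp weight evaluation and a
ridge of $10^{-12}\cdot\mathrm{scale}^2$ on the dual Hessian; strict
inequalities at every published cutoff (0.7, 1.0, the 115° syn window, the
0.5 median mass); eRMSD ties at the centroid resolved to the lowest index;
clique ties to the lexicographically smallest set; set ranking ties to the
lexicographic cluster-id string; the parsimony feasibility boundary at
relative $10^{-12}$.

## Known limitations

Modified nucleotides are rejected with a clear error rather than guessed
at. The deposited 29-mer hairpin entry (PDB 5LSN) distinguishes two *syn*
sub-states of its loop residue 16 (χ ≈ 100° vs ≈ 40°); both are `1` in the
bitstring and the package deliberately exposes raw χ values rather than
inventing a sub-state boundary the literature does not define. The
ensemble-level violation aggregate is one convention among several, and
labelled as such in output metadata. Finally, the motif search scans
libraries the user provides; it does not download or mirror the PDB.
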