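---
title: "Sequence-structure co-design of antibody CDR loops"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequence-structure co-design of antibody CDR loops}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

The six complementarity determining regions (CDRs) of an antibody —
three loops on the heavy chain, three on the light chain — mediate
antigen binding. Designing a CDR means choosing, for a fixed
antibody-antigen framework, both a loop *backbone geometry* and a loop
*amino-acid sequence* that are mutually consistent and complementary
to the antigen surface. `flexcdr` implements a residue-level
(C-alpha-only) co-design pipeline: a masked antibody-antigen complex
graph goes into an E(3)-equivariant graph neural network (EGNN) that
simultaneously predicts the masked loop's coordinates and a 20-way
amino-acid distribution per position.

The package covers the full method end to end at desk scale: PDB I/O
and CDR bookkeeping, the flexible-CDR anchor augmentation, graph
encoding, the equivariant stack with per-layer coordinate masking, the
complete training loss suite with layer-wise local losses, a seeded
training loop, evaluation metrics (CDR RMSD, Top-1/Top-3 amino-acid
recovery), sequence sampling and PDB assembly of designed chains, and
a generator of synthetic antibody-like complexes on which everything
can be exercised and trained in minutes on one CPU.

## Flexible CDR definition as data augmentation

Numbering schemes (Chothia, IMGT, North) disagree about exactly where
a CDR starts and ends; the residues flanking the loop (the *anchors*)
are to some degree a convention. The package turns this freedom into
augmentation: for a located CDR, both anchor positions are shifted by
every combination $(\delta_s, \delta_e) \in [-k, k]^2$, keeping a
variant whenever the shifted window is non-empty and both shifted
anchors still exist on the chain. An interior CDR therefore yields
$(2k+1)^2$ variants — 49 for $k = 3$, 121 for the study default
$k = 5$. Variants are *not* filtered for overlap with neighbouring
CDRs: only the chain-bounds retention rule applies, which matches the
stated $(2k+1)^2$ count. `build_pair_dataset()` combines location,
completeness checking, augmentation, and exclusion of CDR sequences
identical (or, for the strict split, >= 50% Needleman-Wunsch identity,
BLOSUM62-scored) to a held-out set.

CDR completeness is decided structurally rather than by author
numbering: residues missing from a deposited structure leave a chain
break, i.e. a consecutive C-alpha distance far above the ~3.8 A
peptide geometry, so any step above 4.5 A across the
anchor-to-anchor window marks the CDR incomplete. A numbering-gap
test would wrongly reject short loops, whose schemes legitimately
skip author numbers.

## Input encoding

A sample is one design chain (in full), its partner antibody chain if
paired (in full), and only those antigen residues within 16 A minimum
C-alpha distance of the design chain (inclusive boundary — the
convention is documented and tested). Chains are concatenated design
chain first. Each residue carries

* its C-alpha coordinate $x \in \mathbb{R}^3$ (Angstrom),
* a learnable amino-acid embedding (256-D by default; 21 rows: 20
  canonical types plus a MASK token), and
* a learnable 2-D chain-type embedding (antibody vs antigen),

giving the default 258-wide input feature. The CDR to be designed is
masked: its tokens become MASK and its coordinates are placed on
evenly spaced points along the line joining the two anchors,
$x_i = a + (b - a)\,i/(n+1)$ for $i = 1..n$. The spacing excludes the
anchor endpoints — anchors are real residues with real coordinates,
and the $n$ unknown residues occupy the interior fractions. The graph
connects every node to its 64 nearest neighbours (directed edges,
ties broken by lower index). Edges are computed once, on the masked
input coordinates, and held fixed across layers; recomputing the
topology per layer is exposed nowhere because the simpler fixed
topology is the default reading and keeps the pass deterministic.

## The equivariant stack

The model is $N$ sequential EGNN layers (16 by default) followed by a
two-layer feed-forward head that maps final node features to 20
amino-acid logits. Each layer computes edge messages
$m_{ij} = \phi_e(f_i, f_j, \lVert x_i - x_j \rVert^2)$, coordinate
updates along difference vectors
$x_i' = x_i + \tfrac{1}{|\mathcal{N}(i)|}\sum_j
\frac{x_i - x_j}{d_{ij} + 1}\,\phi_x(m_{ij})$, and a residual feature
update $f_i' = f_i + \phi_h(f_i, \sum_j m_{ij})$. Because features
depend on coordinates only through squared distances and coordinate
updates are linear combinations of difference vectors, features are
E(3)-invariant and coordinates E(3)-equivariant; the test suite
asserts this end to end under random rigid transforms at float64
(coordinates to 1e-3 A, logits to 1e-4).

After every layer the coordinate mask is applied:
$\tilde{x}^k = x^k \odot M + x^{\mathrm{input}} \odot (1 - M)$, with
$M_i = 1$ exactly on CDR residues. Non-CDR coordinates are therefore
pinned to the input *exactly*, at every depth — the suite checks this
bitwise.

Numerical choices worth recording:

* Squared distances enter the message network in nm^2 (i.e. scaled by
  0.01 from A^2) so edge inputs stay O(1); a pure units choice that
  leaves invariance untouched.
* The coordinate update normalises difference vectors by
  $d_{ij} + 1$, the standard stabilised variant.
* The 258-wide input embedding is linearly projected to the hidden
  width before layer 1.
* Initialisation is Gaussian with 1/sqrt(fan-in) scales; the last
  linear map of each coordinate head is down-scaled by 0.01 so early
  coordinate updates are small. All computation is in R doubles
  (float64).
* Activation is SiLU throughout.

No deep-learning framework is used: the forward pass caches its
intermediates and an analytic reverse-mode backward pass accumulates
parameter gradients, which the tests verify against central finite
differences (absolute agreement to ~1e-6 on O(1) gradients).

## The loss suite

All losses are *local*: they attach to every layer's output, not only
the last, which keeps gradients healthy in a deep stack.

* **RMSD loss** — mean over all $N$ layers of the CDR C-alpha RMSD
  against ground truth. Computed in the fixed complex frame with no
  superposition: the coordinate mask pins all non-CDR atoms, so
  predicted and true frames coincide by construction.
* **Repulsion loss** — for layers $5..N$, the mean over CDR x non-CDR
  residue pairs of $\max(\tau - d_{ij}, 0)$ with $\tau = 4.2$ A,
  averaged over those $N - 4$ layers. A clash hinge: zero beyond
  $\tau$, linear inside.
* **Neighbour loss** — for layers $5..N$, the mean absolute deviation
  between predicted and true consecutive C-alpha distances along the
  $N_{\mathrm{CDR}} + 1$ edges of the anchor-loop-anchor path
  (the denominator counts both anchor-adjacent edges, the only
  reading consistent with $N_{\mathrm{CDR}} + 1$).
* **Cross-entropy** — label-smoothed (0.1) 20-way CE of the shared
  head applied to each layer's features: on non-CDR residues for all
  layers, on CDR residues only for the last four (structure first,
  sequence once the structure is reasonable).

The total is $L = 10\,(L_{\mathrm{RMSD}} + L_{\mathrm{rep}} +
L_{\mathrm{nei}}) + (L_{\mathrm{CE,CDR}} + L_{\mathrm{CE,nonCDR}})$;
both composition identities are asserted exactly in the tests, and
every structural term is checked against naive double-loop oracles to
1e-6 on random fixtures.

Two boundary conventions: the layer ranges "after the 4th layer" mean
$\{5,\dots,N\}$; and a 4-layer model is accepted (the violation-loss
range is then empty and those terms are zero) because the desk-scale
recovery experiment uses exactly that depth. With fewer than 4 layers
the CDR cross-entropy range would be ill-defined, so
`model_config()` requires $N \ge 4$.

## Training, checkpointing, evaluation

Training is one CDR-antigen pair per step (batch size 1 — sample
lengths vary), Adam, gradient clipping off by default. The reference
learning rate of 1e-6 is the `train_config()` default, appropriate
for database-scale corpora; the synthetic desk-scale experiments in
this package use 2e-3, chosen once as a sensible rate for a
35k-parameter model on toy data. Validation runs every `val_every`
steps; the retained checkpoint is the best by validation Top-1
amino-acid recovery, tie-broken by validation RMSD ("accuracy of the
validation data" is ambiguous between the two, so both are logged and
the criterion is configurable). Runs are bit-reproducible given the
seed; non-finite losses abort with a diagnostic.

Evaluation mirrors the field's metrics: per CDR type, the mean
fixed-frame CDR C-alpha RMSD over samples, and Top-1/Top-3 amino-acid
recovery (AAR) pooled over residues (micro-average — "how many
predicted types match" — rather than a per-sample macro-average).
Top-$k$ ties are broken by the lower amino-acid index.

## What the synthetic complexes emulate — and what they do not

`make_toy_dataset()` builds antibody-like complexes with learnable
structure. The design chain is an idealised C-alpha helix (exact
3.8 A virtual bonds); the loop window is one of a small number of
*canonical loop classes* — equal-chord circular arcs differing in
length, curvature (via the anchor-gap fraction, 0.60-0.85 of the
contour length) and bulge direction (within 45 degrees of the
direction away from the partner chain) — echoing the canonical
conformation clustering of real CDR1/CDR2 loops. Each class has a
fixed loop sequence, and the class is selected *deterministically* by
the two framework residues on each side of the loop (the flank code).
That determinism maximises the mutual information between visible
context and hidden loop, which is precisely what makes the recovery
experiment meaningful: a model that reads context can in principle
reach 100% recovery, and chance is 5%.

A 12-residue partner helix and a 12-residue antigen segment (placed
7 A beyond the loop apex, clash-checked at 3 A, within the 16 A
context) complete the complex; Gaussian noise of 0.1 A — small enough
to keep class membership unambiguous — is added last. Loop lengths
default to 7-11 residues over 6 classes.

What the toy data does *not* have: real side chains, real
immunoglobulin sequence statistics, conformational heterogeneity,
loop-context coupling subtler than the deterministic code, or
crystallographic artefacts. Passing the recovery experiment therefore
demonstrates that the architecture, losses, gradients and training
loop work as specified — not that the model generalises to real
antibodies, which requires database-scale training outside this
package's scope.

## The recovery experiment

The acceptance-style experiment in the test suite generates 240
complexes (seed fixed), trains a 4-layer, 32-wide model with 16
neighbours for 2,000 steps on 200 of them, selects the best
checkpoint on 20 validation complexes, and evaluates on 20 held-out
complexes. The suite requires held-out Top-1 AAR above 60% (chance
5%) and mean CDR RMSD below the straight-line anchor initialisation
baseline, and that the end-of-run training loss is below its starting
level. These problem sizes were chosen so the whole experiment runs
in a few minutes on one CPU while leaving a wide margin over chance.

## Known limitations

* C-alpha-only: no backbone frames, side chains or full-atom
  geometry. Full-atom reconstruction and relaxation are adapter
  contracts (`full_atom_adapter()`) for external tools; the package
  never requires them.
* Binding-energy estimation is out of scope; the designed complexes
  are written as C-alpha PDBs for downstream tools.
* Automatic numbering assignment from raw sequence (ANARCI-style) is
  out of scope: chain roles and scheme-consistent numbering are
  inputs.
* The fixed edge topology (built on masked input coordinates) means
  very large predicted loop excursions could outrun their neighbour
  lists; at the loop scales tested this has no visible effect.
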