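---
title: "Assigning secondary structure from C-alpha traces: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assigning secondary structure from C-alpha traces: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cassign)
```

## The problem

Coarse-grained protein models, low-resolution cryo-EM builds and a small
class of legacy PDB deposits describe a protein chain by its C-alpha atoms
only. Without backbone amides and carbonyls, hydrogen-bond-based assigners
such as DSSP cannot run, yet almost every downstream analysis — trajectory
annotation, all-atom reconstruction, structure comparison — starts from a
per-residue helix/strand/coil (H/E/C) labelling. `cassign` assigns these
three states from the C-alpha trace alone: rotation- and
translation-invariant geometric descriptors are computed over a sliding
sequence window and classified by a small feed-forward neural network, one
prediction per window, attached to the window's middle residue.

## Features

Three nested blocks are computed for an `N`-residue window
(`N` in 5, 7, 9, 11, 13; default 11):

* **Local distances.** All `r(i,i+2)`, `r(i,i+3)` and `r(i,i+4)` C-alpha
  distances inside the window: `N-2`, `N-3` and `N-4` values. The `i,i+3`
  distance is *chirality-signed*: its magnitude is multiplied by the sign
  of the triple product of the three intervening pseudo-bond vectors, so a
  right-handed helical turn (~+5.05 Å) and its left-handed mirror
  (~-5.05 Å) are distinct. A triple product within `1e-7` of zero (an
  exactly planar quadruplet, which arises in idealised strands) is clamped
  to the `+1` tie-break so the feature stays deterministic and
  rigid-motion invariant; genuinely chiral conformations are orders of
  magnitude away from this deadband.
* **Neighbour counts.** For each window residue, the number of C-alpha
  atoms of the same chain within 4, 4.5, 5 and 6 Å, excluding atoms less
  than 3 residues away along the sequence (`4N` integers). Core residues in
  regular elements are densely packed; exposed loops are not. Counts are
  computed within the query chain, matching single-chain training.
* **Coarse-grained hydrogen bonds.** A triangle is built on every three
  consecutive C-alpha atoms. Two triangles bond when their centroid
  distance falls in `[4, 6]` Å, their normals are near-parallel
  (`|cos| >= 0.7`), the centroid displacement is near-normal to both
  triangles (`|cos| >= 0.5`), and the central residues are at least 3 apart
  in sequence. Each triangle side can host one bond (nearest centroid wins,
  ties to the lower partner index), so per-residue counts are 0, 1 or 2 —
  the saturation value of an interior strand in a three-stranded sheet.
  These four thresholds were fixed once from the cross-strand C-alpha
  geometry of ideal sheets (spacing ~4.8 Å, coplanar normals) and are
  stored inside every model file, so training and inference always agree.
  The parallelism test uses absolute cosines, making parallel and
  antiparallel sheets equally detectable. The displacement gate is applied
  symmetrically to both normals so that bonding is a property of the pair
  (if a bonds b, b bonds a) — with near-parallel normals the two
  projections are nearly equal, and symmetry makes the per-residue counts
  well defined.

For `N = 7` with all blocks the input vector has `12 + 28 + 7 = 47`
dimensions; for the default `N = 11`, `24 + 44 + 11 = 79`. Block order
(r2, signed r3, r4, neighbours residue-major/cutoff-ascending, hbonds) is
fixed and recorded in the model file's feature manifest, since any
consistent order is equivalent but train/inference parity demands one
choice.

## Classifier

A multi-layer perceptron with two 128-neuron hidden layers and a 3-neuron
softmax output. Raw features are z-scored with statistics computed on the
training rows (zero-variance columns are stored with unit spread); the
hidden layers use the logistic sigmoid. We read "activating the input
layer" with a sigmoid as feature standardization: a literal sigmoid on
Å-scale raw distances would saturate immediately, and z-scoring is the
conventional realisation of that intent. Training minimises the categorical
cross-entropy over one-hot targets with plain mini-batch SGD (learning rate
0.01, batch 32, seeded shuffling), so a fixed seed reproduces training bit
for bit. Gradient correctness is checked in the tests against central
differences on a small network.

Residues that do not own a complete, break-free window — the `(N-1)/2`
residues at each terminus and residues adjacent to a chain break — cannot
be classified and are assigned `C` with probabilities `(0, 0, 1)`, coil
being the safest prior. Probability ties resolve deterministically in the
order H > E > C. Windows spanning a chain break (consecutive C-alpha
distance outside `[2.5, 4.3]` Å, a window admitting both trans ~3.8 Å and
cis ~2.9 Å peptides) are excluded from training and scored as coil at
inference, since distances across a gap are physically meaningless.

Models serialize to a versioned JSON text file carrying weights at 17
significant digits (exact double round-trip), the standardization
statistics, the window configuration and the hydrogen-bond criteria.

## Eight-state reduction

Reference labels produced by DSSP use eight states; they are reduced by the
common convention H,G,I → H; E,B → E; everything else (T, S, C, blanks)
→ C. The source method does not state its mapping; this is the one most
assigners use, and it is applied uniformly to training and evaluation so
any systematic difference cancels in Q3 comparisons.

## Synthetic corpus

The generators produce labelled chains with the geometry each class is
defined by, so the whole pipeline trains and validates without downloading
structures:

* helices on the textbook C-alpha parametrisation (rise 1.5 Å, radius
  2.3 Å, 100°/residue — consecutive distance ~3.83 Å, `r(i,i+3)`
  ~+5.05 Å);
* planar 3.8 Å zigzag strands (axial step 3.3 Å, lateral 0.942 Å);
* antiparallel sheets at 4.8 Å spacing joined by equal-chord circular-arc
  loops (one contiguous chain, E on strands, C on loops);
* self-avoiding random coils (3.8 Å steps, pseudo-bond angles uniform in
  [60°, 180°], non-adjacent approach >= 4 Å), which are expanded and
  irregular — low neighbour counts, no persistent `i,i+3` geometry;
* mixed topologies assembled by clash-checked rigid placement (proper
  rotations only, preserving chirality).

The default corpus (`make_structure_set()`) mixes pure helices,
helix-coil-helix chains, two- and three-stranded sheets, isolated strand
pairs and coils (roughly 35% H, 28% E, 37% C residues), all seeded and
contiguous.

What the corpus deliberately does not model: Ramachandran-statistics
backbone variation, bent/frayed element ends, pi-helices and 3-10 helices,
strand twist variation, and the continuous ambiguity of real element
boundaries. Passing the recovery test therefore shows that the feature set
separates the defining geometries and that training works end to end — it
does not certify the accuracy level reachable on experimentally determined
structures, which requires a curated PDB corpus with DSSP labels.

## Problem sizes and settings used in the tests

The recovery experiment trains on 600 synthetic chains (~12,000 windows,
80/20 chain-level split, `N = 11`, all feature blocks). The full protocol
default of 3500 epochs is far past convergence on this corpus: the
training loss plateaus by a few hundred epochs, so the experiment uses 600
epochs, where held-out window-level Q3 is ~0.97 with per-class recall
>= 0.96 for all three classes. Validation is window-level: every held-out
residue owning a complete window is scored. Whole-chain scoring (where
forced-coil termini count against the assigner) is available through
`predict_chain()` + `eval_report()` and is what the CLI's `eval` command
reports.

## Numerical choices and degenerate inputs

* Collinear triangle triples get no normal and never bond.
* Planar `i,i+3` quadruplets sign +1 (see deadband above).
* Zero-variance feature columns standardize with unit spread.
* Alternate PDB locations resolve to the highest occupancy, first on tie;
  HETATM C-alpha records (e.g. selenomethionine) are accepted.
* Q3 histogram bins are left-open/right-closed so a chain at exactly 95.0%
  falls in the 92.5–95.0 bin; the bottom bin includes 0.
* Aggregate Q3 is residue-weighted over the concatenated chains;
  per-protein Q3 values are reported separately.

## Known limitations

* The coarse-grained hydrogen-bond thresholds are geometric defaults
  derived from ideal sheet geometry, not fitted to PDB statistics; helical
  `i,i+3`/`i,i+4` triangle pairs can register as bonds, which is harmless
  for classification (the counts are just features) but means the counts
  are not a literal hydrogen-bond census.
* Neighbour counts are computed within one chain; inter-chain sheet edges
  in multimeric deposits will look less packed than they are.
* Terminal residues are never classified from geometry; short chains
  (length < N) return an all-coil assignment with a warning.
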