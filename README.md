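# cassign

Three-state protein secondary structure assignment (H = helix, E = strand,
C = coil) from C-alpha-only traces.

Coarse-grained simulations, low-resolution cryo-EM builds and a small set
of legacy PDB deposits provide only C-alpha coordinates, so
hydrogen-bond-based assigners (DSSP, STRIDE) cannot be applied. `cassign`
labels every residue of a C-alpha trace by computing rotation- and
translation-invariant geometric features over a sliding N-residue window
and classifying the window's middle residue with a small multi-layer
perceptron. It is aimed at people analysing coarse-grained trajectories or
C-alpha-only models who need a fast, reproducible H/E/C annotation.

## Method

For each contiguous window of N residues (N ∈ {5, 7, 9, 11, 13}, default
11) the input vector concatenates:

* **local distances** — all r(i,i+2), r(i,i+3) and r(i,i+4) C-alpha
  distances in the window, with r(i,i+3) signed by the chirality of the
  three intervening pseudo-bond vectors, sgn[(v_i × v_{i+1}) · v_{i+2}],
  so right- and left-handed turns are distinct;
* **neighbour counts** — for every window residue, the number of C-alpha
  atoms within 4, 4.5, 5 and 6 Å, excluding sequence neighbours closer
  than 3 positions;
* **coarse-grained hydrogen bonds** — per-residue counts in {0, 1, 2} of
  bonded, roughly parallel triangle pairs built on consecutive C-alpha
  triples (centroid distance 4–6 Å, |cos| of normals ≥ 0.7, displacement
  near-normal to both triangles).

For N = 7 that is 12 + 28 + 7 = 47 inputs. The classifier is an MLP with
two 128-neuron sigmoid hidden layers and a 3-class softmax output, trained
with mini-batch SGD on the categorical cross-entropy over one-hot labels
(learning rate 0.01). Residues without a complete break-free window (chain
termini, break-adjacent residues) are assigned C. Accuracy is reported as
Q3 — the fraction of residues whose assignment matches the reference —
plus row-normalized confusion matrices and per-protein Q3 histograms.

The package also ships generators for labelled synthetic structures
(ideal helices, strands, multi-strand sheets, self-avoiding coils, mixed
topologies), so the full train → predict → evaluate pipeline runs without
any downloads.

## Worked example

Train on 600 synthetic chains and assign a mixed helix–coil–strand chain:

```r
library(cassign)

set <- make_structure_set(600, seed = 11)
fit <- train_assigner(set, window_config(11),
                      control = train_control(epochs = 600, seed = 11))
glance(fit$validation)
#> # A tibble: 1 × 7
#>      q3 n_chains n_residues n_perfect recall_H recall_E recall_C
#>   <dbl>    <int>      <int>     <int>    <dbl>    <dbl>    <dbl>
#> 1 0.972      120       1653        94    0.981    0.970    0.968

protein <- make_protein("H18-C6-E8", seed = 4)
res <- predict_chain(fit$model, protein$trace)
paste(res$ss, collapse = "")
#> "CCCCCHHHHHHHHHHHHHCCCCCCEEECCCCC"
protein$labels
#> "HHHHHHHHHHHHHHHHHHCCCCCCEEEEEEEE"
```

Held-out window-level Q3 is 0.972: of the 1653 held-out residues owning a
complete window, 97.2% receive the generator's label, with per-class
recall ≥ 0.97 for all three states. In the example assignment the five
residues at each terminus have no complete 11-residue window and are
forced to `C`; every interior residue matches the construction labels.
`save_mlp()`/`load_mlp()` persist the model as portable JSON text, and
`autoplot()` draws the loss curve (model) or Q3 histogram (report).

The same pipeline is scriptable from a shell via the bundled CLI
(`inst/exec/cassign`): `synth`, `train`, `predict`, `eval` and `features`
subcommands, all seeded and bit-reproducible.

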