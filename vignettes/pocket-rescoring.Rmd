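---
title: "Ligand-aware rescoring of binding-pocket decoys: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ligand-aware rescoring of binding-pocket decoys: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Cavity-detection tools such as fpocket or P2Rank propose many candidate
binding pockets ("decoys") per protein, and their own geometric scores often
fail to put the true ligand-binding site at the top of the list. When the
ligand is known, its chemistry carries information the geometric score
ignores. `pocketrank` rescores a set of pocket decoys *for a given ligand*:
each (ligand, pocket) pair is embedded as a fixed-length vector and a
feed-forward classifier outputs the probability that the pocket is
native-like for that ligand. Decoys are then ranked by this probability and
the top three are reported as the candidate sites.

The package does not detect cavities itself; it consumes the per-pocket PDB
files that detection tools emit (`pocket<k>_atm.pdb`).

## Featurization

Both molecules and pockets are represented with a mol2vec-style
substructure-embedding sum:

* A molecule is a "sentence" of words, one word per (heavy atom, radius)
  pair for radii 0 and 1. A word is the atom-centered circular (Morgan)
  substructure identifier at that radius.
* An embedding table maps each identifier to a vector in
  $\mathbb{R}^{300}$; the molecule vector is the element-wise sum of its
  word vectors. Out-of-vocabulary words contribute zero by default (an
  `UNK`-row policy is available).
* A pocket residue is featurized as the free amino acid: its three-letter
  name is mapped to a canonical SMILES (the 20-entry table `AA_SMILES`) and
  that molecule is embedded. The pocket vector is the sum over its
  residues, which makes the map additive and order-independent.
* The classifier input is the 600-dimensional concatenation
  $[\,v_\text{ligand} \mid v_\text{pocket}\,]$.

Featurizing residues as free amino acids is a deliberate design choice: the
alternative — cutting residue fragments out of the bonded protein graph —
creates broken-valence artifacts and would make identifiers depend on the
local bonding perception of each structure file. The free-amino-acid route
is reproducible from the residue name alone.

### Substructure identifiers

SMILES perception (atoms, bonds, kekulized aromatic orders) is delegated to
Open Babel via ChemmineR. The circular identifiers themselves are computed
in-package by iterated neighborhood hashing:

* radius 0: hash of (element symbol, heavy-atom degree, bond-order sum);
* radius $r$: hash of (r, own identifier at $r-1$, the sorted list of
  (bond order, neighbor identifier at $r-1$) pairs).

The hash is an exact-integer polynomial hash modulo $2^{31}-1$, so
identifiers are deterministic across platforms. They are internally
consistent — the synthetic table generator and the featurizer share the
scheme, and symmetric atoms (e.g. all six benzene carbons) provably collide
— but they are *not* numerically equal to RDKit's Morgan hashes. A
pre-trained embedding table keyed by RDKit identifiers therefore cannot be
used directly; tables must be keyed by this package's identifiers (the
word2vec text format itself is supported unchanged, header line plus one
`identifier f1 ... f300` row per word).

## The decoy-labeling protocol

Distances are in nm (coordinates stay in Å; 1 nm = 10 Å) and all
geometry runs on Cα-centroid positions:

* **Known pocket**: every protein residue with at least one atom within
  1.0 nm of any ligand atom. Waters and monoatomic ions are never pocket
  residues; hydrogens, if present, participate in the distance test but not
  in centroids.
* **Positives**: decoys whose Cα centroid is closer than 0.3 nm to the
  known pocket's centroid (strategy `near_native`), or the known pocket
  itself (strategy `native`).
* **Negative candidates**: decoys farther than 1.0 nm. The band
  0.3–1.0 nm (inclusive at both ends) is excluded from both classes.
* **Similarity filter**: a negative candidate whose pocket vector has
  cosine similarity ≥ 0.995 with the known pocket's vector is removed —
  it is a disguised copy of the native site (fpocket frequently emits
  overlapping decoys). Removal at equality is intentional: an exact
  duplicate must not survive.
* **Sampling**: up to three negatives per complex, uniformly without
  replacement, from the filtered candidate pool.

The filter runs *before* sampling. Filtering afterwards would silently
shrink the negative set whenever a collinear decoy happened to be drawn,
and the protocol's intent is that such decoys never enter the pool.

Distance boundaries (exactly 0.3 or 1.0 nm) fall into the excluded band;
this affects only zero-measure configurations in practice and keeps the
partition exhaustive and disjoint by construction, a property the test
suite asserts on random decoy sets.

A positive-replication knob (`replicate_positives`) can repeat each
positive row to rebalance training sets in which negatives dominate
(three-fold replication turns a 1:3 ratio into parity); the default is 1 so
that example counts equal distinct-pocket counts.

## The classifier

The densely connected feed-forward network (DFCNN) consists of
`n_blocks = 16` hidden blocks of `units = 100` ReLU units. Block $k$
receives the concatenation of the raw input and the outputs of *all*
preceding blocks — the input counts as layer 0, so block $k$ has input
width $600 + (k-1)\cdot 100$ and the sigmoid output unit reads all
$600 + 16 \cdot 100 = 2{,}200$ features. Including the raw input in every
concatenation is the design decision here; the "all outputs of preceding
layers" connectivity is ambiguous on that point and the inclusive reading
is the one that makes block 1 well defined.

* Inverted dropout (rate 0.25) follows each hidden block's activation; no
  dropout on the raw input or the output layer.
* Training minimizes binary cross-entropy with mini-batch Adam
  (learning rate $10^{-3}$, batch 128 — both configurable and recorded in
  checkpoints). The default epoch budget is 1,500, the point where
  validation performance plateaus in the reference setting; early stopping
  is deliberately not enabled by default.
* Weights are He-style uniform ($\pm\sqrt{6/\text{fan-in}}$), seeded;
  initialization, shuffling and dropout all derive from the configured
  seed, so training trajectories are bit-reproducible.
* Degenerate cases fail loudly: single-class training sets and non-finite
  losses abort with a diagnostic rather than returning a broken model.

Inputs are normalized by a single scalar affine map
$t \mapsto (t - \text{mean})/\text{std}$ over all 600 components — not
per-dimension, matching the scalar constants the reference training sets
produce (mean $-0.5696$, std $30.8744$ for near-native positives; mean
$-0.9610$, std $63.6607$ for native positives;
`reference_norm_params()`). Fixed training-set constants are the default
at ranking time; self-normalization (constants from the data being scored)
exists behind a flag for comparison, and the parameters actually applied
always travel with the model checkpoint.

## Metrics

`metric_suite()` computes accuracy, TPR (sensitivity is reported as the
same quantity), precision, specificity and MCC from confusion counts;
probability outputs are thresholded at 0.5 with the boundary counted
positive. AUC is the rank-based Mann–Whitney statistic with ties counted
half. Ratios with zero denominators are `NA`, and MCC is 0 when a marginal
is zero. `counts_from_rates()` inverts printed summary tables — given class
sizes, TPR and precision it reconstructs integer TP/FP/TN/FN (nearest
integer, ties away from zero), which lets summary metrics like MCC be
recomputed from published rate tables to two decimals.

## The synthetic generators

Three generators produce everything the pipeline consumes, in the same
file dialects as the real inputs (PDB, fpocket-style pocket directories,
word2vec text tables, TSV manifests):

* `make_embedding_table()` — i.i.d. standard-normal vectors over a
  vocabulary that covers all amino-acid identifiers plus a configurable
  ligand alphabet, so featurization of generated data never leaves
  vocabulary unless a test wants it to.
* `make_toy_complex()` — a Cα-scaffold protein: eight pocket-shell
  residues 6 Å from a three-atom ligand at the origin (their centroid is
  exactly the origin), distant bulk residues, and one decoy per requested
  centroid distance. Decoy residues are placed in ± offset pairs 15 Å
  from the decoy center, so the centroid is exact while no decoy atom
  enters the ligand's 1 nm shell — the known pocket stays exactly the
  shell no matter where decoys sit. Residue names cycle through the 20
  standard amino acids: near-native decoys reuse the shell composition
  with one substitution, far decoys draw fresh 4-residue compositions.
  Uniform poly-alanine naming would have been simpler but makes every
  pocket vector a scalar multiple of one residue vector, i.e. cosine
  similarity exactly 1 between all pockets, which would defeat the
  similarity filter; varied names keep negative-candidate similarities
  comfortably below the 0.995 cutoff while the optional
  `duplicate_decoy` copies the shell composition exactly and is provably
  collinear.
* `make_separable_vectors()` — two Gaussian classes at mean distance
  `separation` (in within-class SD units) with identity covariance, for
  which the Bayes AUC has the closed form $\Phi(\text{sep}/\sqrt 2)$;
  separation 3 gives 0.983, the analytic anchor used by the training
  tests.

What the generators emulate is the *geometry and bookkeeping* of the real
task: controlled centroid distances, fpocket file dialects, compositional
similarity between near-native decoys and the native pocket. What they do
not emulate: real pocket chemistry, learned (rather than random) embedding
vectors, conformational variability, or class overlap structure of
predicted decoys. Passing tests therefore demonstrate that the machinery —
geometry, labeling, featurization, optimization, ranking — is correct and
reproducible, not that the trained toy models transfer to experimental
structures; training on a large curated complex collection with a
published embedding model is required for that.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use scaled-down study sizes
chosen to exercise every code path with comfortable statistical margins:
Gaussian recovery runs at 2,000 + 2,000 examples in 600 dimensions with an
8-block × 100-unit network for 15 epochs (held-out AUC ≈ 0.96 against a
Bayes bound of 0.983, shuffled-label control ≈ 0.5); the end-to-end
pipeline trains a 4-block × 50-unit network for 50 epochs on eight toy
complexes and ranks a held-out complex, where the near-native decoy wins
rank 1. Forward passes are verified against a scalar-loop oracle at 1e-6
on ≤3-block configurations; cosine similarity, AUC and centroid arithmetic
against brute-force computations at 1e-12.

Other numerical conventions: PDB coordinates are written at the format's
3-decimal precision (round-trip error ≤ 5e-4 Å); alternate locations keep
the first-listed conformation; score ties at ranking time break by pocket
id ascending so output is deterministic; pockets that cannot be featurized
are reported with an `NA` sentinel rather than dropped.

## Known limitations

* Identifier hashes are package-specific (see above); published
  RDKit-keyed embedding tables require re-keying before use.
* `counts_from_rates()` reconstructions inherit the rounding of printed
  rates; two-decimal agreement is the supported resolution.
* mmCIF input, biological-assembly expansion and cavity detection are out
  of scope; modified residues featurize as zero vectors unless a SMILES is
  supplied via `extra_smiles`.
* Training is CPU-bound pure R linear algebra: adequate for the scaled
  study sizes here, not for corpus-scale training.
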