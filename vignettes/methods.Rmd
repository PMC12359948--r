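---
title: "Molecular graphs from 3D-optimised structures and the nested warm-start training protocol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 3D molecular graphs and the nested warm-start protocol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its methods: the model and
its assumptions, the parameters that matter, what the synthetic data
emulate (and do not), the numerical choices, and the design decisions
taken where the design was genuinely open.

## 1. From SMILES to a standardised parent molecule

A compound record is a (identifier, SMILES, binary label) triple. The
standardisation pipeline applies, in order: parse, element screening,
normalisation, parent-fragment selection, tautomer canonicalisation. The
first failing stage is recorded in a rejects table with a message; failure
is a result, never an exception.

**Element screening** keeps only molecules whose atoms all belong to the
ten elements prevalent in approved small-molecule drugs: H, C, N, O, F, P,
S, Cl, Br, I. Records containing boron, arsenic, metals or other rare
elements are rejected whole. Because screening precedes fragment
selection, a salt whose counterion is a metal (sodium acetate, say) is
rejected at screening even though its parent fragment would pass; this
ordering is deliberate and matches the screen-first design. Users who
prefer counterion stripping first can set `screen_after_parent = TRUE` in
`standardize_record()`/`standardize_dataset()`, which moves screening
after parent selection. A consequence of the screen-first default is that
the "disconnect metal atoms" part of normalisation never sees a metal;
metal-containing records are caught upstream, and ionic salts are already
disconnected fragments in SMILES. Covalently metal-bonded structures are
out of scope.

**Normalisation** folds explicit hydrogens into implicit counts and
neutralises ionic charges where a proton can be added or removed
(protonated amines, carboxylates). Genuinely zwitterionic groups that have
no neutral form — the nitro group, quaternary ammonium — are left intact;
"zero net charge" is required only where chemically attainable. The
operation is idempotent.

**Parent selection** keeps the fragment with the greatest heavy-atom
count. Hydrogens are not counted because normalisation has already made
them implicit. Ties are broken by the lexicographically smallest canonical
SMILES, which is deterministic and invariant to the input atom order.

**Tautomer canonicalisation** maps all tautomers of a compound to one
form. The delegate toolkit (OpenBabel) has no tautomer canonicaliser, so
the package implements one: a breadth-first closure over symmetric 1,3
proton shifts H–X–Y=Z ⇌ X=Y–Z–H with X, Z ∈ {C, N, O, S}, on the Kekulé
bond graph with implicit hydrogens (a shift is therefore just a pair of
bond-order changes; the valence model restores hydrogen counts). Because
the move set is its own inverse, the reachable set is an equivalence
class, which makes the chosen representative independent of the starting
tautomer and the operation idempotent. Bonds of all-carbon aromatic rings
are frozen — shifts there only manufacture quinoid junk and blow up the
closure on fused systems — while heteroaromatic and hetero-substituted
rings (pyridones, the pyranone ring of warfarin) do participate. The
representative maximises, in order: the number of aromatic atoms as
perceived on each candidate's canonical SMILES (so an aromatic form is
never traded away), a stability score over double bonds (C=O and C=S
scored 4; N=O, S=O, P=O scored 3; C=N 2; C=C 1 — oxo forms beat enols,
imines beat enamines), and finally the lexicographically smallest
canonical SMILES. The closure is capped at 512 states; past the cap the
input's canonical form is returned unchanged. Drug-sized molecules in the
test fixtures stay far below the cap.

## 2. Conformers, MMFF94, and what reproducibility means here

Each standardised molecule receives explicit hydrogens and one 3D
conformer from the toolkit's builder (`method = "med"`, rule-based
construction with force-field clean-up; `"dist"` selects distance
geometry). The geometry is validity-checked — finite coordinates, every
bonded pair between 0.7 and 2.5 Å — and the builder is retried until valid
or until `max_attempts` (default 5,000) is exhausted, in which case a
failure record is returned. In practice the first attempt succeeds for
drug-like organics and the cap exists for pathological inputs.

The toolkit's conformer search seeds its random stream from the clock and
exposes no seed parameter, so embedding is *not* bit-reproducible; the
`seed` argument is recorded in the output for provenance only. This is an
accepted limitation with a documented tolerance: the only geometric
quantity that enters the learned features is the bond length, and after
MMFF94 minimisation to a tight criterion (2,000 steps, energy criterion
1e-6) bond lengths agree across independent embeddings to roughly 0.01 Å,
because bond stretching is by far the stiffest term in the force field.
Torsional geometry does differ across runs, and nothing downstream
consumes it. End-to-end reproducibility is therefore defined from the
featurised graphs onward: given a graph dataset, a configuration and
seeds, training and evaluation are exactly deterministic, and the
serialised graph container (JSON at 17 significant digits) round-trips
bit-exactly.

Energies are totals from the MMFF94 implementation of the `obenergy` tool,
in kcal/mol; `converged` means the energy did not increase. The
bond-length-change analysis reports absolute percent change
`100·|after−before|/before` per bond (magnitudes, matching how such
changes are conventionally summarised; signed values stay available from
the raw table), and a two-sided paired t-test compares matched samples of
changes.

## 3. Feature schemas

Two schemas are defined. `basic`: one-hot atomic number over the ten
allowed elements (d_node = 10) and one-hot bond type over
{single, double, triple, aromatic} (d_edge = 4). `custom` (d_node = 29,
d_edge = 6) adds, per node: heavy-atom degree, formal charge, one-hot
hybridisation over {SP, SP2, SP3, SP3D, SP3D2, other} (from SYBYL atom
types), an aromaticity flag, hydrogen count, ring membership (an atom or
bond is in a ring iff the bond is not a graph bridge), one-hot chirality
over {none, CW, CCW, other} (taken from the stereo annotations of the
standardised SMILES; `other` covers extended stereo types), radical
electron count, the Gasteiger partial charge, and total/explicit valence;
per edge: the ring flag and the MMFF94-optimised bond length in Å.

Encoding choices the source conventions leave open were fixed once:
categorical features one-hot over fixed vocabularies, counts as real
scalars, charge and length as raw scalars. Graphs are over heavy atoms
only — hydrogens, which were explicit for the 3D step, contribute through
the hydrogen-count feature — and every chemical bond is stored as two
directed arcs carrying identical edge features. Valence is defined on the
hydrogen-suppressed graph: explicit valence is the bond-order sum over
heavy neighbours (aromatic bonds 1.5), total valence adds the hydrogen
count; the two coincide only for atoms without hydrogens, which is why
both are kept. Non-finite Gasteiger charges (not observed on the allowed
element set, but possible in principle) are replaced by 0 and flagged per
molecule. No feature standardisation is applied by default; the features
are consumed raw.

## 4. The four convolutions and the model stack

The layer equations are implemented exactly as stated in the README. Two
ambiguities were resolved as follows. First, how edge features enter the
convolutions: the GCN normalisation supports a scalar arc weight
e<sub>j,i</sub>, exposed through `gcn_edge_weight` ("none", the default
weight 1, or "bond_length", the reciprocal optimised length); GAT can
concatenate edge features into its attention logit (`gat_edge_attn`,
default off); GraphSAGE and GIN take no edge terms, as their equations
contain none. The defaults mirror the operator definitions as printed.
Second, GAT uses a single attention head with LeakyReLU slope 0.2 (the
convention of the original attention-network work); ε in the GIN update is
a fixed, untrained scalar, default 0.

The model is three convolutions with widths 2h, h, h/2 (`hidden_channels`
h must be even so h/2 is an integer width), a rectifier after each,
inverted dropout after layer 3 (training mode only), global mean pooling,
and a linear map to one logit. The binary loss is sigmoid cross-entropy
evaluated in the numerically stable softplus form; a two-logit softmax
cross-entropy variant (`n_output_logits = 2`) exists for two-class
datasets, and the two agree exactly when the two-logit model is
constrained to logits (0, z). All weights are Glorot-uniform initialised
(`U(±√(6/(fan_in+fan_out)))`, biases zero) from a recorded seed. Forward
and backward passes are hand-written matrix code; neighbourhood
aggregation is grouped `rowsum` gather/scatter, which on molecule-sized
graphs is faster than sparse-matrix dispatch. Gradients are verified
against central finite differences at a generic point (biases perturbed
off zero, since a zero-initialised bias can park an entire ReLU layer
exactly at its kink, where the subgradient convention and a two-sided
difference legitimately disagree). The optimiser is Adam (β₁ = 0.9,
β₂ = 0.999, ε = 1e-8) at the grid's learning rate — the de-facto standard
for these architectures; `max_epochs` defaults to 500 with early-stopping
patience 50.

## 5. The nested cross-validation protocol

`make_fold_plan()` deals each class round-robin after a seeded shuffle
into `outer_k` stratified outer folds (default 4; the held-out fold is 25%
of the data), and each outer-training portion into `inner_k` stratified
inner folds (default 5, giving the 60/15/25 train/validation/test split).
Per-fold class counts are within one sample of proportional by
construction.

Per outer fold: **grid search** trains every combination of the
hyperparameter grid on each inner split with early stopping and collects
the validation AUCs. The default grid — batch size {16, 32, 64}, hidden
channels {32, 64, 128}, dropout {0.1, 0.3, 0.5}, learning rate
{1e-4, 3e-4, 1e-3, 3e-3, 1e-2} — enumerates 3·3·3·5 = 135 combinations and
is fully overridable; the winner minimises the sum of its rank by median
and its rank by minimum validation AUC (descending; exact ties go to the
earliest enumeration index). **Seed reinitialisation** then retrains the
winning configuration from 20 fresh Xavier initialisations (fresh fits,
not reuse of grid-search fits — the two stages are distinct) and selects
the seed by the same combined rank. **Sequential warm starts** train the
selected model across inner folds 1→5 in fold-plan order, each fold's fit
warm-started from the previous fold's best-epoch parameters, emitting 5
validation AUCs per run per outer fold. After each run the AUCs are pooled
across the outer folds (20 values per run in the full protocol) and
compared with each of the two previous runs by a one-sided Wilcoxon
rank-sum test in the improvement direction; the warm starts halt when both
p-values exceed the Sidak-corrected level `1−(1−α)^(1/2)` at α = 0.05,
never before three completed runs and never after a hard cap of 10 runs
(loop protection on pathological data). The model evaluated on the outer
test fold is the final warm-started state after the last completed run.

Pooling the Wilcoxon samples across outer folds (rather than testing per
fold) follows the protocol's description of "20 validation AUC scores per
run"; the rank-sum (unpaired) test is used as named, although the run
scores are arguably paired — a signed-rank variant would be a different
protocol and is not implemented. Classification metrics on the test folds
threshold the sigmoid probability at 0.5.

The statistics are implemented in-package because the protocol pins down
their algorithms: AUC in the Mann–Whitney mid-rank formulation (ties count
one half); Wilcoxon rank-sum exact by enumeration of all C(n+m, n)
assignments when n+m ≤ 12 (handling ties via mid-ranks), otherwise a
normal approximation with tie and continuity correction; F1 and MCC with
the zero-denominator → 0 convention. Each is cross-checked in the tests
against an independent reference (`t.test`, `wilcox.test`, `pROC`, direct
enumeration).

A leakage audit tracks, per outer fold, every graph id touched by any
training or selection step; `evaluate_outer()` raises a hard error if a
test id appears in its fold's record.

## 6. Synthetic data: what it emulates and what it does not

The generator assembles chemically valid, drug-like SMILES from fragment
templates over the ten allowed elements — five scaffolds (substituted
benzene, branched chains, cyclohexane, an anilide, a quaternary-carbon
chain) crossed with ten decorations — so no validity-filter loop is
needed and every molecule embeds and optimises.

Two signals are available. **Substructure** (the default): positives carry
a planted nitro group, negatives a benign substituent; the label is the
signal XOR a Bernoulli noise flip (default rate 0.05, class balance 0.5).
**Charge threshold**: molecules are drawn from isomeric template pairs
(α-fluoro vs ω-fluoro carboxylic acids, α-chloro vs ω-chloro amides,
fluoro alcohols) whose members share elemental composition and bond-type
multiset; the label is whether the molecule's maximum Gasteiger charge
exceeds its template family's threshold τ (the midpoint of the two
members' statistics — per-family thresholds, since absolute charge scales
differ across chemistries). By construction the classes are separable in
custom-feature space, where the charge is an input, while the basic
atomic-number/bond-type features must infer the halogen's position from
topology alone.

These datasets emulate a learnable structure–property signal at realistic
molecule sizes; they do not emulate real pharmacology — no activity
cliffs, no scaffold bias, no assay noise structure, and duplicate
scaffold–substituent combinations can recur across folds. Passing the
scaled-down protocol on them demonstrates that the machinery (featurised
signal, training, selection, stopping, evaluation) works end to end, not
that comparable AUCs would be reached on curated drug datasets.

## 7. Scaled-down study conditions

The bundled end-to-end runs (acceptance script and acceptance tests) use
problem sizes chosen for a single CPU: 300 molecules (substructure signal,
noise 0.05) with 2 outer × 3 inner folds, an 8-combination grid (batch
{16, 32} × hidden {16, 32} × dropout 0.1 × learning rate {3e-3, 1e-2}),
3 candidate seeds, at most 3 warm-start runs, `max_epochs` 100 and
patience 25; and a 160-molecule charge-threshold dataset with a
2-combination grid and 2 seeds for the custom-vs-basic feature contrast.
GraphSAGE is the protocol's architecture in these runs — across the four
convolution types it trains most reliably at small widths here, consistent
with its self + mean-neighbour form preserving node-level signal that
degree-normalised averaging dilutes. Hidden widths below 16 were observed
to under-fit even the planted signal (dead rectifier stacks at width
h/2 = 4 and below), which is why the scaled grid starts at 16.

## 8. Known limitations

- Conformer embedding is not seedable through the delegate's API (§2);
  bond lengths carry a ~0.01 Å run-to-run tolerance.
- The tautomer enumerator covers 1,3 shifts; longer-range (1,5+)
  prototropic systems outside aromatic rings map to per-class
  representatives only if a chain of 1,3 moves connects them.
- Chirality features come from the input SMILES annotations; unannotated
  stereocentres are "none", and no 3D-derived parity is assigned.
- The GAT implementation is single-head; multi-head ensembles are out of
  scope.
- Metrics assume binary labels; the two-task variant trains one task at a
  time.
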