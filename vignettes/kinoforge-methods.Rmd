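---
title: "Methods: interpretable latent-space generative design of kinase-family ligands"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: interpretable latent-space generative design of kinase-family ligands}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem and the approach

Kinase inhibitors are structurally constrained molecules: the ATP site is
highly conserved across the kinome, and its ligands concentrate on a small
set of fused aromatic chemotypes (quinazolines, aminopyrimidines,
pyrrolopyrimidines and relatives). `kinoforge` implements a modular,
chemistry-first pipeline for *family-targeted* ligand design in a
continuous latent space, built so that every stage is interpretable and
independently testable:

1. **chemstore** — molecule standardization, a fixed 20-descriptor panel,
   drug-likeness filters, Morgan-fingerprint Tanimoto similarity;
2. **latent core** — a trainable character-level SMILES variational
   autoencoder (VAE) with a stochastic decode-and-retry protocol;
3. **KAL** — a random-forest *Kinase Association Likelihood* scorer: the
   probability that a molecule lies in the chemical space of a target
   family's ligands (a structural-similarity score, not an activity
   prediction);
4. **bayesopt** — global search over the latent box by Gaussian-process
   Bayesian optimization of the KAL objective;
5. **neighborhood** — local, cluster-guided remodeling: K-means centroids
   define chemically coherent neighborhoods, and each molecule is moved a
   controlled fraction of the way toward its centroid before decoding;
6. **landscape** — PCA and kernel-density diagnostics of the latent
   manifold, per-family latent statistics and generation reports;
7. **synthkit** — seeded synthetic molecule libraries and Gaussian-mixture
   latent fixtures that make the whole pipeline exercisable offline;
8. a campaign driver (`runCampaign()`) and a thin command-line wrapper.

Chemistry primitives (parsing, canonicalization, tautomer normalization,
descriptors, fingerprints) are delegated to RDKit through a bundled,
batched Python helper; everything the pipeline *contributes* — the scorer,
the optimizer, the remodeling operator, the diagnostics — is implemented
in the package and covered by oracle tests.

# Standardization and the descriptor panel

`standardizeMolecule()` keeps the largest organic fragment (heavy-atom
count, ties by molecular weight; fragments without carbon are not eligible
parents), neutralizes residual charges, normalizes the tautomer with the
toolkit's canonical-tautomer enumeration, preserves stereo descriptors and
emits canonical SMILES. The operation is idempotent, which the tests check
as a fixed-point property. Tautomer canonicalization follows the RDKit
rule set and is therefore toolkit-version sensitive; the canonical forms
are stable within one installed version.

The 20 descriptors (see `descriptorNames()`) group into aromatic features,
topological complexity (including bridgehead atoms, counted with the
toolkit's strict fused-bicyclic definition), physicochemical properties
(molecular weight, logP, QED, synthetic accessibility, Labute ASA,
Hall–Kier alpha) and pharmacophoric elements (H-bond donors/acceptors,
rotatable bonds, sp³ carbon fraction, stereocenters *including unassigned
centers*, amide bonds matched by the non-ring-restricted SMARTS `C(=O)N`).
The twentieth descriptor, `aromatic_atom_fraction` (aromatic atoms /
heavy atoms), operationalizes "aromaticity" as a dimensionless companion
to the ring counts; it can be dropped or replaced by retraining on a
modified matrix, since scoring always uses the exact descriptor ordering
stored in the model.

Library filters default to the extended rule-of-five cutoffs used
throughout (MW < 700 Da, logP in [−4, 6], ≤ 6 rotatable bonds, ≤ 12
HBD/HBA) plus a biologically relevant element whitelist (C, N, O, F, S, P,
Cl, Br, I). Each rejected molecule is attributed to the *first* violated
rule in a fixed order so that the per-rule counts and the retained count
always sum to the input count — a conservation law the tests enforce.

Morgan fingerprints default to radius 2 folded to 2048 bits (the de facto
standard ECFP4-like setting); both parameters are configurable and a
parameter mismatch between two fingerprint sets is a hard error. Two empty
bit sets are treated as identical (similarity 1); this corner is unreachable
for organic molecules but defined for completeness.

# The character-level SMILES autoencoder

The pipeline is written against a minimal *embedding contract* — any
object with `encodeLatent()` (deterministic), `decodeDraws()` (stochastic)
and `latentDim()` methods plugs in, and the test suite exercises the
contract with a lookup-table fake. The built-in model is a
**position-factorized feed-forward VAE**: the tokenized, padded SMILES
(multi-character tokens: bracket atoms, `Cl`, `Br`, `@@`, two-digit ring
closures) is one-hot encoded; a tanh layer feeds a diagonal-Gaussian
posterior; the decoder maps a latent point through a tanh layer to one
softmax per sequence position. Training is hand-written
backpropagation with Adam, teacher-free (the decoder sees only `z`), with
the KL term linearly annealed from 0 to `klWeightMax` over the first half
of training. Gradients are verified against finite differences in the
test suite.

A recurrent autoregressive decoder would be the conventional choice; we
use the position-factorized form because it trains reliably on
desk-scale corpora (hundreds of molecules) in seconds without a deep
learning framework, keeps encoding exactly deterministic, and preserves
every protocol built on top (posterior-mean encoding, temperature-sampled
stochastic decoding, decode retries). The cost is that the decoder cannot
model inter-position dependencies, which depresses the validity of
samples taken far from the training manifold — a limitation discussed
below because it interacts with the noise parameter of local remodeling.

Defaults: latent dimension 196 (matching the continuous embedding
convention used throughout the field; desk-scale campaigns use 8–32),
hidden width 128, KL weight capped at 0.2 (campaigns use 0.05), learning
rate 2e-3. The log-variance head is clamped to [−10, 10] and the softmax
is max-stabilized; a non-finite loss aborts with diagnostics rather than
silently diverging.

**Decode-and-retry.** `decodeWithRetries()` samples the decoder up to
`maxAttempts` times (default 500) at a fixed latent point and accepts the
first draw that (i) parses as a valid molecule and (ii) has a canonical
SMILES of at least `minSmilesLength` characters (default 10; the length
filter is applied to the canonical string, and length exactly 10 is
retained). Vectors whose draws include valid-but-short strings only are
classified `length_filtered`, distinct from `decode_failed`, so the
generation ledger can attribute every loss to a stage. Draws are generated
in one batch — identical in distribution and, under a fixed seed,
identical in value to sequential retries — and validated in a single
back-end call with memoization, which makes the 500-retry protocol cheap.

# The KAL scorer

`assembleTrainingSet()` builds the classifier pool: target-family ligands
as positives, all other-family ligands as negatives, plus a seeded uniform
subsample of the drug-like background. Subsampling (rather than class
weighting) is used deliberately: with the full background the negative
class would be so dominant that the forest could trivially predict
"negative" everywhere, washing out sensitivity to the minority target
class. Pools are deduplicated by canonical SMILES and the classes are
disjoint by construction (overlaps are removed from the negatives and
logged).

`trainKal()` fits a random forest on the 20-descriptor panel — 500 trees,
unlimited depth, √p candidate features per split, fixed seed. Both a
binary (target vs. rest) and a multiclass (per-family) mode are provided;
the score is the positive-class vote fraction, so it is a probability in
[0, 1] by construction. Because the published protocol does not state the
evaluation design, the default is stratified 5-fold cross-validation with
pooled out-of-fold predictions, which gives honest metrics on small
libraries; a resubstitution mode is available for comparison with
apparent-error reporting. Metrics follow the standard confusion-matrix
definitions (accuracy, per-class precision/recall/F1/support, macro and
support-weighted averages; zero denominators score 0), and ROC-AUC is the
tie-aware rank probability (Mann–Whitney). All of these are checked
against brute-force oracles and, for AUC, against an independent
implementation. Feature importances are mean decrease in Gini impurity,
normalized to sum to one.

On the synthetic library the binary target-vs-rest F1 exceeds the same
family's multiclass F1 when families share scaffold features — the
qualitative signature of signal dilution across structurally homologous
classes — and the tests reproduce this direction on a library built with
deliberately overlapping cores.

# Bayesian optimization over the latent box

The search space is the per-dimension [min, max] of the embedded
reference library expanded by 10% (`latentBox()`); the box is the only
place the otherwise unbounded latent space enters the optimizer. The
surrogate is a zero-trend GP with an isotropic Matérn 5/2 kernel — the
standard choice for response surfaces that are continuous but not
necessarily smooth — with length-scale, signal and noise variances fitted
by maximizing the log marginal likelihood (bounded L-BFGS-B on the log
scale, three orders of magnitude around the start). Predictions use a
cached Cholesky factorization with escalating jitter; an indefinite
covariance after the last escalation is a hard error with diagnostics.

Acquisition is Expected Improvement,
EI(x) = (μ − y* − ξ)Φ(u) + σφ(u), u = (μ − y* − ξ)/σ, with the σ = 0
limit handled exactly and ξ = 0.01 by default, maximized by L-BFGS-B from
10 uniform restarts (best local optimum wins; if every restart fails the
best random probe is used with a warning). The run protocol mirrors the
published one: optional seeded initialization (encoded reference ligands
are scored and enter the surrogate before any acquisition step),
hyperparameter refits every 100 steps (factorization-only updates in
between), a 1500-step cap, and a plateau rule that stops when the best
score improves by less than 0.001 over 100 consecutive steps. Desk-scale
campaigns shrink the cap and refit period (40 steps, refit every 10) but
keep the protocol; histories beyond `gpCap` points are refit on the
incumbent best plus the most recent points, a standard budget device for
exact GPs.

The objective for a latent vector is the KAL score of its decoded
molecule; undecodable vectors score 0 by default (no molecule, no kinase
likeness), with a "skip" mode that excludes them from the surrogate
instead. The zero default makes decode failure informative to the
optimizer — it learns to avoid sparse regions — at the price of a
discontinuous objective; the Matérn kernel tolerates this in practice.

# Cluster-guided local remodeling

K-means (seeded k-means++ initialization, Lloyd iterations) partitions the
kinase-ligand embedding into k neighborhoods; k = 3 is the default, and
`selectK()` re-runs a small remodeling trial for each candidate k (2–5 by
default) scoring valid-molecule yield first and scaffold diversity (mean
pairwise Tanimoto distance of the valid outputs) as the tie-break, with
remaining ties resolved toward the smallest k.

The remodeling operator is the controlled interpolation

  x* = x + s·(c − x) + ε,

where c is the centroid of the molecule's cluster (new molecules are
assigned to the nearest centroid of their own encoding), s ∈ [0, 1] is
the scaling factor (0 keeps the original encoding, 1 jumps to the
centroid) and ε is isotropic Gaussian noise. The contraction identity
‖x* − c‖ = (1 − s)‖x − c‖ holds exactly at ε = 0 and is tested as such.
Defaults follow the published protocol: s = 0.8 and noise sd 5.0 in raw
latent units. Because 5.0 is large against typical per-dimension spreads
(≈1.3–2 both in the published latent statistics and in our trained toy
models), a "relative" noise mode is provided that scales the sd by the
per-dimension spread of the reference embedding; the absolute mode
remains the default for protocol fidelity.

**Noise saturation in the substitute decoder.** In the built-in
feed-forward VAE, valid-decode yield falls steeply as noise grows from 0
to about three latent standard deviations and then *flattens*: beyond
that distance the tanh decoder is saturated, so sd 5 and sd 10 sample the
same asymptotic regime and their yields are statistically
indistinguishable (the acceptance suite measures the non-strict
direction, yield(5) ≥ yield(10), on a paired, pooled design, together
with the unambiguous degradation from sd 0 to sd 10). A recurrent decoder
would likely degrade more gradually; the steep-then-flat profile is a
property of the substitute architecture, not of the protocol.

`generateNeighborhood()` chains encode → remodel → decode-with-retries →
length filter → KAL scoring, deduplicates identical decodes with a
multiplicity count, attaches origin family, source molecule, attempt
counts, similarity to the reference set and drug-likeness properties, and
flags qualifiers (KAL > 0.7 marks a *potential target-family-like
ligand*). A per-input ledger assigns every input exactly one fate
(`generated`, `decode_failed`, `length_filtered`, `descriptor_failed`) —
a conservation law enforced by stub-harness tests. Identical seeds
reproduce the generated set byte for byte.

# Diagnostics

`pcaProject()` is mean-centered PCA with components ordered by explained
variance; `kdeDensity()` lays a Gaussian kernel density on a 200×200 grid
over the projected range plus a 5% margin, with per-axis bandwidths from
Scott's rule (σ·n^(−1/6) in two dimensions); degenerate (zero-variance)
projections error with advice to jitter. `familyLatentStats()` reports,
per family, the global min/max over all latent entries and the extrema of
the per-dimension means and standard deviations — the compact summary
format used for family-level latent comparisons (single-vector families
report zero sds). `generationReport()` computes qualifier counts and
percentages (rounded half-up to two decimals, matching printed
conventions; 0.5 is the exploration baseline and 0.7 the qualification
threshold), KAL summaries, similarity summaries with the 0.75
high-similarity cutoff (strict inequality), property histograms (integer
bins for ring counts, 20 equal-width bins for continuous properties) and
per-origin-family attribution fractions among qualifiers (summing to 1).
An empty generated set yields a defined all-zero report.

# The synthetic library

`generateToyLibrary()` emulates the *structure* of a kinase-ligand corpus
at desk scale: four families built on fused aromatic cores echoing real
kinase chemotypes (4-anilinoquinazoline-, pyrrolopyrimidine-,
aminopyrimidine- and quinazoline-ether-like), each substituted from a
common pool via string templates with a single attachment point (which
keeps validity at 100% without a reaction engine), against a mostly
acyclic ester/amine background. The designed contrast — families carry at
least two more aromatic rings than the background on average — makes the
family signal learnable, which is the parameter-recovery check for the
whole pipeline (cross-validated AUC ≥ 0.95 with ring-related descriptors
top-ranked). Synthetic potencies are log-normal around 50 nM for family
members. What the library does **not** emulate: real structure–activity
relationships, realistic scaffold diversity within a family, tautomeric
and stereochemical richness, or the size of real corpora. Passing tests
on it demonstrates that the pipeline's machinery is correct and that its
statistical behavior is directionally faithful — not that the real-data
numbers of any particular study are reproduced.

Default sizes are 60 molecules per family and 240 background molecules
(480 total), the campaign default throughout; the test suite uses 25/90
for speed. These sizes keep the full campaign (training, scoring,
clustering, generation at 500 decode retries, one optimizer run) around a
minute on one CPU.

# Determinism and numerical choices

Every stochastic stage takes a seed; `runCampaign()` fans a single global
seed out to per-stage seeds via a documented splitting rule
(`spawnSeed()`), so stages can be re-run in isolation and identical
configurations reproduce identical artifacts byte for byte. Random-forest
fits, k-means initialization, VAE training, decoder sampling, noise
draws, background subsampling and optimizer probes all draw from seeded
streams that are restored afterwards.

Numerical safeguards: Cholesky jitter escalation (0 → 1e-4) for GP
covariances; log-variance clamping and max-stabilized softmax in the VAE;
EI's σ → 0 limit handled analytically; posterior variances clamped at 0;
argmax ties broken by first occurrence everywhere (similarity argmax,
CV-pooled class predictions); `selectK` ties resolved toward smaller k;
qualifier percentages rounded half-away-from-zero to two decimals.

# Known limitations

* The feed-forward decoder cannot represent inter-position dependencies;
  its off-manifold validity profile saturates (see above) and it
  under-generates multi-ring systems when sampling far from training
  points — the same representational bottleneck that motivates
  scaffold-aware generation in the first place.
* KAL is a structural-similarity probability, not an activity or potency
  model; its scores are only as meaningful as the training pools.
* The exact GP limits history sizes (subsetting beyond `gpCap`); inducing
  point approximations are out of scope.
* Tautomer-normalized canonical SMILES depend on the installed RDKit
  version.
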