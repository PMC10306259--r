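---
title: "Methods: fragment-based generative design with multiobjective RL"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fragment-based generative design with multiobjective RL}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its models and the design
choices behind them. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The problem

Given (i) a corpus of drug-like molecules and (ii) a profile of desired
properties, produce novel molecules that satisfy the profile. The package
solves this in three stages: preparation of training data from SMILES,
supervised training of a generative model of chemistry, and a
reinforcement-learning (RL) stage in which the generator is rewarded by a
multiobjective scoring environment.

## Molecule preparation

Standardization canonicalizes each input with Open Babel, keeps the
largest covalent component of multi-component inputs (salt/solvent
stripping) *before* the organic test, and neutralizes charges where a
single proton addition or removal suffices (e.g. `[NH3+]` to `N`,
carboxylate to acid); quaternary nitrogens and other charges that cannot
be fixed by a proton are left as they are. "Organic" means all elements
within {H, B, C, N, O, P, S, F, Cl, Br, I} and at least one carbon — the
standard medicinal-chemistry element set. The training window is 200–1000
Da of average molecular weight; both bounds are `prepConfig()` parameters.

Fragmentation implements the published BRICS chemical-environment labels
(L1–L16) and their allowed-pair table as predicates on the package's own
molecular graph, cleaving all matched acyclic single bonds (plus the
olefin double-bond rule) in one pass; RECAP is provided as a reduced
bond-rule set (amide, ester, amine, urea, ether, olefin, quaternary N,
aromatic-N–aliphatic-C, lactam-N, biaryl, sulfonamide). The BRICS
implementation is checked in the test suite against leaf counts computed
independently with RDKit's implementation on a reference set, and against
a hand-derived count for biphenyl.

Fragment–molecule training pairs enumerate subsets of a molecule's
distinct leaf fragments up to `maxFragments` (default 4) per subset. The
number of subsets is capped (default 16 per molecule, sampled under a
fixed seed) so corpus size stays linear in molecule count; an uncapped
enumeration would grow as 2^leaves.

## Encodings

The SMILES codec tokenizes with bracket atoms, `%nn` ring closures and
the two-letter elements as atomic tokens, and frames sequences as
`GO … EOS PAD…`. The `"."` fragment separator is always in the
vocabulary so fragment combinations encode without a rebuild.

The graph codec writes a 5 × L integer matrix (L = 400 by default) in
four blocks: one GO column, a fragment block of width d = L − 2 − 38
(38 columns are reserved for linking), one EOS column, and the linking
block. Within a fragment, atoms appear in BFS order from the
lowest-numbered atom of the canonical structure, one column per atom
(atom-type code, 0-based index, bonded-neighbor index — self at a
fragment start — bond code, 1-based fragment index); a bond that closes a
ring appears as an extra column whose atom index refers back to an
existing atom. Linking columns restore the bonds cleaved between
fragments, so decoding reconstructs the complete molecule; round-trip
identity over fixture corpora is asserted in the tests.

Two deliberate choices:

* **Kekulized bond orders.** The codec stores single/double/triple bonds
  only (the aromatic code exists in the bond vocabulary but is unused by
  the default codec). Reason: the graph sampler guarantees validity by a
  *local* valence audit, and aromatic (order-1.5) bonds break locality —
  a sampled aromatic bond is only chemically meaningful if a complete
  aromatic ring closes later, which a per-step mask cannot promise.
  Aromatic systems are learned as alternating Kekulé patterns and
  re-perceived on decoding.
* **Stereochemistry** is preserved by the SMILES codec (it is plain text)
  and dropped by the graph codec, whose atom vocabulary is element +
  formal charge.

## Generators

No deep-learning backend is available to R in this environment, and the
generators are part of the package's subject matter, so they run on a
small reverse-mode automatic-differentiation engine written here
(`R/autodiff.R`): a tape of matrix operations (matmul, broadcast add,
sigmoid/tanh/relu, softmax with masks, layer normalization, embedding
gather, fused softmax-cross-entropy) with gradients verified against
finite differences in the test suite. Adam with a fixed learning rate is
the only optimizer; training is bit-reproducible under a fixed seed
because everything runs through R's own RNG and BLAS-free `%*%` on small
matrices.

Hyperparameter defaults are deliberately desk-scale (embedding 32, hidden
64, model dim 32, 2 heads, 1–2 transformer layers); the recurrent depth
default is three layers. Sampling is multinomial at temperature 1.

* **RNN**: token-level SMILES language model; unconditional.
* **Sequence transformer**: decoder-only; conditioning is in-band
  (`GO frags SEP molecule EOS`) with the loss restricted to positions
  after `SEP`. Sampling continues a `GO frags SEP` prefix.
* **Graph transformer**: a transformer encoder reads the input-fragment
  columns; its mean-pooled context feeds a GRU decoder that emits events:
  *add atom of type t bonded to atom i with order b*, *close a bond
  between atoms i and j*, or *stop*. During sampling each head is masked
  to chemically admissible options (free valence on both ends, no
  duplicate bonds, bond order capped by the remaining valence), so every
  sampled graph is a valid molecule — validity is structural, not
  learned, and holds for an untrained model, which the tests exploit.
  If generation stops with the input fragments still disconnected, the
  sampler links components with single bonds where valence allows (and
  otherwise keeps the largest component). The decoder records its exact
  event trajectory so the policy gradient rescales the log-probabilities
  of the actions actually taken.

One known asymmetry: during training the conditioning columns come from
the parent molecule's traversal, while at sampling time they come from
parsing the fragment combination itself. The two orderings can differ for
isomorphic fragments; this is a distribution-shift quality issue, not a
correctness issue, and is acceptable at the package's scale.

## Scoring environment

Raw scorers map SMILES to numbers; invalid molecules score `NA`.
Modifiers map raw scores to [0, 1] desirability:

* `modifierClipped(low, high)` — piecewise-linear ramp, 0 at/beyond
  `low`, 1 at/beyond `high`, reversed when `low > high`.
* `modifierGaussian(center, sigma)` — `exp(−(x−center)²/(2σ²))`.
* `modifierSmoothHump(lower, upper, width)` — a plateau built as the
  product of two logistic sigmoids shifted outward by `width` with scale
  `width/5`, rescaled so the supremum (at the plateau midpoint) is
  exactly 1. The exact functional form is this package's choice; the
  requirements it meets are: ≈1 on `[lower, upper]`, symmetric decay on
  scale `width` outside, range [0, 1].
* `modifierIdentity()` — clamps to [0, 1]; for scorers that already emit
  desirabilities.

A compound is **desired** when every objective's modified score is at or
above its threshold; the comparison is `>=` so a threshold of 1.0 is
reachable. Thresholds default to 0.5. Invalid molecules get modified
score 0 on every objective (rather than being dropped), keeping batches
rectangular and letting RL penalize invalidity implicitly. A scorer that
raises an error loses its column for that batch (logged), and the failed
column does not veto desirability.

## Multiobjective ranking

* **WS** — dynamic weighted sum with w_j ∝ 1 − (column mean of objective
  j), normalized to sum 1: the worse the population currently does on an
  objective, the more that objective counts. The choice of the *mean* as
  the population statistic is this package's; minima would be more
  aggressive but are dominated by single outliers.
* **PRCD / PRTD** — non-dominated sorting (domination-count algorithm,
  checked against a definitional peeling oracle on random instances)
  followed by intra-front ranking: NSGA-II crowding distance (boundary
  solutions infinite, interior solutions the normalized neighbor-gap
  sum) or the mean Tanimoto distance of each molecule to the rest of its
  front (2048-bit circular fingerprints, radius 2, computed on the
  package's molecular graph). The global order maps linearly to rewards
  with desired compounds in [0.5, 1] and undesired in [0, 0.5) — the
  split value and the linear map are package choices; they preserve order
  within each class and give a lone desired compound reward 1 and a lone
  undesired compound reward 0. Ties everywhere break on canonical SMILES
  so runs are reproducible.

## The explorer

Per epoch: sample `batchSize` molecules, each from the frozen prior with
probability ε (default 0.1) and otherwise from the agent (optionally
50/50 from the current agent and an auxiliary copy refreshed every
`syncInterval` = 50 epochs — on by default only for the RNN); score;
assign rewards (invalid molecules forced to 0); take one REINFORCE step
with loss `mean_b[ −Σ_t log p(token_t) · reward_b ]`; log metrics. The
desirability ratio selects the best epoch; patience controls early
stopping. Metric definitions: valid = parsable fraction; unique =
distinct canonical SMILES over batch size; accurate (fragment models) =
fraction of valid outputs containing all their input fragments as
substructures; arithmetic/geometric means are per-molecule means of
modified scores averaged over valid molecules, so geometric ≤ arithmetic
holds row-wise and in aggregate.

## The synthetic corpus

`makeCorpus()` assembles molecules combinatorially from curated building
blocks — aromatic and saturated rings, amide/ester/ether/sulfonamide/
alkyl linkers, small substituents — with per-unit ring-closure digits so
nesting is always syntactically valid, then canonicalizes, deduplicates
and filters to the requested weight window. This guarantees validity and
reproducibility without downloads, and `elementBias` lets tests construct
property-shifted corpora (e.g. nitrogen-rich) with the same seed.

What it emulates: a small drug-like screening series with 2–3 ring
systems and synthetic linkers, MW ~200–500 Da. What it does not: the
property distributions, scaffold diversity and size range of real
compound collections (ChEMBL-scale corpora, macrocycles, charged species,
stereochemistry-rich chemistry). Passing tests therefore demonstrate the
*mechanics* — codecs, training dynamics, reward plumbing, the validity
guarantee — at desk scale, not generative quality on real screening data.

## Problem sizes and numerical choices

The test suite and acceptance script use corpora of 100–250 molecules,
generators with 10⁴–10⁵ parameters, pretraining runs of 30–45 epochs and
RL runs of 10–12 epochs × 32 molecules from 5 seeds — sizes chosen so the
whole suite completes in minutes on one CPU while still exhibiting the
qualitative behavior of interest (loss descent, fine-tuning shift,
desirability improvement in ≥4 of 5 seeds). Other numerics: softmax
probabilities are floored at 1e−12 inside logs; early stopping improves
on the best monitor by more than 1e−12; layer-norm ε is 1e−5; Adam uses
(0.9, 0.999, 1e−8); weight init is uniform ±1/√fan-in with layer-norm
gains fixed at 1.

## Known limitations

* Open Babel is the chemistry oracle: canonicalization, kekulization and
  aromaticity perception follow its conventions; molecules it rejects are
  treated as invalid.
* The internal aromaticity perception used by the fragmentation
  predicates is a Hückel-style rule for the common 5/6-membered and fused
  benzenoid systems; exotic aromatics may be labeled conservatively.
* RECAP is a reduced rule set; BRICS is the default and the one checked
  against an independent implementation.
* The graph codec drops stereochemistry; the sequence models may emit
  invalid SMILES (flagged, never silently dropped).
* Policy-gradient updates use the REINFORCE estimator without a baseline;
  at desk scale the dynamic-weight and Pareto rewards are informative
  enough, but large-scale use would warrant variance reduction.
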