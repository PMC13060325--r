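---
title: "Methods: surrogate-guided tree search for plastic-binding peptides"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: surrogate-guided tree search for plastic-binding peptides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(pepmcts)
```

This vignette explains the models and procedures implemented in `pepmcts`,
the assumptions behind them, the parameters that matter, and the design
decisions taken where the design was genuinely open. It states no result
that the package's tests or `scripts/acceptance.R` do not themselves
compute.

## The design problem

The object of study is a 12-residue peptide over an 18-letter alphabet (the
20 canonical amino acids minus proline, which restricts backbone
conformations, and cysteine, which forms disulfide crosslinks). An upstream
biophysical design tool assigns each peptide an energy-like score — a
binding free-energy estimate plus a scaled internal-energy term — where more
negative means stronger predicted adsorption to a plastic surface. That
score is expensive: it requires sampling peptide conformations on the
surface. `pepmcts` operates downstream of such a tool. It consumes
`sequence : score` tables, learns a fast surrogate, and searches sequence
space for peptides the surrogate predicts to bind strongly, optionally
trading affinity against water solubility or against binding to a competing
surface.

## Sequence-to-score surrogate

**Model.** An embedding layer maps each residue (integer-coded against the
alphabet, a strict bijection) to a dense vector; three stacked LSTM layers
read the embedded sequence N- to C-terminus; a linear head on the last
hidden state of the top layer emits the predicted score. The recurrent
architecture is chosen because residue contributions are context-dependent:
a purely compositional model cannot represent neighbour effects, which the
synthetic oracle deliberately includes (see below).

**Training.** Adam on mean-squared error, learning rate 0.001, 200 epochs
by default, minibatches of 256. Scores are standardised to the training
mean and standard deviation internally (predictions are returned on the
original scale); without standardisation the loss surface depends on the
arbitrary score offset. After every epoch the validation MSE is evaluated
and the parameter snapshot with the lowest validation loss across all
epochs — not necessarily the last — is returned, a cheap guard against
late-training overfitting. Training tables are deduplicated first: the
upstream tool scores a sequence once per conformation, and only the best
(most negative) score per sequence is meaningful as a label. The
train/validation/test split is a random 80/10/10 partition per record,
seeded; whether the original pipeline split by record or by design run is
unknowable from the outside, and a per-record split is the neutral choice.

**Architecture defaults** (hidden 64, embedding 16, batch 256) are sized
for a 12-mer problem on one desktop CPU; they are configuration, not
inference — no reference values exist for them. Sequences of any length
other than the model's training length are rejected rather than padded:
the design problem is fixed-length, and silent padding would change the
meaning of positions.

**Implementation note.** The LSTM, backpropagation through time and Adam
are implemented directly over R's BLAS-backed matrix operations. Minibatch
forward/backward passes are matrix-matrix products, so the R-level loop
overhead is negligible; training 40,000 records for 6 epochs at hidden size
32 takes about a minute on one CPU. Inference is deterministic for a fixed
trained state; training is reproducible per seed because all stochastic
elements (initialisation, shuffling) draw from one seeded stream.

## Constrained Monte Carlo tree search

The tree's nodes are sequence prefixes; an edge appends one residue. Each
iteration runs the four canonical phases:

1. **Selection** descends from the root by maximising UCB1,
   `X̄ + C·sqrt(ln n / n_i)`, over the legal children; unvisited children
   score `+Inf` and are taken first, ties broken by a seeded uniform draw.
2. **Expansion** creates one unvisited legal child.
3. **Rollout** completes the prefix by uniform draws over legal actions and
   evaluates the reward of the complete peptide.
4. **Backpropagation** increments visit counts and adds the (normalised)
   reward along the root path.

Every complete rollout sequence is deposited in a harvest pool keyed by
sequence; the design output is the top `pool_size` (default 100) unique
sequences by reward. This "best of rollouts" harvesting means the search
result does not depend on the tree's final greedy path, only on what the
rollouts actually visited.

**The UCB1 radical.** The canonical UCB1 bound has the square root; the
rule is sometimes printed without it. The package defaults to the canonical
`sqrt` form and exposes `ucb1_form = "printed"` for the literal no-radical
variant; both are tested against hand arithmetic.

**Reward normalisation.** Rewards from the score scale are unbounded and
their spread is problem-dependent, while UCB1's exploration term presumes
rewards of order one. By default the reward passed to the tree bookkeeping
is rescaled by the running minimum/maximum of all rewards seen so far
(`running_minmax`); the harvest pool always stores raw rewards. With
normalisation the default `C = sqrt(2)` is on a meaningful scale. Setting
`normalization = "none"` recovers literal bookkeeping.

**Constraints.** Per-residue maximum counts (e.g. `c(W = 3)`, the
three-tryptophan rule used to keep designs soluble) are enforced by action
pruning: a residue is legal only if its count has head-room *and* the
remaining positions can still be completed under the constraint set, so a
rollout can never paint itself into a corner. Unsatisfiable constraint sets
are rejected up front. The suite verifies that every harvested sequence in
constrained runs satisfies every constraint.

**Defaults** (`iterations = 20000`, `rollouts_per_expansion = 1`,
`C = sqrt(2)`) are choices, not reproductions: no reference values exist.
On an exhaustively enumerable instance (3-letter alphabet, length 4, 81
sequences) 20,000 iterations recover the brute-force optimum in at least
18 of 20 seeded runs, which the acceptance suite checks.

## Reward variants

- *affinity*: `−Score`.
- *solubility-augmented*: `−Score + SF·Sol`.
- *competitive*: `−(Score_target − Score_off) + SF·Sol`, maximising the
  predicted score gap favouring the target surface; swapping the two
  surrogates yields the mirror-image design problem.

`SF ≥ 0` (dimensionless) weighs solubility against the score terms;
`SF = 2` is the default for competitive design, the value found to balance
the two well. Rewards are kept literal here — normalisation is the search
module's concern — and `rewardComponents()` exposes the per-term breakdown
so affinity/solubility trade-off curves can be plotted directly.

**The solubility sign convention.** Summing a transmembrane-tendency
hydrophobicity scale over a peptide measures *membrane* affinity: a high
sum means a poorly water-soluble peptide. A reward that *adds* the raw sum
would therefore reward insolubility. Every `SolubilityScorer` in this
package returns larger = more soluble, so the ttH-based scorer exposes the
*negated* sum by default, with a `sign` option for the literal raw form.
The shipped scale (transmembrane tendency, Zhao & London 2006) is a data
file, replaceable by any `residue<TAB>value` table.

**The intrinsic-profile stand-in.** Sequence-based intrinsic solubility
predictors of the kind used in practice are proprietary; the package
provides a transparent stand-in with the same shape: each residue scores
`w_h·(hydrophilicity) + w_c·|side-chain charge| − w_a·(aromatic/bulk)`,
the profile is smoothed by a centred moving average (window 7, truncated at
the termini), and the sequence score is the smoothed-profile mean. With
window 1 the score is composition-determined; with window > 1 it
distinguishes clustered from dispersed hydrophobics, qualitatively matching
the observation that solubility depends on how hydrophobic residues are
arranged, not just how many there are. Externally computed solubility
values can be plugged in bit-faithfully via `externalSolubility()`; the
stand-in makes no claim of numeric agreement with any proprietary method.

## Shapley attribution

Attribution uses permutation-sampling Shapley estimation, which is
model-agnostic (it treats the predictor as a black box) and whose axioms
are testable. For each of `n_samples` (default 200) sampled permutations of
the 12 positions, a background sequence is drawn (uniform over the
alphabet by default; empirical frequencies optional), the true residues are
revealed in permutation order, and a position's marginal contribution is
the prediction change upon its reveal. The estimator telescopes, so the
per-peptide efficiency identity — values sum to `f(peptide) − E[f]` with
the expectation estimated over the sampled backgrounds — holds by
construction, and the Monte-Carlo standard error of every value is
reported. On a purely additive oracle the closed form
`value_i = w(s_i) − mean_alphabet(w)` is recovered within sampling error
(tested). Negative values indicate residues pushing the prediction toward
stronger binding. Peptide sets for attribution are drawn by stratified
sampling over 10 equal-width score bins with proportional (largest
remainder) allocation, which preserves the marginal score distribution the
summaries depend on.

## The synthetic oracle

The generator stands in for the upstream biophysical tool so the whole
pipeline is testable without external data. Its noiseless score is

`score(s) = b + a·( Σ_i [w(s_i) + m(i)] + Σ_i J(s_i, s_{i+1}) )`

with per-residue weights `w` (derived from the transmembrane-tendency
scale so bulky hydrophobics are favourable), a mild N-terminal positional
gradient `m`, and sparse nearest-neighbour couplings `J` (a few
bulky-pair penalties and salt-bridge-like bonuses). The couplings exist so
that a surrogate must learn genuine sequence context, while setting
`J = 0` yields closed-form Shapley values for testing. Dataset sampling
adds Gaussian noise, `noise_sd = 2` score units by default — small against
a score sd of ~11, capping attainable R² near 0.97 so surrogate evaluation
operates in a realistic high-but-not-perfect regime.

**Calibration.** `calibrateOracle()` draws `n_probe = 10000` uniform
random 12-mers and solves for `(a, b)` so the probe's noiseless sample
mean and sd equal the targets exactly; the polyethylene-like oracle is
calibrated to (−26, 11) and the polystyrene-like one to (−15, 9), the
reference statistics of the two upstream datasets. A fresh sample then
matches the targets within sampling error plus the small noise inflation
(`sqrt(11² + 2²) ≈ 11.18`), which the acceptance checks accommodate within
their stated bands. Calibration requires nonzero raw variance and is
idempotent.

**The biased source** mimics design-trajectory concentration at favourable
scores: uniform candidates are importance-resampled with Boltzmann weight
`exp(−score/T)` (default temperature 10 score units, 10× oversampling).

**What the generator does not emulate**: real conformational physics, the
actual residue preferences of any plastic surface, heavy-tailed or
multimodal score marginals, and correlations between scores of similar
sequences beyond nearest-neighbour coupling. Tests passing against the
synthetic oracle therefore demonstrate that the machinery (training,
search, attribution, analytics) works as specified — not that any
particular real plastic binds the designed peptides.

## Numerical and interface choices

- Positions are 1-based from the N-terminus, matching sequence-logo
  convention.
- Score tables accept tab or comma delimiters on read and always emit tab;
  lower-case sequences are uppercased rather than rejected.
- The standard deviation of a single-record table is reported as 0 with a
  `degenerate` flag rather than an error.
- Enrichment uses the natural log by default (configurable base) with
  pseudocount `1/(2K)` for a K-letter alphabet; the log ratio is undefined
  at zero frequencies and the pseudocount keeps disjoint-support
  comparisons finite (both behaviours tested).
- Kernel density comparisons use Scott's bandwidth rule on a shared,
  slightly padded grid.
- Unvisited-node UCB1 is `+Inf`; all stochastic tie-breaks draw from the
  search's seeded stream, so entire runs are bit-reproducible per seed.
- Saved surrogates keep weights and score-normalisation together in one
  binary payload so reloaded models predict bit-identically; the JSON
  manifest (format version, alphabet, architecture) is checked on load and
  inconsistencies are refused.

## Problem sizes used by the test suite

The suite exercises the study conditions at sizes chosen for a single CPU:
oracle calibration checks use 10,000-record tables; the constrained design
check harvests 100 peptides from a 20,000-iteration run; optimum-recovery
runs 20 seeded searches of 20,000 iterations on the 81-sequence instance;
surrogate recovery trains on 50,000 records (hidden size 32, two recurrent
layers, 6 epochs — capacity and training length sized to the additive+
coupling oracle, comfortably past the R² ≥ 0.8 bar); the solubility
trade-off scans SF over {0.5, 1, 2, 5, 10, 20} with 4,000-iteration
searches; competitive design uses paired oracles diverging only in
tryptophan. Larger runs change none of the code paths, only runtime.

## Known limitations

- The surrogate trains on CPU only and at desk scale; no GPU path, no
  transformer/graph architectures.
- Exact (exponential) Shapley values are out of reach at length 12; only
  the sampling estimator is provided, with its standard errors.
- The intrinsic-solubility stand-in is a documented heuristic, not a
  validated predictor; use the external-values plugin for production
  solubility scores.
- Search is single-threaded and uses no transposition table: prefixes that
  permute to the same multiset are learned independently.
- The synthetic oracle's realism limits end-to-end conclusions, as
  discussed above.
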