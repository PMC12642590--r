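---
title: "Biophysics-informed variant effect prediction: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Biophysics-informed variant effect prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biovep)
```

## The problem

Deep mutational scanning (DMS) measures functional scores for thousands of
protein variants by selecting a mutant library and sequencing the input and
post-selection pools. Supervised variant effect predictors (VEPs) trained on
such data interpolate well but extrapolate poorly: when asked about mutation
types, or worse, residue positions never seen during training, purely
sequence-encoded models collapse to near-zero correlation. The premise of
this package is that the physics of protein stability — how much each
substitution perturbs the folding free energy, and how flexible each residue
is — carries exactly the information that transfers across positions, because
it is computed per substitution from the structure rather than learned from
the assay.

`biovep` implements that idea end to end: per-residue feature encodings that
combine sequence one-hot and amino-acid-property channels with per-site
mutational energy terms (Rosetta energy units, REU) and residue flexibility
(RMSF); four regressor families (linear, dense, sequence-convolutional,
graph-convolutional); leakage-free extrapolation splits; a read-resampling
benchmark; and a synthetic data generator for controlled experiments.

## Feature encoding

A variant of an L-residue protein becomes an `L x D` matrix. Row `i`
describes the amino acid present at position `i`:

* **One-hot (21 columns).** Indicator over the 20 canonical amino acids plus
  the stop symbol `*`.
* **Amino-acid properties (19 columns).** An AAIndex-style `20 x P` property
  matrix is column-centered and compressed by PCA. Twenty centered points
  span at most 19 dimensions, so 19 components carry 100% of the variance;
  each score column is min-max normalized to [0, 1]. PCA runs first and
  normalization second, which preserves the orthogonality of the scores.
* **Energy terms (8 columns, biophysics mode).** A precomputed table holds,
  for every (position, substitution) pair including the wild-type
  self-substitution, the total folding free-energy change (`ddg_total`) and
  its per-term components. Because the table is computed by an external
  side-chain repacking protocol (repacking radius 12 Å, one repacking
  iteration; recorded in the table's header), very large positive values are
  steric-clash artifacts: values above 50 REU are squashed with
  `t + t*tanh((x - t)/t)`, a C1 map that is the identity below the threshold
  and saturates below `2t`. The total plus the 7 highest-variance component
  terms are kept (low-variance terms are uninformative), then min-max
  normalized. Wild-type rows carry the self-substitution entry; stop-symbol
  rows, which have no table entry, use the squash ceiling — a stop codon
  truncates the protein, so "maximally destabilizing" is the honest fallback.
* **RMSF (1 column, biophysics mode).** Per-residue Cα root-mean-square
  fluctuation from a molecular-dynamics trajectory, min-max normalized.

D is 40 without the biophysics blocks and 49 with them. Multi-mutant variants
place each mutation's single-mutation energy row at its own position;
additivity across sites is left to the model, mirroring how single-mutation
energetics are used to score higher-order variants.

Two normalization choices deserve a note. First, the energy and RMSF
normalizers are fitted on the full energy table and profile rather than on
the training split: both resources derive from the structure alone and
contain no assay labels, so no label leakage is possible, and
split-independent encodings let an experiment encode each dataset once.
Second, values outside a normalizer's range are clipped to [0, 1] rather
than extrapolated, so test-time features stay in the training envelope.

## Models

All four families minimize mean-squared error on the scores and are
evaluated with Pearson r, Spearman rho and MAE (stratified by mutation
count). Pearson/Spearman are reported as missing, not zero, when either
vector is constant.

* **LR** is an affine map on the flattened matrix, fitted by exact least
  squares (primal normal equations when `n >= p`, the dual minimum-norm form
  otherwise). An iterative fit adds nothing for a convex quadratic and the
  exact solve keeps the resampling grid fast.
* **NN** stacks dense layers with leaky ReLU.
* **CNN** applies stride-1, valid-padding 1-D convolutions across residue
  positions with features as channels, then flatten, a dense layer with leaky
  ReLU, dropout 0.2 and a scalar linear output.
* **GCN** replaces the convolutions with graph convolutions
  `H' = Ahat H W` over the symmetric-normalized contact-graph propagation
  matrix `Ahat = D^(-1/2)(A + I)D^(-1/2)` (self-loops added; an edgeless
  graph gives the identity, i.e. a per-residue dense layer). The contact
  graph joins residues whose representative atoms (Cα for glycine, Cβ
  otherwise) lie within a cutoff — 7 Å by default, 6 Å being more
  appropriate for large beta-rich proteins.

Training is seeded mini-batch Adam with decoupled (AdamW-style) weight decay
and early stopping on validation loss; initialization, batch order and
dropout masks are all deterministic functions of the config seed. Targets
are standardized internally (and predictions de-standardized) so the default
learning rate is scale-free. The gradient engine is implemented in plain
matrix algebra; batches flow through the convolutional layers in a
`(samples x positions) x channels` layout in which a stride-1 valid
convolution is `k` block matrix products, which is what makes CPU training
practical.

### Training for extrapolation: head decay, burn-in, snapshot averaging

Positional extrapolation puts unusual demands on the optimizer, and three
config-exposed mechanisms address them.

*Head-only weight decay.* In the CNN and GCN the convolution filters are
shared across positions, but the dense head after flatten indexes positions
individually. Under a positional split the features at held-out positions
are constant in the whole training set, so those head weights receive no
signal-aligned gradient: whatever the shared filters learn, an unconstrained
head absorbs the training fit into position-specific weights that transfer
arbitrarily — even with the energy channels present, the positional test
correlation of an undecayed model hovers near zero. Applying decoupled
(AdamW-style) weight decay to the dense layers only, while leaving the
shared filters free, makes position-specific readouts expensive and
position-balanced readouts cheap: the economical way to fit the training
data becomes "read the energy channels through the shared filters and
aggregate them near-uniformly", which is the solution that transfers. The
CNN and GCN default to a strong rate (10); a pure dense network would have
every layer penalized, so NN defaults to none.

*Burn-in and selection metric.* Under an extrapolation split the validation
set also lives at unseen positions, and its MSE is dominated by calibration
error long after the model ranks unseen-position variants well; tracked
across training, test rank correlation stabilizes while validation MSE
still fluctuates by tens of percent, so an MSE-argmax can select an
essentially untrained epoch. Two remedies: `early_stop = "spearman"`
selects by validation rank correlation (calibration-insensitive), and
`min_epochs` declares an initial burn-in whose epochs are never selected
(the transferable signal needs tens of epochs to emerge, while spurious
validation optima occur from epoch one).

*Snapshot averaging.* Transfer quality fluctuates epoch to epoch because
the head's unseen-position components keep drifting. Keeping the
`snapshots` best-validation weight copies and averaging their predictions
(iterate ensembling) removes much of that fluctuation at zero additional
training cost.

Two further knobs exist for experimentation — `restart_every` (warm
restarts: reload best weights, reset optimizer moments) and
`group_dropout` (feature bagging over whole encoding blocks) — but neither
improved positional transfer on the synthetic benchmark and both default
off.

## Splits

* **Random** 70/15/15: validation and test receive `floor(0.15 N)` variants
  each, the remainder trains.
* **Mutational extrapolation**: the unique (position, mutant) pairs are
  partitioned 70/15/15; a variant joins a partition only if *all* its
  mutations belong to it, otherwise it is dropped and logged. This is the
  only reading that guarantees zero mutation leakage; the drop is symmetric
  (training loses spanning variants too).
* **Positional extrapolation**: the same rule on mutated positions.

Splits are pure functions of (dataset, fractions, seed); wild-type records,
which carry no mutations, default to the training partition.

## The synthetic world

`generate_world()` builds a self-consistent fixture set: a random sequence on
an idealized alpha-helix backbone (2.3 Å radius, 1.5 Å rise, 100° twist,
Cβ 1.53 Å radially outward — the representative-atom contact graph is
connected at 7 Å), an energy table with 19 REF2015-style component terms of
geometrically decreasing variance (so variance-based selection is
exercised), about 2% of entries pushed past the squash threshold to mimic
clashes, zero self-substitutions, `ddg_total` equal to the component sum, a
smooth non-negative RMSF profile, and a random 20 x 30 property matrix.

Ground-truth fitness is a logistic stability-threshold model,

$$F(v) = \frac{F_{max}}{1 + \exp\!\big((\textstyle\sum_m \Delta\Delta G_{tot}(m) - \mu)/\sigma_f\big)},$$

with midpoint `mu = 5` REU and softness `sigma_f = 2` REU — cumulative
destabilization beyond a threshold abolishes function, the standard
stability-threshold view of mutational robustness. The logistic (rather than
a linear link) is deliberate: it creates the nonlinearity that separates the
convolutional families from plain linear regression. Observation noise is
Gaussian with s.d. 0.02 on a fitness scale of 1.

`generate_dms()` simulates the assay: variants drawn with a 45/45/10
single/double/triple mutation mix (the single-and-double-dominated shape of
typical DMS libraries), Gamma-distributed library abundances (wild type
enriched tenfold), input counts multinomial at 2x10^6 reads, selected counts
multinomial with probabilities proportional to `abundance * exp(3 F)`, and
enrichment scores `log2((sel+0.5)/(inp+0.5))` centered on the wild type —
the standard two-condition pseudocount form. At these settings the
enrichment scores rank-correlate with true fitness at rho ≈ 0.94, i.e. the
simulated assay is informative but not noise-free.

Because fitness depends on sequence *only through the energy table*, the
biophysics features are sufficient statistics for the fitness landscape.
This makes the generator a controlled testbed for the central claim: under
positional extrapolation, models without the energy channels have nothing
that transfers, while models with them do. Features of real data the
generator does *not* emulate: epistasis (non-additive interactions), errors
in the energy model itself (the table that generates fitness is the table
the models see, unless table noise is added explicitly), position-dependent
mutation biases, and replicate structure. Passing tests on synthetic data
therefore demonstrate the machinery and the extrapolation mechanism, not
real-data accuracy.

## The resampling benchmark

`score_and_grid()` reproduces the dataset-quality experiment: hold out a
fixed test set (default 10,000 variants, truncated to the dataset), then for
each (library size, read budget) cell repeatedly draw a uniform variant
subset, renormalize its input/selected counts into multinomial
distributions, split the read budget between pools in proportion to the base
pool's total input:selected fraction, draw fresh counts (always summing
exactly to the budget), rescore with the enrichment formula, train the
specified model and measure test Pearson r. Cells whose library size exceeds
the pool are reported empty. The default model for the grid is exact LR,
which keeps a full grid affordable; any config can be supplied. Resampled
libraries are scored against the *base* wild-type counts, since the wild
type need not survive subsampling and the centering term is a constant
offset that cannot change a correlation.

Accuracy is expected to be non-decreasing in both grid axes, but only above
the read-starved corner: at a very small budget, a larger library means
fewer reads per variant and noisier scores, a genuine tradeoff rather than
noise. `resample_trends()` therefore tests the directional claim with a
sampling-noise allowance (two standard errors of the cell-median
difference, estimated from the replicate spread), and the shipped checks
place the trend grid above starvation while probing the starved cell
separately for its expected degradation.

## Numerical choices and degenerate inputs

* Squashing is exactly the identity at and below the threshold and
  continuous with unit slope there; inputs must be finite.
* `fit_minmax()` refuses constant features (the correct response is to
  exclude them, as the variance-based term selection already does).
* Term-selection ties break lexicographically, so selection is deterministic.
* Constant-score datasets train fine; correlations are flagged undefined.
* The dual least-squares path adds a 1e-10 jitter for numerical stability;
  the primal path retries with the same jitter only on exact singularity.
* Early stopping keeps the best-validation weights, not the last ones.

## Problem sizes used in the shipped experiments

The package's own experiments (tests and the acceptance script) run on a
50-residue world with 5,000 variants, five seeded repeats per condition, and
resampling grids of a few hundred variants — sizes chosen so the full suite
reproduces the qualitative results of the large-scale experiments in
minutes on a laptop core while remaining statistically stable (medians over
five seeds).

## Known limitations

* Positional-extrapolation transfer in the CNN/GCN rides on
  kernel-window (or graph-neighborhood) overlap between trained and unseen
  positions, because the flatten-then-dense head is position-indexed and its
  unseen-position weights receive no training signal. The achievable
  unseen-position correlation is therefore partition-dependent and
  substantially below the interpolation regime even when the energy features
  determine fitness exactly; expect run-to-run spread across split seeds and
  judge experiments on medians over several repeats.

* The energy adapter contract is data-only: the package reads the table
  format but never runs a molecular-mechanics engine, so real-protein use
  requires an external ddG computation.
* Single chain, single model, no insertion codes in structures; no
  multi-chain complexes.
* The enrichment score is the two-condition pseudocount form; multi-timepoint
  regression scoring (as in full Enrich2) is out of scope, so absolute score
  scales differ from pipelines that use it.
* Training is CPU-bound plain R; it is sized for tens of residues and
  thousands of variants, not for half-million-variant datasets.
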