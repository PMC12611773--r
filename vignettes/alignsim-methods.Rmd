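---
title: "alignsim: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{alignsim: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alignsim)
```

This vignette is the package's own account of its models and the
choices behind them. It states no empirical result that the test suite
or the acceptance script does not itself compute.

## 1. The choice model

Every behavioural quantity in the package reduces to one generative
rule: given a triplet {i, j, k} with pairwise similarities
`S_uv = x_u' x_v` (raw dot products, deliberately unnormalized — the
cosine and Pearson kernels exist only in the RSA module, where scale
invariance is wanted), the probability that pair (a, b) is judged most
similar is the three-way softmax at temperature τ,

$$ p(a,b) = \frac{\exp(S_{ab}/\tau)}{\exp(S_{ij}/\tau) +
\exp(S_{ik}/\tau) + \exp(S_{jk}/\tau)}, $$

computed with max-subtraction so large similarity magnitudes cannot
overflow. The odd one out is the item excluded from the argmax pair.
Exact ties are broken in the fixed order (i,j) < (i,k) < (j,k): the
literature does not prescribe a tie rule, and a deterministic one makes
every downstream computation reproducible and testable. Entropies are
natural-log (nats): rank correlations with latency are base-invariant,
and nats make the KL bookkeeping exact against the losses.

## 2. Synthetic world

The generator exists so that every downstream stage is testable with no
external data. Its defaults encode the stated world of the tests, not
tunable dials.

**Concept hierarchy.** `generate_hierarchy()` draws superordinate
centroids from an isotropic Gaussian (spread `level_spreads[1]`), basic
centroids around them (`level_spreads[2]`), and items around basic
centroids (`level_spreads[3]`). Isotropic Gaussians at each level are
the simplest generative process with the right qualitative signature:
within-basic distances < within-superordinate < across-superordinate
whenever spreads decrease down the hierarchy. The subordinate label
coincides with the basic cell's leaf by default — the generator has
three geometric stages, so a finer subordinate geometry would be
invented structure; analyses that need all four relation levels
populated (the hierarchy contrast) accept arbitrary label tables.

**Annotators.** A rater chooses from the softmax rule at a personal
temperature, except with probability `lapse_rate` the choice is uniform
— the standard lapse-contaminated psychometric observer. Response
times follow `log RT = a + b·H + ε`, with H the entropy of the
lapse-mixed choice distribution and ε Gaussian. No published generative
model of odd-one-out RTs exists; the log-linear entropy link is an
artifact choice, made on the log scale deliberately so the evaluation
module's log-transform preprocessing is exercised non-trivially. The
base seed is split into one deterministic substream per annotator, so
simulations are reproducible and annotators independent.

**What a green test does not establish.** The generator produces
exchangeable Gaussian items, rater homogeneity up to temperature/lapse,
and an exactly log-linear RT coupling. Real image datasets have heavy
class imbalance, non-Gaussian embedding geometry, individual
differences across participants, and RT confounds (fatigue, position
effects) that this world omits. Recovery results here certify the
estimators, not ecological validity.

## 3. Uncertainty model

`fit_uncertainty_model()` fits a mean-field Gaussian embedding
(μ, σ per item and latent dimension) by maximizing the reparameterized
expected log-likelihood of the observed hard choices. Design choices:

- **Prior.** The original spike-and-slab variational prior serves
  sparse interpretable dimensions, which this package does not need;
  it is replaced by a standard-normal KL regularizer with a small
  weight (default 1e-3 per response). What matters downstream is only
  that the posterior produces calibrated triplet distributions.
- **Positivity.** σ is parameterized through a softplus link so the
  optimizer is unconstrained.
- **Monte-Carlo posterior.** `mc_triplet_probabilities()` averages the
  τ=1 softmax over R sampled embeddings; R = 50 is the default (the
  published operating point). The estimate is always a simplex point;
  its across-seed variance shrinks as R grows (tested).
- **Convergence.** Fixed epoch budget with early stopping on held-out
  NLL (seeded 20% split, patience 20). The MC seed used for held-out
  scoring is fixed across epochs so the stopping criterion compares
  like with like.

## 4. Affine alignment (uncertainty distillation)

`fit_transform()` minimizes
`mean KL(p* || q(Wx+b)) + λ ||W − (tr W/p) I||_F²` by minibatch Adam
with hand-derived analytic gradients (no autodiff framework exists in
the dependency footprint; the gradient of the penalty is exactly
`2λ(W − (trW/p)I)` because the trace term's inner derivative cancels).

- **Initialization** at W = I, b = 0: the penalty's null space is the
  scaled identities, so the starting objective carries no penalty and
  the pretrained similarity structure is the point of departure. This
  also makes self-distillation (targets produced by the untransformed
  space) an exact fixed point — a test anchors this.
- **λ default 0.01**, with the grid 1e-3…1e1 exercised in tests: the
  deviation of W from a scaled identity shrinks monotonically along
  the grid, which is the penalty's stated purpose
  (nearest-neighbour preservation is asserted at ≥ 90% in the
  self-distillation test).
- **τ = 1** inside q, consistent with the hard-alignment likelihood.
- A note on recovery testing: an *orthogonal* target map is
  undetectable in this objective, because rotations preserve all dot
  products. Recovery tests therefore use a well-conditioned general
  affine map (identity plus Gaussian perturbation, plus bias), which
  is the weakest structure that makes the problem non-trivial.

## 5. Triplet sampling and pseudo-labelling

Four samplers share one contract — every emitted triplet satisfies its
defining constraint, checked exhaustively per batch in tests:

- *random*: three distinct items uniformly;
- *class boundary*: two items from one class, one from another (the
  eligible pair-class is drawn uniformly over classes with ≥ 2 items);
- *cluster boundary*: identical, with seeded k-means labels
  (5 restarts, best inertia) in place of classes — it degrades exactly
  to class-boundary sampling when clusters coincide with classes;
- *levels-stratified*: superclass draws are uniform over superclasses
  (not items), then one subclass, then items — so over-represented
  fine classes are not over-sampled; `coarse` takes three superclasses,
  `fine` three items of one subclass, `boundary` two plus one.

`select_k_elbow()` operationalizes the elbow criterion as the interior
candidate maximizing the discrete second difference of the inertia
curve. A knee is only declared when the maximal curvature exceeds 20%
of the total inertia drop; otherwise the curve is effectively smooth
(featureless data), and the smallest candidate is returned flagged
`low_curvature` — a documented fallback rather than a silent arbitrary
pick. Full-scale runs would fix c around the published operating point
(hundreds of clusters); desk-scale tests let the elbow choose from a
small grid.

Pseudo-labels are deterministic: the τ=1 softmax of transformed teacher
similarities (soft) and its argmax (hard). Duplicate triplets across
draws are allowed — the sampling design does not deduplicate.

## 6. Student distillation

`distill()` minimizes the batch-mean
`KL(σ(S′, τ′) || σ(S†, τ†)) + λ_wd ||θ* − θ||²` over the student
parameters. Teacher distributions are precomputed and frozen, matching
an offline pseudo-labelling pipeline. Built-in students are a linear
map and a one-hidden-layer tanh network over item features, trained by
backpropagated analytic gradients; the contract accepts the two
built-ins, and the loss functions accept any similarity matrix, so an
external encoder can be evaluated against the same objective.

Temperatures default to τ′ = 1 and τ† = 100 — the published full-scale
operating point, where backbone similarity magnitudes are of order
hundreds. Desk-scale synthetic similarities are O(1), so the pipeline
config and the tests pass τ† = 1; at τ† = 100 the student softmax is
nearly uniform at desk scale and gradients vanish. Both temperatures
are plain arguments precisely because this scale mismatch is expected.

Weight decay is to *initialization*, not to zero: the penalty is the
squared distance from the pre-fine-tuning snapshot, stored by the
encoder constructor. The penalty-dominated limit (huge λ_wd, small
step size) pins parameters to the snapshot, which the tests verify at
relative change < 1e-3.

## 7. Evaluation

- **Majority responses**: modal pair per triplet; 2-2-1 ties (possible
  with 5 raters) are broken uniformly from the seeded stream and the
  rule is documented rather than silent.
- **Noise ceiling**: leave-one-out — each held-out response is
  compared with the majority of the remaining raters of the same
  triplet; triplets with one response are excluded with a warning.
  Unanimous data gives exactly 1; uniform raters converge to 1/3.
- **RT preprocessing**: natural log; trials above 10 s excluded with a
  *strict* inequality (10.0 s stays in); no lower bound. Participant
  filters: catch accuracy ≥ 0.90 and ≤ 10 missing trials.
- **RSA**: Pearson-kernel RSMs (cosine of row-centred vectors;
  constant rows are rejected by name), compared by Spearman correlation
  of strictly-upper triangles with average-rank ties.
- **Hierarchy contrast**: all pairwise Euclidean distances per
  checkpoint are z-scored within the checkpoint (removing global scale,
  which grows during training), and the per-pair change in z is
  averaged per relation level. Pairs are first aggregated within their
  sorted basic-category pair so populous categories do not dominate a
  level mean — a fixed-effect substitute for the mixed-effects
  regression that would account for cluster non-independence, which is
  out of scope here. Euclidean distance is used because the analysis
  concerns geometric reorganization; similarity-based behaviour always
  uses dot products.
- **Bootstrap CIs**: percentile 95% intervals of the mean over 100
  item-level resamples of 1,000 (defaults), seeded.

## 8. Numerical conventions

Softmax with max-subtraction everywhere; 0·log 0 := 0 in entropies and
KL entropy terms; cross-entropy guards probabilities at 1e-300 (softmax
outputs cannot be exactly 0 in exact arithmetic, but subnormal
underflow can occur at extreme similarity scales); soft-target rows
must sum to 1 within 1e-6; matrices serialize at 17 significant digits
so TSV round trips are exact to < 1e-12; all on-disk indices are
0-based, all in-memory indices 1-based, converted only at the IO
boundary; derived seeds use a fixed affine hash kept below 2^31.

## 9. Known limitations

- The optimizers are plain-R Adam loops: adequate at desk scale
  (hundreds of items, thousands of triplets, seconds to minutes), not
  for million-triplet corpora.
- The variational fit maximizes likelihood with a simplified prior; it
  recovers choice structure and disagreement ordering (tested) but is
  not a faithful reimplementation of the published sparse variational
  embedding, and its dimensions are not interpretable.
- The annotator model has no individual-difference structure beyond
  temperature and lapse; noise ceilings on synthetic data are
  therefore optimistic relative to human panels.
- Full-scale published results (vision backbones, external triplet
  corpora, benchmark gains) require GPU-scale models and external
  datasets; nothing here reproduces them, and the acceptance report's
  single in-paper target is the relative-improvement computation on
  the published teacher accuracies.
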