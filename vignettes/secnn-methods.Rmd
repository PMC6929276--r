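---
title: "secnn: methods, assumptions, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{secnn: methods, assumptions, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models and procedures `secnn` implements, the
assumptions behind them, the tunable parameters and why their defaults are
what they are, and what the synthetic benchmarks do and do not establish.
Nothing here states an empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The problem

Super-enhancers (SEs) are stitched clusters of enhancers with exceptionally
high Mediator (Med1) occupancy. The reference procedure for defining them
(ROSE) needs Med1 ChIP-seq; the question this package operationalizes is
whether SE status is predictable from a broader, cheaper panel of chromatin
features — histone marks, coactivators, chromatin regulators, cohesin,
DNase hypersensitivity, transcription-factor binding, and sequence-derived
quantities — and which of those features carry the signal.

## Signal quantification

Read densities are reads-per-million-mapped per base pair:

    density(region) = overlapped_bases / region_length * 1e6 / total_mapped

* Overlap is counted in **bases of (extended) reads**, not read midpoints,
  and is linear in read multiplicity (duplicated reads count twice; no
  deduplication — out of scope).
* Reads are extended to `max(read_length, ext_len)` in their strand
  direction, default `ext_len = 200` bp. 200 bp is the conventional ChIP
  fragment size; the source procedure leaves it unspecified.
* Background normalization is **unfloored subtraction** of the matched
  control density. Negative densities are allowed and documented: SE
  calling ranks entities by *total* signal, and flooring would silently
  reorder the ranking near zero.

## SE calling

1. **Stitching**: enhancer intervals on one chromosome whose end-to-start
   gap is at most 12.5 kb merge transitively (overlaps always merge);
   isolated enhancers pass through as singleton entities. The gap is
   measured end-to-start, the standard ROSE behaviour.
2. **Ranking**: each stitched entity is scored by
   `background-normalized density over its span x span length`.
3. **Cutoff**: signals are sorted ascending; both axes are min-max scaled;
   the cutoff is the signal at the left end of the first segment whose
   discrete slope exceeds 1; entities strictly above it are SEs. If no
   slope exceeds 1 (all signals equal) the cutoff is the maximum and
   nothing is called.

Two caveats are worth stating plainly. First, on a min-max-scaled ranked
curve the *mean* discrete slope is exactly 1, so the slope rule is only
meaningful for convex, hockey-stick-shaped curves — the shape real ranked
Med1 signal has. On a featureless (near-linear) curve the first slope > 1
occurs early and a large fraction of entities would be called; the package
does not guard against this, it is inherent to the rule. Second, the
negative class used downstream ("typical enhancers") is simply *stitched
entities not called SE*; this is a modelling convention, not a biological
definition.

The TSS-proximal exclusion some ROSE variants offer is deliberately not
implemented (not part of the procedure being reproduced).

## The 36-feature matrix

The fixed registry (see `feature_registry()`) holds 31 signal columns —
four histone marks, Brd4, Cdk8, Cdk9, Med12, p300, CBP, Pol2, Lsd1, Brg1,
Smc1, Nipbl, Mi2b, CHD7, HDAC2, HDAC, DNaseI, and eleven transcription
factors — plus AT content, GC content, mean phastCons, phastConsP, and
soft-masked repeat fraction. Notes:

* **Med1 is excluded by construction** (it defines the labels); Med12, a
  distinct Mediator subunit, is a feature. `assemble_features()` refuses a
  `Med1` column outright.
* HDAC and HDAC2 sit in the registry although no standard mESC ChIP track
  exists for them in the reference data inventory; callers typically fill
  them from affinity proxies or zeros. The discrepancy is inherited from
  the source feature list and kept for fidelity.
* TF columns may be ChIP densities where tracks exist or PWM affinities
  where they do not; `assemble_features()` records each column's source
  part in the `sources` attribute.
* `phastConsP` is the fraction of bases with conservation ≥ 0.5 (the name
  reads as "proportion"; the threshold is an argument).
* Motif affinity is the **best-hit log2-odds** over all windows on both
  strands (`sum_k log2(p_k/bg_k)`), with a sum-over-threshold alternative
  (`method = "sumthr"`). Best-hit is the simplest defensible reading of
  "binding affinity score"; no formula is given in the source.
* Per-column z-scoring defaults **on** for model input: the raw rpm scales
  differ by orders of magnitude across tracks and full-precision Adam at
  learning rate 5e-5 is poorly conditioned without it.

## The classifier

`build_cnn(L)` for L in 2..4 produces the published layouts: convolutional
layers of 32, 64, 128, 256 width-3 kernels (stride 1, same padding, ReLU),
each followed by a max-pool of width 3, 3, 2, 2 respectively, then one
256→64 fully connected layer with dropout and a 64→2 softmax. From an input
of length 36 every variant flattens to exactly 256 dense inputs
(36→12→4 for 2L; →2 for 3L; →1 for 4L, with channels doubling), which
`propagate_shapes()` verifies and the acceptance targets assert.

Treating the 36 features as a 1-D signal for convolution is a modelling
quirk inherited from the source architecture: adjacency in the registry
order is not biologically meaningful, and the registry order is therefore
fixed so results are reproducible.

Training minimizes the binary cross-entropy of the positive-class softmax
output with backpropagation and Adam. Choices where the source is silent:

| parameter | default | rationale |
|---|---|---|
| dropout rate | 0.5 | cited dropout method's canonical rate |
| batch size | 128 | see below |
| Adam β₁, β₂, ε | 0.9, 0.999, 1e-8 | the cited optimizer's defaults |
| weight init | seeded He scaling | "random initialization", scaled for ReLU |
| loss clip ε | 1e-12 | keeps `log` finite without visibly biasing J |
| early stopping | none | epoch counts are swept explicitly |

**Batch size.** The original design sketch here called for full-batch
steps by default. Implementation proved that wrong: at the published
settings (130 epochs, learning rate 5e-5) full-batch training performs only
130 Adam updates and cannot approach the loss minimum, while the source
procedure itself describes stochastic gradient descent. Default is
mini-batch 128; `batch_size = Inf` restores full-batch.

**Engine.** The production forward/backward/Adam loop is compiled
(RcppArmadillo; im2col convolutions so all heavy work is BLAS gemm). A
pure-R implementation of the identical algorithm ships in the package
(`engine = "r"`) and the suite asserts exact agreement between the two in
full-batch mode, plus finite-difference gradient checks — a dual-route
verification of the learning core. Both engines draw initialization,
shuffling and dropout from R's seeded RNG, so training is bitwise
reproducible per seed; the two engines shuffle differently, so they agree
exactly only where batch composition cannot differ.

**Degenerate regime.** At learning rates 1e-2–5e-2 on 9:1 imbalanced data
the optimizer thrashes and the model collapses to the majority class, so
accuracy pins at the negative fraction (~0.9) — the suite reproduces this
plateau on synthetic data as a property of the training dynamics, not as a
claim about real data.

## Evaluation

Precision `TP/(TP+FP)`, recall `TP/(TP+FN)`, `F1 = 2PR/(P+R)`, accuracy
`(TP+TN)/n`. Undefined denominators raise errors rather than returning 0;
`eval_report()` records them as absent with a note so cross-validation can
aggregate. AUC is computed as the Mann–Whitney statistic (ties ½), which
equals the trapezoidal area under the ROC curve; the tie convention is
explicit and tested against O(n²) pair counting. Cross-validation is
stratified: per-class shuffled round-robin assignment, each sample tested
exactly once. The grid search scores all 264 combinations (3 layer counts ×
11 epoch values × 8 learning rates) by cross-validated accuracy — held-out
accuracy, since the source does not say; ties break toward the smaller
model, then fewer epochs, then the smaller rate.

Feature ranking is the Pearson correlation of each column with the 0/1
label vector (point-biserial), ranked by |r|: the source reports positive
correlations only, and |r| is the safe generalization when effects can run
either way. Constant columns are excluded and reported.

## The synthetic world

`simulate_reads()` draws Poisson read counts on a piecewise-constant rate
(uniform background × per-peak fold) with uniform placement and 50/50
strands. It emulates enrichment and library-size normalization; it does
**not** emulate fragment-size distributions, GC bias, mappability, or
duplicate artifacts. `make_se_fixture()` plants clusters of 2–4 enhancers
(gaps ≤ 8 kb, well under stitching range) spaced 60 kb apart (well over
it), with 5 of 100 clusters at fold 60 Med1 enrichment against weak fold
2–4 bodies — a clean hockey stick.

`simulate_feature_table()` draws class-conditional Gaussian columns
(negatives mean 0, positives mean dⱼ, common sd 1) with the published class
sizes 1119/9981. Gaussian conditionals were chosen deliberately: they make
the point-biserial closed form
`r = d√(p(1−p)) / √(d²p(1−p) + 1)`
available as an independent oracle. Default effects, chosen once: the six
columns that dominate real-data rankings (Med12, Cdk8, Brd4, Cdk9, p300,
H3K27ac) get strictly decreasing shifts 3.0, 2.5, 2.0, 1.5, 1.25, 1.0 sd —
large-to-moderate, with |r| gaps wide enough (≥ 0.05 at n = 11100) that
order recovery is not a coin flip — remaining signal tracks get 0.1
(weakly informative, as real co-binding tracks are), sequence columns 0.

What a green run establishes: the full pipeline is internally consistent,
the learning machinery can extract planted multivariate structure at the
published architecture and training settings, and the ranking recovers
planted effect order. What it does not establish: performance on real mESC
data, where features are heavy-tailed, correlated, and spatially
structured — the published real-data metrics are not reproducible at desk
scale and are not asserted anywhere in this package.

## Numerical and degenerate-input conventions

* Coordinates are 0-based half-open everywhere internally; SAM's 1-based
  positions and wiggle's 1-based starts are converted on ingest; CIGAR is
  ignored (read span = POS .. POS + sequence length).
* PWM columns are count-normalized with pseudocount 0.01 per cell against a
  uniform background; columns must sum to 1 within 1e-6.
* Feature TSVs print 6 significant digits; reading then rewriting a table
  is a byte-level fixpoint.
* Softmax subtracts the row maximum; prediction ties resolve to class 0.
* Max-pool argmax ties resolve to the first (leftmost) position in both
  engines.
* Zero-length regions, empty libraries, single-entity cutoffs, all-constant
  feature matrices, single-class ROC labels, and undefined
  precision/recall denominators are all explicit errors, not silent values.

## Known limitations

* The CNN treats an arbitrary feature ordering as spatial structure
  (inherited quirk, see above).
* The elbow rule degrades on non-convex ranked curves (see SE calling).
* `cross_validate()` requires every class to have at least k members;
  leave-one-out with two classes is therefore rejected rather than
  degenerating.
* The grid search at full data scale is computationally heavy by design
  (264 × k trainings); use a restricted `grid` for exploration.
* No GPU path, no attention/residual variants, no transfer of externally
  trained weights — all out of scope.
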