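# secnn

Super-enhancer calling and CNN-based prediction from chromatin features.

Super-enhancers (SEs) are large clusters of transcriptionally active
enhancers, marked by unusually strong Mediator (Med1) coactivator binding,
that drive the expression of cell-identity genes and many disease-associated
loci. Calling them directly requires Med1 ChIP-seq, which is costly; `secnn`
implements the alternative: call SEs once from Med1 the classical ROSE way,
then train a small 1-D convolutional neural network to predict SE status
from 36 cheaper chromatin and sequence features, and rank those features by
how much they carry the signal.

The package covers the whole workflow at desk scale, for computational
biologists who want a self-contained, testable re-implementation rather
than a pipeline of external binaries:

1. **Signal quantification** — read densities of ChIP-seq libraries over
   enhancer intervals in rpm/bp:
   `density = (overlapped bases / region length) x 1e6 / total mapped reads`,
   with strand-aware fragment extension and unfloored control subtraction.
2. **SE calling (ROSE-style)** — enhancers within 12.5 kb are stitched into
   single entities; entities are ranked by total background-normalized Med1
   signal (density x span); the cutoff is the elbow of the min-max-scaled
   ranked curve (first discrete slope > 1); entities above it are SEs.
3. **Feature assembly** — the canonical 36-column matrix: 31 signal/TF
   densities (H3K27ac ... Nr5a2), AT/GC content, soft-masked repeat
   fraction, mean phastCons and conserved-base proportion, with optional
   PWM log2-odds binding affinities and per-column z-scoring.
4. **Classifier** — 1-D CNNs with 2/3/4 convolutional layers (kernel counts
   32/64/128/256, width-3 kernels, stride 1, same padding, max-pools
   3,3,2,2), a 256→64 dense layer with dropout, and a softmax head; trained
   with backpropagation and Adam on the binary cross-entropy
   `J(θ) = -(1/m) Σ yⁱ log h_θ(xⁱ) + (1-yⁱ) log(1-h_θ(xⁱ))`.
   All three architectures flatten to exactly 256 dense inputs from a
   length-36 input. The training engine is compiled (RcppArmadillo) with a
   pure-R reference implementation kept for verification.
5. **Evaluation & ranking** — precision/recall/F1/accuracy, ROC/AUC
   (Mann–Whitney with ties at ½), stratified k-fold cross-validation, the
   published hyper-parameter grid (L ∈ 2–4, epochs 50–150 step 10, eight
   learning rates 1e-5 … 5e-2), and point-biserial Pearson feature ranking.
6. **Simulators** — seeded generators for reads with planted enriched peaks
   and for class-imbalanced 36-feature tables (default 1119 positives /
   9981 negatives), so every stage runs with no external data.

## Worked example

```r
library(secnn)

## plant 5 strong Med1 clusters among 95 weak ones and call them
fx <- make_se_fixture(seed = 42)
calls <- call_super_enhancers(fx$enhancers, fx$med1, fx$control)
calls
#> se_calls: 100 stitched entities, 5 super-enhancers (cutoff 755001 )
all(calls$entities$label == fx$expected$label)
#> [1] TRUE

## simulate the imbalanced 36-feature table and train the 4-layer model
fm <- simulate_feature_table(seed = 1)   # 1119 positives, 9981 negatives
fm$features <- zscore_columns(fm$features)
cv <- cross_validate(build_cnn(4), fm,
                     train_config(alpha = 5e-5, epochs = 130, seed = 1),
                     k = 5)
str(cv$mean)
#> List of 5
#>  $ precision: num 0.958
#>  $ recall   : num 0.944
#>  $ f1       : num 0.951
#>  $ accuracy : num 0.99
#>  $ auc      : num 0.998

## which features carry the signal?
head(pearson_rank(fm), 6)
#>   feature         r rank
#> 1   Med12 0.6710842    1
#> 2    Cdk8 0.6082244    2
#> 3    Brd4 0.5127810    3
#> 4    Cdk9 0.4091941    4
#> 5    p300 0.3482899    5
#> 6 H3K27ac 0.2849628    6
```

The cross-validated F1 (0.95) and AUC (0.998) say the planted class
structure is fully learnable by the 4-layer model at the published training
settings; the ranking recovers the planted effect-size order (the Mediator
and coactivator columns first), mirroring the ordering such feature
rankings produce on real mouse embryonic stem cell data.

A command-line interface wraps every stage
(`quantify`, `call-se`, `build-features`, `train`, `tune`, `predict`,
`evaluate`, `rank-features`, `simulate`):

```sh
Rscript -e 'quit(status = secnn::secnn_cli())' call-se \
  --enhancers enh.bed --med1 med1.sam --control input.sam --out se.bed
```

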