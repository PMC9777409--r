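---
title: "Hybrid feature fusion for skin-lesion classification: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid feature fusion for skin-lesion classification: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lesionfuse)
```

# The model

`lesionfuse` classifies dermoscopic-style images of pigmented skin lesions
as benign or malignant. The working assumption is the clinical one: the two
classes differ in asymmetry, border irregularity, colour uniformity and
diameter (the ABCD cues), and those cues leave complementary traces in
*texture statistics* and in *learned convolutional embeddings*. The pipeline
therefore runs two feature branches over the same denoised image and fuses
them before classification.

**Denoising.** Each channel is convolved with a discrete isotropic Gaussian,
$G(x,y) = \tfrac{1}{2\pi\sigma^2} e^{-(x^2+y^2)/2\sigma^2}$, evaluated on
the integer window grid and renormalised to unit sum. The continuous density
says nothing about discretisation, so renormalisation is the natural choice:
it makes the operator an averaging filter that preserves constants exactly.
Boundaries use symmetric reflection padding — zero padding would darken the
border and inject artificial texture into the LBP branch downstream.

**Texture branch.** Local binary patterns on the 3×3 neighbourhood:
$\mathrm{LBP}(c) = \sum_{i=0}^{7} 2^i\, g(I_i - I_c)$ with $g(v)=1$ for
$v \ge 0$. Ties count as 1 — the comparison is "greater or equal" — and the
neighbour order is frozen as clockwise from the top-left corner. Any fixed
ordering yields an equivalent descriptor (it permutes bit weights); freezing
one makes results reproducible. Border pixels are skipped rather than
padded. The branch feature is the 256-bin code histogram, normalised so its
scale is commensurate with the deep branch at fusion time. Codes depend only
on intensity *differences*, so the descriptor is invariant to additive
illumination shifts — a property the test suite checks directly.

**Deep branch.** The backbone is deliberately a *contract* — input side,
feature dimension, forward map — rather than a fixed architecture. The
production declaration is an Inception-V3-like extractor (299 px input,
2048-d embedding, factorized convolutions); its externally trained weights
are an artifact this package cannot ship, so the default instantiation is a
small CNN: two blocks of 3×3 valid convolution + ReLU + 2×2 max-pool, global
average pooling, and a trained projection `relu(W1·g + b1)`. Global average
pooling keeps the base independent of the input side, so one code path
serves every contract size.

Training follows the frozen-base transfer-learning regime: the convolutional
base keeps its seeded He initialisation and only the projection and softmax
head are fitted, with mini-batch Adam on the label-smoothing cross-entropy
$\ell = -\sum_k s'(k)\log p(k)$, $s'(k) = (1-\varepsilon)\delta_{k,z} +
\varepsilon/K$. The loss obeys the identity
$\ell = (1-\varepsilon)H(\mathrm{onehot},p) + \varepsilon H(\mathrm{uniform},p)$,
asserted to $10^{-6}$ in the tests, and its logit gradient is $p - s$,
bounded in $[-1,1]$.

Two numerical choices matter here and were made after observing training
failures, not metric outcomes:

* *Pooled-activation standardisation.* Global-average-pooled ReLU activations
  are all positive with a large common mean. In mini-batch gradients this
  mean couples to the batch's class composition and drowns the class signal:
  with the published step size the head moved glacially. The base's pooled
  output is therefore z-scored with training-set statistics (persisted in
  the backbone, applied identically at inference) — the standard "stem
  normalisation" cure, after which the head converges in a handful of
  epochs.
* *Zero-initialised softmax head.* With few Adam steps available, a random
  initial rotation of the head dominates the decision. Zero-initialising the
  classification layer (common fine-tuning practice) makes the decision
  direction entirely learned from step one.

**Fusion and entropy selection.** The fused vector is the concatenation
$f = [f_{\text{deep}}, f_{\text{lbp}}]$, with per-position provenance
retained (fusion is lossless and invertible). Each branch is z-scored with
training-set statistics first, so neither branch's numeric scale can
dominate the ranking. Selection treats the normalised magnitudes as a
probability over positions, $p_i = |f_i| / \sum_j |f_j|$, and scores each
position with its Shannon entropy term $-p_i \log_2 p_i$; the scores sum to
the Shannon entropy of $p$ and are invariant to positive rescaling of the
whole vector. The retained set is the top `keep_n` positions (default 1186),
ties broken towards the lower index for determinism.

Two design questions were genuinely open and resolved as follows:

* *Per-sample or aggregate selection?* Scores are averaged over the
  **training samples only** and the index set is frozen. Re-selecting per
  sample would change the meaning of each classifier input coordinate from
  image to image and leak validation data into the transformation.
* *What does the entropy score buy?* Under magnitude normalisation the score
  is maximised near $p_i = 1/e$: it prefers features that carry a
  consistent, non-negligible share of the vector's mass and discards both
  dead positions and single dominating spikes. It is a screening heuristic,
  not a supervised relevance measure — a deliberate limitation, see below.

**Classifier.** The selected vector is chunked row-major into timesteps of
width 7 (zero-padded at the tail; 1186 features → 170 steps) and fed to
LSTM → batch-norm → ReLU → residual addition → LSTM → dense(ReLU) → dense →
softmax. Chunking a flat vector into a short sequence is a reconstruction of
how a recurrent classifier consumes non-temporal features; width 7 is the
declared input width of the reference architecture. The reference layer
table also lists 22-unit output layers and block multiplicities (5×
batch-norm, 8× ReLU, 7× second LSTM) that are inconsistent with a binary
task; this implementation uses a 2-way softmax head and one block of each
type, treating the multiplicities as unexplained repetition. Both LSTM
stacks, batch-norm and backpropagation through time are implemented in
batched base-R matrix operations; the analytic gradients are verified
against finite differences to $10^{-6}$ in the test suite.

Batch-norm uses batch statistics while training and exponential running
statistics (momentum 0.9) at inference, so prediction is deterministic and a
stored model reproduces its probabilities bit-for-bit.

**Metrics.** Confusion counts with malignant as the positive class;
precision, accuracy, recall, F1; threshold-sweep ROC with trapezoidal AUC
(equal to the tie-aware pair-ordering probability, asserted against an
$O(n^2)$ oracle). Zero-denominator metrics return 0 with a warning rather
than raising, so evaluation over degenerate folds keeps running.

# Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `gaussian_sigma` / `gaussian_size` | 1.0 / 5 px | denoising strength / window; neither is prescribed by the reference setup, so these are conventional mild-smoothing values |
| `lbp_side` | 227 px | resize for the texture branch |
| `backbone input_side` | 64 px (contract: 299) | resize for the deep branch |
| `keep_n` | 1186 | retained fused features |
| `lstm_step_width` | 7 | features per timestep |
| `lstm_hidden` | 128 (small preset: 32) | LSTM state size |
| Adam `lr, β₁, β₂, ε` | 0.001, 0.98, 0.999, 10⁻⁷ | published settings; β₁ = 0.98 is unusual (0.9 is conventional) but is kept exactly as stated |
| `label_smoothing` | 0.1 (backbone), 0 (classifier) | ε left symbolic in the reference; 0.1 is the customary value |
| `train_fraction` | 0.75 | stratified per-class split |

The two printed input sides (227 for the standard image, 299 for the deep
extractor) conflict if read as one resize; the pipeline resolves this by
resizing **per branch**, honouring both numbers.

# The synthetic corpus

`generate_dataset()` emulates a balanced two-class corpus: 500 images per
class at 600 × 450 by default, with a small preset (64 × 64, 50 per class)
for CPU-budget test runs. A lesion is rendered as an elongated ellipse whose
radius is modulated by sinusoidal harmonics,
$r(\theta) = R\,(1 + \sum_k a_k \sin(k\theta + \varphi_k))$, over noisy skin
tone. Class parameter ranges encode the ABCD cues directly — benign: radius
0.12–0.20 of the short side, harmonic amplitudes ≤ 0.02, one colour, mild
elongation; malignant: radius 0.18–0.30, amplitudes 0.04–0.15, 3–5 darker
colour patches, elongation 1.2–1.6. The radius ranges overlap deliberately
so diameter alone is informative but not sufficient (a diameter threshold
reaches roughly 90%, and the tests only require > 80%, on the small preset).
Every image derives its own seed from the corpus seed, so corpora are
bit-identical across runs, and PNG output is quantised to 8 bits so a
write–read round trip is exact.

What the generator does **not** emulate: hair and ruler artifacts,
vignetting, specular reflections, true dermoscopic colour distributions, or
inter-patient skin-tone variation. A green end-to-end test therefore
establishes that the pipeline's stages compose correctly and can learn the
ABCD-style signal it was designed for — not that the defaults would attain
any particular accuracy on real dermoscopy corpora, which additionally
require externally trained backbone weights.

# Numerical and degenerate-input choices

* Kernel symmetry is exact (the kernel is built from an outer product);
  normalisation is within $10^{-9}$.
* Smoothing output is clamped to the input's range, removing round-off
  excursions only (the operator is a convex combination of input pixels).
* Resizing uses align-corners bilinear interpolation: same-size resize is
  the identity, constants stay constant.
* All-zero fused vectors are a degenerate-input error for entropy scoring;
  zero-variance feature columns standardise to centred zeros (divisor 1).
* `keep_n` larger than the fused dimension makes selection a no-op rather
  than an error.
* Grayscale inputs at prediction time are channel-replicated to RGB.
* Every stage seed is derived from the single pipeline seed by fixed
  offsets; training, splitting and corpus generation are reproducible to
  the bit on one machine.
* The small preset sets `keep_n = 200` (of 320 fused features) so that the
  selection stage does real work in scaled-down runs; the full-scale default
  keeps 1186.

# Known limitations

* The entropy score is unsupervised; it never sees labels and can retain
  uninformative-but-variable features. Mutual-information or variance
  screening are deliberate non-goals.
* The default backbone is small and randomly initialised at the base; it
  stands in for, and does not approximate, an ImageNet-pretrained
  Inception V3.
* Uniform and rotation-invariant LBP variants, multi-scale radii, HOG
  features, and multi-class outputs are out of scope.
* Training is single-threaded CPU R; it is sized for hundreds of small
  images, not thousands of full-resolution ones.
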