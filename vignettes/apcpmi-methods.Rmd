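---
title: "Adaptive partition mutual information for EEG synchronization and seizure classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive partition mutual information for EEG synchronization and seizure classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apcpmi)
```

## The problem

Epileptic seizures manifest in scalp EEG as abrupt changes in the
*synchronization* between channels. A window-level classifier therefore needs
a per-window summary of how statistically dependent every channel pair is.
Mutual information (MI) is a natural pairwise dependence measure — it is
model-free and comparatively noise-robust — but estimating MI from continuous
amplitudes requires discretizing each channel, and the estimate depends
strongly on how the amplitude axis is partitioned. Equal-probability
(quantile) bins impose a distributional assumption the data need not satisfy.

This package implements the alternative adopted here: derive each channel's
partitions from the data itself by clustering its amplitude values with
affinity propagation (AP), convert the clusters into ordered amplitude
partitions, and compute MI on those partitions (**APCPMI**). Collecting the
APCPMI of all channel pairs gives a per-window synchronization matrix
(**CMAPCPMI**); flattened, it is the feature vector of a cross-layer fully
connected network (**CLFCNN**) trained to label windows seizure /
non-seizure.

## The pipeline and its quantities

For a window of $n$ channels, $N$ samples each:

1. **Partitioning.** Each channel's samples are sorted ascending and
   clustered by AP with similarity $s(i,k) = -(x_i - x_k)^2$ and a shared
   diagonal *preference* (the "reference degree"), by default the median of
   the off-diagonal similarities. Each cluster $i$ spans
   $[Z^{min}_i, Z^{max}_i]$ and becomes a partition with center
   $C_i = (Z^{max}_i + Z^{min}_i)/2$ and radius
   $R_i = |Z^{max}_i - Z^{min}_i|/2$. The cut between consecutive partitions
   is placed at $(C_i + R_i) + D(i, i{+}1)$ where
   $D(i,j) = ((C_j - R_j) - (C_i + R_i))/2$ is the half-gap — i.e. the
   midpoint of the empty interval. The half-gap formula alone is a length,
   not a coordinate; the midpoint is the only symmetric completion, and it
   guarantees the cuts reproduce the training clustering exactly.
2. **Count equalization.** Two channels generally produce different partition
   counts $N(X) \ne N(Y)$. The scheme with more partitions has its adjacent
   pair with the smallest center-to-center gap merged (repeatedly) until the
   counts agree; the smaller scheme is never touched.
3. **MI.** With both channels discretized (half-open, lower-inclusive bins;
   a value on a cut goes to the upper bin; out-of-range values clamp), the
   empirical joint distribution gives
   $I(X,Y) = H(X) + H(Y) - H(X,Y)$ in bits (base-2 logs, $0\log 0 = 0$,
   maximum-likelihood probabilities with no smoothing — smoothing would
   silently shift every value).
4. **Matrix.** The AP clustering is run once per channel and reused across
   all $n(n-1)/2$ pairs. The diagonal is the channel's self-entropy under its
   own scheme ($I(X,X) = H(X)$); the matrix definition leaves the diagonal
   open and the classifier consumes all $n^2$ entries, so the self-MI
   identity is the consistent completion. A 23-channel montage yields the
   529-dimensional feature vector.

## Affinity propagation: determinism, damping, convergence

AP alternates responsibility and availability messages,

$$R(i,k) \leftarrow S(i,k) - \max_{k' \ne k}\{A(i,k') + S(i,k')\}, \qquad
A(i,k) \leftarrow \min\{0,\ R(k,k) + \sum_{i' \notin \{i,k\}} \max(0, R(i',k))\},$$

with damping, until the exemplar set (points with $R(k,k)+A(k,k) > 0$) is
unchanged for `convergence_iter` (default 15) sweeps; `max_iter` defaults
to 200. Non-convergence is reported, not raised. Exemplars are always actual
data points, and each sample is assigned to its most similar exemplar.

Three numerical choices deserve explanation because the textbook algorithm
is not deterministic-friendly:

* **Symmetry-breaking jitter.** Noise-free messages oscillate forever on
  symmetric inputs (three equally spaced tight groups is enough; reference
  implementations avoid this by adding random noise to $S$). We add the same
  vanishing jitter — about one part in $10^{16}$, far below any data scale —
  but draw it from a fixed linear congruential sequence, so every run is
  bit-reproducible. Runs on identical inputs are identical.
* **Damping escalation.** The default damping 0.5 converges on small,
  well-separated inputs (where it provably matches exhaustive
  exemplar-subset search — see the acceptance suite) but can oscillate on
  dense windows of hundreds of samples. `ap_cluster()` detects sustained
  oscillation (60 consecutive sweeps that change the exemplar set), aborts
  the rung, and retries at damping 0.7, 0.9, 0.95, reporting `damping_used`.
  A fixed high damping is not a substitute: on small inputs it converges
  prematurely into a degenerate all-singleton fixed point.
* **Empty exemplar sets** (all values identical) short-circuit to a single
  cluster; during warm-up an empty set is never counted toward convergence.

AP is $O(N^2)$ per sweep in time and memory; a 2,048-sample window is
noticeable, which is why `APConfig$max_points` exists (cluster evenly spaced
order statistics, then bin all samples with the learned cuts). It defaults to
off so results match the unsubsampled definition.

## The classifier

The CLFCNN stacks dense layers 529 → 80 → 20 → 1 with an edge from *every*
earlier layer to every later layer ($L(L+1)/2$ connections). Each edge has
its own weights and bias; a layer's activation is the **sum of per-edge
rectified contributions** $\sum_j \mathrm{ReLU}(W_{j i}^\top a_j + b_{j i})$.
The nominal forward rule wraps this sum in an outer rectifier; since a sum of
rectified terms is already non-negative, the outer rectifier is the identity
and both readings coincide (asserted in tests rather than guessed). The
"merge layer" that concatenates incoming paths carries fixed weight 1 and
bias 0, i.e. it is exactly this unweighted summation and holds no trainable
parameters — consistent with the per-edge parameter accounting
(42,400 / 10,600 / 530 / 1,620 / 81 / 21; 55,252 total).

Training is mini-batch (50) gradient descent on the mean squared error with
momentum 0.9, learning rate 0.01 and weight decay 2e-4, applied
element-wise:
$v \leftarrow 0.9v - 0.0002\,\epsilon\,\omega - \epsilon\,\nabla L$,
$\omega \leftarrow \omega + v$. Input dropout 0.1 uses inverted scaling so
inference needs no rescaling; hidden layers have no dropout. Early stopping
monitors *training* accuracy with configurable patience (default 1 epoch of
non-increase) and restores the parameters of the best epoch.

Two implementation choices the architecture description leaves open:

* **Feature standardization** (`standardize = TRUE`). Raw MI features are
  all positive with means well above the 0/1 label scale. Fed raw through
  Glorot-initialized weights, the first MSE/momentum steps are large enough
  to drive every rectifier permanently dead (outputs identically zero,
  gradient zero, no recovery — observed, not hypothetical). Standardizing to
  zero mean and unit variance with statistics from the training pool (stored
  in the model, reapplied at prediction) makes training stable across every
  seed tested while keeping every training hyper-parameter. Raw features
  remain available via `standardize = FALSE`.
* **Decision threshold 0.5** on the rectified scalar output (labels are 0/1
  under squared error; the cutoff is otherwise unspecified).

Evaluation follows the usual shuffle (seed 7), 64/16/20
train/validation/test split, five-fold cross-validation over the pooled
train+validation samples, and a final model retrained on the pool and scored
on the held-out test set. Metrics: sensitivity, specificity, accuracy,
precision, G-mean $\sqrt{\text{sens} \times \text{spec}}$, F-measure
$(1+\beta^2)PS/(\beta^2 P + S)$ with $\beta = 1$, and rank-based (midrank)
AUC. Two typographic conventions are resolved toward the standard
definitions: the G-mean is the square *root* of the product, and the
F-measure denominator uses $\beta^2$ (at $\beta = 1$ both readings agree).
Zero denominators yield `NA`, never a silent 0.

## Windowing and balanced sampling

Recordings are cut into non-overlapping windows (2,048 samples = 8 s at
256 Hz by default). For a seizure stage of length $S$:
$\mathrm{count}(seizure) = \lfloor S/W \rfloor$ seizure windows from the
stage start, $\mathrm{count}(prior) = \lfloor \tfrac12 S / W \rfloor$
non-seizure windows before the stage and
$\mathrm{count}(posterior) = \mathrm{count}(seizure) -
\mathrm{count}(prior)$ after it, so classes balance exactly. The source
procedure invokes a Markov-chain sampler but specifies only these counts and
constraints; the sampler here is seeded uniform placement without
replacement over valid starts (overlaps rejected, with a non-overlapping
grid fallback for tightly packed regions), bounded by the neighbouring
seizure stages, which satisfies every stated constraint reproducibly.

## What the synthetic generator does and does not establish

`synthetic_spec()` emulates windowed multichannel EEG as
$x_c(t) = \rho\, g_c\, s(t) + (1-\rho)\, \eta_c(t)$: a shared order-2
autoregressive latent $s$ with poles at modulus 0.95 and centre frequency
6 Hz (spectral mass in the 3–12 Hz band at 256 Hz — oscillatory and
amplitude-multimodal enough for AP to find non-trivial partitions, without
claiming physiological realism), per-channel gains $g_c \sim U(0.8, 1.2)$
drawn once per dataset to break channel symmetry, and independent unit
Gaussian noise. Coupling $\rho$ is the dial: 0.8 for "seizure"
(hypersynchronous) windows, 0.2 for "non-seizure". Defaults are 23 channels
and 2,048 samples; `synthetic_spec_fast()` is the 8-channel / 512-sample
profile used by the test suite. Every window is deterministic given
`(seed, index, label)`.

A green pipeline on this generator establishes that the implementation
separates two coupling regimes through the complete
partition → MI → matrix → classifier chain. It does **not** establish
clinical performance: real EEG has artifacts, non-stationarity,
patient-to-patient montage and amplitude diversity, and seizure dynamics far
richer than a single global coupling dial. Full-corpus clinical accuracies
require the external 23-channel dataset and on the order of a day of feature
computation, and are deliberately out of scope at desk scale.

## Known limitations

* AP's $O(N^2)$ footprint makes 23 × 2,048 windows minutes-per-window in
  this implementation unless `max_points` is set.
* The MI estimates are maximum-likelihood and therefore biased upward for
  finite windows; partition-count equalization bounds but does not remove
  the bias. The permutation-null comparisons in the test suite show the
  practical ceiling.
* The rectified scalar output with a squared-error loss is kept because the
  architecture states it; it is an unusual pairing, and the standardization
  plus best-epoch restoration described above are what make it train
  reliably.
* EDF input is not bundled (no reader among the package's dependencies);
  CSV recordings with a sampling-rate sidecar are the supported interchange,
  and `read_recording(format = "edf")` fails with a clear message.
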