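---
title: "Methods: fascicle segmentation and evaluation in fascseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fascicle segmentation and evaluation in fascseg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

MicroCT of osmium-stained peripheral nerve yields stacks of 16-bit
cross-sections in which the myelin-rich fascicles appear as bright blobs
inside the dimmer epineurial sheath. Building anatomically realistic nerve
models — for instance for vagus nerve stimulation — requires segmenting
every fascicle on every slice, and manual segmentation of a multi-centimetre
nerve takes weeks. `fascseg` implements an automated pipeline for this task:
synthetic phantom generation, stack I/O and grouped cross-validation splits,
the preprocessing chain, on-the-fly augmentation, a Dice-loss U-Net, and —
centrally — an evaluation framework that scores segmentations both per pixel
and per fascicle instance.

Because area-overlap scores hide instance-level mistakes, the evaluation
framework complements the Dice coefficient

$$\mathrm{DSC} = \frac{2\,|T \cap P|}{|T| + |P|}$$

with an instance-matching analysis. Fascicle instances are connected
components of the binary masks; for ground-truth fascicle $i$ and predicted
fascicle $j$,

$$\mathrm{IoU}_{i,j} = \frac{|T_i \cap P_j|}{|T_i \cup P_j|},$$

and at a matching threshold $t$ a row whose maximum reaches $t$ is a
detected fascicle (TP), a row below $t$ everywhere is a missed fascicle
(FN), and a column below $t$ everywhere is an added fascicle (FP). The
detection score is

$$F_1 = \frac{TP}{TP + \tfrac{1}{2}(FP + FN)}.$$

Rows (columns) with more than one entry above an effective IoU of 0.1 flag
split (merged) fascicles; the 0.1 value is deliberately permissive so that
even weak secondary overlaps count as part of a split or merge. Errors are
stratified by fascicle cross-section area into four classes: large
($\ge 3\times10^5\,\mu m^2$), medium ($[9\times10^4, 3\times10^5)$), small
($[2\times10^4, 9\times10^4)$), and tiny ($< 2\times10^4\,\mu m^2$).

## The synthetic phantom generator

Real microCT volumes are large, proprietary to their archives, and slow to
download; every stage of the toolkit is therefore exercised on synthetic
phantoms whose *statistical* structure matches the real data:

* a three-level intensity model — background ≈ 3,000, epineurium ≈ 8,000,
  fascicle ≈ 14,000 on the 16-bit scale — with additive Gaussian noise
  (sd 250) and a multiplicative per-slice brightness factor drawn from
  [0.85, 1.15], emulating staining and illumination drift;
* elliptical fascicle blobs whose total area tracks a target coverage of
  5% of the frame, with one anchor fascicle per size class (when at least
  four fascicles are requested) so all four bins are populated;
* rare staining-artifact specks with 16-bit values above 18,000, so the
  saturation rule of the preprocessing chain is always exercised;
* smooth slice-to-slice drift of fascicle centres, and — at a configurable
  rate per millimetre — merge/split events in which a pair of fascicles is
  drawn together over a ~1 mm window until their blobs fuse into one
  connected component and separate again. Real human vagus nerves show
  roughly one such event per 0.56 mm; the default rate (0.5/mm) is gentler
  so that default phantoms keep mostly distinct fascicles, and the rate is
  a parameter, not a constant.

The geometry is intentionally simple — convex ellipses, no perineurial
texture, no partial-volume blur, no bias fields beyond the global drift.
Passing tests on phantoms therefore demonstrates that the pipeline's
*mechanics* (losses, matching, error taxonomy, augmentation bookkeeping)
are correct, not that the default network would reach the same accuracy on
real nerves, whose fascicles are lower-contrast and less regular.

Each stack is a deterministic function of its parameter object, including
the seed: one RNG stream per stack, nothing shared across stacks.

## Preprocessing conventions

The chain is: border-slice exclusion → epineurium-centroid centring and
cropping → 16→8-bit contrast enhancement → mean normalization → Gaussian
smoothing. Decisions that the procedure leaves open are fixed as follows:

* **Percentile tails exclude saturated pixels.** Artifact pixels above
  18,000 are zeroed *before* the 0.1% tails are computed, and the tails are
  computed over the surviving pixels only — including a large zero mass
  would corrupt the low tail.
* **Tails are per-slice**, matching the per-image description of the
  procedure; a per-volume variant would couple slices through a global
  histogram.
* **Crop windows beyond the image are zero-padded**; zero is background in
  microCT. The centroid is snapped to the pixel grid by rounding half away
  from zero, and 8-bit values are rounded to the nearest integer with ties
  to even — both purely for cross-platform determinism.
* **Degenerate contrast** (all non-saturated pixels equal) maps to 255 with
  a warning; any constant is defensible, an explicit one is debuggable.
* **Smoothing (σ = 1 px) is applied after normalization.** The order
  relative to normalization is not dictated by the procedure; it is fixed
  here and recorded in each slice's provenance. The kernel is a sampled
  Gaussian truncated at 4σ and renormalized, with reflective boundaries, so
  constants are preserved exactly and total intensity to well within 0.1%.

## Augmentation

Each training image/mask pair passes through: rotation (p = 0.5, uniform
0–270°), vertical and horizontal flips (p = 1/3 each, independent), scaling
(p = 2/3, uniform 0.9–1.2 about the centre on a fixed canvas), additive
Gaussian noise (always, σ uniform in 0.001–0.003 on the mean-1 intensity
scale), and a sinusoidal intensity field (p = 0.5),
$f(x,y) = A\sin(ax) + B\sin(by) + 1$ with all four parameters uniform in
0.001–0.3 and $x, y$ pixel indices. The field is applied
*multiplicatively*: it is centred at 1, and an additive field of order 1
would overwhelm a mean-1 image, so the multiplicative reading is the only
one whose magnitudes make sense. Geometric transforms draw one parameter
set shared by image and mask (bilinear for the image, nearest-neighbour for
the mask), so a fascicle never moves relative to its image; rotations at
multiples of 90° take an exact permutation path with no interpolation loss.
The sub-transform order is rotation → flips → scale → noise → field, and
every applied transform with its sampled parameters is returned as a tidy
record.

## The segmenter

The U-Net family is configured by depth and base width: two 3×3
same-padded convolutions with ReLU per encoder level, 2×2 max-pooling,
a mirrored decoder with nearest-neighbour up-sampling and skip
concatenation, and a final 1×1 convolution with a logistic output.
Same-padding keeps the 400×400 (or any $2^{depth}$-divisible) input size
through the network. The full-scale default is depth 4 / base 64; the
desk-scale configuration used throughout the tests is depth 2 / base 16 on
128×128 crops, which trains in minutes on one CPU. All numerical kernels
(im2col/GEMM convolution with analytic backward passes, pooling,
up-sampling) are implemented in compiled code inside the package and are
verified against numerical gradients in the test suite.

Training follows the published recipe: soft Dice loss (smoothing constant
ε = 1 in pixel-count units; the loss and the soft Dice sum exactly to 1),
Adam, 60 epochs at full scale, initial learning rate 5×10⁻⁴ multiplied by
0.75 every 8 epochs, mini-batches of 20. The model state with the best
validation Dice (binarized at 0.5) is retained — the selection rule is not
dictated by the recipe, and best-validation is both logged and recoverable
from the history. One seed governs weight initialization; a second governs
shuffling and augmentation draws.

The toolkit's own acceptance bar for the desk-scale experiment — validation
Dice ≥ 0.80 and detection F1 at $t = 0.4$ ≥ 0.70 after ≥ 20 epochs on ≥ 40
easy 128×128 phantom slices — is a design decision: it sits below
real-data performance of mature networks because phantom difficulty is
configurable, and it is meant to catch regressions in the training loop,
not to claim anatomical accuracy. The experiment in
`scripts/acceptance.R` uses two 20-slice training phantoms, one 8-slice
held-out phantom, 22 epochs, and batch size 10 — sizes chosen so the whole
experiment runs in minutes on a single CPU while still being clearly past
the convergence knee (in practice it reaches Dice ≈ 0.95).

## Evaluation conventions

* **Connectivity is 8-connected** (configurable): diagonally touching
  pixels belong to one fascicle, avoiding spurious splits of thin diagonal
  structures. Labels are assigned in raster order of each component's first
  pixel, and every metric is invariant under relabeling.
* **Both-empty slices score Dice = precision = recall = 1**: the synthetic
  edge cases include empty slices, and a convention is required.
* **Detection counts are truth-centric for TP/FN and prediction-centric
  for FP.** At $t \le 0.5$ one predicted component may support two detected
  rows (a split); this is deliberately not double-penalized, because splits
  are tallied separately by the 0.1-threshold flags.
* **Size attribution**: missed and split errors are sized by the true
  fascicle, added and merged errors by the predicted fascicle — the side on
  which each error is observable. Bins are half-open downward, so an area
  exactly on a shared endpoint belongs to the larger class.
* **PR sweep**: thresholds 0, 0.02, …, 1 (51 points); pixels are pooled
  over the stack at each threshold. For the curve and its AUC an empty
  prediction set contributes precision 1 (the standard boundary convention;
  it is also what makes a perfect predictor integrate to exactly 1 by
  trapezoid over recall). The standalone `pixel_precision_recall()` keeps
  the stricter convention — empty prediction against non-empty truth scores
  precision 0. The optimal threshold is the grid point maximizing Dice,
  ties broken towards the lower threshold. Degenerate single-recall curves
  get the rectangle area.
* The detection F1 is reported both averaged per slice and pooled over the
  stack's summed counts, since either reading of "per image" is defensible;
  the two agree in the limit of homogeneous slices.

The whole instance-matching framework is checked for exact agreement with
an independent brute-force pixel-set oracle (explicit `intersect`/`union`
on pixel index sets, component membership from a graph library) on hundreds
of randomized mask pairs in the test suite.

## Known limitations

* Phantoms are convex and high-contrast; no claim is made about real-nerve
  accuracy, which requires the archived imaging data and full-scale
  training.
* Instance matching is per-slice (2-D); volumetric tracking of fascicles
  across slices is out of scope.
* The epineurium is used only for centring and border exclusion; the
  network predicts the fascicle class alone.
* Training on one CPU restricts practical experiments to the desk scale;
  the architecture code is scale-agnostic but no GPU path is provided.
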