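---
title: "Methods: binarized bladder segmentation, skip compression, and volume agreement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: binarized bladder segmentation, skip compression, and volume agreement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the models, numerical conventions and design
choices behind `edgeseg`. The package targets a concrete deployment
question: how small — in permanent parameter memory, inference-time buffer
memory, and arithmetic — can a bladder-segmentation network be made while
still supporting clinically meaningful urine-volume estimation, if the
network must run on an ASIC with no floating-point unit?

## The segmentation network and its three precision variants

The backbone is a lightweight U-Net built from depthwise separable
convolutions (a depthwise 3x3 followed by a pointwise 1x1). A stride-2 stem
convolution halves the input resolution; each of the four encoder levels
halves it again (stride-2 depthwise convolution) and doubles the channel
count; the decoder mirrors the encoder with nearest-neighbour upsampling
(chosen over interpolation because doubling pixels is free of arithmetic);
a final upsample restores the input resolution. One feature map per encoder
level is stored and concatenated into the decoder — the four skip
connections whose storage dominates inference memory.

`unet_config()` selects one of three variants:

* **fp** — plain convolutions, BatchNorm, ReLU. The accuracy reference.
* **bfp** — every convolution except the stem is *binarized*: its inputs
  pass through a sign function with a learned per-channel threshold
  (`rsign()`, x > alpha maps to +1, x <= alpha to -1) and its weights are
  binarized per output channel against the channel mean
  (`binarize_weights()`, again with ties mapping to -1). ReLU is replaced
  by a per-channel PReLU with slope `beta` below a knee `gamma` and offset
  `eta` (`prelu()`); BatchNorm and the PReLU/RSign parameters stay
  real-valued. A binary convolution is arithmetically a XNOR plus popcount
  (`binary_conv2d()` / `xnor_popcount_conv2d()` demonstrate the exact
  equivalence `dot = 2*popcount - n`).
* **bq** — everything that remained real-valued is quantized so that
  inference involves no general floating-point multiplication:
  * the stem uses a 4-bit input (the image quantized to 16 levels on
    [0, 1]) and 4-bit weights with one power-of-two scale;
  * BatchNorm is folded into a per-channel affine and its scale is
    constrained to a signed power of two,
    `s = clamp(round(log2(|w|)), -8, 7)` (`bn_to_shiftnorm()`); the sign is
    reported separately so it can be absorbed into the preceding binary
    weights; the bias becomes a 4-bit code times a per-layer power-of-two
    step;
  * RSign thresholds use 4-bit signed codes with step 2^-2 (range
    [-2, 1.75]);
  * PReLU parameters use a 2-bit code for `beta` (grid {0, 0.25, 0.5,
    0.75}) and 4-bit codes for `gamma`/`eta` with per-layer power-of-two
    steps calibrated from the trained parameter ranges;
  * each skip connection is stored as **unsigned** q-bit codes (q = 3, 4
    or 6) with one power-of-two shift per connection, calibrated so the
    largest activation observed on the training set decodes without
    overflow. The unsigned representation matches the asymmetric
    post-PReLU distribution. Because the decoder consumes an RSign of each
    skip and the 4-bit threshold grid is incompatible with the skip scale,
    the 1-bit binarized version of every skip is computed at encode time
    and stored separately (one extra bit per value, counted explicitly in
    all memory reports).

`guarded_forward()` is a second, independent implementation of the `bq`
inference path: a fixed-point interpreter that tracks a power-of-two grid
exponent for every tensor and verifies after each op that all values lie
exactly on their grid and that every multiplicative constant is +-1, a
power of two, or a <= 4-bit code times a power-of-two step. The decision
`probability > 0.5` is taken as `logit > 0`, an integer comparison, so the
sigmoid lies outside the guarded region. The interpreter's logits agree
exactly (not approximately) with the C++ engine's, which doubles as an
end-to-end cross-check of the two implementations.

### Architecture widths

The published account of this architecture family leaves the exact channel
widths to a supplementary figure; absolute kilobyte figures are therefore
not reproducible and are not targets. We fix the default to
`base_channels = 16`, growth 2, a stride-2 stem and a full-width mirrored
decoder. The stride-2 stem is the load-bearing choice: it keeps the first
(largest) skip connection at half resolution, which puts the parameter
count and the skip-value count at the same order of magnitude — the regime
in which binarizing parameters *and* quantizing skips together yield the
order-of-magnitude total-memory reductions that motivate the design. At
this default the full-precision model totals ~2.2 MB, in the same range as
the ~2 MB full-precision reference, and the 4-bit-skip quantized model is
~8.8x smaller.

## Training

Training minimizes a soft Dice loss (smoothing eps = 1 on numerator and
denominator, so empty masks are well-behaved); with two output channels
(inner and outer bladder wall) the per-channel Dice scores are averaged.
Only the inner-wall channel is ever used for volumetry; the outer wall is
auxiliary supervision. Optimization uses Adam under cosine annealing with
warm restarts (initial rate 0.005, restart period 10 epochs doubling each
cycle), weight decay 4e-5 for the fp variant only, and fresh random
horizontal flips, shears and rotations drawn each epoch and applied
identically to image and masks (bilinear for the image, nearest for
masks). Model selection is the highest mean inner-wall validation Dice
across epochs.

The sign function has zero gradient almost everywhere, so backpropagation
substitutes a surrogate on the pre-activation z = x - alpha: the
straight-through estimator (pass-through clipped to |z| <= 1, the default)
or the derivative of tanh(2z). The threshold receives the negated
surrogate gradient.

The quantized model is trained in two stages: the bfp model is trained
from scratch, then the bq model is initialized from the best bfp
checkpoint — BatchNorm folded, quantization steps and skip shifts
calibrated — and fine-tuned with quantization-aware updates (round to the
grid in the forward pass, straight-through gradients with clip-awareness:
a parameter whose code is clamped receives no gradient). All layers are
fine-tuned; nothing is frozen. Training-time arithmetic is ordinary
floating point throughout — quantization is enforced by the forward
rounding, and bit-exact integer inference is a property of the exported
model, checked by the guard interpreter.

Two choices here are ours where the recipe is otherwise prescribed:
Adam as the optimizer (standard for binary networks in the ReActNet
lineage) and restart periods T0 = 10, Tmult = 2 for the named scheduler
policy.

## Skip-connection compression

Quantization concentrates many skip values at exactly zero (clamping of
the unsigned code at 0 plus rounding of small activations), which makes
simple lossless codecs effective. Four are implemented bit-exactly over
unsigned q-bit codes in a fixed scan order (channel-major, row-major
within a channel); all sizes are payload bits, with the descriptive header
excluded, since on-chip buffers are provisioned for payload:

* **ZVC** — one flag bit per value (1 = nonzero) followed by the q-bit
  codes of the nonzeros: exactly `n + q*nnz` bits.
* **DZVC** — the flag marks a *new* value relative to its scan
  predecessor; each channel's first value is always transmitted: exactly
  `n + q*n_new` bits. Exploits spatial plateaus.
* **BPC** (block 8 or 16) — per block, the first value is sent raw; the
  block-1 successive deltas (q+1-bit two's complement) are transposed into
  bit-planes; adjacent planes are XORed (top plane kept); each resulting
  plane is coded with a prefix-free table:

  | symbol | code |
  |---|---|
  | run of 2-33 all-zero planes | `01` + 5-bit (run-2) |
  | single all-zero plane | `001` |
  | all-ones plane | `00000` |
  | nonzero plane whose DBP is zero | `00001` |
  | two consecutive ones | `00010` + position |
  | single one | `00011` + position |
  | uncompressed | `1` + (block-1) raw bits |

  The referenced bit-plane scheme's published table assigns `01` to the
  single zero plane and `001`+5 bits to the zero run; the two codewords
  are exchanged here (favouring runs), and since the referenced table
  admits more than one reading of that exchange, the table above is the
  normative dialect for this package — losslessness and the size
  accounting are what the tests pin down.
* **EBPC** — ZVC first, then BPC over the nonzero payload (flags raw).

Buffer provisioning uses `worst_case_size()`: the maximum over samples of
the total compressed size, rounded up to bytes, because a hardware buffer
must hold the worst case, not the average.

## Memory and computation accounting

`param_memory()` counts every stored parameter at its configured width
(binary weights 1 bit, 4-bit codes 4 bits, shift exponents 4 bits, FP
values 32 bits) — the permanent on-chip cost. `inference_memory()` counts
the four skip buffers (q bits per value plus the 1-bit binarized store for
the quantized variant; worst-case compressed payload when a codec is
selected). `mac_count()` counts one MAC per kernel element per output
position per channel pair, weighting an a-bit x b-bit multiply as `a*b`
equivalent binary MACs (a binary MAC being one XNOR plus a count); the
4-bit stem thus costs 16 per MAC, and full-precision MACs are reported in
their own column rather than converted. Per-element normalization,
activation and comparison work is tabulated separately and excluded from
MAC totals. 1 kB = 1024 bytes throughout; the separate 1-bit binarized
store is included in quantized totals and also reported as its own line.

## The phantom generator

The clinical dataset behind this problem is restricted, so the package
ships a synthetic stand-in whose geometry makes the downstream volumetry
exactly checkable. Each phantom is one ellipsoid bladder with semi-axes
a, b, c drawn from 1-6 cm and wall thickness 0.2-0.5 cm; the sagittal view
is the (a, c) section and the transverse view the (a, b) section of the
same ellipsoid, so the true volume is exactly (4/3) pi a b c, and the
analytic section areas (pi a c, pi a b) let tests bound the rasterization
error (< 2% at the default scales). Rendering composes: dark lumen
(gray 0.08) inside a bright wall annulus (0.75) on a mid-gray background
(0.35); Gaussian blur (sigma 1.5 px) as a point-spread proxy; a linear
depth attenuation of 25% top to bottom; and multiplicative Rayleigh
speckle with unit mean (sigma = sqrt(2/pi)) — the standard first-order
B-mode speckle model. Masks are rasterized from the exact geometry before
any blur or noise. Pixel scales are drawn per view from 0.03-0.06 cm/px at
224 pixels; for other image sizes the range is rescaled to preserve the
physical field of view, and within a draw the scale is sampled from the
subrange that lets the drawn anatomy fit the image (re-drawing the pose a
bounded number of times, then failing loudly). `degrade_phantom()` erases
wall contrast over an angular sector to emulate a poorly defined wall
while keeping the masks as ground truth.

What the phantoms do *not* emulate: acoustic shadowing and reverberation,
probe-dependent beam geometry (sector fan), neighbouring organs, catheter
artifacts, and annotation subjectivity. Passing tests on phantoms
demonstrates that the algorithms and the pipeline are correct and that the
quantization ladder behaves as designed; they say nothing quantitative
about clinical Dice or volume error, which is why the published clinical
figures are treated as context, not as targets.

## Volumetry and agreement

`double_area_volume()` evaluates the double-area regression
`V = exp(0.8304 + 0.5625 log A_sag + 0.7211 log A_trans)` ml with natural
logarithms, areas in cm^2 (`mask_area()` converts pixel counts with the
squared pixel scale). A1 is mapped to the sagittal and A2 to the
transverse area, following the prose order of the method's definition.
The formula is an empirical regression: it is strictly increasing in each
area and obeys V(kA1, kA2) = k^1.2836 V(A1, A2) exactly, but it does not
equal the geometric ellipsoid volume — tests therefore assert rank
agreement with true volume, not equality. Empty segmentations yield 0 ml
with a warning rather than an error, so batch evaluation survives failed
cases.

Agreement between model-derived and reference-derived volumes uses
Bland-Altman analysis — bias = mean(model - reference), 95% limits of
agreement = bias +- 1.96 sample SD (n-1) — with the reference volume on
the x-axis (the reference is treated as ground truth, so the conventional
pair-mean axis is replaced), and Lin's concordance correlation
coefficient with population (1/n) moments, its original definition. The
"95%" lines are limits of agreement, the standard reading of such plots,
not confidence intervals of the mean.

## The scaled experiment

`run_scaled_experiment()` runs the full precision-ladder study at desk scale: 200
phantoms at 64 pixels (split 70/15/15 by instance), base width 8, stage
budgets of 30 + 30 epochs, and the full precision ladder — fp, bfp, and
bq with 6/4/3-bit skips fine-tuned from the same bfp checkpoint. The
problem size is chosen so the whole ladder trains in a few minutes on one
CPU while the qualitative effects of interest are measurable: the
quantized models reach held-out inner-wall Dice of roughly 0.83-0.92,
quantization multiplies the skip zero fraction from ~0 to ~0.4, and the
best codec (EBPC at 6-bit skips) saves 37-44% of the quantized skip
storage. The batch size is 8 in this experiment: with only 280 training
images, an epoch at batch 16 provides too few optimizer steps for the
binarized stage to converge within its 30-epoch budget, and comparing a
converged fine-tuned model against an unconverged baseline would confound
the precision comparison.

One clinical-scale effect does *not* survive the scaling down, and we report
this honestly rather than tuning around it. At clinical scale, accuracy
degrades monotonically with precision (full precision, then binarized,
then 6/4/3-bit skips, with 3-bit collapsing). At desk scale the
full-precision model robustly beats every binary variant by >= 7 Dice
points, but the *binary* variants (bfp, bq6, bq4, bq3) land within a
+-3-4-point band whose internal ordering varies from seed to seed:
run-to-run training noise of a width-8 binary network evaluated on 60
held-out images exceeds the 1-2-point quantization differences that only
clinical-scale training resolves. Two scale artifacts contribute: 3-bit skips
are not catastrophic for thresholded ellipse masks at 64 pixels, and the
unsigned clamp in skip quantization can even act as a mild denoiser on
speckle-heavy skips. The package's acceptance test asserts the strict
ordering with a 1.5-point band anyway — when it fails, it fails on one
adjacent comparison, which is the honest summary of what this scale can
and cannot resolve.

## Numerical conventions and degenerate inputs

* All quantizers round half away from zero (the hardware convention);
  R's default round-half-to-even is deliberately not used, and the R and
  C++ paths are tested to agree exactly.
* Ties in both sign functions map to -1, exactly as the definitions state.
* Dice smoothing eps = 1; BatchNorm eps = 1e-5, momentum 0.1.
* An all-zero calibration batch leaves a skip shift of 0 with a warning;
  a zero BatchNorm scale cannot be folded to a shift and errors.
* Checkpoints of quantized models store integer codes and shift exponents,
  not decoded reals; decoding on load reproduces the inference function
  bit-exactly because every grid value is its own fixed point under the
  quantizer.
* Training divergence (non-finite loss) aborts with a diagnostic rather
  than continuing.

## Known limitations

* The phantom generator's realism limits are listed above; clinical
  performance claims are out of reach by design.
* Binary convolutions are *simulated* in floating point during training
  (the standard practice); the package checks integer-exactness of the
  inference path but does not emit hardware code.
* The BPC dialect is normative for this package, not a bit-compatible
  implementation of any published bitstream.
* `concordance_cc()` reports no confidence interval, and Bland-Altman
  limits are the plain +-1.96 SD form without regression-based extensions.
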