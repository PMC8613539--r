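---
title: "Methods: radial simulation and recurrent de-aliasing in radcine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: radial simulation and recurrent de-aliasing in radcine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

radcine simulates highly undersampled tiny golden-angle radial real-time
cardiac cine acquisitions and removes the resulting streaking artifacts
with a recurrent residual U-Net that processes frames one at a time.
This vignette documents the model, the numerical choices, and the
limitations; the README shows a worked end-to-end example.

## Acquisition model

### Tiny golden-angle schedule

Spoke $j$ (zero-based) has azimuthal angle $j\,\psi_N \bmod 360°$ with
the tiny golden angle $\psi_N = 180°/(\varphi + N - 1)$,
$\varphi = (1+\sqrt 5)/2$. The package default is order $N = 7$,
$\psi_7 \approx 23.63°$, which keeps eddy-current-driving angle jumps
small while retaining near-uniform angular coverage for any contiguous
window of spokes. The schedule is continuous across frames: frame $k$
simply takes the next `spokes_per_frame` spokes of one global sequence
(`make_trajectory(params, n_spokes, start_index)`), so sliding-window
and streaming reconstructions can reuse spokes across frame boundaries.

### Acceleration and timing

With $n_s$ samples per readout, the radial Nyquist criterion requires
$\lceil \pi/2 \cdot n_s \rceil$ spokes; the acceleration factor of a
frame built from $S$ spokes is $R = (\pi/2 \cdot n_s)/S$
(`acceleration_factor()`). For the studied $n_s = 192$ readout this
gives $R = 23.2$ at 13 spokes down to $R = 9.1$ at 33 spokes. Frame
duration is $S \times T_R$ with $T_R = 3.2$ ms, rounded to the nearest
millisecond (`frame_duration_ms()`); 17 spokes give 54 ms (about 18.5
frames/s).

### Exact non-uniform Fourier operators

Retrospective undersampling uses the exact type-2 non-uniform discrete
Fourier transform (and its adjoint) rather than an approximate gridding
kernel: at the studied matrix sizes the separable direct evaluation
(two dense phase matrices and BLAS products per spoke set) is fast
enough, and exactness makes the operator pair testable against a
brute-force oracle and the dot-product identity to near machine
precision.

Numerical conventions, chosen once and used everywhere:

* **Density compensation** is the analytic ramp
  $w(k) = |k| \cdot \Delta k \cdot \pi / n_\text{spokes}$, with the
  center sample weighted $\Delta k / 8$ (the area of the innermost
  half-pixel disc shared by all spokes).
* **2x readout oversampling.** `degrade_series()` and
  `simulate_spoke_stream()` default to $n_s = 2H$ samples for an
  $H \times H$ image. With critical sampling ($n_s = H$) the ramp
  quadrature error alone leaves ~20% NRMSE on a fully sampled
  reconstruction; with 2x oversampling the same reconstruction reaches
  NRMSE ≈ 0.03 and SSIM > 0.95. Clinical radial readouts are
  conventionally oversampled the same way.
* **Normalization.** Ground-truth series are min-max normalized over
  the whole series. Offline degraded series are normalized over the
  series; the streaming reconstructor normalizes each frame
  independently (`normalize = "frame"`), because a causal system cannot
  know the future intensity range. Networks are always trained and run
  on unit-range inputs.

## Phantom corpus

`generate_cine()` renders a soft-edged ellipse heart model in seven
standard orientations (SAX, FCH, LVLA, RVLA, LVOT, RVOT, PA), with a
periodic contraction (phase $= n_\text{cycles}(t-1)/n_\text{frames}$),
small seeded per-series geometry jitter, and a static seeded intensity
texture. The texture is deliberately constant over time so that the
series is exactly periodic — a property the tests rely on. Device
simulation imprints multiplicative Gaussian attenuation: a balloon
catheter is one blob whose full-visibility factor at the center is
$1 - 0.8 = 0.2$ (an 80% signal drop), a guidewire is five blobs spaced
6 px along the wire direction; visibility follows raised-cosine ramps
(`device_path()`, `apply_balloon()`, `apply_guidewire()`).

The phantom emulates the *reconstruction problem* — periodic anatomy
under radial streaking with optional devices — not cardiac physiology:
there is no through-plane motion, no breathing, no coil sensitivity
structure, no noise model, and contrast is arbitrary. Conclusions about
absolute image quality on clinical data cannot be drawn from it;
paired comparisons between reconstructions of the same simulated data
are its intended use.

## Recurrent residual U-Net

`build_model(unet_spec())` builds a three-scale U-Net whose five
convolutional blocks (two encoder, one bottleneck, two decoder) are all
ConvLSTM cells: a single 3x3 convolution of the concatenated input and
previous hidden state produces the four gates
($i, f, o$ sigmoid, $g$ tanh; no peephole connections), with
$C_t = f \circ C_{t-1} + i \circ g$ and $H_t = o \circ \tanh C_t$.
Downsampling is 2x2 max pooling; upsampling is 2x2 nearest-neighbor
followed by a channel-halving 3x3 convolution; skips are concatenated;
a linear 1x1 head produces a correction that is **added to the input
frame** (residual learning), so a zero-weight network is the identity.
The reference configuration (128x128 input, hidden widths 32/64/128)
has exactly 1,790,465 trainable parameters (~1.79 M) — this count is
pinned by a test, so any architectural drift is caught. Hidden state
gives the network temporal context at every scale while keeping
inference strictly causal (one frame in, one frame out), which is what
makes low-latency streaming possible; `warmup()` optionally primes the
state with a few Gaussian-noise frames.

All forward and backward passes are written in base R on im2col patch
matrices with cached index maps, so the heavy lifting is BLAS matrix
multiplication; gradients are verified against central differences in
the test suite.

## Training

`train()` minimizes mean absolute error with Adam
($\epsilon = 10^{-7}$). Series are cut into 8-frame chunks
(`chunk_series()`): gradients flow across frames within a chunk
(backpropagation through time), only the state *values* cross chunk
boundaries (truncated BPTT, detached carry), and the state is reset at
each series end. Up to `batch_size` series advance chunk-synchronously
with one averaged update per chunk position. The model with the best
validation loss is returned. Full-scale defaults are 100 epochs, lr
0.001, batch size 4.

Because a full-scale study (128x128, 30-frame series, tens of subjects)
does not fit an unaccelerated CPU session, the package's own experiment
defaults and its end-to-end test use frozen scaled conditions chosen
*before* the final test was written: 48x48 phantoms, 16 frames, 4
series per view (2 train / 1 val / 1 test), hidden widths 8/16/32,
16 epochs, lr 0.002, batch size 1. Under these conditions, training at
17 spokes/frame lifts held-out SSIM from ≈ 0.66 (gridded) to ≈ 0.90,
and a single rate-generic network trails the rate-specific one by
≈ 0.017 SSIM — the same qualitative conclusions the full-scale setting
is designed to probe, at ~12 min of CPU.

## Evaluation and streaming

* `metrics()` reports MAE, MSE, PSNR and per-frame-averaged SSIM
  (11x11 Gaussian window, $\sigma = 1.5$, population covariances,
  valid-region average — verified against scikit-image to $10^{-10}$)
  over frames 5–25 by default, after the recurrent state has settled.
* `paired_wilcoxon()` uses the exact signed-rank null for $n \le 25$
  without ties (verified against brute-force sign-flip enumeration);
  `normality_check()` wraps Shapiro-Wilk.
* `sliding_window_recon()` is the non-learned low-latency baseline: a
  99-spoke window stepped by 17 spokes shares its center k-space line
  with the corresponding gridded frame and needs a 41-spoke lead-in.
* `stream_reconstruct()` emulates the deployment loop — grid each
  frame as soon as its spokes arrive, normalize per frame, one stateful
  network step, clip to [0, 1] — and records per-frame stage
  timestamps. Streaming output is bit-identical to offline
  `reconstruct_series()` on the same gridded frames; timestamps
  describe the host and are never used as quality measures.

## Limitations

* Magnitude-image simulation only: no complex coil data, no
  coil compression, no off-resonance.
* The exact NUDFT scales as $O(H^2)$ per sample; it is meant for the
  simulated matrix sizes, not for production gridding.
* Pure-R training is practical at the scaled study size; the reference
  1.79 M-parameter configuration is instantiable and testable but slow
  to train in R.
* Timing events measure this host's wall clock and are not comparable
  across machines.
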