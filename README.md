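# radcine

Deep artifact suppression for tiny golden-angle radial real-time cardiac
MRI, in pure R.

Real-time cardiac cine trades image quality for speed: acquiring only
13–33 radial spokes per frame (acceleration factors R ≈ 23 down to ≈ 9
for a 192-sample readout) keeps frame times at 42–106 ms but leaves
severe streaking artifacts after gridding. `radcine` simulates this
acquisition end to end — tiny golden-angle trajectories, exact
non-uniform Fourier degradation of a synthetic beating-heart phantom
corpus (seven views, optional balloon catheter / guidewire devices) —
and removes the streaking with a **residual U-Net whose convolution
blocks are ConvLSTM cells**, so each frame is de-aliased in a single
causal, stateful step. That makes the network usable in a low-latency
streaming loop, which the package also emulates.

The model, in brief: spoke *j* has angle *j*·ψ₇ mod 360°, ψ₇ =
180°/(φ+6) ≈ 23.63°; frame *k* takes the next *S* spokes of this one
continuous sequence; the aliased frame is the ramp-weighted adjoint
NUDFT of those spokes; the network computes a correction that is added
back to its input (zero weights = identity). The reference
configuration (128×128, hidden widths 32/64/128) has exactly 1,790,465
(~1.79 M) trainable parameters. Training is Adam on MAE with truncated
backpropagation through time (8-frame chunks, state values carried
across chunks, reset at series ends).

See `vignette("radcine-methods")` for the full methods description and
numerical conventions.

## Worked example

Train a small de-aliasing network on simulated short-axis cines at 17
spokes/frame (R = 17.7 at the package's 2× oversampled readout) and
evaluate on an unseen series. This is the scaled-down setting used
throughout the package (48×48 phantoms, hidden widths 8/16/32); it runs
in about 3 minutes of CPU (30 epochs, 4 training series).

```r
library(radcine)

tiny_golden_angle(7)            # 23.62814
acceleration_factor(13, 192)    # 23.2
frame_duration_ms(17)           # 54 (ms per frame)

## held-out test series and its aliased version
gt <- generate_cine(phantom_config("SAX", n_frames = 16, matrix = 48, seed = 42))
al <- degrade_series(gt, spokes_per_frame = 17)

## paired training corpus: 4 train + 1 val series
ds <- lapply(1:5, function(i) {
  g <- generate_cine(phantom_config("SAX", n_frames = 16, matrix = 48, seed = 42 + i))
  structure(list(input = degrade_series(g, 17), target = g,
                 accel = acceleration_spec(17, sequence_params(n_samples = 96,
                                                               spokes_per_frame = 17)),
                 split = c("train", "train", "train", "train", "val")[i],
                 view = "SAX"),
            class = "paired_sample")
})

model <- build_model(unet_spec(48, c(8, 16, 32)), seed = 1)
fit <- train(model, ds, train_config(epochs = 30, lr = 2e-3, batch_size = 1, seed = 1))

metrics(al, gt, frame_range = c(5, 16))
#> <metric_report> frames 5-16: MAE 0.0361  MSE 0.00208  PSNR 26.82 dB  SSIM 0.7334
rec <- reconstruct_series(fit$model, al)
metrics(rec, gt, frame_range = c(5, 16))
#> <metric_report> frames 5-16: MAE 0.0171  MSE 0.00059  PSNR 32.27 dB  SSIM 0.8942
```

The network lifts SSIM on the unseen series from 0.73 to 0.89 and PSNR
by 5.5 dB. The same trained model can be served in the streaming loop,
which consumes spokes incrementally, normalizes each frame causally,
and emits one de-aliased frame per stateful network step:

```r
st  <- simulate_spoke_stream(gt, spokes_per_frame = 17)
out <- stream_reconstruct(st, fit$model)
metrics(out$series, gt, frame_range = c(5, 16))
#> <metric_report> frames 5-16: MAE 0.0353  MSE 0.00269  PSNR 25.70 dB  SSIM 0.8347
head(out$events, 3)
#>   frame t_spokes t_gridded t_dealiased policy
#> 1     1    0.059     0.068       0.102 warmup
#> 2     2    0.103     0.112       0.140  carry
#> 3     3    0.141     0.151       0.179  carry
```

(Streaming SSIM is slightly below the offline value because the causal
per-frame normalization cannot use the series-wide intensity range.)

Larger studies — rate-specific vs rate-generic networks across the six
studied spoke counts, and leave-one-orientation-out generalization —
are wrapped by `run_acceleration_experiment()` and
`run_loo_experiment()`; a thin command-line interface around the same
functions is installed at `inst/cli/radcine.R`.

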