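# pulseband

Lightweight multi-band recovery of the blood volume pulse (BVP) from
facial-video spatio-temporal maps, with heart rate (HR) and heart rate
variability (HRV) analysis — for researchers working on remote
photoplethysmography (rPPG) who need a small, fully inspectable pipeline
that trains and validates end to end without any dataset download.

## What it does

The input is a *spatio-temporal map*: the per-frame mean RGB of a few
facial regions, a `T x I x 3` array (default 450 frames x 4 regions x 3
channels = 15 s at 30 fps). The pipeline:

1. **Preprocess** — rotate RGB to a modified YUV space
   (`Y = 0.299 R + 0.587 G + 0.114 B`, chroma rows `(-0.169, -0.331, 0.5)`
   and `(0.5, -0.419, -0.081)`), then z-score each region-channel trace
   (time-domain normalization); optionally add white-noise augmentation at
   a chosen SNR during training.
2. **Decompose** — split every trace into K disjoint frequency bands
   (default 0.6–1.5, 1.5–3.0, 3.0–4.2 Hz) by masking its orthonormal DCT
   spectrum in place and inverting.
3. **Recover** — a per-band encoder/decoder network with independent
   branch weights (temporal multiscale convolutions with kernels 3/5/7,
   batch-norm, ELU, pooling; transposed convolutions and spectrum
   self-attention on the way back up), fused by a 1x1 convolution into one
   BVP waveform. The default configuration has 9,064 trainable parameters
   (budget: 11,000) and needs 4,559,073 FLOPs per 15 s window (budget:
   1.3e8, counting 1 multiply-accumulate as 2 FLOPs).
4. **Analyze** — HR as the Welch spectral peak in 0.6–4.2 Hz (one pass, no
   beat counting); beat detection with parabolic peak refinement; HRV as
   LF (0.04–0.15 Hz) and HF (0.15–0.4 Hz) power of the 4 Hz interbeat
   tachogram in normalized units, plus the LF/HF ratio.

Training minimizes `1 - r(pred, target)` (negative Pearson correlation) in
two phases: all samples at a large learning rate, then HR-stratified
over-sampling batches at a small rate so rare heart-rate ranges get equal
exposure. A seeded synthetic generator supplies spatio-temporal maps with
known ground-truth BVP/HR/IBI under realistic disturbances (illumination
drift, motion transients, optional narrowband interference, white noise).

## Worked example

```r
library(pulseband)

# one synthetic 15 s window with known ground truth
sample <- gen_sample(synth_config(seed = 42), 1)
map    <- preprocess_stmap(sample$stmap)        # modified YUV + normalization
stack  <- decompose_multiband(map)              # 3 x 450 x 4 x 3 band stack

net <- build_srrn(srrn_config())
count_params(net)                               # 9064
count_flops(net)                                # 4559073

# quick training run on 64 synthetic windows
ds      <- gen_dataset(synth_config(n_samples = 64, seed = 7))
records <- lapply(ds$samples, function(s)
  sample_record(preprocess_stmap(s$stmap), scale(s$gt_bvp)[, 1], s$gt_hr))
fit <- train_srrn(net, records,
                  train_plan(phase1_epochs = 6, phase2_epochs = 3,
                             batch_size = 16, rng_seed = 1))

bvp <- predict_bvp(fit$net, map)
hr_from_bvp(bvp)$hr_bpm                         # 84.2 (truth: 84.2)
cor(bvp$values, sample$gt_bvp)                  # 0.77
ib <- detect_peaks(bandpass_bvp(bvp$values, 30), fps = 30)
length(ib$peak_times)                           # 21 beats
hrv <- hrv_lf_hf(ib)                            # lf_nu + hf_nu == 1
```

At this toy scale (64 windows, 9 epochs, ~1 min on one CPU) the spectral HR
is already exact and the waveform correlation reaches ~0.77; a 400-window
run reaches held-out HR MAE below 0.2 bpm and mean correlation ~0.95.

## Command line

A thin wrapper over the same functions lives at `inst/cli/pulseband`:

```sh
pulseband synth      --out data/ --n 100 --seed 1
pulseband preprocess --in data/sample_00001.rds --out map.rds
pulseband decompose  --in map.rds --bands 0.6-1.5,1.5-3.0,3.0-4.2 --out bands.rds
pulseband train      --data data/ --out model.rds
pulseband infer      --model model.rds --in map.rds --out bvp.csv
pulseband evaluate   --pred bvp.csv --truth truth.csv --report report.json
pulseband config     --dump -
```

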