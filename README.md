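# coseg — co-optimized semi-supervised segmentation of ischemic penumbra

`coseg` segments penumbra-like lesions in multi-modal MRI slices when only a
handful of labeled cases exist. It implements a co-optimization strategy: a
supervised encoder-decoder **segmentation branch (S)** is assisted by an
unsupervised **reconstruction branch (R)** — an adversarial autoencoder with
a **discriminator (D)** — coupled through a **transfer block (T)** that maps
R's bottleneck feature with Conv1×1→BN→ReLU and adds it onto S's bottleneck.
Every training image is used twice: once with its label (feeding S) and once
as a *pseudo unlabeled* sample with the label withheld (feeding R).

Training minimises the mixed objective

```
loss_mix = loss_s + λ · loss_r
loss_s   = 1 − (2 Σ p·y + s) / (Σ p + Σ y + s)          (soft Dice)
loss_r   = MSE(R(x), x) + w_adv · CE(D(R(x)), real)     (generator side)
```

with λ = 0.2 by default; λ = 0 reduces exactly to supervised training.
Evaluation uses the stroke-challenge triplet — Dice coefficient (DC),
Hausdorff distance (HD, mm) and average symmetric surface distance
(ASSD, mm) — computed on boundary pixel sets with physical spacing.

Because the real challenge MRI cannot be redistributed, the package ships a
seed-deterministic **stroke-phantom generator**: 6-channel 2-D slices
(DWI/CBV/Tmax/CBF/T2/TTP-like contrasts), 2 mm isotropic spacing, a dark
infarct core ellipse surrounded by the penumbra ring that is the
segmentation target. All network machinery (reverse-mode autodiff,
convolution, BatchNorm, Adam) is implemented in R with Rcpp kernels, so
everything runs at desk scale on one CPU.

## Worked example

```r
library(coseg)

# 100 phantom cases: 6-channel 64x64 slices, 2 mm spacing
cfg   <- phantom_config(n_cases = 100, seed = 42)
train <- generate_dataset(cfg)
test  <- generate_dataset(phantom_config(n_cases = 10, seed = 99))

# 80% labels; every training image also feeds the reconstruction branch
split <- split_dataset(train, label_fraction = 0.8, validation_split = 0.2,
                       seed = 1)
#> 64 labeled / 16 validation / 84 pseudo-unlabeled

tc  <- desk_train_config(seed = 1, lam = 0.2)   # desk-scale schedule
pre <- pretrain_reconstruction(split$pseudo_unlabeled, tc)
fit <- train_cooptimized(split, tc, state = pre$state)
#> best epoch: 10  validation Dice: 0.689

preds  <- predict_masks(fit$state, test)
truths <- setNames(lapply(test, `[[`, "mask"), sapply(test, `[[`, "case_id"))
report <- evaluate_cases(preds, truths, spacing_mm = 2)
print(report$summary, digits = 3)
#>    metric  mean     sd  n
#> 1      dc 0.705 0.0977 10
#> 2   hd_mm 6.753 2.1065 10
#> 3 assd_mm 1.889 0.3229 10
```

A test Dice of 0.71 with surface errors of a few millimetres means the
segmenter recovers the penumbra ring closely on held-out phantoms after a
two-minute CPU run. `run_label_fraction_experiment()` reproduces the
label-fraction ablation (Dice rises steeply from 10% to 100% labels) and
`run_lambda_sweep()` compares λ values on identical data; both write
CSV tables and per-epoch `history.csv` files.

A command-line interface wrapping these functions lives at
`inst/cli/coseg.R`:

```sh
Rscript inst/cli/coseg.R simulate --out data/ --cases 30 --seed 1
Rscript inst/cli/coseg.R train --manifest data/manifest.json \
        --fraction 0.8 --lam 0.2 --seed 1 --desk --out runs/r1
Rscript inst/cli/coseg.R predict --run runs/r1 \
        --manifest data/manifest.json --out preds/
Rscript inst/cli/coseg.R evaluate --pred preds/ --truth data/ --out metrics.csv
```

Datasets are stored as per-case NIfTI volumes (channels on the 4th axis),
uint8 NIfTI or PNG masks, and a `manifest.json` with ids, roles, relative
paths and spacing.

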